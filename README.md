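# vascuquant

Dual quantification of thyroid-nodule vascularization, with the
statistics to compare the two readouts.

Thyroid nodules are common and mostly benign; whether a nodule's blood
supply helps separate malignant from benign lesions is still debated.
Two quantitative readouts of nodule vascularization can be obtained for
the same patient:

* **Monochrome SMI sonography.** In superb-microvascular-imaging (SMI)
  Doppler mode, pixel gray level encodes microvascular flow strength.
  Drawing a nodule region of interest (ROI-A) and a size- and
  depth-matched region in the adjacent normal parenchyma (ROI-B), two
  per-region measurements are taken: the mean gray value and the
  *area fraction* — the proportion of ROI pixels at or above a
  flow-positivity threshold *t*,

  `AF(R) = #{(i,j) ∈ R : I(i,j) ≥ t} / #R`.

  Their node-to-parenchyma ratios are *vascularization quotients*,
  `VQ = m(ROI-A) / m(ROI-B)`, computed per section plane (longitudinal,
  cross, and a whole-lobe "all" region), giving ten parameters per
  nodule.

* **CD34 immunohistochemistry.** After resection, CD34-labelled
  sections mark vessel endothelium with the Fast-Red chromogen.
  Brightfield RGB micrographs are converted to optical density
  (`OD = −log10(I / I₀)`, Beer–Lambert), unmixed per pixel by least
  squares against unit-norm haematoxylin and Fast-Red stain vectors,
  and the Fast-Red-positive pixel fraction is measured in a calibrated
  1440 × 1443-px rectangle (2,077,920 px = 1 mm² at 100×, 16 mm² at
  25×). Four 100× fields and one 25× field summarise to the CD34
  100-fold, 25-fold and overall fractions.

The statistics layer is built for very small cohorts (n = 16, groups of
13 and 3): exact-enumeration Wilcoxon rank-sum tests, Spearman
correlations with exact (n ≤ 8) or seeded-permutation (n ≤ 20)
p-values, and rank-based partial correlations controlling for age and
BMI. Because no raw study images are publicly available, the package
ships synthetic generators — speckled sonograms with planted
flow-positive strokes, Beer–Lambert-composed histology fields, and
Gaussian-copula cohorts — whose exact ground truth makes every stage
testable.

## Worked example

Plant a synthetic sonogram with 30% flow-positive pixels in the nodule
and 15% in the parenchyma, then recover the area-fraction quotient with
the isodata auto-threshold:

```r
library(vascuquant)

p_node <- roi_polygon(rbind(c(10, 10), c(60, 60)),  role = "node_A")
p_par  <- roi_polygon(rbind(c(10, 70), c(60, 120)), role = "parenchyma_B")
spec  <- smi_scene_spec(130, 130, p_node, p_par,
                        node_vessel_fraction = 0.30,
                        parenchyma_vessel_fraction = 0.15,
                        speckle_sd = 8, seed = 11)
scene <- generate_smi_scene(spec)

af_node <- area_fraction(scene$image, p_node, threshold_isodata())
af_par  <- area_fraction(scene$image, p_par,  threshold_isodata())
c(af_node, af_par, quotient(af_node, af_par))
#> [1] 0.30 0.15 2.00
```

The isodata rule resolves to gray level 110 here (background mean 20,
vessel mean 200), and both planted fractions are recovered exactly, so
the vascularization quotient is 2: the nodule is twice as
flow-positive as its parenchyma.

The histology chain, on a synthetic field with a 5% planted vessel
fraction:

```r
ihc  <- generate_ihc_scene(ihc_scene_spec(200, 200,
                                          vessel_mask_fraction = 0.05,
                                          seed = 3))
conc <- unmix(rgb_to_od(ihc$image))
cd34_fraction(conc$fast_red,
              sampling_rect(c(0, 0), "x100", 200, 200),
              positive_threshold = 0.5)
#> [1] 0.05        # generator ground truth: 0.05
```

And an exact Spearman correlation:

```r
spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))
#> <stat_result> spearman_exact: statistic=0.6 estimate=0.6 p=0.4167 (n=4, excluded=0)
```

A whole study — synthesize, quantify both modalities, emit the three
result tables (`table2.csv`, `table3.csv`, `table4.csv`) and a run
report — is one call:

```r
res <- run_all(list(synth = list(n_benign = 13, n_malignant = 3,
                                 latent_spearman_rho = 0.556),
                    seed = 1),
               "results/demo")
```

or, from a shell, `Rscript inst/cli/vascuquant.R all --config study.yaml
--out results/ --seed 42`.

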