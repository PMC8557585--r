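test_that("SMI scene generation is seed-deterministic with exact masks", {
  spec <- default_smi_spec(0.3, 0.15, speckle_sd = 8, seed = 11)
  g1 <- generate_smi_scene(spec)
  g2 <- generate_smi_scene(spec)
  expect_identical(g1, g2)

  p <- test_polygons()
  node_mask <- rasterize_roi(p$node, dim(g1$image))
  par_mask <- rasterize_roi(p$par, dim(g1$image))
  # conservation: planted pixels never leave their polygon
  expect_true(all(node_mask[g1$node_vessel_mask]))
  expect_true(all(par_mask[g1$parenchyma_vessel_mask]))
  # realised fraction within one placement quantum of the request
  expect_lte(abs(sum(g1$node_vessel_mask) / sum(node_mask) - 0.3),
             1 / sum(node_mask))
  # per-pixel recount agrees with the reported ground truth
  expect_equal(g1$node_fraction_true,
               sum(g1$node_vessel_mask & node_mask) / sum(node_mask))
})

test_that("SMI scene degenerate fractions behave exactly", {
  g0 <- generate_smi_scene(default_smi_spec(0, 0, speckle_sd = 8, seed = 2))
  expect_equal(sum(g0$node_vessel_mask), 0)
  expect_equal(sum(g0$parenchyma_vessel_mask), 0)

  g1 <- generate_smi_scene(default_smi_spec(1, 0, speckle_sd = 0, seed = 2))
  p <- test_polygons()
  node_mask <- rasterize_roi(p$node, dim(g1$image))
  expect_true(all(g1$image[node_mask] == 200))
  expect_true(all(g1$image[!node_mask & !g1$parenchyma_vessel_mask] == 20))
})

test_that("SMI scene specs validate geometry and intensities", {
  p <- test_polygons()
  overlapping <- roi_polygon(rbind(c(30, 30), c(80, 80)),
                             role = "parenchyma_B")
  expect_error(smi_scene_spec(130, 130, p$node, overlapping, 0.1, 0.1),
               class = "vq_geometry_error")
  outside <- roi_polygon(rbind(c(100, 100), c(200, 200)),
                         role = "parenchyma_B")
  expect_error(smi_scene_spec(130, 130, p$node, outside, 0.1, 0.1),
               class = "vq_geometry_error")
  expect_error(smi_scene_spec(130, 130, p$node, p$par, 0.1, 0.1,
                              vessel_intensity_mean = 10,
                              background_intensity_mean = 20),
               class = "vq_domain_error")
  expect_error(smi_scene_spec(130, 130, p$node, p$par, 1.2, 0.1),
               class = "vq_domain_error")
})

test_that("IHC scenes compose white background and pure-stain extremes", {
  blank <- generate_ihc_scene(ihc_scene_spec(20, 20, 0, nucleus_density = 0,
                                             noise_od_sd = 0, seed = 1))
  expect_equal(blank$image, array(255, dim = c(20, 20, 3)))
  expect_equal(blank$true_fraction, 0)

  spec <- ihc_scene_spec(20, 20, 1, nucleus_density = 0, noise_od_sd = 0,
                         fastred_od_level = 0.8, seed = 1)
  g <- generate_ihc_scene(spec)
  expected <- 255 * 10^(-0.8 * unclass(spec$stains)[, "fast_red"])
  for (ch in 1:3) {
    expect_equal(unique(as.vector(g$image[, , ch])), expected[ch],
                 tolerance = 1e-12)
  }
  expect_equal(g$true_fraction, 1)
})

test_that("IHC scene generation is deterministic and reports exact truth", {
  spec <- ihc_scene_spec(50, 50, 0.07, noise_od_sd = 0.05, seed = 5)
  g1 <- generate_ihc_scene(spec)
  g2 <- generate_ihc_scene(spec)
  expect_identical(g1, g2)
  expect_equal(g1$true_fraction, sum(g1$vessel_mask) / (50 * 50))
  expect_lte(abs(g1$true_fraction - 0.07), 1 / (50 * 50))
  expect_true(min(g1$image) >= 0 && max(g1$image) <= 255)
})

test_that("cohort copula hits the requested Spearman correlation", {
  # comonotone: ranks identical, sample Spearman exactly 1
  co <- generate_cohort(cohort_spec(n_benign = 30, n_malignant = 0,
                                    latent_spearman_rho = 1, seed = 5))
  expect_equal(cor(co$quotient, co$cd34_fraction, method = "spearman"), 1)
  co <- generate_cohort(cohort_spec(n_benign = 30, n_malignant = 0,
                                    latent_spearman_rho = -1, seed = 5))
  expect_equal(cor(co$quotient, co$cd34_fraction, method = "spearman"), -1)

  co <- generate_cohort(cohort_spec(n_benign = 500, n_malignant = 0,
                                    latent_spearman_rho = 0.55, seed = 1))
  expect_lt(abs(cor(co$quotient, co$cd34_fraction, method = "spearman") -
                  0.55), 0.10)

  expect_error(cohort_spec(latent_spearman_rho = 1.2),
               class = "vq_domain_error")
})

test_that("cohort labels, supports and determinism hold", {
  co <- generate_cohort(cohort_spec(n_benign = 10, n_malignant = 0, seed = 3))
  expect_true(all(co$label == "benign"))
  co <- generate_cohort(cohort_spec(seed = 9))
  expect_identical(co, generate_cohort(cohort_spec(seed = 9)))
  expect_equal(nrow(co), 16)
  expect_equal(sum(co$label == "benign"), 13)
  expect_true(all(co$quotient > 0))
  expect_true(all(co$cd34_fraction >= 0 & co$cd34_fraction <= 1))
  expect_true(all(co$age > 0) && all(co$bmi > 0) && all(co$length_mm > 0))
})

test_that("cohort marginals converge to the specified group moments", {
  sp <- cohort_spec(n_benign = 2000, n_malignant = 0, seed = 17)
  co <- generate_cohort(sp)
  n <- nrow(co)
  se_mean <- sp$benign_quotient_sd / sqrt(n)
  expect_lt(abs(mean(co$quotient) - sp$benign_quotient_mean), 3 * se_mean)
  se_cd <- sp$benign_cd34_sd / sqrt(n)
  expect_lt(abs(mean(co$cd34_fraction) - sp$benign_cd34_mean), 3 * se_cd)
  # SDs within 10% at this n
  expect_lt(abs(sd(co$quotient) - sp$benign_quotient_sd),
            0.1 * sp$benign_quotient_sd)
  expect_lt(abs(sd(co$cd34_fraction) - sp$benign_cd34_sd),
            0.1 * sp$benign_cd34_sd)
})
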