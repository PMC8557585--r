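# Synthetic brightfield CD34 immunohistochemistry micrographs built by a
# Beer-Lambert forward model: per-pixel haematoxylin and Fast-Red
# concentrations -> optical density -> RGB transmittance.

# pixels per mm at a given magnification; calibrated so the 1440 x 1443
# sampling rectangle covers 1 mm^2 at 100x.
px_per_mm <- function(magnification) {
  m <- as.numeric(sub("^x", "", magnification))
  1440 * m / 100
}

#' Specification of a synthetic IHC scene
#'
#' Describes a brightfield micrograph of CD34-stained tissue: vessel
#' endothelium carries the Fast-Red chromogen (pink), nuclei carry
#' haematoxylin (blue), and the image is composed through the
#' Beer-Lambert forward map that [unmix()] inverts.
#'
#' @param image_height_px,image_width_px image size in pixels.
#' @param vessel_mask_fraction target fraction of pixels covered by
#'   Fast-Red-positive vessel profiles, in \[0, 1\].
#' @param nucleus_density nuclei per mm^2 of tissue (default 1500).
#' @param hematoxylin_od_level optical-density concentration of nuclear
#'   haematoxylin (default 0.6).
#' @param fastred_od_level optical-density concentration of vessel
#'   Fast-Red (default 1.0).
#' @param stains a [stain_matrix()]; the generator always composes with
#'   the configured matrix so unmixing round trips are exact.
#' @param noise_od_sd Gaussian optical-density noise SD (default 0).
#' @param magnification `"x100"` or `"x25"`; sets the pixel size and
#'   hence the nucleus count and radius.
#' @param vessel_width_px stroke width of vessel profiles in pixels.
#' @param seed integer seed.
#' @return an object of class `ihc_scene_spec`.
#' @export
ihc_scene_spec <- function(image_height_px, image_width_px,
                           vessel_mask_fraction,
                           nucleus_density = 1500,
                           hematoxylin_od_level = 0.6,
                           fastred_od_level = 1.0,
                           stains = stain_matrix(),
                           noise_od_sd = 0,
                           magnification = "x100",
                           vessel_width_px = 4,
                           seed = 1L) {
  if (vessel_mask_fraction < 0 || vessel_mask_fraction > 1) {
    vq_stop("vessel_mask_fraction must lie in [0, 1]", "vq_domain_error")
  }
  if (nucleus_density < 0 || hematoxylin_od_level < 0 ||
      fastred_od_level < 0 || noise_od_sd < 0) {
    vq_stop("densities, OD levels and noise SD must be >= 0",
            "vq_domain_error")
  }
  if (!inherits(stains, "stain_matrix")) {
    vq_stop("`stains` must be a stain_matrix()", "vq_config_error")
  }
  if (!magnification %in% c("x100", "x25")) {
    vq_stop("magnification must be 'x100' or 'x25'", "vq_config_error")
  }
  structure(list(image_height_px = as.integer(image_height_px),
                 image_width_px = as.integer(image_width_px),
                 vessel_mask_fraction = vessel_mask_fraction,
                 nucleus_density = nucleus_density,
                 hematoxylin_od_level = hematoxylin_od_level,
                 fastred_od_level = fastred_od_level,
                 stains = stains,
                 noise_od_sd = noise_od_sd,
                 magnification = magnification,
                 vessel_width_px = vessel_width_px,
                 seed = as.integer(seed)),
            class = "ihc_scene_spec")
}

#' Generate a synthetic IHC scene
#'
#' Plants curvilinear Fast-Red vessel profiles to exactly
#' `round(fraction * pixels)` pixels, scatters haematoxylin nuclei at the
#' requested areal density, then composes the RGB image by Beer-Lambert:
#' `OD = stains %*% concentrations (+ noise)`,
#' `RGB = 255 * 10^(-OD)`.  The image is kept in floating point
#' (values in \[0, 255\]); 8-bit quantization happens only on PNG export,
#' so unmixing the in-memory image round-trips the concentrations
#' exactly when noise is zero.
#'
#' @param spec an [ihc_scene_spec()].
#' @return list with `image` (`h x w x 3` double array in \[0, 255\]),
#'   `vessel_mask` (logical), `true_fraction` (exact planted fraction)
#'   and `concentrations` (list of the ground-truth haematoxylin and
#'   Fast-Red concentration matrices).
#' @export
generate_ihc_scene <- function(spec) {
  stopifnot(inherits(spec, "ihc_scene_spec"))
  h <- spec$image_height_px; w <- spec$image_width_px
  with_seed(spec$seed, {
    vessel <- plant_strokes(matrix(TRUE, h, w), spec$vessel_mask_fraction,
                            spec$vessel_width_px)
    c_fr <- matrix(0, h, w)
    c_fr[vessel] <- spec$fastred_od_level

    ppm <- px_per_mm(spec$magnification)
    area_mm2 <- (h * w) / ppm^2
    n_nuc <- round(spec$nucleus_density * area_mm2)
    c_h <- matrix(0, h, w)
    if (n_nuc > 0) {
      rad <- max(1L, round(0.004 * ppm))    # ~8 um nucleus diameter
      off <- expand.grid(di = -rad:rad, dj = -rad:rad)
      off <- off[off$di^2 + off$dj^2 <= rad^2, , drop = FALSE]
      ci <- sample.int(h, n_nuc, replace = TRUE)
      cj <- sample.int(w, n_nuc, replace = TRUE)
      for (k in seq_len(n_nuc)) {
        ii <- ci[k] + off$di; jj <- cj[k] + off$dj
        ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
        c_h[cbind(ii[ok], jj[ok])] <- spec$hematoxylin_od_level
      }
    }

    m <- unclass(spec$stains)
    od <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      od[, , ch] <- m[ch, 1] * c_h + m[ch, 2] * c_fr
    }
    if (spec$noise_od_sd > 0) {
      od <- od + stats::rnorm(length(od), 0, spec$noise_od_sd)
      od[od < 0] <- 0
    }
    img <- 255 * 10^(-od)
    list(image = img,
         vessel_mask = vessel,
         true_fraction = sum(vessel) / (h * w),
         concentrations = list(hematoxylin = c_h, fast_red = c_fr))
  })
}
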