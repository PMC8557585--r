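# Synthetic monochrome SMI sonograms with planted flow-positive pixels
# and exact per-pixel ground-truth masks.

# Plant curvilinear vessel strokes into the allowed region until exactly
# round(fraction * n_allowed) pixels are covered.  Strokes are random
# walks stamped with a disk of the given width; the last stamp is
# trimmed so the realised count hits the target exactly (placement
# quantum = one pixel).
plant_strokes <- function(allowed, fraction, width = 3) {
  h <- nrow(allowed); w <- ncol(allowed)
  planted <- matrix(FALSE, h, w)
  n_allowed <- sum(allowed)
  target <- round(fraction * n_allowed)
  if (target <= 0L) return(planted)
  if (target >= n_allowed) {
    planted[allowed] <- TRUE
    return(planted)
  }
  r <- width / 2
  off <- expand.grid(di = -ceiling(r):ceiling(r), dj = -ceiling(r):ceiling(r))
  off <- off[off$di^2 + off$dj^2 <= r^2 + 1e-9, , drop = FALSE]
  count <- 0L
  free <- allowed & !planted
  while (count < target) {
    idx <- which(free)
    if (!length(idx)) break
    start <- idx[sample.int(length(idx), 1L)]
    pi_ <- ((start - 1L) %% h) + 1L
    pj_ <- ((start - 1L) %/% h) + 1L
    pos <- c(pi_, pj_)
    ang <- stats::runif(1, 0, 2 * pi)
    for (step in 1:400) {
      ci <- round(pos[1]); cj <- round(pos[2])
      ii <- ci + off$di; jj <- cj + off$dj
      ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
      cells <- cbind(ii[ok], jj[ok])
      hit <- cells[free[cells], , drop = FALSE]
      if (nrow(hit)) {
        need <- target - count
        if (nrow(hit) > need) hit <- hit[seq_len(need), , drop = FALSE]
        planted[hit] <- TRUE
        free[hit] <- FALSE
        count <- count + nrow(hit)
        if (count >= target) break
      }
      ang <- ang + stats::rnorm(1, 0, 0.35)
      pos <- pos + c(sin(ang), cos(ang))
      ni <- round(pos[1]); nj <- round(pos[2])
      if (ni < 1 || ni > h || nj < 1 || nj > w || !allowed[ni, nj]) break
    }
  }
  planted
}

#' Specification of a synthetic SMI sonogram scene
#'
#' Describes a monochrome SMI frame containing a nodule region and a
#' matched parenchyma region, each with a controllable density of
#' planted flow-positive (bright) vessel pixels over a speckled
#' background.  Flow signal is brighter than background, as in
#' monochrome SMI where pixel gray level encodes flow strength.
#'
#' @param image_height_px,image_width_px image size in pixels.
#' @param node_polygon,parenchyma_polygon disjoint [roi_polygon()]s fully
#'   inside the image.
#' @param node_vessel_fraction,parenchyma_vessel_fraction target fraction
#'   of region pixels carrying flow signal, in \[0, 1\].
#' @param vessel_intensity_mean mean gray level of flow pixels (0, 255\].
#' @param background_intensity_mean mean gray level of the speckle
#'   background, strictly below `vessel_intensity_mean`.
#' @param speckle_sd standard deviation of the Gaussian speckle,
#'   truncated to \[0, 255\].
#' @param vessel_width_px stroke width of planted vessels in pixels.
#' @param seed integer seed; the scene is a deterministic function of the
#'   spec.
#' @return an object of class `smi_scene_spec`.
#' @export
smi_scene_spec <- function(image_height_px, image_width_px,
                           node_polygon, parenchyma_polygon,
                           node_vessel_fraction,
                           parenchyma_vessel_fraction,
                           vessel_intensity_mean = 200,
                           background_intensity_mean = 20,
                           speckle_sd = 8,
                           vessel_width_px = 3,
                           seed = 1L) {
  fr <- c(node_vessel_fraction, parenchyma_vessel_fraction)
  if (min(fr) < 0 || max(fr) > 1) {
    vq_stop("vessel fractions must lie in [0, 1]", "vq_domain_error")
  }
  if (vessel_intensity_mean <= background_intensity_mean) {
    vq_stop("flow signal must be brighter than background", "vq_domain_error")
  }
  shp <- c(image_height_px, image_width_px)
  node_mask <- rasterize_roi(node_polygon, shp)          # errors if outside
  par_mask <- rasterize_roi(parenchyma_polygon, shp)
  if (any(node_mask & par_mask)) {
    vq_stop("node and parenchyma polygons overlap", "vq_geometry_error")
  }
  structure(list(image_height_px = as.integer(image_height_px),
                 image_width_px = as.integer(image_width_px),
                 node_polygon = node_polygon,
                 parenchyma_polygon = parenchyma_polygon,
                 node_vessel_fraction = node_vessel_fraction,
                 parenchyma_vessel_fraction = parenchyma_vessel_fraction,
                 vessel_intensity_mean = vessel_intensity_mean,
                 background_intensity_mean = background_intensity_mean,
                 speckle_sd = speckle_sd,
                 vessel_width_px = vessel_width_px,
                 seed = as.integer(seed)),
            class = "smi_scene_spec")
}

#' Generate a synthetic SMI sonogram scene
#'
#' Draws the speckle background, then plants curvilinear vessel strokes
#' inside the node and parenchyma polygons until each region's planted
#' pixel count equals `round(fraction * region_pixels)` exactly.  Planted
#' pixels take gray values around `vessel_intensity_mean` with the same
#' speckle SD.  The returned masks are the exact per-pixel ground truth.
#'
#' @param spec an [smi_scene_spec()].
#' @return list with `image` (integer gray matrix in \[0, 255\]),
#'   `node_vessel_mask`, `parenchyma_vessel_mask` (logical matrices) and
#'   the realised ground-truth fractions `node_fraction_true`,
#'   `parenchyma_fraction_true`.
#' @export
generate_smi_scene <- function(spec) {
  stopifnot(inherits(spec, "smi_scene_spec"))
  h <- spec$image_height_px; w <- spec$image_width_px
  shp <- c(h, w)
  node_mask <- rasterize_roi(spec$node_polygon, shp)
  par_mask <- rasterize_roi(spec$parenchyma_polygon, shp)
  with_seed(spec$seed, {
    img <- matrix(round(clamped_normal(h * w, spec$background_intensity_mean,
                                       spec$speckle_sd)), h, w)
    vn <- plant_strokes(node_mask, spec$node_vessel_fraction,
                        spec$vessel_width_px)
    vp <- plant_strokes(par_mask, spec$parenchyma_vessel_fraction,
                        spec$vessel_width_px)
    planted <- vn | vp
    n_pl <- sum(planted)
    if (n_pl) {
      img[planted] <- round(clamped_normal(n_pl, spec$vessel_intensity_mean,
                                           spec$speckle_sd))
    }
    list(image = img,
         node_vessel_mask = vn,
         parenchyma_vessel_mask = vp,
         node_fraction_true = sum(vn) / sum(node_mask),
         parenchyma_fraction_true = sum(vp) / sum(par_mask))
  })
}
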