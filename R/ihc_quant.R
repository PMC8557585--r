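# CD34 immunohistochemistry quantification: RGB -> optical density ->
# two-stain (haematoxylin / Fast-Red) unmixing -> positive-pixel fraction
# in calibrated sampling rectangles.

#' Stain matrix for optical-density unmixing
#'
#' Columns are unit-norm RGB optical-density vectors, one per stain.
#' The defaults are the widely used haematoxylin OD vector and a
#' Fast-Red chromogen vector; real-slide vectors vary, so both can be
#' overridden (e.g. from a measured single-stain control).
#'
#' @param hematoxylin RGB OD triple for haematoxylin.
#' @param fast_red RGB OD triple for the Fast-Red (CD34) chromogen.
#' @return 3 x 2 matrix of class `stain_matrix` with unit-norm columns.
#' @export
stain_matrix <- function(hematoxylin = c(0.650, 0.704, 0.286),
                         fast_red = c(0.2140, 0.8511, 0.4779)) {
  m <- cbind(hematoxylin = as.numeric(hematoxylin),
             fast_red = as.numeric(fast_red))
  if (nrow(m) != 3L || anyNA(m)) {
    vq_stop("stain vectors must be RGB OD triples", "vq_config_error")
  }
  nrm <- sqrt(colSums(m^2))
  if (any(nrm == 0)) vq_stop("zero stain vector", "vq_config_error")
  m <- sweep(m, 2, nrm, "/")
  # collinearity check: angle between columns must be bounded away from 0
  cosang <- abs(sum(m[, 1] * m[, 2]))
  if (cosang > 1 - 1e-6) {
    vq_stop("stain vectors are collinear; unmixing is ill-posed",
            "vq_config_error")
  }
  structure(m, class = c("stain_matrix", "matrix"))
}

#' Convert an RGB image to optical density
#'
#' Per channel, `od = -log10(max(I, 1) / white_level)` (Beer-Lambert):
#' white maps to 0 OD and one OD unit is a tenfold attenuation.
#' Zero intensities are clamped to 1 before the log so the transform is
#' always finite.
#'
#' @param image numeric `h x w x 3` array with values in \[0, 255\].
#' @param white_level intensity of unstained background (default 255).
#' @return `h x w x 3` array of optical densities (>= 0).
#' @export
rgb_to_od <- function(image, white_level = 255) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    vq_stop("`image` must be an h x w x 3 RGB array", "vq_input_error")
  }
  if (min(image) < 0 || max(image) > 255) {
    vq_stop("RGB values must lie in [0, 255]", "vq_domain_error")
  }
  -log10(pmax(image, 1) / white_level)
}

#' Unmix an optical-density image into per-stain concentrations
#'
#' Solves, for every pixel, the least-squares system
#' `stain_matrix %*% concentrations = od` and clips negative
#' concentrations to zero after solving.  With an exact stain matrix a
#' pure-stain pixel recovers its concentration on that stain and zero on
#' the other.
#'
#' @param od_image `h x w x 3` optical-density array (see [rgb_to_od()]).
#' @param stains a [stain_matrix()].
#' @return named list of `h x w` concentration matrices, one per stain
#'   column.
#' @export
unmix <- function(od_image, stains = stain_matrix()) {
  if (!inherits(stains, "stain_matrix")) stains <- do.call(stain_matrix, as.list(stains))
  d <- dim(od_image)
  odm <- matrix(od_image, ncol = 3L)          # N x 3, channels as columns
  m <- unclass(stains)
  pseudo <- m %*% solve(crossprod(m))         # 3 x k right pseudo-inverse^T
  conc <- odm %*% pseudo                      # N x k least-squares solution
  conc[conc < 0] <- 0
  out <- lapply(seq_len(ncol(m)), function(k) matrix(conc[, k], d[1], d[2]))
  names(out) <- colnames(m)
  out
}

#' Calibrated sampling rectangle
#'
#' The analysis rectangle used on extracted Fast-Red images:
#' 1440 x 1443 pixels = 2,077,920 pixels, corresponding to 1 mm^2 of
#' tissue at 100x magnification and 16 mm^2 at 25x.  `top_left` uses the
#' package's 0-based (row, col) raster convention.  Smaller rectangles
#' may be requested for reduced-scale synthetic material; the
#' magnification-to-area calibration is unchanged.
#'
#' @param top_left numeric `(row, col)` of the rectangle's top-left corner.
#' @param magnification `"x100"` or `"x25"`.
#' @param height_px,width_px rectangle size in pixels (defaults are the
#'   calibrated 1443 x 1440).
#' @return an object of class `sampling_rect`.
#' @export
sampling_rect <- function(top_left = c(0, 0),
                          magnification = "x100",
                          height_px = 1443L, width_px = 1440L) {
  if (!magnification %in% c("x100", "x25", "x50")) {
    vq_stop("unknown magnification (use 'x100' or 'x25')",
            "vq_config_error")
  }
  structure(list(top_left = as.numeric(top_left),
                 height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 magnification = magnification),
            class = "sampling_rect")
}

#' Physical tissue area of a sampling rectangle
#'
#' The calibrated rectangle covers 1 mm^2 at 100x magnification; area
#' scales with the inverse square of magnification, giving 16 mm^2 at
#' 25x (`(100/25)^2 * 1 mm^2`).
#'
#' @param rect a [sampling_rect()] or a magnification string.
#' @return area in mm^2.
#' @export
physical_area <- function(rect) {
  mag <- if (inherits(rect, "sampling_rect")) rect$magnification else rect
  if (!is.character(mag) || length(mag) != 1L || !grepl("^x[0-9]+$", mag)) {
    vq_stop("unknown magnification", "vq_config_error")
  }
  m <- as.numeric(sub("^x", "", mag))
  if (m <= 0) vq_stop("unknown magnification", "vq_config_error")
  (100 / m)^2
}

#' CD34-positive pixel fraction in a sampling rectangle
#'
#' The fraction of rectangle pixels whose Fast-Red concentration is at
#' or above `positive_threshold` -- the quantitative measure of
#' microscopically detectable vascularization.
#'
#' @param fastred_concentration `h x w` Fast-Red concentration matrix
#'   (from [unmix()]).
#' @param rect a [sampling_rect()] fully inside the image.
#' @param positive_threshold concentration threshold (OD-concentration
#'   units; default 0.15).
#' @return fraction in \[0, 1\].
#' @export
cd34_fraction <- function(fastred_concentration, rect = sampling_rect(),
                          positive_threshold = 0.15) {
  d <- dim(fastred_concentration)
  r0 <- rect$top_left[1]; c0 <- rect$top_left[2]
  if (r0 < 0 || c0 < 0 || r0 + rect$height_px > d[1] ||
      c0 + rect$width_px > d[2]) {
    vq_stop("sampling rectangle exceeds the image bounds",
            "vq_geometry_error")
  }
  rows <- (floor(r0) + 1L):(floor(r0) + rect$height_px)
  cols <- (floor(c0) + 1L):(floor(c0) + rect$width_px)
  sub <- fastred_concentration[rows, cols]
  sum(sub >= positive_threshold) / (rect$height_px * rect$width_px)
}

#' Summarise CD34 fractions over magnifications
#'
#' `cd34_100_fold` is the mean Fast-Red-positive fraction over four
#' 100x fields; `cd34_all` averages the 100x mean with the single 25x
#' fraction.
#'
#' @param field_fractions_100x numeric vector of exactly four 100x field
#'   fractions, each in \[0, 1\].
#' @param fraction_25x single 25x fraction in \[0, 1\].
#' @return a `cd34_profile`: list with `cd34_100_fold`, `cd34_25_fold`,
#'   `cd34_all`.
#' @examples
#' cd34_summary(c(0.1, 0.2, 0.3, 0.4), 0.5)  # 0.25, 0.5, 0.375
#' @export
cd34_summary <- function(field_fractions_100x, fraction_25x) {
  if (length(field_fractions_100x) != 4L) {
    vq_stop("exactly four 100x field fractions are required",
            "vq_input_error")
  }
  vals <- c(field_fractions_100x, fraction_25x)
  if (anyNA(vals) || min(vals) < 0 || max(vals) > 1) {
    vq_stop("fractions must lie in [0, 1]", "vq_domain_error")
  }
  f100 <- mean(field_fractions_100x)
  structure(list(cd34_100_fold = f100,
                 cd34_25_fold = fraction_25x,
                 cd34_all = (f100 + fraction_25x) / 2),
            class = "cd34_profile")
}

#' @export
as.data.frame.cd34_profile <- function(x, ...) {
  data.frame(cd34_100_fold = x$cd34_100_fold,
             cd34_25_fold = x$cd34_25_fold,
             cd34_all = x$cd34_all)
}

#' @export
print.cd34_profile <- function(x, ...) {
  cat(sprintf("<cd34_profile> 100x %.4f | 25x %.4f | all %.4f\n",
              x$cd34_100_fold, x$cd34_25_fold, x$cd34_all))
  invisible(x)
}
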