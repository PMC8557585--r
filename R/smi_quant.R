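# SMI sonogram quantification: mean gray value, flow-positive area
# fraction, node/parenchyma vascularization quotients.

as_gray_image <- function(image) {
  m <- as.matrix(image)
  if (!is.numeric(m) || length(m) == 0L) {
    vq_stop("a gray image must be a non-empty numeric matrix",
            "vq_input_error")
  }
  if (min(m) < 0 || max(m) > 255) {
    vq_stop("gray values must lie in [0, 255]", "vq_domain_error")
  }
  m
}

resolve_mask <- function(image, roi) {
  if (is.logical(roi) && is.matrix(roi)) {
    if (!identical(dim(roi), dim(image))) {
      vq_stop("mask dimensions do not match the image", "vq_input_error")
    }
    if (!any(roi)) vq_stop("empty ROI mask", "vq_degenerate_roi")
    return(roi)
  }
  rasterize_roi(roi, dim(image))
}

#' Threshold rules for flow-positive area fractions
#'
#' `threshold_fixed(k)` always resolves to `k`; `threshold_isodata()`
#' resolves to the intermeans (isodata) fixed point of the masked
#' histogram, the classic ImageJ default auto-threshold.
#'
#' @param k fixed threshold in gray levels (0--256).
#' @return an object of class `vq_threshold`.
#' @export
threshold_fixed <- function(k) {
  if (!is_scalar_number(k)) vq_stop("`k` must be a number", "vq_input_error")
  structure(list(method = "fixed", k = k), class = "vq_threshold")
}

#' @rdname threshold_fixed
#' @export
threshold_isodata <- function() {
  structure(list(method = "isodata"), class = "vq_threshold")
}

as_threshold_rule <- function(rule) {
  if (inherits(rule, "vq_threshold")) return(rule)
  if (is_scalar_number(rule)) return(threshold_fixed(rule))
  if (is.list(rule) && !is.null(rule$method)) {
    return(switch(rule$method,
                  fixed = threshold_fixed(rule$k),
                  isodata = threshold_isodata(),
                  vq_stop(sprintf("unknown threshold method '%s'", rule$method),
                          "vq_config_error")))
  }
  vq_stop("not a threshold rule", "vq_config_error")
}

#' Resolve a threshold rule on a masked image region
#'
#' For the isodata rule the intermeans iteration is run on the pixels
#' under the mask: starting from the rounded region mean, the threshold
#' is repeatedly replaced by the mean of the below-threshold and
#' at-or-above-threshold class means until it stabilises.  Pixels with
#' value `>=` the resolved threshold count as flow-positive.
#'
#' A constant region has no intermeans fixed point; the rule then returns
#' `max(value) + 1` with a warning, so the resulting area fraction is 0.
#'
#' @param image numeric gray matrix in \[0, 255\].
#' @param mask logical matrix selecting the region (or an [roi_polygon()]).
#' @param rule a [threshold_fixed()] / [threshold_isodata()] rule.
#' @return integer threshold.
#' @export
resolve_threshold <- function(image, mask, rule) {
  image <- as_gray_image(image)
  rule <- as_threshold_rule(rule)
  if (rule$method == "fixed") return(as.integer(round(rule$k)))
  mask <- resolve_mask(image, mask)
  v <- image[mask]
  if (max(v) == min(v)) {
    warning("constant region: isodata threshold undefined; returning max + 1")
    return(as.integer(max(v)) + 1L)
  }
  t_cur <- as.integer(round(mean(v)))
  t_cur <- max(t_cur, as.integer(ceiling(min(v))) + 1L)
  for (iter in 1:256) {
    lo <- v[v < t_cur]
    hi <- v[v >= t_cur]
    if (!length(lo) || !length(hi)) break
    t_new <- as.integer(floor((mean(lo) + mean(hi)) / 2 + 0.5))
    t_new <- max(t_new, as.integer(ceiling(min(v))) + 1L)
    if (t_new == t_cur) break
    t_cur <- t_new
  }
  t_cur
}

#' Mean gray value over an ROI
#'
#' Arithmetic mean of the pixel gray values whose centres fall inside the
#' ROI polygon.
#'
#' @inheritParams resolve_threshold
#' @param roi an [roi_polygon()] or a logical mask.
#' @return mean gray value (dimensionless, gray levels).
#' @export
mean_gray <- function(image, roi) {
  image <- as_gray_image(image)
  mask <- resolve_mask(image, roi)
  mean(image[mask])
}

#' Flow-positive area fraction over an ROI
#'
#' The fraction of ROI pixels whose gray value is at or above the
#' resolved threshold -- the proportion of the selected node (or
#' parenchyma) area carrying a positive flow signal.
#'
#' @inheritParams mean_gray
#' @param threshold a threshold rule ([threshold_fixed()],
#'   [threshold_isodata()]) or a bare number, taken as fixed.
#' @return area fraction in \[0, 1\].
#' @export
area_fraction <- function(image, roi, threshold) {
  image <- as_gray_image(image)
  mask <- resolve_mask(image, roi)
  thr <- resolve_threshold(image, mask, threshold)
  mean(image[mask] >= thr)
}

#' Node-to-parenchyma vascularization quotient
#'
#' Ratio of a vascularization measurement in the nodule region to the
#' same measurement in the matched adjacent-parenchyma region.  When the
#' parenchyma value is zero the quotient is undefined and returned as
#' `NA` (never infinity); downstream statistics drop such values
#' pairwise.
#'
#' @param node_value measurement in the nodule ROI (>= 0).
#' @param parenchyma_value measurement in the parenchyma ROI (>= 0).
#' @return `node_value / parenchyma_value`, or `NA_real_` if the
#'   denominator is zero.
#' @export
quotient <- function(node_value, parenchyma_value) {
  if (is.na(node_value) || is.na(parenchyma_value)) return(NA_real_)
  if (parenchyma_value < 0) {
    vq_stop("parenchyma value must be >= 0", "vq_domain_error")
  }
  if (parenchyma_value == 0) return(NA_real_)
  node_value / parenchyma_value
}

profile_fields <- c(
  "roi_longitudinal", "roi_longitudinal_area_fraction",
  "roi_cross", "roi_cross_area_fraction",
  "quotient_longitudinal", "quotient_longitudinal_area_fraction",
  "quotient_cross", "quotient_cross_area_fraction",
  "quotient_all", "quotient_all_area_fraction")

#' Compute the full SMI vascularization profile of one nodule
#'
#' Reproduces the per-nodule measurement scheme: in each section plane
#' two frames are acquired; the nodule ROI (ROI-A) mean gray value and
#' flow-positive area fraction are averaged over the two frames, as are
#' the matched parenchyma ROI (ROI-B) values; plane-wise quotients divide
#' the nodule value by the parenchyma value.  The whole-lobe frame (ROI
#' total) supplies the `quotient_all` pair from its nodal vs parenchymal
#' sub-areas.  The threshold rule is resolved independently for every
#' analysed region.
#'
#' Frames are combined by averaging the computed parameter, not the
#' pixels, which is robust to frame-to-frame misalignment.  A warning is
#' issued when the ROI-B pixel area differs from the ROI-A area by more
#' than 25%, since the parenchyma region is meant to match the nodule
#' region in size and depth.
#'
#' @param images list with elements `longitudinal` (list of 2 gray
#'   frames), `cross` (list of 2 gray frames) and `total` (1 gray frame).
#' @param rois list with elements `A_long`, `B_long`, `A_cross`,
#'   `B_cross`, `total_node`, `total_parenchyma`, each an
#'   [roi_polygon()].
#' @param threshold threshold rule used for all area fractions
#'   (default isodata).
#' @return a `vascularization_profile`: named list of the ten parameters;
#'   undefined quotients (zero parenchyma denominator) are `NA`.
#' @export
compute_profile <- function(images, rois, threshold = threshold_isodata()) {
  for (p in c("longitudinal", "cross")) {
    if (is.null(images[[p]]) || length(images[[p]]) < 2L) {
      vq_stop(sprintf("missing frame(s) for plane '%s' (two required)", p),
              "vq_input_error")
    }
  }
  if (is.null(images$total)) {
    vq_stop("missing frame for plane 'total'", "vq_input_error")
  }
  for (nm in c("A_long", "B_long", "A_cross", "B_cross",
               "total_node", "total_parenchyma")) {
    if (is.null(rois[[nm]])) {
      vq_stop(sprintf("missing ROI '%s'", nm), "vq_input_error")
    }
  }

  plane_value <- function(frames, roi, fun) {
    mean(vapply(frames, fun, numeric(1), roi))
  }
  mg <- function(img, roi) mean_gray(img, roi)
  af <- function(img, roi) area_fraction(img, roi, threshold)

  check_matched <- function(frame, roi_a, roi_b, plane) {
    a <- sum(rasterize_roi(roi_a, dim(frame)))
    b <- sum(rasterize_roi(roi_b, dim(frame)))
    if (abs(a - b) / a > 0.25) {
      warning(sprintf(
        "%s ROI-B area (%d px) differs from ROI-A area (%d px) by more than 25%%",
        plane, b, a))
    }
  }
  check_matched(images$longitudinal[[1]], rois$A_long, rois$B_long,
                "longitudinal")
  check_matched(images$cross[[1]], rois$A_cross, rois$B_cross, "cross")

  a_long_mg <- plane_value(images$longitudinal, rois$A_long, mg)
  b_long_mg <- plane_value(images$longitudinal, rois$B_long, mg)
  a_long_af <- plane_value(images$longitudinal, rois$A_long, af)
  b_long_af <- plane_value(images$longitudinal, rois$B_long, af)
  a_cross_mg <- plane_value(images$cross, rois$A_cross, mg)
  b_cross_mg <- plane_value(images$cross, rois$B_cross, mg)
  a_cross_af <- plane_value(images$cross, rois$A_cross, af)
  b_cross_af <- plane_value(images$cross, rois$B_cross, af)
  tot_node_mg <- mg(images$total, rois$total_node)
  tot_par_mg <- mg(images$total, rois$total_parenchyma)
  tot_node_af <- af(images$total, rois$total_node)
  tot_par_af <- af(images$total, rois$total_parenchyma)

  prof <- list(
    roi_longitudinal = a_long_mg,
    roi_longitudinal_area_fraction = a_long_af,
    roi_cross = a_cross_mg,
    roi_cross_area_fraction = a_cross_af,
    quotient_longitudinal = quotient(a_long_mg, b_long_mg),
    quotient_longitudinal_area_fraction = quotient(a_long_af, b_long_af),
    quotient_cross = quotient(a_cross_mg, b_cross_mg),
    quotient_cross_area_fraction = quotient(a_cross_af, b_cross_af),
    quotient_all = quotient(tot_node_mg, tot_par_mg),
    quotient_all_area_fraction = quotient(tot_node_af, tot_par_af))
  structure(prof, class = "vascularization_profile")
}

#' @export
as.data.frame.vascularization_profile <- function(x, ...) {
  as.data.frame(lapply(unclass(x), function(v) if (is.null(v)) NA_real_ else v))
}

#' @export
print.vascularization_profile <- function(x, ...) {
  cat("<vascularization_profile>\n")
  for (nm in profile_fields) {
    cat(sprintf("  %-37s %s\n", nm,
                ifelse(is.na(x[[nm]]), "NA (undefined)",
                       format(x[[nm]], digits = 5))))
  }
  invisible(x)
}
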