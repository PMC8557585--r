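#' Region-of-interest polygon
#'
#' A planar polygon in image pixel coordinates with a role tag and a view
#' plane.  Coordinates follow the raster convention used throughout the
#' package: `(row, col)` with a 0-based origin at the top-left image
#' corner, so the centre of the pixel stored at matrix position
#' `[i, j]` is `(i - 0.5, j - 0.5)`.
#'
#' An axis-aligned rectangle may be given as just its two opposite
#' corners; it is expanded to a four-vertex polygon.  Rectangles are
#' half-open: the corner pair `(0,0)`--`(2,2)` covers pixel centres in
#' `[0,2) x [0,2)`, i.e. a 2 x 2 pixel block.
#'
#' @param vertices numeric matrix (or coercible) with columns `(row, col)`.
#'   Either >= 3 polygon vertices, or exactly 2 rows read as opposite
#'   rectangle corners.
#' @param role one of `"node_A"`, `"parenchyma_B"`, `"total_node"`,
#'   `"total_parenchyma"`.
#' @param plane one of `"longitudinal"`, `"cross"`.
#' @return an object of class `roi_polygon`.
#' @examples
#' roi_polygon(rbind(c(0, 0), c(2, 2)), role = "node_A")
#' @export
roi_polygon <- function(vertices,
                        role = c("node_A", "parenchyma_B",
                                 "total_node", "total_parenchyma"),
                        plane = c("longitudinal", "cross")) {
  role <- match.arg(role)
  plane <- match.arg(plane)
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L || anyNA(v)) {
    vq_stop("`vertices` must be a numeric (row, col) matrix without NAs",
            "vq_geometry_error")
  }
  if (nrow(v) == 2L) {
    r0 <- min(v[, 1]); r1 <- max(v[, 1])
    c0 <- min(v[, 2]); c1 <- max(v[, 2])
    v <- rbind(c(r0, c0), c(r0, c1), c(r1, c1), c(r1, c0))
  }
  if (nrow(v) < 3L) {
    vq_stop("a polygon needs at least 3 vertices (or 2 rectangle corners)",
            "vq_geometry_error")
  }
  dimnames(v) <- list(NULL, c("row", "col"))
  structure(list(vertices = v, role = role, plane = plane),
            class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon> role=%s plane=%s, %d vertices\n",
              x$role, x$plane, nrow(x$vertices)))
  invisible(x)
}

# Even-odd (ray casting) point-in-polygon test, vectorised over points.
# Points exactly on a horizontal-crossing edge follow the half-open
# convention implied by the strict/non-strict comparison pair below.
point_in_polygon <- function(pr, pc, vr, vc) {
  n <- length(vr)
  inside <- logical(length(pr))
  j <- n
  for (i in seq_len(n)) {
    ri <- vr[i]; ci <- vc[i]
    rj <- vr[j]; cj <- vc[j]
    crosses <- ((ri > pr) != (rj > pr)) &
      (pc < (cj - ci) * (pr - ri) / (rj - ri) + ci)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize an ROI polygon to a pixel mask
#'
#' A pixel belongs to the mask iff its centre lies inside the polygon
#' (even-odd rule).  With the 0-based vertex convention the centre of the
#' pixel at matrix position `[i, j]` is `(i - 0.5, j - 0.5)`.
#'
#' @param roi an [roi_polygon()] (or a bare vertex matrix, which is
#'   wrapped with default role/plane).
#' @param image_shape integer `c(height_px, width_px)`.
#' @return logical matrix of dimension `image_shape`; `TRUE` inside the ROI.
#' @examples
#' m <- rasterize_roi(roi_polygon(rbind(c(0, 0), c(2, 2))), c(4, 4))
#' sum(m)  # 4 pixels
#' @export
rasterize_roi <- function(roi, image_shape) {
  if (!inherits(roi, "roi_polygon")) roi <- roi_polygon(roi)
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  v <- roi$vertices
  if (max(v[, 1]) <= 0 || min(v[, 1]) >= h ||
      max(v[, 2]) <= 0 || min(v[, 2]) >= w) {
    vq_stop("ROI polygon lies fully outside the image", "vq_geometry_error")
  }
  if (min(v[, 1]) < 0 || max(v[, 1]) > h ||
      min(v[, 2]) < 0 || max(v[, 2]) > w) {
    vq_stop("ROI polygon extends outside the image bounds",
            "vq_geometry_error")
  }
  mask <- matrix(FALSE, h, w)
  # only pixels whose centre falls in the bounding box can be inside
  i_lo <- max(1L, floor(min(v[, 1])) + 1L)
  i_hi <- min(h, ceiling(max(v[, 1])))
  j_lo <- max(1L, floor(min(v[, 2])) + 1L)
  j_hi <- min(w, ceiling(max(v[, 2])))
  ii <- i_lo:i_hi
  jj <- j_lo:j_hi
  pr <- rep(ii - 0.5, times = length(jj))
  pc <- rep(jj - 0.5, each = length(ii))
  ins <- point_in_polygon(pr, pc, v[, 1], v[, 2])
  mask[cbind(rep(ii, times = length(jj)), rep(jj, each = length(ii)))] <- ins
  if (!any(mask)) {
    vq_stop("ROI rasterizes to zero pixels (degenerate ROI)",
            "vq_degenerate_roi")
  }
  mask
}
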