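# File I/O: 8-bit PNG images, ROI / field-rectangle JSON, commented CSVs.

#' Read and write 8-bit images
#'
#' Gray images are integer matrices in \[0, 255\]; RGB images are
#' `h x w x 3` arrays in \[0, 255\].  PNG is the canonical on-disk
#' format; TIFF is read when the `tiff` package is available.
#'
#' @param path file path.
#' @param image matrix (gray) or `h x w x 3` array (RGB) in \[0, 255\].
#' @return `read_gray_image()` an integer matrix; `read_rgb_image()` an
#'   array; the writers return `path` invisibly.
#' @name image_io
NULL

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      vq_stop("reading TIFF requires the 'tiff' package", "vq_input_error")
    }
    return(tiff::readTIFF(path))
  }
  png::readPNG(path)
}

#' @rdname image_io
#' @export
read_gray_image <- function(path) {
  a <- read_raster(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]           # gray stored as RGB
  matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
}

#' @rdname image_io
#' @export
write_gray_image <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' @rdname image_io
#' @export
read_rgb_image <- function(path) {
  a <- read_raster(path)
  if (length(dim(a)) == 2L) a <- array(a, dim = c(dim(a), 3))
  a[, , 1:3, drop = FALSE] * 255
}

#' @rdname image_io
#' @export
write_rgb_image <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Read ROI annotations from JSON
#'
#' Expected layout:
#' `{"rois": [{"role": "node_A", "plane": "longitudinal",
#'   "vertices": [[r, c], ...]}, ...]}` with 0-based (row, col)
#' vertices.
#'
#' @param path JSON file path.
#' @return named list of [roi_polygon()]s, keyed by the conventional
#'   slot names (`A_long`, `B_long`, `A_cross`, `B_cross`, `total_node`,
#'   `total_parenchyma`).
#' @export
read_roi_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (is.null(doc$rois)) vq_stop("no 'rois' entry in ROI JSON",
                                 "vq_input_error")
  out <- list()
  for (r in doc$rois) {
    v <- do.call(rbind, lapply(r$vertices, as.numeric))
    roi <- roi_polygon(v, role = r$role, plane = r$plane)
    key <- switch(paste(r$role, r$plane),
                  "node_A longitudinal" = "A_long",
                  "parenchyma_B longitudinal" = "B_long",
                  "node_A cross" = "A_cross",
                  "parenchyma_B cross" = "B_cross",
                  "total_node longitudinal" = "total_node",
                  "total_parenchyma longitudinal" = "total_parenchyma",
                  paste(r$role, r$plane, sep = "_"))
    out[[key]] <- roi
  }
  out
}

#' @rdname read_roi_json
#' @param rois named list of [roi_polygon()]s.
#' @export
write_roi_json <- function(rois, path) {
  doc <- list(rois = lapply(rois, function(r) {
    list(role = r$role, plane = r$plane,
         vertices = unname(apply(r$vertices, 1, as.numeric, simplify = FALSE)))
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# CSVs carry a provenance header ("# key=value" lines) above the data
write_study_csv <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_study_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
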