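# File-based pipeline: synthesize -> quantify SMI -> quantify IHC ->
# statistics -> tables.  Every stage is a thin, logged wrapper over the
# quantification modules; all randomness flows from the config seed.

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    cfg <- yaml::read_yaml(config)
    cfg$`.config_path` <- normalizePath(config)
    cfg$`.config_md5` <- unname(tools::md5sum(config))
    return(cfg)
  }
  if (!is.list(config)) vq_stop("config must be a YAML path or a list",
                                "vq_config_error")
  config$`.config_md5` <- config$`.config_md5` %||% "in-memory"
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_threshold <- function(cfg) {
  thr <- cfg$threshold %||% list(method = "isodata")
  as_threshold_rule(thr)
}

config_stains <- function(cfg) {
  if (is.null(cfg$stain_matrix)) return(stain_matrix())
  stain_matrix(hematoxylin = as.numeric(cfg$stain_matrix$hematoxylin),
               fast_red = as.numeric(cfg$stain_matrix$fast_red))
}

csv_header <- function(cfg) {
  c(sprintf("seed=%s", cfg$seed %||% "NA"),
    sprintf("config_md5=%s", cfg$`.config_md5`),
    sprintf("vascuquant=%s",
            as.character(utils::packageVersion("vascuquant"))))
}

#' Synthesize a complete study on disk
#'
#' Generates a cohort, then per patient a full set of SMI sonogram
#' frames (two longitudinal, two cross-sectional, one whole-lobe) with
#' ROI annotations, and CD34 histology fields (four 100x, one 25x) with
#' sampling rectangles.  Per-patient planted signal densities are tied
#' to the cohort draw: the parenchyma flow fraction is fixed at
#' `parenchyma_fraction` and the node fraction is
#' `quotient * parenchyma_fraction` (capped at 0.95), so the measured
#' area-fraction quotient tracks the cohort's latent quotient; the IHC
#' vessel fraction equals the cohort's CD34 fraction.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @param smi_px side length of the square SMI frames in pixels.
#' @param ihc_px side length of the square IHC fields in pixels.
#' @param parenchyma_fraction planted flow fraction in parenchyma.
#' @param noise_od_sd optical-density noise of the IHC scenes.
#' @param speckle_sd speckle SD of the SMI scenes.
#' @return invisibly, the study config (also written to
#'   `<out_dir>/study.yaml`).
#' @export
synthesize_study <- function(spec = cohort_spec(), out_dir,
                             smi_px = 160L, ihc_px = 220L,
                             parenchyma_fraction = 0.2,
                             noise_od_sd = 0.02, speckle_sd = 8) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(spec)
  n <- nrow(cohort)

  s <- smi_px
  q1 <- round(s * 0.12); q2 <- round(s * 0.44)
  q3 <- round(s * 0.56); q4 <- round(s * 0.88)
  node_poly <- function(plane) roi_polygon(rbind(c(q1, q1), c(q2, q2)),
                                           role = "node_A", plane = plane)
  par_poly <- function(plane) roi_polygon(rbind(c(q1, q3), c(q2, q4)),
                                          role = "parenchyma_B", plane = plane)
  rois <- list(
    A_long = node_poly("longitudinal"),
    B_long = par_poly("longitudinal"),
    A_cross = node_poly("cross"),
    B_cross = par_poly("cross"),
    total_node = roi_polygon(rbind(c(q1, q1), c(q2, q2)),
                             role = "total_node", plane = "longitudinal"),
    total_parenchyma = roi_polygon(rbind(c(q1, q3), c(q2, q4)),
                                   role = "total_parenchyma",
                                   plane = "longitudinal"))

  # the sampling rectangle spans the whole synthetic field, so the
  # measured fraction is comparable to the generator's image-wide truth
  margin <- 0L
  rect_px <- as.integer(ihc_px)
  stains <- stain_matrix()
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- cohort$patient_id[i]
    pdir <- file.path(out_dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    node_frac <- min(0.95, cohort$quotient[i] * parenchyma_fraction)
    smi_paths <- list(longitudinal = character(2), cross = character(2),
                      total = NULL)
    frame_names <- c("long1", "long2", "cross1", "cross2", "total")
    for (f in seq_along(frame_names)) {
      sc <- smi_scene_spec(
        s, s,
        node_polygon = rois$A_long, parenchyma_polygon = rois$B_long,
        node_vessel_fraction = node_frac,
        parenchyma_vessel_fraction = parenchyma_fraction,
        speckle_sd = speckle_sd,
        seed = (spec$seed * 10000L + i * 100L + f) %% .Machine$integer.max)
      img <- generate_smi_scene(sc)$image
      p <- file.path(pdir, paste0("smi_", frame_names[f], ".png"))
      write_gray_image(img, p)
      if (f <= 2) smi_paths$longitudinal[f] <- p
      else if (f <= 4) smi_paths$cross[f - 2] <- p
      else smi_paths$total <- p
    }
    roi_path <- file.path(pdir, "rois.json")
    write_roi_json(rois, roi_path)

    fields <- vector("list", 4)
    for (f in 1:4) {
      sc <- ihc_scene_spec(
        ihc_px, ihc_px, vessel_mask_fraction = cohort$cd34_fraction[i],
        stains = stains, noise_od_sd = noise_od_sd, magnification = "x100",
        seed = (spec$seed * 10000L + i * 100L + 10L + f) %% .Machine$integer.max)
      p <- file.path(pdir, sprintf("ihc_100x_%d.png", f))
      write_rgb_image(generate_ihc_scene(sc)$image, p)
      fields[[f]] <- list(image = p, rect = list(row = margin, col = margin))
    }
    sc25 <- ihc_scene_spec(
      ihc_px, ihc_px, vessel_mask_fraction = cohort$cd34_fraction[i],
      nucleus_density = 1500, stains = stains, noise_od_sd = noise_od_sd,
      magnification = "x25",
      seed = (spec$seed * 10000L + i * 100L + 15L) %% .Machine$integer.max)
    p25 <- file.path(pdir, "ihc_25x.png")
    write_rgb_image(generate_ihc_scene(sc25)$image, p25)

    patients[[i]] <- list(
      id = pid,
      smi = list(longitudinal = as.list(smi_paths$longitudinal),
                 cross = as.list(smi_paths$cross),
                 total = smi_paths$total, rois = roi_path),
      ihc = list(fields_100x = fields,
                 field_25x = list(image = p25,
                                  rect = list(row = margin, col = margin)),
                 rect_height_px = rect_px, rect_width_px = rect_px))
  }

  cohort_csv <- file.path(out_dir, "cohort.csv")
  cfg <- list(seed = spec$seed,
              threshold = list(method = "isodata"),
              cd34_threshold = 0.5,
              stain_matrix = list(hematoxylin = unname(stains[, 1]),
                                  fast_red = unname(stains[, 2])),
              stats_mode = "auto",
              cohort_csv = cohort_csv,
              patients = patients)
  write_study_csv(cohort, cohort_csv,
                  header = c(sprintf("seed=%d", spec$seed),
                             "generator=vascuquant cohort"))
  cfg_path <- file.path(out_dir, "study.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg$`.config_path` <- cfg_path
  cfg$`.config_md5` <- unname(tools::md5sum(cfg_path))
  invisible(cfg)
}

#' Run the SMI quantification stage
#'
#' Computes one [compute_profile()] row per patient from the image and
#' ROI paths in the config.  A per-patient failure (e.g. a missing file)
#' is recorded and the run continues.
#'
#' @param config study config: a YAML path or the list returned by
#'   [synthesize_study()].
#' @param out_csv output CSV path (default `profiles.csv` next to the
#'   config's outputs).
#' @return data.frame of profiles (one row per patient), with an
#'   `errors` attribute naming failed patients.  Also written to
#'   `out_csv` with a provenance header.
#' @export
run_smi <- function(config, out_csv) {
  cfg <- load_config(config)
  thr <- config_threshold(cfg)
  rows <- list(); errs <- character()
  for (pt in cfg$patients) {
    if (is.null(pt$smi)) next
    res <- tryCatch({
      imgs <- list(
        longitudinal = lapply(pt$smi$longitudinal, read_gray_image),
        cross = lapply(pt$smi$cross, read_gray_image),
        total = read_gray_image(pt$smi$total))
      rois <- read_roi_json(pt$smi$rois)
      prof <- compute_profile(imgs, rois, threshold = thr)
      cbind(data.frame(patient_id = pt$id), as.data.frame(prof))
    }, error = function(e) {
      errs[[pt$id]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 11)),
                    c("patient_id", profile_fields))
  if (!missing(out_csv) && !is.null(out_csv)) {
    write_study_csv(out, out_csv, header = csv_header(cfg))
  }
  attr(out, "errors") <- errs
  out
}

#' Run the CD34 quantification stage
#'
#' For each patient, unmixes every field image (RGB -> OD ->
#' haematoxylin / Fast-Red concentrations), measures the
#' Fast-Red-positive fraction in the field's sampling rectangle, and
#' summarises four 100x fields and one 25x field into a CD34 profile.
#'
#' @inheritParams run_smi
#' @return data.frame with columns `patient_id, cd34_100_fold,
#'   cd34_25_fold, cd34_all`, with an `errors` attribute.
#' @export
run_ihc <- function(config, out_csv) {
  cfg <- load_config(config)
  stains <- config_stains(cfg)
  thr <- cfg$cd34_threshold %||% 0.15
  rows <- list(); errs <- character()
  field_fraction <- function(fld, mag, hpx, wpx) {
    img <- read_rgb_image(fld$image)
    conc <- unmix(rgb_to_od(img), stains)
    rect <- sampling_rect(top_left = c(fld$rect$row, fld$rect$col),
                          magnification = mag,
                          height_px = hpx, width_px = wpx)
    cd34_fraction(conc$fast_red, rect, positive_threshold = thr)
  }
  for (pt in cfg$patients) {
    if (is.null(pt$ihc)) next
    res <- tryCatch({
      hpx <- pt$ihc$rect_height_px %||% 1443L
      wpx <- pt$ihc$rect_width_px %||% 1440L
      f100 <- vapply(pt$ihc$fields_100x, field_fraction, numeric(1),
                     mag = "x100", hpx = hpx, wpx = wpx)
      f25 <- field_fraction(pt$ihc$field_25x, "x25", hpx, wpx)
      prof <- cd34_summary(f100, f25)
      cbind(data.frame(patient_id = pt$id), as.data.frame(prof))
    }, error = function(e) {
      errs[[pt$id]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 4)),
                    c("patient_id", "cd34_100_fold", "cd34_25_fold",
                      "cd34_all"))
  if (!missing(out_csv) && !is.null(out_csv)) {
    write_study_csv(out, out_csv, header = csv_header(cfg))
  }
  attr(out, "errors") <- errs
  out
}

summary_row <- function(values, labels, mode) {
  gs <- group_summary(values, labels)
  wt <- tryCatch(
    wilcoxon_rank_sum(values[labels == "benign" & !is.na(values)],
                      values[labels == "malignant" & !is.na(values)],
                      mode = if (mode == "auto") "auto" else mode),
    error = function(e) NULL)
  row <- data.frame(n_benign = 0L, benign_mean = NA_real_,
                    benign_sd = NA_real_, benign_median = NA_real_,
                    benign_min = NA_real_, benign_max = NA_real_,
                    n_malignant = 0L, malignant_mean = NA_real_,
                    malignant_sd = NA_real_, malignant_median = NA_real_,
                    malignant_min = NA_real_, malignant_max = NA_real_,
                    p_value = if (is.null(wt)) NA_real_ else wt$p_value)
  for (grp in c("benign", "malignant")) {
    g <- gs[gs$label == grp, ]
    if (!nrow(g)) next
    row[[paste0("n_", grp)]] <- g$n
    for (st in c("mean", "sd", "median", "min", "max")) {
      row[[paste0(grp, "_", st)]] <- g[[st]]
    }
  }
  row
}

#' Run the statistics stage
#'
#' Joins the SMI profiles, CD34 profiles and cohort covariates on
#' `patient_id` and emits the study's three result tables plus a machine
#' readable run report: `table2.csv` (SMI parameter group summaries and
#' Wilcoxon p-values), `table3.csv` (the same for the CD34 fractions),
#' `table4.csv` (the Spearman correlation matrix between the ten SMI
#' parameters and the three CD34 fractions) and `report.json`.
#' Undefined values are excluded pairwise, never imputed; all p-values
#' are raw (no multiple-testing adjustment).
#'
#' @param profiles_csv CSV from [run_smi()] (or a data.frame).
#' @param cd34_csv CSV from [run_ihc()] (or a data.frame).
#' @param cohort_csv cohort CSV (or a data.frame) with `patient_id`,
#'   `label`, `age`, `bmi`.
#' @param out_dir directory for the output tables.
#' @param mode p-value mode for the correlation table.
#' @param config optional study config for provenance headers.
#' @return invisibly, a list with `table2`, `table3`, `table4` and
#'   `report`.
#' @export
run_stats <- function(profiles_csv, cd34_csv, cohort_csv, out_dir,
                      mode = "auto", config = list(seed = NA)) {
  cfg <- load_config(config)
  as_df <- function(x) if (is.data.frame(x)) x else read_study_csv(x)
  profiles <- as_df(profiles_csv)
  cd34 <- as_df(cd34_csv)
  cohort <- as_df(cohort_csv)
  merged <- merge(merge(cohort, profiles, by = "patient_id"),
                  cd34, by = "patient_id")
  unmatched <- setdiff(unique(c(cohort$patient_id, profiles$patient_id,
                                cd34$patient_id)),
                       merged$patient_id)
  if (!nrow(merged)) vq_stop("no patients joined across inputs",
                             "vq_input_error")

  smi_cols <- intersect(profile_fields, names(merged))
  cd34_cols <- intersect(c("cd34_100_fold", "cd34_25_fold", "cd34_all"),
                         names(merged))
  t2 <- do.call(rbind, lapply(smi_cols, function(p) {
    cbind(data.frame(parameter = p),
          summary_row(merged[[p]], merged$label, mode))
  }))
  t3 <- do.call(rbind, lapply(cd34_cols, function(p) {
    cbind(data.frame(parameter = p),
          summary_row(merged[[p]], merged$label, mode))
  }))
  ct <- correlation_table(merged, smi_cols, cd34_cols, mode = mode)
  t4 <- data.frame(parameter = rownames(ct$r))
  for (cc in colnames(ct$r)) {
    t4[[paste0("r_", cc)]] <- ct$r[, cc]
    t4[[paste0("p_", cc)]] <- ct$p[, cc]
    t4[[paste0("n_", cc)]] <- ct$n[, cc]
  }

  report <- list(
    n_joined = nrow(merged),
    unmatched_patient_ids = as.list(unmatched),
    n_benign = sum(merged$label == "benign"),
    n_malignant = sum(merged$label == "malignant"),
    excluded_pairs = sum(is.na(merged[smi_cols])),
    seed = cfg$seed,
    stats_mode = mode,
    package_version = as.character(utils::packageVersion("vascuquant")))

  if (!missing(out_dir) && !is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hd <- csv_header(cfg)
    write_study_csv(t2, file.path(out_dir, "table2.csv"), hd)
    write_study_csv(t3, file.path(out_dir, "table3.csv"), hd)
    write_study_csv(t4, file.path(out_dir, "table4.csv"), hd)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(table2 = t2, table3 = t3, table4 = t4, report = report,
                 merged = merged))
}

#' Run the full pipeline
#'
#' `synthesize (optional) -> run_smi -> run_ihc -> run_stats`.  When the
#' config has a `synth` entry (fields of [cohort_spec()]), the study is
#' generated first under `out_dir/input`.
#'
#' @param config study config (YAML path or list).
#' @param out_dir output directory.
#' @return invisibly, the [run_stats()] result list.
#' @export
run_all <- function(config, out_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cfg$synth)) {
    sp_args <- cfg$synth
    sp_args$seed <- sp_args$seed %||% cfg$seed %||% 1L
    sp <- do.call(cohort_spec, sp_args)
    gen <- synthesize_study(sp, file.path(out_dir, "input"))
    gen$stats_mode <- cfg$stats_mode %||% gen$stats_mode
    cfg <- gen
  }
  profiles <- run_smi(cfg, file.path(out_dir, "profiles.csv"))
  cd34 <- run_ihc(cfg, file.path(out_dir, "cd34.csv"))
  res <- run_stats(profiles, cd34, cfg$cohort_csv, out_dir,
                   mode = cfg$stats_mode %||% "auto", config = cfg)
  invisible(res)
}
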