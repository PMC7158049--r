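# NIfTI and CSV input/output. Raster data travels as NIfTI with voxel
# dimensions in the header; frame times, precontrast count, tube signals and
# acquisition parameters travel in a JSON sidecar next to the 4-D file.

#' Write a parametric map (or mask) to NIfTI
#'
#' @param map A [parametric_map()], or a 3-D array with `voxel_dims_mm`.
#' @param path Output `.nii` path.
#' @param voxel_dims_mm Voxel size when `map` is a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti_map <- function(map, path, voxel_dims_mm = c(0.78, 0.78, 5.0)) {
  if (inherits(map, "parametric_map")) {
    arr <- map$values
    arr[!map$mask] <- 0
    voxel_dims_mm <- map$voxel_dims_mm
  } else {
    arr <- map * 1  # logical -> numeric
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_dims_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-D NIfTI volume
#'
#' @param path `.nii` path.
#' @return A list with `values` (3-D array) and `voxel_dims_mm`.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = array(as.numeric(img), dim = dim(img)),
       voxel_dims_mm = RNifti::pixdim(img)[1:3])
}

#' Write a dynamic series to NIfTI + JSON sidecar
#'
#' The 4-D array goes to `<stem>.nii`; frame times, precontrast count,
#' acquisition parameters, tube chamber signals, mask and provenance go to
#' `<stem>.json`.
#'
#' @param series A `dce_series`.
#' @param stem Output path without extension.
#' @return Character vector of the two files written, invisibly.
#' @export
write_dce_series <- function(series, stem) {
  stopifnot(inherits(series, "dce_series"))
  nii <- paste0(stem, ".nii"); sidecar <- paste0(stem, ".json")
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_dims_mm, 1)
  RNifti::writeNifti(img, nii)
  meta <- list(
    kind = series$kind,
    times_s = series$times_s,
    acquisition = unclass(series$acquisition),
    voxel_dims_mm = series$voxel_dims_mm,
    mask_index = which(series$mask),
    mask_dim = dim(series$mask),
    tube = if (!is.null(series$tube)) as.list(series$tube),
    provenance = series$provenance)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(nii, sidecar))
}

#' Read a dynamic series written by [write_dce_series()]
#'
#' @param stem Path without extension (expects `<stem>.nii` + `<stem>.json`).
#' @param mask Optional 3-D logical mask to validate against the series shape.
#' @return A `dce_series`.
#' @export
read_dce_series <- function(stem, mask = NULL) {
  nii <- paste0(stem, ".nii"); sidecar <- paste0(stem, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar metadata: ", sidecar)
  img <- RNifti::readNifti(nii)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  d <- dim(img)
  m <- array(FALSE, meta$mask_dim)
  m[meta$mask_index] <- TRUE
  if (!all(dim(m) == d[1:3])) stop("mask shape does not match series shape")
  if (!is.null(mask)) {
    if (!all(dim(mask) == d[1:3])) stop("mask shape does not match series shape")
    m <- mask
  }
  acq <- meta$acquisition
  structure(list(
    data = array(as.numeric(img), dim = d),
    times_s = meta$times_s,
    acquisition = acquisition_config(
      tr_ms = acq$tr_ms, te_ms = acq$te_ms, flip_deg = acq$flip_deg,
      frame_times_s = acq$frame_times_s, n_precontrast = acq$n_precontrast,
      relaxivity_r1 = acq$relaxivity_r1),
    mask = m,
    voxel_dims_mm = RNifti::pixdim(img)[1:3],
    tube = if (!is.null(meta$tube)) tibble::as_tibble(meta$tube),
    kind = meta$kind,
    provenance = meta$provenance
  ), class = "dce_series")
}

#' Write / read a cohort table as CSV
#'
#' @param cohort Cohort tibble (one row per patient).
#' @param path CSV path.
#' @return `path` invisibly / the cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Run the whole analysis pipeline on a synthetic cohort
#'
#' Generates a cohort of phantoms, simulates each patient's dynamic
#' acquisition, converts signals to concentration, fits the Tofts model
#' voxelwise (or uses the ground-truth maps when `fit_maps = FALSE`, useful
#' for large cohorts), refines masks on the synthetic T2 volume, computes
#' per-patient biomarkers, runs the percentile and threshold sweeps, and fits
#' univariate Cox models for the selected biomarkers. All outputs are written
#' under `out_dir` together with a manifest and the resolved configuration.
#'
#' @param cohort_cfg A [cohort_config()].
#' @param phantom_cfg Template [phantom_config()].
#' @param out_dir Output directory (created if missing).
#' @param noise_sd Signal noise sd for the simulated acquisitions.
#' @param fit_maps Fit the Tofts model per voxel (`TRUE`) or read biomarkers
#'   off the ground-truth maps (`FALSE`).
#' @param thresholds Threshold grid for the sweep.
#' @param percentiles Percentile grid for the sweep.
#' @param horizon_months ROC outcome horizon.
#' @param write_images Also write per-patient NIfTI maps/series (slow for
#'   large cohorts).
#' @return A list with `cohort` (biomarker-augmented tibble),
#'   `percentile_sweep`, `threshold_sweep`, `optima`, `cox`, `manifest`.
#' @export
run_pipeline <- function(cohort_cfg = cohort_config(),
                         phantom_cfg = phantom_config(),
                         out_dir = tempfile("dcerisk_run_"),
                         noise_sd = 0,
                         fit_maps = FALSE,
                         thresholds = threshold_grid(step = 0.01),
                         percentiles = seq(5, 95, by = 5),
                         horizon_months = 60,
                         write_images = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_line <- function(...) message(sprintf(...))

  log_line("[simulate] generating %d-patient cohort", cohort_cfg$n_patients)
  cg <- generate_cohort(cohort_cfg, phantom_cfg)
  cohort <- cg$cohort

  dists <- vector("list", nrow(cohort))
  bio <- vector("list", nrow(cohort))
  acq <- acquisition_config()
  aif <- aif_params()
  for (p in seq_len(nrow(cohort))) {
    ph <- cg$phantoms[[p]]
    series <- simulate_dce_series(ph, aif, acq, noise_sd = noise_sd,
                                  seed = cohort_cfg$seed + p)
    # refine the mask on T2: drop the hyperintense fluid tail
    refined <- exclude_voxels(ph$tumor_mask, ph$synthetic_t2, upper_cut = 200)
    if (fit_maps) {
      conc <- concentration_from_signal(series, method = "spgr")
      fit <- fit_tofts_volume(conc$data, conc$times_s, refined & conc$mask,
                              aif, voxel_dims_mm = ph$voxel_dims_mm)
      kmap <- fit$ktrans
    } else {
      kmap <- parametric_map(ph$ktrans_map$values,
                             ph$tumor_mask & refined,
                             ph$voxel_dims_mm, "ktrans")
    }
    dists[[p]] <- frequency_distribution(kmap)
    bio[[p]] <- compute_biomarkers(kmap, series = series)
    if (write_images) {
      write_nifti_map(kmap, file.path(out_dir, sprintf("ktrans_%03d.nii", p)))
      write_dce_series(series, file.path(out_dir, sprintf("series_%03d", p)))
    }
  }
  bio_tbl <- dplyr::bind_rows(bio) |>
    dplyr::rename(analyzed_volume_cm3 = "tumor_volume_cm3")
  cohort <- dplyr::bind_cols(cohort, bio_tbl)

  log_line("[sweep] percentile and threshold sweeps")
  psw <- percentile_sweep(cohort, dists, percentiles, horizon_months)
  tsw <- threshold_sweep(cohort, dists, thresholds, horizon_months)
  optima <- dplyr::bind_rows(glance(psw), glance(tsw))

  log_line("[survival] univariate Cox models")
  cox <- dplyr::bind_rows(lapply(c("rv_ktrans_cm3", "p_ktrans", "tumor_volume_cm3"),
    function(v) {
      dplyr::bind_rows(lapply(c("dfs", "os"), function(ep) {
        fit <- cox_fit(cohort, v, time = paste0(ep, "_months"),
                       event = paste0(ep, "_event"))
        dplyr::mutate(tidy(fit), endpoint = ep, .before = 1)
      }))
    }))

  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  utils::write.csv(psw, file.path(out_dir, "percentile_sweep.csv"),
                   row.names = FALSE)
  utils::write.csv(tsw, file.path(out_dir, "threshold_sweep.csv"),
                   row.names = FALSE)
  utils::write.csv(cox, file.path(out_dir, "cox_univariate.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(cohort_config = unclass(cohort_cfg),
         phantom_config = unclass(phantom_cfg),
         noise_sd = noise_sd, fit_maps = fit_maps,
         horizon_months = horizon_months),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list.files(out_dir, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"))
  manifest <- list.files(out_dir, recursive = TRUE)  # now includes itself
  log_line("[done] %.1f s, outputs in %s",
           as.numeric(difftime(Sys.time(), t0, units = "secs")), out_dir)

  list(cohort = cohort, percentile_sweep = psw, threshold_sweep = tsw,
       optima = optima, cox = cox, out_dir = out_dir, manifest = manifest)
}
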