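#' Analyze a single Jones-matrix volume
#'
#' Runs the per-volume chain: noise estimation, intensity, noise-bias-
#' corrected entropy, surface segmentation (unless surfaces are supplied),
#' the three layer en-face maps, the retinal thickness map and the fovea
#' estimate.
#'
#' @param jv a [jones_volume()].
#' @param kernel coherency averaging window, see [entropy_volume()].
#' @param floor_db detection threshold above the noise floor (dB).
#' @param entropy_threshold depolarization threshold (strict `>`).
#' @param background_rows axial indices of the noise-only region used to
#'   estimate the noise power; default the top 6% (at least 4 rows).
#' @param surfaces optional precomputed `oct_surfaces` (e.g. phantom truth);
#'   when NULL, [segment_surfaces()] is run.
#' @param min_valid_frac en-face slab validity fraction.
#' @return an `oct_analysis` list: `intensity`, `entropy`, `surfaces`,
#'   `maps` (named by layer), `thickness_um`, `fovea`, `sigma2`.
#' @export
analyze_jones_volume <- function(jv, kernel = c(3, 3), floor_db = 3,
                                 entropy_threshold = 0.1,
                                 background_rows = NULL, surfaces = NULL,
                                 min_valid_frac = 0.5) {
  stopifnot(inherits(jv, "jones_volume"))
  background_rows <- background_rows %||% seq_len(max(4L, round(jv$nz * 0.06)))
  sigma2 <- estimate_noise_power(jv, background_rows)
  iv <- intensity_db(jv, floor_db = floor_db,
                     noise_power = max(4 * sigma2, .Machine$double.xmin))
  ev <- entropy_volume(jv, kernel = kernel, sigma2 = sigma2, mask = iv)
  s <- surfaces %||% segment_surfaces(iv, ev, floor_db = floor_db)
  maps <- lapply(c(retina = "retina", rpe = "rpe", choroid = "choroid"),
                 function(l) enface_entropy_map(ev, s, l, min_valid_frac))
  structure(list(
    intensity = iv, entropy = ev, surfaces = s, maps = maps,
    thickness_um = retinal_thickness(s, jv$axial_pitch_um),
    fovea = find_fovea(s),
    sigma2 = sigma2,
    entropy_threshold = entropy_threshold,
    lateral_pitch_um = jv$lateral_pitch_um,
    axial_pitch_um = jv$axial_pitch_um
  ), class = "oct_analysis")
}

#' Configure an end-to-end pipeline run
#'
#' Bundles a phantom specification (or a directory of stored volumes), the
#' analysis parameters and the longitudinal design into a validated,
#' serializable configuration. A run is fully reproducible from the
#' configuration and its seed.
#'
#' @param phantom a [phantom_spec()] describing the eye to simulate; or NULL
#'   with `input_dir` pointing at volumes stored by [write_jones_tiff()].
#' @param input_dir directory of stored volumes (prefix per timepoint).
#' @param eye_id identifier carried into output tables.
#' @param timepoints visit labels.
#' @param irradiated_sectors ETDRS sector labels treated by the laser.
#' @param d_rpe_schedule,edema_um_schedule,retina_thickness_schedule per-
#'   timepoint phantom schedules, see [longitudinal_series()].
#' @param kernel,floor_db,entropy_threshold analysis parameters.
#' @param use_truth_surfaces use the phantom's exact surfaces instead of
#'   running segmentation (FALSE by default).
#' @param seed integer seed.
#' @param out_dir output directory for CSV/TIFF/PNG artifacts, or NULL to
#'   keep results in memory only.
#' @return a `run_config` object.
#' @export
run_config <- function(phantom = NULL, input_dir = NULL, eye_id = "eye1",
                       timepoints = c("baseline", "1m", "2m", "3m", "6m"),
                       irradiated_sectors = character(),
                       d_rpe_schedule = NULL, edema_um_schedule = NULL,
                       retina_thickness_schedule = NULL,
                       kernel = c(3, 3), floor_db = 3,
                       entropy_threshold = 0.1,
                       use_truth_surfaces = FALSE,
                       seed = 1L, out_dir = NULL) {
  if (is.null(phantom) && is.null(input_dir))
    stop("either a phantom spec or an input directory is required")
  bad <- setdiff(irradiated_sectors, etdrs_sector_labels())
  if (length(bad)) stop("unknown sector label: ", paste(bad, collapse = ", "))
  kernel <- as.integer(kernel)
  if (any(kernel < 1) || any(kernel %% 2 == 0))
    stop("kernel must be odd positive integers")
  stopifnot(entropy_threshold >= 0, entropy_threshold <= 1)
  structure(list(
    phantom = phantom, input_dir = input_dir, eye_id = eye_id,
    timepoints = timepoints, irradiated_sectors = irradiated_sectors,
    d_rpe_schedule = d_rpe_schedule, edema_um_schedule = edema_um_schedule,
    retina_thickness_schedule = retina_thickness_schedule,
    kernel = kernel, floor_db = floor_db,
    entropy_threshold = entropy_threshold,
    use_truth_surfaces = isTRUE(use_truth_surfaces),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

#' Run the full pipeline for one eye
#'
#' Chains phantom generation (or volume loading), entropy computation,
#' segmentation, en-face mapping, ETDRS sector extraction, B-scan metrics
#' and the longitudinal statistics, optionally exporting tables, maps and a
#' run log. Outputs are deterministic for a fixed configuration.
#'
#' @param cfg a [run_config()].
#' @return an `oct_run`: `sector_table` (eye, timepoint, layer, sector,
#'   mean, n_valid), `bscan_table` (RPE entropy-area percentage and foci
#'   counts per timepoint), `thickness_table`, `stats` (per layer/scope
#'   Friedman + Bonferroni-adjusted baseline contrasts, when >= 3
#'   timepoints), `grid`, `analyses`, and `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  tp <- cfg$timepoints

  if (!is.null(cfg$phantom)) {
    series <- longitudinal_series(
      cfg$phantom, timepoints = tp,
      irradiated_sectors = cfg$irradiated_sectors,
      d_rpe_schedule = cfg$d_rpe_schedule,
      edema_um_schedule = cfg$edema_um_schedule,
      retina_thickness_schedule = cfg$retina_thickness_schedule,
      seed = cfg$seed)
    volumes <- lapply(series$phantoms, `[[`, "jones")
    truths <- lapply(series$phantoms, `[[`, "truth")
  } else {
    volumes <- lapply(tp, function(t)
      read_jones_tiff(file.path(cfg$input_dir, t)))
    names(volumes) <- tp
    truths <- NULL
  }

  analyses <- list()
  sector_rows <- list(); bscan_rows <- list(); thick_rows <- list()
  grid <- NULL
  for (t in tp) {
    jv <- volumes[[t]]
    truth <- if (!is.null(truths)) truths[[t]] else NULL
    an <- analyze_jones_volume(
      jv, kernel = cfg$kernel, floor_db = cfg$floor_db,
      entropy_threshold = cfg$entropy_threshold,
      background_rows = if (!is.null(truth)) truth$background_rows else NULL,
      surfaces = if (cfg$use_truth_surfaces && !is.null(truth))
        truth$surfaces else NULL)
    analyses[[t]] <- an
    fov <- if (!is.null(truth)) truth$fovea else an$fovea
    if (is.null(grid))
      grid <- etdrs_grid(fov, jv$lateral_pitch_um,
                         if (!is.null(truth)) truth$laterality else "OD",
                         c(jv$n_ascans, jv$n_bscans))
    for (l in names(an$maps)) {
      sm <- sector_means(an$maps[[l]], grid,
                         irradiated = if (length(cfg$irradiated_sectors))
                           cfg$irradiated_sectors else NULL)
      sm$eye_id <- cfg$eye_id; sm$timepoint <- t; sm$layer <- l
      sector_rows[[paste(t, l)]] <- sm
    }
    th <- an$thickness_um
    thm <- sector_means(list(values = th, mask = !is.na(th)), grid,
                        irradiated = if (length(cfg$irradiated_sectors))
                          cfg$irradiated_sectors else NULL)
    thm$eye_id <- cfg$eye_id; thm$timepoint <- t; thm$layer <- "thickness_um"
    thick_rows[[t]] <- thm

    bm <- rpe_entropy_area_percent(an$entropy, an$surfaces, fov[2], fov[1],
                                   jv$lateral_pitch_um,
                                   threshold = cfg$entropy_threshold)
    fs <- detect_hrf(an$intensity, an$entropy, an$surfaces, fov[2], fov[1],
                     jv$lateral_pitch_um, threshold = cfg$entropy_threshold)
    bscan_rows[[t]] <- tibble::tibble(
      eye_id = cfg$eye_id, timepoint = t, percent = bm$percent,
      n_band_px = bm$n_band_px, n_signal_px = bm$n_signal_px,
      n_hrf = fs$n_hrf, n_dots = fs$n_dots, n_overlap = fs$n_overlap)
  }
  sector_table <- do.call(rbind, unname(sector_rows))
  bscan_table <- do.call(rbind, unname(bscan_rows))
  thickness_table <- do.call(rbind, unname(thick_rows))

  # cohort statistics need several eyes; combine per-eye sector tables with
  # rbind and call longitudinal_stats() on the result
  stats <- NULL
  if (length(tp) >= 3 && length(unique(sector_table$eye_id)) >= 2) {
    scopes <- c("whole_grid",
                if (length(cfg$irradiated_sectors)) "irradiated")
    stats <- longitudinal_stats(sector_table, baseline = tp[1],
                                scopes = scopes)
  }

  run <- structure(list(
    sector_table = sector_table, bscan_table = bscan_table,
    thickness_table = thickness_table, stats = stats,
    grid = grid, analyses = analyses, config = cfg
  ), class = "oct_run")
  if (!is.null(cfg$out_dir)) export_run(run, cfg$out_dir)
  run
}

#' @export
print.oct_run <- function(x, ...) {
  cat(sprintf("<oct_run> eye %s, %d timepoints, %d sector rows\n",
              x$config$eye_id, length(x$config$timepoints),
              nrow(x$sector_table)))
  invisible(x)
}

# write the CSV / TIFF / PNG / log bundle of a pipeline run
export_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(run$sector_table, "sector_means.csv")
  wcsv(run$bscan_table, "bscan_metrics.csv")
  wcsv(run$thickness_table, "thickness_sectors.csv")
  for (t in names(run$analyses)) {
    an <- run$analyses[[t]]
    for (l in names(an$maps))
      write_enface_tiff(an$maps[[l]],
                        file.path(out_dir, sprintf("enface_%s_%s.tif", t, l)))
    write_surfaces_csv(an$surfaces,
                       file.path(out_dir, sprintf("surfaces_%s.csv", t)))
  }
  cfg <- run$config
  cfg_json <- jsonlite::serializeJSON(cfg[setdiff(names(cfg), "out_dir")])
  log <- list(
    package_version = as.character(utils::packageVersion("polent")),
    seed = cfg$seed,
    timepoints = cfg$timepoints,
    config_hash = rlang::hash(cfg_json),
    valid_voxel_fraction = vapply(run$analyses,
                                  function(a) mean(a$entropy$valid),
                                  numeric(1))
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
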