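# End-to-end demo pipeline and tidy result aggregation.

#' Default pipeline configuration
#'
#' Calibration and stage parameters used across the pipeline, with the
#' defaults documented in each stage's help page. Override entries via
#' `...`.
#'
#' @param ... named overrides of the defaults.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    pixel_size_um = 0.5,
    frame_interval_s = 1,
    z_step_um = 1,
    n_scales = 3L,
    sholl_step_um = 2,
    threshold_k = 2.5,
    gap_frames = 0L,
    min_integral_um2s = 4,
    min_s_max_um2 = 10,
    min_duration_s = 2,
    pattern_size = 128L,
    demo_n_events = 15L,
    demo_alpha_area = 2.7,
    demo_alpha_duration = 2.75
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x, digits = 12), collapse = ","), character(1L)),
    collapse = ";")
  # small polynomial rolling hash; provenance tag only
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

result_row <- function(sample_id, metric, value, units, stage) {
  data.frame(sample_id = sample_id, metric = metric,
             value = as.numeric(value), units = units, stage = stage,
             stringsAsFactors = FALSE)
}

#' Run the full synthetic demonstration pipeline
#'
#' Generates one synthetic input of every kind from `seed`, runs every
#' analysis stage on it, and aggregates the results into one long-format
#' table (`sample_id`, `metric`, `value`, `units`, `stage`, `config_hash`).
#' Identical `(seed, config)` yields an identical table. Stage errors are
#' caught and recorded as `NA` rows so the remaining stages still run.
#'
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @param config a [default_config()] list.
#' @param out_dir optional directory; if given, the table is written there as
#'   `results.csv`.
#' @return Data frame (long format) with one row per metric.
#' @export
run_demo <- function(seed = 1, config = default_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- as.integer(seed)
  sub <- function(k) (seed * 131L + k) %% 2147483629L
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  safely <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      add(result_row(stage, "error", NA_real_, "", stage))
      warning(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
              call. = FALSE)
    })
  }

  # texture calibration: entropy/complexity of the three pattern kinds
  safely("ec", {
    sys <- build_system(config$pattern_size, config$n_scales)
    for (kind in c("periodic", "branching", "noise")) {
      img <- gen_pattern(kind, config$pattern_size, sub(1L))
      m <- map_entropy_complexity(img, system = sys)
      add(result_row(paste0("pattern_", kind), "mean_Hs",
                     m$summary["mean_Hs"], "", "entropy_complexity"))
      add(result_row(paste0("pattern_", kind), "mean_C",
                     m$summary["mean_C"], "", "entropy_complexity"))
    }
  })

  # morphology: mask, Sholl, volume fraction
  safely("morphometry", {
    ast <- gen_astrocyte(n_rays = 6, ray_length_um = 40,
                         leaflet_vf = 0.034,
                         pixel_size = config$pixel_size_um, seed = sub(2L))
    bm <- make_branch_mask(ast)
    sp <- sholl_profile(bm, step_um = config$sholl_step_um)
    add(result_row("astro_1", "n_primary", sp$metrics$n_primary, "count",
                   "sholl"))
    add(result_row("astro_1", "peak_count", sp$metrics$peak_count, "count",
                   "sholl"))
    add(result_row("astro_1", "enclosing_radius",
                   sp$metrics$enclosing_radius_um, "um", "sholl"))
    vp <- vf_from_synthetic(ast)
    add(result_row("astro_1", "mean_leaflet_vf", vp$mean_leaflet_vf, "%",
                   "volume_fraction"))
  })

  # coupling decay
  safely("coupling", {
    cs <- gen_coupling_set(33, n = 50, noise_sd = 0.1, seed = sub(3L))
    cf <- fit_coupling(cs)
    add(result_row("coupling_1", "c_lambda", cf$c_lambda, "um", "coupling"))
    add(result_row("coupling_1", "n_cells", cf$n_cells, "count", "coupling"))
    add(result_row("coupling_1", "r2", cf$r2, "", "coupling"))
  })

  # calcium events
  safely("ca_events", {
    mv <- gen_ca_movie(n_events = config$demo_n_events,
                       alpha_area = config$demo_alpha_area,
                       alpha_duration = config$demo_alpha_duration,
                       frame_interval = config$frame_interval_s,
                       pixel_size = config$pixel_size_um, seed = sub(4L))
    m <- subtract_dark_noise(mv$movie, mv$dark_frames)
    dm <- compute_dff(m, mv$frame_interval, mv$pixel_size,
                      threshold_k = config$threshold_k)
    ev <- filter_events(detect_events(dm, threshold_k = config$threshold_k,
                                      gap_frames = config$gap_frames),
                        config$min_integral_um2s, config$min_s_max_um2,
                        config$min_duration_s)
    fov_mm2 <- (dim(mv$movie)[2L] * mv$pixel_size / 1000)^2
    dur_s <- dim(mv$movie)[1L] * mv$frame_interval
    add(result_row("movie_1", "n_events", nrow(ev), "count", "ca_events"))
    add(result_row("movie_1", "frequency_density",
                   frequency_density(ev, fov_mm2, dur_s), "s-1 mm-2",
                   "ca_events"))
    if (nrow(ev) > 0L) {
      add(result_row("movie_1", "median_s_max", stats::median(ev$s_max_um2),
                     "um2", "ca_events"))
      add(result_row("movie_1", "median_duration",
                     stats::median(ev$duration_s), "s", "ca_events"))
    }
    # exponent recovery on direct power-law samples (the movie plants too
    # few events for a per-movie fit)
    smp <- with_seed(sub(5L), sample_power_law(1e4, config$demo_alpha_area,
                                               config$min_s_max_um2))
    pf <- fit_power_law(smp, x_min = config$min_s_max_um2)
    add(result_row("sample_1", "alpha_s_max", pf$alpha, "", "power_law"))
    add(result_row("sample_1", "alpha_s_max_stderr", pf$fit_stderr, "",
                   "power_law"))
  })

  # electrophysiology
  safely("ephys", {
    ts <- gen_traces(tau_s = 2.5, ik5_ratio = 0.72, tau5_ratio = 1.45,
                     ltp_early = 1.73, seed = sub(6L))
    ik1 <- measure_ik(ts$ik1, ts$stim_times$ik)
    ik5 <- measure_ik(isolate_fifth(ts$resp5, ts$resp4),
                      ts$stim_times$train[5L])
    add(result_row("cell_1", "tau_decay_ik1", ik1$tau_decay_s, "s", "ephys"))
    add(result_row("cell_1", "ik5_over_ik1", ik5$ik_amp / ik1$ik_amp, "",
                   "ephys"))
    add(result_row("cell_1", "tau5_over_tau1",
                   ik5$tau_decay_s / ik1$tau_decay_s, "", "ephys"))
    fm <- fepsp_metrics(ts$fepsp, ts$stim_times$fepsp)
    add(result_row("slice_1", "ppr", fm$ppr, "", "ephys"))
    add(result_row("slice_1", "fepsp_amp1", fm$amplitude_mV[1L], "mV",
                   "ephys"))
    gf <- fit_gompertz(ts$io_points)
    add(result_row("slice_1", "io_max_slope", gf$max_slope, "", "ephys"))
    lt <- ltp_magnitude(ts$ltp_series)
    add(result_row("slice_1", "ltp_magnitude", lt$magnitude, "", "ephys"))
  })

  out <- do.call(rbind, rows)
  out$config_hash <- config_hash(config)
  out$seed <- seed
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
  }
  out
}

#' Volume-fraction profile of a synthetic astrocyte
#'
#' Convenience wrapper around [vf_profile()]: places the 45-um profile line
#' halfway between the first two rays (so the leaflet region is branch-free
#' by construction), with the soma and background ROIs derived from the
#' generator's ground truth.
#'
#' @param ast a [gen_astrocyte()] object.
#' @param line_length_um profile line length (default 45 um).
#' @return A `vf_profile` object.
#' @export
vf_from_synthetic <- function(ast, line_length_um = 45) {
  stopifnot(inherits(ast, "synthetic_astrocyte"))
  zmid <- ast$soma_center["z"]
  plane <- ast$image_stack[zmid, , ]
  cy <- ast$soma_center["y"]; cx <- ast$soma_center["x"]
  npx <- nrow(plane)
  yy <- matrix(seq_len(npx), npx, npx)
  xx <- matrix(seq_len(npx), npx, npx, byrow = TRUE)
  r_um <- sqrt((yy - cy)^2 + (xx - cx)^2) * ast$pixel_size
  soma_roi <- r_um <= ast$truth$soma_radius_um - 2
  bg_roi <- r_um > ast$truth$domain_radius_um + 5
  ang <- ast$truth$ray_angles[1L] +
    pi / ast$truth$n_primary_rays          # halfway between rays 1 and 2
  p1 <- c(cy, cx) + (line_length_um / ast$pixel_size) *
    c(sin(ang), cos(ang))
  vf_profile(plane, rbind(c(cy, cx), p1), soma_roi, bg_roi,
             pixel_size = ast$pixel_size)
}
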