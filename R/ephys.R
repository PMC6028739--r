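# Whole-cell and field-potential measurements: K+ current amplitude and
# decay, 5-minus-4 stimulus isolation, fEPSP metrics, Gompertz input-output
# fit, LTP magnitude.

trace_df <- function(x, value_col) {
  if (is.data.frame(x)) {
    tcol <- grep("^time", names(x), value = TRUE)[1L]
    vcol <- setdiff(names(x), tcol)[1L]
    list(t = x[[tcol]], y = x[[vcol]])
  } else stop("expected a data frame (time, value)", call. = FALSE)
}

#' Measure the slow K+ current
#'
#' The current amplitude is read 200 ms after the stimulus — past the fast
#' field-potential and transporter components — and the decay from that point
#' is fitted with a mono-exponential `A exp(-(t - t0)/tau)` to give
#' `tau_decay`. A non-decaying or flat tail flags the measurement invalid.
#'
#' @param trace data frame `(time_s, current)`; baseline-subtracted.
#' @param stim_time stimulus time, seconds.
#' @param fit_span_s length of the fitted window after the 200 ms point
#'   (default 2 s, truncated at the trace end).
#' @param measure_delay_s delay of the measurement point (default 0.2 s).
#' @return `ik_measurement`: list with `ik_amp`, `tau_decay_s`, `valid`,
#'   `fit_window_s`.
#' @export
measure_ik <- function(trace, stim_time, fit_span_s = 2,
                       measure_delay_s = 0.2) {
  tr <- trace_df(trace)
  t0 <- stim_time + measure_delay_s
  if (max(tr$t) < t0 + 0.1)
    stop("trace too short after the measurement point", call. = FALSE)
  ik_amp <- stats::approx(tr$t, tr$y, xout = t0)$y
  sel <- tr$t >= t0 & tr$t <= min(t0 + fit_span_s, max(tr$t))
  ts <- tr$t[sel] - t0
  ys <- tr$y[sel]
  out <- list(ik_amp = ik_amp, tau_decay_s = NA_real_, valid = FALSE,
              fit_window_s = c(t0, t0 + max(ts)))
  if (all(abs(ys) < .Machine$double.eps^0.5) || ik_amp <= 0) {
    class(out) <- "ik_measurement"
    return(out)
  }
  # log-linear start, refined by nls
  pos <- ys > 0
  start_tau <- if (sum(pos) > 2) {
    sl <- unname(coef(stats::lm(log(ys[pos]) ~ ts[pos]))[2L])
    if (is.finite(sl) && sl < 0) -1 / sl else NA_real_
  } else NA_real_
  if (!is.na(start_tau)) {
    # nls refinement; on an exact (zero-residual) exponential nls cannot
    # improve and errors out, in which case the log-linear solution stands
    fit <- try(stats::nls(ys ~ A * exp(-ts / tau),
                          start = list(A = ik_amp, tau = start_tau),
                          control = stats::nls.control(maxiter = 200)),
               silent = TRUE)
    tau <- if (!inherits(fit, "try-error"))
      unname(coef(fit)["tau"]) else start_tau
    if (is.finite(tau) && tau > 0) {
      out$tau_decay_s <- tau
      out$valid <- TRUE
    }
  }
  class(out) <- "ik_measurement"
  out
}

#' Isolate the 5th-stimulus response
#'
#' Pointwise subtraction of the 4-stimulus response from the 5-stimulus
#' response on a shared time base, isolating the current evoked by the 5th
#' stimulus of the train.
#'
#' @param resp_5stim,resp_4stim data frames `(time_s, current)` of equal
#'   length on the same time base.
#' @return Data frame `(time_s, current_pA)` of the difference.
#' @export
isolate_fifth <- function(resp_5stim, resp_4stim) {
  a <- trace_df(resp_5stim); b <- trace_df(resp_4stim)
  if (length(a$y) != length(b$y))
    stop("responses have different lengths", call. = FALSE)
  if (max(abs(a$t - b$t)) > .Machine$double.eps^0.5 * max(abs(a$t), 1))
    stop("responses are not on the same time base", call. = FALSE)
  data.frame(time_s = a$t, current_pA = a$y - b$y)
}

#' fEPSP amplitude, 20-80% rise slope, fiber volley and paired-pulse ratio
#'
#' For each stimulus: the fiber volley (PrV) is the peak negative deflection
#' in its early window; the fEPSP amplitude is baseline-to-peak of the
#' negative deflection in the fEPSP window; the rising-phase slope is
#' measured between the 20% and 80% amplitude crossings (linear
#' interpolation), in mV/ms (magnitude). With two stimuli the paired-pulse
#' ratio is `amp2 / amp1`.
#'
#' @param sweep data frame `(time_s, v_mV)`.
#' @param stim_times stimulus times, seconds (1 or 2).
#' @param prv_window,fepsp_window search windows relative to each stimulus,
#'   seconds (defaults 0-3 ms and 3-45 ms).
#' @param baseline_window seconds before the first stimulus averaged as
#'   baseline (default 10 ms).
#' @return `fepsp_metrics`: list with `amplitude_mV` (per stimulus),
#'   `slope_20_80_mV_per_ms`, `prv_amp_mV`, `ppr`, `flags`.
#' @export
fepsp_metrics <- function(sweep, stim_times, prv_window = c(0, 0.003),
                          fepsp_window = c(0.003, 0.045),
                          baseline_window = 0.01) {
  tr <- trace_df(sweep)
  bl_sel <- tr$t < stim_times[1L] & tr$t >= stim_times[1L] - baseline_window
  baseline <- if (any(bl_sel)) mean(tr$y[bl_sel]) else 0
  y <- tr$y - baseline

  amp <- slope <- prv <- rep(NA_real_, length(stim_times))
  flags <- character(0)
  for (i in seq_along(stim_times)) {
    s <- stim_times[i]
    win_end <- if (i < length(stim_times)) min(s + fepsp_window[2L],
                                               stim_times[i + 1L]) else
                 s + fepsp_window[2L]
    pv <- tr$t >= s + prv_window[1L] & tr$t <= s + prv_window[2L]
    fw <- tr$t > s + fepsp_window[1L] & tr$t <= win_end
    if (!any(fw)) { flags <- c(flags, sprintf("no fEPSP window for stim %d", i)); next }
    prv[i] <- -min(y[pv])
    pk_i <- which(fw)[which.min(y[fw])]
    amp[i] <- -y[pk_i]
    if (amp[i] <= 0) { flags <- c(flags, sprintf("no negative peak for stim %d", i)); next }
    # 20/80% crossings on the rising (downward) phase before the peak
    rise_i <- which(tr$t > s + fepsp_window[1L] & seq_along(y) <= pk_i)
    yy <- -y[rise_i]; ttm <- tr$t[rise_i]
    t_cross <- function(level) {
      below <- which(yy < level)
      if (!length(below)) return(NA_real_)
      j <- max(below)
      if (j >= length(yy)) return(NA_real_)
      ttm[j] + (level - yy[j]) * (ttm[j + 1L] - ttm[j]) / (yy[j + 1L] - yy[j])
    }
    t20 <- t_cross(0.2 * amp[i]); t80 <- t_cross(0.8 * amp[i])
    if (is.na(t20) || is.na(t80) || t80 <= t20) {
      flags <- c(flags, sprintf("20-80%% crossings not found for stim %d", i))
    } else {
      slope[i] <- 0.6 * amp[i] / ((t80 - t20) * 1000)  # mV per ms
    }
  }
  structure(list(amplitude_mV = amp, slope_20_80_mV_per_ms = slope,
                 prv_amp_mV = prv,
                 ppr = if (length(amp) >= 2L) amp[2L] / amp[1L] else NA_real_,
                 flags = flags),
            class = "fepsp_metrics")
}

#' Fit a Gompertz input-output curve
#'
#' Nonlinear least squares for `y = a exp(-exp(-k (x - xc)))` relating fEPSP
#' amplitude to fiber-volley amplitude. Initialization: `a = max(y)`, `xc` at
#' the half-maximum crossing, `k` from the central finite-difference slope
#' (`k = e * max slope / a`). The curve's maximum slope is `a k / e`,
#' attained at `x = xc`.
#'
#' @param io_points data frame with columns `prv` (x) and `fepsp` (y), >= 5
#'   points spanning the sigmoid.
#' @return `gompertz_fit`: list with `a`, `k`, `xc`, `max_slope`, `valid`,
#'   `residuals`.
#' @export
fit_gompertz <- function(io_points) {
  x <- io_points[[1L]]; y <- io_points[[2L]]
  if (length(x) < 5L) stop("need at least 5 input-output points", call. = FALSE)
  if (all(abs(y) < .Machine$double.eps^0.5))
    return(structure(list(a = NA_real_, k = NA_real_, xc = NA_real_,
                          max_slope = NA_real_, valid = FALSE,
                          residuals = y),
                     class = "gompertz_fit"))
  a0 <- max(y)
  xc0 <- x[which.min(abs(y - a0 / 2))]
  dy <- diff(y) / diff(x)
  k0 <- max(exp(1) * max(dy, na.rm = TRUE) / a0, 0.1)
  # warnOnly: on noiseless data the optimizer hits zero residual and cannot
  # meet the relative-offset criterion; the parameters are still exact
  fit <- try(suppressWarnings(
    stats::nls(y ~ a * exp(-exp(-k * (x - xc))),
               start = list(a = a0, k = k0, xc = xc0),
               control = stats::nls.control(maxiter = 500,
                                            warnOnly = TRUE))),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    return(structure(list(a = NA_real_, k = NA_real_, xc = NA_real_,
                          max_slope = NA_real_, valid = FALSE,
                          residuals = rep(NA_real_, length(y))),
                     class = "gompertz_fit"))
  cf <- coef(fit)
  structure(list(a = unname(cf["a"]), k = unname(cf["k"]),
                 xc = unname(cf["xc"]),
                 max_slope = unname(cf["a"] * cf["k"] / exp(1)),
                 valid = is.finite(cf["a"]) && cf["a"] > 0,
                 residuals = stats::residuals(fit)),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf("Gompertz fit: a = %.3f, k = %.3f, xc = %.3f; max slope ak/e = %.4f%s\n",
              x$a, x$k, x$xc, x$max_slope,
              if (!x$valid) " [INVALID]" else ""))
  invisible(x)
}

#' LTP magnitude from a slope time series
#'
#' Averages the fEPSP rising slope over the baseline window (20 min before
#' induction) and over a post-induction window (47-60 min after, by default)
#' and reports their ratio.
#'
#' @param slope_timeseries data frame `(time_min, slope)`; times relative to
#'   the recording, `hfs_time` marking induction.
#' @param hfs_time induction time, minutes (default 0).
#' @param window_min post-induction averaging window relative to induction,
#'   minutes (default `c(47, 60)`).
#' @param baseline_min baseline window length before induction (default 20).
#' @return `ltp_result`: list with `baseline_mean_slope`,
#'   `potentiated_mean_slope`, `magnitude`, `window_min`.
#' @export
ltp_magnitude <- function(slope_timeseries, hfs_time = 0,
                          window_min = c(47, 60), baseline_min = 20) {
  t <- slope_timeseries[[1L]]; s <- slope_timeseries[[2L]]
  bl <- t >= hfs_time - baseline_min & t < hfs_time
  po <- t >= hfs_time + window_min[1L] & t <= hfs_time + window_min[2L]
  if (!any(bl)) stop("no baseline samples in the 20 min before induction",
                     call. = FALSE)
  if (!any(po)) stop("no samples in the post-induction window", call. = FALSE)
  b <- mean(s[bl]); p <- mean(s[po])
  structure(list(baseline_mean_slope = b, potentiated_mean_slope = p,
                 magnitude = p / b, window_min = window_min),
            class = "ltp_result")
}

#' @export
print.ltp_result <- function(x, ...) {
  cat(sprintf("LTP magnitude %.3f (baseline %.3f -> %.3f at %g-%g min)\n",
              x$magnitude, x$baseline_mean_slope, x$potentiated_mean_slope,
              x$window_min[1L], x$window_min[2L]))
  invisible(x)
}
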