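# Synthetic dye-coupling records and electrophysiology trace sets.

#' Generate synthetic dye-coupling records
#'
#' Somatic fluorescence of gap-junction-coupled cells decaying exponentially
#' with 3D distance from the patched soma: `I(d) = I0 exp(-d / c_lambda)`,
#' corrupted by multiplicative lognormal noise. Intensities are normalized to
#' the patched soma and clipped to (0, 1].
#'
#' @param c_lambda_um coupling length constant, micrometers (> 0).
#' @param n number of coupled cells (>= 3).
#' @param noise_sd sd of the lognormal noise on the log scale (0 = noiseless).
#' @param seed integer seed.
#' @param d_range sampling range of distances, micrometers (default 5-100).
#' @param i0 normalized intensity extrapolated to zero distance (default 0.8).
#' @return `synthetic_coupling_set`: list with `records` (data frame
#'   `distance_um`, `normalized_intensity`), `c_lambda_true`, `i0_true`,
#'   `noise_sd`.
#' @export
gen_coupling_set <- function(c_lambda_um, n = 50, noise_sd = 0.1, seed = 1,
                             d_range = c(5, 100), i0 = 0.8) {
  if (c_lambda_um <= 0) stop("c_lambda_um must be > 0", call. = FALSE)
  n <- as.integer(n)
  if (n < 3L) stop("n must be >= 3", call. = FALSE)
  with_seed(seed, {
    d <- sort(stats::runif(n, d_range[1L], d_range[2L]))
    I <- i0 * exp(-d / c_lambda_um)
    if (noise_sd > 0) I <- I * stats::rlnorm(n, 0, noise_sd)
    I <- pmin(pmax(I, .Machine$double.eps), 1)
    structure(list(
      records = data.frame(distance_um = d, normalized_intensity = I),
      c_lambda_true = c_lambda_um, i0_true = i0, noise_sd = noise_sd
    ), class = "synthetic_coupling_set")
  })
}

#' Generate synthetic electrophysiology traces
#'
#' Builds every trace family the electrophysiology metrics consume, with the
#' exact ground truth attached:
#' \itemize{
#'   \item a synaptically evoked K+ current: a fast contaminating transient
#'     (gone within 100 ms of the stimulus) plus a slow mono-exponential
#'     component `A exp(-t/tau)`;
#'   \item responses to 4 and 5 stimuli at 50 Hz, whose pointwise difference
#'     isolates the 5th-stimulus K+ current;
#'   \item a paired-pulse field-potential sweep (negative-going fEPSPs with a
#'     fast fiber-volley spike, 50 ms interstimulus interval);
#'   \item input-output samples on a Gompertz curve
#'     `y = a exp(-exp(-k (x - xc)))`;
#'   \item a per-minute fEPSP slope time series around high-frequency
#'     stimulation at t = 0, with post-induction level
#'     `ltp_late + (ltp_early - ltp_late) exp(-t / ltp_decay_min)` times
#'     baseline.
#' }
#'
#' @param tau_s slow K+ current decay constant, seconds (> 0; default 2.5).
#' @param ik_amp_pA amplitude of the slow component at the stimulus (default
#'   30 pA).
#' @param ik5_ratio planted `I_K(5)/I_K(1)` amplitude ratio measured 200 ms
#'   post-stimulus (default 0.72).
#' @param tau5_ratio planted `tau(5)/tau(1)` ratio (default 1.45).
#' @param gompertz named vector `c(a, k, xc)` (default `c(3.32, 6, 0.5)`).
#' @param ltp_early,ltp_late post-induction/baseline slope ratio immediately
#'   after induction and at late times (defaults 1.73 and 1.73: sustained
#'   potentiation; set `ltp_early > ltp_late` for decaying potentiation).
#' @param ltp_decay_min decay constant of the potentiation transient, minutes
#'   (default 20).
#' @param fepsp_amp1_mV,ppr,prv_amp_mV paired-pulse fEPSP parameters
#'   (defaults 0.8 mV, 1.3, 0.3 mV).
#' @param noise_sd additive Gaussian noise sd relative to each trace's
#'   amplitude scale (default 0 = noiseless).
#' @param dt_s sample interval of the current/voltage traces (default 2e-4 s,
#'   i.e. 5 kHz).
#' @param io_noise_sd sd of the Gompertz sample noise as a fraction of `a`
#'   (default `noise_sd`).
#' @param seed integer seed.
#' @return `synthetic_trace_set`: list of trace data frames (`ik1`, `resp4`,
#'   `resp5`, `fepsp`, `io_points`, `ltp_series`), `stim_times`, and `truth`.
#' @export
gen_traces <- function(tau_s = 2.5, ik_amp_pA = 30, ik5_ratio = 0.72,
                       tau5_ratio = 1.45, gompertz = c(a = 3.32, k = 6,
                                                       xc = 0.5),
                       ltp_early = 1.73, ltp_late = ltp_early,
                       ltp_decay_min = 20, fepsp_amp1_mV = 0.8, ppr = 1.3,
                       prv_amp_mV = 0.3, noise_sd = 0, dt_s = 2e-4,
                       io_noise_sd = noise_sd, seed = 1) {
  if (tau_s <= 0) stop("tau_s must be > 0", call. = FALSE)
  with_seed(seed, {
    stim <- 0.5
    t <- seq(0, stim + 4 * tau_s * max(1, tau5_ratio), by = dt_s)

    slow <- function(amp, tau, t0)
      ifelse(t >= t0, amp * exp(-(t - t0) / tau), 0)
    fast <- function(amp, t0)  # contaminant, extinct < 100 ms after t0
      ifelse(t >= t0 & t < t0 + 0.1, amp * exp(-(t - t0) / 0.015), 0)

    ik1 <- slow(ik_amp_pA, tau_s, stim) + fast(2 * ik_amp_pA, stim)

    # 4- and 5-stimulus composites: 50 Hz train starting at `stim`
    tau5 <- tau_s * tau5_ratio
    # amplitude of the 5th-stimulus slow component chosen so that the
    # 200 ms measurements give exactly ik5_ratio
    t5 <- stim + 4 * 0.02
    amp5 <- ik5_ratio * ik_amp_pA * exp(-0.2 / tau_s) / exp(-0.2 / tau5)
    resp4 <- Reduce(`+`, lapply(0:3, function(i)
      slow(ik_amp_pA * 0.85^i, tau_s, stim + i * 0.02) +
        fast(2 * ik_amp_pA, stim + i * 0.02)))
    resp5 <- resp4 + slow(amp5, tau5, t5) + fast(2 * ik_amp_pA, t5)

    if (noise_sd > 0) {
      ik1 <- ik1 + stats::rnorm(length(t), 0, noise_sd * ik_amp_pA)
      resp4 <- resp4 + stats::rnorm(length(t), 0, noise_sd * ik_amp_pA)
      resp5 <- resp5 + stats::rnorm(length(t), 0, noise_sd * ik_amp_pA)
    }

    # paired-pulse field sweep
    tf <- seq(0, 0.2, by = dt_s)
    fepsp_stims <- c(0.02, 0.07)
    # fEPSP onset follows the fiber volley after a ~4 ms synaptic delay
    alpha_fun <- function(amp, t0, tau_r = 0.003, delay = 0.004)
      ifelse(tf >= t0 + delay,
             -amp * (tf - t0 - delay) / tau_r *
               exp(1 - (tf - t0 - delay) / tau_r), 0)
    volley <- function(amp, t0)
      -amp * exp(-((tf - (t0 + 0.0012)) / 4e-4)^2)
    sweep <- alpha_fun(fepsp_amp1_mV, fepsp_stims[1L]) +
      alpha_fun(fepsp_amp1_mV * ppr, fepsp_stims[2L]) +
      volley(prv_amp_mV, fepsp_stims[1L]) + volley(prv_amp_mV, fepsp_stims[2L])
    if (noise_sd > 0)
      sweep <- sweep + stats::rnorm(length(tf), 0, noise_sd * fepsp_amp1_mV)

    # input-output samples on the Gompertz curve
    gp <- as.numeric(gompertz); names(gp) <- c("a", "k", "xc")
    x_io <- seq(0.05, gp["xc"] * 2 + 0.5, length.out = 12)
    y_io <- gp["a"] * exp(-exp(-gp["k"] * (x_io - gp["xc"])))
    if (io_noise_sd > 0)
      y_io <- y_io + stats::rnorm(length(x_io), 0, io_noise_sd * gp["a"])

    # per-minute slope series, HFS at t = 0
    tl <- seq(-20, 60, by = 1)
    ratio <- ifelse(tl < 0, 1,
                    ltp_late + (ltp_early - ltp_late) *
                      exp(-pmax(tl, 0) / ltp_decay_min))
    slope <- ratio
    if (noise_sd > 0)
      slope <- slope + stats::rnorm(length(tl), 0, noise_sd)

    structure(list(
      ik1 = data.frame(time_s = t, current_pA = ik1),
      resp4 = data.frame(time_s = t, current_pA = resp4),
      resp5 = data.frame(time_s = t, current_pA = resp5),
      fepsp = data.frame(time_s = tf, v_mV = sweep),
      io_points = data.frame(prv = x_io, fepsp = y_io),
      ltp_series = data.frame(time_min = tl, slope = slope),
      stim_times = list(ik = stim, train = stim + 0.02 * 0:4,
                        fepsp = fepsp_stims, hfs_min = 0),
      truth = list(tau_s = tau_s, tau5_s = tau5, ik_amp_pA = ik_amp_pA,
                   ik5_ratio = ik5_ratio, tau5_ratio = tau5_ratio,
                   amp5_pA = amp5, gompertz = gp,
                   max_slope = unname(gp["a"] * gp["k"] / exp(1)),
                   ltp_early = ltp_early, ltp_late = ltp_late,
                   ltp_decay_min = ltp_decay_min,
                   fepsp_amp1_mV = fepsp_amp1_mV, ppr = ppr,
                   prv_amp_mV = prv_amp_mV)
    ), class = "synthetic_trace_set")
  })
}
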