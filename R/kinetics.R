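#' Construct a current sweep trace
#'
#' A uniformly sampled current recording with stimulus metadata and analysis
#' windows. Inward currents are negative by convention; figure-facing code
#' may take magnitudes, the data model keeps the sign.
#'
#' @param time_ms Uniform time grid (ms).
#' @param current_pA Current samples (pA), same length as `time_ms`.
#' @param stim_onset_ms,stim_duration_ms Stimulus timing (ms).
#' @param holding_mV Holding potential (mV), or `NA`.
#' @param baseline_window Two-element ms interval preceding the stimulus used
#'   for baseline statistics.
#' @param response_window Two-element ms interval searched for the response.
#' @param truth Optional generator ground truth (kept by the simulator).
#' @return A `sweep_trace` list.
#' @export
sweep_trace <- function(time_ms, current_pA, stim_onset_ms,
                        stim_duration_ms = 0.5, holding_mV = NA_real_,
                        baseline_window = NULL, response_window = NULL,
                        truth = NULL) {
  if (length(time_ms) != length(current_pA)) {
    stop("time_ms and current_pA must have equal length")
  }
  if (length(time_ms) < 3) stop("a trace needs at least 3 samples")
  dt <- diff(time_ms)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1])) {
    stop("time_ms must be a uniform grid")
  }
  if (is.null(baseline_window)) baseline_window <- c(time_ms[1], stim_onset_ms)
  if (is.null(response_window)) {
    response_window <- c(stim_onset_ms + stim_duration_ms,
                         time_ms[length(time_ms)])
  }
  check_window <- function(w, nm) {
    if (length(w) != 2 || w[1] >= w[2] || w[1] < time_ms[1] ||
        w[2] > time_ms[length(time_ms)] + 1e-9) {
      stop(sprintf("%s must be an increasing interval inside the trace", nm))
    }
  }
  check_window(baseline_window, "baseline_window")
  check_window(response_window, "response_window")
  if (baseline_window[2] > stim_onset_ms + 1e-9) {
    stop("baseline_window must precede the stimulus")
  }
  structure(
    list(time_ms = time_ms, current_pA = current_pA,
         stim_onset_ms = stim_onset_ms, stim_duration_ms = stim_duration_ms,
         holding_mV = holding_mV, baseline_window = baseline_window,
         response_window = response_window,
         sample_period_ms = mean(dt), truth = truth),
    class = "sweep_trace"
  )
}

window_idx <- function(trace, window) {
  which(trace$time_ms >= window[1] - 1e-9 & trace$time_ms <= window[2] + 1e-9)
}

# Centred moving average with shrinking windows at the edges; width forced
# odd. Stands in for the trial averaging applied to evoked responses before
# kinetic measurements.
boxcar <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

smooth_trace <- function(trace, smooth_ms) {
  if (smooth_ms <= 0) return(trace)
  width <- round(smooth_ms / trace$sample_period_ms)
  trace$current_pA <- boxcar(trace$current_pA, width)
  trace
}

#' Baseline mean and standard deviation of a sweep
#'
#' @param trace A [sweep_trace()].
#' @return List with `mean_pA` and `sd_pA` over the baseline window.
#' @export
baseline_stats <- function(trace) {
  stopifnot(inherits(trace, "sweep_trace"))
  idx <- window_idx(trace, trace$baseline_window)
  if (length(idx) < 2) stop("baseline window contains fewer than 2 samples")
  x <- trace$current_pA[idx]
  list(mean_pA = mean(x), sd_pA = stats::sd(x))
}

#' Signed peak response amplitude
#'
#' Extremum of the current in the response window minus the baseline mean;
#' the sign is preserved (inward currents negative).
#'
#' @param trace A [sweep_trace()].
#' @return Signed amplitude in pA.
#' @export
response_amplitude <- function(trace) {
  stopifnot(inherits(trace, "sweep_trace"))
  base <- baseline_stats(trace)
  idx <- window_idx(trace, trace$response_window)
  dev <- trace$current_pA[idx] - base$mean_pA
  dev[which.max(abs(dev))]
}

# Peak sample index (within the full trace) of the response deflection.
response_peak_index <- function(trace, base) {
  idx <- window_idx(trace, trace$response_window)
  dev <- trace$current_pA[idx] - base$mean_pA
  idx[which.max(abs(dev))]
}

require_response <- function(amp, base, k_sd) {
  if (abs(amp) <= k_sd * base$sd_pA) {
    stop("non-responder: no response exceeding ", k_sd,
         " x baseline SD detected", call. = FALSE)
  }
}

#' 10-90% rise time of an evoked response
#'
#' Finds the peak deflection in the response window and measures the time
#' between the first crossings of 10% and 90% of the peak amplitude on the
#' rising phase, with linear interpolation between samples.
#'
#' @param trace A [sweep_trace()].
#' @param k_sd Response-detection threshold in baseline SDs (default 3).
#' @param smooth_ms Width (ms) of a centred moving average applied before
#'   measurement (default 1), standing in for the averaging of evoked
#'   responses; 0 disables smoothing.
#' @return Rise time in ms.
#' @export
rise_time_10_90 <- function(trace, k_sd = 3, smooth_ms = 1) {
  stopifnot(inherits(trace, "sweep_trace"))
  trace <- smooth_trace(trace, smooth_ms)
  base <- baseline_stats(trace)
  amp <- response_amplitude(trace)
  require_response(amp, base, k_sd)
  pk <- response_peak_index(trace, base)
  start <- window_idx(trace, trace$response_window)[1]
  seg <- seq(start, pk)
  # deflection in the direction of the peak, rising towards |amp|
  d <- sign(amp) * (trace$current_pA[seg] - base$mean_pA)
  t <- trace$time_ms[seg]
  cross_time <- function(level) {
    i <- which(d >= level)[1]
    if (is.na(i)) stop("response never reaches the requested level")
    if (i == 1) return(t[1])
    # linear interpolation between samples i-1 and i
    t[i - 1] + (level - d[i - 1]) / (d[i] - d[i - 1]) * (t[i] - t[i - 1])
  }
  cross_time(0.9 * abs(amp)) - cross_time(0.1 * abs(amp))
}

#' Monoexponential decay fit of an evoked response
#'
#' Least-squares fit of `I(t) = baseline + A * exp(-(t - t_peak)/tau)` from
#' the response peak to the end of the response window, initialized by a
#' log-linear regression on the decaying deflection.
#'
#' @param trace A [sweep_trace()].
#' @param k_sd Response-detection threshold in baseline SDs (default 3).
#' @return List with `tau_ms`, `amplitude_pA` (fitted A, signed), and `rmse`.
#' @export
fit_monoexp_decay <- function(trace, k_sd = 3) {
  stopifnot(inherits(trace, "sweep_trace"))
  base <- baseline_stats(trace)
  amp <- response_amplitude(trace)
  require_response(amp, base, k_sd)
  pk <- response_peak_index(trace, base)
  stop_i <- window_idx(trace, trace$response_window)
  stop_i <- stop_i[length(stop_i)]
  seg <- seq(pk, stop_i)
  if (length(seg) < 10) stop("too few samples after the peak to fit a decay")
  t <- trace$time_ms[seg] - trace$time_ms[pk]
  d <- sign(amp) * (trace$current_pA[seg] - base$mean_pA)
  window_len <- t[length(t)]
  # log-linear initialization on the positive part of the deflection
  pos <- d > 0
  if (sum(pos) < 10) stop("decay fit failed: deflection not sustained")
  init <- stats::lm(log(d[pos]) ~ t[pos])
  slope <- stats::coef(init)[2]
  tau0 <- if (is.finite(slope) && slope < 0) -1 / slope else window_len
  fit <- tryCatch(
    minpack.lm::nlsLM(
      d ~ A * exp(-t / tau),
      start = list(A = max(d), tau = min(max(tau0, 1e-3), 10 * window_len)),
      lower = c(A = 0, tau = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("decay fit failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  est <- stats::coef(fit)
  tau <- unname(est["tau"])
  if (!is.finite(tau) || tau <= 0 || tau > 10 * window_len) {
    stop("decay fit failed: tau outside (0, 10 x fit window]", call. = FALSE)
  }
  if (unname(est["A"]) <= k_sd * base$sd_pA) {
    stop("decay fit failed: fitted amplitude below the detection threshold",
         call. = FALSE)
  }
  list(tau_ms = tau, amplitude_pA = sign(amp) * unname(est["A"]),
       rmse = sqrt(mean(stats::resid(fit)^2)))
}

#' Synaptic latency from stimulus end to response onset
#'
#' Operationalizes the "discernible beginning of the response": the response
#' is detected at the first sample after the end of the stimulus whose
#' deflection from baseline exceeds `k_sd` baseline SDs for `hold_samples`
#' consecutive samples, then the onset is refined by walking back from the
#' detection point to the last sample at or below the baseline (in the
#' direction of the response). The backtrack removes the threshold-height
#' bias of plain crossing detection and reduces, on a noiseless trace, to
#' the first sample deviating from baseline.
#'
#' @param trace A [sweep_trace()].
#' @param k_sd Threshold in baseline SDs (default 3).
#' @param hold_samples Consecutive supra-threshold samples required
#'   (default 5).
#' @return Latency in ms.
#' @export
synaptic_latency <- function(trace, k_sd = 3, hold_samples = 5L) {
  stopifnot(inherits(trace, "sweep_trace"))
  hold_samples <- assert_count(hold_samples, "hold_samples")
  base <- baseline_stats(trace)
  stim_end <- trace$stim_onset_ms + trace$stim_duration_ms
  idx <- which(trace$time_ms >= stim_end - 1e-9)
  if (!length(idx)) stop("no samples after the stimulus end")
  dev <- trace$current_pA[idx] - base$mean_pA
  above <- abs(dev) > k_sd * base$sd_pA
  run <- 0L
  detect_i <- NA_integer_
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= hold_samples) {
      detect_i <- i - hold_samples + 1L
      break
    }
  }
  if (is.na(detect_i)) {
    stop("non-responder: threshold never crossed for ", hold_samples,
         " consecutive samples", call. = FALSE)
  }
  # backtrack: last pre-detection sample at/below baseline in the response
  # direction; the onset is the sample after it
  s <- sign(dev[detect_i])
  onset_i <- detect_i
  while (onset_i > 1L && s * dev[onset_i - 1L] > 0) onset_i <- onset_i - 1L
  trace$time_ms[idx[onset_i]] - stim_end
}

#' Full kinetics summary of an evoked response
#'
#' Convenience wrapper returning amplitude, 10-90% rise time, monoexponential
#' decay constant, latency and baseline statistics in one object.
#'
#' @param trace A [sweep_trace()].
#' @param k_sd,hold_samples Detection parameters, see [synaptic_latency()].
#' @return A `kinetics_result` list.
#' @export
kinetics_summary <- function(trace, k_sd = 3, hold_samples = 5L) {
  base <- baseline_stats(trace)
  decay <- fit_monoexp_decay(trace, k_sd)
  structure(
    list(
      amplitude_pA = response_amplitude(trace),
      rise_time_ms = rise_time_10_90(trace, k_sd),
      decay_tau_ms = decay$tau_ms,
      latency_ms = synaptic_latency(trace, k_sd, hold_samples),
      baseline_mean_pA = base$mean_pA,
      baseline_sd_pA = base$sd_pA,
      fit_rmse = decay$rmse
    ),
    class = "kinetics_result"
  )
}
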