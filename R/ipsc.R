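#' A current recording trace
#'
#' @param current current samples in pA (inward currents negative).
#' @param sampling_rate sampling rate in Hz (default 10000).
#' @param temperature optional temperature label (e.g. "22C").
#' @param condition optional condition label (e.g. "pre", "drug", "wash").
#' @return An object of class `recording_trace`.
#' @export
recording_trace <- function(current, sampling_rate = 10000,
                            temperature = NA_character_,
                            condition = NA_character_) {
  if (any(!is.finite(current))) stop("current must be finite")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  structure(list(current = as.numeric(current),
                 sampling_rate = sampling_rate,
                 temperature = temperature, condition = condition),
            class = "recording_trace")
}

#' @exportS3Method base::print
print.recording_trace <- function(x, ...) {
  cat("Recording trace: ", length(x$current), " samples at ",
      x$sampling_rate, " Hz (", length(x$current) / x$sampling_rate,
      " s)\n", sep = "")
  invisible(x)
}

#' Synaptic event template (difference of exponentials)
#'
#' Unit-peak waveform `(exp(-t/tau_decay) - exp(-t/tau_rise))`, normalized,
#' used both by the sliding-template detector and the synthetic trace
#' generator.
#'
#' @param rise_tau,decay_tau time constants in ms (`decay_tau > rise_tau`).
#' @param length_ms template length in ms (default `rise_tau + 4 *
#'   decay_tau` capped at 100 ms).
#' @param sampling_rate Hz.
#' @return Numeric vector with unit peak.
#' @export
event_template <- function(rise_tau, decay_tau, length_ms = NULL,
                           sampling_rate = 10000) {
  if (!(decay_tau > rise_tau) || rise_tau <= 0)
    stop("need decay_tau > rise_tau > 0")
  if (is.null(length_ms)) length_ms <- min(rise_tau + 4 * decay_tau, 100)
  t <- seq(0, length_ms, by = 1000 / sampling_rate)
  y <- exp(-t / decay_tau) - exp(-t / rise_tau)
  y / max(y)
}

#' Detect synaptic events by sliding scaled-template matching
#'
#' Slides a stereotyped event template across the trace; at each offset the
#' template is optimally scaled and offset by least squares and the
#' detection criterion is the fitted scale divided by its standard error
#' (the Clements-Bekkers statistic). Local maxima of the criterion above
#' the threshold are detections; detections closer together than half a
#' template length are merged, keeping the larger criterion. Deterministic
#' for fixed inputs.
#'
#' @param trace a [recording_trace()].
#' @param template_rise,template_decay template kinetics in ms.
#' @param threshold detection criterion threshold (default 3.5).
#' @param direction `"negative"` (inward currents, default) or
#'   `"positive"`.
#' @param template_length_ms optional template length override.
#' @param measure also measure amplitude, 10-90\% rise and decay tau for
#'   each detection (default TRUE).
#' @param baseline_ms pre-onset window used as baseline (default 5 ms).
#' @return data.frame with one row per event: `onset_index`, `onset_time`
#'   (s), `criterion`, and if `measure` is TRUE `amplitude` (pA),
#'   `rise_10_90` (ms), `decay_tau` (ms), `r_squared`, `accepted`.
#' @export
detect_events <- function(trace, template_rise = 1, template_decay = 15,
                          threshold = 3.5,
                          direction = c("negative", "positive"),
                          template_length_ms = NULL, measure = TRUE,
                          baseline_ms = 5) {
  stopifnot(inherits(trace, "recording_trace"))
  direction <- match.arg(direction)
  if (threshold <= 0) stop("threshold must be > 0")
  fs <- trace$sampling_rate
  y <- trace$current
  if (direction == "negative") y <- -y
  tpl <- event_template(template_rise, template_decay,
                        length_ms = template_length_ms,
                        sampling_rate = fs)
  m <- length(tpl)
  n <- length(y)
  empty <- data.frame(onset_index = integer(), onset_time = numeric(),
                      criterion = numeric())
  if (m >= n) stop("template must be shorter than the trace")
  if (stats::sd(y) == 0) return(empty)

  # running sums over all windows of length m
  cs <- cumsum(c(0, y)); cs2 <- cumsum(c(0, y^2))
  nw <- n - m + 1
  Sy <- cs[(m + 1):(n + 1)] - cs[1:nw]
  Sy2 <- cs2[(m + 1):(n + 1)] - cs2[1:nw]
  # sliding dot product with the template via FFT
  # (convolve type "filter" computes sum(y[k..k+m-1] * tpl) at offset k)
  Sty <- stats::convolve(y, tpl, type = "filter")
  St <- sum(tpl); St2 <- sum(tpl^2)
  denom <- St2 - St^2 / m
  scale <- (Sty - St * Sy / m) / denom
  sse <- pmax(Sy2 - Sy^2 / m - scale^2 * denom, 0)
  se <- sqrt(sse / (m - 2) / denom)
  crit <- ifelse(se > 0, scale / se, 0)

  above <- which(crit > threshold)
  if (!length(above)) return(empty)
  # local maxima of the criterion among super-threshold samples
  is_peak <- above[crit[above] >= c(-Inf, crit[above[-length(above)]]) &
                     crit[above] > c(crit[above[-1]], -Inf)]
  # also require a strict local max within +-2 samples to drop plateaus
  keep <- vapply(is_peak, function(i) {
    lo <- max(1, i - 2); hi <- min(nw, i + 2)
    crit[i] >= max(crit[lo:hi])
  }, logical(1))
  peaks <- is_peak[keep]
  if (!length(peaks)) return(empty)
  # merge detections closer than one template length, keeping the larger
  # criterion: the criterion stays elevated along an event's decay tail,
  # so a shorter merge window splits single events
  min_sep <- m
  peaks <- peaks[order(crit[peaks], decreasing = TRUE)]
  chosen <- integer(0)
  for (p in peaks)
    if (!length(chosen) || all(abs(chosen - p) >= min_sep))
      chosen <- c(chosen, p)
  chosen <- sort(chosen)

  out <- data.frame(onset_index = chosen,
                    onset_time = (chosen - 1) / fs,
                    criterion = crit[chosen])
  if (measure && nrow(out)) {
    met <- lapply(chosen, function(i)
      measure_event(y, i, fs, span = m, baseline_ms = baseline_ms))
    met <- do.call(rbind, met)
    out <- cbind(out, met)
    out$amplitude <- if (direction == "negative") -out$amplitude
      else out$amplitude
  }
  out
}

# peak, 10-90% rise and decay tau of one detected (positive-going) event
measure_event <- function(y, onset, fs, span, baseline_ms) {
  nb <- max(1, round(baseline_ms * fs / 1000))
  b0 <- max(1, onset - nb)
  baseline <- mean(y[b0:max(b0, onset - 1)])
  win_end <- min(length(y), onset + span - 1)
  seg <- y[onset:win_end]
  ipk <- which.max(seg)
  amp <- seg[ipk] - baseline
  rise <- tryCatch(
    rise_time_10_90(c(baseline, seg[seq_len(ipk)]), dt = 1000 / fs,
                    baseline = baseline),
    error = function(e) NA_real_)
  dec <- seg[ipk:length(seg)]
  fit <- if (length(dec) >= 10)
    fit_decay(dec, dt = 1000 / fs, mode = "mono")
  else list(tau = NA_real_, r_squared = NA_real_, ok = FALSE)
  data.frame(amplitude = amp, rise_10_90 = rise, decay_tau = fit$tau,
             r_squared = fit$r_squared,
             accepted = isTRUE(fit$ok) && is.finite(fit$r_squared) &&
               fit$r_squared >= 0.5)
}

#' Ten-to-ninety percent rise time
#'
#' Rise time between 10\% and 90\% of the baseline-to-peak amplitude,
#' computed by linear interpolation between the samples bracketing each
#' threshold. Invariant under amplitude scaling and baseline offset.
#'
#' @param window numeric vector from baseline through the peak (either
#'   polarity).
#' @param dt sample interval in ms.
#' @param baseline baseline level; default: first sample of the window.
#' @return Rise time in ms.
#' @export
rise_time_10_90 <- function(window, dt, baseline = NULL) {
  if (length(window) < 2) stop("window too short")
  if (is.null(baseline)) baseline <- window[1]
  y <- window - baseline
  ipk <- which.max(abs(y))
  if (ipk == 1) stop("peak at first sample: rise time undefined")
  y <- y / y[ipk]                      # normalized 0..1 toward the peak
  y <- y[seq_len(ipk)]
  cross <- function(level) {
    i90 <- which(y >= level)[1]
    if (i90 == 1) return(0)
    i0 <- i90 - 1
    (i0 - 1 + (level - y[i0]) / (y[i90] - y[i0])) * dt
  }
  t10 <- cross(0.1); t90 <- cross(0.9)
  t90 - t10
}

#' Fit an exponential decay to an event or averaged waveform
#'
#' Nonlinear least squares by Nelder-Mead simplex on the decay window
#' (which must start at the peak): mono-exponential
#' `A exp(-t/tau) + C` or bi-exponential
#' `A1 exp(-t/tau1) + A2 exp(-t/tau2) + C`, the latter reported with its
#' amplitude-weighted time constant. Time constants are optimized on a log
#' scale so they stay positive.
#'
#' @param window numeric decay window starting at the peak (>= 10
#'   samples), either polarity.
#' @param dt sample interval in ms.
#' @param mode `"mono"` or `"bi"`.
#' @param offset fit an additive baseline offset `C`? Keep `TRUE` for
#'   recordings (unknown baseline); set `FALSE` for quantities known to
#'   decay to zero, such as simulated open-receptor counts, where a free
#'   offset trades against the time constant on noisy tails.
#' @return List with `tau` (ms; amplitude-weighted for `bi`), `r_squared`,
#'   `ok` (fit usable), `pars`, and for `bi` also `tau1`, `tau2`,
#'   `fractions`.
#' @export
fit_decay <- function(window, dt, mode = c("mono", "bi"), offset = TRUE) {
  mode <- match.arg(mode)
  y <- as.numeric(window)
  if (length(y) < 10) stop("decay window needs >= 10 samples")
  t <- (seq_along(y) - 1) * dt
  sgn <- if (abs(min(y)) > abs(max(y))) -1 else 1
  y <- sgn * y                       # work on a positive-going decay
  a0 <- y[1] - y[length(y)]
  c0 <- y[length(y)]
  fail <- list(tau = NA_real_, r_squared = NA_real_, ok = FALSE,
               pars = NULL, mode = mode)
  if (!(a0 > 0)) return(fail)        # non-decaying window
  i63 <- which(y - c0 <= a0 * exp(-1))[1]
  tau0 <- if (is.na(i63) || i63 < 2) max(t) / 3 else t[i63]
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(fail)

  if (mode == "mono") {
    obj <- if (offset) function(p) {
      f <- p[1] * exp(-t / exp(p[2])) + p[3]
      sum((y - f)^2)
    } else function(p) {
      f <- p[1] * exp(-t / exp(p[2]))
      sum((y - f)^2)
    }
    start <- if (offset) c(a0, log(tau0), c0) else c(y[1], log(tau0))
    op <- stats::optim(start, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    tau <- exp(op$par[2])
    r2 <- 1 - op$value / sst
    cpar <- if (offset) sgn * op$par[3] else 0
    list(tau = tau, r_squared = r2, ok = op$par[1] > 0 && is.finite(tau),
         pars = c(A = sgn * op$par[1], tau = tau, C = cpar),
         mode = mode)
  } else {
    obj <- function(p) {
      f <- p[1] * exp(-t / exp(p[2])) + p[3] * exp(-t / exp(p[4])) + p[5]
      sum((y - f)^2)
    }
    st <- c(0.7 * a0, log(tau0 * 2), 0.3 * a0, log(tau0 / 3), c0)
    op <- stats::optim(st, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    a <- op$par[c(1, 3)]
    taus <- exp(op$par[c(2, 4)])
    o <- order(taus)
    taus <- taus[o]; a <- a[o]
    wtau <- sum(a * taus) / sum(a)
    r2 <- 1 - op$value / sst
    list(tau = wtau, tau1 = taus[1], tau2 = taus[2],
         fractions = a / sum(a), r_squared = r2,
         ok = all(is.finite(taus)) && sum(a) > 0,
         pars = c(A1 = sgn * a[1], tau1 = taus[1], A2 = sgn * a[2],
                  tau2 = taus[2], C = sgn * op$par[5]),
         mode = mode)
  }
}

#' Temperature coefficient Q10 of a decay time constant
#'
#' Fold-change of the decay rate per 10 degrees Celsius:
#' `(tau_cold / tau_warm) ^ (10 / delta_T)`. Values above ~2 indicate
#' kinetics limited by protein conformational changes rather than by
#' aqueous diffusion.
#'
#' @param tau_cold,tau_warm decay time constants (ms) at the lower and
#'   higher temperature.
#' @param delta_T temperature difference in degrees Celsius (default 10).
#' @return Dimensionless Q10.
#' @export
q10 <- function(tau_cold, tau_warm, delta_T = 10) {
  if (any(c(tau_cold, tau_warm) <= 0)) stop("time constants must be > 0")
  if (delta_T == 0) stop("delta_T must be nonzero")
  (tau_cold / tau_warm)^(10 / delta_T)
}

#' Drug effect as percent of control
#'
#' Normalizes a drug-phase mean to the average of the pre-drug and wash
#' phases (controlling for run-down or run-up):
#' `100 * drug / mean(pre, wash)`. With no wash value the pre-drug mean
#' alone is the reference and the result carries `wash_used = FALSE`.
#'
#' @param pre_mean,drug_mean pre-drug and drug-phase means (> 0).
#' @param wash_mean wash-phase mean, or `NULL` if unavailable.
#' @return Percent of control (numeric) with attribute `wash_used`.
#' @export
percent_of_control <- function(pre_mean, drug_mean, wash_mean = NULL) {
  if (any(c(pre_mean, drug_mean, wash_mean) <= 0))
    stop("phase means must be > 0")
  if (is.null(wash_mean)) {
    warning("no wash phase: normalizing to pre-drug mean only")
    ref <- pre_mean
    used <- FALSE
  } else {
    ref <- mean(c(pre_mean, wash_mean))
    used <- TRUE
  }
  structure(100 * drug_mean / ref, wash_used = used)
}

#' Corner frequency of the recording RC filter
#'
#' `f_c = 1 / (2 pi R C)` for the series resistance and cell capacitance
#' acting as a low-pass filter on the recorded current.
#'
#' @param series_resistance in megaohm.
#' @param capacitance in picofarad.
#' @return Frequency in Hz.
#' @export
rc_corner_frequency <- function(series_resistance, capacitance) {
  if (any(c(series_resistance, capacitance) <= 0))
    stop("resistance and capacitance must be > 0")
  1 / (2 * pi * series_resistance * 1e6 * capacitance * 1e-12)
}

#' Per-cell summary of detected events
#'
#' Averages event parameters for one cell, the convention being to fit
#' individual events first and then average the fitted parameters
#' (`average = "parameters"`); averaging waveforms first and fitting once
#' is an explicit alternative, never mixed. Events with decay-fit R^2
#' below `r2_min` are excluded and counted.
#'
#' @param events event table from [detect_events()] (with measurements).
#' @param trace the source [recording_trace()], required for
#'   `average = "waveform"`.
#' @param average `"parameters"` or `"waveform"`.
#' @param r2_min acceptance threshold on the decay-fit R^2 (default 0.5).
#' @param window_ms waveform-average window (default 60 ms).
#' @return List of class `cell_summary`: `n_events`, `n_excluded`,
#'   `mean_amplitude`, `mean_rise`, `mean_tau`, `average_mode`, and for
#'   waveform mode the mean waveform and its single fit.
#' @export
cell_summary <- function(events, trace = NULL,
                         average = c("parameters", "waveform"),
                         r2_min = 0.5, window_ms = 60) {
  average <- match.arg(average)
  ok <- !is.na(events$decay_tau) & !is.na(events$r_squared) &
    events$r_squared >= r2_min
  out <- list(n_events = sum(ok), n_excluded = sum(!ok),
              average_mode = average)
  if (average == "parameters") {
    out$mean_amplitude <- mean(events$amplitude[ok])
    out$mean_rise <- mean(events$rise_10_90[ok], na.rm = TRUE)
    out$mean_tau <- mean(events$decay_tau[ok])
  } else {
    if (is.null(trace)) stop("waveform averaging needs the trace")
    fs <- trace$sampling_rate
    nw <- round(window_ms * fs / 1000)
    segs <- lapply(events$onset_index[ok], function(i) {
      if (i + nw - 1 <= length(trace$current))
        trace$current[i:(i + nw - 1)]
    })
    segs <- segs[!vapply(segs, is.null, logical(1))]
    wave <- rowMeans(do.call(cbind, segs))
    ipk <- which.max(abs(wave - wave[1]))
    fit <- fit_decay(wave[ipk:length(wave)], dt = 1000 / fs)
    out$mean_waveform <- wave
    out$mean_amplitude <- wave[ipk] - wave[1]
    out$mean_rise <- rise_time_10_90(wave[seq_len(ipk)], dt = 1000 / fs)
    out$mean_tau <- fit$tau
    out$fit <- fit
  }
  class(out) <- "cell_summary"
  out
}

#' @exportS3Method base::print
print.cell_summary <- function(x, ...) {
  cat("Cell summary (", x$average_mode, "): ", x$n_events,
      " events accepted, ", x$n_excluded, " excluded; mean amplitude ",
      signif(x$mean_amplitude, 4), " pA, mean 10-90 rise ",
      signif(x$mean_rise, 3), " ms, mean decay tau ",
      signif(x$mean_tau, 4), " ms\n", sep = "")
  invisible(x)
}
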