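test_that("10-90% rise time has the textbook closed forms", {
  dt <- 0.001
  # linear ramp of duration 1 ms rises 10->90% in 0.8 ms
  ramp <- c(seq(0, 1, by = dt), rep(1, 100))
  expect_equal(rise_time_10_90(ramp, dt = dt), 0.8, tolerance = 1e-3)
  # exponential rise with tau_r: t90 - t10 = ln(9) tau_r
  tt <- seq(0, 12, by = dt)
  expo <- 1 - exp(-tt / 1)
  expect_equal(rise_time_10_90(expo, dt = dt), log(9), tolerance = 1e-3)
  # invariant under amplitude scaling and baseline offset, either polarity
  expect_equal(rise_time_10_90(5 - 40 * expo, dt = dt),
               rise_time_10_90(expo, dt = dt), tolerance = 1e-9)
  expect_error(rise_time_10_90(c(1, 0.5, 0.1), dt = dt, baseline = 0),
               "first sample")
})

test_that("decay fit recovers exact and composite exponentials", {
  dt <- 0.1
  tt <- seq(0, 120, by = dt)
  y <- -30 * exp(-tt / 12.9)
  fit <- fit_decay(y, dt = dt)
  expect_equal(fit$tau, 12.9, tolerance = 5e-4)
  expect_gt(fit$r_squared, 0.9999)
  # mono fit of a double exponential lands between the two taus
  y2 <- 20 * exp(-tt / 5) + 10 * exp(-tt / 40)
  fit2 <- fit_decay(y2, dt = dt)
  expect_gt(fit2$tau, 5)
  expect_lt(fit2$tau, 40)
  # bi-exponential mode resolves both and weights the taus
  fb <- fit_decay(y2, dt = dt, mode = "bi")
  expect_equal(fb$tau1, 5, tolerance = 0.05)
  expect_equal(fb$tau2, 40, tolerance = 0.05)
  expect_equal(fb$tau, (20 * 5 + 10 * 40) / 30, tolerance = 0.1)
  # degenerate inputs
  expect_error(fit_decay(y[1:5], dt = dt), "samples")
  flat <- fit_decay(rep(1, 50), dt = dt)
  expect_false(flat$ok)
})

test_that("decay fit tolerates additive noise", {
  set.seed(42)
  dt <- 0.1
  tt <- seq(0, 100, by = dt)
  taus <- replicate(200, {
    y <- -50 * exp(-tt / 15) + rnorm(length(tt), 0, 5)   # SNR 10
    fit_decay(y, dt = dt)$tau
  })
  expect_lt(abs(stats::median(taus) - 15) / 15, 0.05)
})

test_that("Q10 from per-condition decay constants rounds to 3", {
  expect_equal(round(q10(47.3, 15.7)), 3)      # 3.01
  expect_equal(q10(47.3, 15.7), 3.01, tolerance = 0.005)
  expect_equal(round(q10(60.1, 20.3)), 3)      # 2.96
  expect_equal(q10(10, 10), 1)
  # exponent generalizes to other temperature gaps
  expect_equal(q10(4, 1, delta_T = 20), 2)
  expect_error(q10(10, 10, delta_T = 0), "nonzero")
  expect_error(q10(-1, 10), "> 0")
})

test_that("percent of control averages pre and wash phases", {
  expect_equal(as.numeric(percent_of_control(100, 100, 100)), 100)
  expect_equal(as.numeric(percent_of_control(100, 121, 120)), 110)
  p <- suppressWarnings(percent_of_control(100, 90))
  expect_false(attr(p, "wash_used"))
  expect_equal(as.numeric(p), 90)
  expect_error(percent_of_control(0, 50, 50), "> 0")

  # null drug effect with run-down stays near 100%
  set.seed(8)
  pcs <- replicate(300, {
    pre <- rnorm(1, 100, 5)
    drug <- rnorm(1, 95, 5)    # run-down continues linearly
    wash <- rnorm(1, 90, 5)
    as.numeric(percent_of_control(pre, drug, wash))
  })
  expect_lt(abs(mean(pcs) - 100), 2 * sd(pcs) / sqrt(length(pcs)) + 1)
})

test_that("RC corner frequency is computed in recording units", {
  expect_equal(round(rc_corner_frequency(20, 20)), 398)
  expect_equal(rc_corner_frequency(20, 10),
               2 * rc_corner_frequency(20, 20))
  # R = 1 ohm, C = 1 F -> 1/(2 pi) Hz
  expect_equal(rc_corner_frequency(1e-6, 1e12), 1 / (2 * pi))
})

test_that("sliding-template detection finds noiseless events exactly", {
  fs <- 10000
  tpl <- event_template(1, 15, sampling_rate = fs)
  n <- 5 * fs   # 5 s
  cur <- numeric(n)
  onsets <- c(0.4, 1.2, 2.1, 3.3, 4.1) * fs + 1
  for (o in onsets) {
    j <- o:(o + length(tpl) - 1)
    cur[j] <- cur[j] - 40 * tpl
  }
  ev <- detect_events(recording_trace(cur, fs), template_rise = 1,
                      template_decay = 15, threshold = 3.5)
  expect_equal(nrow(ev), 5L)
  expect_true(all(abs(ev$onset_index - onsets) <= 3))
  expect_true(all(ev$amplitude < 0))
  expect_equal(ev$decay_tau, rep(15, 5), tolerance = 0.05)
  # flat trace: no events, no error
  expect_equal(nrow(detect_events(recording_trace(numeric(2000), fs))),
               0L)
})

test_that("detection on pure noise is quiet at criterion threshold 4", {
  set.seed(12)
  noise <- recording_trace(rnorm(1e6, 0, 3), 10000)
  ev4 <- detect_events(noise, template_rise = 1, template_decay = 15,
                       threshold = 4, measure = FALSE)
  expect_lte(nrow(ev4), 3L)   # false positives of order 1 per 10^6
  ev5 <- detect_events(noise, template_rise = 1, template_decay = 15,
                       threshold = 5, measure = FALSE)
  expect_equal(nrow(ev5), 0L)
})

test_that("detection and fitting round-trip a synthetic train", {
  syn <- gen_ipsc_trace(event_rate = 1, amp_mean = 50, amp_sd = 10,
                        rise_tau = 1, decay_tau = 15, noise_sd = 10,
                        duration = 40, seed = 99)   # SNR 5
  ev <- detect_events(syn$trace, template_rise = 1, template_decay = 15,
                      threshold = 4)
  truth <- syn$truth$params$events
  tol <- 30   # samples
  hit <- vapply(truth$onset_index, function(o)
    any(abs(ev$onset_index - o) <= tol), logical(1))
  claimed <- vapply(ev$onset_index, function(o)
    any(abs(truth$onset_index - o) <= tol), logical(1))
  expect_gte(mean(hit), 0.95)       # recall
  expect_gte(mean(claimed), 0.95)   # precision
  expect_lt(abs(stats::median(ev$decay_tau, na.rm = TRUE) - 15) / 15,
            0.05)
})

test_that("event metrics are invariant under scaling and offset", {
  syn <- gen_ipsc_trace(event_rate = 0.5, noise_sd = 0, duration = 20,
                        decay_tau = 20, seed = 3)
  tr1 <- syn$trace
  tr2 <- recording_trace(3 * tr1$current - 250, tr1$sampling_rate)
  e1 <- detect_events(tr1, template_decay = 20)
  e2 <- detect_events(tr2, template_decay = 20)
  expect_equal(nrow(e1), nrow(e2))
  # rounding in the criterion can shift a local maximum by one sample
  expect_true(all(abs(e1$onset_index - e2$onset_index) <= 2))
  expect_equal(e1$rise_10_90, e2$rise_10_90, tolerance = 1e-3)
  expect_equal(e1$decay_tau, e2$decay_tau, tolerance = 1e-3)
  expect_equal(e2$amplitude, 3 * e1$amplitude, tolerance = 1e-3)
})

test_that("per-cell summaries average parameters or waveforms explicitly", {
  syn <- gen_ipsc_trace(event_rate = 0.8, noise_sd = 4, duration = 30,
                        decay_tau = 18, seed = 17)
  ev <- detect_events(syn$trace, template_decay = 18)
  cs <- cell_summary(ev)
  expect_equal(cs$average_mode, "parameters")
  expect_equal(cs$n_events + cs$n_excluded, nrow(ev))
  expect_lt(abs(cs$mean_tau - 18) / 18, 0.15)
  cw <- cell_summary(ev, trace = syn$trace, average = "waveform")
  expect_equal(cw$average_mode, "waveform")
  expect_lt(abs(cw$mean_tau - 18) / 18, 0.15)
})
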