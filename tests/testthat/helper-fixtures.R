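# shared fixtures built in code

# minimal two-state channel: C -> O at beta /ms, O -> C at alpha /ms
two_state_scheme <- function(beta = 2, alpha = 8) {
  kinetic_scheme(
    data.frame(label = c("C", "O"), open = c(FALSE, TRUE),
               n_bound = c(0L, 0L)),
    data.frame(from = c("C", "O"), to = c("O", "C"),
               rate = c(beta, alpha), order = c(0L, 0L)),
    name = "two_state")
}

# a fast, small cleft configuration for functional tests
small_sim_config <- function(...) {
  args <- utils::modifyList(list(n_molecules = 500, duration = 10,
                                 sample_dt = 0.1, seed = 11),
                            list(...))
  do.call(sim_config, args)
}

# brute-force all-pairs time-averaged MSD (O(N^2) oracle)
msd_brute_force <- function(traj, max_lag, fps) {
  n <- nrow(traj)
  out <- data.frame(lag_frames = seq_len(max_lag), msd = NA_real_,
                    n_pairs = 0L)
  for (k in seq_len(max_lag)) {
    acc <- 0; cnt <- 0L
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (traj$frame[j] - traj$frame[i] == k) {
        acc <- acc + (traj$x[j] - traj$x[i])^2 + (traj$y[j] - traj$y[i])^2
        cnt <- cnt + 1L
      }
    }
    if (cnt > 0) {
      out$msd[k] <- acc / cnt
      out$n_pairs[k] <- cnt
    }
  }
  out[out$n_pairs > 0, ]
}

# confined-model MSD curve (exact), as an msd_curve object
confined_curve <- function(L, D, D_mac, lags_s, fps = 40) {
  msd <- L^2 / 3 * (1 - exp(-12 * D * lags_s / L^2)) + 4 * D_mac * lags_s
  structure(data.frame(lag = lags_s, lag_frames = round(lags_s * fps),
                       msd = msd, n_pairs = 100L, sem = NA_real_),
            class = c("msd_curve", "data.frame"), fps = fps)
}
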