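# All generators are seed-deterministic: they sandbox R's RNG, so the same
# seed and parameters regenerate a dataset bit-identically without touching
# the caller's RNG state.
with_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed)) stop("seed must be set explicitly")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

synth_truth <- function(generator, params, seed) {
  structure(list(generator = generator, params = params, seed = seed),
            class = "synth_truth")
}

#' @exportS3Method base::print
print.synth_truth <- function(x, ...) {
  cat("Synthetic truth (", x$generator, ", seed ", x$seed, "):\n",
      sep = "")
  utils::str(x$params, give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

# photobleaching-like track lengths: geometric with the requested mean,
# truncated below so the minimum-length filter has realistic work to do
draw_lengths <- function(n_tracks, n_points, length_dist, min_length = 5) {
  if (length_dist == "fixed") return(rep(n_points, n_tracks))
  pmax(min_length, stats::rgeom(n_tracks, 1 / n_points) + 1L)
}

make_track_df <- function(xs, ys, fps, start_frame = 1L) {
  n <- length(xs)
  data.frame(frame = start_frame + seq_len(n) - 1L,
             t = (start_frame + seq_len(n) - 2L) / fps, x = xs, y = ys)
}

bind_tracks <- function(tracks, fps) {
  df <- do.call(rbind, Map(function(tr, id)
    cbind(track_id = id, tr), tracks, seq_along(tracks)))
  trajectory_set(df, fps = fps)
}

#' Generate freely diffusing 2D trajectories
#'
#' Brownian tracks with per-axis step variance `2 D / fps` plus i.i.d.
#' Gaussian localization noise per point, emulating single-particle
#' tracking of membrane receptors at video rates with 40-60 nm
#' localization precision.
#'
#' @param D diffusion coefficient, um^2/s.
#' @param n_tracks number of tracks.
#' @param n_points points per track (the mean, for geometric lengths).
#' @param fps frame rate, 20 or 40 Hz typically.
#' @param sigma_loc localization precision, um (default 0.05).
#' @param seed integer seed (mandatory).
#' @param field_size side of the square field over which track origins are
#'   scattered, um.
#' @param length_dist `"geometric"` (photobleaching-like, default) or
#'   `"fixed"`.
#' @return List with `tracks` (a [trajectory_set()]) and `truth` (a
#'   `synth_truth` carrying every generating parameter).
#' @export
gen_free_tracks <- function(D, n_tracks = 500, n_points = 50, fps = 40,
                            sigma_loc = 0.05, seed, field_size = 20,
                            length_dist = c("geometric", "fixed")) {
  length_dist <- match.arg(length_dist)
  stopifnot(D >= 0, n_tracks >= 1, n_points >= 2, fps > 0, sigma_loc >= 0)
  tracks <- with_seed(seed, {
    lens <- draw_lengths(n_tracks, n_points, length_dist)
    sg <- sqrt(2 * D / fps)
    lapply(lens, function(L) {
      x0 <- stats::runif(2, 0, field_size)
      xs <- x0[1] + cumsum(c(0, stats::rnorm(L - 1, 0, sg)))
      ys <- x0[2] + cumsum(c(0, stats::rnorm(L - 1, 0, sg)))
      make_track_df(xs + stats::rnorm(L, 0, sigma_loc),
                    ys + stats::rnorm(L, 0, sigma_loc), fps)
    })
  })
  list(tracks = bind_tracks(tracks, fps),
       truth = synth_truth("free_tracks",
                           list(D = D, n_tracks = n_tracks,
                                n_points = n_points, fps = fps,
                                sigma_loc = sigma_loc,
                                field_size = field_size,
                                length_dist = length_dist), seed))
}

# reflect a coordinate into [lo, hi]
reflect_into <- function(v, lo, hi) {
  w <- hi - lo
  for (it in 1:64) {
    out <- v < lo | v > hi
    if (!any(out)) break
    v[v < lo] <- 2 * lo - v[v < lo]
    v[v > hi] <- 2 * hi - v[v > hi]
  }
  pmin(pmax(v, lo), hi)
}

#' Generate confined 2D trajectories
#'
#' Reflected Brownian motion inside a square (or disk) domain of size `L`
#' whose centre itself diffuses with coefficient `D_mac` (hop-diffusion
#' model). With `D_mac = 0` the long-lag MSD saturates at the plateau
#' `L^2/3` (square side L); with `D_mac > 0` the long-lag slope tends to
#' `4 D_mac`. Reflection (rather than a harmonic potential) matches the
#' square-domain confinement model behind the plateau identity.
#'
#' @param D_micro short-time diffusion coefficient inside the domain,
#'   um^2/s.
#' @param L domain size in um (side of square / diameter of disk).
#' @param D_mac domain-centre diffusion coefficient, um^2/s.
#' @param geometry `"square"` or `"disk"`.
#' @param centers optional matrix of domain centres (one row per track);
#'   defaults to scattering over `field_size`.
#' @param n_substeps Brownian substeps per frame for reflection fidelity.
#' @inheritParams gen_free_tracks
#' @return List with `tracks` and `truth` as in [gen_free_tracks()].
#' @export
gen_confined_tracks <- function(D_micro, L, D_mac = 0,
                                geometry = c("square", "disk"),
                                n_tracks = 500, n_points = 50, fps = 40,
                                sigma_loc = 0.05, seed, field_size = 20,
                                length_dist = c("geometric", "fixed"),
                                centers = NULL, n_substeps = 10) {
  geometry <- match.arg(geometry)
  length_dist <- match.arg(length_dist)
  stopifnot(L > 0, D_micro >= 0, D_mac >= 0)
  step_frame <- sqrt(2 * D_micro / fps)
  if (step_frame > L / 2)
    stop("frame step length ", signif(step_frame, 3), " um exceeds L/2; ",
         "increase fps or L (resolution)")
  tracks <- with_seed(seed, {
    lens <- draw_lengths(n_tracks, n_points, length_dist)
    sg <- sqrt(2 * D_micro / fps / n_substeps)
    sgc <- sqrt(2 * D_mac / fps)
    half <- L / 2
    lapply(seq_along(lens), function(i) {
      n <- lens[i]
      c0 <- if (is.null(centers)) stats::runif(2, 0, field_size)
        else centers[((i - 1) %% nrow(centers)) + 1, ]
      # domain-centre walk
      cxs <- c0[1] + cumsum(c(0, stats::rnorm(n - 1, 0, sgc)))
      cys <- c0[2] + cumsum(c(0, stats::rnorm(n - 1, 0, sgc)))
      # particle position relative to the centre, reflected each substep
      rel <- matrix(0, n, 2)
      if (geometry == "square") {
        p <- stats::runif(2, -half, half)
      } else {
        repeat {
          p <- stats::runif(2, -half, half)
          if (sum(p^2) <= half^2) break
        }
      }
      for (k in seq_len(n)) {
        if (k > 1) for (s in seq_len(n_substeps)) {
          p <- p + stats::rnorm(2, 0, sg)
          if (geometry == "square") {
            p[1] <- reflect_into(p[1], -half, half)
            p[2] <- reflect_into(p[2], -half, half)
          } else {
            r <- sqrt(sum(p^2))
            if (r > half) p <- p * (2 * half - r) / r
          }
        }
        rel[k, ] <- p
      }
      make_track_df(cxs + rel[, 1] + stats::rnorm(n, 0, sigma_loc),
                    cys + rel[, 2] + stats::rnorm(n, 0, sigma_loc), fps)
    })
  })
  list(tracks = bind_tracks(tracks, fps),
       truth = synth_truth("confined_tracks",
                           list(D_micro = D_micro, L = L, D_mac = D_mac,
                                geometry = geometry, n_tracks = n_tracks,
                                n_points = n_points, fps = fps,
                                sigma_loc = sigma_loc,
                                field_size = field_size,
                                length_dist = length_dist), seed))
}

#' Generate a two-population trajectory mixture
#'
#' A clustered, slow, confined population plus a freely diffusing fast
#' population, producing the bimodal instantaneous-D histograms
#' characteristic of membrane receptors that partition between synaptic
#' clusters and free membrane. If a mask is supplied, slow tracks are
#' seeded inside its puncta.
#'
#' @param frac_slow fraction of tracks in the slow confined population.
#' @param D_slow,D_fast diffusion coefficients of the two populations,
#'   um^2/s.
#' @param L confinement size of the slow population, um.
#' @param mask optional [synaptic_mask()]; slow tracks start at its
#'   foreground puncta.
#' @inheritParams gen_free_tracks
#' @return List with `tracks`, `truth` (per-track population labels in
#'   `truth$params$population`).
#' @export
gen_two_population_tracks <- function(frac_slow = 0.5, D_slow = 0.004,
                                      D_fast = 0.1, L = 0.25,
                                      mask = NULL, n_tracks = 500,
                                      n_points = 50, fps = 40,
                                      sigma_loc = 0.05, seed,
                                      field_size = 20,
                                      length_dist = c("geometric",
                                                      "fixed")) {
  length_dist <- match.arg(length_dist)
  stopifnot(frac_slow >= 0, frac_slow <= 1)
  n_slow <- round(frac_slow * n_tracks)
  n_fast <- n_tracks - n_slow
  centers <- NULL
  if (!is.null(mask)) {
    if (!any(mask$pixels)) {
      warning("mask has no foreground; ignoring it")
    } else {
      cc <- which(mask$pixels, arr.ind = TRUE)
      centers <- cbind((cc[, "col"] - 0.5) * mask$pixel_size,
                       (cc[, "row"] - 0.5) * mask$pixel_size)
      if (!is.null(mask$truth_centers))
        centers <- mask$truth_centers
    }
  }
  slow <- if (n_slow > 0) {
    cen <- if (!is.null(centers))
      with_seed(seed + 1L,
                centers[sample(nrow(centers), n_slow, replace = TRUE), ,
                        drop = FALSE])
    else NULL
    gen_confined_tracks(D_micro = D_slow, L = L, D_mac = 0,
                        n_tracks = n_slow, n_points = n_points, fps = fps,
                        sigma_loc = sigma_loc, seed = seed + 2L,
                        field_size = field_size,
                        length_dist = length_dist, centers = cen)$tracks
  }
  fast <- if (n_fast > 0)
    gen_free_tracks(D = D_fast, n_tracks = n_fast, n_points = n_points,
                    fps = fps, sigma_loc = sigma_loc, seed = seed + 3L,
                    field_size = field_size,
                    length_dist = length_dist)$tracks
  parts <- list()
  pop <- character(0)
  if (!is.null(slow)) {
    parts <- c(parts, list(as.data.frame(slow)))
    pop <- c(pop, rep("slow", length(unique(slow$track_id))))
  }
  if (!is.null(fast)) {
    f <- as.data.frame(fast)
    f$track_id <- f$track_id + n_slow
    parts <- c(parts, list(f))
    pop <- c(pop, rep("fast", length(unique(fast$track_id))))
  }
  ts <- trajectory_set(do.call(rbind, parts), fps = fps)
  list(tracks = ts,
       truth = synth_truth("two_population_tracks",
                           list(frac_slow = frac_slow, D_slow = D_slow,
                                D_fast = D_fast, L = L,
                                n_tracks = n_tracks, n_points = n_points,
                                fps = fps, sigma_loc = sigma_loc,
                                population = pop,
                                mask_seeded = !is.null(centers)), seed))
}

#' Generate a punctate presynaptic mask
#'
#' Binary disks (puncta) at given or Poisson-scattered centres, emulating
#' bright immobile presynaptic terminals. Overlapping puncta are merged in
#' the mask; the truth retains every generating centre.
#'
#' @param centers matrix of punctum centres in um (one row each), or
#'   `NULL` to scatter `Poisson(lambda * area)` centres.
#' @param lambda punctum intensity per um^2 (used when `centers` is NULL).
#' @param radius punctum radius, um (> pixel_size).
#' @param image_size `c(width, height)` in um.
#' @param pixel_size um per pixel.
#' @param seed integer seed (mandatory when scattering).
#' @return List with `mask` (a [synaptic_mask()], with the generating
#'   centres attached as `truth_centers`) and `truth`.
#' @export
gen_mask <- function(centers = NULL, lambda = NULL, radius = 0.25,
                     image_size = c(20, 20), pixel_size = 0.1, seed = 1) {
  if (radius <= pixel_size)
    stop("punctum radius must exceed the pixel size")
  if (is.null(centers)) {
    if (is.null(lambda)) stop("give centers or lambda")
    centers <- with_seed(seed, {
      n <- stats::rpois(1, lambda * prod(image_size))
      cbind(stats::runif(n, 0, image_size[1]),
            stats::runif(n, 0, image_size[2]))
    })
  }
  centers <- matrix(centers, ncol = 2)
  nr <- round(image_size[2] / pixel_size)
  nc <- round(image_size[1] / pixel_size)
  px <- matrix(FALSE, nr, nc)
  if (nrow(centers)) {
    xs <- (seq_len(nc) - 0.5) * pixel_size
    ys <- (seq_len(nr) - 0.5) * pixel_size
    for (i in seq_len(nrow(centers))) {
      dc <- which(abs(xs - centers[i, 1]) <= radius)
      dr <- which(abs(ys - centers[i, 2]) <= radius)
      if (length(dc) && length(dr)) {
        d2 <- outer((ys[dr] - centers[i, 2])^2, (xs[dc] - centers[i, 1])^2,
                    `+`)
        px[dr, dc] <- px[dr, dc] | (d2 <= radius^2)
      }
    }
  }
  mask <- synaptic_mask(px, pixel_size)
  mask$truth_centers <- centers
  list(mask = mask,
       truth = synth_truth("mask",
                           list(centers = centers, radius = radius,
                                image_size = image_size,
                                pixel_size = pixel_size,
                                lambda = lambda,
                                merged = nrow(centers) > 1), seed))
}

#' Generate a synthetic synaptic-current recording
#'
#' Sum of difference-of-exponential events at Poisson onset times plus
#' white Gaussian noise, sampled like a whole-cell recording (10 kHz
#' default). Events are negative-going (inward currents); overlaps are
#' permitted and recorded in the truth table.
#'
#' @param event_rate events per second.
#' @param amp_mean,amp_sd event peak amplitude distribution (pA, positive
#'   magnitudes; amplitudes are truncated below at `amp_mean / 4`).
#' @param rise_tau,decay_tau event kinetics, ms (`decay_tau > rise_tau`).
#' @param noise_sd white noise SD in pA.
#' @param duration trace length in s.
#' @param sampling_rate Hz.
#' @param seed integer seed (mandatory).
#' @return List with `trace` (a [recording_trace()]) and `truth`
#'   (per-event onset times, amplitudes and kinetics).
#' @export
gen_ipsc_trace <- function(event_rate = 1, amp_mean = 50, amp_sd = 10,
                           rise_tau = 1, decay_tau = 15, noise_sd = 2,
                           duration = 60, sampling_rate = 10000, seed) {
  if (!(decay_tau > rise_tau) || rise_tau <= 0)
    stop("need decay_tau > rise_tau > 0")
  n <- round(duration * sampling_rate)
  # long template so slow decays are not visibly truncated
  tpl <- event_template(rise_tau, decay_tau,
                        length_ms = rise_tau + 8 * decay_tau,
                        sampling_rate = sampling_rate)
  out <- with_seed(seed, {
    n_ev <- stats::rpois(1, event_rate * duration)
    onsets <- sort(stats::runif(n_ev, 0, duration))
    amps <- pmax(stats::rnorm(n_ev, amp_mean, amp_sd), amp_mean / 4)
    cur <- stats::rnorm(n, 0, noise_sd)
    idx <- round(onsets * sampling_rate) + 1L
    for (i in seq_len(n_ev)) {
      j <- idx[i]:min(n, idx[i] + length(tpl) - 1L)
      cur[j] <- cur[j] - amps[i] * tpl[seq_along(j)]
    }
    list(cur = cur, onsets = onsets, amps = amps, idx = idx)
  })
  events <- data.frame(time = out$onsets, onset_index = out$idx,
                       amplitude = -out$amps)
  list(trace = recording_trace(out$cur, sampling_rate),
       truth = synth_truth("ipsc_trace",
                           list(event_rate = event_rate,
                                amp_mean = amp_mean, amp_sd = amp_sd,
                                rise_tau = rise_tau,
                                decay_tau = decay_tau,
                                noise_sd = noise_sd, duration = duration,
                                sampling_rate = sampling_rate,
                                events = events), seed))
}
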