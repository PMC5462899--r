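#' A set of single-particle trajectories
#'
#' Stored as one data.frame with columns `track_id`, `frame` (strictly
#' increasing within a track; gaps allowed), `t` (s), `x` and `y` (um),
#' plus a frames-per-second attribute.
#'
#' @param df data.frame with the five columns above.
#' @param fps frame rate in Hz; inferred from `t` if missing.
#' @return An object of class `trajectory_set` (still a data.frame).
#' @export
trajectory_set <- function(df, fps = NULL) {
  need <- c("track_id", "frame", "t", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- df[order(df$track_id, df$frame), need]
  d <- unlist(tapply(df$frame, df$track_id, diff, simplify = FALSE),
              use.names = FALSE)
  if (length(d) && any(d <= 0))
    stop("frames must be strictly increasing within a track")
  if (is.null(fps)) {
    dts <- diff(df$t[df$track_id == df$track_id[1]])
    fps <- if (length(dts)) round(1 / min(dts)) else NA_real_
  }
  rownames(df) <- NULL
  structure(df, class = c("trajectory_set", "data.frame"), fps = fps)
}

#' @exportS3Method base::print
print.trajectory_set <- function(x, ...) {
  len <- table(x$track_id)
  cat("Trajectory set: ", length(len), " tracks, ", nrow(x),
      " localizations at ", attr(x, "fps"), " Hz (track length ",
      min(len), "-", max(len), ")\n", sep = "")
  invisible(x)
}

split_tracks <- function(ts) {
  split(as.data.frame(ts)[c("frame", "t", "x", "y")], ts$track_id)
}

#' Time-averaged mean-squared displacement of one trajectory
#'
#' For each lag of k frames, averages the squared displacement over all
#' overlapping pairs of localizations k frames apart (the time-averaged
#' convention). Frame gaps are respected: only pairs whose frame numbers
#' differ by exactly k contribute.
#'
#' @param traj a data.frame with columns `frame`, `t`, `x`, `y` (one
#'   track), or a `trajectory_set` with a single track.
#' @param max_lag maximum lag in frames (default: track span - 1; larger
#'   requests are truncated with a warning).
#' @param fps frame rate (Hz) used to convert lags to seconds; inferred
#'   from `t` if missing.
#' @return data.frame of class `msd_curve`: `lag` (s), `lag_frames`,
#'   `msd` (um^2), `n_pairs`, `sem`.
#' @export
compute_msd <- function(traj, max_lag = NULL, fps = NULL) {
  if (inherits(traj, "trajectory_set")) {
    if (is.null(fps)) fps <- attr(traj, "fps")
    tr <- split_tracks(traj)
    if (length(tr) != 1) stop("compute_msd expects a single track")
    traj <- tr[[1]]
  }
  if (nrow(traj) < 2) stop("trajectory must have length >= 2")
  if (is.null(fps)) fps <- round(1 / min(diff(traj$t)))
  span <- max(traj$frame) - min(traj$frame)
  if (is.null(max_lag)) max_lag <- span
  if (max_lag > span) {
    warning("max_lag exceeds track span; truncated to ", span)
    max_lag <- span
  }
  # index positions by frame offset so gaps are honoured
  off <- traj$frame - min(traj$frame) + 1L
  nx <- rep(NA_real_, max(off)); ny <- nx
  nx[off] <- traj$x; ny[off] <- traj$y
  res <- lapply(seq_len(max_lag), function(k) {
    i <- seq_len(length(nx) - k)
    d2 <- (nx[i + k] - nx[i])^2 + (ny[i + k] - ny[i])^2
    d2 <- d2[!is.na(d2)]
    n <- length(d2)
    data.frame(lag = k / fps, lag_frames = k,
               msd = if (n) mean(d2) else NA_real_, n_pairs = n,
               sem = if (n > 1) stats::sd(d2) / sqrt(n) else NA_real_)
  })
  out <- do.call(rbind, res)
  out <- out[out$n_pairs > 0, ]
  rownames(out) <- NULL
  structure(out, class = c("msd_curve", "data.frame"), fps = fps)
}

#' Ensemble mean MSD across trajectories
#'
#' Applies the minimum-track-length filter (default 20 localizations, the
#' convention that keeps the relative error of individual MSD curves
#' manageable), computes each surviving track's time-averaged MSD and
#' averages them per lag. Per-cell diffusion coefficients are derived from
#' this mean curve rather than from individual tracks.
#'
#' @param ts a [trajectory_set()].
#' @param min_length minimum localizations per track (default 20).
#' @param max_lag maximum lag in frames (default 20).
#' @return An `msd_curve` (mean +- SEM across tracks per lag) with
#'   attributes `n_included` and `n_excluded`; zero rows (with
#'   `n_included = 0`) if nothing passes the filter.
#' @export
mean_msd <- function(ts, min_length = 20, max_lag = 20) {
  stopifnot(inherits(ts, "trajectory_set"))
  fps <- attr(ts, "fps")
  tracks <- split_tracks(ts)
  len <- vapply(tracks, nrow, integer(1))
  keep <- len >= min_length
  if (!any(keep)) {
    out <- data.frame(lag = numeric(), lag_frames = integer(),
                      msd = numeric(), n_pairs = integer(),
                      sem = numeric())
    return(structure(out, class = c("msd_curve", "data.frame"), fps = fps,
                     n_included = 0L, n_excluded = sum(!keep)))
  }
  curves <- lapply(tracks[keep], function(tr)
    suppressWarnings(compute_msd(tr, max_lag = max_lag, fps = fps)))
  lags <- sort(unique(unlist(lapply(curves, `[[`, "lag_frames"))))
  lags <- lags[lags <= max_lag]
  mat <- vapply(curves, function(cv)
    cv$msd[match(lags, cv$lag_frames)], numeric(length(lags)))
  mat <- matrix(mat, nrow = length(lags))
  m <- rowMeans(mat, na.rm = TRUE)
  nn <- rowSums(!is.na(mat))
  sem <- apply(mat, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  })
  out <- data.frame(lag = lags / fps, lag_frames = lags, msd = m,
                    n_pairs = nn, sem = sem)
  structure(out, class = c("msd_curve", "data.frame"), fps = fps,
            n_included = sum(keep), n_excluded = sum(!keep))
}

#' @export
plot.msd_curve <- function(x, ...) {
  graphics::plot(x$lag, x$msd, type = "b", pch = 16,
                 xlab = "lag (s)", ylab = expression(MSD ~ (mu * m^2)),
                 ...)
  if (any(is.finite(x$sem)))
    graphics::arrows(x$lag, x$msd - x$sem, x$lag, x$msd + x$sem,
                     angle = 90, code = 3, length = 0.02)
  invisible(x)
}

#' Linear MSD fit: free diffusion with a localization-noise offset
#'
#' Least-squares line through the first `n_points` lags of an MSD curve:
#' `MSD(t) = 4 D t + b`. The slope gives the diffusion coefficient
#' `D = slope / 4` (um^2/s) and the intercept `b` absorbs static
#' localization noise (`b ~ 4 sigma^2` for localization precision sigma).
#' A negative slope is clamped to `D = 0` and flagged.
#'
#' @param curve an `msd_curve` with at least `n_points` lags.
#' @param n_points number of initial points to fit (default 4).
#' @return List of class `diffusion_fit` with `D` (um^2/s), `b` (um^2),
#'   `r_squared`, `clamped`, `model = "linear"`.
#' @export
fit_msd_linear <- function(curve, n_points = 4) {
  if (nrow(curve) < n_points)
    stop("curve has ", nrow(curve), " lags; need at least ", n_points)
  d <- curve[seq_len(n_points), ]
  fit <- stats::lm(msd ~ lag, data = d)
  co <- stats::coef(fit)
  D <- unname(co[2]) / 4
  clamped <- FALSE
  if (D < 0) { D <- 0; clamped <- TRUE }
  sst <- sum((d$msd - mean(d$msd))^2)
  r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 1
  structure(list(D = D, b = unname(co[1]), r_squared = r2,
                 clamped = clamped, n_points = n_points,
                 model = "linear"),
            class = "diffusion_fit")
}

#' Confined-diffusion MSD fit
#'
#' Nonlinear fit of the confined (hop-diffusion) model
#' \deqn{MSD(t) = \frac{L^2}{3}\left(1 - e^{-12 D t / L^2}\right)
#'   + 4 D_{mac} t}
#' with confinement size `L` (um, the side of the confining domain),
#' short-time diffusion coefficient `D` and long-time (macroscopic)
#' coefficient `D_mac`. With `D_mac = 0` the curve saturates at the
#' plateau `L^2/3`. Fitting uses Levenberg-Marquardt with non-negativity
#' bounds; non-convergence falls back to the linear fit with a flag. The
#' fit is marked `unstable` when the confinement shoulder is not reached
#' within the fitted lags (`12 D t_max / L^2 < 1`) or the relative
#' standard error of `L` exceeds 50%, as happens for freely diffusing
#' particles.
#'
#' @param curve an `msd_curve` spanning at least 10 lags.
#' @return List of class `diffusion_fit` with `L` (um), `D`, `D_mac`
#'   (um^2/s), `plateau` (`L^2/3`), `r_squared`, `unstable`, `converged`,
#'   `model = "confined"`; on fallback, the linear fit with
#'   `converged = FALSE`.
#' @export
fit_msd_confined <- function(curve) {
  if (nrow(curve) < 10)
    stop("confined fit needs lags beyond the shoulder (>= 10 lags)")
  d <- as.data.frame(curve)[c("lag", "msd")]
  n_tail <- max(2, ceiling(nrow(d) / 4))
  tail_idx <- (nrow(d) - n_tail + 1):nrow(d)
  slope_tail <- stats::coef(stats::lm(msd ~ lag,
                                      data = d[tail_idx, ]))[2]
  dmac0 <- max(unname(slope_tail) / 4, 0)
  plateau0 <- max(max(d$msd) - 4 * dmac0 * max(d$lag), min(d$msd[d$msd > 0],
                                                           0.001))
  L0 <- sqrt(3 * plateau0)
  D0 <- max((d$msd[2] - d$msd[1]) / (d$lag[2] - d$lag[1]) / 4, 1e-4)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      msd ~ L^2 / 3 * (1 - exp(-12 * D * lag / L^2)) + 4 * Dmac * lag,
      data = d, start = list(L = L0, D = D0, Dmac = dmac0),
      lower = c(1e-4, 0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- fit_msd_linear(curve, n_points = min(4, nrow(curve)))
    out$converged <- FALSE
    out$unstable <- TRUE
    return(out)
  }
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  shoulder <- 12 * co["D"] * max(d$lag) / co["L"]^2
  unstable <- !is.finite(se["L"]) || se["L"] / co["L"] > 0.5 ||
    shoulder < 1
  ss_res <- sum(stats::resid(fit)^2)
  sst <- sum((d$msd - mean(d$msd))^2)
  structure(list(L = unname(co["L"]), D = unname(co["D"]),
                 D_mac = unname(co["Dmac"]),
                 plateau = unname(co["L"])^2 / 3,
                 r_squared = if (sst > 0) 1 - ss_res / sst else 1,
                 unstable = unname(unstable), converged = TRUE,
                 model = "confined"),
            class = "diffusion_fit")
}

#' @exportS3Method base::print
print.diffusion_fit <- function(x, ...) {
  if (x$model == "linear") {
    cat("Linear MSD fit: D = ", signif(x$D, 4), " um^2/s, b = ",
        signif(x$b, 4), " um^2 (R^2 ", signif(x$r_squared, 3),
        if (x$clamped) ", slope clamped to 0" else "", ")\n", sep = "")
  } else {
    cat("Confined MSD fit: L = ", signif(x$L, 4), " um, D = ",
        signif(x$D, 4), ", D_mac = ", signif(x$D_mac, 4),
        " um^2/s, plateau ", signif(x$plateau, 4), " um^2",
        if (isTRUE(x$unstable)) " [unstable]" else "", "\n", sep = "")
  }
  invisible(x)
}
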