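#' Binary presynaptic mask
#'
#' A logical pixel matrix marking presynaptic (synaptotagmin-rich) puncta,
#' with a physical pixel size. Row index increases with y, column index
#' with x, origin at the image corner, so trajectory coordinates in um map
#' directly onto pixel indices.
#'
#' @param pixels logical (or 0/1) matrix.
#' @param pixel_size pixel edge in um (> 0).
#' @param threshold provenance note: the threshold used to binarize, if
#'   any.
#' @return An object of class `synaptic_mask`.
#' @export
synaptic_mask <- function(pixels, pixel_size, threshold = NA_real_) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  px <- matrix(as.logical(pixels), nrow(pixels), ncol(pixels))
  structure(list(pixels = px, pixel_size = pixel_size,
                 threshold = threshold),
            class = "synaptic_mask")
}

#' @exportS3Method base::print
print.synaptic_mask <- function(x, ...) {
  cat("Synaptic mask: ", nrow(x$pixels), "x", ncol(x$pixels),
      " pixels at ", x$pixel_size, " um/px (",
      signif(mean(x$pixels) * 100, 3), "% foreground)\n", sep = "")
  invisible(x)
}

# square binary dilation by k pixels via shifted ORs
dilate_mask <- function(px, k) {
  if (k <= 0) return(px)
  out <- px
  n <- nrow(px); m <- ncol(px)
  for (dr in -k:k) for (dc in -k:k) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(n, n + dr)
    cs <- max(1, 1 + dc):min(m, m + dc)
    out[rs, cs] <- out[rs, cs] | px[rs - dr, cs - dc]
  }
  out
}

points_in_mask <- function(x, y, mask) {
  px <- mask$pixels
  col <- floor(x / mask$pixel_size) + 1L
  row <- floor(y / mask$pixel_size) + 1L
  ok <- col >= 1 & col <= ncol(px) & row >= 1 & row <= nrow(px)
  inside <- logical(length(x))
  inside[ok] <- px[cbind(row[ok], col[ok])]
  inside
}

#' Classify trajectories against a presynaptic mask
#'
#' A trajectory is `synaptic` if at least `synaptic_frac` of its
#' localizations fall inside the (dilated) mask, `extrasynaptic` if at
#' most `extrasynaptic_frac` do, and `exchanging` otherwise (entering or
#' leaving a synaptic region during the track). The mask is dilated by one
#' localization precision to absorb pointing error at punctum edges.
#'
#' @param ts a [trajectory_set()] sharing the mask's coordinate frame.
#' @param mask a [synaptic_mask()].
#' @param synaptic_frac,extrasynaptic_frac residency thresholds (defaults
#'   0.8 and 0.2).
#' @param dilate_um mask dilation in um (default 0.05, one localization
#'   precision).
#' @return List of class `mask_classification`: per-track `label` (factor
#'   synaptic/extrasynaptic/exchanging), `inside_frac`, `track_id`,
#'   `exchange_fraction` and `counts`.
#' @export
classify_by_mask <- function(ts, mask, synaptic_frac = 0.8,
                             extrasynaptic_frac = 0.2, dilate_um = 0.05) {
  stopifnot(inherits(ts, "trajectory_set"), inherits(mask, "synaptic_mask"))
  m <- mask
  if (!any(m$pixels)) {
    warning("empty mask: all trajectories classified extrasynaptic")
  } else if (dilate_um > 0) {
    m$pixels <- dilate_mask(m$pixels,
                            as.integer(ceiling(dilate_um / m$pixel_size)))
  }
  inside <- points_in_mask(ts$x, ts$y, m)
  frac <- tapply(inside, ts$track_id, mean)
  ids <- names(frac)
  frac <- as.numeric(frac)
  label <- ifelse(frac >= synaptic_frac, "synaptic",
                  ifelse(frac <= extrasynaptic_frac, "extrasynaptic",
                         "exchanging"))
  label <- factor(label,
                  levels = c("synaptic", "extrasynaptic", "exchanging"))
  structure(list(track_id = ids, label = label, inside_frac = frac,
                 exchange_fraction = mean(label == "exchanging"),
                 counts = table(label)),
            class = "mask_classification")
}

#' @exportS3Method base::print
print.mask_classification <- function(x, ...) {
  cat("Mask classification: ", paste(names(x$counts), as.integer(x$counts),
                                     sep = "=", collapse = ", "),
      "; exchange fraction ", signif(x$exchange_fraction, 3), "\n",
      sep = "")
  invisible(x)
}

#' Instantaneous diffusion coefficients and bimodality
#'
#' Fits each trajectory's own time-averaged MSD with the linear model
#' ([fit_msd_linear()]) to obtain one "instantaneous" diffusion
#' coefficient per track, then summarizes the population as a histogram
#' over log10 D. Bimodality is assessed on a kernel-smoothed log-density:
#' the split point is the minimum between the two dominant modes, with a
#' fixed fallback split at `fallback_split` when the density is unimodal.
#'
#' @param ts a [trajectory_set()].
#' @param n_points MSD points per track fit (default 4).
#' @param min_length track-length filter (default 20).
#' @param fallback_split split used when no interior minimum exists
#'   (default 0.02 um^2/s).
#' @param floor_D values at or below this (clamped fits) are excluded from
#'   the log histogram but counted (default 1e-5 um^2/s).
#' @return List of class `inst_d`: `D` (per track), `track_id`,
#'   `histogram` (hist object over log10 D), `bimodal`, `split` (um^2/s),
#'   `frac_slow`, `n_excluded`.
#' @export
instantaneous_D <- function(ts, n_points = 4, min_length = 20,
                            fallback_split = 0.02, floor_D = 1e-5) {
  stopifnot(inherits(ts, "trajectory_set"))
  fps <- attr(ts, "fps")
  tracks <- split_tracks(ts)
  len <- vapply(tracks, nrow, integer(1))
  keep <- len >= min_length
  tracks <- tracks[keep]
  D <- vapply(tracks, function(tr) {
    cv <- suppressWarnings(compute_msd(tr, max_lag = n_points, fps = fps))
    if (nrow(cv) < n_points) return(NA_real_)
    fit_msd_linear(cv, n_points = n_points)$D
  }, numeric(1))
  ok <- is.finite(D) & D > floor_D
  logd <- log10(D[ok])
  h <- if (length(logd))
    graphics::hist(logd, breaks = "FD", plot = FALSE) else NULL
  split <- fallback_split
  bimodal <- FALSE
  if (length(logd) >= 20) {
    den <- stats::density(logd)
    yi <- den$y
    loc_max <- which(diff(sign(diff(yi))) == -2) + 1
    if (length(loc_max) >= 2) {
      top2 <- loc_max[order(yi[loc_max], decreasing = TRUE)][1:2]
      top2 <- sort(top2)
      valley <- top2[1] + which.min(yi[top2[1]:top2[2]]) - 1
      p2 <- min(yi[top2])
      # second mode must be substantial and the valley a real dip
      if (p2 >= 0.1 * max(yi[top2]) && yi[valley] <= 0.8 * p2) {
        bimodal <- TRUE
        split <- 10^den$x[valley]
      }
    }
  }
  structure(list(D = D, track_id = names(tracks), histogram = h,
                 bimodal = bimodal, split = split,
                 frac_slow = mean(D[is.finite(D)] < split),
                 n_excluded = sum(!keep) + sum(!is.finite(D))),
            class = "inst_d")
}

#' @exportS3Method base::print
print.inst_d <- function(x, ...) {
  cat("Instantaneous D: ", sum(is.finite(x$D)), " tracks, ",
      if (x$bimodal) "bimodal" else "unimodal",
      " log10-D distribution; split at ", signif(x$split, 3),
      " um^2/s, slow fraction ", signif(x$frac_slow, 3), "\n", sep = "")
  invisible(x)
}

#' @export
plot.inst_d <- function(x, ...) {
  if (is.null(x$histogram)) stop("no finite diffusion coefficients")
  plot(x$histogram, xlab = expression(log[10] ~ D ~ (mu * m^2 / s)),
       main = "Instantaneous diffusion coefficients", ...)
  graphics::abline(v = log10(x$split), lty = 2)
  invisible(x)
}

#' Population mobility report
#'
#' Combines the ensemble diffusion coefficient (from the mean MSD curve),
#' the mobile fraction, synaptic/extrasynaptic diffusion and confinement
#' size into one report.
#'
#' The mobile fraction ("free diffusion or changing domains") is decided
#' hierarchically, because per-track confinement fits on tracks of typical
#' length are too noisy to classify single trajectories reliably. If the
#' instantaneous-D distribution is bimodal ([instantaneous_D()]), mobile
#' trajectories are those in the fast mode (above the split) plus the
#' mask-exchanging ones. If it is unimodal, the confined fit of the
#' ensemble mean MSD decides for the population as a whole: a stable
#' confinement fit means only exchanging tracks are mobile; an unstable
#' one (free diffusion) means all tracks are. Synaptic diffusion
#' coefficients are reported both including and excluding the exchanging
#' tracks.
#'
#' @param ts a [trajectory_set()].
#' @param classification optional [classify_by_mask()] result.
#' @param min_length track-length filter (default 20).
#' @param max_lag lags for the ensemble MSD (default 20).
#' @return List of class `mobility_report`: `D_ensemble` (um^2/s from the
#'   mean MSD), `mobile_fraction`, `exchange_fraction`, `bimodal`,
#'   `confinement_L` (ensemble fitted L, um; NA when unconfined),
#'   `D_synaptic`, `D_synaptic_resident` (exchangers excluded),
#'   `D_extrasynaptic`, `counts`, `n_tracks`.
#' @export
mobility_metrics <- function(ts, classification = NULL, min_length = 20,
                             max_lag = 20) {
  stopifnot(inherits(ts, "trajectory_set"))
  fps <- attr(ts, "fps")
  tracks <- split_tracks(ts)
  len <- vapply(tracks, nrow, integer(1))
  tracks <- tracks[len >= min_length]
  ids <- names(tracks)

  ens_msd <- function(sel_ids, lags = max_lag) {
    sub <- ts[ts$track_id %in% sel_ids, ]
    if (!nrow(sub)) return(NULL)
    mean_msd(trajectory_set(as.data.frame(sub), fps = fps),
             min_length = min_length, max_lag = lags)
  }
  ens_D <- function(sel_ids) {
    cv <- ens_msd(sel_ids)
    if (is.null(cv) || nrow(cv) < 4) return(NA_real_)
    fit_msd_linear(cv)$D
  }

  inst <- instantaneous_D(ts, min_length = min_length)
  Di <- inst$D[match(ids, inst$track_id)]

  exch <- rep(FALSE, length(ids))
  lab <- NULL
  if (!is.null(classification)) {
    lab <- classification$label[match(ids, classification$track_id)]
    exch <- !is.na(lab) & lab == "exchanging"
  }

  cv_all <- ens_msd(ids, lags = max_lag + 5)
  cfit <- if (!is.null(cv_all) && nrow(cv_all) >= 10)
    fit_msd_confined(cv_all) else NULL
  confined_pop <- !is.null(cfit) && identical(cfit$model, "confined") &&
    isTRUE(cfit$converged) && !isTRUE(cfit$unstable)

  if (inst$bimodal) {
    mobile <- (is.finite(Di) & Di > inst$split) | exch
  } else if (confined_pop) {
    mobile <- exch
  } else {
    mobile <- rep(TRUE, length(ids))
  }

  out <- list(
    n_tracks = length(ids),
    D_ensemble = ens_D(ids),
    mobile_fraction = mean(mobile),
    exchange_fraction = if (is.null(classification)) NA_real_
      else classification$exchange_fraction,
    bimodal = inst$bimodal,
    split = inst$split,
    confinement_L = if (confined_pop) cfit$L else NA_real_,
    counts = c(mobile = sum(mobile), confined = sum(!mobile)))
  if (!is.null(lab)) {
    syn <- ids[!is.na(lab) & lab == "synaptic"]
    out$D_synaptic <- ens_D(c(syn, ids[exch]))
    out$D_synaptic_resident <- ens_D(syn)
    out$D_extrasynaptic <- ens_D(ids[!is.na(lab) & lab == "extrasynaptic"])
  }
  class(out) <- "mobility_report"
  out
}

#' @exportS3Method base::print
print.mobility_report <- function(x, ...) {
  cat("Mobility report over ", x$n_tracks, " tracks: D(ensemble) = ",
      signif(x$D_ensemble, 3), " um^2/s, mobile fraction ",
      signif(x$mobile_fraction, 3),
      if (is.finite(x$confinement_L))
        paste0(", confinement L = ", signif(x$confinement_L, 3), " um"),
      "\n", sep = "")
  if (!is.null(x$D_synaptic))
    cat("  synaptic D ", signif(x$D_synaptic, 3), " (resident only ",
        signif(x$D_synaptic_resident, 3), "), extrasynaptic D ",
        signif(x$D_extrasynaptic, 3), " um^2/s\n", sep = "")
  invisible(x)
}

#' Density-based cluster detection and inter-cluster distances
#'
#' Greedy density-based clustering (DBSCAN with a grid-bucketed neighbour
#' search): a point with at least `min_pts` neighbours within `eps` is a
#' core point; clusters are the connected components of core points plus
#' their border points. Reports cluster centroids, sizes, and the
#' nearest-neighbour distances between centroids.
#'
#' @param x,y point coordinates in um (e.g. localizations), or `x` may be
#'   a two-column matrix.
#' @param eps neighbourhood radius in um (default 0.1).
#' @param min_pts minimum neighbours for a core point (default 10).
#' @return List of class `cluster_report`: `centroids` (matrix), `sizes`,
#'   `labels` (0 = noise), `nn_dist`, `mean_nn`, `sem_nn`. Zero clusters
#'   give empty fields.
#' @export
detect_clusters_and_distances <- function(x, y = NULL, eps = 0.1,
                                          min_pts = 10) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  n <- length(x)
  if (n < 1) stop("need at least one point")
  cell <- eps
  cx <- floor(x / cell); cy <- floor(y / cell)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  neigh <- function(i) {
    ks <- as.vector(outer(cx[i] + (-1:1), cy[i] + (-1:1), paste))
    cand <- unlist(buckets[ks], use.names = FALSE)
    cand[(x[cand] - x[i])^2 + (y[cand] - y[i])^2 <= eps^2]
  }
  nb_count <- vapply(seq_len(n), function(i) length(neigh(i)), integer(1))
  core <- nb_count >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      for (k in neigh(j)) {
        if (labels[k] == 0L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  if (cl == 0L)
    return(structure(list(centroids = matrix(numeric(0), 0, 2),
                          sizes = integer(0), labels = labels,
                          nn_dist = numeric(0), mean_nn = NA_real_,
                          sem_nn = NA_real_),
                     class = "cluster_report"))
  cent <- t(vapply(seq_len(cl), function(c)
    c(mean(x[labels == c]), mean(y[labels == c])), numeric(2)))
  colnames(cent) <- c("x", "y")
  sizes <- tabulate(labels, cl)
  nn <- if (cl >= 2) {
    dd <- as.matrix(stats::dist(cent))
    diag(dd) <- Inf
    apply(dd, 1, min)
  } else numeric(0)
  structure(list(centroids = cent, sizes = sizes, labels = labels,
                 nn_dist = nn, mean_nn = if (length(nn)) mean(nn)
                 else NA_real_,
                 sem_nn = if (length(nn) > 1)
                   stats::sd(nn) / sqrt(length(nn)) else NA_real_),
            class = "cluster_report")
}

#' @exportS3Method base::print
print.cluster_report <- function(x, ...) {
  cat("Cluster report: ", nrow(x$centroids), " clusters (sizes ",
      if (length(x$sizes)) paste(range(x$sizes), collapse = "-") else "-",
      "), mean nearest-neighbour distance ", signif(x$mean_nn, 3),
      " um\n", sep = "")
  invisible(x)
}
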