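#' Read a tracking table
#'
#' Reads a CSV export from common localization/tracking software. Required
#' columns: `track_id`, `frame`, `t`, `x`, `y` (header row mandatory).
#' Rows with missing or non-numeric coordinates are dropped and counted.
#'
#' @param path CSV file path.
#' @param dialect coordinate units: `"um"` (default) or `"nm"` (converted
#'   to um on read).
#' @return A [trajectory_set()]; the number of dropped rows is attached as
#'   attribute `n_malformed` and reported via a message.
#' @export
read_tracks <- function(path, dialect = c("um", "nm")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "t", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("tracking table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(df)) {
    warning("empty tracking table")
    out <- trajectory_set(df[need], fps = NA_real_)
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  for (cc in c("frame", "t", "x", "y"))
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  bad <- !stats::complete.cases(df[need]) |
    !is.finite(df$x) | !is.finite(df$y)
  if (any(bad))
    message(sum(bad), " malformed row(s) dropped")
  df <- df[!bad, ]
  if (dialect == "nm") {
    df$x <- df$x / 1000
    df$y <- df$y / 1000
  }
  out <- trajectory_set(df)
  attr(out, "n_malformed") <- sum(bad)
  out
}

#' Write a tracking table
#'
#' @param ts a [trajectory_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "trajectory_set"))
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

#' Read and write binary masks as TIFF images
#'
#' Masks are stored as single-channel TIFF with foreground = 1; the
#' physical pixel size travels separately (argument / sidecar config), not
#' in the image.
#'
#' @param path TIFF file path.
#' @param pixel_size um per pixel.
#' @return [read_mask()]: a [synaptic_mask()]; [write_mask()]: `path`.
#' @export
read_mask <- function(path, pixel_size) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  synaptic_mask(img > 0.5, pixel_size)
}

#' @rdname read_mask
#' @param mask a [synaptic_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "synaptic_mask"))
  tiff::writeTIFF(matrix(as.numeric(mask$pixels), nrow(mask$pixels)),
                  path)
  invisible(path)
}

#' Read and write a current trace
#'
#' Two-column CSV (`time` in s, `current` in pA); the sampling rate is
#' recovered from the time column.
#'
#' @param path CSV path.
#' @return [read_trace()]: a [recording_trace()]; [write_trace()]: `path`.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time", "current") %in% names(df)))
    stop("trace file needs columns: time, current")
  fs <- round(1 / stats::median(diff(df$time)))
  recording_trace(df$current, sampling_rate = fs)
}

#' @rdname read_trace
#' @param trace a [recording_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "recording_trace"))
  n <- length(trace$current)
  utils::write.csv(data.frame(time = (seq_len(n) - 1) /
                                trace$sampling_rate,
                              current = trace$current),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write simulation configurations as structured text
#'
#' A [sim_config()] round-trips through a YAML file mirroring its fields,
#' with the gating scheme embedded as states and transitions.
#'
#' @param config a [sim_config()].
#' @param path YAML file path.
#' @return [write_sim_config()]: `path`; [read_sim_config()]: a
#'   [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$geometry
  obj <- list(
    geometry = list(bouton_width = g$bouton[["width"]],
                    bouton_depth = g$bouton[["depth"]],
                    bouton_height = g$bouton[["height"]],
                    cleft_width_nm = g$cleft * 1000,
                    plane_side = g$plane_side,
                    cluster_side_nm = g$cluster * 1000,
                    escape_radius = g$escape_radius),
    scheme = list(name = config$scheme$name,
                  states = config$scheme$states,
                  transitions = config$scheme$transitions),
    n_receptors = config$n_receptors,
    n_molecules = config$n_molecules,
    release_times = config$release_times,
    release_pos = config$release_pos,
    D = config$D, dt = config$dt, duration = config$duration,
    sample_dt = config$sample_dt, arrangement = config$arrangement,
    capture_radius = config$capture_radius, seed = config$seed,
    record_events = config$record_events)
  yaml::write_yaml(obj, path, column.major = FALSE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  g <- obj$geometry
  geom <- synapse_geometry(
    bouton_width = g$bouton_width, bouton_depth = g$bouton_depth,
    bouton_height = g$bouton_height, cleft_width = g$cleft_width_nm,
    plane_side = g$plane_side, cluster_side = g$cluster_side_nm,
    escape_radius = g$escape_radius)
  scheme <- kinetic_scheme(
    do.call(rbind.data.frame, obj$scheme$states),
    do.call(rbind.data.frame, obj$scheme$transitions),
    name = obj$scheme$name)
  sim_config(geometry = geom, scheme = scheme,
             n_receptors = obj$n_receptors,
             n_molecules = obj$n_molecules,
             release_times = unlist(obj$release_times),
             release_pos = unlist(obj$release_pos),
             D = obj$D, dt = obj$dt, duration = obj$duration,
             sample_dt = obj$sample_dt, arrangement = obj$arrangement,
             capture_radius = obj$capture_radius, seed = obj$seed,
             record_events = obj$record_events)
}

#' Expand a global seed into reproducible per-stage seeds
#'
#' Deterministic counter scheme mapping one user-facing seed to an
#' arbitrary number of independent stage seeds, all below 2^31, so
#' multi-stage runs and sweeps stay reproducible from a single seed.
#'
#' @param seed global integer seed.
#' @param n number of stage seeds.
#' @param stage stage counter offset (default 0).
#' @return Integer vector of length `n`.
#' @export
expand_seeds <- function(seed, n, stage = 0) {
  as.integer((as.double(seed) * 7919 + (stage + seq_len(n)) * 104729)
             %% 2147483647)
}

#' Write analysis results with a reproducibility manifest
#'
#' Writes each data.frame in `results` as a CSV table (deterministic
#' column order, fixed float precision) and each non-tabular element as
#' JSON, plus a `manifest.json` recording the seed, configuration, file
#' checksums and package version - sufficient to reproduce the outputs
#' from the same inputs.
#'
#' @param results named list of data.frames and/or lists.
#' @param out_dir output directory (created if missing).
#' @param seed the seed that produced the results.
#' @param config optional configuration object stored in the manifest.
#' @param force overwrite existing files? Default FALSE (collision is an
#'   error).
#' @param digits significant digits for floats in CSV tables (default 8).
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(results, out_dir, seed = NULL, config = NULL,
                          force = FALSE, digits = 8) {
  stopifnot(is.list(results), !is.null(names(results)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      if (file.exists(f) && !force)
        stop("refusing to overwrite ", f, " (use force = TRUE)")
      num <- vapply(x, is.double, logical(1))
      x[num] <- lapply(x[num], function(v) signif(v, digits))
      utils::write.csv(x, f, row.names = FALSE)
    } else {
      f <- file.path(out_dir, paste0(nm, ".json"))
      if (file.exists(f) && !force)
        stop("refusing to overwrite ", f, " (use force = TRUE)")
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
    }
    files <- c(files, f)
  }
  manifest <- list(
    package = "synkin",
    version = as.character(utils::packageVersion("synkin")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config,
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

#' Read a sweep table back
#'
#' @param path CSV written by [write_results()] from a
#'   [parameter_sweep()] table.
#' @return A `sweep_result` data.frame.
#' @export
read_sweep <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("sweep_result", "data.frame")
  out
}
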