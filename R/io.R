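#' Write and read dwell-event lists in DWT-style text format
#'
#' The QuB-ecosystem dwell format: one header line per segment
#' (`Segment: <i> Dwells: <n>`) followed by one line per event with the
#' class index (0 = closed, 1 = open) and the duration in milliseconds
#' (written to 0.001 ms, the format's precision). Durations are seconds in
#' memory, milliseconds in files.
#'
#' @param events a single event data.frame (`class`, `duration` in s) or a
#'   list of them (one per segment).
#' @param path output file.
#' @return `write_dwt`: `path`, invisibly. `read_dwt`: a list of event
#'   data.frames (`class`, `duration` in seconds), one per segment.
#' @export
write_dwt <- function(events, path) {
  if (is.data.frame(events)) events <- list(events)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(events)) {
    ev <- events[[i]]
    cls_idx <- ifelse(as.character(ev$class) == "open", 1L, 0L)
    writeLines(sprintf("Segment: %d Dwells: %d", i, nrow(ev)), con)
    if (nrow(ev))
      writeLines(sprintf("\t%d\t%.3f", cls_idx, ev$duration * 1000), con)
  }
  invisible(path)
}

#' @rdname write_dwt
#' @export
read_dwt <- function(path) {
  lines <- readLines(path)
  segs <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) { i <- i + 1L; next }
    m <- regmatches(ln, regexec("^Segment:\\s*(\\d+)\\s+Dwells:\\s*(\\d+)", ln))[[1]]
    if (length(m) != 3L)
      stop("malformed segment header at line ", i, ": '", ln, "'")
    n <- as.integer(m[3])
    if (i + n > length(lines)) stop("truncated segment starting at line ", i)
    ev <- if (n > 0) {
      body <- lines[(i + 1L):(i + n)]
      parts <- strsplit(trimws(body), "\\s+")
      bad <- which(lengths(parts) < 2L)
      if (length(bad))
        stop("malformed dwell line at line ", i + bad[1])
      cls <- as.integer(vapply(parts, `[[`, "", 1L))
      dur <- as.numeric(vapply(parts, `[[`, "", 2L))
      if (anyNA(cls) || anyNA(dur))
        stop("malformed dwell line in segment starting at line ", i)
      data.frame(class = ifelse(cls == 1L, "open", "closed"),
                 duration = dur / 1000)
    } else data.frame(class = character(), duration = numeric())
    segs[[length(segs) + 1L]] <- ev
    i <- i + n + 1L
  }
  segs
}

#' Write and read sampled traces as CSV
#'
#' Two-column CSV (`time_s`, `current_pA`); metadata (sample rate,
#' amplitudes, conditions) travels in a JSON sidecar written next to the
#' CSV when `sidecar = TRUE`.
#'
#' @param trace a `sampled_trace`.
#' @param path output CSV path.
#' @param sidecar write `<path>.json` with the trace metadata.
#' @return `write_trace_csv`: `path` invisibly; `read_trace_csv`: a
#'   `sampled_trace`.
#' @export
write_trace_csv <- function(trace, path, sidecar = TRUE) {
  n <- length(trace$current)
  tt <- (seq_len(n) - 0.5) / trace$sample_rate
  utils::write.csv(data.frame(time_s = tt, current_pA = trace$current),
                   path, row.names = FALSE)
  if (sidecar)
    jsonlite::write_json(
      list(sample_rate = trace$sample_rate,
           amplitudes = as.list(trace$amplitudes),
           noise_sd = trace$noise_sd,
           filter_cutoff = trace$filter_cutoff,
           conditions = unclass(trace$conditions)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write and read sampled traces as flat float32 binary
#'
#' Little-endian 4-byte floats of the current samples, with the metadata
#' JSON sidecar at `<path>.json` (sample rate, amplitudes, conditions).
#' Compact interchange format for long traces; note the precision drop to
#' single floats.
#'
#' @param trace a `sampled_trace`.
#' @param path output file path.
#' @return `write_trace_bin`: `path` invisibly; `read_trace_bin`: a
#'   `sampled_trace`.
#' @export
write_trace_bin <- function(trace, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(trace$current), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(sample_rate = trace$sample_rate,
         n_samples = length(trace$current),
         amplitudes = as.list(trace$amplitudes),
         noise_sd = trace$noise_sd,
         filter_cutoff = trace$filter_cutoff,
         conditions = unclass(trace$conditions)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace_bin
#' @export
read_trace_bin <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar: ", side)
  meta <- jsonlite::fromJSON(side)
  con <- file(path, "rb")
  on.exit(close(con))
  cur <- readBin(con, numeric(), n = meta$n_samples, size = 4,
                 endian = "little")
  structure(list(current = cur, sample_rate = meta$sample_rate,
                 amplitudes = unlist(meta$amplitudes),
                 noise_sd = meta$noise_sd,
                 filter_cutoff = meta$filter_cutoff,
                 conditions = if (!is.null(meta$conditions))
                   do.call(conditions, meta$conditions) else NULL),
            class = "sampled_trace")
}

#' Write a MIL fit result as JSON
#'
#' Serializes estimates, standard errors, log-likelihood, convergence
#' flags and per-dataset conditions of a [fit_mil()] result.
#'
#' @param fit a `mil_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mil_fit <- function(fit, path) {
  stopifnot(inherits(fit, "mil_fit"))
  jsonlite::write_json(
    list(estimates = as.list(fit$estimates), se = as.list(fit$se),
         log_likelihood = fit$log_likelihood, n_events = fit$n_events,
         converged = fit$converged, se_available = fit$se_available,
         non_identifiable = fit$non_identifiable,
         conditions = lapply(fit$conditions, unclass)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::fromJSON(paste0(path, ".json")) else list()
  fs <- meta$sample_rate
  if (is.null(fs)) fs <- 1 / stats::median(diff(d$time_s))
  structure(list(current = d$current_pA, sample_rate = fs,
                 amplitudes = unlist(meta$amplitudes),
                 noise_sd = meta$noise_sd,
                 filter_cutoff = meta$filter_cutoff,
                 conditions = if (!is.null(meta$conditions))
                   do.call(conditions, meta$conditions) else NULL),
            class = "sampled_trace")
}
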