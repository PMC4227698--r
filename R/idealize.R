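#' Idealize a sampled trace by segmented k-means (SKM)
#'
#' Alternates (i) Viterbi decoding of the class sequence under a discrete
#' hidden Markov model with Gaussian emissions (class means = amplitude
#' estimates, pooled common variance) and transition probabilities
#' re-estimated from the current segmentation, with (ii) amplitude and
#' variance re-estimation as per-class sample means and pooled variance.
#' Iteration stops when the segmentation no longer changes. Classes are
#' labelled by amplitude order: the most positive class is `"open"`
#' (upward-deflection convention).
#'
#' This is the plain SKM variant: no amplitude constraints, no baseline
#' drift nodes, pooled emission variance across classes.
#'
#' @param trace a `sampled_trace` (see [render_trace()]) or numeric vector
#'   of currents (then `sample_rate` must be given).
#' @param n_classes number of conductance classes (2 for single-channel
#'   open/closed).
#' @param init_amplitudes starting class means, pA; default: symmetric
#'   quantiles of the trace.
#' @param max_iter maximum SKM iterations.
#' @param sample_rate sampling rate in Hz when `trace` is a bare vector.
#' @return an `idealized_events` data.frame with columns `class`,
#'   `duration` (s), `amplitude` (pA mean over the event), and attributes
#'   `amplitudes`, `noise_sd`, `converged`, `n_iter`, `dead_time` (0),
#'   `sample_rate`.
#' @export
skm_idealize <- function(trace, n_classes = 2, init_amplitudes = NULL,
                         max_iter = 30, sample_rate = NULL) {
  if (inherits(trace, "sampled_trace")) {
    y <- trace$current; fs <- trace$sample_rate
  } else {
    y <- as.numeric(trace); fs <- sample_rate
    if (is.null(fs)) stop("sample_rate required for a bare numeric trace")
  }
  if (length(y) <= 10L) stop("trace too short to idealize")
  k <- as.integer(n_classes)
  stopifnot(k >= 2L)
  if (is.null(init_amplitudes)) {
    qs <- stats::quantile(y, probs = seq(0.02, 0.98, length.out = k),
                          names = FALSE)
    mu <- as.numeric(qs)
    if (any(duplicated(mu))) mu <- mu + seq_len(k) * 1e-8
  } else {
    if (length(init_amplitudes) != k) stop("need one init amplitude per class")
    if (any(duplicated(init_amplitudes))) stop("init_amplitudes must be distinct")
    mu <- sort(as.numeric(init_amplitudes))
  }
  sdv <- max(stats::sd(y) / 2, 1e-8)
  logA <- log(matrix((1 - 0.95) / (k - 1), k, k) + diag(rep(0.95 - (1 - 0.95) / (k - 1), k)))
  log_init <- rep(log(1 / k), k)

  path_prev <- NULL; converged <- FALSE; reinit_used <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    path <- .viterbi_gauss(y, mu, sdv, log_init, logA)
    mom <- .class_moments(y, path, k)
    if (any(mom$n == 0)) {
      if (reinit_used) stop("degenerate class: no samples assigned after reinitialization")
      reinit_used <- TRUE
      empty <- which(mom$n == 0)
      mu[empty] <- stats::quantile(y, probs = (empty - 0.5) / k, names = FALSE)
      next
    }
    mu_new <- mom$sum / mom$n
    ss <- sum(mom$sumsq - mom$sum^2 / mom$n)
    sdv <- max(sqrt(ss / length(y)), 1e-8)
    # transition probabilities from the segmentation (pseudo-count 0.5)
    trans <- table(factor(path[-length(path)], levels = 1:k),
                   factor(path[-1], levels = 1:k)) + 0.5
    logA <- log(trans / rowSums(trans))
    occ <- mom$n / length(y)
    log_init <- log(pmax(occ, 1e-12))
    if (!is.null(path_prev) && identical(path, path_prev) &&
        max(abs(mu_new - mu)) < 1e-10) {
      mu <- mu_new; converged <- TRUE; break
    }
    mu <- mu_new; path_prev <- path
  }
  if (!converged) path <- .viterbi_gauss(y, mu, sdv, log_init, logA)

  # order classes by amplitude; top class = open
  ord <- order(mu)
  rank_of <- integer(k); rank_of[ord] <- seq_len(k)
  path_ranked <- rank_of[path]
  r <- rle(path_ranked)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cs <- c(0, cumsum(y))
  amp <- (cs[ends + 1L] - cs[starts]) / r$lengths
  cls <- if (k == 2L) c("closed", "open")[r$values] else r$values - 1L
  out <- data.frame(class = cls, duration = r$lengths / fs, amplitude = amp)
  structure(out,
            amplitudes = sort(mu), noise_sd = sdv, converged = converged,
            n_iter = it, dead_time = 0, sample_rate = fs,
            class = c("idealized_events", "data.frame"))
}

#' Impose a dead time on an event list
#'
#' Every event shorter than `td` is removed and its duration absorbed into
#' the flanking events, which merge when they then share a class; the scan
#' restarts until no event is shorter than `td`. Total duration is
#' conserved exactly. Idempotent for a fixed `td`.
#'
#' @param events an `idealized_events` or data.frame with `class` and
#'   `duration` columns (optionally `amplitude`).
#' @param td dead time, seconds (>= 0).
#' @return event list of the same shape, with attribute `dead_time = td`.
#' @export
impose_dead_time <- function(events, td) {
  stopifnot(td >= 0)
  cls <- as.character(events$class)
  dur <- as.numeric(events$duration)
  amp <- if ("amplitude" %in% names(events)) as.numeric(events$amplitude)
         else rep(NA_real_, length(dur))
  if (td > sum(dur)) stop("dead time exceeds the total record duration")
  if (td > 0) {
    repeat {
      n <- length(dur)
      short <- which(dur < td)
      if (!length(short) || n == 1L) break
      i <- short[1]
      if (i == 1L) {
        dur[2] <- dur[2] + dur[1]
        keep <- -1L
      } else if (i == n) {
        dur[n - 1L] <- dur[n - 1L] + dur[n]
        keep <- -n
      } else if (cls[i - 1L] == cls[i + 1L]) {
        w <- c(dur[i - 1L], dur[i + 1L])
        amp[i - 1L] <- sum(w * c(amp[i - 1L], amp[i + 1L])) / sum(w)
        dur[i - 1L] <- dur[i - 1L] + dur[i] + dur[i + 1L]
        keep <- c(-i, -(i + 1L))
      } else {
        dur[i - 1L] <- dur[i - 1L] + dur[i]
        keep <- -i
      }
      cls <- cls[keep]; dur <- dur[keep]; amp <- amp[keep]
    }
    # merge any residual same-class neighbours
    r <- rle(cls)
    if (any(r$lengths > 1L)) {
      grp <- rep(seq_along(r$lengths), r$lengths)
      dur2 <- as.vector(tapply(dur, grp, sum))
      amp2 <- as.vector(tapply(dur * amp, grp, sum)) / dur2
      cls <- r$values; dur <- dur2; amp <- amp2
    }
  }
  out <- data.frame(class = cls, duration = dur, amplitude = amp)
  at <- attributes(events)
  for (nm in setdiff(names(at), c("names", "row.names", "class")))
    attr(out, nm) <- at[[nm]]
  attr(out, "dead_time") <- td
  class(out) <- c("idealized_events", "data.frame")
  out
}

#' Segment an event list into clusters of channel activity
#'
#' A closed event longer than `tau_crit` terminates a cluster; clusters
#' containing no opening are discarded. Long desensitized dwells are
#' orders of magnitude longer than intra-cluster closings, so the result
#' is insensitive to `tau_crit` over a broad range.
#'
#' @param events event list with `class` and `duration`.
#' @param tau_crit critical closed duration, seconds (> 0).
#' @return data.frame with one row per cluster: `start`, `end` (event
#'   indices, inclusive), `n_open` (number of openings).
#' @export
segment_clusters <- function(events, tau_crit) {
  stopifnot(tau_crit > 0)
  n <- nrow(events)
  gap <- which(events$class == "closed" & events$duration > tau_crit)
  starts <- c(1L, gap + 1L)
  ends <- c(gap - 1L, n)
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  n_open <- mapply(function(s, e) sum(events$class[s:e] == "open"),
                   starts, ends)
  out <- data.frame(start = starts, end = ends, n_open = n_open)
  out[out$n_open > 0, , drop = FALSE]
}

#' Critical time between two exponential closed components
#'
#' Equal-misclassification criterion: the tau_crit between a fast
#' (intra-cluster) and a slow (inter-cluster) exponential component solves
#' `a_f exp(-t/tau_f) = a_s (1 - exp(-t/tau_s))`... the conventional form
#' equates the two misclassified areas. Used as the automatic default for
#' [segment_clusters()].
#'
#' @param tau_fast,tau_slow component time constants, s.
#' @param area_fast,area_slow component areas (weights).
#' @return tau_crit in seconds.
#' @export
tau_crit_equal_misclass <- function(tau_fast, tau_slow,
                                    area_fast = 0.5, area_slow = 0.5) {
  stopifnot(tau_fast < tau_slow)
  f <- function(t) area_fast * exp(-t / tau_fast) -
    area_slow * (1 - exp(-t / tau_slow))
  stats::uniroot(f, c(tau_fast, tau_slow * 20), tol = 1e-12)$root
}
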