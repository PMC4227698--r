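#' Exact stochastic simulation of gating dwells
#'
#' Gillespie simulation of the continuous-time Markov chain defined by a
#' kinetic scheme: the sojourn in state i is Exponential(-Q[i,i]) and the
#' successor is drawn with probability Q[i,j]/(-Q[i,i]). The initial state
#' is drawn from the equilibrium distribution unless given.
#'
#' @param scheme a [kinetic_scheme()].
#' @param cond a [conditions()] object.
#' @param n_events number of dwells to simulate (mutually exclusive with
#'   `total_time`).
#' @param total_time simulate until this much accumulated time (s); the last
#'   dwell is kept whole, so the total may overshoot.
#' @param seed RNG seed for reproducibility (`set.seed` is called when not
#'   `NULL`).
#' @param init_state optional starting state label.
#' @return a `dwell_sequence`: data.frame with columns `state`, `class`,
#'   `duration` (s) and attributes `conditions` and `seed`.
#' @export
simulate_dwells <- function(scheme, cond, n_events = NULL, total_time = NULL,
                            seed = NULL, init_state = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"), inherits(cond, "conditions"))
  if (is.null(n_events) == is.null(total_time))
    stop("give exactly one of n_events, total_time")
  if (!is.null(n_events) && n_events <= 0) stop("n_events must be > 0")
  if (!is.null(total_time) && total_time <= 0) stop("total_time must be > 0")
  if (!is.null(seed)) set.seed(seed)

  Q <- generator_matrix(scheme, cond)
  n <- nrow(Q)
  exit <- -diag(Q)
  if (any(exit <= 0)) stop("internal error: absorbing state in scheme")
  P <- Q / exit
  diag(P) <- 0

  cur <- if (is.null(init_state)) {
    pi0 <- equilibrium_probs(Q)
    sample.int(n, 1L, prob = pi0)
  } else match(init_state, scheme$states)
  if (is.na(cur)) stop("unknown init_state")

  cap <- if (!is.null(n_events)) n_events else
    max(64L, ceiling(total_time * max(exit)))
  st <- integer(cap); dur <- numeric(cap)
  i <- 0L; t_acc <- 0
  repeat {
    i <- i + 1L
    if (i > length(st)) { st <- c(st, integer(cap)); dur <- c(dur, numeric(cap)) }
    d <- stats::rexp(1L, exit[cur])
    st[i] <- cur; dur[i] <- d; t_acc <- t_acc + d
    if (!is.null(n_events) && i >= n_events) break
    if (!is.null(total_time) && t_acc >= total_time) break
    cur <- sample.int(n, 1L, prob = P[cur, ])
  }
  out <- data.frame(state = scheme$states[st[1:i]],
                    class = scheme$classes[st[1:i]],
                    duration = dur[1:i])
  attr(out, "conditions") <- cond
  attr(out, "seed") <- seed
  class(out) <- c("dwell_sequence", "data.frame")
  out
}

#' Collapse consecutive same-class dwells into aggregate sojourns
#'
#' Observed dwell times are sojourns in a conductance class, not a state;
#' consecutive dwells of the same class (e.g. C followed by D1) merge into
#' one closed interval. The result strictly alternates open/closed.
#'
#' @param dwells a `dwell_sequence` or any data.frame with `class` and
#'   `duration` columns.
#' @return data.frame with columns `class`, `duration`, alternating classes.
#' @export
aggregate_classes <- function(dwells) {
  r <- rle(as.character(dwells$class))
  grp <- rep(seq_along(r$lengths), r$lengths)
  out <- data.frame(class = r$values,
                    duration = as.vector(tapply(dwells$duration, grp, sum)))
  rownames(out) <- NULL
  out
}

# -3 dB cutoff fc of a Gaussian filter corresponds to sigma_t = 0.1325/fc.
.gauss_kernel <- function(sample_rate, cutoff) {
  sigma <- 0.1325 / cutoff * sample_rate      # in samples
  m <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-m, m), sd = sigma)
  k / sum(k)
}

#' Render a noisy sampled current trace from a dwell sequence
#'
#' Builds the piecewise-constant ideal current from class amplitudes,
#' applies a Gaussian low-pass filter (stand-in for the recording
#' hardware's anti-alias filter) and adds i.i.d. Gaussian noise. Open
#' deflections are positive, following the usual cell-attached display
#' convention.
#'
#' @param dwells a `dwell_sequence` (or alternating class/duration frame).
#' @param amplitudes named vector `c(closed = , open = )` in pA.
#' @param noise_sd noise SD in pA (>= 0).
#' @param sample_rate sampling rate, Hz.
#' @param filter_cutoff -3 dB Gaussian filter cutoff, Hz, or `NULL` for no
#'   filtering. Must satisfy `sample_rate > 2 * filter_cutoff`.
#' @param seed RNG seed for the noise.
#' @return a `sampled_trace`: list with `current` (pA), `sample_rate`,
#'   `amplitudes`, `noise_sd`, `filter_cutoff`, `conditions`.
#' @export
render_trace <- function(dwells, amplitudes = c(closed = 0, open = 7),
                         noise_sd = 1, sample_rate = 25000,
                         filter_cutoff = 10000, seed = NULL) {
  stopifnot(all(c("closed", "open") %in% names(amplitudes)), noise_sd >= 0)
  if (!is.null(filter_cutoff) && sample_rate <= 2 * filter_cutoff)
    stop("sample_rate must exceed twice the filter cutoff")
  if (!is.null(seed)) set.seed(seed)
  agg <- aggregate_classes(dwells)
  bounds <- cumsum(agg$duration)
  n <- max(1L, floor(bounds[length(bounds)] * sample_rate))
  tt <- (seq_len(n) - 0.5) / sample_rate
  idx <- findInterval(tt, c(0, bounds), rightmost.closed = TRUE)
  ideal <- unname(amplitudes[agg$class[pmin(idx, nrow(agg))]])
  cur <- ideal
  if (!is.null(filter_cutoff)) {
    k <- .gauss_kernel(sample_rate, filter_cutoff)
    if (length(k) > 1L) {
      m <- (length(k) - 1L) %/% 2L
      padded <- c(rep(ideal[1], m), ideal, rep(ideal[n], m))
      cur <- stats::filter(padded, k, sides = 2)[(m + 1L):(m + n)]
      cur <- as.numeric(cur)
    }
  }
  if (noise_sd > 0) cur <- cur + stats::rnorm(n, 0, noise_sd)
  structure(list(current = cur, sample_rate = sample_rate,
                 amplitudes = amplitudes, noise_sd = noise_sd,
                 filter_cutoff = filter_cutoff,
                 conditions = attr(dwells, "conditions")),
            class = "sampled_trace")
}

#' @export
print.sampled_trace <- function(x, ...) {
  cat(sprintf("Sampled trace: %d samples at %g kHz (%.2f s), noise %g pA\n",
              length(x$current), x$sample_rate / 1000,
              length(x$current) / x$sample_rate, x$noise_sd))
  invisible(x)
}

#' Simulate a multi-channel patch as summed independent channels
#'
#' `n_channels` independent copies of the scheme are simulated for the same
#' total time and their ideal currents summed; used to exercise NPo-style
#' activity measures.
#'
#' @inheritParams simulate_dwells
#' @param n_channels number of independent channels in the patch.
#' @param sample_rate sampling rate, Hz.
#' @return list with `level` (integer vector, number of simultaneously open
#'   channels per sample), `sample_rate`, `total_time`.
#' @export
simulate_multichannel_levels <- function(scheme, cond, n_channels, total_time,
                                         sample_rate = 25000, seed = NULL) {
  stopifnot(n_channels >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- floor(total_time * sample_rate)
  lev <- integer(n)
  for (ch in seq_len(n_channels)) {
    dw <- simulate_dwells(scheme, cond, total_time = total_time)
    agg <- aggregate_classes(dw)
    bounds <- cumsum(agg$duration)
    tt <- (seq_len(n) - 0.5) / sample_rate
    idx <- pmin(findInterval(tt, c(0, bounds), rightmost.closed = TRUE),
                nrow(agg))
    lev <- lev + as.integer(agg$class[idx] == "open")
  }
  list(level = lev, sample_rate = sample_rate, total_time = total_time)
}

# Deterministic per-dataset seed derived from the master seed so adding a
# condition or cell never perturbs the others. Kept below 2^31.
.derive_seed <- function(master, cell, cond_idx) {
  h <- (master %% 2147483647) * 48271
  h <- (h + cell * 69621 + cond_idx * 16807) %% 2147483647
  as.integer(h) + 1L
}

#' Generate a full synthetic dose/voltage experiment
#'
#' Produces one dataset per (cell, condition) with the statistical
#' structure the blockade analysis assumes: clusters of openings separated
#' by long desensitized dwells, brief intra-cluster closings, and
#' blocker-concentration-dependent blocked dwells. The default design
#' mirrors the dose experiment (100 uM agonist; blocker at 0/5/10/20 uM;
#' replicate cells).
#'
#' @param config list with elements:
#'   \describe{
#'     \item{rates}{named true rates (see [build_blockade_scheme()]).}
#'     \item{n_block_modes}{1 (default) or 2.}
#'     \item{doses}{blocker concentrations, uM (non-empty).}
#'     \item{voltages}{membrane potentials Vm, mV (default 0 = the
#'       reference potential).}
#'     \item{vsens_block}{voltage sensitivity of blocking, mV^-1 (default 0).}
#'     \item{conc_ACh}{agonist concentration, uM (default 100).}
#'     \item{n_cells}{replicate cells (default 3).}
#'     \item{n_events}{dwells per dataset (default 3000).}
#'     \item{seed}{master seed.}
#'     \item{render}{logical; also render sampled traces (default FALSE).}
#'     \item{amplitudes, noise_sd, sample_rate, filter_cutoff}{trace
#'       rendering parameters, as in [render_trace()].}
#'   }
#' @param out_dir optional directory; when given, dwell sequences (DWT
#'   format), trace CSVs and a JSON manifest are written there.
#' @return a `synth_experiment` list: `datasets` (each with `cell`, `cond`,
#'   `seed`, `dwells`, optionally `trace`), `config`, `manifest`
#'   (data.frame).
#' @export
synth_experiment <- function(config, out_dir = NULL) {
  cfg <- utils::modifyList(list(
    n_block_modes = 1, doses = NULL, voltages = 0, vsens_block = 0,
    conc_ACh = 100, n_cells = 3, n_events = 3000, seed = 1,
    render = FALSE, amplitudes = c(closed = 0, open = 7), noise_sd = 1,
    sample_rate = 25000, filter_cutoff = 10000), config)
  if (is.null(cfg$doses) || !length(cfg$doses)) stop("config$doses is empty")
  if (is.null(cfg$rates)) stop("config$rates missing")
  scheme <- build_blockade_scheme(cfg$rates, cfg$n_block_modes,
                                  vsens_block = cfg$vsens_block)
  grid <- expand.grid(dose = cfg$doses, Vm = cfg$voltages,
                      KEEP.OUT.ATTRS = FALSE)
  datasets <- list(); manifest <- NULL
  for (cell in seq_len(cfg$n_cells)) {
    for (ci in seq_len(nrow(grid))) {
      cond <- conditions(conc_ACh = cfg$conc_ACh,
                         conc_blocker = grid$dose[ci], Vm = grid$Vm[ci])
      sd_i <- .derive_seed(cfg$seed, cell, ci)
      dw <- simulate_dwells(scheme, cond, n_events = cfg$n_events,
                            seed = sd_i)
      ds <- list(cell = cell, cond = cond, seed = sd_i, dwells = dw)
      if (isTRUE(cfg$render))
        ds$trace <- render_trace(dw, cfg$amplitudes, cfg$noise_sd,
                                 cfg$sample_rate, cfg$filter_cutoff,
                                 seed = sd_i + 1L)
      id <- sprintf("cell%02d_dose%g_Vm%g", cell, grid$dose[ci], grid$Vm[ci])
      datasets[[id]] <- ds
      manifest <- rbind(manifest, data.frame(
        id = id, cell = cell, dose = grid$dose[ci], Vm = grid$Vm[ci],
        seed = sd_i, n_events = nrow(dw)))
    }
  }
  out <- structure(list(datasets = datasets, config = cfg,
                        manifest = manifest, scheme = scheme),
                   class = "synth_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(datasets)) {
      write_dwt(aggregate_classes(datasets[[id]]$dwells),
                file.path(out_dir, paste0(id, ".dwt")))
      if (!is.null(datasets[[id]]$trace))
        write_trace_csv(datasets[[id]]$trace,
                        file.path(out_dir, paste0(id, ".csv")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", digits = NA)
  }
  out
}
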