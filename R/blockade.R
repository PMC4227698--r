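#' Apparent mean open time across replicate cells
#'
#' The apparent mean open time (tau_app) is the mean duration of the
#' identified opening events, pooled within a cell; across cells the
#' per-cell means are summarized as mean +/- SEM. Open-channel block
#' shortens tau_app dose-dependently because blocker binding terminates
#' openings in competition with closing and desensitization.
#'
#' @param cells a single event data.frame (`class`, `duration`) or a list
#'   of them, one per cell.
#' @return list with `tau_app` (s), `sem`, `n_cells`, `per_cell` (s).
#' @export
apparent_open_time <- function(cells) {
  if (is.data.frame(cells)) cells <- list(cells)
  per_cell <- vapply(cells, function(ev) {
    op <- ev$duration[ev$class == "open"]
    if (!length(op)) stop("no open events in a cell")
    mean(op)
  }, 0)
  n <- length(per_cell)
  list(tau_app = mean(per_cell),
       sem = if (n > 1) stats::sd(per_cell) / sqrt(n) else NA_real_,
       n_cells = n, per_cell = per_cell)
}

#' Fit an exponential mixture to closed dwell times
#'
#' Maximum-likelihood fit (EM) of a mixture of exponential densities to
#' closed-time durations, with deterministic quantile-based initialization,
#' plus a log10-binned square-root-ordinate histogram for display. The
#' number of components is either given or chosen by a BIC scan over 2..6.
#' Components whose fitted area falls below 1/n are dropped and the model
#' refit (reported in `$dropped`).
#'
#' @param events event data.frame (`class`, `duration`) or a numeric
#'   vector of closed durations in seconds.
#' @param n_components number of exponential components, or `NULL` for a
#'   BIC scan over 2..6.
#' @param max_iter,tol EM stopping controls.
#' @param n_bins histogram bin count.
#' @return list with `tau` (s, increasing), `area`, `log_likelihood`,
#'   `bic`, `n`, `dropped`, and `histogram` (data.frame: `log10_ms`,
#'   `count`, `sqrt_count`).
#' @export
closed_time_components <- function(events, n_components = NULL,
                                   max_iter = 500, tol = 1e-8, n_bins = 40) {
  x <- if (is.data.frame(events)) events$duration[events$class == "closed"]
       else as.numeric(events)
  x <- x[x > 0]
  if (length(x) < 50) stop("need at least 50 closed events")
  fit_m <- function(m) {
    tau <- as.numeric(stats::quantile(x, probs = (seq_len(m) - 0.5) / m,
                                      names = FALSE))
    tau <- sort(unique(pmax(tau, min(x) / 2)))
    if (length(tau) < m) tau <- tau * exp(seq(-0.1, 0.1, length.out = m))
    a <- rep(1 / m, m)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d <- vapply(seq_len(m), function(j) a[j] / tau[j] * exp(-x / tau[j]),
                  numeric(length(x)))
      tot <- rowSums(d)
      tot[tot <= 0] <- 1e-300
      ll <- sum(log(tot))
      r <- d / tot
      nk <- colSums(r)
      a <- nk / length(x)
      tau <- colSums(r * x) / nk
      if (abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    ord <- order(tau)
    list(tau = tau[ord], area = a[ord], log_likelihood = ll,
         bic = -2 * ll + (2 * m - 1) * log(length(x)), m = m)
  }
  dropped <- 0L
  if (is.null(n_components)) {
    fits <- lapply(2:6, fit_m)
    best <- fits[[which.min(vapply(fits, `[[`, 0, "bic"))]]
  } else {
    stopifnot(n_components >= 1)
    best <- fit_m(n_components)
  }
  while (any(best$area < 1 / length(x)) && best$m > 1L) {
    dropped <- dropped + sum(best$area < 1 / length(x))
    best <- fit_m(best$m - sum(best$area < 1 / length(x)))
  }
  lx <- log10(x * 1000)
  br <- seq(min(lx), max(lx), length.out = n_bins + 1L)
  h <- hist(lx, breaks = br, plot = FALSE)
  list(tau = best$tau, area = best$area,
       log_likelihood = best$log_likelihood, bic = best$bic,
       n = length(x), dropped = dropped,
       histogram = data.frame(log10_ms = h$mids, count = h$counts,
                              sqrt_count = sqrt(h$counts)))
}

#' Dose-dependence summary of blockade kinetics
#'
#' The headline estimator: the bimolecular blocking rate constant `k_plus_B`
#' is the slope of the unweighted least-squares line (intercept fitted and
#' reported) of blocking rate versus blocker concentration, with the
#' slope's standard error; the unblocking rate constant `k_minus_B` is the
#' unweighted mean of the unblocking rates over all doses and cells, with
#' SEM; and `Kd = k_minus_B / k_plus_B` with first-order (delta-method)
#' error propagation. With two blockade modes each mode is summarized
#' separately; modes are matched across datasets by unblocking-rate
#' ordering (fast = larger `k_minus_B`).
#'
#' @param rates data.frame with one row per (cell, dose, mode): columns
#'   `dose` (uM), `blocking_rate` (s^-1 at that dose), `unblocking_rate`
#'   (s^-1), optional `cell`, `mode` (`"fast"`/`"slow"`), `excluded`
#'   (logical exclusion hook).
#' @param through_origin also report the slope of the no-intercept fit.
#' @return a `blockade_summary`: list with one element per mode, each
#'   holding `k_plus_B`, `k_plus_B_se`, `intercept`, `k_plus_B_origin`,
#'   `k_minus_B`, `k_minus_B_sem`, `n_unblocking`, `Kd`, `Kd_se`, and
#'   `per_dose` (mean +/- SEM of rates by dose).
#' @export
blocking_kinetics <- function(rates, through_origin = TRUE) {
  stopifnot(all(c("dose", "blocking_rate", "unblocking_rate") %in%
                  names(rates)))
  if (!is.null(rates$excluded)) rates <- rates[!rates$excluded, , drop = FALSE]
  if (is.null(rates$mode)) rates$mode <- "single"
  out <- list()
  for (md in unique(rates$mode)) {
    d <- rates[rates$mode == md, , drop = FALSE]
    if (length(unique(d$dose[d$dose > 0])) < 2)
      stop("need blocking rates at >= 2 non-zero doses to fit a slope")
    fit <- stats::lm(blocking_rate ~ dose, data = d)
    sm <- summary(fit)$coefficients
    kpb <- sm["dose", "Estimate"]; kpb_se <- sm["dose", "Std. Error"]
    k0 <- if (through_origin)
      summary(stats::lm(blocking_rate ~ dose + 0, data = d))$coefficients["dose", "Estimate"]
    else NA_real_
    ub <- d$unblocking_rate
    kmb <- mean(ub)
    kmb_sem <- if (length(ub) > 1) stats::sd(ub) / sqrt(length(ub)) else 0
    kd <- kmb / kpb
    kd_se <- kd * sqrt((kmb_sem / kmb)^2 + (kpb_se / kpb)^2)
    agg <- function(v) {
      mns <- tapply(v, d$dose, mean)
      sems <- tapply(v, d$dose, function(z)
        if (length(z) > 1) stats::sd(z) / sqrt(length(z)) else 0)
      list(mean = mns, sem = sems)
    }
    br <- agg(d$blocking_rate); ur <- agg(d$unblocking_rate)
    out[[md]] <- list(
      k_plus_B = kpb, k_plus_B_se = kpb_se,
      intercept = sm["(Intercept)", "Estimate"],
      k_plus_B_origin = k0,
      k_minus_B = kmb, k_minus_B_sem = kmb_sem, n_unblocking = length(ub),
      Kd = kd, Kd_se = kd_se,
      per_dose = data.frame(dose = as.numeric(names(br$mean)),
                            blocking_rate = as.numeric(br$mean),
                            blocking_sem = as.numeric(br$sem),
                            unblocking_rate = as.numeric(ur$mean),
                            unblocking_sem = as.numeric(ur$sem)))
  }
  structure(out, class = "blockade_summary")
}

#' @export
print.blockade_summary <- function(x, ...) {
  for (md in names(x)) {
    s <- x[[md]]
    cat(sprintf("mode %s: k+B = %.3g +/- %.2g uM^-1 s^-1, k-B = %.3g +/- %.2g s^-1, Kd = %.3g +/- %.2g uM (n=%d)\n",
                md, s$k_plus_B, s$k_plus_B_se, s$k_minus_B, s$k_minus_B_sem,
                s$Kd, s$Kd_se, s$n_unblocking))
  }
  invisible(x)
}

#' Build a per-dataset rate frame from per-dose MIL fits
#'
#' Converts `mil_fit` objects (one per cell x dose) into the flat table
#' [blocking_kinetics()] consumes. Blocking rates are the fitted
#' bimolecular constants scaled by each dataset's blocker concentration.
#' With two blockade modes, modes are labelled fast/slow by the fitted
#' unblocking-rate ordering within each dataset (nearest-lifetime
#' matching across datasets).
#'
#' @param fits list of `mil_fit` objects.
#' @param cells,doses vectors parallel to `fits`.
#' @return data.frame with `cell`, `dose`, `mode`, `blocking_rate`,
#'   `unblocking_rate` and standard-error columns.
#' @export
blockade_rate_frame <- function(fits, cells, doses) {
  stopifnot(length(fits) == length(cells), length(fits) == length(doses))
  rows <- list()
  for (i in seq_along(fits)) {
    est <- fits[[i]]$estimates; se <- fits[[i]]$se
    if (all(c("kB_on", "kB_off") %in% names(est))) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell = cells[i], dose = doses[i], mode = "single",
        blocking_rate = est[["kB_on"]] * doses[i],
        blocking_se = se[["kB_on"]] * doses[i],
        unblocking_rate = est[["kB_off"]], unblocking_se = se[["kB_off"]])
    } else {
      labs <- c("fast", "slow")
      offs <- c(est[["kB_off_fast"]], est[["kB_off_slow"]])
      ord <- order(offs, decreasing = TRUE)   # fast = larger k-B
      src <- c("fast", "slow")[ord]
      for (k in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          cell = cells[i], dose = doses[i], mode = labs[k],
          blocking_rate = est[[paste0("kB_on_", src[k])]] * doses[i],
          blocking_se = se[[paste0("kB_on_", src[k])]] * doses[i],
          unblocking_rate = est[[paste0("kB_off_", src[k])]],
          unblocking_se = se[[paste0("kB_off_", src[k])]])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Voltage dependence of blockade
#'
#' Cell-attached recordings do not clamp the true membrane potential:
#' `Vm = V_rest - V_hold`, where the resting potential `V_rest` is
#' estimated as the reversal point of the line of single-channel current
#' amplitude versus holding potential. The voltage dependence of blocking
#' is summarized as the least-squares slope of `ln(k_plus_B)` versus `Vm`.
#' For a cationic pore blocker, blocking accelerates with
#' hyperpolarization (negative slope).
#'
#' @param amplitude_data data.frame with `V_hold` (mV) and `amplitude` (pA).
#' @param kb_data data.frame with `V_hold` (mV) and `k_plus_B`
#'   (uM^-1 s^-1); >= 3 holding potentials.
#' @param slope_tol minimum |slope| (pA/mV) for the amplitude line to
#'   define a reversal point.
#' @return a `voltage_series` list: `V_rest`, `Vm`, `slope`, `slope_se`,
#'   `increases_with_hyperpolarization`, `amp_fit`, `data`.
#' @export
voltage_dependence <- function(amplitude_data, kb_data, slope_tol = 1e-6) {
  stopifnot(nrow(kb_data) >= 3)
  af <- stats::lm(amplitude ~ V_hold, data = amplitude_data)
  b <- stats::coef(af)
  if (abs(b[["V_hold"]]) < slope_tol)
    stop("amplitude-vs-V_hold slope too small: V_rest undefined")
  v_rest <- -b[["(Intercept)"]] / b[["V_hold"]]
  kb <- kb_data
  kb$Vm <- v_rest - kb$V_hold
  lf <- stats::lm(log(k_plus_B) ~ Vm, data = kb)
  sm <- summary(lf)$coefficients
  slope <- sm["Vm", "Estimate"]; slope_se <- sm["Vm", "Std. Error"]
  structure(list(V_rest = v_rest, Vm = kb$Vm,
                 slope = slope, slope_se = slope_se,
                 increases_with_hyperpolarization = slope < 0,
                 amp_fit = b, data = kb), class = "voltage_series")
}

#' Channel activity (NPo) from a multi-level record
#'
#' `NPo = sum_i i * P_o,i`, where `P_o,i` is the fraction of time with `i`
#' channels simultaneously open and `N_max` the maximal number of
#' simultaneously open channels. The standard definition is used. Mean
#' open time is taken from sojourns at exactly one open channel.
#'
#' @param x either the result of [simulate_multichannel_levels()] (a list
#'   with `level` and `sample_rate`) or a data.frame of events with integer
#'   `class` levels and `duration`.
#' @param N_max maximal level considered; default: the observed maximum.
#' @return an `agonist_activity` list: `NPo`, `N_max`, `P_o` (named vector
#'   over levels 0..N_max), `mean_open_time` (s, NA if no level-1 sojourn).
#' @export
agonist_activity <- function(x, N_max = NULL) {
  if (is.data.frame(x)) {
    lev <- as.integer(x$class); dur <- x$duration
  } else {
    lev <- as.integer(x$level); dur <- rep(1 / x$sample_rate, length(lev))
  }
  if (is.null(N_max)) N_max <- max(lev)
  if (N_max == 0) {
    warning("no open levels observed; NPo = 0")
    return(structure(list(NPo = 0, N_max = 0L,
                          P_o = c(`0` = 1), mean_open_time = NA_real_),
                     class = "agonist_activity"))
  }
  tt <- tapply(dur, factor(pmin(lev, N_max), levels = 0:N_max), sum)
  tt[is.na(tt)] <- 0
  P_o <- as.numeric(tt) / sum(dur)
  names(P_o) <- 0:N_max
  NPo <- sum((0:N_max) * P_o)
  r <- rle(lev)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cumdur <- c(0, cumsum(dur))
  sojourn <- cumdur[ends + 1L] - cumdur[starts]
  mot <- if (any(r$values == 1L)) mean(sojourn[r$values == 1L]) else NA_real_
  structure(list(NPo = NPo, N_max = as.integer(N_max), P_o = P_o,
                 mean_open_time = mot), class = "agonist_activity")
}
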