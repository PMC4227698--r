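test_that("two-state interval likelihood equals exponential log-densities", {
  sch <- two_state_scheme(alpha = 100, beta = 50)
  cond <- conditions()
  # a single complete open dwell of 10 ms terminated by a closure
  ll <- interval_log_likelihood(sch, cond,
                                data.frame(class = "open", duration = 0.01),
                                censor_last = FALSE)
  expect_equal(ll, log(100) - 100 * 0.01, tolerance = 1e-12)

  # any alternating sequence: sum of independent exponential log-densities
  set.seed(3)
  n <- 40
  dw <- data.frame(class = rep(c("open", "closed"), n / 2),
                   duration = c(rbind(rexp(n / 2, 100), rexp(n / 2, 50))))
  ll2 <- interval_log_likelihood(sch, cond, dw, censor_last = FALSE)
  by_hand <- sum(log(100) - 100 * dw$duration[dw$class == "open"]) +
    sum(log(50) - 50 * dw$duration[dw$class == "closed"])
  expect_equal(ll2, by_hand, tolerance = 1e-10)

  # censored final interval contributes only the survivor
  ll3 <- interval_log_likelihood(sch, cond, dw, censor_last = TRUE)
  expect_equal(ll3, by_hand - log(50), tolerance = 1e-10)

  expect_error(interval_log_likelihood(sch, cond,
    data.frame(class = c("open", "open"), duration = c(0.1, 0.1))),
    "alternate")
})

test_that("interval likelihood matches a matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  # one open state, two closed states
  sch3 <- three_state_scheme()
  cond <- conditions()
  dw <- aggregate_classes(simulate_dwells(sch3, cond, n_events = 200, seed = 17))
  for (censor in c(TRUE, FALSE)) {
    got <- interval_log_likelihood(sch3, cond, dw, censor_last = censor)
    want <- oracle_interval_ll(sch3, cond, dw, censor_last = censor)
    expect_equal(got, want, tolerance = 1e-6)
  }

  # two open states exercise the general forward pass
  scho <- two_open_scheme()
  dwo <- aggregate_classes(simulate_dwells(scho, cond, n_events = 200, seed = 18))
  got <- interval_log_likelihood(scho, cond, dwo)
  want <- oracle_interval_ll(scho, cond, dwo)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("likelihood is invariant to state permutation within an aggregate", {
  cond <- conditions()
  sch_a <- three_state_scheme(80, 900, 30, 25)
  # same model with the closed states defined in the opposite order
  sch_b <- kinetic_scheme(c("C2", "O", "C1"), c("closed", "open", "closed"),
    rbind(scheme_edge("O", "C1", "a1", rate_law(80)),
          scheme_edge("C1", "O", "b1", rate_law(900)),
          scheme_edge("O", "C2", "a2", rate_law(30)),
          scheme_edge("C2", "O", "b2", rate_law(25))))
  dw <- aggregate_classes(simulate_dwells(sch_a, cond, n_events = 150, seed = 4))
  expect_equal(interval_log_likelihood(sch_a, cond, dw),
               interval_log_likelihood(sch_b, cond, dw), tolerance = 1e-10)
})

test_that("two-state MIL equals the closed-form exponential MLE", {
  sch <- two_state_scheme(alpha = 100, beta = 50)
  cond <- conditions()
  dw <- aggregate_classes(simulate_dwells(sch, cond, n_events = 10000, seed = 2))
  if (dw$class[nrow(dw)] == "open") dw <- dw[-nrow(dw), ]
  fit <- fit_mil(sch, list(list(dwells = dw, cond = cond)),
                 free = c("alpha", "beta"), n_starts = 2)
  op <- dw$duration[dw$class == "open"]
  cl <- dw$duration[dw$class == "closed"]
  alpha_hat <- 1 / mean(op)                      # all open dwells complete
  beta_hat <- (length(cl) - 1) / sum(cl)         # final closed dwell censored
  expect_equal(unname(fit$estimates["alpha"]), alpha_hat,
               tolerance = 1e-6)
  expect_equal(unname(fit$estimates["beta"]), beta_hat,
               tolerance = 1e-6)
  expect_lt(abs(fit$estimates["alpha"] - 100), 3 * fit$se["alpha"])
  expect_lt(abs(fit$estimates["beta"] - 50), 3 * fit$se["beta"])
  expect_true(fit$converged)
  expect_true(fit$se_available)
})

test_that("blockade rate constants are recovered from dwell data", {
  sch <- build_blockade_scheme(default_rate_table(1))
  cond <- conditions(conc_blocker = 10)
  dw <- aggregate_classes(simulate_dwells(sch, cond, n_events = 4000, seed = 6))
  fit <- fit_mil(sch, list(list(dwells = dw, cond = cond)),
                 free = c("kB_on", "kB_off"), n_starts = 3)
  expect_lt(abs(fit$estimates["kB_on"] - 15), 3 * fit$se["kB_on"])
  expect_lt(abs(fit$estimates["kB_off"] - 2), 3 * fit$se["kB_off"])
})

test_that("rates unexercised by the data are flagged non-identifiable", {
  sch <- build_blockade_scheme(default_rate_table(1))
  cond0 <- conditions(conc_blocker = 0)
  dw <- aggregate_classes(simulate_dwells(sch, cond0, n_events = 300, seed = 10))
  fit <- fit_mil(sch, list(list(dwells = dw, cond = cond0)),
                 free = c("kB_on"), n_starts = 1)
  expect_identical(fit$non_identifiable, "kB_on")
  expect_true(is.na(fit$estimates["kB_on"]))
})

test_that("estimator error shrinks with the number of events", {
  sch <- two_state_scheme(alpha = 100, beta = 50)
  cond <- conditions()
  rmse <- function(n_events, reps) {
    errs <- vapply(seq_len(reps), function(r) {
      dw <- aggregate_classes(simulate_dwells(sch, cond, n_events = n_events,
                                              seed = 1000 + 7 * r + n_events))
      f <- fit_mil(sch, list(list(dwells = dw, cond = cond)),
                   free = c("alpha", "beta"), n_starts = 1)
      f$estimates[["alpha"]] - 100
    }, 0)
    sqrt(mean(errs^2))
  }
  expect_lt(rmse(10000, 20), rmse(1000, 20))
})

test_that("joint and per-dose fits agree on shared blockade constants", {
  sch <- build_blockade_scheme(default_rate_table(1))
  doses <- c(5, 10, 20)
  sets <- lapply(seq_along(doses), function(i) {
    cond <- conditions(conc_blocker = doses[i])
    list(dwells = aggregate_classes(
      simulate_dwells(sch, cond, n_events = 3000, seed = 40 + i)),
      cond = cond)
  })
  joint <- fit_mil(sch, sets, free = c("kB_on", "kB_off"), n_starts = 2)
  seps <- lapply(sets, function(s)
    fit_mil(sch, list(s), free = c("kB_on", "kB_off"), n_starts = 2))
  rf <- blockade_rate_frame(seps, cells = rep(1, 3), doses = doses)
  slope <- blocking_kinetics(rf)
  comb_se <- sqrt(slope$single$k_plus_B_se^2 + joint$se[["kB_on"]]^2)
  expect_lt(abs(slope$single$k_plus_B - joint$estimates[["kB_on"]]),
            3 * comb_se + 1e-8)
})
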