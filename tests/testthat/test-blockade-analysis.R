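test_that("apparent open time averages openings and tracks competing exits", {
  one_cell <- data.frame(class = c("open", "closed", "open"),
                         duration = c(0.002, 0.1, 0.004))
  res <- apparent_open_time(one_cell)
  expect_equal(res$tau_app, 0.003)

  # control: total open exit rate 500 /s -> 2 ms; blocker doubling the exit
  # rate halves tau_app
  r <- default_rate_table(1)
  sch <- build_blockade_scheme(r)
  dw0 <- simulate_dwells(sch, conditions(conc_blocker = 0),
                         n_events = 6000, seed = 51)
  a0 <- aggregate_classes(dw0)
  op0 <- a0$duration[a0$class == "open"]
  expect_lt(abs(mean(op0) - 0.002), 3 * sd(op0) / sqrt(length(op0)))

  # kB_on * c = 500 at c = 500/15 uM
  dwb <- simulate_dwells(sch, conditions(conc_blocker = 500 / 15),
                         n_events = 6000, seed = 52)
  ab <- aggregate_classes(dwb)
  opb <- ab$duration[ab$class == "open"]
  expect_lt(abs(mean(opb) - 0.001), 3 * sd(opb) / sqrt(length(opb)))

  cells <- list(one_cell, data.frame(class = "open", duration = 0.005))
  mc <- apparent_open_time(cells)
  expect_equal(mc$tau_app, mean(c(0.003, 0.005)))
  expect_equal(mc$n_cells, 2L)
  expect_error(apparent_open_time(data.frame(class = "closed", duration = 1)),
               "no open")
})

test_that("exponential mixture fitting recovers components", {
  set.seed(61)
  x1 <- rexp(5000, 1 / 0.010)            # tau = 10 ms
  f1 <- closed_time_components(x1, n_components = 1)
  expect_length(f1$tau, 1L)
  expect_lt(abs(f1$tau - 0.010), 3 * 0.010 / sqrt(5000))

  x2 <- c(rexp(2500, 1 / 0.001), rexp(2500, 1 / 0.100))
  f2 <- closed_time_components(x2)       # BIC scan
  expect_length(f2$tau, 2L)
  se_area <- sqrt(0.5 * 0.5 / 5000)
  expect_lt(abs(f2$area[1] - 0.5), 3 * se_area + 0.02)
  expect_lt(abs(f2$tau[1] - 0.001), 0.0002)
  expect_lt(abs(f2$tau[2] - 0.100), 0.010)
  expect_identical(sum(f2$histogram$count), 5000L)
  expect_error(closed_time_components(rexp(10, 1)), "at least 50")
})

test_that("blockade closed component grows with dose at constant lifetime", {
  sch <- build_blockade_scheme(default_rate_table(1))
  fits <- lapply(c(5, 20), function(dose) {
    dw <- aggregate_classes(simulate_dwells(
      sch, conditions(conc_blocker = dose), n_events = 8000,
      seed = 70 + dose))
    closed_time_components(dw, n_components = 3)
  })
  # slowest component ~ blocked lifetime 1/kB_off = 500 ms at both doses
  tauB <- vapply(fits, function(f) f$tau[3], 0)
  areaB <- vapply(fits, function(f) f$area[3], 0)
  expect_gt(areaB[2], areaB[1])                 # area rises with dose
  expect_lt(abs(log(tauB[2] / tauB[1])), 0.35)  # lifetime dose-invariant
  expect_lt(abs(tauB[1] - 0.5), 0.15)
})

test_that("blocking kinetics reduce to exact arithmetic on exact inputs", {
  rates <- data.frame(dose = c(5, 10, 20),
                      blocking_rate = c(75, 150, 300),
                      unblocking_rate = c(2, 2, 2))
  # exact inputs: lm warns about a perfect fit, which is the point here
  bs <- suppressWarnings(blocking_kinetics(rbind(rates, rates[1, ])))
  s <- bs$single
  expect_equal(s$k_plus_B, 15, tolerance = 1e-12)
  expect_equal(s$intercept, 0, tolerance = 1e-10)
  expect_equal(s$k_minus_B, 2, tolerance = 1e-12)
  expect_equal(s$k_minus_B_sem, 0)
  expect_equal(s$Kd, 2 / 15, tolerance = 1e-12)
  # error propagation reduces to the exact ratio when both SEs vanish
  expect_equal(s$Kd_se, 0, tolerance = 1e-12)
  expect_error(blocking_kinetics(data.frame(dose = 5, blocking_rate = 75,
                                            unblocking_rate = 2)),
               ">= 2")
})

test_that("exclusion hook drops flagged rows", {
  rates <- data.frame(dose = c(5, 10, 20, 20),
                      blocking_rate = c(75, 150, 300, 9000),
                      unblocking_rate = c(2, 2, 2, 50),
                      excluded = c(FALSE, FALSE, FALSE, TRUE))
  s <- suppressWarnings(blocking_kinetics(rates))$single
  expect_equal(s$k_plus_B, 15, tolerance = 1e-12)
  expect_equal(s$k_minus_B, 2, tolerance = 1e-12)
})

test_that("two-mode fits keep the fast/slow unblocking order", {
  sch <- build_blockade_scheme(default_rate_table(2), n_block_modes = 2)
  cond <- conditions(conc_blocker = 10)
  n_rep <- 20
  ok <- 0L
  for (r in seq_len(n_rep)) {
    dw <- aggregate_classes(simulate_dwells(sch, cond, n_events = 2500,
                                            seed = 500 + r))
    f <- fit_mil(sch, list(list(dwells = dw, cond = cond)),
                 free = c("kB_on_fast", "kB_off_fast",
                          "kB_on_slow", "kB_off_slow"), n_starts = 2)
    rf <- blockade_rate_frame(list(f), cells = 1, doses = 10)
    kfast <- rf$unblocking_rate[rf$mode == "fast"]
    kslow <- rf$unblocking_rate[rf$mode == "slow"]
    # both modes detected in the characteristic ranges, correctly ordered
    ok <- ok + (kfast > kslow && kfast > 20 && kslow < 10)
  }
  expect_gte(ok, 19L)
})

test_that("voltage dependence recovers the reversal point and e-fold slope", {
  # exact line: amplitude = 0.1 V_hold + 2 reverses at V_hold = -20 mV
  amp <- data.frame(V_hold = c(50, 70, 100, 130),
                    amplitude = 0.1 * c(50, 70, 100, 130) + 2)
  # end-to-end: voltage-sensitive blocking k+B(Vm) = k0 exp(-Vm / 50 mV)
  sch <- build_blockade_scheme(default_rate_table(1), vsens_block = -0.02)
  sch_blind <- build_blockade_scheme(default_rate_table(1))
  v_rest <- -20
  v_hold <- c(50, 70, 100, 130)
  fits <- lapply(v_hold, function(vh) {
    cond <- conditions(conc_blocker = 20, Vm = v_rest - vh)
    dw <- aggregate_classes(simulate_dwells(sch, cond, n_events = 2500,
                                            seed = 300 + vh))
    # apparent k+B at each potential: fit without the voltage model
    fit_mil(sch_blind,
            list(list(dwells = dw, cond = conditions(conc_blocker = 20))),
            free = c("kB_on", "kB_off"), n_starts = 2)
  })
  kb <- data.frame(V_hold = v_hold,
                   k_plus_B = vapply(fits, function(f)
                     unname(f$estimates["kB_on"]), 0))
  vs <- voltage_dependence(amp, kb)
  expect_equal(vs$V_rest, -20, tolerance = 1e-9)
  expect_equal(vs$Vm, v_rest - v_hold)
  # SE floor: the line has only 2 residual df, so 3 SE alone can be
  # accidentally tight
  expect_lt(abs(vs$slope - (-0.02)), 3 * vs$slope_se + 0.002)
  expect_true(vs$increases_with_hyperpolarization)

  # voltage-insensitive blocking: slope CI covers zero
  sch0 <- build_blockade_scheme(default_rate_table(1), vsens_block = 0)
  fits0 <- lapply(v_hold, function(vh) {
    cond <- conditions(conc_blocker = 20, Vm = v_rest - vh)
    dw <- aggregate_classes(simulate_dwells(sch0, cond, n_events = 2500,
                                            seed = 400 + vh))
    fit_mil(sch0, list(list(dwells = dw, cond = cond)),
            free = c("kB_on", "kB_off"), n_starts = 2)
  })
  kb0 <- data.frame(V_hold = v_hold,
                    k_plus_B = vapply(fits0, function(f)
                      unname(f$estimates["kB_on"]), 0))
  vs0 <- voltage_dependence(amp, kb0)
  expect_lt(abs(vs0$slope), 3 * vs0$slope_se + 0.002)

  flat <- data.frame(V_hold = c(50, 70, 100), amplitude = c(5, 5, 5))
  expect_error(voltage_dependence(flat, kb), "V_rest undefined")
})

test_that("NPo activity follows the occupancy definition", {
  # one channel open 30% of the time
  ev <- data.frame(class = c(0L, 1L, 0L, 1L),
                   duration = c(0.4, 0.2, 0.3, 0.1))
  aa <- agonist_activity(ev)
  expect_equal(aa$NPo, 0.3, tolerance = 1e-12)
  expect_equal(sum(aa$P_o), 1, tolerance = 1e-12)
  expect_equal(aa$mean_open_time, 0.15, tolerance = 1e-12)

  # two independent channels with Po = 0.5 each
  sch <- two_state_scheme(alpha = 100, beta = 100)
  lev <- simulate_multichannel_levels(sch, conditions(), n_channels = 2,
                                      total_time = 40, seed = 71)
  aa2 <- agonist_activity(lev)
  expect_equal(sum(aa2$P_o), 1, tolerance = 1e-12)
  expect_identical(aa2$N_max, 2L)
  expect_lt(abs(aa2$NPo - 1), 0.1)

  expect_warning(aa0 <- agonist_activity(
    data.frame(class = 0L, duration = 1)), "NPo = 0")
  expect_equal(aa0$NPo, 0)
})
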