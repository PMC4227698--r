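test_that("blockade scheme construction matches the sequential-block topology", {
  sch1 <- build_blockade_scheme(default_rate_table(1), n_block_modes = 1)
  expect_length(sch1$states, 6L)
  expect_identical(sum(sch1$classes == "open"), 1L)

  sch2 <- build_blockade_scheme(default_rate_table(2), n_block_modes = 2)
  expect_length(sch2$states, 7L)
  expect_true(all(c("B_fast", "B_slow") %in% sch2$states))
  # blocked states adjacent only to O
  for (b in c("B_fast", "B_slow")) {
    nb <- unique(c(sch2$edges$to[sch2$edges$from == b],
                   sch2$edges$from[sch2$edges$to == b]))
    expect_identical(nb, "O")
  }

  expect_error(build_blockade_scheme(default_rate_table(1, kB_off = 0)),
               "positive")
  expect_error(build_blockade_scheme(default_rate_table(1), n_block_modes = 3),
               "n_block_modes")
  expect_error(build_blockade_scheme(default_rate_table(1)[-1]), "missing")
})

test_that("generator matrix obeys mass action and conservation", {
  sch <- build_blockade_scheme(default_rate_table(1))
  Q0 <- generator_matrix(sch, conditions(conc_blocker = 0))
  expect_identical(Q0["O", "B"], 0)

  Q1 <- generator_matrix(sch, conditions(conc_blocker = 7))
  Q2 <- generator_matrix(sch, conditions(conc_blocker = 14))
  expect_equal(Q2["O", "B"], 2 * Q1["O", "B"])
  # no other off-diagonal changes
  off <- row(Q1) != col(Q1)
  chg <- which(off & (Q1 != Q2), arr.ind = TRUE)
  expect_identical(nrow(chg), 1L)

  for (Q in list(Q0, Q1, Q2)) {
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_true(all(Q[row(Q) != col(Q)] >= 0))
    expect_equal(max(rowSums(abs(Q))), 2 * max(abs(diag(Q))))
  }
})

test_that("equilibrium distribution solves pi Q = 0", {
  sch <- build_blockade_scheme(default_rate_table(1))
  Q <- generator_matrix(sch, conditions(conc_blocker = 10))
  p <- equilibrium_probs(Q)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_lt(max(abs(p %*% Q)), 1e-10)
})

test_that("phase-type dwell densities match closed forms", {
  # single exponential open dwell in the two-state scheme
  sch <- two_state_scheme(alpha = 100, beta = 50)
  cond <- conditions()
  t <- c(0, 0.001, 0.01, 0.05)
  expect_equal(phase_type_dwell_density(sch, cond, "open", t),
               100 * exp(-100 * t), tolerance = 1e-10)

  # competing exits from a single open state: O -> C (alpha), O -> B (kB c)
  schb <- kinetic_scheme(
    c("C", "O", "B"), c("closed", "open", "closed"),
    rbind(scheme_edge("C", "O", "beta", rate_law(50)),
          scheme_edge("O", "C", "alpha", rate_law(100)),
          scheme_edge("O", "B", "kB_on", rate_law(15, ligand = "blocker")),
          scheme_edge("B", "O", "kB_off", rate_law(2))))
  condb <- conditions(conc_blocker = 10)
  rate_tot <- 100 + 15 * 10
  expect_equal(phase_type_dwell_density(schb, condb, "open", t),
               rate_tot * exp(-rate_tot * t), tolerance = 1e-10)
})

test_that("multi-component closed density integrates to one and has the closed-form mean", {
  sch <- build_blockade_scheme(default_rate_table(1))
  cond <- conditions(conc_blocker = 10)
  f <- function(t) phase_type_dwell_density(sch, cond, "closed", t)
  total <- integrate(f, 0, Inf, rel.tol = 1e-10, subdivisions = 500L)$value
  expect_equal(total, 1, tolerance = 1e-8)
  m_quad <- integrate(function(t) t * f(t), 0, Inf,
                      rel.tol = 1e-10, subdivisions = 500L)$value
  expect_equal(mean_dwell_time(sch, cond, "closed"), m_quad,
               tolerance = 1e-7)
  expect_error(phase_type_dwell_density(sch, cond, "shut", 0.1))
})

test_that("mean open dwell follows the competing-exit backbone", {
  r <- default_rate_table(1)
  sch <- build_blockade_scheme(r)
  for (conc in c(0, 5, 20)) {
    expected <- 1 / (r[["alpha"]] + r[["d1_on"]] + r[["d2_on"]] +
                       r[["d3_on"]] + r[["kB_on"]] * conc)
    expect_equal(mean_dwell_time(sch, conditions(conc_blocker = conc), "open"),
                 unname(expected), tolerance = 1e-12)
  }
})

test_that("scheme JSON serialization round-trips exactly", {
  sch <- build_blockade_scheme(default_rate_table(2, kB_on_fast = 9.123456789012345),
                               n_block_modes = 2, vsens_block = -0.0213)
  tf <- tempfile(fileext = ".json")
  scheme_to_json(sch, tf)
  back <- scheme_from_json(tf)
  expect_identical(back$states, sch$states)
  expect_identical(back$classes, sch$classes)
  expect_identical(get_rates(back), get_rates(sch))
  expect_identical(
    vapply(back$edges$law, `[[`, 0, "vsens"),
    vapply(sch$edges$law, `[[`, 0, "vsens"))
  Q1 <- generator_matrix(sch, conditions(conc_blocker = 3, Vm = -20))
  Q2 <- generator_matrix(back, conditions(conc_blocker = 3, Vm = -20))
  expect_identical(Q1, Q2)
})

test_that("voltage sensitivity scales flagged rates only", {
  sch <- build_blockade_scheme(default_rate_table(1), vsens_block = -0.02)
  Q0 <- generator_matrix(sch, conditions(conc_blocker = 10, Vm = 0))
  Qh <- generator_matrix(sch, conditions(conc_blocker = 10, Vm = -50))
  expect_equal(Qh["O", "B"], Q0["O", "B"] * exp(-0.02 * -50))
  expect_equal(Qh["O", "C"], Q0["O", "C"])
  expect_equal(Qh["B", "O"], Q0["B", "O"])
})
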