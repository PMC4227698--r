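# Shared scheme builders for the test suite.

two_state_scheme <- function(alpha = 100, beta = 50) {
  kinetic_scheme(c("C", "O"), c("closed", "open"),
                 rbind(scheme_edge("C", "O", "beta", rate_law(beta)),
                       scheme_edge("O", "C", "alpha", rate_law(alpha))))
}

# C1 <-> O <-> C2: one open state, two-component closed aggregate
three_state_scheme <- function(k_oc1 = 80, k_c1o = 900,
                               k_oc2 = 30, k_c2o = 25) {
  kinetic_scheme(c("C1", "O", "C2"), c("closed", "open", "closed"),
                 rbind(scheme_edge("O", "C1", "a1", rate_law(k_oc1)),
                       scheme_edge("C1", "O", "b1", rate_law(k_c1o)),
                       scheme_edge("O", "C2", "a2", rate_law(k_oc2)),
                       scheme_edge("C2", "O", "b2", rate_law(k_c2o))))
}

# two open states, to exercise the general (non-scalar) likelihood path
two_open_scheme <- function() {
  kinetic_scheme(c("C", "O1", "O2"), c("closed", "open", "open"),
                 rbind(scheme_edge("C", "O1", "b1", rate_law(200)),
                       scheme_edge("O1", "C", "a1", rate_law(300)),
                       scheme_edge("O1", "O2", "g12", rate_law(150)),
                       scheme_edge("O2", "O1", "g21", rate_law(250)),
                       scheme_edge("O2", "C", "a2", rate_law(50))))
}

# independent reference for interval likelihoods: plain forward products of
# matrix exponentials (Matrix::expm, scaling-and-squaring), no spectral
# shortcuts shared with the implementation
oracle_interval_ll <- function(scheme, cond, dwells, censor_last = TRUE) {
  Q <- generator_matrix(scheme, cond)
  p <- equilibrium_probs(Q)
  cls <- as.character(dwells$class)
  a1 <- which(scheme$classes == cls[1])
  b1 <- setdiff(seq_along(scheme$states), a1)
  flux <- p[b1] %*% Q[b1, a1, drop = FALSE]
  v <- flux / sum(flux)
  ll <- 0
  n <- nrow(dwells)
  for (i in seq_len(n)) {
    a <- which(scheme$classes == cls[i])
    b <- setdiff(seq_along(scheme$states), a)
    P <- as.matrix(Matrix::expm(Q[a, a, drop = FALSE] * dwells$duration[i]))
    v <- v %*% P
    v <- if (i < n || !censor_last) v %*% Q[a, b, drop = FALSE] else v
    sc <- sum(abs(v))
    ll <- ll + log(sc)
    v <- v / sc
  }
  if (censor_last) ll + log(sum(v)) else ll + log(sum(v))
}
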