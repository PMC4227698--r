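#' Rate law for a kinetic transition
#'
#' A transition rate of an aggregated Markov gating scheme. Rates are either
#' unimolecular (s^-1) or, when tied to a ligand, bimolecular mass-action
#' rates (uM^-1 s^-1) that are multiplied by the ligand concentration when
#' the generator matrix is built. A rate may additionally carry an
#' exponential voltage sensitivity, `rate * exp(vsens * Vm)` with `Vm` the
#' membrane potential in mV; this is how a charged pore blocker senses the
#' transmembrane field.
#'
#' @param base_rate positive base rate, s^-1 (or uM^-1 s^-1 if `ligand` is
#'   not `"none"`). Refers to the reference potential of the dose
#'   experiments (`Vm = 0` in the model's convention).
#' @param ligand one of `"none"`, `"ACh"`, `"blocker"`; order-1 mass action
#'   scaling by the corresponding concentration.
#' @param vsens voltage sensitivity, mV^-1 (0 = voltage-insensitive).
#' @return an object of class `rate_law`.
#' @export
rate_law <- function(base_rate, ligand = "none", vsens = 0) {
  stopifnot(is.numeric(base_rate), length(base_rate) == 1L, is.finite(base_rate))
  if (base_rate <= 0) stop("base_rate must be > 0")
  ligand <- match.arg(ligand, c("none", "ACh", "blocker"))
  stopifnot(is.numeric(vsens), length(vsens) == 1L, is.finite(vsens))
  structure(list(base_rate = base_rate, ligand = ligand, vsens = vsens),
            class = "rate_law")
}

#' Evaluate a rate law under experimental conditions
#'
#' @param law a [rate_law()].
#' @param cond a [conditions()] object.
#' @return the evaluated rate in s^-1.
#' @export
eval_rate <- function(law, cond) {
  conc <- switch(law$ligand, none = 1, ACh = cond$conc_ACh,
                 blocker = cond$conc_blocker)
  law$base_rate * conc * exp(law$vsens * cond$Vm)
}

#' Experimental conditions
#'
#' @param conc_ACh agonist concentration, uM.
#' @param conc_blocker blocker concentration, uM.
#' @param Vm membrane potential, mV (cell-attached convention:
#'   `Vm = V_rest - V_hold`, measured relative to the reference potential of
#'   the dose experiments).
#' @return an object of class `conditions`.
#' @export
conditions <- function(conc_ACh = 100, conc_blocker = 0, Vm = 0) {
  stopifnot(conc_ACh >= 0, conc_blocker >= 0, is.finite(Vm))
  structure(list(conc_ACh = conc_ACh, conc_blocker = conc_blocker, Vm = Vm),
            class = "conditions")
}

#' Construct an aggregated Markov kinetic scheme
#'
#' States are observed only through their conductance class (`"open"` or
#' `"closed"`); blocked and desensitized states are conductance-class
#' closed. The directed graph of non-zero rates must be strongly connected,
#' with no self-edges and at least one state of each class.
#'
#' @param states character vector of state labels.
#' @param classes conductance class per state, `"open"` or `"closed"`.
#' @param edges a data.frame with columns `from`, `to`, `name` and a list
#'   column `law` of [rate_law()] objects (or the result of repeated
#'   [scheme_edge()] calls combined with `rbind`).
#' @return an object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(states, classes, edges) {
  stopifnot(is.character(states), length(states) >= 2L,
            !anyDuplicated(states))
  classes <- match.arg(classes, c("open", "closed"), several.ok = TRUE)
  stopifnot(length(classes) == length(states))
  if (!any(classes == "open") || !any(classes == "closed"))
    stop("scheme needs at least one open-class and one closed-class state")
  stopifnot(is.data.frame(edges),
            all(c("from", "to", "name", "law") %in% names(edges)))
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  if (!all(edges$from %in% states) || !all(edges$to %in% states))
    stop("edge endpoints must be scheme states")
  if (anyDuplicated(edges[c("from", "to")]))
    stop("duplicate edges")
  if (anyDuplicated(edges$name)) stop("duplicate rate names")
  for (l in edges$law)
    if (!inherits(l, "rate_law")) stop("edges$law must hold rate_law objects")
  if (!all(states %in% edges$from))
    stop("every state needs at least one outgoing edge")
  sch <- structure(list(states = states, classes = classes,
                        edges = edges), class = "kinetic_scheme")
  if (!.strongly_connected(sch))
    stop("scheme graph (non-zero rates) must be strongly connected")
  sch
}

#' @rdname kinetic_scheme
#' @param from,to state labels of one transition.
#' @param name rate-constant name (used to address free parameters in fits).
#' @param law a [rate_law()].
#' @export
scheme_edge <- function(from, to, name, law) {
  stopifnot(inherits(law, "rate_law"))
  d <- data.frame(from = from, to = to, name = name)
  d$law <- list(law)
  d
}

.strongly_connected <- function(scheme) {
  n <- length(scheme$states)
  adj <- matrix(FALSE, n, n, dimnames = list(scheme$states, scheme$states))
  adj[cbind(scheme$edges$from, scheme$edges$to)] <- TRUE
  reach <- function(a) {
    seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
    while (length(frontier)) {
      nxt <- which(colSums(a[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE; frontier <- nxt
    }
    all(seen)
  }
  reach(adj) && reach(t(adj))
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme:", length(x$states), "states (",
      sum(x$classes == "open"), "open /",
      sum(x$classes == "closed"), "closed ),",
      nrow(x$edges), "transitions\n")
  for (i in seq_len(nrow(x$edges)))
    cat(sprintf("  %-4s -> %-6s %-12s %g%s%s\n",
                x$edges$from[i], x$edges$to[i], x$edges$name[i],
                x$edges$law[[i]]$base_rate,
                if (x$edges$law[[i]]$ligand != "none")
                  paste0(" * [", x$edges$law[[i]]$ligand, "]") else "",
                if (x$edges$law[[i]]$vsens != 0)
                  sprintf(" * exp(%g Vm)", x$edges$law[[i]]$vsens) else ""))
  invisible(x)
}

#' Build the sequential-blockade gating scheme
#'
#' Constructs the gating model of the receptor with open-channel block: a
#' closed state C in equilibrium with a single open state O, three
#' desensitized states D1-D3 entered from O (star topology by default, the
#' desensitized dwell structure being a nuisance for blockade estimation),
#' and one or two blocked states B (B_fast/B_slow, labelled by unblocking
#' speed) reachable only from O. Blocked and desensitized states are
#' conductance-class closed. Blocking rates are bimolecular in the blocker
#' concentration; opening is bimolecular in agonist.
#'
#' @param rates named list/vector of base rates (all positive):
#'   `beta` (C->O opening, uM^-1 s^-1 in ACh), `alpha` (O->C closing, s^-1),
#'   `d1_on`,`d1_off`,`d2_on`,`d2_off`,`d3_on`,`d3_off` (O<->Dk, s^-1), and
#'   for one blockade mode `kB_on` (uM^-1 s^-1 in blocker) and `kB_off`
#'   (s^-1); for two modes `kB_on_fast`,`kB_off_fast`,`kB_on_slow`,
#'   `kB_off_slow`.
#' @param n_block_modes 1 or 2 blockade modes.
#' @param vsens_block voltage sensitivity (mV^-1) applied to the blocking
#'   rate(s); by default only blocking is voltage-sensitive.
#' @param d_topology `"star"` (D1..D3 each adjacent to O) or `"linear"`
#'   (O-D1-D2-D3 chain).
#' @return a [kinetic_scheme()].
#' @export
build_blockade_scheme <- function(rates, n_block_modes = 1,
                                  vsens_block = 0,
                                  d_topology = c("star", "linear")) {
  d_topology <- match.arg(d_topology)
  if (!n_block_modes %in% c(1, 2)) stop("n_block_modes must be 1 or 2")
  need <- c("beta", "alpha", "d1_on", "d1_off", "d2_on", "d2_off",
            "d3_on", "d3_off",
            if (n_block_modes == 1) c("kB_on", "kB_off")
            else c("kB_on_fast", "kB_off_fast", "kB_on_slow", "kB_off_slow"))
  rates <- unlist(rates)
  miss <- setdiff(need, names(rates))
  if (length(miss)) stop("missing rates: ", paste(miss, collapse = ", "))
  if (any(rates[need] <= 0)) stop("all rates must be positive")

  states <- c("C", "O", "D1", "D2", "D3",
              if (n_block_modes == 1) "B" else c("B_fast", "B_slow"))
  classes <- c("closed", "open", rep("closed", length(states) - 2L))

  e <- rbind(
    scheme_edge("C", "O", "beta", rate_law(rates[["beta"]], ligand = "ACh")),
    scheme_edge("O", "C", "alpha", rate_law(rates[["alpha"]])))
  if (d_topology == "star") {
    for (k in 1:3) {
      e <- rbind(e,
        scheme_edge("O", paste0("D", k), paste0("d", k, "_on"),
                    rate_law(rates[[paste0("d", k, "_on")]])),
        scheme_edge(paste0("D", k), "O", paste0("d", k, "_off"),
                    rate_law(rates[[paste0("d", k, "_off")]])))
    }
  } else {
    chain <- c("O", "D1", "D2", "D3")
    for (k in 1:3) {
      e <- rbind(e,
        scheme_edge(chain[k], chain[k + 1], paste0("d", k, "_on"),
                    rate_law(rates[[paste0("d", k, "_on")]])),
        scheme_edge(chain[k + 1], chain[k], paste0("d", k, "_off"),
                    rate_law(rates[[paste0("d", k, "_off")]])))
    }
  }
  if (n_block_modes == 1) {
    e <- rbind(e,
      scheme_edge("O", "B", "kB_on",
                  rate_law(rates[["kB_on"]], ligand = "blocker",
                           vsens = vsens_block)),
      scheme_edge("B", "O", "kB_off", rate_law(rates[["kB_off"]])))
  } else {
    for (m in c("fast", "slow")) {
      e <- rbind(e,
        scheme_edge("O", paste0("B_", m), paste0("kB_on_", m),
                    rate_law(rates[[paste0("kB_on_", m)]], ligand = "blocker",
                             vsens = vsens_block)),
        scheme_edge(paste0("B_", m), "O", paste0("kB_off_", m),
                    rate_law(rates[[paste0("kB_off_", m)]])))
    }
  }
  kinetic_scheme(states, classes, e)
}

#' Default rate table for the blockade gating model
#'
#' Reference rates for the adult muscle-type receptor gating model at the
#' dose-experiment reference potential. The gating and desensitization
#' rates are representative values chosen once for the synthetic study
#' design: opening `beta` = 10 uM^-1 s^-1 (1000 s^-1 at 100 uM agonist,
#' i.e. ~1 ms intra-cluster closings), closing `alpha` = 400 s^-1 and
#' desensitization entries 50/30/20 s^-1 giving a 2 ms mean open time,
#' with desensitized lifetimes of 1, 10 and 100 ms (D1-D3 ranked by
#' lifetime; D3 sojourns separate clusters). The blockade defaults are the
#' single-mode constants of the reference blocker (`kB_on` = 15
#' uM^-1 s^-1, `kB_off` = 2 s^-1, i.e. Kd ~ 0.13 uM); for a two-mode
#' blocker the defaults place the fast and slow unblocking rates at 60 and
#' 3 s^-1 (within the characteristic fast/slow ranges) with blocking
#' constants 10 and 8 uM^-1 s^-1.
#'
#' @param n_block_modes 1 or 2.
#' @param ... named rate overrides.
#' @return named numeric vector accepted by [build_blockade_scheme()].
#' @export
default_rate_table <- function(n_block_modes = 1, ...) {
  r <- c(beta = 10, alpha = 400, d1_on = 50, d1_off = 1000,
         d2_on = 30, d2_off = 100, d3_on = 20, d3_off = 10,
         if (n_block_modes == 1) c(kB_on = 15, kB_off = 2)
         else c(kB_on_fast = 10, kB_off_fast = 60,
                kB_on_slow = 8, kB_off_slow = 3))
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(r))
    if (length(bad)) stop("unknown rate names: ", paste(bad, collapse = ", "))
    r[names(ov)] <- ov
  }
  r
}

#' Generator (Q) matrix of a scheme under given conditions
#'
#' Off-diagonal entries are the evaluated transition rates (mass-action
#' scaling by ligand concentration and the voltage factor applied); the
#' diagonal makes every row sum to zero.
#'
#' @param scheme a [kinetic_scheme()].
#' @param cond a [conditions()] object.
#' @return square numeric matrix with state labels as dimnames.
#' @export
generator_matrix <- function(scheme, cond) {
  stopifnot(inherits(scheme, "kinetic_scheme"), inherits(cond, "conditions"))
  n <- length(scheme$states)
  Q <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  for (i in seq_len(nrow(scheme$edges)))
    Q[scheme$edges$from[i], scheme$edges$to[i]] <-
      eval_rate(scheme$edges$law[[i]], cond)
  diag(Q) <- -rowSums(Q)
  Q
}

#' Equilibrium state probabilities
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` by replacing one balance equation with
#' the normalization constraint.
#'
#' @param Q generator matrix.
#' @return named probability vector.
#' @export
equilibrium_probs <- function(Q) {
  n <- nrow(Q)
  A <- t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  p <- solve(A, b)
  names(p) <- rownames(Q)
  p
}

# Split Q into within/between blocks for a conductance class; `which` are
# the state indices of the aggregate, `other` the complement.
.class_blocks <- function(scheme, Q, cls) {
  a <- which(scheme$classes == cls)
  if (!length(a)) stop("no states of class '", cls, "' in scheme")
  b <- setdiff(seq_along(scheme$states), a)
  list(a = a, b = b,
       Qaa = Q[a, a, drop = FALSE], Qab = Q[a, b, drop = FALSE],
       Qba = Q[b, a, drop = FALSE])
}

# Equilibrium entry probabilities into an aggregate: the stationary flux
# into each state of the class, normalized.
.entry_probs <- function(scheme, Q, cls) {
  bl <- .class_blocks(scheme, Q, cls)
  p <- equilibrium_probs(Q)
  flux <- as.vector(p[bl$b] %*% bl$Qba)
  flux / sum(flux)
}

#' Phase-type dwell-time density of an aggregate
#'
#' Density of a sojourn in the open or closed aggregate, entered with the
#' equilibrium entry probabilities: `f(t) = pi_e' expm(Qaa t) Qab 1`. Dwell
#' distributions of an aggregated Markov scheme are mixtures of
#' exponentials; this is the analytic form behind fitted dwell histograms.
#'
#' @param scheme a [kinetic_scheme()].
#' @param cond a [conditions()] object.
#' @param cls `"open"` or `"closed"`.
#' @param t vector of times (s), `t >= 0`.
#' @return vector of density values (s^-1).
#' @export
phase_type_dwell_density <- function(scheme, cond, cls, t) {
  stopifnot(all(t >= 0))
  Q <- generator_matrix(scheme, cond)
  bl <- .class_blocks(scheme, Q, cls)
  pe <- .entry_probs(scheme, Q, cls)
  eg <- eigen(bl$Qaa)
  V <- eg$vectors
  w <- as.vector(t(solve(V, rowSums(bl$Qab))) * (pe %*% V))
  dens <- vapply(t, function(tt) Re(sum(w * exp(eg$values * tt))), 0)
  pmax(dens, 0)
}

#' Mean dwell time of an aggregate (closed form)
#'
#' `-pi_e' Qaa^{-1} 1`, the expectation of the phase-type dwell density.
#'
#' @inheritParams phase_type_dwell_density
#' @return mean dwell duration in seconds.
#' @export
mean_dwell_time <- function(scheme, cond, cls) {
  Q <- generator_matrix(scheme, cond)
  bl <- .class_blocks(scheme, Q, cls)
  pe <- .entry_probs(scheme, Q, cls)
  -sum(pe %*% solve(bl$Qaa))
}

#' Serialize a kinetic scheme to JSON (and back)
#'
#' The JSON document stores states, conductance classes and the edge list
#' with rate names, base rates, ligand tags and voltage sensitivities.
#' Numbers round-trip bit-exactly (written at full precision).
#'
#' @param scheme a [kinetic_scheme()].
#' @param path file path; for `scheme_to_json(NULL)` the JSON string is
#'   returned invisibly instead of written.
#' @return `scheme_to_json`: the JSON string, invisibly. `scheme_from_json`:
#'   a [kinetic_scheme()].
#' @export
scheme_to_json <- function(scheme, path = NULL) {
  doc <- list(
    states = scheme$states,
    classes = scheme$classes,
    edges = lapply(seq_len(nrow(scheme$edges)), function(i)
      list(from = scheme$edges$from[i], to = scheme$edges$to[i],
           name = scheme$edges$name[i],
           rate = scheme$edges$law[[i]]$base_rate,
           ligand = scheme$edges$law[[i]]$ligand,
           vsens = scheme$edges$law[[i]]$vsens)))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' @rdname scheme_to_json
#' @param json JSON string or file path containing a serialized scheme.
#' @export
scheme_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  e <- do.call(rbind, lapply(doc$edges, function(ed)
    scheme_edge(ed$from, ed$to, ed$name,
                rate_law(ed$rate, ligand = ed$ligand, vsens = ed$vsens))))
  kinetic_scheme(unlist(doc$states), unlist(doc$classes), e)
}

#' Update named base rates of a scheme
#'
#' @param scheme a [kinetic_scheme()].
#' @param rates named numeric vector; names must match edge rate names.
#' @return the modified scheme.
#' @export
set_rates <- function(scheme, rates) {
  idx <- match(names(rates), scheme$edges$name)
  if (anyNA(idx)) stop("unknown rate names: ",
                       paste(names(rates)[is.na(idx)], collapse = ", "))
  if (any(rates <= 0)) stop("rates must be positive")
  for (k in seq_along(idx))
    scheme$edges$law[[idx[k]]]$base_rate <- unname(rates[k])
  scheme
}

#' Extract named base rates of a scheme
#'
#' @param scheme a [kinetic_scheme()].
#' @return named numeric vector of base rates.
#' @export
get_rates <- function(scheme) {
  r <- vapply(scheme$edges$law, function(l) l$base_rate, 0)
  names(r) <- scheme$edges$name
  r
}
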