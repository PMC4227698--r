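---
title: "Kinetic analysis of open-channel blockade from single-channel records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic analysis of open-channel blockade from single-channel records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scblock)
```

## The model

`scblock` analyses single-channel patch-clamp records of a ligand-gated
channel in the presence of an open-channel blocker. The channel is an
aggregated continuous-time Markov chain: states are hidden, only their
conductance class (open or closed) is observed. The default scheme built by
`build_blockade_scheme()` is

```
        beta[ACh]                 kB_on[B]
  C  <=============>  O  <=================>  B
        alpha          \        kB_off
                        \
                         +--> D1, D2, D3 (desensitized, closed class)
```

with a single open state `O`, a short-lived closed state `C` responsible for
the brief intra-cluster gaps, three desensitized states `D1`-`D3` of
increasing lifetime attached to `O` (the longest, `D3`, produces the long
quiet periods that separate clusters of openings), and one or two blocked
states `B` reachable only from the open state. That last restriction is the
*sequential blockade* mechanism: a blocker molecule can occlude the pore
only while the pore is open, and the channel cannot shut or desensitize
while occluded. Blocked and desensitized states are electrically silent, so
all of them belong to the closed class.

Two rates are bimolecular and scale with concentration by mass action:
opening (`beta`, per-µM of agonist) and blocking (`kB_on`, per-µM of
blocker). Everything else is unimolecular. Under this scheme, open-channel
block has three observable signatures:

* the apparent mean open time `tau_app` shortens with blocker dose, because
  `1/tau_app = alpha + d1_on + d2_on + d3_on + kB_on * [B]`;
* a new closed-time component appears whose *area* grows with dose;
* the *lifetime* of that component, `tau_B = 1/kB_off`, is dose-invariant,
  reflecting unimolecular dissociation.

The headline constants are `kB_on` (slope of blocking rate against dose),
`kB_off` (mean of the per-dose unblocking rates), and their ratio
`Kd = kB_off / kB_on`, the equilibrium dissociation constant of the
blocker for the open pore.

Membrane potential enters only rates explicitly flagged voltage-sensitive,
as `rate * exp(s * Vm)` with `s` in mV^-1. By default only blocking is
voltage-sensitive, reflecting a charged blocker binding within the
transmembrane field; in cell-attached recordings `Vm = V_rest - V_hold`,
with `V_rest` estimated from the reversal of the single-channel
current-voltage line (`voltage_dependence()`). Base rates refer to the
reference potential of the dose experiments, so the dose analysis can be
run entirely at `Vm = 0`.

## Default rates (the synthetic study conditions)

`default_rate_table()` fixes the generating rates for synthetic studies.
The blockade constants are the reference blocker's: `kB_on` = 15 µM^-1 s^-1
and `kB_off` = 2 s^-1 (`Kd` ≈ 0.13 µM, blocked dwells of 500 ms). The
gating and desensitization rates are not uniquely determined by any printed
table, so representative values were chosen once and kept: opening 10
µM^-1 s^-1 (1 ms closed gaps at 100 µM agonist), closing 400 s^-1 and
desensitization entries 50/30/20 s^-1 (2 ms mean open time at zero
blocker), desensitized lifetimes 1, 10 and 100 ms. These place the closed
dwell components roughly a decade apart and two decades below the blocked
dwell lifetime, which is what makes the blockade component identifiable in
closed-time histograms — the qualitative structure the analysis relies on.
For two-mode blockers the defaults put the fast and slow unblocking rates
at 60 and 3 s^-1, inside the characteristic ranges for the two dissociation
modes, with blocking constants 10 and 8 µM^-1 s^-1.

The exact connectivity of the three desensitized states is not observable
from dwell data at this resolution; the star topology (each D adjacent to
O) is the default, with a linear chain available via `d_topology`. The
desensitized dwell structure is a nuisance parameter for blockade
estimation, so this choice does not propagate into the headline constants.

## Simulation and trace rendering

`simulate_dwells()` is an exact Gillespie simulation of the scheme's
generator; the initial state is drawn from the equilibrium distribution.
`render_trace()` turns class dwells into a sampled current: 0 pA closed,
+7 pA open (upward deflections), convolved with a Gaussian low-pass kernel
(sigma_t = 0.1325/f_c, the -3 dB equivalence) and overlaid with i.i.d.
Gaussian noise of 1 pA SD. Defaults are 25 kHz sampling with a 10 kHz
cutoff. The Gaussian kernel stands in for the recording chain's anti-alias
filter because it is the standard choice for simulated single-channel data
and analytically tractable; no claim of matching any particular hardware
filter beyond its bandwidth is made. The generator deliberately omits
baseline drift, mains interference and seal breakdown, so passing tests
demonstrate correctness of the estimators under the model's assumptions,
not robustness to instrumentation artifacts.

`synth_experiment()` enumerates (cell × dose × voltage) datasets with
per-dataset seeds derived deterministically from the master seed, so adding
a condition never perturbs the draws of another.

## Idealization

`skm_idealize()` implements a plain segmented-k-means procedure: Viterbi
decoding under a discrete Gaussian-emission HMM alternating with
re-estimation of class means (per-class sample means), a pooled emission
variance, and transition probabilities counted from the segmentation.
Pooling the variance across classes is appropriate because filtered
baseline noise is class-independent to first order. No amplitude
constraints or drift nodes are included. Labels follow the amplitude order
(most positive class = open), so swapped initial amplitudes converge to
the same segmentation.

`impose_dead_time()` then deletes events shorter than the dead time td and
absorbs their duration into the flanking events (merging them when they
share a class), iterating until stable; total duration is conserved
exactly and the operation is idempotent. The default td is two sampling
intervals (0.2 ms at 10 kHz). `segment_clusters()` cuts the record at
closed dwells longer than `tau_crit`; `tau_crit_equal_misclass()` supplies
the equal-misclassification crossing between the slowest intra-cluster and
fastest inter-cluster closed components, though any value between the D2
and D3 lifetimes gives the same clusters here.

## Interval likelihood and missed events

`interval_log_likelihood()` evaluates the standard interval likelihood of
an alternating dwell sequence,

    L = pi_e' [ prod_i expm(Q_aa t_i) Q_ab ] expm(Q_NN t_N) 1,

with the first interval entered from the equilibrium entry distribution
and the final interval contributing only its survivor function (the record
simply ends; `censor_last = FALSE` switches the final interval to a
complete dwell). Within-class propagators come from spectral decomposition
of the small class blocks; for schemes with a single open state the whole
likelihood collapses to sums of scalar exponential mixtures and is fully
vectorized. Per-interval scaling keeps the evaluation in log space.

Dead-time handling deserves a note. Fitting dead-time-imposed dwells with
the uncorrected likelihood is *not* a second-order approximation under
these conditions: with 1 ms gaps and ~1.3-2 ms openings against td =
0.2 ms, roughly 15% of openings fall below td, and each such opening merges
its two flanking closed dwells — halving the count of observed blockade
events at that rate and biasing `kB_on` down by ~10%. The likelihood
therefore applies the first-order missed-event correction of Roux and
Sauvé whenever `dead_time > 0`: within-class generators become

    eQ_aa = Q_aa + Q_ab [ integral_0^td expm(Q_bb s) ds ] Q_ba,

folding unresolved sub-td excursions into the complementary class into the
apparent within-class dynamics; observed transitions are gated by
`expm(Q_bb td)` (the destination sojourn must survive the dead time); and
propagators run over the apparent duration minus td. This is the same
correction used by the standard MIL implementations this analysis follows.
Residual bias at the default conditions is ~2-3% (second order in td times
the fastest rates); an exact correction is a possible future extension.

`fit_mil()` maximizes the summed likelihood over log-transformed free
rates with `nlminb` (box bounds 10^-3..10^6), five jittered starts by
default under a fixed jitter seed, and standard errors from the inverse
observed information in log-rate space, delta-method transformed. Free
ligand-scaled rates whose ligand is absent from every dataset are flagged
structurally non-identifiable instead of being fit. In the dose pipeline
only the blockade rates are freed per dataset, with gating and
desensitization rates held at their control values — the synthetic
analogue of fixing the gating model on the blocker-free condition first.

## Dose, voltage and activity summaries

`blocking_kinetics()` follows the conventional estimator exactly:
`kB_on` is the slope of the unweighted least-squares line (intercept
fitted and reported; a through-origin slope is also computed) of blocking
rate against dose, with the slope's standard error; `kB_off` is the
unweighted mean of the unblocking rates pooled over all doses and cells,
with SEM; `Kd = kB_off/kB_on` with first-order error propagation
`SE(Kd) = Kd sqrt((SE-/k-)^2 + (SE+/k+)^2)`, which reduces to the exact
ratio when both SEs vanish. The intercept is fitted because any
dose-independent termination process is absorbed there rather than tilting
the slope. With two modes, each is summarized separately and modes are
matched by unblocking-rate order (fast = larger `kB_off`); per-dataset
rows can be flagged `excluded` to drop conditions where a mode is not
resolvable. `closed_time_components()` fits exponential mixtures by EM
with deterministic quantile initialization, BIC scan over 2-6 components
when the count is not given, degenerate components (area < 1/n) dropped
with a refit, and a log10-binned square-root-ordinate histogram for
display. `agonist_activity()` uses the standard occupancy definition
NPo = sum_i i * P_o,i over simultaneously-open levels.

## Molecular complexity

`bertz_index()` scores a molecular graph with the original two-term
information measure: C = C(eta) + C(E), each term of the form
`2 n log2 n - sum_i n_i log2 n_i`. For the connectivity term the objects
are "connections" — unordered pairs of adjacent edges on the heavy-atom
multigraph, a double bond contributing two parallel edges — partitioned
into equivalence classes induced by Morgan-refined atom classes (iterated
neighborhood refinement, an orbit approximation that is exact on the
bundled structures; the test suite checks it against brute-force
automorphism orbits on small graphs). The element term applies the same
formula to the partition of heavy atoms by element. Hydrogens are
implicit; formal charges are not scored. Which Bertz variant produced any
given published figure is generally unknowable, so cross-compound
comparisons are reported as *ratios*, which are far less sensitive to
variant choice than absolute scores.

The bundled structure table is a reconstruction, marked as such in its
filename and header: the PEG-based bis-quaternary blockers are rebuilt
from their structural description (an octa(ethylene glycol)-derived
backbone with seven ether oxygens and two terminal quaternary ammonium
groups; the PQ1 and PQ5 termini are stated explicitly, PQ2-PQ4 are
plausible choices respecting the stated size ordering), and the comparator
blockers use their standard structures with minor regiochemical
approximation in tubocurarine's methoxy/hydroxy placement. Comparator
affinities are indicative literature values only.

## Problem sizes and numerical choices

The test suite and the acceptance script use desk-scale designs chosen for
estimator precision: the dose-recovery study simulates 3 cells × 3 doses
(5/10/20 µM) × 6000 dwells, rendered at 25 kHz and idealized by SKM, which
puts the sampling SD of the recovered `kB_on` slope near 0.3 µM^-1 s^-1;
distributional properties (KS agreement, mixture recovery, two-mode
ordering) run on 10^2-10^4-event simulations with fixed seeds. Numerical
tie-breaks worth knowing: spectral decompositions of class blocks may be
complex (real parts are taken at the end, and the blocks are diagonal for
the star topology anyway); EM component lifetimes are reported sorted;
equilibrium distributions solve the balance equations with the
normalization row substituted; all optimization is on log rates.

## Limitations

* The missed-event correction is first order; at dead times comparable to
  the fastest dwell components an exact correction would be needed.
* Idealization assumes a stable baseline and a single conductance level
  per class; no drift tracking or subconductance support.
* The likelihood treats segments as stationary; rundown or modal shifts
  within a recording are not modeled.
* Synthetic data validate the estimators under the generating model; real
  recordings bring artifacts the generator deliberately omits.
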