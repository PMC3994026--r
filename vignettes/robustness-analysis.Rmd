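---
title: "Guaranteed robustness analysis of stochastic reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guaranteed robustness analysis of stochastic reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochrob)
```

## The problem

A bounded-population chemical reaction network induces a continuous-time
Markov chain (CTMC): states are population vectors, transitions are
reaction firings, and each reaction fires with an exponential rate given
by its propensity.  When rate constants are uncertain — known only as
intervals — every point $p$ of the resulting *perturbation box* $P$
defines a different chain $C_p$, and any quantitative question about the
system (a reachability probability, an expected time in a set, the noise
of a species at a time instant) becomes a function $\lambda(p)$ of the
parameters, the *evaluation function*.

`stochrob` computes guaranteed lower and upper bounds
$[\lambda^{\min}_{P_i}, \lambda^{\max}_{P_i}]$ of that function on an
adaptively refined partition $\{P_i\}$ of the box, and aggregates them
into a *robustness degree*: the integral of $\lambda$ over $P$ under a
uniform perturbation density.  Everything is numeric and conservative —
no sampling is involved in the bounds themselves — so the output comes
with an explicit error, the volume-weighted mean width of the
per-subspace brackets.

## Model class

* **Species** carry hard population bounds.  A reaction whose firing
  would push any species (or any declared *total* of species) past its
  bound is disabled in that state, not clipped; the reachable state
  space is the breadth-first closure of the initial states under this
  rule.
* **Mass-action propensities** use the combinatorial convention
  $k\,\prod_l \binom{x_l}{r_l} r_l!$ (i.e. $kx$, $kx(x-1)$, … for orders
  1, 2, …), the standard stochastic form.
* **Sigmoid production** models an autoregulated gene abstractly:
  $k_{\max}\,\theta^n / (\theta^n + x^n)$, where $x$ is the summed
  population of the regulated forms, $\theta$ the midpoint and $n$ a
  Hill coefficient.  $n = 0$ gives the unregulated constant rate
  $k_{\max}/2$; larger $n$ switches production off more sharply above
  $\theta$.  For fixed $x$ the law is monotone in $n$ (increasing below
  the midpoint, decreasing above), so interval bounds are attained at
  endpoints.

## Parameterised uniformisation

Classical uniformisation writes the transient distribution as
$\pi(t) = \sum_i \mathrm{Pois}(i; qt)\, \pi_0 P^i$ with
$P = I + Q/q$ and $q$ at least the maximal exit rate.  Over a box we
propagate per-state *envelopes* $v^{\min}, v^{\max}$ instead of one
vector: at every uniformisation step and every state, the probability
update is extremised over the box, taking the extremal predecessor
values from the previous step.  Two design choices matter:

* **Mass-action terms are coordinated per constant.**  All transitions
  sharing one rate constant $k$ contribute linearly in $k$ to a state's
  net inflow−outflow, so the per-state extreme lies at an interval
  endpoint, selected from the sign of the net coefficient.  This keeps
  inflow and outflow of the *same* constant consistent within a state's
  update.
* **Sigmoid terms are bounded per transition.**  The same Hill
  parameter can push different states' rates in opposite directions, so
  inflow uses the per-transition upper (lower) rate bound and outflow
  the opposite one.  This is conservative; near the non-monotone regime
  it widens the envelopes, which the adaptive refinement then splits.

Because the extremisation is local — per state and per step — the
envelopes do not correspond to any single chain $C_p$; they may be
strictly wider than $\min_p/\max_p$ of the true transient.  That excess
is exactly what shrinks (empirically, and to zero for continuous
$\lambda$) as the box is bisected, and it is observable only jointly
with the decomposition error, so the package reports the single
combined bracket width.

The uniformisation constant $q$ is taken once, from the per-state sums
of upper rate bounds over the box, and held across steps.  The Poisson
window keeps truncated mass below the requested tolerance (default
$10^{-8}$); the forward pass additionally tightens the window by the
state count, because the dropped mass is charged to every state's upper
bound, and charges it explicitly so the upper envelope stays sound.
The same machinery runs *backward*: iterating $u' = Pu$ from a value
vector bounds, for **every** start state at once, the probability of a
target set at time $t$ — which is why adding initial states to the
perturbation space costs nothing for path and reward properties.

Degenerate (point) boxes collapse both envelopes to classical
uniformisation; the test suite pins this, together with enclosure of
sampled-point transients computed independently, against matrix
exponentials and closed forms.

## The logic and its min–max evaluation

Properties are drawn from a bounded-time stochastic logic: boolean
state predicates over populations, probability operators over
time-bounded *until* and *globally* paths, top-level cumulative-reward
operators, and a distribution post-processing operator (mean quadratic
deviation).  A formula's top-level threshold, if present, is ignored
for the quantitative value and reported as a three-valued status
(`valid-for-all` / `invalid-for-all` / `undecided`).

* **Until** `phi U[t1,t2] psi` reduces to two backward transient
  passes: over $(t_1, t_2]$ with `psi` absorbing success and `!phi`
  absorbing failure, then over $[0, t_1]$ with `!phi` absorbing.
  `G[t1,t2] phi` is evaluated as the dual of an until on the negation.
* **Nested thresholds** under box uncertainty yield a pair of
  satisfaction sets: states that satisfy the subformula for *all*
  points (`sat_min`) and for *some* point (`sat_max`).  Outer bounds
  are obtained by evaluating the lower envelope against the pessimistic
  sets and the upper envelope against the optimistic ones — a
  conservative completion; the brackets of a nested formula can
  therefore be loose near the threshold, and the evaluation function
  itself may be discontinuous there (the depth cap below exists for
  exactly that case).
* **Cumulative rewards** over a window $[t_1, t_2]$ use the
  uniformisation identity
  $\mathbb{E}\!\int_{t_1}^{t_2} \rho(X_u)\,du =
  \tfrac1q\sum_i \big(\Pr(N_{qt_2} > i) - \Pr(N_{qt_1} > i)\big)\,
  \rho^\top \pi_i$, driven by the same bounded backward step vectors,
  so windowed rewards need no subtraction of two runs.
* **Mean quadratic deviation** of a species at time $t$ is bounded from
  the forward envelopes: first and second moments are extremised over
  the transfer polytope $\{\ell \le p \le u,\ \sum p = 1\}$ by
  fractional knapsack, then combined as the interval
  $\mathbb{E}[X^2] - \mu^2$ with $\mu$ ranging over its own bounds.
  This is conservative (the two moments are not extremised jointly) but
  never unsound, which is what the rejection-sampling tests assert.

## Refinement, robustness degrees, PLA

`refine_landscape()` evaluates the root box, bisects any box whose
bracket width exceeds the requested absolute error at the midpoint of
its widest dimension (relative to the root; ties to the lowest index),
and stops at `max_depth` (default 12) — the supplementary termination
criterion that keeps a genuinely discontinuous evaluation function from
refining forever; in that case the achieved error is reported above the
request with a warning.  Subspace evaluations are mutually independent,
so they parallelise trivially; the package keeps the schedule
sequential and deterministic.

Four robustness definitions are supported on a landscape, all under a
uniform perturbation density (non-uniform densities are out of scope):
**1a** the volume fraction where a threshold comparison holds, with
undecided subspaces counted only into the upper bound; **1b** the
threshold-relative mean (1c divided by $r$, uncapped); **1c** the
absolute mean of the evaluation function; **1d** the mean plus a
volume-weighted variance of subspace midpoints, flagged approximate
because midpoints carry no guarantee.  For a finite initial-state set
the robustness integral is the uniform average of per-state integrals;
all states share each backward pass, and refinement splits on the
widest per-state bracket so every state's landscape meets the error
request.

`pla_refine()` intersects, at each grid point, the bound intervals of
all incident subspaces and interpolates linearly in between.  The
result is usually tighter than the step-shaped landscape but is
explicitly *not* conservative; an empty intersection would prove the
bounds unsound and raises a hard error.

## The fixtures and what they do (not) show

**Birth–death** (`birth_death()`): one species bounded at 40, uncertain
production $k_1 \in [0.05, 0.1]$, degradation $0.005\,X$; 41 states.
Canonical query: population in $[15, 20]$ at $t = 1000$.  Small enough
that every engine is cross-checked against dense linear algebra.

**Gene regulation** (`gene_regulation()`): a two-gene bistable switch —
a tumour-suppressor protein A and a positively self-regulating
transcription factor B, each bounded at 10 molecules, one DNA copy per
gene.  Each gene carries a single operator site binding either TF
exclusively; expression is promoted from B-bound complexes, silenced
under bound A, and spontaneous from free genes, gene *b*'s spontaneous
mode at the low rate 0.05 that makes B's self-activation the dominant
production path.  The chain has 1078 states and 5919 transitions.
Kinetic defaults set binding, dissociation and promoted production to a
common unit rate — the package's own parameterisation, chosen for the
pinned chain size and the qualitative switch behaviour, not asserted as
measured constants.  The uncertain constant is A's degradation rate
$\gamma_A \in [0.005, 0.5]$: faster removal of the repressor locks B in
its high mode, so the low-mode hypothesis (time with $B \le 2$ in
$[500, 1000]$ s) weakens with $\gamma_A$ while the high-mode hypothesis
strengthens — the direction the acceptance suite checks.

**Two-component signalling** (`two_component()`): histidine kinase
H/Hp and response regulator R/Rp with signal-driven phosphorylation,
phosphotransfer, spontaneous (basic) or additionally H-catalysed
(modified) dephosphorylation, sigmoid-regulated production of both
components and common first-order decay.  The defaults are a deliberate
desk-scale reduction: totals capped at 10, sigmoid midpoint
$\theta = 5$ (half the cap), $k_{\max} = 1$, $\gamma = 0.1$ so the
unregulated mean total $k_{\max}/2\gamma$ equals $\theta$, and a
stabilisation horizon of 60 time units (production/degradation relax on
the $1/\gamma = 10$ scale, phosphorylation much faster).  Truncating
the totals shrinks the measurable noise — the caps clip the
distribution's tails — so *absolute* mean-quadratic-deviation values at
this scale are not comparable to a full-size model; the direction of
the regulation effect (larger $n$, less output noise at low signal) is
what the tests assert, and what survives the reduction.

The synthetic random networks used by the property-style tests are
small mass-action chains (one or two species, bounds ≤ 6, production /
degradation / conversion) with one or two uncertain constants.  They
exercise enclosure and duality, not biology: passing them shows the
bounds are sound on arbitrary small topologies, not that any particular
organism-scale model is well approximated.

## Numerical choices and limitations

* Truncation tolerance defaults to $10^{-8}$; oracle comparisons in the
  tests run at $10\times$ that tolerance.
* Envelopes are clamped to $[0, 1]$ (probabilities) or
  $[0, \max\rho \cdot (t_2 - t_1)]$ (rewards); clamping can only
  tighten sound bounds.
* Problem sizes in the test and acceptance runs — the 41-state and
  1078-state fixtures at horizons up to 1000 time units, the reduced
  4356-state signalling model at horizon 60, refinement depths up to 4,
  and $10^4$ Monte-Carlo draws for the integral cross-check — were
  chosen so the whole suite completes comfortably on a single core
  while still exercising every engine at its full time horizon.
* Steady-state (unbounded-time) operators, non-uniform perturbation
  densities, infinite state spaces and statistical model checking are
  out of scope; the PLA output is a visual/diagnostic refinement, never
  an input to the guaranteed bounds.
* The parameterised envelopes are conservative by construction; their
  width is an over-estimate of the true min–max gap, and the only
  remedy offered is refinement (automatic) and, for sigmoid models,
  narrower Hill-coefficient boxes.
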