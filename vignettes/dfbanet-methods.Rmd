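---
title: "Basis-tracked dynamic FBA and metabolite-mediated interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Basis-tracked dynamic FBA and metabolite-mediated interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfbanet)
```

## The model

Flux balance analysis (FBA) treats an organism's metabolism as a linear
program: find internal reaction fluxes $\psi$ maximizing a growth
objective $\gamma \cdot \psi$ subject to steady-state balance of internal
metabolites ($\Gamma^{\dagger}\psi = 0$), bounds on exchange rates
($c^1 \le \Gamma^{*}\psi \le c^2(y)$) and constant flux bounds
($d^1 \le \psi \le d^2$). Here $\Gamma^{*}$ maps fluxes to exchange with
a shared environmental pool $y$; we orient its rows so a positive
exchange rate means uptake.

Dynamic FBA (DFBA) couples one such LP per organism to the environment:

$$\frac{dx_i}{dt} = x_i\,(\gamma_i \cdot \psi_i), \qquad
  \frac{dy}{dt} = \phi - \sum_i x_i\, \Gamma^{*}_i \psi_i,$$

with biomass $x_i$ (gDW), metabolite amounts $y$ (mmol), time in hours,
and optional constant inflow $\phi$ (used e.g. to hold a culture
aerobic). The key modeling assumption is that only the *uptake* bounds
depend on the environment, one metabolite each:
$c^2_{ij}(y_j)$ non-decreasing, with all other bounds constant. Units are
a labeling convention; no conversion is performed.

## Basis tracking

By the fundamental theorem of linear programming an optimal vertex can be
written as the solution of a square invertible subsystem of active
constraints, $B_i \psi_i = \bar c_i(y)$. As long as that basis stays
optimal, the flux is an explicit function of $y$ and the whole community
follows a *smooth* ODE — no re-optimization needed. The simulation is
therefore a sequence of segments: solve each organism's LP, extract a
basis, integrate the smooth dynamics until the basis solution violates
some non-basic constraint (or a metabolite hits zero), then re-optimize
and select a new basis. Each segment admits the closed form

$$\frac{dx_i}{dt} = x_i\Big(C_i + \sum_j a_{ij}\,c^2_{ij}(y_j)\Big),
\qquad
\frac{dy_l}{dt} = \phi_l - \sum_i x_i\Big(D_{il} + \sum_j
b_{ijl}\,c^2_{ij}(y_j)\Big),$$

whose coefficients come from $\gamma_i^{\top} B_i^{-1}$ and
$\Gamma^{*}_i B_i^{-1}$ applied to the basis right-hand sides. $C_i$ is
the *intrinsic growth* contributed by constant bounds; $a_{ij} \ne 0$
exactly when metabolite $j$'s uptake bound row is in the basis, i.e. when
$j$ is rate-limiting.

Choices made where the design was genuinely open:

* **Active-set basis, not a solver basis.** The basis is a set of `n`
  constraint rows (independent balance equalities first, then active
  bound rows), so it is independent of any LP solver's internal variable
  encoding and matches the linear-system form above literally.
* **Dual feasibility filter.** At a degenerate vertex many invertible
  active-row subsets reproduce the current flux, but only those whose
  multipliers $\gamma^{\top}B^{-1}$ have the right signs (non-negative on
  upper rows, non-positive on lower rows) stay *optimal* when the vertex
  moves. Candidates failing this are discarded.
* **Forward selection.** Among remaining candidates the package computes
  each non-basic active constraint's slack time-derivative under the
  induced dynamics (with the community drift $\dot y$ estimated jointly
  from all organisms' refined LP solutions) and keeps candidates whose
  minimum slack derivative is above `-deriv_tol`; of those it takes the
  one maximizing that minimum — locally, the basis expected to stay valid
  longest. Ties, and the non-degenerate case, fall back to the fixed
  lowest-row-index order, so runs are bit-for-bit reproducible. When no
  candidate passes, the simulator takes a protective explicit step of
  halving size (capped at 40 halvings) and re-optimizes.
* **Parsimonious refinement.** FBA optima need not be unique; after each
  optimization the package minimizes total flux $\sum_r |\psi_r|$ at the
  fixed optimal growth (variable splitting keeps this a pure LP). This
  removes futile cycles and pins a reproducible representative optimum.
  The refinement runs at every re-optimization by default
  (`refine_policy = "always"`); `"initial"` restricts it to $t = 0$.
* **LP backend.** The constraint systems here are dense and tiny, so the
  package ships a deterministic two-phase revised simplex with Bland's
  anti-cycling rule behind a narrow solve contract
  (rows + objective in, status + vertex out). Determinism of the pivot
  sequence matters because degenerate tie-breaks feed directly into which
  basis, and hence which network, is reported. Tests cross-check it
  against an independent LP implementation.
* **Integration and events.** Segments are integrated with
  `deSolve::lsodar`, which combines adaptive stepping with root
  localization; the root functions are the slacks of every non-basic
  bound row of every organism (shifted by `active_tol`) plus every
  $y_j + \texttt{active\_tol}$. This monitored set is exactly the set of
  ways a basis solution can stop obeying the problem constraints, and it
  is what makes the non-negative orthant forward invariant: trajectories
  are stopped and re-based before $y$ can cross zero by more than the
  tolerance.
* **Infeasible organisms.** If an organism's LP is infeasible at the
  current state its flux is set to zero for the segment (no growth, no
  exchange) — a modeling convention for a case the underlying theory
  leaves open.
* **Stationarity.** When, at a re-optimization point, every
  $|x_i \gamma_i \psi_i|$ and every $|\dot y_j|$ falls below
  `stationary_tol`, the state is frozen: the trajectory is padded to the
  horizon and the run is labelled `stationary`.

Default tolerances (`dfba_config()`): `active_tol`, `feasibility_tol`,
`optimality_tol` $= 10^{-7}$ (standard double-precision LP practice),
`deriv_tol` $= 10^{-9}$, event time localization ~$10^{-8}$ h via the
integrator, `cond_max` $= 10^{12}$ for basis conditioning, integrator
`rtol` $10^{-9}$ / `atol` $10^{-10}$. All are configurable.

## From segments to networks

Within a segment the closed form above is read term by term as a directed
multigraph:

| term | edge | weight |
|------|------|--------|
| $a_{ij}\,x_i\,c^2_{ij}(y_j)$ | $Y_j \to X_i$ | $a_{ij}$ |
| $D_{il}\,x_i$ | $X_i \to Y_l$ | $-D_{il}$ |
| $b_{ill}\,x_i\,c^2_{il}(y_l)$ | $X_i \to Y_l$ | $-b_{ill}$ |
| $b_{ijl}\,x_i\,c^2_{ij}(y_j)$, $j \ne l$ | $X_i \to Y_l$, mediator $Y_j$ | $-b_{ijl}$ |

Weights are *effect-signed*: the sign of the edge's contribution to
$d(\text{target})/dt$, so consumption is negative and production
positive. The raw coefficient is kept alongside (`raw_coeff`); the sign
flip on the $dy$ rows reflects the overall minus in the metabolite
equation. This convention makes the species-species heuristic below
consistent: a microbe that depletes a metabolite contributes negative
outgoing weight, so competition products come out negative.

The mediated terms also define a metabolite-metabolite network
($Y_j \to Y_l$, labelled by the mediating microbe, weight $-b_{ijl}$ per
unit biomass; weights are per-unit-biomass coefficients because $x_i(t)$
varies within the segment and edge weights should be segment constants).
Self-loops ($j = l$, a metabolite limiting its own consumption) are kept
behind a default-on flag.

The species-species heuristic sums over all length-two paths
$X_i \to Y_l \to X_j$: $\tilde w_{ij} = \sum_l w_{il} w_{lj}$, where
$w_{il}$ aggregates all microbe-to-metabolite edges (mediated ones
included by default, excludable) and $w_{lj}$ aggregates growth edges.
Negative products read as resource competition, positive ones as
cross-feeding; per-metabolite path products are retained on each edge.
Series summaries are computed per segment and then duration-weighted
(mean $\bar w = \sum_k \Delta t_k w_k / \sum_k \Delta t_k$, population
variance likewise; an edge absent from a segment counts as weight 0).
Species-species networks are built per segment and *then* averaged —
averaging first and composing paths after would interleave
non-commuting operations.

For contrast with a non-dynamic baseline, `fba_direct_network()` builds
the network a single FBA solve supports: exchange fluxes become
microbe-to-metabolite edges, and every consumed metabolite gets a
marker edge into the microbe. Such marker edges exist for *every*
consumed metabolite, whereas basis-derived growth edges exist only for
rate-limiting ones — the baseline systematically over-reports
metabolite-to-microbe influence, which is the point of the comparison.

## The fixtures: what they emulate and what they do not

All tests run on hand-constructed organisms with pencil-and-paper
dynamics (no downloads, no randomness in the fixtures themselves):

* `monod_linear()` — one organism, uptake bound $\kappa y$, yield 1/2:
  $dx/dt = \kappa x y / 2$, $dy/dt = -\kappa x y$, conserving $x + y/2$.
* `capped_growth()` — adds a growth cap; from $(x_0, y_0) = (0.1, 30)$
  with $\kappa = 1$, cap 10, the uptake bound binds at
  $t^* = \ln(51)/10 \approx 0.39318$ and biomass tends to 15.1.
* `diauxie()` — two substrates sharing one uptake capacity with unequal
  yields; exercises degenerate basis rewiring and mediated
  (glucose-spares-acetate) edges.
* `crossfeed_pair()` / `competition_pair()` — sign semantics of the
  species-species heuristic (positive cross-feeding path, symmetric
  negative competition).
* `random_community(seed)` — seeded random 1-3 organism communities
  (linear-uptake metabolisms, optional secretion, all fluxes capped) for
  property tests only: forward invariance, oracle agreement, LP
  cross-checks. Never used for the analytic expectations.

An independent oracle, `direct_dfba_oracle()`, re-solves every LP at
every integrator evaluation (the textbook DFBA route) and is compared
against basis tracking on all fixtures at a $10^{-3}$ state-normalized
tolerance.

Passing these tests shows the machinery is faithful to the mathematics:
event times, conserved quantities, network algebra, sign conventions,
determinism. It does *not* show that predictions transfer to real
communities: genome-scale reconstructions bring thousands of reactions,
degenerate optima far beyond these fixtures' mild degeneracy, uptake
kinetics that are rarely known (the linear default with
$\kappa = 1\,/\mathrm{h}/\mathrm{gDW}$ is a declared convention, not a
measurement), and model-quality issues (missing secondary metabolism)
that no simulator can repair. Problem sizes used by the test suite —
fixtures of 1-4 reactions, 20 seeded random communities, 100 random
networks, horizons of 3-5 h — were chosen as the smallest instances that
exercise every code path with analytically checkable answers.

## Worked example

```{r example}
fx <- capped_growth()
res <- simulate_community(fx$model, fx$env, x0 = 0.1, t_final = 5)
res
res$transitions
sm <- network_series(res, "species_metabolite")
sm$networks[[1]]$edges[, c("source", "target", "weight", "term_kind")]
sm$networks[[2]]$edges[, c("source", "target", "weight", "term_kind")]
summarize_series(sm)$mean$edges[, c("source", "target", "weight")]
```

The first epoch shows purely intrinsic growth (the cap binds; glucose is
consumed at a constant per-biomass rate but is not rate-limiting, so
there is no glucose-to-microbe edge). After the transition — reported
with the violated constraint, here the glucose uptake upper bound — the
growth edge appears and consumption becomes glucose-mediated.

## Known limitations

* The species-species heuristic is pairwise; higher-order effects are
  visible only through the sequence of networks, not within one.
* Basis non-uniqueness at degenerate optima means the reported networks
  are one deterministic representative of a family; the tie-break rules
  above make the choice reproducible, not canonical.
* The forward-selection score uses local (first-order) information; a
  basis optimal for the next instant need not maximize the actual
  segment length.
* The SBML reader/writer covers the Level 3 + FBC subset the package
  emits (single compartment pair, boundary-condition species for the
  environment, bound parameters, one active objective); it is not a
  general SBML implementation, and metabolite-dependent uptake bounds
  travel in a package-specific annotation because SBML has no field for
  them.
* Stiff dynamics are handled by `lsodar`'s automatic method switching,
  but pathological models (e.g. near-singular bases within
  `cond_max`) may still force protective stepping.
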