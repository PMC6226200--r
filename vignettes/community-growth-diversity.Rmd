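---
title: "Community FBA, abundance FVA and the growth-diversity tradeoff"
author: "commfba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community FBA, abundance FVA and the growth-diversity tradeoff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commfba)
```

## The model and its assumptions

`commfba` implements steady-state community flux balance analysis in the
SteadyCom formulation: each species $k$ contributes abundance-scaled
aggregate fluxes $V^k$ (mmol/h per unit total community biomass), all
species share one growth rate $\mu$, and a common extracellular
compartment (the "lumen") balances every exchanged metabolite. The
constraints are linear at fixed $\mu$:

* intracellular steady state per species, $S^k V^k = 0$;
* flux bounds scaling with abundance, $l_j p_k \le V^k_j \le u_j p_k$,
  so an absent species ($p_k = 0$) carries no flux;
* growth coupling $V^k_{\mathrm{bio}} = \mu\,p_k$ — every resident
  species grows at the community rate, the defining steady-state
  assumption (otherwise its abundance would drift);
* lumen balance $\sum_k V^k_{ex(m)} = e_m$ with diet bounds
  $-U_m \le e_m \le e^{\max}$.

Total community biomass is normalized to 1, so abundances are fractions
and single-species and community diet numbers share one scale. The
environment is assumed homogeneous (no spatial structure), kinetics-free
(capacities, not rates), and thermodynamically unconstrained.

Feasibility of a growth rate is decided by maximizing $\sum_k p_k$
subject to the constraints above: $\mu$ is feasible for a unit community
iff the optimum reaches 1. `maximize_community_growth()` brackets
$\mu^{\max}$ by the largest relaxed single-species growth rate — no
community can outgrow its fastest member, because each member's
per-abundance flux vector is itself a feasible single-species state — and
bisects. The solution is then re-extracted at the feasible endpoint with
$\sum_k p_k = 1$ imposed exactly.

### Diets and crossfeeding policy

A diet is a table of maximum uptake rates. At the species level it caps
each exchange reaction's uptake (never relaxing the model's own
transporter capacity); at the community level it caps the lumen's supply
from outside (`0` for metabolites not in the diet — the union-of-diets
convention). The crossfeeding policy then raises every species' uptake
allowance for crossfed metabolites to a common bound (default
10 mmol/gDW/h — a single value because metabolite- and species-resolved
uptake data are rarely available) and forbids uptake of blocked
metabolites entirely. Butyrate- and propionate-like SCFAs are blocked at
the *species* level rather than the community level so their net
community synthesis remains observable. Because the lumen can only be
stocked by the diet or by secretion, these relaxed species-level bounds
leave single-species behavior unchanged — which is also why a one-member
community reproduces standalone FBA exactly (a property the test suite
asserts to $10^{-6}$).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `crossfeed_uptake_bound` | 10 | mmol/gDW/h | uptake allowance for crossfed metabolites |
| `secretion_cap` | 1000 | mmol/h | community secretion bound; effectively unbounded while keeping LPs bounded |
| ATPM lower bound | model-specific | mmol/gDW/h | non-growth maintenance; 10 is typical for curated reconstructions |
| `mu_tol` | 1e-6 | 1/h | bisection tolerance on the maximal growth rate |
| FVA threshold | 0.01 | fraction | strict cutoff for "possible"/"essential" species |
| `f_cut` | 0.70 | fraction | coexistence cutoff for community reduction |
| campaign schedule | 900 cases, levels 0.60–0.99 | — | more cases at low growth where diverse communities live; `reduced_schedule()` runs 10/level |
| bin centers | 0.71–0.99, width 0.02 | fraction | growth-fraction bins for campaign summaries |
| `sum_tol` | 1e-4 | — | acceptance tolerance on the solution abundance sum |

## The abundance-bound sampler

`sample_bounds()` draws $p_j^U = \min(1,\, 2 r_j p_j^{\max} / \sum_i
p_i^{\max})$ with $r_j \sim U[0,1]$. The factor 2 cancels the uniform
draw's expectation of 0.5, so the mean unclamped bound equals the
normalized FVA maximum — species that FVA allows to be abundant get, on
average, looser caps. Three design choices were genuinely open:

* **Clamping at 1.** The raw formula can exceed 1 when one species
  dominates the FVA maxima; abundances are fractions, so bounds above 1
  are meaningless and are clamped.
* **Redraw, not rescale.** Draws with $\sum_j p_j^U < 1$ would make the
  unit-abundance constraint infeasible. Rescaling such draws up would
  distort the sampling distribution; the whole vector is redrawn instead
  (up to 1000 attempts), preserving the distribution conditional on
  feasibility.
* **Discard rule.** A case is discarded when the *returned solution's*
  abundance sum deviates from 1 by more than `1e-4`. Because the
  extraction step imposes the sum as an equality, discards flag numerical
  trouble rather than being routine; the campaign logs discarded and
  failed cases rather than dropping them silently.

Per-case seeds are derived from the master seed and the case counter
(`master + 7919 * index`, kept below $2^{31}$), so any case can be
reproduced in isolation and the full table is bit-identical across runs.

## Abundance FVA choices

Growth is fixed as an **equality** at $f \mu^{\max}$ in the FVA
subproblems. The alternative ($\ge$) nests feasible sets across $f$; the
equality does not, so a species can be possible at a high fraction yet
not at a lower one. Consequences drawn from this choice: coexistence
cutoffs are reported on an explicit grid (default
$\{0.1, \ldots, 0.9, 0.95, 0.99, 0.9999\}$) rather than located by
bisection, and a monotonicity flag accompanies each species' cutoff.
Threshold comparisons are strict (`> 1%`), so a species whose maximum
abundance is exactly the threshold is not "possible". If the LP is
infeasible at exactly $f\mu^{\max}$ (possible at $f = 1$, where
$\mu^{\max}$ carries the bisection tolerance), the analysis retries once
at $f\mu^{\max}(1 - 10^{-6})$.

## Numerical layer

To keep the package free of external solver dependencies, `solve_lp()`
implements a dense two-phase primal simplex directly, with three
stabilizing devices chosen after observing the failure modes of
community LPs (which are massively degenerate — an absent species pins a
whole flux block at zero against many binding constraints):

* **row equilibration** (constraint rows scaled to unit max magnitude),
  because stoichiometric coefficients and bound caps span four orders of
  magnitude;
* a **Harris-style two-pass ratio test** — minimum ratio with a small
  feasibility relaxation, then the numerically largest pivot among
  candidates — to avoid pivoting on vanishing elements at degenerate
  vertices; after a burst budget the pricing falls back to Bland's rule,
  which guarantees termination;
* **periodic refactorization**: after at most 40 pivots the basis
  inverse is recomputed from the original data by direct solve, reduced
  costs are re-derived, and optimality is only ever certified on that
  clean tableau. If drift still produces a primal-infeasible basis the
  phase restarts once with tiny bursts and Bland pricing throughout.

A returned solution is finally checked against the original constraints;
irrecoverable solves report `numeric_failure` rather than a wrong answer.
The bisection treats such failures (which cluster exactly at critical,
degenerate growth rates) by splitting the bracket at an alternative
interior point — any interior split preserves the bisection invariant.
The solver is validated in the test suite against exhaustive
vertex-enumeration on random LPs, and every accepted community solution
is re-verified for mass balance ($\|S^kV^k\|_\infty \le 10^{-6}$), lumen
balance, growth coupling and unit abundance sum.

Degenerate optima are returned as-is: when several abundance vectors
support the optimum (e.g. equal-yield species without crossfeeding), the
reported split is an arbitrary vertex, and uniqueness is decided only by
FVA (minimum equal to maximum for every species).

## What the synthetic communities emulate — and what they do not

The toy generator (`toy_species_def()`, `make_toy_community()`) builds
species around one internal energy currency: substrate catabolism yields
energy and byproducts, biomass formation consumes energy at
$q/\mathrm{yield}$, and ATPM drains it. This gives closed-form
single-species growth rates,
$\mu = (\sum_s q_s u_s - a)\,\mathrm{yield}/q_{\mathrm{primary}}$, which
the tests compare against FBA at $10^{-9}$. The fixtures encode the
structural features the analyses assume: heterogeneous growth rates with
a fastest specialist, obligate crossfeeders (zero growth alone), one
species whose maintenance exactly exhausts its energy supply at ATPM 10,
three SCFA analogs with distinct producer sets and blocked uptake, and an
acyclic crossfeeding topology (cycles must be flagged explicitly, since
with per-step energy yields a contracting cycle is the only thing keeping
free-energy generation bounded).

In the eight-species fixture the non-specialist growth ceilings were
placed at 0.7–0.96 of the specialist's rate so that abundance-capped
communities land across the 0.71–0.99 growth-fraction bins rather than
piling up at the optimum — the regime in which the binned analyses are
informative. One consequence to keep in mind when reading toy results: a
species can catabolize substrate beyond its growth needs and vent excess
energy through the maintenance reaction, so byproduct supply is bounded
by uptake capacity, not by the producer's growth rate.

What passing tests on these fixtures do **not** show: anything about real
reconstructions' metabolic accuracy. The toys have no realistic biomass
composition, no cofactor balancing, no realistic SCFA yields, and
only a handful of exchangeable metabolites. They validate the
*machinery* — LP correctness, conservation, sampler distribution,
metric definitions, determinism — not gut biology.

## Reporting conventions

* Exchange sign convention: positive = secretion into the lumen,
  negative = uptake, for both species and community exchanges.
* Crossfeeding statistics average $|$rate$|$ over all
  species x metabolite (x case) entries *including zeros* by default, so
  "few species exchanging a lot" and "many species exchanging a little"
  separate in the standard deviation; `include_zeros = FALSE` restricts
  to active entries.
* Campaign bins are half-open $[c - 0.01, c + 0.01)$; a case at exactly
  0.70 therefore falls in the first bin, and cases at or above 1.0 are
  flagged out-of-range. Bin width 0.02 follows from 15 centers spanning
  0.71–0.99.
* The abundance-growth association uses Spearman rank correlation with a
  seeded permutation null: optimal communities leave many species at
  exactly zero abundance, which rank methods handle gracefully.
* The ten-byproduct reporting list of the single-species profiles and the
  crossfed-metabolite list are separate configuration entries; blocked
  SCFAs appear in the first but never in the second.

## Problem sizes

The shipped analyses run the three-species fixture (closed-form oracles,
simplex-grid scans at 0.01 resolution) and the eight-species fixture
(9 FVA levels, reduced campaigns of 90 cases). These sizes keep the full
test suite and the acceptance script in the low minutes on one CPU while
exercising every code path; the machinery itself is size-agnostic up to
the dense-LP limit of a few hundred constraints.

## Known limitations

* The dense simplex targets toy-scale problems; genome-scale community
  models (tens of thousands of reactions) require a sparse industrial
  solver behind the same `solve_lp()` contract.
* Growth maximization is the only objective; no parsimonious-FBA
  post-processing, no lexicographic or quadratic objectives, and no true
  Pareto-front computation for the growth-diversity surface — the
  sampler's upper bounds do not guarantee Pareto optimality of the cases.
* No dynamic extension (dFBA), pH, or thermodynamic constraints.
* SBML support is the minimal Level 3 + FBC subset the fixtures need;
  models relying on other SBML packages will not round-trip.
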