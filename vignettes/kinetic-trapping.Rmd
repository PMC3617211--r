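---
title: "Kinetic trapping in reversible pathways: model, fates and the enrichment statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic trapping in reversible pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathtrap)
library(dplyr)
```

## The model and its assumptions

`pathtrap` models the fate of a single damaged locus in a non-essential
molecular pathway as a three-state continuous-time Markov chain: damage
substrate `S`, intermediate `I` and repaired product `P`. Five mass-action
rate constants define the scheme — `k1` (`S -> I`, enzyme F1), `k_m1`
(`I -> S`, R1), `k2` (`I -> P`, F2), `k_m2` (`P -> I`, R2) and `k3`
(`S -> P`, the compensatory route EC). The assumptions worth stating
explicitly:

* **Linearity.** Enzymes act far from saturation, so each transition is
  first-order and the system is a linear ODE, `dx/dt = Q x`. Concentrations
  and single-molecule probabilities are then the same object up to scale; we
  fix the total at 1 and speak of probabilities.
* **Closed system.** No damage influx and no absorbing "fully repaired and
  forgotten" sink: the five edges above are the entire dynamics. Probability
  is conserved exactly (every generator column sums to zero).
* **Initial condition.** All fate evaluations start from freshly damaged DNA,
  `S = 1`. This matters because knockouts make the chain reducible and the
  long-time behavior then depends on the start.
* **Time units are arbitrary.** Only rate ratios matter for limiting
  behavior; the package makes no attempt to map to minutes. Limiting
  distributions are invariant under uniform rescaling of all five rates (a
  tested property).
* **Toxicity is an interpretation.** The model tracks occupancy; calling `I`
  "toxic" (and occupancy above 50% "death") is the biological reading, not a
  dynamical ingredient.

### Exact solutions, not integrators

Time courses are computed through the matrix exponential
(`x(t) = expm(Qt) x(0)`), exact up to floating point, so there is no solver
tolerance to tune. The long-time ("steady state") distribution is computed
analytically by `limiting_state()`:

1. find the closed communicating classes of the positive-rate edge graph
   (knockouts create these kinetic traps — absorbing states or absorbing
   `{I, P}` cycles);
2. solve the stationary distribution inside each closed class (null space of
   the restricted generator, solved by QR with a residual check at `1e-10`);
3. weight the classes by the absorption probabilities from the initial
   condition (a small linear system in the transient states).

For an irreducible chain this reduces to the unique stationary distribution,
independent of the start — spot-checked in the tests against two independent
oracles (an SVD null-space solve and the Markov-chain tree theorem, whose
three-state closed form is rederived by hand in the test helpers) and
against long-horizon integration. "Steady state" in this package therefore
always means the `t -> Inf` limit from `S = 1`, which is well defined for
every admissible rate set, reducible or not.

`time_to_repair()` brackets the first time `P(t)` reaches a threshold by
geometric doubling and bisects to a relative tolerance of `1e-6` on the exact
solution. If the limiting repaired probability is below the threshold it
returns `Inf` without searching.

## Fate classification

From the limiting distribution `d` (starting at `S = 1`), with the default
threshold 0.5:

* `d$P > 0.5`: repaired. The label is `COMPENSATED` when the first passage
  into `P` uses the direct `S -> P` edge with probability above 0.5
  (closed form `q = a/(1 - bc)`, `a = k3/(k1+k3)`, `b = k1/(k1+k3)`,
  `c = k_m1/(k2+k_m1)`), else `REPAIRED_MAIN`.
* otherwise `DD` if `d$S > 0.5`, `DT` if `d$I > 0.5`, and `DEAD_MIXED` when
  no single state clears 50%.

Three deliberate choices here:

* **Strict inequality.** "Above 50%" is strict; a probability exactly at the
  threshold is not above it. Cells exactly on a fate boundary (they exist:
  with equal backward anchors, the `r2 = 1` line of the phase diagram has
  `P^s = 0.5` exactly) are classified by the `else` branch, and their color
  under floating point is ill-conditioned by construction — the tests avoid
  asserting anything on exact ties.
* **First-passage routing for `COMPENSATED`.** "Repair is performed by the
  compensatory pathway" needs a flux-free formalization; first-passage
  routing gives probability 1 whenever the main path is severed (`k1 = 0` or
  `k2 = 0`), which matches every compensated scenario in the catalogue, and
  a sub-50% value for intact main paths in the normal regime.
* **`DEAD_MIXED` is kept separate** from the phase-diagram coloring. The
  absolute ">50%" rules (for `DD`/`DT`) and the relative green/blue rule
  (is `I` bigger than `S`?) disagree on boundary cases; the package exposes
  both views instead of merging them.

### Control parameters and the reconstruction caveat

The fate map is controlled by `r1 = k1/k_m1`, `r2 = k2/k_m2` and
`rb = k_m1/k_m2`. These formulas are a **reconstruction**: they are the
unique per-step forward/backward ratios plus the backward/backward ratio
consistent with the degenerate phase-diagram slices (the `k_m1 = 0` slice can
only vary `r2`, so `r2` must not contain `k_m1`; the `k1 = 0` slice needs a
replacement for `r1`, so `r1` must contain `k1`) and with `rb` being the
ratio of the two backward reactions. On the `k1 = 0` slice the first axis
sweeps `k3/k_m1` (how fast the compensatory route is relative to the
backward step) — flagged in the exported TSV metadata. The `k_m1 = 0` slice
needs an explicit `k1` anchor (its `r1` is infinite); the default is 1.
Ratios with zero denominators are `Inf` sentinels; `0/0` is returned as `NaN`
rather than an error.

## Reference baselines and the scenario catalogue

The two normal regimes are represented by
`NR = (k1=1, k_m1=0.1, k2=1, k_m2=0.001, k3=0.1)` (`rb = 100`) and
`NF = (1, 0.1, 1, 0.1, 0.1)` (`rb = 1`). Both obey the normal-regime
constraint that each forward rate exceeds its backward rate; they were chosen
(once, analytically, via the tree theorem) so that NR survives all five
single knockouts while NF fails exactly the F2 knockout — the qualitative
difference the backward-rate ratio is supposed to carry. No claim is made
that these equal any previously used values; they are this package's stated
world.

The catalogue (`scenario_catalogue()`) pins each scenario to the baseline
where its expected fate is well posed. Two entries deserve comment:

* **F2 knockout and its R1-overexpression rescue sit on NR.** Under NF the
  rescued repaired probability tends to 0.5 *from below* as the R1 factor
  grows (with `k3 = k_m2`, the substrate and product tree weights grow at the
  same rate), so the strict 50% rule can never fire; under NR the rescue is
  clean (`P^s ~ 0.985` at factor 20).
* **The R2-overexpression + F1-knockout rescue is flagged
  `sensitive`.** Its repaired probability under the reference rates is ~0.22:
  a partial rescue, reported but not asserted.

The default overexpression factor is 20: at factor 10 the two
dosage-lethality scenarios on NF sit in the `DEAD_MIXED` boundary zone
(`I^s` just under 0.5), while 20 pushes them above the strict rule without
disturbing any other label.

### Suppressor epistasis and the futile cycle

The biological suppression analog — the toxic trap of the R1/F2 double
knockout being relieved by additionally knocking out F1, so that repair
reroutes through the compensatory path — holds in this model **only when the
second step is irreversible** (`k_m2 = 0`, a variant the model explicitly
allows; second-step reversibility is not needed for the trapping mechanism
itself). With any `k_m2 > 0`, the triple knockout's only flow is
`S -> P -> I`, so at `t -> Inf` every trajectory ends in the intermediate no
matter how slow the `P -> I` leak: the suppression is then a (possibly very
long-lived) transient, not a limiting fate. The acceptance test therefore
asserts the suppression on the `k_m2 = 0` variant of the fragile reference
and, separately, asserts the futile-cycle limit under the reversible
reference — both are computed facts about the model, and the distinction is
exactly the reason a final irreversible "repair committed" step (out of scope
here) stabilizes real pathways.

## Phase diagrams

`compute_phase_diagram()` classifies a log-spaced `r2 x r1` grid (default 41
points per axis over `[1e-2, 1e2]`, per-axis configurable) at fixed anchor
backward rates; the three regimes of interest are realized as
`rb in {0.1, 1, 100}` with `k3 = 0.1`. Coloring: red if `P^s > 0.5`, else
green if `I^s > S^s`, else blue. Tested structural properties: the red region
is upward-closed in `r2` along any row (no re-entrant death in a linear
model), the fast-forward corner with `rb >= 1` is red, the starved-`r2`
corner with `rb <= 1` is green, and diagrams are invariant to uniform rate
rescaling.

## The enrichment statistic and the synthetic screen

For interaction screens, the statistic is: stringent negative interactions
(`epsilon < -0.12` and `p < 0.05` by default — conventional stringent cutoffs
for genome-wide yeast screens, exposed as configuration since screens differ)
between members of a gene set, minus pairs co-occurring in any molecular
complex, divided by `S(S-1)/2`. Pairs are unordered and deduplicated keeping
the most negative epsilon; identifier matching is exact and case-sensitive
(no alias resolution); a pair inside several pathways counts for each of
them, but only once in the global complex fraction.

The synthetic generator (`simulate_interaction_screen()`) emulates the
statistical skeleton of such a screen: independent per-pair Bernoulli draws
at a background rate (default `p_bg = 0.02`), an elevated rate inside planted
pathways (`p_wp = 0.2`, i.e. 10x background — the same order as the strongest
real pathways, whose proportions reach ~0.14), and a separate within-complex
rate (`p_c = 0.5`, complexes being negative-interaction-dense); negative
pairs get epsilon in `[-0.6, -0.15]` and p-values in `[0, 0.01]` (strictly
inside the default filter), and 5% of null pairs are emitted with mild
epsilon in `[-0.08, 0.08]` (strictly outside) so the filter is actually
exercised. The default universe is 200 genes with pathways of 20, 15 and 15,
the first planted, and complexes of 5 and 4 nested in the first two. All
randomness flows from one seed.

What the generator does **not** emulate — and hence what a green test does
not establish: colony-size measurement noise and its correlation structure,
fitness-dependent epsilon magnitudes, overlapping pathway memberships, hub
genes, and any real gene identity. Green planted-recovery tests establish
that the statistic is implemented correctly and calibrated against its own
generative model (the observed planted proportion is unbiased for
`p_wp * (N_pairs - N_complex_pairs) / N_pairs`), not that it would rank any
real pathway first.

## Numerical choices, degenerate inputs, limitations

* Stationary/limiting solves carry residual checks at `1e-10`; matrix
  exponentials are exact to machine precision for this 3x3 system;
  `time_to_repair()` bisects to relative tolerance `1e-6`.
* Degenerate inputs: the all-zero rate set is rejected (nothing moves); a
  rate set whose product state is unreachable makes the route probability an
  error rather than a silent 0/0; `0/0` control ratios are `NaN` flags.
* Ties at the 50% threshold are classified by the strict rule (not above);
  see the boundary discussion above.
* Out of scope by design: stochastic (Gillespie) simulation — the linear
  model's single-molecule law *is* the master equation, so nothing would be
  gained at this scale; enzyme saturation kinetics; the kinetic-proofreading
  extension with an irreversible final repair step; and reproducing published
  real-screen rankings, which require external interaction and pathway
  catalogues (the readers accept such files, in TSV/GMT form, if supplied).
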