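---
title: "Modelling glucose flux with size-dependent glucosome clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glucose flux with size-dependent glucosome clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucosim)
```

## The model

Cancer cells spatially organize the four rate-limiting cytoplasmic enzymes
of glucose metabolism — liver-type phosphofructokinase-1 (PFKL),
fructose-1,6-bisphosphatase (FBPase), pyruvate kinase M2 (PKM2) and
phosphoenolpyruvate carboxykinase 1 (PEPCK1) — into multienzyme assemblies
("glucosomes") that come in three observable size classes. `glucosim`
implements a deterministic kinetic model of how the size of these clusters
redirects glucose-derived carbon between three lumped fates: the pentose
phosphate shunt ($P_1$), serine biosynthesis ($P_2$) and downstream
glycolysis ($P_3$).

The state has 19 variables: seven metabolic intermediates $S_1..S_7$
(glucose through oxaloacetate, several non-branching intermediates lumped
away), nine enzyme species (free PFKL $E_1$, FBPase $E_2$, PKM2 dimer
$E_3$, PEPCK1 $E_4$, small/medium/large clusters $E_S$, $E_M$, $E_L$, the
catalytically active PKM2 tetramer $E_3^*$ and glycosylated, inactive PFKL
$E_1^{gly}$) and the three products. Twenty-eight reaction propensities
drive the dynamics:

* $R_1..R_{12}$: metabolite interconversions, mass-action except for the
  PFK and FBPase steps, which carry hyperbolic allosteric inhibition
  ($R_4 \propto K_1/(K_1+S_3)$, $R_5 \propto K_2/(K_2+S_2)$) and
  cluster-weighted enzyme pools such as
  $E_1 + E_S + c_2 E_M + e_2 E_L$;
* $R_{13}..R_{18}$: cluster assembly/disassembly — PFKL forms small
  single-enzyme clusters, a small cluster plus one copy each of FBPase,
  PKM2 and PEPCK1 forms a medium cluster, and **11 medium clusters condense
  into one large cluster** ($R_{17} = k_{al} E_M^{11}$), a ratio taken from
  imaging counts of medium and large clusters per cell;
* $R_{19}/R_{20}$: PFKL glycosylation/de-glycosylation;
* $R_{21}/R_{22}$: PKM2 tetramer/dimer interconversion, with
  tetramerization allosterically promoted by fructose-1,6-bisphosphate;
* $R_{23}..R_{28}$: first-order product formation and degradation.

The derivative is assembled from three stoichiometry blocks
($\nu_S$: 7×15, $\nu_E$: 9×10, $\nu_P$: 3×6); the formation propensities
$R_{23}..R_{25}$ feed both the metabolite and the product blocks, so all 28
propensities are evaluated once per right-hand-side call. The $\pm 11$
entries in the $E_M$ row of $\nu_E$ encode the 11-to-1 condensation.
`conservation_totals()` exposes the four structural invariants — e.g.
$E_1 + E_1^{gly} + E_S + E_M + 11 E_L$ for PFKL — which equal 100 at the
default initial state and are conserved exactly by construction (the
weighted column sums of $\nu_E$ vanish; a unit test checks this
algebraically).

All quantities, including time, are non-dimensional ("arbitrary units");
there is deliberately no unit-conversion layer.

### Parameters and defaults

`default_parameters()` carries the model's 40 rate constants. Generic
enzymatic steps sit at 10; $k_2/k_{-2} = 40/7$ and $k_4/k_{-4} = 14/7$ bias
free-enzyme flux toward glycolysis so that $P_3 \gg P_1, P_2$ with no
clusters; products form at 5 and degrade at 0.5. The cluster-efficiency
factors implement the two biological hypotheses: medium clusters decelerate
glycolysis and accelerate gluconeogenesis ($c_2 = 0.2$, $c_{-d} = 0.1$,
$c_{-2} = c_{-6} = 10$), shunting flux to the pentose phosphate pathway,
while large clusters redirect it to serine biosynthesis ($e_2 = 2.5$,
$e_{-6} = 10$, $e_{-2} = 0.1$, $e_{-d} = 0.05$). These defaults were chosen
by the model's authors to reproduce qualitative flux changes, not fitted to
data; the package treats them as the definition of the study conditions and
provides no fitting machinery.

The allosteric constants $K_1$ (inhibition of the PFK step, labelled as
acting through fructose-1,6-bisphosphate) and $K_2$ (inhibition of the
FBPase step by fructose-6-phosphate) are implemented exactly as the
propensity table prints them, without biological reinterpretation.

## Scenarios

`apply_scenario()` realizes the four cluster regimes by zeroing parameters,
always on a copy made after any user override (so sweeping a parameter a
scenario zeroes is permitted and yields a constant envelope — documented
behaviour, not an error):

| scenario | zeroed |
|---|---|
| `NO_CLUSTER` | $k_{as}, k_{-as}, k_{am}, k_{-am}, k_{al}, k_{-al}$ and all $c_i$, $e_i$ |
| `SMALL` | $k_{am}, k_{-am}, k_{al}, k_{-al}$ and all $c_i$, $e_i$ |
| `MEDIUM` | $k_{al}, k_{-al}$ and all $e_i$ |
| `LARGE` | nothing (the full model) |

Small PFKL clusters are single-enzyme assemblies with free-enzyme
activity, which is why `SMALL` keeps only the association rates: with
glycosylation switched off the small-cluster and no-cluster metabolite
dynamics coincide exactly (every propensity then depends on PFKL only
through $E_1 + E_S$) — a property test in the suite.

## Numerical choices

* **Integrator.** `deSolve::ode(method = "lsoda")` with `rtol = 1e-8`,
  `atol = 1e-10`. The system is stiff: enzyme pools of order 100 coexist
  with metabolites of order 0.01, and $R_{17} = k_{al} E_M^{11}$ has an
  enormous local Lipschitz constant in $E_M$.
* **Compiled right-hand side.** The RHS is written twice: once in R
  (`propensities()` / `derivative()`, routed through the stoichiometry
  matrices — the documented model surface) and once in C for the
  integrator, the usual deSolve compiled-model pattern. Tests pin the two
  routes against each other and against an independently transcribed
  equation-by-equation oracle.
* **Negative excursions.** The solver may step infinitesimally below zero;
  propensity evaluation clips its local copy of the state at 0 (the 11th
  power would otherwise amplify a tiny negative $E_M$), while the stored
  trajectory is left untouched. Trajectories from the default initial
  state stay above $-10^{-9}$.
* **Grid.** Default `t_end = 10`, `n_points = 1001`. All headline readouts
  are quoted at $t = 10$; the horizon is configurable. `product_levels_at()`
  requires an exact grid hit rather than interpolating, so a reported value
  is always a solver output.
* **Conservation watchdog.** Every simulation computes the four enzyme
  totals on the full grid and warns if any drifts more than $10^{-6}$ from
  its initial value (observed drift is ~$10^{-12}$).

## Sensitivity analysis

`lhs_sample()` draws a Latin hypercube over every parameter with default
$d > 0$, uniform on $[d/2, 2d]$, one draw per equal-probability bin
(`lhs::randomLHS` supplies the stratified unit hypercube). A parameter
with default 0 has a degenerate interval and must be excluded explicitly —
relevant only for user-modified parameter sets, since all 40 defaults are
positive. `evaluate_samples()` simulates each row and records
$(P_1, P_2, P_3)$ at the end time; `prcc()` computes partial rank
correlation coefficients and `classify_sensitive()` flags pairs with
$|\mathrm{PRCC}| > 0.2$ and $p < 0.01$.

Design choices where the procedure was underdetermined:

* **Scenario.** The published analysis does not state the cluster regime;
  `LARGE` is the default here because it is the only regime in which every
  sampled parameter is active (no scenario zeroing), making the
  $[d/2, 2d]$ interval well-defined for all of them.
* **Sampled set.** Every strictly positive parameter, including $\alpha$
  and $K_1..K_3$, with an `exclude` argument for restriction.
* **PRCC computation.** Columns are rank-transformed (average ties — ties
  have probability zero for continuous LHS anyway); the partial
  correlation of parameter $j$ with an output, controlling for all other
  parameter ranks, is read off the inverse of the rank-correlation matrix.
  The test suite checks this against a brute-force oracle that explicitly
  residualizes with `lm()` and correlates residuals, to $10^{-10}$.
* **p-values.** From $t = \mathrm{PRCC}\sqrt{(n-2-k)/(1-\mathrm{PRCC}^2)}$
  with $k$ the number of controlled parameters, against a $t$ distribution
  with $n - 2 - k$ degrees of freedom (the source method is cited without
  formulas; this is the standard partial-correlation test).
* **Sample count.** The reference analysis uses 20,000 samples (the
  `cmd_prcc()` default). The test suite runs 2,000: PRCC estimates at that
  size are stable to well under 0.1 across seeds, and every coefficient
  with $|\mathrm{PRCC}| > 0.3$ already has its sign confirmed by central
  finite differences at the defaults, so the scaled-down run supports the
  same sensitive/not-sensitive partition at a fraction of the cost.
* **Initial state.** Always the default initial conditions; only
  parameters vary.

## Ensemble (population-level) prediction

A cell population is described by the fractions of cells displaying each
cluster regime (`read_distribution()` reads a small delimited table;
percent vs fraction rows are auto-detected from row sums, and rows summing
to neither ~1 nor ~100 within 0.5% are rejected by name rather than
guessed). `ensemble_flux()` simulates the four scenarios once on a common
grid and mixes **product levels only**:
$P_m^{ens}(t) = \sum_{s} f_s\, P_m^{(s)}(t)$. The prediction is therefore a
convex combination — it always lies within the envelope of the four
scenario outputs, and is linear in the distribution; both properties are
tested. Scenario runs may be precomputed and shared across distributions
(`simulate_scenarios()`), which is bit-identical to uncached evaluation.

The packaged fixture `hs578t_cluster_distributions.csv` carries the five
measured Hs578T populations (control; methylene blue;
fructose-1,6-bisphosphate; EGF; 2-deoxyglucose). With the default
parameters the control population's glycolytic product reaches ≈ 7 a.u. at
$t = 10$ and the 2-deoxyglucose population's ≈ 5 a.u. — the 2-DG shift of
cells toward medium and large clusters diverts flux from glycolysis into
the anabolic branches. The exact values are recomputed by
`scripts/acceptance.R` and by the test suite, not stated here.

## What the simulations do and do not show

The model is non-dimensional and hand-parameterized: it encodes the
cluster-size hypotheses as efficiency factors and reproduces qualitative
flux redirection, but its outputs are not calibrated concentrations, and
no parameter was estimated from data. The ensemble prediction treats a
population as a static mixture of four pure regimes — no cell switches
class during a simulation, and the measured fractions enter as given
(image analysis is out of scope). Propensities are integrated
deterministically; no stochastic (Gillespie) interpretation is offered,
and there is no SBML import/export. Conclusions about real cells therefore
rest on the direction and ordering of effects, which is exactly what the
test suite pins down.
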