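# glucosim

Deterministic kinetic simulation of glucose flux in cancer cells whose
rate-limiting metabolic enzymes assemble into multienzyme clusters
("glucosomes") of different sizes.

## The problem

In cancer cells, liver-type phosphofructokinase-1 (PFKL),
fructose-1,6-bisphosphatase, pyruvate kinase M2 and PEPCK1 spatially
organize into small, medium and large cytoplasmic clusters. Cluster size
correlates with where glucose-derived carbon goes: medium multienzyme
clusters shunt flux into the pentose phosphate pathway, large clusters
divert it into serine biosynthesis, and free or small-clustered enzymes
let glycolysis dominate. `glucosim` implements a 19-variable, 28-reaction
ODE model of this system for anyone who wants to simulate cluster
scenarios, quantify parameter sensitivity, or predict population-level
metabolic outcomes from imaging-derived cluster-size distributions.

## The model in brief

State: intermediates S₁..S₇, enzyme species (E₁ PFKL, E₂ FBPase, E₃ PKM2
dimer, E₄ PEPCK1, E_S/E_M/E_L clusters, E₃* PKM2 tetramer, E₁ᵍˡʸ
glycosylated PFKL) and products P₁ (pentose phosphate shunt), P₂ (serine
biosynthesis), P₃ (glycolysis). Dynamics: dS/dt = ν_S R_S,
dE/dt = ν_E R_E, dP/dt = ν_P R_P with 28 propensities — mass action plus
hyperbolic allosteric terms, e.g.

    R4 = k2 (E1 + E_S + c2 E_M + e2 E_L) S2 K1/(K1 + S3)
    R17 = k_al E_M^11        # 11 medium clusters condense into one large
    R22 = k_md (E3 + c_md E_M + e_md E_L) (1 + α S3/(S3 + K3))

Cluster-size-dependent catalysis enters through the efficiency factors c_i
(medium) and e_i (large). Each enzyme's total pool (large clusters
counting 11-fold) is structurally conserved at 100. Four scenarios —
`NO_CLUSTER`, `SMALL`, `MEDIUM`, `LARGE` — are realized by zeroing the
corresponding association rates and efficiencies. All units are
non-dimensional (a.u.). See the vignette in `vignettes/glucosome-model.Rmd`
for the full account.

## Worked example

```r
library(glucosim)

# single-cell scenario: everything assembled into large clusters
tr <- simulate_pathway(scenario = "LARGE", t_end = 10)
tr
#> <glucosome_trajectory> scenario LARGE, 1001 points over t = [0, 10]
#>   products at t_end: P1 = 4.792  P2 = 12.43  P3 = 2.55
#>   max conservation drift: 8.1e-13
```

Large clusters divert flux into serine biosynthesis: P₂ (12.43 a.u.)
dominates P₁ and P₃ at t = 10, and the enzyme conservation totals drift by
less than 10⁻¹² over the run.

```r
# population-level prediction from measured cluster-size fractions
dists <- read_distribution(system.file("extdata",
  "hs578t_cluster_distributions.csv", package = "glucosim"))
ensemble_flux(dists[[1]])   # Hs578T control population
#> <ensemble_trajectory> Hs578T (Control) (1.6%/58.3%/13.4%/26.7%)
#>   products at t_end: P1 = 6.293  P2 = 6.513  P3 = 7.004
ensemble_flux(dists[[5]])   # after 2-deoxyglucose treatment
#> <ensemble_trajectory> Hs578T with 2-Deoxyglucose (0.0%/34.7%/21.2%/44.1%)
#>   products at t_end: P1 = 7.078  P2 = 7.631  P3 = 5.09
```

In the untreated population glycolysis narrowly leads (P₃ ≈ 7.0 a.u.);
2-deoxyglucose shifts cells toward medium/large clusters, inhibiting the
ensemble glycolytic flux to ≈ 5.1 a.u. while promoting both anabolic
branches.

Sensitivity analysis and sweeps:

```r
s <- lhs_sample(n_samples = 2000, seed = 1)     # each parameter on [d/2, 2d]
tab <- prcc(s, evaluate_samples(s, scenario = "LARGE"))
subset(tab, sensitive & product == "P3")         # |PRCC| > 0.2, p < 0.01

sweep_parameter("k2", 40, 10, 5, scenarios = "MEDIUM")  # envelope of P1..P3
```

A command-line interface wraps the same functions:

```sh
exec/glucosim simulate --out-dir runs/demo
exec/glucosim ensemble --distribution inst/extdata/hs578t_cluster_distributions.csv --out-dir runs/demo
exec/glucosim prcc --n-samples 2000 --seed 1 --out-dir runs/demo
```

Every command writes CSV outputs plus a JSON manifest that fully specifies
the run (parameters, grid, version), and a `run.log` with conservation
diagnostics.

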