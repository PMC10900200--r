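# glycobalance

Kinetic and thermodynamic analysis of dynamic covalent molecular balances
that assemble in situ as *Z*/*E* enamine pairs.

## The problem

Weak aromatic interactions — CH/π contacts, cation/π and anion/π forces —
steer molecular recognition, catalysis and carbohydrate–protein binding,
but their free energies are fractions of a kcal/mol and exquisitely
solvent-dependent. A *molecular balance* measures them by letting a single
molecule interconvert between two states, only one of which forms the
contact: the state populations then report the interaction directly. The
balances this package analyzes form spontaneously in solution from a
carbohydrate-derived amine and a 2-arylpropionaldehyde, as a pair of
*Z*/*E* enamines in which only the *Z* isomer folds the interaction
fragment onto an aromatic platform. Their formation and equilibration are
monitored as NMR (HSQC) cross-peak integrals over hours to days.

The package is for chemists running such assays (or simulating them) who
need the full chain from raw kinetic series to interaction free energies
and solvent trends:

1. **Kinetics** — mass-action simulation of the three-reaction network
   (amine + aldehyde ⇌ intermediate ⇌ *Z*/*E* enamines) with six rate
   constants, plus closed-form equilibrium and initial-flux ratios and
   kinetic-regime classification (`simulate_network`,
   `closed_form_ratios`, `classify_regime`).
2. **Ratio-curve fitting** — the population ratio follows
   [Z]/[E] = K<sub>eq</sub> + A·e<sup>−t/c</sup> (or a two-exponential
   variant); nonlinear fits extract K<sub>eq</sub><sup>Z/E</sup> (the
   asymptote) and the initial flux ratio k<sub>1Z</sub>/k<sub>1E</sub>
   (the extrapolated t = 0 value), with AICc-based selection between the
   one- and two-exponential forms (`fit_ratio_exponential`, `select_fit`).
3. **Thermodynamics** — ΔG<sub>Z/E</sub> = −RT ln K<sub>eq</sub>, the
   differential quantities ΔG<sub>int</sub>, ΔG<sub>charge</sub>,
   ΔG<sub>pol</sub> by reference/isostere subtraction, a tiered relative
   error model for K<sub>eq</sub> (5% / 7.5% / 10% / 15% by magnitude)
   and quadrature error propagation (`delta_g_from_keq`,
   `interaction_free_energy`, `isostere_contribution`).
4. **Solvent trends** — least-squares regression of charge/polarization
   contributions against Hunter hydrogen-bond α/β parameters, and
   stability rankings of complex classes per solvent
   (`regress_vs_parameter`, `rank_hierarchy`).
5. **Synthetic data** — a seeded generator of noisy HSQC-integral time
   series with the statistical structure of the real assays, with ground
   truth in a sidecar for blind recovery tests (`sample_rate_constants`,
   `generate_experiment`).
6. **Pipeline** — a balance registry (YAML) drives the whole chain and
   emits per-balance, per-class and per-solvent tables (`run_pipeline`);
   a thin command-line wrapper lives in `inst/scripts/glycobalance`.

## Worked example

The dichloromethane proof-of-concept values are desk-derivable from three
measured equilibrium constants — K<sub>eq</sub> = 0.45 for the reference
balance R0, 1.3 for the neutral isostere R6, 8.0 for the
trimethylammonium model M6, all at 293 K:

```r
library(glycobalance)

m6 <- dg_ze_record(8.0,  293, "M6", solvent = "DCM")
r6 <- dg_ze_record(1.3,  293, "R6", solvent = "DCM")
r0 <- dg_ze_record(0.45, 293, "R0", solvent = "DCM")

interaction_free_energy(m6, r0)
#> dG_int = -1.676 +/- 0.0508 kcal/mol (T = 293 K, DCM)  [M6 vs R0]
isostere_contribution(m6, r6, "charge")
#> dG_charge = -1.058 +/- 0.0508 kcal/mol (T = 293 K, DCM)  [M6 vs R6]
```

The cationic complex is worth −1.68 kcal/mol, of which −1.06 kcal/mol
(63%) is contributed by the charge; errors are the quadrature sums of the
tier-implied ΔG errors of the two inputs.

A full synthetic kinetic experiment, from rates to fitted K<sub>eq</sub>:

```r
k <- sample_rate_constants("slow_bimolecular", 1, seed = 42)[[1]]
series <- generate_experiment(k, experiment_design(seed = 42))
fit <- select_fit(build_ratio_series(series))
summary(fit)
#> Z/E ratio fit (1 exponential)
#>   Keq           = 7.05976
#>   A1 = 2.69159   c1 = 44.2971 min
#>   initial Z/E   = 9.75134 (extrapolated t = 0)
#>   SSE           = 6.706 over 64 points
#>   Keq error tier = 7.5% (duplicate-based tiers)
#>   dG(Z/E) at 293 K = -1.138 +/- 0.04211 kcal/mol
```

The fitted K<sub>eq</sub> = 7.06 against a ground truth of 7.03 — inside
the 7.5% error tier, as the recovery suite demands of at least 90% of
experiments.

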