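# bedalloc

Balancing bed occupancy across hospital departments by census, simulation
and integer programming.

Large tertiary hospitals often run some departments far above the 85–90%
bed-occupancy band considered safe and efficient (with overflow beds in
corridors) while others sit well below it. `bedalloc` is for hospital
bed-planning analysts and health-operations researchers who want to
rebalance a *fixed* stock of beds across departments from routinely
collected admission/discharge data. It implements a three-stage workflow:

1. **Census** (`department_census()`): per-department length of stay (LOS)
   and bed occupancy rate (BOR) from a registry, over a fixed analysis year.
   Stays are split into those discharged inside the year (type 1), those
   carrying past it (type 2, censored at the year end) and discharges with
   missing admission records (type 3, imputed at the department's median
   type-1 stay). `BOR = (LOS1 + LOS2 + LOS3) / (beds × days)`, and
   departments are grouped A (under-used, BOR < 0.85), B (overloaded,
   BOR > 0.90) or C (in band).
2. **Simulation + curve estimation** (`sweep_beds()`, `fit_bor_curves()`):
   a day-stepped discrete-event simulation of one department — daily
   arrival counts from a fitted Johnson SB or uniform distribution,
   admission with probability *p*, an unbounded FIFO queue for `C` identical
   beds, constant median-LOS service — swept across candidate bed counts
   under common random numbers. Eight curve-estimation families (linear,
   logarithm, quadratic, composite, power, growth, exponential, logistic)
   are fitted to the resulting (beds, BOR) table by (log-linearized) OLS and
   ranked by R²; the quadratic response `BOR_i(C_i) = β_i + a_i C_i + b_i
   C_i²` is exported.
3. **Allocation** (`solve_exact()`, `solve_ga()`): choose integer bed counts
   `C_i` minimizing the occupancy imbalance

       Z = Σ_i | BOR_i(C_i) − (Σ_j BOR_j(C_j)) / n |

   subject to `Σ C_i = C_t` (fixed total), `L_i ≤ C_i ≤ U_i`, and ward-mix
   integrality `C_i = K_i1 + 2 K_i2 + 3 K_i3` with at least two single-,
   double- and triple-bed wards each (gender separation), enumerated
   post-hoc by `enumerate_ward_mixes()`. A genetic algorithm with a
   budget-repair operator solves general instances; an exhaustive
   enumeration solver provides the exact optimum (and the GA's validation
   oracle) when the bounded space is tractable.

`run_pipeline()` chains the stages from a single config; synthetic
generators (`generate_registry()`, `generate_bor_curve()`,
`generate_problem()`) provide ground-truth fixtures; a five-department case
study (departments W9, W10, W6, W27, W19 of a 28-department tertiary
hospital, 644 beds) ships in `inst/extdata/` with its sweep tables, fitted
responses and bounds. A thin CLI lives at `inst/scripts/bedalloc`.

## Worked example: the packaged case study

```r
library(bedalloc)

# Stage II(b): fit the eight families to the W9 sweep, best first
summary(fit_bor_curves(case_study_sweeps()$W9))
#> Curve-estimation ranking (14 points), best fit first:
#>         form r_squared  f_stat df1 df2      sig    b0       b1        b2
#>    quadratic     0.977 231.398   2  11 1.03e-09 0.721  0.00449 -1.95e-05
#>       linear     0.836  61.377   1  12 4.65e-06 1.250 -0.00218        NA
#>    composite     0.821  54.865   1  12 8.20e-06 1.370  0.99700        NA
#>       growth     0.821  54.865   1  12 8.20e-06 0.313 -0.00263        NA
#>  exponential     0.821  54.865   1  12 8.20e-06 1.370 -0.00263        NA
#>     logistic     0.821  54.865   1  12 8.20e-06 0.732  1.00000        NA
#>    logarithm     0.725  31.558   1  12 1.13e-04 2.550 -0.32800        NA
#>        power     0.704  28.562   1  12 1.75e-04 6.460 -0.39200        NA

# Stage III: how imbalanced is the current allocation?
objective_z(case_study_initial_bors())
#> [1] 0.7344

# ... and the exact optimum over all ~4.9e7 feasible allocations
summary(solve_exact(case_study_problem()))
#> Bed allocation (exact solver): Z = 0.0112398
#>  department beds    bor
#>          W9  170 83.75%
#>         W10  121 84.01%
#>          W6  140 84.03%
#>         W27  168 83.87%
#>         W19   45 83.26%
#> Total beds: 644; BOR spread (max - min): 0.77%
#> Example ward mixes (k1 singles, k2 doubles, k3 triples):
#>   W9 (2160 mixes): (2,3,54) (2,6,52) (2,9,50)
#>   ...
```

The quadratic family wins the R² ranking (0.977) and its coefficients give
W9's occupancy response. The current allocation scores Z = 0.7344 — the five
departments' occupancies (69.5% … 98.5%) deviate from their mean by a
combined 73 percentage points. Reallocating within bounds at the same
644-bed total brings every department to 83–84% occupancy (Z = 0.0112, a
spread of 0.8 points). `solve_ga(case_study_problem(), seed = 1)` reaches
the same optimum.

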