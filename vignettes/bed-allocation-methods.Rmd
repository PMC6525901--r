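---
title: "Methods: census, occupancy simulation and bed allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: census, occupancy simulation and bed allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedalloc)
```

# The problem

Large tertiary hospitals often run at a high overall bed occupancy rate
(BOR) while individual departments sit far apart: some above 100% (corridor
beds), others well under the 85–90% band usually regarded as both safe and
efficient. `bedalloc` rebalances a *fixed* stock of beds across departments
in three stages: a registry census (Stage I), a per-department occupancy
simulation plus curve estimation (Stage II), and an integer allocation model
(Stage III). This vignette documents the modelling choices behind each
stage, the tunable parameters, and what the packaged tests do and do not
demonstrate.

# Stage I — census

The census works on an admission/discharge registry restricted to one
analysis window (a calendar year; `capacity_days` = number of days in the
window, 365 for 2013). Stays are partitioned by where the discharge falls:

* **type1** — discharged inside the window with an admission record. Its
  in-window length of stay (LOS) is `discharge − max(admission, start)`.
* **type2** — admitted on or before the window end but not discharged inside
  it (discharge later, or still open). Contribution:
  `end − max(admission, start)`.
* **type3** — discharged inside the window with *no* admission record
  (registries routinely contain such rows). Its LOS cannot be computed, so
  the department's **median type1 LOS** is imputed.
* **out** — no overlap with the window; dropped with a logged count.

Day counting is a whole-day date difference, exclusive of the discharge day
(admitted the 1st, discharged the 11th = 10 bed-days). Window clipping means
an in-window contribution never exceeds `capacity_days`. Two deliberate
choices deserve a note:

* The type2 rule uses the **window end** (December 31) as the censoring
  date on both of its branches; the window is configurable via
  `analysis_window()` should a different censoring day be wanted.
* The type3 imputation is applied **unclipped**: the median is added as-is
  rather than truncated at the window boundary. Medians of annual stays are
  far shorter than the window, so clipping would never bind in practice;
  leaving it unclipped keeps the imputation identical to the department's
  reported median.
* The median is taken over *in-window* type1 LOS values (the same quantity
  the census sums), with the standard average-of-middle-two convention for
  even counts, used unrounded.

The BOR is `total LOS / (beds × capacity_days)` and may legitimately exceed
1 — hospitals add corridor beds when demand overflows, and those extra
bed-days are counted in the numerator but not the denominator. Departments
are grouped `A` (BOR below `low`, default 0.85), `B` (above `high`, default
0.90) or `C` (the inclusive band), mirroring the usual optimal-occupancy
range. When type3 rows are not present as records, their count can be
supplied externally per department (total reported discharges minus the
type1 count), which is how registries with separate discharge ledgers are
handled.

# Stage II(a) — occupancy simulation

`simulate_department()` is a day-stepped discrete-event simulation with one
department, `beds` identical servers, and a constant service time equal to
the department's median LOS. LOS distributions for such registries fit
poorly to standard families, while the median is stable; treating the stay
as a constant is the standard simplification and is what the census median
feeds into.

The arrival model is a distribution of **daily arrival counts**: one real
draw per day (Johnson SB or uniform), clamped at zero and rounded half-up.
The Johnson SB family — a logit transform of a standard normal,
`x = ξ + λ / (1 + exp((γ − z)/δ))` with support `(ξ, ξ + λ)` — is the
bounded, skewed family that arrival-rate fitters typically select for
admission volumes. Reading the fitted parameters as daily counts (rather
than inter-arrival times) is the interpretation under which the packaged
case-study parameters reproduce the registry's annual admission volume
(mean ≈ 34.3/day ≈ 12 500/year for the largest department, against ~12 700
registered admissions).

Each arrival is admitted independently with probability `admit_prob` (the
hospitalization proportion; non-admitted arrivals leave immediately).
Admitted patients join an **unbounded FIFO queue**: blocked patients wait
rather than balk. This matches the near-but-below-100% occupancies seen at
small bed counts in the packaged sweep tables — with balking, occupancy
would pin at 1 after the initial transient; with waiting, only the
empty-start ramp keeps it just under.

Conventions, all deliberate: the system starts empty with no warm-up;
arrivals land at day start and discharges happen at day end, so a patient
with LOS 10 occupies a bed for exactly 10 counted bed-days; a discharge is
counted only when service completes *inside* the horizon (default 365
days); BOR is in-horizon occupied bed-days over `beds × horizon_days` and
is therefore always in `[0, 1]`. Runs are bit-reproducible from the config
seed, and the seed handling never disturbs the caller's RNG stream.

`sweep_beds()` reuses one sampled admission stream per replication across
every candidate bed count (common random numbers), which makes BOR
non-increasing and discharges non-decreasing in the bed count *pathwise* —
a property the tests check — and averages over replications arithmetically.

A reproducibility caveat recorded here rather than hidden: the packaged
case-study sweep tables were produced by a different (commercial) simulator
before being shipped with this package, and they are not exactly
reproducible from the packaged arrival parameters. Re-simulating the
236-bed department from its own Johnson SB parameters and admission
probability yields ≈ 5 300 annual discharges and BOR ≈ 0.62, about 10%
below the tabled 5 984 / 0.695 — while agreeing within ~1% with the
registry's observed 5 478 discharges. In other words, the shipped tables
overstate throughput relative to what their own stated inputs imply; the
package reproduces the inputs faithfully and documents the gap instead of
rescaling anything to match.

# Stage II(b) — curve estimation

`fit_bor_curves()` fits the eight classic single-predictor curve-estimation
families to the (beds, BOR) sweep:

| family      | model                          | fitting scale        |
|-------------|--------------------------------|----------------------|
| linear      | `y = b0 + b1 x`                | y                    |
| logarithm   | `y = b0 + b1 ln x`             | y                    |
| quadratic   | `y = b0 + b1 x + b2 x²`        | y                    |
| composite   | `y = b0 b1^x`                  | ln y                 |
| power       | `y = b0 x^b1`                  | ln y vs ln x         |
| growth      | `y = exp(b0 + b1 x)`           | ln y                 |
| exponential | `y = b0 exp(b1 x)`             | ln y                 |
| logistic    | `y = 1/(1/u + b0 b1^x)`        | ln(1/y − 1/u)        |

The multiplicative families are fitted by **log-linearized OLS**, and their
R², F, degrees of freedom and p-value are reported on the transformed
scale — exactly the behaviour of the classic curve-estimation procedure, so
fit tables computed elsewhere can be compared row by row. An original-scale
R² is additionally stored for diagnostics. The logistic ceiling `u`
defaults to `Inf` (the bound left unspecified), under which the logistic
row becomes the composite fit of `1/y`; that default is what reproduces the
packaged case-study fit tables exactly. Families whose domain constraints
fail on the data (non-positive responses for the multiplicative families,
non-positive predictors for the log-x families) are skipped with a message
during selection, not errored.

Selection ranks by R² on the fitting scale, breaking ties toward fewer
coefficients (so data exactly on a line selects the linear form even though
the quadratic also attains R² = 1). The allocation stage requires a
quadratic response `BOR(C) = β + aC + bC²`; `as_bor_function()` exports it,
and `run_pipeline()` falls back to the quadratic fit (with a warning) in
the rare case another family wins the ranking.

# Stage III — allocation

With `n` departments, quadratic responses `BOR_i(C_i)`, bounds
`L_i ≤ C_i ≤ U_i` and a fixed budget `Σ C_i = C_t`, the model minimizes the
imbalance

    Z = Σ_i | BOR_i(C_i) − mean_j BOR_j(C_j) |

the total absolute deviation of department occupancies from their mean.
`Z ≥ 0` with equality iff all BORs are equal, and `Z` is invariant to a
common shift of every department's intercept — both tested properties.
Responses are evaluated **unclamped** during optimization (values outside
`[0, 1]` are logged, not truncated): the fitted polynomials are the model,
and clamping would silently flatten the objective.

Two solvers share the same solution contract (budget, bounds, and a Z that
recomputes from the returned BORs to 10⁻¹²):

* `solve_exact()` — exhaustive enumeration with the last department
  eliminated through the budget equality, vectorized over the final two
  free departments and visited in lexicographic order. A new incumbent must
  improve by more than a tie tolerance (10⁻¹², configurable), so among
  numerically tied optima the lexicographically smallest bed vector is
  returned; the tolerance exists because identical objective values can
  differ at the 10⁻¹⁷ level depending on evaluation order. The packaged
  five-department case study (≈ 4.9 × 10⁷ candidates) enumerates in a few
  seconds; a `cap` (default 10⁸ candidates) refuses larger spaces and
  points to the GA.
* `solve_ga()` — an integer GA with uniform-random initialization,
  tournament selection (size 2), uniform crossover (probability 0.9),
  per-gene random-reset mutation (probability 0.1), elitism (2), population
  200 and 500 generations by default, reproducible bit-for-bit from its
  seed. Infeasible offspring are **repaired**, not penalized: the budget
  residual is redistributed one bed at a time, each step moving the bed
  whose reassignment most decreases Z without leaving the bounds, so every
  evaluated individual satisfies the equality constraint. The defaults were
  chosen for a low-dimensional integer search and validated against the
  exhaustive oracle (the test suite requires agreement within 10⁻⁶ on at
  least 95% of 20 seeded runs over generated problems small enough to
  enumerate); no published hyperparameters existed to adopt.

Ward-mix integrality — beds arranged in single/double/triple rooms with at
least two rooms of each type for gender separation, `C = k1 + 2k2 + 3k3`,
`k_j ≥ 2` — is handled **after** optimization: every `C ≥ 12` admits at
least one mix, so the constraint never binds at realistic bounds and
`enumerate_ward_mixes()` simply lists the feasible mixes (lexicographically,
with an exact count even when the listing is truncated). Bounds below 12
are flagged at construction.

On the packaged case study the exhaustive optimum is Z* ≈ 0.0112 at beds
(170, 121, 140, 168, 45) — noticeably better than the historically
documented allocation (166, 121, 135, 178, 44), which scores ≈ 0.0835 under
the same packaged response functions. The historical record also quotes an
optimized occupancy for the fourth department (83.48% at 178 beds) that its
own packaged quadratic contradicts (it evaluates to 79.92% at 178), so the
accompanying headline Z of 0.0409 cannot be recomputed from the shipped
coefficients; the package reports what the shipped equations imply and
leaves the discrepancy visible rather than reverse-engineering unstated
coefficients.

# Synthetic data

The generators exist so every stage is testable without hospital data, and
they are pure functions of spec + seed:

* `generate_registry()` — Poisson daily admissions per department over a
  lead-in period plus the window, discretized-lognormal LOS (median-matched,
  log-scale SD 0.5 by default; only medians are reliably known for such
  registries, and the census never depends on the generating family),
  optional forced carry-overs past the window end, and admission dates
  deleted at a configurable rate. The exact census a perfect reader should
  produce is computed alongside by direct arithmetic, so round-trip tests
  compare against ground truth, not against the census code itself.
* `generate_bor_curve()` — a known quadratic plus Gaussian noise, for
  coefficient-recovery and coverage tests.
* `generate_problem()` — 2–4 departments with random concave quadratics and
  narrow bounds (enumeration ≤ 10⁶ states), shipped with its `solve_exact()`
  optimum attached, as the GA-vs-oracle harness.

What the synthetic registries deliberately do **not** emulate: seasonality,
weekday effects, correlated departments, transfers, or time-varying LOS.
Passing round-trip tests therefore shows the accounting is correct, not
that real registries are this clean.

# Problem sizes and tolerances used by the test suite

The suite runs the full case-study enumeration (4.9 × 10⁷ candidates), a
20-seed GA-vs-oracle comparison at the default GA settings, 10⁶-draw
moment checks for the Johnson SB sampler, 100-seed coverage for noisy-curve
recovery, and 10-seed simulator replications — sizes chosen to keep the
whole suite under a minute while leaving the stochastic checks comfortably
powered. Exact-arithmetic assertions use tolerances at or below 10⁻⁸;
stochastic assertions state their bands explicitly in the tests.

# Known limitations

* The DES uses whole-day granularity and a constant LOS; departments whose
  stays are highly dispersed or sub-day are outside its intended use.
* Log-linearized fitting is not nonlinear least squares; for the
  multiplicative families the two differ under heteroscedastic noise. The
  original-scale R² is reported so users can see when it matters.
* The allocation model treats beds as the only resource; staffing,
  infection separation and mixed-sex constraints beyond the two-rooms rule
  are out of scope.
* `solve_exact()` is exponential in the number of departments; beyond the
  enumeration cap the GA is the only option and carries the usual
  metaheuristic caveat, mitigated here by the repair operator and the
  oracle-validated defaults.
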