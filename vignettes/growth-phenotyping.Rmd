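---
title: "Growth-curve phenotyping of yeast micro-cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-curve phenotyping of yeast micro-cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoplate)
```

## The problem

Functional screens of membrane transporters (here, plant PIP aquaporins
expressed in yeast) read out growth of 96-well micro-cultures (200 µl,
OD650 recorded every 10 min for ~250 cycles) under chemical treatments.
Two systematic obstacles stand between the raw plate-reader traces and a
comparable fitness statistic:

1. **Detector nonlinearity.** Optical density saturates at high cell
   density, compressing the upper part of every growth curve and biasing
   the derived traits.
2. **Unequal culture maturity.** Lines expressing different transporters
   grow at inherently different rates even untreated, so any fixed
   measurement time point under- or over-states treatment effects
   depending on the line.

`phenoplate` implements the full correction and quantification chain, a
synthetic plate simulator to validate it end to end, and the comparison
statistics used to rank lines.

## The model

### OD calibration

Recorded OD `x` (blank-subtracted) maps to true 1-cm-path OD through a
zero-intercept quartic

y = c4 x^4 + c3 x^3 + c2 x^2 + c1 x,

fitted by ordinary least squares on the monomial basis from a dilution
series whose "true" ODs follow from dilution factors anchored at a point
in the linear detection regime. The zero intercept is structural (a blank
reads zero); the degree is fixed at four, matching the single functional
form that describes the reference instrument, and the fitted polynomial
must be strictly increasing on its domain (checked numerically; inversion
is by bisection to 1e-10). The relationship is spectrophotometer-specific,
so models carry an `instrument_id` and values beyond the fitted domain
are extrapolated with a warning rather than an error, since growth curves
can slightly exceed the calibration series.

The packaged `reference_calibration()` holds the quartic determined on
the assay's reference reader (c4 = 1.9481, c3 = -4.2474, c2 = 5.0329,
c1 = 0.3441); real deployments fit their own.

### Growth traits

Corrected OD series are despiked with a running median (window 5) and
smoothed with a centered moving average (window 3) — micro-cultures
aggregate and sediment, producing isolated spikes. The exact filter chain
is this package's own choice; both windows are configurable, endpoints
use shrunken symmetric windows, and the filters are identities on
constant and linear stretches.

The growth curve is the log ratio L(t) = ln(OD(t)/OD_i) with OD_i the
mean of the first three corrected readings (averaging suppresses
first-cycle noise; floored at 1e-4 OD so the log is always defined).
Traits are extracted nonparametrically:

- **μ** (max specific growth rate, per min): the largest sliding-window
  OLS slope of L(t). Window default 5 points (50 min at 10-min cycles) —
  wide enough to reject single-cycle noise, narrow enough to resolve an
  exponential phase lasting a few hours. Earliest window wins ties.
- **λ** (lag, min): the tangent construction — where the maximal-slope
  tangent crosses L = 0; defined as 0 for non-growing curves.
- **κ** (carrying capacity, OD): the maximum smoothed corrected OD, i.e.
  the plateau level on the OD scale rather than the log scale.

### The dynamic measuring point ф

AUC measured too early misses slow phenotypes; measured too late, the
plateaued control lets treated cultures catch up. ф is therefore defined
on the *reference culture of each genotype* (untreated for toxic
compounds; highest supplementation for required nutrients) as the first
time its growth rate falls below 5% of μ, scanning forward from the time
of maximal rate with linear interpolation between window centers. Each
genotype gets its own ф because heterologous expression alters inherent
growth; a `global` mode (control genotype's ф for everyone) is available
for sensitivity analysis. On a logistic culture the 5% rule lands at
94–96.5% of carrying capacity (per-capita rate r(1 − N/K) falls to 5% of
its initial value at N ≈ 0.95 K when N0 ≪ K), which the tests assert.

AUC is the trapezoidal integral of L(t) from inoculation to ф, with the
final partial interval interpolated and negative log-ratios clipped to
zero by default (cumulative growth cannot be negative in this readout;
configurable). ΔAUC = AUC_treated/AUC_control summarizes the treatment,
and a second normalization ΔAUC_genotype/ΔAUC_empty expresses it relative
to the empty-vector control. Shifting ф forward (ф+t, capped at the
observation window) recovers late growth — e.g. freeze-thaw survivors —
at the cost of underestimating ΔAUC because the control plateaued
earlier; `run_phi_shift_sweep()` reports ΔAUC across shifts and asserts
AUC is non-decreasing in the shift.

### Dose–response and concentration selection

Per-concentration ΔAUC means follow a four-parameter logistic
ΔAUC(c) = bottom + (top − bottom)/(1 + (c/EC50)^h), fitted in the
untransformed form (no log(c) singularity at the untreated anchor) by
Levenberg–Marquardt least squares with multi-start over h ∈ {0.5, 1, 2,
4} and a geometric EC50 grid; with fewer than four distinct
concentrations the top is fixed at 1. Screening doses are chosen at the
commencement of pronounced inhibition, operationalized as the tested
concentrations whose fitted ΔAUC is nearest 0.75 and 0.5 (configurable):
those levels sit on the upper shoulder/linear range where resolution per
unit dose is highest. A response spanning < 0.05 ΔAUC is flagged flat and
yields no recommendation.

### Spheroplast bursting kinetics

Osmotic shock of wall-less yeast cells produces a biphasic OD650 decay:
a fast phase (spheroplasts swelling and bursting; amplitude A1 indexes
water permeability) and a slow settling/drift phase. The model
y(t) = A1 e^(−t/τ1) + A2 e^(−t/τ2) is fitted unconstrained with
multi-start (τ1 over {0.05, 0.1, 0.2, 0.5} s; τ2 over {1, 3, 10, −10} s;
amplitudes by linear solve at each start). The slow term may legitimately
converge to a negative amplitude with negative time constant (a slow
drift), as in the packaged empty-vector reference set; the fast phase is
defined operationally as the term with the *smallest positive* time
constant, which makes the permeability ranking deterministic, and a fit
with no positive time constant is rejected. Ranking is by descending A1
with ties broken by smaller τ1, then name.

### Comparison statistics

One-way ANOVA with Fisher's LSD compares each line to the designated
control only (matching how screen figures mark significance against the
empty vector), on the pooled MSE with N − k df; marks are `*` (p < 0.05)
and `**` (p < 0.01). Tukey HSD covers all pairs via the studentized range
(Tukey–Kramer standard errors for unbalanced groups), summarized as a
compact letter display built by insert-and-absorb: groups sorted by
descending mean start in one letter; each significant pair splits every
letter containing both; subset letters are absorbed. Two groups share a
letter if and only if their adjusted p ≥ α, which the tests verify
exhaustively against the pairwise p matrix on randomized instances.
Experimental runs are pooled, not blocked — the screen's replicate counts
are reported across runs and no run identifier survives into the result
tables.

## The simulator

`simulate_screen()` generates the statistical structure the analysis
assumes, so every stage is testable without instrument data. Growth is
the Zwietering reparameterization of the Gompertz curve,
L(t) = A exp(−exp((μ e / A)(λ − t) + 1)), chosen because its parameters
*are* the traits: the inflection tangent has slope μ and crosses L = 0 at
λ, and κ = OD_i e^A. Treatment effects are phenomenological trait
modifiers (Hill-shaped lag extension and rate/capacity depression for
toxic compounds; saturable rate/capacity recovery for nutrients;
freeze-thaw scales the viable inoculum by s per cycle and leaves traits
untouched, so the lag extends emergently — by ln(1/s^n)/μ — only through
the detection floor of the analysis). True OD is compressed into recorded
OD by inverting the calibration, then blank offset (0.08), additive
Gaussian detector noise (SD 0.003 on the recorded scale), and sporadic
multiplicative sedimentation spikes (probability 0.002) are applied;
replicate trait jitter is CV 2%. Noise defaults are fixture choices of
this package, stated here because no instrument values exist for them;
everything is deterministic given a seed.

What the simulator does *not* emulate: plate-position effects,
run-to-run batch structure, diauxic shifts, death phases, and condensation
artifacts. Passing recovery tests therefore demonstrates correctness of
the estimators under the stated noise model, not robustness to every
artifact of real plates.

One subtlety the tests encode: the Gompertz tail is infinite, so with a
short nominal lag the curve has already risen slightly at inoculation.
The analysis normalizes to the *observed* initial OD, which makes the
observable tangent lag exactly λ + L(0)/μ; the trait-recovery oracles use
that closed form, and recovery is asserted on sampling grids fine enough
to resolve the exponential phase (the slope window must fit inside it).

## Worked example

```{r example, eval = FALSE}
genos <- list(empty = well_sim_spec(od_init = 0.05, lambda = 300,
                                    mu = 0.012, A = 3),
              pip = well_sim_spec(od_init = 0.05, lambda = 330,
                                  mu = 0.011, A = 3))
tox <- treatment_model("toxic", on_lambda = c(1, 1, 2),
                       on_mu = c(0.6, 1, 2), on_kappa = c(0.4, 1, 2))
sim <- simulate_screen(genos, tox, doses = c(0, 0.5, 1, 2),
                       replicates = 3, seed = 7)
res <- run_screen(sim$timeseries, sim$map, reference_calibration())
aggregate(delta_auc_vs_control ~ genotype + concentration,
          res$results, mean)

dr <- build_dose_response(res$results[res$results$genotype == "empty", ],
                          "inhibitory")
fit <- fit_four_pl(dr)
recommend_concentrations(fit, unique(dr$concentration))
```

## Numerical choices and limitations

- Problem sizes in the test suite (plate grids of up to 250 cycles, 20
  noise seeds for stochastic suites, 2000 null instances for the LSD
  calibration check) keep full validation in well under ten minutes on
  one core.
- ф interpolates linearly between adjacent window-slope centers; ties
  resolve to the earliest crossing. Whether to interpolate or snap to a
  cycle is a genuinely open choice; interpolation makes ф continuous in
  the data.
- The tangent-construction λ is standard for the depicted trait geometry
  but is not a mechanistic lag; non-growing curves report λ = 0 rather
  than NA so that downstream tables stay numeric (flagged).
- Degenerate inputs: all-zero wells produce a flagged L ≡ 0 curve; zero
  pooled variance with unequal means reports p = 0 with a degeneracy
  flag; a reference culture that never leaves exponential phase reports
  ф at the last observed time with `reached = FALSE`.
- The 4PL module does not model hormesis/biphasic responses; a growth
  *increase* under a nominally toxic dose will fit poorly and should be
  inspected, not trusted.
- A1 is a relative permeability index only; no conversion to an osmotic
  permeability coefficient is attempted.
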