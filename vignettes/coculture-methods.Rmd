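---
title: "Methods: coculture population dynamics from total-OD growth curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coculture population dynamics from total-OD growth curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocult)
```

## The problem

Pairwise coculture screens ask whether two microbial strains growing in the
same well do better, worse, or the same as expected from their monocultures.
`cocult` implements the full analysis chain for the microplate design used
in wine-yeast interaction screens: five species, three strains each,
every monoculture in biological triplicate and every unordered strain pair
in quadruplicate, OD600 read every 30 minutes for 24 hours, plus 10,000-event
flow cytometry at inoculation (T0) and 24 h (T24) to resolve the two members
of each pair.

The central difficulty is that the plate reader sees only *total* OD. All
inference about interactions is therefore relative to a monoculture
reference, and the package's synthetic-data generator exists to make that
inference testable against planted truth.

## Growth model and kinetic parameters

Each well's curve is truncated to the 24 h analysis window and summarised
by four parameters:

* **latency** — first time OD600 exceeds 0.25, measured directly on the
  readings (linear interpolation between the bracketing samples by
  default; a step-function variant is available). A curve that never
  crosses the threshold has undefined latency, which is a valid outcome.
* **maxOD** — the maximum reading in the window, measured directly.
* **r** and **AUC** — from a logistic fit
  \(N(t) = K / (1 + ((K - N_0)/N_0)\,e^{-rt})\)
  by Levenberg–Marquardt nonlinear least squares. The AUC is the *model*
  integral, available in closed form
  \((K/r)\,[\ln(A + e^{rT}) - \ln(A + 1)]\) with \(A = (K-N_0)/N_0\),
  evaluated with `log1p` so large \(rT\) cannot overflow. The empirical
  trapezoid AUC is carried along as a diagnostic column only.

Numerical choices for the fit: data-driven starts (`K` from the maximum
OD, `r` from the early log-slope), box bounds `r <= 10 h^-1` and
`K <= 3 max(od)`. The `K` cap is correct for curves that have plateaued
but can sit below the true `K` of a slow grower still rising at 24 h, so
when the solution lands on the cap the bound is escalated (×5, at most
three times) and the model refit; several `K` start candidates are tried
and the lowest-RSS fit kept. Curves whose total OD range stays below
0.05 are declared non-growing and not fitted — their latency and maxOD
are still reported, with `r`/`AUC` missing. Failed fits are retried from
five jittered starts under a fixed sub-seed before being flagged.

## Monoculture structure: nested ANOVA

Species and strain are hierarchical (strain nested in species). For the
(near-)balanced design the package uses the expected-mean-squares tests:
the species F statistic is the species mean square over the
strain-within-species mean square (df \(s-1\), \(s(t-1)\)); the strain
effect is tested against the residual. For balanced data this coincides
with the mixed-model (random strain) analysis, is exactly computable
without an optimizer, and the equivalence is verified in the test suite
against `lmerTest` on balanced cases. When every species contributes a
single strain the strain stratum is empty and the species test falls back
to the residual denominator (with a warning), reproducing one-way ANOVA
exactly.

Species letter displays use all-pairs studentized-range (Tukey) p-values
with the same error term as the species test, followed by an
insert-and-absorb compact letter display; species sharing a letter are
not significantly different at `alpha` (default 0.05).

## Interaction index and outcome classes

For each coculture and parameter, the interaction index is the signed
relative deviation from the monoculture average:

\[ Id = \frac{P_{co} - (P_{m1} + P_{m2})/2}{(P_{m1} + P_{m2})/2} \]

Zero means the coculture sits on the monoculture average. The outcome
classifier runs a Welch t-test ladder at level `alpha`:

1. coculture replicates vs per-replicate monoculture averages
   (two-sided). Not significant → **A**, no perceived interaction.
2. else, one-sided vs the better monoculture → **B**, overyielding.
3. else, one-sided vs the worse monoculture → **C**, underyielding.
4. else → **D**: off the average but within the monoculture range.

Design choices here, made once and logged: the monoculture-average
replicate set is built by pairing replicates (\((m_{1,i}+m_{2,i})/2\) up
to the smaller replicate count), which preserves the replicate count and
variance scale; Welch (unequal-variance) tests throughout, two-sided for
the A-gate and one-sided for the B/C gates since over/underyielding is
directional; no multiple-testing correction by default (each coculture is
its own hypothesis, as in per-pair screening practice) with a
Benjamini–Hochberg option available to the caller via `p.adjust` on the
returned p-values. For latency the *biological* direction is inverted — a
positive latency index means delayed growth, hence a negative
interaction — which is handled in `effect_direction()`, not in the class
ladder.

Under the generator's neutral scenario the A-rate is ~95% and one-sided
B/C calls stay near 2.5% each; this calibration is checked by the
acceptance suite on 525 simulated null cocultures.

## Interaction matrices, clustering, stability

Per parameter, indices fill a symmetric strain-by-strain matrix with a
zero diagonal (a strain with itself is the monoculture reference).
Rows are clustered with Euclidean distance and complete linkage, cut at
`k` clusters; `k` defaults to the number of species. Cluster labels are
renumbered by first appearance in lexicographic strain order so the
partition is invariant to input row order. The diagonal zero is kept in
the row feature vectors (an exclude-self flag exists; the effect is
negligible when within-species indices are small).

Stability is scored clusterboot-style: resample strains (`bootstrap`:
n rows with replacement; `subset`: half the rows without replacement,
fraction configurable), re-cluster each resample at the same `k`, and
credit each original cluster with its best Jaccard similarity to any
cluster of the resampled solution, restricted to the resampled strains;
the mean over assessable iterations is reported, with mean Jaccard < 0.5
flagged as dissolved. `B` defaults to 1000 in the pipeline. Note a
structural property of fixed-`k` resampling: when a genuine singleton is
absent from a resample, the forced `k`-cut must split some other cluster,
so the stability of tight clusters is mildly depressed by the presence of
borderline strains — visible in the test suite's borderline-singleton
case.

## Cytometry fold changes

Gate counts become within-sample fractions; a strain's fold change is its
T24 fraction over its T0 fraction. For two gates the per-replicate
reciprocity \(f_A s_{A0} + f_B s_{B0} = 1\) holds algebraically and is
tested exactly. The test against "no composition change" is a two-sided
one-sample t-test of the replicate fold changes against 1 on the raw
scale (matching how such screens report mean ± sd of raw fold changes); a
log-scale option exists. No correction across the 210 strain-in-pair
tests by default.

## What the generator simulates — and what it does not

Each well is a two-population generalized Lotka–Volterra system

\[ dN_A/dt = r_A N_A \left(1 - \frac{N_A + \alpha_{AB} N_B}{K_A}\right)
   - \tau N_A N_B \]

(symmetrically for B), each population held at its inoculum until its lag
elapses, integrated with a fixed-step RK4 scheme at Δt = 0.01 h and
clamped non-negative. A monoculture is the same strain twice under
neutral coupling, so monocultures and cocultures flow through identical
code. Strain parameters are drawn around species-level means (carrying
capacities and growth rates set to the five species' reported monoculture
means) with a multiplicative strain-level CV; per-replicate lag jitter
(sd 0.3 h) and additive Gaussian OD noise (sd 0.02, chosen to reproduce
replicate SDs on the order of 0.5–1.5 h in AUC) complete the noise model.
Cytometry counts are multinomial draws of 10,000 events from the
simulated population shares. A master seed fans out to per-well sub-seed
streams (a counter scheme over well index and stage), so any single well
is reproducible in isolation and identical configs give byte-identical
datasets.

Two modeling decisions deserve emphasis:

* **The no-interaction null is full niche overlap** (\(\alpha = 1\) on a
  common carrying capacity), *not* independent growth. With a total-OD
  readout, two independently growing populations (\(\alpha = 0\)) would
  stack two carrying capacities and read as strong overyielding. The
  neutral calibration scenario also shares the growth rate and lag
  across species: with a shared niche, a faster partner fills the niche
  first and displaces the total curve from the monoculture average, which
  is a real (detectable) interaction signal rather than a null.
  Facilitation is planted as \(\alpha < 1\) (partial niche release);
  antagonism as \(\alpha > 1\) and/or \(\tau > 0\) — the toxicity term is
  what produces true case-C underyielding below both monocultures.
* **The inoculum is 0.1 OD-equivalents total** (50:50 split). A
  10^6 cells/mL yeast suspension corresponds to roughly 0.1 OD600 at the
  usual ~10^7 cells/mL per OD unit; at a 10-fold lower inoculum the slow
  species would not approach their observed maximum populations or
  latencies within the 24 h window, contradicting the monoculture
  behaviour the generator is meant to emulate.

The generator does *not* attempt mechanistic fermentation chemistry
(sugars, nitrogen, ethanol), oxygen limitation, plate-position or
evaporation effects, run-to-run batch effects (the `run` label is carried
but adds no variance), or consortia beyond two members. Passing tests on
this simulator therefore demonstrate that the analysis recovers planted
structure under idealized logistic-like kinetics with additive noise —
not that the biological conclusions of any particular screen are correct.

## Problem sizes and runtime

The shipped analyses use the full design (465 wells × 49 time points) for
the end-to-end checks; 525 simulated null cocultures for classifier
calibration; 200 noiseless and 100 noisy curves for fit recovery; 200/500
simulation runs for ANOVA power/size; B = 100 for stability checks in the
tests (B = 1000 in the pipeline default). The whole validation suite runs
in a few minutes on one CPU.

## Known limitations

* With a total-OD readout, a positive index cannot be attributed to one
  member of the pair; the cytometry fold change is the only
  member-resolved signal.
* Case counts from the classifier depend on the unstated test conventions
  (variant, sidedness, α) of any given published screen; they are
  reproducible only up to those choices.
* The subset stability method on 15 strains resamples very small row sets
  at `k = 5`; its Jaccard values run systematically below the bootstrap
  method's on identical input, and the two should not be compared across
  studies.
* Latency of a never-crossing curve is undefined and the pair is skipped
  for that parameter; with very slow planted growth this can reduce the
  latency denominator below 105.
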