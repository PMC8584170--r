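---
title: "Quantifying nucleoside kinase activity from luciferase ATP-depletion plates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleoside kinase activity from luciferase ATP-depletion plates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nkscreen)
```

## The assay and its model

Nucleoside kinases (NKs) transfer the γ-phosphate of a nucleoside
5′-triphosphate donor (usually ATP) onto a (deoxy)nucleoside, yielding the
monophosphate. In the luciferase ATP-depletion readout, the luminescence of
a well is proportional to its residual donor concentration over the assay's
linear range, so enzymatic activity shows up as signal *loss* against an
enzyme-free control. Because the readout is indirect, the whole analysis
hinges on a per-plate control scheme:

* **negative control** (no enzyme): full-donor signal `N`;
* **substrate control** (no donor): background/autoluminescence `S` of the
  substrate itself;
* **basal-activity control** (no substrate): donor consumed by the enzyme
  independently of the substrate, entering as the correction
  `B = max(0, N − basal)`.

Consumed donor and product formation for a reaction group with mean signal
`R` are

$$\mathrm{Consumed}\,[\%] = 100 - 100\,\frac{R + B + S}{N + S},
\qquad
\mathrm{Product}\,[\%] = \mathrm{Consumed} \times \mathrm{ratio},$$

with `ratio = 1.2` for the standard 0.4 mM donor / 0.33 mM substrate
stoichiometry, and both quantities clamped to 0–100%. The formula is
implemented exactly as written, including the *positive* sign of `S` in the
numerator: for a luminescent substrate this damps apparent consumption
asymmetrically rather than subtracting the background, which looks
anomalous, but fidelity to the established calculation was preferred over
reinterpretation. With the default zero-background simulation (`S = 0`) the
two readings coincide anyway.

Three further conventions were genuinely open and are resolved as follows:

* **Direction of `B`.** "Difference of the negative control and the basal
  activity" does not fix an order; `B = N − basal`, floored at 0, is the
  only physically sensible reading — it is a positive correction when the
  enzyme consumes donor without substrate.
* **Clamping.** The restriction to 0–100% is applied after *each* equation
  (consumed and product). Group means are clamped after averaging;
  per-replicate values feeding the reported standard deviation are pushed
  through both equations unclamped and clamped at the end.
* **Replicate aggregation.** Controls are averaged first; the group
  estimate uses the mean reaction signal; `sd_pct` is the SD over
  replicate-level product percentages.

## Plate quality and interference

The screening window is summarised per plate by

$$Z' = 1 - \frac{3\,SD_{neg} + 3\,SD_{sub}}{\overline{X}_{neg} - \overline{X}_{sub}},$$

computed from that plate's pooled negative and substrate controls with
sample (n−1) standard deviations (the convention is not fixed by the
formula; sample SD is the usual choice for small control groups). `Z′ = 1`
is a perfect window; `run_screen()` fails plate QC below a configurable
minimum of 0.5, the common screening convention. Note the substrate
controls here are the signal *floor* (they lack donor), so this `Z′`
measures the full assay window rather than a positive/negative compound
separation.

Interference of a compound with the luciferase (autoluminescence or
inhibition) is reported qualitatively in the underlying assay work;
`interference_check()` operationalises it as: flag when the relative mean
shift exceeds 10%, *or* when a Welch two-sample test rejects equality at
α = 0.05 **and** the shift still exceeds 5%. The second branch needs both
conditions so that statistically resolvable but practically irrelevant
shifts do not flag. `amp_titration_check()` plays mixed ATP/AMP standards
against the signal an ATP standard curve predicts for their ATP content,
flagging levels off the curve by more than the same shift threshold.

## Calibration and donor acceptance

`fit_standard_curve()` is an ordinary least-squares line on **all replicate
points**, not on level means, with a freely estimated intercept; r² on the
same points therefore reflects replicate scatter as well as lack of fit
(fitting on means would typically report a slightly higher r²; which the
original workflow used is unknown, and the pointwise choice is the more
conservative). Inversion to concentration clips to the calibrated range and
flags extrapolation. Donor acceptance is ranked by signal at the 500 µM
reference relative to ATP; the acceptance floor of 30 RLU mirrors the
grouping of dGTP, dCTP and TTP ("< 30 RLU") as non-substrates of the
luciferase, and is configurable.

## HPLC cross-quantification

Peak tables (integrated areas; peak detection is out of scope) are
annotated by nearest-retention-time matching within a 0.3 min tolerance —
the typical times are only quoted to one decimal, and 0.3 min separates the
adenosine nucleotides (AMP 8.2, ADP 15.4, ATP 22.9 min) by an order of
magnitude more than the tolerance. Libraries whose entries are closer than
twice the tolerance are rejected outright. Missing ADP/AMP peaks count as
zero area rather than erroring, since low-conversion samples may show no
detectable ADP. Consumed ATP is `1 − A_ATP/A_pool` over the adenosine pool
and product formation is the product share of the substrate + product pool;
which phosphorylation intermediates belong in the product set is chemical
knowledge, so products are declared per substrate (defaulting to
`<substrate>-MP`).

## What the simulator emulates — and what it does not

`simulate_plate()` generates layout, readings and a ground-truth table for
one 96-well plate under the assay's stated conditions, which are the
generator defaults:

| parameter | default | rationale |
|---|---|---|
| `donor_conc` | 400 µM | standard reaction condition |
| `substrate_conc` | 333 µM | standard reaction condition (ratio 1.2) |
| `standard_levels` | 0–500 µM, 7 levels | spans the calibrated range; the level count is not specified, 7 levels give ≥3 distinct points with headroom |
| `n_replicates` / `n_standard_replicates` | 3 / 2 | samples measured three times, standards twice |
| `n_control_replicates` | 3 | the luminescence measurement is performed in triplicate for every well, controls included |
| `noise_cv` | 0.03 | measurement noise is not stated; 3% multiplicative CV is typical plate-reader repeatability |
| `basal_consumption` | 0.02 | basal activity is reported only as a correction term; 2% is a placeholder magnitude |
| `atp_degradation` | 0.01 | matches the ~1% AMP accumulation seen by HPLC in enzyme-free controls |

Per reaction the mass balance is: fraction of donor consumed by the kinase
`conv_frac = min(1, conversion · substrate_conc / donor_conc)`; residual
donor `c_res = donor_conc · (1 − conv_frac − basal − degradation)` floored
at 0; emitted RLU is the donor's linear response at `c_res` times
`(1 + ε)`, `ε ~ N(0, noise_cv)`. Negative controls sit at
`donor_conc·(1 − degradation)`, basal controls additionally lose the basal
fraction, substrate controls emit intercept-level signal (zero by default;
`substrate_autolum` switches autoluminescence on to exercise the
interference detector). The matched chromatograms route kinase- and
basal-consumed donor to ADP (a kinase transfers one phosphate — no
di-/triphosphate products) and degradation to AMP, and split the
substrate pool by the true conversion; both pools conserve mass before
noise. Layout placement is column-major with controls adjacent to their
reaction group — a bookkeeping choice, nothing downstream depends on well
positions.

Under this model the two estimators have closed forms the ground-truth
table records: the luminescence route recovers
`100·conv_frac/(1 − degradation)` consumed donor (the `B` correction
cancels basal consumption exactly; degradation inflates the estimate
slightly because it also depletes the negative control), and the HPLC
route recovers `conv_frac + basal + degradation` from the adenosine pool
and the true conversion from the substrate pool. The test suite asserts
exact (≤ 1e-9) agreement of each estimator with its own closed form at
zero noise, and the two routes agree exactly with each other when basal
consumption and degradation are switched off and the exact concentration
ratio is used — with the rounded 1.2 multiplier they differ by ~0.1% of
the value, which is why pipeline-level comparisons pass
`ratio = donor_conc/substrate_conc`.

What the simulator deliberately does **not** model: reaction kinetics
(time courses, Michaelis–Menten saturation), spatial plate effects
(edge/evaporation gradients), luciferase signal drift, carry-over, or
correlated noise between replicates. Passing recovery tests therefore
demonstrate correctness of the estimators under the assay's *assumed*
statistical structure, not robustness to these real-data pathologies; the
<10% verification flag and the HPLC cross-check are the package's
mitigations on real data, exactly as in bench practice.

## Numerical and degenerate-input choices

* RLU parsing accepts plain numbers and comma-thousands (`"57,892"`);
  dot-thousands is *not* auto-detected because it is ambiguous with
  decimals.
* `consumed_donor()` refuses `N + S ≤ 0` (an uninterpretable plate);
  `z_prime()` refuses coincident control means and groups smaller than 2.
* Multiplicative noise is floored at 0 RLU to respect the non-negativity
  of luminescence.
* Ties in donor ranking break alphabetically; duplicate
  (enzyme, substrate) spectrum cells are averaged with a warning.
* A missing basal control degrades to `B = 0` with a warning — the
  correction is optional; missing negative or substrate controls are hard
  errors naming the group.
* An apparent product of exactly 0 is *not* flagged for verification:
  zero conversion is not a "low positive".

## Problem sizes in the test suite

The packaged checks run a single simulated plate per case (3–6 reaction
groups, 14 standards) and 200 seeded plates of 6 pairs each (1200
recoveries) for the noise-level recovery property; oracle-equivalence
checks use 1000 random inputs per formula. These sizes make every
distributional claim in this vignette reproducible in well under a minute
while keeping the Monte-Carlo margins (e.g. ≥95% of recoveries within
5 percentage points at 3% noise) statistically meaningful.
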