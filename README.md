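# nkscreen

Analysis toolkit for **luciferase-based nucleoside kinase (NK) substrate
screening** in 96-well plates. NKs catalyse the first phosphorylation of
(deoxy)nucleosides — including antiviral and anticancer nucleoside
analogues — and choosing the best-performing kinase for a substrate panel
requires screening many enzyme x substrate combinations. In the
ATP-depletion readout, residual phosphate donor after the kinase reaction
is detected as luminescence (relative light units, RLU), so kinase
activity appears as a *loss* of signal relative to an enzyme-free control.
`nkscreen` turns raw plate-reader exports plus a plate-layout table into
calibrated conversion percentages, quality statistics and an
enzyme x substrate spectrum matrix, and cross-checks them against HPLC
peak-area quantification.

## The model

With same-plate controls — negative (no enzyme, signal `N`), substrate
(no donor, signal `S`) and basal activity (no substrate) — consumed donor
and product formation for a reaction with mean signal `R` are

    Consumed[%] = 100 − 100 · (R + B + S) / (N + S),   B = max(0, N − basal)
    Product[%]  = Consumed[%] × ratio                  (ratio = 1.2 for
                                                        0.4 mM donor / 0.33 mM substrate)

both clamped to 0–100%. Plate quality uses the screening-window statistic

    Z′ = 1 − (3·SD_negative + 3·SD_substrate) / (Avg_negative − Avg_substrate)

and the orthogonal HPLC quantities are area ratios over the adenosine
pool and the substrate/product pool:

    Consumed_HPLC[%] = (1 − A_ATP / (A_ATP + A_ADP + A_AMP)) · 100
    Product_HPLC[%]  = 100 · P_products / (A_substrate + P_products)

Calibration is an ordinary least-squares standard curve RLU = a·conc + b
per phosphate donor; donors are ranked by their signal relative to ATP,
with a 30 RLU acceptance floor. Product formations below 10% are flagged
for orthogonal verification, where the depletion readout is most
error-prone.

## Worked example

Simulate a small screen with known ground truth and quantify it:

```r
library(nkscreen)
tc  <- data.frame(enzyme = "HsdCK", substrate = c("dCyd", "Thd"),
                  conversion = c(0.8, 0.1))
cfg <- sim_config(seed = 42, true_conversion = tc)
scr <- data.frame(enzyme = "HsdCK", substrate = c("dCyd", "Thd", "Urd"),
                  donor = "ATP")
sim <- simulate_plate(cfg, scr)
ann <- join_layout(sim$readings, sim$layout)
res <- quantify_plate(ann, ratio = cfg$donor_conc / cfg$substrate_conc)
res[, c("substrate", "consumed_pct", "product_pct", "sd_pct", "flag_verify")]
#> Kinase screening results: 3 reaction group(s), 1 flagged for verification
#>   substrate consumed_pct product_pct sd_pct flag_verify
#> 1      dCyd       68.018      81.703  0.568       FALSE
#> 2       Thd       10.079      12.107  3.644       FALSE
#> 3       Urd        2.461       2.957  5.089        TRUE
plate_qc(ann)$z_prime
#> [1] 0.872502
calibrate_plate(ann)$ATP
#> Standard curve for ATP
#>   RLU = 116.2 * conc[uM] + 289.4
#>   r-squared = 0.996  (n = 14, range 0-500 uM)
```

The dCyd estimate (81.7% product) recovers the simulated 80% conversion
(its closed-form expectation is 80.8%); Urd, never phosphorylated in this
simulation, shows ~3% apparent conversion from assay noise and is flagged
for HPLC verification — exactly the false-positive regime the <10% rule
exists for. `Z′ = 0.87` marks an excellent assay window. The HPLC branch
(`simulate_peak_table()`, `annotate_peaks()`, `quantify_hplc()`,
`compare_methods()`) agrees with these numbers to within ~3 percentage
points at 3% reader noise, and `run_screen()` performs the whole
calibrate → QC → quantify → HPLC → compare → spectrum pipeline from CSV
files on disk.

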