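---
title: "Modeling dual-TF gene regulatory logic in single cells"
author: "stressgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dual-TF gene regulatory logic in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The biology being modeled

The yeast general stress response factors Msn2 and Msn4 bind the same
stress response elements (STREs) and were long treated as redundant.
Single-cell imaging shows they are not: target promoters with *fast*
activation kinetics are induced by either factor alone (an OR gate),
while *slow* promoters — which need a long remodeling delay before they
fire — require both factors under a transient input (an AND gate). The
logic is dynamic: prolonging the input makes Msn4 dispensable on slow
promoters (Msn2 remains required). At single-cell resolution, Msn2 acts
as a low-threshold **switch** on slow promoters (expression turns on
once its nuclear level crosses roughly a quarter of its maximal level,
and further Msn2 does not raise — and can even suppress — output),
while Msn4, though ~3-fold lower in nuclear level and much more
variable between cells, acts as a linear **rheostat** setting the
induction level.

`stressgate` packages (i) a generative kinetic model of these dynamics
so that every analysis stage can be exercised on synthetic single-cell
data with known ground truth, and (ii) the analysis stack itself:
trace features, TF-level binning, gate classification and
switch-vs-rheostat model fitting.

## The generative model

### TF nuclear translocation

Each cell draws a maximal translocation amplitude per TF from a
log-normal distribution: Msn2 with mean 40 normalized a.u. and CV 0.2;
Msn4 with a 3-fold lower mean and CV 0.5 (so Msn4 has the higher CV
but the *lower* absolute SD, matching the observed heterogeneity
pattern). "Normalized a.u." means both channels are on a common scale
after RFP/YFP cross-channel calibration (see
`compute_scaling_factor()`). The nuclear level relaxes first-order
toward `amplitude x drive(t)` with an import timescale of 1.5 min and
an export timescale of 3 min; Msn4 follows the shared upstream PKA
signal with a 2.5-min lag. Three input programs are supported:

* `pulse` — a square inhibitor pulse of given dose and duration;
* `adaptive_transient` — a sustained stressor (osmotic-shock-like) to
  which the TF response adapts with a 15-min timescale, producing a
  transient translocation pulse roughly half an hour wide;
* `sustained` — a stressor (ethanol-like) holding the TFs nuclear for
  the whole experiment. Sustained stress additionally draws a per-cell
  translational capacity from Beta(0.3, 1.2) (most mass near zero),
  standing in for the translational arrest that leaves the majority of
  cells unable to express the reporter.

Additive Gaussian measurement noise (SD 0.5 a.u.) is applied to every
observed channel after the dynamics; deletion genotypes have their
channel identically zero. Sampling is a closed uniform grid, 2-min
cadence over 180 min.

### Promoter activation

Chromatin opening is modeled as `n_steps = 8` sequential remodeling
steps, each proceeding at rate

```
n_steps * k_open * a_w(t) * H(t),
a_w(t) = (w2*x2 + w4*x4) / (K_occ + x2 + x4)
```

so the mean opening time at saturating drive is `1/k_open` with
relative dispersion `1/sqrt(n_steps)`. The multi-step structure is
essential: it gives slow promoters a genuine activation *delay*, which
is what lets them filter 30-min inputs yet respond to 60-min inputs. A
single-step two-state promoter cannot reproduce that duration-dependent
logic: with one step, the msn4&Delta;/WT expression ratio is the same
functional of the shared gate at every duration, so a promoter that is
an AND gate at 30 min can never become Msn4-independent at 60 min.

The gate `H(t)` encodes the Msn2 switch: for the slow class `H = 1`
only while the Msn2 level is at or above `theta_msn2 = 10` normalized
a.u. — 25% of the mean maximal Msn2 level, so the threshold sits at the
position estimated from the binned dose-response. For the fast class
`H = 1` whenever combined TF level exceeds a 1 a.u. basal level.

The occupancy weights differ by class. For the slow class the opening
drive is Msn4-potent (`w2 = 0.35`, `w4 = 3`): Msn4's potency in
recruiting remodelers compensates its 3-fold lower nuclear level, which
(a) makes Msn4 the limiting activator of slow promoters under transient
inputs, and (b) makes the wild-type slow-promoter opening drive match
the fast-promoter drive, so the effective activation-timescale ratio
between classes equals the `k_open` ratio of 5. Because Msn2 occupies
shared sites (the `x2` in the denominator) while contributing weakly to
opening, raising Msn2 at fixed Msn4 *lowers* the opening drive once
Msn2 is well above the Msn4 level — the ratio-suppression effect. For
the fast class both weights are 1 and either factor saturates the
drive.

Once open, the promoter transcribes at
`beta_max * (x2 + 2*x4) / (K_occ + x2 + x4)` (equal weights for the
fast class) scaled by the cell's capacity, and attenuates irreversibly
at `k_close`. The attenuation gives each promoter a finite expression
window matched to its class (`1/k_close` = 4 min fast, 20 min slow,
the same 5:1 scaling as `k_open`; `beta_max` also scales 5:1 so total
output is comparable). Two consequences: reporter trajectories reach a
plateau within the 3-h experiment, and the fast-class reporter
trajectory is approximately a 5x time-dilation of the slow one, which
is what makes the half-of-final-rise estimator in
`estimate_kinetic_ratio()` recover the 5:1 class ratio. The mild Msn4
tilt (1:2) in the open-state rate keeps the binned expression-vs-Msn4
relationship close to linear across its observed range (the rheostat),
where strictly equal rate weights saturate visibly. The reporter is
stable (no degradation) and observed after a pure 10-min maturation
delay.

### Default parameters

| parameter | fast | slow | units | why |
|---|---|---|---|---|
| `k_open` | 0.45 | 0.09 | 1/min | 5:1 class timescale ratio |
| `k_close` | 0.25 | 0.05 | 1/min | finite expression window, 5:1 |
| `beta_max` | 5 | 1 | a.u./min | dilation-invariant total output |
| `theta_msn2` | — | 10 | norm. a.u. | 25% of mean maximal Msn2 |
| `K_occ` | 5 | 5 | norm. a.u. | shared-site half-saturation |
| `w2 / w4` (opening) | 1 / 1 | 0.35 / 3 | — | Msn4-potent slow opening |
| rate weights | 1 / 1 | 1 / 2 | — | near-linear Msn4 response |
| `n_steps` | 8 | 8 | — | sharp activation delay |
| maturation | 10 | 10 | min | fluorophore maturation |

The free rates were calibrated once so that the deletion-panel truth
table holds at defaults (fast promoter OR at 30 min; slow promoter AND
at 30 min with both deletions under 25% of WT; Msn4 dispensable — over
50% of WT — at 60 min) and then frozen; they are ordinary defaults of
`promoter_params()` and can be overridden.

## What the generator does and does not emulate

It emulates: 2-min sampling over 3 h; transient, adaptive-transient and
sustained translocation dynamics; the ~3-fold Msn2/Msn4 level
difference with Msn4's higher relative heterogeneity and 2–3 min lag;
deletion genotypes; reporter plateau within 3 h; fast/slow promoter
classes differing 5-fold in activation timescale; switch, rheostat and
ratio-suppression behaviour; translational arrest under sustained
stress.

It does not emulate: stochastic transcriptional bursting or
mRNA-level kinetics (per-cell dynamics are deterministic given the
drawn amplitudes), cell growth and division, photobleaching,
segmentation/tracking artifacts, or correlated (non-Gaussian)
measurement noise. Passing tests on this synthetic data therefore
validate the analysis pipeline's logic and the internal consistency of
the model, not microscope-specific error modes of real data.

## Numerical choices

* The promoter ODE is integrated with a fixed-step classical
  Runge-Kutta scheme (dt = 0.2 min), with the TF traces interpolated
  linearly between samples; a test compares it with a brute-force
  explicit-Euler integration at dt = 0.005 min and requires endpoint
  agreement within 1%.
* TF relaxation uses exact exponential updates on a 0.1-min grid.
* Half-max crossing times interpolate linearly between samples; ties
  are broken by the earliest crossing. Export times are flagged `NA`
  for sustained inputs.
* Ensemble SDs use the n-1 denominator; the CV at peak is computed at
  the peak time of the mean trace.
* Quantiles (responder threshold, distribution summaries) are
  sort-based order statistics (quantile type 1).
* AUC is the plain sum of in-window 2-min samples — the convention for
  these traces — not a trapezoid rule.
* Empty TF bins are reported as missing, never as zero; cells outside
  the bin range (or with undefined Msn2:Msn4 ratio) are excluded and
  counted.
* Model selection in `fit_regulator_mode()` uses AICc at the effective
  sample size `sum(n_per_bin)` on cell-weighted bin means; exact ties
  prefer flat over switch over rheostat. The threshold is scanned over
  interior bin boundaries, so its resolution is the bin width.
* Gate cutoffs (25% / 50% of WT) are analysis conventions chosen to
  make the qualitative deletion-panel calls robust; they are arguments
  of `classify_gate()`. The 60-min slow-promoter state is reported as
  `MSN2_REQUIRED` rather than `OR`: Msn4 is dispensable but Msn2 is
  not, and the classifier keeps that distinction.
* All randomness flows through a single `set.seed()` per experiment;
  amplitude and noise draws are made for every channel regardless of
  genotype so that deletion strains are RNG-aligned with wild type
  (zeroing a channel and simulating the deletion are identical).

## Open choices made here

* Whether chemically induced and stress-induced inputs differ in
  amplitude as well as shape is not constrained by the data we emulate;
  the programs differ only in shape by default (`dose` rescales any of
  them).
* The distributional family of the amplitudes is taken log-normal for
  positivity and multiplicative noise; only means and CVs are anchored.
* Peak/AUC windows are onset-aligned (`[onset, onset+30]` by default);
  endpoint expression is read at 180 min. Both endpoint and
  maximum-level expression statistics are exposed (`stat = "max"`),
  and they coincide at plateau up to noise.
* The absolute ~10 a.u. threshold is meaningful only relative to this
  package's normalized scale; only its relative form (% of maximal
  Msn2) is treated as a recoverable quantity.

## Worked example

```{r, eval = FALSE}
library(stressgate)

# deletion panel on the slow promoter, 30- vs 60-min pulses
mk <- function(dur, geno, seed)
  generate_experiment(tf_params(), promoter_params("slow"),
                      stimulus_program("pulse", duration_min = dur),
                      geno, n_cells = 300, seed = seed)
panel <- list(
  "30" = list(WT = mk(30, "WT", 1), msn2d = mk(30, "msn2d", 2),
              msn4d = mk(30, "msn4d", 3)),
  "60" = list(WT = mk(60, "WT", 4), msn2d = mk(60, "msn2d", 5),
              msn4d = mk(60, "msn4d", 6)))
gate_vs_duration(panel)

# switch-vs-rheostat fits on dose-pooled wild-type cells
doses <- c(0.1, 0.25, 0.5, 0.75, 1)
ft <- do.call(rbind, lapply(seq_along(doses), function(i)
  compute_features(generate_experiment(
    tf_params(), promoter_params("slow"),
    stimulus_program("pulse", dose = doses[i], duration_min = 30),
    "WT", 400, seed = 10 + i))))
ctrl <- generate_experiment(tf_params(), promoter_params("slow"),
                            stimulus_program("pulse", dose = 0),
                            "WT", 300, seed = 99)
rule <- derive_responder_threshold(ctrl)
fit_regulator_mode(bin_by_tf(ft, "msn2", responder_rule = rule))
```

The problem sizes used by the shipped tests and the acceptance script
(200 cells per class for timescale recovery, 2000 pooled cells for the
threshold and amplitude-ratio recoveries, 250–300 cells per
deletion-panel condition) were chosen as typical single-cell imaging
yields at which the estimators are comfortably stable.

## Known limitations

* The switch threshold estimate is quantized to bin boundaries; with
  5 equal-width bins its resolution is ~12% of the TF range.
* `estimate_kinetic_ratio()` assumes the reporter rise is
  promoter-limited; for inputs much shorter than the slow promoter's
  expression window the half-rise delay compresses toward the input
  midpoint and the ratio is underestimated.
* The capacity model lumps all translational-arrest effects into one
  Beta-distributed multiplier; it does not model recovery over time.
* Gate calls are population-level statements about means; they do not
  model cell-cycle or lineage structure.
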