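# stressgate

Single-cell analysis of the gene regulatory logic implemented by the
yeast general stress response transcription factors **Msn2** and
**Msn4**, paired with a generative kinetic simulator so that every
stage of the analysis can be exercised on synthetic single-cell data
with known ground truth.

## The science

Msn2 and Msn4 translocate to the nucleus under stress, bind the same
stress response elements, and were long considered redundant. At
single-cell resolution they are not:

* **Fast-kinetics promoters** (e.g. the *DCS2* class) are fully induced
  by either factor alone — an **OR gate**.
* **Slow-kinetics promoters** (e.g. the *SIP18* class), whose chromatin
  needs a long remodeling delay, require *both* factors under a
  transient (30-min) input — an **AND gate** — but become
  Msn4-independent when the input is prolonged to 60 min (Msn2 is still
  required).
* Within single cells, Msn2 acts as a low-threshold **switch**:
  expression turns on once nuclear Msn2 exceeds a threshold θ ≈ 25% of
  its maximal level, `E = b + h·1(x₂ ≥ θ)`, and more Msn2 beyond that
  does not help (excess Msn2 competes with Msn4 for shared sites and
  suppresses output). Msn4 acts as a linear **rheostat**,
  `E = b + m·x₄`, despite its ~3-fold lower and far more heterogeneous
  nuclear level.

The package's promoter model makes this mechanism executable: chromatin
opens through a chain of remodeling steps at rate
`k_open · (w₂x₂ + w₄x₄)/(K + x₂ + x₄)` gated by the Msn2 threshold
(slow class), then transcribes under shared-site occupancy with an
attenuating open state; fast and slow classes differ 5-fold in their
rate constants. See `vignette("dual-tf-logic")` for the full model,
parameter table and calibration rationale.

## Worked example

```r
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
#>   duration_min         label  wt_mean msn2d_mean msn4d_mean  frac_msn2d frac_msn4d
#> 1           30           AND 15.59746 0.02865179   3.267979 0.001836952  0.2095199
#> 2           60 MSN2_REQUIRED 21.00614 0.00000000  12.898960 0.000000000  0.6140566
```

Both deletions abolish slow-promoter expression at 30 min (AND gate:
msn2Δ and msn4Δ both under 25% of wild type); at 60 min the msn4Δ
strain reaches 61% of wild type — Msn4 is dispensable — while msn2Δ
remains dark, so the call is `MSN2_REQUIRED`.

```r
# switch-vs-rheostat fit on dose-pooled wild-type cells (5 x 400 cells)
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
#> <regulator_mode_fit> mode: switch
#>   threshold 10.9 a.u. (22.7% of max mean TF level 48.1); step height 13.5
#>   AICc: flat 7633.29 | switch 1220.56 | rheostat 4226.09
```

The step model wins decisively over flat and linear alternatives, and
the recovered threshold (≈23% of the maximal mean Msn2 level) matches
the generator's 25%-of-max switch.

A complete simulate → features → analyze → gates → report run is one
call: `run_pipeline(default_demo_config(seed = 1), "out/")` writes
`features.tsv`, `binned.tsv`, `gates.json` and `report.md`. The same
stages are available from a shell via the thin CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/stressgate", package="stressgate"))')" demo --seed 1 --out demo_out
```

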