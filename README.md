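# memsim

Stochastic simulation and fluctuation analysis of gene-expression **memory**
in dividing cells.

Clonal mammalian cell populations expressing identical reporter genes are
strongly heterogeneous, yet daughter cells often inherit their mother's
expression level for several generations. `memsim` implements the modelling
framework used to dissect this phenomenon: a **random-telegraph (two-state
promoter) model** of reporter expression coupled to **scheduled cell-division
events**, plus the statistics that quantify how long the expression level is
remembered. It is aimed at quantitative cell biologists studying expression
noise with fluorescent-reporter clones (flow cytometry and time-lapse
microscopy), and ships a synthetic-data generator so every analysis runs
without real movies or FCS files.

## Model

Per reporter gene (two independent reporters per cell, sharing only the
division clock):

* chromatin switches OPEN ⇌ CLOSED at rates `k_open`, `k_close` (1/min);
* while OPEN, transcription bursts fire at rate `k_burst`, each making a
  shifted-geometric number of mRNAs with mean *b*;
* mRNAs translate at `k_tl` per mRNA and decay at `δ_m = ln 2 / t½(mRNA)`;
  proteins decay at `δ_p = ln 2 / t½(protein)`;
* cells divide every `T_div` minutes; molecules are split equally (odd
  molecule by fair coin), chromatin state is inherited; volume grows
  linearly 1 → 2 over the cycle and the observable is the volume-normalized
  level `p/V` (the "mean fluorescence").

Key statistics: the normalized variance `NV = σ²/µ²` of expression across a
population or a long trace; the autocorrelation function of `p/V` and its
half-decay time `τ½` — the operational memory timescale; quadrant fractions
of two-channel snapshots; FRAP-style recovery labels.

Two built-in half-life regimes (`default_genes("stable")`,
`default_genes("unstable")`) contrast long-lived gene products
(mRNA 3.5 h, proteins 43 h / 29.5 h) with destabilized ones
(mRNA 1.5 h / 1.9 h, proteins 6 h 30 / 5 h 40). Stable products buffer
transcriptional bursts and carry the expression level across divisions;
destabilized products expose the bursts and erase the memory within one
cycle. See `vignettes/expression-memory.Rmd` for the full account.

## Worked example

```r
library(memsim)
genes <- default_genes("stable")          # 43 h / 29.5 h proteins, 3.5 h mRNA
cyc   <- cell_cycle_params(T_div = 2160)  # 36 h cycle, regular divisions

# one followed cell line, 30 division cycles, chromatin held open
tr <- simulate_cell(genes, cyc, t_end = 30 * 2160, dt = 10, seed = 1,
                    interventions = list(intervention("CLAMP_OPEN", 0, "A")))
x <- trace_values(tr, "A", "norm_level")[-(1:648)]   # drop 3 cycles
normalized_variance(x)
#> [1] 0.0152
tau_half(autocorrelation(x, dt = 10, max_lag = 5000))$tau_half
#> [1] 1087

# a two-channel cytometry-like snapshot with measurement noise
snap <- generate_cytometry_snapshot(genes, cyc, n_cells = 60, seed = 2)
thr <- positivity_threshold(sample_noise_floor(measurement_model(), 5000))
round(quadrant_fractions(snap$fl_A, snap$fl_B, thr, thr), 2)
#>   pp   pn   np   nn
#> 0.27 0.20 0.33 0.20
```

With chromatin clamped open the stable regime is quiet (`NV ≈ 0.015`) and
remembers its level for almost a day (`τ½ ≈ 18 h`). The snapshot shows the
four subpopulations (both reporters on, one on, none on) produced by rare,
independent chromatin switching of the two transgenes.

In-silico experiments: `grow_clone()` (lineage trees with passaging),
`subclone_experiment()` (sort HIGH/LOW/NEGATIVE founders, reculture, track
median/NV/fraction positive), `frap_experiment()` (whole-cell
photobleaching with inhibitor controls), `silencing_scenario()`
(dilution of a silenced reporter), `generate_timelapse_table()` +
`analyze_tracking()` (per-line τ½ cohorts).

A command-line wrapper is installed at `inst/cli/memsim`:

```sh
Rscript inst/cli/memsim simulate --config config.yaml --seed 1 --out out/
```

Configs may be TOML, YAML or JSON; half-lives can be given as
`*_half_life_h` keys. Every run writes TSV tables plus a `manifest.json`
echoing the resolved parameters (all rates in 1/min) and the seed.

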