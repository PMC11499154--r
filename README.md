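# clonoscape

Selecting a dominant antigen-specific T-cell receptor (TCR) clonotype from
targeted single-cell multi-omic data — and validating it with LDH
cytotoxicity statistics — as one reproducible, fully testable desk-scale
pipeline.

## Who this is for

Groups that expand antigen-specific T-cells (e.g. against a cancer-testis
antigen peptide presented on MHC-I), sequence them on a targeted
single-cell platform with paired full-length TCR chains and sample-tag
multiplexing, and need to pick *which* clonotype to clone into an
expression construct. The selection logic is simple to state — take the
most expanded clonotype, break ties by predicted peptide binding — but it
sits on top of a long chain of molecule-level processing whose behavior
is usually hidden inside vendor pipelines. `clonoscape` reimplements that
chain as small, contract-tested functions, together with a synthetic-data
generator that plants a known truth so every stage can be verified
offline.

## What the pipeline computes

1. **UMI error correction.** Molecules are rows of (cell label, UMI,
   feature, reads). *RSEC* merges a UMI `u` into a Hamming-distance-1
   neighbour `v` when `reads(v) >= 2·reads(u) − 1`, recursively; *DBEC*
   splits each feature's log2 read-depth distribution at the exhaustive
   minimum-within-class-variance threshold and removes the low class if
   the class means are ≥ 1 log2 unit apart.
2. **Cell calling.** Barcodes are ranked by total reads; the knee of the
   (log10 rank, log10 cumulative read fraction) curve — the rank
   minimising the discrete second derivative — separates cells from noise
   barcodes.
3. **Demultiplexing.** Per sample tag, a noise threshold of
   mean + 3·SD over cells where the tag is not maximal; one tag above
   threshold assigns the cell, two or more flag a multiplet.
4. **Expression gating.** Counts-per-million per cell, zeros→1 then
   log2, and a CD8 > 0 & CD4 ≤ 0 & FOXP3 ≤ 0 gate for effector T-cells;
   PCA with a scree table and UMAP on the first 4 PCs for visualisation.
5. **Clonotypes.** The productive TRA and TRB chains with the highest
   duplicate count are paired per cell; clonotype identity is the V/J
   calls plus full-length amino-acid chain sequences.
6. **Dominance.** Among clonotypes that are predominantly
   CD8+CD4−FOXP3−, the winner maximises (cell count, mean predicted
   binding score) lexicographically. Binding scores in [0, 1] come from an
   external predictor's CSV dialect or a deterministic built-in surrogate.
7. **Cytotoxicity.** Percent specific lysis from an LDH plate,

   ```
   % cytotoxicity = 100 · (OD_T+targets − OD_T) / (OD_max − OD_spont)
   ```

   per-donor summaries, and a one-way ANOVA with Tukey HSD across
   (cell line × condition) groups.

## Worked example

```r
library(clonoscape)

cfg <- sim_config(seed = 42)   # ~5000 cells, dominant clonotype of 14
rep <- run_pipeline(cfg)
print(rep)
#> run_report (seed 42):
#>   cells called:       5000
#>   multiplets:         98
#>   gated CD8+:         4994 (99.88%)
#>   clonotypes:         2762 (863 with >= 2 cells)
#>   dominant clonotype: CEMKYMREHMWMVFCF / CWLCFLTEHF
#>     cells: 14, mean binding score: 0.671
dominant_recovered(rep)
#> [1] TRUE
```

All 5000 planted cells are called (the knee sits exactly at the planted
real/noise boundary), ~2% multiplets are excluded, 99.88% of cells pass
the CD8 gate (the planted fraction is 99.9%), and the planted 14-cell
dominant clonotype is reported with its CDR3α/CDR3β pair and a medium
binding score — the configuration the selection rule is designed for.

The cytotoxicity side, on the packaged per-donor fixture (three tumor
cell lines × TCR-transduced (LV) vs vehicle (Veh), n = 7 donors):

```r
summarize_donors(table1_cytotoxicity())[, .(cell_line, condition, mean_2dp, sd_2dp)]
#>     cell_line condition mean_2dp sd_2dp
#> 1:    HCT-116        LV    41.44  10.78
#> 2:    HCT-116       Veh    35.83  10.28
#> 3: MDA-MB-231        LV    27.78  14.27
#> 4: MDA-MB-231       Veh    19.34   9.04
#> 5:   SK-MEL-5        LV    72.65   8.41
#> 6:   SK-MEL-5       Veh    31.93  12.12

res <- anova_tukey(table1_cytotoxicity())
tukey_p(res, "SK-MEL-5 LV", "SK-MEL-5 Veh")
#> [1] 5.822246e-07
```

The TCR-transduced cells kill the antigen-high SK-MEL-5 line far more
than the vehicle control (adjusted p ≈ 6e-7), with the effect shrinking
for the antigen-low and antigen-negative lines — the pattern expected of
an antigen-specific receptor.

## Command line

```sh
inst/cli/clonoscape demo --out runs/demo            # simulate + full run
inst/cli/clonoscape run --config cfg.json --out runs/x --seed 7
inst/cli/clonoscape cytotox-summary --table donors.csv --out summary.csv
```

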