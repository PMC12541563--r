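# metaprogramr

Discovery of recurrent transcriptional **meta-programs** across multi-sample
single-cell (or single-nucleus) RNA-seq cohorts, such as panels of tumor
patient-derived organoids.

Cells within one tumor sample occupy distinct expression states — cycling,
stress/translation, stem-like, patient-specific states. `metaprogramr`
answers the cohort-level question: *which of these within-sample programs
recur across samples?* It implements the standard pipeline end to end:

1. per-sample non-negative matrix factorization, `X ≈ WH` with
   `W ≥ 0` (genes × k), `H ≥ 0` (k × cells), minimizing `‖X − WH‖_F` by
   Lee–Seung multiplicative updates on log1p CP10K expression
   (default `k = 15` per sample);
2. a **program** per factor: its top 50 genes by loading;
3. a binned-control **module score** of every program on every pooled cell
   (mean member expression minus mean of expression-bin-matched control
   genes, 24 bins, 100 controls per gene);
4. Pearson **correlation** of program scores over all pooled cells;
5. hierarchical clustering of `d = 1 − r` with a dendrogram **cut at
   height 1.3**; clusters that are recurrent (≥ 3 programs spanning ≥ 2
   samples), coherent (mean pairwise `r ≥ 0.5`) and consensual (consensus
   support ≥ 0.5) become **meta-programs (MPs)**;
6. a 50-gene **consensus** per MP (most frequently occurring genes across
   member programs) and per-cell MP assignment.

A seeded synthetic-cohort generator with planted shared and private
programs provides ground truth, so recovery of the planted architecture is
measurable (Jaccard-matched against MP consensus sets). With 9 samples and
`k = 15`, the correlation stage receives 9 × 15 = 135 programs.

## Worked example

Simulate the default cohort (9 samples × 500 cells × 2,000 genes, 4 shared
programs, 1 private program per sample) and run the full pipeline:

```r
library(metaprogramr)

cohort <- generate_cohort(cohort_config(seed = 1))
cohort$samples$S1
#> <count_matrix> sample S1: 2000 genes x 500 cells, 704967 non-zero

result <- run_cohort(cohort$samples)
result
#> <mp_result> 9 samples, 135 programs, 4 MP(s)

glance(result$metaprograms)
#> # A tibble: 4 × 4
#>   mp_id n_programs n_samples n_consensus_genes
#>   <chr>      <int>     <int>             <int>
#> 1 MP1           24         9                50
#> 2 MP2           21         9                50
#> 3 MP3           14         9                50
#> 4 MP4           14         9                50
```

All 135 programs enter the correlation stage; four clusters qualify as
meta-programs, each supported by 14–24 programs from all 9 samples and
summarized by a 50-gene consensus. Scoring recovery against the planted
truth:

```r
report <- recovery_metrics(cohort$truth, result$metaprograms,
                           result$assignments)
report
#> <recovery_report> 4 planted shared program(s), 4 recovered MP(s), mean matched Jaccard 1.000
#>   cell-label agreement: 0.940

report$matches
#> # A tibble: 4 × 3
#>   program_id mp_id jaccard
#>   <chr>      <chr>   <dbl>
#> 1 SP1        MP1         1
#> 2 SP2        MP3         1
#> 3 SP3        MP4         1
#> 4 SP4        MP2         1
```

Every planted shared program is recovered exactly (Jaccard 1 between its
50 planted genes and the matched MP's 50-gene consensus), and 94% of
planted-active cells are assigned to the matching MP. Per-sample MP
composition and consensus tables are plain tibbles:

```r
head(result$composition, 4)
#> # A tibble: 4 × 4
#>   sample_id mp_id n_cells fraction
#>   <chr>     <chr>   <int>    <dbl>
#> 1 S1        MP1       194    0.388
#> 2 S1        MP2       103    0.206
#> 3 S1        MP3        96    0.192
#> 4 S1        MP4       107    0.214
```

`autoplot(result$correlation, result$partition)` draws the program
correlation heatmap in dendrogram order;
`plot_mp_composition(result$assignments)` shows stacked per-sample MP
fractions. Disk-based workflows use `simulate_cohort_dir()` +
`run_pipeline(manifest, out_dir)`, which read/write 10x-style
Matrix-Market directories, GMT gene sets, CSV score/correlation tables, a
YAML manifest and a JSON provenance block; `inst/cli/metaprogram.R` wraps
them as a small command line tool.

## Package layout

- `R/` — generator, IO, preprocessing, NMF, program extraction, module
  scoring, meta-program consensus, recovery metrics, pipeline drivers,
  plotting.
- `vignettes/metaprogram-discovery.Rmd` — the model, its assumptions,
  parameter meanings and defaults, numerical choices, and what the
  synthetic cohorts do and do not emulate.
- `tests/testthat/` — oracle-backed unit tests per stage plus end-to-end
  acceptance checks.
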