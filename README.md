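# ibcrep

Downstream analysis of multiplexed single-cell studies of
**insulin-reactive B cells (IBCs)** — the autoreactive B cells whose
receptors bind insulin and that participate in type 1 diabetes — for
immunologists working with 10x-style VDJ + expression + hashtag
libraries and SPR/ELISA binding data.

The package covers four analysis stages and the synthetic generators
needed to validate them without any external download:

1. **Hashtag demultiplexing** — assign each cell to its donor mouse
   from hashtag-oligo UMI counts via per-cell centered log-ratio (CLR)
   normalization and background-referenced thresholds
   (`clr_normalize()`, `demultiplex()`).
2. **Kappa light-chain repertoire** — Smith–Waterman germline V/J
   assignment (match +1, mismatch −1, affine gaps), per-mouse and
   mean-across-mice clonotype frequency tables with a 0.2% "others"
   bin, CDR3 translation numbered so the V–J joint falls at position
   97, mutation counting per region, and a strain
   polymorphism/charge-class comparison
   (`assign_germline()`, `build_clonotype_table()`, `extract_cdr3()`,
   `compare_strains()`).
3. **Transcriptome** — depth normalization, PCA + k-means clustering
   with silhouette-selected k, one-vs-rest rank-sum marker detection
   (p < 0.05), and projection onto a reference B-cell atlas by
   gene-wise z-scores
   \(z_{gp} = (m_{gp} - \mu_g)/\sigma_g\), where \(m_{gp}\) is the
   median expression of gene *g* in population *p* and
   \(\mu_g, \sigma_g\) are taken across all reference populations
   (`cluster_cells()`, `find_markers()`, `project_to_atlas()`).
4. **Binding kinetics** — ELISA titration AUC over log10 dilution and
   global 1:1 Langmuir SPR fitting,
   association \(R(t) = R_{eq}(1 - e^{-(k_a C + k_d)t})\) with
   \(R_{eq} = R_{max} k_a C/(k_a C + k_d)\), dissociation
   \(R(t) = R_0 e^{-k_d t}\), \(K_D = k_d/k_a\)
   (`fit_langmuir()`, `elisa_auc()`, `compare_groups()`).

Module 0 is the **synthetic-data generator** (`simulate_repertoire()`,
`simulate_hashtags()`, `simulate_expression()`,
`make_reference_atlas()`, `simulate_sensorgram()`, `simulate_elisa()`):
first-class, tested code whose defaults encode the emulated study
design — three donor mice with 2081/1947/63 cells, a kappa-only
repertoire dominated by five V/J light chains with an L/S junction
dimorphism at CDR3 position 97, three transcriptional subpopulations
with marginal-zone / follicular / memory signatures, and sensorgrams
obeying 1:1 kinetics over a six-point concentration series.  The
bundled germline reference is *synthetic* (see the methods vignette);
it must not be used to annotate real data.

## Worked example

```r
library(ibcrep)

## simulate the default three-mouse fixture and run the repertoire stage
sim   <- simulate_repertoire(repertoire_config(), seed = 1)
light <- sim$contigs[sim$contigs$chain == "IGK", ]
calls <- call_germlines(sim$sequences[light$contig_id], sim$reference)
tab   <- build_clonotype_table(sim$contigs, calls,
                               sequences = sim$sequences)
round(100 * tab$pair_freq[, "mean"], 1)
#>   IGKV4-74|IGKJ5   IGKV4-74|IGKJ2   IGKV4-57|IGKJ5   IGKV4-57|IGKJ2
#>             64.3             20.3              6.7              3.9
#>  IGKV10-94|IGKJ1 IGKV17-127|IGKJ1   IGKV4-91|IGKJ1   IGKV4-91|IGKJ2
#>              0.7              0.7              0.7              0.2
#>           others
#>              2.6

round(100 * position_composition(tab, "IGKV4-74", "IGKJ5", 97), 1)
#>    L    S
#> 56.6 43.4

## fit 1:1 Langmuir kinetics to a simulated sensorgram set (1 RU noise)
fit <- fit_langmuir(preprocess_sensorgram(
  simulate_sensorgram(spr_config(), seed = 2)))
#> ka = 1.01e+05 1/(M s), kd = 0.000999 1/s, KD = 9.92e-09 M,
#> Rmax = 100.0 RU, RMS = 1.03 RU
```

Reading: the dominant rearrangement is Vκ4-74/Jκ5 at a mean-across-mice
frequency of 64.3% (the three small extra rows are rare clonotypes that
fluctuated above the 0.2% binning threshold in mouse 3, which has only
63 cells); within that clone, 56.6% of cells carry leucine at the V–J
joint (position 97).  The kinetic fit recovers the generator's true
parameters (ka = 1e5, kd = 1e-3, KD = 10 nM, Rmax = 100 RU) to within
1% under 1% read noise.

The full pipeline — simulation, demultiplexing, repertoire,
clustering/markers/projection, binding — runs from one config and
writes all artifacts plus a machine-readable `summary.json`:

```r
run_pipeline(pipeline_config(outdir = "run1", seed = 1))
```

A small CLI wrapping the same stages lives in `inst/cli/ibcrep`
(subcommands `demux`, `repertoire`, `fit-spr`, `elisa-auc`,
`pipeline`).

## Layout

* `R/` — generators, demultiplexing, alignment/clonotype/CDR3,
  transcriptome, kinetics, I/O, pipeline driver
* `src/` — Smith–Waterman local alignment (Rcpp)
* `tests/testthat/` — module tests, property tests, and
  `test-acceptance.R` (the acceptance criteria at their stated
  tolerances)
* `vignettes/ibcrep-methods.Rmd` — models, parameter choices, design
  decisions and limitations
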