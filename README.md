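# hpbody

Quantitative analyses for bacterial ribonucleoprotein condensates and
their downstream effects on RNA metabolism, written for researchers
studying membraneless organelles (such as the Hfq–polyphosphate bodies
of nitrogen-starved *E. coli*) with single-molecule imaging and
sequencing. The package bundles four independent, fully tested analysis
stages plus seeded synthetic-data generators that make each stage
verifiable end to end:

- **Condensate partitioning** (`spt_partition()` and friends):
  Laplacian-of-Gaussian focus detection on frame-summed movies,
  trajectory classification by focus overlap, multi-state fitting of
  the squared-displacement CDF

  P(r², τ) = 1 − Σᵢ αᵢ · exp( −r² / ((8/3) Dᵢ τ) ),   Σᵢ αᵢ = 1,

  (the 8/3 factor is the full-frame motion-blur correction), and the
  partition fractions F_condensate, F_nucleoid and F_free. One-phase
  association FRAP fits (`fit_frap_recovery()`) included.
- **Transcript half-lives** (`normalize_with_spikeins()`,
  `fit_decay_curves()`, `classify_stability()`): ERCC-spike-in-anchored
  normalization of rifampicin-chase count tables, per-gene fits of
  y = a·exp(−t/b), four-category stability classification between
  genotypes, and rank-sum gene-set shift tests.
- **Untemplated poly(A) tails** (`count_terminal_A()`,
  `assign_reads_to_tail_windows()`, `fit_zinb_tails()`): terminal-A
  calling from 3′-end reads, strand-aware 3′-window assignment, and
  per-gene zero-inflated negative binomial models with one mean per
  genotype-by-condition cell and shared zero-inflation and
  overdispersion.
- **GO-term-set overlap** (`build_term_set()`,
  `permutation_overlap_test()`): term-set intersections between a
  condensate proteome and P-body / stress-granule protein sets, with
  protein-resampling permutation p-values.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()`/`plot_*()` ggplot2 displays. Inputs and outputs are plain
tables (tibbles, CSV/TSV), with readers for SAM/BAM, GFF3/BED, GAF and
multi-frame TIFF where those formats occur.

## Worked example

Simulate one imaging replicate — 1500 trajectories in a 3 × 1 μm cell
with a 0.35 μm condensate, latent state weights
(condensate, nucleoid, free) = (0.45, 0.30, 0.25) — and run the whole
partition pipeline:

```r
library(hpbody)

cfg <- spt_sim_config(n_trajectories = 1500,
                      weights = c(0.45, 0.30, 0.25), seed = 42)
sim <- simulate_spt(cfg)
res <- spt_partition(sim$tracks, frame_interval = 0.02,
                     pixel_size = 0.1, field = cfg$field)
res$full_fit
#> <diffusion_fit> 3 states, n = 12854 steps, tau = 0.02 s
#>   D     (um^2/s): 0.05101, 0.31, 2.006
#>   alpha         : 0.469, 0.2895, 0.2414
#>   objective 0.01267, converged: TRUE
res$fractions[, c("F_condensate", "F_nucleoid", "F_free", "N_in", "N_total_steps")]
#> # A tibble: 1 × 5
#>   F_condensate F_nucleoid F_free  N_in N_total_steps
#>          <dbl>      <dbl>  <dbl> <int>         <int>
#> 1        0.472      0.286  0.241  5956         12854
```

The three-state CDF fit recovers the planted diffusion coefficients
(0.05, 0.3, 2.0 μm²/s) and the pipeline's partition fractions land
within a few percent of the planted (0.45, 0.30, 0.25): 47 % of the
molecules' steps are attributed to the condensate, 29 % to the nucleoid
(by subtraction) and 24 % to free diffusion. `N_in` counts the pooled
displacement steps contributed by trajectories fully inside a detected
focus.

The same pattern holds for the other stages, e.g. the overlap
permutation test on a simulated 500-protein universe with a planted
35 % term-set overlap:

```r
go <- simulate_go_universe(go_sim_config(seed = 8))
permutation_overlap_test(go$sets$hp, go$universe, go$annotation,
                         go$truth$pb_terms, go$truth$sg_terms,
                         n_perm = 1000, seed = 3)
#> <overlap_permutation> 1000 permutations, seed 3
#>   pb    observed 41, p = 0.01598
#>   sg    observed 40, p = 0.01499
#>   joint observed 46, p = 0.01598
```

See `vignettes/hpbody-methods.Rmd` for the models, their assumptions,
and every numerical and design choice.

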