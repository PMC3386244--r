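# introgressim

Simulation and likelihood inference for **competitive exclusion of introgressed
genomic segments**.

When a chromosomal segment from *Drosophila sechellia* is placed, by repeated
backcrossing, into a *D. simulans* genome, it can be perfectly viable and
fertile and still lose a multi-generation competition against the resident
wild-type alleles. The experimental design behind this package tracks a neutral
microsatellite marker inside each introgressed segment: bottle populations are
founded from F1 flies (marker frequency exactly 0.5), bred for 20 generations
at ~150 flies per sex, and destructively sampled (~40 flies) at generations
6/7, 14 and 20. The marker declines only because it hitch-hikes with linked
incompatibility alleles, so the trajectory carries information about the
selection coefficient *s*, the dominance *h*, and the marker–incompatibility
recombination fraction *c* (female meiosis only; *Drosophila* males are
achiasmate).

The package is aimed at population geneticists who want to re-run, stress-test
or extend that analysis without any wet-lab data: every input can be generated
synthetically under known ground truth.

## What's inside

* **Forward simulator** — individual-based two-locus Wright–Fisher bottles with
  viability selection `w = (1, 1 − hs, 1 − s)`, female-limited recombination,
  fixed census, and destructive sampling (`run_replicate()`,
  `founder_population()`, `viability_selection()`, `make_gamete()`,
  `reproduce()`, `sample_marker_frequency()`), plus a lossless vectorised
  batch engine (`simulate_sampled_frequencies()`) and a deterministic
  infinite-population oracle (`expected_trajectory()`; at c = 0 it is
  q' = (q²(1−s) + pq(1−hs)) / (p² + 2pq(1−hs) + q²(1−s))).
* **Likelihood inference** — sampled frequencies binned into 40 bins of width
  0.025 (`bin_index()`, `build_distribution()`); per-generation union-of-bins
  log-likelihood (`observation_log_likelihood()`); grid search over
  c ∈ {1e-4 … 0.5}, s ∈ {0.1 … 0.9} at each h ∈ {0, 0.5, 0.9, 1}
  (`fit_grid()`, `grid_to_long()`); summary table over markers
  (`summarize_mle_table()`).
* **Empirical statistics** — mating-share decomposition and exact one-tailed
  sign test (`mating_shares()`, `aggregate_mating()`,
  `sign_test_one_tailed()`), fertility summaries with one-way ANOVA
  (`fertility_summary()`), a permutation test for genotypic linkage
  disequilibrium (`ld_permutation_test()`), and the single- vs
  double-introgression comparison (`compare_single_double()`). The published
  summary tables ship as plain-text data (`mating_counts()`,
  `fertility_line_means()`, `mle_estimates()`).
* **Synthetic data** — trajectory datasets with the experiment's structure,
  mating counts and fertility records under known parameters
  (`synthetic_study_spec()`, `generate_marker_dataset()`,
  `generate_mating_counts()`, `generate_fertility_records()`).
* **Orchestration** — validated JSON configs, schema-checked CSV round-trips
  and an end-to-end pipeline (`read_observations()`, `pipeline_config()`,
  `run_pipeline()`), plus a CLI at `inst/cli/introgressim`
  (`synth`, `simulate`, `fit`, `stats`, `run-all`).

## Worked example: recover selection on a synthetic segment

```r
library(introgressim)

design <- experiment_design()                      # 150+150 flies, 20 generations
truth  <- selection_params(s = 0.4, h = 0.5, c = 0.0001)
obs <- generate_marker_dataset(synthetic_study_spec(list(list(
  experiment_id = "X", params = truth, design = design, label = "single")),
  seed = 1000))
head(obs[, 1:6], 4)
#>   experiment_id replicate_id generation n_alleles sech_count frequency
#> 1             X         rep1          7        80         16    0.2000
#> 2             X         rep1         14        80          9    0.1125
#> 3             X         rep1         20        80          2    0.0250
#> 4             X         rep2          7        80         12    0.1500

fit <- fit_grid(obs, grid_spec(h_values = 0.5), design,
                n_iterations = 2000, seed = 1)
fit[["h0.5"]]$mle
#> $s
#> [1] 0.4
#> $c
#> [1] 1e-04
#> $loglik
#> [1] -1.139434
```

The marker drops from 0.5 to ~0.2 by generation 7 and the grid MLE recovers
the true (s, c). Across repeated seeds the MLE of s lands within one grid step
of the truth in ≈90% of trials (the union likelihood tends to sit one step
high; see the vignette).

The published summary statistics reproduce from the shipped tables:

```r
summarize_mle_table(mle_estimates())
#>   grand averages: c = 0.06, s = 0.43
#>   markers with c ~ 0 at all h: 7 of 9 (78%)

agg <- aggregate_mating(mating_counts())
#> mean shares: overall 0.47, female 0.50, male 0.44; 6/8 lines below 0.5
sign_test_one_tailed(agg$lines_below_half, agg$n_lines)
#> [1] 0.1445312   # prints as 0.14
fertility_summary(fertility_line_means())$grand_mean
#> [1] 290.875     # prints as 291
```

## Documentation

The methods vignette (`vignettes/competitive-exclusion.Rmd`) documents the
model and its assumptions, the two simulation engines and their equivalence,
the binned likelihood and its tie-break/flooring conventions, what the
synthetic-data generator does and does not emulate, and known limitations.
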