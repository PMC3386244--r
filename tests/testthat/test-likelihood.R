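# Binning, distribution building, the union log-likelihood, grid fitting and
# the MLE summary table.

test_that("bin_index uses half-open bins with a closed last bin", {
  expect_identical(bin_index(0), 0L)
  expect_identical(bin_index(1), 39L)          # closed last bin
  expect_identical(bin_index(0.025), 1L)       # boundary goes up
  expect_identical(bin_index(0.9749999), 38L)
  # sampled frequencies are multiples of 1/80: k/80 falls in bin floor(k/2)
  k <- 0:80
  expect_identical(bin_index(k / 80), pmin(k %/% 2L, 39L))
  expect_error(bin_index(1.01), class = "value_range_error")
  expect_error(bin_index(-0.1), class = "value_range_error")
})

test_that("build_distribution conserves iterations and is seed-deterministic", {
  p <- selection_params(0.4, 0.5, 0.0001)
  des <- experiment_design()
  d1 <- build_distribution(p, des, n_iterations = 400, seed = 11)
  expect_equal(unname(rowSums(d1$counts)), rep(400, 3))
  expect_identical(dim(d1$counts), c(3L, 40L))
  d2 <- build_distribution(p, des, n_iterations = 400, seed = 11)
  expect_identical(d1$counts, d2$counts)

  # lethal dominant, complete linkage: all mass in bin 0 at every generation
  dx <- build_distribution(selection_params(1, 1, 0), des,
                           n_iterations = 100, seed = 12)
  expect_equal(unname(dx$counts[, 1]), rep(100, 3))

  # the two engines produce identically-shaped, conserved distributions
  di <- build_distribution(p, small_design(), n_iterations = 50,
                           engine = "individual", seed = 13)
  expect_equal(unname(rowSums(di$counts)), rep(50, 2))
})

test_that("union log-likelihood follows the added-bins rule", {
  counts <- rbind(c(1000, rep(0, 39)),                  # gen 3: all mass bin 0
                  c(100, 900, rep(0, 38)))              # gen 6: 10% / 90%
  dist <- fake_distribution(counts, c(3, 6), 1000)

  # union bins carry all iteration mass -> log(1) = 0
  obs_all <- data.frame(generation = c(3, 6, 6), frequency = c(0.01, 0.01, 0.03))
  expect_equal(observation_log_likelihood(obs_all, dist), 0)

  # one replicate, one generation, bin holding 10% of iterations
  obs_one <- data.frame(generation = 6, frequency = 0.01)
  expect_equal(observation_log_likelihood(obs_one, dist), log(0.1))

  # replicates in the same bin count once (union), but multiply per-replicate
  obs_dup <- data.frame(generation = 6, frequency = c(0.01, 0.015))
  expect_equal(observation_log_likelihood(obs_dup, dist), log(0.1))
  expect_equal(observation_log_likelihood(obs_dup, dist, method = "per_replicate"),
               2 * log(0.1))

  # zero-mass observed bin floored at 1/(n_iterations + 1)
  obs_zero <- data.frame(generation = 3, frequency = 0.5)
  expect_equal(observation_log_likelihood(obs_zero, dist), log(1 / 1001))

  # per-generation terms add across generations
  obs_two <- data.frame(generation = c(3, 6), frequency = c(0.01, 0.01))
  expect_equal(observation_log_likelihood(obs_two, dist), 0 + log(0.1))

  expect_lte(observation_log_likelihood(obs_dup, dist), 0)
  expect_error(observation_log_likelihood(
    data.frame(generation = 5, frequency = 0.1), dist),
    class = "generation_mismatch_error")
  expect_error(observation_log_likelihood(data.frame(x = 1), dist),
               class = "missing_column_error")
})

test_that("fit_grid breaks likelihood ties toward smallest s then smallest c", {
  # observations covering every bin in every sampled generation give log(1) = 0
  # in every cell: a full tie, resolved to the smallest (s, c)
  des <- small_design()
  centers <- (0:39) / 40 + 0.0125
  obs <- expand.grid(generation = des$sample_generations, frequency = centers)
  fit <- fit_grid(obs, grid_spec(s_values = c(0.2, 0.5),
                                 c_values = c(0.0001, 0.1), h_values = 0.5),
                  design = des, n_iterations = 40, seed = 5)
  expect_length(fit, 1)
  expect_true(all(fit[[1]]$loglik == 0))
  expect_equal(fit[[1]]$mle$s, 0.2)
  expect_equal(fit[[1]]$mle$c, 0.0001)
})

test_that("fit_grid is deterministic and recovers strong selection signal", {
  des <- experiment_design()
  truth <- selection_params(0.4, 0.5, 0.0001)
  obs <- do.call(rbind, lapply(1:5, function(i) {
    run_replicate(truth, des, seed = 100 + i)
  }))
  grid <- grid_spec(s_values = c(0.1, 0.4, 0.8), c_values = c(0.0001, 0.5),
                    h_values = 0.5)
  f1 <- fit_grid(obs, grid, des, n_iterations = 500, seed = 99)
  f2 <- fit_grid(obs, grid, des, n_iterations = 500, seed = 99)
  expect_identical(f1[[1]]$loglik, f2[[1]]$loglik)
  expect_identical(f1[[1]]$mle, f2[[1]]$mle)
  # a sharp decline is not attributed to near-neutrality or free recombination
  expect_gt(f1[[1]]$mle$s, 0.1)
  expect_equal(f1[[1]]$mle$c, 0.0001)

  long <- grid_to_long(f1)
  expect_equal(nrow(long), 6)
  expect_equal(sum(long$is_mle), 1)
  expect_true(all(long$loglik <= 0))
  expect_equal(long$loglik[long$is_mle],
               max(long$loglik)) # mle attains the matrix maximum
})

test_that("summarize_mle_table reproduces the published summary", {
  summ <- summarize_mle_table(mle_estimates())
  expect_equal(round_half_up(summ$grand$mean_s, 2), 0.43)
  expect_equal(round_half_up(summ$grand$mean_c, 2), 0.06)
  expect_equal(summ$zero_c$n, 7)
  expect_equal(summ$zero_c$n_markers, 9)
  expect_equal(round_half_up(100 * summ$zero_c$fraction), 78)
  ph <- summ$per_h
  expect_equal(round_half_up(ph$mean_s[ph$h == 0], 2), 0.58)
  expect_equal(round_half_up(ph$mean_s[ph$h == 0.5], 2), 0.42)
  expect_equal(round_half_up(ph$mean_s[ph$h == 1], 2), 0.37)
  expect_equal(round_half_up(ph$mean_c[ph$h == 0.5], 2), 0.08)

  single <- summarize_mle_table(data.frame(marker = "Z", h = c(0, 1),
                                           c = c(0.1, 0.3), s = c(0.5, 0.7)))
  expect_equal(single$grand$mean_s, 0.6) # single marker: averages are its own
  expect_equal(single$grand$mean_c, 0.2)
  expect_equal(single$zero_c$n, 0)

  expect_error(summarize_mle_table(data.frame()), class = "missing_column_error")
  expect_error(summarize_mle_table(data.frame(marker = character(0),
                                              h = numeric(0), c = numeric(0),
                                              s = numeric(0))),
               class = "validation_error")
})
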