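# Individual-based simulator: founder, selection, gametes, reproduction,
# sampling, full replicates, and the deterministic oracle.

test_that("founder population is all coupling-phase double heterozygotes", {
  pop <- founder_population(experiment_design())
  expect_equal(nrow(pop$males) + nrow(pop$females), 300)
  expect_identical(pop$generation, 0L)
  expect_equal(marker_frequency(pop), 0.5)
  H <- rbind(pop$males, pop$females)
  # full coupling: only the sech/sech (code 3) and sim/sim (code 0) haplotypes
  expect_setequal(unique(as.vector(H)), c(0L, 3L))
  expect_true(all(rowSums(H) == 3L)) # every individual heterozygous

  tiny <- founder_population(experiment_design(n_males = 1, n_females = 1,
                                               sample_males = 1, sample_females = 1))
  expect_equal(nrow(tiny$males) + nrow(tiny$females), 2)
})

test_that("genotype_fitness depends only on the fitness locus", {
  p <- selection_params(0.43, 0.5, 0)
  simsim <- individual(haplotype("sech", "sim"), haplotype("sim", "sim"))
  het <- individual(haplotype("sim", "sech"), haplotype("sech", "sim"))
  sechsech <- individual(haplotype("sim", "sech"), haplotype("sech", "sech"))
  expect_equal(genotype_fitness(simsim, p), 1)           # marker alleles ignored
  expect_equal(genotype_fitness(het, selection_params(0.3, 1, 0)), 0.7)
  expect_equal(genotype_fitness(sechsech, p), 0.57)
})

test_that("viability selection retains by genotype and signals extinction", {
  des <- experiment_design(n_males = 50, n_females = 50)
  pop <- founder_population(des)
  set.seed(1)
  expect_identical(viability_selection(pop, selection_params(0, 0.5, 0))$males,
                   pop$males) # s = 0: everyone survives

  # mixed population at s = 1, h = 1: only sim/sim fitness homozygotes survive
  mixed <- make_population(rbind(hap_rows(0L, 0L, 10), hap_rows(3L, 0L, 10)),
                           rbind(hap_rows(2L, 0L, 10), hap_rows(3L, 3L, 10)))
  set.seed(2)
  surv <- viability_selection(mixed, selection_params(1, 1, 0))
  H <- rbind(surv$males, surv$females)
  expect_equal(nrow(H), 20) # codes 0 and 2 carry the sim fitness allele
  expect_true(all(H[, 1] %% 2L == 0L & H[, 2] %% 2L == 0L))

  set.seed(3)
  cond <- tryCatch(viability_selection(pop, selection_params(1, 1, 0)),
                   extinction_error = function(e) e)
  expect_s3_class(cond, "extinction_error")
})

test_that("gamete formation: achiasmate males, female recombination at c", {
  dbl_het <- function(sex) individual(haplotype("sech", "sech"),
                                      haplotype("sim", "sim"), sex = sex)
  draw <- function(parent, c, n = 4000) {
    vapply(seq_len(n), function(i) make_gamete(parent, c)$code, integer(1))
  }
  set.seed(10)
  gm <- draw(dbl_het("male"), 0.5)
  expect_setequal(unique(gm), c(0L, 3L)) # males never recombine
  expect_lt(abs(mean(gm == 3L) - 0.5), 3 * sqrt(0.25 / 4000))

  set.seed(11)
  gf0 <- draw(dbl_het("female"), 0)
  expect_setequal(unique(gf0), c(0L, 3L))

  # c = 0.5: gamete classes (1-c)/2 and c/2 all equal 1/4
  set.seed(12)
  gf5 <- draw(dbl_het("female"), 0.5)
  tab <- tabulate(gf5 + 1L, 4) / 4000
  expect_true(all(abs(tab - 0.25) < 3 * sqrt(0.25 * 0.75 / 4000)))

  # intermediate c: recombinant fraction = c
  set.seed(13)
  gf2 <- draw(dbl_het("female"), 0.2)
  rec <- mean(gf2 %in% c(1L, 2L))
  expect_lt(abs(rec - 0.2), 3 * sqrt(0.2 * 0.8 / 4000))
})

test_that("reproduction restores the census and recycles parental material", {
  des <- experiment_design(n_males = 40, n_females = 60)
  p <- selection_params(0.4, 0.5, 0)
  pop <- founder_population(des)
  set.seed(20)
  off <- reproduce(pop, p, des)
  expect_equal(nrow(off$males), 40)
  expect_equal(nrow(off$females), 60)
  expect_identical(off$generation, 1L)

  # monomorphic parents stay monomorphic
  mono <- make_population(hap_rows(0L, 0L, 5), hap_rows(0L, 0L, 5))
  off2 <- reproduce(mono, p, des)
  expect_true(all(off2$males == 0L) && all(off2$females == 0L))

  # one mother x one father, c = 0: offspring haplotypes are parental only
  single <- make_population(hap_rows(3L, 0L, 1), hap_rows(2L, 1L, 1))
  set.seed(21)
  off3 <- reproduce(single, selection_params(0.4, 0.5, 0), des)
  expect_true(all(off3$males[, 1] %in% c(2L, 1L))) # maternal gamete
  expect_true(all(off3$males[, 2] %in% c(3L, 0L))) # paternal gamete

  empty <- make_population(hap_rows(0L, 0L, 5)[0, , drop = FALSE],
                           hap_rows(0L, 0L, 5))
  expect_error(reproduce(empty, p, des), class = "extinction_error")
})

test_that("destructive sampling removes flies and counts sech marker alleles", {
  des <- experiment_design()
  mono <- make_population(hap_rows(3L, 3L, 150), hap_rows(2L, 2L, 150))
  set.seed(30)
  smp <- sample_marker_frequency(mono, des)
  expect_equal(smp$observation$frequency, 1)       # all sech at the marker
  expect_equal(smp$observation$sech_count, 80)
  expect_equal(smp$observation$n_alleles, 80)      # 2 x 40 flies
  expect_equal(nrow(smp$population$males) + nrow(smp$population$females), 260)

  few <- make_population(hap_rows(0L, 0L, 20), hap_rows(0L, 0L, 150))
  expect_error(sample_marker_frequency(few, des),
               class = "insufficient_survivors_error")
})

test_that("run_replicate yields one observation per scheduled generation", {
  p <- selection_params(0.4, 0.5, 0.0001)
  des <- experiment_design()
  out <- run_replicate(p, des, seed = 42, experiment_id = "E", replicate_id = "r1")
  expect_equal(out$generation, c(7, 14, 20))
  expect_equal(out$n_alleles, rep(80, 3))
  expect_equal(out$frequency, out$sech_count / out$n_alleles)
  expect_identical(out, run_replicate(p, des, seed = 42, experiment_id = "E",
                                      replicate_id = "r1")) # same seed, same result

  # lethal dominant with complete linkage: marker eliminated by generation 1
  lethal <- run_replicate(selection_params(1, 1, 0), des, seed = 7)
  expect_equal(lethal$frequency, c(0, 0, 0))
})

test_that("expected_trajectory matches the single-locus recursion at c = 0", {
  # hand-derived: generation-1 frequency 0.4375 at s = 0.4, h = 0.5, p0 = 0.5
  tr <- expected_trajectory(selection_params(0.4, 0.5, 0), 0.5, 1)
  expect_equal(tr$frequency[2], 0.4375, tolerance = 1e-12)

  for (case in list(c(0.2, 0), c(0.43, 0.5), c(0.8, 1), c(0.6, 0.9))) {
    p <- selection_params(case[1], case[2], 0)
    got <- expected_trajectory(p, 0.5, 10)$frequency
    want <- single_locus_recursion(0.5, case[1], case[2], 10)
    expect_equal(got, want, tolerance = 1e-10,
                 info = sprintf("s=%g h=%g", case[1], case[2]))
  }

  # neutral: constant at p0 for any c
  flat <- expected_trajectory(selection_params(0, 0.5, 0.3), 0.37, 8)$frequency
  expect_equal(flat, rep(0.37, 9), tolerance = 1e-12)

  # lethal dominant, complete linkage: 0 from generation 1 onward
  dead <- expected_trajectory(selection_params(1, 1, 0), 0.5, 5)$frequency
  expect_equal(dead, c(0.5, 0, 0, 0, 0, 0))
})

test_that("recombination frees the marker from a lethal dominant allele", {
  # at c = 0.5 the marker survives selection against carriers; at c = 0 it dies
  free <- expected_trajectory(selection_params(1, 1, 0.5), 0.5, 7)$frequency
  linked <- expected_trajectory(selection_params(1, 1, 0), 0.5, 7)$frequency
  expect_true(all(free[-1] > linked[-1]))
  expect_equal(free[2], 0.25, tolerance = 1e-12) # half of maternal gametes usable
})
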