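# One replicate bottle: the generation loop, and the deterministic
# infinite-population oracle used to validate it.

#' Simulate one replicate competition bottle
#'
#' Runs the per-generation cycle reproduction -> viability selection ->
#' (destructive sampling when scheduled) starting from the all-heterozygote
#' coupling founder of [founder_population()]. Selection is not applied to the
#' founder itself: for the founder every individual has the same genotype, so
#' selection there is a uniform thinning that cannot change frequencies, and
#' skipping it keeps generation indices aligned with the bottle generations
#' (and keeps extreme parameter sets such as s = 1, h = 1 meaningful).
#'
#' Terminal states are absorbed rather than propagated: if a sex goes extinct
#' at selection, or survivors are too few to sample, the replicate freezes the
#' current marker frequency and reports it for all remaining scheduled
#' generations (with `sech_count` rounded to the standard allele denominator).
#' Loss or fixation of the *sechellia* fitness allele is not terminal - the
#' marker keeps drifting.
#'
#' @param params a [selection_params()].
#' @param design an [experiment_design()].
#' @param seed optional integer seed for this replicate.
#' @param scheme fitness scheme, see [fitness_weights()].
#' @param experiment_id,replicate_id labels copied into the output.
#' @return data.frame with one row per sampled generation: `experiment_id`,
#'   `replicate_id`, `generation`, `n_alleles`, `sech_count`, `frequency`.
#' @export
#' @examples
#' run_replicate(selection_params(0.4, 0.5, 0), experiment_design(), seed = 1)
run_replicate <- function(params, design, seed = NULL, scheme = "standard",
                          experiment_id = "exp", replicate_id = "rep") {
  stopifnot(inherits(params, "selection_params"),
            inherits(design, "experiment_design"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_alleles_std <- 2L * (design$sample_males + design$sample_females)
  sched <- design$sample_generations
  obs <- vector("list", length(sched))

  pop <- founder_population(design)   # generation 0, selection skipped
  frozen <- NA_real_
  for (g in seq_len(design$n_generations)) {
    if (is.na(frozen)) {
      pop <- reproduce(pop, params, design)
      surv <- tryCatch(viability_selection(pop, params, scheme),
                       extinction_error = function(e) {
                         s <- e$survivors
                         f <- if (!is.null(s) && (nrow(s$males) + nrow(s$females)) > 0) {
                           marker_frequency(s)
                         } else {
                           marker_frequency(pop)  # last living flies
                         }
                         frozen <<- f
                         NULL
                       })
      if (!is.null(surv)) pop <- surv
    }
    if (g %in% sched) {
      k <- match(g, sched)
      if (is.na(frozen)) {
        smp <- tryCatch(sample_marker_frequency(pop, design),
                        insufficient_survivors_error = function(e) {
                          frozen <<- marker_frequency(pop)
                          NULL
                        })
        if (!is.null(smp)) {
          obs[[k]] <- smp$observation
          pop <- smp$population
        }
      }
      if (!is.na(frozen)) {
        obs[[k]] <- data.frame(generation = g,
                               n_alleles = n_alleles_std,
                               sech_count = as.integer(round(frozen * n_alleles_std)),
                               frequency = frozen)
      }
    }
    if (!is.na(frozen) && g >= max(sched)) break
  }
  out <- do.call(rbind, obs)
  cbind(data.frame(experiment_id = experiment_id, replicate_id = replicate_id),
        out, row.names = NULL)
}

# Female/male gamete distribution matrices: 16 ordered genotypes (maternal
# haplotype index i, paternal j; haplotypes indexed 1..4 = code + 1) by 4
# haplotypes. Shared with the batch engine.
HAP_MARKER <- c(0L, 0L, 1L, 1L)
HAP_FITNESS <- c(0L, 1L, 0L, 1L)

gamete_matrices <- function(c_rec) {
  Gf <- matrix(0, 16, 4)
  Gm <- matrix(0, 16, 4)
  for (i in 1:4) {
    for (j in 1:4) {
      g <- (i - 1L) * 4L + j
      Gm[g, i] <- Gm[g, i] + 0.5
      Gm[g, j] <- Gm[g, j] + 0.5
      r1 <- 2L * HAP_MARKER[i] + HAP_FITNESS[j] + 1L
      r2 <- 2L * HAP_MARKER[j] + HAP_FITNESS[i] + 1L
      Gf[g, i] <- Gf[g, i] + (1 - c_rec) / 2
      Gf[g, j] <- Gf[g, j] + (1 - c_rec) / 2
      Gf[g, r1] <- Gf[g, r1] + c_rec / 2
      Gf[g, r2] <- Gf[g, r2] + c_rec / 2
    }
  }
  list(female = Gf, male = Gm)
}

genotype_weights16 <- function(params, scheme) {
  w <- fitness_weights(params, scheme)
  i <- rep(1:4, each = 4)
  j <- rep(1:4, times = 4)
  list(w = w[HAP_FITNESS[i] + HAP_FITNESS[j] + 1L],
       sech_marker = HAP_MARKER[i] + HAP_MARKER[j])
}

#' Deterministic infinite-population trajectory (testing oracle)
#'
#' Iterates the exact expectation dynamics of the simulator in the
#' infinite-census limit: a 16-cell joint distribution over ordered
#' (maternal, paternal) haplotype pairs, with viability selection, female-only
#' recombination at `c`, and random union of gametes. The reported frequency at
#' generation `g >= 1` is the post-selection *sechellia* marker frequency (the
#' quantity the destructive samples estimate); generation 0 reports `p0`.
#'
#' For `p0 = 0.5` the founder is the simulator's exact founder (every
#' individual a coupling double heterozygote). For other `p0` no founder is
#' defined by the experiment, so coupling haplotypes at frequency `p0` are
#' paired independently.
#'
#' With `c = 0` this reduces to the classical single-locus recursion
#' `q' = (q^2 (1-s) + p q (1-hs)) / (p^2 + 2 p q (1-hs) + q^2 (1-s))`.
#'
#' @param params a [selection_params()].
#' @param p0 initial *sechellia* frequency in `[0, 1]`.
#' @param n_generations number of generations.
#' @param scheme fitness scheme, see [fitness_weights()].
#' @return data.frame with columns `generation` (0..n) and `frequency`.
#' @export
#' @examples
#' # q' = 0.4375 after one generation at s = 0.4, h = 0.5, c = 0
#' expected_trajectory(selection_params(0.4, 0.5, 0), 0.5, 1)
expected_trajectory <- function(params, p0 = 0.5, n_generations = 20,
                                scheme = "standard") {
  stopifnot(inherits(params, "selection_params"))
  stopifnot_proportion(p0, "p0")
  G <- gamete_matrices(params$c)
  gw <- genotype_weights16(params, scheme)

  geno <- numeric(16)
  if (isTRUE(all.equal(p0, 0.5))) {
    geno[(4L - 1L) * 4L + 1L] <- 1   # all (sech-coupling, sim-coupling)
  } else {
    u <- c(1 - p0, 0, 0, p0)
    # outer(u, u)[i, j]: maternal i, paternal j; flatten row-major so the
    # linear index (i-1)*4 + j matches gamete_matrices()
    geno <- as.numeric(t(outer(u, u)))
  }

  freq <- numeric(n_generations + 1)
  freq[1] <- p0
  for (g in seq_len(n_generations)) {
    # gamete pools from current (post-selection) adults
    u <- as.numeric(geno %*% G$female)
    v <- as.numeric(geno %*% G$male)
    pre <- as.numeric(t(outer(u, v)))          # offspring genotype dist
    post <- pre * gw$w
    tot <- sum(post)
    if (tot <= 0) {                            # total extinction: absorb
      freq[(g + 1):(n_generations + 1)] <- freq[g]
      return(data.frame(generation = 0:n_generations, frequency = freq))
    }
    geno <- post / tot
    freq[g + 1] <- sum(geno * gw$sech_marker) / 2
  }
  data.frame(generation = 0:n_generations, frequency = freq)
}
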