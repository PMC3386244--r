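# Batched replicate engine.
#
# Individuals of the same sex and ordered (maternal, paternal) haplotype pair
# are exchangeable, so a replicate's state reduces without approximation to two
# 16-cell genotype count vectors (one per sex). Viability selection is then
# binomial thinning per cell, reproduction a multinomial draw over the 16
# offspring genotypes (product of the maternal and paternal gamete pools), and
# destructive sampling a multivariate hypergeometric draw. All replicates of a
# grid cell advance together as rows of count matrices, which is what makes the
# 10,000-iteration distributions and the full grid fit tractable in R. The
# individual-based path (run_replicate) realises the same process one fly at a
# time; the two are cross-checked in the test suite.

# Row-wise multinomial: one draw of `size` items per row of probability matrix
# P, by sequential binomial conditioning. Rows with zero total mass leave all
# counts in no category (they are handled by the caller's freeze logic).
rmultinom_rows <- function(size, P) {
  n <- nrow(P)
  K <- ncol(P)
  tail <- P
  for (k in (K - 1):1) tail[, k] <- tail[, k] + tail[, k + 1]
  out <- matrix(0L, n, K)
  rem <- rep.int(as.integer(size), n)
  for (k in seq_len(K - 1)) {
    pk <- P[, k] / tail[, k]
    pk[!is.finite(pk)] <- 0
    pk <- pmin(pmax(pk, 0), 1)
    x <- stats::rbinom(n, rem, pk)
    out[, k] <- x
    rem <- rem - x
  }
  out[, K] <- rem
  out
}

# Row-wise multivariate hypergeometric: draw `k` individuals without
# replacement from each row of count matrix C. Caller guarantees k <= rowSums.
rhyper_rows <- function(k, C) {
  n <- nrow(C)
  K <- ncol(C)
  out <- matrix(0L, n, K)
  pool <- rowSums(C)
  rem <- rep.int(as.integer(k), n)
  for (j in seq_len(K - 1)) {
    x <- stats::rhyper(n, C[, j], pool - C[, j], rem)
    out[, j] <- x
    rem <- rem - x
    pool <- pool - C[, j]
  }
  out[, K] <- rem
  out
}

rbinom_mat <- function(C, w16) {
  matrix(stats::rbinom(length(C), as.vector(C), rep(w16, each = nrow(C))),
         nrow = nrow(C))
}

#' Simulate sampled marker frequencies for many replicates at once
#'
#' Runs `n_iterations` independent replicates of the competition experiment
#' under one parameter set and returns the *sechellia* marker frequency of the
#' destructive sample at each scheduled generation. Distributionally identical
#' to looping [run_replicate()], but advances all replicates together on
#' exchangeable genotype counts, which is orders of magnitude faster.
#'
#' @param params a [selection_params()].
#' @param design an [experiment_design()].
#' @param n_iterations number of replicates.
#' @param scheme fitness scheme, see [fitness_weights()].
#' @return numeric matrix `n_iterations` x `length(design$sample_generations)`,
#'   columns named `gen<g>`; entries are multiples of
#'   `1 / (2 * (sample_males + sample_females))` except for frozen terminal
#'   states.
#' @export
#' @examples
#' f <- simulate_sampled_frequencies(selection_params(0, 0.5, 0),
#'                                   experiment_design(), 200)
#' colMeans(f)   # ~0.5 at every generation under neutrality
simulate_sampled_frequencies <- function(params, design, n_iterations,
                                         scheme = "standard") {
  stopifnot(inherits(params, "selection_params"),
            inherits(design, "experiment_design"))
  if (!is_count(n_iterations) || n_iterations < 1) {
    abort("`n_iterations` must be a positive integer", "validation_error")
  }
  n <- as.integer(n_iterations)
  G <- gamete_matrices(params$c)
  gw <- genotype_weights16(params, scheme)
  nm <- design$n_males
  nf <- design$n_females
  sm <- design$sample_males
  sf <- design$sample_females
  sched <- design$sample_generations
  n_sample <- sm + sf
  mk16 <- matrix(gw$sech_marker, ncol = 1)

  out <- matrix(NA_real_, n, length(sched),
                dimnames = list(NULL, paste0("gen", sched)))
  # founder: all (sech-coupling maternal, sim-coupling paternal) = cell 13
  Fc <- matrix(0L, n, 16)
  Mc <- matrix(0L, n, 16)
  Fc[, 13] <- nf
  Mc[, 13] <- nm
  frozen <- rep(FALSE, n)
  freeze_freq <- rep(NA_real_, n)
  dummy_pool <- c(1, 0, 0, 0)

  for (g in seq_len(design$n_generations)) {
    # gamete pools of the current parents
    pf <- (Fc %*% G$female) / rowSums(Fc)
    pm <- (Mc %*% G$male) / rowSums(Mc)
    if (any(frozen)) {
      nz <- sum(frozen)
      pf[frozen, ] <- rep(dummy_pool, each = nz)
      pm[frozen, ] <- rep(dummy_pool, each = nz)
    }
    P <- matrix(0, n, 16)
    for (i in 1:4) {
      for (j in 1:4) P[, (i - 1L) * 4L + j] <- pf[, i] * pm[, j]
    }
    newM <- rmultinom_rows(nm, P)
    newF <- rmultinom_rows(nf, P)
    Ms <- rbinom_mat(newM, gw$w)
    Fs <- rbinom_mat(newF, gw$w)
    tms <- rowSums(Ms)
    tfs <- rowSums(Fs)

    newly <- !frozen & (tms == 0L | tfs == 0L)
    if (any(newly)) {
      surv_mk <- as.numeric((Ms[newly, , drop = FALSE] +
                               Fs[newly, , drop = FALSE]) %*% mk16)
      tot <- tms[newly] + tfs[newly]
      pre_mk <- as.numeric((newM[newly, , drop = FALSE] +
                              newF[newly, , drop = FALSE]) %*% mk16)
      freeze_freq[newly] <- ifelse(tot > 0, surv_mk / (2 * tot),
                                   pre_mk / (2 * (nm + nf)))
      frozen[newly] <- TRUE
    }

    if (g %in% sched) {
      k <- match(g, sched)
      insuf <- !frozen & (tms <= sm | tfs <= sf)
      if (any(insuf)) {
        mk <- as.numeric((Ms[insuf, , drop = FALSE] +
                            Fs[insuf, , drop = FALSE]) %*% mk16)
        freeze_freq[insuf] <- mk / (2 * (tms + tfs)[insuf])
        frozen[insuf] <- TRUE
      }
      freq <- freeze_freq
      act <- !frozen
      if (any(act)) {
        smpF <- rhyper_rows(sf, Fs[act, , drop = FALSE])
        smpM <- rhyper_rows(sm, Ms[act, , drop = FALSE])
        cnt <- as.numeric((smpF + smpM) %*% mk16)
        freq[act] <- cnt / (2 * n_sample)
        Fs[act, ] <- Fs[act, , drop = FALSE] - smpF
        Ms[act, ] <- Ms[act, , drop = FALSE] - smpM
      }
      out[, k] <- freq
    }

    Mc <- Ms
    Fc <- Fs
    if (any(frozen)) {
      # park a valid monomorphic dummy population in frozen rows; their
      # recorded frequency comes from freeze_freq, never from these counts
      Mc[frozen, ] <- 0L
      Fc[frozen, ] <- 0L
      Mc[frozen, 1] <- nm
      Fc[frozen, 1] <- nf
    }
  }
  out
}
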