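# Table-level statistics of the wet-lab assays: mating-success shares and sign
# test, fertility summaries, linkage-disequilibrium permutation test, and the
# single- vs double-introgression comparison.

#' Introgression mating-share decomposition
#'
#' From mating counts of a multiple-choice cage assay (S = wild-type
#' *simulans*, I = introgression line; `n_si` = *simulans* female x
#' introgression male, etc.), computes the share of mating participants that
#' came from the introgression line, overall and per sex:
#' * overall = `(n_si + n_is + 2 n_ii) / (2 n_total)`
#' * female  = `(n_is + n_ii) / n_total`
#' * male    = `(n_si + n_ii) / n_total`
#'
#' Overall is always the mean of the two sex shares. Values are returned in
#' full precision; round only for reporting (the printed tables round half-up
#' to 2 decimals, see [round_half_up()]).
#'
#' @param counts data.frame with columns `n_ss`, `n_si`, `n_is`, `n_ii` (one
#'   row per line; extra columns such as `line` are carried through).
#' @return data.frame with the input identifiers plus `n_total`, `overall`,
#'   `female`, `male`.
#' @export
#' @examples
#' mating_shares(data.frame(line = "78P", n_ss = 38, n_si = 19,
#'                          n_is = 34, n_ii = 29))
mating_shares <- function(counts) {
  need <- c("n_ss", "n_si", "n_is", "n_ii")
  if (!all(need %in% names(counts))) {
    abort("`counts` needs columns n_ss, n_si, n_is, n_ii", "missing_column_error")
  }
  k <- counts[need]
  if (any(as.matrix(k) < 0) || anyNA(k)) {
    abort("mating counts must be non-negative", "value_range_error")
  }
  n_total <- rowSums(k)
  if (any(n_total == 0)) abort("mating table with zero total", "validation_error")
  id <- counts[setdiff(names(counts), need)]
  out <- data.frame(id,
                    n_total = n_total,
                    overall = (k$n_si + k$n_is + 2 * k$n_ii) / (2 * n_total),
                    female = (k$n_is + k$n_ii) / n_total,
                    male = (k$n_si + k$n_ii) / n_total)
  rownames(out) <- NULL
  out
}

#' Aggregate mating shares across lines
#'
#' Unweighted arithmetic means across lines (the printed averages match
#' unweighted means, not totals pooled over cages), the number of lines whose
#' overall introgression share falls below 1/2, and the wild-type minus
#' introgression differential per sex.
#'
#' @param counts data.frame of per-line mating counts (see [mating_shares()]).
#' @return list with `shares` (per-line shares), `mean_overall`, `mean_female`,
#'   `mean_male`, `n_lines`, `lines_below_half`, and `differential` (named
#'   vector: overall/female/male wild-type-minus-introgression share
#'   difference).
#' @export
aggregate_mating <- function(counts) {
  shares <- mating_shares(counts)
  if (nrow(shares) < 1) abort("need at least one line", "validation_error")
  m <- c(overall = mean(shares$overall), female = mean(shares$female),
         male = mean(shares$male))
  list(shares = shares,
       mean_overall = m[["overall"]],
       mean_female = m[["female"]],
       mean_male = m[["male"]],
       n_lines = nrow(shares),
       lines_below_half = sum(shares$overall < 0.5),
       differential = (1 - m) - m)
}

#' One-tailed sign test
#'
#' Exact binomial upper-tail probability `P(X >= k_below)` for
#' `X ~ Binomial(n, 1/2)`: the probability of seeing at least this many lines
#' below a 50% share if introgression and wild-type genotypes mated at random.
#'
#' @param k_below number of lines below the null share.
#' @param n number of lines tested.
#' @return the one-tailed p-value.
#' @export
#' @examples
#' sign_test_one_tailed(6, 8) # 37/256 ~= 0.14
sign_test_one_tailed <- function(k_below, n) {
  if (!is_count(k_below) || !is_count(n) || k_below < 0 || k_below > n) {
    abort("need 0 <= k_below <= n, both integers", "validation_error")
  }
  stats::pbinom(k_below - 1, n, 0.5, lower.tail = FALSE)
}

#' Summarise fertility assays
#'
#' Accepts either replicate-level records (columns `line`, `progeny`: total
#' progeny of three pairs of flies per replicate vial) or a pre-summarised
#' table of per-line means (columns `line`, `mean`, with `NA` for lines that
#' were lost before testing). Returns per-line means +/- standard errors, the
#' grand mean (unweighted mean of per-line means, missing lines excluded), and
#' for replicate input the one-way ANOVA F for line differences.
#'
#' @param x data.frame of records or of line means; an optional logical/char
#'   column `role` marks non-introgression lines (e.g. the wild-type strain),
#'   which are excluded from the grand mean.
#' @return list with `per_line` (data.frame `line`, `n`, `mean`, `se`),
#'   `grand_mean`, and `anova` (list `f`, `df`, `p`; `NULL` for means input).
#' @export
fertility_summary <- function(x) {
  if (!"line" %in% names(x)) abort("`x` needs a `line` column", "missing_column_error")
  intro <- if ("role" %in% names(x)) x$role %in% c("introgression", NA) else rep(TRUE, nrow(x))
  if ("progeny" %in% names(x)) {
    if (any(x$progeny < 0, na.rm = TRUE)) {
      abort("progeny counts must be non-negative", "value_range_error")
    }
    xr <- x[!is.na(x$progeny), , drop = FALSE]
    if (nrow(xr) == 0) abort("no usable fertility records", "validation_error")
    spl <- split(xr$progeny, xr$line)
    per_line <- data.frame(
      line = names(spl),
      n = vapply(spl, length, integer(1)),
      mean = vapply(spl, mean, numeric(1)),
      se = vapply(spl, function(v) {
        if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
      }, numeric(1)),
      row.names = NULL)
    anova_res <- NULL
    if (length(spl) >= 2 && nrow(xr) > length(spl)) {
      fit <- stats::oneway.test(progeny ~ line, data = xr, var.equal = TRUE)
      anova_res <- list(f = unname(fit$statistic), df = unname(fit$parameter),
                        p = fit$p.value)
    }
    intro_lines <- unique(x$line[intro])
  } else if ("mean" %in% names(x)) {
    per_line <- data.frame(line = x$line, n = NA_integer_, mean = x$mean,
                           se = if ("se" %in% names(x)) x$se else NA_real_)
    anova_res <- NULL
    intro_lines <- x$line[intro]
  } else {
    abort("`x` needs a `progeny` (records) or `mean` (summary) column",
          "missing_column_error")
  }
  keep <- per_line$line %in% intro_lines & !is.na(per_line$mean)
  if (!any(keep)) abort("no non-missing lines for the grand mean", "validation_error")
  list(per_line = per_line,
       grand_mean = mean(per_line$mean[keep]),
       anova = anova_res)
}

# log multivariate-hypergeometric (Fisher) probability of a contingency table
# given its margins
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Permutation test for genotypic linkage disequilibrium
#'
#' Tests whether genotypes at one marker assort independently of genotypes at a
#' second marker, from a 3 x 3 table of joint one-locus genotype counts
#' (*sechellia* homozygote / heterozygote / *simulans* homozygote at each
#' marker). The test statistic is the conditional (Fisher) probability of the
#' table given its margins; the null distribution is generated by shuffling one
#' locus's genotype labels across individuals, which preserves both margins.
#' The p-value is the proportion of permuted tables at most as probable as the
#' observed one, with the +1 correction `(k + 1) / (n + 1)` standard for
#' Monte-Carlo tests. This replaces the Markov-chain exact test of the original
#' analysis; its `dememorization`/`batches`/`iterations` knobs map onto
#' `n_permutations`.
#'
#' @param tab 3 x 3 matrix (or table) of joint genotype counts.
#' @param n_permutations number of label permutations.
#' @param seed optional integer seed (same seed, same p).
#' @return list with `p_value`, `log_prob_observed`, `n_permutations`.
#' @export
ld_permutation_test <- function(tab, n_permutations = 2000, seed = NULL) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(3, 3)) || any(tab < 0) || sum(tab) == 0) {
    abort("`tab` must be a 3x3 matrix of non-negative counts with positive total",
          "validation_error")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx <- which(tab > 0, arr.ind = TRUE)
  a <- rep(idx[, 1], tab[idx])   # locus-1 genotype per individual
  b <- rep(idx[, 2], tab[idx])   # locus-2 genotype per individual
  obs <- log_table_prob(tab)
  hits <- 0L
  for (i in seq_len(n_permutations)) {
    bp <- b[sample.int(length(b))]
    perm <- matrix(tabulate((a - 1L) * 3L + bp, nbins = 9L), 3, 3, byrow = TRUE)
    if (log_table_prob(perm) <= obs + 1e-9) hits <- hits + 1L
  }
  list(p_value = (hits + 1) / (n_permutations + 1),
       log_prob_observed = obs,
       n_permutations = as.integer(n_permutations))
}

#' Compare marker frequencies between two experiment groups
#'
#' Standard one-way (two-group, equal-variance) comparison of replicate marker
#' frequencies, as used to contrast single- against double-introgression
#' experiments at a sampled generation.
#'
#' @param group_a,group_b numeric vectors of replicate frequencies (each of
#'   length >= 2 and not all constant across both groups).
#' @return list with `mean_a`, `mean_b`, `difference` (a - b), `f_statistic`,
#'   `df`, `p_value`.
#' @export
compare_single_double <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2 ||
      anyNA(group_a) || anyNA(group_b)) {
    abort("each group needs >= 2 non-missing values", "validation_error")
  }
  vals <- c(group_a, group_b)
  grp <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  if (stats::var(vals) == 0) {
    f <- 0; p <- 1; df <- c(1, length(vals) - 2)
  } else {
    fit <- stats::oneway.test(vals ~ grp, var.equal = TRUE)
    f <- unname(fit$statistic); p <- fit$p.value; df <- unname(fit$parameter)
  }
  list(mean_a = mean(group_a), mean_b = mean(group_b),
       difference = mean(group_a) - mean(group_b),
       f_statistic = f, df = df, p_value = p)
}
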