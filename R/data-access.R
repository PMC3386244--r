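# Accessors for the empirical tables shipped with the package. These are the
# published summary tables of the simulans/sechellia introgression competition
# study: per-line mating counts from the multiple-choice cage assays, per-line
# fertility means from the vial assays, and the per-marker maximum-likelihood
# estimates of (c, s) at each dominance level.

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "introgressim")
  if (!nzchar(p)) abort(sprintf("bundled data file %s not found", file),
                        "validation_error")
  p
}

#' Published mating counts of the introgression-line cage assays
#'
#' Counts of copulating pairs by type for the eight introgression lines tested
#' against the wild-type *D. simulans* strain (the ninth line, 25H, was lost
#' before testing). Columns `n_ss`, `n_si`, `n_is`, `n_ii` follow the
#' female-type x male-type convention of [mating_shares()].
#'
#' @return data.frame with one row per line.
#' @export
#' @examples
#' aggregate_mating(mating_counts())$mean_overall # ~0.47
mating_counts <- function() {
  utils::read.csv(extdata_path("mating_counts.csv"), stringsAsFactors = FALSE)
}

#' Published per-line fertility means
#'
#' Mean total progeny (three pairs of flies, 15 days, 10 replicate vials) with
#' standard errors, for the wild-type strain and the introgression lines; the
#' lost line 25H carries `NA`.
#'
#' @return data.frame with columns `line`, `role`, `mean`, `se`,
#'   `n_replicates`.
#' @export
fertility_line_means <- function() {
  utils::read.csv(extdata_path("fertility_line_means.csv"),
                  stringsAsFactors = FALSE)
}

#' Published per-marker maximum likelihood estimates
#'
#' MLEs of the recombination fraction `c` and selection coefficient `s` for
#' each of the nine tracked microsatellite markers at each of the four
#' dominance levels, read off the original likelihood surfaces. Printed zeros
#' correspond to the near-zero part of the fitting grid (c <= 0.01).
#'
#' @return long data.frame with columns `marker`, `h`, `c`, `s` (36 rows).
#' @export
#' @examples
#' summarize_mle_table(mle_estimates())
mle_estimates <- function() {
  utils::read.csv(extdata_path("mle_estimates.csv"), stringsAsFactors = FALSE)
}
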