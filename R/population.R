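# Individual-based population representation and the per-generation operations:
# founding, viability selection, gamete formation, reproduction, sampling.
#
# Internally a haplotype is an integer code 0..3 = 2*marker + fitness, with
# allele 0 = simulans, 1 = sechellia at each locus. A sex's individuals are the
# rows of an n x 2 integer matrix of (haplotype_1, haplotype_2) codes. This
# keeps the per-generation operations vectorised while the exported
# haplotype()/individual() constructors provide the record-level view.

SPECIES_ALLELES <- c("sim", "sech")

hap_code <- function(marker, fitness) 2L * marker + fitness
hap_marker <- function(code) code %/% 2L
hap_fitness <- function(code) code %% 2L

#' Construct a two-locus haplotype
#'
#' @param marker,fitness allele at the marker / fitness locus: `"sim"` or
#'   `"sech"`.
#' @return object of class `haplotype` with fields `marker`, `fitness` and the
#'   internal integer `code`.
#' @export
#' @examples
#' haplotype("sech", "sech")  # sechellia coupling haplotype
haplotype <- function(marker, fitness) {
  marker <- match.arg(marker, SPECIES_ALLELES)
  fitness <- match.arg(fitness, SPECIES_ALLELES)
  structure(list(marker = marker, fitness = fitness,
                 code = hap_code(match(marker, SPECIES_ALLELES) - 1L,
                                 match(fitness, SPECIES_ALLELES) - 1L)),
            class = "haplotype")
}

hap_from_code <- function(code) {
  structure(list(marker = SPECIES_ALLELES[hap_marker(code) + 1L],
                 fitness = SPECIES_ALLELES[hap_fitness(code) + 1L],
                 code = as.integer(code)),
            class = "haplotype")
}

#' @export
print.haplotype <- function(x, ...) {
  cat(sprintf("<haplotype> marker = %s, fitness = %s\n", x$marker, x$fitness))
  invisible(x)
}

#' Construct a diploid individual
#'
#' @param hap1,hap2 [haplotype()] objects.
#' @param sex `"male"` or `"female"`.
#' @return object of class `individual`.
#' @export
individual <- function(hap1, hap2, sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (!inherits(hap1, "haplotype") || !inherits(hap2, "haplotype")) {
    abort("`hap1` and `hap2` must be haplotype objects", "validation_error")
  }
  structure(list(haplotype_1 = hap1, haplotype_2 = hap2, sex = sex),
            class = "individual")
}

#' @export
print.individual <- function(x, ...) {
  cat(sprintf("<individual> %s: %s-%s / %s-%s\n", x$sex,
              x$haplotype_1$marker, x$haplotype_1$fitness,
              x$haplotype_2$marker, x$haplotype_2$fitness))
  invisible(x)
}

new_population <- function(males, females, generation) {
  structure(list(males = males, females = females,
                 generation = as.integer(generation)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> generation %d: %d males, %d females; sech marker frequency %.4f\n",
              x$generation, nrow(x$males), nrow(x$females), marker_frequency(x)))
  invisible(x)
}

#' Found a generation-0 competition population
#'
#' Every founder is a coupling-phase double heterozygote (one
#' sechellia-marker/sechellia-fitness haplotype and one simulans/simulans
#' haplotype), the genotype of the F1 flies that seeded the experimental
#' bottles. The marker allele frequency is therefore exactly 0.5 and no
#' repulsion haplotypes exist at generation 0.
#'
#' @param design an [experiment_design()].
#' @return a `population` at generation 0 with `n_males + n_females`
#'   individuals.
#' @export
#' @examples
#' marker_frequency(founder_population(experiment_design())) # exactly 0.5
founder_population <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  founder_row <- c(hap_code(1L, 1L), hap_code(0L, 0L)) # sech coupling / sim coupling
  males <- matrix(founder_row, nrow = design$n_males, ncol = 2, byrow = TRUE)
  females <- matrix(founder_row, nrow = design$n_females, ncol = 2, byrow = TRUE)
  new_population(males, females, 0L)
}

#' Sechellia marker allele frequency of a population
#'
#' @param pop a `population`.
#' @return proportion of marker alleles that are *sechellia*, in `[0, 1]`.
#' @export
marker_frequency <- function(pop) {
  H <- rbind(pop$males, pop$females)
  if (nrow(H) == 0) return(NA_real_)
  sum(hap_marker(H)) / (2 * nrow(H))
}

# Survival probability for each row of a haplotype-code matrix.
fitness_of_rows <- function(H, params, scheme = "standard") {
  w <- fitness_weights(params, scheme)
  n_sech <- hap_fitness(H[, 1L]) + hap_fitness(H[, 2L])
  unname(w[n_sech + 1L])
}

#' Survival probability of a single individual
#'
#' Viability depends only on the fitness-locus genotype: marker alleles are
#' neutral.
#'
#' @param ind an [individual()].
#' @param params a [selection_params()].
#' @param scheme fitness scheme, see [fitness_weights()].
#' @return survival probability in `[0, 1]`.
#' @export
#' @examples
#' het <- individual(haplotype("sech", "sech"), haplotype("sim", "sim"))
#' genotype_fitness(het, selection_params(s = 0.3, h = 1)) # 0.7
genotype_fitness <- function(ind, params, scheme = "standard") {
  stopifnot(inherits(ind, "individual"))
  H <- matrix(c(ind$haplotype_1$code, ind$haplotype_2$code), nrow = 1)
  fitness_of_rows(H, params, scheme)
}

#' Apply viability selection to a population
#'
#' Each individual survives independently with its genotype's survival
#' probability. The generation index is unchanged.
#'
#' @inheritParams genotype_fitness
#' @param pop a `population`.
#' @return the surviving `population`.
#' @section Errors: signals a condition of class `extinction_error` when either
#'   sex has zero survivors; the condition carries the partial survivors in its
#'   `survivors` field so callers can implement an absorbing terminal state.
#' @export
viability_selection <- function(pop, params, scheme = "standard") {
  stopifnot(inherits(pop, "population"))
  if (nrow(pop$males) == 0 && nrow(pop$females) == 0) {
    abort("population is empty", "validation_error")
  }
  keep_m <- stats::runif(nrow(pop$males)) < fitness_of_rows(pop$males, params, scheme)
  keep_f <- stats::runif(nrow(pop$females)) < fitness_of_rows(pop$females, params, scheme)
  surv <- new_population(pop$males[keep_m, , drop = FALSE],
                         pop$females[keep_f, , drop = FALSE],
                         pop$generation)
  if (nrow(surv$males) == 0 || nrow(surv$females) == 0) {
    abort_extinction(sprintf("sex extinct after selection at generation %d",
                             pop$generation),
                     survivors = surv)
  }
  surv
}

# Vectorised gamete formation: H is an n x 2 matrix of parental haplotype
# codes (one row per gamete needed); c_rec applies to every row (pass 0 for
# males). Recombinants take the marker from one parental haplotype and the
# fitness allele from the other.
gametes_from_parents <- function(H, c_rec) {
  n <- nrow(H)
  if (n == 0) return(integer(0))
  swap <- stats::runif(n) < 0.5
  first <- ifelse(swap, H[, 2L], H[, 1L])
  second <- ifelse(swap, H[, 1L], H[, 2L])
  rec <- if (c_rec > 0) stats::runif(n) < c_rec else rep(FALSE, n)
  as.integer(ifelse(rec, hap_code(hap_marker(first), hap_fitness(second)), first))
}

#' Draw one gamete from a parent
#'
#' Males are achiasmate: they transmit one intact haplotype with probability
#' 1/2 each regardless of `c`. Females recombine with probability `c`, in which
#' case each of the two recombinant haplotypes is transmitted with probability
#' 1/2; otherwise each parental haplotype is transmitted with probability 1/2.
#'
#' @param parent an [individual()].
#' @param c recombination fraction in `[0, 0.5]` (ignored for males).
#' @return a [haplotype()].
#' @export
make_gamete <- function(parent, c) {
  stopifnot(inherits(parent, "individual"))
  stopifnot_proportion(c, "c", upper = 0.5)
  c_eff <- if (parent$sex == "female") c else 0
  H <- matrix(c(parent$haplotype_1$code, parent$haplotype_2$code), nrow = 1)
  hap_from_code(gametes_from_parents(H, c_eff))
}

#' Random mating: produce the next censused generation
#'
#' Each offspring is formed independently by drawing a surviving mother and
#' father uniformly with replacement and taking one gamete from each (female
#' gametes recombine at rate `params$c`, male gametes never). Exactly
#' `design$n_males` male and `design$n_females` female offspring are produced
#' and the generation index is incremented. Selection is purely viability:
#' there are no lifetime pairs or fecundity differences.
#'
#' @param survivors a `population` of post-selection parents.
#' @param params a [selection_params()] (supplies the recombination fraction).
#' @param design an [experiment_design()].
#' @return the offspring `population`.
#' @section Errors: signals `extinction_error` if either sex has no survivors.
#' @export
reproduce <- function(survivors, params, design) {
  stopifnot(inherits(survivors, "population"))
  nm_par <- nrow(survivors$males)
  nf_par <- nrow(survivors$females)
  if (nm_par == 0 || nf_par == 0) {
    abort_extinction("cannot reproduce: a sex has no survivors",
                     survivors = survivors)
  }
  n_off <- design$n_males + design$n_females
  mothers <- survivors$females[sample.int(nf_par, n_off, replace = TRUE), , drop = FALSE]
  fathers <- survivors$males[sample.int(nm_par, n_off, replace = TRUE), , drop = FALSE]
  h_mat <- gametes_from_parents(mothers, params$c)
  h_pat <- gametes_from_parents(fathers, 0)
  off <- cbind(h_mat, h_pat)
  new_population(off[seq_len(design$n_males), , drop = FALSE],
                 off[design$n_males + seq_len(design$n_females), , drop = FALSE],
                 survivors$generation + 1L)
}

#' Destructively sample flies and record the marker frequency
#'
#' Removes `sample_males` + `sample_females` individuals uniformly without
#' replacement (the experimental samples were destructive: sampled flies were
#' genotyped, not returned to the bottle) and records the *sechellia* marker
#' allele count among them.
#'
#' @param pop a `population` (post-selection survivors).
#' @param design an [experiment_design()].
#' @return a list with `observation` (one-row data.frame: `generation`,
#'   `n_alleles`, `sech_count`, `frequency`) and `population` (the remaining
#'   individuals).
#' @section Errors: signals `insufficient_survivors_error` when either sex has
#'   no more individuals than its sample size (breeding would be impossible
#'   after removal).
#' @export
sample_marker_frequency <- function(pop, design) {
  stopifnot(inherits(pop, "population"))
  if (nrow(pop$males) <= design$sample_males ||
      nrow(pop$females) <= design$sample_females) {
    abort(sprintf("generation %d: survivors (%dM/%dF) insufficient for a %dM/%dF sample",
                  pop$generation, nrow(pop$males), nrow(pop$females),
                  design$sample_males, design$sample_females),
          "insufficient_survivors_error")
  }
  im <- sample.int(nrow(pop$males), design$sample_males)
  if_ <- sample.int(nrow(pop$females), design$sample_females)
  sampled <- rbind(pop$males[im, , drop = FALSE], pop$females[if_, , drop = FALSE])
  n_alleles <- 2L * nrow(sampled)
  sech <- sum(hap_marker(sampled))
  rest <- new_population(pop$males[-im, , drop = FALSE],
                         pop$females[-if_, , drop = FALSE],
                         pop$generation)
  list(observation = data.frame(generation = pop$generation,
                                n_alleles = n_alleles,
                                sech_count = as.integer(sech),
                                frequency = sech / n_alleles),
       population = rest)
}
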