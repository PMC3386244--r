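# Parameter objects: selection parameters, experimental design, fitting grid.

#' Selection parameters for an introgressed segment
#'
#' The model assumes a neutral microsatellite marker linked at recombination
#' fraction `c` (female meiosis only; Drosophila males are achiasmate) to a
#' single selected locus carrying a deleterious *D. sechellia* incompatibility
#' allele with selection coefficient `s` and dominance `h`.
#'
#' @param s selection coefficient against the *sechellia* fitness allele, in
#'   `[0, 1]`. The *sechellia* homozygote survives viability selection with
#'   probability `1 - s` (standard scheme).
#' @param h dominance of the deleterious effect, in `[0, 1]` (`0` recessive,
#'   `1` dominant). Heterozygote survival is `1 - h * s`.
#' @param c recombination fraction between marker and fitness locus per female
#'   meiosis, in `[0, 0.5]`.
#' @return an object of class `selection_params`.
#' @seealso [fitness_weights()] for the survival probabilities implied by a
#'   parameter set, [experiment_design()] for the demographic design.
#' @export
#' @examples
#' selection_params(s = 0.43, h = 0.5, c = 0)
selection_params <- function(s, h = 0.5, c = 0) {
  stopifnot_proportion(s, "s")
  stopifnot_proportion(h, "h")
  stopifnot_proportion(c, "c", upper = 0.5)
  structure(list(s = s, h = h, c = c), class = "selection_params")
}

#' @export
print.selection_params <- function(x, ...) {
  cat(sprintf("<selection_params> s = %g, h = %g, c = %g\n", x$s, x$h, x$c))
  invisible(x)
}

#' Demographic design of a competition experiment
#'
#' Defaults mirror the bottle experiments the simulator emulates: censuses of
#' 150 flies per sex per generation for 20 generations, destructive samples of
#' 20 males and 20 females taken after viability selection and before random
#' mating at generations 7, 14 and 20, and five replicate bottles per
#' experiment. The first sample generation is configurable because the real
#' bottles were sampled at generation 6 or 7.
#'
#' @param n_males,n_females census counts restored every generation.
#' @param n_generations number of generations simulated (founder is
#'   generation 0).
#' @param sample_generations increasing integer vector of generations at which
#'   destructive samples are taken (each in `1..n_generations`).
#' @param sample_males,sample_females flies removed per sex at each sampled
#'   generation.
#' @param n_replicates replicate bottles per experiment (used by the
#'   synthetic-data generator).
#' @return an object of class `experiment_design`.
#' @export
#' @examples
#' experiment_design()                       # the default bottle design
#' experiment_design(sample_generations = c(6, 14, 20))
experiment_design <- function(n_males = 150, n_females = 150,
                              n_generations = 20,
                              sample_generations = c(7, 14, 20),
                              sample_males = 20, sample_females = 20,
                              n_replicates = 5) {
  for (nm in c("n_males", "n_females", "n_generations",
               "sample_males", "sample_females", "n_replicates")) {
    v <- get(nm)
    if (!is_count(v) || v < 1) {
      abort(sprintf("`%s` must be a positive integer, got %s", nm, deparse(v)),
            "validation_error")
    }
  }
  sg <- as.integer(sample_generations)
  if (length(sg) < 1 || anyNA(sg) || any(sg < 1) || is.unsorted(sg, strictly = TRUE)) {
    abort("`sample_generations` must be a strictly increasing vector of generations >= 1",
          "validation_error")
  }
  if (max(sg) > n_generations) {
    abort("max(sample_generations) must not exceed n_generations", "validation_error")
  }
  if (sample_males > n_males || sample_females > n_females) {
    abort("sample sizes must not exceed census sizes", "validation_error")
  }
  structure(list(n_males = as.integer(n_males), n_females = as.integer(n_females),
                 n_generations = as.integer(n_generations),
                 sample_generations = sg,
                 sample_males = as.integer(sample_males),
                 sample_females = as.integer(sample_females),
                 n_replicates = as.integer(n_replicates)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment_design> %d males + %d females, %d generations\n  samples: %d M + %d F at generations %s; %d replicates\n",
    x$n_males, x$n_females, x$n_generations, x$sample_males, x$sample_females,
    paste(x$sample_generations, collapse = ", "), x$n_replicates))
  invisible(x)
}

#' Parameter grid for maximum-likelihood fitting
#'
#' Defaults are the grid used in the original analysis: eight recombination
#' fractions spanning complete linkage (1e-4) to free recombination (0.5),
#' nine selection coefficients 0.1..0.9, and four dominance levels.
#'
#' @param c_values,s_values,h_values numeric vectors of grid values; all must
#'   lie within the bounds enforced by [selection_params()].
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(c_values = c(0.0001, 0.001, 0.01, 0.1, 0.2, 0.3, 0.4, 0.5),
                      s_values = seq(0.1, 0.9, by = 0.1),
                      h_values = c(0, 0.5, 0.9, 1)) {
  if (length(c_values) < 1 || length(s_values) < 1 || length(h_values) < 1) {
    abort("grid value vectors must be non-empty", "validation_error")
  }
  if (any(c_values < 0 | c_values > 0.5)) {
    abort("all c_values must lie in [0, 0.5]", "validation_error")
  }
  if (any(s_values < 0 | s_values > 1) || any(h_values < 0 | h_values > 1)) {
    abort("s_values and h_values must lie in [0, 1]", "validation_error")
  }
  structure(list(c_values = sort(as.numeric(c_values)),
                 s_values = sort(as.numeric(s_values)),
                 h_values = sort(as.numeric(h_values))),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec>\n")
  cat("  c:", paste(x$c_values, collapse = ", "), "\n")
  cat("  s:", paste(x$s_values, collapse = ", "), "\n")
  cat("  h:", paste(x$h_values, collapse = ", "), "\n")
  invisible(x)
}

#' Genotype survival probabilities implied by a parameter set
#'
#' Returns the viability of individuals carrying 0, 1 or 2 copies of the
#' *sechellia* allele at the fitness locus. The `"standard"` scheme is
#' `(1, 1 - h*s, 1 - s)`. The `"literal"` scheme `(1, h*s, s)` reproduces the
#' original description verbatim; it is retained only as a configuration
#' switch because it contradicts the stated meaning of `s` and `h` (under it,
#' larger `s` means weaker selection and `h = 0` is lethal to heterozygotes).
#'
#' @param params a [selection_params()] object.
#' @param scheme `"standard"` (default) or `"literal"`.
#' @return numeric vector of length 3: survival probability for 0, 1, 2
#'   *sechellia* fitness alleles.
#' @export
#' @examples
#' fitness_weights(selection_params(s = 0.3, h = 1)) # 1.0 0.7 0.7
fitness_weights <- function(params, scheme = c("standard", "literal")) {
  scheme <- match.arg(scheme)
  w <- switch(scheme,
              standard = c(1, 1 - params$h * params$s, 1 - params$s),
              literal  = c(1, params$h * params$s, params$s))
  names(w) <- c("sim/sim", "het", "sech/sech")
  w
}
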