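# Synthetic-data generators: every empirical input the pipeline consumes can be
# produced under known ground truth, so each downstream stage is testable
# without any external data.

#' Specify a synthetic competition study
#'
#' A study is a set of competition experiments, each with a true parameter set,
#' a demographic design and a single/double-introgression label. The default
#' emulates the original study's structure: six experiments (three single-,
#' three double-introgression) of five replicate bottles each, marker frequency
#' starting at 0.5, samples at generations 7, 14 and 20, and true parameters at
#' the study-level average estimates (s = 0.43, h = 0.5, c ~ 0).
#'
#' @param experiments list of experiments, each a list with `experiment_id`,
#'   `params` ([selection_params()]), `design` ([experiment_design()]) and
#'   `label` (`"single"` or `"double"`).
#' @param seed global integer seed; replicate `i` of the study (counting across
#'   experiments) is simulated with seed `seed + i`.
#' @return object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(experiments = default_experiments(), seed = 1) {
  if (length(experiments) < 1) abort("need at least one experiment", "validation_error")
  for (e in experiments) {
    if (!all(c("experiment_id", "params", "design", "label") %in% names(e)) ||
        !inherits(e$params, "selection_params") ||
        !inherits(e$design, "experiment_design") ||
        !e$label %in% c("single", "double")) {
      abort("each experiment needs experiment_id, params, design, label ('single'/'double')",
            "validation_error")
    }
  }
  if (!is_count(seed)) abort("`seed` must be an integer", "validation_error")
  structure(list(experiments = experiments, seed = as.integer(seed)),
            class = "synthetic_study_spec")
}

#' @rdname synthetic_study_spec
#' @export
default_experiments <- function() {
  ids <- c("A", "B", "C", "D", "E", "F")
  labels <- rep(c("single", "double"), each = 3)
  lapply(seq_along(ids), function(i) {
    list(experiment_id = ids[i],
         params = selection_params(s = 0.43, h = 0.5, c = 0.0001),
         design = experiment_design(),
         label = labels[i])
  })
}

#' Generate replicate marker-frequency trajectories for a study
#'
#' Reuses the individual-based simulator as the generator: each experiment's
#' replicates are independent [run_replicate()] runs at that experiment's true
#' parameters, with deterministic per-replicate seeds `spec$seed + i`.
#'
#' @param spec a [synthetic_study_spec()].
#' @param scheme fitness scheme, see [fitness_weights()].
#' @return data.frame in the trajectory schema: `experiment_id`,
#'   `replicate_id`, `generation`, `n_alleles`, `sech_count`, `frequency`,
#'   plus a `label` column.
#' @export
generate_marker_dataset <- function(spec, scheme = "standard") {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  counter <- 0L
  rows <- lapply(spec$experiments, function(e) {
    reps <- lapply(seq_len(e$design$n_replicates), function(r) {
      counter <<- counter + 1L
      df <- run_replicate(e$params, e$design, seed = spec$seed + counter,
                          scheme = scheme,
                          experiment_id = e$experiment_id,
                          replicate_id = paste0("rep", r))
      df$label <- e$label
      df
    })
    do.call(rbind, reps)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Specify a synthetic mating assay
#'
#' Pair-type probabilities are proportional to (female-type success) x
#' (male-type success) relative to wild-type, and a fixed total number of
#' matings is drawn multinomially over the four pair types. The 1-hour /
#' 60-matings-per-cage stopping rule of the real assay is modelled as this
#' fixed total (default 120 = two cages).
#'
#' @param female_success_ratio,male_success_ratio introgression-to-wild-type
#'   relative mating success per sex (positive; 1 = no difference).
#' @param n_matings total matings scored.
#' @return object of class `mating_model_spec`.
#' @export
mating_model_spec <- function(female_success_ratio = 1,
                              male_success_ratio = 1,
                              n_matings = 120) {
  if (female_success_ratio <= 0 || male_success_ratio <= 0) {
    abort("success ratios must be positive", "validation_error")
  }
  if (!is_count(n_matings) || n_matings < 1) {
    abort("`n_matings` must be a positive integer", "validation_error")
  }
  structure(list(female_success_ratio = female_success_ratio,
                 male_success_ratio = male_success_ratio,
                 n_matings = as.integer(n_matings)),
            class = "mating_model_spec")
}

#' Generate mating counts under a mating model
#'
#' @param model a [mating_model_spec()].
#' @param line label copied into the output.
#' @param seed optional integer seed.
#' @return one-row data.frame with columns `line`, `n_ss`, `n_si`, `n_is`,
#'   `n_ii` summing to `model$n_matings`.
#' @export
generate_mating_counts <- function(model, line = "synthetic", seed = NULL) {
  stopifnot(inherits(model, "mating_model_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  fr <- model$female_success_ratio
  mr <- model$male_success_ratio
  p <- c(ss = 1, si = mr, is = fr, ii = fr * mr)
  p <- p / sum(p)
  k <- as.integer(stats::rmultinom(1, model$n_matings, p))
  data.frame(line = line, n_ss = k[1], n_si = k[2], n_is = k[3], n_ii = k[4])
}

#' Generate replicate fertility records around known line means
#'
#' Progeny counts per replicate vial are drawn from a normal distribution
#' truncated at zero (negative draws are redrawn) and rounded to integers; the
#' real assays report only means +/- SE, so the noise model is a stated choice.
#'
#' @param line_means named numeric vector (names = line labels) or data.frame
#'   with columns `line`, `mean`; lines with `NA` means are skipped.
#' @param sd replicate-to-replicate standard deviation (> 0); the printed
#'   per-line SEs of ~10 replicates correspond to sd ~ 100-260.
#' @param n_replicates replicate vials per line.
#' @param seed optional integer seed.
#' @return data.frame with columns `line`, `replicate`, `progeny`.
#' @export
generate_fertility_records <- function(line_means, sd = 150, n_replicates = 10,
                                       seed = NULL) {
  if (is.data.frame(line_means)) {
    means <- stats::setNames(line_means$mean, line_means$line)
  } else {
    means <- line_means
  }
  means <- means[!is.na(means)]
  if (length(means) == 0 || is.null(names(means))) {
    abort("`line_means` must be a named vector or line/mean data.frame",
          "validation_error")
  }
  if (!is.numeric(sd) || sd <= 0) abort("`sd` must be > 0", "validation_error")
  if (!is_count(n_replicates) || n_replicates < 1) {
    abort("`n_replicates` must be a positive integer", "validation_error")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  rows <- lapply(names(means), function(ln) {
    draws <- stats::rnorm(n_replicates, means[[ln]], sd)
    while (any(bad <- draws < 0)) {
      draws[bad] <- stats::rnorm(sum(bad), means[[ln]], sd)
    }
    data.frame(line = ln, replicate = seq_len(n_replicates),
               progeny = as.integer(round(draws)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
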