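# File round-tripping: trajectory CSVs and pipeline configuration.
# CSV dialect: UTF-8, comma-separated, '.' decimal, header row mandatory.

TRAJECTORY_COLUMNS <- c("experiment_id", "replicate_id", "generation",
                        "n_alleles", "sech_count", "frequency")

empty_observations <- function() {
  data.frame(experiment_id = character(0), replicate_id = character(0),
             generation = integer(0), n_alleles = integer(0),
             sech_count = integer(0), frequency = numeric(0))
}

#' Read marker-frequency trajectory observations
#'
#' Reads and validates a long-format trajectory CSV (one row per replicate per
#' sampled generation). Validation failures raise classed conditions:
#' `missing_column_error`, `count_mismatch_error` (frequency does not equal
#' `sech_count / n_alleles`, or `sech_count > n_alleles`), and
#' `value_range_error`. An empty file yields an empty, correctly-typed
#' data.frame with a warning, so partially staged studies can be read.
#'
#' @param path CSV file path.
#' @return data.frame with the trajectory schema columns (extra columns are
#'   preserved).
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "validation_error")
  first <- readLines(path, n = 2L, warn = FALSE)
  if (length(first) == 0) {
    warning("empty observations file: ", path)
    return(empty_observations())
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRAJECTORY_COLUMNS, names(df))
  if (length(missing) > 0) {
    abort(sprintf("missing columns: %s", paste(missing, collapse = ", ")),
          "missing_column_error")
  }
  if (nrow(df) == 0) {
    warning("observations file has a header but no rows: ", path)
    return(df)
  }
  if (any(df$n_alleles <= 0) || any(df$sech_count < 0) || any(df$generation < 0)) {
    abort("generation, n_alleles and sech_count must be non-negative (n_alleles > 0)",
          "value_range_error")
  }
  if (any(df$frequency < 0 | df$frequency > 1)) {
    abort("frequency out of [0, 1]", "value_range_error")
  }
  if (any(df$sech_count > df$n_alleles)) {
    abort("sech_count exceeds n_alleles", "count_mismatch_error")
  }
  if (any(abs(df$frequency - df$sech_count / df$n_alleles) > 1e-6)) {
    abort("frequency does not match sech_count / n_alleles", "count_mismatch_error")
  }
  df
}

#' Write trajectory observations to CSV
#'
#' @param observations data.frame in the trajectory schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  missing <- setdiff(TRAJECTORY_COLUMNS, names(observations))
  if (length(missing) > 0) {
    abort(sprintf("missing columns: %s", paste(missing, collapse = ", ")),
          "missing_column_error")
  }
  utils::write.csv(observations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble / read a pipeline configuration
#'
#' `pipeline_config()` builds a validated configuration;
#' `read_pipeline_config()` reads one from JSON (keys matching the argument
#' names; `design` and `grid` given as objects of their fields). Grid and
#' design values are validated before any compute.
#'
#' @param seed integer base seed for all stochastic stages.
#' @param design an [experiment_design()].
#' @param grid a [grid_spec()].
#' @param n_iterations simulated replicates per likelihood grid cell.
#' @param scheme fitness scheme, see [fitness_weights()].
#' @param experiments experiment list as in [synthetic_study_spec()].
#' @param out_dir output directory for [run_pipeline()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, design = experiment_design(),
                            grid = grid_spec(), n_iterations = 500,
                            scheme = c("standard", "literal"),
                            experiments = default_experiments(),
                            out_dir = "introgressim-run") {
  scheme <- match.arg(scheme)
  if (!is_count(seed)) abort("`seed` must be an integer", "validation_error")
  if (!is_count(n_iterations) || n_iterations < 1) {
    abort("`n_iterations` must be a positive integer", "validation_error")
  }
  stopifnot(inherits(design, "experiment_design"), inherits(grid, "grid_spec"))
  structure(list(seed = as.integer(seed), design = design, grid = grid,
                 n_iterations = as.integer(n_iterations), scheme = scheme,
                 experiments = experiments, out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON configuration file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "validation_error")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  design <- if (is.null(raw$design)) experiment_design() else
    do.call(experiment_design, as.list(raw$design))
  grid <- if (is.null(raw$grid)) grid_spec() else do.call(grid_spec, as.list(raw$grid))
  experiments <- if (is.null(raw$experiments)) {
    default_experiments()
  } else {
    lapply(seq_len(nrow(raw$experiments)), function(i) {
      e <- raw$experiments[i, ]
      list(experiment_id = e$experiment_id,
           params = selection_params(e$s, e$h, e$c),
           design = design,
           label = e$label)
    })
  }
  pipeline_config(seed = raw$seed %||% 1, design = design, grid = grid,
                  n_iterations = raw$n_iterations %||% 500,
                  scheme = raw$scheme %||% "standard",
                  experiments = experiments,
                  out_dir = raw$out_dir %||% "introgressim-run")
}
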