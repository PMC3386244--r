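# Binned frequency distributions and the grid-search maximum likelihood
# estimator of (s, c) at fixed dominance h.

N_BINS <- 40L
BIN_WIDTH <- 0.025

#' Frequency bin index
#'
#' Maps a marker frequency to one of 40 bins of width 0.025 over `[0, 1]`.
#' Bins are half-open `[k * 0.025, (k + 1) * 0.025)` with the last bin closed
#' at 1, so boundary frequencies (sampled frequencies are multiples of 1/80 and
#' do hit boundaries, e.g. 0.025) are assigned deterministically to the
#' upper bin.
#'
#' @param freq numeric vector of frequencies in `[0, 1]`.
#' @return integer vector of bin indices in `0..39`.
#' @export
#' @examples
#' bin_index(c(0, 0.024, 0.025, 0.5, 1)) # 0 0 1 20 39
bin_index <- function(freq) {
  if (!is.numeric(freq) || anyNA(freq) || any(freq < 0 | freq > 1)) {
    abort("frequencies must be numeric in [0, 1]", "value_range_error")
  }
  # 1e-9 absorbs float error in frequencies that are exact bin boundaries
  as.integer(pmin(floor(freq / BIN_WIDTH + 1e-9), N_BINS - 1L))
}

#' Build binned distributions of sampled marker frequencies
#'
#' Simulates `n_iterations` replicates at one parameter set and bins the
#' sampled frequency of each replicate, per scheduled generation, into the 40
#' bins of [bin_index()]. These distributions are the reference against which
#' observed trajectories are scored.
#'
#' @param params a [selection_params()].
#' @param design an [experiment_design()].
#' @param n_iterations replicates to simulate (the original analysis used
#'   10,000 per parameter combination).
#' @param scheme fitness scheme, see [fitness_weights()].
#' @param engine `"batch"` (default, vectorised exchangeable-count engine) or
#'   `"individual"` (loops [run_replicate()] with per-iteration seeds
#'   `seed + i`; slow, retained for cross-validation).
#' @param seed optional integer seed.
#' @return object of class `freq_distribution`: list with `params`,
#'   `n_iterations`, `generations`, and `counts`, an
#'   `length(generations)` x 40 integer matrix whose rows each sum to
#'   `n_iterations`.
#' @export
build_distribution <- function(params, design, n_iterations = 10000,
                               scheme = "standard",
                               engine = c("batch", "individual"),
                               seed = NULL) {
  engine <- match.arg(engine)
  if (engine == "batch") {
    if (!is.null(seed)) set.seed(as.integer(seed))
    freqs <- simulate_sampled_frequencies(params, design, n_iterations, scheme)
  } else {
    base <- seed %||% 0
    rows <- lapply(seq_len(n_iterations), function(i) {
      run_replicate(params, design, seed = base + i, scheme = scheme)$frequency
    })
    freqs <- do.call(rbind, rows)
    colnames(freqs) <- paste0("gen", design$sample_generations)
  }
  counts <- apply(freqs, 2, function(f) tabulate(bin_index(f) + 1L, nbins = N_BINS))
  counts <- t(counts) # generations x bins
  rownames(counts) <- colnames(freqs)
  structure(list(params = params, n_iterations = as.integer(n_iterations),
                 generations = design$sample_generations, counts = counts),
            class = "freq_distribution")
}

#' @export
print.freq_distribution <- function(x, ...) {
  cat(sprintf("<freq_distribution> s = %g, h = %g, c = %g; %d iterations\n",
              x$params$s, x$params$h, x$params$c, x$n_iterations))
  means <- apply(x$counts, 1, function(cnt) {
    sum(((seq_len(N_BINS) - 0.5) * BIN_WIDTH) * cnt) / sum(cnt)
  })
  for (i in seq_along(x$generations)) {
    cat(sprintf("  generation %2d: mean binned frequency %.3f\n",
                x$generations[i], means[i]))
  }
  invisible(x)
}

#' Log-likelihood of observed trajectories under a simulated distribution
#'
#' Per sampled generation, the bins containing any replicate's observed
#' frequency are collected; the summed count of those bins divided by the
#' number of iterations is the generation's likelihood, and the total
#' log-likelihood is the sum of the per-generation logs. Replicates that fall
#' in the same bin count it once (`method = "union"`); the per-replicate
#' product alternative (`method = "per_replicate"`) is provided for sensitivity
#' analysis. Observed bins holding zero simulated mass are floored at
#' `1 / (n_iterations + 1)` so grids remain finite and comparable.
#'
#' @param observations data.frame with columns `generation` and `frequency`
#'   (one row per replicate per sampled generation).
#' @param dist a [build_distribution()] object whose generations cover every
#'   observed generation.
#' @param method `"union"` or `"per_replicate"`.
#' @return the log-likelihood (<= 0).
#' @export
observation_log_likelihood <- function(observations, dist,
                                       method = c("union", "per_replicate")) {
  method <- match.arg(method)
  stopifnot(inherits(dist, "freq_distribution"))
  if (!all(c("generation", "frequency") %in% names(observations))) {
    abort("observations need `generation` and `frequency` columns",
          "missing_column_error")
  }
  gens <- unique(observations$generation)
  if (!all(gens %in% dist$generations)) {
    abort(sprintf("observed generations (%s) not all present in distribution (%s)",
                  paste(gens, collapse = ","),
                  paste(dist$generations, collapse = ",")),
          "generation_mismatch_error")
  }
  floor_p <- 1 / (dist$n_iterations + 1)
  total <- 0
  for (g in gens) {
    bins <- bin_index(observations$frequency[observations$generation == g])
    row <- dist$counts[match(g, dist$generations), ]
    if (method == "union") {
      mass <- sum(row[unique(bins) + 1L]) / dist$n_iterations
      total <- total + log(max(mass, floor_p))
    } else {
      p <- row[bins + 1L] / dist$n_iterations
      total <- total + sum(log(pmax(p, floor_p)))
    }
  }
  total
}

#' Grid-search maximum likelihood estimation of (s, c) per dominance level
#'
#' For each dominance value in the grid, simulates a binned frequency
#' distribution at every (s, c) cell, scores the observed trajectories with
#' [observation_log_likelihood()], and reports the arg-max. Ties are broken
#' toward the smallest s, then the smallest c (the weakest selection and
#' tightest linkage consistent with the data).
#'
#' @param observations data.frame with columns `generation` and `frequency`.
#' @param grid a [grid_spec()].
#' @param design an [experiment_design()].
#' @param n_iterations simulated replicates per grid cell.
#' @param scheme fitness scheme, see [fitness_weights()].
#' @param seed optional base seed; each cell's distribution uses a seed derived
#'   deterministically from it, so identical inputs give identical grids.
#' @param method likelihood combination rule, see
#'   [observation_log_likelihood()].
#' @return list of `likelihood_grid` objects, one per dominance value: each has
#'   `h`, `s_values`, `c_values`, `loglik` (s x c matrix), `mle`
#'   (list `s`, `c`, `loglik`) and `n_iterations`.
#' @export
fit_grid <- function(observations, grid = grid_spec(),
                     design = experiment_design(), n_iterations = 10000,
                     scheme = "standard", seed = NULL, method = "union") {
  stopifnot(inherits(grid, "grid_spec"))
  out <- vector("list", length(grid$h_values))
  cell <- 0L
  for (hi in seq_along(grid$h_values)) {
    h <- grid$h_values[hi]
    ll <- matrix(NA_real_, length(grid$s_values), length(grid$c_values),
                 dimnames = list(s = format(grid$s_values),
                                 c = format(grid$c_values)))
    for (si in seq_along(grid$s_values)) {
      for (ci in seq_along(grid$c_values)) {
        cell <- cell + 1L
        pars <- selection_params(grid$s_values[si], h, grid$c_values[ci])
        d <- build_distribution(pars, design, n_iterations, scheme,
                                engine = "batch",
                                seed = if (is.null(seed)) NULL else derive_seed(seed, cell))
        ll[si, ci] <- observation_log_likelihood(observations, d, method)
      }
    }
    top <- which(ll == max(ll), arr.ind = TRUE)
    top <- top[order(top[, 1], top[, 2]), , drop = FALSE][1, ] # min s, then min c
    out[[hi]] <- structure(
      list(h = h, s_values = grid$s_values, c_values = grid$c_values,
           loglik = ll,
           mle = list(s = grid$s_values[top[1]], c = grid$c_values[top[2]],
                      loglik = ll[top[1], top[2]]),
           n_iterations = as.integer(n_iterations)),
      class = "likelihood_grid")
  }
  names(out) <- paste0("h", grid$h_values)
  out
}

#' @export
print.likelihood_grid <- function(x, ...) {
  cat(sprintf("<likelihood_grid> h = %g (%d iterations/cell): MLE s = %g, c = %g, loglik = %.3f\n",
              x$h, x$n_iterations, x$mle$s, x$mle$c, x$mle$loglik))
  invisible(x)
}

#' Flatten likelihood grids to a long data.frame
#'
#' The long format (one row per (h, s, c) cell with its log-likelihood and an
#' `is_mle` flag) is the data behind contour plots of the likelihood surface.
#'
#' @param grids a single `likelihood_grid` or the list returned by
#'   [fit_grid()].
#' @return data.frame with columns `h`, `s`, `c`, `loglik`, `is_mle`.
#' @export
grid_to_long <- function(grids) {
  if (inherits(grids, "likelihood_grid")) grids <- list(grids)
  do.call(rbind, lapply(grids, function(g) {
    df <- expand.grid(s = g$s_values, c = g$c_values, KEEP.OUT.ATTRS = FALSE)
    df <- data.frame(h = g$h, df, loglik = as.vector(g$loglik))
    df$is_mle <- df$s == g$mle$s & df$c == g$mle$c
    df
  }))
}

#' Summarise per-marker maximum likelihood estimates
#'
#' Aggregates a long table of per-marker MLEs over dominance levels into the
#' summary layout of the original analysis: per-marker averages across h,
#' per-h averages across markers, grand averages, and the count of markers
#' whose c estimate is effectively zero at every dominance level. Grid values
#' of c at or below `zero_c_threshold` (default 0.01, i.e. the near-zero part
#' of the default grid: 0.0001, 0.001, 0.01) are treated as zero for that
#' count and displayed as 0 by the print method, while raw values are kept in
#' the returned object.
#'
#' @param mles data.frame with columns `marker`, `h`, `c`, `s`.
#' @param zero_c_threshold c values `<=` this count as zero.
#' @return object of class `mle_summary`: list with `per_marker`, `per_h`
#'   data.frames, `grand` (list `mean_c`, `mean_s`), and `zero_c` (list `n`,
#'   `n_markers`, `fraction`, `markers`).
#' @export
#' @examples
#' summarize_mle_table(mle_estimates())
summarize_mle_table <- function(mles, zero_c_threshold = 0.01) {
  need <- c("marker", "h", "c", "s")
  if (!all(need %in% names(mles))) {
    abort("`mles` needs columns marker, h, c, s", "missing_column_error")
  }
  if (nrow(mles) == 0) abort("`mles` is empty", "validation_error")
  per_marker <- stats::aggregate(cbind(c, s) ~ marker, data = mles, FUN = mean)
  names(per_marker) <- c("marker", "mean_c", "mean_s")
  per_h <- stats::aggregate(cbind(c, s) ~ h, data = mles, FUN = mean)
  names(per_h) <- c("h", "mean_c", "mean_s")
  zero_by_marker <- tapply(mles$c <= zero_c_threshold, mles$marker, all)
  zero_markers <- names(zero_by_marker)[zero_by_marker]
  structure(list(
    per_marker = per_marker,
    per_h = per_h,
    grand = list(mean_c = mean(per_marker$mean_c), mean_s = mean(per_marker$mean_s)),
    zero_c = list(n = sum(zero_by_marker), n_markers = length(zero_by_marker),
                  fraction = mean(zero_by_marker), markers = zero_markers),
    zero_c_threshold = zero_c_threshold),
    class = "mle_summary")
}

#' @export
print.mle_summary <- function(x, ...) {
  disp <- function(v) ifelse(v <= x$zero_c_threshold, 0, v)
  cat("<mle_summary>\n  per-h averages:\n")
  ph <- x$per_h
  ph$mean_c <- round_half_up(ph$mean_c, 2)
  ph$mean_s <- round_half_up(ph$mean_s, 2)
  print(ph, row.names = FALSE)
  pm <- x$per_marker
  pm$mean_c <- round_half_up(disp(pm$mean_c), 3)
  pm$mean_s <- round_half_up(pm$mean_s, 3)
  cat("  per-marker averages:\n")
  print(pm, row.names = FALSE)
  cat(sprintf("  grand averages: c = %.2f, s = %.2f\n",
              round_half_up(x$grand$mean_c, 2), round_half_up(x$grand$mean_s, 2)))
  cat(sprintf("  markers with c ~ 0 at all h: %d of %d (%.0f%%)\n",
              x$zero_c$n, x$zero_c$n_markers,
              round_half_up(100 * x$zero_c$fraction)))
  invisible(x)
}
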