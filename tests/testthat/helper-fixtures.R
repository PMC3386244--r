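# Shared fixtures and independent oracles for the test suite.

# Independent single-locus oracle: classical deterministic recursion for the
# post-selection frequency of a deleterious allele under viability selection.
# Used to validate expected_trajectory() at c = 0 (complete linkage).
single_locus_recursion <- function(q0, s, h, n_generations) {
  q <- numeric(n_generations + 1)
  q[1] <- q0
  for (g in seq_len(n_generations)) {
    qq <- q[g]
    p <- 1 - qq
    wbar <- p^2 + 2 * p * qq * (1 - h * s) + qq^2 * (1 - s)
    q[g + 1] <- if (wbar > 0) (qq^2 * (1 - s) + p * qq * (1 - h * s)) / wbar else qq
  }
  q
}

# Build a population with explicit haplotype-code rows (codes 0..3).
make_population <- function(male_rows, female_rows, generation = 1L) {
  pop <- founder_population(experiment_design(
    n_males = max(1, nrow(male_rows)), n_females = max(1, nrow(female_rows)),
    sample_males = 1, sample_females = 1))
  pop$males <- male_rows
  pop$females <- female_rows
  pop$generation <- as.integer(generation)
  pop
}

hap_rows <- function(h1, h2, n) {
  matrix(c(h1, h2), nrow = n, ncol = 2, byrow = TRUE)
}

# Hand-made binned distribution object for likelihood unit tests.
fake_distribution <- function(counts, generations, n_iterations) {
  structure(list(params = selection_params(0.5, 0.5, 0),
                 n_iterations = as.integer(n_iterations),
                 generations = generations,
                 counts = counts),
            class = "freq_distribution")
}

# Default bottle design scaled down for cheap smoke tests.
small_design <- function(...) {
  experiment_design(n_males = 30, n_females = 30, n_generations = 6,
                    sample_generations = c(3, 6), sample_males = 5,
                    sample_females = 5, ...)
}
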