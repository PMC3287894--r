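# Small in-code fixtures shared across test files.

# A hand-sized carrier-coded matrix with known columns.
tiny_carrier <- function() {
  m <- cbind(
    a = c(1L, 0L, 0L, 0L),
    b = c(0L, 0L, 1L, 0L),
    c = c(1L, 1L, 0L, 0L),
    d = c(0L, 0L, 0L, 1L)
  )
  genotype_matrix(m, coding = "carrier",
                  individual_ids = paste0("i", 1:4))
}

# Random carrier matrix of given size.
random_carrier <- function(n, p, prob = 0.2, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n * p, 1, prob), n, p,
              dimnames = list(paste0("i", seq_len(n)),
                              paste0("v", seq_len(p))))
  genotype_matrix(m, coding = "carrier")
}

# A small simulated cohort for pipeline-level tests.
small_cohort <- function(seed = 42, n = 250, genes = 10,
                         functional = 2, reps = 2) {
  cfg <- sim_config(n_individuals = n, n_genes = genes,
                    variants_per_gene = c(3, 8),
                    n_functional_genes = functional,
                    functional_variants_per_gene = 2,
                    n_replicates = reps)
  co <- simulate_cohort(cfg, seed = seed)
  ph <- simulate_phenotypes(co, n_replicates = reps, noise_sd = 1,
                            seed = seed + 1)
  list(cohort = co, pheno = ph)
}

# Brute-force OR over a subgroup, one individual at a time.
or_oracle <- function(g, subgroup) {
  vapply(seq_len(nrow(g)), function(i) {
    as.integer(any(unclass(g)[i, subgroup] == 1L))
  }, integer(1))
}
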