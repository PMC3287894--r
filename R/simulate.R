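#' Simulation configuration for a mini-exome cohort
#'
#' Defines a synthetic quantitative-trait cohort in the style of a
#' mini-exome sequencing study: many genes each holding a handful of
#' variants, a MAF spectrum dominated by rare alleles (most below 5%, many
#' below 1%), a few "functional" genes whose rare variants carry linear
#' effects on the trait, and multiple phenotype replicates simulated over
#' one fixed genotype matrix.
#'
#' Defaults give a desk-scale cohort: 700 individuals, 50 genes of 4-12
#' variants, 87% rare variants, 3 functional genes with 5 functional rare
#' variants each, per-variant effects uniform on `[0.17, 1.2]` trait units
#' per allele copy, unit residual noise, 20 phenotype replicates. Rare MAFs
#' are drawn as `0.05 * Beta(0.35, 1)` (about half the rare mass below 1%),
#' common MAFs uniform on `[0.05, 0.5]`.
#'
#' @param n_individuals cohort size N.
#' @param n_genes number of genes K.
#' @param variants_per_gene length-2 integer range (min, max) or a single
#'   fixed count.
#' @param rare_fraction fraction of variants drawn from the rare MAF law.
#' @param rare_beta_shape1,rare_beta_shape2 shape of the rare MAF law
#'   `rare_threshold * Beta(a, b)`.
#' @param rare_threshold rarity threshold (default 0.05).
#' @param n_functional_genes genes carrying trait effects.
#' @param functional_variants_per_gene functional rare variants per such
#'   gene.
#' @param effect_range per-allele effect size range (uniform draw), trait
#'   units.
#' @param noise_sd residual standard deviation of the trait.
#' @param n_replicates phenotype replicates sharing the genotype matrix.
#' @param effect_on `"dosage"` (effects multiply allele copies 0/1/2, the
#'   default, mirroring a generative model richer than the carrier coding
#'   used in analysis) or `"carrier"`.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_individuals = 700, n_genes = 50,
                       variants_per_gene = c(4, 12), rare_fraction = 0.87,
                       rare_beta_shape1 = 0.35, rare_beta_shape2 = 1,
                       rare_threshold = 0.05, n_functional_genes = 3,
                       functional_variants_per_gene = 5,
                       effect_range = c(0.17, 1.2), noise_sd = 1,
                       n_replicates = 20, effect_on = c("dosage", "carrier")) {
  effect_on <- match.arg(effect_on)
  if (length(variants_per_gene) == 1) {
    variants_per_gene <- rep(variants_per_gene, 2)
  }
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_genes = as.integer(n_genes),
    variants_per_gene = as.integer(variants_per_gene),
    rare_fraction = rare_fraction, rare_beta_shape1 = rare_beta_shape1,
    rare_beta_shape2 = rare_beta_shape2, rare_threshold = rare_threshold,
    n_functional_genes = as.integer(n_functional_genes),
    functional_variants_per_gene = as.integer(functional_variants_per_gene),
    effect_range = as.numeric(effect_range), noise_sd = noise_sd,
    n_replicates = as.integer(n_replicates), effect_on = effect_on
  )
  if (cfg$n_individuals < 1 || cfg$n_genes < 1) {
    abort("need at least one individual and one gene.")
  }
  if (cfg$rare_fraction < 0 || cfg$rare_fraction > 1) {
    abort("rare_fraction must lie in [0, 1].")
  }
  if (cfg$noise_sd <= 0) abort("noise_sd must be positive.")
  if (cfg$n_functional_genes > cfg$n_genes) {
    abort("more functional genes than genes.")
  }
  if (any(cfg$variants_per_gene < 1) ||
      cfg$variants_per_gene[1] > cfg$variants_per_gene[2]) {
    abort("variants_per_gene must be a valid positive range.")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a genotype cohort
#'
#' Per variant, a true MAF is drawn from the configured spectrum and
#' genotypes are sampled i.i.d. `Binomial(2, maf)` across individuals
#' (Hardy-Weinberg, no linkage disequilibrium). Functional variants are
#' sampled among the rare (true MAF below threshold) variants of the
#' designated functional genes, with effects drawn uniformly from
#' `effect_range`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of (cfg, seed).
#' @return list of class `sim_cohort`: `genotypes` (dosage
#'   [genotype_matrix()]), `gene_map` (tibble `variant_id`, `gene`),
#'   `variants` ([variant_table()] with empirical MAF), `truth` (list:
#'   `functional` tibble of `variant_id`, `gene`, `true_maf`, `effect`;
#'   `true_maf` for all variants; `seed`).
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    k <- cfg$n_genes
    m_k <- sample(seq(cfg$variants_per_gene[1], cfg$variants_per_gene[2]),
                  k, replace = TRUE)
    gene_ids <- sprintf("G%03d", seq_len(k))
    gene_of <- rep(gene_ids, times = m_k)
    p_total <- sum(m_k)
    variant_ids <- sprintf("%s_V%02d", gene_of,
                           unlist(lapply(m_k, seq_len), use.names = FALSE))

    is_rare_law <- runif(p_total) < cfg$rare_fraction
    true_maf <- numeric(p_total)
    true_maf[is_rare_law] <- cfg$rare_threshold *
      rbeta(sum(is_rare_law), cfg$rare_beta_shape1, cfg$rare_beta_shape2)
    true_maf[!is_rare_law] <- runif(sum(!is_rare_law), cfg$rare_threshold, 0.5)

    values <- vapply(true_maf, function(p) rbinom(cfg$n_individuals, 2, p),
                     integer(cfg$n_individuals))
    g <- genotype_matrix(values, coding = "dosage",
                         individual_ids = sprintf("ind%04d", seq_len(cfg$n_individuals)),
                         variant_ids = variant_ids)

    # functional genes are drawn among genes able to host the configured
    # number of functional rare variants
    need <- cfg$functional_variants_per_gene
    n_rare_by_gene <- vapply(gene_ids, function(gn) {
      sum(gene_of == gn & true_maf < cfg$rare_threshold & true_maf > 0)
    }, integer(1))
    eligible <- gene_ids[n_rare_by_gene >= need]
    if (length(eligible) < cfg$n_functional_genes) {
      abort(sprintf(
        "only %d gene(s) hold >= %d rare variants; cannot place %d functional genes.",
        length(eligible), need, cfg$n_functional_genes))
    }
    functional_genes <- sort(sample(eligible, cfg$n_functional_genes))
    func_rows <- integer()
    for (gn in functional_genes) {
      cand <- which(gene_of == gn & true_maf < cfg$rare_threshold & true_maf > 0)
      func_rows <- c(func_rows, sample(cand, need))
    }
    effects <- runif(length(func_rows), cfg$effect_range[1], cfg$effect_range[2])

    is_func <- seq_len(p_total) %in% func_rows
    eff_all <- numeric(p_total)
    eff_all[func_rows] <- effects

    variants <- variant_table(
      variant_id = variant_ids, gene = gene_of,
      maf = compute_maf(g), is_functional = is_func, effect = eff_all,
      rare_threshold = cfg$rare_threshold
    )
    truth <- list(
      functional = tibble(variant_id = variant_ids[func_rows],
                          gene = gene_of[func_rows],
                          true_maf = true_maf[func_rows],
                          effect = effects),
      functional_genes = functional_genes,
      true_maf = stats::setNames(true_maf, variant_ids),
      effect_on = cfg$effect_on,
      seed = seed
    )
    structure(list(genotypes = g,
                   gene_map = tibble(variant_id = variant_ids, gene = gene_of),
                   variants = variants, truth = truth, config = cfg),
              class = "sim_cohort")
  })
}

#' Simulate phenotype replicates over a fixed genotype matrix
#'
#' Each replicate is `Y = sum_v effect_v * g_v + e`, `e ~ N(0, noise_sd^2)`
#' i.i.d.; genotypes (and effects) are shared across replicates, noise is
#' fresh per replicate. Effects act on dosage or carrier coding according
#' to the cohort's configuration.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()], or a list with
#'   `genotypes` and `truth`.
#' @param n_replicates number of phenotype replicates.
#' @param noise_sd residual standard deviation.
#' @param seed integer seed for the noise.
#' @return long tibble: `individual_id`, `replicate` (1-based integer),
#'   `value`; extract one replicate with [phenotype_vector()].
#' @export
simulate_phenotypes <- function(cohort, n_replicates = 20, noise_sd = 1,
                                seed = 1) {
  g <- cohort$genotypes
  truth <- cohort$truth
  missing_ids <- setdiff(truth$functional$variant_id, colnames(g))
  if (length(missing_ids)) {
    abort(sprintf("truth references unknown variant(s): %s",
                  paste(head(missing_ids, 5), collapse = ", ")))
  }
  gmat <- unclass(g)[, truth$functional$variant_id, drop = FALSE]
  if ((truth$effect_on %||% "dosage") == "carrier") gmat <- (gmat > 0) * 1L
  signal <- as.numeric(gmat %*% truth$functional$effect)
  n <- nrow(g)
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      tibble(individual_id = rownames(g), replicate = r,
             value = signal + rnorm(n, 0, noise_sd))
    })
  })
}

#' Extract one phenotype replicate as a named vector
#'
#' @param pheno long phenotype tibble from [simulate_phenotypes()] or
#'   [read_phenotype_tsv()].
#' @param replicate which replicate to extract.
#' @return named numeric vector (names = individual ids).
#' @export
phenotype_vector <- function(pheno, replicate = 1) {
  rows <- pheno$replicate == replicate
  if (!any(rows)) abort(sprintf("no replicate %s in phenotype table.", replicate))
  stats::setNames(pheno$value[rows], pheno$individual_id[rows])
}
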