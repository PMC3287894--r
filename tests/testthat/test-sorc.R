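test_that("stabilities live on the {0, 1/R, ..., 1} lattice and sum to the per-repetition tally", {
  sc <- small_cohort(seed = 3, n = 150, genes = 6, reps = 1)
  y <- phenotype_vector(sc$pheno, 1)
  fit <- suppressMessages(
    run_sorc(sc$cohort$genotypes, sc$cohort$gene_map, y, R = 7, seed = 2)
  )
  st <- tidy(fit)
  expect_true(all(abs(st$stability * fit$R - round(st$stability * fit$R)) < 1e-12))
  expect_equal(sum(st$stability),
               sum(fit$repetitions$n_variants_selected) / fit$R)

  # R = 1: stabilities are exactly 0 or 1
  fit1 <- suppressMessages(
    run_sorc(sc$cohort$genotypes, sc$cohort$gene_map, y, R = 1, seed = 2)
  )
  expect_true(all(tidy(fit1)$stability %in% c(0, 1)))
})

test_that("identical seeds give identical stability tables, different seeds need not", {
  sc <- small_cohort(seed = 8, n = 120, genes = 5, reps = 1)
  y <- phenotype_vector(sc$pheno, 1)
  f1 <- suppressMessages(run_sorc(sc$cohort$genotypes, sc$cohort$gene_map, y,
                                  R = 5, seed = 77))
  f2 <- suppressMessages(run_sorc(sc$cohort$genotypes, sc$cohort$gene_map, y,
                                  R = 5, seed = 77))
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$repetitions, f2$repetitions)
})

test_that("recorded plans replay to the identical stability table", {
  sc <- small_cohort(seed = 5, n = 120, genes = 5, reps = 1)
  y <- phenotype_vector(sc$pheno, 1)
  f1 <- suppressMessages(run_sorc(sc$cohort$genotypes, sc$cohort$gene_map, y,
                                  R = 4, seed = 13, keep_plans = TRUE))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_plans_jsonl(f1$plans, path)
  plans <- read_plans_jsonl(path)
  f2 <- suppressMessages(run_sorc(sc$cohort$genotypes, sc$cohort$gene_map, y,
                                  R = 4, seed = 13, plans = plans))
  expect_identical(tidy(f1), tidy(f2))
})

test_that("a gene with a single variant has a fixed design column: stability equals the fixed-design selection frequency", {
  # every gene holds exactly one variant, so the design is identical in
  # all repetitions and only the CV fold draw varies
  set.seed(41)
  n <- 150; p <- 8
  m <- matrix(rbinom(n * p, 1, 0.15), n, p,
              dimnames = list(paste0("i", 1:n), paste0("v", 1:p)))
  g <- genotype_matrix(m, coding = "carrier")
  gmap <- tibble::tibble(variant_id = colnames(g),
                         gene = paste0("gene", seq_len(p)))
  y <- 1.2 * m[, 1] - 0.8 * m[, 5] + rnorm(n)
  names(y) <- rownames(g)
  R <- 6
  fit <- run_sorc(g, gmap, y, R = R, seed = 19)
  st <- tidy(fit)

  rbg <- split(colnames(g), gmap$gene)
  plans <- lapply(sort(names(rbg)), function(gn) list(rbg[[gn]]))
  names(plans) <- sort(names(rbg))
  d <- build_design(g, plans, character())
  counts <- stats::setNames(numeric(p), colnames(g))
  for (r in seq_len(R)) {
    sel <- lasso_select(y, d, cv_folds = 10, fold_seed = fit$fold_seeds[r])
    counts[sel$selected_rare] <- counts[sel$selected_rare] + 1
  }
  expect_equal(stats::setNames(st$stability, st$variant_id)[colnames(g)],
               counts / R)
})

test_that("a pure-noise phenotype yields low stabilities", {
  set.seed(55)
  cfg <- sim_config(n_individuals = 300, n_genes = 12,
                    variants_per_gene = c(3, 6), n_functional_genes = 0,
                    functional_variants_per_gene = 0, n_replicates = 1)
  co <- simulate_cohort(cfg, seed = 56)
  y <- stats::setNames(rnorm(300), rownames(co$genotypes))
  fit <- suppressMessages(run_sorc(co$genotypes, co$gene_map, y,
                                   R = 20, seed = 57))
  st <- tidy(fit)
  expect_lt(stats::median(st$stability), 0.2)
  expect_lt(mean(st$stability), 0.25)
})

test_that("variant ranking breaks ties lexicographically", {
  st <- tibble::tibble(
    variant_id = c("d", "c", "b", "a"),
    gene = "g", maf = 0.01, is_rare = TRUE,
    stability = c(0.1, 0.95, 0.95, 1.0)
  )
  rk <- rank_variants(st, top_t = 2)
  expect_equal(rk$variant_id, c("a", "b", "c", "d"))
  expect_equal(rk$variant_id[rk$in_top], c("a", "b"))

  st$stability <- 0.5
  expect_equal(rank_variants(st)$variant_id, c("a", "b", "c", "d"))
})

test_that("gene ranking uses max stability then the >=0.5 member count", {
  st <- tibble::tibble(
    variant_id = paste0("v", 1:6),
    gene = c("A", "A", "B", "C", "C", "C"),
    stability = c(0.2, 1.0, 0.9, 1.0, 0.7, 0.6)
  )
  rk <- rank_genes(st)
  expect_equal(rk$gene, c("C", "A", "B")) # C wins the max=1 tie on n_high

  set.seed(6)
  st2 <- tibble::tibble(
    variant_id = paste0("v", 1:200),
    gene = sample(paste0("g", 1:50), 200, replace = TRUE),
    stability = round(runif(200), 2)
  )
  rk2 <- rank_genes(st2)
  oracle <- aggregate(stability ~ gene, st2, max)
  nh <- aggregate(stability ~ gene, st2, function(s) sum(s >= 0.5))
  odf <- merge(oracle, nh, by = "gene")
  odf <- odf[order(-odf$stability.x, -odf$stability.y, odf$gene), ]
  expect_equal(rk2$gene, odf$gene)
})

test_that("identification counts tally top-T membership across replicates", {
  mk <- function(genes) tibble::tibble(rank = seq_along(genes), gene = genes)
  rks <- list(mk(c("A", "B", "C")), mk(c("B", "A", "D")), mk(c("A", "C", "B")))
  cnt <- count_identifications(rks, top_t = 2)
  expect_equal(cnt$n_identified[cnt$gene == "A"], 3L)
  expect_equal(cnt$n_identified[cnt$gene == "B"], 2L)
  expect_equal(cnt$n_identified[cnt$gene == "C"], 1L)
  expect_equal(cnt$n_identified[cnt$gene == "D"], 0L)

  set.seed(12)
  rks2 <- lapply(1:20, function(i) mk(sample(paste0("g", 1:30), 30)))
  cnt2 <- count_identifications(rks2, top_t = 5)
  for (gn in cnt2$gene) {
    brute <- sum(vapply(rks2, function(r) {
      which(r$gene == gn) <= 5
    }, logical(1)))
    expect_equal(cnt2$n_identified[cnt2$gene == gn], brute)
  }
})
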