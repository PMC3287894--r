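test_that("single-marker test matches the pooled-variance two-sample t test", {
  set.seed(14)
  x <- rbinom(120, 1, 0.3)
  y <- 0.4 * x + rnorm(120)
  res <- single_marker_test(y, x, unit = "v")
  tt <- t.test(y[x == 1], y[x == 0], var.equal = TRUE)
  expect_equal(abs(res$statistic), abs(unname(tt$statistic)), tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(res$neg_log10_p, -log10(res$p_value))
  expect_equal(res$df, 118)
})

test_that("no association gives p near 1; monomorphic columns are rejected", {
  y <- c(1, 1, 2, 2)
  x <- c(0, 1, 0, 1)
  res <- single_marker_test(y, x)
  expect_gt(res$p_value, 0.99)
  expect_error(single_marker_test(rnorm(5), rep(1, 5)), "monomorphic")
})

test_that("permutation null p-values are uniform", {
  set.seed(8)
  x <- rbinom(100, 1, 0.4)
  y <- rnorm(100)
  ps <- replicate(500, single_marker_test(sample(y), x)$p_value)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("gene collapsing reduces to the single-marker test for one variant", {
  g <- random_carrier(100, 4, prob = 0.2, seed = 44)
  set.seed(45)
  y <- rnorm(100)
  r1 <- gene_collapse_test(y, g, "v2", unit = "gene")
  r2 <- single_marker_test(y, unclass(g)[, "v2"], unit = "gene")
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)

  # complementary carriers saturate the indicator
  m <- cbind(a = c(1L, 1L, 0L, 0L), b = c(0L, 0L, 1L, 1L))
  gsat <- genotype_matrix(m, coding = "carrier")
  expect_error(gene_collapse_test(rnorm(4), gsat, c("a", "b")), "monomorphic")
})

test_that("the collapsing test equals a two-group comparison on the indicator", {
  sc <- small_cohort(seed = 16, n = 200, genes = 10, reps = 1)
  y <- unname(phenotype_vector(sc$pheno, 1))
  gc <- recode_to_carrier(fold_to_minor(sc$cohort$genotypes))
  res <- run_baseline(sc$cohort$genotypes, sc$cohort$gene_map, y,
                      method = "collapse")
  maf <- compute_maf(fold_to_minor(sc$cohort$genotypes))
  for (i in seq_len(nrow(res))) {
    gn <- res$unit[i]
    ids <- sc$cohort$gene_map$variant_id[sc$cohort$gene_map$gene == gn]
    ids <- ids[maf[ids] > 0 & maf[ids] < 0.05]
    ind <- collapse_indicator(gc, ids)
    tt <- t.test(y[ind == 1], y[ind == 0], var.equal = TRUE)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("the CMC F statistic matches a normal-equations oracle", {
  set.seed(71)
  n <- 80
  g <- random_carrier(n, 5, prob = 0.25, seed = 72)
  y <- rnorm(n) + 0.8 * unclass(g)[, 1]
  vt <- tibble::tibble(variant_id = colnames(g),
                       maf = compute_maf(g))
  rare <- vt[vt$maf < 0.05 & vt$maf > 0, ]
  common <- vt$variant_id[vt$maf >= 0.05]
  res <- cmc_test(y, g, rare, common, unit = "g1")

  # brute-force F from the normal equations
  cols <- list()
  if (nrow(rare)) cols <- c(cols, list(collapse_indicator(g, rare$variant_id)))
  for (id in common) cols <- c(cols, list(unclass(g)[, id]))
  Z <- do.call(cbind, cols)
  Z <- Z[, apply(Z, 2, var) > 0, drop = FALSE]
  Zi <- cbind(1, Z)
  beta <- solve(crossprod(Zi), crossprod(Zi, y))
  rss1 <- sum((y - Zi %*% beta)^2)
  rss0 <- sum((y - mean(y))^2)
  q <- ncol(Z)
  fr <- ((rss0 - rss1) / q) / (rss1 / (n - q - 1))
  expect_equal(res$statistic, fr, tolerance = 1e-8)
  expect_equal(res$p_value, pf(fr, q, n - q - 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("CMC with a single column equals the single-marker test and drops duplicates", {
  g <- random_carrier(90, 3, prob = 0.3, seed = 81)
  set.seed(82)
  y <- rnorm(90)
  vt0 <- tibble::tibble(variant_id = character(), maf = numeric())
  r_cmc <- cmc_test(y, g, vt0, common_ids = "v1", unit = "g")
  r_sm <- single_marker_test(y, unclass(g)[, "v1"])
  expect_lt(abs(r_cmc$p_value - r_sm$p_value), 1e-10)

  # duplicated column: rank drop leaves p unchanged
  r_dup <- cmc_test(y, g, vt0, common_ids = c("v1", "v1"), unit = "g")
  expect_equal(r_dup$p_value, r_cmc$p_value, tolerance = 1e-10)
  expect_equal(r_dup$df, r_cmc$df)
})

test_that("all three tests are invariant to shifting and rescaling the trait", {
  sc <- small_cohort(seed = 26, n = 150, genes = 6, reps = 1)
  y <- unname(phenotype_vector(sc$pheno, 1))
  for (method in c("single", "collapse", "cmc")) {
    r1 <- run_baseline(sc$cohort$genotypes, sc$cohort$gene_map, y, method = method)
    r2 <- run_baseline(sc$cohort$genotypes, sc$cohort$gene_map,
                       5 + 3 * y, method = method)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  }
})

test_that("ranking by -log10 p orders results and maps variants to genes by the best member", {
  res <- tibble::tibble(
    unit = c("v1", "v2", "v3"),
    gene = c("A", "A", "B"),
    statistic = 1, p_value = c(1e-8, 1e-3, 0.5),
    neg_log10_p = -log10(c(1e-8, 1e-3, 0.5)), df = 10
  )
  rk_v <- rank_by_neglogp(res, level = "variant")
  expect_equal(rk_v$unit, c("v1", "v2", "v3"))
  rk_g <- rank_by_neglogp(res, level = "gene")
  expect_equal(rk_g$unit, c("A", "B"))
  expect_equal(rk_g$score[1], 8)

  set.seed(31)
  res2 <- tibble::tibble(unit = paste0("u", 1:100),
                         neg_log10_p = runif(100, 0, 10))
  rk2 <- rank_by_neglogp(res2, level = "variant")
  o <- res2[order(-res2$neg_log10_p, res2$unit), ]
  expect_equal(rk2$unit, o$unit)
})
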