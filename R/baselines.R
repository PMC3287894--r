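#' Single-marker association test
#'
#' Simple linear regression of the quantitative trait on one carrier
#' column; two-sided t test on the slope with `N - 2` degrees of freedom.
#'
#' @param y numeric phenotype vector.
#' @param x 0/1 carrier vector of the same length.
#' @param unit label for the tested unit (variant id).
#' @return one-row tibble: `unit`, `statistic` (t), `p_value`,
#'   `neg_log10_p`, `df`.
#' @export
single_marker_test <- function(y, x, unit = "variant") {
  if (length(unique(x)) < 2) {
    abort(sprintf("'%s' is monomorphic in this sample; cannot test.", unit))
  }
  fit <- lm(y ~ x)
  cf <- summary(fit)$coefficients
  tstat <- cf["x", "t value"]
  p <- cf["x", "Pr(>|t|)"]
  p <- max(p, .Machine$double.xmin) # underflow floor keeps -log10 finite
  tibble(unit = unit, statistic = as.numeric(tstat), p_value = p,
         neg_log10_p = -log10(p), df = fit$df.residual)
}

#' Gene-level collapsing test
#'
#' Collapses all of a gene's rare variants into one whole-gene carrier
#' indicator (presence of a minor allele at any member site) and applies
#' the single-marker test to the indicator.
#'
#' @param y numeric phenotype vector.
#' @param g carrier-coded [genotype_matrix()].
#' @param rare_ids the gene's rare variant ids (non-empty).
#' @param unit label (gene id).
#' @return one-row tibble as in [single_marker_test()].
#' @export
gene_collapse_test <- function(y, g, rare_ids, unit = "gene") {
  ind <- collapse_indicator(g, rare_ids)
  single_marker_test(y, ind, unit = unit)
}

#' CMC test for one gene (quantitative trait)
#'
#' The combined multivariate and collapsing test: the gene's rare variants
#' are collapsed by a predefined MAF criterion (whole-gene by default, or
#' two bins split at `maf_cut`) while its common variants stay as
#' individual carrier columns; the multivariate test is the overall F test
#' of the multiple linear regression of the trait on all columns.
#' Collinear columns are dropped by the QR pivot (input order priority), so
#' the numerator degrees of freedom equal the design rank.
#'
#' @param y numeric phenotype vector.
#' @param g carrier-coded [genotype_matrix()].
#' @param rare_variants tibble (`variant_id`, `maf`) of the gene's rare
#'   variants (may be empty).
#' @param common_ids the gene's common variant ids (may be empty).
#' @param maf_cut optional MAF cut for a two-bin rare collapse (default
#'   `NULL` = single whole-gene subgroup).
#' @param rare_threshold rarity threshold (default 0.05).
#' @param unit label (gene id).
#' @return one-row tibble: `unit`, `statistic` (F), `p_value`,
#'   `neg_log10_p`, `df` (a "q,den" descriptor).
#' @export
cmc_test <- function(y, g, rare_variants, common_ids = character(),
                     maf_cut = NULL, rare_threshold = 0.05, unit = "gene") {
  cols <- list()
  if (nrow(rare_variants) > 0) {
    subs <- fixed_maf_partition(rare_variants, cut = maf_cut,
                                rare_threshold = rare_threshold)
    for (s in subs) cols[[length(cols) + 1L]] <- collapse_indicator(g, s)
  }
  for (id in common_ids) cols[[length(cols) + 1L]] <- unclass(g)[, id]
  if (!length(cols)) abort(sprintf("gene '%s' has no polymorphic variants.", unit))
  Z <- do.call(cbind, cols)
  keep <- apply(Z, 2, function(cc) var(cc) > 0)
  if (!any(keep)) abort(sprintf("gene '%s' design is constant.", unit))
  Z <- Z[, keep, drop = FALSE]
  colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  fit <- lm(y ~ Z)
  q <- fit$rank - 1L # collinear columns dropped by pivoting
  if (q < 1) abort(sprintf("gene '%s' design is rank deficient to constant.", unit))
  den_df <- fit$df.residual
  if (den_df < 1) abort(sprintf("insufficient residual df for gene '%s'.", unit))
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum((y - mean(y))^2)
  fstat <- ((rss0 - rss1) / q) / (rss1 / den_df)
  p <- pf(fstat, q, den_df, lower.tail = FALSE)
  p <- max(min(p, 1), .Machine$double.xmin)
  tibble(unit = unit, statistic = as.numeric(fstat), p_value = p,
         neg_log10_p = -log10(p), df = sprintf("%d,%d", q, den_df))
}

#' Run a baseline method over a cohort
#'
#' Applies one of the three comparison approaches to every testable unit:
#' `"single"` tests each polymorphic variant individually; `"collapse"`
#' collapses each gene's rare variants into one indicator and tests it;
#' `"cmc"` runs the per-gene CMC multivariate test. Monomorphic variants
#' and untestable units (constant designs) are skipped.
#'
#' @param g a [genotype_matrix()] (dosage or carrier).
#' @param gene_map tibble `variant_id`, `gene`.
#' @param y phenotype vector aligned with `rownames(g)`.
#' @param method `"single"`, `"collapse"` or `"cmc"`.
#' @param rare_threshold rarity threshold (default 0.05).
#' @param maf_cut optional CMC two-bin cut (default `NULL`).
#' @param variants optional [variant_table()] used for the nonsynonymous
#'   filter.
#' @return tibble of test results (one row per tested unit) with a `gene`
#'   column for variant-level results.
#' @export
run_baseline <- function(g, gene_map, y,
                         method = c("single", "collapse", "cmc"),
                         rare_threshold = 0.05, maf_cut = NULL,
                         variants = NULL) {
  method <- match.arg(method)
  y <- align_phenotype(y, rownames(g))
  prep <- prepare_variants(g, gene_map, rare_threshold, variants)
  gc <- prep$g_carrier
  rare_ids <- unlist(prep$rare_by_gene, use.names = FALSE)

  if (method == "single") {
    ids <- c(rare_ids, prep$common_ids)
    res <- purrr::map(ids, function(id) {
      single_marker_test(y, unclass(gc)[, id], unit = id)
    })
    out <- bind_rows(res)
    out$gene <- unname(prep$gene_of[out$unit])
    return(out)
  }

  if (method == "collapse") {
    res <- purrr::map(names(prep$rare_by_gene), function(gn) {
      ind <- collapse_indicator(gc, prep$rare_by_gene[[gn]])
      if (length(unique(ind)) < 2) return(NULL)
      single_marker_test(y, ind, unit = gn)
    })
    return(bind_rows(purrr::compact(res)))
  }

  # cmc: every gene with at least one polymorphic (rare or common) variant
  common_by_gene <- split(prep$common_ids, prep$gene_of[prep$common_ids])
  genes <- sort(union(names(prep$rare_by_gene), names(common_by_gene)))
  maf_tbl <- tibble(variant_id = names(prep$maf), maf = as.numeric(prep$maf))
  res <- purrr::map(genes, function(gn) {
    rv <- maf_tbl[maf_tbl$variant_id %in% prep$rare_by_gene[[gn]], ]
    cm <- common_by_gene[[gn]] %||% character()
    tryCatch(
      cmc_test(y, gc, rv, cm, maf_cut = maf_cut,
               rare_threshold = rare_threshold, unit = gn),
      error = function(e) NULL
    )
  })
  bind_rows(purrr::compact(res))
}

#' Rank test results by -log10(p)
#'
#' @param results tibble from [run_baseline()] or the `*_test` functions.
#' @param level `"variant"` ranks rows as they are; `"gene"` maps
#'   variant-level results to genes by the best (maximum) member
#'   `neg_log10_p` (gene-level inputs pass through).
#' @return tibble `rank`, `unit`, `score` sorted descending, ties broken by
#'   id.
#' @export
rank_by_neglogp <- function(results, level = c("variant", "gene")) {
  level <- match.arg(level)
  stopifnot(nrow(results) > 0)
  df <- results
  if (level == "gene" && "gene" %in% names(df)) {
    df <- df |>
      group_by(unit = .data$gene) |>
      summarise(neg_log10_p = max(.data$neg_log10_p), .groups = "drop")
  }
  out <- df |>
    arrange(desc(.data$neg_log10_p), .data$unit) |>
    mutate(rank = row_number(), score = .data$neg_log10_p) |>
    select("rank", "unit", "score")
  if (level == "gene") out$gene <- out$unit
  out
}
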