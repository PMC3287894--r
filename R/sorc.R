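#' Stability selection on random collapsing (SORC)
#'
#' The full SORC engine for one phenotype vector. For each of `R`
#' repetitions the rare variants of every gene are split into two random
#' subgroups and collapsed into carrier indicators; the LASSO (penalty
#' chosen by cross-validation) is fit on the collapsed indicators plus the
#' uncollapsed common carriers; the variants surviving selection are
#' recorded. A variant's stability is the fraction of repetitions in which
#' it was selected, and ranking by stability is the SORC ranking.
#'
#' Monomorphic variants are dropped before analysis (they carry no signal
#' and break standardization); only nonsynonymous variants enter the model.
#' Dosage input is folded to the minor allele and recoded to carrier 0/1.
#' Two independent RNG streams are derived from `seed`: one drives the
#' random partitions (consumed in sorted gene order), the other the CV fold
#' assignments, so the collapsing sequence is invariant to `cv_folds`.
#'
#' @param g a [genotype_matrix()] (dosage or carrier coded).
#' @param gene_map tibble with columns `variant_id`, `gene` covering every
#'   analyzed variant exactly once.
#' @param y numeric phenotype vector aligned with `rownames(g)`, or a named
#'   vector matched by individual id.
#' @param R number of random-collapsing repetitions (default 100).
#' @param cv_folds cross-validation folds for the penalty (default 10).
#' @param rare_threshold MAF below which a variant is rare (default 0.05).
#' @param seed integer seed controlling both RNG streams.
#' @param variants optional [variant_table()]; when supplied its
#'   `is_nonsynonymous` column filters the candidate set (default all).
#' @param plans optional replay: list of length `R` of per-repetition plan
#'   lists (as drawn by [draw_collapse_plans()]) to reuse instead of fresh
#'   randomization.
#' @param keep_plans record the drawn plans in the result (for audit /
#'   replay, see [write_plans_jsonl()]).
#' @param nlambda,lambda_min_ratio,zero_tol passed to [lasso_select()].
#' @return an object of class `sorc_fit`; see [tidy.sorc_fit()],
#'   [glance.sorc_fit()], [rank_variants()], [rank_genes()].
#' @export
run_sorc <- function(g, gene_map, y, R = 100, cv_folds = 10,
                     rare_threshold = 0.05, seed = 1, variants = NULL,
                     plans = NULL, keep_plans = FALSE,
                     nlambda = 100, lambda_min_ratio = 0.001,
                     zero_tol = 1e-8) {
  stopifnot(inherits(g, "genotype_matrix"), R >= 1)
  y <- align_phenotype(y, rownames(g))
  prep <- prepare_variants(g, gene_map, rare_threshold, variants)
  gc <- prep$g_carrier
  seeds <- derive_seeds(seed, c("partition", "fold"))
  rep_partition_seeds <- with_seed(seeds[["partition"]],
                                   sample.int(.Machine$integer.max - 1L, R))
  rep_fold_seeds <- with_seed(seeds[["fold"]],
                              sample.int(.Machine$integer.max - 1L, R))

  all_ids <- c(unlist(prep$rare_by_gene, use.names = FALSE), prep$common_ids)
  counts <- stats::setNames(integer(length(all_ids)), all_ids)
  lambdas <- numeric(R); nnz <- integer(R); nsel <- integer(R)
  kept_plans <- if (keep_plans || !is.null(plans)) vector("list", R) else NULL

  for (r in seq_len(R)) {
    rep_plans <- if (!is.null(plans)) plans[[r]] else
      with_seed(rep_partition_seeds[r], draw_collapse_plans(prep$rare_by_gene))
    design <- build_design(gc, rep_plans, prep$common_ids)
    sel <- lasso_select(y, design, cv_folds = cv_folds,
                        fold_seed = rep_fold_seeds[r], nlambda = nlambda,
                        lambda_min_ratio = lambda_min_ratio,
                        zero_tol = zero_tol)
    hit <- c(sel$selected_rare, sel$selected_common)
    counts[hit] <- counts[hit] + 1L
    lambdas[r] <- sel$lambda_used; nnz[r] <- sel$n_nonzero
    nsel[r] <- length(hit)
    if (!is.null(kept_plans)) kept_plans[[r]] <- rep_plans
  }

  stab <- tibble(
    variant_id = all_ids,
    gene = prep$gene_of[all_ids],
    maf = prep$maf[all_ids],
    is_rare = all_ids %in% unlist(prep$rare_by_gene, use.names = FALSE),
    stability = as.numeric(counts[all_ids]) / R
  ) |>
    arrange(desc(.data$stability), .data$variant_id) |>
    mutate(rank = row_number())

  structure(
    list(
      stability = stab,
      R = R,
      seed = seed,
      params = list(cv_folds = cv_folds, rare_threshold = rare_threshold,
                    nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                    zero_tol = zero_tol),
      repetitions = tibble(repetition = seq_len(R), lambda = lambdas,
                           n_nonzero = nnz, n_variants_selected = nsel),
      fold_seeds = rep_fold_seeds,
      dropped_monomorphic = prep$dropped,
      plans = kept_plans
    ),
    class = "sorc_fit"
  )
}

# Shared preparation: fold, MAF, carrier recode, rare/common split,
# nonsynonymous filter, gene lookup. Used by run_sorc and the baselines.
prepare_variants <- function(g, gene_map, rare_threshold = 0.05,
                             variants = NULL) {
  stopifnot(all(c("variant_id", "gene") %in% names(gene_map)))
  if (anyDuplicated(gene_map$variant_id)) {
    abort("gene map assigns a variant to more than one gene.")
  }
  missing_map <- setdiff(colnames(g), gene_map$variant_id)
  if (length(missing_map)) {
    abort(sprintf("gene map is missing variant(s): %s",
                  paste(head(missing_map, 5), collapse = ", ")))
  }
  g <- fold_to_minor(g)
  maf <- compute_maf(g)
  keep_ns <- colnames(g)
  if (!is.null(variants) && "is_nonsynonymous" %in% names(variants)) {
    keep_ns <- variants$variant_id[variants$is_nonsynonymous]
  }
  vt <- tibble(variant_id = colnames(g), maf = as.numeric(maf))
  split <- split_rare_common(vt, rare_threshold)
  if (length(split$dropped)) {
    inform(sprintf("dropping %d monomorphic variant(s).", length(split$dropped)))
  }
  rare_ids <- intersect(split$rare, keep_ns)
  common_ids <- intersect(split$common, keep_ns)
  gene_of <- stats::setNames(gene_map$gene, gene_map$variant_id)
  rare_by_gene <- split(rare_ids, gene_of[rare_ids])
  rare_by_gene <- rare_by_gene[lengths(rare_by_gene) > 0]
  list(
    g_carrier = recode_to_carrier(g),
    maf = maf,
    gene_of = gene_of,
    rare_by_gene = rare_by_gene,
    common_ids = common_ids,
    dropped = split$dropped
  )
}

align_phenotype <- function(y, individual_ids) {
  if (is.data.frame(y)) abort("pass one phenotype vector; see phenotype_vector().")
  if (!is.null(names(y))) {
    missing_ids <- setdiff(individual_ids, names(y))
    if (length(missing_ids)) {
      abort(sprintf("phenotype is missing individual(s): %s",
                    paste(head(missing_ids, 5), collapse = ", ")))
    }
    y <- y[individual_ids]
  }
  if (length(y) != length(individual_ids)) {
    abort("phenotype length does not match the genotype matrix.")
  }
  if (anyNA(y) || any(!is.finite(y))) abort("phenotype must be finite.")
  as.numeric(y)
}

#' @export
print.sorc_fit <- function(x, ...) {
  cat(sprintf("<sorc_fit> %d variants, R = %d repetitions (seed %s)\n",
              nrow(x$stability), x$R, format(x$seed)))
  print(head(x$stability, 10))
  invisible(x)
}

#' Tidy a SORC fit into its stability table
#'
#' @param x a `sorc_fit` from [run_sorc()].
#' @param ... unused.
#' @return tibble: `variant_id`, `gene`, `maf`, `is_rare`, `stability`
#'   (fraction of repetitions selected, on the lattice `{0, 1/R, ..., 1}`),
#'   `rank`.
#' @method tidy sorc_fit
#' @export
tidy.sorc_fit <- function(x, ...) x$stability

#' One-row summary of a SORC fit
#'
#' @param x a `sorc_fit`.
#' @param ... unused.
#' @return one-row tibble: repetitions, variant counts, mean selected set
#'   size and median penalty across repetitions.
#' @method glance sorc_fit
#' @export
glance.sorc_fit <- function(x, ...) {
  tibble(
    R = x$R,
    n_variants = nrow(x$stability),
    n_rare = sum(x$stability$is_rare),
    n_common = sum(!x$stability$is_rare),
    mean_n_selected = mean(x$repetitions$n_nonzero),
    median_lambda = stats::median(x$repetitions$lambda),
    max_stability = max(x$stability$stability)
  )
}

#' Plot per-variant stabilities
#'
#' Lollipop plot of the top variants by stability, coloured by gene.
#'
#' @param object a `sorc_fit`.
#' @param top_n how many variants to show (default 30).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot sorc_fit
#' @export
autoplot.sorc_fit <- function(object, top_n = 30, ...) {
  df <- head(tidy(object), top_n)
  df$variant_id <- stats::reorder(df$variant_id, df$stability)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stability, y = .data$variant_id,
                                   colour = .data$gene)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$stability,
                                       yend = .data$variant_id),
                          linewidth = 0.3, colour = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "stability (selection frequency)", y = NULL,
                  colour = "gene") +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' Rank variants by stability
#'
#' @param st a `sorc_fit` or its [tidy.sorc_fit()] tibble.
#' @param top_t flag the top-`top_t` variants (default 15).
#' @return tibble sorted by stability descending (ties broken by variant
#'   id) with columns `rank`, `variant_id`, `gene`, `score`, `in_top`.
#' @export
rank_variants <- function(st, top_t = 15) {
  stopifnot(top_t >= 1)
  df <- if (inherits(st, "sorc_fit")) tidy(st) else st
  df |>
    arrange(desc(.data$stability), .data$variant_id) |>
    mutate(rank = row_number(), score = .data$stability,
           in_top = .data$rank <= top_t) |>
    select("rank", "variant_id", "gene", "score", "in_top")
}

#' Rank genes by member-variant stability
#'
#' A gene's score is the maximum stability over its member variants; ties
#' are broken by the number of members with stability >= 0.5, then by gene
#' id.
#'
#' @param st a `sorc_fit` or a tibble with `variant_id`, `gene`, `stability`.
#' @return tibble: `rank`, `gene`, `score`, `n_high` (members >= 0.5).
#' @export
rank_genes <- function(st) {
  df <- if (inherits(st, "sorc_fit")) tidy(st) else st
  df |>
    group_by(.data$gene) |>
    summarise(score = max(.data$stability),
              n_high = sum(.data$stability >= 0.5), .groups = "drop") |>
    arrange(desc(.data$score), desc(.data$n_high), .data$gene) |>
    mutate(rank = row_number()) |>
    select("rank", "gene", "score", "n_high")
}

#' Count gene identifications across phenotype replicates
#'
#' A gene counts as identified in a replicate when it ranks within the top
#' `top_t` of that replicate's gene ranking.
#'
#' @param rankings list of gene rankings (tibbles with `rank`, `gene`), one
#'   per phenotype replicate.
#' @param top_t identification cut-off (default 15).
#' @return tibble `gene`, `n_identified`, sorted by count descending then
#'   gene id; every gene appearing in any ranking is reported.
#' @export
count_identifications <- function(rankings, top_t = 15) {
  stopifnot(length(rankings) >= 1)
  all_genes <- sort(unique(unlist(lapply(rankings, function(r) r$gene))))
  counts <- vapply(all_genes, function(gn) {
    sum(vapply(rankings, function(r) {
      any(r$gene == gn & r$rank <= top_t)
    }, logical(1)))
  }, integer(1))
  tibble(gene = all_genes, n_identified = as.integer(counts)) |>
    arrange(desc(.data$n_identified), .data$gene)
}
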