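#' Random two-subgroup partition of a gene's rare variants
#'
#' Draws the subgroup size `S` uniformly from `{1, ..., m}`, then samples
#' `S` of the `m` variants without replacement as the first subgroup; the
#' remainder forms the second subgroup. When `S == m` (always the case for
#' `m == 1`) the second subgroup is empty and the gene degenerates to a
#' whole-gene collapse for that repetition. Consumes the current RNG
#' stream; seed it for reproducibility.
#'
#' @param m number of rare variants in the gene (>= 1).
#' @return list with integer index vectors `subgroup1`, `subgroup2`
#'   (possibly empty), disjoint and covering `1:m`.
#' @export
random_partition <- function(m) {
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != round(m)) {
    abort("`m` must be a positive integer.")
  }
  m <- as.integer(m)
  s <- sample.int(m, 1L)
  g1 <- sort(sample.int(m, s))
  list(subgroup1 = g1, subgroup2 = setdiff(seq_len(m), g1))
}

#' Draw one repetition's collapse plans for all genes
#'
#' One independent random partition per gene, consumed from a single RNG
#' stream in sorted gene-id order so the sequence is platform-reproducible.
#'
#' @param rare_by_gene named list: gene id -> character vector of that
#'   gene's rare variant ids (each non-empty).
#' @return named list (sorted by gene id) of plans; each plan is a list of
#'   1 or 2 non-empty character vectors partitioning the gene's rare set.
#' @export
draw_collapse_plans <- function(rare_by_gene) {
  genes <- sort(names(rare_by_gene))
  plans <- lapply(genes, function(gn) {
    ids <- rare_by_gene[[gn]]
    part <- random_partition(length(ids))
    subs <- list(ids[part$subgroup1], ids[part$subgroup2])
    subs[lengths(subs) > 0] # empty second subgroup dropped
  })
  names(plans) <- genes
  plans
}

#' Collapse a subgroup of variants into a carrier indicator
#'
#' The burden indicator: individual `i` scores 1 when it carries a minor
#' allele at any variant of the subgroup (logical OR across columns).
#'
#' @param g a carrier-coded [genotype_matrix()].
#' @param subgroup non-empty character vector of variant ids present in `g`.
#' @return integer 0/1 vector of length `nrow(g)`.
#' @export
collapse_indicator <- function(g, subgroup) {
  stopifnot(inherits(g, "genotype_matrix"), geno_coding(g) == "carrier")
  if (length(subgroup) == 0) abort("subgroup must be non-empty.")
  missing_ids <- setdiff(subgroup, colnames(g))
  if (length(missing_ids)) {
    abort(sprintf("unknown variant id(s): %s",
                  paste(head(missing_ids, 5), collapse = ", ")))
  }
  as.integer(rowSums(g[, subgroup, drop = FALSE]) > 0)
}

#' Build the collapsed design for one repetition
#'
#' Assembles `X`, the matrix of collapsed rare-variant indicators (one
#' column per plan subgroup, in sorted (gene, subgroup) order), and `U`,
#' the uncollapsed common-variant carrier columns (input order). A gene
#' with a single rare variant contributes a column identical to that
#' variant's carrier column; common variants are never collapsed.
#'
#' @param g a carrier-coded [genotype_matrix()].
#' @param plans plans as returned by [draw_collapse_plans()].
#' @param common_ids character vector of common variant ids (may be empty).
#' @return list of class `collapsed_design`: `X` (N x sum(J_k) 0/1 matrix),
#'   `column_map` (tibble: `column`, `gene`, `subgroup`, list-column
#'   `variants`), `U` (N x C 0/1 matrix), `u_ids`.
#' @export
build_design <- function(g, plans, common_ids = character()) {
  stopifnot(inherits(g, "genotype_matrix"), geno_coding(g) == "carrier")
  rare_ids <- unlist(plans, use.names = FALSE)
  overlap <- intersect(rare_ids, common_ids)
  if (length(overlap)) {
    abort(sprintf("plan references common variant(s): %s",
                  paste(head(overlap, 5), collapse = ", ")))
  }
  genes <- names(plans)
  cols <- list(); map_gene <- character(); map_sub <- integer(); map_vars <- list()
  for (gn in genes) {
    subs <- plans[[gn]]
    for (j in seq_along(subs)) {
      cols[[length(cols) + 1L]] <- collapse_indicator(g, subs[[j]])
      map_gene <- c(map_gene, gn)
      map_sub <- c(map_sub, j)
      map_vars[[length(map_vars) + 1L]] <- subs[[j]]
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(integer(), nrow = nrow(g), ncol = 0)
  if (ncol(X)) colnames(X) <- paste0(map_gene, ".s", map_sub)
  missing_u <- setdiff(common_ids, colnames(g))
  if (length(missing_u)) {
    abort(sprintf("unknown common variant id(s): %s",
                  paste(head(missing_u, 5), collapse = ", ")))
  }
  U <- unclass(g)[, common_ids, drop = FALSE]
  structure(
    list(
      X = X,
      column_map = tibble(column = seq_along(map_gene), gene = map_gene,
                          subgroup = map_sub, variants = map_vars),
      U = U,
      u_ids = common_ids
    ),
    class = "collapsed_design"
  )
}

#' Fixed MAF-based partition of one gene's rare variants
#'
#' The predefined-criterion collapse used by the CMC baseline: rare
#' variants with `maf < cut` form one subgroup and those with
#' `cut <= maf < rare_threshold` the other; empty subgroups are dropped.
#' With `cut = NULL` the whole rare set is one subgroup.
#'
#' @param variants tibble with columns `variant_id`, `maf` for the gene's
#'   rare variants.
#' @param cut MAF cut-point in `(0, rare_threshold)`, or `NULL` for a
#'   single whole-gene subgroup.
#' @param rare_threshold rarity threshold (default 0.05).
#' @return list of non-empty character vectors (1 or 2 subgroups).
#' @export
fixed_maf_partition <- function(variants, cut = NULL, rare_threshold = 0.05) {
  if (is.null(cut)) return(list(variants$variant_id))
  stopifnot(cut > 0, cut < rare_threshold)
  subs <- list(
    variants$variant_id[variants$maf < cut],
    variants$variant_id[variants$maf >= cut & variants$maf < rare_threshold]
  )
  subs[lengths(subs) > 0]
}
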