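#' Construct a genotype matrix
#'
#' The core genotype container: an integer matrix of individuals (rows) by
#' variants (columns), either dosage-coded (0/1/2 copies of the counted
#' allele) or carrier-coded (0/1 presence of at least one minor allele).
#' Row names are individual ids and column names are variant ids.
#'
#' @param values integer matrix, individuals x variants.
#' @param coding `"dosage"` (entries 0/1/2) or `"carrier"` (entries 0/1).
#' @param individual_ids,variant_ids optional id vectors; taken from
#'   `dimnames(values)` when omitted, generated (`ind1...`, `v1...`) when
#'   absent there too.
#' @return an object of class `genotype_matrix` (an integer matrix with a
#'   `coding` attribute).
#' @export
genotype_matrix <- function(values, coding = c("dosage", "carrier"),
                            individual_ids = NULL, variant_ids = NULL) {
  coding <- match.arg(coding)
  if (!is.matrix(values)) abort("`values` must be a matrix.")
  if (nrow(values) < 1 || ncol(values) < 1) {
    abort("genotype matrix needs at least one individual and one variant.")
  }
  individual_ids <- individual_ids %||% rownames(values) %||%
    paste0("ind", seq_len(nrow(values)))
  variant_ids <- variant_ids %||% colnames(values) %||%
    paste0("v", seq_len(ncol(values)))
  if (anyDuplicated(variant_ids)) abort("duplicate variant ids.")
  if (anyDuplicated(individual_ids)) abort("duplicate individual ids.")
  storage.mode(values) <- "integer"
  check_coding(values, coding)
  dimnames(values) <- list(individual_ids, variant_ids)
  structure(values, coding = coding, class = c("genotype_matrix", "matrix", "array"))
}

check_coding <- function(values, coding) {
  alphabet <- if (coding == "dosage") c(0L, 1L, 2L) else c(0L, 1L)
  bad <- !(values %in% alphabet)
  if (any(bad)) {
    abort(sprintf(
      "coding violation: %d entr%s outside {%s} for coding '%s' (missing genotypes are not supported).",
      sum(bad), if (sum(bad) == 1) "y" else "ies",
      paste(alphabet, collapse = ","), coding
    ))
  }
  invisible(TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d individuals x %d variants, coding = %s\n",
    nrow(x), ncol(x), geno_coding(x)
  ))
  invisible(x)
}

#' Coding of a genotype matrix
#' @param g a [genotype_matrix()].
#' @return `"dosage"` or `"carrier"`.
#' @export
geno_coding <- function(g) attr(g, "coding") %||% "dosage"

#' Minor allele frequency per variant
#'
#' For dosage coding the allele count is folded to the minor allele:
#' `maf_j = min(s_j, 2N - s_j) / (2N)` with `s_j` the column sum. For
#' carrier coding only carrier status is observable, so the MAF is
#' recovered by Hardy-Weinberg inversion `1 - sqrt(1 - c_j)` from the
#' carrier fraction `c_j`, capped into `[0, 0.5]`; this is an approximation
#' that assumes HWE.
#'
#' @param g a [genotype_matrix()].
#' @return named numeric vector of MAFs in `[0, 0.5]`, one per variant.
#' @export
compute_maf <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  check_coding(unclass(g), geno_coding(g))
  n <- nrow(g)
  if (geno_coding(g) == "dosage") {
    s <- colSums(g)
    maf <- pmin(s, 2 * n - s) / (2 * n)
  } else {
    carrier_frac <- colMeans(g)
    maf <- 1 - sqrt(pmax(0, 1 - carrier_frac))
    maf <- pmin(pmax(maf, 0), 0.5)
  }
  stats::setNames(as.numeric(maf), colnames(g))
}

#' Re-orient dosages to count the minor allele
#'
#' Columns whose allele frequency exceeds 0.5 are flipped (`2 - dosage`) so
#' that dosages count minor-allele copies. No-op on carrier coding.
#'
#' @param g a dosage-coded [genotype_matrix()].
#' @return a [genotype_matrix()] with every column oriented to the minor allele.
#' @export
fold_to_minor <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (geno_coding(g) != "dosage") return(g)
  s <- colSums(g)
  flip <- s > nrow(g) # allele freq s/(2N) > 0.5
  if (any(flip)) {
    v <- unclass(g)
    v[, flip] <- 2L - v[, flip]
    g <- genotype_matrix(v, coding = "dosage",
                         individual_ids = rownames(g), variant_ids = colnames(g))
  }
  g
}

#' Recode dosages to carrier indicators
#'
#' An individual is a carrier of a variant when it holds at least one
#' minor-allele copy (`dosage >= 1`). Idempotent on carrier-coded input.
#' Dosages are assumed oriented to the minor allele (see [fold_to_minor()]).
#'
#' @param g a [genotype_matrix()].
#' @return a carrier-coded [genotype_matrix()].
#' @export
recode_to_carrier <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (geno_coding(g) == "carrier") return(g)
  v <- unclass(g)
  v <- (v > 0L) * 1L
  genotype_matrix(v, coding = "carrier",
                  individual_ids = rownames(g), variant_ids = colnames(g))
}

#' Build a variant metadata table
#'
#' @param variant_id character vector.
#' @param gene gene id per variant.
#' @param maf minor allele frequency per variant, in `[0, 0.5]`.
#' @param is_nonsynonymous logical; synonymy annotation is taken as given
#'   input, never computed (default `TRUE`).
#' @param is_functional,effect simulation ground truth (default `FALSE` / 0).
#' @param rare_threshold MAF strictly below this is "rare" (default 0.05).
#' @return a tibble with one row per variant; `is_rare` is `maf > 0 & maf <
#'   rare_threshold`.
#' @export
variant_table <- function(variant_id, gene, maf,
                          is_nonsynonymous = TRUE,
                          is_functional = FALSE, effect = 0,
                          rare_threshold = 0.05) {
  if (any(maf < 0 | maf > 0.5)) abort("maf must lie in [0, 0.5].")
  tibble(
    variant_id = as.character(variant_id),
    gene = as.character(gene),
    maf = as.numeric(maf),
    is_rare = maf > 0 & maf < rare_threshold,
    is_nonsynonymous = rep_len(is_nonsynonymous, length(variant_id)),
    is_functional = rep_len(is_functional, length(variant_id)),
    effect = rep_len(as.numeric(effect), length(variant_id))
  )
}

#' Split variants into rare and common sets
#'
#' Rare means `0 < maf < rare_threshold` (strict); common means
#' `maf >= rare_threshold`. Monomorphic variants (`maf == 0`) belong to
#' neither set and are returned separately.
#'
#' @param variants a tibble with columns `variant_id` and `maf` (e.g. from
#'   [variant_table()]).
#' @param rare_threshold threshold in `(0, 0.5]`, default 0.05.
#' @return list with character vectors `rare`, `common`, `dropped`
#'   (monomorphic).
#' @export
split_rare_common <- function(variants, rare_threshold = 0.05) {
  stopifnot(rare_threshold > 0, rare_threshold <= 0.5)
  list(
    rare = variants$variant_id[variants$maf > 0 & variants$maf < rare_threshold],
    common = variants$variant_id[variants$maf >= rare_threshold],
    dropped = variants$variant_id[variants$maf == 0]
  )
}
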