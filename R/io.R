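#' Read a genotype matrix from TSV
#'
#' Layout: header row of variant ids, first column individual ids,
#' tab-separated integer dosages (or carrier codes).
#'
#' @param path file path.
#' @param coding `"dosage"` or `"carrier"`.
#' @return a [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path, coding = "dosage") {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  if (anyNA(m)) abort("missing genotype codes in TSV; missing data are not supported.")
  genotype_matrix(m, coding = coding, individual_ids = ids,
                  variant_ids = colnames(df)[-1])
}

#' Write a genotype matrix to TSV
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(g, path) {
  df <- data.frame(individual_id = rownames(g), unclass(g),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses diploid GT fields of biallelic SNVs into a dosage matrix
#' (count of ALT alleles). Multiallelic and non-SNV records are skipped
#' with a warning; missing genotypes raise an error.
#'
#' @param path VCF path (plain or gzipped).
#' @return a dosage-coded [genotype_matrix()] whose variant ids are the
#'   VCF ID column (or `chrom:pos` when ID is missing).
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1
  if (any(!keep)) {
    warn(sprintf("skipping %d multiallelic/non-SNV record(s).", sum(!keep)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  ids <- fix[keep, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[keep, "CHROM"][noid], ":", fix[keep, "POS"][noid])
  dose <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_integer_)
    alleles <- strsplit(x, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  })
  if (anyNA(dose)) abort("missing genotypes in VCF; missing data are not supported.")
  genotype_matrix(t(dose), coding = "dosage",
                  individual_ids = colnames(gt), variant_ids = ids)
}

#' Write a minimal VCF for a dosage genotype matrix
#'
#' Synthetic single-contig coordinates (one position per variant); REF/ALT
#' fixed to A/T. Intended for round-tripping simulated cohorts.
#'
#' @param g a dosage-coded [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(g, path) {
  stopifnot(geno_coding(g) == "dosage")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrS,length=100000000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g)), collapse = "\t")
  ), con)
  gtcode <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g))) {
    row <- c("chrS", j * 100L, colnames(g)[j], "A", "T", ".", "PASS", ".",
             "GT", gtcode[unclass(g)[, j] + 1L])
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write a variant-to-gene map
#'
#' Two tab-separated columns, `variant_id` then `gene`; a header row is
#' auto-detected (first line starting with `variant_id`).
#'
#' @param path file path.
#' @return tibble `variant_id`, `gene`.
#' @export
read_gene_map_tsv <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^variant_id\\b", first)
  df <- read.delim(path, header = has_header, colClasses = "character")
  names(df)[1:2] <- c("variant_id", "gene")
  as_tibble(df[, 1:2])
}

#' @rdname read_gene_map_tsv
#' @param gene_map tibble `variant_id`, `gene`.
#' @export
write_gene_map_tsv <- function(gene_map, path) {
  write.table(gene_map[, c("variant_id", "gene")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write phenotype replicates
#'
#' Wide TSV: first column `individual_id`, one column per replicate
#' (`rep_1`, `rep_2`, ...). The in-memory form is the long tibble of
#' [simulate_phenotypes()].
#'
#' @param path file path.
#' @return long tibble `individual_id`, `replicate`, `value`.
#' @export
read_phenotype_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  long <- tidyr::pivot_longer(df, -1, names_to = "replicate",
                              values_to = "value")
  names(long)[1] <- "individual_id"
  long$replicate <- as.integer(sub("^rep_", "", long$replicate))
  long |> arrange(.data$replicate) |> as_tibble()
}

#' @rdname read_phenotype_tsv
#' @param pheno long phenotype tibble.
#' @export
write_phenotype_tsv <- function(pheno, path) {
  wide <- tidyr::pivot_wider(pheno, names_from = "replicate",
                             values_from = "value", names_prefix = "rep_")
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a stability table to TSV
#' @param fit a `sorc_fit` or its tidy tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stability_tsv <- function(fit, path) {
  df <- if (inherits(fit, "sorc_fit")) tidy(fit) else fit
  write.table(df[, c("variant_id", "gene", "maf", "stability", "rank")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ranking table to TSV
#' @param ranking tibble with `rank`, an id column and `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path) {
  id_col <- intersect(c("gene", "variant_id", "unit"), names(ranking))[1]
  df <- data.frame(rank = ranking$rank, id = ranking[[id_col]],
                   score = ranking$score)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / replay collapse plans
#'
#' One JSON object per line: `{"repetition": r, "gene": g, "subgroups":
#' [[ids...], ...]}` — an audit trail sufficient to rerun the selection
#' without re-randomizing (pass the result of [read_plans_jsonl()] as
#' `plans` to [run_sorc()]).
#'
#' @param plans list over repetitions of plan lists (from [run_sorc()] with
#'   `keep_plans = TRUE`, element `$plans`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plans_jsonl <- function(plans, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_along(plans)) {
    for (gn in names(plans[[r]])) {
      # each subgroup as an explicit JSON array so singleton subgroups
      # survive the round trip
      subs <- lapply(plans[[r]][[gn]], as.list)
      writeLines(jsonlite::toJSON(
        list(repetition = r, gene = gn, subgroups = subs),
        auto_unbox = TRUE
      ), con)
    }
  }
  invisible(path)
}

#' @rdname write_plans_jsonl
#' @export
read_plans_jsonl <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
  reps <- vapply(recs, function(x) as.integer(x$repetition), integer(1))
  out <- vector("list", max(reps))
  for (i in seq_along(recs)) {
    r <- reps[i]
    if (is.null(out[[r]])) out[[r]] <- list()
    out[[r]][[recs[[i]]$gene]] <-
      lapply(recs[[i]]$subgroups, function(s) as.character(unlist(s)))
  }
  out
}
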