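#' Phenotype table I/O
#'
#' TSV with columns `pedigree_id`, `individual_id`, `visit`, `age`, `sex`
#' (1 = male, 0 = female), `smoke`, `medicated`, `trait`.
#'
#' @param pheno Long phenotype tibble.
#' @param path File path.
#' @return `path` (writer, invisibly) or the tibble (reader).
#' @export
write_pheno_tsv <- function(pheno, path) {
  cols <- c("pedigree_id", "individual_id", "visit", "age", "sex",
            "smoke", "medicated", "trait")
  readr::write_tsv(pheno[intersect(cols, names(pheno))], path)
  invisible(path)
}

#' @rdname write_pheno_tsv
#' @export
read_pheno_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    pedigree_id = "c", individual_id = "c"))
}

#' Dosage matrix I/O as TSV
#'
#' The TSV carries one row per SNP (`snp_id`, `chrom`, `pos`, then one
#' column per individual).
#'
#' @param geno A [dosage_matrix()].
#' @param path File path.
#' @return `path` (writer, invisibly) or a [dosage_matrix()] (reader).
#' @export
write_dosage_tsv <- function(geno, path) {
  m <- snp_map(geno)
  wide <- tibble::as_tibble(t(unclass(geno)))
  readr::write_tsv(dplyr::bind_cols(m, wide), path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(snp_id = "c", chrom = "c"))
  ids <- setdiff(names(tbl), c("snp_id", "chrom", "pos"))
  mat <- t(as.matrix(tbl[ids]))
  rownames(mat) <- ids
  dosage_matrix(mat, chrom = tbl$chrom, pos = tbl$pos)
}

#' Write dosages as a VCF 4.2 file with a DS FORMAT field
#'
#' Alleles are written as placeholder REF/ALT (`A`/`B`); the dosage is the
#' expected ALT allele count.
#'
#' @param geno A [dosage_matrix()].
#' @param path Output path (plain text, uncompressed).
#' @return `path`, invisibly.
#' @export
write_vcf_ds <- function(geno, path) {
  m <- snp_map(geno)
  ids <- rownames(geno)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  body <- apply(
    cbind(m$chrom, m$pos, m$snp_id, "A", "B", ".", "PASS", ".", "DS",
          t(format(unclass(geno), trim = TRUE, digits = 6))),
    1, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read DS dosages from a VCF file
#'
#' Uses `vcfR` to parse the file and extracts the per-sample DS field.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @return A [dosage_matrix()] (individuals x SNPs).
#' @export
read_vcf_ds <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  mat <- t(ds)
  dosage_matrix(mat, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
}

#' Write the generative truth record as JSON
#'
#' @param truth The `truth` element of [simulate_longitudinal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write association results as TSV
#'
#' @param results Association result tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  readr::write_tsv(results, path)
  invisible(path)
}
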