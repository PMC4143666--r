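#' Construct and validate a pedigree table
#'
#' A pedigree table records one individual per row with links to its parents.
#' Founders have both parents missing. Individuals are grouped into pedigrees
#' (families); parent links must stay within a pedigree and must be acyclic.
#'
#' @param data A data frame with columns `pedigree_id`, `individual_id`,
#'   `father_id`, `mother_id` (use `NA` or `"0"` for a missing parent) and
#'   `sex` (`"male"`/`"female"` or the PLINK codes `1`/`2`).
#' @param strict If `TRUE`, an individual referenced as a parent but absent
#'   from the table is an error. The default materializes such individuals as
#'   founders (sex inferred from the parental role) with a warning.
#'
#' @return A tibble of class `kinlong_pedigree` with character columns
#'   `pedigree_id`, `individual_id`, `father_id`, `mother_id` (`NA` =
#'   missing) and `sex` in `"male"`/`"female"`. Row order is preserved;
#'   materialized parents are appended at the end of their pedigree's rows.
#' @export
#' @examples
#' trio <- pedigree(data.frame(
#'   pedigree_id = "F1", individual_id = c("dad", "mum", "kid"),
#'   father_id = c(NA, NA, "dad"), mother_id = c(NA, NA, "mum"),
#'   sex = c(1, 2, 1)))
pedigree <- function(data, strict = FALSE) {
  required <- c("pedigree_id", "individual_id", "father_id", "mother_id", "sex")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("pedigree data is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  ped <- tibble::as_tibble(data)[required]
  ped$pedigree_id <- as.character(ped$pedigree_id)
  ped$individual_id <- as.character(ped$individual_id)
  ped$father_id <- normalize_parent(ped$father_id)
  ped$mother_id <- normalize_parent(ped$mother_id)
  ped$sex <- normalize_sex(ped$sex)

  dup <- ped |>
    dplyr::count(.data$pedigree_id, .data$individual_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate individual_id within pedigree: ",
         paste(dup$pedigree_id, dup$individual_id, sep = ":", collapse = ", "))
  }

  ped <- materialize_parents(ped, strict = strict)
  check_acyclic(ped)
  class(ped) <- c("kinlong_pedigree", class(ped))
  ped
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x %in% c("0", "")] <- NA_character_
  x
}

normalize_sex <- function(x) {
  x <- as.character(x)
  out <- dplyr::case_match(x,
    c("1", "male")   ~ "male",
    c("2", "female") ~ "female",
    .default = NA_character_
  )
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unrecognized sex code(s): ", paste(bad, collapse = ", "),
         " (expected 1/2 or male/female)")
  }
  out
}

# Parents referenced but not listed become founders; the parental role fixes
# their sex. An id used as both father and mother is irreconcilable.
materialize_parents <- function(ped, strict = FALSE) {
  extra <- list()
  for (fid in unique(ped$pedigree_id)) {
    rows <- ped[ped$pedigree_id == fid, ]
    fathers <- setdiff(stats::na.omit(rows$father_id), rows$individual_id)
    mothers <- setdiff(stats::na.omit(rows$mother_id), rows$individual_id)
    both <- intersect(
      stats::na.omit(rows$father_id),
      stats::na.omit(rows$mother_id)
    )
    if (length(both) > 0) {
      stop("id(s) used as both father and mother in pedigree ", fid, ": ",
           paste(both, collapse = ", "))
    }
    if (strict && (length(fathers) > 0 || length(mothers) > 0)) {
      stop("parent(s) referenced but absent in pedigree ", fid, ": ",
           paste(c(fathers, mothers), collapse = ", "))
    }
    if (length(fathers) + length(mothers) > 0) {
      extra[[fid]] <- tibble::tibble(
        pedigree_id = fid,
        individual_id = c(fathers, mothers),
        father_id = NA_character_,
        mother_id = NA_character_,
        sex = c(rep("male", length(fathers)), rep("female", length(mothers)))
      )
    }
  }
  if (length(extra) > 0) {
    extra <- dplyr::bind_rows(extra)
    warning("materialized ", nrow(extra),
            " individual(s) appearing only as parents as founders: ",
            paste(utils::head(extra$individual_id, 5), collapse = ", "),
            if (nrow(extra) > 5) ", ..." else "")
    ped <- dplyr::bind_rows(ped, extra) |>
      dplyr::arrange(match(.data$pedigree_id, unique(ped$pedigree_id)))
  }
  ped
}

check_acyclic <- function(ped) {
  for (fid in unique(ped$pedigree_id)) {
    topo_order_one(ped[ped$pedigree_id == fid, ], fid)
  }
  invisible(ped)
}

# Kahn's algorithm; ties broken by input row order so results are
# deterministic. Returns row indices (within the pedigree block) in an order
# where every parent precedes its children.
topo_order_one <- function(rows, fid) {
  n <- nrow(rows)
  idx_of <- setNames(seq_len(n), rows$individual_id)
  fa <- unname(idx_of[rows$father_id])
  mo <- unname(idx_of[rows$mother_id])
  indeg <- (!is.na(fa)) + (!is.na(mo))
  done <- rep(FALSE, n)
  order_out <- integer(0)
  repeat {
    ready <- which(!done & indeg == 0L)
    if (length(ready) == 0) break
    j <- ready[1]  # smallest input index first
    done[j] <- TRUE
    order_out <- c(order_out, j)
    kids <- which(fa == j | mo == j)
    indeg[kids] <- indeg[kids] - ifelse(fa[kids] == j & !is.na(fa[kids]), 1L, 0L) -
      ifelse(mo[kids] == j & !is.na(mo[kids]), 1L, 0L)
  }
  if (length(order_out) < n) {
    cyc <- rows$individual_id[!done]
    stop("cyclic parentage in pedigree ", fid, " involving: ",
         paste(cyc, collapse = ", "))
  }
  order_out
}

#' Read a pedigree from a PLINK FAM/PED file
#'
#' Parses the first five whitespace-delimited columns (FID, IID, PAT, MAT,
#' SEX); trailing columns (the FAM phenotype, PED genotypes) are ignored.
#' Missing parents are coded `"0"`; sex is `1` = male, `2` = female (other
#' codes are rejected).
#'
#' @param path Path to the file.
#' @param dialect `"fam"` or `"ped"`; both share the leading five columns.
#' @param strict Passed to [pedigree()].
#' @return A validated [pedigree()] tibble.
#' @export
read_pedigree <- function(path, dialect = c("fam", "ped"), strict = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  short <- which(vapply(fields, length, 1L) < 5L)
  if (length(short) > 0) {
    stop("line(s) with fewer than 5 columns: ", paste(short, collapse = ", "))
  }
  m <- t(vapply(fields, function(f) f[1:5], character(5)))
  pedigree(tibble::tibble(
    pedigree_id = m[, 1], individual_id = m[, 2],
    father_id = m[, 3], mother_id = m[, 4], sex = m[, 5]
  ), strict = strict)
}

#' Write a pedigree as a PLINK FAM file
#'
#' @param ped A [pedigree()] tibble.
#' @param path Output path.
#' @param phenotype Optional numeric vector for the sixth FAM column
#'   (defaults to `-9`, PLINK's missing code).
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, phenotype = NULL) {
  sex_code <- ifelse(ped$sex == "male", 1L, 2L)
  pheno <- if (is.null(phenotype)) rep(-9, nrow(ped)) else phenotype
  out <- data.frame(
    ped$pedigree_id, ped$individual_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex_code, pheno
  )
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' @export
print.kinlong_pedigree <- function(x, ...) {
  founders <- sum(is.na(x$father_id) & is.na(x$mother_id))
  cat("<pedigree: ", nrow(x), " individuals in ",
      length(unique(x$pedigree_id)), " pedigree(s); ",
      founders, " founders>\n", sep = "")
  NextMethod()
}
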