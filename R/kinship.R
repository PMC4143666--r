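#' Kinship / numerator-relationship matrix of a pedigree
#'
#' Computes pairwise kinship coefficients by the standard recursion in
#' topological (parents-before-children) order:
#' `phi_jj = (1 + phi_fm) / 2` and `phi_jk = (phi_kf + phi_km) / 2`,
#' with a missing parent contributing 0. The matrix is block-diagonal by
#' pedigree: individuals in different pedigrees are unrelated by construction.
#'
#' @param ped A [pedigree()] tibble. Individual ids must be unique across
#'   pedigrees (they index the rows/columns of the joint matrix).
#' @param scale `"numerator"` (default) returns the numerator-relationship
#'   matrix `2 * phi`, so that the diagonal is 1 for non-inbred individuals
#'   and additive genetic variance is on its natural scale; `"phi"` returns
#'   raw kinship coefficients.
#' @return A dense symmetric matrix of class `kinship_matrix` with dimnames
#'   the individual ids in input row order, and attributes `blocks` (a named
#'   list of per-pedigree index vectors) and `scale`.
#' @export
#' @examples
#' trio <- pedigree(data.frame(
#'   pedigree_id = "F1", individual_id = c("dad", "mum", "kid"),
#'   father_id = c(NA, NA, "dad"), mother_id = c(NA, NA, "mum"),
#'   sex = c(1, 2, 1)))
#' kinship_matrix(trio, scale = "phi")["dad", "kid"]  # 0.25
kinship_matrix <- function(ped, scale = c("numerator", "phi")) {
  scale <- match.arg(scale)
  if (anyDuplicated(ped$individual_id)) {
    stop("individual ids must be globally unique to build a joint kinship matrix")
  }
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$individual_id, ped$individual_id))
  ped_ids <- unique(ped$pedigree_id)
  blocks <- lapply(ped_ids, function(fid) which(ped$pedigree_id == fid))
  names(blocks) <- ped_ids
  for (fid in ped_ids) {
    idx <- blocks[[fid]]
    K[idx, idx] <- kinship_block(ped[idx, ], fid)
  }
  if (scale == "numerator") K <- 2 * K
  structure(K, blocks = blocks, scale = scale,
            class = c("kinship_matrix", class(K)))
}

# phi matrix for a single pedigree, in that block's input row order
kinship_block <- function(rows, fid) {
  n <- nrow(rows)
  ord <- topo_order_one(rows, fid)
  idx_of <- setNames(seq_len(n), rows$individual_id)
  fa <- unname(idx_of[rows$father_id])
  mo <- unname(idx_of[rows$mother_id])
  phi <- matrix(0, n, n)
  seen <- integer(0)
  for (j in ord) {
    f <- fa[j]; m <- mo[j]
    phi_fm <- if (!is.na(f) && !is.na(m)) phi[f, m] else 0
    phi[j, j] <- 0.5 * (1 + phi_fm)
    if (length(seen) > 0) {
      pf <- if (!is.na(f)) phi[seen, f] else rep(0, length(seen))
      pm <- if (!is.na(m)) phi[seen, m] else rep(0, length(seen))
      v <- 0.5 * (pf + pm)
      phi[seen, j] <- v
      phi[j, seen] <- v
    }
    seen <- c(seen, j)
  }
  phi
}

#' Extract one pedigree's block of a kinship matrix
#'
#' @param K A [kinship_matrix()].
#' @param pedigree_id Pedigree label.
#' @return The dense square sub-matrix for that pedigree's individuals.
#' @export
block_view <- function(K, pedigree_id) {
  blocks <- attr(K, "blocks")
  if (is.null(blocks[[pedigree_id]])) {
    stop("unknown pedigree_id: ", pedigree_id)
  }
  idx <- blocks[[pedigree_id]]
  unclass(K)[idx, idx, drop = FALSE]
}

# Subset a kinship matrix to a set of individual ids, preserving the block
# attribute (indices remapped to the subset).
kinship_subset <- function(K, ids) {
  missing_ids <- setdiff(ids, rownames(K))
  if (length(missing_ids) > 0) {
    stop("individual(s) absent from kinship matrix: ",
         paste(utils::head(missing_ids, 10), collapse = ", "))
  }
  pos <- match(ids, rownames(K))
  sub <- unclass(K)[pos, pos, drop = FALSE]
  old_blocks <- attr(K, "blocks")
  blocks <- lapply(old_blocks, function(b) which(pos %in% b))
  blocks <- blocks[vapply(blocks, length, 1L) > 0]
  structure(sub, blocks = blocks, scale = attr(K, "scale"),
            class = c("kinship_matrix", "matrix", "array"))
}

#' Write a kinship matrix to disk
#'
#' `format = "pairs"` writes a TSV of the nonzero entries (`id1`, `id2`,
#' `coefficient`) with each unordered pair once (upper triangle including the
#' diagonal); `format = "dense"` writes the full labelled matrix.
#'
#' @param K A [kinship_matrix()].
#' @param path Output path.
#' @param format `"pairs"` or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(K, path, format = c("pairs", "dense")) {
  format <- match.arg(format)
  if (format == "dense") {
    df <- as.data.frame(unclass(K))
    readr::write_tsv(tibble::as_tibble(df, rownames = "individual_id"), path)
  } else {
    keep <- which(upper.tri(K, diag = TRUE) & K != 0, arr.ind = TRUE)
    readr::write_tsv(tibble::tibble(
      id1 = rownames(K)[keep[, 1]],
      id2 = colnames(K)[keep[, 2]],
      coefficient = K[keep]
    ), path)
  }
  invisible(path)
}
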