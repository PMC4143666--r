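#' Gene-drop genotypes through a pedigree
#'
#' Founders draw two alleles independently as Bernoulli(`maf`); each
#' non-founder inherits one uniformly chosen allele from each parent.
#' Dosage is the minor-allele count, so transmission is Mendelian-consistent
#' by construction and the additive genetic correlation between relatives
#' equals their numerator relationship.
#'
#' @param ped A [pedigree()] tibble.
#' @param maf Minor allele frequency in (0, 1); may be a vector of length
#'   `n`, one per variant.
#' @param n Number of independent variants to drop.
#' @return An integer matrix (individuals x variants) of dosages in 0..2,
#'   rownames the individual ids.
#' @export
gene_drop <- function(ped, maf, n = 1) {
  if (any(maf < 0) || any(maf > 1)) stop("maf must lie in [0, 1]")
  maf <- rep_len(maf, n)
  al <- drop_alleles(ped, founder_draw = function(n_founder_alleles) {
    matrix(stats::rbinom(n_founder_alleles * n, 1L,
                         rep(maf, each = n_founder_alleles)),
           nrow = n_founder_alleles)
  })
  al$a1 + al$a2
}

# Shared transmission engine. founder_draw(n_rows) returns a matrix of
# founder allele values, 2 consecutive rows per founder. Children are filled
# in topological order with vectorized parent-allele picks across variants.
drop_alleles <- function(ped, founder_draw) {
  n_ind <- nrow(ped)
  founder <- is.na(ped$father_id) & is.na(ped$mother_id)
  probe <- founder_draw(2L)
  n_var <- ncol(probe)
  a1 <- matrix(0L, n_ind, n_var, dimnames = list(ped$individual_id, NULL))
  a2 <- a1
  f_idx <- which(founder)
  fdraw <- founder_draw(2L * length(f_idx))
  a1[f_idx, ] <- fdraw[seq(1, by = 2, length.out = length(f_idx)), , drop = FALSE]
  a2[f_idx, ] <- fdraw[seq(2, by = 2, length.out = length(f_idx)), , drop = FALSE]
  idx_of <- setNames(seq_len(n_ind), ped$individual_id)
  for (fid in unique(ped$pedigree_id)) {
    rows <- which(ped$pedigree_id == fid)
    ord <- topo_order_one(ped[rows, ], fid)
    for (j in rows[ord]) {
      if (founder[j]) next
      f <- idx_of[[ped$father_id[j]]]
      m <- idx_of[[ped$mother_id[j]]]
      pick_f <- stats::runif(n_var) < 0.5
      pick_m <- stats::runif(n_var) < 0.5
      a1[j, ] <- ifelse(pick_f, a1[f, ], a2[f, ])
      a2[j, ] <- ifelse(pick_m, a1[m, ], a2[m, ])
    }
  }
  list(a1 = a1, a2 = a2)
}

#' Monte-Carlo kinship estimation by gene-dropping founder allele labels
#'
#' Drops uniquely labelled founder alleles `n_drops` times and estimates the
#' kinship coefficient of every pair (including self-kinship) as the average
#' probability that two randomly picked alleles, one from each individual,
#' are identical by descent. Serves as an independent oracle for
#' [kinship_matrix()].
#'
#' @param ped A [pedigree()] tibble (single or multiple pedigrees).
#' @param n_drops Number of independent drops.
#' @return A list with `phi` (estimated kinship matrix) and `se` (per-entry
#'   Monte-Carlo standard error of the estimate).
#' @export
gene_drop_ibd <- function(ped, n_drops = 1e5) {
  n_ind <- nrow(ped)
  label_counter <- 0L
  al <- drop_alleles(ped, founder_draw = function(n_rows) {
    out <- matrix(seq.int(label_counter + 1L,
                          label_counter + n_rows * n_drops),
                  nrow = n_rows)
    label_counter <<- label_counter + n_rows * n_drops
    out
  })
  phi <- matrix(0, n_ind, n_ind,
                dimnames = list(ped$individual_id, ped$individual_id))
  se <- phi
  for (j in seq_len(n_ind)) {
    for (k in j:n_ind) {
      share <- 0.25 * ((al$a1[j, ] == al$a1[k, ]) + (al$a1[j, ] == al$a2[k, ]) +
                       (al$a2[j, ] == al$a1[k, ]) + (al$a2[j, ] == al$a2[k, ]))
      phi[j, k] <- phi[k, j] <- mean(share)
      se[j, k] <- se[k, j] <- stats::sd(share) / sqrt(n_drops)
    }
  }
  list(phi = phi, se = se)
}

#' Simulate a panel of common SNP dosages
#'
#' Gene-drops `length(mafs)` independent SNPs through the pedigree and
#' packages them with chromosome-3-style identifiers. Optionally appends,
#' for the first `ld_pairs` SNPs, a correlated partner built by re-dropping
#' a fraction of individuals' genotypes (approximate target correlation
#' `ld_rho`), to exercise LD pruning.
#'
#' @param ped A [pedigree()] tibble.
#' @param mafs Vector of minor allele frequencies.
#' @param chrom Chromosome label used in SNP ids (`<chrom>_<pos>`).
#' @param start_pos,spacing Base-pair position of the first SNP and gap
#'   between consecutive SNPs.
#' @param ld_pairs Number of leading SNPs that get a correlated partner.
#' @param ld_rho Approximate dosage correlation of each partner (the partner
#'   copies the original for a `ld_rho` fraction of individuals and is an
#'   independent drop for the rest).
#' @return A [dosage_matrix()].
#' @export
sim_genotypes <- function(ped, mafs, chrom = 3, start_pos = 1e6,
                          spacing = 5000, ld_pairs = 0, ld_rho = 0.7) {
  n_snp <- length(mafs)
  dos <- gene_drop(ped, mafs, n = n_snp)
  if (ld_pairs > 0) {
    ld_pairs <- min(ld_pairs, n_snp)
    extra <- gene_drop(ped, mafs[seq_len(ld_pairs)], n = ld_pairs)
    keep_orig <- matrix(stats::runif(nrow(dos) * ld_pairs) < ld_rho,
                        nrow(dos), ld_pairs)
    partner <- ifelse(keep_orig, dos[, seq_len(ld_pairs), drop = FALSE], extra)
    # partners interleave right after their originals in position order
    combined <- cbind(dos, partner)
    ord <- order(c(seq_len(n_snp) * 2, seq_len(ld_pairs) * 2 + 1))
    dos <- combined[, ord, drop = FALSE]
  }
  pos <- start_pos + (seq_len(ncol(dos)) - 1L) * spacing
  dosage_matrix(dos, chrom = chrom, pos = pos)
}

#' Dosage matrix container
#'
#' @param mat Numeric matrix, individuals x SNPs, dosages in \[0, 2\];
#'   rownames are individual ids.
#' @param chrom Chromosome label(s), recycled across SNPs.
#' @param pos Base-pair positions (non-decreasing within a chromosome);
#'   SNP ids are `<chrom>_<pos>`.
#' @return The matrix with class `dosage_matrix`, colnames set to the SNP
#'   ids and a `map` attribute (tibble: snp_id, chrom, pos).
#' @export
dosage_matrix <- function(mat, chrom, pos) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), length(pos) == ncol(mat))
  if (any(mat < 0 | mat > 2)) stop("dosages must lie in [0, 2]")
  chrom <- rep_len(as.character(chrom), ncol(mat))
  ids <- paste(chrom, as.integer(pos), sep = "_")
  if (anyDuplicated(ids)) stop("duplicate snp ids (chrom_pos)")
  for (ch in unique(chrom)) {
    if (is.unsorted(pos[chrom == ch])) {
      stop("positions must be non-decreasing within a chromosome")
    }
  }
  colnames(mat) <- ids
  structure(mat,
            map = tibble::tibble(snp_id = ids, chrom = chrom,
                                 pos = as.integer(pos)),
            class = c("dosage_matrix", class(mat)))
}

#' Per-SNP minor allele frequency of a dosage matrix
#'
#' `MAF = min(f, 1 - f)` with `f = mean(dosage) / 2`.
#'
#' @param geno A [dosage_matrix()].
#' @return Named numeric vector of MAFs.
#' @export
maf <- function(geno) {
  f <- colMeans(unclass(geno)) / 2
  pmin(f, 1 - f)
}

snp_map <- function(geno) attr(geno, "map")

# Subset columns, keeping the map in sync
dosage_subset <- function(geno, snp_ids) {
  keep <- match(snp_ids, colnames(geno))
  if (anyNA(keep)) stop("unknown snp id(s)")
  m <- attr(geno, "map")[keep, ]
  structure(unclass(geno)[, keep, drop = FALSE], map = m,
            class = c("dosage_matrix", "matrix", "array"))
}
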