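#' Filter SNPs by minor allele frequency
#'
#' Keeps SNPs with estimated MAF >= `min_maf` (inclusive), where
#' `MAF = min(f, 1 - f)` and `f` is mean dosage / 2.
#'
#' @param geno A [dosage_matrix()].
#' @param min_maf Minimum minor allele frequency.
#' @return The filtered [dosage_matrix()].
#' @export
maf_filter <- function(geno, min_maf = 0.05) {
  keep <- maf(geno) >= min_maf
  dosage_subset(geno, colnames(geno)[keep])
}

#' Greedy LD pruning by pairwise dosage correlation
#'
#' Scans SNPs in position order; a SNP is kept iff its squared dosage
#' correlation with every previously kept SNP within the trailing window of
#' `window` position-ordered SNPs is below `r2_threshold`. With identical
#' SNPs the first by position wins (deterministic tie-break).
#' Zero-variance SNPs are skipped with a warning.
#'
#' @param geno A [dosage_matrix()].
#' @param r2_threshold Squared-correlation threshold; pairs at or above it
#'   may not both be kept.
#' @param window Number of preceding position-ordered SNPs compared against.
#' @return Character vector of kept SNP ids, in position order.
#' @export
ld_prune <- function(geno, r2_threshold = 0.2, window = 50L) {
  m <- snp_map(geno)
  ord <- order(m$chrom, m$pos)
  X <- unclass(geno)[, ord, drop = FALSE]
  v <- col_vars(X)
  if (any(v < 1e-12)) {
    warning("skipping ", sum(v < 1e-12), " zero-variance SNP(s)")
  }
  n_snp <- ncol(X)
  kept <- logical(n_snp)
  chroms <- m$chrom[ord]
  for (j in seq_len(n_snp)) {
    if (v[j] < 1e-12) next
    prev <- if (j == 1L) integer(0) else {
      lo <- max(1L, j - window)
      which(kept[lo:(j - 1)]) + lo - 1L
    }
    prev <- prev[chroms[prev] == chroms[j]]
    ok <- TRUE
    if (length(prev) > 0) {
      r2 <- drop(stats::cor(X[, j], X[, prev, drop = FALSE]))^2
      ok <- all(r2 < r2_threshold)
    }
    kept[j] <- ok
  }
  colnames(X)[kept]
}

#' Bonferroni significance threshold
#'
#' @param n_independent Number of (approximately) independent tests.
#' @param alpha Family-wise significance level.
#' @return `alpha / n_independent`.
#' @export
bonferroni_threshold <- function(n_independent, alpha = 0.05) {
  if (length(n_independent) != 1 || n_independent < 1) {
    stop("n_independent must be a single count >= 1")
  }
  alpha / n_independent
}

#' Genomic-control inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`; a calibrated test
#' gives lambda close to 1, inflation pushes it above 1.
#'
#' @param p Vector of p-values in (0, 1]; `NA`s are excluded with a message.
#' @return The scalar inflation factor.
#' @export
genomic_lambda <- function(p) {
  n_na <- sum(is.na(p))
  if (n_na > 0) {
    message("excluding ", n_na, " NA p-value(s)")
    p <- p[!is.na(p)]
  }
  if (length(p) == 0) stop("no p-values supplied")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Power as the proportion of significant replicates
#'
#' For each method, the proportion of simulation replicates whose
#' causal-SNP p-value falls below `threshold`, with a Wilson 95% interval.
#'
#' @param summaries Tibble with columns `method` and `p_at_causal` (one row
#'   per replicate and method), or already carrying a logical `significant`
#'   column.
#' @param threshold Significance threshold applied to `p_at_causal` when
#'   `significant` is absent.
#' @return Tibble: `method`, `n_replicates`, `n_significant`, `power`,
#'   `ci_lower`, `ci_upper`.
#' @export
estimate_power <- function(summaries, threshold = NULL) {
  if (!"significant" %in% names(summaries)) {
    if (is.null(threshold)) stop("supply a threshold or a significant column")
    summaries$significant <- summaries$p_at_causal < threshold
  }
  summaries |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      n_significant = sum(.data$significant),
      .groups = "drop"
    ) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      power = .data$n_significant / .data$n_replicates,
      ci_lower = wilson_interval(.data$n_significant, .data$n_replicates)[1],
      ci_upper = wilson_interval(.data$n_significant, .data$n_replicates)[2]
    ) |>
    dplyr::ungroup()
}

# Wilson score interval (prop.test without continuity correction)
wilson_interval <- function(x, n, conf = 0.95) {
  as.numeric(stats::prop.test(x, n, correct = FALSE,
                              conf.level = conf)$conf.int)
}

#' Top association hits per method
#'
#' The `k` smallest p-values per method, ties broken by larger `|effect|`
#' then by snp id.
#'
#' @param results An association result tibble (see [run_all()]).
#' @param k Hits per method.
#' @return The ranked tibble with a `rank` column.
#' @export
top_hits <- function(results, k = 10) {
  results |>
    dplyr::group_by(.data$method) |>
    dplyr::arrange(.data$p, dplyr::desc(abs(.data$effect)), .data$snp_id,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Plot-ready Manhattan table
#'
#' One row per (SNP, method) with `neg_log10_p`; `p = 0` is clamped to the
#' smallest positive double with a message.
#'
#' @param results An association result tibble.
#' @return Tibble: `snp_id`, `chrom`, `pos`, `method`, `neg_log10_p`.
#' @export
manhattan_export <- function(results) {
  p <- results$p
  zero <- !is.na(p) & p == 0
  if (any(zero)) {
    message("clamping ", sum(zero), " zero p-value(s) to .Machine$double.xmin")
    p[zero] <- .Machine$double.xmin
  }
  tibble::tibble(
    snp_id = results$snp_id, chrom = results$chrom, pos = results$pos,
    method = results$method, neg_log10_p = -log10(p)
  )
}
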