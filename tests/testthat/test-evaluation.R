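make_dosages <- function(cols, n_ind = 100, pos = NULL) {
  mat <- do.call(cbind, cols)
  rownames(mat) <- sprintf("i%d", seq_len(n_ind))
  if (is.null(pos)) pos <- seq_len(ncol(mat)) * 1000
  dosage_matrix(mat, chrom = 3, pos = pos)
}

test_that("MAF filtering applies the inclusive 5% rule", {
  n <- 100
  col_with_f <- function(f) c(rep(1, round(2 * n * f)),
                              rep(0, n - round(2 * n * f)))
  geno <- make_dosages(list(
    col_with_f(0.01), col_with_f(0.04), col_with_f(0.05), col_with_f(0.3),
    2 - col_with_f(0.05)  # f = 0.95 -> MAF 0.05, kept
  ))
  kept <- maf_filter(geno, 0.05)
  expect_equal(ncol(kept), 3)
  expect_setequal(colnames(kept), colnames(geno)[3:5])

  zero <- make_dosages(list(rep(0, n), col_with_f(0.2)))
  expect_equal(colnames(maf_filter(zero)), colnames(zero)[2])
})

test_that("LD pruning keeps the first of identical SNPs and all independent ones", {
  set.seed(61)
  n <- 200
  x <- rbinom(n, 2, 0.3)
  geno <- make_dosages(list(x, x), n_ind = n)
  expect_equal(ld_prune(geno), colnames(geno)[1])

  indep <- make_dosages(replicate(30, rbinom(n, 2, 0.3), simplify = FALSE),
                        n_ind = n)
  expect_equal(length(ld_prune(indep)), 30)

  const <- make_dosages(list(x, rep(1, n)), n_ind = n)
  expect_warning(kept <- ld_prune(const), "zero-variance")
  expect_equal(kept, colnames(const)[1])
})

test_that("pruning output never contains an in-window pair at or above the threshold", {
  set.seed(62)
  n <- 150
  cols <- list()
  for (i in 1:60) {
    base <- rbinom(n, 2, runif(1, 0.1, 0.5))
    cols[[2 * i - 1]] <- base
    mixed <- base
    swap <- runif(n) < 0.3
    mixed[swap] <- rbinom(sum(swap), 2, 0.3)
    cols[[2 * i]] <- mixed  # correlated partner
  }
  geno <- make_dosages(cols, n_ind = n)
  kept <- ld_prune(geno, r2_threshold = 0.2, window = 50)
  # brute-force oracle: re-check every kept pair within the window
  X <- unclass(geno)[, kept]
  idx <- match(kept, colnames(geno))
  for (a in seq_along(kept)) {
    for (b in seq_len(a - 1)) {
      if (idx[a] - idx[b] <= 50) {
        expect_lt(cor(X[, a], X[, b])^2, 0.2)
      }
    }
  }
  # roughly one of each constructed pair survives
  expect_equal(length(kept), 60, tolerance = 0.15)
})

test_that("Bonferroni thresholds divide alpha by the independent test count", {
  expect_equal(bonferroni_threshold(25676), 0.05 / 25676)
  expect_equal(bonferroni_threshold(25676), 1.9474e-6, tolerance = 1e-4)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(50), 1e-3)
  expect_error(bonferroni_threshold(0), "count")
})

test_that("genomic lambda sits at 1 for flat p-values and rises under inflation", {
  expect_equal(genomic_lambda(rep(0.5, 99)), 1.0)
  set.seed(63)
  p <- runif(20000)
  lam <- genomic_lambda(p)
  expect_equal(lam, 1, tolerance = 0.02)
  expect_gt(genomic_lambda(p / 2), lam)   # pointwise shrinkage inflates
  expect_equal(genomic_lambda(sample(p)), lam)  # order invariance
  expect_message(genomic_lambda(c(p[1:100], NA)), "excluding")
  expect_error(genomic_lambda(numeric(0)), "no p-values")
  expect_error(genomic_lambda(c(0.5, 0)), "must lie")
})

test_that("power estimation is a proportion with a Wilson interval", {
  mk <- function(n_sig, n) tibble::tibble(
    method = "m", p_at_causal = c(rep(1e-9, n_sig), rep(0.5, n - n_sig)))
  thr <- bonferroni_threshold(25676)
  expect_equal(estimate_power(mk(0, 200), thr)$power, 0)
  pw <- estimate_power(mk(44, 200), thr)
  expect_equal(pw$power, 0.22)
  expect_true(pw$ci_lower < 0.22 && pw$ci_upper > 0.22)
  expect_equal(estimate_power(mk(3, 200), threshold = 1)$power, 1)

  # monotone in the threshold
  set.seed(64)
  tbl <- tibble::tibble(method = "m", p_at_causal = runif(200))
  p1 <- estimate_power(tbl, 0.01)$power
  p2 <- estimate_power(tbl, 0.1)$power
  expect_lte(p1, p2)
})

test_that("top hits are ranked by p with deterministic tie-breaks", {
  res <- tibble::tibble(
    snp_id = c("s1", "s2", "s3", "s4"), chrom = "3", pos = 1:4,
    method = "m", effect = c(1, -2, 0.5, 3), se = 1,
    p = c(0.01, 0.01, 0.5, 0.001),
    n_individuals = 10, n_observations = 10, note = NA_character_
  )
  th <- top_hits(res, k = 3)
  expect_equal(th$snp_id, c("s4", "s2", "s1"))  # tie at 0.01 -> larger |effect|
  expect_true(!is.unsorted(th$p))
  expect_equal(nrow(top_hits(res, k = 10)), 4)
})

test_that("the Manhattan export is plot-ready and clamps p = 0", {
  res <- tibble::tibble(
    snp_id = c("a", "b"), chrom = "3", pos = c(1, 2), method = "m",
    effect = 0, se = 1, p = c(1, 0.001), n_individuals = 1,
    n_observations = 1, note = NA_character_
  )
  me <- manhattan_export(res)
  expect_equal(me$neg_log10_p, c(0, 3))
  expect_equal(nrow(me), 2)

  res$p[1] <- 0
  expect_message(me2 <- manhattan_export(res), "clamping")
  expect_true(is.finite(me2$neg_log10_p[1]))

  s <- small_sim(seed = 65, n_pedigrees = 5)
  full <- run_all(s$pheno, s$geno, s$K)
  expect_equal(nrow(manhattan_export(full)), ncol(s$geno) * 4)
  expect_s3_class(plot_manhattan(full), "ggplot")
  expect_s3_class(plot_qq(full), "ggplot")
})
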