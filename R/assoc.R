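#' Family-based association scans
#'
#' The four kinship-structured association strategies, each mapping
#' phenotypes, SNP dosages and a kinship matrix to one result row per SNP:
#'
#' * `run_baseline()` - person-level model on each person's first visit
#'   (ML).
#' * `run_lme()` - longitudinal mixed-effects model on all person-visit
#'   rows with a kinship-structured person random intercept (REML).
#' * `run_mean()` - person-level model on the mean trait (and averaged
#'   time-varying covariates) across visits (ML).
#' * `run_twostage()` - stage 1 fits the longitudinal model once without
#'   any SNP and extracts per-person random-intercept BLUPs; stage 2
#'   regresses the BLUPs on each SNP (intercept + SNP only) with its own
#'   kinship random effect (ML). Stage 1 is SNP-independent, making this
#'   the fastest exact per-SNP method.
#'
#' In the default `mode = "exact"` the variance components are re-estimated
#' for every SNP and the SNP coefficient is Wald-tested. `mode = "fast"`
#' freezes the variance components at the no-SNP null fit and score-tests
#' each SNP against the implied covariance; the reported effect and SE are
#' the one-step (score/information) estimates. The fast path is fully
#' vectorized across SNPs and is intended for large null calibrations.
#'
#' SNPs with (near) zero dosage variance among analyzed individuals are
#' flagged `monomorphic` with `p = 1`.
#'
#' @param pheno Person-level tibble (from [extract_baseline()] /
#'   [mean_over_visits()]) for `run_baseline`/`run_mean`, or the long
#'   person-visit tibble for `run_lme`/`run_twostage`.
#' @param geno A [dosage_matrix()] whose rownames cover every analyzed
#'   individual.
#' @param K A [kinship_matrix()] covering every analyzed individual.
#' @param covariates Character vector of covariate column names (see
#'   [build_covariates()]).
#' @param trait Trait column name.
#' @param mode `"exact"` (per-SNP variance-component refits) or `"fast"`
#'   (frozen null variance components + score test).
#' @param criterion Optional override of the estimation criterion; defaults
#'   follow the method (REML for `run_lme`, ML elsewhere).
#' @param id Individual-id column name.
#' @return A tibble with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `method`, `effect`, `se`, `p`, `n_individuals`, `n_observations`,
#'   `note`.
#' @name assoc_methods
NULL

#' @rdname assoc_methods
#' @export
run_baseline <- function(pheno, geno, K, covariates = c("age", "sex", "smoke"),
                         trait = "trait", mode = c("exact", "fast"),
                         criterion = "ML", id = "individual_id") {
  assoc_engine(pheno, geno, K, covariates, trait, match.arg(mode),
               criterion, id, method = "baseline")
}

#' @rdname assoc_methods
#' @export
run_mean <- function(pheno, geno, K, covariates = c("age", "sex", "smoke"),
                     trait = "trait", mode = c("exact", "fast"),
                     criterion = "ML", id = "individual_id") {
  assoc_engine(pheno, geno, K, covariates, trait, match.arg(mode),
               criterion, id, method = "mean")
}

#' @rdname assoc_methods
#' @export
run_lme <- function(pheno, geno, K, covariates = c("age", "sex", "smoke"),
                    trait = "trait", mode = c("exact", "fast"),
                    criterion = "REML", id = "individual_id") {
  assoc_engine(pheno, geno, K, covariates, trait, match.arg(mode),
               criterion, id, method = "lme")
}

#' @rdname assoc_methods
#' @export
run_twostage <- function(pheno, geno, K,
                         covariates = c("age", "sex", "smoke"),
                         trait = "trait", mode = c("exact", "fast"),
                         criterion = "ML", id = "individual_id") {
  stage1 <- fit_lmm(pheno, stats::reformulate(covariates, response = trait),
                    K, id = id, criterion = criterion)
  if (!stage1$converged) stop("stage-1 longitudinal fit did not converge")
  alpha <- blup(stage1)
  names(alpha)[names(alpha) == "individual_id"] <- id
  if (stats::var(alpha$blup) < 1e-12) {
    # full shrinkage: the stage-2 response carries no signal
    m <- snp_map(geno)
    return(tibble::tibble(
      snp_id = m$snp_id, chrom = m$chrom, pos = m$pos, method = "twostage",
      effect = 0, se = Inf, p = 1,
      n_individuals = nrow(alpha), n_observations = nrow(alpha),
      note = "degenerate-stage1"
    ))
  }
  assoc_engine(alpha, geno, K, covariates = NULL, trait = "blup",
               match.arg(mode), criterion, id, method = "twostage")
}

#' Run all four association methods on a longitudinal phenotype table
#'
#' Applies the preprocessing pipeline per method (medication imputation if
#' any visit is flagged, baseline/mean/longitudinal views, trait-specific
#' covariate construction) and then the four runners on a shared,
#' alignment-checked set of individuals.
#'
#' @param pheno_long Long person-visit tibble.
#' @param geno A [dosage_matrix()].
#' @param K A [kinship_matrix()].
#' @param trait_kind `"sbp_like"` or `"dbp_like"` (see
#'   [build_covariates()]).
#' @param trait Trait column name.
#' @param mode `"exact"` or `"fast"`.
#' @param impute Impute medicated values first (default: yes, when any row
#'   is flagged).
#' @return Row-bound results of the four methods (4 x SNPs rows).
#' @export
run_all <- function(pheno_long, geno, K, trait_kind = "sbp_like",
                    trait = "trait", mode = c("exact", "fast"),
                    impute = TRUE) {
  mode <- match.arg(mode)
  check_alignment(pheno_long, geno, K)
  if (impute && any(pheno_long$medicated == 1)) {
    pheno_long <- impute_medicated(pheno_long, trait = trait)
  }
  base_cv <- build_covariates(extract_baseline(pheno_long, trait), trait_kind)
  mean_cv <- build_covariates(mean_over_visits(pheno_long, trait), trait_kind)
  long_cv <- build_covariates(pheno_long, trait_kind)
  dplyr::bind_rows(
    run_baseline(base_cv$data, geno, K, base_cv$covariates, trait, mode),
    run_lme(long_cv$data, geno, K, long_cv$covariates, trait, mode),
    run_mean(mean_cv$data, geno, K, mean_cv$covariates, trait, mode),
    run_twostage(long_cv$data, geno, K, long_cv$covariates, trait, mode)
  )
}

check_alignment <- function(pheno, geno, K, id = "individual_id") {
  ids <- unique(as.character(pheno[[id]]))
  miss_k <- setdiff(ids, rownames(K))
  miss_g <- setdiff(ids, rownames(geno))
  if (length(miss_k) > 0 || length(miss_g) > 0) {
    stop("individual(s) missing from ",
         if (length(miss_k) > 0) paste0("kinship matrix: ",
           paste(utils::head(miss_k, 10), collapse = ", "), "; ") else "",
         if (length(miss_g) > 0) paste0("genotypes: ",
           paste(utils::head(miss_g, 10), collapse = ", ")) else "")
  }
  invisible(TRUE)
}

# Shared scan over SNPs. Builds the rotated base design once; exact mode
# re-optimizes the variance ratio per SNP, fast mode freezes it at the null
# fit and computes vectorized score tests in column chunks.
assoc_engine <- function(pheno, geno, K, covariates, trait, mode,
                         criterion, id, method, chunk = 2000L) {
  check_alignment(pheno, geno, K, id = id)
  fml <- if (is.null(covariates) || length(covariates) == 0) {
    stats::reformulate("1", response = trait)
  } else {
    stats::reformulate(covariates, response = trait)
  }
  md <- lmm_model_data(pheno, fml, K, id)
  m <- snp_map(geno)
  n_snp <- nrow(m)
  S_person <- unclass(geno)[md$persons, , drop = FALSE]
  storage.mode(S_person) <- "double"
  dos_var <- col_vars(S_person)
  mono <- unname(dos_var < 1e-12)

  null_best <- lmm_optimize(md$ty, md$tX, md$decomp$d, criterion)
  at <- lmm_profile_eval(null_best$delta, md$ty, md$tX, md$decomp$d, criterion)

  effect <- numeric(n_snp); se <- rep(NA_real_, n_snp); p <- rep(1, n_snp)
  row_of_person <- match(md$person, md$persons)

  if (mode == "fast") {
    w <- at$w
    wres <- w * at$resid
    XtWX_inv <- chol2inv(at$chol_XtWX)
    for (start in seq(1, n_snp, by = chunk)) {
      cols <- start:min(start + chunk - 1L, n_snp)
      live <- cols[!mono[cols]]
      if (length(live) == 0) next
      S_rows <- S_person[row_of_person, live, drop = FALSE]
      tS <- rotate_rows(S_rows, md$decomp)
      score <- drop(crossprod(tS, wres)) / at$s2
      B <- crossprod(md$tX, w * tS)                     # p x m
      info <- (colSums(w * tS^2) - colSums(B * (XtWX_inv %*% B))) / at$s2
      ok <- info > 1e-12
      eff <- ifelse(ok, score / info, 0)
      effect[live] <- eff
      se[live] <- ifelse(ok, 1 / sqrt(info), Inf)
      chisq <- ifelse(ok, score^2 / info, 0)
      p[live] <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    }
  } else {
    for (j in which(!mono)) {
      s_rows <- S_person[row_of_person, j]
      ts <- rotate_rows(s_rows, md$decomp)
      tX2 <- cbind(md$tX, snp = ts)
      best <- lmm_optimize(md$ty, tX2, md$decomp$d, criterion)
      at_j <- lmm_profile_eval(best$delta, md$ty, tX2, md$decomp$d, criterion)
      k <- ncol(tX2)
      est <- at_j$beta[k]
      se_j <- sqrt(at_j$s2 * chol2inv(at_j$chol_XtWX)[k, k])
      z <- est / se_j
      effect[j] <- est
      se[j] <- se_j
      p[j] <- 2 * stats::pnorm(-abs(z))
    }
  }
  se[mono] <- Inf
  tibble::tibble(
    snp_id = m$snp_id, chrom = m$chrom, pos = m$pos, method = method,
    effect = effect, se = se, p = p,
    n_individuals = length(md$persons), n_observations = md$decomp$n,
    note = ifelse(mono, "monomorphic", NA_character_)
  )
}

# column variances without extra dependencies
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}
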