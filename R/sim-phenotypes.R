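#' Draw kinship-structured polygenic effects
#'
#' Samples one multivariate-normal vector with covariance
#' `var_g * K`, pedigree block by pedigree block (eigendecomposition of each
#' block; eigenvalues clipped at zero up to round-off).
#'
#' @param K A [kinship_matrix()].
#' @param var_g Polygenic variance (>= 0).
#' @return Named numeric vector, one effect per individual.
#' @export
simulate_polygenic <- function(K, var_g) {
  stopifnot(var_g >= 0)
  n <- nrow(K)
  out <- setNames(numeric(n), rownames(K))
  if (var_g == 0) return(out)
  blocks <- attr(K, "blocks")
  if (is.null(blocks)) blocks <- list(seq_len(n))
  for (idx in blocks) {
    B <- unclass(K)[idx, idx, drop = FALSE]
    eig <- eigen(B, symmetric = TRUE)
    if (any(eig$values < -1e-8 * max(abs(eig$values), 1))) {
      stop("kinship block is not positive semidefinite")
    }
    lam <- pmax(eig$values, 0)
    z <- stats::rnorm(length(idx))
    out[idx] <- eig$vectors %*% (sqrt(var_g * lam) * z)
  }
  out
}

#' Simulate longitudinal phenotypes on a pedigree
#'
#' Generates person-visit records following the additive model
#' `y_ijt = b0 + b_age * age_ijt + b_sex * male_ij + b_smoke * smoke_ijt
#'  + b_snp * SNP_ij + g_ij + a_ij + e_ijt`,
#' where `g` is polygenic (covariance `var_polygenic * K`), `a` is an
#' i.i.d. person-level intercept (`var_person`) and `e` i.i.d. occasion
#' noise (`var_occasion`). Baseline age depends on generation (founders
#' oldest); ages advance by `visit_gap_years` per visit; smoking is a
#' time-varying 0/1 covariate with person-level persistence. With
#' `config$dropout > 0`, a random subset of individuals attends only the
#' baseline exam. If `config$medication` is set, [apply_medication()] is
#' applied to the latent trait.
#'
#' @param ped A [pedigree()] tibble.
#' @param config A [sim_config()]; `beta_*` and `var_*` set the generative
#'   model. The RNG state is used as-is (seed handling belongs to the
#'   caller), so wrap calls in `withr::with_seed()` or `set.seed()`.
#' @param causal Optional named dosage vector (one entry per individual) for
#'   the causal SNP; scaled by `config$beta_snp`.
#' @param K Optional precomputed [kinship_matrix()] for `ped` (numerator
#'   scale); computed when missing.
#' @return A list: `pheno`, a long tibble with columns `pedigree_id`,
#'   `individual_id`, `visit`, `age`, `sex` (1 = male, 0 = female), `smoke`,
#'   `medicated`, `trait` (plus `trait_latent` when medication masking is
#'   on); and `truth`, the generative record (effect sizes, variance
#'   components, per-person `g` and `a`, causal dosages).
#' @export
simulate_longitudinal <- function(ped, config, causal = NULL, K = NULL) {
  if (is.null(K)) K <- kinship_matrix(ped, scale = "numerator")
  n <- nrow(ped)
  ids <- ped$individual_id
  b <- config$beta_covars

  g <- simulate_polygenic(K, config$var_polygenic)[ids]
  a <- stats::rnorm(n, 0, sqrt(config$var_person))
  depth <- generation_depth(ped)[ids]
  base_age <- pmax(18, 72 - 24 * depth + stats::rnorm(n, 0, 6))
  sex_male <- as.integer(ped$sex == "male")
  smoker <- stats::rbinom(n, 1L, 0.25)
  snp_term <- if (is.null(causal)) rep(0, n) else {
    stopifnot(all(ids %in% names(causal)))
    config$beta_snp * as.numeric(causal[ids])
  }

  n_visits_i <- rep(config$n_visits, n)
  if (config$dropout > 0) {
    n_visits_i[stats::runif(n) < config$dropout] <- 1L
  }

  rows <- purrr::map(seq_len(config$n_visits), function(v) {
    keep <- n_visits_i >= v
    age_v <- base_age + (v - 1) * config$visit_gap_years
    smoke_v <- stats::rbinom(n, 1L, ifelse(smoker == 1, 0.8, 0.05))
    e <- stats::rnorm(n, 0, sqrt(config$var_occasion))
    y <- b[["intercept"]] + b[["age"]] * age_v + b[["sex"]] * sex_male +
      b[["smoke"]] * smoke_v + snp_term + g + a + e
    tibble::tibble(
      pedigree_id = ped$pedigree_id, individual_id = ids,
      visit = v, age = age_v, sex = sex_male, smoke = smoke_v,
      medicated = 0L, trait = as.numeric(y)
    )[keep, ]
  })
  pheno <- dplyr::bind_rows(rows) |>
    dplyr::arrange(match(.data$individual_id, ids), .data$visit)

  truth <- list(
    beta_snp = config$beta_snp, beta_covars = b,
    var_polygenic = config$var_polygenic, var_person = config$var_person,
    var_occasion = config$var_occasion,
    g = setNames(as.numeric(g), ids), a = setNames(a, ids),
    causal_dosage = causal, n_visits = setNames(n_visits_i, ids)
  )
  if (!is.null(config$medication)) {
    pheno <- apply_medication(pheno, threshold = config$medication$threshold,
                              effect = config$medication$effect)
    truth$latent_trait <- pheno$trait_latent
  }
  list(pheno = pheno, truth = truth)
}

#' Mask high trait values with an antihypertensive-style treatment effect
#'
#' Visits whose latent trait exceeds `threshold` are flagged `medicated = 1`
#' and observed at `latent - effect`; all other visits are untouched. The
#' latent value is retained in a `trait_latent` column. This is a minimal
#' treatment model whose purpose is to make medication-aware imputation
#' exercisable.
#'
#' @param pheno A long phenotype tibble (see [simulate_longitudinal()]).
#' @param threshold Trait value above which a visit is treated.
#' @param effect Subtractive treatment effect in trait units.
#' @return `pheno` with updated `medicated`/`trait` and a `trait_latent`
#'   column.
#' @export
apply_medication <- function(pheno, threshold, effect = 10) {
  latent <- pheno$trait
  flag <- latent > threshold
  pheno$trait_latent <- latent
  pheno$medicated <- as.integer(flag)
  pheno$trait <- ifelse(flag, latent - effect, latent)
  pheno
}
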