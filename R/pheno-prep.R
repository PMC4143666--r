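#' Impute medicated blood-pressure values
#'
#' For each person-visit flagged `medicated`, the observed (on-treatment)
#' value `v` is replaced by the mean of a reference pool: all
#' pre-imputation person-visit observations of *other* subjects of the same
#' sex, aged within +/- 10 years of the subject at that visit, whose value
#' strictly exceeds `v`. Pools are always computed from pre-imputation
#' values, so the order of imputation does not matter. If a pool is empty
#' the observed value is retained and a warning is issued.
#'
#' @param tbl Long phenotype tibble with columns `individual_id`, `age`,
#'   `sex`, `medicated` and the trait column.
#' @param trait Name of the trait column.
#' @param age_window Half-width of the closed age window (years).
#' @return `tbl` with imputed trait values; an `audit` attribute records,
#'   per medicated row, the pool size and the old/new values.
#' @export
impute_medicated <- function(tbl, trait = "trait", age_window = 10) {
  if (!trait %in% names(tbl)) stop("trait column not found: ", trait)
  stopifnot(all(c("individual_id", "age", "sex", "medicated") %in% names(tbl)))
  v0 <- tbl[[trait]]
  med_rows <- which(tbl$medicated == 1)
  if (length(med_rows) == 0) return(tbl)

  new_vals <- v0
  audit <- vector("list", length(med_rows))
  empty_pool <- character(0)
  for (i in seq_along(med_rows)) {
    r <- med_rows[i]
    pool <- which(
      tbl$individual_id != tbl$individual_id[r] &
        tbl$sex == tbl$sex[r] &
        abs(tbl$age - tbl$age[r]) <= age_window &
        v0 > v0[r]
    )
    if (length(pool) > 0) {
      new_vals[r] <- mean(v0[pool])
    } else {
      empty_pool <- c(empty_pool, tbl$individual_id[r])
    }
    audit[[i]] <- tibble::tibble(
      row = r, individual_id = tbl$individual_id[r],
      visit = if ("visit" %in% names(tbl)) tbl$visit[r] else NA_integer_,
      pool_size = length(pool), observed = v0[r], imputed = new_vals[r]
    )
  }
  if (length(empty_pool) > 0) {
    warning("empty imputation pool; observed value retained for: ",
            paste(unique(empty_pool), collapse = ", "))
  }
  tbl[[trait]] <- new_vals
  attr(tbl, "audit") <- dplyr::bind_rows(audit)
  tbl
}

#' Write the imputation audit log
#'
#' @param tbl Output of [impute_medicated()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_imputation_audit <- function(tbl, path) {
  audit <- attr(tbl, "audit")
  if (is.null(audit)) audit <- tibble::tibble()
  readr::write_tsv(audit, path)
  invisible(path)
}

#' Reduce a longitudinal table to each person's baseline visit
#'
#' Keeps, per individual, the row with the smallest visit index; trait and
#' covariates are taken at that visit.
#'
#' @param tbl Long phenotype tibble.
#' @param trait Name of the trait column.
#' @return A person-level tibble (one row per individual) with
#'   `n_visits_used = 1`.
#' @export
extract_baseline <- function(tbl, trait = "trait") {
  tbl |>
    dplyr::group_by(.data$pedigree_id, .data$individual_id) |>
    dplyr::slice_min(.data$visit, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(n_visits_used = 1L) |>
    dplyr::select(-"visit")
}

#' Average a longitudinal table over each person's visits
#'
#' The trait and time-varying covariates (`age`, `smoke`) are averaged over
#' the individual's observed visits; time-invariant covariates (`sex`) pass
#' through; `n_visits_used` records the number of visits averaged.
#'
#' @inheritParams extract_baseline
#' @return A person-level tibble, one row per individual.
#' @export
mean_over_visits <- function(tbl, trait = "trait") {
  tbl |>
    dplyr::group_by(.data$pedigree_id, .data$individual_id) |>
    dplyr::summarise(
      age = mean(.data$age),
      sex = .data$sex[1],
      smoke = mean(.data$smoke),
      medicated = max(.data$medicated),
      "{trait}" := mean(.data[[trait]]),
      n_visits_used = dplyr::n(),
      .groups = "drop"
    )
}

#' Build the covariate set for a blood-pressure-like trait
#'
#' Systolic-like traits are adjusted for age, sex and smoking;
#' diastolic-like traits additionally for centered age squared, with the
#' centering mean taken over all rows of the analysis table in use.
#'
#' @param tbl Phenotype tibble (person-level or longitudinal) containing
#'   `age`, `sex`, `smoke`.
#' @param trait_kind `"sbp_like"` or `"dbp_like"`.
#' @return A list: `data` (the table, augmented with `age_c_sq` for
#'   dbp-like traits) and `covariates` (character vector of column names).
#' @export
build_covariates <- function(tbl, trait_kind = c("sbp_like", "dbp_like")) {
  trait_kind <- match.arg(trait_kind)
  needed <- c("age", "sex", "smoke")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0) {
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (trait_kind == "sbp_like") {
    return(list(data = tbl, covariates = needed))
  }
  tbl$age_c_sq <- (tbl$age - mean(tbl$age))^2
  list(data = tbl, covariates = c(needed, "age_c_sq"))
}

#' Screen candidate covariates in the kinship random-intercept model
#'
#' Each candidate is tested one at a time as the sole fixed effect (plus
#' intercept) in a linear mixed model with a kinship-structured person
#' random intercept; candidates with Wald p < `alpha` are selected.
#'
#' @param tbl Phenotype tibble (person-level or longitudinal).
#' @param K A [kinship_matrix()] covering the individuals in `tbl`.
#' @param candidates Character vector of numeric column names to screen.
#' @param trait Trait column name.
#' @param alpha Selection threshold for the Wald p-value.
#' @param criterion `"ML"` or `"REML"`.
#' @return A tibble with one row per candidate: estimate, se, p, selected.
#' @export
screen_covariates <- function(tbl, K, candidates, trait = "trait",
                              alpha = 0.05, criterion = "ML") {
  if (length(candidates) == 0) {
    return(tibble::tibble(candidate = character(0), estimate = numeric(0),
                          se = numeric(0), p = numeric(0),
                          selected = logical(0)))
  }
  bad <- candidates[!vapply(tbl[candidates], is.numeric, TRUE)]
  if (length(bad) > 0) stop("non-numeric candidate(s): ",
                            paste(bad, collapse = ", "))
  purrr::map_dfr(candidates, function(cv) {
    fml <- stats::reformulate(cv, response = trait)
    fit <- fit_lmm(tbl, fml, K, criterion = criterion)
    w <- wald_test(fit, cv)
    tibble::tibble(candidate = cv, estimate = w$estimate, se = w$se,
                   p = w$p, selected = w$p < alpha)
  })
}
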