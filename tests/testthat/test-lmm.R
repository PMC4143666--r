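test_that("zero-noise data are fit exactly with variances at the boundary", {
  ped <- build_pedigrees(sim_config(n_pedigrees = 6,
                                    pedigree_template = "sibship",
                                    template_size = 3))
  K <- kinship_matrix(ped)
  set.seed(1)
  dat <- tibble::tibble(individual_id = ped$individual_id, x = rnorm(nrow(ped)))
  dat$trait <- 2 + 3 * dat$x
  fit <- fit_lmm(dat, trait ~ x, K)
  expect_equal(fit$beta$estimate, c(2, 3), tolerance = 1e-8)
  expect_lt(fit$vc[["var_kin"]] + fit$vc[["var_resid"]], 1e-10)
})

test_that("with unrelated singletons the GLS estimate collapses to OLS", {
  n <- 60
  singles <- pedigree(data.frame(
    pedigree_id = sprintf("S%d", 1:n), individual_id = sprintf("i%d", 1:n),
    father_id = NA, mother_id = NA, sex = 1
  ))
  K <- kinship_matrix(singles)
  set.seed(2)
  dat <- tibble::tibble(individual_id = singles$individual_id,
                        x = rnorm(n), trait = 1 + 0.7 * rnorm(n) + rnorm(n))
  fit <- fit_lmm(dat, trait ~ x, K)
  ols <- lm(trait ~ x, dat)
  expect_equal(fit$beta$estimate, unname(coef(ols)), tolerance = 1e-7)
  # components are not separately identified, but their sum is the ML
  # residual variance
  expect_equal(fit$vc[["var_kin"]] + fit$vc[["var_resid"]],
               mean(resid(ols)^2), tolerance = 1e-6)
})

test_that("profiled likelihood equals the dense log-density at arbitrary parameters", {
  s <- small_sim(seed = 41, n_pedigrees = 3, k = 3)
  mt <- mean_over_visits(s$pheno)
  for (crit in c("ML", "REML")) {
    md <- kinlong:::lmm_model_data(mt, trait ~ age + sex, s$K)
    Z <- incidence_matrix(md$person)
    Kmat <- unclass(s$K)[colnames(Z), colnames(Z)]
    set.seed(43)
    for (i in 1:20) {
      delta <- 10^runif(1, -3, 3)
      prof <- kinlong:::lmm_profile_eval(delta, md$ty, md$tX, md$decomp$d, crit)
      # dense loglik at (var_kin = delta * s2, var_resid = s2)
      V <- prof$s2 * (delta * Z %*% Kmat %*% t(Z) + diag(length(md$y)))
      expect_equal(prof$ll, dense_loglik(md$y, md$X, V, crit),
                   tolerance = 1e-6)
    }
  }
})

test_that("ML and REML agree closely on a large balanced family sample", {
  cfg <- sim_config(n_pedigrees = 300, pedigree_template = "sibship",
                    template_size = 4, var_person = 0, var_occasion = 1,
                    n_visits = 1)
  ped <- build_pedigrees(cfg)
  K <- kinship_matrix(ped)
  set.seed(44)
  sim <- simulate_longitudinal(ped, cfg, K = K)
  fml <- trait ~ age + sex + smoke
  f_ml <- fit_lmm(sim$pheno, fml, K, criterion = "ML")
  f_reml <- fit_lmm(sim$pheno, fml, K, criterion = "REML")
  expect_equal(f_ml$vc[["var_kin"]], f_reml$vc[["var_kin"]], tolerance = 0.02)
  expect_equal(f_ml$vc[["var_resid"]], f_reml$vc[["var_resid"]],
               tolerance = 0.02)
})

test_that("Wald tests behave at their reference points", {
  fit <- structure(list(beta = tibble::tibble(
    term = c("a", "b"), estimate = c(0, 1.959964), se = c(1, 1)
  )), class = "kinlong_fit")
  expect_equal(wald_test(fit, "a")$p, 1)
  expect_equal(wald_test(fit, "b")$p, 0.05, tolerance = 1e-6)
  expect_error(wald_test(fit, "zzz"), "unknown")
})

test_that("BLUPs match the dense formula and respect block independence", {
  s <- small_sim(seed = 45, n_pedigrees = 4, k = 3)
  fit <- fit_lmm(s$pheno, trait ~ age + sex + smoke, s$K, criterion = "REML")
  md <- fit$data
  Z <- incidence_matrix(md$person)
  Kmat <- unclass(s$K)[colnames(Z), colnames(Z)]
  ab <- dense_blup(md$y, md$X, Kmat, Z, fit$vc[["var_kin"]],
                   fit$vc[["var_resid"]], fit$beta$estimate)
  expect_equal(unname(fit$blups[colnames(Z)]), unname(ab), tolerance = 1e-8)

  # shuffling the rows of other pedigrees leaves a pedigree's BLUPs alone
  ph <- s$pheno
  others <- ph$pedigree_id != "P1"
  ph2 <- dplyr::bind_rows(ph[!others, ], ph[others, ][sample(sum(others)), ])
  fit2 <- fit_lmm(ph2, trait ~ age + sex + smoke, s$K, criterion = "REML")
  p1 <- s$ped$individual_id[s$ped$pedigree_id == "P1"]
  expect_equal(fit2$blups[p1], fit$blups[p1], tolerance = 1e-6)
})

test_that("BLUPs shrink toward zero as the variance ratio shrinks", {
  s <- small_sim(seed = 46, n_pedigrees = 4, k = 3)
  md <- kinlong:::lmm_model_data(mean_over_visits(s$pheno),
                                 trait ~ age + sex, s$K)
  blup_at <- function(delta) {
    at <- kinlong:::lmm_profile_eval(delta, md$ty, md$tX, md$decomp$d, "ML")
    kinlong:::lmm_blup_internal(md, delta, at)
  }
  deltas <- c(0, 0.01, 0.1, 1, 10)
  norms <- vapply(deltas, function(d) sqrt(sum(blup_at(d)^2)), 0)
  expect_equal(norms[1], 0)                 # full shrinkage at delta = 0
  expect_true(all(diff(norms) > 0))         # overall shrinkage is monotone
})

test_that("degenerate designs error and missing rows are dropped with a message", {
  s <- small_sim(seed = 47, n_pedigrees = 2, k = 2)
  mt <- mean_over_visits(s$pheno)
  mt$dup <- mt$age
  expect_error(fit_lmm(mt, trait ~ age + dup, s$K), "singular")
  mt$age[1] <- NA
  expect_message(fit_lmm(mt, trait ~ age + sex, s$K), "dropping 1 row")
})

test_that("tidy and glance return the broom-style summaries", {
  s <- small_sim(seed = 48, n_pedigrees = 3, k = 2)
  fit <- fit_lmm(mean_over_visits(s$pheno), trait ~ age + sex, s$K)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_true(all(c("logLik", "var_kin", "var_resid", "nobs") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})
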