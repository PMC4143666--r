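test_that("pedigree templates produce the expected counts, deterministically", {
  cfg <- sim_config(n_pedigrees = 125, pedigree_template = "sibship",
                    template_size = 4)
  ped <- build_pedigrees(cfg)
  expect_equal(nrow(ped), 750)  # 500 sibs + 250 founder parents
  expect_equal(sum(is.na(ped$father_id) & is.na(ped$mother_id)), 250)

  cfg3 <- sim_config(n_pedigrees = 20, pedigree_template = "three_generation")
  ped3 <- build_pedigrees(cfg3)
  K <- kinship_matrix(ped3)
  expect_equal(length(attr(K, "blocks")), 20)

  expect_identical(build_pedigrees(cfg), build_pedigrees(cfg))
})

test_that("identical config and seed give identical simulated data", {
  s1 <- small_sim(seed = 9)
  s2 <- small_sim(seed = 9)
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(unclass(s1$geno), unclass(s2$geno))
})

test_that("gene dropping matches its closed-form moments", {
  cfg <- sim_config(n_pedigrees = 40, pedigree_template = "sibship",
                    template_size = 2)
  ped <- build_pedigrees(cfg)

  expect_true(all(gene_drop(ped, 0, n = 3) == 0))

  set.seed(101)
  n_drop <- 20000
  dos <- gene_drop(ped, 0.3, n = n_drop)
  founders <- ped$individual_id[is.na(ped$father_id)]
  # founder dosage mean = 2 * maf
  expect_equal(mean(dos[founders, ]), 0.6, tolerance = 0.02)
  # additive correlation between full sibs = 2 * phi = 0.5
  sib1 <- ped$individual_id[grepl("_I3$", ped$individual_id)]
  sib2 <- ped$individual_id[grepl("_I4$", ped$individual_id)]
  r <- cor(as.vector(dos[sib1, ]), as.vector(dos[sib2, ]))
  expect_equal(r, 0.5, tolerance = 3 / sqrt(n_drop * length(sib1)) * 10)
  expect_true(all(dos >= 0 & dos <= 2))
})

test_that("gene-dropped correlation structure agrees with the kinship matrix", {
  ped <- trio_pedigree()
  K <- kinship_matrix(ped)
  set.seed(11)
  dos <- gene_drop(ped, 0.4, n = 50000)
  emp <- cor(t(dos))
  expect_equal(emp["dad", "kid"], unclass(K)["dad", "kid"], tolerance = 0.02)
  expect_equal(emp["dad", "mum"], 0, tolerance = 0.02)
})

test_that("polygenic simulation honours the kinship covariance", {
  ped <- pedigree(data.frame(
    pedigree_id = "F1", individual_id = c("p1", "p2", "a", "b"),
    father_id = c(NA, NA, "p1", "p1"), mother_id = c(NA, NA, "p2", "p2"),
    sex = c(1, 2, 1, 2)
  ))
  K <- kinship_matrix(ped)
  expect_identical(simulate_polygenic(K, 0), setNames(numeric(4), rownames(K)))
  set.seed(5)
  reps <- t(vapply(1:10000, function(i) simulate_polygenic(K, 2), numeric(4)))
  emp <- cov(reps)
  expect_equal(emp, 2 * unclass(K), ignore_attr = TRUE, tolerance = 0.12)

  singles <- pedigree(data.frame(
    pedigree_id = sprintf("S%d", 1:2000), individual_id = sprintf("i%d", 1:2000),
    father_id = NA, mother_id = NA, sex = 1
  ))
  Ks <- kinship_matrix(singles)
  set.seed(6)
  g <- simulate_polygenic(Ks, 3)
  expect_equal(var(g), 3, tolerance = 0.3)  # iid with variance var_g * diag
})

test_that("the longitudinal generator obeys its variance identities", {
  # no noise, no SNP: trait is an exact linear function of the covariates
  cfg0 <- sim_config(n_pedigrees = 5, pedigree_template = "sibship",
                     template_size = 3, var_polygenic = 0, var_person = 0,
                     var_occasion = 0)
  ped0 <- build_pedigrees(cfg0)
  set.seed(3)
  sim0 <- simulate_longitudinal(ped0, cfg0)
  b <- cfg0$beta_covars
  pred <- b[["intercept"]] + b[["age"]] * sim0$pheno$age +
    b[["sex"]] * sim0$pheno$sex + b[["smoke"]] * sim0$pheno$smoke
  expect_equal(sim0$pheno$trait, pred, tolerance = 1e-12)

  # residual variance decomposition at the visit and person-mean levels
  cfg <- sim_config(n_pedigrees = 400, pedigree_template = "sibship",
                    template_size = 4, var_polygenic = 0.5,
                    var_person = 0.5, var_occasion = 2)
  ped <- build_pedigrees(cfg)
  K <- kinship_matrix(ped)
  set.seed(4)
  sim <- simulate_longitudinal(ped, cfg, K = K)
  ph <- sim$pheno
  bb <- cfg$beta_covars
  resid <- ph$trait - (bb[["intercept"]] + bb[["age"]] * ph$age +
                         bb[["sex"]] * ph$sex + bb[["smoke"]] * ph$smoke)
  expect_equal(var(resid), 0.5 + 0.5 + 2, tolerance = 0.15)
  pm <- tapply(resid, ph$individual_id, mean)
  expect_equal(var(as.numeric(pm)), 0.5 + 0.5 + 2 / 4, tolerance = 0.12)
})

test_that("medication masking flags exactly the visits above the threshold", {
  s <- small_sim(seed = 21)
  unchanged <- apply_medication(s$pheno, threshold = Inf)
  expect_equal(unchanged$trait, s$pheno$trait)
  expect_true(all(unchanged$medicated == 0))

  all_flagged <- apply_medication(s$pheno, threshold = -Inf, effect = 5)
  expect_true(all(all_flagged$medicated == 1))
  expect_equal(all_flagged$trait, s$pheno$trait - 5)
  expect_equal(all_flagged$trait_latent, s$pheno$trait)

  # threshold at the latent 90th percentile flags about 10% of visits
  big <- small_sim(seed = 22, n_pedigrees = 200)
  q90 <- quantile(big$pheno$trait, 0.9)
  flagged <- apply_medication(big$pheno, threshold = q90)
  expect_equal(mean(flagged$medicated), 0.1, tolerance = 0.01)
})

test_that("dropout leaves only baseline visits for the affected individuals", {
  cfg <- sim_config(n_pedigrees = 100, pedigree_template = "sibship",
                    template_size = 2, dropout = 0.3)
  ped <- build_pedigrees(cfg)
  set.seed(8)
  sim <- simulate_longitudinal(ped, cfg)
  nv <- table(sim$pheno$individual_id)
  expect_true(all(nv %in% c(1, 4)))
  expect_equal(mean(nv == 1), 0.3, tolerance = 0.07)
})
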