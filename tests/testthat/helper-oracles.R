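# Independent oracles and fixtures shared across tests.

# Dense multivariate-normal (restricted) log-likelihood with GLS beta,
# computed straight from the covariance matrix -- no profiling, no
# eigendecomposition. Cross-checks the package's profiled engine.
dense_loglik <- function(y, X, V, criterion = "ML") {
  n <- length(y)
  p <- ncol(X)
  ch <- chol(V)
  Vi <- chol2inv(ch)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- drop(t(r) %*% Vi %*% r)
  logdetV <- 2 * sum(log(diag(ch)))
  if (criterion == "ML") {
    -0.5 * (n * log(2 * pi) + logdetV + quad)
  } else {
    -0.5 * ((n - p) * log(2 * pi) + logdetV +
              as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) + quad)
  }
}

# Dense-matrix BLUP: var_kin * K Z' V^{-1} (y - X beta)
dense_blup <- function(y, X, K, Z, var_kin, var_resid, beta) {
  V <- var_kin * Z %*% K %*% t(Z) + var_resid * diag(length(y))
  drop(var_kin * K %*% t(Z) %*% solve(V, y - X %*% beta))
}

# Brute-force maximization of the dense likelihood over the two variance
# components: coarse log-grid then Nelder-Mead refinement. Independent of
# the package's 1-D profiled search.
dense_grid_optimum <- function(y, X, K, Z, criterion = "ML") {
  obj <- function(par) {
    V <- exp(par[1]) * Z %*% K %*% t(Z) + exp(par[2]) * diag(length(y))
    -dense_loglik(y, X, V, criterion)
  }
  gr <- expand.grid(a = seq(-9, 4, length.out = 27),
                    b = seq(-9, 4, length.out = 27))
  vals <- apply(gr, 1, function(r) tryCatch(obj(as.numeric(r)),
                                            error = function(e) Inf))
  start <- as.numeric(gr[which.min(vals), ])
  op <- stats::optim(start, obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-15, maxit = 10000))
  list(loglik = -op$value, var_kin = exp(op$par[1]),
       var_resid = exp(op$par[2]))
}

incidence_matrix <- function(person) {
  persons <- unique(person)
  Z <- matrix(0, length(person), length(persons))
  Z[cbind(seq_along(person), match(person, persons))] <- 1
  colnames(Z) <- persons
  Z
}

trio_pedigree <- function() {
  pedigree(data.frame(
    pedigree_id = "F1",
    individual_id = c("dad", "mum", "kid"),
    father_id = c(NA, NA, "dad"),
    mother_id = c(NA, NA, "mum"),
    sex = c(1, 2, 1)
  ))
}

# Pedigree whose last member is the child of a full-sib mating:
# phi_self = 0.5 * (1 + 0.25) = 0.625.
sib_mating_pedigree <- function() {
  pedigree(data.frame(
    pedigree_id = "F1",
    individual_id = c("gp1", "gp2", "s1", "s2", "inbred"),
    father_id = c(NA, NA, "gp1", "gp1", "s1"),
    mother_id = c(NA, NA, "gp2", "gp2", "s2"),
    sex = c(1, 2, 1, 2, 1)
  ))
}

# 20-member, 3-generation pedigree with two inbreeding loops: a full-sib
# mating (R, S and their children) and a first-cousin mating (O, P, Q).
inbred20_pedigree <- function() {
  pedigree(data.frame(
    pedigree_id = "X1",
    individual_id = c("A", "B", "C", "D", "E", "F", "G", "H",
                      "J", "K", "L", "M", "N",
                      "O", "P", "Q", "R", "S", "T", "U"),
    father_id = c(NA, NA, NA, NA, "A", "A", "C", "C",
                  "E", "E", "E", "H", "H",
                  "J", "J", "J", "K", "K", "R", "R"),
    mother_id = c(NA, NA, NA, NA, "B", "B", "D", "D",
                  "G", "G", "G", "F", "F",
                  "M", "M", "M", "L", "L", "Q", "Q"),
    sex = c(1, 2, 1, 2, 1, 2, 2, 1,
            1, 1, 2, 2, 1,
            2, 1, 2, 1, 2, 1, 2)
  ))
}

# A small longitudinal dataset with known structure, for smoke tests.
small_sim <- function(seed = 1, n_pedigrees = 20, template = "sibship",
                      k = 4, beta_snp = 0, n_snps = 5, ...) {
  cfg <- sim_config(n_pedigrees = n_pedigrees, pedigree_template = template,
                    template_size = k, beta_snp = beta_snp,
                    n_snps = n_snps, seed = seed, ...)
  ped <- build_pedigrees(cfg)
  K <- kinship_matrix(ped)
  set.seed(seed)
  geno <- sim_genotypes(ped, runif(n_snps, 0.05, 0.5))
  causal <- if (beta_snp != 0) setNames(unclass(geno)[, 1], rownames(geno)) else NULL
  sim <- simulate_longitudinal(ped, cfg, causal = causal, K = K)
  list(cfg = cfg, ped = ped, K = K, geno = geno,
       pheno = sim$pheno, truth = sim$truth)
}
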