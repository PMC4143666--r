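#' Fit a kinship-structured linear mixed model
#'
#' Fits `y = X beta + Z alpha + e` with `alpha ~ N(0, var_kin * K)` over
#' individuals (a single person-level random intercept whose covariance is
#' the kinship matrix) and `e ~ N(0, var_resid * I)` over observations, by
#' maximum likelihood or restricted maximum likelihood.
#'
#' The likelihood is profiled down to one dimension: with
#' `delta = var_kin / var_resid`, each pedigree block of `Z K Z'` is
#' eigendecomposed once, the model is rotated into the eigenbasis where the
#' covariance is diagonal, and `beta` and the total scale are solved in
#' closed form at each `delta`. The optimum over `delta` is located on a
#' 64-point log grid on \[1e-6, 1e6\] refined by Brent's method
#' (`delta = 0` is always evaluated as a boundary candidate).
#'
#' @param data Data frame with the response, covariates and an individual-id
#'   column; rows with missing values in modelled variables are dropped with
#'   a message.
#' @param formula Model formula for the fixed effects, e.g.
#'   `trait ~ age + sex + smoke`.
#' @param K A [kinship_matrix()] covering every individual in `data`.
#' @param id Name of the individual-id column (maps rows to `K`).
#' @param criterion `"ML"` or `"REML"`.
#' @return An object of class `kinlong_fit`: fixed-effect estimates and
#'   standard errors, variance components (`var_kin`, `var_resid`), the
#'   maximized (restricted) log-likelihood, per-person BLUPs of the random
#'   intercept, and a convergence/boundary flag. Standard errors come from
#'   the inverse expected information of the GLS step at the variance
#'   optimum.
#' @export
fit_lmm <- function(data, formula, K, id = "individual_id",
                    criterion = c("ML", "REML")) {
  criterion <- match.arg(criterion)
  md <- lmm_model_data(data, formula, K, id)
  fit <- lmm_fit_profiled(md, criterion)
  fit$call <- match.call()
  fit
}

# Build the aligned model pieces: y, X, person index, block decomposition.
lmm_model_data <- function(data, formula, K, id = "individual_id") {
  if (!id %in% names(data)) stop("id column not found: ", id)
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    stop("variable(s) not in data: ", paste(missing_vars, collapse = ", "))
  }
  ok <- stats::complete.cases(data[vars])
  if (!all(ok)) {
    message("dropping ", sum(!ok), " row(s) with missing modelled values")
    data <- data[ok, ]
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design matrix is singular")
  person <- as.character(data[[id]])
  persons <- unique(person)
  Ksub <- kinship_subset(K, persons)
  decomp <- lmm_decompose(Ksub, person)
  list(y = y, X = X, person = person, persons = persons,
       K = Ksub, decomp = decomp,
       ty = rotate_rows(y, decomp), tX = rotate_rows(X, decomp))
}

# Per-pedigree eigendecomposition of Z K Z' (K indexed by the person of each
# row). Rows of a block need not be contiguous; index vectors track them.
lmm_decompose <- function(Ksub, person) {
  n <- length(person)
  blocks <- attr(Ksub, "blocks")
  if (is.null(blocks)) blocks <- list(seq_len(nrow(Ksub)))
  person_pos <- match(person, rownames(Ksub))
  d_all <- numeric(n)
  out_blocks <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    pidx <- blocks[[b]]                      # person indices in Ksub
    rows <- which(person_pos %in% pidx)      # observation rows of the block
    R <- unclass(Ksub)[person_pos[rows], person_pos[rows], drop = FALSE]
    eig <- eigen(R, symmetric = TRUE)
    d <- pmax(eig$values, 0)
    d_all[rows] <- d
    out_blocks[[b]] <- list(
      rows = rows, U = eig$vectors, d = d,
      persons = pidx, person_rows = person_pos[rows]
    )
  }
  list(blocks = out_blocks, d = d_all, n = n)
}

# Rotate a vector or matrix into the blockwise eigenbasis (U' x per block).
rotate_rows <- function(x, decomp) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  out <- x
  for (b in decomp$blocks) {
    out[b$rows, ] <- crossprod(b$U, x[b$rows, , drop = FALSE])
  }
  if (vec) out[, 1] else out
}

# Profiled (restricted) log-likelihood pieces at a given variance ratio.
# In the rotated basis V = var_resid * diag(1 + delta * d).
lmm_profile_eval <- function(delta, ty, tX, d, criterion) {
  n <- length(ty)
  p <- ncol(tX)
  w <- 1 / (1 + delta * d)
  XtWX <- crossprod(tX, w * tX)
  XtWy <- crossprod(tX, w * ty)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  resid <- ty - tX %*% beta
  rss <- sum(w * resid^2)
  logdet_w <- sum(log1p(delta * d))        # log|V|/var_resid part
  if (criterion == "ML") {
    s2 <- max(rss / n, 1e-300)
    ll <- -0.5 * (n * (log(2 * pi) + log(s2) + 1) + logdet_w)
  } else {
    s2 <- max(rss / (n - p), 1e-300)
    logdet_xtwx <- 2 * sum(log(diag(ch)))
    ll <- -0.5 * ((n - p) * (log(2 * pi) + log(s2) + 1) +
                    logdet_w + logdet_xtwx)
  }
  list(ll = ll, beta = drop(beta), s2 = s2, chol_XtWX = ch, w = w,
       resid = drop(resid))
}

# Locate the optimum over the variance ratio: 64-point log10 grid on
# [1e-6, 1e6] refined by Brent; delta = 0 always competes as a boundary
# candidate.
lmm_optimize <- function(ty, tX, d, criterion) {
  obj <- function(log10_delta) {
    lmm_profile_eval(10^log10_delta, ty, tX, d, criterion)$ll
  }
  grid <- seq(-6, 6, length.out = 64)
  ll_grid <- vapply(grid, obj, 0)
  ll0 <- lmm_profile_eval(0, ty, tX, d, criterion)$ll
  best <- which.max(ll_grid)
  lo <- grid[max(best - 1, 1)]
  hi <- grid[min(best + 1, length(grid))]
  opt <- stats::optimize(obj, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  if (ll0 >= opt$objective) {
    list(delta = 0, ll = ll0, boundary = TRUE)
  } else {
    list(delta = 10^opt$maximum, ll = opt$objective,
         boundary = best %in% c(1L, length(grid)))
  }
}

lmm_fit_profiled <- function(md, criterion) {
  ty <- md$ty; tX <- md$tX; d <- md$decomp$d
  best <- lmm_optimize(ty, tX, d, criterion)
  delta <- best$delta
  ll <- best$ll
  boundary <- best$boundary
  at <- lmm_profile_eval(delta, ty, tX, d, criterion)
  se <- sqrt(at$s2 * diag(chol2inv(at$chol_XtWX)))
  beta <- setNames(at$beta, colnames(tX))
  vc <- c(var_kin = delta * at$s2, var_resid = at$s2)
  blups <- lmm_blup_internal(md, delta, at)
  structure(list(
    beta = tibble::tibble(term = names(beta), estimate = unname(beta),
                          se = unname(se)),
    vc = vc, delta = delta, loglik = ll, criterion = criterion,
    blups = blups, converged = is.finite(ll), boundary = boundary,
    n_obs = length(ty), n_individuals = length(md$persons),
    data = md
  ), class = "kinlong_fit")
}

# BLUP of the person random intercept:
#   alpha_hat = var_kin * K Z' V^{-1} (y - X beta_hat),
# evaluated blockwise in the eigenbasis where V^{-1} = W / var_resid.
lmm_blup_internal <- function(md, delta, at) {
  out <- setNames(numeric(length(md$persons)), md$persons)
  if (delta == 0) return(out)
  wr <- at$w * at$resid        # W (ty - tX beta) in rotated basis
  Kmat <- unclass(md$K)
  for (b in md$decomp$blocks) {
    vinv_r <- b$U %*% wr[b$rows]               # V^{-1} resid * var_resid
    KZt <- Kmat[b$persons, b$person_rows, drop = FALSE]
    out[b$persons] <- delta * (KZt %*% vinv_r)
  }
  out
}

#' Wald test of a fixed-effect coefficient
#'
#' Two-sided z test (`z = estimate / se`, standard-normal reference,
#' equivalent to a 1-df chi-square).
#'
#' @param fit A [fit_lmm()] result.
#' @param coef Coefficient name (a term of the fixed-effect design).
#' @return A one-row tibble: `term`, `estimate`, `se`, `statistic`, `p`.
#' @export
wald_test <- function(fit, coef) {
  row <- fit$beta[fit$beta$term == coef, ]
  if (nrow(row) == 0) stop("unknown coefficient: ", coef)
  z <- row$estimate / row$se
  tibble::tibble(term = coef, estimate = row$estimate, se = row$se,
                 statistic = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Per-person BLUPs of the random intercept
#'
#' @param fit A [fit_lmm()] result.
#' @return A tibble with `individual_id` and `blup`.
#' @export
blup <- function(fit) {
  tibble::tibble(individual_id = names(fit$blups),
                 blup = unname(fit$blups))
}

#' @export
print.kinlong_fit <- function(x, ...) {
  cat("<kinship LMM fit (", x$criterion, ")>\n", sep = "")
  cat("  n obs:", x$n_obs, " individuals:", x$n_individuals, "\n")
  cat("  var_kin:", signif(x$vc[["var_kin"]], 4),
      " var_resid:", signif(x$vc[["var_resid"]], 4), "\n")
  cat("  logLik:", signif(x$loglik, 8),
      if (x$boundary) " (boundary)" else "", "\n")
  print(x$beta)
  invisible(x)
}

#' @rdname fit_lmm
#' @param x A `kinlong_fit` object.
#' @param ... Unused.
#' @method tidy kinlong_fit
#' @export
tidy.kinlong_fit <- function(x, ...) {
  z <- x$beta$estimate / x$beta$se
  tibble::tibble(term = x$beta$term, estimate = x$beta$estimate,
                 std.error = x$beta$se, statistic = z,
                 p.value = 2 * stats::pnorm(-abs(z)))
}

#' @rdname fit_lmm
#' @method glance kinlong_fit
#' @export
glance.kinlong_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, criterion = x$criterion,
                 var_kin = x$vc[["var_kin"]], var_resid = x$vc[["var_resid"]],
                 nobs = x$n_obs, n_individuals = x$n_individuals,
                 converged = x$converged, boundary = x$boundary)
}
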