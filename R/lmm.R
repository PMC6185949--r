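# REML linear mixed models with a pedigree kinship kernel.
#
# Model: y = W alpha + x beta + g + e, g ~ N(0, sigma_g^2 A), e ~ N(0,
# sigma_e^2 I). A is eigendecomposed once; the restricted likelihood is then
# a 1-D function of the variance ratio lambda = sigma_g^2 / sigma_e^2, with
# sigma_e^2 and the fixed effects profiled out in the rotated basis.

.RATIO_RANGE <- c(1e-5, 1e5)

#' Eigendecompose a kinship kernel for repeated mixed-model fits
#'
#' Scans and simulations fit hundreds of models against one kinship matrix;
#' decomposing it once and rotating the data makes each subsequent REML fit a
#' one-dimensional optimisation. Small negative eigenvalues (numerical noise)
#' are clipped to zero; genuinely negative spectra are an error.
#'
#' @param K symmetric numerator relationship matrix.
#' @return object of class `kin_eigen` with elements `U` (eigenvectors),
#'   `d` (eigenvalues) and `ids` (rownames of `K`).
#' @export
kinship_eigen <- function(K) {
  K <- as.matrix(K)
  if (!isSymmetric(unname(K), tol = 1e-8)) stop("kinship matrix not symmetric")
  e <- eigen(K, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1)
  if (min(e$values) < -tol)
    stop("kinship matrix is not positive semi-definite (min eigenvalue ",
         format(min(e$values)), ")")
  structure(list(U = e$vectors, d = pmax(e$values, 0), ids = rownames(K)),
            class = "kin_eigen")
}

# Profiled REML log-likelihood and weighted-LS pieces at one lambda, in the
# rotated basis (yr = U'y, Xr = U'X).
.reml_pieces <- function(lambda, yr, Xr, d) {
  n <- length(yr)
  p <- ncol(Xr)
  w <- 1 / (1 + lambda * d)
  XtWX <- crossprod(Xr, w * Xr)
  XtWy <- crossprod(Xr, w * yr)
  R <- chol(XtWX)
  beta <- backsolve(R, backsolve(R, XtWy, transpose = TRUE))
  r <- yr - Xr %*% beta
  rss <- sum(w * r * r)
  sigma_e2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * (log(2 * pi) + 1 + log(sigma_e2)) +
                  sum(log1p(lambda * d)) + 2 * sum(log(diag(R))))
  list(ll = ll, beta = as.vector(beta), sigma_e2 = sigma_e2,
       XtWX = XtWX, R = R)
}

# Core REML fit in the rotated basis. Returns coefficient table and variance
# components. `fixed_ratio` pins lambda (used for GLS-equivalence checks and
# the shared-components scan mode).
.reml_fit_rotated <- function(yr, Xr, d, fixed_ratio = NULL) {
  if (is.null(fixed_ratio)) {
    obj <- function(loglam) .reml_pieces(exp(loglam), yr, Xr, d)$ll
    opt <- stats::optimize(obj, log(.RATIO_RANGE), maximum = TRUE,
                           tol = 1e-8)
    lambda <- exp(opt$maximum)
    ll <- opt$objective
    # compare with the lambda = 0 boundary (no genetic variance)
    ll0 <- .reml_pieces(0, yr, Xr, d)$ll
    if (ll0 >= ll) {
      lambda <- 0
      ll <- ll0
    }
  } else {
    lambda <- fixed_ratio
    ll <- NULL
  }
  pc <- .reml_pieces(lambda, yr, Xr, d)
  if (is.null(ll)) ll <- pc$ll
  Vinv <- chol2inv(pc$R) * pc$sigma_e2
  se <- sqrt(diag(Vinv))
  list(beta = pc$beta, se = se, lambda = lambda, loglik = ll,
       sigma_e2 = pc$sigma_e2, sigma_g2 = lambda * pc$sigma_e2)
}

.lmm_design <- function(n, covariates) {
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    W <- as.matrix(covariates)
    if (nrow(W) != n) stop("covariates and response differ in length")
    X <- cbind(X, W)
  }
  X
}

#' Mixed-model association of a score with a phenotype
#'
#' Fits `y = W alpha + x beta + g + e` with `g ~ N(0, sigma_g^2 A)` by REML
#' (eigendecomposition of A, bounded 1-D search over the variance ratio on
#' the log scale) and reports the Wald test of `beta` against the standard
#' normal. With `A = I` the fit collapses to ordinary least squares.
#'
#' @param y numeric response (binary 0/1 status or a quantitative scale);
#'   order must match the kinship matrix.
#' @param x predictor of interest, typically a standardized risk score.
#' @param covariates optional numeric matrix of extra fixed effects (an
#'   intercept is always included).
#' @param kinship numerator relationship matrix, or a prepared
#'   [kinship_eigen()] object.
#' @param fixed_ratio optionally pin the variance ratio
#'   `sigma_g^2 / sigma_e^2` instead of estimating it (then the fit is
#'   generalized least squares at that ratio).
#' @return object of class `lmm_fit`: list with `beta`, `se`, `p` (for `x`),
#'   `sigma_g2`, `sigma_e2`, `lambda`, `loglik`, `n` and the full
#'   coefficient table `coefficients`.
#' @export
fit_lmm_association <- function(y, x, covariates = NULL, kinship,
                                fixed_ratio = NULL) {
  ke <- if (inherits(kinship, "kin_eigen")) kinship else kinship_eigen(kinship)
  y <- as.numeric(y)
  x <- as.numeric(x)
  n <- length(y)
  if (length(x) != n || length(ke$d) != n)
    stop("y, x and kinship dimensions do not match")
  if (stats::sd(x) == 0) stop("predictor x is constant")
  X <- cbind(.lmm_design(n, covariates), score = x)
  yr <- crossprod(ke$U, y)
  Xr <- crossprod(ke$U, X)
  fit <- .reml_fit_rotated(yr, Xr, ke$d, fixed_ratio)
  k <- ncol(X)
  z <- fit$beta[k] / fit$se[k]
  structure(list(beta = fit$beta[k], se = fit$se[k],
                 p = 2 * stats::pnorm(-abs(z)),
                 sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
                 lambda = fit$lambda, loglik = fit$loglik, n = n,
                 coefficients = data.frame(term = colnames(X),
                                           estimate = fit$beta,
                                           se = fit$se)),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("LMM association: beta = %.4g (SE %.4g), p = %.3g, n = %d\n",
              x$beta, x$se, x$p, x$n))
  cat(sprintf("  variance components: sigma_g2 = %.4g, sigma_e2 = %.4g\n",
              x$sigma_g2, x$sigma_e2))
  invisible(x)
}

#' Narrow-sense heritability with a pedigree kernel
#'
#' REML fit of `y = W alpha + g + e`; reports
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)` and a likelihood-ratio test of
#' `sigma_g^2 = 0` against the boundary-corrected `0.5 chi2_0 + 0.5 chi2_1`
#' null mixture.
#'
#' @inheritParams fit_lmm_association
#' @return object of class `heritability_fit` with `h2`, `p`, `lrt`,
#'   `sigma_g2`, `sigma_e2`, `n`.
#' @export
estimate_heritability <- function(y, covariates = NULL, kinship) {
  ke <- if (inherits(kinship, "kin_eigen")) kinship else kinship_eigen(kinship)
  if (max(ke$d) - min(ke$d) < 1e-10 * max(ke$d, 1))
    stop("kinship matrix proportional to identity: ",
         "genetic variance unidentifiable")
  y <- as.numeric(y)
  n <- length(y)
  if (length(ke$d) != n) stop("y and kinship dimensions do not match")
  X <- .lmm_design(n, covariates)
  yr <- crossprod(ke$U, y)
  Xr <- crossprod(ke$U, X)
  fit <- .reml_fit_rotated(yr, Xr, ke$d)
  ll0 <- .reml_pieces(0, yr, Xr, ke$d)$ll
  lrt <- max(0, 2 * (fit$loglik - ll0))
  p <- if (lrt <= 0) 0.5 else
    0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(h2 = fit$lambda / (1 + fit$lambda), lrt = lrt, p = p,
                 sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
                 loglik = fit$loglik, n = n),
            class = "heritability_fit")
}

#' @export
print.heritability_fit <- function(x, ...) {
  cat(sprintf("Heritability: h2 = %.3f (LRT = %.3g, p = %.3g, n = %d)\n",
              x$h2, x$lrt, x$p, x$n))
  invisible(x)
}

#' Leave-one-out association excluding a carrier set
#'
#' Refits the mixed-model association after removing all carriers of a
#' Mendelian variant (kinship submatrix extracted and re-decomposed), to
#' check whether a polygenic association is driven by a strong-effect carrier
#' subgroup. Returns the full-cohort and reduced fits side by side.
#'
#' @inheritParams fit_lmm_association
#' @param carriers character ids (matching rownames of `kinship`) or logical/
#'   integer index of individuals to drop.
#' @return list with elements `full` and `loo` (both `lmm_fit`),
#'   `n_removed`, `n_remaining`.
#' @export
leave_one_out_association <- function(y, x, covariates = NULL, kinship,
                                      carriers) {
  K <- as.matrix(kinship)
  ids <- rownames(K)
  drop <- if (is.character(carriers)) {
    if (is.null(ids)) stop("kinship matrix lacks ids; pass an index instead")
    if (!all(carriers %in% ids))
      stop("carrier id not in cohort: ",
           paste(setdiff(carriers, ids), collapse = ", "))
    ids %in% carriers
  } else if (is.logical(carriers)) carriers
  else seq_len(nrow(K)) %in% carriers
  keep <- !drop
  if (!any(keep)) stop("all individuals are carriers; nothing to refit")
  full <- fit_lmm_association(y, x, covariates, K)
  y2 <- y[keep]
  if (stats::sd(as.numeric(y2)) == 0)
    stop("phenotype constant after removing carriers")
  cov2 <- if (is.null(covariates)) NULL else
    as.matrix(covariates)[keep, , drop = FALSE]
  loo <- fit_lmm_association(y2, x[keep], cov2, K[keep, keep, drop = FALSE])
  list(full = full, loo = loo, n_removed = sum(drop), n_remaining = sum(keep))
}
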