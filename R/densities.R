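# Contaminated Gaussian density machinery. Everything is computed and kept in
# log space: the eta-inflated component underflows quickly in double
# precision, so mixture weights are always combined by log-sum-exp.

#' Cluster parameters of a contaminated Gaussian component
#'
#' A contaminated Gaussian is a two-part mixture sharing a mean: with
#' probability `alpha` an observation is "good" and drawn from
#' N(mu, Sigma); with probability 1 - alpha it is a "bad" (mildly outlying)
#' point from N(mu, eta * Sigma), `eta > 1` inflating the covariance. The
#' covariance is also carried in its volume/shape/orientation
#' eigen-decomposition Sigma = lambda * D A D' with det(A) = 1, which is what
#' the parsimonious covariance family constrains.
#'
#' @param alpha Proportion of good points, in (0.5, 1).
#' @param mu Mean vector (length p).
#' @param Sigma p x p symmetric positive-definite covariance.
#' @param eta Contamination inflation factor, > 1.
#' @return An object of class `cnmix_params` with fields `alpha`, `mu`,
#'   `Sigma`, `eta`, and the decomposition `lambda`, `A`, `D`.
#' @export
cluster_params <- function(alpha, mu, Sigma, eta) {
  Sigma <- as.matrix(Sigma)
  p <- length(mu)
  stopifnot(nrow(Sigma) == p, ncol(Sigma) == p)
  if (!(alpha > 0.5 && alpha < 1))
    stop("alpha must lie in (0.5, 1)", call. = FALSE)
  if (!(eta > 1)) stop("eta must exceed 1", call. = FALSE)
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(1, max(abs(Sigma))))
    stop("Sigma must be symmetric", call. = FALSE)
  if (p == 1L || max(abs(Sigma - diag(diag(Sigma), p))) <
        1e-14 * max(abs(diag(Sigma)))) {
    ev <- list(values = sort(diag(Sigma), decreasing = TRUE), vectors = NULL)
  } else {
    ev <- eigen(Sigma, symmetric = TRUE)
  }
  if (min(ev$values) <= 0)
    stop("Sigma must be positive definite (degenerate covariance)",
         call. = FALSE)
  lambda <- exp(mean(log(ev$values)))      # |Sigma|^(1/p)
  A <- diag(ev$values / lambda, p)
  D <- ev$vectors %||% diag(p)[, order(diag(Sigma), decreasing = TRUE),
                               drop = FALSE]
  structure(list(alpha = alpha, mu = as.numeric(mu), Sigma = Sigma,
                 eta = eta, lambda = lambda, A = A, D = D, p = p),
            class = "cnmix_params")
}

#' Full mixture model over G contaminated Gaussian components
#'
#' @param pi Mixing proportions, positive, summing to one.
#' @param components List of G [cluster_params()] objects with a common p.
#' @param model_name Covariance structure name from the 14-member family
#'   (see [covariance_models()]); `"VVV"` places no constraint.
#' @return An object of class `cnmix_model`.
#' @export
mixture_model <- function(pi, components, model_name = "VVV") {
  G <- length(components)
  stopifnot(G >= 1L, length(pi) == G)
  if (any(pi <= 0)) stop("all mixing proportions must be positive", call. = FALSE)
  if (abs(sum(pi) - 1) > 1e-10) stop("mixing proportions must sum to 1", call. = FALSE)
  p <- components[[1L]]$p
  for (comp in components)
    if (comp$p != p) stop("components disagree on dimension", call. = FALSE)
  if (!(model_name %in% c(names(covariance_models()), "E", "V")))
    stop("unknown covariance model: ", model_name, call. = FALSE)
  structure(list(G = G, pi = as.numeric(pi), components = components,
                 model_name = model_name, p = p),
            class = "cnmix_model")
}

# Cholesky factor with a one-shot ridge rescue used during fitting: if the
# factorisation fails, add 1e-8 * mean(diag) once, then error.
#' @noRd
safe_chol <- function(Sigma, what = "covariance") {
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) {
    ridge <- 1e-8 * mean(diag(Sigma))
    R <- tryCatch(chol(Sigma + diag(ridge, nrow(Sigma))),
                  error = function(e) NULL)
    if (is.null(R))
      stop("degenerate covariance (", what, " not positive definite)",
           call. = FALSE)
  }
  R
}

#' Squared Mahalanobis distance
#'
#' Computes (x - mu)' Sigma^{-1} (x - mu) through a Cholesky triangular
#' solve; the covariance is never explicitly inverted.
#'
#' @param x,mu Numeric vectors of length p.
#' @param Sigma p x p symmetric positive-definite matrix.
#' @return Non-negative scalar.
#' @export
mahalanobis_sq <- function(x, mu, Sigma) {
  R <- safe_chol(as.matrix(Sigma))
  u <- backsolve(R, x - mu, transpose = TRUE)
  sum(u^2)
}

# Vectorised Gaussian log-density for all rows of X at once; returns also the
# squared Mahalanobis distances (reused by the eta update).
#' @noRd
gaussian_logpdf_rows <- function(X, mu, Sigma, what = "covariance") {
  R <- safe_chol(Sigma, what)
  p <- ncol(X)
  U <- backsolve(R, t(X) - mu, transpose = TRUE)   # p x n
  d2 <- colSums(U^2)
  logdet <- 2 * sum(log(diag(R)))
  list(logpdf = -0.5 * (p * log(2 * pi) + logdet + d2), d2 = d2)
}

#' Multivariate Gaussian log-density
#'
#' @inheritParams mahalanobis_sq
#' @return log phi(x; mu, Sigma), with the log-determinant taken from the
#'   Cholesky factorisation.
#' @export
gaussian_logpdf <- function(x, mu, Sigma) {
  gaussian_logpdf_rows(matrix(x, nrow = 1L), mu, as.matrix(Sigma))$logpdf
}

# log of alpha*phi(x;mu,Sigma) + (1-alpha)*phi(x;mu,eta*Sigma) for all rows;
# also returns the log of each branch (needed for good-point posteriors).
# A single Cholesky factorisation serves both branches: the inflated
# component only rescales the distance and the determinant.
#' @noRd
contaminated_logpdf_rows <- function(X, alpha, mu, Sigma, eta,
                                     what = "covariance") {
  R <- safe_chol(Sigma, what)
  p <- ncol(X)
  U <- backsolve(R, t(X) - mu, transpose = TRUE)
  d2 <- colSums(U^2)
  if (p == 1L) d2 <- as.numeric(d2)
  logdet <- 2 * sum(log(diag(R)))
  base <- -0.5 * (p * log(2 * pi) + logdet)
  lg <- log(alpha) + base - 0.5 * d2
  lb <- log1p(-alpha) + base - 0.5 * (p * log(eta) + d2 / eta)
  m <- pmax(lg, lb)
  list(logpdf = m + log(exp(lg - m) + exp(lb - m)),
       log_good = lg, log_bad = lb, d2 = d2)
}

#' Contaminated Gaussian log-density
#'
#' log of alpha * phi(x; mu, Sigma) + (1 - alpha) * phi(x; mu, eta * Sigma),
#' combined by log-sum-exp.
#'
#' @param x Numeric vector of length p.
#' @param params A [cluster_params()] object.
#' @return Scalar log-density.
#' @export
contaminated_logpdf <- function(x, params) {
  stopifnot(inherits(params, "cnmix_params"))
  contaminated_logpdf_rows(matrix(x, nrow = 1L), params$alpha, params$mu,
                           params$Sigma, params$eta)$logpdf
}

#' Mixture log-density
#'
#' log sum_g pi_g f(x; theta_g), with f the contaminated Gaussian density of
#' each component, combined by log-sum-exp.
#'
#' @param x Numeric vector of length p.
#' @param model A [mixture_model()] object.
#' @return Scalar log-density.
#' @export
mixture_logpdf <- function(x, model) {
  stopifnot(inherits(model, "cnmix_model"))
  lg <- vapply(seq_len(model$G), function(g) {
    log(model$pi[g]) + contaminated_logpdf(x, model$components[[g]])
  }, numeric(1L))
  logsumexp(lg)
}
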