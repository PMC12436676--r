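# The 14-member parsimonious covariance family obtained by constraining the
# eigen-decomposition Sigma_g = lambda_g D_g A_g D_g' (volume, shape,
# orientation) to be equal (E) or variable (V) across clusters, or identity /
# axis-aligned (I). Constrained maximisers follow the classical
# eigen-decomposition treatment of Gaussian parsimonious clustering; the
# orientation-coupled structures use an inner majorise-maximise update on the
# common orthogonal matrix.

#' Registry of the 14 parsimonious covariance structures
#'
#' @return Named list keyed by model name, each entry holding the `volume`
#'   (`"equal"`/`"variable"`), `shape` (`"spherical"`/`"equal"`/`"variable"`)
#'   and `orientation` (`"none"`/`"axis-aligned"`/`"equal"`/`"variable"`)
#'   constraint pattern.
#' @export
covariance_models <- function() {
  def <- function(volume, shape, orientation)
    list(volume = volume, shape = shape, orientation = orientation)
  list(
    EII = def("equal",    "spherical", "none"),
    VII = def("variable", "spherical", "none"),
    EEI = def("equal",    "equal",     "axis-aligned"),
    VEI = def("variable", "equal",     "axis-aligned"),
    EVI = def("equal",    "variable",  "axis-aligned"),
    VVI = def("variable", "variable",  "axis-aligned"),
    EEE = def("equal",    "equal",     "equal"),
    VEE = def("variable", "equal",     "equal"),
    EVE = def("equal",    "variable",  "equal"),
    EEV = def("equal",    "equal",     "variable"),
    VVE = def("variable", "variable",  "equal"),
    VEV = def("variable", "equal",     "variable"),
    EVV = def("equal",    "variable",  "variable"),
    VVV = def("variable", "variable",  "variable")
  )
}

# Resolve a model name, collapsing the family for p = 1 where only the
# volume constraint survives: "E" (equal scalar variance) and "V"
# (per-cluster scalar variance) are accepted directly.
#' @noRd
resolve_model_name <- function(model_name, p) {
  if (model_name %in% c("E", "V")) {
    if (p != 1L)
      stop("models 'E'/'V' are univariate; got p = ", p, call. = FALSE)
    return(if (model_name == "E") "EII" else "VII")
  }
  if (!model_name %in% names(covariance_models()))
    stop("unknown covariance model '", model_name, "'; valid names: ",
         paste(c(names(covariance_models()), "E", "V"), collapse = ", "),
         call. = FALSE)
  model_name
}

#' Covariance free-parameter count of a parsimonious structure
#'
#' The number of free covariance parameters implied by the constraint
#' pattern: a volume term (1 or G), a shape term (0 spherical, p - 1 equal,
#' G(p - 1) variable) and an orientation term (0, p(p - 1)/2 equal,
#' G p(p - 1)/2 variable).
#'
#' @param model_name One of the 14 structure names (or `"E"`/`"V"` for
#'   univariate fits).
#' @param G Number of clusters.
#' @param p Number of variables.
#' @return Integer count of free covariance parameters.
#' @export
count_free_parameters <- function(model_name, G, p) {
  stopifnot(G >= 1L, p >= 1L)
  if (model_name %in% c("E", "V")) {
    if (p != 1L) stop("models 'E'/'V' are univariate", call. = FALSE)
    return(if (model_name == "E") 1L else as.integer(G))
  }
  pat <- covariance_models()[[model_name]]
  if (is.null(pat))
    stop("unknown covariance model '", model_name, "'; valid names: ",
         paste(names(covariance_models()), collapse = ", "), call. = FALSE)
  vol <- if (pat$volume == "equal") 1L else G
  shp <- switch(pat$shape,
                spherical = 0L, equal = p - 1L, variable = G * (p - 1L))
  ori <- switch(pat$orientation,
                none = 0L, `axis-aligned` = 0L,
                equal = p * (p - 1L) / 2L, variable = G * p * (p - 1L) / 2L)
  as.integer(vol + shp + ori)
}

#' Total free-parameter count of a fitted mixture
#'
#' Adds to the covariance count the mixing proportions (G - 1), means (G p),
#' good-point proportions alpha (G) and inflation factors eta (G).
#'
#' @inheritParams count_free_parameters
#' @return Integer total parameter count.
#' @export
total_free_parameters <- function(model_name, G, p) {
  count_free_parameters(model_name, G, p) +
    as.integer((G - 1L) + G * p + G + G)
}

# --- constrained covariance maximisers -------------------------------------

# Normalise a vector of positive diagonal entries to unit geometric mean
# (det = 1 as a shape matrix); returns list(shape, size) with
# size = |diag|^(1/p).
#' @noRd
det_normalise <- function(d) {
  d <- pmax(d, 1e-300)
  size <- exp(mean(log(d)))
  list(shape = d / size, size = size)
}

# MM update of a common orthogonal orientation D minimising
# sum_g tr(Lambda_g^{-1} D' W_g D) over orthogonal D, with Lambda_g
# diagonal. Convex-tangent majorisation + orthogonal Procrustes; each call
# does not decrease the objective.
#' @noRd
update_common_orientation <- function(Wg, Lambda_inv, D) {
  p <- nrow(D)
  P <- matrix(0, p, p)
  for (g in seq_along(Wg)) {
    omega <- max(eigen(Wg[[g]], symmetric = TRUE, only.values = TRUE)$values)
    B <- omega * diag(p) - Wg[[g]]
    P <- P + B %*% D %*% diag(Lambda_inv[[g]], p)
  }
  sv <- svd(P)
  sv$u %*% t(sv$v)
}

#' Constrained covariance estimates for the parsimonious family
#'
#' Given per-cluster scatter matrices S_g (responsibility-weighted ML
#' covariances) and cluster sizes n_g, returns the covariance matrices
#' maximising the complete-data likelihood under the named constraint
#' pattern. Closed forms are used wherever they exist; the
#' orientation-coupled structures (VEE, EVE, VVE) alternate shape/volume
#' updates with a majorise-maximise orthogonal update (inner tolerance 1e-6,
#' at most 100 inner iterations; non-convergence warns and returns the best
#' iterate).
#'
#' @param scatters List of G symmetric positive semi-definite p x p matrices.
#' @param weights Numeric G-vector of effective cluster sizes.
#' @param model_name Structure name (see [covariance_models()]).
#' @param init Optional warm start for the iterative structures: a list with
#'   `D` (orthogonal p x p) and/or `A` (positive p-vector). Warm-starting
#'   from the current parameters keeps the surrounding ECM iteration
#'   monotone; a cold start may converge to a different stationary point.
#' @return List of G symmetric positive-definite covariance matrices.
#' @export
apply_structure <- function(scatters, weights, model_name, init = NULL) {
  G <- length(scatters)
  p <- nrow(scatters[[1L]])
  model_name <- resolve_model_name(model_name, p)
  ng <- as.numeric(weights)
  n <- sum(ng)
  Wg <- lapply(seq_len(G), function(g) ng[g] * scatters[[g]])
  Wsum <- Reduce(`+`, Wg)

  rep_list <- function(M) lapply(seq_len(G), function(g) M)

  if (p == 1L) model_name <- if (substr(model_name, 1L, 1L) == "E") "EII" else "VII"

  out <- switch(model_name,
    EII = rep_list(diag(sum(diag(Wsum)) / (n * p), p)),
    VII = lapply(seq_len(G), function(g)
      diag(sum(diag(Wg[[g]])) / (ng[g] * p), p)),
    EEI = rep_list(diag(diag(Wsum) / n, p)),
    VVI = lapply(seq_len(G), function(g) diag(diag(Wg[[g]]) / ng[g], p)),
    EVI = {
      nd <- lapply(Wg, function(W) det_normalise(diag(W)))
      lambda <- sum(vapply(nd, `[[`, numeric(1L), "size")) / n
      lapply(nd, function(x) diag(lambda * x$shape, p))
    },
    VEI = fit_vei(lapply(Wg, diag), ng, p, A_init = init$A),
    EEE = rep_list(Wsum / n),
    VVV = lapply(seq_len(G), function(g) Wg[[g]] / ng[g]),
    EEV = {
      eigs <- lapply(Wg, function(W) eigen(W, symmetric = TRUE))
      C <- Reduce(`+`, lapply(eigs, `[[`, "values"))
      lapply(eigs, function(e)
        e$vectors %*% diag(C / n, p) %*% t(e$vectors))
    },
    VEV = {
      eigs <- lapply(Wg, function(W) eigen(W, symmetric = TRUE))
      diag_fit <- fit_vei(lapply(eigs, `[[`, "values"), ng, p,
                          A_init = if (!is.null(init$A))
                            sort(init$A, decreasing = TRUE))
      lapply(seq_len(G), function(g)
        eigs[[g]]$vectors %*% diag_fit[[g]] %*% t(eigs[[g]]$vectors))
    },
    EVV = {
      eigs <- lapply(Wg, function(W) eigen(W, symmetric = TRUE))
      nd <- lapply(eigs, function(e) det_normalise(e$values))
      lambda <- sum(vapply(nd, `[[`, numeric(1L), "size")) / n
      lapply(seq_len(G), function(g)
        eigs[[g]]$vectors %*% diag(lambda * nd[[g]]$shape, p) %*%
          t(eigs[[g]]$vectors))
    },
    VEE = fit_common_orientation(Wg, ng, p, volume = "variable",
                                 shape = "equal", D_init = init$D),
    EVE = fit_common_orientation(Wg, ng, p, volume = "equal",
                                 shape = "variable", D_init = init$D),
    VVE = fit_common_orientation(Wg, ng, p, volume = "variable",
                                 shape = "variable", D_init = init$D),
    stop("unhandled model ", model_name, call. = FALSE)
  )
  lapply(out, function(S) {
    S <- (S + t(S)) / 2
    dimnames(S) <- NULL
    S
  })
}

# VEI (and the diagonalised core of VEV): Sigma_g = lambda_g * A with A
# diagonal, det(A) = 1. Alternating fixed point on (lambda_g, A); `dg` is the
# list of per-cluster scatter diagonals (or eigenvalues).
#' @noRd
fit_vei <- function(dg, ng, p, tol = 1e-8, max_iter = 200L, A_init = NULL) {
  G <- length(dg)
  A <- if (!is.null(A_init) && length(A_init) == p && all(A_init > 0))
    A_init / exp(mean(log(A_init))) else rep(1, p)
  lambda <- vapply(seq_len(G), function(g) sum(dg[[g]]) / (ng[g] * p),
                   numeric(1L))
  for (it in seq_len(max_iter)) {
    lambda_new <- vapply(seq_len(G), function(g)
      sum(dg[[g]] / A) / (ng[g] * p), numeric(1L))
    Asum <- Reduce(`+`, lapply(seq_len(G), function(g) dg[[g]] / lambda_new[g]))
    A_new <- det_normalise(Asum)$shape
    delta <- max(abs(lambda_new - lambda) / pmax(lambda, 1e-12),
                 max(abs(A_new - A)))
    lambda <- lambda_new
    A <- A_new
    if (delta < tol) break
  }
  lapply(seq_len(G), function(g) diag(lambda[g] * A, p))
}

# Structures with a common (equal) orientation D: VEE, EVE, VVE. Alternates
# closed-form volume/shape updates given D with the MM orthogonal update of
# D given the diagonal parts.
#' @noRd
fit_common_orientation <- function(Wg, ng, p, volume, shape,
                                   tol = 1e-6, max_iter = 100L,
                                   D_init = NULL) {
  G <- length(Wg)
  n <- sum(ng)
  # warm start from the caller's current orientation when available (keeps
  # the outer ECM monotone); otherwise the pooled scatter's eigenvectors
  D <- if (!is.null(D_init) && all(dim(D_init) == p) &&
           max(abs(crossprod(D_init) - diag(p))) < 1e-6) D_init
       else eigen(Reduce(`+`, Wg), symmetric = TRUE)$vectors
  obj_old <- Inf
  Lambdas <- NULL
  for (it in seq_len(max_iter)) {
    dg <- lapply(Wg, function(W) pmax(diag(t(D) %*% W %*% D), 1e-300))
    if (volume == "variable" && shape == "variable") {        # VVE
      Lambdas <- lapply(seq_len(G), function(g) dg[[g]] / ng[g])
    } else if (volume == "variable" && shape == "equal") {    # VEE
      Lambdas <- lapply(fit_vei(dg, ng, p), diag)
    } else {                                                  # EVE
      nd <- lapply(dg, det_normalise)
      lambda <- sum(vapply(nd, `[[`, numeric(1L), "size")) / n
      Lambdas <- lapply(nd, function(x) lambda * x$shape)
    }
    obj <- sum(vapply(seq_len(G), function(g)
      sum(dg[[g]] / Lambdas[[g]]) + ng[g] * sum(log(Lambdas[[g]])),
      numeric(1L)))
    if (is.finite(obj_old) && abs(obj_old - obj) < tol * (abs(obj_old) + 1e-3)) {
      obj_old <- obj
      break
    }
    obj_old <- obj
    D <- update_common_orientation(Wg, lapply(Lambdas, function(L) 1 / L), D)
    if (it == max_iter)
      warning("common-orientation update did not converge in ", max_iter,
              " inner iterations; returning best iterate", call. = FALSE)
  }
  lapply(seq_len(G), function(g) D %*% diag(Lambdas[[g]], p) %*% t(D))
}
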