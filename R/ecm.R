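# Expectation-conditional-maximisation for contaminated Gaussian mixtures.
# The E-step augments each observation with a cluster responsibility z_ig and
# a good-point probability v_ig; the CM-step updates {pi, alpha, mu, Sigma}
# given the current inflation eta, then eta given the new Sigma. The
# observed-data log-likelihood is non-decreasing across iterations.

#' Fitting configuration
#'
#' @param n_init Number of EM starts (k-means initialisations with random
#'   responsibility smoothing).
#' @param max_iter Maximum ECM iterations per start.
#' @param tol Aitken-acceleration convergence tolerance on the asymptotic
#'   log-likelihood estimate.
#' @param seed Root seed; all randomness (initialisation substreams) derives
#'   from it.
#' @param alpha_bounds Numeric guards for the good-point proportion, kept
#'   inside the open interval (0.5, 1).
#' @param eta_bounds Numeric guards for the inflation factor, kept above 1.
#' @param init_alpha,init_eta Starting values for alpha and eta; eta must
#'   start visibly above 1 so the contamination component can engage.
#' @param smooth Responsibility-smoothing weight applied to the k-means hard
#'   labels in starts after the first.
#' @return A list of class `cnmix_config`.
#' @export
fit_config <- function(n_init = 10L, max_iter = 500L, tol = 1e-5, seed = 1L,
                       alpha_bounds = c(0.501, 0.999),
                       eta_bounds = c(1.001, 1000),
                       init_alpha = 0.95, init_eta = 10, smooth = 0.1) {
  structure(list(n_init = as.integer(n_init), max_iter = as.integer(max_iter),
                 tol = tol, seed = seed, alpha_bounds = alpha_bounds,
                 eta_bounds = eta_bounds, init_alpha = init_alpha,
                 init_eta = init_eta, smooth = smooth),
            class = "cnmix_config")
}

#' Read a fitting configuration from YAML or JSON
#'
#' Recognised keys are the arguments of [fit_config()] plus `G` and `model`;
#' unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `G`, `model` (possibly `NULL`) and `config`
#'   (a `cnmix_config`).
#' @export
read_fit_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- c("G", "model", names(formals(fit_config)))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg_keys <- intersect(names(raw), names(formals(fit_config)))
  list(G = raw$G, model = raw$model,
       config = do.call(fit_config, raw[cfg_keys]))
}

#' E-step: responsibilities, good-point probabilities, log-likelihood
#'
#' @param data A [cnmix_dataset()].
#' @param model A [mixture_model()].
#' @return List with `posterior` (fields `z` n x G responsibilities, `v`
#'   n x G good-point probabilities, `w` effective weights
#'   v + (1 - v)/eta) and `loglik`, the observed-data log-likelihood.
#' @export
e_step <- function(data, model) {
  X <- data$values
  n <- nrow(X)
  G <- model$G
  L <- matrix(0, n, G)       # log pi_g + log f(x_i; theta_g)
  LG <- matrix(0, n, G)      # log alpha_g phi_good branch
  d2 <- matrix(0, n, G)
  for (g in seq_len(G)) {
    cp <- model$components[[g]]
    dens <- tryCatch(
      contaminated_logpdf_rows(X, cp$alpha, cp$mu, cp$Sigma, cp$eta,
                               what = paste0("cluster ", g)),
      error = function(e) stop("cluster ", g, ": ", conditionMessage(e),
                               call. = FALSE))
    L[, g] <- log(model$pi[g]) + dens$logpdf
    LG[, g] <- dens$log_good - dens$logpdf
    d2[, g] <- dens$d2
  }
  ll_i <- row_logsumexp(L)
  z <- exp(L - ll_i)
  v <- exp(LG)
  eta <- vapply(model$components, `[[`, numeric(1L), "eta")
  w <- v + (1 - v) * rep(1 / eta, each = n)
  list(posterior = list(z = z, v = v, w = w, d2 = d2),
       loglik = sum(ll_i))
}

#' CM-step: update all mixture parameters given the posterior
#'
#' Updates pi, alpha, mu and the structure-constrained Sigma given the
#' current eta, then eta given the new mean and covariance (a conditional
#' maximisation, so the observed-data likelihood cannot decrease).
#'
#' @param data A [cnmix_dataset()].
#' @param post Posterior list from [e_step()].
#' @param model_name Covariance structure name.
#' @param current Current [mixture_model()] (supplies eta and G).
#' @param config A [fit_config()] (bounds).
#' @return Updated [mixture_model()].
#' @export
cm_step <- function(data, post, model_name, current, config = fit_config()) {
  X <- data$values
  n <- nrow(X)
  p <- ncol(X)
  G <- current$G
  z <- post$z
  v <- post$v
  eta_old <- vapply(current$components, `[[`, numeric(1L), "eta")
  w <- v + (1 - v) * rep(1 / eta_old, each = n)

  ng <- colSums(z)
  small <- which(ng < 2)
  if (length(small))
    stop(structure(class = c("cnmix_empty_cluster", "error", "condition"),
                   list(message = paste0("cluster ", small[1L],
                                         " collapsed (effective size ",
                                         format(ng[small[1L]], digits = 3), ")"),
                        call = NULL, cluster = small[1L])))

  pi_new <- ng / n
  alpha_new <- clamp(colSums(z * v) / ng,
                     config$alpha_bounds[1L], config$alpha_bounds[2L])
  zw <- z * w
  mu_new <- lapply(seq_len(G), function(g) {
    colSums(X * zw[, g]) / sum(zw[, g])
  })
  scatters <- lapply(seq_len(G), function(g) {
    Xc <- X - matrix(mu_new[[g]], n, p, byrow = TRUE)
    crossprod(Xc * zw[, g], Xc) / ng[g]
  })
  warm <- list(D = current$components[[1L]]$D,
               A = diag(current$components[[1L]]$Sigma) /
                 current$components[[1L]]$lambda)
  Sigmas <- apply_structure(scatters, ng, model_name, init = warm)
  check_spd_scale(Sigmas, X)

  components <- vector("list", G)
  for (g in seq_len(G)) {
    R <- safe_chol(Sigmas[[g]], paste0("cluster ", g))
    U <- backsolve(R, t(X) - mu_new[[g]], transpose = TRUE)
    d2 <- colSums(U^2)
    zb <- z[, g] * (1 - v[, g])
    denom <- sum(zb)
    eta_g <- if (denom > 1e-12) sum(zb * d2) / (p * denom) else eta_old[g]
    eta_g <- clamp(eta_g, config$eta_bounds[1L], config$eta_bounds[2L])
    components[[g]] <- cluster_params(alpha_new[g], mu_new[[g]],
                                      Sigmas[[g]], eta_g)
  }
  mixture_model(pi_new, components, model_name)
}

# Reject spike clusters: a covariance whose smallest eigenvalue collapses
# relative to the overall data scale signals a degenerate (unbounded-
# likelihood) solution, not a genuine cluster. Raised as a restart signal.
#' @noRd
check_spd_scale <- function(Sigmas, X) {
  v_scale <- mean(colMeans(X^2) - colMeans(X)^2)
  for (g in seq_along(Sigmas)) {
    S <- Sigmas[[g]]
    emin <- if (max(abs(S - diag(diag(S), nrow(S)))) == 0) min(diag(S))
            else min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (!is.finite(emin) || emin < 1e-8 * v_scale)
      stop(structure(class = c("cnmix_degenerate", "error", "condition"),
                     list(message = paste0("cluster ", g,
                            " covariance collapsed (spike solution)"),
                          call = NULL, cluster = g)))
  }
  invisible(TRUE)
}

# k-means initial responsibilities on standardised data, optionally smoothed
# towards random Dirichlet-like weights so repeated starts explore distinct
# basins. Returns an n x G matrix with rows summing to one.
#' @noRd
init_responsibilities <- function(X, G, seed, smooth = 0) {
  n <- nrow(X)
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  withr::with_seed(seed, {
    labels <- if (G == 1L) rep(1L, n)
              else tryCatch(stats::kmeans(Xs, centers = G, nstart = 3L)$cluster,
                            error = function(e) sample.int(G, n, replace = TRUE))
    z <- matrix(0, n, G)
    z[cbind(seq_len(n), labels)] <- 1
    if (smooth > 0) {
      noise <- matrix(stats::runif(n * G), n, G)
      noise <- noise / rowSums(noise)
      z <- (1 - smooth) * z + smooth * noise
    }
    z
  })
}

# One ECM run from a given initial responsibility matrix.
#' @noRd
run_ecm_once <- function(data, G, model_name, z0, config) {
  n <- data$n
  v0 <- matrix(0.99, n, G)
  eta0 <- rep(config$init_eta, G)
  w0 <- v0 + (1 - v0) / rep(eta0, each = n)
  post <- list(z = z0, v = v0, w = w0)
  # initial M-step with provisional alpha/eta so eta starts away from 1
  seed_model <- local({
    ng <- colSums(z0)
    if (any(ng < 2))
      stop(structure(class = c("cnmix_empty_cluster", "error", "condition"),
                     list(message = "initial responsibilities leave a cluster empty",
                          call = NULL, cluster = which(ng < 2)[1L])))
    zw <- z0 * w0
    mu <- lapply(seq_len(G), function(g) colSums(data$values * zw[, g]) / sum(zw[, g]))
    scatters <- lapply(seq_len(G), function(g) {
      Xc <- data$values - matrix(mu[[g]], n, data$p, byrow = TRUE)
      crossprod(Xc * zw[, g], Xc) / ng[g]
    })
    Sigmas <- apply_structure(scatters, ng, model_name)
    check_spd_scale(Sigmas, data$values)
    mixture_model(ng / n,
                  lapply(seq_len(G), function(g)
                    cluster_params(config$init_alpha, mu[[g]], Sigmas[[g]],
                                   eta0[g])),
                  model_name)
  })

  model <- seed_model
  trace <- numeric(0L)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    es <- e_step(data, model)
    trace <- c(trace, es$loglik)
    k <- length(trace)
    if (k >= 3L) {
      dk <- trace[k] - trace[k - 1L]
      dk1 <- trace[k - 1L] - trace[k - 2L]
      if (abs(dk) < 1e-12) { converged <- TRUE; break }
      a <- dk / dk1
      if (is.finite(a) && a < 1) {
        l_inf <- trace[k - 1L] + dk / (1 - a)
        if (abs(l_inf - trace[k]) < config$tol) { converged <- TRUE; break }
      }
    }
    model <- cm_step(data, es$posterior, model_name, model, config)
  }
  es <- e_step(data, model)
  if (length(trace) == 0L || es$loglik > trace[length(trace)] + 1e-9)
    trace <- c(trace, es$loglik)
  list(model = model, posterior = es$posterior, loglik = es$loglik,
       trace = trace, converged = converged, n_iter = length(trace))
}

#' Fit a contaminated Gaussian mixture by ECM
#'
#' Multi-start ECM under one of the 14 parsimonious covariance structures.
#' Each start initialises responsibilities from k-means on standardised data
#' (later starts add random responsibility smoothing); convergence is judged
#' by Aitken acceleration of the observed-data log-likelihood. Starts that
#' collapse a cluster or degenerate a covariance are replaced by fresh
#' seeded starts.
#'
#' @param data A [cnmix_dataset()].
#' @param G Number of clusters.
#' @param model_name Covariance structure name (`"E"`/`"V"` when p = 1).
#' @param config A [fit_config()].
#' @return An object of class `cnmix_fit`: the fitted `model`, `posterior`
#'   (z, v, w), `loglik`, per-iteration `loglik_trace`, `converged`,
#'   `n_iter`, MAP `labels`, `bad_flags` (good-point probability below 1/2
#'   at the assigned cluster), per-observation `uncertainty`, and `criteria`
#'   (all eight information criteria, smaller is better).
#' @export
fit_ecm <- function(data, G, model_name, config = fit_config()) {
  stopifnot(inherits(data, "cnmix_dataset"), G >= 1L)
  model_name <- if (data$p == 1L && model_name %in% c("E", "V")) model_name
                else resolve_model_name(model_name, data$p)
  m_tot <- total_free_parameters(model_name, G, data$p)
  if (data$n <= m_tot)
    warning("n = ", data$n, " does not exceed the ", m_tot,
            " free parameters of ", model_name, " with G = ", G,
            call. = FALSE)

  best <- NULL
  failures <- character(0L)
  attempt <- 0L
  starts_done <- 0L
  max_attempts <- config$n_init + 10L
  while (starts_done < config$n_init && attempt < max_attempts) {
    attempt <- attempt + 1L
    seed_s <- substream(config$seed, "init", attempt)
    z0 <- init_responsibilities(data$values, G, seed_s,
                                smooth = if (attempt == 1L) 0 else config$smooth)
    res <- tryCatch(run_ecm_once(data, G, model_name, z0, config),
                    cnmix_empty_cluster = function(e) e,
                    cnmix_degenerate = function(e) e,
                    error = function(e) e)
    if (inherits(res, "condition")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    starts_done <- starts_done + 1L
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best))
    stop("all ", attempt, " starts failed; last failures: ",
         paste(utils::tail(failures, 3L), collapse = " | "), call. = FALSE)

  z <- best$posterior$z
  v <- best$posterior$v
  labels <- max.col(z, ties.method = "first")
  bad_flags <- v[cbind(seq_len(data$n), labels)] < 0.5
  uncertainty <- 1 - z[cbind(seq_len(data$n), labels)]
  entropy <- -sum(ifelse(z > 0, z * log(z), 0))
  crit <- vapply(criteria_names(), function(nm)
    criterion_value(nm, best$loglik, m_tot, data$n, entropy = entropy),
    numeric(1L))

  structure(list(model = best$model, posterior = best$posterior,
                 loglik = best$loglik, loglik_trace = best$trace,
                 converged = best$converged, n_iter = best$n_iter,
                 labels = labels, bad_flags = bad_flags,
                 uncertainty = uncertainty, criteria = crit,
                 m = m_tot, G = G, model_name = model_name,
                 variable_names = data$variable_names, n = data$n, p = data$p,
                 config = config, n_failed_starts = length(failures)),
            class = "cnmix_fit")
}

#' @export
print.cnmix_fit <- function(x, ...) {
  cat(sprintf("<cnmix_fit> %s, G = %d, loglik = %.3f (%s, %d iterations)\n",
              x$model_name, x$G, x$loglik,
              if (x$converged) "converged" else "max iterations", x$n_iter))
  cat(sprintf("  BIC = %.2f | cluster sizes: %s | flagged bad: %d\n",
              x$criteria[["BIC"]],
              paste(tabulate(x$labels, x$G), collapse = "/"),
              sum(x$bad_flags)))
  invisible(x)
}

#' MAP classification and outlier flags of a fit
#'
#' @param fit A `cnmix_fit`.
#' @return List with `labels` (MAP cluster) and `bad_flags` (TRUE where the
#'   good-point probability at the assigned cluster is below 1/2).
#' @export
classify_and_flag <- function(fit) {
  stopifnot(inherits(fit, "cnmix_fit"))
  list(labels = fit$labels, bad_flags = fit$bad_flags)
}

#' Classify new observations under a frozen fit
#'
#' Runs the E-step of the fitted model on new data and applies the same
#' MAP/outlier rules; no parameter is re-estimated.
#'
#' @param object A `cnmix_fit`.
#' @param new_data A [cnmix_dataset()] with the same variables in the same
#'   order.
#' @param ... Unused.
#' @return List with `labels`, `z` (responsibilities), `v` (good-point
#'   probabilities) and `bad_flags`.
#' @export
predict.cnmix_fit <- function(object, new_data, ...) {
  stopifnot(inherits(new_data, "cnmix_dataset"))
  if (!identical(new_data$variable_names, object$variable_names)) {
    missing_v <- setdiff(object$variable_names, new_data$variable_names)
    extra <- setdiff(new_data$variable_names, object$variable_names)
    stop("variable mismatch",
         if (length(missing_v)) paste0("; missing: ", paste(missing_v, collapse = ", ")),
         if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")),
         if (!length(missing_v) && !length(extra)) "; columns out of order",
         call. = FALSE)
  }
  es <- e_step(new_data, object$model)
  z <- es$posterior$z
  labels <- max.col(z, ties.method = "first")
  bad_flags <- es$posterior$v[cbind(seq_len(new_data$n), labels)] < 0.5
  list(labels = labels, z = z, v = es$posterior$v, bad_flags = bad_flags)
}

#' Serialise a fit to JSON
#'
#' Writes parameters, per-observation posteriors, labels and flags, the
#' log-likelihood trace and the information criteria, stamped with the seed.
#'
#' @param fit A `cnmix_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "cnmix_fit"))
  comp <- lapply(fit$model$components, function(cp)
    list(alpha = cp$alpha, mu = cp$mu, Sigma = cp$Sigma, eta = cp$eta,
         lambda = cp$lambda, shape = diag(cp$A)))
  out <- list(
    model_name = fit$model_name, G = fit$G, pi = fit$model$pi,
    components = comp, loglik = fit$loglik, loglik_trace = fit$loglik_trace,
    converged = fit$converged, n_iter = fit$n_iter, criteria = as.list(fit$criteria),
    labels = fit$labels, bad_flags = fit$bad_flags,
    uncertainty = fit$uncertainty, z = fit$posterior$z, v = fit$posterior$v,
    seed = fit$config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
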