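# Stepwise variable selection for clustering: variables enter in order of
# within-group variance, subject to a correlation threshold against the
# variables already selected that relaxes from linear to quintic in the
# within-group variance. The subset minimising mean clustering uncertainty
# wins.

#' Within-group variance of each standardised variable
#'
#' W_j = (1/n) sum_g sum_i z_ig (x_ij - mu_gj)^2 with mu_gj the
#' responsibility-weighted cluster mean. On standardised columns the total
#' variance is 1, so W_j close to 0 marks a clustering-informative variable
#' and W_j close to 1 an uninformative one.
#'
#' @param data_std A [cnmix_dataset()] whose columns have zero mean and unit
#'   variance (checked).
#' @param z n x G responsibility matrix with rows summing to one.
#' @return Named numeric p-vector of within-group variances.
#' @export
within_group_variance <- function(data_std, z) {
  stopifnot(inherits(data_std, "cnmix_dataset"))
  X <- data_std$values
  n <- nrow(X)
  sds <- apply(X, 2L, stats::sd) * sqrt((n - 1) / n)
  # accept either ML or n-1 standardisation
  ok <- abs(apply(X, 2L, stats::sd) - 1) < 1e-6 | abs(sds - 1) < 1e-6
  if (any(!ok))
    stop("columns not standardised to unit variance: ",
         paste(data_std$variable_names[!ok], collapse = ", "), call. = FALSE)
  z <- as.matrix(z)
  stopifnot(nrow(z) == n, max(abs(rowSums(z) - 1)) < 1e-8)
  W <- numeric(ncol(X))
  for (g in seq_len(ncol(z))) {
    zg <- z[, g]
    if (sum(zg) < 1e-12) next     # cluster with no mass contributes nothing
    mu_g <- colSums(X * zg) / sum(zg)
    Xc <- X - matrix(mu_g, n, ncol(X), byrow = TRUE)
    W <- W + colSums(zg * Xc^2)
  }
  setNames(W / n, data_std$variable_names)
}

#' Candidate variable subsets at exponents 1..5
#'
#' Each subset V_i is seeded with the variable of smallest within-group
#' variance; the remaining variables are scanned in ascending-W order and
#' variable j joins iff |rho_jr| < 1 - W_j^i against every r already in V_i.
#' Larger exponents relax the correlation threshold (linear through
#' quintic).
#'
#' @param W Named p-vector of within-group variances.
#' @param rho p x p correlation matrix.
#' @return Named list `i1`..`i5` of integer index vectors (each containing
#'   `which.min(W)`), with variable names attached.
#' @export
build_subsets <- function(W, rho) {
  p <- length(W)
  rho <- as.matrix(rho)
  stopifnot(nrow(rho) == p, ncol(rho) == p, max(abs(rho)) <= 1 + 1e-8)
  ord <- order(W)
  subsets <- vector("list", 5L)
  for (i in 1:5) {
    V <- ord[1L]
    for (j in ord[-1L]) {
      if (all(abs(rho[j, V]) < 1 - W[j]^i)) V <- c(V, j)
    }
    if (!is.null(names(W))) V <- setNames(V, names(W)[V])
    subsets[[i]] <- V
  }
  names(subsets) <- paste0("i", 1:5)
  subsets
}

#' Stepwise variable selection with contaminated-mixture refits
#'
#' Procedure: (1) standardise; (2) fit contaminated mixtures on all
#' variables, choosing the covariance structure by BIC, to obtain initial
#' responsibilities; (3) compute within-group variances and the correlation
#' matrix; (4) build the five candidate subsets; (5) refit each distinct
#' subset on the original (unstandardised) values of its variables;
#' (6) choose the subset with the smallest mean clustering uncertainty
#' (1/n) sum_i (1 - max_g z_ig), breaking ties towards the smaller subset,
#' then the smaller exponent.
#'
#' @param data A [cnmix_dataset()] with p >= 2.
#' @param G Number of clusters.
#' @param config A [fit_config()].
#' @param model_names Structures scanned by BIC for the initial fit
#'   (default: all 14).
#' @param reselect_structure If `TRUE`, re-select the structure by BIC for
#'   every candidate subset; if `FALSE` (default) reuse the initially
#'   selected structure (univariate subsets always re-select among
#'   `"E"`/`"V"`).
#' @return An object of class `cnmix_vscc`: `W`, `rho`, `subsets` (the five
#'   candidate index sets), `uncertainty` (per exponent), `fits` (per
#'   exponent), `chosen_i`, `chosen_vars`, `initial_fit`, `final_fit`.
#' @export
vscc_select <- function(data, G, config = fit_config(), model_names = NULL,
                        reselect_structure = FALSE) {
  stopifnot(inherits(data, "cnmix_dataset"), data$p >= 2L)
  model_names <- model_names %||% names(covariance_models())

  Xs <- scale(data$values)
  data_std <- cnmix_dataset(Xs, variable_names = data$variable_names,
                            true_labels = data$true_labels)

  pick_fit <- function(d, names_to_try, cfg) {
    tab <- sweep_models(d, G, names_to_try, cfg)
    bb <- best_by(tab)[["BIC"]]
    if (is.null(bb))
      stop("initial contaminated-mixture fit failed for every structure",
           call. = FALSE)
    attr(tab, "fits")[[paste0(bb$model, ":", bb$G)]]
  }

  cfg0 <- config
  cfg0$seed <- substream(config$seed, "vscc-initial")
  initial_fit <- tryCatch(pick_fit(data, model_names, cfg0),
                          error = function(e)
                            stop("variable selection, initial fit: ",
                                 conditionMessage(e), call. = FALSE))

  W <- within_group_variance(data_std, initial_fit$posterior$z)
  rho <- stats::cor(data$values)
  subsets <- build_subsets(W, rho)

  keys <- vapply(subsets, function(v) paste(sort(v), collapse = ","),
                 character(1L))
  fits <- vector("list", 5L)
  names(fits) <- names(subsets)
  cache <- list()
  for (i in 1:5) {
    key <- keys[i]
    if (is.null(cache[[key]])) {
      vars <- subsets[[i]]
      d_sub <- subset_variables(data, vars)
      cfg <- config
      cfg$seed <- substream(config$seed, "vscc-subset", i)
      cache[[key]] <- tryCatch({
        if (d_sub$p == 1L) {
          pick_fit(d_sub, c("E", "V"), cfg)
        } else if (reselect_structure) {
          pick_fit(d_sub, model_names, cfg)
        } else {
          suppressWarnings(fit_ecm(d_sub, G, initial_fit$model_name, cfg))
        }
      }, error = function(e) e)
    }
    fits[[i]] <- cache[[key]]
  }

  unc <- vapply(1:5, function(i) {
    f <- fits[[i]]
    if (inherits(f, "error")) Inf else mean(f$uncertainty)
  }, numeric(1L))
  sizes <- lengths(subsets)
  ord <- order(unc, sizes, seq_along(unc))
  chosen_i <- ord[1L]
  if (!is.finite(unc[chosen_i]))
    stop("every candidate-subset refit failed", call. = FALSE)

  structure(list(W = W, rho = rho, subsets = subsets,
                 uncertainty = setNames(unc, names(subsets)),
                 fits = fits, chosen_i = chosen_i,
                 chosen_vars = data$variable_names[subsets[[chosen_i]]],
                 initial_fit = initial_fit,
                 final_fit = fits[[chosen_i]]),
            class = "cnmix_vscc")
}

#' @export
print.cnmix_vscc <- function(x, ...) {
  cat("<cnmix_vscc> stepwise variable selection\n")
  for (i in 1:5)
    cat(sprintf("  exponent %d: {%s}  mean uncertainty %.4f%s\n", i,
                paste(names(x$subsets[[i]]), collapse = ", "),
                x$uncertainty[i], if (i == x$chosen_i) "  <- chosen" else ""))
  invisible(x)
}

#' Export a variable-selection report
#'
#' @param state A `cnmix_vscc`.
#' @param path Output path ending in `.csv` (subset membership table) or
#'   `.json` (full report).
#' @return Invisibly, `path`.
#' @export
write_vscc_report <- function(state, path) {
  stopifnot(inherits(state, "cnmix_vscc"))
  if (grepl("\\.json$", path)) {
    out <- list(W = as.list(state$W),
                subsets = lapply(state$subsets, names),
                uncertainty = as.list(state$uncertainty),
                chosen_i = state$chosen_i, chosen_vars = state$chosen_vars,
                final_model = state$final_fit$model_name,
                final_loglik = state$final_fit$loglik)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    p <- length(state$W)
    tab <- data.frame(variable = names(state$W), W = as.numeric(state$W))
    for (i in 1:5)
      tab[[paste0("in_V", i)]] <- seq_len(p) %in% state$subsets[[i]]
    tab$chosen <- tab$variable %in% state$chosen_vars
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}
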