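# Information criteria for mixture model selection. All eight are oriented
# so that SMALLER is better; the entropy-penalised criteria (ICL, AWE) take
# the classification entropy -sum_i sum_g z_ig log z_ig as an extra input,
# which is zero for hard responsibilities.

#' Names of the eight model-selection criteria
#'
#' @return Character vector: AIC, AICc, AIC3, AICu, CAIC, BIC, AWE, ICL.
#' @export
criteria_names <- function() {
  c("AIC", "AICc", "AIC3", "AICu", "CAIC", "BIC", "AWE", "ICL")
}

#' Evaluate one model-selection criterion
#'
#' Formulas (l = log-likelihood, m = total free parameters, n = sample
#' size, E = classification entropy): AIC = -2l + 2m;
#' AICc = AIC + 2m(m+1)/(n-m-1); AIC3 = -2l + 3m;
#' AICu = AICc + n log(n/(n-m-1)); CAIC = -2l + m(log n + 1);
#' BIC = -2l + m log n; ICL = BIC + 2E;
#' AWE = -2(l - E) + 2m(3/2 + log n). All minimised.
#'
#' @param name Criterion name (see [criteria_names()]).
#' @param loglik Maximised observed-data log-likelihood.
#' @param m Total number of free parameters.
#' @param n Number of observations.
#' @param entropy Classification entropy of the responsibilities (>= 0);
#'   only ICL and AWE use it.
#' @return Criterion value (smaller is better).
#' @export
criterion_value <- function(name, loglik, m, n, entropy = 0) {
  stopifnot(n > 0, m >= 1)
  if ((name %in% c("AICc", "AICu")) && n <= m + 1)
    stop(name, " undefined for n <= m + 1 (n = ", n, ", m = ", m, ")",
         call. = FALSE)
  d <- -2 * loglik
  switch(name,
    AIC  = d + 2 * m,
    AICc = d + 2 * m + 2 * m * (m + 1) / (n - m - 1),
    AIC3 = d + 3 * m,
    AICu = d + 2 * m + 2 * m * (m + 1) / (n - m - 1) + n * log(n / (n - m - 1)),
    CAIC = d + m * (log(n) + 1),
    BIC  = d + m * log(n),
    AWE  = d + 2 * entropy + 2 * m * (1.5 + log(n)),
    ICL  = d + m * log(n) + 2 * entropy,
    stop("unknown criterion '", name, "'; valid: ",
         paste(criteria_names(), collapse = ", "), call. = FALSE)
  )
}

#' Sweep cluster counts and covariance structures
#'
#' Fits every requested (structure, G) pair by multi-start ECM, scores each
#' fit with all eight criteria, and records failures without aborting the
#' sweep.
#'
#' @param data A [cnmix_dataset()].
#' @param G_range Integer vector of cluster counts.
#' @param model_names Character vector of structure names (default: all 14,
#'   or `"E"`/`"V"` when p = 1).
#' @param config A [fit_config()]; each pair derives its own seed substream
#'   from `config$seed`.
#' @return A `cnmix_criteria_table`: data frame with one row per pair
#'   (columns `model`, `G`, `loglik`, `m`, `converged`, `error`, one column
#'   per criterion), with attributes `best_by` (per criterion, the winning
#'   pair) and `fits` (the fitted objects, keyed `"model:G"`).
#' @export
sweep_models <- function(data, G_range, model_names = NULL,
                         config = fit_config()) {
  stopifnot(inherits(data, "cnmix_dataset"), length(G_range) >= 1L)
  model_names <- model_names %||%
    (if (data$p == 1L) c("E", "V") else names(covariance_models()))
  grid <- expand.grid(model = model_names, G = as.integer(G_range),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  fits <- list()
  for (k in seq_len(nrow(grid))) {
    mn <- grid$model[k]
    G <- grid$G[k]
    cfg <- config
    cfg$seed <- substream(config$seed, "sweep", k)
    fit <- tryCatch(suppressWarnings(fit_ecm(data, G, mn, cfg)),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[k]] <- data.frame(model = mn, G = G, loglik = NA_real_,
                              m = total_free_parameters(mn, G, data$p),
                              converged = NA, error = conditionMessage(fit),
                              stringsAsFactors = FALSE)
      crit <- setNames(rep(NA_real_, 8L), criteria_names())
    } else {
      fits[[paste0(mn, ":", G)]] <- fit
      rows[[k]] <- data.frame(model = mn, G = G, loglik = fit$loglik,
                              m = fit$m, converged = fit$converged,
                              error = NA_character_, stringsAsFactors = FALSE)
      crit <- fit$criteria
    }
    for (nm in criteria_names()) rows[[k]][[nm]] <- crit[[nm]]
  }
  tab <- do.call(rbind, rows)
  best_by <- list()
  for (nm in criteria_names()) {
    vals <- tab[[nm]]
    if (all(is.na(vals))) next
    i <- which.min(vals)
    best_by[[nm]] <- list(model = tab$model[i], G = tab$G[i])
  }
  structure(tab, best_by = best_by, fits = fits,
            class = c("cnmix_criteria_table", "data.frame"))
}

#' Best (structure, G) pair per criterion
#'
#' @param table A table from [sweep_models()].
#' @return Named list mapping criterion name to `list(model, G)`.
#' @export
best_by <- function(table) attr(table, "best_by")

#' Export a criteria table
#'
#' @param table A table from [sweep_models()].
#' @param path Output path ending in `.csv` or `.json`.
#' @return Invisibly, `path`.
#' @export
write_criteria_table <- function(table, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(table = as.data.frame(table),
                              best_by = attr(table, "best_by")),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  }
  invisible(path)
}
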