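# Heuristic clustering comparators and the adjusted Rand index used to score
# every method against the known partition. The heuristic methods
# (hierarchical, k-means, k-medoids) operate on standardised data, as they
# must; the model-based fits use the raw values.

#' Adjusted Rand index (Hubert-Arabie)
#'
#' Chance-corrected agreement between two partitions from their contingency
#' table: 1 for identical partitions, about 0 for independent ones, negative
#' for worse-than-chance agreement. Invariant to relabelling.
#'
#' @param a,b Partition label vectors of equal length (any label coding).
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("partitions have different lengths", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("need at least two observations", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  E <- sum_a * sum_b / comb2(n)
  denom <- (sum_a + sum_b) / 2 - E
  if (denom == 0) return(1)   # both partitions trivial (all-one-cluster etc.)
  (sum_ij - E) / denom
}

# Standardise columns; constant columns become zeros rather than NaN.
#' @noRd
standardised_values <- function(data) {
  Xs <- scale(data$values)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  Xs
}

#' Agglomerative hierarchical clustering baseline
#'
#' Euclidean distance on standardised data, the named linkage, tree cut at k
#' groups.
#'
#' @param data A [cnmix_dataset()].
#' @param linkage One of `"average"`, `"ward"`, `"single"`, `"complete"`.
#' @param k Number of groups to cut.
#' @return Integer label vector (1..k).
#' @export
run_hierarchical <- function(data, linkage = c("average", "ward", "single",
                                               "complete"), k = 2L) {
  linkage <- match.arg(linkage)
  stopifnot(k >= 1L, k <= data$n)
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::dist(standardised_values(data)), method = method)
  as.integer(stats::cutree(hc, k = k))
}

#' k-means baseline
#'
#' Lloyd-style k-means (multi-start) on standardised data.
#'
#' @param data A [cnmix_dataset()].
#' @param k Number of clusters.
#' @param seed Seed for the restarts.
#' @return Integer label vector.
#' @export
run_kmeans <- function(data, k = 2L, seed = 1L) {
  stopifnot(k >= 1L, k <= data$n)
  withr::with_seed(substream(seed, "kmeans"),
    as.integer(stats::kmeans(standardised_values(data), centers = k,
                             nstart = 10L)$cluster))
}

#' k-medoids (PAM) baseline
#'
#' Partitioning around medoids on standardised data.
#'
#' @inheritParams run_kmeans
#' @return Integer label vector.
#' @export
run_kmedoids <- function(data, k = 2L, seed = 1L) {
  stopifnot(k >= 1L, k <= data$n)
  withr::with_seed(substream(seed, "kmedoids"),
    as.integer(cluster::pam(standardised_values(data), k = k,
                            cluster.only = TRUE)))
}

#' Clustering comparison table
#'
#' Runs the full comparison roster against a known partition: four
#' hierarchical linkages, k-means, k-medoids, one univariate contaminated
#' mixture per variable, and the multivariate contaminated mixture with
#' variable selection. Reports the adjusted Rand index per method; a method
#' that fails contributes an NA row rather than aborting the table.
#'
#' @param data A [cnmix_dataset()].
#' @param truth Known partition (label vector of length n); defaults to
#'   `data$true_labels`.
#' @param k Number of groups for every method (default 2).
#' @param config A [fit_config()] for the model-based rows.
#' @param model_names Structures scanned during variable selection (default:
#'   all 14).
#' @param vscc Optional precomputed [vscc_select()] state for this data,
#'   reused instead of re-running the selection.
#' @return Data frame with columns `method` and `ARI` (6 + p + 1 rows), with
#'   the variable-selection state attached as attribute `"vscc"`.
#' @export
comparison_table <- function(data, truth = NULL, k = 2L,
                             config = fit_config(), model_names = NULL,
                             vscc = NULL) {
  stopifnot(inherits(data, "cnmix_dataset"))
  truth <- truth %||% data$true_labels
  if (is.null(truth)) stop("no known labels supplied", call. = FALSE)

  rows <- list()
  add <- function(method, labels_or_error) {
    ari <- if (inherits(labels_or_error, "error")) NA_real_
           else adjusted_rand_index(truth, labels_or_error)
    rows[[length(rows) + 1L]] <<- data.frame(method = method, ARI = ari,
                                             stringsAsFactors = FALSE)
  }

  for (link in c("average", "ward", "single", "complete"))
    add(paste0("hierarchical (", link, ")"),
        tryCatch(run_hierarchical(data, link, k), error = function(e) e))
  add("k-means", tryCatch(run_kmeans(data, k, config$seed),
                          error = function(e) e))
  add("k-medoids", tryCatch(run_kmedoids(data, k, config$seed),
                            error = function(e) e))

  for (j in seq_len(data$p)) {
    d1 <- subset_variables(data, j)
    cfg <- config
    cfg$seed <- substream(config$seed, "univariate", j)
    lab <- tryCatch({
      tab <- sweep_models(d1, k, c("E", "V"), cfg)
      bb <- best_by(tab)[["BIC"]]
      attr(tab, "fits")[[paste0(bb$model, ":", bb$G)]]$labels
    }, error = function(e) e)
    add(paste0("univariate contaminated mixture (", data$variable_names[j], ")"),
        lab)
  }

  if (is.null(vscc))
    vscc <- tryCatch(vscc_select(data, k, config, model_names = model_names),
                     error = function(e) e)
  add("multivariate contaminated mixture (variable selection)",
      if (inherits(vscc, "error")) vscc else vscc$final_fit$labels)

  out <- do.call(rbind, rows)
  attr(out, "vscc") <- if (inherits(vscc, "error")) NULL else vscc
  out
}
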