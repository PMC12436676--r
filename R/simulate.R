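# Synthetic cohorts from the contaminated Gaussian mixture model, with
# ground truth (cluster membership and good/bad status) carried alongside.
# The cohort preset emulates a two-group study of 122 children (71 controls,
# 51 with dyslexia) over nine cognitive-skill scores in which a minority of
# variables separate the groups.

#' Simulation specification
#'
#' @param n Total number of observations (ignored when `sizes` is given).
#' @param pi Mixing proportions (ignored when `sizes` is given).
#' @param mu G x p matrix of cluster means.
#' @param Sigmas List of G covariance matrices.
#' @param alpha G-vector of good-point proportions in (0.5, 1].
#' @param eta G-vector of inflation factors (> 1; irrelevant when alpha = 1).
#' @param seed Mandatory seed.
#' @param sizes Optional fixed per-cluster counts (reproducible shapes);
#'   overrides `n`/`pi` draws.
#' @param variable_names Optional p-vector of names.
#' @return A list of class `cnmix_simspec`.
#' @export
sim_spec <- function(n, pi, mu, Sigmas, alpha, eta, seed, sizes = NULL,
                     variable_names = NULL) {
  mu <- as.matrix(mu)
  G <- nrow(mu)
  p <- ncol(mu)
  problems <- character(0L)
  if (length(pi) != G || abs(sum(pi) - 1) > 1e-10 || any(pi <= 0))
    problems <- c(problems, "pi must be positive and sum to 1, one per cluster")
  if (length(Sigmas) != G) problems <- c(problems, "need one Sigma per cluster")
  if (length(alpha) != G || any(alpha <= 0.5 | alpha > 1))
    problems <- c(problems, "alpha must lie in (0.5, 1], one per cluster")
  if (length(eta) != G || any(eta <= 1 & alpha < 1))
    problems <- c(problems, "eta must exceed 1 wherever alpha < 1")
  if (missing(seed) || is.null(seed)) problems <- c(problems, "seed is mandatory")
  if (!is.null(sizes) && length(sizes) != G)
    problems <- c(problems, "sizes must have one entry per cluster")
  if (length(problems))
    stop("invalid simulation spec:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  structure(list(n = if (is.null(sizes)) n else sum(sizes), pi = pi, mu = mu,
                 Sigmas = Sigmas, alpha = alpha, eta = eta, seed = seed,
                 sizes = sizes,
                 variable_names = variable_names %||% paste0("V", seq_len(p)),
                 G = G, p = p),
            class = "cnmix_simspec")
}

#' Write / read a simulation specification as YAML
#'
#' @param spec A [sim_spec()].
#' @param path YAML path.
#' @return `write_sim_spec` returns `path` invisibly; `read_sim_spec`
#'   returns the reconstructed `cnmix_simspec`.
#' @export
write_sim_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cnmix_simspec"))
  yaml::write_yaml(list(
    n = spec$n, pi = spec$pi, mu = lapply(seq_len(spec$G), function(g) spec$mu[g, ]),
    Sigmas = lapply(spec$Sigmas, function(S) apply(as.matrix(S), 1L, identity,
                                                   simplify = FALSE)),
    alpha = spec$alpha, eta = spec$eta, seed = spec$seed,
    sizes = spec$sizes, variable_names = spec$variable_names), path)
  invisible(path)
}

#' @rdname write_sim_spec
#' @export
read_sim_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_spec(n = raw$n, pi = unlist(raw$pi),
           mu = do.call(rbind, raw$mu),
           Sigmas = lapply(raw$Sigmas, function(S) do.call(cbind, S)),
           alpha = unlist(raw$alpha), eta = unlist(raw$eta), seed = raw$seed,
           sizes = if (length(raw$sizes)) unlist(raw$sizes) else NULL,
           variable_names = unlist(raw$variable_names))
}

#' Draw a dataset from a contaminated Gaussian mixture
#'
#' Per observation: draw a cluster (from `pi`, or deterministically when
#' `sizes` fixes the counts); draw good/bad from Bernoulli(alpha_g); emit
#' N(mu_g, Sigma_g) if good, N(mu_g, eta_g Sigma_g) if bad.
#'
#' @param spec A [sim_spec()].
#' @return List with `data` (a [cnmix_dataset()] carrying the true cluster
#'   labels) and `truth` (list with `labels` and logical `bad`).
#' @export
simulate_mixture <- function(spec) {
  stopifnot(inherits(spec, "cnmix_simspec"))
  G <- spec$G
  p <- spec$p
  withr::with_seed(substream(spec$seed, "simulate"), {
    labels <- if (!is.null(spec$sizes)) rep(seq_len(G), times = spec$sizes)
              else sample.int(G, spec$n, replace = TRUE, prob = spec$pi)
    n <- length(labels)
    bad <- stats::runif(n) > spec$alpha[labels]
    X <- matrix(0, n, p)
    for (g in seq_len(G)) {
      R <- chol(as.matrix(spec$Sigmas[[g]]))
      for (badness in c(FALSE, TRUE)) {
        idx <- which(labels == g & bad == badness)
        if (!length(idx)) next
        scale_g <- if (badness) sqrt(spec$eta[g]) else 1
        Z <- matrix(stats::rnorm(length(idx) * p), length(idx), p)
        X[idx, ] <- Z %*% (scale_g * R) +
          matrix(spec$mu[g, ], length(idx), p, byrow = TRUE)
      }
    }
    colnames(X) <- spec$variable_names
    list(data = cnmix_dataset(X, spec$variable_names, true_labels = labels),
         truth = list(labels = labels, bad = bad))
  })
}

# Preset parameters of the two-group cognitive-skill cohort: 71 controls and
# 51 children with dyslexia over nine scores. Standardised-scale mean gaps:
# Reading 3.0 (strong), Phonology 1.2 and RAN 1.0 (moderate), Tone 0.5
# (weak, plus a variance shift standing in for its differing left tail), the
# remaining five variables uninformative. Diagonal equal-volume (EVI)
# within-cluster covariance; alpha = 0.95, eta = 20 in both groups.
#' @noRd
dyslexia_spec <- function(seed, eta = 20) {
  vars <- c("Reading", "Phonology", "RAN", "Attention", "Rhythm", "Tone",
            "VAS1", "VAS2", "Implicit")
  gaps <- c(Reading = 3.0, Phonology = 1.2, RAN = 1.0, Attention = 0,
            Rhythm = 0, Tone = 0.5, VAS1 = 0, VAS2 = 0, Implicit = 0)
  mu <- rbind(control = rep(0, 9L), dyslexia = -gaps)
  shape2 <- rep(1, 9L)
  shape2[vars == "Tone"] <- 1.44
  shape2 <- shape2 / exp(mean(log(shape2)))   # det-1 shape: EVI, equal volume
  sim_spec(n = 122L, pi = c(71, 51) / 122,
           mu = mu,
           Sigmas = list(diag(9L), diag(shape2, 9L)),
           alpha = c(0.95, 0.95), eta = c(eta, eta), seed = seed,
           sizes = c(71L, 51L), variable_names = vars)
}

#' Two-group cognitive-skill cohort preset
#'
#' Generates a 122 x 9 dataset with fixed cluster sizes 71 (control) and 51
#' (dyslexia), informative variables Reading (3 sd gap), Phonology (1.2),
#' RAN (1.0) and Tone (0.5, with a variance shift), five uninformative
#' variables, EVI within-cluster covariance, and 5% variance-inflated bad
#' points (alpha = 0.95, eta = 20).
#'
#' @param seed Seed.
#' @param eta Inflation factor override (default 20).
#' @return As [simulate_mixture()]: list with `data` and `truth`
#'   (labels: 1 = control, 2 = dyslexia).
#' @export
dyslexia_preset <- function(seed, eta = 20) {
  simulate_mixture(dyslexia_spec(seed, eta = eta))
}

#' Parameter-recovery simulation preset
#'
#' A larger, more separated two-cluster EVI design used for validating
#' parameter recovery and outlier detection: n observations (cluster drawn
#' from equal mixing), p = 9, four informative variables with 3.5-sd mean
#' gaps, mild shape differences between the clusters (equal volume), 5%
#' bad points.
#'
#' @param seed Seed.
#' @param eta Inflation factor (default 20).
#' @param n Sample size (default 500).
#' @return As [simulate_mixture()].
#' @export
recovery_preset <- function(seed, eta = 20, n = 500L) {
  gaps <- c(3.5, 3.5, 3.5, 3.5, 0, 0, 0, 0, 0)
  shape2 <- c(1.3, 0.8, 1.2, 0.9, 1, 1, 1, 1, 1)
  shape2 <- shape2 / exp(mean(log(shape2)))
  spec <- sim_spec(n = n, pi = c(0.5, 0.5),
                   mu = rbind(rep(0, 9L), -gaps),
                   Sigmas = list(diag(9L), diag(shape2, 9L)),
                   alpha = c(0.95, 0.95), eta = c(eta, eta), seed = seed)
  simulate_mixture(spec)
}

#' Cohort preset extended with unclassified units
#'
#' Appends 81 additional draws from the same two-component model, each from
#' either cluster with its mean mildly shrunk (by 30%) towards the grand
#' mean, emulating borderline children for whom the original criteria gave
#' no diagnosis while leaving the two-group structure intact, for a combined
#' sample of 203 units.
#'
#' @param seed Seed.
#' @return List with `data` (203 x 9; `true_labels` give the generating
#'   cluster for every unit) and `truth` (fields `labels`, `bad`, and
#'   logical `unclassified` marking the appended 81 rows).
#' @export
unclassified_preset <- function(seed) {
  base <- dyslexia_preset(seed)
  spec <- dyslexia_spec(seed)
  grand <- colSums(spec$mu * c(71, 51) / 122)
  mu_shrunk <- t(apply(spec$mu, 1L, function(m) m + 0.3 * (grand - m)))
  extra_spec <- sim_spec(n = 81L, pi = c(0.5, 0.5), mu = mu_shrunk,
                         Sigmas = spec$Sigmas, alpha = spec$alpha,
                         eta = spec$eta,
                         seed = substream(seed, "unclassified"),
                         variable_names = spec$variable_names)
  extra <- simulate_mixture(extra_spec)
  values <- rbind(base$data$values, extra$data$values)
  labels <- c(base$truth$labels, extra$truth$labels)
  bad <- c(base$truth$bad, extra$truth$bad)
  list(data = cnmix_dataset(values, spec$variable_names, true_labels = labels),
       truth = list(labels = labels, bad = bad,
                    unclassified = c(rep(FALSE, 122L), rep(TRUE, 81L))))
}
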