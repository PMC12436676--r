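# Internal numerical helpers shared across the package.

#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix (max.col avoids an apply() per call).
#' @noRd
row_logsumexp <- function(lx) {
  m <- lx[cbind(seq_len(nrow(lx)), max.col(lx, ties.method = "first"))]
  m + log(rowSums(exp(lx - m)))
}

# Deterministic sub-seed derivation: one root seed, named substreams
# (simulation, initialisation, multistart, ...) so every stochastic stage is
# reproducible independently. Kept strictly below 2^31 - 1.
#' @noRd
substream <- function(seed, name, k = 0L) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.double(seed) * 7919 + h * 104729 + as.double(k) * 65537) %% 2147483629
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Clamp a numeric vector to [lo, hi].
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
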