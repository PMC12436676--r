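# Independent oracles used to check the package's implementations. Each is
# written in the most direct (often brute-force) style possible and shares
# no code with the implementation under test.

# Naive mixture density by plain arithmetic (no log-space tricks).
naive_mixture_pdf <- function(x, pi, comps) {
  total <- 0
  for (g in seq_along(pi)) {
    cp <- comps[[g]]
    p <- length(cp$mu)
    dens <- function(S) {
      (2 * base::pi)^(-p / 2) * det(S)^(-1 / 2) *
        exp(-0.5 * t(x - cp$mu) %*% solve(S) %*% (x - cp$mu))
    }
    total <- total +
      pi[g] * (cp$alpha * dens(cp$Sigma) +
               (1 - cp$alpha) * dens(cp$eta * cp$Sigma))
  }
  as.numeric(total)
}

# Per-observation Bayes posteriors by direct arithmetic.
naive_e_step <- function(X, pi, comps) {
  n <- nrow(X)
  G <- length(pi)
  z <- matrix(0, n, G)
  v <- matrix(0, n, G)
  for (i in seq_len(n)) {
    x <- X[i, ]
    f <- numeric(G)
    good <- numeric(G)
    for (g in seq_len(G)) {
      cp <- comps[[g]]
      p <- length(cp$mu)
      dens <- function(S) {
        (2 * base::pi)^(-p / 2) * det(S)^(-1 / 2) *
          exp(-0.5 * t(x - cp$mu) %*% solve(S) %*% (x - cp$mu))
      }
      good[g] <- cp$alpha * dens(cp$Sigma)
      f[g] <- good[g] + (1 - cp$alpha) * dens(cp$eta * cp$Sigma)
    }
    z[i, ] <- pi * f / sum(pi * f)
    v[i, ] <- good / f
  }
  list(z = z, v = v)
}

# Exhaustive O(n^2) pair-counting adjusted Rand index.
pair_count_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_idx == expected) return(1)
  (n11 - expected) / (max_idx - expected)
}

# Symbolic free-parameter tally for the covariance structures: counts the
# distinct volume scalars, shape entries (det-1 constraint removes one per
# distinct shape matrix) and orientation entries (p(p-1)/2 per distinct
# orthogonal matrix), directly from the letters of the name.
symbolic_cov_params <- function(name, G, p) {
  letters3 <- strsplit(name, "")[[1]]
  vol <- if (letters3[1] == "E") 1 else G
  shp <- switch(letters3[2], I = 0, E = p - 1, V = G * (p - 1))
  ori <- switch(letters3[3], I = 0, E = p * (p - 1) / 2, V = G * p * (p - 1) / 2)
  vol + shp + ori
}

# Direct double-loop within-group variance on standardised data.
naive_within_group_variance <- function(X, z) {
  n <- nrow(X)
  p <- ncol(X)
  G <- ncol(z)
  W <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (g in seq_len(G)) {
      mu_gj <- sum(z[, g] * X[, j]) / sum(z[, g])
      for (i in seq_len(n)) acc <- acc + z[i, g] * (X[i, j] - mu_gj)^2
    }
    W[j] <- acc / n
  }
  W
}

# Small random SPD matrix.
random_spd <- function(p, seed) {
  withr::with_seed(seed, {
    M <- matrix(rnorm(p * p), p)
    crossprod(M) + diag(p) * 0.5
  })
}

# Quick two-blob dataset for baseline checks.
two_blob_data <- function(n_per = 30L, gap = 10, p = 2L, seed = 1L) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * p), ncol = p),
               matrix(rnorm(n_per * p, mean = gap), ncol = p))
    cnmix_dataset(X, true_labels = rep(1:2, each = n_per))
  })
}
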