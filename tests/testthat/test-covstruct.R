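test_that("the registry holds exactly the 14 structures with a name/pattern bijection", {
  reg <- covariance_models()
  expect_length(reg, 14L)
  expect_false(anyDuplicated(names(reg)) > 0)
  patterns <- vapply(reg, function(x)
    paste(x$volume, x$shape, x$orientation), character(1))
  expect_false(anyDuplicated(patterns) > 0)
  # the name letters encode the pattern
  for (nm in names(reg)) {
    expect_equal(substr(nm, 1, 1), if (reg[[nm]]$volume == "equal") "E" else "V")
    expect_equal(substr(nm, 2, 2),
                 switch(reg[[nm]]$shape, spherical = "I", equal = "E",
                        variable = "V"))
  }
})

test_that("covariance parameter counts match an independent symbolic tally", {
  for (nm in names(covariance_models()))
    for (G in c(1L, 2L, 3L, 4L))
      for (p in c(1L, 2L, 5L, 9L))
        expect_equal(count_free_parameters(nm, G, p),
                     symbolic_cov_params(nm, G, p),
                     info = sprintf("%s G=%d p=%d", nm, G, p))
  expect_error(count_free_parameters("XXX", 2, 2), "valid names")
})

test_that("published instances of the counting formulas hold", {
  expect_equal(count_free_parameters("EII", 2, 9), 1L)
  expect_equal(count_free_parameters("VVV", 2, 4), 20L)   # G p (p+1)/2
  expect_equal(count_free_parameters("VEI", 3, 2), 4L)    # G + p - 1
  # totals add (G-1) + Gp + G + G
  expect_equal(total_free_parameters("VVV", 2, 4), 20L + 1L + 8L + 2L + 2L)
})

test_that("single-cluster structures project the scatter correctly", {
  S <- random_spd(3, 11)
  expect_equal(apply_structure(list(S), 50, "VVV")[[1]], S, tolerance = 1e-12)
  eii <- apply_structure(list(S), 50, "EII")[[1]]
  expect_equal(eii, diag(mean(diag(S)), 3), tolerance = 1e-12)
  eee <- apply_structure(list(S), 50, "EEE")[[1]]
  expect_equal(eee, S, tolerance = 1e-12)
})

test_that("EVI produces diagonal matrices with a shared determinant-normalised volume", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      d1 <- runif(4, 0.5, 3)
      d2 <- runif(4, 0.5, 3)
      out <- apply_structure(list(diag(d1), diag(d2)), c(40, 60), "EVI")
      for (S in out) expect_equal(S, diag(diag(S)), tolerance = 1e-12)
      lam <- vapply(out, function(S) det(S)^(1 / 4), numeric(1))
      expect_equal(lam[1], lam[2], tolerance = 1e-10)
      shapes <- lapply(out, function(S) diag(S) / lam[1])
      for (sh in shapes) expect_equal(prod(sh), 1, tolerance = 1e-10)
    }
  })
})

test_that("EEE pools scatters and diagonal family zeroes off-diagonals", {
  S1 <- random_spd(3, 1)
  S2 <- random_spd(3, 2)
  pooled <- apply_structure(list(S1, S2), c(30, 30), "EEE")
  expect_equal(pooled[[1]], (S1 + S2) / 2, tolerance = 1e-12)
  expect_equal(pooled[[1]], pooled[[2]])
  for (nm in c("EII", "VII", "EEI", "VEI", "EVI", "VVI")) {
    out <- apply_structure(list(S1, S2), c(30, 30), nm)
    for (S in out) expect_lt(max(abs(S - diag(diag(S)))), 1e-12)
  }
})

test_that("every structure respects its volume/shape/orientation constraints", {
  withr::with_seed(5, {
    scatters <- list(random_spd(4, 101), random_spd(4, 102), random_spd(4, 103))
    ng <- c(50, 70, 40)
    for (nm in names(covariance_models())) {
      out <- apply_structure(scatters, ng, nm)
      pat <- covariance_models()[[nm]]
      lam <- vapply(out, function(S) det(S)^(1 / 4), numeric(1))
      if (pat$volume == "equal")
        expect_lt(max(abs(lam - lam[1])), 1e-6 * lam[1])
      if (pat$shape == "spherical")
        for (S in out) expect_lt(max(abs(S - diag(mean(diag(S)), 4))),
                                 1e-8 * mean(diag(S)))
      if (pat$shape == "equal") {
        shapes <- lapply(seq_along(out), function(g)
          sort(eigen(out[[g]], symmetric = TRUE, only.values = TRUE)$values) / lam[g])
        for (g in 2:3) expect_equal(shapes[[g]], shapes[[1]], tolerance = 1e-5)
      }
      if (pat$orientation %in% c("none", "axis-aligned"))
        for (S in out) expect_lt(max(abs(S - diag(diag(S)))),
                                 1e-8 * sum(diag(S)))
      if (pat$orientation == "equal" && pat$shape != "spherical") {
        # shared eigenvectors: each Sigma_g must commute with the first
        for (g in 2:3)
          expect_lt(max(abs(out[[g]] %*% out[[1]] - out[[1]] %*% out[[g]])),
                    1e-4 * sum(diag(out[[1]])))
      }
      # structures never lose the complete-data likelihood to the closest
      # unconstrained fit in the nested direction: objective finite & SPD
      for (S in out)
        expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  })
})

test_that("common-orientation structures improve on an axis-aligned start", {
  # complete-data deviance sum_g [tr(W_g S_g^-1) + n_g log det S_g] should be
  # no worse under VVE than under its diagonal counterpart VVI when the true
  # scatters share a rotated orientation
  withr::with_seed(9, {
    theta <- 0.6
    Q <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    S1 <- Q %*% diag(c(4, 0.5)) %*% t(Q)
    S2 <- Q %*% diag(c(2, 0.2)) %*% t(Q)
    ng <- c(80, 60)
    dev <- function(Sigmas) sum(vapply(1:2, function(g)
      ng[g] * (sum(diag(solve(Sigmas[[g]], list(S1, S2)[[g]]))) +
               determinant(Sigmas[[g]])$modulus), numeric(1)))
    expect_lt(dev(apply_structure(list(S1, S2), ng, "VVE")),
              dev(apply_structure(list(S1, S2), ng, "VVI")) - 1)
    # and VVV (unconstrained) is at least as good as VVE
    expect_lte(dev(apply_structure(list(S1, S2), ng, "VVV")),
               dev(apply_structure(list(S1, S2), ng, "VVE")) + 1e-8)
  })
})

test_that("univariate model names E and V collapse the family", {
  expect_equal(count_free_parameters("E", 3, 1), 1L)
  expect_equal(count_free_parameters("V", 3, 1), 3L)
  out <- apply_structure(list(matrix(2), matrix(6)), c(10, 30), "E")
  expect_equal(out[[1]][1, 1], (10 * 2 + 30 * 6) / 40)
  outv <- apply_structure(list(matrix(2), matrix(6)), c(10, 30), "V")
  expect_equal(vapply(outv, function(S) S[1, 1], numeric(1)), c(2, 6))
  expect_error(count_free_parameters("E", 2, 3), "univariate")
})
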