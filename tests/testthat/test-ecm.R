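test_that("E-step posteriors match a naive Bayes-rule oracle", {
  withr::with_seed(31, {
    comps <- list(
      cluster_params(0.9, c(0, 0), random_spd(2, 61), eta = 5),
      cluster_params(0.8, c(3, -2), random_spd(2, 62), eta = 15))
    model <- mixture_model(c(0.45, 0.55), comps)
    X <- rbind(matrix(rnorm(30), ncol = 2),
               matrix(rnorm(30, mean = 2), ncol = 2))
    data <- cnmix_dataset(X)
    es <- e_step(data, model)
    oracle <- naive_e_step(X, c(0.45, 0.55), comps)
    expect_equal(es$posterior$z, oracle$z, tolerance = 1e-10)
    expect_equal(es$posterior$v, oracle$v, tolerance = 1e-10)
    expect_equal(max(abs(rowSums(es$posterior$z) - 1)), 0, tolerance = 1e-10)
    expect_true(all(es$posterior$v >= 0 & es$posterior$v <= 1))
    expect_true(all(es$posterior$w > 0 & es$posterior$w <= 1))
    # loglik is the sum of per-observation mixture log-densities
    expect_equal(es$loglik,
                 sum(apply(X, 1, mixture_logpdf, model = model)),
                 tolerance = 1e-10)
  })
})

test_that("identical components give symmetric responsibilities and v -> 1 at the mean under extreme inflation", {
  cp <- cluster_params(0.9, c(0, 0), diag(2), eta = 4)
  model <- mixture_model(c(0.5, 0.5), list(cp, cp))
  data <- cnmix_dataset(matrix(rnorm(20), ncol = 2))
  es <- e_step(data, model)
  expect_equal(es$posterior$z, matrix(0.5, 10, 2), ignore_attr = TRUE)

  big_eta <- cluster_params(0.9, c(0, 0), diag(2), eta = 900)
  m1 <- mixture_model(1, list(big_eta))
  es1 <- e_step(cnmix_dataset(matrix(0, 1, 2)), m1)
  expect_equal(es1$posterior$v[1, 1], 1, tolerance = 1e-3)
})

test_that("with no contamination mass the CM-step reduces to the Gaussian M-step", {
  withr::with_seed(17, {
    X <- matrix(rnorm(60), ncol = 2)
    data <- cnmix_dataset(X)
    cur <- mixture_model(1, list(cluster_params(0.99, c(0, 0), diag(2),
                                                eta = 1.001)))
    post <- list(z = matrix(1, 30, 1), v = matrix(1, 30, 1))
    up <- cm_step(data, post, "VVV", cur)
    expect_equal(up$components[[1]]$mu, colMeans(X))
    expect_equal(up$components[[1]]$Sigma,
                 crossprod(scale(X, scale = FALSE)) / 30, tolerance = 1e-10)
    # EII: trace-minimising spherical projection of the ML covariance
    up_eii <- cm_step(data, post, "EII", cur)
    S_ml <- crossprod(scale(X, scale = FALSE)) / 30
    expect_equal(up_eii$components[[1]]$Sigma,
                 diag(sum(diag(S_ml)) / 2, 2), tolerance = 1e-10)
  })
})

test_that("a collapsed cluster raises a restart signal carrying the index", {
  data <- cnmix_dataset(matrix(rnorm(40), ncol = 2))
  cur <- mixture_model(c(0.5, 0.5), list(
    cluster_params(0.9, c(0, 0), diag(2), eta = 2),
    cluster_params(0.9, c(1, 1), diag(2), eta = 2)))
  z <- cbind(rep(1, 20), rep(0, 20))
  post <- list(z = z, v = matrix(1, 20, 2))
  err <- tryCatch(cm_step(data, post, "VVV", cur), condition = identity)
  expect_s3_class(err, "cnmix_empty_cluster")
  expect_equal(err$cluster, 2L)
})

test_that("the contaminated fit attains at least the Gaussian maximum likelihood on clean data", {
  withr::with_seed(5150, {
    X <- matrix(rnorm(400, sd = 1.3), ncol = 2)
  })
  data <- cnmix_dataset(X)
  fit <- suppressWarnings(fit_ecm(data, 1, "VVV",
                                  fit_config(n_init = 2, seed = 1,
                                             tol = 1e-10, max_iter = 5000)))
  # Gaussian MLE log-likelihood in closed form (the boundary alpha -> 1)
  S_ml <- crossprod(scale(X, scale = FALSE)) / nrow(X)
  ll_gauss <- sum(apply(X, 1, function(x)
    gaussian_logpdf(x, colMeans(X), S_ml)))
  expect_gte(fit$loglik, ll_gauss - 1e-6)
})

test_that("well-separated clusters are recovered exactly and the trace ascends", {
  withr::with_seed(99, {
    X <- rbind(matrix(rnorm(300), ncol = 2),
               matrix(rnorm(300, mean = 6), ncol = 2))
  })
  data <- cnmix_dataset(X, true_labels = rep(1:2, each = 150))
  fit <- fit_ecm(data, 2, "VVI", fit_config(n_init = 3, seed = 2))
  expect_equal(adjusted_rand_index(fit$labels, data$true_labels), 1)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_equal(fit$labels, max.col(fit$posterior$z))
  expect_true(fit$converged)
})

test_that("structure constraints survive fitting", {
  sim <- recovery_preset(404, n = 300)
  fit_e <- fit_ecm(sim$data, 2, "EVI", fit_config(n_init = 2, seed = 3))
  lam <- vapply(fit_e$model$components, `[[`, numeric(1), "lambda")
  expect_lt(max(abs(lam - lam[1])), 1e-6 * lam[1])
  for (cp in fit_e$model$components)
    expect_lt(max(abs(cp$Sigma - diag(diag(cp$Sigma)))),
              1e-8 * sum(diag(cp$Sigma)))
})

test_that("boundary alpha and eta reproduce a plain Gaussian mixture fit", {
  withr::with_seed(72, {
    X <- rbind(matrix(rnorm(200), ncol = 2),
               matrix(rnorm(200, mean = 4), ncol = 2))
  })
  data <- cnmix_dataset(X)
  cfg <- fit_config(n_init = 1, seed = 4,
                    alpha_bounds = c(1 - 1e-10, 1 - 1e-10),
                    eta_bounds = c(1 + 1e-10, 1 + 1e-10),
                    init_alpha = 1 - 1e-10, init_eta = 1 + 1e-10)
  fit <- fit_ecm(data, 2, "VVV", cfg)
  # reference: plain Gaussian EM via mclust on the same data
  withr::local_package("mclust")
  ref <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-4)
})

test_that("classification rules: MAP labels, bad iff v < 1/2 at the assigned cluster", {
  sim <- recovery_preset(7, eta = 30)
  fit <- fit_ecm(sim$data, 2, "EVI", fit_config(n_init = 2, seed = 5))
  cf <- classify_and_flag(fit)
  v_at_map <- fit$posterior$v[cbind(seq_len(sim$data$n), cf$labels)]
  expect_identical(cf$bad_flags, v_at_map < 0.5)
  expect_identical(cf$labels, max.col(fit$posterior$z))
  # a point at a cluster mean is good
  mu1 <- fit$model$components[[1]]$mu
  at_mean <- predict(fit, cnmix_dataset(matrix(mu1, 1),
                                        variable_names = fit$variable_names))
  expect_false(at_mean$bad_flags[1])
  expect_gt(at_mean$v[1, at_mean$labels[1]],
            fit$model$components[[at_mean$labels[1]]]$alpha)
})

test_that("prediction is idempotent on training data and flags far points", {
  sim <- recovery_preset(12, n = 300)
  fit <- fit_ecm(sim$data, 2, "EVI", fit_config(n_init = 2, seed = 6))
  pred <- predict(fit, sim$data)
  expect_identical(pred$labels, fit$labels)
  expect_identical(pred$bad_flags, fit$bad_flags)

  far <- matrix(50, 1, 9)
  pred_far <- predict(fit, cnmix_dataset(far, variable_names = fit$variable_names))
  expect_true(pred_far$bad_flags[1])

  wrong <- cnmix_dataset(matrix(0, 2, 3), variable_names = c("a", "b", "c"))
  expect_error(predict(fit, wrong), "variable mismatch")
})

test_that("fit configuration round-trips through YAML and rejects unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(G = 2, model = "EVI", n_init = 4, seed = 9,
                        tol = 1e-4), path)
  rc <- read_fit_config(path)
  expect_equal(rc$G, 2)
  expect_equal(rc$model, "EVI")
  expect_equal(rc$config$n_init, 4L)
  expect_equal(rc$config$tol, 1e-4)
  yaml::write_yaml(list(G = 2, bogus_key = 1), path)
  expect_error(read_fit_config(path), "unknown configuration keys")
})

test_that("fit serialisation writes valid JSON with posteriors and trace", {
  sim <- dyslexia_preset(3)
  fit <- fit_ecm(sim$data, 2, "EVI", fit_config(n_init = 1, seed = 8))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$G, 2)
  expect_equal(back$loglik, fit$loglik, tolerance = 1e-12)
  expect_length(back$labels, 122)
  expect_equal(back$seed, 8)
})
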