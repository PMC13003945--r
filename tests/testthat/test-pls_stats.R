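test_that("z-scoring: exact small case, idempotence, round trip, guard", {
  z <- zscore_columns(data.frame(a = c(1, 2, 3)))
  expect_equal(z$scaled[, "a"], c(-1, 0, 1))
  z2 <- zscore_columns(z$scaled)
  expect_equal(z2$scaled, z$scaled, tolerance = 1e-12)
  set.seed(2)
  X <- matrix(rnorm(60), 20); colnames(X) <- c("u", "v", "w")
  zz <- zscore_columns(X)
  expect_equal(zscore_invert(zz), X, tolerance = 1e-12)
  X[, 2] <- 7
  expect_error(zscore_columns(X), "v")
})

test_that("correlation filter removes duplicates and spares orthogonal sets", {
  set.seed(4)
  X <- matrix(rnorm(200), 50); colnames(X) <- paste0("x", 1:4)
  X <- cbind(X, x5 = X[, 2])                 # exact duplicate of x2
  rep <- correlation_filter(scale(X))
  expect_equal(nrow(rep$removed), 1)
  expect_true(rep$removed$name %in% c("x2", "x5"))
  expect_setequal(union(rep$removed$name, rep$retained), colnames(X))

  Q <- qr.Q(qr(matrix(rnorm(100), 20, 5))); colnames(Q) <- paste0("q", 1:5)
  expect_equal(nrow(correlation_filter(Q)$removed), 0)
})

test_that("correlation filter agrees with the all-orders brute-force oracle", {
  for (s in 1:5) {
    set.seed(s)
    Z <- matrix(rnorm(40 * 2), 40)
    X <- cbind(Z[, 1], Z[, 1] + rnorm(40, 0, 0.05),
               Z[, 1] + rnorm(40, 0, 0.08),
               Z[, 2], Z[, 2] + rnorm(40, 0, 0.06))
    colnames(X) <- paste0("v", 1:5)
    X <- scale(X)
    mine <- sort(correlation_filter(X, 0.95)$retained)
    all_orders <- oracle_corr_filter_all_orders(as.data.frame(X), 0.95)
    expect_true(length(all_orders) >= 1)
    expect_true(any(vapply(all_orders, identical, logical(1), y = mine)))
  }
})

test_that("VIF filter: orthogonal clean, near-collinear removed, closed form", {
  Q <- qr.Q(qr(matrix(rnorm(200), 40, 5))) * 3
  colnames(Q) <- paste0("q", 1:5)
  rep <- vif_filter(scale(Q))
  expect_equal(nrow(rep$removed), 0)

  set.seed(9)
  x1 <- rnorm(40); x2 <- rnorm(40)
  X <- cbind(x1 = x1, x2 = x2, x3 = x1 + x2 + rnorm(40, 0, 0.05),
             x4 = rnorm(40))
  Xs <- scale(X)
  v_oracle <- oracle_vif(Xs)
  rep2 <- vif_filter(Xs)
  expect_equal(rep2$removed$name[1], colnames(X)[which.max(v_oracle)])

  # two-column X with r = 0.9 -> VIF = 1/(1-0.81), both kept
  n <- 2000; set.seed(1)
  a <- rnorm(n); b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(n)
  V <- oracle_vif(scale(cbind(a, b)))
  expect_equal(V[1], 1 / (1 - cor(a, b)^2), tolerance = 1e-6)
  expect_equal(nrow(vif_filter(scale(cbind(a = a, b = b)))$removed), 0)

  # exact collinearity recorded as infinite VIF
  Z <- cbind(p = x1, q = x2, r = x1 + x2)
  rep3 <- vif_filter(scale(Z))
  expect_true(is.infinite(rep3$removed$vif[1]))
})

test_that("NIPALS PLS: single predictor, full rank = OLS, rank guard", {
  set.seed(3)
  x <- rnorm(30); y <- 2.5 * x
  fit <- fit_pls(matrix(x, ncol = 1), y, 1)
  expect_equal(fit$r2y_cum[1], 100, tolerance = 1e-9)
  expect_equal(as.numeric(vip_scores(fit)), 1)

  X <- matrix(rnorm(200), 40, 5)
  y2 <- X %*% runif(5) + rnorm(40, 0, 0.3)
  expect_error(fit_pls(X, y2, 6), "rank")
  fit5 <- fit_pls(X, y2, 5)
  ols <- stats::lm.fit(cbind(1, scale(X)), scale(y2)[, 1])
  expect_lt(max(abs(fit5$fitted_scaled - ols$fitted.values)), 1e-8)

  # noiseless two-latent construction reaches 100% at two components
  tt <- latent_truth(n_samples = 30, n_predictors = 8, n_latent = 2,
                     n_active_per_latent = c(4, 4),
                     noise_sd = 0, response_noise_sd = 0, seed = 8)
  d <- generate_pls_dataset(tt)
  fit2 <- fit_pls(d$X, d$y, 2)
  expect_equal(fit2$r2y_cum[2], 100, tolerance = 1e-7)
})

test_that("PLS invariants: score orthogonality, R2Y monotone, VIP norm", {
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(43 * 12), 43)
    y <- X[, 1] - X[, 5] + rnorm(43)
    fit <- fit_pls(X, y, 4)
    G <- crossprod(fit$scores)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
    expect_true(all(diff(fit$r2y_cum) >= -1e-10))
    expect_equal(mean(vip_scores(fit)^2), 1, tolerance = 1e-8)
  }
})

test_that("VIP in the orthogonal one-relevant-predictor case", {
  p <- 6; n <- 240
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  y <- Q[, 3]
  fit <- fit_pls(Q, y, 1)
  vip <- vip_scores(fit)
  expect_equal(unname(vip[3]), sqrt(p), tolerance = 0.05)
  expect_lt(max(vip[-3]), 0.2)
})

test_that("cross-validation selects the latent dimension and is deterministic", {
  tt <- latent_truth(n_samples = 40, n_predictors = 12, n_latent = 3,
                     n_active_per_latent = c(5, 4, 3), noise_sd = 0.05,
                     response_noise_sd = 0.05, seed = 21)
  d <- generate_pls_dataset(tt)
  cv <- cross_validate_components(d$X, d$y, k = 10, max_components = 6,
                                  seed = 2)
  expect_equal(cv$selected, 3)
  expect_lt(cv$rmsecv[3], cv$rmsecv[1])
  expect_lt(cv$rmsecv[3], cv$rmsecv[2])
  cv2 <- cross_validate_components(d$X, d$y, k = 10, max_components = 6,
                                   seed = 2)
  expect_identical(cv, cv2)
  expect_error(cross_validate_components(d$X, d$y, k = 100), "exceed")
})

test_that("irrelevant predictors give non-positive Q2 in most null draws", {
  bad <- 0
  for (s in 1:60) {
    set.seed(1000 + s)
    X <- matrix(rnorm(40 * 8), 40)
    y <- rnorm(40)
    cv <- cross_validate_components(X, y, k = 10, max_components = 3,
                                    seed = s)
    if (any(cv$q2 > 0)) bad <- bad + 1
  }
  expect_lt(bad, 30)   # majority criterion
})

test_that("component assignment follows the max-weight rule", {
  set.seed(6)
  X <- matrix(rnorm(43 * 10), 43)
  y <- X[, 1] + rnorm(43, 0, 0.2)
  a1 <- assign_variables_to_components(fit_pls(X, y, 1))
  expect_true(all(a1$component == 1))

  # disjoint orthogonal blocks are assigned to their own component
  tt <- latent_truth(n_samples = 60, n_predictors = 10, n_latent = 2,
                     n_active_per_latent = c(5, 5), noise_sd = 0.02,
                     response_noise_sd = 0.05, seed = 3)
  d <- generate_pls_dataset(tt)
  asg <- assign_variables_to_components(fit_pls(d$X, d$y, 2))
  blk1 <- asg$component[match(paste0("x", 1:5), asg$variable)]
  blk2 <- asg$component[match(paste0("x", 6:10), asg$variable)]
  expect_true(all(blk1 == blk1[1]))
  expect_true(all(blk2 == blk2[1]))
  expect_false(blk1[1] == blk2[1])
})

test_that("latent-variable regression p-values behave at the extremes", {
  set.seed(12)
  X <- matrix(rnorm(43 * 8), 43)
  y <- X %*% rnorm(8)
  fit <- fit_pls(X, y, 2)
  # response equal to the first score: essentially perfect fit
  y2 <- fit$scores[, 1]
  fit2 <- fit_pls(X, y2 * sd(y2) + 3, 1)
  expect_lt(model_p_value(fit2)[1], 1e-10)
  expect_error(model_p_value(fit, n_components = length(y) - 1),
               "degrees of freedom")
})

test_that("required sample size: boundary behaviour and infeasibility guard", {
  expect_error(required_sample_size(-0.1), "positive")
  # enormous effect: N just above predictors + 2
  expect_lte(required_sample_size(50, 0.05, 0.80, 4), 8)
  expect_error(required_sample_size(1e-9, 0.05, 0.999, 4, n_max = 50),
               "unreachable")
})
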