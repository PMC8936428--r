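# PLS1, VIP, component choice and cross-validated prognosis.

test_that("full-rank PLS reproduces the least-squares fit", {
  set.seed(10)
  X <- matrix(rnorm(30), 10, 3)
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(10)
  fit <- pls1_fit(X, y, ncomp = 3)
  ols <- drop(cbind(1, X) %*% stats::lm.fit(cbind(1, X), y)$coefficients)
  expect_equal(fit$fitted, ols, tolerance = 1e-8)
  # exact interpolation of a noiseless linear response
  y0 <- drop(X %*% c(2, 1, -1))
  fit0 <- pls1_fit(X, y0, ncomp = 3)
  expect_lt(max(abs(fit0$fitted - y0)), 1e-8)
})

test_that("scores are orthogonal and variance explained is monotone", {
  set.seed(20)
  for (i in 1:5) {
    X <- matrix(rnorm(12 * 8), 12, 8)
    y <- rnorm(12)
    fit <- pls1_fit(X, y, ncomp = 5)
    G <- crossprod(fit$T)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
    expect_true(all(diff(fit$cum_var) >= -1e-12))
    expect_lte(fit$cum_var[5], 1 + 1e-12)
  }
})

test_that("the first weight vector tracks a dominant predictor", {
  set.seed(30)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- 10 * X[, 4] + rnorm(40)     # SNR 10:1 on column 4
  fit <- pls1_fit(X, y, ncomp = 1)
  expect_equal(which.max(abs(fit$W[, 1])), 4L)
  v <- vip_scores(fit)
  expect_equal(order(-v$vip), order(-abs(fit$W[, 1])))
})

test_that("zero-variance predictors are rejected by name", {
  X <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(pls1_fit(X, rnorm(10), 1), "b")
  expect_error(pls1_fit(X[, 1, drop = FALSE], rnorm(10), 2), "rank")
})

test_that("component choice follows the cumulative-variance rule", {
  set.seed(40)
  X <- matrix(rnorm(30), 10, 3)
  # response along a principal direction of the scaled predictors is a
  # fixed point of the weight iteration: one component captures it fully
  y1 <- svd(scale(X))$u[, 1]
  expect_equal(choose_n_components(X, y1), 1L)
  expect_equal(pls1_fit(X, y1, 1)$cum_var[1], 1, tolerance = 1e-10)
  expect_equal(choose_n_components(X, rnorm(10), threshold = 0), 1L)

  # 12 x 20 instance with three orthogonal signal directions of distinct
  # strength: the 90% rule needs exactly three components
  set.seed(11)
  n <- 12; p <- 20
  Tm <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  P <- qr.Q(qr(matrix(rnorm(p * 3), p, 3)))
  signal <- Tm %*% diag(c(12, 4, 1)) %*% t(P)
  X3 <- signal + matrix(rnorm(n * p, sd = 0.05 * sd(signal)), n, p)
  y3 <- drop(Tm %*% sqrt(c(0.4, 0.3, 0.3)))
  expect_equal(choose_n_components(X3, y3, threshold = 0.9), 3L)
  fit3 <- pls1_fit(X3, y3, 3)
  expect_lt(fit3$cum_var[2], 0.9)
  expect_gte(fit3$cum_var[3], 0.9)
})

test_that("VIP satisfies its normalization identity on every fit", {
  set.seed(50)
  for (i in 1:20) {
    n <- sample(8:20, 1)
    p <- sample(3:15, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    a <- sample(seq_len(min(p, n - 2, 4)), 1)
    v <- vip_scores(pls1_fit(X, y, a))
    expect_equal(sum(v$vip^2), p, tolerance = 1e-10)
  }
})

test_that("a single active weight concentrates all importance", {
  # orthogonal design where only predictor 2 covaries with y: the weight
  # vector has one nonzero entry, so VIP = (0, sqrt(p))
  X <- cbind(x1 = c(1, 1, -1, -1), x2 = c(1, -1, 1, -1))
  y <- X[, 2]
  fit <- pls1_fit(X, y, 1)
  v <- vip_scores(fit)
  expect_equal(v$vip, c(0, sqrt(2)), tolerance = 1e-10)
})

test_that("biomarker thresholding keeps order and falls back when empty", {
  v <- tibble::tibble(predictor = c("a", "b", "c"), vip = c(1, 1, 1))
  expect_equal(select_biomarkers(v)$predictor, c("a", "b", "c"))
  expect_equal(select_biomarkers(v, threshold = 0)$predictor,
               c("a", "b", "c"))
  expect_warning(all_back <- select_biomarkers(v, threshold = 2),
                 "falling back")
  expect_equal(nrow(all_back), 3)
  # 3 informative of 20 at 10:1 SNR are the selected set
  set.seed(60)
  X <- matrix(rnorm(60 * 20), 60, 20)
  colnames(X) <- sprintf("f%02d", 1:20)
  y <- drop(X[, c(4, 9, 17)] %*% c(5, 5, 5)) + rnorm(60, sd = 0.5)
  fit <- pls1_fit(X, y, ncomp = 3)
  v <- vip_scores(fit)
  sel <- select_biomarkers(v)
  # the informative trio passes the threshold and tops the ranking
  expect_true(all(c("f04", "f09", "f17") %in% sel$predictor))
  expect_setequal(v$predictor[order(-v$vip)][1:3], c("f04", "f09", "f17"))
})

test_that("LOOCV trains n models and respects degenerate folds", {
  set.seed(70)
  X <- matrix(rnorm(12 * 5), 12, 5)
  y <- rnorm(12)
  cv <- loocv_predict(X, y, 2)
  expect_equal(nrow(cv), 12)
  expect_equal(cv$fold, 1:12)
  expect_true(all(cv$ncomp_used == 2))
  # constant response: every prediction is that constant
  cvc <- loocv_predict(X, rep(3, 12), 2)
  expect_true(all(abs(cvc$predicted - 3) < 1e-12))
  # noiseless linear response at full rank: near-perfect out-of-fold r
  X2 <- matrix(rnorm(50 * 5), 50, 5)
  y2 <- drop(X2 %*% c(1, 2, -1, 0.5, 3))
  cv2 <- loocv_predict(X2, y2, 5)
  expect_gte(cor(cv2$predicted, cv2$observed), 0.99)
})

test_that("prediction summaries report r and RMSE consistently", {
  obs <- c(2, 5, 9, 4, 7)
  rep1 <- evaluate_predictions(obs, obs, fma_t0 = c(20, 25, 14, 30, 22))
  expect_equal(rep1$r_delta, 1)
  expect_equal(rep1$r_post, 1)
  expect_equal(rep1$rmse, 0)
  rep2 <- evaluate_predictions(obs + 2, obs)
  expect_equal(rep2$r_delta, 1)
  expect_equal(rep2$rmse, 2)
  expect_error(evaluate_predictions(1:2, 1:2), "at least 3")
  # with dominant baseline variance the level correlation exceeds the
  # gain correlation -- constructed, not assumed
  set.seed(80)
  t0 <- sample(10:45, 12)
  delta <- rnorm(12, 5, 2)
  predd <- delta + rnorm(12, 0, 2)
  rep3 <- evaluate_predictions(predd, delta, fma_t0 = t0)
  expect_gt(rep3$r_post, rep3$r_delta)
})

test_that("pipeline predictions are invariant to predictor rescaling", {
  set.seed(90)
  X <- matrix(runif(12 * 6), 12, 6)
  colnames(X) <- sprintf("f%d", 1:6)
  y <- rnorm(12, 5, 2)
  p1 <- suppressWarnings(pls_prognosis(X, y))
  X2 <- X
  X2[, 3] <- X2[, 3] * 100
  p2 <- suppressWarnings(pls_prognosis(X2, y))
  expect_equal(p1$report$r_delta, p2$report$r_delta, tolerance = 1e-8)
  expect_equal(p1$cv_predictions$predicted, p2$cv_predictions$predicted,
               tolerance = 1e-8)
})

test_that("selection-before-CV is optimistic where nested CV is honest", {
  set.seed(99)
  res <- purrr::map(1:40, function(i) {
    X <- matrix(runif(12 * 20), 12, 20)
    colnames(X) <- sprintf("f%02d", 1:20)
    y <- rnorm(12, 5, 3) # null: response independent of predictors
    pp <- suppressWarnings(pls_prognosis(X, y, cv = "paper"))
    pn <- suppressWarnings(pls_prognosis(X, y, cv = "nested"))
    c(paper = pp$report$r_delta, nested = pn$report$r_delta)
  })
  res <- do.call(rbind, res)
  expect_gt(mean(res[, "paper"]), 0.2)
  expect_gt(mean(res[, "paper"]) - mean(res[, "nested"]), 0.3)
  expect_lt(abs(mean(res[, "nested"])), 0.35)
})

test_that("training predictions match an independent PLS implementation", {
  set.seed(95)
  X <- matrix(rnorm(12 * 6), 12, 6)
  colnames(X) <- sprintf("x%d", 1:6)
  y <- rnorm(12)
  for (a in c(1, 2, 3)) {
    fit <- pls1_fit(X, y, ncomp = a)
    mo <- mixOmics::pls(X, y, ncomp = a, mode = "regression", scale = TRUE)
    mo_pred <- predict(mo, X)$predict[, 1, a]
    expect_equal(fit$fitted, unname(mo_pred), tolerance = 1e-8)
  }
})

test_that("tidy and glance expose the fitted quantities", {
  set.seed(100)
  X <- matrix(rnorm(30), 10, 3)
  colnames(X) <- c("a", "b", "c")
  y <- rnorm(10)
  fit <- pls1_fit(X, y, 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 6)
  expect_named(td, c("predictor", "component", "weight", "loading", "vip"))
  gl <- glance(fit)
  expect_equal(gl$ncomp, 2)
  expect_equal(gl$y_variance_explained, fit$cum_var[2])
  rep <- evaluate_predictions(y, y + 1)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_named(glance(rep), c("n", "r_delta", "r_post", "rmse"))
})

test_that("plot constructors return ggplot objects", {
  set.seed(101)
  X <- matrix(rnorm(36), 12, 3)
  y <- rnorm(12)
  fit <- pls1_fit(X, y, 2)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_vip(vip_scores(fit)), "ggplot")
  expect_s3_class(autoplot(evaluate_predictions(y, y + rnorm(12))), "ggplot")
})
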