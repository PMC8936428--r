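# PLS1 regression (NIPALS), VIP biomarker selection and leave-one-out
# cross-validated prognosis.

.as_predictor_matrix <- function(x) {
  if (is.data.frame(x)) {
    nm <- names(x)
    num <- vapply(x, is.numeric, logical(1))
    x <- as.matrix(x[, num, drop = FALSE])
    colnames(x) <- nm[num]
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  x
}

#' Fit a single-response PLS regression (NIPALS)
#'
#' Sequential NIPALS extraction on autoscaled predictors and a centered
#' response.  For each component `a`: the weight vector is the (normalized)
#' covariance direction `w_a = X' y / ||X' y||`, scores `t_a = X w_a`,
#' x-loadings `p_a = X' t_a / (t_a' t_a)`, y-loading
#' `b_a = y' t_a / (t_a' t_a)`, after which both `X` and `y` are deflated.
#' Successive score vectors are mutually orthogonal and the cumulative
#' fraction of response variance explained is non-decreasing in `a`.
#'
#' @param x Predictor matrix or data frame (subjects x predictors), no
#'   missing entries.  Zero-variance columns are rejected by name.
#' @param y Numeric response (intervention gains).
#' @param ncomp Number of components; must not exceed the rank of the
#'   centered predictor matrix.
#' @return An object of class `pls1_fit`: weights `W`, loadings `P`, scores
#'   `T`, y-loadings `b`, scaling constants, `cum_var` (cumulative response
#'   variance fraction per component) and the implied regression
#'   coefficients on the original scale.
#' @seealso [vip_scores()], [loocv_predict()], [choose_n_components()]
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 20, 3)
#' y <- x %*% c(1, -1, 0.5) + rnorm(20, sd = 0.1)
#' fit <- pls1_fit(x, y, ncomp = 3)
#' glance(fit)
pls1_fit <- function(x, y, ncomp) {
  X <- .as_predictor_matrix(x)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) abort("`y` must have one value per row of `x`.")
  if (anyNA(X) || anyNA(y)) abort("Missing entries are not allowed.")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    abort(paste0(
      "Zero-variance predictor column(s): ",
      paste(colnames(X)[sds == 0], collapse = ", ")
    ))
  }
  x_means <- colMeans(X)
  Xs <- scale(X, center = x_means, scale = sds)
  rk <- qr(Xs)$rank
  if (ncomp > rk) {
    abort(paste0("`ncomp` = ", ncomp, " exceeds the predictor rank (", rk,
                 ")."))
  }
  y_mean <- mean(y)
  yc <- y - y_mean
  ss_y <- sum(yc^2)

  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  b <- numeric(ncomp)
  Xd <- Xs; yd <- yc
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      # response fully explained: later components would be arbitrary
      ncomp <- a - 1L
      if (ncomp == 0) abort("`y` does not covary with any predictor.")
      W <- W[, seq_len(ncomp), drop = FALSE]
      P <- P[, seq_len(ncomp), drop = FALSE]
      Tm <- Tm[, seq_len(ncomp), drop = FALSE]
      b <- b[seq_len(ncomp)]
      break
    }
    w <- w / nw
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xd, t_a)) / tt
    b_a <- sum(yd * t_a) / tt
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; b[a] <- b_a
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - b_a * t_a
  }
  ssy_comp <- b^2 * colSums(Tm^2)
  cum_var <- if (ss_y > 0) cumsum(ssy_comp) / ss_y else rep(NA_real_, ncomp)

  # coefficients on the autoscaled scale, then back-transformed
  R <- W %*% solve(crossprod(P, W))
  beta_s <- drop(R %*% b)
  beta <- beta_s / sds
  intercept <- y_mean - sum(beta * x_means)

  structure(
    list(
      ncomp = ncomp, n = n, p = p, rank = rk,
      predictors = colnames(X),
      W = W, P = P, T = Tm, b = b,
      x_means = x_means, x_scales = sds, y_mean = y_mean, ss_y = ss_y,
      ssy_comp = ssy_comp, cum_var = cum_var,
      coefficients = stats::setNames(beta, colnames(X)),
      intercept = intercept,
      fitted = y_mean + drop(Tm %*% b),
      y = y
    ),
    class = "pls1_fit"
  )
}

#' @export
print.pls1_fit <- function(x, ...) {
  cat(sprintf(
    "<pls1_fit> %d component(s), %d subjects x %d predictors; cumulative y-variance: %s\n",
    x$ncomp, x$n, x$p,
    paste(sprintf("%.3f", x$cum_var), collapse = " ")
  ))
  invisible(x)
}

#' Predict from a fitted PLS1 model
#'
#' @param object A [pls1_fit()] object.
#' @param newdata Predictor matrix or data frame with the training columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls1_fit <- function(object, newdata, ...) {
  X <- .as_predictor_matrix(newdata)
  X <- X[, object$predictors, drop = FALSE]
  drop(object$intercept + X %*% object$coefficients)
}

#' Cumulative response variance explained
#'
#' Fraction of response sum of squares captured by the first `a` components:
#' `sum_{i <= a} b_i^2 (t_i' t_i) / SS_y`.  Non-decreasing in `a` and at most
#' 1.
#'
#' @param fit A [pls1_fit()] object.
#' @param a Component count, `1 <= a <= ncomp` (default: all).
#' @return Numeric vector of cumulative fractions.
#' @export
y_variance_explained <- function(fit, a = seq_len(fit$ncomp)) {
  stopifnot(inherits(fit, "pls1_fit"), all(a >= 1), all(a <= fit$ncomp))
  fit$cum_var[a]
}

#' Smallest component count reaching a variance threshold
#'
#' Fits the full-rank PLS sequence and returns the smallest number of
#' components whose cumulative response-variance fraction reaches
#' `threshold` (default 0.90).  If the threshold is unreachable the rank is
#' returned with a warning.
#'
#' @inheritParams pls1_fit
#' @param threshold Target fraction in `(0, 1)`; `threshold = 0` yields 1
#'   component.
#' @return Integer component count.
#' @export
choose_n_components <- function(x, y, threshold = 0.90) {
  stopifnot(threshold >= 0, threshold < 1)
  X <- .as_predictor_matrix(x)
  rk <- qr(scale(X))$rank
  fit <- pls1_fit(X, y, ncomp = rk)
  hit <- which(fit$cum_var >= threshold)
  if (length(hit) == 0) {
    warn(paste0(
      "Cumulative variance reaches only ",
      sprintf("%.3f", fit$cum_var[rk]), " at full rank ", rk,
      "; returning the rank."
    ))
    return(rk)
  }
  max(1L, min(hit))
}

#' Variable importance in projection (VIP)
#'
#' Per-predictor importance aggregated over components:
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{aj}/\|w_a\|)^2 / \sum_a SSY_a}}
#' with `SSY_a = b_a^2 (t_a' t_a)` the response sum of squares captured by
#' component `a`.  The squared VIPs average to exactly 1
#' (`sum_j VIP_j^2 = p`).
#'
#' @param fit A [pls1_fit()] object.
#' @return Tibble with `predictor`, `vip`, in training column order.
#' @export
vip_scores <- function(fit) {
  stopifnot(inherits(fit, "pls1_fit"))
  ssy <- fit$ssy_comp
  Wn <- sweep(fit$W, 2, sqrt(colSums(fit$W^2)), `/`)
  vip <- sqrt(fit$p * drop(Wn^2 %*% ssy) / sum(ssy))
  tibble(predictor = fit$predictors, vip = vip)
}

#' Threshold VIP scores into a biomarker set
#'
#' Keeps predictors with `vip >= threshold` (default 1.0, the conventional
#' cut-off), preserving the original predictor order.  If nothing survives,
#' all predictors are returned with a warning so the downstream model is
#' still estimable.
#'
#' @param vip Tibble from [vip_scores()].
#' @param threshold VIP cut-off (default 1.0).
#' @return Tibble of selected rows of `vip`.
#' @export
select_biomarkers <- function(vip, threshold = 1.0) {
  stopifnot(is_tibble(vip) || is.data.frame(vip), "vip" %in% names(vip))
  keep <- vip$vip >= threshold
  if (!any(keep)) {
    warn("No predictor reaches the VIP threshold; falling back to all.")
    return(as_tibble(vip))
  }
  as_tibble(vip[keep, , drop = FALSE])
}

#' Leave-one-out cross-validated predictions
#'
#' Fits `n` PLS1 models, each on `n - 1` subjects (autoscaling recomputed
#' inside every fold) and applied to the held-out subject.  When a fold's
#' predictor rank drops below `ncomp`, that fold uses its rank instead and
#' the reduction is recorded.
#'
#' @inheritParams pls1_fit
#' @param ncomp Components per fold (normally the full-sample choice).
#' @return Tibble with `fold`, `observed`, `predicted`, `ncomp_used`.
#' @export
loocv_predict <- function(x, y, ncomp) {
  X <- .as_predictor_matrix(x)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < ncomp + 2) abort("Too few subjects for this component count.")
  res <- purrr::map(seq_len(n), function(i) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    if (sd(ytr) == 0) {
      # centered response is identically zero: prediction is the fold mean
      return(tibble(fold = i, observed = y[i], predicted = mean(ytr),
                    ncomp_used = 0L))
    }
    rk <- qr(scale(Xtr))$rank
    a <- min(ncomp, rk)
    fit <- pls1_fit(Xtr, ytr, ncomp = a)
    tibble(fold = i, observed = y[i],
           predicted = predict(fit, X[i, , drop = FALSE]),
           ncomp_used = as.integer(a))
  })
  bind_rows(res)
}

#' Summarize predicted against observed gains
#'
#' Pearson correlation between predicted and observed intervention gains
#' (`r_delta`), the same correlation on outcome levels
#' (`fma_t0 + delta` on both sides, `r_post`), and the RMSE of the gain
#' predictions.
#'
#' @param predictions,observations Aligned numeric vectors of predicted and
#'   observed gains (>= 3 subjects).
#' @param fma_t0 Baseline scores used to form outcome levels; omit to skip
#'   `r_post`.
#' @return Object of class `prediction_report`: per-subject tibble plus the
#'   summary metrics.  Use [tidy()] / [glance()] to extract them.
#' @export
evaluate_predictions <- function(predictions, observations, fma_t0 = NULL) {
  if (length(predictions) != length(observations)) {
    abort("`predictions` and `observations` must be aligned.")
  }
  if (length(predictions) < 3) {
    abort("Need at least 3 subjects to correlate predictions.")
  }
  subjects <- tibble(
    subject = seq_along(predictions),
    observed_delta = observations,
    predicted_delta = predictions
  )
  r_post <- NA_real_
  if (!is.null(fma_t0)) {
    stopifnot(length(fma_t0) == length(predictions))
    subjects <- subjects %>% mutate(
      fma_t0 = fma_t0,
      observed_post = fma_t0 + observations,
      predicted_post = fma_t0 + predictions
    )
    r_post <- cor(subjects$predicted_post, subjects$observed_post)
  }
  structure(
    list(
      subjects = subjects,
      r_delta = cor(predictions, observations),
      r_post = r_post,
      rmse = sqrt(mean((predictions - observations)^2))
    ),
    class = "prediction_report"
  )
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf(
    "<prediction_report> n = %d: r(delta) = %.3f, r(post) = %s, RMSE = %.3f\n",
    nrow(x$subjects), x$r_delta,
    ifelse(is.na(x$r_post), "NA", sprintf("%.3f", x$r_post)), x$rmse
  ))
  invisible(x)
}

#' Full prognosis stage: component choice, VIP selection, LOOCV
#'
#' Runs the complete prediction protocol on a feature table: choose the
#' component count by the cumulative-variance rule, compute VIP scores,
#' select biomarkers at the VIP threshold, refit on the selected set and
#' estimate out-of-sample performance by leave-one-out cross-validation.
#'
#' Two cross-validation protocols are available.  `cv = "paper"` (default)
#' selects biomarkers once on the full sample and holds the set fixed inside
#' the folds -- the published protocol, optimistic because selection has seen
#' every subject.  `cv = "nested"` repeats component choice and VIP
#' selection inside each training fold, giving an honest (near-unbiased)
#' out-of-fold estimate.
#'
#' @param features Tibble/matrix of predictors (subjects x band-pair
#'   coherences).
#' @param gains Numeric intervention gains, one per subject.
#' @param fma_t0 Optional baseline scores for outcome-level correlations.
#' @param variance_threshold Cumulative response-variance target for
#'   [choose_n_components()] (default 0.90).
#' @param vip_threshold VIP cut-off for [select_biomarkers()] (default 1.0).
#' @param cv `"paper"` or `"nested"` (see Details).
#' @return List of class `pls_prognosis`: the full-sample `fit`, `ncomp`,
#'   `vip`, `biomarkers`, refitted `biomarker_fit`, LOOCV `cv_predictions`
#'   and the [evaluate_predictions()] `report`.
#' @export
pls_prognosis <- function(features, gains, fma_t0 = NULL,
                          variance_threshold = 0.90, vip_threshold = 1.0,
                          cv = c("paper", "nested")) {
  cv <- match.arg(cv)
  X <- .as_predictor_matrix(features)
  ncomp <- choose_n_components(X, gains, threshold = variance_threshold)
  fit <- pls1_fit(X, gains, ncomp = ncomp)
  vip <- vip_scores(fit)
  biomarkers <- select_biomarkers(vip, threshold = vip_threshold)
  Xb <- X[, biomarkers$predictor, drop = FALSE]
  ncomp_b <- min(ncomp, qr(scale(Xb))$rank)
  biomarker_fit <- pls1_fit(Xb, gains, ncomp = ncomp_b)

  cvpred <- if (cv == "paper") {
    loocv_predict(Xb, gains, ncomp = ncomp_b)
  } else {
    n <- nrow(X)
    bind_rows(purrr::map(seq_len(n), function(i) {
      Xtr <- X[-i, , drop = FALSE]
      ytr <- gains[-i]
      a_i <- choose_n_components(Xtr, ytr, threshold = variance_threshold)
      sel_i <- select_biomarkers(vip_scores(pls1_fit(Xtr, ytr, a_i)),
                                 threshold = vip_threshold)
      Xi <- Xtr[, sel_i$predictor, drop = FALSE]
      a_fit <- min(a_i, qr(scale(Xi))$rank)
      fit_i <- pls1_fit(Xi, ytr, ncomp = a_fit)
      tibble(
        fold = i, observed = gains[i],
        predicted = predict(fit_i,
                            X[i, sel_i$predictor, drop = FALSE]),
        ncomp_used = as.integer(a_fit)
      )
    }))
  }
  report <- evaluate_predictions(cvpred$predicted, cvpred$observed, fma_t0)
  structure(
    list(
      fit = fit, ncomp = ncomp, vip = vip, biomarkers = biomarkers,
      biomarker_fit = biomarker_fit, cv = cv,
      cv_predictions = cvpred, report = report,
      variance_threshold = variance_threshold,
      vip_threshold = vip_threshold
    ),
    class = "pls_prognosis"
  )
}

#' @export
print.pls_prognosis <- function(x, ...) {
  cat(sprintf(
    "<pls_prognosis> %d components, %d/%d biomarkers (VIP >= %g), %s CV\n",
    x$ncomp, nrow(x$biomarkers), x$fit$p, x$vip_threshold, x$cv
  ))
  print(x$report)
  invisible(x)
}

# ---- broom-style accessors ------------------------------------------------

#' Tidy a PLS1 fit
#'
#' One row per predictor x component: weights, loadings and the per-predictor
#' VIP score.
#'
#' @param x A [pls1_fit()] object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pls1_fit <- function(x, ...) {
  vip <- vip_scores(x)
  purrr::map(seq_len(x$ncomp), function(a) {
    tibble(
      predictor = x$predictors,
      component = a,
      weight = x$W[, a],
      loading = x$P[, a]
    )
  }) %>%
    bind_rows() %>%
    left_join(vip, by = "predictor")
}

#' @rdname tidy.pls1_fit
#' @export
glance.pls1_fit <- function(x, ...) {
  tibble(
    n = x$n, p = x$p, ncomp = x$ncomp,
    y_variance_explained = x$cum_var[x$ncomp],
    rmse_train = sqrt(mean((x$fitted - x$y)^2))
  )
}

#' @rdname tidy.prediction_report
#' @export
glance.prediction_report <- function(x, ...) {
  tibble(
    n = nrow(x$subjects), r_delta = x$r_delta, r_post = x$r_post,
    rmse = x$rmse
  )
}

#' Tidy a prediction report
#'
#' @param x An [evaluate_predictions()] object.
#' @param ... Unused.
#' @return Per-subject tibble of observed and predicted values.
#' @export
tidy.prediction_report <- function(x, ...) x$subjects
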