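# FMA-UE clinical score management and within-group outcome statistics.

.check_clinical <- function(records, cols = c("subject_id", "fma_t0",
                                              "fma_tpost")) {
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0) {
    abort(paste0(
      "Clinical table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  invisible(records)
}

#' Last-observation-carried-forward imputation of the 6-month score
#'
#' Replaces a missing 6-month follow-up FMA-UE by the post-training score and
#' flags the record (`imputed_t6m`).  Records already complete pass through
#' untouched; a record with no post-training score cannot be imputed and is
#' rejected.
#'
#' @param records Clinical tibble with `fma_t0`, `fma_tpost`, `fma_t6m`
#'   (NA = missing).
#' @return `records` with `fma_t6m` completed and an `imputed_t6m` flag.
#' @export
#' @examples
#' locf_impute(fma_table1())[c("subject_id", "fma_t6m", "imputed_t6m")]
locf_impute <- function(records) {
  .check_clinical(records, c("subject_id", "fma_t0", "fma_tpost", "fma_t6m"))
  if (anyNA(records$fma_tpost) || anyNA(records$fma_t0)) {
    bad <- records$subject_id[is.na(records$fma_tpost) | is.na(records$fma_t0)]
    abort(paste0(
      "Cannot impute: missing baseline or post-training score for ",
      paste(bad, collapse = ", ")
    ))
  }
  records %>%
    mutate(
      imputed_t6m = is.na(.data$fma_t6m),
      fma_t6m = ifelse(is.na(.data$fma_t6m), .data$fma_tpost, .data$fma_t6m)
    )
}

#' Tukey-fence screening of follow-up changes
#'
#' Flags participants whose post-training to 6-month change
#' `d = fma_t6m - fma_tpost` lies outside the Tukey fences
#' `[Q1 - k*IQR, Q3 + k*IQR]` computed across the cohort.  Quartiles default
#' to Tukey hinges ([stats::fivenum()]); `method = "quantile7"` uses
#' [stats::quantile()] type 7 instead.
#'
#' @param records Clinical tibble with complete `fma_tpost` and `fma_t6m`.
#' @param k Fence multiplier (default 1.5).
#' @param method Quartile convention, `"hinges"` (default) or `"quantile7"`.
#' @return Character vector of flagged `subject_id`s (possibly empty).
#' @export
tukey_outlier_flags <- function(records, k = 1.5,
                                method = c("hinges", "quantile7")) {
  method <- match.arg(method)
  .check_clinical(records, c("subject_id", "fma_tpost", "fma_t6m"))
  ok <- !is.na(records$fma_tpost) & !is.na(records$fma_t6m)
  if (sum(ok) < 4) {
    abort("Need at least 4 records with both post and 6-month scores.")
  }
  d <- records$fma_t6m[ok] - records$fma_tpost[ok]
  q <- switch(method,
    hinges = fivenum(d)[c(2, 4)],
    quantile7 = unname(quantile(d, c(0.25, 0.75), type = 7))
  )
  iqr <- q[2] - q[1]
  out <- d < q[1] - k * iqr | d > q[2] + k * iqr
  records$subject_id[ok][out]
}

#' Classify recovery by the minimal clinically important difference
#'
#' A participant shows good recovery when either intervention gain --
#' `delta_post = fma_tpost - fma_t0` or `delta_6m = fma_t6m - fma_t0` --
#' reaches the MCID (4 FMA-UE points); otherwise poor.  By default the MCID
#' itself counts as good (`rule = "gte"`); `rule = "gt"` requires strictly
#' more.  Both conventions reproduce the published labels for the packaged
#' cohort.
#'
#' @param records Clinical tibble, 6-month scores completed (see
#'   [locf_impute()]).
#' @param mcid MCID threshold in FMA-UE points (default 4).
#' @param rule `"gte"` (default) or `"gt"`.
#' @return `records` with `delta_post`, `delta_6m` and a `recovery` factor
#'   (`good`/`poor`) added.
#' @export
#' @examples
#' dplyr::count(classify_recovery(locf_impute(fma_table1())), group, recovery)
classify_recovery <- function(records, mcid = 4, rule = c("gte", "gt")) {
  rule <- match.arg(rule)
  .check_clinical(records, c("subject_id", "fma_t0", "fma_tpost", "fma_t6m"))
  if (anyNA(records$fma_t6m)) {
    abort("`fma_t6m` has missing values; run locf_impute() first.")
  }
  cmp <- if (rule == "gte") `>=` else `>`
  records %>%
    mutate(
      delta_post = .data$fma_tpost - .data$fma_t0,
      delta_6m = .data$fma_t6m - .data$fma_t0,
      recovery = factor(
        ifelse(cmp(pmax(.data$delta_post, .data$delta_6m), mcid),
               "good", "poor"),
        levels = c("good", "poor")
      )
    )
}

#' Tie-corrected Friedman test
#'
#' Friedman's rank test for `k` repeated measures on `n` subjects with the
#' tie correction used by standard statistical software: scores are ranked
#' within each subject (mean ranks for ties) and
#' \deqn{\chi^2 = \frac{\frac{12}{nk(k+1)}\sum_j R_j^2 - 3n(k+1)}{1 -
#'   \sum (t^3 - t) / (n k (k^2 - 1))}}
#' where the tie sum runs over tie groups within each subject's row.  With no
#' ties this reduces to the textbook statistic (and matches
#' [stats::friedman.test()]).
#'
#' @param scores Numeric matrix or data frame, subjects x timepoints, no
#'   missing cells.
#' @return One-row tibble: `statistic` (chi-squared), `df`, `p_value`, `n`,
#'   `k`.
#' @export
#' @examples
#' ngao <- fma_table1() |> locf_impute() |> dplyr::filter(group == "NG-AO")
#' friedman_tie_corrected(ngao[, c("fma_t0", "fma_tpost", "fma_t6m")])
friedman_tie_corrected <- function(scores) {
  m <- as.matrix(scores)
  if (!is.numeric(m)) abort("`scores` must be numeric.")
  if (anyNA(m)) abort("`scores` has missing cells; impute first.")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) abort("Need at least 2 subjects and 2 timepoints.")
  R <- t(apply(m, 1, rank))
  Rj <- colSums(R)
  chi_raw <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- sum(apply(m, 1, function(r) {
    tt <- table(r)
    sum(tt^3 - tt)
  }))
  C <- 1 - ties / (n * k * (k^2 - 1))
  if (C <= 0) abort("All scores tied within every subject; test undefined.")
  chi <- chi_raw / C
  tibble(
    statistic = chi, df = k - 1,
    p_value = pchisq(chi, k - 1, lower.tail = FALSE),
    n = n, k = k
  )
}

#' Wilcoxon signed-rank test, normal approximation
#'
#' Paired signed-rank test in the convention of mainstream clinical software:
#' zero differences are dropped, absolute differences are ranked with mean
#' ranks for ties, and
#' \deqn{Z = \frac{\min(W^+, W^-) - n'(n'+1)/4}{\sqrt{n'(n'+1)(2n'+1)/24 -
#'   \sum(t^3 - t)/48}}}
#' with no continuity correction; the two-sided p-value comes from the normal
#' tail.  `Z` is reported negative whenever a systematic change exists
#' (`min(W+, W-) <= mean`).
#'
#' @param pre,post Paired numeric vectors.
#' @return One-row tibble: `z`, `p_value`, `n_nonzero`, `w_plus`, `w_minus`.
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  if (length(pre) != length(post)) abort("`pre` and `post` must be paired.")
  d <- post - pre
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    abort("All paired differences are zero; signed-rank test is degenerate.")
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  mu <- n * (n + 1) / 4
  tt <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
  if (sigma2 <= 0) abort("Zero variance in signed ranks; test undefined.")
  z <- (min(w_plus, w_minus) - mu) / sqrt(sigma2)
  tibble(
    z = z, p_value = 2 * pnorm(z), n_nonzero = n,
    w_plus = w_plus, w_minus = w_minus
  )
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` elementwise, for a family of `m` comparisons.
#'
#' @param p Numeric vector of p-values.
#' @param m Family size (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  pmin(1, p * m)
}

#' Within-group clinical outcome report
#'
#' For each group: the tie-corrected Friedman test across the three FMA-UE
#' timepoints, followed by the three pairwise signed-rank post hoc contrasts
#' with Bonferroni correction (family of 3).
#'
#' @param records Clinical tibble with a `group` column; 6-month scores are
#'   imputed on the fly if needed.
#' @return List with tibbles `friedman` (one row per group) and `posthoc`
#'   (three rows per group: contrast, z, p, p_bonferroni).
#' @export
#' @examples
#' rep <- clinical_outcome_report(fma_table1())
#' rep$friedman
clinical_outcome_report <- function(records) {
  .check_clinical(records, c("subject_id", "group", "fma_t0", "fma_tpost",
                             "fma_t6m"))
  records <- locf_impute(records)
  groups <- unique(records$group)
  fried <- purrr::map(groups, function(g) {
    m <- records %>% filter(.data$group == g)
    friedman_tie_corrected(m[, c("fma_t0", "fma_tpost", "fma_t6m")]) %>%
      mutate(group = g, .before = 1)
  }) %>% bind_rows()
  contrasts <- list(
    c("fma_t0", "fma_tpost"),
    c("fma_t0", "fma_t6m"),
    c("fma_tpost", "fma_t6m")
  )
  posthoc <- purrr::map(groups, function(g) {
    m <- records %>% filter(.data$group == g)
    purrr::map(contrasts, function(ct) {
      wilcoxon_signed_rank(m[[ct[1]]], m[[ct[2]]]) %>%
        mutate(group = g, contrast = paste(ct, collapse = " vs "),
               .before = 1)
    }) %>% bind_rows()
  }) %>%
    bind_rows() %>%
    group_by(.data$group) %>%
    mutate(p_bonferroni = bonferroni_adjust(.data$p_value, m = 3)) %>%
    ungroup()
  list(friedman = fried, posthoc = posthoc)
}
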