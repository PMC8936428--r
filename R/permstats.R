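# Group-difference and correlation screening: exact permutation t-tests,
# Hedges' g, FDR, Spearman screening with a seeded permutation null, and the
# predictor-selection rule feeding the PLS stage.

# Pooled-variance two-sample t statistic for every column of a 0/1 group-A
# membership matrix (n x n_assignments).  Degenerate assignments (zero pooled
# variance) get |t| = Inf when the means differ, 0 otherwise.
.t_all_assignments <- function(x, member, na) {
  n <- length(x)
  nb <- n - na
  sa <- as.vector(crossprod(x, member))          # group-A sums
  sqa <- as.vector(crossprod(x^2, member))
  stot <- sum(x)
  sqtot <- sum(x^2)
  ma <- sa / na
  mb <- (stot - sa) / nb
  ssa <- sqa - na * ma^2
  ssb <- (sqtot - sqa) - nb * mb^2
  sp2 <- (ssa + ssb) / (n - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  zero <- se <= 0 | !is.finite(t)
  if (any(zero)) {
    t[zero] <- ifelse(abs(ma[zero] - mb[zero]) > 0, Inf, 0)
  }
  t
}

.assignment_matrix <- function(n, na) {
  idx <- combn(n, na)
  member <- matrix(0, n, ncol(idx))
  member[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = na))] <- 1
  member
}

#' Exact two-sample permutation t-test
#'
#' Enumerates every assignment of the pooled observations into groups of the
#' observed sizes (`choose(n, n_a)` splits) and reports the two-sided
#' p-value: the fraction of assignments whose pooled-variance t statistic is
#' at least as extreme (in absolute value) as the observed one.  The observed
#' assignment is one of the enumerated splits, so `p >= 1/choose(n, n_a)` by
#' construction and no Monte-Carlo correction is needed.  Fully
#' deterministic.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @param max_assignments Guard on the enumeration size (default `1e6`);
#'   larger designs are rejected rather than silently subsampled.
#' @return One-row tibble: `t` (observed statistic), `p_value`,
#'   `n_assignments`.
#' @export
#' @examples
#' exact_permutation_ttest(c(1, 2), c(3, 4)) # p = 2/6
exact_permutation_ttest <- function(a, b, max_assignments = 1e6) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) abort("Each group needs at least 2 observations.")
  n <- na + nb
  n_assign <- choose(n, na)
  if (n_assign > max_assignments) {
    abort(paste0(
      "choose(", n, ", ", na, ") = ", format(n_assign, big.mark = ","),
      " assignments exceed the enumeration guard; use a Monte-Carlo test."
    ))
  }
  x <- c(a, b)
  member <- .assignment_matrix(n, na)
  t_all <- .t_all_assignments(x, member, na)
  t_obs <- .t_all_assignments(x, matrix(c(rep(1, na), rep(0, nb))), na)
  # relative tolerance so the observed split always counts itself
  thr <- abs(t_obs) * (1 - 1e-12)
  p <- sum(abs(t_all) >= thr) / n_assign
  tibble(t = t_obs, p_value = p, n_assignments = n_assign)
}

#' Hedges' g effect size
#'
#' Bias-corrected standardized mean difference
#' `g = J * (mean(a) - mean(b)) / s_pooled` with pooled SD on `n - 1`
#' denominators and small-sample correction `J = 1 - 3 / (4(n_a + n_b) - 9)`.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return A single numeric effect size.
#' @export
#' @examples
#' hedges_g(c(1, 2, 3), c(4, 5, 6)) # -2.4
hedges_g <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) abort("Each group needs at least 2 observations.")
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 <= 0) abort("Zero pooled SD; Hedges' g is undefined.")
  J <- 1 - 3 / (4 * (na + nb) - 9)
  J * (mean(a) - mean(b)) / sqrt(sp2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()] (`method = "BH"`).
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Spearman rank correlation
#'
#' Tie-safe Spearman coefficient (Pearson correlation of mean-ranked data)
#' via [stats::cor()].  Constant input is rejected: the coefficient is
#' undefined there.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A single correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Spearman correlation is undefined for constant input.")
  }
  cor(x, y, method = "spearman")
}

#' Permutation-null test for a Spearman correlation
#'
#' Shuffles `y` `n_perm` times with a seeded generator, recomputes the
#' Spearman coefficient for each shuffle, and reports
#' `p = (1 + #\{|rho_perm| >= |rho_obs|\}) / (n_perm + 1)` -- the add-one
#' form that keeps Monte-Carlo p-values off zero.  The seed is echoed in the
#' result so every screen is reproducible.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param n_perm Number of shuffles (default 5000).  Below 100 a warning is
#'   issued.
#' @param seed Integer seed for the shuffle stream.
#' @return One-row tibble: `rho`, `p_value`, `n_perm`, `seed`.
#' @export
permutation_corr_test <- function(x, y, n_perm = 5000, seed = 20210925) {
  rho <- spearman_rho(x, y)
  if (n_perm < 100) {
    warn(paste0("n_perm = ", n_perm, " is very small; p resolution is 1/",
                n_perm + 1, "."))
  }
  rx <- rank(x)
  ry <- rank(y)
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      abs(cor(rx, sample(ry))) >= abs(rho) - 1e-12
    }, logical(1)))
  })
  tibble(
    rho = rho,
    p_value = (1 + exceed) / (n_perm + 1),
    n_perm = as.integer(n_perm),
    seed = as.integer(seed)
  )
}

#' Good-vs-poor network comparisons
#'
#' For every band x network combination, compares the network coherence of
#' good- and poor-recovery participants with the exact permutation t-test,
#' attaches Hedges' g, and BH-adjusts the p-values across the whole band x
#' network family (20 comparisons with the default five networks and four
#' bands).
#'
#' @param network_values Tibble from [network_aggregate()] (`subject_id`,
#'   `band`, `network`, `value`).
#' @param labels Tibble with `subject_id` and a `recovery` factor
#'   (see [classify_recovery()]).
#' @param alpha Significance level used for the `discriminative` flag
#'   (default 0.05, applied to the raw permutation p, matching the published
#'   screening logic; set `use_fdr = TRUE` to flag on the adjusted p).
#' @param use_fdr Flag discriminative combinations on `p_fdr` instead of the
#'   raw permutation p.
#' @return Tibble: `band`, `network`, `n_good`, `n_poor`, `t`, `p_perm`,
#'   `p_fdr`, `hedges_g`, `discriminative`.
#' @export
group_comparison_report <- function(network_values, labels, alpha = 0.05,
                                    use_fdr = FALSE) {
  dat <- left_join(network_values, labels %>%
                     select("subject_id", "recovery"), by = "subject_id")
  if (anyNA(dat$recovery)) {
    abort("Some subjects in `network_values` have no recovery label.")
  }
  class_n <- table(dat$recovery[!duplicated(dat$subject_id)])
  if (any(class_n[c("good", "poor")] < 2) || length(class_n) < 2) {
    warn(paste0(
      "Fewer than 2 subjects in a recovery class (good = ",
      class_n[["good"]], ", poor = ", class_n[["poor"]],
      "); group comparison is undefined."
    ))
    out <- dat %>%
      distinct(.data$band, .data$network) %>%
      mutate(
        n_good = class_n[["good"]], n_poor = class_n[["poor"]],
        t = NA_real_, p_perm = NA_real_, n_assignments = NA_real_,
        p_fdr = NA_real_, hedges_g = NA_real_, discriminative = FALSE
      )
    return(out)
  }
  out <- dat %>%
    group_by(.data$band, .data$network) %>%
    summarise(
      n_good = sum(.data$recovery == "good"),
      n_poor = sum(.data$recovery == "poor"),
      res = list(exact_permutation_ttest(
        .data$value[.data$recovery == "good"],
        .data$value[.data$recovery == "poor"]
      )),
      hedges_g = hedges_g(
        .data$value[.data$recovery == "good"],
        .data$value[.data$recovery == "poor"]
      ),
      .groups = "drop"
    ) %>%
    tidyr::unnest("res") %>%
    rename(p_perm = "p_value") %>%
    mutate(p_fdr = bh_fdr(.data$p_perm))
  out$discriminative <- if (use_fdr) out$p_fdr < alpha else out$p_perm < alpha
  out
}

#' Pair-level correlation screen against intervention gains
#'
#' Spearman correlation between each band x electrode-pair coherence and an
#' intervention gain, validated by the seeded permutation null.
#'
#' @param pair_values Canonical-frame profile tibble (`subject_id`, `band`,
#'   `pair`, `electrode_a`, `electrode_b`, `coherence`).
#' @param outcomes Tibble with `subject_id` and the gain column named by
#'   `outcome`.
#' @param outcome Which gain to screen against: `"delta_post"` (default) or
#'   `"delta_6m"`.
#' @param n_perm,seed Passed to [permutation_corr_test()]; the seed is
#'   advanced deterministically per pair so screens are reproducible.
#' @param alpha Significance level for the `significant` flag (default 0.05,
#'   on the permutation p).
#' @return Tibble: `band`, `electrode_a`, `electrode_b`, `pair`, `outcome`,
#'   `rho`, `p_perm`, `n_perm`, `seed`, `significant`.
#' @export
correlation_screen <- function(pair_values, outcomes,
                               outcome = c("delta_post", "delta_6m"),
                               n_perm = 5000, seed = 20210925, alpha = 0.05) {
  outcome <- match.arg(outcome)
  if (!outcome %in% names(outcomes)) {
    abort(paste0("`outcomes` has no column `", outcome, "`."))
  }
  dat <- left_join(pair_values,
                   outcomes %>% select("subject_id", all_of(outcome)),
                   by = "subject_id")
  if (anyNA(dat[[outcome]])) {
    abort("Some subjects in `pair_values` have no outcome value.")
  }
  grid <- dat %>% distinct(.data$band, .data$pair) %>%
    arrange(.data$band, .data$pair)
  res <- purrr::pmap(
    list(grid$band, grid$pair, seq_len(nrow(grid))),
    function(b, p, i) {
      sub <- dat %>% filter(.data$band == b, .data$pair == p)
      permutation_corr_test(sub$coherence, sub[[outcome]],
                            n_perm = n_perm, seed = seed + i) %>%
        rename(p_perm = "p_value") %>%
        mutate(
          band = b, pair = p,
          electrode_a = sub$electrode_a[1], electrode_b = sub$electrode_b[1],
          outcome = outcome, .before = 1
        )
    }
  ) %>% bind_rows()
  res %>% mutate(significant = .data$p_perm < alpha)
}

#' Select PLS predictors from the two screening stages
#'
#' A band x pair coherence qualifies as a PLS predictor when (i) its pair
#' passed the correlation screen against the post-training gain and (ii) the
#' pair belongs to a network whose band x network comparison discriminated
#' good from poor recovery.  Output order is deterministic: band order delta
#' < theta < alpha < beta, then pair label (lexicographic).
#'
#' @param discriminative Tibble with `band`, `network` -- the discriminative
#'   combinations (e.g. `group_comparison_report()` rows with
#'   `discriminative == TRUE`, or [reported_discriminative_networks()]).
#' @param screened Tibble with `band` and `pair` (or
#'   `electrode_a`/`electrode_b`) -- the significant pairs of the
#'   `delta_post` correlation screen.
#' @param networks Network membership (canonical frame), see
#'   [network_pairs()].
#' @return Tibble with `band`, `pair`, `electrode_a`, `electrode_b`,
#'   `network`, ordered as above.  Zero rows (with a warning) when the
#'   intersection is empty.
#' @export
#' @examples
#' sel <- select_pls_inputs(reported_discriminative_networks(),
#'                          reported_significant_pairs())
#' nrow(sel) # 20
select_pls_inputs <- function(discriminative, screened,
                              networks = network_pairs()) {
  if (!"pair" %in% names(screened)) {
    screened <- screened %>%
      mutate(pair = pair_label(.data$electrode_a, .data$electrode_b))
  }
  member <- networks %>% select("network", "pair", "electrode_a",
                                "electrode_b")
  flagged <- discriminative %>%
    mutate(band = band_factor(as.character(.data$band)),
           network = as.character(.data$network)) %>%
    select("band", "network") %>%
    left_join(member %>% mutate(network = as.character(.data$network)),
              by = "network", relationship = "many-to-many")
  out <- screened %>%
    mutate(band = band_factor(as.character(.data$band))) %>%
    select("band", "pair") %>%
    dplyr::inner_join(flagged, by = c("band", "pair")) %>%
    distinct(.data$band, .data$pair, .keep_all = TRUE) %>%
    arrange(.data$band, .data$pair)
  if (nrow(out) == 0) {
    warn("No predictors survive both screens; the PLS stage has no inputs.")
  }
  out %>% select("band", "pair", "electrode_a", "electrode_b", "network")
}
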