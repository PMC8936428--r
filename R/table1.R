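# Packaged clinical fixture (the published 22-participant cohort) and the
# published biomarker-screening results used as inputs to predictor
# selection.

.TABLE1_MD5 <- "c4dda12b4f746c0eab1e8af90a480b12"

#' Published clinical table of the 22 retained participants
#'
#' Demographics and FMA-UE scores for the two intervention arms: 12
#' participants who received neural-guided action-observation robot-hand
#' training (`NG-AO`) and 10 who received text-instructed training
#' (`nNG-text`).  Two recruited participants excluded by Tukey-fence
#' screening are not part of the table.  `fma_t6m` is `NA` for the two
#' participants whose 6-month follow-up is missing (S2, S11; see
#' [locf_impute()]); `reported_recovery` carries the published good/poor
#' labels for cross-checking against [classify_recovery()].
#'
#' @return Tibble with one row per participant: `subject_id`, `group`,
#'   `gender`, `age`, `stroke_type`, `lesion_side`, `tss_years`, `fma_t0`,
#'   `fma_tpost`, `fma_t6m`, `reported_recovery`, `training_intensity`.
#' @export
#' @examples
#' dplyr::count(fma_table1(), group)
fma_table1 <- function() {
  path <- system.file("extdata", "table1_clinical.csv",
                      package = "strokecoh", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .TABLE1_MD5)) {
    warn("Packaged clinical fixture does not match its recorded checksum.")
  }
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    fma_t0 = "i", fma_tpost = "i", fma_t6m = "i",
                    age = "i", training_intensity = "i",
                    tss_years = "d", .default = "c"
                  ))
}

#' Published discriminative band-network combinations
#'
#' The band x network combinations whose good-vs-poor permutation t-test was
#' significant in the NG-AO arm: interhemispheric delta, theta and alpha, and
#' contralesional-local beta.  Intended as one of the two inputs to
#' [select_pls_inputs()].
#'
#' @return Tibble with columns `band`, `network`.
#' @export
reported_discriminative_networks <- function() {
  tibble(
    band = band_factor(c("delta", "theta", "alpha", "beta")),
    network = c("InterHemi", "InterHemi", "InterHemi", "ContraLHemi")
  )
}

#' Published pair-level correlation-screen hits
#'
#' Electrode pairs whose pre-training coherence correlated significantly with
#' the post-training intervention gain in the NG-AO arm, per band (canonical
#' lesion frame, ipsilesional = right).  Nine interhemispheric delta pairs;
#' five interhemispheric plus one contralesional theta pair; three
#' interhemispheric plus three contralesional alpha pairs; three
#' contralesional beta pairs; one ipsilesional-SMA delta pair.
#'
#' @return Tibble with `band`, `electrode_a`, `electrode_b`, `pair`,
#'   `outcome` (all `"delta_post"`).
#' @export
reported_significant_pairs <- function() {
  spec <- list(
    delta = list(
      c("C3", "C4"), c("C3", "FC4"), c("C3", "CP4"), c("C4", "FC3"),
      c("C4", "CP3"), c("FC3", "FC4"), c("FC3", "CP4"), c("FC4", "CP3"),
      c("CP3", "CP4"), c("C4", "Cz")
    ),
    theta = list(
      c("C3", "C4"), c("C3", "CP4"), c("C4", "CP3"), c("FC4", "CP3"),
      c("CP3", "CP4"), c("C3", "CP3")
    ),
    alpha = list(
      c("C3", "CP4"), c("C4", "CP3"), c("CP3", "CP4"),
      c("C3", "FC3"), c("C3", "CP3"), c("FC3", "CP3")
    ),
    beta = list(
      c("C3", "FC3"), c("C3", "CP3"), c("FC3", "CP3")
    )
  )
  purrr::imap(spec, function(pairs, band) {
    tibble(
      band = band_factor(band),
      electrode_a = purrr::map_chr(pairs, 1),
      electrode_b = purrr::map_chr(pairs, 2)
    )
  }) %>%
    bind_rows() %>%
    mutate(
      pair = pair_label(.data$electrode_a, .data$electrode_b),
      outcome = "delta_post"
    )
}
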