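# Pipeline orchestration: a config object with the study defaults, and the
# simulate / coherence / stats / predict stages wired together with
# machine-readable reports.

#' Pipeline configuration
#'
#' Assembles every tunable of the pipeline with its study default:
#' band definitions, Welch parameters (2 s hann segments, 50% overlap,
#' linear detrend), the canonical lesion convention (ipsilesional = right),
#' preprocessing edges (2-60 Hz band-pass, 48-52 Hz notch), MCID 4,
#' 5000-shuffle correlation null, FDR over the band x network family, VIP
#' threshold 1.0, 90% variance rule, and the published leave-one-out
#' protocol (`cv = "paper"`).  Overrides are supplied as named arguments or
#' loaded from a YAML file; the full config (plus a hash) is echoed into
#' every report.
#'
#' @param ... Named overrides of the defaults.
#' @param yaml_file Optional YAML file of overrides (applied before `...`).
#' @return Named list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(n_perm = 1000)
#' cfg$n_perm
pipeline_config <- function(..., yaml_file = NULL) {
  cfg <- list(
    bands = coh_bands(),
    seg_sec = 2, overlap = 0.5, window = "hann", detrend = "linear",
    bandpass = c(2, 60), notch = c(48, 52),
    ipsi_side = "right",
    mcid = 4, mcid_rule = "gte",
    n_perm = 5000, seed = 20210925,
    fdr_alpha = 0.05,
    vip_threshold = 1.0, variance_threshold = 0.90,
    cv = "paper",
    duration = 180, fs = 256
  )
  if (!is.null(yaml_file)) {
    over <- yaml::read_yaml(yaml_file)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  if (length(dots) > 0) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown) > 0) {
      abort(paste0("Unknown config field(s): ",
                   paste(unknown, collapse = ", ")))
    }
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

.config_echo <- function(config) {
  plain <- lapply(unclass(config), function(v) {
    if (is.data.frame(v)) as.data.frame(lapply(v, as.character)) else v
  })
  list(
    config = plain,
    config_hash = rlang::hash(plain),
    package_version = as.character(utils::packageVersion("strokecoh"))
  )
}

.write_report <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Simulate a synthetic study to disk
#'
#' Writes a reproducible synthetic two-arm study ([generate_study()]): one
#' EEG CSV + YAML sidecar per subject, the clinical table, and the ground
#' truth (subject gammas and the outcome model) as JSON.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param seed Seed forwarded to the generator (default: the config seed).
#' @param n_ngao,n_nng Arm sizes.
#' @return Invisibly, the study list from [generate_study()].
#' @export
pipeline_simulate <- function(config = pipeline_config(), out_dir,
                              seed = config$seed, n_ngao = 12, n_nng = 10) {
  study <- generate_study(
    n_ngao = n_ngao, n_nng = n_nng,
    duration = config$duration, fs = config$fs, seed = seed
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  purrr::walk(study$recordings, write_eeg_csv, dir = file.path(out_dir, "eeg"))
  readr::write_csv(study$clinical, file.path(out_dir, "clinical.csv"))
  truth <- c(.config_echo(config), list(seed = seed,
                                        truth = study$truth))
  .write_report(truth, file.path(out_dir, "ground_truth.json"))
  invisible(study)
}

#' Coherence stage
#'
#' Preprocesses each recording, computes the band x pair profile,
#' canonicalizes the lesion frame and aggregates the five networks; writes
#' tidy CSVs when `out_dir` is given.
#'
#' @param recordings List of [eeg_recording()] objects, or a directory
#'   containing `*_eeg.csv` + sidecars.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List with `pairs` (canonical profile tibble, all subjects) and
#'   `networks`.
#' @export
pipeline_coherence <- function(recordings, config = pipeline_config(),
                               out_dir = NULL) {
  if (is.character(recordings)) {
    files <- list.files(recordings, pattern = "_eeg\\.csv$",
                        full.names = TRUE)
    if (length(files) == 0) abort("No `*_eeg.csv` files found.")
    recordings <- purrr::map(files, read_eeg_csv)
  }
  profs <- purrr::map(recordings, function(rec) {
    rec %>%
      eeg_preprocess(bandpass = config$bandpass, notch = config$notch) %>%
      coherence_profile(bands = config$bands, seg_sec = config$seg_sec,
                        overlap = config$overlap, window = config$window,
                        detrend = config$detrend) %>%
      canonicalize_lesion(ipsi_side = config$ipsi_side)
  }) %>% bind_rows()
  nets <- network_aggregate(profs,
                            networks = network_pairs(config$ipsi_side))
  if (!is.null(out_dir)) {
    write_coherence_csv(profs, nets, file.path(out_dir, "coherence"))
  }
  list(pairs = profs, networks = nets)
}

#' Statistics stage
#'
#' Clinical outcomes (tie-corrected Friedman + signed-rank post hocs per
#' group), recovery classification, good-vs-poor network comparisons (exact
#' permutation t-test, Hedges' g, FDR) and the pair-level correlation screen
#' against the post-training gain, per group.
#'
#' @param clinical Clinical tibble (see [fma_table1()] for the layout).
#' @param coherence Output of [pipeline_coherence()] (may be `NULL` for a
#'   clinical-only report).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for CSV/JSON reports.
#' @return List: `clinical_outcomes`, `records` (labeled), per-group
#'   `group_comparisons` and `correlation_screens`.
#' @export
pipeline_stats <- function(clinical, coherence = NULL,
                           config = pipeline_config(), out_dir = NULL) {
  outcomes <- clinical_outcome_report(clinical)
  records <- clinical %>%
    locf_impute() %>%
    classify_recovery(mcid = config$mcid, rule = config$mcid_rule)
  comparisons <- NULL
  screens <- NULL
  if (!is.null(coherence)) {
    groups <- unique(records$group)
    comparisons <- purrr::map(groups, function(g) {
      ids <- records$subject_id[records$group == g]
      nets <- coherence$networks %>% filter(.data$subject_id %in% ids)
      group_comparison_report(nets, records, alpha = config$fdr_alpha) %>%
        mutate(group = g, .before = 1)
    }) %>% bind_rows()
    screens <- purrr::map(groups, function(g) {
      ids <- records$subject_id[records$group == g]
      pv <- coherence$pairs %>% filter(.data$subject_id %in% ids)
      correlation_screen(pv, records, outcome = "delta_post",
                         n_perm = config$n_perm, seed = config$seed,
                         alpha = config$fdr_alpha) %>%
        mutate(group = g, .before = 1)
    }) %>% bind_rows()
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(outcomes$friedman, file.path(out_dir, "friedman.csv"))
    readr::write_csv(outcomes$posthoc, file.path(out_dir, "posthoc.csv"))
    readr::write_csv(records, file.path(out_dir, "recovery_labels.csv"))
    if (!is.null(comparisons)) {
      readr::write_csv(comparisons,
                       file.path(out_dir, "group_comparisons.csv"))
      readr::write_csv(screens, file.path(out_dir, "correlation_screen.csv"))
    }
    .write_report(
      c(.config_echo(config), list(
        friedman = outcomes$friedman, seed = config$seed
      )),
      file.path(out_dir, "stats_report.json")
    )
  }
  list(clinical_outcomes = outcomes, records = records,
       group_comparisons = comparisons, correlation_screens = screens)
}

#' Prediction stage
#'
#' Builds the subjects x predictors feature table from the selected band x
#' pair coherences of one group (default the intervention arm) and runs
#' [pls_prognosis()]: component choice, VIP selection, leave-one-out
#' validation.
#'
#' @param stats Output of [pipeline_stats()] (needs the screens and
#'   comparisons).
#' @param coherence Output of [pipeline_coherence()].
#' @param config A [pipeline_config()].
#' @param group Which group to model (default `"NG-AO"`).
#' @param out_dir Optional output directory.
#' @return The [pls_prognosis()] object, with the predictor table attached
#'   as `features`.
#' @export
pipeline_predict <- function(stats, coherence, config = pipeline_config(),
                             group = "NG-AO", out_dir = NULL) {
  comp <- stats$group_comparisons %>%
    filter(.data$group == !!group, .data$discriminative)
  scr <- stats$correlation_screens %>%
    filter(.data$group == !!group, .data$significant)
  sel <- select_pls_inputs(comp, scr,
                           networks = network_pairs(config$ipsi_side))
  if (nrow(sel) == 0) {
    warn("Predictor selection is empty; prediction stage skipped.")
    return(NULL)
  }
  ids <- stats$records$subject_id[stats$records$group == group]
  feat <- coherence$pairs %>%
    filter(.data$subject_id %in% ids) %>%
    dplyr::inner_join(sel %>% select("band", "pair"),
                      by = c("band", "pair")) %>%
    mutate(predictor = paste(.data$band, .data$pair)) %>%
    select("subject_id", "predictor", "coherence") %>%
    tidyr::pivot_wider(names_from = "predictor",
                       values_from = "coherence") %>%
    arrange(match(.data$subject_id, ids))
  rec <- stats$records %>% filter(.data$subject_id %in% feat$subject_id)
  rec <- rec[match(feat$subject_id, rec$subject_id), ]
  prog <- pls_prognosis(
    feat %>% select(-"subject_id"), rec$delta_post, fma_t0 = rec$fma_t0,
    variance_threshold = config$variance_threshold,
    vip_threshold = config$vip_threshold, cv = config$cv
  )
  prog$features <- feat
  prog$selected_inputs <- sel
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(tidy(prog$report),
                     file.path(out_dir, "predictions.csv"))
    .write_report(
      c(.config_echo(config), list(
        seed = config$seed,
        group = group,
        n_components = prog$ncomp,
        n_predictors = nrow(sel),
        biomarkers = prog$biomarkers$predictor,
        metrics = as.list(glance(prog$report))
      )),
      file.path(out_dir, "prediction_report.json")
    )
  }
  prog
}

#' Run the whole pipeline on a study
#'
#' Coherence -> statistics -> prognosis over a list of recordings plus a
#' clinical table (or a directory produced by [pipeline_simulate()]).
#'
#' @param recordings List of recordings or a `pipeline_simulate()` output
#'   directory.
#' @param clinical Clinical tibble; when `recordings` is a directory the
#'   packaged `clinical.csv` there is used by default.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for all stage reports.
#' @param group Group to model in the prediction stage.
#' @return List with `coherence`, `stats`, `prognosis`.
#' @export
pipeline_run <- function(recordings, clinical = NULL,
                         config = pipeline_config(), out_dir = NULL,
                         group = "NG-AO") {
  if (is.character(recordings)) {
    if (is.null(clinical)) {
      clinical <- readr::read_csv(file.path(recordings, "clinical.csv"),
                                  show_col_types = FALSE)
    }
    recordings <- file.path(recordings, "eeg")
  }
  coherence <- pipeline_coherence(recordings, config,
                                  out_dir = out_dir)
  stats <- pipeline_stats(clinical, coherence, config, out_dir = out_dir)
  prognosis <- pipeline_predict(stats, coherence, config, group = group,
                                out_dir = out_dir)
  list(coherence = coherence, stats = stats, prognosis = prognosis)
}
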