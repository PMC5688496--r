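#' Validated pipeline configuration
#'
#' Collects every tunable of the simulate-normalise-test-screen pipeline
#' in one declarative object, with the study's conventions as defaults:
#' FDR level 0.05 with a 1.5 fold-change threshold for differential
#' expression, and 99% specificity for the adaptive reference ranges.
#' Unknown keys and out-of-range values are rejected up front, before any
#' stage runs.
#'
#' @param seed Integer seed driving every source of randomness.
#' @param preset Design preset name (see [make_mds_design()]).
#' @param ref_level,background,cv_dup Generator MFI scale, additive
#'   background and replicate CV (see [simulate_expression()]).
#' @param drop_rate Per-block missingness rate (default 21/364, the
#'   study's observed attrition).
#' @param floor Background-subtraction floor (MFI).
#' @param lod,min_fraction Limit-of-detection filter settings (see
#'   [lod_filter()]).
#' @param ref_probes Reference probe names.
#' @param alpha FDR significance level.
#' @param fc_threshold Fold-change threshold.
#' @param specificity Adaptive-model specificity level.
#' @param passport_mode `"sequential"` or `"batch"`.
#' @param out_dir Output directory.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, preset = "MDS",
                            ref_level = 5000, background = 30,
                            cv_dup = 0.133, drop_rate = 21 / 364,
                            floor = 0.5, lod = 50, min_fraction = 0.8,
                            ref_probes = reference_probes(),
                            alpha = 0.05, fc_threshold = 1.5,
                            specificity = 0.99,
                            passport_mode = "sequential",
                            out_dir = tempfile("txpassport_run_")) {
  cfg <- list(seed = as.integer(seed), preset = preset,
              ref_level = ref_level, background = background,
              cv_dup = cv_dup, drop_rate = drop_rate, floor = floor,
              lod = lod, min_fraction = min_fraction,
              ref_probes = ref_probes, alpha = alpha,
              fc_threshold = fc_threshold, specificity = specificity,
              passport_mode = passport_mode, out_dir = out_dir)
  .assert_prob(cfg$alpha, "alpha")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$fc_threshold < 1) stop("`fc_threshold` must be >= 1", call. = FALSE)
  if (cfg$specificity <= 0.5 || cfg$specificity >= 1) {
    stop("`specificity` must lie in (0.5, 1)", call. = FALSE)
  }
  .assert_prob(cfg$drop_rate, "drop_rate")
  if (!cfg$passport_mode %in% c("sequential", "batch")) {
    stop("`passport_mode` must be 'sequential' or 'batch'", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Extract per-subject longitudinal profiles from an expression matrix
#'
#' @param em An `expr_matrix`.
#' @param marker Marker row to extract.
#' @param arm Arm whose samples to take.
#' @return Named list mapping subject to day-ordered numeric profile.
#' @export
marker_profiles <- function(em, marker, arm) {
  meta <- em$sample_meta
  idx <- which(meta$arm == arm)
  idx <- idx[order(meta$day[idx])]
  v <- em$values[marker, idx]
  split(unname(v), meta$subject[idx])
}

#' Run the full synthetic-study pipeline
#'
#' Executes the whole analysis end to end: simulate the crossover panel
#' and haematology data, apply sample attrition, normalise to the
#' reference-gene geometric mean, filter markers below the limit of
#' detection, run the moderated differential-expression analysis with the
#' staged selection cascade, screen every analysable marker (plus HGB and
#' OFF-score) through the adaptive passport model with leave-one-out
#' cross-validation, and write all result documents to
#' `config$out_dir`. Per-stage record counts are logged via `message()`.
#' Everything is deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results: `design`,
#'   `panel`, `haematology`, `em` (LOD-filtered expression matrix),
#'   `dropped_markers`, `de` (list of `de_tests`), `cascade`,
#'   `passport` (summary data frame), `files` (paths written).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- make_mds_design(config$preset)
  msg <- function(stage, ...) message(sprintf("[%s] %s", stage,
                                              sprintf(...)))

  params <- default_gene_params(design)
  panel <- simulate_expression(design, params, ref_level = config$ref_level,
                               background = config$background,
                               cv_dup = config$cv_dup, seed = config$seed)
  scheduled <- length(unique(paste(panel$subject, panel$arm, panel$timepoint)))
  panel <- apply_missingness(panel, config$drop_rate, seed = config$seed + 1L)
  retained <- length(unique(paste(panel$subject, panel$arm, panel$timepoint)))
  msg("simulate", "%d of %d scheduled sample blocks retained (%d records)",
      retained, scheduled, nrow(panel))
  haem <- simulate_haematology(design, seed = config$seed + 2L)

  em <- normalise_panel(panel, ref_probes = config$ref_probes,
                        background = config$background, floor = config$floor)
  lf <- lod_filter(em, lod = config$lod, min_fraction = config$min_fraction)
  em <- lf$kept
  msg("normalise", "%d markers kept, %d below LOD (%s); mean assay CV %.1f%%",
      nrow(em$values), length(lf$dropped),
      paste(lf$dropped, collapse = ", "), assay_cv(panel))

  de <- de_analysis(em, design, alpha = config$alpha,
                    fc_threshold = config$fc_threshold)
  cascade <- selection_cascade(de[[design$arms[1]]], alpha = config$alpha,
                               fc_threshold = config$fc_threshold)
  msg("de", "selection cascade: S1=%d S2=%d S3=%d S4=%d markers",
      length(cascade$S1), length(cascade$S2), length(cascade$S3),
      length(cascade$S4))

  treated <- design$arms[1]
  placebo <- design$arms[2]
  tx_results <- lapply(rownames(em$values), function(m) {
    loo_screen(marker_profiles(em, m, placebo),
               marker_profiles(em, m, treated),
               specificity_level = config$specificity,
               mode = config$passport_mode)
  })
  names(tx_results) <- rownames(em$values)
  haem_profiles <- function(marker, arm) {
    sub <- haem[haem$arm == arm, ]
    sub <- sub[order(sub$day), ]
    split(sub[[marker]], sub$subject)
  }
  haem_results <- lapply(c(HGB = "HGB", OFF = "OFF"), function(m) {
    loo_screen(haem_profiles(m, placebo), haem_profiles(m, treated),
               specificity_level = config$specificity,
               mode = config$passport_mode)
  })
  passport <- rbind(
    passport_summary_table(haem_results, kind = "haematology"),
    passport_summary_table(tx_results, kind = "transcript")
  )
  msg("passport", "%d markers screened; median sensitivity %.0f%%",
      nrow(passport), median(passport$sensitivity))

  files <- c(
    panel = write_panel_table(panel, file.path(config$out_dir,
                                               "panel_raw.tsv")),
    haematology = write_haematology_table(haem,
                                          file.path(config$out_dir,
                                                    "haematology.csv"))
  )
  files <- c(files,
             setNames(write_expression_matrix(
               em, file.path(config$out_dir, "expression_matrix.tsv")),
               c("expression", "sample_meta")))
  files <- c(files, build_results_tables(de, passport, config$out_dir))
  cascade_df <- data.frame(
    stage = rep(names(cascade), lengths(cascade)),
    marker = unlist(cascade, use.names = FALSE), stringsAsFactors = FALSE)
  p <- file.path(config$out_dir, "selection_cascade.tsv")
  write.table(cascade_df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  files["cascade"] <- p
  msg("report", "wrote %d documents to %s", length(files), config$out_dir)

  invisible(list(design = design, panel = panel, haematology = haem,
                 em = em, dropped_markers = lf$dropped, de = de,
                 cascade = cascade, passport = passport, files = files))
}
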