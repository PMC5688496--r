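#' Published adaptive-model summary of the microdose cohort
#'
#' Loads the packaged transcription of the original microdose trial's
#' adaptive-model results: cohort mean, within- and between-subject
#' variance, sensitivity (%), specificity (%) and ROC area for
#' haemoglobin, the OFF-score and the 41 analysable transcripts (43 rows).
#' The file ships with a recorded checksum; a mismatch (a corrupted or
#' edited fixture) is an error, so aggregate results computed from it are
#' reproducible.
#'
#' @return Data frame with columns `marker`, `kind` (`"haematology"` or
#'   `"transcript"`), `mean`, `sigma2_within`, `sigma2_between`,
#'   `sensitivity`, `specificity`, `roc_area`.
#' @export
load_adaptive_summary <- function() {
  path <- .extdata("adaptive_model_summary.tsv")
  md5 <- unname(tools::md5sum(path))
  expected <- "91bfac7681739641c6ca27e37b5bad55"
  if (!identical(md5, expected)) {
    stop("adaptive_model_summary.tsv failed its checksum; ",
         "the packaged fixture is corrupted", call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 43L, sum(df$kind == "transcript") == 41L)
  df
}

#' Mean variance components across the transcript panel
#'
#' Arithmetic means of the within- and between-subject variance columns
#' over the transcript rows of an adaptive-model summary, rounded to two
#' decimals for reporting. In the microdose cohort the between-subject
#' component dominates (0.21 vs 0.13), which is what makes individualised
#' reference ranges worthwhile.
#'
#' @param summary Data frame as returned by [load_adaptive_summary()].
#' @return Named numeric vector `c(within = ..., between = ...)`.
#' @export
mean_variances <- function(summary) {
  if (!all(c("kind", "sigma2_within", "sigma2_between") %in% names(summary))) {
    stop("`summary` must carry kind and variance columns", call. = FALSE)
  }
  tx <- summary[summary$kind == "transcript", ]
  if (nrow(tx) == 0L) stop("no transcript rows in `summary`", call. = FALSE)
  c(within = round(mean(tx$sigma2_within), 2),
    between = round(mean(tx$sigma2_between), 2))
}

#' Transcripts exceeding sensitivity and specificity thresholds
#'
#' @param summary Data frame as returned by [load_adaptive_summary()].
#' @param sens_min Minimum sensitivity in percent.
#' @param spec_min Minimum specificity in percent.
#' @return Character vector of transcript names, in the summary's order.
#' @examples
#' \dontrun{
#' filter_high_performers(load_adaptive_summary(), 93, 71)  # 15 markers
#' }
#' @export
filter_high_performers <- function(summary, sens_min = 93, spec_min = 71) {
  .assert_scalar_number(sens_min, "sens_min")
  .assert_scalar_number(spec_min, "spec_min")
  if (sens_min < 0 || sens_min > 101 || spec_min < 0 || spec_min > 101) {
    stop("thresholds must be percentages", call. = FALSE)
  }
  tx <- summary[summary$kind == "transcript", ]
  tx$marker[tx$sensitivity >= sens_min & tx$specificity >= spec_min]
}

#' Wide differential-expression results table
#'
#' Reshapes a `de_tests` object into the publication layout: one row per
#' marker with per-timepoint log2 fold-change, signed fold-change,
#' uncorrected p and FDR columns.
#'
#' @param tests A `de_tests` from [moderated_tests()].
#' @param contrasts Which contrast labels to include (default: all
#'   fitted).
#' @return Data frame with columns `marker`, then `log2FC.<tp>`,
#'   `FC.<tp>`, `p.<tp>`, `FDR.<tp>` blocks.
#' @export
de_results_table <- function(tests, contrasts = NULL) {
  ct <- tests$contrasts
  if (is.null(contrasts)) contrasts <- unique(ct$contrast)
  ct <- ct[ct$contrast %in% contrasts, ]
  markers <- unique(ct$marker)
  grab <- function(col) {
    m <- vapply(contrasts, function(tp) {
      sub <- ct[ct$contrast == tp, ]
      sub[[col]][match(markers, sub$marker)]
    }, numeric(length(markers)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(markers))
    m
  }
  out <- data.frame(marker = markers, stringsAsFactors = FALSE)
  for (col in c("log2fc", "fc", "p_raw", "fdr")) {
    block <- grab(col)
    colnames(block) <- paste(switch(col, log2fc = "log2FC", fc = "FC",
                                    p_raw = "p", fdr = "FDR"),
                             contrasts, sep = ".")
    out <- cbind(out, round(block, if (col %in% c("log2fc", "fc")) 2 else 5))
  }
  out
}

#' Adaptive-model summary table from screening results
#'
#' Assembles the publication-layout summary (marker, mean, variance
#' components, sensitivity %, specificity %, ROC area) from per-marker
#' [loo_screen()] results, rounding as the convention dictates: variances
#' to 3 decimals, sensitivity/specificity to the nearest integer, ROC area
#' to 2 decimals.
#'
#' @param results Named list of `detection_result` objects, keyed by
#'   marker.
#' @param kind Character scalar or vector labelling each row
#'   (`"transcript"` / `"haematology"`).
#' @return Data frame in the same layout as [load_adaptive_summary()].
#' @export
passport_summary_table <- function(results, kind = "transcript") {
  rows <- lapply(names(results), function(m) {
    r <- results[[m]]
    data.frame(marker = m,
               mean = round(r$components$mu, 2),
               sigma2_within = round(r$components$sigma2_within, 3),
               sigma2_between = round(r$components$sigma2_between, 3),
               sensitivity = round(r$sensitivity),
               specificity = round(r$specificity),
               roc_area = round(r$roc_area, 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(out[1], kind = rep_len(kind, nrow(out)), out[-1])
  rownames(out) <- NULL
  out
}

#' Write the pipeline's result documents
#'
#' Emits the differential-expression tables (treated arm and
#' arm-difference) and the adaptive-model summary as TSV files.
#'
#' @param de Named list of `de_tests` as returned by [de_analysis()].
#' @param passport Data frame from [passport_summary_table()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
build_results_tables <- function(de, passport, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  treated <- names(de)[1]
  t1 <- de_results_table(de[[treated]])
  p <- file.path(dir, "de_treated_arm.tsv")
  write.table(t1, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["de_treated"] <- p
  if ("difference" %in% names(de)) {
    t2 <- de_results_table(de[["difference"]], contrasts = paste0("P", 1:3))
    p <- file.path(dir, "de_arm_difference.tsv")
    write.table(t2, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["de_difference"] <- p
  }
  if (!all(c("marker", "sensitivity", "specificity") %in% names(passport))) {
    stop("`passport` is missing required columns", call. = FALSE)
  }
  p <- file.path(dir, "adaptive_model_summary.tsv")
  write.table(passport, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["adaptive_summary"] <- p
  invisible(paths)
}
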