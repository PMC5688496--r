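#' OFF-score haematological stimulation index
#'
#' The Athlete Biological Passport's OFF-hr score,
#' `OFF = HGB - 60 * sqrt(RET%)` with haemoglobin in g/L and reticulocytes
#' in percent. High values indicate erythropoiesis suppressed after
#' withdrawal of stimulation (high haemoglobin with few young cells), the
#' signature of recent blood doping.
#'
#' @param hgb Haemoglobin in g/L, positive.
#' @param ret Reticulocyte percentage, non-negative.
#' @return OFF-score in score units; vectorised.
#' @examples
#' off_score(150, 1)  # 90
#' @export
off_score <- function(hgb, ret) {
  if (!is.numeric(hgb) || any(!is.finite(hgb)) || any(hgb <= 0)) {
    stop("`hgb` must be positive (g/L)", call. = FALSE)
  }
  if (!is.numeric(ret) || any(!is.finite(ret)) || any(ret < 0)) {
    stop("`ret` must be non-negative (%)", call. = FALSE)
  }
  hgb - 60 * sqrt(ret)
}

#' Holm step-down multiple-testing adjustment
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Holm-adjusted p-values, order-preserving with the input.
#' @examples
#' holm_adjust(c(0.01, 0.04))  # 0.02, 0.04
#' @export
holm_adjust <- function(p_values) {
  .assert_pvalues(p_values)
  p.adjust(p_values, method = "holm")
}

#' Paired within-subject timepoint comparisons of a blood marker
#'
#' For each non-baseline timepoint, tests whether subjects' values differ
#' from their own baseline mean: a two-sided paired t test of
#' `value - subject baseline mean` against zero, with Holm adjustment
#' across timepoints. This within-subject design with family-wise error
#' control is the package's substitute for a full mixed-model fit; it
#' preserves the subject-as-random-block structure and the stated
#' multiplicity correction.
#'
#' @param records Haematology data frame from [simulate_haematology()] (or
#'   the same layout read from file), containing `subject`, `arm`,
#'   `timepoint` and the marker column.
#' @param marker Column to test: `"HGB"`, `"HCT"`, `"RET"` or `"OFF"`.
#' @param design The `study_design` defining baseline labels.
#' @param arm Which arm's records to test (default: the treated arm).
#' @param alpha Family-wise significance level for the flags.
#' @param baseline_mode `"averaged"` or `"single"`, as in
#'   [fit_contrasts()].
#' @return Data frame with one row per non-baseline timepoint: `timepoint`,
#'   `estimate` (mean paired difference), `p_raw`, `p_holm`,
#'   `significant`.
#' @export
paired_timepoint_tests <- function(records, marker, design,
                                   arm = design$arms[1], alpha = 0.05,
                                   baseline_mode = c("averaged", "single")) {
  baseline_mode <- match.arg(baseline_mode)
  if (!marker %in% names(records)) {
    stop("marker column not found: ", marker, call. = FALSE)
  }
  blabs <- baseline_labels(design)
  if (baseline_mode == "single") blabs <- blabs[length(blabs)]
  rec <- records[records$arm == arm, ]
  base <- tapply(rec[[marker]][rec$timepoint %in% blabs],
                 rec$subject[rec$timepoint %in% blabs], mean)
  contrasts <- setdiff(design$timepoints$label, baseline_labels(design))
  rows <- lapply(contrasts, function(tp) {
    sub <- rec[rec$timepoint == tp, ]
    sub <- sub[sub$subject %in% names(base), ]
    if (nrow(sub) < 2L) {
      return(data.frame(timepoint = tp, estimate = NA_real_,
                        p_raw = NA_real_, stringsAsFactors = FALSE))
    }
    d <- sub[[marker]] - base[sub$subject]
    if (stats::sd(d) == 0) {
      # constant differences: no evidence against zero unless shifted
      p <- if (all(d == 0)) 1 else 0
      return(data.frame(timepoint = tp, estimate = mean(d), p_raw = p,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(d)
    data.frame(timepoint = tp, estimate = mean(d), p_raw = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_raw)
  out$p_holm <- NA_real_
  out$p_holm[ok] <- holm_adjust(out$p_raw[ok])
  out$significant <- !is.na(out$p_holm) & out$p_holm < alpha
  out
}
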