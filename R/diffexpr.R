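#' Within-subject longitudinal contrasts
#'
#' Fits the randomised-block contrast estimator underlying the
#' differential-expression analysis: each subject's baseline mean is
#' subtracted from their value at every non-baseline timepoint, and the
#' per-timepoint coefficient is the average of these paired differences
#' over subjects. For the crossover comparison between arms, the estimator
#' is the difference of differences: each subject's baseline-corrected
#' value in the treated arm minus the same subject's baseline-corrected
#' value in the placebo arm, averaged over subjects. Residual variance per
#' marker is pooled over timepoints around the per-timepoint means.
#'
#' @param em An `expr_matrix` from [normalise_panel()].
#' @param design The `study_design` the samples follow.
#' @param baseline_mode `"averaged"` (mean of all baseline visits, the
#'   default) or `"single"` (the final pre-treatment visit only).
#' @return An object of class `de_fit`: list with `tables`, a named list
#'   (one per arm plus `"difference"`), each holding `coef` (markers x
#'   contrasts matrix of log2 fold-changes), `n` (subjects per contrast),
#'   `s2` (per-marker pooled residual variance) and `df` (residual degrees
#'   of freedom); plus `contrast_labels` and `baseline_mode`.
#' @export
fit_contrasts <- function(em, design, baseline_mode = c("averaged", "single")) {
  baseline_mode <- match.arg(baseline_mode)
  validate_design(design)
  meta <- em$sample_meta
  blabs <- baseline_labels(design)
  if (baseline_mode == "single") blabs <- blabs[length(blabs)]
  contrasts <- setdiff(design$timepoints$label, baseline_labels(design))

  per_arm <- lapply(design$arms, function(arm) {
    idx <- which(meta$arm == arm)
    if (!length(idx)) stop("no samples for arm ", arm, call. = FALSE)
    m <- meta[idx, ]
    v <- em$values[, idx, drop = FALSE]
    subjects <- unique(m$subject)
    no_base <- subjects[vapply(subjects, function(s) {
      !any(m$subject == s & m$timepoint %in% blabs)
    }, logical(1))]
    if (length(no_base)) {
      stop("subject(s) without a baseline sample in arm ", arm, ": ",
           paste(no_base, collapse = ", "), call. = FALSE)
    }
    base <- vapply(subjects, function(s) {
      rowMeans(v[, m$subject == s & m$timepoint %in% blabs, drop = FALSE])
    }, numeric(nrow(v)))
    if (is.null(dim(base))) base <- matrix(base, nrow = 1)
    colnames(base) <- subjects
    # markers x subjects matrix of baseline-corrected values per contrast
    d <- lapply(contrasts, function(tp) {
      sub <- m$subject[m$timepoint == tp]
      if (!length(sub)) return(NULL)
      dd <- v[, m$timepoint == tp, drop = FALSE] - base[, sub, drop = FALSE]
      colnames(dd) <- sub
      dd
    })
    names(d) <- contrasts
    d
  })
  names(per_arm) <- design$arms

  summarise <- function(dlist) {
    present <- !vapply(dlist, is.null, logical(1))
    coef <- vapply(dlist[present], rowMeans, numeric(nrow(em$values)))
    if (is.null(dim(coef))) coef <- matrix(coef, nrow = 1,
                                           dimnames = list(rownames(em$values),
                                                           names(dlist)[present]))
    n <- vapply(dlist[present], ncol, integer(1))
    ss <- rep(0, nrow(em$values))
    df <- 0L
    for (j in which(present)) {
      dev <- dlist[[j]] - rowMeans(dlist[[j]])
      ss <- ss + rowSums(dev^2)
      df <- df + ncol(dlist[[j]]) - 1L
    }
    if (df < 1L) stop("no residual degrees of freedom; need >= 2 subjects",
                      call. = FALSE)
    list(coef = coef, n = n, s2 = ss / df, df = df)
  }

  tables <- lapply(per_arm, summarise)
  if (length(design$arms) >= 2L) {
    a1 <- per_arm[[design$arms[1]]]
    a2 <- per_arm[[design$arms[2]]]
    dd <- lapply(contrasts, function(tp) {
      d1 <- a1[[tp]]; d2 <- a2[[tp]]
      if (is.null(d1) || is.null(d2)) return(NULL)
      common <- intersect(colnames(d1), colnames(d2))
      if (length(common) < 2L) return(NULL)
      d1[, common, drop = FALSE] - d2[, common, drop = FALSE]
    })
    names(dd) <- contrasts
    tables$difference <- summarise(dd)
  }
  structure(list(tables = tables, contrast_labels = contrasts,
                 baseline_mode = baseline_mode,
                 markers = rownames(em$values)),
            class = "de_fit")
}

# Newton solve of trigamma(x) == y, vectorised (method-of-moments helper)
.trigamma_inverse <- function(y) {
  out <- y
  hi <- y > 1e7
  lo <- y < 1e-6
  out[hi] <- 1 / sqrt(y[hi])
  out[lo] <- 1 / y[lo]
  mid <- !(hi | lo)
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(-dif / x) < 1e-8) break
    }
    out[mid] <- x
  }
  out
}

#' Empirical-Bayes moderation of per-marker variances
#'
#' Shrinks each marker's residual variance towards a common prior by
#' fitting a scaled inverse-chi-square prior with `d0` degrees of freedom
#' and scale `s0_sq` to the observed sample variances, using the method of
#' moments on log variances (matching the distribution of log scaled-F
#' deviates). The posterior (moderated) variance is the precision-weighted
#' compromise `(d0 * s0_sq + df * s2) / (d0 + df)`. With `d0 = Inf` all
#' markers share `s0_sq`; with `d0 = 0` no moderation occurs.
#'
#' @param sample_variances Per-marker residual variances (>= 2 markers).
#' @param df Residual degrees of freedom (scalar, or one per marker).
#' @param d0 Optional forced prior degrees of freedom; `NULL` (default)
#'   estimates it from the data.
#' @return An object of class `moderation_state`: list with `d0`, `s0_sq`,
#'   `var_post` (per-marker moderated variance) and `df_total`
#'   (`df + d0`, the moderated test's degrees of freedom).
#' @export
moderate_variances <- function(sample_variances, df, d0 = NULL) {
  s2 <- sample_variances
  if (length(s2) < 2L) stop("need >= 2 markers to moderate", call. = FALSE)
  if (any(!is.finite(s2)) || any(s2 < 0)) {
    stop("sample variances must be finite and non-negative", call. = FALSE)
  }
  if (all(s2 == 0)) stop("all sample variances are zero (degenerate)",
                         call. = FALSE)
  if (any(df < 1)) stop("`df` must be >= 1", call. = FALSE)
  df <- rep_len(df, length(s2))
  if (any(s2 == 0)) {
    warning("zero sample variances floored for moderation")
    s2 <- pmax(s2, min(s2[s2 > 0]) * 1e-6)
  }
  if (!is.null(d0)) {
    if (d0 < 0) stop("`d0` must be >= 0", call. = FALSE)
    if (d0 == 0) {
      return(structure(list(d0 = 0, s0_sq = exp(mean(log(s2))),
                            var_post = s2, df_total = df),
                       class = "moderation_state"))
    }
  }
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  if (is.null(d0)) {
    evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
    if (evar > 0) {
      d0 <- 2 * .trigamma_inverse(evar)
    } else {
      d0 <- Inf
    }
  }
  # no excess dispersion: all true variances equal; use the geometric
  # mean of the sample variances so equal inputs are a fixed point
  s0_sq <- if (is.infinite(d0)) {
    exp(mean(z))
  } else {
    exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  var_post <- if (is.infinite(d0)) {
    rep(s0_sq, n)
  } else {
    (d0 * s0_sq + df * s2) / (d0 + df)
  }
  structure(list(d0 = d0, s0_sq = s0_sq, var_post = var_post,
                 df_total = df + d0),
            class = "moderation_state")
}

#' Moderated t and F tests for fitted contrasts
#'
#' Computes per-contrast moderated t statistics (coefficients scaled by the
#' moderated standard error, on `df + d0` degrees of freedom) with
#' two-sided p-values, and a per-marker overall moderated F statistic (the
#' mean of squared moderated t statistics across contrasts) testing whether
#' the marker moved at any timepoint. FDR columns are Benjamini-Hochberg
#' adjusted across markers within each contrast, and across markers for
#' the overall F.
#'
#' @param table One element of a `de_fit`'s `tables` (an arm or the
#'   arm-difference), carrying `coef`, `n`, `s2`, `df`.
#' @param state A `moderation_state` fitted on the same markers'
#'   variances.
#' @param alpha Significance level applied to the FDR (default 0.05).
#' @param fc_threshold Fold-change threshold applied to the signed
#'   fold-change magnitude (default 1.5).
#' @return List of class `de_tests`: `contrasts`, a data frame with
#'   columns `marker`, `contrast`, `log2fc`, `fc`, `p_raw`, `fdr`,
#'   `significant`; and `overall`, a data frame with `marker`, `F`,
#'   `p_raw`, `fdr`.
#' @export
moderated_tests <- function(table, state, alpha = 0.05, fc_threshold = 1.5) {
  coef <- table$coef
  if (length(state$var_post) != nrow(coef)) {
    stop("moderation state does not match the fitted marker set",
         call. = FALSE)
  }
  df_total <- rep_len(state$df_total, nrow(coef))
  se <- sqrt(state$var_post) %o% (1 / sqrt(table$n))
  tstat <- coef / se
  p <- 2 * pt(abs(tstat), df = df_total, lower.tail = FALSE)
  fdr <- apply(p, 2, bh_fdr)
  if (is.null(dim(fdr))) fdr <- matrix(fdr, nrow = nrow(p),
                                       dimnames = dimnames(p))
  long <- data.frame(
    marker = rep(rownames(coef), times = ncol(coef)),
    contrast = rep(colnames(coef), each = nrow(coef)),
    log2fc = as.vector(coef),
    fc = signed_fold_change(as.vector(coef)),
    p_raw = as.vector(p),
    fdr = as.vector(fdr),
    stringsAsFactors = FALSE
  )
  long$significant <- long$fdr < alpha & abs(long$fc) >= fc_threshold
  fstat <- rowMeans(tstat^2)
  pF <- pf(fstat, df1 = ncol(coef), df2 = df_total, lower.tail = FALSE)
  overall <- data.frame(marker = rownames(coef), F = fstat, p_raw = pF,
                        fdr = bh_fdr(pF), stringsAsFactors = FALSE)
  rownames(overall) <- NULL
  structure(list(contrasts = long, overall = overall, alpha = alpha,
                 fc_threshold = fc_threshold),
            class = "de_tests")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment, order-preserving with the input.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p_values) {
  .assert_pvalues(p_values)
  p.adjust(p_values, method = "BH")
}

#' Signed fold-change
#'
#' Renders a log2 fold-change `L` as the field's signed fold convention:
#' `2^L` for up-regulation and `-2^(-L)` for down-regulation (a halving is
#' -2, not 0.5), with `signed_fold_change(0) == 1`.
#'
#' @param log2fc Finite log2 fold-change(s).
#' @return Signed fold-change(s); `abs()` always `>= 1`.
#' @examples
#' signed_fold_change(0.94)   #  1.92
#' signed_fold_change(-1.32)  # -2.50
#' @export
signed_fold_change <- function(log2fc) {
  if (!is.numeric(log2fc) || any(!is.finite(log2fc))) {
    stop("`log2fc` must be finite", call. = FALSE)
  }
  ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
}

#' Staged marker-selection cascade
#'
#' Reproduces the four-stage selection used on the treated arm of the
#' microdose study: (S1) markers whose overall moderated F test is
#' significant at FDR < `alpha`; (S2) those of S1 whose contrast one week
#' after the last injection (P1) is significant; (S3) those of S2 whose
#' fold-change ten days after the first injection (D2) is significant and
#' exceeds `fc_threshold` in magnitude; (S4) those of S3 consistently
#' over-expressed at D2-D5 and under-expressed at P1-P3, all at FDR <
#' `alpha` with the fold threshold.
#'
#' @param tests A `de_tests` from [moderated_tests()] on the treated arm.
#' @param alpha FDR significance level (default 0.05).
#' @param fc_threshold Fold-change magnitude threshold (default 1.5).
#' @return Named list `S1`..`S4` of marker character vectors, each a
#'   subset of the previous.
#' @export
selection_cascade <- function(tests, alpha = 0.05, fc_threshold = 1.5) {
  ct <- tests$contrasts
  needed <- c(paste0("D", 2:5), paste0("P", 1:3))
  missing_ct <- setdiff(needed, unique(ct$contrast))
  if (length(missing_ct)) {
    stop("missing required contrasts: ", paste(missing_ct, collapse = ", "),
         call. = FALSE)
  }
  lfc_thr <- log2(fc_threshold)
  S1 <- tests$overall$marker[tests$overall$fdr < alpha]
  sig_at <- function(markers, tp, min_lfc = NULL, sign = 0) {
    sub <- ct[ct$contrast == tp & ct$marker %in% markers, ]
    ok <- sub$fdr < alpha
    if (!is.null(min_lfc)) {
      ok <- ok & if (sign > 0) sub$log2fc >= min_lfc
                 else if (sign < 0) sub$log2fc <= -min_lfc
                 else abs(sub$log2fc) >= min_lfc
    }
    sub$marker[ok]
  }
  S2 <- intersect(S1, sig_at(S1, "P1"))
  S3 <- intersect(S2, sig_at(S2, "D2", lfc_thr, sign = 0))
  S4 <- S3
  for (tp in paste0("D", 2:5)) {
    S4 <- intersect(S4, sig_at(S4, tp, lfc_thr, sign = +1))
  }
  for (tp in paste0("P", 1:3)) {
    S4 <- intersect(S4, sig_at(S4, tp, lfc_thr, sign = -1))
  }
  list(S1 = S1, S2 = S2, S3 = S3, S4 = S4)
}

#' One-call differential expression analysis
#'
#' Convenience wrapper chaining [fit_contrasts()], [moderate_variances()]
#' and [moderated_tests()] for each arm and the arm difference.
#'
#' @param em An `expr_matrix`.
#' @param design The `study_design`.
#' @param alpha FDR level.
#' @param fc_threshold Fold-change threshold.
#' @param baseline_mode Passed to [fit_contrasts()].
#' @return Named list of `de_tests` (one per arm plus `"difference"`).
#' @export
de_analysis <- function(em, design, alpha = 0.05, fc_threshold = 1.5,
                        baseline_mode = "averaged") {
  fit <- fit_contrasts(em, design, baseline_mode = baseline_mode)
  lapply(fit$tables, function(tab) {
    st <- moderate_variances(tab$s2, tab$df)
    moderated_tests(tab, st, alpha = alpha, fc_threshold = fc_threshold)
  })
}
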