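#' Simulate raw panel fluorescence data for a crossover trial
#'
#' Generates per-probe median fluorescence intensity (MFI) records under the
#' hierarchical model the downstream passport analysis assumes. For each
#' marker g and subject j one between-subject offset `b_gj ~ N(0,
#' sigma2_between)` is drawn (shared across both crossover arms, since the
#' same individual serves in both). Each scheduled sample's latent log2
#' expression is
#' `x = mu_g + b_gj + delta_g(timepoint) * [arm == treated] + eps`,
#' `eps ~ N(0, sigma2_within)`, and its mean fluorescence is
#' `ref_level * 2^x + background`. Technical replicates jitter that mean
#' with multiplicative log-normal noise of coefficient of variation
#' `cv_dup` (mean-one, so `cv_dup = 0` reproduces the latent value
#' exactly).
#'
#' @param design A `study_design` from [make_mds_design()].
#' @param params List of [gene_params()] (see [default_gene_params()]).
#' @param ref_level MFI scale factor: the fluorescence of a probe at log2
#'   expression 0, before background. Positive.
#' @param background Additive instrument background MFI, non-negative.
#' @param cv_dup Coefficient of variation of technical replicates,
#'   non-negative fraction (the study's panel ran at roughly 0.08-0.16).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A data frame of class `panel_samples` with columns `subject`,
#'   `arm`, `timepoint`, `day`, `probe`, `replicate`, `MFI`.
#' @examples
#' d <- make_mds_design("MDS", n_subjects = 2)
#' p <- list(gene_params("ALAS2", 3, 0.2, 0.3, effect = c(D2 = 0.86)))
#' sim <- simulate_expression(d, p, seed = 1)
#' head(sim)
#' @export
simulate_expression <- function(design, params,
                                ref_level = 5000, background = 30,
                                cv_dup = 0.133, seed) {
  validate_design(design)
  if (length(params) == 0L) stop("`params` must be non-empty", call. = FALSE)
  if (!all(vapply(params, inherits, logical(1), "gene_params"))) {
    stop("`params` must be a list of gene_params objects", call. = FALSE)
  }
  .assert_scalar_number(ref_level, "ref_level")
  .assert_scalar_number(background, "background")
  .assert_scalar_number(cv_dup, "cv_dup")
  if (ref_level <= 0) stop("`ref_level` must be positive", call. = FALSE)
  if (background < 0) stop("`background` must be non-negative", call. = FALSE)
  if (cv_dup < 0) stop("`cv_dup` must be non-negative", call. = FALSE)
  s2 <- vapply(params, function(p) c(p$sigma2_within, p$sigma2_between),
               numeric(2))
  if (any(s2 < 0)) stop("variances must be non-negative", call. = FALSE)
  baselines <- baseline_labels(design)
  for (p in params) {
    bad <- intersect(names(p$effect)[p$effect != 0], baselines)
    if (length(bad)) {
      stop(sprintf("marker %s has a non-zero effect on baseline timepoint %s",
                   p$marker_id, bad[1]), call. = FALSE)
    }
    unknown <- setdiff(names(p$effect), design$timepoints$label)
    if (length(unknown)) {
      stop(sprintf("marker %s has effects for unknown timepoints: %s",
                   p$marker_id, paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
  }

  subjects <- design_subjects(design)
  tp <- design$timepoints
  reps <- design$replicates_per_sample
  treated <- design$arms[1]
  blocks <- expand.grid(timepoint = tp$label, arm = design$arms,
                        subject = subjects, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  blocks$day <- tp$day[match(blocks$timepoint, tp$label)]
  n_blocks <- nrow(blocks)
  sdlog <- sqrt(log(1 + cv_dup^2))

  out <- withr::with_seed(seed, {
    lapply(params, function(p) {
      b <- rnorm(length(subjects), 0, sqrt(p$sigma2_between))
      names(b) <- subjects
      delta <- rep(0, n_blocks)
      if (length(p$effect)) {
        idx <- blocks$arm == treated
        delta[idx] <- ifelse(is.na(p$effect[blocks$timepoint[idx]]), 0,
                             p$effect[blocks$timepoint[idx]])
      }
      eps <- rnorm(n_blocks, 0, sqrt(p$sigma2_within))
      x <- p$mu + b[blocks$subject] + delta + eps
      mfi_mean <- ref_level * 2^x + background
      jitter <- if (cv_dup > 0) {
        exp(rnorm(n_blocks * reps, -sdlog^2 / 2, sdlog))
      } else {
        rep(1, n_blocks * reps)
      }
      data.frame(
        subject = rep(blocks$subject, each = reps),
        arm = rep(blocks$arm, each = reps),
        timepoint = rep(blocks$timepoint, each = reps),
        day = rep(blocks$day, each = reps),
        probe = p$marker_id,
        replicate = rep(seq_len(reps), times = n_blocks),
        MFI = rep(mfi_mean, each = reps) * jitter,
        stringsAsFactors = FALSE
      )
    })
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("panel_samples", "data.frame")
  res
}

#' Simulate haematology records for a crossover trial
#'
#' Draws haemoglobin (HGB, g/L), haematocrit (HCT, %) and reticulocyte
#' percentage (RET, %) per subject, arm and timepoint, plus the derived
#' OFF-score via [off_score()]. The treated arm's means follow the
#' per-timepoint trajectory multipliers in `haem_params`; the placebo arm
#' is flat at baseline in expectation. HGB and HCT receive additive
#' Gaussian between-subject and within-subject noise; RET% receives
#' log-normal noise (variance components on the log scale) so it remains
#' positive. With all variance components zero the records equal the
#' deterministic trajectory means exactly.
#'
#' @param design A `study_design`.
#' @param haem_params Parameter list as built by [default_haem_params()].
#' @param seed Integer seed.
#' @return Data frame with columns `subject`, `arm`, `timepoint`, `day`,
#'   `HGB`, `HCT`, `RET`, `OFF`.
#' @export
simulate_haematology <- function(design, haem_params = default_haem_params(design),
                                 seed) {
  validate_design(design)
  labels <- design$timepoints$label
  for (m in c("HGB", "HCT", "RET")) {
    hp <- haem_params[[m]]
    if (is.null(hp)) stop("haem_params must contain ", m, call. = FALSE)
    traj <- hp$doped_multiplier
    if (length(traj) != length(labels) ||
        !setequal(names(traj), labels)) {
      stop(sprintf("%s trajectory must be named by all %d design timepoints",
                   m, length(labels)), call. = FALSE)
    }
    if (hp$sigma2_within < 0 || hp$sigma2_between < 0) {
      stop("haematology variances must be non-negative", call. = FALSE)
    }
  }
  subjects <- design_subjects(design)
  treated <- design$arms[1]
  blocks <- expand.grid(timepoint = labels, arm = design$arms,
                        subject = subjects, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  blocks$day <- design$timepoints$day[match(blocks$timepoint, labels)]
  n <- nrow(blocks)

  res <- withr::with_seed(seed, {
    vals <- lapply(c("HGB", "HCT", "RET"), function(m) {
      hp <- haem_params[[m]]
      mult <- ifelse(blocks$arm == treated,
                     hp$doped_multiplier[blocks$timepoint], 1)
      b <- rnorm(length(subjects), 0, sqrt(hp$sigma2_between))
      names(b) <- subjects
      eps <- rnorm(n, 0, sqrt(hp$sigma2_within))
      if (m == "RET") {
        hp$baseline * mult * exp(b[blocks$subject] + eps)
      } else {
        hp$baseline * mult + b[blocks$subject] + eps
      }
    })
    names(vals) <- c("HGB", "HCT", "RET")
    vals
  })
  out <- data.frame(blocks[c("subject", "arm", "timepoint", "day")],
                    HGB = res$HGB,
                    HCT = pmin(pmax(res$HCT, 0), 100),
                    RET = res$RET,
                    stringsAsFactors = FALSE)
  out$OFF <- off_score(out$HGB, out$RET)
  rownames(out) <- NULL
  out
}

#' Remove whole sample blocks at random
#'
#' Emulates the sample attrition of a real trial: each (subject, arm,
#' timepoint) block is independently dropped with probability `drop_rate`;
#' surviving records are untouched. The microdose study collected 343 of
#' 364 scheduled samples, i.e. an attrition rate of 21/364, which is the
#' default.
#'
#' @param samples A `panel_samples` data frame.
#' @param drop_rate Per-block drop probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The filtered `panel_samples`.
#' @export
apply_missingness <- function(samples, drop_rate = 21 / 364, seed) {
  .assert_scalar_number(drop_rate, "drop_rate")
  if (drop_rate < 0 || drop_rate > 1) {
    stop("`drop_rate` must lie in [0, 1]", call. = FALSE)
  }
  key <- interaction(samples$subject, samples$arm, samples$timepoint,
                     drop = TRUE)
  blocks <- levels(key)
  keep <- withr::with_seed(seed, stats::runif(length(blocks)) >= drop_rate)
  out <- samples[keep[as.integer(key)], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("panel_samples", "data.frame")
  out
}
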