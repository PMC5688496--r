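#' Estimate within- and between-subject variance components
#'
#' One-way random-effects analysis of variance with subject as the random
#' factor, as used to parameterise the adaptive passport model from
#' placebo (undoped) data. The within-subject variance is the within-group
#' mean square; the between-subject variance is
#' `(MS_between - MS_within) / n0` with the unbalanced-design effective
#' group size `n0 = (N - sum(n_i^2)/N) / (k - 1)`. A negative
#' method-of-moments between-component is clipped to zero with a warning.
#'
#' @param values_by_subject Named list mapping subject to that subject's
#'   numeric observations (log2 expression, or a blood marker).
#' @return An object of class `marker_components`: list with `mu` (grand
#'   mean), `sigma2_within`, `sigma2_between`, `n_subjects`, `clipped`
#'   (logical: was the between-component negative before clipping).
#' @examples
#' estimate_components(list(A = c(0, 2), B = c(4, 6)))
#' # mu 3, sigma2_within 2, sigma2_between 7
#' @export
estimate_components <- function(values_by_subject) {
  values_by_subject <- values_by_subject[lengths(values_by_subject) > 0]
  k <- length(values_by_subject)
  if (k < 2L) stop("need >= 2 subjects to separate variance components",
                   call. = FALSE)
  x <- unlist(values_by_subject, use.names = FALSE)
  if (any(!is.finite(x))) stop("observations must be finite", call. = FALSE)
  ni <- lengths(values_by_subject)
  N <- sum(ni)
  if (N <= k) stop("need repeated observations within subjects", call. = FALSE)
  mu <- mean(x)
  means <- vapply(values_by_subject, mean, numeric(1))
  ssw <- sum(vapply(values_by_subject,
                    function(v) sum((v - mean(v))^2), numeric(1)))
  msw <- ssw / (N - k)
  ssb <- sum(ni * (means - mu)^2)
  msb <- ssb / (k - 1)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  s2b <- (msb - msw) / n0
  clipped <- s2b < 0
  if (clipped) {
    warning("negative between-subject variance estimate clipped to 0")
    s2b <- 0
  }
  structure(list(mu = mu, sigma2_within = msw, sigma2_between = s2b,
                 n_subjects = k, clipped = clipped),
            class = "marker_components")
}

#' Construct marker components directly
#'
#' @param mu Population mean.
#' @param sigma2_within Within-subject variance, `>= 0`.
#' @param sigma2_between Between-subject variance, `>= 0`.
#' @return A `marker_components` object.
#' @export
marker_components <- function(mu, sigma2_within, sigma2_between) {
  .assert_scalar_number(mu, "mu")
  .assert_scalar_number(sigma2_within, "sigma2_within")
  .assert_scalar_number(sigma2_between, "sigma2_between")
  if (sigma2_within < 0 || sigma2_between < 0) {
    stop("variances must be non-negative", call. = FALSE)
  }
  structure(list(mu = mu, sigma2_within = sigma2_within,
                 sigma2_between = sigma2_between, n_subjects = NA_integer_,
                 clipped = FALSE),
            class = "marker_components")
}

# posterior over the subject's own mean given n prior observations
.posterior_mean_var <- function(components, history) {
  mu <- components$mu
  s2b <- components$sigma2_between
  s2w <- components$sigma2_within
  n <- length(history)
  if (s2b == 0) return(list(m = mu, tau2 = 0))
  if (n == 0L) return(list(m = mu, tau2 = s2b))
  if (s2w == 0) {
    xbar <- mean(history)
    if (any(history != history[1])) {
      stop("degenerate model: zero within-subject variance with a ",
           "non-constant history", call. = FALSE)
    }
    return(list(m = xbar, tau2 = 0))
  }
  prec <- 1 / s2b + n / s2w
  list(m = (mu / s2b + n * mean(history) / s2w) / prec, tau2 = 1 / prec)
}

#' Adaptive individual reference limits
#'
#' The conjugate Normal-Normal update at the heart of the Athlete
#' Biological Passport: given universal variance components and a
#' subject's prior observations, the posterior over the subject's own mean
#' has mean `m_n = (mu/s2b + n*xbar/s2w) / (1/s2b + n/s2w)` and variance
#' `tau2_n = 1 / (1/s2b + n/s2w)`; the predictive reference range for the
#' next observation is `m_n +/- z * sqrt(tau2_n + s2w)` with
#' `z = qnorm(1 - (1 - specificity_level)/2)` (two-sided). With no history
#' this is the population prior predictive; as history grows the limits
#' individualise and tighten towards the subject's own mean.
#'
#' @param components A `marker_components`.
#' @param history Numeric vector of the subject's prior observations (may
#'   be empty).
#' @param specificity_level Target specificity of the range, in
#'   `(0.5, 1)`; the passport convention is 0.99.
#' @param one_sided If `TRUE`, uses the one-sided quantile
#'   `qnorm(specificity_level)` instead (off by default).
#' @return Numeric vector `c(lower, upper)`.
#' @export
predictive_limits <- function(components, history = numeric(0),
                              specificity_level = 0.99, one_sided = FALSE) {
  .assert_scalar_number(specificity_level, "specificity_level")
  if (specificity_level <= 0.5 || specificity_level >= 1) {
    stop("`specificity_level` must lie in (0.5, 1)", call. = FALSE)
  }
  if (length(history) && any(!is.finite(history))) {
    stop("history must be finite", call. = FALSE)
  }
  if (components$sigma2_within == 0 && components$sigma2_between == 0 &&
      length(history) && any(history != components$mu)) {
    stop("degenerate model: zero variances with history away from mu",
         call. = FALSE)
  }
  post <- .posterior_mean_var(components, history)
  z <- if (one_sided) qnorm(specificity_level) else {
    qnorm(1 - (1 - specificity_level) / 2)
  }
  half <- z * sqrt(post$tau2 + components$sigma2_within)
  c(lower = post$m - half, upper = post$m + half)
}

#' Sequentially evaluate one subject's longitudinal profile
#'
#' Walks the profile in time order, testing each observation against the
#' adaptive limits built from all preceding observations (the first
#' against the population prior predictive). An observation outside its
#' limits is atypical; every observation, atypical or not, enters the
#' history for subsequent steps. A subject is flagged if at least one
#' observation is atypical. A batch mode tests all observations against
#' the prior predictive without updating, for comparison.
#'
#' @param profile Ordered numeric observations (e.g. 13 weekly values).
#' @param components A `marker_components`.
#' @param specificity_level Specificity of the limits (default 0.99).
#' @param mode `"sequential"` (default) or `"batch"`.
#' @return List with `atypical` (integer indices), `flagged` (logical),
#'   and `limits` (profile-length x 2 matrix of the bounds each
#'   observation was tested against).
#' @export
evaluate_profile <- function(profile, components, specificity_level = 0.99,
                             mode = c("sequential", "batch")) {
  mode <- match.arg(mode)
  if (length(profile) == 0L) stop("profile must be non-empty", call. = FALSE)
  if (any(!is.finite(profile))) stop("profile must be finite", call. = FALSE)
  n <- length(profile)
  limits <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("lower", "upper")))
  for (t in seq_len(n)) {
    hist_t <- if (mode == "sequential") profile[seq_len(t - 1L)] else numeric(0)
    limits[t, ] <- predictive_limits(components, hist_t, specificity_level)
  }
  atypical <- which(profile < limits[, 1] | profile > limits[, 2])
  list(atypical = atypical, flagged = length(atypical) > 0L, limits = limits)
}

#' Two-sided extremeness score of a profile
#'
#' Scores each observation by how far into the tails of its sequential
#' posterior-predictive distribution it falls, `|2 * F(x) - 1|` with `F`
#' the predictive CDF given the preceding observations, and returns the
#' maximum over the profile. A profile sitting at the predictive median
#' scores 0; an observation at the 99.5th percentile scores at least
#' 0.99. Used as the continuous score underlying the ROC analysis.
#'
#' @param profile Ordered numeric observations.
#' @param components A `marker_components`.
#' @return Score in `[0, 1]`.
#' @export
profile_percentile_score <- function(profile, components) {
  if (length(profile) == 0L) stop("profile must be non-empty", call. = FALSE)
  if (any(!is.finite(profile))) stop("profile must be finite", call. = FALSE)
  n <- length(profile)
  score <- 0
  for (t in seq_len(n)) {
    post <- .posterior_mean_var(components, profile[seq_len(t - 1L)])
    sdev <- sqrt(post$tau2 + components$sigma2_within)
    u <- if (sdev == 0) {
      if (profile[t] == post$m) 0.5 else as.numeric(profile[t] > post$m)
    } else {
      pnorm(profile[t], post$m, sdev)
    }
    score <- max(score, abs(2 * u - 1))
  }
  score
}

#' Leave-one-out cohort screening
#'
#' Cohort-level evaluation of a marker exactly as the passport analysis
#' prescribes: variance components are estimated from undoped (placebo)
#' profiles only; each placebo subject is evaluated against components
#' estimated from the *other* placebo subjects (leave-one-out, guarding
#' against overfitting the subject's own data), while each doped subject
#' is evaluated against components from the full placebo set. Sensitivity
#' is the percentage of doped subjects with at least one atypical value,
#' specificity the percentage of placebo subjects with none, and the ROC
#' area is computed from the [profile_percentile_score()]s by
#' [roc_auc()].
#'
#' @param placebo_profiles Named list mapping subject to ordered placebo
#'   observations (>= 3 subjects).
#' @param doped_profiles Named list of doped profiles; may be empty, in
#'   which case sensitivity and ROC are `NA`.
#' @param specificity_level Specificity of the limits (default 0.99).
#' @param mode Evaluation mode, as in [evaluate_profile()].
#' @return An object of class `detection_result`: list with `per_subject`
#'   (data frame: `subject`, `group`, `n_atypical`, `flagged`, `score`),
#'   `sensitivity`, `specificity` (percent, unrounded), `roc_area`, and
#'   `components` (full-placebo `marker_components`).
#' @export
loo_screen <- function(placebo_profiles, doped_profiles = list(),
                       specificity_level = 0.99,
                       mode = c("sequential", "batch")) {
  mode <- match.arg(mode)
  if (length(placebo_profiles) < 3L) {
    stop("need >= 3 placebo subjects for leave-one-out screening",
         call. = FALSE)
  }
  full <- estimate_components(placebo_profiles)
  eval_one <- function(profile, comps) {
    ev <- evaluate_profile(profile, comps, specificity_level, mode = mode)
    data.frame(n_atypical = length(ev$atypical), flagged = ev$flagged,
               score = profile_percentile_score(profile, comps))
  }
  placebo_rows <- lapply(names(placebo_profiles), function(s) {
    comps <- estimate_components(placebo_profiles[names(placebo_profiles) != s])
    cbind(data.frame(subject = s, group = "placebo",
                     stringsAsFactors = FALSE),
          eval_one(placebo_profiles[[s]], comps))
  })
  doped_rows <- lapply(names(doped_profiles), function(s) {
    cbind(data.frame(subject = s, group = "doped", stringsAsFactors = FALSE),
          eval_one(doped_profiles[[s]], full))
  })
  per_subject <- do.call(rbind, c(placebo_rows, doped_rows))
  rownames(per_subject) <- NULL
  spec <- 100 * mean(!per_subject$flagged[per_subject$group == "placebo"])
  sens <- if (length(doped_profiles)) {
    100 * mean(per_subject$flagged[per_subject$group == "doped"])
  } else {
    NA_real_
  }
  roc <- if (length(doped_profiles)) {
    roc_auc(per_subject$score, per_subject$group == "doped")
  } else {
    NA_real_
  }
  structure(list(per_subject = per_subject, sensitivity = sens,
                 specificity = spec, roc_area = roc, components = full,
                 specificity_level = specificity_level),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("detection_result: sensitivity %s%%, specificity %s%%, ROC area %s\n",
              ifelse(is.na(x$sensitivity), "NA", round(x$sensitivity)),
              round(x$specificity),
              ifelse(is.na(x$roc_area), "NA", format(round(x$roc_area, 2)))))
  invisible(x)
}

#' ROC area by Mann-Whitney pair counting
#'
#' The area under the ROC curve equals the Mann-Whitney U statistic scaled
#' by the number of (positive, negative) pairs, counting ties as half.
#'
#' @param scores Numeric scores (higher = more doping-like).
#' @param labels Logical (or coercible) vector: `TRUE` for doped.
#' @return Area in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.4, 0.8, 0.3), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` lengths differ", call. = FALSE)
  }
  pos <- scores[labels]
  neg <- scores[!labels]
  if (!length(pos) || !length(neg)) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(c(pos, neg), ties.method = "average")
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}
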