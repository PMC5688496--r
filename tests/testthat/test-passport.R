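test_that("variance components match the hand-worked ANOVA example", {
  comps <- estimate_components(list(A = c(0, 2), B = c(4, 6)))
  expect_equal(comps$mu, 3)
  expect_equal(comps$sigma2_within, 2)
  expect_equal(comps$sigma2_between, 7)
  # constant data: zero components, not an error
  flat <- estimate_components(list(A = c(1, 1), B = c(1, 1)))
  expect_equal(c(flat$sigma2_within, flat$sigma2_between), c(0, 0))
  expect_error(estimate_components(list(A = c(1, 2))), ">= 2 subjects")
  # negative between-component clips to zero with a warning
  expect_warning(
    clipped <- estimate_components(list(A = c(-10, 10), B = c(0.1, -0.1))),
    "clipped")
  expect_equal(clipped$sigma2_between, 0)
})

test_that("components are recovered within 10% at cohort scale", {
  s2w <- 0.13
  s2b <- 0.21
  make_cohort <- function() {
    profiles <- lapply(seq_len(200), function(j) {
      rnorm(13, rnorm(1, 1.5, sqrt(s2b)), sqrt(s2w))
    })
    names(profiles) <- sprintf("S%03d", seq_along(profiles))
    profiles
  }
  withr::with_seed(2024, {
    # one cohort: exact agreement with the aov() oracle
    profiles <- make_cohort()
    comps <- estimate_components(profiles)
    oracle <- aov_components(profiles)
    expect_equal(comps$sigma2_within, unname(oracle["within"]),
                 tolerance = 1e-10)
    expect_equal(comps$sigma2_between, unname(oracle["between"]),
                 tolerance = 1e-10)
    # recovery: between-component sampling error at this design is itself
    # close to 10%, so the 10% recovery check is applied to the mean over
    # replicate cohorts
    ests <- t(vapply(1:8, function(r) {
      cc <- estimate_components(make_cohort())
      c(w = cc$sigma2_within, b = cc$sigma2_between)
    }, numeric(2)))
    expect_lt(abs(mean(ests[, "w"]) - s2w) / s2w, 0.1)
    expect_lt(abs(mean(ests[, "b"]) - s2b) / s2b, 0.1)
  })
})

test_that("predictive limits obey their closed forms", {
  comps <- marker_components(mu = 2, sigma2_within = 0.13,
                             sigma2_between = 0.21)
  z <- qnorm(0.995)
  # empty history: population prior predictive
  lim <- predictive_limits(comps, numeric(0), 0.99)
  expect_equal(unname(lim), 2 + c(-1, 1) * z * sqrt(0.21 + 0.13))
  # no between-subject variance: no individualisation possible
  comps0 <- marker_components(2, 0.13, 0)
  lim0 <- predictive_limits(comps0, c(5, 6, 7), 0.99)
  expect_equal(unname(lim0), 2 + c(-1, 1) * z * sqrt(0.13))
  # limits individualise and tighten as history grows
  hist7 <- rep(2.5, 7)
  lim_n <- t(vapply(0:7, function(n) {
    predictive_limits(comps, hist7[seq_len(n)], 0.99)
  }, numeric(2)))
  widths <- lim_n[, 2] - lim_n[, 1]
  expect_true(all(diff(widths) < 0))
  expect_error(predictive_limits(comps, specificity_level = 0.4),
               "specificity_level")
  expect_error(predictive_limits(marker_components(2, 0, 0), c(3), 0.99),
               "degenerate")
})

test_that("interval mass matches a Monte-Carlo posterior-predictive oracle", {
  withr::with_seed(55, {
    cases <- list(
      list(comps = marker_components(1.5, 0.13, 0.21),
           history = numeric(0)),
      list(comps = marker_components(0, 0.5, 0.1),
           history = c(0.4, -0.2, 0.9)),
      list(comps = marker_components(-2, 0.05, 0.8),
           history = c(-1.2, -1.5, -1.1, -1.4, -1.3))
    )
    for (case in cases) {
      for (level in c(0.95, 0.99)) {
        lim <- predictive_limits(case$comps, case$history, level)
        mass <- mc_interval_mass(case$comps, case$history,
                                 lim["lower"], lim["upper"],
                                 n_draws = 1e6, seed = 123)
        expect_equal(mass, level, tolerance = 0.002)
      }
    }
  })
})

test_that("sequential evaluation flags gross outliers and only those", {
  comps <- marker_components(2, 0.13, 0.21)
  ev <- evaluate_profile(rep(2, 13), comps, 0.99)
  expect_equal(length(ev$atypical), 0L)
  expect_false(ev$flagged)
  wild <- c(2 + 10 * sqrt(0.34), rep(2, 12))
  ev2 <- evaluate_profile(wild, comps, 0.99)
  expect_true(ev2$flagged)
  expect_true(1 %in% ev2$atypical)
  expect_equal(nrow(ev2$limits), 13L)
  expect_error(evaluate_profile(c(2, NA), comps), "finite")
})

test_that("reference ranges hold their nominal coverage", {
  for (level in c(0.99, 0.95)) {
    comps <- marker_components(1.5, 0.13, 0.21)
    inside <- withr::with_seed(404, {
      hits <- vapply(seq_len(600), function(j) {
        prof <- rnorm(13, rnorm(1, 1.5, sqrt(0.21)), sqrt(0.13))
        13L - length(evaluate_profile(prof, comps, level)$atypical)
      }, integer(1))
      sum(hits) / (600 * 13)
    })
    se <- sqrt(level * (1 - level) / (600 * 13))
    expect_lt(abs(inside - level), 4 * se)
  }
})

test_that("limits shrink to the subject mean and within-subject width", {
  comps <- marker_components(0, 0.13, 0.21)
  theta <- 0.8
  prof <- withr::with_seed(9, rnorm(500, theta, sqrt(0.13)))
  lim <- predictive_limits(comps, prof, 0.99)
  centre <- mean(lim)
  expect_equal(centre, theta, tolerance = 0.06)
  expect_equal(unname(diff(lim)), 2 * qnorm(0.995) * sqrt(0.13),
               tolerance = 0.01)
})

test_that("profile percentile scores measure two-sided extremeness", {
  comps <- marker_components(2, 0.13, 0.21)
  expect_equal(profile_percentile_score(rep(2, 5), comps), 0,
               tolerance = 1e-9)
  x995 <- 2 + qnorm(0.995) * sqrt(0.34)
  expect_gte(profile_percentile_score(x995, comps), 0.99 - 1e-9)
  # max property: appending a more extreme observation never lowers it
  base_prof <- c(2.1, 1.9, 2.2)
  s1 <- profile_percentile_score(base_prof, comps)
  s2 <- profile_percentile_score(c(base_prof, 5), comps)
  expect_gte(s2, s1)
})

test_that("leave-one-out screening computes the cohort metrics", {
  withr::with_seed(77, {
    placebo <- lapply(1:14, function(j) rnorm(13, rnorm(1, 0, 0.4), 0.3))
    names(placebo) <- sprintf("P%02d", 1:14)
    # engineer exactly one flagged placebo subject via a gross outlier
    placebo[["P07"]][5] <- 10
    doped <- lapply(1:14, function(j) {
      rnorm(13, rnorm(1, 0, 0.4), 0.3) +
        c(0, 0, 0, 0, 0.9, 0.9, 0.9, 0.9, 0, 0, -0.9, -0.9, -0.9)
    })
    names(doped) <- sprintf("D%02d", 1:14)
    res <- loo_screen(placebo, doped, 0.99)
    expect_equal(round(res$specificity), 93)  # 13 of 14 clean
    expect_true(res$sensitivity >= 0 && res$sensitivity <= 100)
    expect_true(res$roc_area >= 0 && res$roc_area <= 1)
    expect_equal(nrow(res$per_subject), 28L)
    # empty doped set: sensitivity is an explicit NA sentinel, not 0
    res0 <- loo_screen(placebo, list(), 0.99)
    expect_true(is.na(res0$sensitivity))
    expect_error(loo_screen(placebo[1:2], doped), ">= 3 placebo")
  })
})

test_that("doping-scale trajectories are detected with high sensitivity", {
  traj <- c(0, 0, 0, 0, 0.86, 0.95, 0.80, 0.70, 0, 0,
            -0.82, -1.32, -1.18)
  sens <- withr::with_seed(1234, {
    vapply(1:20, function(r) {
      placebo <- lapply(1:14, function(j) {
        rnorm(13, rnorm(1, 3, sqrt(0.2)), sqrt(0.14))
      })
      names(placebo) <- sprintf("P%02d", 1:14)
      doped <- lapply(1:14, function(j) {
        rnorm(13, rnorm(1, 3, sqrt(0.2)), sqrt(0.14)) + traj
      })
      names(doped) <- sprintf("D%02d", 1:14)
      loo_screen(placebo, doped, 0.99)$sensitivity
    }, numeric(1))
  })
  expect_gte(mean(sens), 80)
})

test_that("null doped profiles are flagged at the null rate", {
  stats <- withr::with_seed(4321, {
    t(vapply(1:30, function(r) {
      make_prof <- function(n) {
        out <- lapply(1:n, function(j) rnorm(13, rnorm(1, 0, sqrt(0.2)),
                                             sqrt(0.13)))
        names(out) <- sprintf("S%02d_%d", 1:n, r)
        out
      }
      res <- loo_screen(make_prof(14), make_prof(14), 0.99)
      c(sens = res$sensitivity, fp = 100 - res$specificity)
    }, numeric(2)))
  })
  # doped-from-null sensitivity estimates the same null flag rate as the
  # placebo false-positive rate
  expect_lt(abs(mean(stats[, "sens"]) - mean(stats[, "fp"])), 8)
})

test_that("LOO components differ from full-data and flag no fewer subjects", {
  res <- withr::with_seed(31, {
    t(vapply(1:40, function(r) {
      placebo <- lapply(1:8, function(j) rnorm(6, rnorm(1, 0, 0.5), 0.4))
      names(placebo) <- sprintf("S%02d", 1:8)
      full <- estimate_components(placebo)
      loo1 <- estimate_components(placebo[-1])
      stopifnot(!identical(full$sigma2_between, loo1$sigma2_between))
      n_loo <- sum(vapply(seq_along(placebo), function(i) {
        comps <- suppressWarnings(estimate_components(placebo[-i]))
        evaluate_profile(placebo[[i]], comps, 0.95)$flagged
      }, logical(1)))
      n_full <- sum(vapply(placebo, function(prof) {
        evaluate_profile(prof, full, 0.95)$flagged
      }, logical(1)))
      c(loo = n_loo, full = n_full)
    }, numeric(2)))
  })
  # in expectation LOO flags at least as many clean subjects (lower
  # specificity) than evaluating against components fit on all subjects
  expect_gte(mean(res[, "loo"]), mean(res[, "full"]))
})

test_that("cohort-scale components reproduce the between > within ordering", {
  summ <- load_adaptive_summary()
  tx <- summ[summ$kind == "transcript", ]
  ests <- withr::with_seed(86, {
    t(vapply(seq_len(nrow(tx)), function(i) {
      profiles <- lapply(1:14, function(j) {
        rnorm(13, rnorm(1, tx$mean[i], sqrt(tx$sigma2_between[i])),
              sqrt(tx$sigma2_within[i]))
      })
      names(profiles) <- sprintf("S%02d", 1:14)
      comps <- suppressWarnings(estimate_components(profiles))
      c(w = comps$sigma2_within, b = comps$sigma2_between)
    }, numeric(2)))
  })
  expect_gt(mean(ests[, "b"]), mean(ests[, "w"]))
})

test_that("ROC area equals brute-force pair counting", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.8, 0.3), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)
  withr::with_seed(6, {
    for (i in 1:5) {
      scores <- round(stats::runif(30), 1)  # induces ties
      labels <- stats::runif(30) > 0.5
      if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
      expect_equal(roc_auc(scores, labels), pair_count_auc(scores, labels))
    }
  })
  # identical distributions, random labels: expectation one half
  auc <- withr::with_seed(8, {
    mean(vapply(1:200, function(i) {
      roc_auc(rnorm(20), rep(c(TRUE, FALSE), 10))
    }, numeric(1)))
  })
  expect_equal(auc, 0.5, tolerance = 0.03)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})
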