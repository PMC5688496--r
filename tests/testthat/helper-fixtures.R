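# shared fixture builders for the test suite; everything is generated in
# code so no binary data ships with the package

# construct an expr_matrix directly from a values matrix and metadata
make_em <- function(values, subject, arm, timepoint, day) {
  sample_id <- paste(subject, arm, timepoint, sep = ".")
  colnames(values) <- sample_id
  structure(
    list(values = values,
         sample_meta = data.frame(sample_id = sample_id, subject = subject,
                                  arm = arm, timepoint = timepoint, day = day,
                                  stringsAsFactors = FALSE),
         marker_meta = data.frame(probe = rownames(values),
                                  stringsAsFactors = FALSE),
         adjusted_mfi = 2^values * 1000),
    class = "expr_matrix"
  )
}

# gene params with no doping effect, for null simulations
null_gene_params <- function(design, n = 10, s2w = 0.15, s2b = 0.2) {
  c(lapply(seq_len(n), function(i) {
    gene_params(sprintf("G%02d", i), mu = 2, sigma2_within = s2w,
                sigma2_between = s2b)
  }),
  lapply(reference_probes(), function(m) {
    gene_params(m, mu = 0, sigma2_within = 0.005, sigma2_between = 0.01,
                is_reference = TRUE)
  }))
}

# ANOVA variance-component oracle: textbook mean squares from aov()
aov_components <- function(values_by_subject) {
  df <- data.frame(
    y = unlist(values_by_subject, use.names = FALSE),
    subject = factor(rep(names(values_by_subject),
                         lengths(values_by_subject)))
  )
  ms <- summary(stats::aov(y ~ subject, data = df))[[1]][["Mean Sq"]]
  ni <- lengths(values_by_subject)
  N <- sum(ni)
  k <- length(ni)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  c(within = ms[2], between = max(0, (ms[1] - ms[2]) / n0))
}

# brute-force AUC by pair counting (ties count half)
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# importance-sampling oracle for the posterior-predictive interval mass:
# draws subject means from the population prior, weights them by the
# likelihood of the observed history, and averages the Normal mass each
# assigns to the interval
mc_interval_mass <- function(components, history, lower, upper,
                             n_draws = 1e6, seed = 1) {
  withr::with_seed(seed, {
    theta <- rnorm(n_draws, components$mu, sqrt(components$sigma2_between))
    logw <- rep(0, n_draws)
    for (x in history) {
      logw <- logw + dnorm(x, theta, sqrt(components$sigma2_within),
                           log = TRUE)
    }
    w <- exp(logw - max(logw))
    mass <- pnorm(upper, theta, sqrt(components$sigma2_within)) -
      pnorm(lower, theta, sqrt(components$sigma2_within))
    sum(w * mass) / sum(w)
  })
}
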