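#' Per-marker generator parameters
#'
#' A `gene_params` object carries the hierarchical model parameters for one
#' probe: the population mean `mu` of log2 reference-normalised expression,
#' the within-subject variance `sigma2_within` (week-to-week fluctuation
#' inside one individual), the between-subject variance `sigma2_between`
#' (spread of individual set-points), and an `effect` map from timepoint
#' label to the log2 fold-change added under the treated arm. Effects must
#' be zero (or absent) on baseline timepoints.
#'
#' @param marker_id Probe name.
#' @param mu Population mean of log2 expression.
#' @param sigma2_within Within-subject variance (log2 scale), `>= 0`.
#' @param sigma2_between Between-subject variance (log2 scale), `>= 0`.
#' @param effect Named numeric vector of log2 fold-changes keyed by
#'   timepoint label; missing labels mean no effect.
#' @param is_reference Logical; reference (housekeeping) probes are used for
#'   normalisation and never carry an effect.
#' @return A list of class `gene_params`.
#' @examples
#' gene_params("ALAS2", mu = 3.09, sigma2_within = 0.204,
#'             sigma2_between = 0.282, effect = c(D2 = 0.86))
#' @export
gene_params <- function(marker_id, mu, sigma2_within, sigma2_between,
                        effect = numeric(0), is_reference = FALSE) {
  stopifnot(is.character(marker_id), length(marker_id) == 1L)
  .assert_scalar_number(mu, "mu")
  .assert_scalar_number(sigma2_within, "sigma2_within")
  .assert_scalar_number(sigma2_between, "sigma2_between")
  if (sigma2_within < 0 || sigma2_between < 0) {
    stop("variances must be non-negative", call. = FALSE)
  }
  if (length(effect) > 0 && is.null(names(effect))) {
    stop("`effect` must be a named vector keyed by timepoint label",
         call. = FALSE)
  }
  if (is_reference && length(effect) > 0 && any(effect != 0)) {
    stop("reference probes cannot carry a doping effect", call. = FALSE)
  }
  structure(
    list(marker_id = marker_id, mu = mu,
         sigma2_within = sigma2_within, sigma2_between = sigma2_between,
         effect = effect, is_reference = isTRUE(is_reference)),
    class = "gene_params"
  )
}

#' The five reference (housekeeping) probes of the expression panel
#' @return Character vector of probe names.
#' @export
reference_probes <- function() {
  c("ACTB", "ACTR10", "MRFAP1", "PPIB", "RAB11A")
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "txpassport")
  if (!nzchar(path)) stop("missing packaged data file: ", file, call. = FALSE)
  path
}

#' Default generator parameters for the microdose-study panel
#'
#' Builds the full 50-probe roster the panel assays: 41 analysable target
#' transcripts parameterised by their published cohort mean and
#' within/between-subject variance components, 4 synthetic low-abundance
#' placeholder probes standing in for the targets that fell below the assay
#' limit of detection (their identities are not published), and the 5
#' reference probes. The 11 transcripts with published per-timepoint doping
#' log2 fold-changes carry those trajectories as their treated-arm effect;
#' all other probes have zero effect.
#'
#' @param design A `study_design`; effects are validated against its
#'   timepoint labels.
#' @return A list of [gene_params()], one per probe (45 targets then 5
#'   references).
#' @export
default_gene_params <- function(design = make_mds_design("MDS")) {
  summ <- utils::read.delim(.extdata("adaptive_model_summary.tsv"),
                            stringsAsFactors = FALSE)
  summ <- summ[summ$kind == "transcript", ]
  eff <- utils::read.delim(.extdata("doping_effect_log2fc.tsv"),
                           stringsAsFactors = FALSE)
  labels <- design$timepoints$label
  params <- lapply(seq_len(nrow(summ)), function(i) {
    m <- summ$marker[i]
    e <- numeric(0)
    j <- match(m, eff$marker)
    if (!is.na(j)) {
      e <- unlist(eff[j, -1])
      names(e) <- colnames(eff)[-1]
      e <- e[names(e) %in% labels]
    }
    gene_params(m, mu = summ$mean[i],
                sigma2_within = summ$sigma2_within[i],
                sigma2_between = summ$sigma2_between[i],
                effect = e)
  })
  # synthetic placeholders for the four below-LOD targets (identities
  # unpublished); very low abundance so background dominates their signal
  lod_fillers <- lapply(sprintf("LOWTX%d", 1:4), function(m) {
    gene_params(m, mu = -9, sigma2_within = 0.1, sigma2_between = 0.1)
  })
  # references sit at log2 = 0 so their geometric mean anchors the
  # normalised scale at the published cohort means
  refs <- lapply(reference_probes(), function(m) {
    gene_params(m, mu = 0, sigma2_within = 0.005, sigma2_between = 0.01,
                is_reference = TRUE)
  })
  c(params, lod_fillers, refs)
}

#' Default haematology generator parameters
#'
#' Baseline means, variance components and treated-arm trajectory
#' multipliers for haemoglobin (HGB, g/L), haematocrit (HCT, %) and
#' reticulocyte percentage (RET, %) over the 13 microdose-study timepoints.
#' The trajectories encode the qualitative course of microdose rHuEpo:
#' HGB and HCT rise gradually through administration and peak one week
#' after the last injection; RET% rises rapidly after the first injection,
#' stays elevated for four weeks, then falls below baseline throughout the
#' post phase (the rebound the OFF-score is designed to catch). HGB and HCT
#' take additive Gaussian subject and visit noise; RET% is log-normal so it
#' stays positive.
#'
#' @param design A `study_design` whose timepoint labels key the
#'   trajectories.
#' @return Named list with components `HGB`, `HCT`, `RET`, each a list of
#'   `baseline`, `sigma2_within`, `sigma2_between`, `doped_multiplier`
#'   (named by timepoint label). RET variances are on the log scale.
#' @export
default_haem_params <- function(design = make_mds_design("MDS")) {
  labels <- design$timepoints$label
  if (!identical(labels,
                 c("B1", "B2", "B3", paste0("D", 1:7), paste0("P", 1:3)))) {
    stop("default haematology trajectories are defined for the MDS preset; ",
         "supply explicit trajectories for other designs", call. = FALSE)
  }
  mult <- function(x) setNames(x, labels)
  list(
    HGB = list(baseline = 150, sigma2_within = 29, sigma2_between = 36,
               doped_multiplier = mult(c(1, 1, 1, 1.00, 1.01, 1.02, 1.03,
                                         1.04, 1.05, 1.06, 1.07, 1.05, 1.03))),
    HCT = list(baseline = 44, sigma2_within = 2.0, sigma2_between = 3.0,
               doped_multiplier = mult(c(1, 1, 1, 1.00, 1.01, 1.02, 1.03,
                                         1.04, 1.05, 1.06, 1.07, 1.05, 1.03))),
    RET = list(baseline = 0.93, sigma2_within = 0.010, sigma2_between = 0.040,
               doped_multiplier = mult(c(1, 1, 1, 1.45, 1.55, 1.50, 1.40,
                                         1.15, 1.00, 0.90, 0.55, 0.60, 0.75)))
  )
}
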