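#' Background subtraction with a positive floor
#'
#' Subtracts instrument background from an MFI value, flooring the result
#' at a small positive value so downstream log2 transforms stay defined.
#'
#' @param mfi Non-negative MFI value(s).
#' @param background Non-negative background MFI.
#' @param floor Positive floor applied after subtraction.
#' @return `pmax(mfi - background, floor)`.
#' @examples
#' subtract_background(57.5, 7.5)  # 50
#' subtract_background(3, 10)      # floored at 0.5
#' @export
subtract_background <- function(mfi, background, floor = 0.5) {
  if (!is.numeric(mfi) || any(!is.finite(mfi)) || any(mfi < 0)) {
    stop("`mfi` must be non-negative and finite", call. = FALSE)
  }
  .assert_scalar_number(background, "background")
  .assert_scalar_number(floor, "floor")
  if (background < 0) stop("`background` must be non-negative", call. = FALSE)
  if (floor <= 0) stop("`floor` must be positive", call. = FALSE)
  pmax(mfi - background, floor)
}

#' Geometric mean
#'
#' @param values Non-empty vector of positive values.
#' @return `exp(mean(log(values)))`.
#' @examples
#' geometric_mean(c(1, 2, 4, 8, 16))  # 4
#' @export
geometric_mean <- function(values) {
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values)) || any(values <= 0)) {
    stop("all values must be positive and finite", call. = FALSE)
  }
  exp(mean(log(values)))
}

#' Reference-gene normalisation of one sample
#'
#' Normalises a sample's (background-adjusted) probe MFIs to the geometric
#' mean of its reference probes and returns log2 values for the target
#' probes. A target whose MFI equals the reference geometric mean maps
#' to 0.
#'
#' @param probe_mfis Named numeric vector of adjusted MFIs (targets and
#'   references together).
#' @param ref_probes Character vector of reference probe names; all must be
#'   present in `probe_mfis` with positive values.
#' @return Named numeric vector: `log2(target / geomean(references))` for
#'   each non-reference probe.
#' @export
normalise_sample <- function(probe_mfis, ref_probes = reference_probes()) {
  if (is.null(names(probe_mfis))) {
    stop("`probe_mfis` must be named by probe", call. = FALSE)
  }
  missing_refs <- setdiff(ref_probes, names(probe_mfis))
  if (length(missing_refs)) {
    stop("missing reference probe(s): ", paste(missing_refs, collapse = ", "),
         call. = FALSE)
  }
  refs <- probe_mfis[ref_probes]
  if (any(!is.finite(refs)) || any(refs <= 0)) {
    stop("reference probe MFIs must be positive", call. = FALSE)
  }
  gm <- geometric_mean(refs)
  targets <- probe_mfis[setdiff(names(probe_mfis), ref_probes)]
  log2(targets / gm)
}

#' Replicate coefficient of variation
#'
#' Assay precision on the raw MFI scale: 100 times the sample standard
#' deviation over the mean of a sample's technical replicates.
#'
#' @param replicate_values At least two positive MFI values.
#' @return CV in percent.
#' @examples
#' replicate_cv(c(90, 110))  # 14.14
#' @export
replicate_cv <- function(replicate_values) {
  if (length(replicate_values) < 2L) {
    stop("replicate_cv needs at least 2 replicates", call. = FALSE)
  }
  if (!is.numeric(replicate_values) || any(!is.finite(replicate_values)) ||
      any(replicate_values <= 0)) {
    stop("replicate values must be positive", call. = FALSE)
  }
  100 * stats::sd(replicate_values) / mean(replicate_values)
}

#' Mean assay CV of a panel data set
#'
#' Averages [replicate_cv()] over all (subject, arm, timepoint, probe)
#' replicate groups with at least two replicates.
#'
#' @param samples A `panel_samples` data frame.
#' @return Mean CV in percent.
#' @export
assay_cv <- function(samples) {
  key <- interaction(samples$subject, samples$arm, samples$timepoint,
                     samples$probe, drop = TRUE)
  cvs <- tapply(samples$MFI, key, function(v) {
    if (length(v) < 2L) NA_real_ else replicate_cv(v)
  })
  mean(unlist(cvs), na.rm = TRUE)
}

#' Build the log2 reference-normalised expression matrix
#'
#' The panel-to-matrix pipeline: technical replicates are averaged on the
#' MFI scale, background is subtracted with a positive floor, each sample's
#' probes are normalised to the geometric mean of its reference probes, and
#' target values are log2 transformed. Reference probes never appear as
#' analysis rows.
#'
#' @param samples A `panel_samples` data frame (long format).
#' @param ref_probes Reference probe names (default: the panel's five).
#' @param background Instrument background MFI to subtract.
#' @param floor Positive floor applied after background subtraction.
#' @return An object of class `expr_matrix`: list with `values` (targets x
#'   samples matrix of log2 normalised expression), `sample_meta` (data
#'   frame: `sample_id`, `subject`, `arm`, `timepoint`, `day`),
#'   `marker_meta` (data frame: `probe`), and `adjusted_mfi` (targets x
#'   samples matrix of replicate-averaged, background-adjusted MFI, kept
#'   for limit-of-detection filtering).
#' @export
normalise_panel <- function(samples, ref_probes = reference_probes(),
                            background = 30, floor = 0.5) {
  if (nrow(samples) == 0L) stop("`samples` is empty", call. = FALSE)
  key <- paste(samples$subject, samples$arm, samples$timepoint, sep = "\r")
  agg <- aggregate(MFI ~ probe + key, data = data.frame(samples, key = key),
                   FUN = mean)
  adj <- subtract_background(agg$MFI, background, floor)
  sample_ids <- sort(unique(agg$key))
  probes <- sort(unique(agg$probe))
  mfimat <- matrix(NA_real_, length(probes), length(sample_ids),
                   dimnames = list(probes, sample_ids))
  mfimat[cbind(match(agg$probe, probes), match(agg$key, sample_ids))] <- adj

  missing_refs <- setdiff(ref_probes, probes)
  if (length(missing_refs)) {
    stop("missing reference probe(s): ", paste(missing_refs, collapse = ", "),
         call. = FALSE)
  }
  refmat <- mfimat[ref_probes, , drop = FALSE]
  if (anyNA(refmat)) {
    bad <- colnames(refmat)[colSums(is.na(refmat)) > 0][1]
    stop("sample ", gsub("\r", "/", bad), " lacks a reference probe measurement",
         call. = FALSE)
  }
  gm <- exp(colMeans(log(refmat)))
  targets <- setdiff(probes, ref_probes)
  values <- log2(sweep(mfimat[targets, , drop = FALSE], 2, gm, "/"))

  meta_idx <- match(sample_ids, key)
  parts <- do.call(rbind, strsplit(sample_ids, "\r", fixed = TRUE))
  sample_meta <- data.frame(
    sample_id = paste(parts[, 1], parts[, 2], parts[, 3], sep = "."),
    subject = parts[, 1], arm = parts[, 2], timepoint = parts[, 3],
    day = samples$day[meta_idx], stringsAsFactors = FALSE
  )
  colnames(values) <- sample_meta$sample_id
  adjusted <- mfimat[targets, , drop = FALSE]
  colnames(adjusted) <- sample_meta$sample_id
  structure(
    list(values = values, sample_meta = sample_meta,
         marker_meta = data.frame(probe = targets, stringsAsFactors = FALSE),
         adjusted_mfi = adjusted),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d markers x %d samples (log2 reference-normalised)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Subset an expression matrix to a marker set
#'
#' @param em An `expr_matrix`.
#' @param markers Character vector of marker names to keep.
#' @return The subset `expr_matrix`.
#' @export
subset_markers <- function(em, markers) {
  keep <- rownames(em$values) %in% markers
  em$values <- em$values[keep, , drop = FALSE]
  em$adjusted_mfi <- em$adjusted_mfi[keep, , drop = FALSE]
  em$marker_meta <- em$marker_meta[em$marker_meta$probe %in% markers, ,
                                   drop = FALSE]
  em
}

#' Limit-of-detection marker filter
#'
#' Drops markers whose background-adjusted MFI exceeds the assay limit of
#' detection in fewer than `min_fraction` of samples. In the microdose
#' study this step reduced the 45-target panel to 41 analysable
#' transcripts.
#'
#' @param em An `expr_matrix` carrying `adjusted_mfi`.
#' @param lod MFI limit of detection.
#' @param min_fraction Minimum fraction of samples that must exceed `lod`
#'   for a marker to be kept, in `(0, 1]`.
#' @return List with `kept` (the filtered `expr_matrix`) and `dropped`
#'   (character vector of removed markers).
#' @export
lod_filter <- function(em, lod = 50, min_fraction = 0.8) {
  if (!inherits(em, "expr_matrix") || nrow(em$values) == 0L) {
    stop("`em` must be a non-empty expr_matrix", call. = FALSE)
  }
  .assert_scalar_number(min_fraction, "min_fraction")
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("`min_fraction` must lie in (0, 1]", call. = FALSE)
  }
  frac_above <- rowMeans(em$adjusted_mfi > lod)
  dropped <- rownames(em$values)[frac_above < min_fraction]
  kept <- subset_markers(em, setdiff(rownames(em$values), dropped))
  list(kept = kept, dropped = dropped)
}
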