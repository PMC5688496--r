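#' Study designs for the microdose rHuEpo crossover trial and its templates
#'
#' A `study_design` records the sampling grid everything downstream indexes:
#' subjects, trial arms, ordered timepoints with their day offsets, and the
#' number of technical replicates per sample. The `"MDS"` preset reproduces
#' the microdose study layout: 14 subjects crossing over between rHuEpo and
#' placebo arms, sampled at three baseline visits (days -14, -7, 0), weekly
#' during seven weeks of administration (days 3 to 45) and for three weeks
#' post administration (days 52, 59, 66) -- 13 timepoints, 364 scheduled
#' samples. `"ATS-runners"` and `"MDS-exercise"` are scenario templates
#' reusing the same machinery with altitude-training and acute-exercise
#' sampling grids.
#'
#' @param preset Design preset name: `"MDS"`, `"ATS-runners"` or
#'   `"MDS-exercise"`.
#' @param n_subjects Optional override of the preset's subject count.
#' @param replicates_per_sample Technical replicates measured per sample
#'   (the panel assay runs duplicates).
#'
#' @return An object of class `study_design`: a list with elements
#'   `n_subjects`, `arms` (character, treated arm first), `timepoints`
#'   (data frame with columns `label`, `day`, `phase`) and
#'   `replicates_per_sample`.
#' @examples
#' d <- make_mds_design("MDS")
#' nrow(d$timepoints)  # 13
#' @export
make_mds_design <- function(preset = "MDS", n_subjects = NULL,
                            replicates_per_sample = 2L) {
  presets <- c("MDS", "ATS-runners", "MDS-exercise")
  if (!is.character(preset) || length(preset) != 1L || !preset %in% presets) {
    stop("unknown design preset; valid presets: ",
         paste(shQuote(presets), collapse = ", "), call. = FALSE)
  }
  tp <- switch(preset,
    "MDS" = data.frame(
      label = c("B1", "B2", "B3", paste0("D", 1:7), paste0("P", 1:3)),
      day   = c(-14, -7, 0, 3, 10, 17, 24, 31, 38, 45, 52, 59, 66),
      phase = c(rep("baseline", 3), rep("during", 7), rep("post", 3)),
      stringsAsFactors = FALSE
    ),
    "ATS-runners" = data.frame(
      label = c("B1", "D1", "P1", "P2", "P3", "P4"),
      day   = c(-7, 10, 16, 21, 30, 42),
      phase = c("baseline", "during", rep("post", 4)),
      stringsAsFactors = FALSE
    ),
    "MDS-exercise" = data.frame(
      # pre / immediately-post / 30-min-post sprints, at baseline and after
      # the final injection; sub-day offsets keep days strictly increasing
      label = c("B1", "E1", "E2", "P0", "E3", "E4"),
      day   = c(0, 0.01, 0.03, 49, 49.01, 49.03),
      phase = c("baseline", "exercise", "exercise",
                "baseline", "exercise", "exercise"),
      stringsAsFactors = FALSE
    )
  )
  n_default <- switch(preset, "MDS" = 14L, "ATS-runners" = 12L,
                      "MDS-exercise" = 14L)
  arms <- switch(preset,
    "MDS" = c("rHuEpo", "placebo"),
    "ATS-runners" = c("altitude", "control"),
    "MDS-exercise" = c("rHuEpo", "placebo")
  )
  n <- if (is.null(n_subjects)) n_default else as.integer(n_subjects)
  design <- structure(
    list(n_subjects = n, arms = arms, timepoints = tp,
         replicates_per_sample = as.integer(replicates_per_sample)),
    class = "study_design"
  )
  validate_design(design)
}

#' Validate a study design
#'
#' Checks the structural invariants of a [make_mds_design()] object:
#' at least two subjects, at least one arm, unique timepoint labels,
#' strictly increasing day offsets and a positive replicate count.
#'
#' @param design A `study_design`.
#' @return The design, invisibly usable in a pipe; errors on violation.
#' @export
validate_design <- function(design) {
  if (!inherits(design, "study_design")) {
    stop("`design` must be a study_design object", call. = FALSE)
  }
  if (design$n_subjects < 2L) stop("a design needs >= 2 subjects", call. = FALSE)
  if (length(design$arms) < 1L) stop("a design needs >= 1 arm", call. = FALSE)
  tp <- design$timepoints
  if (anyDuplicated(tp$label)) stop("timepoint labels must be unique", call. = FALSE)
  if (any(diff(tp$day) <= 0)) stop("timepoint days must be strictly increasing", call. = FALSE)
  if (design$replicates_per_sample < 1L) {
    stop("replicates_per_sample must be >= 1", call. = FALSE)
  }
  design
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: %d subjects x %d arms x %d timepoints (%d replicates/sample)\n",
              x$n_subjects, length(x$arms), nrow(x$timepoints),
              x$replicates_per_sample))
  cat("arms:", paste(x$arms, collapse = ", "), "\n")
  cat("timepoints:",
      paste(sprintf("%s(%g)", x$timepoints$label, x$timepoints$day),
            collapse = " "), "\n")
  invisible(x)
}

#' Baseline timepoint labels of a design
#'
#' @param design A `study_design`.
#' @return Character vector of labels with phase `"baseline"`.
#' @export
baseline_labels <- function(design) {
  design$timepoints$label[design$timepoints$phase == "baseline"]
}

#' Subject identifiers of a design
#'
#' @param design A `study_design`.
#' @return Character vector `S01`, `S02`, ...
#' @export
design_subjects <- function(design) {
  sprintf("S%02d", seq_len(design$n_subjects))
}
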