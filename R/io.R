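.sep_for <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

#' Read and write long-format panel tables
#'
#' The on-disk panel format is long (tidy): one row per technical
#' replicate measurement with columns `subject`, `arm`, `timepoint`,
#' `day`, `probe`, `replicate`, `MFI`. Extension picks the delimiter
#' (`.csv` comma, otherwise tab). Unknown columns are preserved.
#'
#' @param path File to read or write.
#' @return `read_panel_table()` returns a `panel_samples` data frame.
#' @export
read_panel_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = .sep_for(path), stringsAsFactors = FALSE)
  required <- c("subject", "arm", "timepoint", "day", "probe", "replicate",
                "MFI")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("panel table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$MFI)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$MFI))))[1]
    stop("non-numeric MFI at row ", bad, call. = FALSE)
  }
  class(df) <- c("panel_samples", "data.frame")
  df
}

#' @rdname read_panel_table
#' @param samples A `panel_samples` data frame to write.
#' @export
write_panel_table <- function(samples, path) {
  write.table(samples, path, sep = .sep_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read and write haematology tables
#'
#' On-disk columns are `subject`, `arm`, `timepoint`, `day`, `HGB_gL`,
#' `HCT_pct`, `RET_pct` and (if present) `OFF`; in memory the package uses
#' the bare names `HGB` (g/L), `HCT` (%), `RET` (%), `OFF`.
#'
#' @param path File to read or write (`.csv` or `.tsv`).
#' @return `read_haematology_table()` returns the in-memory data frame.
#' @export
read_haematology_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = .sep_for(path), stringsAsFactors = FALSE)
  required <- c("subject", "arm", "timepoint", "day", "HGB_gL", "HCT_pct",
                "RET_pct")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("haematology table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  names(df)[match(c("HGB_gL", "HCT_pct", "RET_pct"), names(df))] <-
    c("HGB", "HCT", "RET")
  df
}

#' @rdname read_haematology_table
#' @param records In-memory haematology data frame to write.
#' @export
write_haematology_table <- function(records, path) {
  out <- records
  names(out)[match(c("HGB", "HCT", "RET"), names(out))] <-
    c("HGB_gL", "HCT_pct", "RET_pct")
  write.table(out, path, sep = .sep_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix with its sample-metadata sidecar
#'
#' @param em An `expr_matrix`.
#' @param path TSV for the markers x samples matrix.
#' @param meta_path TSV for the per-sample metadata; defaults to
#'   `<path>` with a `_samples.tsv` suffix.
#' @return Invisibly, `c(path, meta_path)`.
#' @export
write_expression_matrix <- function(em, path,
                                    meta_path = sub("\\.tsv$", "_samples.tsv",
                                                    path)) {
  tab <- data.frame(marker = rownames(em$values), em$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(em$sample_meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(path, meta_path))
}
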