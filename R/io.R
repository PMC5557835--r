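# Reading and writing the tabular interchange formats. The intensity matrix
# is a plain CSV/TSV (first column sample_id, one column per metabolite);
# sample and metabolite metadata travel in sidecar files so the matrix stays
# machine-parseable by any tool.

delim_for <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

read_delim_checked <- function(path, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  utils::read.table(path, header = TRUE, sep = delim_for(path),
                    na.strings = c("", "NA"), stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "")
}

#' Read a MetaboliteTable from CSV/TSV files
#'
#' Reads the intensity matrix and its two metadata sidecars and returns a
#' validated [metabolite_table()]. Empty cells and `"NA"` map to missing;
#' sample and metabolite order is preserved from the files.
#'
#' @param path Intensity matrix file: first column `sample_id`, remaining
#'   columns one per metabolite. `.csv` is comma-, `.tsv`/`.txt`
#'   tab-separated.
#' @param sample_meta_path CSV/TSV with columns `sample_id`, `group`,
#'   `patient_id`.
#' @param metabolite_meta_path CSV/TSV with columns `name`,
#'   `is_uremic_solute` (0/1), `is_internal_standard` (0/1), `ion_mode`.
#' @return A validated `metabolite_table`.
#' @export
read_feature_table <- function(path, sample_meta_path, metabolite_meta_path) {
  mat_df <- read_delim_checked(path, "intensity matrix")
  sm <- read_delim_checked(sample_meta_path, "sample metadata")
  mm <- read_delim_checked(metabolite_meta_path, "metabolite metadata")

  if (ncol(mat_df) < 2L) stopf("intensity matrix needs a sample_id column plus metabolites")
  ids <- as.character(mat_df[[1L]])
  x <- as.matrix(mat_df[, -1L, drop = FALSE])
  if (!is.numeric(x)) stopf("non-numeric intensity cell found in %s", path)

  if (nrow(sm) != nrow(x)) {
    stopf("dimension mismatch: intensity matrix has %d rows but sample_meta has %d",
          nrow(x), nrow(sm))
  }
  if (nrow(mm) != ncol(x)) {
    stopf("dimension mismatch: intensity matrix has %d metabolite columns but metabolite_meta has %d rows",
          ncol(x), nrow(mm))
  }
  if (!identical(ids, as.character(sm$sample_id))) {
    stopf("sample_id order in matrix and sample_meta differ")
  }
  if (!identical(colnames(x), as.character(mm$name))) {
    stopf("metabolite name order in matrix and metabolite_meta differ")
  }
  sm$patient_id <- ifelse(is.na(sm$patient_id), "", as.character(sm$patient_id))
  mm$is_uremic_solute <- as.logical(as.integer(mm$is_uremic_solute))
  mm$is_internal_standard <- as.logical(as.integer(mm$is_internal_standard))
  metabolite_table(x, sm, mm)
}

#' Write a MetaboliteTable to CSV files
#'
#' Inverse of [read_feature_table()]; `read -> write -> read` reproduces the
#' table (values to full double precision, metadata exactly).
#'
#' @param tab A `metabolite_table`.
#' @param path,sample_meta_path,metabolite_meta_path Output CSV paths.
#' @return The three paths, invisibly.
#' @export
write_feature_table <- function(tab, path, sample_meta_path,
                                metabolite_meta_path) {
  validate_metabolite_table(tab)
  x <- tab$intensities
  df <- data.frame(sample_id = tab$sample_meta$sample_id,
                   apply(x, 2L, fmt_num), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(tab$sample_meta, sample_meta_path, row.names = FALSE,
                   quote = FALSE, na = "")
  mm <- tab$metabolite_meta
  mm$is_uremic_solute <- as.integer(mm$is_uremic_solute)
  mm$is_internal_standard <- as.integer(mm$is_internal_standard)
  utils::write.csv(mm, metabolite_meta_path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(c(path, sample_meta_path, metabolite_meta_path))
}

# full-precision decimal rendering of a numeric vector ("" for NA)
fmt_num <- function(v) {
  out <- vapply(v, function(z) {
    if (is.na(z)) "" else sprintf("%.15g", z)
  }, character(1L))
  out
}

#' Write per-metabolite statistics to CSV
#'
#' Fixed column order `metabolite, contrast, statistic, p, q, fold_change,
#' direction, is_uremic_solute`; numeric fields are written with 15
#' significant digits so re-reading reproduces them.
#'
#' @param rows Data frame of per-metabolite univariate results, as returned
#'   by [test_contrast()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stat_table <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0L) {
    stopf("write_stat_table: empty statistics table")
  }
  cols <- c("metabolite", "contrast", "statistic", "p", "q", "fold_change",
            "direction", "is_uremic_solute")
  missing_cols <- setdiff(cols, names(rows))
  if (length(missing_cols)) {
    stopf("write_stat_table: missing column(s) %s",
          paste(missing_cols, collapse = ", "))
  }
  out <- rows[, cols]
  for (nm in c("statistic", "p", "q", "fold_change")) {
    out[[nm]] <- fmt_num(out[[nm]])
  }
  out$is_uremic_solute <- as.integer(out$is_uremic_solute)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read back a statistics table written by [write_stat_table()]
#' @param path CSV path.
#' @return Data frame with typed columns.
#' @export
read_stat_table <- function(path) {
  df <- read_delim_checked(path, "statistics table")
  for (nm in c("statistic", "p", "q", "fold_change")) df[[nm]] <- as.numeric(df[[nm]])
  df$is_uremic_solute <- as.logical(as.integer(df$is_uremic_solute))
  df
}

#' Write cohort ground truth to CSV
#' @param truth A `cohort_truth` object from [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  df <- data.frame(
    metabolite = names(truth$region),
    region = unname(truth$region),
    cleared_by_hd = as.integer(names(truth$region) %in% truth$cleared_by_hd),
    cleared_by_hfd = as.integer(names(truth$region) %in% truth$cleared_by_hfd),
    high_rsd = as.integer(names(truth$region) %in% truth$high_rsd),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
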