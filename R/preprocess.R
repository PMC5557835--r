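# The data-reduction chain applied before any statistics:
# 80% rule -> internal-standard normalization -> QC RSD filter ->
# half-minimum imputation -> unit-variance scaling.

#' Missing-value filter (the "80% rule")
#'
#' Keeps a metabolite iff its non-missing fraction is at least `threshold`
#' (inclusive) within at least one non-QC study group, the per-group variant
#' of the rule: a metabolite reliably detected in one group is kept even
#' when undetectable elsewhere, which is exactly the pattern detection-limit
#' censoring produces for disease-specific compounds. Internal-standard
#' columns are always kept; sample rows are unchanged.
#'
#' @param tab A `metabolite_table` with at least one non-QC study group.
#' @param threshold Minimum non-missing fraction, default 0.8.
#' @return List with `table` (filtered) and `dropped` (character vector of
#'   removed metabolite names). An empty result is allowed.
#' @export
eighty_percent_rule <- function(tab, threshold = 0.8) {
  validate_metabolite_table(tab)
  groups <- intersect(STUDY_GROUPS, unique(tab$sample_meta$group))
  if (!length(groups)) stopf("eighty_percent_rule: no non-QC study group present")
  x <- tab$intensities
  keep <- tab$metabolite_meta$is_internal_standard
  for (g in groups) {
    rows <- group_rows(tab, g)
    frac <- colMeans(!is.na(x[rows, , drop = FALSE]))
    keep <- keep | (frac >= threshold)
  }
  dropped <- tab$metabolite_meta$name[!keep]
  list(table = subset_table(tab, metabolites = which(keep)), dropped = dropped)
}

#' Internal-standard normalization
#'
#' Divides every intensity by the same-sample internal-standard intensity of
#' the matching ion mode, removing per-sample instrument response drift.
#' Each ion mode must have exactly one designated internal-standard column
#' with strictly positive, non-missing values in every sample. The IS
#' columns are removed from the returned table. Missing entries stay
#' missing.
#'
#' @param tab A `metabolite_table` carrying its internal standards.
#' @return The normalized `metabolite_table` without IS columns.
#' @export
normalize_by_is <- function(tab) {
  validate_metabolite_table(tab)
  mm <- tab$metabolite_meta
  x <- tab$intensities
  modes <- unique(mm$ion_mode[!mm$is_internal_standard])
  for (mode in modes) {
    is_col <- which(mm$is_internal_standard & mm$ion_mode == mode)
    if (length(is_col) != 1L) {
      stopf("normalize_by_is: ion mode '%s' has %d internal-standard columns, need exactly 1",
            mode, length(is_col))
    }
    is_val <- x[, is_col]
    bad <- which(is.na(is_val) | is_val <= 0)
    if (length(bad)) {
      stopf("normalize_by_is: internal standard '%s' missing or nonpositive in sample '%s'",
            mm$name[is_col], tab$sample_meta$sample_id[bad[1L]])
    }
    target <- which(!mm$is_internal_standard & mm$ion_mode == mode)
    x[, target] <- x[, target, drop = FALSE] / is_val
  }
  tab$intensities <- x
  subset_table(tab, metabolites = which(!mm$is_internal_standard))
}

#' Per-metabolite QC relative standard deviation
#'
#' RSD% = 100 * sample SD / mean over the QC injections, computed on
#' non-missing QC entries (n - 1 denominator).
#'
#' @param tab A `metabolite_table` with QC samples.
#' @return Named numeric vector of RSD percentages (`NA` when fewer than two
#'   QC values are present or the QC mean is zero).
#' @export
qc_rsd <- function(tab) {
  qc <- tab$intensities[group_rows(tab, "qc"), , drop = FALSE]
  mu <- colMeans(qc, na.rm = TRUE)
  sd_ <- apply(qc, 2L, stats::sd, na.rm = TRUE)
  rsd <- ifelse(is.na(mu) | is.nan(mu) | mu == 0 | is.na(sd_), NA_real_,
                100 * sd_ / mu)
  stats::setNames(rsd, tab$metabolite_meta$name)
}

#' QC-based analytical reliability filter
#'
#' Keeps metabolites whose QC RSD% is strictly below `threshold_pct`.
#' Metabolites whose QC mean is zero or whose RSD cannot be computed are
#' dropped. Expects IS-normalized data and at least 3 QC samples.
#'
#' @param tab An IS-normalized `metabolite_table` with >= 3 QC samples.
#' @param threshold_pct RSD threshold in percent, default 30.
#' @return List with `table` (filtered), `rsd` (per-metabolite RSD% on the
#'   input), `fraction_below` (fraction of input metabolites with RSD% <
#'   `threshold_pct`) and `dropped` (names).
#' @export
qc_rsd_filter <- function(tab, threshold_pct = 30) {
  validate_metabolite_table(tab)
  n_qc <- length(group_rows(tab, "qc"))
  if (n_qc < 3L) {
    stopf("qc_rsd_filter: need at least 3 QC samples, found %d", n_qc)
  }
  rsd <- qc_rsd(tab)
  keep <- !is.na(rsd) & rsd < threshold_pct
  list(table = subset_table(tab, metabolites = which(keep)),
       rsd = rsd,
       fraction_below = mean(keep),
       dropped = tab$metabolite_meta$name[!keep])
}

#' Half-minimum imputation
#'
#' Replaces each remaining missing entry by half the minimum observed value
#' of that metabolite across all samples — the conventional stand-in for a
#' value censored at the detection limit. Run after the 80% rule so no
#' metabolite is mostly imputed.
#'
#' @param tab A `metabolite_table`.
#' @return The completed `metabolite_table`.
#' @export
impute_half_minimum <- function(tab) {
  validate_metabolite_table(tab)
  x <- tab$intensities
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) {
      if (all(miss)) {
        stopf("impute_half_minimum: metabolite '%s' has no observed values (should have been filtered)",
              tab$metabolite_meta$name[j])
      }
      x[miss, j] <- min(x[, j], na.rm = TRUE) / 2
    }
  }
  tab$intensities <- x
  tab
}

#' Unit-variance (UV) scaling
#'
#' Centres every column to mean 0 and scales it to sample SD 1, putting
#' metabolites of very different absolute abundance on a comparable scale
#' for PCA and SVM. The returned means and SDs allow the inverse transform.
#'
#' @param x Complete numeric matrix (no missing entries).
#' @return List with `x` (scaled matrix), `center` and `scale` (per-column
#'   mean and sample SD).
#' @export
uv_scale <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stopf("uv_scale: matrix contains missing values")
  ctr <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  zero <- which(sds == 0)
  if (length(zero)) {
    stopf("uv_scale: column '%s' has zero standard deviation",
          (colnames(x) %||% as.character(seq_len(ncol(x))))[zero[1L]])
  }
  xs <- sweep(sweep(x, 2L, ctr), 2L, sds, "/")
  list(x = xs, center = ctr, scale = sds)
}

#' Run the full preprocessing chain
#'
#' 80% rule, internal-standard normalization and QC RSD filtering in the
#' fixed order of the pipeline, with a report of what was removed at each
#' step. Imputation and scaling are left to the caller because the
#' univariate stage works on the unimputed, unscaled normalized table.
#'
#' @param tab A raw `metabolite_table` (with internal standards and QC
#'   samples).
#' @param missing_threshold Non-missing fraction for [eighty_percent_rule()].
#' @param rsd_threshold_pct QC RSD threshold for [qc_rsd_filter()].
#' @return List with `table` (normalized, filtered) and `report` (a
#'   `preprocess_report`).
#' @export
preprocess <- function(tab, missing_threshold = 0.8, rsd_threshold_pct = 30) {
  n_input <- sum(!tab$metabolite_meta$is_internal_standard)
  step1 <- eighty_percent_rule(tab, missing_threshold)
  n_after_80 <- sum(!step1$table$metabolite_meta$is_internal_standard)
  is_names <- tab$metabolite_meta$name[tab$metabolite_meta$is_internal_standard]
  normed <- normalize_by_is(step1$table)
  step2 <- qc_rsd_filter(normed, rsd_threshold_pct)

  dropped <- c(stats::setNames(rep("missingness", length(step1$dropped)), step1$dropped),
               stats::setNames(rep("is_internal_standard", length(is_names)), is_names),
               stats::setNames(rep("rsd", length(step2$dropped)), step2$dropped))
  report <- structure(list(
    n_input_metabolites = n_input,
    n_after_80_rule = n_after_80,
    n_after_rsd = n_metabolites(step2$table),
    rsd_per_metabolite = step2$rsd,
    fraction_below_30 = step2$fraction_below,
    dropped = dropped),
    class = "preprocess_report")
  list(table = step2$table, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("Preprocessing report\n")
  cat(sprintf("  metabolites in:            %d\n", x$n_input_metabolites))
  cat(sprintf("  after 80%% rule:            %d\n", x$n_after_80_rule))
  cat(sprintf("  after QC RSD filter:       %d\n", x$n_after_rsd))
  cat(sprintf("  QC RSD < threshold:        %.1f%% of metabolites\n",
              100 * x$fraction_below_30))
  invisible(x)
}

#' Write a preprocessing report to CSV
#' @param report A `preprocess_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  rsd <- report$rsd_per_metabolite
  df <- data.frame(metabolite = names(rsd),
                   qc_rsd_pct = unname(rsd),
                   dropped_reason = ifelse(
                     names(rsd) %in% names(report$dropped),
                     report$dropped[names(rsd)], ""),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
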