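# The MetaboliteTable container: a samples x metabolites intensity matrix
# with sample and metabolite sidecar metadata. This is the single object
# that flows through the whole pipeline.

#' Study group labels
#'
#' The five study groups of the paired dialysis design plus the pooled
#' quality-control (QC) injections.
#' @export
GROUP_LEVELS <- c("control", "pre_hd", "post_hd", "pre_hfd", "post_hfd", "qc")

#' Non-QC study groups
#' @export
STUDY_GROUPS <- c("control", "pre_hd", "post_hd", "pre_hfd", "post_hfd")

#' Construct a MetaboliteTable
#'
#' Bundles a nonnegative intensity matrix (rows = samples, columns =
#' metabolites; missing entries are `NA`) with per-sample and per-metabolite
#' metadata and validates the result.
#'
#' @param intensities Numeric matrix, samples in rows, metabolites in
#'   columns. Values must be nonnegative where present; `NA` marks a
#'   missing (undetected) entry. Missingness is first-class here: a value
#'   below the detection limit is absent, never recoded as 0.
#' @param sample_meta Data frame with columns `sample_id` (unique strings),
#'   `group` (one of [GROUP_LEVELS]) and `patient_id` (links the pre and
#'   post sample of one patient; empty string for control and QC samples).
#' @param metabolite_meta Data frame with columns `name` (unique strings),
#'   `is_uremic_solute` (logical), `is_internal_standard` (logical) and
#'   `ion_mode` (`"pos"` or `"neg"`).
#' @return An object of class `metabolite_table`.
#' @examples
#' tab <- metabolite_table(
#'   matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(NULL, c("m1", "m2"))),
#'   data.frame(sample_id = c("s1", "s2"), group = c("control", "control"),
#'              patient_id = c("", "")),
#'   data.frame(name = c("m1", "m2"), is_uremic_solute = FALSE,
#'              is_internal_standard = FALSE, ion_mode = "pos"))
#' n_samples(tab)
#' @export
metabolite_table <- function(intensities, sample_meta, metabolite_meta) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  metabolite_meta <- as.data.frame(metabolite_meta, stringsAsFactors = FALSE)
  rownames(intensities) <- sample_meta$sample_id
  colnames(intensities) <- metabolite_meta$name
  tab <- structure(
    list(intensities = intensities,
         sample_meta = sample_meta,
         metabolite_meta = metabolite_meta),
    class = "metabolite_table")
  validate_metabolite_table(tab)
  tab
}

#' Validate a MetaboliteTable
#'
#' Checks the container invariants: matching dimensions, known group
#' labels, nonnegative intensities and one-to-one pre/post pairing via
#' `patient_id` within each therapy. Errors name the violated invariant.
#'
#' @param tab A `metabolite_table`.
#' @return `tab`, invisibly, if valid.
#' @export
validate_metabolite_table <- function(tab) {
  stopifnot(inherits(tab, "metabolite_table"))
  x <- tab$intensities
  sm <- tab$sample_meta
  mm <- tab$metabolite_meta

  req_s <- c("sample_id", "group", "patient_id")
  if (!all(req_s %in% names(sm))) {
    stopf("sample_meta must have columns %s", paste(req_s, collapse = ", "))
  }
  req_m <- c("name", "is_uremic_solute", "is_internal_standard", "ion_mode")
  if (!all(req_m %in% names(mm))) {
    stopf("metabolite_meta must have columns %s", paste(req_m, collapse = ", "))
  }
  if (nrow(x) != nrow(sm)) {
    stopf("dimension mismatch: intensity matrix has %d rows but sample_meta has %d",
          nrow(x), nrow(sm))
  }
  if (ncol(x) != nrow(mm)) {
    stopf("dimension mismatch: intensity matrix has %d columns but metabolite_meta has %d rows",
          ncol(x), nrow(mm))
  }
  if (anyDuplicated(sm$sample_id)) stopf("invariant violated: duplicate sample_id")
  if (anyDuplicated(mm$name)) stopf("invariant violated: duplicate metabolite name")
  bad_group <- setdiff(unique(as.character(sm$group)), GROUP_LEVELS)
  if (length(bad_group)) {
    stopf("unknown group label: %s", paste(bad_group, collapse = ", "))
  }
  bad_mode <- setdiff(unique(as.character(mm$ion_mode)), c("pos", "neg"))
  if (length(bad_mode)) {
    stopf("unknown ion_mode: %s", paste(bad_mode, collapse = ", "))
  }
  neg <- which(!is.na(x) & x < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stopf("invariant violated: negative intensity at row %d (sample '%s'), column %d (metabolite '%s')",
          neg[1, 1], sm$sample_id[neg[1, 1]], neg[1, 2], mm$name[neg[1, 2]])
  }
  # pre/post pairing: every pre_* patient has exactly one post_* sample of
  # the same therapy, and vice versa
  for (therapy in c("hd", "hfd")) {
    pre <- sm$patient_id[sm$group == paste0("pre_", therapy)]
    post <- sm$patient_id[sm$group == paste0("post_", therapy)]
    if (anyDuplicated(pre) || anyDuplicated(post)) {
      stopf("invariant violated: duplicated patient_id within a %s group", therapy)
    }
    if (!setequal(pre, post)) {
      stopf("invariant violated: unpaired pre/post %s samples for patient(s) %s",
            therapy,
            paste(union(setdiff(pre, post), setdiff(post, pre)), collapse = ", "))
    }
  }
  invisible(tab)
}

#' @export
print.metabolite_table <- function(x, ...) {
  grp <- table(factor(x$sample_meta$group, levels = GROUP_LEVELS))
  cat(sprintf("MetaboliteTable: %d samples x %d metabolites\n",
              nrow(x$intensities), ncol(x$intensities)))
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  cat(sprintf("  missing entries: %d (%.1f%%)\n", sum(is.na(x$intensities)),
              100 * mean(is.na(x$intensities))))
  cat(sprintf("  internal standards: %d; uremic solutes flagged: %d\n",
              sum(x$metabolite_meta$is_internal_standard),
              sum(x$metabolite_meta$is_uremic_solute)))
  invisible(x)
}

#' Number of samples / metabolites in a MetaboliteTable
#' @param tab A `metabolite_table`.
#' @return Integer count.
#' @export
n_samples <- function(tab) nrow(tab$intensities)

#' @rdname n_samples
#' @export
n_metabolites <- function(tab) ncol(tab$intensities)

#' Subset a MetaboliteTable
#'
#' @param tab A `metabolite_table`.
#' @param samples Logical or integer index over rows, or character sample ids.
#' @param metabolites Logical or integer index over columns, or character
#'   metabolite names.
#' @return The subset `metabolite_table`.
#' @export
subset_table <- function(tab, samples = NULL, metabolites = NULL) {
  si <- seq_len(n_samples(tab))
  mi <- seq_len(n_metabolites(tab))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, tab$sample_meta$sample_id) else si[samples]
  }
  if (!is.null(metabolites)) {
    mi <- if (is.character(metabolites)) match(metabolites, tab$metabolite_meta$name) else mi[metabolites]
  }
  if (anyNA(si)) stopf("unknown sample id in subset")
  if (anyNA(mi)) stopf("unknown metabolite name in subset")
  tab$intensities <- tab$intensities[si, mi, drop = FALSE]
  tab$sample_meta <- tab$sample_meta[si, , drop = FALSE]
  rownames(tab$sample_meta) <- NULL
  tab$metabolite_meta <- tab$metabolite_meta[mi, , drop = FALSE]
  rownames(tab$metabolite_meta) <- NULL
  tab
}

#' Rows belonging to a study group
#' @param tab A `metabolite_table`.
#' @param group A group label from [GROUP_LEVELS].
#' @return Integer row indices.
#' @export
group_rows <- function(tab, group) {
  group <- match.arg(group, GROUP_LEVELS)
  which(tab$sample_meta$group == group)
}

#' A two-group contrast between study groups
#'
#' The six contrasts of the study design compare each patient group to
#' control (unpaired) and post- to pre-dialysis within a therapy (paired,
#' linked by `patient_id`). Fold changes are reported as
#' `mean(side_a) / mean(side_b)`.
#'
#' @param name Contrast label used in output tables.
#' @param side_a,side_b Group labels from [STUDY_GROUPS].
#' @param paired Logical; must be `TRUE` exactly when both sides are the
#'   pre and post group of the same therapy.
#' @return An object of class `group_contrast`.
#' @export
group_contrast <- function(name, side_a, side_b, paired = FALSE) {
  side_a <- match.arg(side_a, STUDY_GROUPS)
  side_b <- match.arg(side_b, STUDY_GROUPS)
  same_therapy <- function(a, b) {
    (a == "post_hd" && b == "pre_hd") || (a == "pre_hd" && b == "post_hd") ||
      (a == "post_hfd" && b == "pre_hfd") || (a == "pre_hfd" && b == "post_hfd")
  }
  if (paired != same_therapy(side_a, side_b)) {
    stopf("contrast '%s': paired must be TRUE exactly for pre/post of one therapy",
          name)
  }
  structure(list(name = name, side_a = side_a, side_b = side_b,
                 paired = paired),
            class = "group_contrast")
}

#' The six study contrasts
#'
#' Post-vs-pre within each therapy (paired t test) and each patient group
#' vs control (Mann-Whitney U test). Patient groups are side A so fold
#' changes read as patient/control; paired contrasts are post/pre so a
#' cleared metabolite has fold change below 1.
#'
#' @return A named list of [group_contrast()] objects.
#' @export
default_contrasts <- function() {
  list(
    post_hd_vs_pre_hd = group_contrast("post_hd_vs_pre_hd", "post_hd", "pre_hd", paired = TRUE),
    post_hfd_vs_pre_hfd = group_contrast("post_hfd_vs_pre_hfd", "post_hfd", "pre_hfd", paired = TRUE),
    pre_hd_vs_control = group_contrast("pre_hd_vs_control", "pre_hd", "control"),
    pre_hfd_vs_control = group_contrast("pre_hfd_vs_control", "pre_hfd", "control"),
    post_hd_vs_control = group_contrast("post_hd_vs_control", "post_hd", "control"),
    post_hfd_vs_control = group_contrast("post_hfd_vs_control", "post_hfd", "control")
  )
}
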