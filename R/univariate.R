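# Per-metabolite univariate analysis: Mann-Whitney U for patient-vs-control
# contrasts, paired t for post-vs-pre contrasts, Benjamini-Hochberg FDR per
# contrast, fold changes on IS-normalized (unscaled) intensities, ratio
# features, change-pattern region classification and the HD/HFD clearance
# comparison.

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from midrank sums. The two-sided p value is exact (via the
#' null distribution of U) when `length(a) + length(b) <= 12` and there are
#' no ties, and otherwise uses the normal approximation with tie correction
#' and continuity correction — the convention of mainstream statistics
#' packages. When all observations are tied the statistic carries no
#' information and p = 1.
#'
#' @param a,b Non-empty numeric vectors; `NA`s are removed.
#' @return List with `U` (statistic for sample `a`) and `p`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stopf("mann_whitney_u: empty sample")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (n <= 12L && !has_ties) {
    p_low <- stats::pwilcox(u, na, nb)
    p_high <- 1 - stats::pwilcox(u - 1, na, nb)
    p <- min(1, 2 * min(p_low, p_high))
  } else {
    mu <- na * nb / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U = u, p = p)
}

#' Paired t test on pre/post differences
#'
#' Aligns pre to post samples by patient id, drops pairs with a missing
#' member, and tests `d = pre - post` against zero. When every difference
#' is zero the metabolite is flat and p = 1 by convention; a constant
#' nonzero difference is degenerate and raises an error.
#'
#' @param pre,post Numeric vectors.
#' @param pre_ids,post_ids Patient ids aligning the two vectors (defaults
#'   to `names(pre)` / `names(post)`).
#' @return List with `t`, `p`, `df`, `n_pairs` (complete pairs used) and
#'   `n_excluded` (pairs dropped for missingness).
#' @export
paired_t <- function(pre, post, pre_ids = names(pre), post_ids = names(post)) {
  if (is.null(pre_ids) || is.null(post_ids)) {
    if (length(pre) != length(post)) {
      stopf("paired_t: unnamed vectors must have equal length")
    }
    pre_ids <- post_ids <- as.character(seq_along(pre))
  }
  idx <- match(pre_ids, post_ids)
  if (anyNA(idx)) {
    stopf("paired_t: patient id(s) %s have no post sample",
          paste(pre_ids[is.na(idx)], collapse = ", "))
  }
  d <- pre - post[idx]
  n_excluded <- sum(is.na(d))
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 3L) stopf("paired_t: need at least 3 complete pairs, have %d", n)
  sd_d <- stats::sd(d)
  m_d <- mean(d)
  if (sd_d == 0) {
    if (m_d == 0) {
      return(list(t = 0, p = 1, df = n - 1L, n_pairs = n,
                  n_excluded = n_excluded))
    }
    stopf("paired_t: constant nonzero difference (%.6g); degenerate input", m_d)
  }
  t_stat <- m_d / (sd_d / sqrt(n))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df = n - 1),
       df = n - 1L, n_pairs = n, n_excluded = n_excluded)
}

#' Benjamini-Hochberg adjusted q values
#'
#' Step-up FDR adjustment returning q values in input order (ties share a
#' q value; results capped at 1).
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @return Numeric vector of q values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stopf("bh_fdr: p values must lie in [0, 1] and be non-missing")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Fold change between two groups
#'
#' Ratio of the arithmetic group means of IS-normalized, unscaled
#' intensities (`mean(side_a) / mean(side_b)`), the convention under which
#' printed group means reproduce printed fold changes. Satisfies
#' `fold_change(a, b) * fold_change(b, a) = 1`.
#'
#' @param side_a,side_b Numeric vectors (`NA`s ignored).
#' @return Positive scalar.
#' @export
fold_change <- function(side_a, side_b) {
  ma <- mean(side_a, na.rm = TRUE)
  mb <- mean(side_b, na.rm = TRUE)
  if (!is.finite(ma) || !is.finite(mb) || ma <= 0 || mb <= 0) {
    stopf("fold_change: group means must be positive (got %.6g and %.6g)", ma, mb)
  }
  ma / mb
}

#' Per-sample metabolite ratio feature
#'
#' Element-wise ratio of two metabolite columns on IS-normalized
#' intensities (e.g. glutamate/glutamine as a glutaminase proxy,
#' tryptophan/kynurenine for indoleamine 2,3-dioxygenase). The ratio is
#' missing where either member is missing or the denominator is
#' nonpositive; the number of such undefined samples is attached as
#' attribute `n_undefined`.
#'
#' @param tab A `metabolite_table` (after preprocessing).
#' @param numerator,denominator Metabolite names present in `tab`.
#' @return Named numeric vector (one entry per sample).
#' @export
ratio_feature <- function(tab, numerator, denominator) {
  nm <- tab$metabolite_meta$name
  for (m in c(numerator, denominator)) {
    if (!m %in% nm) stopf("ratio_feature: metabolite '%s' not in table", m)
  }
  num <- tab$intensities[, match(numerator, nm)]
  den <- tab$intensities[, match(denominator, nm)]
  bad_den <- !is.na(den) & den <= 0
  ratio <- ifelse(is.na(num) | is.na(den) | bad_den, NA_real_, num / den)
  names(ratio) <- tab$sample_meta$sample_id
  attr(ratio, "n_undefined") <- sum(is.na(ratio))
  ratio
}

#' Univariate statistics for one contrast
#'
#' For every metabolite, runs the Mann-Whitney U test (unpaired contrasts)
#' or the paired t test (post-vs-pre contrasts, aligned by patient id),
#' adjusts p values by Benjamini-Hochberg across all metabolites of the
#' contrast, and computes the fold change `mean(side_a) / mean(side_b)`.
#' A metabolite is significant when both raw p and q fall below their
#' limits; its direction is `up`/`down` by fold change when significant,
#' otherwise `flat`.
#'
#' @param tab An IS-normalized (unscaled) `metabolite_table`.
#' @param contrast A [group_contrast()].
#' @param alpha Raw p-value limit, default 0.05.
#' @param fdr q-value limit, default 0.05.
#' @return Data frame of per-metabolite rows: `metabolite`, `contrast`,
#'   `statistic`, `p`, `q`, `fold_change`, `direction`,
#'   `is_uremic_solute`, `significant`.
#' @export
test_contrast <- function(tab, contrast, alpha = 0.05, fdr = 0.05) {
  stopifnot(inherits(contrast, "group_contrast"))
  rows_a <- group_rows(tab, contrast$side_a)
  rows_b <- group_rows(tab, contrast$side_b)
  if (!length(rows_a) || !length(rows_b)) {
    stopf("test_contrast '%s': group '%s' or '%s' has no samples",
          contrast$name, contrast$side_a, contrast$side_b)
  }
  x <- tab$intensities
  m <- n_metabolites(tab)
  stat <- p <- fc <- numeric(m)
  ids_a <- tab$sample_meta$patient_id[rows_a]
  ids_b <- tab$sample_meta$patient_id[rows_b]
  for (j in seq_len(m)) {
    va <- x[rows_a, j]
    vb <- x[rows_b, j]
    if (contrast$paired) {
      res <- paired_t(stats::setNames(va, ids_a), stats::setNames(vb, ids_b))
      stat[j] <- res$t
    } else {
      res <- mann_whitney_u(va, vb)
      stat[j] <- res$U
    }
    p[j] <- res$p
    fc[j] <- fold_change(va, vb)
  }
  q <- bh_fdr(p)
  significant <- p < alpha & q < fdr
  direction <- ifelse(!significant, "flat", ifelse(fc > 1, "up", "down"))
  data.frame(metabolite = tab$metabolite_meta$name,
             contrast = contrast$name,
             statistic = stat, p = p, q = q, fold_change = fc,
             direction = direction,
             is_uremic_solute = tab$metabolite_meta$is_uremic_solute,
             significant = significant,
             stringsAsFactors = FALSE)
}

#' Classify metabolites into the four change-pattern regions
#'
#' Formalizes the heat-map regions of the five-group design from the six
#' contrast results. With `sig` meaning significant at the global rule
#' (p < alpha and q < fdr):
#' region `C` — accumulated pre-dialysis and cleared: pre-vs-control
#' significant with fold change > 1 in both therapies AND post-vs-pre a
#' significant decrease in both therapies; region `A` — rises after
#' dialysis: post-vs-pre a significant increase in both therapies AND
#' pre-vs-control fold change <= 1 in both; region `B` — low in patients:
#' all four patient-vs-control contrasts significant with fold change < 1;
#' region `D` — anything else (stable).
#'
#' @param stat_rows Data frame combining [test_contrast()] results for the
#'   six default contrasts (rbind of the six tables).
#' @return Named character vector (metabolite -> region).
#' @export
classify_region <- function(stat_rows) {
  need <- names(default_contrasts())
  have <- unique(stat_rows$contrast)
  if (!all(need %in% have)) {
    stopf("classify_region: missing contrast(s): %s",
          paste(setdiff(need, have), collapse = ", "))
  }
  mets <- unique(stat_rows$metabolite)
  get <- function(contrast, col) {
    sub <- stat_rows[stat_rows$contrast == contrast, ]
    stats::setNames(sub[[col]], sub$metabolite)[mets]
  }
  sig <- lapply(stats::setNames(need, need), get, col = "significant")
  fc <- lapply(stats::setNames(need, need), get, col = "fold_change")

  dec_hd <- sig$post_hd_vs_pre_hd & fc$post_hd_vs_pre_hd < 1
  dec_hfd <- sig$post_hfd_vs_pre_hfd & fc$post_hfd_vs_pre_hfd < 1
  inc_hd <- sig$post_hd_vs_pre_hd & fc$post_hd_vs_pre_hd > 1
  inc_hfd <- sig$post_hfd_vs_pre_hfd & fc$post_hfd_vs_pre_hfd > 1
  pre_up <- sig$pre_hd_vs_control & fc$pre_hd_vs_control > 1 &
    sig$pre_hfd_vs_control & fc$pre_hfd_vs_control > 1
  pre_not_up <- fc$pre_hd_vs_control <= 1 & fc$pre_hfd_vs_control <= 1
  all_low <- sig$pre_hd_vs_control & fc$pre_hd_vs_control < 1 &
    sig$pre_hfd_vs_control & fc$pre_hfd_vs_control < 1 &
    sig$post_hd_vs_control & fc$post_hd_vs_control < 1 &
    sig$post_hfd_vs_control & fc$post_hfd_vs_control < 1

  region <- rep("D", length(mets))
  region[all_low] <- "B"
  region[inc_hd & inc_hfd & pre_not_up] <- "A"
  region[pre_up & dec_hd & dec_hfd] <- "C"
  stats::setNames(region, mets)
}

#' Uremic-solute clearance comparison between HD and HFD
#'
#' From the paired post-vs-pre results of the two therapies, collects the
#' uremic retention solutes significantly decreased by each therapy
#' (significant with fold change post/pre below 1), their intersection, and
#' the solutes cleared only by high-flux dialysis.
#'
#' @param stat_hd,stat_hfd [test_contrast()] results for the HD and HFD
#'   post-vs-pre contrasts, on the same metabolite set.
#' @return An object of class `clearance_report` with sets `decreased_hd`,
#'   `decreased_hfd`, `common`, `hfd_only` and a `counts` vector (including
#'   the number of significant metabolites overall per therapy).
#' @export
clearance_sets <- function(stat_hd, stat_hfd) {
  if (!setequal(stat_hd$metabolite, stat_hfd$metabolite)) {
    diff <- c(setdiff(stat_hd$metabolite, stat_hfd$metabolite),
              setdiff(stat_hfd$metabolite, stat_hd$metabolite))
    stopf("clearance_sets: metabolite sets differ between therapies: %s",
          paste(diff, collapse = ", "))
  }
  decreased <- function(s) {
    s$metabolite[s$is_uremic_solute & s$significant & s$fold_change < 1]
  }
  dec_hd <- decreased(stat_hd)
  dec_hfd <- decreased(stat_hfd)
  structure(list(
    decreased_hd = dec_hd,
    decreased_hfd = dec_hfd,
    common = intersect(dec_hd, dec_hfd),
    hfd_only = setdiff(dec_hfd, dec_hd),
    counts = c(n_significant_hd = sum(stat_hd$significant),
               n_significant_hfd = sum(stat_hfd$significant),
               n_decreased_solutes_hd = length(dec_hd),
               n_decreased_solutes_hfd = length(dec_hfd),
               n_common = length(intersect(dec_hd, dec_hfd)),
               n_hfd_only = length(setdiff(dec_hfd, dec_hd)))),
    class = "clearance_report")
}

#' @export
print.clearance_report <- function(x, ...) {
  cat("Uremic-solute clearance comparison\n")
  cat(sprintf("  significant metabolites: HD %d, HFD %d\n",
              x$counts["n_significant_hd"], x$counts["n_significant_hfd"]))
  cat(sprintf("  solutes decreased: HD %d, HFD %d (common %d)\n",
              x$counts["n_decreased_solutes_hd"],
              x$counts["n_decreased_solutes_hfd"], x$counts["n_common"]))
  cat(sprintf("  cleared by HFD only (%d): %s\n", x$counts["n_hfd_only"],
              if (length(x$hfd_only)) paste(x$hfd_only, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Volcano-plot table for one contrast
#'
#' The data behind a volcano plot: log2 fold change against -log10 p, with
#' q values and the uremic-solute flag.
#'
#' @param stat_rows A [test_contrast()] result.
#' @return Data frame with columns `metabolite`, `log2_fc`, `neg_log10_p`,
#'   `q`, `is_uremic_solute`, `contrast`.
#' @export
volcano_table <- function(stat_rows) {
  data.frame(metabolite = stat_rows$metabolite,
             log2_fc = log2(stat_rows$fold_change),
             neg_log10_p = -log10(pmax(stat_rows$p, .Machine$double.xmin)),
             q = stat_rows$q,
             is_uremic_solute = stat_rows$is_uremic_solute,
             contrast = stat_rows$contrast,
             stringsAsFactors = FALSE)
}
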