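# Synthetic cohort generator. Emulates the paired five-group dialysis
# design (control, pre/post low-flux HD, pre/post high-flux HFD, pooled QC)
# with a log-normal multiplicative intensity model and planted ground truth,
# so every downstream stage of the pipeline has a recoverable target.

# names used for planted solutes so that pipeline outputs read like a
# metabolomics study; the eleven high-flux-only cleared solutes are typical
# small uremic retention solutes
HFD_ONLY_SOLUTE_NAMES <- c(
  "guanidine", "hippuric acid", "cis-aconitic acid", "quinic acid",
  "citramalic acid", "asparagine", "ornithine", "methionine sulfoxide",
  "choline", "trigonelline", "orotidine")
NAMED_REGION_C <- c("urea", "creatinine", "glutamate", "kynurenine")
NAMED_REGION_B <- "tryptophan"
NAMED_REGION_D <- "glutamine"

#' Configuration of a synthetic dialysis cohort
#'
#' Defaults reproduce the study geometry: 47 healthy controls, 85 HD and 42
#' HFD patients each sampled before and after one dialysis session (301
#' study samples), 38 pooled QC injections, 160 metabolites of which 55 are
#' uremic retention solutes (11 cleared only by high-flux dialysis) and 16
#' carry inflated analytical noise so the QC RSD filter has work to do,
#' leaving about 144 reliable metabolites.
#'
#' @param n_control,n_hd_patients,n_hfd_patients,n_qc Cohort sizes. Each HD/
#'   HFD patient contributes a pre- and a post-dialysis sample.
#' @param n_metabolites Number of metabolites, excluding the two internal
#'   standards that are always added (one per ion mode).
#' @param region_fractions Named fractions (regions `A`, `B`, `C`, `D`) of
#'   metabolites per change-pattern region; must sum to 1. Region A rises
#'   after dialysis and is low in patients pre-dialysis; region B is high in
#'   controls only; region C accumulates pre-dialysis and is cleared by
#'   dialysis; region D is flat.
#' @param n_uremic_solutes Number of metabolites flagged as uremic retention
#'   solutes; placed in region C (spilling into region D if region C is
#'   smaller).
#' @param n_hfd_only_cleared How many solutes are cleared by HFD but not HD.
#' @param toxin_fc_pre_vs_control Planted fold change of region-C
#'   metabolites in pre-dialysis groups relative to control.
#' @param clearance_fc_post_vs_pre Multiplicative post/pre factor applied by
#'   a clearing therapy to region-C solutes; in (0, 1).
#' @param hfd_only_extra_clearance Additional post/pre factor applied to
#'   HFD-only solutes under HFD; in (0, 1). Under HD these solutes are not
#'   cleared at all.
#' @param analytical_cv Analytical (injection-to-injection) log-scale SD;
#'   0.15 keeps QC RSDs near 15%, well under the 30% filter.
#' @param biological_cv Between-subject log-scale SD; a patient's pre and
#'   post samples share one draw so the paired design is honoured.
#' @param missing_rate_low_group Probability that an entry is censored
#'   (missing) in the group(s) where a metabolite's expected level is lowest;
#'   mimics detection-limit censoring, which is what the 80% rule targets.
#'   Flat metabolites have no lowest group and receive no missingness.
#' @param n_high_rsd_metabolites Number of metabolites given inflated
#'   analytical noise (log-SD 0.5, QC RSD ~53%) so they fail the 30% RSD
#'   filter. Drawn from non-solute metabolites so the planted clearance
#'   panel stays analytically reliable.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 47L,
                          n_hd_patients = 85L,
                          n_hfd_patients = 42L,
                          n_qc = 38L,
                          n_metabolites = 160L,
                          region_fractions = c(A = 0.10, B = 0.15, C = 0.40, D = 0.35),
                          n_uremic_solutes = 55L,
                          n_hfd_only_cleared = 11L,
                          toxin_fc_pre_vs_control = 4.0,
                          clearance_fc_post_vs_pre = 0.45,
                          hfd_only_extra_clearance = 0.5,
                          analytical_cv = 0.15,
                          biological_cv = 0.30,
                          missing_rate_low_group = 0.25,
                          n_high_rsd_metabolites = 16L,
                          seed = 1L) {
  cfg <- list(n_control = as.integer(n_control),
              n_hd_patients = as.integer(n_hd_patients),
              n_hfd_patients = as.integer(n_hfd_patients),
              n_qc = as.integer(n_qc),
              n_metabolites = as.integer(n_metabolites),
              region_fractions = region_fractions,
              n_uremic_solutes = as.integer(n_uremic_solutes),
              n_hfd_only_cleared = as.integer(n_hfd_only_cleared),
              toxin_fc_pre_vs_control = toxin_fc_pre_vs_control,
              clearance_fc_post_vs_pre = clearance_fc_post_vs_pre,
              hfd_only_extra_clearance = hfd_only_extra_clearance,
              analytical_cv = analytical_cv,
              biological_cv = biological_cv,
              missing_rate_low_group = missing_rate_low_group,
              n_high_rsd_metabolites = as.integer(n_high_rsd_metabolites),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  counts <- c(cfg$n_control, cfg$n_hd_patients, cfg$n_hfd_patients, cfg$n_qc,
              cfg$n_metabolites, cfg$n_uremic_solutes, cfg$n_hfd_only_cleared,
              cfg$n_high_rsd_metabolites)
  if (any(counts < 0L)) stopf("cohort_config: all counts must be >= 0")
  rf <- cfg$region_fractions
  if (!setequal(names(rf), c("A", "B", "C", "D"))) {
    stopf("cohort_config: region_fractions must be named A, B, C, D")
  }
  if (any(rf < 0) || any(rf > 1)) stopf("cohort_config: region fractions must lie in [0, 1]")
  if (abs(sum(rf) - 1) > 1e-9) {
    stopf("cohort_config: region fractions sum to %.12f, not 1", sum(rf))
  }
  if (cfg$n_hfd_only_cleared > cfg$n_uremic_solutes ||
      cfg$n_uremic_solutes > cfg$n_metabolites) {
    stopf("cohort_config: need n_hfd_only_cleared <= n_uremic_solutes <= n_metabolites")
  }
  if (cfg$clearance_fc_post_vs_pre <= 0 || cfg$clearance_fc_post_vs_pre >= 1) {
    stopf("cohort_config: clearance_fc_post_vs_pre must lie in (0, 1)")
  }
  if (cfg$hfd_only_extra_clearance <= 0 || cfg$hfd_only_extra_clearance >= 1) {
    stopf("cohort_config: hfd_only_extra_clearance must lie in (0, 1)")
  }
  if (cfg$toxin_fc_pre_vs_control <= 0) {
    stopf("cohort_config: toxin_fc_pre_vs_control must be positive")
  }
  if (cfg$analytical_cv < 0 || cfg$biological_cv < 0) {
    stopf("cohort_config: noise levels must be >= 0")
  }
  if (cfg$missing_rate_low_group < 0 || cfg$missing_rate_low_group >= 1) {
    stopf("cohort_config: missing_rate_low_group must lie in [0, 1)")
  }
  invisible(cfg)
}

# integer region counts whose sum is exactly n (largest-remainder rounding)
region_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

# fixed log-scale group effects for regions A, B, D; region C is driven by
# the config fold changes. Free parameters of the generator (the study gives
# only the qualitative pattern): region A compounds sit slightly below
# control pre-dialysis and rise ~3.6-fold after dialysis; region B compounds
# run at half the control level in patients.
REGION_A_EFFECT <- c(control = log(0.35), pre = log(0.25), post = log(0.90))
REGION_B_PATIENT_EFFECT <- log(0.5)
HIGH_RSD_LOG_SD <- 0.5

# expected log-effect (relative to metabolite baseline) for one metabolite
# in each of the five study groups
group_log_effects <- function(region, is_hfd_only, cfg) {
  e <- c(control = 0, pre_hd = 0, post_hd = 0, pre_hfd = 0, post_hfd = 0)
  if (region == "A") {
    e["control"] <- REGION_A_EFFECT["control"]
    e[c("pre_hd", "pre_hfd")] <- REGION_A_EFFECT["pre"]
    e[c("post_hd", "post_hfd")] <- REGION_A_EFFECT["post"]
  } else if (region == "B") {
    e[c("pre_hd", "post_hd", "pre_hfd", "post_hfd")] <- REGION_B_PATIENT_EFFECT
  } else if (region == "C") {
    up <- log(cfg$toxin_fc_pre_vs_control)
    clear <- log(cfg$clearance_fc_post_vs_pre)
    e[c("pre_hd", "pre_hfd")] <- up
    if (is_hfd_only) {
      # cleared by high-flux dialysis only: HD leaves the level unchanged
      e["post_hd"] <- up
      e["post_hfd"] <- up + clear + log(cfg$hfd_only_extra_clearance)
    } else {
      e["post_hd"] <- up + clear
      e["post_hfd"] <- up + clear
    }
  }
  e
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws a [metabolite_table()] under a log-normal multiplicative model:
#' log intensity = log baseline + group effect (per region/therapy) +
#' subject random effect (shared by a patient's pre and post samples) +
#' analytical noise. QC samples are drawn around the pooled mean of all
#' study samples with analytical noise only. Two near-constant internal
#' standard columns (one per ion mode) are appended. Missingness is
#' injected at `missing_rate_low_group` in the group(s) where a
#' metabolite's expected level is lowest. Deterministic given
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `table` (the `metabolite_table`) and
#'   `truth` (a `cohort_truth`: per-metabolite `region`, planted
#'   fold-change matrix `planted_fc`, the solute sets `cleared_by_hd`,
#'   `cleared_by_hfd`, `hfd_only`, and the `high_rsd` set).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_control = 5, n_hd_patients = 4,
#'   n_hfd_patients = 3, n_qc = 4, n_metabolites = 20, n_uremic_solutes = 6,
#'   n_hfd_only_cleared = 2, n_high_rsd_metabolites = 2, seed = 7))
#' cohort$table
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  with_local_seed(cfg$seed, {
    m <- cfg$n_metabolites
    counts <- region_counts(cfg$region_fractions, m)
    region <- rep(names(counts), counts)
    region <- sample(region)            # shuffle region layout over columns

    # solutes occupy region C first, spilling into D if C is too small
    c_idx <- which(region == "C")
    d_idx <- which(region == "D")
    solute_idx <- c(c_idx, d_idx)[seq_len(min(cfg$n_uremic_solutes, m))]
    hfd_only_idx <- intersect(solute_idx, c_idx)
    hfd_only_idx <- hfd_only_idx[seq_len(min(cfg$n_hfd_only_cleared,
                                             length(hfd_only_idx)))]

    name <- sprintf("met_%03d", seq_len(m))
    name <- assign_curated_names(name, region, solute_idx, hfd_only_idx)

    # inflated-analytical-noise metabolites come from non-solute, unnamed
    # columns so the planted clearance panel and the ratio-pair anchors
    # (tryptophan, glutamine, ...) survive the RSD filter
    named_idx <- which(!grepl("^met_", name))
    high_rsd_pool <- setdiff(seq_len(m), union(solute_idx, named_idx))
    if (length(high_rsd_pool) < cfg$n_high_rsd_metabolites) {
      stopf("cohort_config: not enough non-solute metabolites (%d) for %d high-RSD metabolites",
            length(high_rsd_pool), cfg$n_high_rsd_metabolites)
    }
    high_rsd_idx <- sort(sample(high_rsd_pool, cfg$n_high_rsd_metabolites))
    log_sd_analytical <- rep(cfg$analytical_cv, m)
    log_sd_analytical[high_rsd_idx] <- HIGH_RSD_LOG_SD

    # per-metabolite expected log effect in each group
    effects <- matrix(0, nrow = 5L, ncol = m,
                      dimnames = list(STUDY_GROUPS, name))
    for (j in seq_len(m)) {
      effects[, j] <- group_log_effects(region[j], j %in% hfd_only_idx, cfg)
    }

    baseline <- exp(stats::rnorm(m, mean = log(100), sd = 1))

    sm <- build_sample_meta(cfg)
    study <- sm$group != "qc"
    n_study <- sum(study)

    # subject random effects: one draw per subject per metabolite, shared by
    # a patient's pre and post samples
    subj <- unique(sm$subject_id[study])
    u <- matrix(stats::rnorm(length(subj) * m, sd = cfg$biological_cv),
                nrow = length(subj), dimnames = list(subj, name))

    x <- matrix(NA_real_, nrow = nrow(sm), ncol = m,
                dimnames = list(sm$sample_id, name))
    noise_sd <- matrix(rep(log_sd_analytical, each = n_study), nrow = n_study)
    srow <- which(study)
    logx <- matrix(log(baseline), nrow = n_study, ncol = m, byrow = TRUE) +
      effects[match(sm$group[srow], STUDY_GROUPS), , drop = FALSE] +
      u[sm$subject_id[srow], , drop = FALSE] +
      matrix(stats::rnorm(n_study * m), nrow = n_study) * noise_sd
    x[srow, ] <- exp(logx)

    # detection-limit censoring in the lowest-expectation group(s)
    if (cfg$missing_rate_low_group > 0) {
      for (j in seq_len(m)) {
        ej <- effects[, j]
        if (max(ej) - min(ej) > 1e-12) {
          low_groups <- STUDY_GROUPS[ej <= min(ej) + 1e-12]
          rows <- srow[sm$group[srow] %in% low_groups]
          drop <- rows[stats::runif(length(rows)) < cfg$missing_rate_low_group]
          x[drop, j] <- NA_real_
        }
      }
    }

    # QC injections: pooled mean of all study samples, analytical noise only
    if (cfg$n_qc > 0L) {
      pooled <- colMeans(x[srow, , drop = FALSE], na.rm = TRUE)
      qrow <- which(!study)
      x[qrow, ] <- exp(
        matrix(log(pooled), nrow = cfg$n_qc, ncol = m, byrow = TRUE) +
          matrix(stats::rnorm(cfg$n_qc * m), nrow = cfg$n_qc) *
            matrix(rep(log_sd_analytical, each = cfg$n_qc), nrow = cfg$n_qc))
    }

    # internal standards: near-constant spiked intensity, one per ion mode
    is_pos <- 1000 * exp(stats::rnorm(nrow(sm), sd = 0.02))
    is_neg <- 1000 * exp(stats::rnorm(nrow(sm), sd = 0.02))
    x <- cbind(x, IS_pos = is_pos, IS_neg = is_neg)

    mm <- data.frame(
      name = c(name, "IS_pos", "IS_neg"),
      is_uremic_solute = c(seq_len(m) %in% solute_idx, FALSE, FALSE),
      is_internal_standard = c(rep(FALSE, m), TRUE, TRUE),
      ion_mode = c(rep_len(c("pos", "neg"), m), "pos", "neg"),
      stringsAsFactors = FALSE)

    tab <- metabolite_table(x, sm[, c("sample_id", "group", "patient_id")], mm)

    planted_fc <- planted_fc_matrix(effects, name)
    c_solutes <- intersect(solute_idx, c_idx)
    truth <- structure(list(
      region = stats::setNames(region, name),
      planted_fc = planted_fc,
      cleared_by_hd = name[setdiff(c_solutes, hfd_only_idx)],
      cleared_by_hfd = name[c_solutes],
      hfd_only = name[hfd_only_idx],
      high_rsd = name[high_rsd_idx]),
      class = "cohort_truth")

    list(table = tab, truth = truth)
  })
}

# overlay domain metabolite names on the generic met_### identifiers
assign_curated_names <- function(name, region, solute_idx, hfd_only_idx) {
  take <- function(pool, k) pool[seq_len(min(k, length(pool)))]
  nm_hfd <- take(HFD_ONLY_SOLUTE_NAMES, length(hfd_only_idx))
  name[hfd_only_idx[seq_along(nm_hfd)]] <- nm_hfd
  other_c <- setdiff(intersect(solute_idx, which(region == "C")), hfd_only_idx)
  nm_c <- take(NAMED_REGION_C, length(other_c))
  name[other_c[seq_along(nm_c)]] <- nm_c
  b_idx <- which(region == "B")
  nm_b <- take(NAMED_REGION_B, length(b_idx))
  name[b_idx[seq_along(nm_b)]] <- nm_b
  d_free <- setdiff(which(region == "D"), solute_idx)
  nm_d <- take(NAMED_REGION_D, length(d_free))
  name[d_free[seq_along(nm_d)]] <- nm_d
  name
}

planted_fc_matrix <- function(effects, name) {
  fc <- cbind(
    post_hd_vs_pre_hd = exp(effects["post_hd", ] - effects["pre_hd", ]),
    post_hfd_vs_pre_hfd = exp(effects["post_hfd", ] - effects["pre_hfd", ]),
    pre_hd_vs_control = exp(effects["pre_hd", ] - effects["control", ]),
    pre_hfd_vs_control = exp(effects["pre_hfd", ] - effects["control", ]),
    post_hd_vs_control = exp(effects["post_hd", ] - effects["control", ]),
    post_hfd_vs_control = exp(effects["post_hfd", ] - effects["control", ]))
  rownames(fc) <- name
  fc
}

build_sample_meta <- function(cfg) {
  rows <- list()
  if (cfg$n_control > 0L) {
    ids <- sprintf("CTRL_%03d", seq_len(cfg$n_control))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = ids, group = "control", patient_id = "",
      subject_id = ids, stringsAsFactors = FALSE)
  }
  for (therapy in c("hd", "hfd")) {
    n <- if (therapy == "hd") cfg$n_hd_patients else cfg$n_hfd_patients
    if (n > 0L) {
      pid <- sprintf("%s_%03d", toupper(therapy), seq_len(n))
      for (phase in c("pre", "post")) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste0(pid, "_", phase),
          group = paste0(phase, "_", therapy),
          patient_id = pid, subject_id = pid, stringsAsFactors = FALSE)
      }
    }
  }
  if (cfg$n_qc > 0L) {
    ids <- sprintf("QC_%03d", seq_len(cfg$n_qc))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = ids, group = "qc", patient_id = "",
      subject_id = ids, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Pooled per-metabolite reference over study samples
#'
#' Mean intensity of every metabolite across all non-QC samples, ignoring
#' missing entries; the level a pooled QC injection is expected to sit at.
#' A metabolite missing in every study sample yields `NA`.
#'
#' @param tab A `metabolite_table` with at least one non-QC sample.
#' @return Named numeric vector, one entry per metabolite.
#' @export
pooled_qc_reference <- function(tab) {
  rows <- which(tab$sample_meta$group != "qc")
  if (!length(rows)) stopf("pooled_qc_reference: table has no non-QC samples")
  mu <- colMeans(tab$intensities[rows, , drop = FALSE], na.rm = TRUE)
  mu[is.nan(mu)] <- NA_real_
  mu
}
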