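# Univariate machinery: Mann-Whitney U, paired t, BH-FDR, fold changes,
# ratios, region classification and clearance sets.

test_that("exact Mann-Whitney p matches full enumeration for all small sizes", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6)),
               list(U = 0, p = 0.1))   # C(6,3) = 20 assignments, 2 extreme
  set.seed(14)
  for (na in 2:5) {
    for (nb in na:(10 - na)) {
      a <- sample(seq_len(100), na)
      b <- sample(setdiff(seq_len(100), a), nb)
      res <- mann_whitney_u(a, b)
      expect_equal(res$p, mw_exact_oracle(a, b),
                   info = sprintf("na=%d nb=%d", na, nb))
    }
  }
})

test_that("tied and degenerate Mann-Whitney inputs are handled", {
  expect_equal(mann_whitney_u(c(5, 5, 5), c(5, 5, 5))$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
  # large separation -> vanishing p under the normal approximation,
  # agreeing with the reference implementation
  a <- seq_len(20)
  b <- a + 1000
  res <- mann_whitney_u(a, b)
  expect_lt(res$p, 1e-6)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_equal(res$U, unname(ref$statistic))
})

test_that("approximate Mann-Whitney matches the tie-corrected reference", {
  set.seed(15)
  for (i in 1:20) {
    a <- sample(1:8, 15, replace = TRUE)   # heavy ties
    b <- sample(2:9, 18, replace = TRUE)
    res <- mann_whitney_u(a, b)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("paired t reproduces closed-form examples and conventions", {
  r <- paired_t(c(2, 4, 6), c(1, 2, 3))          # d = 1, 2, 3
  expect_equal(r$t, 3.4641016, tolerance = 1e-6)
  expect_equal(r$df, 2L)
  expect_equal(r$p, 0.0742, tolerance = 1e-3)

  r2 <- paired_t(c(3, 1, 5, 2), c(1, 2, 2, 2))   # d = 2, -1, 3, 0
  expect_equal(r2$t, 1.0954451, tolerance = 1e-6)
  expect_equal(r2$p, 0.3535, tolerance = 1e-3)
  # cross-check the general case against the reference implementation
  ref <- stats::t.test(c(3, 1, 5, 2), c(1, 2, 2, 2), paired = TRUE)
  expect_equal(r2$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r2$p, ref$p.value, tolerance = 1e-10)

  # identical pre/post: flat with p = 1 by convention
  expect_equal(paired_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # constant nonzero difference is degenerate
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "degenerate")
  # pairs are aligned by id, not position; missing pairs are dropped
  pre <- c(P1 = 5, P2 = 7, P3 = 9, P4 = NA, P5 = 4)
  post <- c(P3 = 6, P1 = 1, P2 = 2, P5 = 1, P4 = 8)
  r3 <- paired_t(pre, post)
  expect_equal(r3$n_pairs, 4L)
  expect_equal(r3$n_excluded, 1L)
  expect_equal(r3$t, unname(stats::t.test(c(5, 7, 9, 4), c(1, 2, 6, 1),
                                          paired = TRUE)$statistic),
               tolerance = 1e-10)
})

test_that("BH q values match hand examples and are order-invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(1), 1)
  p <- c(0.002, 0.5, 0.04, 0.04, 0.9)
  expect_equal(bh_fdr(p), bh_oracle(p))
  # shuffling inputs shuffles outputs identically
  set.seed(16)
  perm <- sample(5)
  expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH matches the brute-force oracle on many random vectors", {
  set.seed(17)
  for (i in seq_len(2000)) {
    p <- round(runif(sample(1:20, 1)), 3)  # rounding forces frequent ties
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("null p values rarely survive the FDR cut", {
  set.seed(18)
  frac <- vapply(seq_len(100), function(i) mean(bh_fdr(runif(1000)) < 0.05),
                 numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("fold change is a ratio of means with reciprocal symmetry", {
  expect_equal(round(fold_change(17.30, 4.63), 2), 3.74)
  expect_equal(round(fold_change(7.87, 4.63), 2), 1.70)
  expect_equal(fold_change(c(2, 4), c(2, 4)), 1)
  set.seed(19)
  a <- rlnorm(30); b <- rlnorm(25)
  expect_equal(fold_change(a, b) * fold_change(b, a), 1, tolerance = 1e-12)
  expect_error(fold_change(c(0, 0), c(1, 2)), "positive")
})

test_that("ratio features are scale-invariant per sample and NA-propagating", {
  tab <- tiny_table(n_met = 4)
  r_self <- ratio_feature(tab, "m01", "m01")
  expect_true(all(r_self == 1))
  r <- ratio_feature(tab, "m01", "m02")
  # multiplying both columns by a per-sample factor leaves ratios unchanged
  tab2 <- tab
  f <- runif(n_samples(tab), 0.5, 2)
  tab2$intensities[, c("m01", "m02")] <-
    tab2$intensities[, c("m01", "m02")] * f
  expect_equal(ratio_feature(tab2, "m01", "m02"), r, tolerance = 1e-12)
  # missing member or nonpositive denominator -> missing, counted
  tab$intensities[1, "m01"] <- NA
  tab$intensities[2, "m02"] <- 0
  r2 <- ratio_feature(tab, "m01", "m02")
  expect_true(all(is.na(r2[1:2])))
  expect_equal(attr(r2, "n_undefined"), 2L)
  expect_error(ratio_feature(tab, "m01", "nope"), "not in table")
})

test_that("planted ratio elevation is recovered from a synthetic cohort", {
  cfg <- cohort_config(n_qc = 0, n_high_rsd_metabolites = 0, seed = 23)
  cohort <- generate_cohort(cfg)
  tab <- normalize_by_is(cohort$table)
  # glutamate is planted region C (pre elevated by the toxin fold change),
  # glutamine region D (flat): the group ratio mean recovers the planted
  # elevation relative to control
  r <- ratio_feature(tab, "glutamate", "glutamine")
  grp <- tab$sample_meta$group
  elev <- mean(r[grp == "pre_hd"], na.rm = TRUE) /
    mean(r[grp == "control"], na.rm = TRUE)
  expect_lt(abs(elev / cfg$toxin_fc_pre_vs_control - 1), 0.10)
})

test_that("region classification recovers planted structure", {
  # near-noise-free cohort: exact recovery
  cohort <- generate_cohort(noiseless_cohort_config(seed = 31))
  pp <- preprocess(cohort$table)
  stats_all <- lapply(default_contrasts(), function(con) test_contrast(pp$table, con))
  regions <- classify_region(do.call(rbind, stats_all))
  expect_equal(mean(regions == cohort$truth$region[names(regions)]), 1.0)

  # all-flat results default to region D
  flat <- do.call(rbind, lapply(names(default_contrasts()), function(cn) {
    data.frame(metabolite = c("x", "y"), contrast = cn, statistic = 0,
               p = 0.9, q = 0.9, fold_change = 1, direction = "flat",
               is_uremic_solute = FALSE, significant = FALSE)
  }))
  expect_true(all(classify_region(flat) == "D"))
  expect_error(classify_region(flat[flat$contrast != "pre_hd_vs_control", ]),
               "missing contrast")
})

test_that("clearance sets follow set algebra and error on mismatched inputs", {
  mk <- function(mets, sig_down) {
    data.frame(metabolite = mets, contrast = "x", statistic = 1,
               p = ifelse(mets %in% sig_down, 0.001, 0.5),
               q = ifelse(mets %in% sig_down, 0.004, 0.6),
               fold_change = ifelse(mets %in% sig_down, 0.4, 1.01),
               direction = "down", is_uremic_solute = TRUE,
               significant = mets %in% sig_down)
  }
  mets <- c("a", "b", "c", "d")
  cr <- clearance_sets(mk(mets, c("a", "b")), mk(mets, c("a", "b", "c")))
  expect_setequal(cr$common, c("a", "b"))
  expect_identical(cr$hfd_only, "c")
  expect_equal(unname(cr$counts["n_hfd_only"]), 1L)
  # identical inputs -> empty HFD-only set
  cr2 <- clearance_sets(mk(mets, "a"), mk(mets, "a"))
  expect_length(cr2$hfd_only, 0L)
  expect_error(clearance_sets(mk(mets, "a"), mk(c(mets, "e"), "a")),
               "differ.*e")
})

test_that("paired-t + BH pipeline controls false positives on null cohorts", {
  # no planted pre/post effect anywhere: all metabolites region D
  fractions <- vapply(1:25, function(seed) {
    cohort <- generate_cohort(cohort_config(
      n_control = 0, n_hd_patients = 30, n_hfd_patients = 0, n_qc = 0,
      n_metabolites = 40, n_uremic_solutes = 0, n_hfd_only_cleared = 0,
      n_high_rsd_metabolites = 0, missing_rate_low_group = 0,
      region_fractions = c(A = 0, B = 0, C = 0, D = 1), seed = seed))
    st <- test_contrast(normalize_by_is(cohort$table),
                        default_contrasts()$post_hd_vs_pre_hd)
    mean(st$significant)
  }, numeric(1))
  expect_lte(mean(fractions), 0.05)
})

test_that("volcano tables carry the log-transformed coordinates", {
  cohort <- generate_cohort(small_cohort_config(seed = 4))
  st <- test_contrast(normalize_by_is(cohort$table),
                      default_contrasts()$post_hd_vs_pre_hd)
  v <- volcano_table(st)
  expect_equal(v$log2_fc, log2(st$fold_change))
  expect_equal(v$neg_log10_p, -log10(pmax(st$p, .Machine$double.xmin)))
  expect_identical(v$metabolite, st$metabolite)
})
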