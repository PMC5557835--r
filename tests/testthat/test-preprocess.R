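# The data-reduction chain: missing-value rule, IS normalization, QC RSD
# filter, imputation, scaling.

test_that("80% rule keeps a metabolite satisfying the rule in any one group", {
  tab <- tiny_table(n_control = 10, n_pairs = 10, n_met = 3)
  x <- tab$intensities
  # m01: complete in control, 10% present elsewhere -> kept
  pre <- group_rows(tab, "pre_hd"); post <- group_rows(tab, "post_hd")
  x[c(pre[-1], post[-1]), 1] <- NA
  # m02: 50% present in every group -> dropped
  x[group_rows(tab, "control")[1:5], 2] <- NA
  x[pre[1:5], 2] <- NA
  x[post[1:5], 2] <- NA
  tab$intensities <- x
  res <- eighty_percent_rule(tab)
  expect_true("m01" %in% res$table$metabolite_meta$name)
  expect_identical(res$dropped, "m02")
})

test_that("80% rule threshold is inclusive at exactly 80% non-missing", {
  tab <- tiny_table(n_control = 4, n_pairs = 85, n_met = 2)
  x <- tab$intensities
  pre <- group_rows(tab, "pre_hd")
  # present in exactly 68 of 85 pre-HD samples (80.0%), sparse elsewhere
  other <- c(group_rows(tab, "control"), group_rows(tab, "post_hd"))
  x[other, 1] <- NA
  x[pre[69:85], 1] <- NA
  # 67 of 85 (78.8%) -> below threshold everywhere
  x[other, 2] <- NA
  x[pre[68:85], 2] <- NA
  tab$intensities <- x
  res <- eighty_percent_rule(tab)
  expect_identical(res$table$metabolite_meta$name, "m01")
  expect_identical(res$dropped, "m02")
})

make_is_table <- function(values, is_values, n_qc = 0) {
  n <- length(values)
  ids <- sprintf("C%02d", seq_len(n))
  grp <- rep("control", n)
  if (n_qc > 0) {
    ids <- c(ids, sprintf("Q%02d", seq_len(n_qc)))
    grp <- c(grp, rep("qc", n_qc))
    values <- c(values, rep(mean(values), n_qc))
    is_values <- c(is_values, rep(1, n_qc))
  }
  metabolite_table(
    cbind(m = values, IS = is_values),
    data.frame(sample_id = ids, group = grp, patient_id = ""),
    data.frame(name = c("m", "IS"), is_uremic_solute = FALSE,
               is_internal_standard = c(FALSE, TRUE), ion_mode = "pos"))
}

test_that("IS normalization divides by the same-sample standard and drops it", {
  tab <- make_is_table(values = c(100, 300), is_values = c(50, 100))
  out <- normalize_by_is(tab)
  expect_identical(out$metabolite_meta$name, "m")
  expect_equal(unname(out$intensities[, "m"]), c(2, 3))
  # a raw fold change of 3 becomes 1.5 after normalization
  expect_equal(fold_change(out$intensities[2, "m"], out$intensities[1, "m"]), 1.5)

  # identity standard leaves values untouched
  tab2 <- make_is_table(values = c(7, 11), is_values = c(1, 1))
  expect_equal(unname(normalize_by_is(tab2)$intensities[, "m"]), c(7, 11))

  # nonpositive or missing IS is an error naming the sample
  tab3 <- make_is_table(values = c(1, 2), is_values = c(0, 1))
  expect_error(normalize_by_is(tab3), "sample 'C01'")
})

test_that("QC RSD filter applies a strict 30% cutoff", {
  n_qc <- 3
  qc_vals <- cbind(steady = c(10, 10, 10), wobbly = c(1, 2, 3),
                   border = c(10, 10, 10))
  # push 'border' to RSD exactly 30%: values mean 1, sd 0.3
  qc_vals[, "border"] <- c(1 - 0.3, 1, 1 + 0.3)
  ids <- c(sprintf("C%02d", 1:2), sprintf("Q%02d", 1:3))
  x <- rbind(matrix(1, 2, 3), qc_vals)
  colnames(x) <- colnames(qc_vals)
  tab <- metabolite_table(
    x, data.frame(sample_id = ids, group = c("control", "control", rep("qc", 3)),
                  patient_id = ""),
    data.frame(name = colnames(qc_vals), is_uremic_solute = FALSE,
               is_internal_standard = FALSE, ion_mode = "pos"))
  res <- qc_rsd_filter(tab, threshold_pct = 30)
  expect_equal(unname(res$rsd[["steady"]]), 0)
  expect_equal(unname(res$rsd[["wobbly"]]), 50)  # mean 2, sd 1
  expect_equal(unname(res$rsd[["border"]]), 30)
  # strict "<": the exactly-30% metabolite is dropped
  expect_identical(res$table$metabolite_meta$name, "steady")
  expect_setequal(res$dropped, c("wobbly", "border"))
  expect_equal(res$fraction_below, 1 / 3)
})

test_that("QC RSD filter needs at least 3 QC samples", {
  tab <- tiny_table(n_qc = 2)
  expect_error(qc_rsd_filter(tab), "at least 3 QC")
})

test_that("half-minimum imputation fills gaps and only gaps", {
  tab <- tiny_table(n_control = 4, n_pairs = 0, n_met = 3)
  x <- tab$intensities
  x[, 1] <- c(2, 4, 8, NA)
  x[, 2] <- c(10, NA, NA, 6)
  keep <- x[, 3]
  tab$intensities <- x
  out <- impute_half_minimum(tab)
  expect_equal(unname(out$intensities[4, 1]), 1)       # half of min 2
  expect_equal(unname(out$intensities[2:3, 2]), c(3, 3))
  expect_equal(out$intensities[, 3], keep)             # untouched column

  tab$intensities[, 3] <- NA
  expect_error(impute_half_minimum(tab), "no observed values")
})

test_that("uv_scale yields mean 0 / sd 1, is invertible and idempotent", {
  expect_equal(unname(uv_scale(cbind(c(1, 2, 3)))$x[, 1]), c(-1, 0, 1))
  set.seed(4)
  x <- matrix(rnorm(60, 5, 3), 12, 5)
  s <- uv_scale(x)
  expect_true(all(abs(colMeans(s$x)) < 1e-10))
  expect_true(all(abs(apply(s$x, 2, sd) - 1) < 1e-10))
  # inverse transform
  expect_equal(sweep(sweep(s$x, 2, s$scale, "*"), 2, s$center, "+"), x,
               tolerance = 1e-12)
  # idempotence on already-scaled input
  expect_equal(uv_scale(s$x)$x, s$x, tolerance = 1e-12)
  # constant column is an error naming the column
  xc <- cbind(a = rnorm(5), b = rep(2, 5))
  expect_error(uv_scale(xc), "column 'b'")
})

test_that("the chain removes inflated-noise metabolites and keeps the rest", {
  # QC count kept at the study's 38 injections: the RSD of an inflated
  # metabolite (~53%) is separated from the 30% cutoff by several standard
  # errors only when the QC series is this long
  hits <- misses <- 0L
  for (seed in 1:10) {
    cohort <- generate_cohort(small_cohort_config(seed = seed, n_qc = 38))
    pp <- preprocess(cohort$table)
    dropped_rsd <- names(pp$report$dropped)[pp$report$dropped == "rsd"]
    hits <- hits + length(intersect(cohort$truth$high_rsd, dropped_rsd))
    misses <- misses + length(setdiff(dropped_rsd, cohort$truth$high_rsd))
  }
  n_inflated <- 10L * 4L
  expect_gte(hits / n_inflated, 0.9)         # inflated columns are removed
  n_clean <- 10L * (30L - 4L)
  expect_lte(misses / n_clean, 0.1)          # clean columns survive
})

test_that("preprocess report counts are consistent", {
  cohort <- generate_cohort(small_cohort_config(seed = 2))
  pp <- preprocess(cohort$table)
  rep_ <- pp$report
  expect_lte(rep_$n_after_rsd, rep_$n_after_80_rule)
  expect_lte(rep_$n_after_80_rule, rep_$n_input_metabolites)
  expect_gte(rep_$fraction_below_30, 0)
  expect_lte(rep_$fraction_below_30, 1)
  expect_equal(rep_$n_after_rsd, n_metabolites(pp$table))
  # every dropped name carries a reason
  expect_true(all(rep_$dropped %in% c("missingness", "rsd", "is_internal_standard")))
})
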