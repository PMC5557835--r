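# Fixtures built in code: tiny hand-made tables plus scaled-down cohorts.

# minimal valid table: n control, n/2 HD pairs, optional QC rows, IS columns
tiny_table <- function(n_control = 4, n_pairs = 3, n_qc = 0, n_met = 4,
                       seed = 1) {
  withr::with_seed(seed, {
    ids <- c(sprintf("C%02d", seq_len(n_control)),
             sprintf("P%02d_pre", seq_len(n_pairs)),
             sprintf("P%02d_post", seq_len(n_pairs)),
             if (n_qc > 0) sprintf("Q%02d", seq_len(n_qc)))
    grp <- c(rep("control", n_control), rep("pre_hd", n_pairs),
             rep("post_hd", n_pairs), rep("qc", n_qc))
    pid <- c(rep("", n_control), sprintf("P%02d", seq_len(n_pairs)),
             sprintf("P%02d", seq_len(n_pairs)), rep("", n_qc))
    n <- length(ids)
    x <- matrix(exp(rnorm(n * n_met, log(10), 0.3)), n, n_met)
    mm <- data.frame(name = sprintf("m%02d", seq_len(n_met)),
                     is_uremic_solute = FALSE,
                     is_internal_standard = FALSE,
                     ion_mode = rep_len(c("pos", "neg"), n_met))
    metabolite_table(x, data.frame(sample_id = ids, group = grp,
                                   patient_id = pid), mm)
  })
}

# small default-structure cohort for fast end-to-end tests
small_cohort_config <- function(seed = 1, ...) {
  args <- list(n_control = 12, n_hd_patients = 14, n_hfd_patients = 12,
               n_qc = 8, n_metabolites = 30, n_uremic_solutes = 10,
               n_hfd_only_cleared = 3, n_high_rsd_metabolites = 4,
               missing_rate_low_group = 0.15, seed = seed)
  do.call(cohort_config, utils::modifyList(args, list(...)))
}

# near-noise-free cohort: deterministic group structure, no censoring
noiseless_cohort_config <- function(seed = 1, ...) {
  args <- list(analytical_cv = 1e-3, biological_cv = 0,
               missing_rate_low_group = 0, n_high_rsd_metabolites = 0,
               n_hfd_only_cleared = 0, seed = seed)
  do.call(small_cohort_config, utils::modifyList(args, list(seed = seed, ...)))
}
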