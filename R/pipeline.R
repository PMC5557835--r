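# Pipeline orchestration: simulate or load -> preprocess -> PCA ->
# SVM-RFE stability selection per contrast -> univariate tables -> region
# classification -> clearance report, written into a run directory with a
# machine-readable manifest.

#' Pipeline configuration
#'
#' Exactly one of `input` (paths to an existing feature table) or `cohort`
#' (a [cohort_config()] to simulate) must be given.
#'
#' @param input Optional named list with `path`, `sample_meta_path`,
#'   `metabolite_meta_path` for [read_feature_table()].
#' @param cohort Optional [cohort_config()] for [generate_cohort()].
#' @param out_dir Output run directory (created; must not already contain a
#'   manifest).
#' @param missing_threshold,rsd_threshold_pct Preprocessing thresholds.
#' @param contrasts Named list of [group_contrast()]s; default the six
#'   study contrasts.
#' @param n_components PCA components, default 2.
#' @param selection Named list of stability-selection parameters:
#'   `n_repeats` (100), `k_folds` (3), `threshold` (0.8), `drop_fraction`
#'   (0.05), `cost` (1). Set `n_repeats = 0` to skip the selection stage.
#' @param alpha,fdr Significance limits (raw p and BH q), default 0.05 each.
#' @param ratio_pairs List of `c(numerator, denominator)` metabolite-name
#'   pairs; pairs absent after filtering are skipped and recorded. Default
#'   glutamate/glutamine and tryptophan/kynurenine.
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, cohort = NULL, out_dir,
                            missing_threshold = 0.8, rsd_threshold_pct = 30,
                            contrasts = default_contrasts(),
                            n_components = 2L,
                            selection = list(),
                            alpha = 0.05, fdr = 0.05,
                            ratio_pairs = list(c("glutamate", "glutamine"),
                                               c("tryptophan", "kynurenine")),
                            seed = 1L) {
  if (is.null(input) == is.null(cohort)) {
    stopf("pipeline_config: exactly one of 'input' or 'cohort' must be given")
  }
  if (!is.null(input) &&
      !all(c("path", "sample_meta_path", "metabolite_meta_path") %in% names(input))) {
    stopf("pipeline_config: input needs path, sample_meta_path, metabolite_meta_path")
  }
  sel_default <- list(n_repeats = 100L, k_folds = 3L, threshold = 0.8,
                     drop_fraction = 0.05, cost = 1)
  unknown <- setdiff(names(selection), names(sel_default))
  if (length(unknown)) {
    stopf("pipeline_config: unknown selection parameter(s): %s",
          paste(unknown, collapse = ", "))
  }
  selection <- utils::modifyList(sel_default, selection)
  stopifnot(missing_threshold > 0, missing_threshold <= 1,
            rsd_threshold_pct > 0, alpha > 0, alpha < 1, fdr > 0, fdr < 1,
            selection$threshold >= 0, selection$threshold <= 1,
            selection$drop_fraction > 0, selection$drop_fraction < 1)
  structure(list(input = input, cohort = cohort, out_dir = out_dir,
                 missing_threshold = missing_threshold,
                 rsd_threshold_pct = rsd_threshold_pct,
                 contrasts = contrasts, n_components = as.integer(n_components),
                 selection = selection, alpha = alpha, fdr = fdr,
                 ratio_pairs = ratio_pairs, seed = as.integer(seed)),
            class = "pipeline_config")
}

log_msg <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", "dialymet", sprintf(fmt, ...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on simulated or loaded data and writes all
#' artifacts (preprocessing report, PCA scores/loadings/R2X/Q2, selection
#' frequencies, statistic and volcano tables per contrast, region
#' assignments, clearance report, run manifest) into `config$out_dir`.
#' Identical config and seed give identical outputs. A failing stage
#' leaves a `FAILED` marker naming the stage next to any partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  stage <- "setup"
  manifest <- list(seed = config$seed,
                   alpha = config$alpha, fdr = config$fdr,
                   missing_threshold = config$missing_threshold,
                   rsd_threshold_pct = config$rsd_threshold_pct,
                   selection = config$selection,
                   stages = list())
  t_stage <- function(expr, name) {
    stage <<- name
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  tryCatch({
    # --- input ---------------------------------------------------------
    dat <- t_stage(name = "input", {
      if (!is.null(config$cohort)) {
        log_msg(log_con, "simulating cohort (seed %d)", config$cohort$seed)
        cohort <- generate_cohort(config$cohort)
        write_truth(cohort$truth, file.path(out, "truth.csv"))
        cohort
      } else {
        log_msg(log_con, "reading feature table from %s", config$input$path)
        list(table = read_feature_table(config$input$path,
                                        config$input$sample_meta_path,
                                        config$input$metabolite_meta_path),
             truth = NULL)
      }
    })
    tab <- dat$table
    manifest$n_samples_in <- n_samples(tab)
    manifest$n_study_samples <- sum(tab$sample_meta$group != "qc")
    manifest$n_metabolites_in <-
      sum(!tab$metabolite_meta$is_internal_standard)
    log_msg(log_con, "%d samples (%d study, %d QC), %d metabolites",
            n_samples(tab), manifest$n_study_samples,
            n_samples(tab) - manifest$n_study_samples,
            manifest$n_metabolites_in)

    # --- preprocessing -------------------------------------------------
    prep <- t_stage(name = "preprocess",
                    preprocess(tab, config$missing_threshold,
                               config$rsd_threshold_pct))
    write_preprocess_report(prep$report, file.path(out, "preprocess_report.csv"))
    manifest$n_after_80_rule <- prep$report$n_after_80_rule
    manifest$n_after_rsd <- prep$report$n_after_rsd
    manifest$fraction_rsd_below_threshold <- prep$report$fraction_below_30
    norm_tab <- prep$table
    log_msg(log_con, "preprocessing: %d -> %d (80%% rule) -> %d (QC RSD)",
            prep$report$n_input_metabolites, prep$report$n_after_80_rule,
            prep$report$n_after_rsd)

    # --- multivariate --------------------------------------------------
    study_tab <- subset_table(norm_tab,
                              samples = norm_tab$sample_meta$group != "qc")
    imputed <- t_stage(name = "impute", impute_half_minimum(study_tab))
    pca <- t_stage(name = "pca", {
      scaled <- uv_scale(imputed$intensities)
      fit_pca(scaled$x, n_components = config$n_components)
    })
    utils::write.csv(data.frame(sample_id = imputed$sample_meta$sample_id,
                                group = imputed$sample_meta$group,
                                pca$scores),
                     file.path(out, "pca_scores.csv"), row.names = FALSE)
    utils::write.csv(data.frame(metabolite = imputed$metabolite_meta$name,
                                pca$loadings),
                     file.path(out, "pca_loadings.csv"), row.names = FALSE)
    manifest$pca_r2x <- pca$r2x
    manifest$pca_q2 <- pca$q2
    log_msg(log_con, "PCA: R2X %s; Q2 %s",
            paste(sprintf("%.3f", pca$r2x), collapse = "/"),
            paste(sprintf("%.3f", pca$q2), collapse = "/"))

    selection_summary <- t_stage(name = "stability_selection", {
      res <- list()
      if (config$selection$n_repeats > 0) {
        for (cn in names(config$contrasts)) {
          con <- config$contrasts[[cn]]
          cm <- contrast_matrix(imputed, con)
          sel <- stability_select(
            cm$x, cm$y,
            n_repeats = config$selection$n_repeats,
            k_folds = config$selection$k_folds,
            threshold = config$selection$threshold,
            drop_fraction = config$selection$drop_fraction,
            cost = config$selection$cost,
            seed = child_seed(config$seed, paste0("select_", cn)),
            contrast = cn)
          write_selection_result(sel, file.path(out, sprintf("selection_%s.csv", cn)))
          res[[cn]] <- c(n_selected = length(sel$selected),
                         accuracy_mean = sel$accuracy_mean,
                         accuracy_sd = sel$accuracy_sd)
          log_msg(log_con, "selection %s: %d features, %.2f%% +/- %.2f%%",
                  cn, length(sel$selected), sel$accuracy_mean, sel$accuracy_sd)
        }
      }
      res
    })
    manifest$selection_summary <- selection_summary

    # --- univariate ----------------------------------------------------
    stats_all <- t_stage(name = "univariate", {
      lapply(config$contrasts, function(con) {
        test_contrast(norm_tab, con, alpha = config$alpha, fdr = config$fdr)
      })
    })
    for (cn in names(stats_all)) {
      write_stat_table(stats_all[[cn]], file.path(out, sprintf("stats_%s.csv", cn)))
      utils::write.csv(volcano_table(stats_all[[cn]]),
                       file.path(out, sprintf("volcano_%s.csv", cn)),
                       row.names = FALSE)
    }
    manifest$n_significant <- vapply(stats_all, function(s) sum(s$significant),
                                     integer(1))

    # --- ratios --------------------------------------------------------
    manifest$ratio_pairs_used <- t_stage(name = "ratios", {
      used <- character(0)
      ratio_rows <- list()
      for (pair in config$ratio_pairs) {
        if (all(pair %in% norm_tab$metabolite_meta$name)) {
          r <- ratio_feature(norm_tab, pair[1], pair[2])
          ratio_rows[[paste(pair, collapse = "_over_")]] <- r
          used <- c(used, paste(pair, collapse = "/"))
        } else {
          log_msg(log_con, "ratio %s skipped: member absent after filtering",
                  paste(pair, collapse = "/"))
        }
      }
      if (length(ratio_rows)) {
        df <- data.frame(sample_id = norm_tab$sample_meta$sample_id,
                         group = norm_tab$sample_meta$group,
                         as.data.frame(ratio_rows, check.names = TRUE))
        utils::write.csv(df, file.path(out, "ratio_features.csv"),
                         row.names = FALSE, na = "")
      }
      used
    })

    # --- regions and clearance ----------------------------------------
    have_six <- all(names(default_contrasts()) %in% names(stats_all))
    if (have_six) {
      t_stage(name = "regions_clearance", {
        regions <- classify_region(do.call(rbind, stats_all))
        utils::write.csv(data.frame(metabolite = names(regions),
                                    region = unname(regions)),
                         file.path(out, "regions.csv"), row.names = FALSE)
        cr <- clearance_sets(stats_all$post_hd_vs_pre_hd,
                             stats_all$post_hfd_vs_pre_hfd)
        manifest$clearance_counts <- as.list(cr$counts)
        manifest$hfd_only_solutes <- cr$hfd_only
        writeLines(utils::capture.output(print(cr)),
                   file.path(out, "clearance_report.txt"))
        utils::write.csv(data.frame(
          metabolite = sort(union(cr$decreased_hd, cr$decreased_hfd)),
          decreased_hd = as.integer(sort(union(cr$decreased_hd, cr$decreased_hfd)) %in% cr$decreased_hd),
          decreased_hfd = as.integer(sort(union(cr$decreased_hd, cr$decreased_hfd)) %in% cr$decreased_hfd)),
          file.path(out, "clearance_sets.csv"), row.names = FALSE)
        log_msg(log_con, "clearance: HD %d, HFD %d, HFD-only %d",
                cr$counts["n_decreased_solutes_hd"],
                cr$counts["n_decreased_solutes_hfd"], cr$counts["n_hfd_only"])
        NULL
      })
    }

    manifest$contrasts <- names(config$contrasts)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_msg(log_con, "run complete: %s", out)
    invisible(manifest)
  }, error = function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               file.path(out, "FAILED"))
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
}

#' Class matrix and labels for one contrast
#'
#' Extracts the (complete) intensity submatrix of the two contrast groups
#' together with the group labels, for the multivariate stage.
#'
#' @param tab A complete (imputed) `metabolite_table`.
#' @param contrast A [group_contrast()].
#' @return List with `x` (matrix) and `y` (factor of group labels).
#' @export
contrast_matrix <- function(tab, contrast) {
  rows <- c(group_rows(tab, contrast$side_a), group_rows(tab, contrast$side_b))
  x <- tab$intensities[rows, , drop = FALSE]
  y <- factor(tab$sample_meta$group[rows],
              levels = c(contrast$side_b, contrast$side_a))
  list(x = x, y = y)
}

#' Summarize a completed run directory
#'
#' One-page plain-text summary from the artifacts of [run_pipeline()]:
#' metabolite counts per filter stage, fraction of QC RSDs under the
#' threshold, selected-feature counts and accuracies per contrast,
#' significant-metabolite and decreased-solute counts, and the HFD-only
#' solute list. Missing artifacts are listed as absent (non-fatal).
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Character vector of summary lines (also printed).
#' @export
summarize_run <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stopf("summarize_run: no manifest.json in %s", run_dir)
  }
  man <- tryCatch(jsonlite::read_json(manifest_path, simplifyVector = TRUE),
                  error = function(e) stopf("summarize_run: corrupted manifest: %s",
                                            conditionMessage(e)))
  lines <- c(
    sprintf("dialymet run summary: %s", run_dir),
    sprintf("seed: %s", man$seed),
    sprintf("samples: %s study + %s QC",
            man$n_study_samples, man$n_samples_in - man$n_study_samples),
    sprintf("metabolites: %s -> %s (80%% rule) -> %s (QC RSD filter)",
            man$n_metabolites_in, man$n_after_80_rule, man$n_after_rsd),
    sprintf("QC RSD below threshold: %.1f%% of metabolites",
            100 * as.numeric(man$fraction_rsd_below_threshold)),
    sprintf("PCA R2X: %s | Q2: %s",
            paste(sprintf("%.3f", as.numeric(man$pca_r2x)), collapse = "/"),
            paste(sprintf("%.3f", as.numeric(man$pca_q2)), collapse = "/")))
  if (length(man$selection_summary)) {
    for (cn in names(man$selection_summary)) {
      s <- as.numeric(unlist(man$selection_summary[[cn]]))
      lines <- c(lines, sprintf(
        "selection %s: %d features, accuracy %.2f%% +/- %.2f%%",
        cn, s[1], s[2], s[3]))
    }
  } else {
    lines <- c(lines, "selection: absent")
  }
  for (cn in names(man$n_significant)) {
    lines <- c(lines, sprintf("significant metabolites (%s): %s", cn,
                              man$n_significant[[cn]]))
  }
  if (!is.null(man$clearance_counts)) {
    lines <- c(lines,
               sprintf("decreased solutes: HD %s, HFD %s, common %s",
                       man$clearance_counts$n_decreased_solutes_hd,
                       man$clearance_counts$n_decreased_solutes_hfd,
                       man$clearance_counts$n_common),
               sprintf("cleared by HFD only: %s",
                       if (length(man$hfd_only_solutes))
                         paste(unlist(man$hfd_only_solutes), collapse = ", ")
                       else "none"))
  } else {
    lines <- c(lines, "clearance report: absent")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
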