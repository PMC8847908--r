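# Formats, configuration and the end-to-end runner.

#' Pipeline configuration
#'
#' Collects the analysis constants: the sparsity sweep, negative-correlation
#' handling, the FDR level, covariate sets for the group screen and the
#' association stage, folds and permutation count, and the master seed
#' (stage seeds are derived as fixed offsets from it).
#'
#' @param sparsity numeric triple `(min, max, step)`.
#' @param negative_handling `"zero"` or `"absolute"`.
#' @param use_fisher_z use Fisher-z connectivity in the FC-association
#'   stage?
#' @param fdr_q FDR level for all screening families.
#' @param covariates_group covariates of the group screen.
#' @param covariates_assoc covariates of the association/partial-correlation
#'   stage.
#' @param k_folds cross-validation folds.
#' @param n_perm permutations for the null distributions.
#' @param seed master seed.
#' @param leakage_free re-estimate metric membership and signs within
#'   training folds for the intrasample prediction (instead of fixing them
#'   on the full scored sample first, which is the classical but
#'   leakage-prone order)?
#' @param truncate_timepoints truncate all subjects to the minimum common
#'   timepoint count before analysis?
#' @return a `run_config` list.
#' @export
run_config <- function(sparsity = c(0.10, 0.30, 0.01),
                       negative_handling = c("zero", "absolute"),
                       use_fisher_z = FALSE, fdr_q = 0.05,
                       covariates_group = c("age", "sex", "motion", "site"),
                       covariates_assoc = c("age", "sex", "motion"),
                       k_folds = 10, n_perm = 1000, seed = 1,
                       leakage_free = FALSE, truncate_timepoints = FALSE) {
  negative_handling <- match.arg(negative_handling)
  sparsity_grid(sparsity[1], sparsity[2], sparsity[3])  # validates
  assert_scalar_number(fdr_q, "fdr_q", lower = 0, upper = 1)
  assert_scalar_number(k_folds, "k_folds", lower = 2)
  assert_scalar_number(n_perm, "n_perm", lower = 40)
  structure(list(sparsity = sparsity, negative_handling = negative_handling,
                 use_fisher_z = use_fisher_z, fdr_q = fdr_q,
                 covariates_group = covariates_group,
                 covariates_assoc = covariates_assoc,
                 k_folds = as.integer(k_folds), n_perm = as.integer(n_perm),
                 seed = as.integer(seed), leakage_free = leakage_free,
                 truncate_timepoints = truncate_timepoints),
            class = "run_config")
}

#' Write a synthetic cohort to disk
#'
#' One TSV per subject (timepoints x ROI columns, header = ROI labels),
#' `phenotypes.csv`, and `truth.json` with the generating parameters.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ts in cohort$timeseries) {
    utils::write.table(ts$data,
                       file.path(dir, paste0(ts$subject_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  net <- cohort$truth$network
  spec <- cohort$truth$spec
  truth <- list(n_nodes = net$n_nodes, base_weights = net$base_weights,
                effect_nodes = net$effect_nodes,
                effect_delta = net$effect_delta, lambda = net$lambda,
                roi_labels = net$roi_labels,
                n_per_group = spec$n_per_group,
                n_timepoints = spec$n_timepoints, noise_sd = spec$noise_sd,
                subject_sd = spec$subject_sd,
                phenotype_weights = spec$phenotype_weights,
                phenotype_noise_sd = spec$phenotype_noise_sd,
                covariate_confounding = spec$covariate_confounding,
                sparsity = spec$sparsity, seed = cohort$truth$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a directory of subject time-series TSVs
#'
#' Every `.tsv` in the directory is one subject (file stem = subject id).
#' The first file fixes the reference ROI order; other files may list the
#' same ROIs in any order and are reordered to match, but a differing ROI
#' set is an error.
#'
#' @param path directory of TSV files.
#' @return list of [roi_timeseries()] in file order.
#' @export
read_timeseries_dir <- function(path) {
  files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stopf("no .tsv files under %s", path)
  out <- vector("list", length(files))
  ref <- NULL
  offenders <- character(0)
  for (i in seq_along(files)) {
    tab <- utils::read.delim(files[i], check.names = FALSE)
    labels <- colnames(tab)
    if (is.null(ref)) {
      ref <- labels
    } else if (!setequal(labels, ref)) {
      offenders <- c(offenders, basename(files[i]))
      next
    }
    m <- as.matrix(tab)[, ref, drop = FALSE]
    if (anyNA(m) || any(!is.finite(m))) {
      bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
      stopf("non-finite value in %s at row %d, column '%s'",
            basename(files[i]), bad[1], ref[bad[2]])
    }
    out[[i]] <- roi_timeseries(sub("\\.tsv$", "", basename(files[i])), m, ref)
  }
  if (length(offenders)) {
    stopf("ROI header mismatch against %s in: %s", basename(files[1]),
          paste(offenders, collapse = ", "))
  }
  out
}

#' Read and validate a phenotype table
#'
#' @param path CSV with columns `subject_id`, `group`, `age`, `sex`,
#'   `motion`, `site` and optionally `ahs` (may be missing e.g. for the
#'   unscored group).
#' @return validated data frame.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "age", "sex", "motion", "site")
  missing_cols <- setdiff(required, names(ph))
  if (length(missing_cols)) {
    stopf("phenotype file lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(ph$subject_id)) {
    stopf("duplicate subject_id(s): %s",
          paste(unique(ph$subject_id[duplicated(ph$subject_id)]),
                collapse = ", "))
  }
  if (!all(ph$group %in% c(0, 1))) stopf("`group` must be coded 0/1")
  if (!"ahs" %in% names(ph)) ph$ahs <- NA_real_
  n_missing <- sum(is.na(ph$ahs))
  if (n_missing) message(n_missing, " subject(s) have no style score")
  ph
}

pipeline_log <- function(verbose, ...) if (verbose) message("[connfp] ", ...)

#' Run the full connectome-fingerprint pipeline
#'
#' Executes construct -> metrics -> group screen -> phenotype association ->
#' prediction/classification on a cohort, mirroring the two-study design:
#' the group screen uses both groups; the association and intrasample
#' prediction stages use the scored (group 1, non-missing score) subjects;
#' cross-sample classification uses both groups with composites whose
#' members/signs were fixed on the scored sample. All stage outputs plus a
#' run manifest are written under `out_dir` when given.
#'
#' @param cohort a `cohort_dataset`, or a list with `timeseries` (list of
#'   [roi_timeseries()]) and `phenotypes` (data frame).
#' @param config a [run_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param verbose log stage progress?
#' @return list with `metrics`, `screen`, `association`, `fc_association`,
#'   `intrasample`, `cross_sample`, `cpm`, `cpm_stability`,
#'   `cpm_cross_sample`, `manifest`.
#' @export
run_full_pipeline <- function(cohort, config = run_config(), out_dir = NULL,
                              verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  ts <- cohort$timeseries
  ph <- cohort$phenotypes
  if (is.null(ts) || is.null(ph)) stopf("cohort needs timeseries + phenotypes")
  warnings_log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    warnings_log <<- c(warnings_log, msg)
    pipeline_log(verbose, msg)
  }

  if (config$truncate_timepoints) {
    t_min <- min(vapply(ts, function(x) nrow(x$data), integer(1)))
    ts <- lapply(ts, function(x) {
      roi_timeseries(x$subject_id, x$data[seq_len(t_min), , drop = FALSE],
                     x$roi_labels)
    })
    note("truncated all subjects to ", t_min, " timepoints")
  }

  pipeline_log(verbose, "stage metrics: ", length(ts), " subjects, ",
               length(ts[[1]]$roi_labels), " nodes")
  metrics <- tryCatch(
    cohort_metrics(ts, config$sparsity[1], config$sparsity[2],
                   config$sparsity[3], config$negative_handling),
    error = function(e) stopf("[metrics] %s", conditionMessage(e)))

  pipeline_log(verbose, "stage screen")
  screen <- tryCatch(
    screen_nodes(metrics, ph, q_level = config$fdr_q,
                 covariates = config$covariates_group),
    error = function(e) stopf("[screen] %s", conditionMessage(e)))
  note(length(screen$consistent_nodes), " consistent node(s) of ",
       ncol(metrics$degree_auc))

  scored <- ph$group == 1 & !is.na(ph$ahs)
  ph_scored <- ph[scored, , drop = FALSE]
  ts_scored <- ts[scored]
  note(nrow(ph_scored), " scored subject(s) enter the association stage")

  association <- NULL
  fc_association <- list()
  intrasample <- NULL
  cross_sample <- NULL
  if (length(screen$consistent_nodes) && nrow(ph_scored) > 2 * config$k_folds) {
    pipeline_log(verbose, "stage associate")
    association <- tryCatch(
      metric_ahs_screen(metrics, ph_scored, nodes = screen$consistent_nodes,
                        q_level = config$fdr_q,
                        covariates = config$covariates_assoc),
      error = function(e) stopf("[associate] %s", conditionMessage(e)))
    note(nrow(association$selected), " metric(s) associated with the score")
    for (node in unique(association$selected$node)) {
      fc_association[[node]] <- node_fc_ahs_screen(
        node, ts_scored, ph_scored, q_level = config$fdr_q,
        covariates = config$covariates_assoc,
        use_fisher_z = config$use_fisher_z)
    }

    if (nrow(association$selected)) {
      pipeline_log(verbose, "stage predict (intrasample)")
      idx <- match(ph_scored$subject_id, rownames(metrics$degree_auc))
      m_scored <- list(degree_auc = metrics$degree_auc[idx, , drop = FALSE],
                       efficiency_auc = metrics$efficiency_auc[idx, , drop = FALSE])
      y <- ph_scored$ahs
      if (config$leakage_free) {
        keep_nodes <- screen$consistent_nodes
        m_restr <- list(
          degree_auc = m_scored$degree_auc[, keep_nodes, drop = FALSE],
          efficiency_auc = m_scored$efficiency_auc[, keep_nodes, drop = FALSE])
        run_cv <- function(yy) {
          suppressWarnings(cpm_predict(m_restr, yy, k = config$k_folds,
                                       alpha = config$fdr_q)$estimate)
        }
        intrasample <- with_seed(config$seed + 1L,
                                 cpm_predict(m_restr, y, k = config$k_folds,
                                             alpha = config$fdr_q))
      } else {
        comp <- build_composites(m_scored, association$selected)
        x <- composite_design(comp)
        run_cv <- function(yy) {
          kfold_predict_continuous(x, yy, k = config$k_folds)$estimate
        }
        intrasample <- kfold_predict_continuous(x, y, k = config$k_folds,
                                                seed = config$seed + 1L)
        intrasample$members <- comp$members
      }
      perm <- permutation_calibrate(run_cv, y, intrasample$estimate,
                                    n_perm = config$n_perm,
                                    seed = config$seed + 2L)
      intrasample[names(perm)] <- perm

      pipeline_log(verbose, "stage classify (cross-sample)")
      cross_sample <- cross_sample_classify(association$selected, metrics,
                                            ph$group, k = config$k_folds,
                                            seed = config$seed + 3L)
      comp_all <- build_composites(metrics, association$selected)
      x_all <- composite_design(comp_all)
      perm_cls <- permutation_calibrate(
        function(lab) kfold_classify(x_all, lab, k = config$k_folds)$estimate,
        ph$group, cross_sample$estimate, n_perm = config$n_perm,
        seed = config$seed + 4L)
      cross_sample[names(perm_cls)] <- perm_cls
    } else {
      note("no associated metrics; prediction stages skipped")
    }
  } else {
    note("association/prediction skipped (no consistent nodes or too few scored subjects)")
  }

  cpm <- NULL
  cpm_stability <- NULL
  cpm_cross <- NULL
  if (nrow(ph_scored) > 2 * config$k_folds) {
    pipeline_log(verbose, "stage cpm")
    idx <- match(ph_scored$subject_id, rownames(metrics$degree_auc))
    m_scored <- list(degree_auc = metrics$degree_auc[idx, , drop = FALSE],
                     efficiency_auc = metrics$efficiency_auc[idx, , drop = FALSE])
    y <- ph_scored$ahs
    cpm <- cpm_predict(m_scored, y, k = config$k_folds, alpha = 0.05,
                       seed = config$seed + 5L)
    # permuted outcomes routinely select no metrics in some folds; the
    # training-mean fallback warning is informative once, not n_perm times
    perm_cpm <- permutation_calibrate(
      function(yy) suppressWarnings(
        cpm_predict(m_scored, yy, k = config$k_folds, alpha = 0.05)$estimate),
      y, cpm$estimate, n_perm = config$n_perm, seed = config$seed + 6L)
    cpm[names(perm_cpm)] <- perm_cpm

    cpm_stability <- stability_select(cpm$fold_selections,
                                      min_count = config$k_folds)
    note(nrow(cpm_stability), " metric(s) pass ", config$k_folds, "/",
         config$k_folds, " stability selection")
    if (nrow(cpm_stability)) {
      signs <- vapply(seq_len(nrow(cpm_stability)), function(i) {
        mat <- if (cpm_stability$metric[i] == "degree") m_scored$degree_auc
               else m_scored$efficiency_auc
        as.integer(sign(stats::cor(mat[, cpm_stability$node[i]], y)))
      }, integer(1))
      sel <- data.frame(node = cpm_stability$node,
                        metric = cpm_stability$metric, sign = signs,
                        stringsAsFactors = FALSE)
      cpm_cross <- cross_sample_classify(sel, metrics, ph$group,
                                         k = config$k_folds,
                                         seed = config$seed + 7L)
      comp_all <- build_composites(metrics, sel)
      x_all <- composite_design(comp_all)
      perm2 <- permutation_calibrate(
        function(lab) kfold_classify(x_all, lab, k = config$k_folds)$estimate,
        ph$group, cpm_cross$estimate, n_perm = config$n_perm,
        seed = config$seed + 8L)
      cpm_cross[names(perm2)] <- perm2
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("connfp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    config_hash = config_hash(config),
    n_subjects = length(ts), n_nodes = length(ts[[1]]$roi_labels),
    n_scored = nrow(ph_scored),
    consistent_nodes = screen$consistent_nodes,
    notes = warnings_log)

  result <- list(metrics = metrics, screen = screen,
                 association = association, fc_association = fc_association,
                 intrasample = intrasample, cross_sample = cross_sample,
                 cpm = cpm, cpm_stability = cpm_stability,
                 cpm_cross_sample = cpm_cross, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

prediction_report <- function(outcome) {
  if (is.null(outcome)) return(NULL)
  rep <- list(estimate = outcome$estimate,
              type = outcome$type, k = outcome$k)
  if (!is.null(outcome$per_group_accuracy)) {
    rep$per_group_accuracy <- as.list(outcome$per_group_accuracy)
  }
  if (!is.null(outcome$ci95)) {
    rep$ci95 <- unname(outcome$ci95)
    rep$significant <- outcome$significant
    rep$p_perm <- outcome$p_perm
  }
  if (!is.null(outcome$members)) rep$members <- outcome$members
  if (!is.null(outcome$fold_selections)) {
    rep$fold_selections <- outcome$fold_selections
  }
  rep
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- result$metrics
  long <- data.frame(
    subject_id = rep(rownames(m$degree_auc), times = ncol(m$degree_auc)),
    roi = rep(colnames(m$degree_auc), each = nrow(m$degree_auc)),
    degree_auc = as.vector(m$degree_auc),
    efficiency_auc = as.vector(m$efficiency_auc))
  write_tsv(long, file.path(out_dir, "metrics.tsv"))
  write_tsv(result$screen$stats, file.path(out_dir, "node_stats.tsv"))
  jsonlite::write_json(result$screen$consistent_nodes,
                       file.path(out_dir, "consistent_nodes.json"),
                       auto_unbox = FALSE)
  if (!is.null(result$association)) {
    write_tsv(result$association$table, file.path(out_dir, "associations.tsv"))
  }
  if (length(result$fc_association)) {
    fdir <- file.path(out_dir, "fc_associations")
    dir.create(fdir, showWarnings = FALSE)
    for (node in names(result$fc_association)) {
      write_tsv(result$fc_association[[node]]$table,
                file.path(fdir, paste0(node, ".tsv")))
    }
  }
  if (!is.null(result$intrasample)) {
    write_tsv(data.frame(observed = result$intrasample$observed,
                         predicted = result$intrasample$predicted),
              file.path(out_dir, "predictions.tsv"))
    write_tsv(data.frame(null_estimate = result$intrasample$null_distribution),
              file.path(out_dir, "null_distribution.tsv"))
  }
  report <- list(intrasample = prediction_report(result$intrasample),
                 cross_sample = prediction_report(result$cross_sample),
                 cpm = prediction_report(result$cpm),
                 cpm_cross_sample = prediction_report(result$cpm_cross_sample))
  jsonlite::write_json(report, file.path(out_dir, "prediction_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
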