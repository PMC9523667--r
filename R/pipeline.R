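#' Full-workflow configuration
#'
#' Bundles the sub-configurations of every stage with the thresholds of the
#' published protocol as defaults: ICC gate 0.75, 7:3 train/test split,
#' fivefold logistic cross-validation, probability cutoff 0.5, and the 2.5 mm
#' method-2 expansion. The ICC stage re-delineates `n_icc_nodes` nodes with
#' contour jitters emulating a same-reader repeat (`icc_intra_jitter_mm`) and
#' an independent second reader (`icc_inter_jitter_mm`).
#'
#' @param cohort a [cohort_config()]
#' @param roi a [roi_params()]
#' @param disc a [disc_config()]
#' @param filters filter subset for the feature bank
#' @param icc_threshold ICC retention gate
#' @param n_icc_nodes nodes re-segmented for the stability test
#' @param icc_intra_jitter_mm,icc_inter_jitter_mm RMS contour jitter of the
#'   simulated repeat segmentations, mm
#' @param kbest_k SelectKBest stage parameter
#' @param min_variance variance-threshold stage parameter
#' @param split_ratio training fraction
#' @param n_folds cross-validation folds
#' @param cutoff probability cutoff for ACC/SE/SP
#' @param seed master seed for split/folds/ICC resampling
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(cohort = cohort_config(), roi = roi_params(),
                            disc = disc_config(), filters = FILTER_NAMES,
                            icc_threshold = 0.75, n_icc_nodes = 45,
                            icc_intra_jitter_mm = 0.3,
                            icc_inter_jitter_mm = 0.5,
                            kbest_k = 100, min_variance = 0,
                            split_ratio = 0.7, n_folds = 5, cutoff = 0.5,
                            seed = 1L) {
  validate_cohort_config(cohort)
  if (icc_threshold < -1 || icc_threshold > 1)
    stopf("pipeline_config: icc_threshold must be in [-1, 1]")
  if (split_ratio <= 0 || split_ratio >= 1)
    stopf("pipeline_config: split_ratio must be in (0, 1)")
  structure(list(cohort = cohort, roi = roi, disc = disc, filters = filters,
                 icc_threshold = icc_threshold, n_icc_nodes = n_icc_nodes,
                 icc_intra_jitter_mm = icc_intra_jitter_mm,
                 icc_inter_jitter_mm = icc_inter_jitter_mm,
                 kbest_k = kbest_k, min_variance = min_variance,
                 split_ratio = split_ratio, n_folds = n_folds,
                 cutoff = cutoff, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

derive_cohort_rois <- function(cohort, method, params) {
  lapply(cohort$masks, derive_roi, method = method,
         spacing = cohort$spacing, params = params)
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the complete radiomics workflow on one synthetic cohort
#'
#' Generates the cohort, derives the four ROI variants, extracts the feature
#' bank per method, applies the ICC stability gate against simulated
#' re-segmentation, screens the training features through the
#' variance/SelectKBest/Lasso cascade, fits the fivefold logistic model,
#' evaluates the refit model on the held-out test set, and compares the four
#' methods' test scores pairwise with the DeLong test. Deterministic given
#' the configuration (which includes all seeds).
#'
#' @param config a [pipeline_config()]
#' @param methods subset of the ROI methods to run (default 1:4)
#' @param verbose log one line per stage per method
#' @return a run report: list with `config_hash`, `split`, per-method
#'   results (`icc`, `screening` counts and trace, `model`, `test_metrics`,
#'   `test_scores`), `delong` pairwise comparisons, and the short-diameter
#'   benchmark (`diameter`)
#' @export
run_pipeline <- function(config = pipeline_config(), methods = 1:4,
                         verbose = TRUE) {
  cohort <- generate_cohort(config$cohort)
  n <- nrow(cohort$records)
  labels <- cohort$records$label
  log_stage(verbose, "cohort: %d nodes generated", n)
  split <- stratified_split(labels, config$split_ratio,
                            seed = mix_seed(config$seed, 101L))
  log_stage(verbose, "split: %d train / %d test",
            length(split$train), length(split$test))

  set.seed(mix_seed(config$seed, 202L))
  icc_nodes <- sort(sample.int(n, min(config$n_icc_nodes, n)))
  icc_ids <- cohort$records$node_id[icc_nodes]

  results <- list()
  for (m in methods) {
    rois <- derive_cohort_rois(cohort, m, config$roi)
    tab <- extract_feature_table(cohort, rois, config$disc, config$filters)
    fx <- feature_matrix(tab)
    log_stage(verbose, "method %d: extracted %d x %d feature table",
              m, nrow(fx), ncol(fx))

    icc_sub <- icc_subtables(cohort, icc_ids, m, config)
    r1a <- fx[icc_ids, , drop = FALSE]
    icc <- stability_filter(r1a, icc_sub$r1b, icc_sub$r2,
                            config$icc_threshold)
    stable <- icc$feature[icc$retained]
    log_stage(verbose, "method %d: ICC gate retained %d / %d features",
              m, length(stable), ncol(fx))
    if (length(stable) < 2)
      stopf("pipeline stage screening, method %d: fewer than 2 ICC-stable features", m)

    xtr <- fx[split$train, stable, drop = FALSE]
    ytr <- labels[split$train]
    trace <- screen_features(xtr, ytr, config$min_variance, config$kbest_k,
                             n_folds = config$n_folds,
                             seed = mix_seed(config$seed, 303L + m))
    log_stage(verbose,
              "method %d: screening %d -> variance %d -> kbest %d -> lasso %d",
              m, length(stable), length(trace$variance),
              length(trace$kbest), length(trace$lasso))
    sel <- trace$lasso
    if (length(sel) == 0) {
      warning(sprintf("method %d: empty Lasso signature; falling back to the top SelectKBest feature", m),
              call. = FALSE)
      sel <- trace$kbest[1]
    }
    fit <- fit_logistic_cv(xtr[, sel, drop = FALSE], ytr,
                           n_folds = config$n_folds,
                           seed = mix_seed(config$seed, 404L + m),
                           cutoff = config$cutoff)
    scores <- predict_prob(fit, fx[split$test, sel, drop = FALSE])
    test_metrics <- roc_metrics(scores, labels[split$test], config$cutoff)
    log_stage(verbose, "method %d: test AUC %.3f over %d nodes",
              m, test_metrics["auc"], length(split$test))
    results[[paste0("method", m)]] <- list(
      icc = icc, n_stable = length(stable), screening = trace,
      signature = sel, model = fit, test_metrics = test_metrics,
      test_scores = scores)
  }

  delong <- list()
  if (length(methods) > 1) {
    pairs <- utils::combn(methods, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      delong[[sprintf("method%d_vs_method%d", a, b)]] <-
        delong_test(results[[paste0("method", a)]]$test_scores,
                    results[[paste0("method", b)]]$test_scores,
                    labels[split$test])
    }
  }

  diam <- cohort$records$short_diameter_mm
  yt <- youden_threshold(diam[split$train], labels[split$train])
  diameter <- list(threshold = yt$threshold, se = yt$se, sp = yt$sp,
                   train_auc = yt$auc,
                   test_auc = auc_mw(diam[split$test], labels[split$test]))

  list(config_hash = config_hash(config), seed = config$seed,
       version = as.character(utils::packageVersion("nodiomics")),
       n_nodes = n, split = split, methods = results, delong = delong,
       diameter = diameter, labels = labels)
}

# simulated second and third segmentation sessions for the ICC stage
icc_subtables <- function(cohort, icc_ids, method, config) {
  sub <- list(records = cohort$records[match(icc_ids, cohort$records$node_id), ],
              images = cohort$images[icc_ids],
              masks = cohort$masks[icc_ids], spacing = cohort$spacing)
  class(sub) <- "node_cohort"
  redo <- function(jitter, tag) {
    masks <- lapply(icc_ids, function(id)
      derive_roi(perturb_mask(cohort$masks[[id]], jitter, cohort$spacing,
                              seed = mix_seed(config$seed,
                                              tag + match(id, icc_ids))),
                 method, cohort$spacing, config$roi))
    names(masks) <- icc_ids
    feature_matrix(extract_feature_table(sub, masks, config$disc,
                                         config$filters))
  }
  list(r1b = redo(config$icc_intra_jitter_mm, 50000L),
       r2 = redo(config$icc_inter_jitter_mm, 60000L))
}

#' Render the report tables of a pipeline run
#'
#' @param report a run report from [run_pipeline()]
#' @param rater_tables optional named list of `c(tp, fp, fn, tn)` vectors;
#'   each becomes one row of the rater table
#' @return list with `metrics` (per method, train refit / CV mean / test),
#'   `screening` (per-stage survivor counts), `delong` (pairwise p-values,
#'   or a "not computed" marker), and `raters`
#' @export
render_tables <- function(report, rater_tables = NULL) {
  need <- c("methods", "split")
  miss <- setdiff(need, names(report))
  if (length(miss))
    stopf("render_tables: report is missing sections: %s",
          paste(miss, collapse = ", "))
  rows <- list()
  counts <- list()
  for (nm in names(report$methods)) {
    r <- report$methods[[nm]]
    rows[[paste0(nm, "_train")]] <-
      data.frame(method = nm, set = "train", t(r$model$train_metrics))
    rows[[paste0(nm, "_cv")]] <-
      data.frame(method = nm, set = "cv_mean", t(r$model$cv_mean))
    rows[[paste0(nm, "_test")]] <-
      data.frame(method = nm, set = "test", t(r$test_metrics))
    counts[[nm]] <- data.frame(
      method = nm, extracted = nrow(r$icc), icc_stable = r$n_stable,
      variance = length(r$screening$variance),
      kbest = length(r$screening$kbest),
      lasso = length(r$screening$lasso))
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  delong <- if (length(report$delong)) {
    do.call(rbind, lapply(names(report$delong), function(nm)
      data.frame(comparison = nm,
                 auc1 = report$delong[[nm]]$auc1,
                 auc2 = report$delong[[nm]]$auc2,
                 z = report$delong[[nm]]$z, p = report$delong[[nm]]$p)))
  } else "not computed"
  raters <- if (!is.null(rater_tables)) {
    do.call(rbind, lapply(names(rater_tables), function(nm) {
      ct <- rater_tables[[nm]]
      data.frame(rater = nm, t(rater_metrics(ct[1], ct[2], ct[3], ct[4])))
    }))
  } else "not computed"
  list(metrics = metrics, screening = do.call(rbind, counts),
       delong = delong, raters = raters)
}
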