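write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full effective-connectivity analysis pipeline
#'
#' End-to-end group analysis of a two-group cohort of ROI time series:
#' \enumerate{
#'   \item condition each subject (confound regression, bandpass filter);
#'   \item per-subject bivariate GC matrix over all ordered ROI pairs;
#'   \item consensus-connection selection (F-score ranking in a LOOCV
#'     linear-SVM loop) and masking of every subject's matrix;
#'   \item regional IFS indicators with two-sample group tests and the
#'     intra/inter correlation follow-up;
#'   \item inter-system IFS (30 ordered network pairs) with group tests,
#'     BH-FDR, and forward-feedback correlation comparisons;
#'   \item windowed inter-system IFS co-evolution with group tests;
#'   \item FPCNA regulation (full vs partial FC strength) with tests;
#'   \item single-indicator LOOCV SVM classification with permutation
#'     significance.
#' }
#' All result tables are written as TSV under `out_dir`; the run is
#' deterministic given `config$rng_seed`.
#'
#' @param subjects Named list of [subject_record()]s (>= 2 per group).
#' @param partition A [network_partition()].
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param confounds Optional named list of confound matrices per subject.
#' @param quiet Suppress stage messages?
#' @return Object of class `gcflow_report` holding every result table.
#' @export
run_pipeline <- function(subjects, partition, config = run_config(),
                         out_dir = NULL, confounds = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  groups <- vapply(subjects, function(s) s$group, character(1))
  if (sum(groups == "NC") < 2 || sum(groups == "AD") < 2)
    gc_abort(sprintf("need >= 2 subjects per group (NC: %d, AD: %d)",
                     sum(groups == "NC"), sum(groups == "AD")), "bad_cohort")
  set.seed(config$rng_seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(out_dir, "eff_conn"), showWarnings = FALSE)
  }

  ## 1: conditioning
  stage_log(quiet, "conditioning %d subjects (%d timepoints x %d ROIs)",
            length(subjects), n_timepoints(subjects[[1]]), n_roi(partition))
  cond <- lapply(subjects, function(s) {
    cf <- confounds[[s$subject_id]]
    s <- regress_confounds(s, cf)
    if (config$bandpass_enabled)
      s <- bandpass_filter(s, config$bandpass[1], config$bandpass[2],
                           config$filter_method, config$butter_order)
    s
  })

  ## 2: effective connectivity
  stage_log(quiet, "pairwise GC (order %d) for %d subjects",
            config$var_order, length(cond))
  ecms <- lapply(cond, pairwise_gc, order = config$var_order)

  ## 3: consensus connections
  features <- gc_feature_matrix(ecms)
  d <- ncol(features)
  k_grid <- config$k_grid %||% unique(pmax(1L, round(seq(0.125, 1, by = 0.125) * d)))
  stage_log(quiet, "consensus selection over k grid {%s} on %d features",
            paste(k_grid, collapse = ", "), d)
  curve <- accuracy_vs_k(features, groups, k_grid, config$svm_C,
                         config$rank_scope)
  mask <- consensus_mask(features, groups, curve$best_k, config$svm_C,
                         config$rank_scope)
  masked <- lapply(ecms, apply_mask, mask = mask)
  stage_log(quiet, "consensus: k = %d -> %d consensus connections",
            curve$best_k, mask$n_consensus)

  ## 4: regional IFS
  reg_ifs <- regional_ifs_table(masked, cond, partition)
  indicators <- c("intra_in", "intra_out", "intra_in_out", "inter_in",
                  "inter_out", "inter_in_out", "intra_inter_in",
                  "intra_inter_out")
  reg_tests <- do.call(rbind, lapply(partition$roi, function(rr) {
    sub <- reg_ifs[reg_ifs$roi == rr, ]
    do.call(rbind, lapply(indicators, function(ind) {
      gs <- group_compare(sub[[ind]][sub$group == "NC"],
                          sub[[ind]][sub$group == "AD"])
      data.frame(roi = rr, network = as.character(sub$network[1]),
                 indicator = ind, t = gs$t, df = gs$df, p = gs$p,
                 direction = gs$direction, stringsAsFactors = FALSE)
    }))
  }))
  reg_tests$significant <- reg_tests$p < config$alpha_primary
  sig_intra <- reg_tests$roi[reg_tests$indicator == "intra_in_out" &
                               reg_tests$significant]
  intra_inter <- if (length(sig_intra) && sum(groups == "AD") >= 3) {
    intra_inter_correlation(reg_ifs, sig_intra, "AD")
  } else NULL
  stage_log(quiet, "regional IFS: %d ROI x indicator tests, %d significant at p < %g",
            nrow(reg_tests), sum(reg_tests$significant), config$alpha_primary)

  ## 5: inter-system IFS
  inter_ifs <- intersystem_ifs_table(masked, cond, partition)
  pairs <- unique(inter_ifs[, c("source_network", "target_network")])
  inter_tests <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    sel <- inter_ifs$source_network == pairs$source_network[k] &
      inter_ifs$target_network == pairs$target_network[k]
    gs <- group_compare(inter_ifs$ifs[sel & inter_ifs$group == "NC"],
                        inter_ifs$ifs[sel & inter_ifs$group == "AD"])
    data.frame(source_network = pairs$source_network[k],
               target_network = pairs$target_network[k],
               t = gs$t, df = gs$df, p = gs$p, direction = gs$direction,
               stringsAsFactors = FALSE)
  }))
  fdr <- bh_fdr(inter_tests$p, config$fdr_q)
  inter_tests$p_fdr <- fdr$p_adjusted
  inter_tests$significant_fdr <- fdr$significant
  ## forward-feedback coordination: correlation of the two directions of
  ## each unordered network pair, per group, compared by Fisher Z
  unord <- pairs[pairs$source_network < pairs$target_network, ]
  ff <- do.call(rbind, lapply(seq_len(nrow(unord)), function(k) {
    a <- unord$source_network[k]; b <- unord$target_network[k]
    v <- function(s, t, g) inter_ifs$ifs[inter_ifs$source_network == s &
      inter_ifs$target_network == t & inter_ifs$group == g]
    res <- lapply(c("NC", "AD"), function(g) {
      tryCatch(correlate(v(a, b, g), v(b, a, g)),
               gcflow_error = function(e) list(r = NA_real_, n = NA, p = NA_real_))
    })
    z <- if (!is.na(res[[1]]$r) && !is.na(res[[2]]$r) &&
             abs(res[[1]]$r) < 1 && abs(res[[2]]$r) < 1 &&
             res[[1]]$n >= 4 && res[[2]]$n >= 4)
      compare_correlations(res[[1]]$r, res[[1]]$n, res[[2]]$r, res[[2]]$n)
    else list(z = NA_real_, p = NA_real_)
    data.frame(pair = paste(a, b, sep = "<->"),
               r_nc = res[[1]]$r, p_nc = res[[1]]$p,
               r_ad = res[[2]]$r, p_ad = res[[2]]$p,
               z_diff = z$z, p_diff = z$p, stringsAsFactors = FALSE)
  }))
  stage_log(quiet, "inter-system IFS: %d tests, %d significant after FDR (cutoff %.4g)",
            nrow(inter_tests), sum(inter_tests$significant_fdr), fdr$cutoff)

  ## 6: dynamic co-evolution
  tr <- cond[[1]]$tr_seconds
  windows <- make_windows(n_timepoints(cond[[1]]), tr, config$window_seconds,
                          config$step_timepoints)
  chains <- list(
    c("FPCNA", "Core", "Core", "DAN"),
    c("FPCNA", "DM", "DM", "DAN"))
  wmask <- if (config$mask_windows) mask else NULL
  coev <- do.call(rbind, lapply(chains, function(ch) {
    z <- vapply(cond, function(s) {
      wa <- windowed_intersystem_ifs(s, partition, ch[1:2], windows,
                                     config$var_order, wmask)
      wb <- windowed_intersystem_ifs(s, partition, ch[3:4], windows,
                                     config$var_order, wmask)
      coevolution(wa, wb)$fisher_z
    }, numeric(1))
    gt <- coevolution_group_tests(z[groups == "NC"], z[groups == "AD"])
    data.frame(chain = paste0(ch[1], "->", ch[2], " vs ", ch[3], "->", ch[4]),
               mean_z_nc = mean(z[groups == "NC"]),
               mean_z_ad = mean(z[groups == "AD"]),
               t_nc = gt$one_sample_nc$t, p_nc = gt$one_sample_nc$p,
               t_ad = gt$one_sample_ad$t, p_ad = gt$one_sample_ad$p,
               t_group = gt$two_sample$t, p_group = gt$two_sample$p,
               stringsAsFactors = FALSE)
  }))
  stage_log(quiet, "co-evolution: %d chains over %d windows", nrow(coev),
            windows$n_windows)

  ## 7: FPCNA regulation
  reg_tab <- regulation_table(cond, partition)
  reg_test <- regulation_tests(reg_tab)
  stage_log(quiet, "regulation: %d blocks", nrow(reg_test))

  ## 8: classification
  ord <- order(-abs(reg_tests$t))
  top <- reg_tests[ord[seq_len(min(config$n_class_features, nrow(reg_tests)))], ]
  feat_tab <- do.call(cbind, lapply(seq_len(nrow(top)), function(k) {
    sel <- reg_ifs$roi == top$roi[k]
    v <- reg_ifs[[top$indicator[k]]][sel]
    stats::setNames(data.frame(v), paste(top$roi[k], top$indicator[k], sep = ":"))
  }))
  feat_tab$group <- reg_ifs$group[reg_ifs$roi == top$roi[1]]
  class_sum <- classify_indicators(
    feat_tab, setdiff(names(feat_tab), "group"), config$svm_C,
    if (config$n_permutations >= 100) config$n_permutations else 0,
    config$rng_seed)
  stage_log(quiet, "classification: %d single-indicator models", nrow(class_sum))

  report <- structure(list(
    config = config, partition = partition, groups = groups,
    ecms = ecms, masked = masked,
    accuracy_curve = curve, mask = mask,
    regional_ifs = reg_ifs, regional_tests = reg_tests,
    intra_inter_correlations = intra_inter,
    intersystem_ifs = inter_ifs, intersystem_tests = inter_tests,
    forward_feedback = ff, coevolution_tests = coev,
    regulation = reg_tab, regulation_tests = reg_test,
    classification = class_sum), class = "gcflow_report")

  if (!is.null(out_dir)) {
    for (e in masked)
      write_eff_conn(e, file.path(out_dir, "eff_conn",
                                  paste0(e$subject_id, ".tsv")))
    write_consensus_mask(mask, file.path(out_dir, "consensus_mask.tsv"))
    write_tsv(reg_ifs, file.path(out_dir, "regional_ifs.tsv"))
    write_tsv(reg_tests, file.path(out_dir, "regional_tests.tsv"))
    if (!is.null(intra_inter))
      write_tsv(intra_inter, file.path(out_dir, "intra_inter_correlations.tsv"))
    write_tsv(inter_tests, file.path(out_dir, "intersystem_tests.tsv"))
    write_tsv(ff, file.path(out_dir, "forward_feedback.tsv"))
    write_tsv(coev, file.path(out_dir, "coevolution_tests.tsv"))
    write_tsv(reg_test, file.path(out_dir, "regulation_tests.tsv"))
    write_tsv(class_sum, file.path(out_dir, "classification.tsv"))
    stage_log(quiet, "results written to %s", out_dir)
  }
  report
}

#' @export
print.gcflow_report <- function(x, ...) {
  cat("<gcflow_report>\n")
  cat(sprintf("  cohort: %d NC, %d AD; %d ROIs\n",
              sum(x$groups == "NC"), sum(x$groups == "AD"),
              length(x$partition$roi)))
  cat(sprintf("  consensus: k = %d -> %d connections\n",
              x$mask$chosen_k, x$mask$n_consensus))
  cat(sprintf("  regional tests significant (p < %g): %d / %d\n",
              x$config$alpha_primary, sum(x$regional_tests$significant),
              nrow(x$regional_tests)))
  cat(sprintf("  inter-system tests significant after FDR: %d / %d\n",
              sum(x$intersystem_tests$significant_fdr),
              nrow(x$intersystem_tests)))
  cat(sprintf("  best classification accuracy: %.3f (%s)\n",
              max(x$classification$accuracy),
              x$classification$indicator[which.max(x$classification$accuracy)]))
  invisible(x)
}

#' Summarize a pipeline report
#'
#' @param object A `gcflow_report`.
#' @param ... Unused.
#' @return The report, invisibly; prints the main result tables.
#' @export
summary.gcflow_report <- function(object, ...) {
  print(object)
  cat("\nInter-system tests (significant after FDR):\n")
  print(object$intersystem_tests[object$intersystem_tests$significant_fdr, ],
        row.names = FALSE)
  cat("\nCo-evolution tests:\n")
  print(object$coevolution_tests, row.names = FALSE)
  cat("\nRegulation tests:\n")
  print(object$regulation_tests, row.names = FALSE)
  cat("\nClassification:\n")
  print(object$classification, row.names = FALSE)
  invisible(object)
}

#' Write a simulated cohort to disk (manifest + TSVs + ground truth)
#'
#' Companion to [simulate_cohort()]: writes one time-series TSV per
#' subject, a manifest, the partition, and a ground-truth JSON (coupling
#' matrices and planted edge list) for test harnesses.
#'
#' @param subjects Result of [simulate_cohort()].
#' @param partition The [network_partition()] used.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(subjects, partition, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "timeseries"), showWarnings = FALSE)
  man <- data.frame(
    subject_id = names(subjects),
    group = vapply(subjects, function(s) s$group, character(1)),
    path = file.path("timeseries", paste0(names(subjects), ".tsv")),
    stringsAsFactors = FALSE)
  for (s in subjects)
    write_timeseries_table(s, file.path(out_dir, "timeseries",
                                        paste0(s$subject_id, ".tsv")))
  write_tsv(man, file.path(out_dir, "manifest.tsv"))
  write_tsv(data.frame(roi_label = partition$roi,
                       network = as.character(partition$network)),
            file.path(out_dir, "partition.tsv"))
  gt <- attr(subjects, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(list(
      scenario = gt$scenario,
      coupling_nc = gt$coupling_nc$A, coupling_ad = gt$coupling_ad$A,
      roi_labels = partition$roi, planted = gt$planted),
      file.path(out_dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(out_dir)
}
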