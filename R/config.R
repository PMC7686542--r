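#' Pipeline run configuration
#'
#' Collects every tunable constant of the analysis. Defaults are the
#' values used throughout the package's reference analysis: VAR order 1,
#' 0.01-0.08 Hz band, 60-s windows shifted by 3 timepoints, primary
#' threshold p < 0.01, FDR q = 0.05, linear SVM with C = 1, 1000 label
#' permutations.
#'
#' @param var_order VAR model order for GC estimation.
#' @param bandpass Length-2 numeric, passband in Hz.
#' @param bandpass_enabled Apply the temporal filter? (default TRUE).
#' @param filter_method `"fft"` (ideal zero-phase, default) or
#'   `"butterworth"` (forward-backward), see [bandpass_filter()].
#' @param butter_order Butterworth order when `filter_method` is
#'   `"butterworth"`.
#' @param window_seconds Sliding-window length in seconds.
#' @param step_timepoints Window shift in samples.
#' @param alpha_primary Uncorrected primary significance level.
#' @param fdr_q Benjamini-Hochberg level for the 30 inter-system tests.
#' @param svm_C Linear-SVM cost parameter.
#' @param n_permutations Label permutations for classification
#'   significance (0 disables the permutation test).
#' @param rng_seed Integer seed making the run reproducible.
#' @param k_grid Candidate consensus feature counts (`NULL` = an
#'   8-point grid spanning the feature count).
#' @param rank_scope `"fold"` (leakage-safe, default) or `"global"`
#'   F-score ranking for consensus selection.
#' @param mask_windows Restrict windowed IFS to consensus connections?
#' @param n_class_features How many top-|t| regional indicators to
#'   classify one at a time.
#' @return Object of class `run_config` (a validated named list).
#' @export
run_config <- function(var_order = 1, bandpass = c(0.01, 0.08),
                       bandpass_enabled = TRUE,
                       filter_method = c("fft", "butterworth"),
                       butter_order = 2,
                       window_seconds = 60, step_timepoints = 3,
                       alpha_primary = 0.01, fdr_q = 0.05, svm_C = 1,
                       n_permutations = 1000, rng_seed = 1, k_grid = NULL,
                       rank_scope = c("fold", "global"), mask_windows = TRUE,
                       n_class_features = 3) {
  rank_scope <- match.arg(rank_scope)
  filter_method <- match.arg(filter_method)
  if (var_order < 1) gc_abort("var_order must be >= 1", "bad_config")
  if (length(bandpass) != 2 || bandpass[1] <= 0 || bandpass[1] >= bandpass[2])
    gc_abort("bandpass must be (low, high) with 0 < low < high", "bad_config")
  if (n_permutations != 0 && n_permutations < 100)
    gc_abort("n_permutations must be 0 or >= 100", "bad_config")
  structure(list(var_order = as.integer(var_order), bandpass = bandpass,
                 bandpass_enabled = isTRUE(bandpass_enabled),
                 filter_method = filter_method,
                 butter_order = as.integer(butter_order),
                 window_seconds = window_seconds,
                 step_timepoints = as.integer(step_timepoints),
                 alpha_primary = alpha_primary, fdr_q = fdr_q, svm_C = svm_C,
                 n_permutations = as.integer(n_permutations),
                 rng_seed = as.integer(rng_seed), k_grid = k_grid,
                 rank_scope = rank_scope, mask_windows = isTRUE(mask_windows),
                 n_class_features = as.integer(n_class_features)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Every key of [run_config()] may appear; missing keys take defaults.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    gc_abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
             "bad_config")
  do.call(run_config, vals)
}

#' Read a cohort manifest
#'
#' A manifest is a TSV with a header and columns `subject_id`, `group`,
#' `path` (time-series table, relative to the manifest's directory or
#' absolute) and optionally `confounds` (path or empty).
#'
#' @param path Manifest file path.
#' @return Data frame with resolved absolute paths.
#' @export
read_manifest <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "path")
  if (!all(need %in% names(tab)))
    gc_abort("manifest needs columns subject_id, group, path", "bad_manifest")
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(p == "" | is.na(p), NA_character_,
                                ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                       file.path(base, p)))
  tab$path <- resolve(tab$path)
  if (!is.null(tab$confounds)) tab$confounds <- resolve(tab$confounds)
  tab
}

#' Load the subjects listed in a manifest
#'
#' @param manifest A [read_manifest()] data frame.
#' @param partition A [network_partition()].
#' @param tr_seconds Sampling interval in seconds.
#' @return Named list of [subject_record()]s.
#' @export
load_subjects <- function(manifest, partition, tr_seconds = 2) {
  subjects <- lapply(seq_len(nrow(manifest)), function(i)
    read_timeseries_table(manifest$path[i], partition,
                          manifest$subject_id[i], manifest$group[i],
                          tr_seconds))
  names(subjects) <- manifest$subject_id
  subjects
}
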