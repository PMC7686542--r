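#' Sliding-window specification
#'
#' Windows are half-open sample ranges `[start, start + window_samples)`
#' with 0-based starts at a constant step: `0, step, 2 step, ...` while
#' the window still fits inside the series. The default geometry (60-s
#' windows shifted by 3 timepoints) gives, at T = 190 and TR = 2 s,
#' 54 windows of 30 samples with last start 159.
#'
#' @param T Series length in samples.
#' @param tr_seconds Sampling interval in seconds.
#' @param window_seconds Window length in seconds (default 60).
#' @param step_samples Shift between consecutive windows, in samples
#'   (default 3).
#' @return Object of class `window_spec`: `window_samples`,
#'   `step_samples`, `starts` (0-based), `n_windows`.
#' @export
make_windows <- function(T, tr_seconds = 2, window_seconds = 60,
                         step_samples = 3) {
  ws <- round(window_seconds / tr_seconds)
  if (ws < 3) gc_abort("window too short", "bad_window")
  if (T < ws)
    gc_abort(sprintf("series length %d shorter than window (%d samples)",
                     T, ws), "bad_window")
  starts <- seq(0L, T - ws, by = step_samples)
  structure(list(window_samples = as.integer(ws),
                 step_samples = as.integer(step_samples),
                 starts = as.integer(starts),
                 n_windows = length(starts)),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %d windows of %d samples, step %d, last start %d\n",
              x$n_windows, x$window_samples, x$step_samples,
              x$starts[x$n_windows]))
  invisible(x)
}

#' Windowed inter-system information-flow strength
#'
#' For one ordered network pair (source, target), computes within every
#' sliding window the GC magnitude of each cross-network ROI pair
#' (optionally restricted to the consensus connections) and averages
#' them, yielding a per-window time course of the directed interaction
#' strength between the two subsystems. Data within each window are
#' re-centred by the estimator's intercept; the series is not re-filtered
#' per window.
#'
#' @param record A conditioned [subject_record()].
#' @param partition A [network_partition()].
#' @param pair Length-2 character vector `(source_network, target_network)`.
#' @param windows A [make_windows()] specification.
#' @param order VAR order (default 1).
#' @param mask Optional [consensus_mask()] restricting the averaged
#'   ROI pairs; if no cross-pair survives the mask, all cross pairs are
#'   used with a warning.
#' @return Object of class `windowed_ifs`: `subject_id`, `pair`,
#'   `values` (one averaged IFS per window), `starts`.
#' @export
windowed_intersystem_ifs <- function(record, partition, pair, windows,
                                     order = 1, mask = NULL) {
  stopifnot(inherits(record, "subject_record"),
            inherits(windows, "window_spec"), length(pair) == 2)
  src <- rois_of(partition, pair[1]); tgt <- rois_of(partition, pair[2])
  if (pair[1] == pair[2]) gc_abort("pair must name two distinct networks",
                                   "bad_pair")
  sel <- expand.grid(source = src, target = tgt, stringsAsFactors = FALSE)
  if (!is.null(mask)) {
    m <- if (inherits(mask, "consensus_mask")) mask$mask else mask
    keep <- m[cbind(match(sel$source, rownames(m)),
                    match(sel$target, colnames(m)))] != 0
    if (!any(keep)) {
      warning("consensus mask removes every cross pair; using all pairs")
    } else sel <- sel[keep, ]
  }
  cols <- union(src, tgt)
  Z <- record$data[, cols, drop = FALSE]
  si <- match(sel$source, cols); ti <- match(sel$target, cols)
  vals <- vapply(windows$starts, function(s0) {
    W <- Z[(s0 + 1):(s0 + windows$window_samples), , drop = FALSE]
    F <- tryCatch(pairwise_gc_matrix(W, order), gcflow_error = function(e)
      gc_abort(sprintf("window starting at %d: %s", s0, conditionMessage(e)),
               "window_failure"))
    mean(F[cbind(si, ti)])
  }, numeric(1))
  structure(list(subject_id = record$subject_id,
                 pair = paste(pair, collapse = "->"),
                 values = vals, starts = windows$starts),
            class = "windowed_ifs")
}

#' Temporal co-evolution of two windowed IFS time courses
#'
#' Pearson correlation across windows between two inter-system IFS time
#' courses, with Fisher's r-to-z transform — the per-subject measure of
#' how tightly two inter-system causal interactions wax and wane
#' together.
#'
#' @param series_a,series_b Numeric vectors (equal length >= 5), e.g. the
#'   `values` of two [windowed_intersystem_ifs()] results.
#' @return A `correlation_result` (see [correlate()]).
#' @export
coevolution <- function(series_a, series_b) {
  if (inherits(series_a, "windowed_ifs")) series_a <- series_a$values
  if (inherits(series_b, "windowed_ifs")) series_b <- series_b$values
  if (length(series_a) < 5) gc_abort("need at least 5 windows", "too_few")
  correlate(series_a, series_b)
}

one_sample_t <- function(z, mu = 0) {
  if (length(z) < 2) gc_abort("group size must be >= 2", "too_few")
  if (stats::sd(z) == 0) {
    if (mean(z) == mu) return(list(t = 0, df = length(z) - 1, p = 1))
    return(list(t = sign(mean(z) - mu) * Inf, df = length(z) - 1, p = 0))
  }
  ht <- stats::t.test(z, mu = mu)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Group-level tests on co-evolution Fisher-z values
#'
#' One-sample t-test of the Fisher-z co-evolution values against zero
#' within each group (is the co-evolution reliably nonzero?) and a
#' pooled two-sample t-test across groups (is it weaker in AD?).
#'
#' @param z_values_nc,z_values_ad Per-subject Fisher-z values.
#' @return List: `one_sample_nc`, `one_sample_ad` (each `t`, `df`, `p`),
#'   `two_sample` (a [group_compare()] result).
#' @export
coevolution_group_tests <- function(z_values_nc, z_values_ad) {
  list(one_sample_nc = one_sample_t(z_values_nc),
       one_sample_ad = one_sample_t(z_values_ad),
       two_sample = group_compare(z_values_nc, z_values_ad))
}
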