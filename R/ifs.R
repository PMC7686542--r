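#' Regional information-flow-strength indicators
#'
#' For each ROI `r` in network `N`, sums the directed GC magnitudes into
#' and out of `r`, split by whether the other endpoint lies inside or
#' outside `N`:
#' \describe{
#'   \item{intra_in / intra_out}{inflow from / outflow to other ROIs of
#'     the same network}
#'   \item{inter_in / inter_out}{inflow from / outflow to ROIs of the
#'     other networks}
#'   \item{intra_in_out, inter_in_out, intra_inter_in, intra_inter_out}{
#'     the four pairwise sums of the above}
#' }
#'
#' @param ecm An [eff_conn()] matrix (typically consensus-masked).
#' @param partition A [network_partition()] matching the matrix labels.
#' @return Data frame, one row per ROI: `subject_id`, `roi`, `network`
#'   and the eight indicators.
#' @export
regional_ifs <- function(ecm, partition) {
  stopifnot(inherits(ecm, "eff_conn"), inherits(partition, "network_partition"))
  F <- ecm$values
  if (!identical(rownames(F), partition$roi))
    gc_abort("matrix ROI labels do not match the partition", "label_mismatch")
  net <- partition$network
  same <- outer(net, net, "==")
  diag(same) <- FALSE                      # self excluded everywhere
  other <- outer(net, net, "!=")
  intra_in  <- colSums(F * same)           # into target (column)
  intra_out <- rowSums(F * same)           # out of source (row)
  inter_in  <- colSums(F * other)
  inter_out <- rowSums(F * other)
  data.frame(
    subject_id = ecm$subject_id, roi = partition$roi, network = net,
    intra_in = intra_in, intra_out = intra_out,
    intra_in_out = intra_in + intra_out,
    inter_in = inter_in, inter_out = inter_out,
    inter_in_out = inter_in + inter_out,
    intra_inter_in = intra_in + inter_in,
    intra_inter_out = intra_out + inter_out,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Inter-system information-flow strength
#'
#' For every ordered pair of distinct networks (source, target), the sum
#' of GC magnitudes from the source network's ROIs to the target
#' network's ROIs: 30 ordered pairs for six networks, separating the
#' forward and feedback flow between each network pair.
#'
#' @inheritParams regional_ifs
#' @return Data frame with `subject_id`, `source_network`,
#'   `target_network`, `ifs`.
#' @export
intersystem_ifs <- function(ecm, partition) {
  stopifnot(inherits(ecm, "eff_conn"), inherits(partition, "network_partition"))
  F <- ecm$values
  if (!identical(rownames(F), partition$roi))
    gc_abort("matrix ROI labels do not match the partition", "label_mismatch")
  nets <- network_names()
  grid <- expand.grid(source_network = nets, target_network = nets,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$source_network != grid$target_network, ]
  grid$ifs <- mapply(function(s, t) {
    sum(F[partition$network == s, partition$network == t])
  }, grid$source_network, grid$target_network)
  data.frame(subject_id = ecm$subject_id, grid, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pooled-variance two-sample t comparison of two groups
#'
#' Student's two-sample t-test with pooled variance (df = n1 + n2 - 2).
#' The t statistic is oriented as AD minus NC, so a negative t means the
#' quantity is lower in the AD group. Degenerate inputs (zero pooled
#' variance) return t = 0 when the means agree and a flagged infinite t
#' otherwise.
#'
#' @param values_nc,values_ad Numeric vectors (>= 2 values each).
#' @return List of class `group_stats`: `t`, `df`, `p`, `mean_nc`,
#'   `mean_ad`, `direction` (`"AD<NC"` / `"AD>NC"` / `"none"`),
#'   `infinite` flag.
#' @export
group_compare <- function(values_nc, values_ad) {
  if (length(values_nc) < 2 || length(values_ad) < 2)
    gc_abort("each group needs at least 2 values", "too_few")
  m1 <- mean(values_ad); m0 <- mean(values_nc)
  pooled <- sum((values_ad - m1)^2) + sum((values_nc - m0)^2)
  df <- length(values_ad) + length(values_nc) - 2
  if (pooled == 0) {
    if (m1 == m0)
      return(structure(list(t = 0, df = df, p = 1, mean_nc = m0, mean_ad = m1,
                            direction = "none", infinite = FALSE),
                       class = "group_stats"))
    return(structure(list(t = sign(m1 - m0) * Inf, df = df, p = 0,
                          mean_nc = m0, mean_ad = m1,
                          direction = if (m1 > m0) "AD>NC" else "AD<NC",
                          infinite = TRUE), class = "group_stats"))
  }
  ht <- stats::t.test(values_ad, values_nc, var.equal = TRUE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_nc = m0, mean_ad = m1,
                 direction = if (m1 == m0) "none"
                             else if (m1 > m0) "AD>NC" else "AD<NC",
                 infinite = FALSE),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g (%s; mean NC %.4g, mean AD %.4g)\n",
              x$df, x$t, x$p, x$direction, x$mean_nc, x$mean_ad))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure at level `q`: the adaptive cutoff is the largest
#' ordered p-value `p_(k)` with `p_(k) <= k q / m`; hypotheses with
#' `p <=` cutoff are declared significant.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List: `significant` (logical, same order as input), `cutoff`
#'   (0 when nothing passes), `p_adjusted` (BH-adjusted p-values).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) gc_abort("empty p-value vector", "too_few")
  if (any(pvals < 0 | pvals > 1)) gc_abort("p-values outside [0, 1]", "bad_p")
  m <- length(pvals)
  ord <- order(pvals)
  pass <- which(pvals[ord] <= seq_len(m) * q / m)
  any_pass <- length(pass) > 0
  cutoff <- if (any_pass) pvals[ord][max(pass)] else 0
  list(significant = if (any_pass) pvals <= cutoff else rep(FALSE, m),
       cutoff = cutoff,
       p_adjusted = stats::p.adjust(pvals, method = "BH"))
}

#' Pearson correlation with Fisher's r-to-z transform
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return List of class `correlation_result`: `r`, `fisher_z`
#'   (`atanh(r)`), `n`, `p` (two-sided).
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) gc_abort("unequal lengths", "length_mismatch")
  if (length(x) < 3) gc_abort("need at least 3 paired values", "too_few")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    gc_abort("zero-variance input", "constant_series")
  ct <- stats::cor.test(x, y)
  structure(list(r = unname(ct$estimate), fisher_z = atanh(unname(ct$estimate)),
                 n = length(x), p = ct$p.value),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (z = %.3f), n = %d, p = %.4g\n",
              x$r, x$fisher_z, x$n, x$p))
  invisible(x)
}

#' Correlation between intra- and inter-network IFS across subjects
#'
#' For each requested ROI, the Pearson correlation (across the subjects
#' of one group) between its `intra_in_out` and `inter_in_out` regional
#' IFS, the standard follow-up for regions whose within-network flow is
#' disrupted.
#'
#' @param ifs_table Row-bound [regional_ifs()] tables for several
#'   subjects, plus a `group` column (see [regional_ifs_table()]).
#' @param rois ROI labels to analyse.
#' @param group Group whose subjects enter the correlation.
#' @return Data frame: `roi`, `r`, `fisher_z`, `n`, `p`.
#' @export
intra_inter_correlation <- function(ifs_table, rois, group = "AD") {
  tab <- ifs_table[ifs_table$group == group, ]
  out <- lapply(rois, function(rr) {
    sub <- tab[tab$roi == rr, ]
    if (nrow(sub) < 3)
      gc_abort(sprintf("fewer than 3 subjects for ROI %s", rr), "too_few")
    ## consensus masking can zero an indicator for every subject; such
    ## degenerate ROIs get NA rather than aborting a cohort-level run
    cr <- tryCatch(correlate(sub$intra_in_out, sub$inter_in_out),
                   gcflow_constant_series = function(e)
                     list(r = NA_real_, fisher_z = NA_real_,
                          n = nrow(sub), p = NA_real_))
    data.frame(roi = rr, r = cr$r, fisher_z = cr$fisher_z, n = cr$n, p = cr$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare two independent correlations (Fisher Z test)
#'
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, referred to
#' the standard normal; two-sided p.
#'
#' @param r1,r2 Correlations with `|r| < 1`.
#' @param n1,n2 Sample sizes (>= 4).
#' @return List: `z`, `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    gc_abort("|r| must be < 1 for the Z test", "bad_r")
  if (n1 < 4 || n2 < 4) gc_abort("need n >= 4 in each group", "too_few")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Regional IFS table for a cohort
#'
#' @param ecms Named list of [eff_conn()] matrices.
#' @param subjects The matching list of [subject_record()]s (for group
#'   labels).
#' @param partition A [network_partition()].
#' @return Row-bound [regional_ifs()] output with a `group` column.
#' @export
regional_ifs_table <- function(ecms, subjects, partition) {
  out <- mapply(function(e, s) {
    tab <- regional_ifs(e, partition)
    tab$group <- s$group
    tab
  }, ecms, subjects, SIMPLIFY = FALSE)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Inter-system IFS table for a cohort
#'
#' @inheritParams regional_ifs_table
#' @return Row-bound [intersystem_ifs()] output with a `group` column.
#' @export
intersystem_ifs_table <- function(ecms, subjects, partition) {
  out <- mapply(function(e, s) {
    tab <- intersystem_ifs(e, partition)
    tab$group <- s$group
    tab
  }, ecms, subjects, SIMPLIFY = FALSE)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
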