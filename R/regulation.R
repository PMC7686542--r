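#' The five default functional-connectivity blocks
#'
#' The blocks over which the frontoparietal regulatory effect is
#' quantified: the within-network blocks of Core, MTL and DM, and the
#' cross-network blocks Core-DAN and DM-DAN.
#'
#' @return Named list; each element is either one network name (within
#'   block) or two (cross block).
#' @export
default_blocks <- function() {
  list(within_Core = "Core", within_MTL = "MTL", within_DM = "DM",
       Core_DAN = c("Core", "DAN"), DM_DAN = c("DM", "DAN"))
}

## unordered ROI pairs of a block: all within pairs of one network, or
## all cross pairs between two networks — each pair counted once
block_pairs <- function(partition, block) {
  if (length(block) == 1) {
    r <- rois_of(partition, block)
    if (length(r) < 2) gc_abort("block needs at least 2 ROIs", "too_few")
    t(utils::combn(r, 2))
  } else {
    a <- rois_of(partition, block[1]); b <- rois_of(partition, block[2])
    as.matrix(expand.grid(a, b, stringsAsFactors = FALSE))
  }
}

#' Summed full functional-connectivity strength of a block
#'
#' Sum over the block's unordered ROI pairs of the Fisher-z-transformed
#' Pearson correlation between the two series.
#'
#' @param record A conditioned [subject_record()].
#' @param partition A [network_partition()].
#' @param block One network name (within block) or two (cross block).
#' @return Scalar summed Fisher-z strength.
#' @export
full_fc_strength <- function(record, partition, block) {
  stopifnot(inherits(record, "subject_record"))
  fc_strength_of(record$data, partition, block)
}

fc_strength_of <- function(data, partition, block) {
  pairs <- block_pairs(partition, block)
  sds <- apply(data, 2, stats::sd)
  used <- unique(c(pairs[, 1], pairs[, 2]))
  if (any(sds[used] == 0))
    gc_abort(sprintf("constant ROI series: %s",
                     paste(used[sds[used] == 0], collapse = ", ")),
             "constant_series")
  cm <- stats::cor(data[, used, drop = FALSE])
  rv <- cm[cbind(match(pairs[, 1], used), match(pairs[, 2], used))]
  rv <- pmin(pmax(rv, -1 + 1e-12), 1 - 1e-12)
  sum(atanh(rv))
}

#' Block strength after regressing out a network's signals
#'
#' Each block ROI's series is replaced by its least-squares residual
#' against an intercept plus every ROI series of the removed network
#' (default FPCNA), then the summed Fisher-z strength is recomputed on
#' the residuals — the block-partial correlation strength. The drop
#' `full - partial` is the removed network's regulatory effect on the
#' block.
#'
#' @inheritParams full_fc_strength
#' @param removed_network Network whose signals are regressed out
#'   (default `"FPCNA"`).
#' @return Scalar summed partial Fisher-z strength.
#' @export
partial_fc_strength <- function(record, partition, block,
                                removed_network = "FPCNA") {
  stopifnot(inherits(record, "subject_record"))
  rem <- rois_of(partition, removed_network)
  data <- record$data
  if (length(rem) == 0) return(fc_strength_of(data, partition, block))
  if (length(rem) >= nrow(data) - 2)
    gc_abort("removed network has too many ROIs for the series length",
             "too_few")
  X <- cbind(1, data[, rem, drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    warning(sprintf("rank-deficient regressor set; dropping: %s",
                    paste(setdiff(colnames(X), colnames(X)[keep]),
                          collapse = ", ")))
    qx <- qr(X[, keep, drop = FALSE])
  }
  resid <- qr.resid(qx, data)
  fc_strength_of(resid, partition, block)
}

#' Per-subject regulation table
#'
#' Full strength, partial strength (after removing the regulating
#' network) and their difference (the regulatory effect) for each block
#' and subject.
#'
#' @param subjects List of conditioned [subject_record()]s.
#' @param partition A [network_partition()].
#' @param blocks List of blocks (default [default_blocks()]).
#' @param removed_network Regulating network (default `"FPCNA"`).
#' @return Data frame: `subject_id`, `group`, `block`, `full`, `partial`,
#'   `effect`.
#' @export
regulation_table <- function(subjects, partition, blocks = default_blocks(),
                             removed_network = "FPCNA") {
  out <- lapply(subjects, function(s) {
    rows <- lapply(names(blocks), function(bn) {
      fu <- full_fc_strength(s, partition, blocks[[bn]])
      pa <- partial_fc_strength(s, partition, blocks[[bn]], removed_network)
      data.frame(subject_id = s$subject_id, group = s$group, block = bn,
                 full = fu, partial = pa, effect = fu - pa,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Group tests on the regulatory effect
#'
#' Per block: a paired t-test of full vs partial strength within each
#' group (is the regulatory effect nonzero?) and a pooled two-sample
#' t-test on the per-subject effects across groups (does the regulating
#' network bear harder on one group?).
#'
#' @param reg_table A [regulation_table()] with both groups present.
#' @return Data frame, one row per block: paired t/df/p per group and
#'   the two-sample t/df/p on the effect (oriented AD minus NC).
#' @export
regulation_tests <- function(reg_table) {
  blocks <- unique(reg_table$block)
  out <- lapply(blocks, function(bn) {
    sub <- reg_table[reg_table$block == bn, ]
    paired <- lapply(c("NC", "AD"), function(g) {
      gg <- sub[sub$group == g, ]
      if (nrow(gg) < 2) gc_abort("group size must be >= 2", "too_few")
      one_sample_t(gg$full - gg$partial)
    })
    two <- group_compare(sub$effect[sub$group == "NC"],
                         sub$effect[sub$group == "AD"])
    data.frame(block = bn,
               t_paired_nc = paired[[1]]$t, p_paired_nc = paired[[1]]$p,
               t_paired_ad = paired[[2]]$t, p_paired_ad = paired[[2]]$p,
               t_group = two$t, df_group = two$df, p_group = two$p,
               direction = two$direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
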