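#' Stack effective-connectivity matrices into a feature matrix
#'
#' Vectorizes every ordered ROI pair (source != target) of each subject's
#' GC matrix into one row, the feature representation used for F-score
#' ranking and SVM classification. Column names are `"source->target"`.
#'
#' @param ecms List of [eff_conn()] objects with identical ROI labels.
#' @return Numeric matrix, subjects x R(R-1), with attribute `pairs`
#'   (data frame `source`, `target`, `row`, `col`) and `roi_labels`.
#' @export
gc_feature_matrix <- function(ecms) {
  stopifnot(length(ecms) >= 1, all(vapply(ecms, inherits, TRUE, "eff_conn")))
  roi <- rownames(ecms[[1]]$values)
  R <- length(roi)
  off <- which(!diag(R))                     # column-major off-diagonal
  idx <- arr_ind <- arrayInd(off, c(R, R))
  pairs <- data.frame(source = roi[idx[, 1]], target = roi[idx[, 2]],
                      row = idx[, 1], col = idx[, 2],
                      stringsAsFactors = FALSE)
  X <- t(vapply(ecms, function(e) {
    if (!identical(rownames(e$values), roi))
      gc_abort("ROI labels differ across subjects", "label_mismatch")
    as.vector(e$values)[off]
  }, numeric(length(off))))
  colnames(X) <- paste0(pairs$source, "->", pairs$target)
  rownames(X) <- vapply(ecms, function(e) e$subject_id, character(1))
  attr(X, "pairs") <- pairs
  attr(X, "roi_labels") <- roi
  X
}

#' F-score ranking of features for a two-class contrast
#'
#' For feature `x` with grand mean `m`, class means `m+`, `m-` and class
#' sample variances `v+`, `v-`:
#' `F = ((m+ - m)^2 + (m- - m)^2) / (v+ + v-)`.
#' Larger F means better univariate separation. A feature whose pooled
#' within-class variance is exactly zero gets `F = Inf` (ranked first,
#' with a warning). Rank ties break by column position (stable).
#'
#' @param features Numeric matrix, samples x features.
#' @param labels Two-class vector, one label per row.
#' @return Data frame of class `feature_ranking`: `feature`, `f_score`,
#'   `rank` (1 = best).
#' @export
f_scores <- function(features, labels) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2) gc_abort("need exactly two classes", "bad_labels")
  if (min(table(labels)) < 2)
    gc_abort("need >= 2 samples per class", "too_few")
  a <- features[labels == classes[1], , drop = FALSE]
  b <- features[labels == classes[2], , drop = FALSE]
  m  <- colMeans(features); ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  f <- ((ma - m)^2 + (mb - m)^2) / (va + vb)
  f[(va + vb) == 0 & ((ma - m)^2 + (mb - m)^2) > 0] <- Inf
  f[(va + vb) == 0 & ((ma - m)^2 + (mb - m)^2) == 0] <- 0
  if (any(is.infinite(f)))
    warning("zero within-class variance: feature(s) ranked first with F = Inf")
  ord <- order(-f, seq_along(f))
  rank <- integer(length(f)); rank[ord] <- seq_along(f)
  structure(data.frame(feature = colnames(features) %||% as.character(seq_along(f)),
                       f_score = unname(f), rank = rank,
                       stringsAsFactors = FALSE),
            class = c("feature_ranking", "data.frame"))
}

## top-k feature indices for one training split
top_k_features <- function(features, labels, k, scope_ranking = NULL) {
  fr <- scope_ranking %||% f_scores(features, labels)
  which(fr$rank <= k)
}

#' LOOCV accuracy as a function of the number of top-ranked features
#'
#' For each candidate `k`, runs leave-one-out cross-validation of a
#' linear SVM on the top-`k` F-score-ranked features. By default the
#' ranking is recomputed inside every fold from the training split only
#' (leakage-safe); `rank_scope = "global"` ranks once on all samples for
#' comparison.
#'
#' @param features Samples x features matrix (see [gc_feature_matrix()]).
#' @param labels Two-class vector.
#' @param k_grid Integer vector of candidate feature counts.
#' @param svm_C SVM cost parameter (default 1).
#' @param rank_scope `"fold"` (default) or `"global"`.
#' @return List: `k` (grid), `accuracy` (LOOCV accuracy per k), `best_k`
#'   (smallest k achieving the maximum).
#' @export
accuracy_vs_k <- function(features, labels, k_grid, svm_C = 1,
                          rank_scope = c("fold", "global")) {
  rank_scope <- match.arg(rank_scope)
  labels <- as.character(labels)
  n <- nrow(features); d <- ncol(features)
  k_grid <- as.integer(k_grid)
  if (any(k_grid < 1 | k_grid > d))
    gc_abort(sprintf("k must lie in [1, %d]", d), "bad_k")
  global_rank <- if (rank_scope == "global") f_scores(features, labels) else NULL
  correct <- matrix(0L, n, length(k_grid))
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    fr <- global_rank %||% f_scores(features[tr, , drop = FALSE], labels[tr])
    for (kk in seq_along(k_grid)) {
      sel <- which(fr$rank <= k_grid[kk])
      pred <- svm_predict_one(features[tr, sel, drop = FALSE], labels[tr],
                              features[i, sel, drop = FALSE], svm_C)
      correct[i, kk] <- as.integer(pred$label == labels[i])
    }
  }
  acc <- colMeans(correct)
  list(k = k_grid, accuracy = acc, best_k = k_grid[which.max(acc)])
}

#' Consensus connection mask across LOOCV folds
#'
#' The consensus set is the intersection, over all leave-one-out folds,
#' of each fold's top-`chosen_k` training-ranked features; connections in
#' the consensus set are marked 1 in an R x R mask (diagonal 0). An empty
#' intersection is permitted and warned about.
#'
#' @inheritParams accuracy_vs_k
#' @param chosen_k Number of top-ranked features retained per fold.
#' @return Object of class `consensus_mask`: list with `mask` (0/1
#'   matrix with ROI dimnames), `chosen_k`, `n_consensus`.
#' @export
consensus_mask <- function(features, labels, chosen_k, svm_C = 1,
                           rank_scope = c("fold", "global")) {
  rank_scope <- match.arg(rank_scope)
  labels <- as.character(labels)
  pairs <- attr(features, "pairs")
  roi <- attr(features, "roi_labels")
  if (is.null(pairs) || is.null(roi))
    gc_abort("features must come from gc_feature_matrix()", "bad_features")
  d <- ncol(features)
  if (chosen_k < 1 || chosen_k > d)
    gc_abort(sprintf("chosen_k must lie in [1, %d]", d), "bad_k")
  n <- nrow(features)
  keep <- rep(TRUE, d)
  global_rank <- if (rank_scope == "global") f_scores(features, labels) else NULL
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    fr <- global_rank %||% f_scores(features[tr, , drop = FALSE], labels[tr])
    keep <- keep & (fr$rank <= chosen_k)
  }
  if (!any(keep))
    warning("consensus set is empty: no feature survives every fold")
  R <- length(roi)
  mask <- matrix(0L, R, R, dimnames = list(roi, roi))
  mask[cbind(pairs$row[keep], pairs$col[keep])] <- 1L
  structure(list(mask = mask, chosen_k = as.integer(chosen_k),
                 n_consensus = sum(keep)),
            class = "consensus_mask")
}

#' @export
print.consensus_mask <- function(x, ...) {
  cat(sprintf("<consensus_mask> %d consensus connections (k = %d)\n",
              x$n_consensus, x$chosen_k))
  invisible(x)
}

#' Apply a consensus mask to an effective-connectivity matrix
#'
#' Entries outside the mask become exactly 0; the matrix is flagged as
#' masked.
#'
#' @param ecm An [eff_conn()] object.
#' @param mask A [consensus_mask()] (or bare 0/1 matrix of same shape).
#' @return A masked [eff_conn()].
#' @export
apply_mask <- function(ecm, mask) {
  stopifnot(inherits(ecm, "eff_conn"))
  m <- if (inherits(mask, "consensus_mask")) mask$mask else mask
  if (!all(dim(m) == dim(ecm$values)))
    gc_abort("mask shape does not match the matrix", "shape_mismatch")
  ecm$values <- ecm$values * (m != 0)
  ecm$masked <- TRUE
  ecm
}

#' Write / read a consensus mask as a 0/1 TSV
#'
#' @param mask A [consensus_mask()].
#' @param path File path.
#' @export
write_consensus_mask <- function(mask, path) {
  stopifnot(inherits(mask, "consensus_mask"))
  utils::write.table(
    data.frame(roi = rownames(mask$mask), mask$mask, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_consensus_mask
#' @param chosen_k The k recorded in the object read back.
#' @export
read_consensus_mask <- function(path, chosen_k = NA_integer_) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "integer"
  structure(list(mask = m, chosen_k = as.integer(chosen_k),
                 n_consensus = sum(m != 0)),
            class = "consensus_mask")
}
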