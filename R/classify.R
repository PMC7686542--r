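## Shared linear-SVM machinery (libsvm via e1071). Training features are
## standardized with the training split's mean/SD only; decision values
## are oriented so that positive means the AD (patient) class.

svm_predict_one <- function(Xtr, ytr, Xte, C = 1, positive = "AD") {
  ytr <- factor(ytr)
  if (nlevels(ytr) < 2)
    gc_abort("training fold contains a single class", "single_class")
  mu <- colMeans(Xtr)
  s <- apply(Xtr, 2, stats::sd); s[s == 0] <- 1
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, s, "/")
  Xte <- sweep(sweep(matrix(Xte, ncol = length(mu)), 2, mu), 2, s, "/")
  m <- e1071::svm(Xtr, ytr, kernel = "linear", cost = C, scale = FALSE,
                  fitted = FALSE)
  w <- crossprod(m$coefs, m$SV)
  dv <- as.vector(Xte %*% t(w)) - m$rho
  ## libsvm's positive decision side is the class of the first training
  ## sample (order of appearance), not the first factor level
  lev <- unique(as.character(ytr))
  pred <- ifelse(dv > 0, lev[1], lev[2])
  if (lev[1] != positive) dv <- -dv          # orient positive class up
  list(label = pred, decision = dv)
}

loocv_core <- function(features, labels, C = 1, positive = "AD") {
  features <- as.matrix(features)
  labels <- as.character(labels)
  n <- nrow(features)
  if (n < 4) gc_abort("need at least 4 samples", "too_few")
  pred <- character(n); dv <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    out <- svm_predict_one(features[tr, , drop = FALSE], labels[tr],
                           features[i, , drop = FALSE], C, positive)
    pred[i] <- out$label; dv[i] <- out$decision
  }
  list(pred = pred, decision = dv)
}

#' Leave-one-out linear-SVM classification
#'
#' Each subject in turn is held out; a linear SVM (cost `C`) is trained
#' on the remaining subjects, with features standardized by the training
#' split's statistics, and predicts the held-out subject. AD is the
#' positive class: accuracy, sensitivity (AD detection rate), specificity
#' (NC detection rate) come from the aggregated confusion counts, and
#' AUC from the held-out decision values.
#'
#' @param features Numeric matrix, subjects x features (a single column
#'   for single-indicator classification).
#' @param labels Vector of `"NC"` / `"AD"` labels.
#' @param C SVM cost parameter (default 1).
#' @return Object of class `classification_result`: `accuracy`,
#'   `sensitivity`, `specificity`, `auc`, `decision_values`,
#'   `predictions`, `confusion`, `n`.
#' @export
loocv_svm <- function(features, labels, C = 1) {
  labels <- as.character(labels)
  res <- loocv_core(features, labels, C, positive = "AD")
  tp <- sum(res$pred == "AD" & labels == "AD")
  tn <- sum(res$pred == "NC" & labels == "NC")
  fp <- sum(res$pred == "AD" & labels == "NC")
  fn <- sum(res$pred == "NC" & labels == "AD")
  n <- length(labels)
  out <- structure(list(
    accuracy = (tp + tn) / n,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auc = roc_auc(res$decision, labels),
    decision_values = res$decision, predictions = res$pred,
    confusion = c(TP = tp, TN = tn, FP = fp, FN = fn), n = n),
    class = "classification_result")
  ## accuracy identity: (sens * n_AD + spec * n_NC) / n
  n_ad <- sum(labels == "AD"); n_nc <- sum(labels == "NC")
  stopifnot(isTRUE(all.equal(
    out$accuracy, (out$sensitivity * n_ad + out$specificity * n_nc) / n)))
  out
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result> n = %d: accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f%s\n",
    x$n, x$accuracy, x$sensitivity, x$specificity, x$auc,
    if (!is.null(x$permutation_p)) sprintf(", permutation p = %.4g", x$permutation_p)
    else ""))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive-class (AD) decision
#' value exceeds a randomly chosen negative-class (NC) value, counting
#' ties as one half — computed from rank sums.
#'
#' @param decision_values Numeric scores, larger = more AD-like.
#' @param labels `"NC"` / `"AD"` labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(decision_values, labels) {
  labels <- as.character(labels)
  n_ad <- sum(labels == "AD"); n_nc <- sum(labels == "NC")
  if (n_ad == 0 || n_nc == 0)
    gc_abort("both classes must be present", "single_class")
  r <- rank(decision_values)               # midranks handle ties
  (sum(r[labels == "AD"]) - n_ad * (n_ad + 1) / 2) / (n_ad * n_nc)
}

#' Permutation p-value for LOOCV classification accuracy
#'
#' Re-runs the complete LOOCV with `n_perm` random label permutations
#' and reports the add-one estimator
#' `p = (1 + #\{permuted accuracy >= observed\}) / (1 + n_perm)`,
#' which is never exactly zero (its minimum is `1/(1+n_perm)`).
#'
#' @inheritParams loocv_svm
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed for the permutations.
#' @return The permutation p-value (scalar in `(0, 1]`).
#' @export
permutation_pvalue <- function(features, labels, C = 1, n_perm = 1000,
                               seed = 1) {
  if (n_perm < 100) gc_abort("n_perm must be at least 100", "bad_nperm")
  labels <- as.character(labels)
  obs <- mean(loocv_core(features, labels, C)$pred == labels)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    pl <- sample(labels)
    acc <- mean(loocv_core(features, pl, C)$pred == pl)
    if (acc >= obs) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

#' Classify a cohort from selected IFS indicators
#'
#' Convenience wrapper: single-indicator (one feature at a time) or
#' multi-feature LOOCV classification with permutation significance.
#'
#' @param feature_table Data frame with one row per subject, a `group`
#'   column and numeric indicator columns.
#' @param indicators Character vector of indicator column names; each is
#'   classified separately.
#' @param C SVM cost (default 1).
#' @param n_perm Permutations for the p-value (default 1000).
#' @param seed Integer seed.
#' @return Data frame: indicator, accuracy, sensitivity, specificity,
#'   auc, permutation_p.
#' @export
classify_indicators <- function(feature_table, indicators, C = 1,
                                n_perm = 1000, seed = 1) {
  out <- lapply(indicators, function(ind) {
    X <- matrix(feature_table[[ind]], ncol = 1)
    res <- loocv_svm(X, feature_table$group, C)
    p <- if (n_perm >= 100)
      permutation_pvalue(X, feature_table$group, C, n_perm, seed)
    else NA_real_
    data.frame(indicator = ind, accuracy = res$accuracy,
               sensitivity = res$sensitivity, specificity = res$specificity,
               auc = res$auc, permutation_p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
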