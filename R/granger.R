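## Lagged design for a VAR-style regression: rows p+1..T of y against
## columns [y_{t-1..t-p} | x_{t-1..t-p}]; intercept added by the caller.
lag_design <- function(y, p, x = NULL) {
  T <- length(y)
  idx <- (p + 1):T
  lags <- function(v) sapply(seq_len(p), function(k) v[idx - k])
  X <- lags(y)
  if (!is.null(x)) X <- cbind(X, lags(x))
  list(resp = y[idx], X = as.matrix(X))
}

ols_rss <- function(resp, X) {
  qx <- qr(cbind(1, X))
  sum(qr.resid(qx, resp)^2)
}

#' Bivariate Granger-causality magnitude for one ordered pair
#'
#' Quantifies the directed influence of series `x` on series `y` as the
#' Geweke log variance ratio
#' `F = ln(RSS_restricted / RSS_full)`,
#' where the restricted model regresses `y_t` on an intercept and its own
#' `p` lags, and the full model adds the `p` lags of `x`. Both models use
#' the same `T - p` estimation rows, so the common residual-variance
#' denominator cancels. The measure is nonnegative (in nats); values that
#' come out negative by rounding are clipped to 0.
#'
#' @param x,y Numeric series of equal length `T >= 10 * order`.
#' @param order VAR model order `p` (default 1).
#' @param signed If `TRUE`, attach the sign of the full model's first
#'   cross-lag coefficient to the magnitude (a sensitivity-analysis
#'   variant; signed values must not be summed into IFS statistics).
#' @return Nonnegative scalar, the GC magnitude `F_{x->y}` (signed when
#'   `signed = TRUE`).
#' @export
gc_pair <- function(x, y, order = 1, signed = FALSE) {
  if (length(x) != length(y))
    gc_abort("series must have equal length", "length_mismatch")
  T <- length(y)
  if (T < 10 * order)
    gc_abort(sprintf("series length %d too short for order %d (need >= %d)",
                     T, order, 10 * order), "too_short")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    gc_abort("constant (zero-variance) series", "constant_series")
  r <- lag_design(y, order)
  f <- lag_design(y, order, x)
  rss_r <- ols_rss(r$resp, r$X)
  rss_f <- ols_rss(f$resp, f$X)
  if (rss_f <= 0) return(0)
  out <- max(0, log(rss_r / rss_f))
  if (signed) {
    beta <- qr.coef(qr(cbind(1, f$X)), f$resp)
    out <- out * sign(beta[2 + order])       # first cross-lag coefficient
  }
  out
}

#' Suggest a VAR model order by BIC
#'
#' Fits univariate AR(p) models to every ROI series over a candidate
#' order grid (common estimation rows) and returns the order minimizing
#' the mean BIC — a quick data-driven check on the default order 1.
#'
#' @param record A conditioned [subject_record()].
#' @param max_order Largest candidate order (default 5).
#' @return List: `order` (suggested), `bic` (mean BIC per candidate).
#' @export
suggest_order <- function(record, max_order = 5) {
  stopifnot(inherits(record, "subject_record"))
  Z <- record$data
  T <- nrow(Z)
  if (T < 10 * max_order)
    gc_abort("series too short for the requested maximum order", "too_short")
  bics <- vapply(seq_len(max_order), function(p) {
    mean(apply(Z, 2, function(y) {
      d <- lag_design(y, max_order)          # common rows across orders
      X <- d$X[, seq_len(p), drop = FALSE]
      n <- length(d$resp)
      rss <- ols_rss(d$resp, X)
      n * log(rss / n) + (p + 1) * log(n)
    }))
  }, numeric(1))
  list(order = which.min(bics), bic = bics)
}

## Closed-form vectorized all-pairs GC for order 1. With an intercept in
## both models, OLS on [1, y_{t-1}] and [1, y_{t-1}, x_{t-1}] reduces to
## regressions among mean-centred lag/response blocks, so every ordered
## pair's RSS comes from three R x R cross-product matrices.
pairwise_gc_order1 <- function(Z) {
  T <- nrow(Z); R <- ncol(Z)
  Y <- scale(Z[2:T, , drop = FALSE], scale = FALSE)
  L <- scale(Z[1:(T - 1), , drop = FALSE], scale = FALSE)
  Syy <- colSums(Y * Y)                      # total SS per target
  GLL <- crossprod(L)                        # lag Gram
  GLY <- crossprod(L, Y)                     # GLY[i, j] = <L_i, Y_j>
  gll <- diag(GLL); gly <- diag(GLY)
  rss_r <- Syy - gly^2 / gll                 # restricted, per target j
  ## full model for source i (rows) -> target j (cols)
  Ajj <- matrix(gll, R, R, byrow = TRUE); Aii <- matrix(gll, R, R)
  Cjj <- matrix(gly, R, R, byrow = TRUE); Cij <- GLY
  det <- Ajj * Aii - GLL^2
  b1 <- (Cjj * Aii - Cij * GLL) / det
  b2 <- (Cij * Ajj - Cjj * GLL) / det
  rss_f <- matrix(Syy, R, R, byrow = TRUE) - (b1 * Cjj + b2 * Cij)
  F <- log(matrix(rss_r, R, R, byrow = TRUE) / rss_f)
  F[!is.finite(F) | F < 0] <- 0
  ## collinear lag pairs (singular 2x2 system): no extra information
  F[abs(det) < .Machine$double.eps * outer(gll, gll)] <- 0
  diag(F) <- 0
  F
}

#' Directed effective-connectivity matrix for one subject
#'
#' Fills an R x R matrix with the bivariate GC magnitude [gc_pair()] for
#' every ordered ROI pair; entry `(i, j)` is the influence of ROI `i`
#' (row, source) on ROI `j` (column, target). The diagonal is zero.
#'
#' @param record A conditioned [subject_record()].
#' @param order VAR model order (default 1). Order 1 uses an exact
#'   closed-form all-pairs path; higher orders loop over [gc_pair()].
#' @return An object of class `eff_conn`: list with `values` (R x R
#'   matrix, dimnames = ROI labels), `subject_id`, `var_order`, `masked`.
#' @export
pairwise_gc <- function(record, order = 1) {
  stopifnot(inherits(record, "subject_record"))
  F <- pairwise_gc_matrix(record$data, order)
  eff_conn(F, record$subject_id, order)
}

## All-pairs GC on a bare timepoints x series matrix (dimnames kept).
pairwise_gc_matrix <- function(Z, order = 1) {
  sds <- apply(Z, 2, stats::sd)
  if (any(sds == 0))
    gc_abort(sprintf("constant (zero-variance) ROI series: %s",
                     paste(colnames(Z)[sds == 0], collapse = ", ")),
             "constant_series")
  if (nrow(Z) < 10 * order)
    gc_abort(sprintf("only %d timepoints: too short for order %d",
                     nrow(Z), order), "too_short")
  R <- ncol(Z)
  if (order == 1) {
    F <- pairwise_gc_order1(Z)
  } else {
    F <- matrix(0, R, R)
    for (j in seq_len(R)) {
      rj <- lag_design(Z[, j], order)
      rss_r <- ols_rss(rj$resp, rj$X)
      for (i in seq_len(R)) {
        if (i == j) next
        fij <- lag_design(Z[, j], order, Z[, i])
        rss_f <- ols_rss(fij$resp, fij$X)
        F[i, j] <- if (rss_f > 0) max(0, log(rss_r / rss_f)) else 0
      }
    }
  }
  dimnames(F) <- list(colnames(Z), colnames(Z))
  F
}

#' Construct an effective-connectivity matrix object
#'
#' @param values Nonnegative R x R matrix with identical row/column ROI
#'   labels; `values[i, j]` is the GC magnitude from ROI i to ROI j.
#' @param subject_id Subject identifier.
#' @param var_order VAR order used in estimation.
#' @param masked Logical: has a consensus mask been applied?
#' @return An object of class `eff_conn`.
#' @export
eff_conn <- function(values, subject_id = "", var_order = 1, masked = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    gc_abort("effective-connectivity matrix must be square", "bad_matrix")
  if (is.null(rownames(values)) ||
      !identical(rownames(values), colnames(values)))
    gc_abort("row and column ROI labels must be present and identical",
             "bad_matrix")
  if (any(!is.finite(values)) || any(values < 0) || any(diag(values) != 0))
    gc_abort("entries must be finite, nonnegative, with a zero diagonal",
             "bad_matrix")
  structure(list(values = values, subject_id = as.character(subject_id),
                 var_order = as.integer(var_order), masked = isTRUE(masked)),
            class = "eff_conn")
}

#' @export
print.eff_conn <- function(x, ...) {
  cat(sprintf("<eff_conn> %s: %d x %d, order %d, %s; %d nonzero edges\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$var_order,
              if (x$masked) "masked" else "unmasked",
              sum(x$values > 0)))
  invisible(x)
}

#' Write / read an effective-connectivity matrix as TSV
#'
#' @param ecm An [eff_conn()] object.
#' @param path File path.
#' @return `path` (write) or an `eff_conn` (read).
#' @export
write_eff_conn <- function(ecm, path) {
  stopifnot(inherits(ecm, "eff_conn"))
  utils::write.table(
    data.frame(roi = rownames(ecm$values), ecm$values, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eff_conn
#' @param subject_id,var_order,masked Metadata for the object read back.
#' @export
read_eff_conn <- function(path, subject_id = basename(path), var_order = 1,
                          masked = FALSE) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (!identical(rownames(m), colnames(m)))
    gc_abort("row and column ROI labels disagree", "bad_matrix")
  eff_conn(m, subject_id, var_order, masked)
}
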