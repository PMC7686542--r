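#' Regress confound signals out of every ROI series
#'
#' Each ROI time course is replaced by its ordinary-least-squares residual
#' against the confound design (an intercept is always included), the
#' standard nuisance-removal step for motion parameters, drift terms and
#' mean tissue signals. With no confounds the series are mean-centred.
#'
#' @param record A [subject_record()].
#' @param confounds Optional numeric matrix (timepoints x k) of confound
#'   regressors, with column names. `NULL` means intercept only.
#' @return A [subject_record()] holding the residual series.
#' @export
regress_confounds <- function(record, confounds = NULL) {
  stopifnot(inherits(record, "subject_record"))
  T <- n_timepoints(record)
  X <- matrix(1, T, 1, dimnames = list(NULL, "(intercept)"))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != T)
      gc_abort(sprintf("confounds have %d rows but series has %d timepoints",
                       nrow(confounds), T), "confound_mismatch")
    if (is.null(colnames(confounds)))
      colnames(confounds) <- paste0("confound_", seq_len(ncol(confounds)))
    X <- cbind(X, confounds)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    gc_abort(sprintf("confound design is rank deficient; offending column(s): %s",
                     paste(dropped, collapse = ", ")), "rank_deficient")
  }
  record$data <- qr.resid(qx, record$data)
  record
}

#' Temporal bandpass filter
#'
#' Zero-phase bandpass applied to each ROI series independently, the
#' standard step for isolating the slow resting-state band (0.01-0.08 Hz
#' by default elsewhere in the package). Two filter families:
#' \describe{
#'   \item{`"fft"` (default)}{ideal rectangular filter in the frequency
#'     domain, as used by the common resting-state toolchains: the series
#'     is mean-centred, Fourier transformed, out-of-band bins are zeroed
#'     and the series inverted back. Exactly zero-phase, linear and
#'     idempotent (it is a spectral projection).}
#'   \item{`"butterworth"`}{Butterworth filter of the given order applied
#'     forward-backward (zero phase) with reflective padding of roughly
#'     one low-frequency period to damp edge transients. Smoother
#'     roll-off, but repeated application keeps attenuating the
#'     transition band.}
#' }
#' Both preserve series length.
#'
#' @param record A [subject_record()].
#' @param low_hz,high_hz Passband edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 * tr_seconds)` (the Nyquist frequency).
#' @param method `"fft"` or `"butterworth"`.
#' @param order Butterworth order (default 2; ignored for `"fft"`).
#' @return A [subject_record()] with filtered series.
#' @export
bandpass_filter <- function(record, low_hz = 0.01, high_hz = 0.08,
                            method = c("fft", "butterworth"), order = 2) {
  stopifnot(inherits(record, "subject_record"))
  method <- match.arg(method)
  tr <- record$tr_seconds
  nyq <- 1 / (2 * tr)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    gc_abort(sprintf(
      "band (%g, %g) Hz invalid: need 0 < low < high < Nyquist = %g Hz",
      low_hz, high_hz, nyq), "bad_band")
  T <- n_timepoints(record)
  X <- scale(record$data, scale = FALSE)     # remove DC exactly
  if (method == "fft") {
    freqs <- (seq_len(T) - 1) / (T * tr)     # DFT bin frequencies
    freqs <- pmin(freqs, 1 / tr - freqs)     # fold to [0, Nyquist]
    keep <- freqs >= low_hz & freqs <= high_hz
    Y <- stats::mvfft(X)
    Y[!keep, ] <- 0
    out <- Re(stats::mvfft(Y, inverse = TRUE)) / T
  } else {
    bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
    npad <- min(T - 1, ceiling(1 / (low_hz * tr)))
    out <- apply(X, 2, function(x) {
      xp <- c(2 * x[1] - x[(npad + 1):2], x,
              2 * x[T] - x[(T - 1):(T - npad)])
      y <- signal::filtfilt(bf, xp)
      y[(npad + 1):(npad + T)]
    })
  }
  dimnames(out) <- dimnames(record$data)
  record$data <- out
  record
}

#' Condition a subject's series (confound regression then bandpass)
#'
#' Applies [regress_confounds()] followed by [bandpass_filter()], the
#' fixed order of the two ROI-level preprocessing steps.
#'
#' @inheritParams regress_confounds
#' @inheritParams bandpass_filter
#' @return A conditioned [subject_record()].
#' @export
condition_subject <- function(record, confounds = NULL,
                              low_hz = 0.01, high_hz = 0.08,
                              method = c("fft", "butterworth"), order = 2) {
  bandpass_filter(regress_confounds(record, confounds), low_hz, high_hz,
                  match.arg(method), order)
}
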