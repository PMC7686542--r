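#' Construct a subject record
#'
#' A subject record holds one subject's ROI time-series matrix (rows =
#' timepoints, columns = ROIs in the partition's canonical order) together
#' with the group label and the sampling interval (TR).
#'
#' @param data Numeric matrix, timepoints x ROIs; column names must match
#'   the partition's ROI labels (any order; columns are reordered).
#' @param partition A [network_partition()].
#' @param subject_id Subject identifier string.
#' @param group Group label, `"NC"` or `"AD"`.
#' @param tr_seconds Repetition time (sampling interval) in seconds.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(data, partition, subject_id, group = c("NC", "AD"),
                           tr_seconds = 2) {
  group <- match.arg(group)
  stopifnot(inherits(partition, "network_partition"))
  data <- as.matrix(data)
  if (!is.numeric(data))
    gc_abort("time-series data must be numeric", "nonnumeric_data")
  if (is.null(colnames(data)))
    gc_abort("time-series matrix must carry ROI column names", "missing_roi")
  missing <- setdiff(partition$roi, colnames(data))
  if (length(missing))
    gc_abort(sprintf("missing ROI column(s): %s", paste(missing, collapse = ", ")),
             "missing_roi")
  if (anyDuplicated(colnames(data)))
    gc_abort(sprintf("duplicate ROI column(s): %s",
                     paste(unique(colnames(data)[duplicated(colnames(data))]),
                           collapse = ", ")),
             "duplicate_roi")
  data <- data[, partition$roi, drop = FALSE]
  if (anyNA(data) || any(!is.finite(data)))
    gc_abort("time-series data contain missing or non-finite values",
             "nonnumeric_data")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    gc_abort("tr_seconds must be a positive number", "bad_tr")
  if (nrow(data) < 3)
    gc_abort("need at least 3 timepoints", "too_short")
  structure(
    list(subject_id = as.character(subject_id), group = group,
         data = data, tr_seconds = tr_seconds),
    class = "subject_record")
}

#' Read one subject's ROI time series from a delimited table
#'
#' The file must be delimited text with a header row of ROI labels and a
#' numeric body (rows = timepoints). Columns are reordered to the
#' partition's canonical ROI order; a missing ROI column, a duplicated
#' label and a non-numeric cell each raise a distinct classed error.
#'
#' @inheritParams subject_record
#' @param path Path to the table (tab-delimited).
#' @return A [subject_record()].
#' @export
read_timeseries_table <- function(path, partition, subject_id = basename(path),
                                  group = c("NC", "AD"), tr_seconds = 2) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  notnum <- names(tab)[!vapply(tab, is.numeric, logical(1))]
  if (length(notnum))
    gc_abort(sprintf("non-numeric values in column(s): %s",
                     paste(notnum, collapse = ", ")),
             "nonnumeric_data")
  subject_record(as.matrix(tab), partition, subject_id, group, tr_seconds)
}

#' Write a subject's time series as a TSV table
#'
#' @param record A [subject_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_table <- function(record, path) {
  stopifnot(inherits(record, "subject_record"))
  utils::write.table(record$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s [%s]: %d timepoints x %d ROIs, TR = %g s\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

n_timepoints <- function(record) nrow(record$data)
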