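#' @keywords internal
"_PACKAGE"

## Classed error helper: every user-facing failure gets a condition class
## "gcflow_<what>" so callers (and tests) can distinguish failure modes.
gc_abort <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("gcflow_", class), "gcflow_error")))
}

#' Names of the six network subsystems
#'
#' The parcellation groups regions of interest (ROIs) into the three
#' default-network subsystems (medial temporal lobe, dorsomedial
#' prefrontal, midline core), the two frontoparietal control subsystems,
#' and the dorsal attention network.
#'
#' @return Character vector of the six network names.
#' @export
network_names <- function() c("MTL", "DM", "Core", "FPCNA", "FPCNB", "DAN")

#' Construct a network partition
#'
#' A network partition assigns each ROI label to exactly one of the six
#' subsystems. ROI order is meaningful: it fixes the column order of every
#' time-series matrix and connectivity matrix downstream.
#'
#' @param roi_labels Character vector of unique ROI identifiers.
#' @param networks Character vector (same length) of network names, each
#'   one of [network_names()].
#' @return An object of class `network_partition`: a list with elements
#'   `roi` (ROI labels in canonical order) and `network` (factor of
#'   network membership, levels in [network_names()] order).
#' @seealso [read_partition()], [default_partition()]
#' @export
network_partition <- function(roi_labels, networks) {
  roi_labels <- as.character(roi_labels)
  networks <- as.character(networks)
  if (length(roi_labels) != length(networks))
    gc_abort("roi_labels and networks must have equal length", "bad_partition")
  if (anyDuplicated(roi_labels)) {
    dup <- unique(roi_labels[duplicated(roi_labels)])
    gc_abort(sprintf("duplicate ROI label(s): %s", paste(dup, collapse = ", ")),
             "duplicate_roi")
  }
  bad <- setdiff(unique(networks), network_names())
  if (length(bad))
    gc_abort(sprintf("unknown network name(s): %s", paste(bad, collapse = ", ")),
             "unknown_network")
  structure(
    list(roi = roi_labels,
         network = factor(networks, levels = network_names())),
    class = "network_partition")
}

#' Read a network partition from a delimited file
#'
#' @param path Path to a tab- or whitespace-delimited text file with a
#'   header row and two columns: `roi_label`, `network`.
#' @return A [network_partition()].
#' @export
read_partition <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    gc_abort("partition file must have columns roi_label and network",
             "bad_partition")
  network_partition(tab[[1]], tab[[2]])
}

#' The packaged default 52-ROI partition
#'
#' Six subsystems with 6 (MTL), 9 (DM), 9 (Core), 11 (FPCNA), 9 (FPCNB)
#' and 8 (DAN) regions, 52 ROIs in total. Labels are systematic
#' (`MTL_01`, ..., `DAN_08`); substitute your own partition file to use
#' anatomical names.
#'
#' @return A [network_partition()] with 52 ROIs.
#' @export
default_partition <- function() {
  read_partition(system.file("extdata", "default_partition.tsv",
                             package = "gcflow", mustWork = TRUE))
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("<network_partition> %d ROIs in %d networks\n",
              length(x$roi), nlevels(x$network)))
  print(table(x$network))
  invisible(x)
}

#' ROIs belonging to one network
#'
#' @param partition A [network_partition()].
#' @param network A network name.
#' @return Character vector of ROI labels.
#' @export
rois_of <- function(partition, network) {
  stopifnot(inherits(partition, "network_partition"))
  if (!network %in% network_names())
    gc_abort(sprintf("unknown network name: %s", network), "unknown_network")
  partition$roi[partition$network == network]
}

n_roi <- function(partition) length(partition$roi)
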