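#' Default network labels of the 12-network cortical partition
#'
#' Labels of the twelve functional networks used throughout the package, in
#' the canonical order of the partition table.
#'
#' @return Character vector of 12 network labels.
#' @export
default_network_names <- function() {
  c("Visual 1", "Visual 2", "Somatomotor", "Cingulo-opercular",
    "Language", "Default mode", "Fronto-parietal", "Auditory",
    "Posterior multimodal", "Dorsal attention", "Ventral multimodal",
    "Orbito-affective")
}

#' Default network sizes for the 360-region cortical parcellation
#'
#' Thirty regions per network. The underlying parcellation has 360 cortical
#' regions in 12 networks; the exact per-network parcel counts are a property
#' of the externally built partition table and are not needed by any
#' computation here, so equal sizes are used as the synthetic default.
#'
#' @return Integer vector of length 12 summing to 360.
#' @export
default_network_sizes <- function() {
  rep(30L, 12L)
}

#' Build a region-to-network partition
#'
#' Assigns contiguous region ids to networks. The partition is the single
#' source of truth for region order: every time-series and FC matrix is
#' validated against its ordered region labels.
#'
#' @param network_sizes Integer vector, number of regions per network.
#' @param network_names Character vector of unique network labels, same
#'   length as `network_sizes`.
#' @return An object of class `network_partition` with fields `region_id`
#'   (0-based integer ids), `region_label` (e.g. `"R000"`), `network`
#'   (factor), `networks`, `n_total`, and `n_c` (named per-network counts).
#' @examples
#' p <- make_partition(c(2, 2), c("A", "B"))
#' p$n_total
#' @export
make_partition <- function(network_sizes = default_network_sizes(),
                           network_names = default_network_names()) {
  if (length(network_sizes) != length(network_names)) {
    stop("`network_sizes` and `network_names` must have equal length")
  }
  network_sizes <- as.integer(network_sizes)
  if (any(is.na(network_sizes)) || any(network_sizes < 1L)) {
    stop("every network must contain at least one region")
  }
  if (anyDuplicated(network_names) > 0L) {
    stop("network names must be unique")
  }
  n_total <- sum(network_sizes)
  network <- factor(rep(network_names, times = network_sizes),
                    levels = network_names)
  structure(
    list(
      region_id = seq_len(n_total) - 1L,
      region_label = sprintf("R%03d", seq_len(n_total) - 1L),
      network = network,
      networks = network_names,
      n_total = n_total,
      n_c = stats::setNames(network_sizes, network_names)
    ),
    class = "network_partition"
  )
}

#' @export
print.network_partition <- function(x, ...) {
  cat("network_partition:", x$n_total, "regions in",
      length(x$networks), "networks\n")
  print(x$n_c)
  invisible(x)
}

# Internal: indices (1-based) of a network's regions; errors on unknown label.
network_indices <- function(partition, network) {
  if (!network %in% partition$networks) {
    stop("unknown network label: ", network)
  }
  which(partition$network == network)
}
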