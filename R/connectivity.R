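# Functional-connectivity matrices and between-network global connectivity
# (BGC) summaries. BGC of region i in network C is the mean FC weight from
# i to every region outside C:
#   BGC_i = sum_{j not in C} W_ij / (N_total - N_C)
# Network-level BGC is the unweighted mean of BGC_i over the network's
# regions. FC weights are averaged as raw Pearson r (no Fisher transform).

#' Pearson functional-connectivity matrix
#'
#' @param ts A [parcellated_ts()] (typically nuisance-regressed residuals
#'   on retained frames).
#' @return Symmetric region x region Pearson correlation matrix with unit
#'   diagonal and the time series' region labels as dimnames.
#' @export
fc_matrix <- function(ts) {
  stopifnot(inherits(ts, "parcellated_ts"))
  if (ncol(ts$data) < 3L) stop("need at least 3 retained frames")
  sds <- apply(ts$data, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance region(s): ",
         paste(ts$region_ids[sds == 0], collapse = ", "))
  }
  W <- stats::cor(t(ts$data))
  diag(W) <- 1
  W
}

#' Region- and network-level between-network global connectivity
#'
#' @param fc Region x region FC matrix aligned with `partition`.
#' @param partition A `network_partition`; must have at least 2 networks.
#' @return Object of class `bgc_profile`: `region_bgc` (named per-region
#'   means over out-of-network connections), `network_bgc` (named unweighted
#'   per-network means of `region_bgc`), `excluded_networks`
#'   (empty for the standard profile).
#' @export
bgc_profile <- function(fc, partition) {
  validate_fc(fc, partition)
  if (length(partition$networks) < 2L) {
    stop("BGC is undefined for a single-network partition")
  }
  n <- partition$n_total
  region_bgc <- numeric(n)
  for (net in partition$networks) {
    idx <- which(partition$network == net)
    out <- setdiff(seq_len(n), idx)
    region_bgc[idx] <- rowMeans(fc[idx, out, drop = FALSE])
  }
  names(region_bgc) <- partition$region_label
  network_bgc <- vapply(partition$networks, function(net) {
    mean(region_bgc[partition$network == net])
  }, numeric(1))
  structure(
    list(region_bgc = region_bgc, network_bgc = network_bgc,
         excluded_networks = character(0)),
    class = "bgc_profile"
  )
}

#' Mean within-network functional connectivity
#'
#' Mean FC over the unordered within-network region pairs (diagonal
#' excluded).
#'
#' @inheritParams bgc_profile
#' @param network Network label.
#' @return Scalar mean within-network FC.
#' @export
within_network_fc <- function(fc, partition, network) {
  validate_fc(fc, partition)
  idx <- network_indices(partition, network)
  if (length(idx) < 2L) stop("network has fewer than 2 regions: ", network)
  sub <- fc[idx, idx]
  mean(sub[upper.tri(sub)])
}

#' Network BGC with selected target networks excluded
#'
#' For each region of `network`, averages FC to regions whose network is
#' neither the region's own nor in `excluded`; the network value is the
#' unweighted mean over the network's regions. With `excluded = character(0)`
#' this equals the standard network BGC exactly.
#'
#' @inheritParams within_network_fc
#' @param excluded Character set of network labels removed from the targets.
#' @return Scalar network-level exclusion BGC.
#' @export
bgc_excluding <- function(fc, partition, network, excluded = character(0)) {
  validate_fc(fc, partition)
  idx <- network_indices(partition, network)
  bad <- setdiff(excluded, partition$networks)
  if (length(bad)) stop("unknown excluded network(s): ",
                        paste(bad, collapse = ", "))
  drop_nets <- union(network, excluded)
  target <- which(!(as.character(partition$network) %in% drop_nets))
  if (!length(target)) {
    stop("no eligible target regions remain after exclusion")
  }
  mean(rowMeans(fc[idx, target, drop = FALSE]))
}

#' Mean functional connectivity between two networks
#'
#' Mean FC over all pairs with one region in `netA` and one in `netB`;
#' symmetric in its arguments.
#'
#' @inheritParams bgc_profile
#' @param netA,netB Distinct network labels.
#' @return Scalar mean between-network FC.
#' @export
between_network_fc <- function(fc, partition, netA, netB) {
  validate_fc(fc, partition)
  if (identical(netA, netB)) stop("netA and netB must differ")
  ia <- network_indices(partition, netA)
  ib <- network_indices(partition, netB)
  mean(fc[ia, ib])
}

# Internal: FC matrix sanity + alignment with the partition.
validate_fc <- function(fc, partition) {
  if (!is.matrix(fc) || nrow(fc) != ncol(fc)) {
    stop("fc must be a square matrix")
  }
  if (nrow(fc) != partition$n_total) {
    stop("fc dimension does not match the partition")
  }
  if (!is.null(rownames(fc))) {
    check_region_alignment(rownames(fc), partition)
  }
  invisible(TRUE)
}
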