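#' Construct a parcellated BOLD time series
#'
#' @param data Numeric region x frame matrix.
#' @param tr Repetition time in seconds.
#' @param subject_id Subject label.
#' @param region_ids Ordered region labels; defaults to the rownames of
#'   `data` or `R000`-style labels.
#' @return An object of class `parcellated_ts`.
#' @export
parcellated_ts <- function(data, tr, subject_id = "sub-000",
                           region_ids = NULL) {
  data <- as.matrix(data)
  if (anyNA(data) || any(!is.finite(data))) {
    stop("time series contains missing or non-finite values")
  }
  if (nrow(data) < 2L) stop("need at least 2 regions")
  if (ncol(data) < 10L) stop("need at least 10 frames")
  if (tr <= 0) stop("tr must be positive")
  if (is.null(region_ids)) {
    region_ids <- rownames(data)
    if (is.null(region_ids)) {
      region_ids <- sprintf("R%03d", seq_len(nrow(data)) - 1L)
    }
  }
  if (length(region_ids) != nrow(data)) {
    stop("region_ids must match the number of rows")
  }
  rownames(data) <- region_ids
  structure(
    list(subject_id = subject_id, data = data, tr = tr,
         region_ids = region_ids),
    class = "parcellated_ts"
  )
}

#' @export
print.parcellated_ts <- function(x, ...) {
  cat(sprintf("parcellated_ts %s: %d regions x %d frames, TR %.3f s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

# Internal: check a ts (or FC matrix) region order against the partition.
check_region_alignment <- function(region_ids, partition) {
  if (length(region_ids) != partition$n_total ||
      !all(region_ids == partition$region_label)) {
    stop("region order does not match the partition's ordered region ids")
  }
  invisible(TRUE)
}
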