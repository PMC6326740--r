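# Delimited-text readers and writers for cohort data. All formats are
# plain TSV so a cohort can be inspected, versioned and regenerated
# without binary files.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory of delimited files
#'
#' Produces the same formats the pipeline reads: per-subject region x frame
#' time-series tables, motion tables (`trans_x..rot_z`), nuisance tables
#' (`ventricle`, `white_matter`, `global`), the partition table
#' (`region_id`, `network`), the cohort metadata table, a `manifest.tsv`
#' listing all subject file paths, and the generating config as
#' `config.yaml`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(cohort$timeseries)
  ts_paths <- file.path(dir, paste0(ids, "_timeseries.tsv"))
  mo_paths <- file.path(dir, paste0(ids, "_motion.tsv"))
  nu_paths <- file.path(dir, paste0(ids, "_nuisance.tsv"))
  for (i in seq_along(ids)) {
    ts <- cohort$timeseries[[i]]
    df <- data.frame(region_id = ts$region_ids, ts$data,
                     check.names = FALSE)
    names(df)[-1] <- sprintf("f%04d", seq_len(ncol(ts$data)))
    write_tsv(df, ts_paths[i])
    write_tsv(as.data.frame(cohort$motion[[i]]), mo_paths[i])
    write_tsv(cohort$nuisance[[i]], nu_paths[i])
  }
  write_partition(cohort$partition, file.path(dir, "partition.tsv"))
  write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  manifest <- data.frame(
    subject_id = ids,
    timeseries_path = basename(ts_paths),
    motion_path = basename(mo_paths),
    nuisance_path = basename(nu_paths)
  )
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  cfg <- unclass(cohort$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(file.path(dir, "manifest.tsv"))
}

#' Write a partition table
#'
#' @param partition A `network_partition`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_partition <- function(partition, path) {
  write_tsv(data.frame(region_id = partition$region_id,
                       network = as.character(partition$network)),
            path)
}

#' Read a partition table
#'
#' Expects columns `region_id` (contiguous, 0-based, in order) and
#' `network`; network level order follows first appearance.
#'
#' @param path Partition TSV path.
#' @return A `network_partition`.
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("region_id", "network") %in% names(df))) {
    stop("partition table needs columns region_id, network")
  }
  if (!identical(as.integer(df$region_id), seq_len(nrow(df)) - 1L)) {
    stop("region_id must be contiguous 0..N-1 in order")
  }
  nets <- unique(df$network)
  sizes <- vapply(nets, function(nm) sum(df$network == nm), integer(1))
  p <- make_partition(sizes, nets)
  if (!all(as.character(p$network) == df$network)) {
    stop("partition table must list regions grouped by network")
  }
  p
}

#' Read a per-subject time-series table
#'
#' @param path TSV with a `region_id` column then one column per frame.
#' @param tr Repetition time in seconds.
#' @param subject_id Subject label.
#' @return A [parcellated_ts()].
#' @export
read_timeseries <- function(path, tr, subject_id = basename(path)) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "region_id") {
    stop("time-series table must start with a region_id column")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  parcellated_ts(m, tr = tr, subject_id = subject_id,
                 region_ids = as.character(df$region_id))
}

#' Read a motion-parameter table
#'
#' @param path TSV with columns `trans_x`, `trans_y`, `trans_z`, `rot_x`,
#'   `rot_y`, `rot_z` (mm and radians).
#' @return Frames x 6 numeric matrix.
#' @export
read_motion <- function(path) {
  df <- utils::read.delim(path)
  need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (!all(need %in% names(df))) {
    stop("motion table needs columns ", paste(need, collapse = ", "))
  }
  as.matrix(df[, need])
}

#' Read a nuisance-signal table
#'
#' @param path TSV with columns `ventricle`, `white_matter`, `global`.
#' @return Data frame of the three series.
#' @export
read_nuisance <- function(path) {
  df <- utils::read.delim(path)
  need <- c("ventricle", "white_matter", "global")
  if (!all(need %in% names(df))) {
    stop("nuisance table needs columns ", paste(need, collapse = ", "))
  }
  df[, need]
}

#' Read a cohort manifest
#'
#' @param path Manifest TSV (`subject_id`, `timeseries_path`,
#'   `motion_path`, `nuisance_path`); relative paths are resolved against
#'   the manifest's directory.
#' @return Data frame with absolute paths.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timeseries_path", "motion_path",
            "nuisance_path")
  if (!all(need %in% names(df))) {
    stop("manifest needs columns ", paste(need, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  for (col in need[-1]) {
    df[[col]] <- ifelse(grepl("^/", df[[col]]), df[[col]],
                        file.path(base, df[[col]]))
  }
  df
}
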