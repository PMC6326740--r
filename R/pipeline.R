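# End-to-end orchestration: generate/load -> preprocess -> FC -> BGC ->
# symptom scoring -> association tables, mirroring the full results surface
# (primary network table, region table, Spearman robustness, age/gender
# residualization, factor partial correlations, connection-exclusion and
# between-network controls, within-network comparison).

#' Pipeline configuration
#'
#' The single source of truth for a pipeline run. Input is either an
#' in-memory cohort (`cohort` = a `synthetic_cohort` or a `cohort_config`
#' to simulate at run time) or file paths (`manifest` + `partition` +
#' `metadata` + `tr`).
#'
#' @param cohort A `synthetic_cohort`, a `cohort_config`, or `NULL`.
#' @param manifest Path to a cohort manifest TSV (used when `cohort` is
#'   `NULL`).
#' @param partition A `network_partition` or path to a partition table;
#'   `NULL` uses the cohort's own partition.
#' @param alt_partition Optional second partition (object or path) for the
#'   alternate-partition rerun of the network-level table.
#' @param metadata Cohort metadata data.frame or path (subject_id, age,
#'   gender, cesd_01..cesd_20, optional hand_01..hand_11).
#' @param tr Repetition time in seconds (required for file input).
#' @param scrub_threshold FD scrub threshold in mm (default 0.3).
#' @param fd_cutoff_hz FD low-pass cutoff in Hz (default 0.3).
#' @param rotation_radius Rotation-to-mm radius in mm (default 50).
#' @param n_before,n_after Censor-window widths (defaults 1 and 2).
#' @param reverse_items Reverse-scored CESD items.
#' @param factor_map CESD factor map (see [cesd_factor_map()]).
#' @param covariates Metadata columns residualized out of the symptom score
#'   for the covariate-controlled rerun (default age and gender).
#' @param fdr_q FDR level used in report text (default 0.05).
#' @param min_retained_frames Subjects with fewer retained frames are
#'   dropped with a warning (default 200).
#' @param effect_network Network of primary interest; `NULL` infers it from
#'   the cohort config (or uses the first network).
#' @param exclusion_networks Trio of networks for the connection-exclusion
#'   control; `NULL` uses the effect network plus the next two networks.
#' @param boxcox_shift Shift for the Box-Cox transform (default 1).
#' @param tables `"full"` or `"network"` (network-level tables only; used
#'   for large simulation sweeps).
#' @param seed Integer seed for any run-time simulation.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, manifest = NULL,
                            partition = NULL, alt_partition = NULL,
                            metadata = NULL, tr = NULL,
                            scrub_threshold = 0.3, fd_cutoff_hz = 0.3,
                            rotation_radius = 50, n_before = 1L,
                            n_after = 2L,
                            reverse_items = c(4L, 8L, 12L, 16L),
                            factor_map = cesd_factor_map(),
                            covariates = c("age", "gender"),
                            fdr_q = 0.05, min_retained_frames = 200L,
                            effect_network = NULL,
                            exclusion_networks = NULL,
                            boxcox_shift = 1, tables = c("full", "network"),
                            seed = 1L) {
  tables <- match.arg(tables)
  if (is.null(cohort) && is.null(manifest)) {
    stop("provide either a cohort (object/config) or a manifest path")
  }
  if (scrub_threshold <= 0) stop("scrub_threshold must be positive")
  if (fdr_q <= 0 || fdr_q >= 1) stop("fdr_q must be in (0, 1)")
  structure(
    list(cohort = cohort, manifest = manifest, partition = partition,
         alt_partition = alt_partition, metadata = metadata, tr = tr,
         scrub_threshold = scrub_threshold, fd_cutoff_hz = fd_cutoff_hz,
         rotation_radius = rotation_radius, n_before = as.integer(n_before),
         n_after = as.integer(n_after),
         reverse_items = as.integer(reverse_items),
         factor_map = factor_map, covariates = covariates, fdr_q = fdr_q,
         min_retained_frames = as.integer(min_retained_frames),
         effect_network = effect_network,
         exclusion_networks = exclusion_networks,
         boxcox_shift = boxcox_shift, tables = tables,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

resolve_partition <- function(x) {
  if (inherits(x, "network_partition")) x else read_partition(x)
}

# Internal: iterate subjects from memory or files, uniform interface.
resolve_inputs <- function(config) {
  if (!is.null(config$cohort)) {
    cohort <- config$cohort
    if (inherits(cohort, "cohort_config")) cohort <- simulate_cohort(cohort)
    stopifnot(inherits(cohort, "synthetic_cohort"))
    partition <- if (is.null(config$partition)) cohort$partition else
      resolve_partition(config$partition)
    list(
      ids = names(cohort$timeseries),
      partition = partition,
      metadata = cohort$metadata,
      effect_default = cohort$config$effect_network,
      get = function(i) list(ts = cohort$timeseries[[i]],
                             motion = cohort$motion[[i]],
                             nuisance = cohort$nuisance[[i]])
    )
  } else {
    if (is.null(config$partition)) {
      stop("file input requires a partition table")
    }
    if (is.null(config$tr)) stop("file input requires tr")
    man <- read_cohort_manifest(config$manifest)
    for (i in seq_len(nrow(man))) {
      for (col in c("timeseries_path", "motion_path", "nuisance_path")) {
        if (!file.exists(man[[col]][i])) {
          stop(sprintf("%s not found for subject %s: %s",
                       sub("_path", " file", col), man$subject_id[i],
                       man[[col]][i]))
        }
      }
    }
    metadata <- config$metadata
    if (is.character(metadata)) {
      metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
    }
    if (is.null(metadata)) stop("file input requires cohort metadata")
    tr <- config$tr
    list(
      ids = man$subject_id,
      partition = resolve_partition(config$partition),
      metadata = metadata,
      effect_default = NULL,
      get = function(i) list(
        ts = read_timeseries(man$timeseries_path[i], tr, man$subject_id[i]),
        motion = read_motion(man$motion_path[i]),
        nuisance = read_nuisance(man$nuisance_path[i])
      )
    )
  }
}

#' Run the full BGC-symptom analysis pipeline
#'
#' Executes preprocessing (FD, low-pass, scrubbing, nuisance regression),
#' per-subject FC and BGC, CESD scoring with Box-Cox normalization, and the
#' full set of association tables. Deterministic given the configuration
#' (including its seed).
#'
#' @param config A [pipeline_config()].
#' @return An object of class `analysis_report`: a list of data.frame
#'   tables (`network_bgc`, `region_bgc`, `spearman`, `residualized`,
#'   `factor_partial`, `within_network`, `exclusion`, `between_fc`,
#'   `alt_network_bgc` when an alternate partition is given,
#'   `scrub_summary`, `cohort_summary`) plus `diagnostics` and
#'   `provenance` lists.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- resolve_inputs(config)
  partition <- inputs$partition
  nets <- partition$networks
  k <- length(nets)
  effect <- config$effect_network
  if (is.null(effect)) effect <- inputs$effect_default
  if (is.null(effect) || !effect %in% nets) effect <- nets[1L]
  trio <- config$exclusion_networks
  if (is.null(trio)) {
    trio <- c(effect, setdiff(nets, effect)[seq_len(min(2L, k - 1L))])
  }
  if (!all(trio %in% nets)) stop("exclusion networks must be in partition")
  pairs <- if (length(trio) > 1L) {
    lapply(setdiff(trio, effect), function(b) c(effect, b))
  } else list()
  alt <- if (!is.null(config$alt_partition)) {
    resolve_partition(config$alt_partition)
  } else NULL

  ids <- inputs$ids
  n_all <- length(ids)
  net_bgc <- matrix(NA_real_, k, n_all, dimnames = list(nets, ids))
  reg_bgc <- matrix(NA_real_, partition$n_total, n_all,
                    dimnames = list(partition$region_label, ids))
  within <- matrix(NA_real_, k, n_all, dimnames = list(nets, ids))
  excl <- matrix(NA_real_, length(trio), n_all,
                 dimnames = list(trio, ids))
  betw <- if (length(pairs)) {
    matrix(NA_real_, length(pairs), n_all,
           dimnames = list(vapply(pairs, paste, "", collapse = " - "), ids))
  } else NULL
  alt_bgc <- if (!is.null(alt)) {
    matrix(NA_real_, length(alt$networks), n_all,
           dimnames = list(alt$networks, ids))
  } else NULL
  scrub_summary <- data.frame(
    subject_id = ids, n_frames = NA_integer_, n_censored = NA_integer_,
    n_retained = NA_integer_, mean_fd = NA_real_, dropped = FALSE
  )

  for (i in seq_len(n_all)) {
    sub <- inputs$get(i)
    check_region_alignment(sub$ts$region_ids, partition)
    pp <- preprocess_subject(
      sub$ts, sub$motion, sub$nuisance,
      scrub_threshold = config$scrub_threshold,
      fd_cutoff_hz = config$fd_cutoff_hz,
      rotation_radius = config$rotation_radius,
      n_before = config$n_before, n_after = config$n_after
    )
    scrub_summary$n_frames[i] <- length(pp$scrub$keep_mask)
    scrub_summary$n_censored[i] <- pp$scrub$n_censored
    scrub_summary$n_retained[i] <- sum(pp$scrub$keep_mask)
    scrub_summary$mean_fd[i] <- mean(pp$scrub$fd_raw)
    if (sum(pp$scrub$keep_mask) < config$min_retained_frames) {
      warning(sprintf("subject %s dropped: %d retained frames < floor %d",
                      ids[i], sum(pp$scrub$keep_mask),
                      config$min_retained_frames))
      scrub_summary$dropped[i] <- TRUE
      next
    }
    W <- fc_matrix(pp$ts)
    prof <- bgc_profile(W, partition)
    net_bgc[, i] <- prof$network_bgc
    reg_bgc[, i] <- prof$region_bgc
    for (nn in nets) within[nn, i] <- within_network_fc(W, partition, nn)
    for (tn in trio) {
      excl[tn, i] <- bgc_excluding(W, partition, tn, setdiff(trio, tn))
    }
    if (length(pairs)) {
      for (j in seq_along(pairs)) {
        betw[j, i] <- between_network_fc(W, partition, pairs[[j]][1],
                                         pairs[[j]][2])
      }
    }
    if (!is.null(alt)) {
      alt_bgc[, i] <- bgc_profile(W, alt)$network_bgc
    }
  }

  keep_subj <- !scrub_summary$dropped
  if (!any(keep_subj)) stop("all subjects dropped during preprocessing")
  ids_kept <- ids[keep_subj]
  metadata <- inputs$metadata
  md <- metadata[match(ids_kept, metadata$subject_id), , drop = FALSE]
  if (anyNA(md$subject_id)) {
    stop("metadata is missing subjects: ",
         paste(setdiff(ids_kept, metadata$subject_id), collapse = ", "))
  }

  # --- symptom scoring -----------------------------------------------------
  item_cols <- sprintf("cesd_%02d", 1:20)
  if (!all(item_cols %in% names(md))) {
    stop("metadata must contain columns cesd_01..cesd_20")
  }
  scores <- lapply(seq_len(nrow(md)), function(i) {
    score_cesd(as.integer(md[i, item_cols]), config$reverse_items,
               config$factor_map)
  })
  totals <- vapply(scores, `[[`, numeric(1), "total")
  fac_names <- names(config$factor_map)
  factors <- vapply(scores, `[[`, numeric(length(fac_names)), "factors")
  if (is.null(dim(factors))) factors <- matrix(factors, nrow = 1L)
  rownames(factors) <- fac_names
  hand_cols <- sprintf("hand_%02d", 1:11)
  lq <- if (all(hand_cols %in% names(md))) {
    vapply(seq_len(nrow(md)), function(i) {
      laterality_quotient(as.numeric(md[i, hand_cols]))
    }, numeric(1))
  } else rep(NA_real_, nrow(md))

  bc_total <- boxcox_normalize(totals, shift = config$boxcox_shift)
  symptom <- bc_total$transformed
  fac_trans <- factors
  fac_lambda <- rep(NA_real_, length(fac_names))
  names(fac_lambda) <- fac_names
  for (f in fac_names) {
    bc_f <- tryCatch(boxcox_normalize(factors[f, ],
                                      shift = config$boxcox_shift),
                     error = function(e) NULL)
    if (!is.null(bc_f)) {
      fac_trans[f, ] <- bc_f$transformed
      fac_lambda[f] <- bc_f$lambda
    }
  }

  nm <- net_bgc[, keep_subj, drop = FALSE]
  wm <- within[, keep_subj, drop = FALSE]
  em <- excl[, keep_subj, drop = FALSE]

  # --- association tables --------------------------------------------------
  network_tbl <- association_table(nm, symptom, "pearson", fdr = TRUE)
  spearman_tbl <- association_table(nm, totals, "spearman", fdr = TRUE)

  cov_cols <- intersect(config$covariates, names(md))
  resid_tbl <- NULL
  if (length(cov_cols)) {
    Zc <- md[, cov_cols, drop = FALSE]
    for (cc in names(Zc)) {
      if (!is.numeric(Zc[[cc]])) {
        Zc[[cc]] <- as.numeric(factor(Zc[[cc]])) - 1
      }
    }
    symptom_resid <- residualize(symptom, as.matrix(Zc))
    resid_tbl <- association_table(nm, symptom_resid, "pearson",
                                   fdr = TRUE)
  }

  excl_tests <- lapply(trio, function(tn) {
    correlation_test(em[tn, ], symptom, "pearson")
  })
  exclusion_tbl <- data.frame(
    network = trio,
    excluded = vapply(trio, function(tn) {
      paste(setdiff(trio, tn), collapse = "; ")
    }, ""),
    estimate = vapply(excl_tests, `[[`, numeric(1), "estimate"),
    p = vapply(excl_tests, `[[`, numeric(1), "p")
  )

  within_tests <- lapply(nets, function(nn) {
    correlation_test(wm[nn, ], symptom, "pearson")
  })
  n_used <- length(symptom)
  within_tbl <- data.frame(
    network = nets,
    estimate = vapply(within_tests, `[[`, numeric(1), "estimate"),
    p = vapply(within_tests, `[[`, numeric(1), "p")
  )
  within_tbl$bgc_estimate <- network_tbl$estimate[match(within_tbl$network,
                                                        network_tbl$unit)]
  zcmp <- mapply(function(rb, rw) {
    unlist(compare_correlations(rb, n_used, rw, n_used))
  }, within_tbl$bgc_estimate, within_tbl$estimate)
  within_tbl$z_vs_bgc <- zcmp["z", ]
  within_tbl$p_vs_bgc <- zcmp["p", ]

  between_tbl <- NULL
  if (!is.null(betw)) {
    bm <- betw[, keep_subj, drop = FALSE]
    btests <- lapply(seq_len(nrow(bm)), function(j) {
      correlation_test(bm[j, ], symptom, "pearson")
    })
    between_tbl <- data.frame(
      pair = rownames(bm),
      estimate = vapply(btests, `[[`, numeric(1), "estimate"),
      p = vapply(btests, `[[`, numeric(1), "p")
    )
  }

  region_tbl <- NULL
  factor_tbl <- NULL
  if (config$tables == "full") {
    region_tbl <- association_table(reg_bgc[, keep_subj, drop = FALSE],
                                    symptom, "pearson", fdr = TRUE)
    rows <- list()
    for (tn in trio) {
      for (f in fac_names) {
        others <- t(fac_trans[setdiff(fac_names, f), , drop = FALSE])
        ct <- partial_rank_correlation(nm[tn, ], fac_trans[f, ], others)
        rows[[length(rows) + 1L]] <- data.frame(
          network = tn, factor = f, estimate = ct$estimate, p = ct$p
        )
      }
    }
    factor_tbl <- do.call(rbind, rows)
  }

  alt_tbl <- NULL
  if (!is.null(alt)) {
    alt_tbl <- association_table(alt_bgc[, keep_subj, drop = FALSE],
                                 symptom, "pearson", fdr = TRUE)
  }

  cohort_summary <- data.frame(
    subject_id = ids_kept,
    age = md$age, gender = md$gender,
    cesd_total = totals,
    t(factors),
    lq = lq,
    check.names = FALSE
  )

  diagnostics <- list(
    boxcox_lambda = bc_total$lambda,
    boxcox_shift = bc_total$shift,
    ks_p_before = bc_total$ks_p_before,
    ks_p_after = bc_total$ks_p_after,
    factor_boxcox_lambda = fac_lambda
  )
  provenance <- list(
    config_hash = hash_config(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("bgcnet")),
    r_version = R.version.string,
    effect_network = effect,
    exclusion_networks = trio,
    fdr_q = config$fdr_q,
    n_subjects_in = n_all,
    n_subjects_analyzed = length(ids_kept),
    n_subjects_dropped = n_all - length(ids_kept)
  )

  structure(
    list(network_bgc = network_tbl, region_bgc = region_tbl,
         spearman = spearman_tbl, residualized = resid_tbl,
         factor_partial = factor_tbl, within_network = within_tbl,
         exclusion = exclusion_tbl, between_fc = between_tbl,
         alt_network_bgc = alt_tbl, scrub_summary = scrub_summary,
         cohort_summary = cohort_summary, diagnostics = diagnostics,
         provenance = provenance,
         measures = list(network_bgc = nm, symptom = symptom,
                         totals = totals)),
    class = "analysis_report"
  )
}

# Internal: md5 of the yaml-serialized (sanitized) config.
hash_config <- function(config) {
  cfg <- unclass(config)
  if (inherits(cfg$cohort, "synthetic_cohort")) {
    cfg$cohort <- unclass(cfg$cohort$config)
  } else if (inherits(cfg$cohort, "cohort_config")) {
    cfg$cohort <- unclass(cfg$cohort)
  }
  for (nm in c("partition", "alt_partition")) {
    if (inherits(cfg[[nm]], "network_partition")) {
      cfg[[nm]] <- list(sizes = as.integer(cfg[[nm]]$n_c),
                        networks = cfg[[nm]]$networks)
    }
  }
  if (is.data.frame(cfg$metadata)) cfg$metadata <- names(cfg$metadata)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report:", x$provenance$n_subjects_analyzed,
      "subjects analyzed\n")
  cat("primary network-level BGC associations:\n")
  print(x$network_bgc, row.names = FALSE)
  invisible(x)
}

#' Write an analysis report as a directory of delimited tables
#'
#' One TSV per table plus a `summary.yaml` holding the diagnostics and
#' provenance (config hash, seed, versions). Deterministic runs produce
#' byte-identical files.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("network_bgc", "region_bgc", "spearman", "residualized",
              "factor_partial", "within_network", "exclusion",
              "between_fc", "alt_network_bgc", "scrub_summary",
              "cohort_summary")
  for (nm in tables) {
    if (!is.null(report[[nm]])) {
      write_tsv(report[[nm]], file.path(dir, paste0(nm, ".tsv")))
    }
  }
  yaml::write_yaml(
    list(diagnostics = lapply(report$diagnostics, as.vector),
         provenance = report$provenance),
    file.path(dir, "summary.yaml")
  )
  invisible(dir)
}
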