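# Synthetic-cohort generator: block-structured multivariate normal BOLD,
# smooth motion with designed spikes, graded-response CESD items, and a
# planted subject-level coupling effect.

#' Target block correlation matrix for one subject
#'
#' Within-network blocks take the network's `w_k`, between-network entries
#' the base coupling `b`, and all entries between the effect network and the
#' other networks are replaced by the subject's realized coupling.
#'
#' @param partition A `network_partition`.
#' @param within_corr Per-network within correlations (recycled if scalar).
#' @param between_corr Baseline between-network correlation.
#' @param effect_network Optional network label whose cross-network entries
#'   are overridden.
#' @param effect_coupling Subject coupling used for the override.
#' @return Symmetric correlation matrix (unit diagonal), not yet guaranteed
#'   positive definite; see [repair_correlation_matrix()].
#' @export
target_covariance <- function(partition, within_corr, between_corr,
                              effect_network = NULL,
                              effect_coupling = between_corr) {
  n <- partition$n_total
  k <- length(partition$networks)
  if (length(within_corr) == 1L) within_corr <- rep(within_corr, k)
  S <- matrix(between_corr, n, n)
  for (i in seq_len(k)) {
    idx <- which(partition$network == partition$networks[i])
    S[idx, idx] <- within_corr[i]
  }
  if (!is.null(effect_network)) {
    if (abs(effect_coupling) >= 1) {
      stop("subject coupling forces |correlation| >= 1")
    }
    idx_e <- network_indices(partition, effect_network)
    idx_o <- setdiff(seq_len(n), idx_e)
    S[idx_e, idx_o] <- effect_coupling
    S[idx_o, idx_e] <- effect_coupling
  }
  diag(S) <- 1
  dimnames(S) <- list(partition$region_label, partition$region_label)
  S
}

#' Repair a correlation matrix to positive definiteness
#'
#' Clips eigenvalues at `min_eigenvalue` and rescales to unit diagonal — the
#' smallest intervention that preserves the block structure. Errors if the
#' repair moves any entry by more than `max_shift`.
#'
#' @param S Symmetric matrix with unit diagonal.
#' @param min_eigenvalue Eigenvalue floor (default 1e-6).
#' @param max_shift Largest entry change tolerated (default 0.05).
#' @return Positive-definite correlation matrix.
#' @export
repair_correlation_matrix <- function(S, min_eigenvalue = 1e-6,
                                      max_shift = 0.05) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= min_eigenvalue) return(S)
  lam <- pmax(e$values, min_eigenvalue)
  S2 <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(S2))
  S2 <- S2 / tcrossprod(d)
  diag(S2) <- 1
  if (max(abs(S2 - S)) > max_shift) {
    stop(sprintf(
      "positive-definiteness repair would move an entry by %.3f (> %.3f)",
      max(abs(S2 - S)), max_shift))
  }
  dimnames(S2) <- dimnames(S)
  S2
}

#' Simulate one subject's parcellated BOLD time series
#'
#' Frames are drawn i.i.d. (or AR(1) if `config$ar1 != 0`) from a zero-mean
#' multivariate normal with the subject's block-structured target
#' correlation. A shared global component scaled by `config$global_amp` is
#' added to every region so that global-signal regression is exercised; the
#' recorded nuisance signals are noisy mixtures of that component (ventricle,
#' white matter) and the region-mean signal (global).
#'
#' @param partition A `network_partition` matching `config`.
#' @param coupling The subject's realized between-network coupling for the
#'   effect network.
#' @param config A `cohort_config`.
#' @param subject_seed Integer seed for this subject.
#' @return List with `ts` (a [parcellated_ts()]) and `nuisance`
#'   (data.frame with columns `ventricle`, `white_matter`, `global`).
#' @export
simulate_subject_timeseries <- function(partition, coupling, config,
                                        subject_seed) {
  S <- target_covariance(partition, config$within_corr,
                         config$between_corr_base,
                         config$effect_network, coupling)
  S <- repair_correlation_matrix(S)
  U <- chol(S)
  n <- partition$n_total
  tn <- config$n_frames
  set.seed(as.integer(subject_seed))
  Z <- matrix(rnorm(tn * n), tn, n)
  if (config$ar1 != 0) {
    phi <- config$ar1
    Z <- apply(Z, 2L, function(z) {
      as.numeric(stats::filter(z * sqrt(1 - phi^2), phi,
                               method = "recursive", init = z[1]))
    })
  }
  X <- Z %*% U
  g <- rnorm(tn)
  Y <- X + config$global_amp * g
  ventricle <- 0.8 * g + 0.6 * rnorm(tn)
  white_matter <- 0.8 * g + 0.6 * rnorm(tn)
  ts <- parcellated_ts(t(Y), tr = config$tr,
                       region_ids = partition$region_label)
  nuisance <- data.frame(
    ventricle = ventricle,
    white_matter = white_matter,
    global = colMeans(ts$data)
  )
  list(ts = ts, nuisance = nuisance)
}

#' Simulate a subject's rigid-body motion trace
#'
#' Smooth low-amplitude sinusoidal drift per parameter plus small white
#' noise, with isolated single-frame translation spikes at randomly chosen
#' frames. Spike amplitude (1 mm) is chosen so that framewise displacement
#' exceeds the 0.3 mm scrub threshold at the spike even after the 0.3 Hz
#' low-pass of the FD trace.
#'
#' @param config A `cohort_config` (uses `n_frames`, `tr`,
#'   `motion_spike_rate`).
#' @param subject_seed Integer seed.
#' @return List with `motion` (frames x 6 matrix, columns
#'   `trans_x/y/z` in mm and `rot_x/y/z` in radians) and `spike_frames`
#'   (1-based frames designed to exceed the FD threshold).
#' @export
simulate_motion <- function(config, subject_seed) {
  tn <- config$n_frames
  set.seed(as.integer(subject_seed))
  tt <- seq_len(tn) * config$tr
  M <- sapply(seq_len(6L), function(j) {
    amp <- runif(1, 0.005, 0.02)
    period <- runif(1, 30, 120)
    phase <- runif(1, 0, 2 * pi)
    drift <- amp * sin(2 * pi * tt / period + phase)
    if (j > 3L) drift <- drift / 50  # rotations in radians, small arc
    drift + rnorm(tn, sd = if (j > 3L) 2e-5 else 1e-3)
  })
  colnames(M) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  spike_frames <- integer(0)
  if (config$motion_spike_rate > 0 && tn > 6L) {
    candidates <- which(runif(tn) < config$motion_spike_rate)
    candidates <- candidates[candidates >= 3L & candidates <= tn - 3L]
    for (f in candidates) {
      if (length(spike_frames) == 0L || f - max(spike_frames) >= 5L) {
        spike_frames <- c(spike_frames, f)
      }
    }
    M[spike_frames, 1L] <- M[spike_frames, 1L] + 1.0
  }
  list(motion = M, spike_frames = spike_frames)
}

#' Default CESD item-generating model
#'
#' A graded-response model: the scored value of item `j` for a subject with
#' latent severity `s` is the number of thresholds `tau_c` with
#' `plogis(loading_j * (s - tau_c))` above a single uniform draw, giving
#' ordered categories 0-3 whose expected total increases in `s`. Reverse
#' items are stored inverted (`3 - scored`) so that CESD scoring recovers
#' the scored value.
#'
#' Thresholds were set so that a standard-normal severity population yields
#' totals with mean near 17 and SD near 9, the range typical of undiagnosed
#' young-adult samples.
#'
#' @param loadings 20 item discriminations.
#' @param thresholds 3 increasing category thresholds on the severity scale.
#' @param reverse_items 1-based indices of reverse-worded items.
#' @return List with elements `loadings`, `thresholds`, `reverse_items`.
#' @export
cesd_item_model <- function(loadings = rep(c(1.0, 1.2, 1.4, 0.9, 1.1), 4L),
                            thresholds = c(-0.3, 1.0, 2.0),
                            reverse_items = c(4L, 8L, 12L, 16L)) {
  stopifnot(length(loadings) == 20L, all(is.finite(loadings)),
            length(thresholds) == 3L, !is.unsorted(thresholds))
  list(loadings = loadings, thresholds = thresholds,
       reverse_items = as.integer(reverse_items))
}

#' Simulate one subject's 20 CESD item responses
#'
#' @param latent_severity Standardized severity score.
#' @param item_model An item model from [cesd_item_model()].
#' @param subject_seed Integer seed.
#' @return Integer vector of 20 responses in `{0,1,2,3}` (reverse items
#'   stored inverted).
#' @export
simulate_cesd_items <- function(latent_severity,
                                item_model = cesd_item_model(),
                                subject_seed) {
  set.seed(as.integer(subject_seed))
  u <- runif(20L)
  scored <- vapply(seq_len(20L), function(j) {
    p <- plogis(item_model$loadings[j] *
                  (latent_severity - item_model$thresholds))
    sum(p > u[j])
  }, integer(1))
  resp <- scored
  rev <- item_model$reverse_items
  resp[rev] <- 3L - scored[rev]
  resp
}

#' Simulate a complete synthetic cohort
#'
#' Draws standardized latent severities `s_j`, realizes per-subject
#' couplings `b_j = between_corr_base + effect_beta * s_j + noise`, and
#' generates per-subject time series, nuisance signals, motion, CESD items
#' and demographics (balanced gender, age uniform 18-35, 11 handedness
#' items). All per-subject seeds derive deterministically from
#' `config$seed`.
#'
#' @param config A `cohort_config`.
#' @return An object of class `synthetic_cohort`: lists `timeseries`,
#'   `motion`, `nuisance`, `spike_frames` (one element per subject),
#'   vectors `severity` and `coupling`, the `partition`, the `config`, and
#'   a `metadata` data.frame (`subject_id`, `age`, `gender`,
#'   `cesd_01..cesd_20`, `hand_01..hand_11`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  partition <- make_partition(config$network_sizes, config$network_names)
  n <- config$n_subjects
  set.seed(config$seed)
  s <- rnorm(n)
  if (n >= 2L) s <- (s - mean(s)) / sd(s)
  coupling <- config$between_corr_base + config$effect_beta * s +
    rnorm(n, sd = config$coupling_noise_sd)
  age <- runif(n, 18, 35)
  gender <- sample(rep(c("female", "male"), length.out = n))
  hand <- matrix(sample(c(2L, 1L, 0L), n * 11L, replace = TRUE,
                        prob = c(0.70, 0.25, 0.05)), n, 11L)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 3L * n), n, 3L)
  item_model <- cesd_item_model()

  timeseries <- vector("list", n)
  nuisance <- vector("list", n)
  motion <- vector("list", n)
  spikes <- vector("list", n)
  items <- matrix(0L, n, 20L)
  ids <- sprintf("sub-%03d", seq_len(n))
  for (i in seq_len(n)) {
    sim <- simulate_subject_timeseries(partition, coupling[i], config,
                                       seeds[i, 1L])
    sim$ts$subject_id <- ids[i]
    timeseries[[i]] <- sim$ts
    nuisance[[i]] <- sim$nuisance
    mo <- simulate_motion(config, seeds[i, 2L])
    motion[[i]] <- mo$motion
    spikes[[i]] <- mo$spike_frames
    items[i, ] <- simulate_cesd_items(s[i], item_model, seeds[i, 3L])
  }
  metadata <- data.frame(subject_id = ids, age = age, gender = gender)
  item_df <- as.data.frame(items)
  names(item_df) <- sprintf("cesd_%02d", seq_len(20L))
  hand_df <- as.data.frame(hand)
  names(hand_df) <- sprintf("hand_%02d", seq_len(11L))
  metadata <- cbind(metadata, item_df, hand_df)
  names(timeseries) <- names(nuisance) <- names(motion) <-
    names(spikes) <- ids
  structure(
    list(config = config, partition = partition, timeseries = timeseries,
         motion = motion, nuisance = nuisance, spike_frames = spikes,
         severity = stats::setNames(s, ids),
         coupling = stats::setNames(coupling, ids),
         metadata = metadata),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects, %d regions, %d frames\n",
              length(x$timeseries), x$partition$n_total,
              x$config$n_frames))
  invisible(x)
}
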