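#' Simulation configuration for a synthetic resting-state cohort
#'
#' Collects every parameter of the synthetic-cohort generator. The defaults
#' emulate the study geometry the pipeline targets: 96 subjects, 360 regions
#' in 12 networks, 1,070 frames at TR = 0.785 s, and a planted negative
#' association between the effect network's between-network coupling and a
#' latent symptom severity.
#'
#' `effect_beta` is the change in the effect network's between-network
#' coupling per unit latent severity (standardized). Its default, together
#' with `coupling_noise_sd`, was calibrated once at the scaled test geometry
#' so that the measured cohort correlation between effect-network BGC and the
#' scored, Box-Cox-transformed CESD total is approximately -0.25 (the
#' association magnitude the analysis is designed to detect).
#'
#' @param n_subjects Number of subjects.
#' @param network_sizes Regions per network (each >= 2).
#' @param network_names Unique network labels.
#' @param n_frames Frames per subject (>= 10).
#' @param tr Repetition time in seconds.
#' @param within_corr Within-network correlation(s) `w_k`; scalar or one per
#'   network, each in (-1, 1).
#' @param between_corr_base Baseline between-network correlation `b`.
#' @param effect_network Label of the network carrying the planted effect.
#' @param effect_beta Change in the effect network's between-network coupling
#'   per unit latent severity (negative plants the depression-like effect).
#' @param coupling_noise_sd SD of subject-level coupling noise.
#' @param global_amp Amplitude of the shared global component added to every
#'   region (exercises global-signal regression; set 0 to disable).
#' @param motion_spike_rate Per-frame probability of a designed motion spike.
#' @param ar1 Optional AR(1) coefficient for temporal autocorrelation of the
#'   frames (0 = i.i.d. frames, the default).
#' @param seed Integer seed; fully determines all generator output.
#' @return An object of class `cohort_config`.
#' @seealso [cohort_config_scaled()] for the scaled-down test geometry.
#' @export
cohort_config <- function(n_subjects = 96L,
                          network_sizes = default_network_sizes(),
                          network_names = default_network_names(),
                          n_frames = 1070L,
                          tr = 0.785,
                          within_corr = 0.30,
                          between_corr_base = 0.05,
                          effect_network = "Fronto-parietal",
                          effect_beta = -0.0049,
                          coupling_noise_sd = 0.01,
                          global_amp = 0.4,
                          motion_spike_rate = 0.02,
                          ar1 = 0,
                          seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  n_frames <- as.integer(n_frames)
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (length(network_sizes) != length(network_names)) {
    stop("network_sizes and network_names must have equal length")
  }
  if (any(network_sizes < 2L)) stop("every network needs >= 2 regions")
  if (n_frames < 10L) stop("n_frames must be >= 10")
  if (tr <= 0) stop("tr must be positive")
  k <- length(network_names)
  if (length(within_corr) == 1L) within_corr <- rep(within_corr, k)
  if (length(within_corr) != k) {
    stop("within_corr must be scalar or one value per network")
  }
  if (any(abs(within_corr) >= 1) || abs(between_corr_base) >= 1) {
    stop("all correlations must lie in (-1, 1)")
  }
  if (!effect_network %in% network_names) {
    stop("effect_network must be one of network_names")
  }
  if (motion_spike_rate < 0 || motion_spike_rate >= 1) {
    stop("motion_spike_rate must be in [0, 1)")
  }
  if (abs(ar1) >= 1) stop("ar1 must be in (-1, 1)")
  if (coupling_noise_sd < 0) stop("coupling_noise_sd must be >= 0")
  structure(
    list(
      n_subjects = n_subjects,
      network_sizes = as.integer(network_sizes),
      network_names = network_names,
      n_frames = n_frames,
      tr = tr,
      within_corr = within_corr,
      between_corr_base = between_corr_base,
      effect_network = effect_network,
      effect_beta = effect_beta,
      coupling_noise_sd = coupling_noise_sd,
      global_amp = global_amp,
      motion_spike_rate = motion_spike_rate,
      ar1 = ar1,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Scaled-down simulation geometry for fast runs
#'
#' Four networks of 15 regions and 600 frames: small enough for routine
#' testing while preserving every code path (effect network plus two
#' companion networks for the exclusion controls, and one sensory-like
#' network). The first three networks stand in for the fronto-parietal,
#' default-mode and language networks of the full partition.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @param n_frames Frames per subject (default 600).
#' @param ... Further arguments passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
cohort_config_scaled <- function(n_subjects = 96L, seed = 1L,
                                 n_frames = 600L, ...) {
  cohort_config(
    n_subjects = n_subjects,
    network_sizes = rep(15L, 4L),
    network_names = c("Fronto-parietal", "Default mode", "Language",
                      "Visual 1"),
    n_frames = n_frames,
    seed = seed,
    ...
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "cohort_config: %d subjects, %d regions in %d networks, %d frames @ TR %.3f s\n",
    x$n_subjects, sum(x$network_sizes), length(x$network_names),
    x$n_frames, x$tr))
  cat(sprintf("  effect network %s, effect_beta %.4f, seed %d\n",
              x$effect_network, x$effect_beta, x$seed))
  invisible(x)
}
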