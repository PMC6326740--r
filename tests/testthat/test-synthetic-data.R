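# Synthetic-cohort generator: partition construction, covariance fidelity,
# motion spikes, CESD item model, determinism, and the planted effect.

test_that("make_partition assigns contiguous regions and validates input", {
  p <- make_partition(c(2, 2), c("A", "B"))
  expect_equal(p$n_total, 4L)
  expect_equal(p$region_id, 0:3)
  expect_equal(as.character(p$network), c("A", "A", "B", "B"))

  full <- make_partition()
  expect_equal(full$n_total, 360L)
  expect_length(full$networks, 12L)

  expect_error(make_partition(c(3), c("A", "B")), "equal length")
  expect_error(make_partition(c(2, 0), c("A", "B")), "at least one region")
  expect_error(make_partition(c(2, 2), c("A", "A")), "unique")
})

test_that("subject time series reproduce the target block correlations", {
  cfg <- cohort_config(n_subjects = 1, network_sizes = c(10L, 10L),
                       network_names = c("A", "B"), n_frames = 5000L,
                       within_corr = 0.3, between_corr_base = 0.05,
                       effect_network = "A", effect_beta = 0,
                       coupling_noise_sd = 0, global_amp = 0, seed = 11)
  part <- make_partition(cfg$network_sizes, cfg$network_names)
  sim <- simulate_subject_timeseries(part, 0.05, cfg, subject_seed = 77)
  W <- stats::cor(t(sim$ts$data))
  ia <- 1:10
  ib <- 11:20
  wa <- W[ia, ia][upper.tri(diag(10))]
  expect_lt(abs(mean(wa) - 0.3), 0.02)
  expect_lt(abs(mean(W[ia, ib]) - 0.05), 0.02)
})

test_that("zero coupling and no global mixing give independent networks", {
  cfg <- cohort_config(n_subjects = 1, network_sizes = c(10L, 10L),
                       network_names = c("A", "B"), n_frames = 5000L,
                       within_corr = 0.3, between_corr_base = 0,
                       effect_network = "A", effect_beta = 0,
                       coupling_noise_sd = 0, global_amp = 0, seed = 12)
  part <- make_partition(cfg$network_sizes, cfg$network_names)
  sim <- simulate_subject_timeseries(part, 0, cfg, subject_seed = 78)
  W <- stats::cor(t(sim$ts$data))
  expect_lt(abs(mean(W[1:10, 11:20])), 0.02)
})

test_that("subject simulation is seed-deterministic and rejects bad coupling", {
  cfg <- cohort_config_scaled(n_subjects = 1, n_frames = 60L, seed = 1)
  part <- make_partition(cfg$network_sizes, cfg$network_names)
  a <- simulate_subject_timeseries(part, 0.05, cfg, 123)
  b <- simulate_subject_timeseries(part, 0.05, cfg, 123)
  expect_identical(a$ts$data, b$ts$data)
  expect_identical(a$nuisance, b$nuisance)
  expect_error(simulate_subject_timeseries(part, 1.0, cfg, 1),
               ">= 1")
})

test_that("positive-definiteness repair is minimal and bounded", {
  # slightly indefinite equicorrelation: min eigenvalue 1 + 3*rho < 0
  S <- matrix(-0.3433, 4, 4)
  diag(S) <- 1
  expect_lt(min(eigen(S, symmetric = TRUE)$values), 0)
  R <- repair_correlation_matrix(S)
  # positive definite after repair (unit-diagonal rescale may nudge the
  # clipped eigenvalue, so test strict positivity rather than the floor)
  expect_gt(min(eigen(R, symmetric = TRUE)$values), 0)
  expect_true(is.matrix(chol(R)))
  expect_equal(diag(R), rep(1, 4))
  expect_lt(max(abs(R - S)), 0.05)

  # strongly indefinite: the repair would move entries too far
  S2 <- matrix(-0.45, 4, 4)
  diag(S2) <- 1
  expect_error(repair_correlation_matrix(S2), "repair")
})

test_that("motion traces stay sub-threshold without spikes and spike as designed", {
  cfg <- cohort_config_scaled(n_subjects = 1, motion_spike_rate = 0,
                              seed = 4)
  m0 <- simulate_motion(cfg, 99)
  expect_length(m0$spike_frames, 0L)
  expect_true(all(framewise_displacement(m0$motion) < 0.3))

  cfg2 <- cohort_config_scaled(n_subjects = 1, motion_spike_rate = 0.03,
                               seed = 4)
  m1 <- simulate_motion(cfg2, 99)
  expect_gt(length(m1$spike_frames), 0L)
  fd <- framewise_displacement(m1$motion)
  expect_true(all(fd[m1$spike_frames] > 0.3))
  # spikes survive the 0.3 Hz low-pass used for scrubbing
  fdf <- lowpass_filter_fd(fd, 0.3, cfg2$tr)
  expect_true(all(fdf[m1$spike_frames] > 0.3))
  m2 <- simulate_motion(cfg2, 99)
  expect_identical(m1$motion, m2$motion)
})

test_that("CESD item model is monotone in severity with valid responses", {
  model <- cesd_item_model()
  totals_at <- function(sev) {
    vapply(seq_len(10000L), function(i) {
      resp <- simulate_cesd_items(sev, model, subject_seed = i)
      score_cesd(resp)$total
    }, numeric(1))
  }
  lo <- totals_at(-3)
  hi <- totals_at(3)
  expect_lt(mean(lo), 3)          # floor: near 0 of 60
  expect_gt(mean(hi), 40)         # upper third of 0-60
  resp <- simulate_cesd_items(0.5, model, 42)
  expect_true(all(resp %in% 0:3))
  expect_identical(resp, simulate_cesd_items(0.5, model, 42))
})

test_that("cohorts are deterministic with standardized severities", {
  cfg <- cohort_config_scaled(n_subjects = 6, n_frames = 60L, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$timeseries[[3]]$data, b$timeseries[[3]]$data)
  expect_equal(mean(a$severity), 0, tolerance = 1e-12)
  expect_equal(sd(a$severity), 1, tolerance = 1e-12)
  items <- as.matrix(a$metadata[, sprintf("cesd_%02d", 1:20)])
  expect_true(all(items %in% 0:3))
})

test_that("stronger planted effects yield stronger coupling-severity association", {
  r_at <- function(beta) {
    cfg <- cohort_config(n_subjects = 400, network_sizes = c(2L, 2L),
                         network_names = c("A", "B"), n_frames = 10L,
                         effect_network = "A", effect_beta = beta,
                         seed = 21)
    co <- simulate_cohort(cfg)
    abs(cor(co$coupling, co$severity))
  }
  r <- vapply(c(0, -0.005, -0.01), r_at, numeric(1))
  expect_lt(r[1], r[2])
  expect_lt(r[2], r[3])
})

test_that("a null cohort shows no BGC-symptom association", {
  cfg <- cohort_config_scaled(n_subjects = 200, n_frames = 300L,
                              effect_beta = 0, seed = 31)
  rep <- run_pipeline(pipeline_config(cohort = cfg, tables = "network",
                                      min_retained_frames = 100L,
                                      seed = 31))
  r_fpn <- rep$network_bgc$estimate[rep$network_bgc$unit == "Fronto-parietal"]
  expect_lt(abs(r_fpn), 0.15)
})
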