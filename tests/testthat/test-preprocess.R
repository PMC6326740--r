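# Preprocessing: framewise displacement, FD low-pass, scrub mask, nuisance
# regression.

test_that("framewise displacement follows the Euclidean-distance definition", {
  m <- matrix(0, 6, 6)
  expect_equal(framewise_displacement(m), rep(0, 6))

  m2 <- matrix(0, 5, 6)
  m2[3:5, 1] <- 0.3                      # single 0.3 mm translation step
  fd <- framewise_displacement(m2)
  expect_equal(fd[3], 0.3)
  expect_equal(fd[c(1, 2, 4, 5)], rep(0, 4))

  m3 <- matrix(0, 5, 6)
  m3[3:5, 4] <- 0.01                     # 0.01 rad step -> 0.5 mm arc at r=50
  expect_equal(framewise_displacement(m3)[3], 0.5)

  # combined translation + rotation step is the 6-vector L2 norm
  m4 <- matrix(0, 4, 6)
  m4[2:4, 1] <- 0.3
  m4[2:4, 4] <- 0.01
  expect_equal(framewise_displacement(m4)[2], sqrt(0.3^2 + 0.5^2))

  expect_error(framewise_displacement(matrix(0, 5, 5)), "6 columns")
  m5 <- matrix(0, 5, 6)
  m5[2, 2] <- NA
  expect_error(framewise_displacement(m5), "non-finite")
})

test_that("FD is invariant to constant offsets in any motion column", {
  set.seed(5)
  m <- matrix(rnorm(60, sd = 0.05), 10, 6)
  fd0 <- framewise_displacement(m)
  for (j in 1:6) {
    m2 <- m
    m2[, j] <- m2[, j] + 3.7
    expect_equal(framewise_displacement(m2), fd0)
  }
})

test_that("FD low-pass has unit DC gain and kills the Nyquist component", {
  tr <- 0.785
  const <- rep(0.17, 80)
  expect_equal(lowpass_filter_fd(const, 0.3, tr), const, tolerance = 1e-9)

  alt <- 0.1 + 0.08 * rep(c(1, -1), 50)   # alternating at Nyquist
  out <- lowpass_filter_fd(alt, 0.3, tr)
  amp_in <- diff(range(alt))
  amp_out <- diff(range(out[20:80]))
  expect_gt(amp_in / amp_out, 10)

  expect_error(lowpass_filter_fd(rep(0.1, 50), 0.8, tr), "Nyquist")
  expect_error(lowpass_filter_fd(rep(0.1, 5), 0.3, tr), "short")
  expect_true(all(lowpass_filter_fd(c(rep(0, 40), 1, rep(0, 40)), 0.3, tr) >= 0))
})

test_that("scrub mask censors one prior and two following with boundary clipping", {
  fd <- c(0.1, 0.1, 0.4, 0.1, 0.1, 0.1)
  keep <- scrub_mask(fd, 0.3)
  expect_equal(which(!keep), 2:5)        # 0-based {1,2,3,4}

  expect_true(all(scrub_mask(rep(0.1, 6), 0.3)))

  keep0 <- scrub_mask(c(0.4, 0.1, 0.1, 0.1, 0.1), 0.3)
  expect_equal(which(!keep0), 1:3)       # clipped prior window

  keepN <- scrub_mask(c(0.1, 0.1, 0.1, 0.1, 0.4), 0.3)
  expect_equal(which(!keepN), 4:5)       # clipped following window
})

test_that("raising the scrub threshold never censors more frames", {
  set.seed(8)
  for (rep_i in 1:20) {
    fd <- abs(rnorm(50, sd = 0.2))
    th <- sort(runif(2, 0.05, 0.6))
    n_lo <- sum(!scrub_mask(fd, th[1]))
    n_hi <- sum(!scrub_mask(fd, th[2]))
    expect_lte(n_hi, n_lo)
  }
})

make_pp_inputs <- function(n_frames = 60L, n_regions = 5L, seed = 13L) {
  set.seed(seed)
  ts <- parcellated_ts(matrix(rnorm(n_regions * n_frames), n_regions),
                       tr = 0.785)
  list(
    ts = ts,
    motion = matrix(rnorm(n_frames * 6, sd = 0.02), n_frames, 6),
    ventricle = rnorm(n_frames),
    white_matter = rnorm(n_frames),
    global_signal = rnorm(n_frames)
  )
}

test_that("nuisance regression matches a normal-equations oracle", {
  inp <- make_pp_inputs()
  keep <- rep(TRUE, 60)
  keep[10:15] <- FALSE
  res <- regress_nuisance(inp$ts, inp$motion, inp$ventricle,
                          inp$white_matter, inp$global_signal, keep)
  # rebuild the documented design independently
  bdiff <- function(m) rbind(0, diff(as.matrix(m)))
  X <- cbind(1, inp$motion, bdiff(inp$motion), inp$ventricle,
             inp$white_matter, bdiff(cbind(inp$ventricle, inp$white_matter)),
             inp$global_signal)
  Xk <- X[keep, ]
  Y <- t(inp$ts$data)[keep, ]
  beta <- solve(t(Xk) %*% Xk, t(Xk) %*% Y)
  oracle <- Y - Xk %*% beta
  expect_equal(unname(t(res$data)), unname(oracle), tolerance = 1e-10)
  expect_equal(ncol(res$data), sum(keep))
  # zero-mean residuals, orthogonal to every design column
  expect_true(all(abs(rowMeans(res$data)) < 1e-10))
  cross <- t(Xk) %*% t(res$data)
  expect_lt(max(abs(cross)) / max(abs(Y)), 1e-8)
})

test_that("a region equal to the global signal is regressed to zero", {
  inp <- make_pp_inputs()
  dat <- inp$ts$data
  dat[2, ] <- inp$global_signal
  ts <- parcellated_ts(dat, tr = 0.785)
  res <- regress_nuisance(ts, inp$motion, inp$ventricle, inp$white_matter,
                          inp$global_signal)
  expect_lt(max(abs(res$data[2, ])), 1e-10)
})

test_that("nuisance regression rejects collinear designs and short masks", {
  inp <- make_pp_inputs()
  expect_error(
    regress_nuisance(inp$ts, inp$motion, inp$ventricle, inp$ventricle,
                     inp$global_signal),
    "collinear.*white_matter"
  )
  keep <- rep(FALSE, 60)
  keep[1:10] <- TRUE
  expect_error(
    regress_nuisance(inp$ts, inp$motion, inp$ventricle, inp$white_matter,
                     inp$global_signal, keep),
    "too few retained frames"
  )
})

test_that("preprocess_subject chains FD, filtering, scrubbing and regression", {
  cfg <- cohort_config_scaled(n_subjects = 1, n_frames = 300L,
                              motion_spike_rate = 0.02, seed = 17)
  co <- simulate_cohort(cfg)
  pp <- preprocess_subject(co$timeseries[[1]], co$motion[[1]],
                           co$nuisance[[1]])
  expect_s3_class(pp$ts, "parcellated_ts")
  expect_equal(length(pp$scrub$keep_mask), 300L)
  expect_equal(pp$scrub$n_censored, sum(!pp$scrub$keep_mask))
  expect_equal(ncol(pp$ts$data), sum(pp$scrub$keep_mask))
  expect_equal(pp$scrub$fd_raw[1], 0)
  expect_true(all(pp$scrub$fd_filtered >= 0))
})
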