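# Motion scrubbing and nuisance regression for parcellated BOLD data.
# Pipeline order is fixed: FD -> low-pass FD -> scrub mask -> nuisance
# regression on retained frames.

#' Framewise displacement from rigid-body motion estimates
#'
#' FD at frame t is the Euclidean (L2) norm of the six frame-to-frame
#' parameter differences, with rotation differences converted to arc length
#' on a sphere of `rotation_radius` mm. The first frame has no predecessor;
#' `fd[1] = 0` by convention.
#'
#' @param motion Frames x 6 numeric matrix: three translations (mm) then
#'   three rotations (radians).
#' @param rotation_radius Sphere radius in mm for the rotation-to-arc-length
#'   conversion (default 50, the field convention).
#' @return Numeric vector of per-frame FD in mm.
#' @export
framewise_displacement <- function(motion, rotation_radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) {
    stop("motion must have 6 columns (3 translations mm, 3 rotations rad)")
  }
  if (nrow(motion) < 2L) stop("need at least 2 frames")
  if (any(!is.finite(motion))) stop("motion contains non-finite values")
  d <- diff(motion)
  d[, 4:6] <- d[, 4:6] * rotation_radius
  c(0, sqrt(rowSums(d^2)))
}

#' Low-pass filter a framewise-displacement trace
#'
#' Zero-phase (forward-backward) order-2 Butterworth low-pass, applied with
#' odd-reflection end padding so a constant trace passes through unchanged
#' (unit DC gain). Used to suppress respiration-band fluctuation in the FD
#' trace before thresholding. Filtered values are clamped at 0 (a zero-phase
#' filter can undershoot next to a spike; FD is a magnitude).
#'
#' @param fd Per-frame FD (mm), length >= 12.
#' @param cutoff_hz Cutoff frequency in Hz (default 0.3); must be below the
#'   Nyquist frequency `1/(2 * tr)`.
#' @param tr Repetition time in seconds.
#' @return Filtered FD, same length as `fd`.
#' @export
lowpass_filter_fd <- function(fd, cutoff_hz = 0.3, tr) {
  nyquist <- 1 / (2 * tr)
  if (cutoff_hz >= nyquist) {
    stop(sprintf("cutoff %.3f Hz is at/above the Nyquist frequency %.3f Hz",
                 cutoff_hz, nyquist))
  }
  if (cutoff_hz <= 0) stop("cutoff must be positive")
  n <- length(fd)
  if (n < 12L) stop("FD trace too short for filter warm-up (need >= 12)")
  bf <- signal::butter(2, cutoff_hz / nyquist, type = "low")
  npad <- min(n - 1L, 30L)
  pre <- 2 * fd[1] - fd[(npad + 1L):2L]
  post <- 2 * fd[n] - fd[(n - 1L):(n - npad)]
  x <- c(pre, fd, post)
  y <- signal::filter(bf, x)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  pmax(y[(npad + 1L):(npad + n)], 0)
}

#' Frame-censoring mask from a filtered FD trace
#'
#' A frame is flagged when its FD exceeds `threshold`; the flagged frame,
#' `n_before` frames prior and `n_after` frames following are censored, with
#' windows clipped at the series boundaries.
#'
#' @param fd_filtered Per-frame FD (mm).
#' @param threshold Scrub threshold in mm (default 0.3).
#' @param n_before Frames censored before each flagged frame (default 1).
#' @param n_after Frames censored after each flagged frame (default 2).
#' @return Logical keep-mask (`TRUE` = frame retained).
#' @export
scrub_mask <- function(fd_filtered, threshold = 0.3, n_before = 1L,
                       n_after = 2L) {
  if (threshold <= 0) stop("threshold must be positive")
  n <- length(fd_filtered)
  keep <- rep(TRUE, n)
  flagged <- which(fd_filtered > threshold)
  if (length(flagged)) {
    idx <- unlist(lapply(flagged, function(f) {
      seq(max(1L, f - n_before), min(n, f + n_after))
    }))
    keep[unique(idx)] <- FALSE
  }
  if (!any(keep)) {
    message("scrub_mask: all frames censored")
  }
  keep
}

#' Nuisance regression on retained frames
#'
#' Regresses each region's series on an intercept plus 17 nuisance
#' regressors: the 6 rigid-body motion estimates and their first
#' differences (the "12 motion parameters"), ventricle and white-matter
#' signals and their first differences, and the global signal. First
#' differences are backward differences with first element 0 and are
#' computed before censoring so gaps do not corrupt them; the least-squares
#' fit uses retained frames only, and residuals are returned only for
#' retained frames.
#'
#' @param ts A [parcellated_ts()].
#' @param motion Frames x 6 motion matrix.
#' @param ventricle,white_matter,global_signal Per-frame nuisance series.
#' @param keep_mask Logical keep-mask (default: keep all frames).
#' @return A `parcellated_ts` of residuals on the retained frames (each
#'   region series has zero mean), with attribute `frames_kept` giving the
#'   retained frame indices.
#' @export
regress_nuisance <- function(ts, motion, ventricle, white_matter,
                             global_signal, keep_mask = NULL) {
  stopifnot(inherits(ts, "parcellated_ts"))
  n_frames <- ncol(ts$data)
  motion <- as.matrix(motion)
  if (nrow(motion) != n_frames ||
      length(ventricle) != n_frames ||
      length(white_matter) != n_frames ||
      length(global_signal) != n_frames) {
    stop("all series must share the time series' frame count")
  }
  if (is.null(keep_mask)) keep_mask <- rep(TRUE, n_frames)
  if (length(keep_mask) != n_frames) {
    stop("keep_mask length must equal the frame count")
  }
  bdiff <- function(m) rbind(0, diff(as.matrix(m)))
  X <- cbind(motion, bdiff(motion), ventricle, white_matter,
             bdiff(cbind(ventricle, white_matter)), global_signal)
  colnames(X) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y",
                   "rot_z", paste0("d_", c("trans_x", "trans_y", "trans_z",
                                           "rot_x", "rot_y", "rot_z")),
                   "ventricle", "white_matter", "d_ventricle",
                   "d_white_matter", "global")
  n_kept <- sum(keep_mask)
  if (n_kept < ncol(X) + 1L + 2L) {
    stop(sprintf("too few retained frames (%d) for %d regressors",
                 n_kept, ncol(X) + 1L))
  }
  design <- cbind(intercept = 1, X)[keep_mask, , drop = FALSE]
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  Y <- t(ts$data)[keep_mask, , drop = FALSE]
  res <- qr.resid(qrd, Y)
  out <- parcellated_ts(t(res), tr = ts$tr, subject_id = ts$subject_id,
                        region_ids = ts$region_ids)
  attr(out, "frames_kept") <- which(keep_mask)
  out
}

#' Run the full per-subject preprocessing chain
#'
#' FD from motion, 0.3 Hz low-pass of the FD trace, scrub mask at the
#' threshold with the one-prior/two-following censor window, then nuisance
#' regression on the retained frames.
#'
#' @param ts A [parcellated_ts()].
#' @param motion Frames x 6 motion matrix.
#' @param nuisance Data frame with columns `ventricle`, `white_matter`,
#'   `global`.
#' @param scrub_threshold FD threshold in mm.
#' @param fd_cutoff_hz FD low-pass cutoff in Hz.
#' @param rotation_radius Rotation-to-mm radius (mm).
#' @param n_before,n_after Censor-window widths.
#' @return List with `ts` (residual series on retained frames) and `scrub`,
#'   an object of class `scrub_result` with fields `fd_raw`, `fd_filtered`,
#'   `keep_mask`, `n_censored`.
#' @export
preprocess_subject <- function(ts, motion, nuisance,
                               scrub_threshold = 0.3, fd_cutoff_hz = 0.3,
                               rotation_radius = 50, n_before = 1L,
                               n_after = 2L) {
  fd <- framewise_displacement(motion, rotation_radius)
  fdf <- lowpass_filter_fd(fd, fd_cutoff_hz, ts$tr)
  keep <- scrub_mask(fdf, scrub_threshold, n_before, n_after)
  clean <- regress_nuisance(ts, motion, nuisance$ventricle,
                            nuisance$white_matter, nuisance$global, keep)
  scrub <- structure(
    list(fd_raw = fd, fd_filtered = fdf, keep_mask = keep,
         n_censored = sum(!keep)),
    class = "scrub_result"
  )
  list(ts = clean, scrub = scrub)
}
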