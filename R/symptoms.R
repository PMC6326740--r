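# CESD scoring, laterality quotient, and symptom-score normalization
# (Kolmogorov-Smirnov normality gate + Box-Cox power transform).

#' Default CESD three-factor item map
#'
#' The three-factor decomposition (somatic symptoms, negative affect,
#' anhedonia) is taken from the three-factor CESD literature; the anhedonia
#' factor is the four reverse-worded items. This map is a documented default,
#' not a fixed property of the scale — pass your own when your factor
#' solution differs.
#'
#' @return Named list of 1-based item index vectors covering all 20 items.
#' @export
cesd_factor_map <- function() {
  list(
    somatic = c(1L, 2L, 5L, 7L, 11L, 13L, 20L),
    negative_affect = c(3L, 6L, 9L, 10L, 14L, 15L, 17L, 18L, 19L),
    anhedonia = c(4L, 8L, 12L, 16L)
  )
}

#' Score the 20-item CESD
#'
#' Reverse-worded items are scored `3 - response`; the total is the sum of
#' the 20 scored items (range 0-60) and each factor score the sum of its
#' scored items.
#'
#' @param items Integer vector of 20 responses in `{0,1,2,3}`.
#' @param reverse_items 1-based indices of reverse-worded items (default
#'   the standard set 4, 8, 12, 16).
#' @param factor_map Named list of non-overlapping item index sets
#'   (default [cesd_factor_map()]).
#' @return List with `total`, `factors` (named numeric), and `scored`
#'   (the 20 scored item values).
#' @export
score_cesd <- function(items, reverse_items = c(4L, 8L, 12L, 16L),
                       factor_map = cesd_factor_map()) {
  items <- as.integer(items)
  if (length(items) != 20L) stop("CESD has 20 items")
  if (anyNA(items) || any(items < 0L | items > 3L)) {
    stop("responses must be in {0, 1, 2, 3}")
  }
  all_idx <- unlist(factor_map, use.names = FALSE)
  if (anyDuplicated(all_idx) > 0L) {
    stop("overlapping factor assignment: an item appears in two factors")
  }
  if (any(all_idx < 1L | all_idx > 20L)) {
    stop("factor map indices must be in 1..20")
  }
  scored <- items
  scored[reverse_items] <- 3L - items[reverse_items]
  factors <- vapply(factor_map, function(ix) sum(scored[ix]), numeric(1))
  list(total = sum(scored), factors = factors, scored = scored)
}

#' Laterality quotient from 11 handedness items
#'
#' Each item is answered always right (2), usually right (1), no preference
#' (0), usually left (-1) or always left (-2); the quotient is
#' `100 * sum / 22`, giving -100 (strong left preference) to 100 (strong
#' right preference).
#'
#' @param answers 11 responses, either the numeric scores above or the
#'   labels `"always_right"`, `"usually_right"`, `"no_preference"`,
#'   `"usually_left"`, `"always_left"`.
#' @return Scalar laterality quotient in `[-100, 100]`.
#' @export
laterality_quotient <- function(answers) {
  if (length(answers) != 11L) stop("expected exactly 11 handedness answers")
  if (is.character(answers) || is.factor(answers)) {
    map <- c(always_right = 2, usually_right = 1, no_preference = 0,
             usually_left = -1, always_left = -2)
    answers <- as.character(answers)
    if (any(!answers %in% names(map))) {
      stop("unknown handedness answer label")
    }
    scores <- map[answers]
  } else {
    scores <- as.numeric(answers)
    if (any(!scores %in% -2:2)) stop("scores must be integers in -2..2")
  }
  100 * sum(scores) / 22
}

#' One-sample Kolmogorov-Smirnov normality test
#'
#' Standardizes `x` with its sample mean and SD and tests against the
#' standard normal, with p from the asymptotic KS distribution. Note this
#' common default is anti-conservative: estimating the parameters from the
#' sample makes the nominal p larger than a Lilliefors-corrected p would be.
#'
#' @param x Numeric values, `n >= 5`, non-degenerate.
#' @return List with `statistic` and `p`.
#' @export
ks_normality <- function(x) {
  if (length(x) < 5L) stop("need at least 5 observations")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("degenerate variance")
  z <- (x - mean(x)) / s
  res <- suppressWarnings(stats::ks.test(z, "pnorm"))
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Box-Cox normalization of symptom scores
#'
#' Shifts scores to be strictly positive (default +1, since the CESD
#' minimum is 0), picks the power `lambda` by profile maximum likelihood
#' over a grid, applies `(y^lambda - 1)/lambda` (`log y` at `lambda = 0`),
#' and reports KS normality p before and after. The transform is monotone,
#' so subject ordering (and hence any rank statistic) is preserved.
#'
#' @param x Numeric scores.
#' @param shift Constant added before transforming; `x + shift` must be
#'   strictly positive.
#' @param lambda Optional fixed power; if `NULL` (default) the grid maximum
#'   likelihood estimate is used.
#' @param lambda_grid Search grid (default -5..5 in steps of 0.01).
#' @return Object of class `boxcox_result`: `transformed`, `lambda`,
#'   `shift`, `ks_p_before`, `ks_p_after`.
#' @export
boxcox_normalize <- function(x, shift = 1, lambda = NULL,
                             lambda_grid = seq(-5, 5, by = 0.01)) {
  y <- x + shift
  if (any(y <= 0)) stop("x + shift must be strictly positive")
  if (stats::sd(x) == 0) stop("constant input cannot be normalized")
  n <- length(y)
  bc <- function(l) if (abs(l) < 1e-12) log(y) else (y^l - 1) / l
  if (is.null(lambda)) {
    slog <- sum(log(y))
    ll <- vapply(lambda_grid, function(l) {
      z <- bc(l)
      -n / 2 * log(mean((z - mean(z))^2)) + (l - 1) * slog
    }, numeric(1))
    lambda <- lambda_grid[which.max(ll)]
  }
  transformed <- bc(lambda)
  structure(
    list(transformed = transformed, lambda = lambda, shift = shift,
         ks_p_before = ks_normality(x)$p,
         ks_p_after = ks_normality(transformed)$p),
    class = "boxcox_result"
  )
}
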