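scott_bandwidth <- function(x) {
  bw <- stats::sd(x) * length(x)^(-1 / 5)
  if (!is.finite(bw) || bw <= 0)
    stop("degenerate bandwidth: input is constant", call. = FALSE)
  bw
}

#' Gaussian kernel density estimate with Scott's bandwidth
#'
#' Returns a density object that can be evaluated anywhere, used to model the
#' score distribution of one activity class. The kernel is Gaussian and the
#' bandwidth follows Scott's rule, `sd(x) * n^(-1/5)`.
#'
#' @param scores numeric vector with at least 2 distinct values.
#' @param bandwidth_rule currently only `"scott"`.
#' @return object of class `score_kde` with elements `fun` (vectorized
#'   density function), `grid` (data frame `x`, `y` on a 2048-point grid
#'   spanning the data +/- 4 bandwidths), `bw`, `n`.
#' @examples
#' k <- fit_kde(rnorm(500))
#' k$fun(0)
#' @export
fit_kde <- function(scores, bandwidth_rule = c("scott")) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  scores <- scores[is.finite(scores)]
  if (length(unique(scores)) < 2L)
    stop("need at least 2 distinct score values", call. = FALSE)
  bw <- scott_bandwidth(scores)
  lo <- min(scores) - 4 * bw
  hi <- max(scores) + 4 * bw
  dens <- stats::density(scores, bw = bw, kernel = "gaussian",
                         from = lo, to = hi, n = 2048L)
  data <- scores
  fun <- function(t) {
    vapply(t, function(tt) sum(stats::dnorm(tt, mean = data, sd = bw)),
           0) / length(data)
  }
  structure(list(fun = fun, grid = data.frame(x = dens$x, y = dens$y),
                 bw = bw, n = length(scores)),
            class = "score_kde")
}

#' @export
print.score_kde <- function(x, ...) {
  cat(sprintf("score_kde: n = %d, Scott bandwidth = %.4g\n", x$n, x$bw))
  invisible(x)
}

#' Fit a KDE-intersection classification threshold
#'
#' Estimates one Gaussian KDE per activity class and takes the crossing
#' point of the two density curves as the classification threshold, the
#' cutoff that penalizes false positives and false negatives evenly. The
#' densities are compared on a 2048-point grid spanning the pooled scores
#' plus three bandwidths on each side; crossings are located by sign change
#' with linear interpolation. When the tails produce several crossings, the
#' one between the two class means and nearest their midpoint is used.
#' The active side of the threshold is inferred from the class means, so the
#' same procedure serves raw docking scores (actives lower) and calibrated
#' scores (actives higher).
#'
#' @param active_scores,inactive_scores numeric score vectors, each with at
#'   least 2 distinct values.
#' @return object of class `threshold_model`: `threshold`, `orientation`
#'   (`"lower_is_active"` or `"higher_is_active"`), per-class bandwidths,
#'   `grid_range`, `n_grid`, and the class means.
#' @export
find_threshold <- function(active_scores, inactive_scores) {
  a <- active_scores[is.finite(active_scores)]
  i <- inactive_scores[is.finite(inactive_scores)]
  if (!length(a) || !length(i))
    stop("both score vectors must be non-empty", call. = FALSE)
  bw_a <- scott_bandwidth(a)
  bw_i <- scott_bandwidth(i)
  pool <- c(a, i)
  pad <- 3 * max(bw_a, bw_i)
  lo <- min(pool) - pad
  hi <- max(pool) + pad
  n_grid <- 2048L
  da <- stats::density(a, bw = bw_a, from = lo, to = hi, n = n_grid)
  di <- stats::density(i, bw = bw_i, from = lo, to = hi, n = n_grid)
  g <- da$x
  d <- da$y - di$y
  s <- sign(d)
  cross <- which(s[-1] * s[-n_grid] < 0 | (s[-n_grid] == 0 & s[-1] != 0))
  roots <- numeric(0)
  for (j in cross) {
    if (d[j] == 0) roots <- c(roots, g[j])
    else roots <- c(roots, g[j] - d[j] * (g[j + 1] - g[j]) / (d[j + 1] - d[j]))
  }
  if (s[n_grid] == 0) roots <- c(roots, g[n_grid])
  roots <- unique(roots)
  if (!length(roots))
    stop(sprintf("class densities do not cross inside the grid [%.4g, %.4g]",
                 lo, hi), call. = FALSE)
  mu_a <- mean(a)
  mu_i <- mean(i)
  mid <- (mu_a + mu_i) / 2
  between <- roots[roots > min(mu_a, mu_i) & roots < max(mu_a, mu_i)]
  cand <- if (length(between)) between else roots
  thr <- cand[which.min(abs(cand - mid))]
  orientation <- if (mu_a <= thr) "lower_is_active" else "higher_is_active"
  structure(list(threshold = thr, orientation = orientation,
                 bandwidth_active = bw_a, bandwidth_inactive = bw_i,
                 grid_range = c(lo, hi), n_grid = n_grid,
                 mean_active = mu_a, mean_inactive = mu_i),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("threshold_model: threshold = %.4f (%s)\n",
              x$threshold, x$orientation))
  cat(sprintf("  class means: active %.4f, inactive %.4f\n",
              x$mean_active, x$mean_inactive))
  invisible(x)
}

#' Classify scores with a threshold model
#'
#' Predicts 1 (active) strictly beyond the threshold on the active side; a
#' score exactly at the threshold is classified inactive.
#'
#' @param scores finite numeric vector.
#' @param model a [find_threshold] model (or any list with `threshold` and
#'   `orientation`).
#' @return integer vector of 0/1 predictions.
#' @export
classify <- function(scores, model) {
  stopifnot(is.numeric(scores), all(is.finite(scores)))
  if (model$orientation == "lower_is_active")
    as.integer(scores < model$threshold)
  else
    as.integer(scores > model$threshold)
}

#' Plot the two class KDEs and the fitted threshold
#'
#' @param x a `threshold_model`.
#' @param active_scores,inactive_scores the score vectors the model was
#'   fitted on.
#' @param ... passed to [graphics::plot].
#' @export
plot.threshold_model <- function(x, active_scores, inactive_scores, ...) {
  da <- stats::density(active_scores, bw = x$bandwidth_active,
                       from = x$grid_range[1], to = x$grid_range[2])
  di <- stats::density(inactive_scores, bw = x$bandwidth_inactive,
                       from = x$grid_range[1], to = x$grid_range[2])
  graphics::plot(da, col = "forestgreen", main = "Class score densities",
                 xlab = "score", ...)
  graphics::lines(di, col = "darkorange")
  graphics::abline(v = x$threshold, lty = 2)
  graphics::legend("topright", legend = c("active", "inactive", "threshold"),
                   col = c("forestgreen", "darkorange", "black"),
                   lty = c(1, 1, 2), bty = "n")
  invisible(x)
}
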