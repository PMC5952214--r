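# Shannon entropy of centroid trajectories.
#
# The entropy here is always the plug-in (histogram) estimate
#   H = -sum_i p_i log p_i,   p_i = count_i / n,   0 log 0 = 0,
# i.e. a pure function of the empirical position histogram. High SE means
# the centroid's next position is hard to predict; a near-immobile centroid
# concentrates its histogram and drives SE towards 0.

#' Histogram Shannon entropy of a sample
#'
#' Bins the samples, forms the empirical probability mass function and
#' returns `-sum(p * log(p))` with `0 * log(0) = 0`. Bins are half-open
#' `[edge, next)`, the last bin closed; all samples must fall inside the
#' binning range.
#'
#' @param x numeric samples (>= 1).
#' @param breaks explicit bin edges (length n_bins + 1), or `NULL` to build
#'   `n_bins` equal-width bins over `range`.
#' @param n_bins number of bins when `breaks` is `NULL`.
#' @param range binning support `c(lo, hi)` when `breaks` is `NULL`
#'   (default: the sample range).
#' @param base logarithm base, 2 (bits, default) or `exp(1)` (nats).
#' @return The entropy, a single number in `[0, log_base(n_bins)]`.
#' @examples
#' shannon_entropy(rep(1:8, 10), n_bins = 8, range = c(1, 9))  # 3 bits
#' shannon_entropy(c(1, 1, 2, 3), breaks = c(1, 2, 3, 4))      # 1.5 bits
#' @export
shannon_entropy <- function(x, breaks = NULL, n_bins = NULL, range = NULL,
                            base = 2) {
  if (length(x) < 1) stop("need at least one sample", call. = FALSE)
  if (is.null(breaks)) {
    if (is.null(n_bins) || n_bins < 1) {
      stop("give `breaks` or a positive `n_bins`", call. = FALSE)
    }
    if (is.null(range)) range <- base::range(x)
    if (range[1] > range[2]) stop("invalid `range`", call. = FALSE)
    if (range[2] - range[1] <= 0) {
      # all mass in one degenerate bin
      if (any(x != range[1])) {
        stop("samples outside the binning range", call. = FALSE)
      }
      return(0)
    }
    breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  }
  if (any(diff(breaks) <= 0)) stop("`breaks` must be increasing", call. = FALSE)
  if (any(x < breaks[1] | x > breaks[length(breaks)])) {
    stop("samples outside the binning range: bins must cover the support",
         call. = FALSE)
  }
  nb <- length(breaks) - 1L
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  p <- tabulate(idx, nbins = nb)
  p <- p / length(x)
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Shannon entropy of a whole clip
#'
#' Computes the per-axis entropies of a centroid trajectory — `H_x` over
#' `n_bins_x` bins spanning the x support, `H_y` over `n_bins_y` bins over
#' the y support — and combines them (arithmetic mean by default). For raw
#' pixel trajectories the supports are the image axes `[0, 640)` and
#' `[0, 480)` with unit-pixel bins, so a centroid jumping uniformly over all
#' pixels attains the maximum `log2(640)` / `log2(480)`; for z-scored input
#' the same bin counts are laid over the observed range (the transform is
#' monotone affine, so entropy is unchanged up to bin-edge effects).
#'
#' @param series a [trajectory_series()].
#' @param n_bins_x,n_bins_y bin counts per axis (defaults: one bin per pixel
#'   of the 640 x 480 frame).
#' @param base log base (2 = bits, default).
#' @param combiner how `H_combined` is formed: `"mean"` (default) or
#'   `"sum"`.
#' @return An `entropy_result`: list with `H_x`, `H_y`, `H_combined`,
#'   `n_bins_x`, `n_bins_y`, `log_base`, `n_samples`, `combiner`.
#' @export
clip_entropy <- function(series, n_bins_x = 640, n_bins_y = 480, base = 2,
                         combiner = c("mean", "sum")) {
  stopifnot(inherits(series, "trajectory_series"))
  combiner <- match.arg(combiner)
  if (nrow(series) == 0) stop("empty trajectory series", call. = FALSE)
  if (!is_normalized(series)) {
    if (any(series$x < 0 | series$x >= n_bins_x) ||
        any(series$y < 0 | series$y >= n_bins_y)) {
      stop("raw trajectory outside the [0, ", n_bins_x, ") x [0, ",
           n_bins_y, ") pixel frame", call. = FALSE)
    }
    hx <- shannon_entropy(series$x, breaks = 0:n_bins_x, base = base)
    hy <- shannon_entropy(series$y, breaks = 0:n_bins_y, base = base)
  } else {
    hx <- shannon_entropy(series$x, n_bins = n_bins_x, base = base)
    hy <- shannon_entropy(series$y, n_bins = n_bins_y, base = base)
  }
  res <- list(
    H_x = hx, H_y = hy,
    H_combined = if (combiner == "mean") (hx + hy) / 2 else hx + hy,
    n_bins_x = n_bins_x, n_bins_y = n_bins_y,
    log_base = base, n_samples = nrow(series), combiner = combiner
  )
  class(res) <- "entropy_result"
  res
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf(
    "<entropy_result> H_x = %.4f, H_y = %.4f, H_combined = %.4f (base %s, %d samples)\n",
    x$H_x, x$H_y, x$H_combined,
    if (abs(x$log_base - exp(1)) < 1e-9) "e" else format(x$log_base),
    x$n_samples
  ))
  invisible(x)
}
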