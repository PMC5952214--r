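# Power-law characterization of SE versus fish number:
#   se = a * n^b + c
# fitted by nonlinear least squares. For b < 0 the curve rises from a + c at
# n = 1 towards the asymptote c as the shoal grows — the saturating shape
# the entropy-versus-group-size data follow.

#' Goodness-of-fit panel
#'
#' The standard nonlinear-regression panel: `sse = sum(residual^2)`,
#' `r2 = 1 - sse/sst` (sst about the mean of `observed`),
#' `adj_r2 = 1 - (1 - r2)(n - 1)/(n - p)` and `rmse = sqrt(sse/(n - p))`
#' with `p = n_params` (degrees-of-freedom convention of common
#' curve-fitting tools).
#'
#' @param observed,fitted equal-length numeric vectors.
#' @param n_params number of fitted parameters (default 3).
#' @return A list: `sse`, `r2`, `adj_r2`, `rmse`.
#' @export
goodness <- function(observed, fitted, n_params = 3) {
  if (length(observed) != length(fitted)) {
    stop("`observed` and `fitted` must have equal length", call. = FALSE)
  }
  n <- length(observed)
  if (n <= n_params) stop("need more points than parameters", call. = FALSE)
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0) stop("zero total variance in `observed`", call. = FALSE)
  sse <- sum((observed - fitted)^2)
  r2 <- 1 - sse / sst
  list(sse = sse, r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - n_params),
       rmse = sqrt(sse / (n - n_params)))
}

#' Fit the power law se = a * n^b + c
#'
#' Nonlinear least squares (Levenberg–Marquardt via \pkg{minpack.lm}) with
#' multi-start: the anchor start `c0 = max(se)`, `a0 = min(se) - c0`,
#' `b0 = -0.5` (the curve approaches `c` from below for b < 0) plus
#' `n_starts - 1` jittered restarts, best SSE kept — the small-n likelihood
#' is nearly flat in (a, b), so single starts are fragile. The exponent is
#' bounded to `[-5, 5]` to prevent overflow at large n. 95% confidence
#' bounds are covariance-based t intervals with `n_points - 3` degrees of
#' freedom.
#'
#' Constant `se` input is returned as a flagged degenerate fit
#' (`a = 0`, `c = mean(se)`, `r2 = 0`) rather than an error.
#'
#' @param n fish counts (all >= 1; at least 4 points).
#' @param se entropy values, same length.
#' @param n_starts number of starts (default 5).
#' @param seed seed for the start jitter.
#' @param mode free-text tag recorded in the result (e.g. `"clips"` or
#'   `"daily_means"`), documenting which observation unit the points are.
#' @return A `power_fit`: list with `coefficients` (a, b, c), `ci_95`
#'   (3 x 2 matrix), `sse`, `r2`, `adj_r2`, `rmse`, `n_points`, `dof`,
#'   `mode`, `degenerate`.
#' @examples
#' d <- generate_se_curve_data(-4.17, -0.49, 5.40, 0, n_values = 1:50)
#' fit <- fit_power(d$n, d$se)
#' round(coef(fit), 3)
#' @export
fit_power <- function(n, se, n_starts = 5, seed = 1, mode = "clips") {
  if (length(n) != length(se)) stop("length mismatch", call. = FALSE)
  if (length(n) < 4) stop("need at least 4 points", call. = FALSE)
  if (any(n < 1)) {
    stop("fish counts must be >= 1 (n^b is undefined at 0 for b < 0)",
         call. = FALSE)
  }
  if (length(unique(n)) < 3 && stats::sd(se) >= 1e-12) {
    stop("need at least 3 distinct fish counts to identify a, b and c",
         call. = FALSE)
  }

  if (stats::sd(se) < 1e-12) {
    fit <- list(
      coefficients = c(a = 0, b = -0.5, c = mean(se)),
      ci_95 = matrix(NA_real_, 3, 2,
                     dimnames = list(c("a", "b", "c"), c("lower", "upper"))),
      sse = 0, r2 = 0, adj_r2 = 0, rmse = 0,
      n_points = length(n), dof = length(n) - 3L,
      mode = mode, degenerate = TRUE
    )
    class(fit) <- "power_fit"
    return(fit)
  }

  c0 <- max(se)
  a0 <- min(se) - c0
  if (abs(a0) < 1e-8) a0 <- -1
  b0 <- -0.5
  set.seed(seed)
  starts <- c(
    list(c(a0, b0, c0)),
    replicate(max(n_starts - 1, 0), {
      c(a0 * stats::runif(1, 0.3, 3), b0 * stats::runif(1, 0.2, 3),
        c0 * stats::runif(1, 0.8, 1.2))
    }, simplify = FALSE)
  )

  d <- data.frame(n = n, se = se)
  best <- NULL
  last_err <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        se ~ a * n^b + c, data = d,
        start = list(a = s[1], b = s[2], c = s[3]),
        lower = c(-Inf, -5, -Inf), upper = c(Inf, 5, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      last_err <- fit
      next
    }
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    stop("power fit failed to converge from any start (last error: ",
         conditionMessage(last_err), "); residual norm unknown",
         call. = FALSE)
  }

  fit <- best$fit
  est <- stats::coef(fit)
  dof <- length(n) - 3L
  se_coef <- summary(fit)$coefficients[, "Std. Error"]
  tq <- stats::qt(0.975, dof)
  ci <- cbind(lower = est - tq * se_coef, upper = est + tq * se_coef)
  g <- goodness(se, stats::fitted(fit), n_params = 3)

  out <- list(
    coefficients = c(a = unname(est["a"]), b = unname(est["b"]),
                     c = unname(est["c"])),
    ci_95 = ci, sse = g$sse, r2 = g$r2, adj_r2 = g$adj_r2, rmse = g$rmse,
    n_points = length(n), dof = dof, mode = mode, degenerate = FALSE
  )
  class(out) <- "power_fit"
  out
}

#' @export
coef.power_fit <- function(object, ...) object$coefficients

#' @export
predict.power_fit <- function(object, n, ...) {
  cf <- object$coefficients
  cf["a"] * n^cf["b"] + cf["c"]
}

#' @export
print.power_fit <- function(x, ...) {
  cat("Power fit: se = a * n^b + c",
      if (x$degenerate) "  [degenerate: no n-dependence]", "\n", sep = "")
  cf <- cbind(estimate = x$coefficients, x$ci_95)
  print(round(cf, 4))
  cat(sprintf("SSE %.4g  R2 %.4f  adj-R2 %.4f  RMSE %.4g  (%d points, %s)\n",
              x$sse, x$r2, x$adj_r2, x$rmse, x$n_points, x$mode))
  invisible(x)
}
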