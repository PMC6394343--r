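#' Sweep cLHS sample sizes and record divergence from the population
#'
#' For each size in `seq(size_min, size_max, step)`, `reps` independent
#' seeded cLHS runs are performed and the mean divergence of each design
#' from the population ([mean_divergence()]) is recorded. Per-run seeds are
#' drawn once from the master seed (`set.seed(seed)` then a single
#' `sample.int` of `n_sizes * reps` seeds, consumed size-major), so reps
#' are independent but the whole sweep is reproducible.
#'
#' @param stack a [covariate_stack()].
#' @param size_min,size_max,step sweep grid (defaults 10, 500, 10);
#'   `size_max` must not exceed the number of valid cells.
#' @param reps cLHS repeats per size (default 10).
#' @param nbins histogram bins for the divergence (default 25).
#' @param metric `"kl"` or `"absdev"`.
#' @param iterations annealing iterations per cLHS run.
#' @param seed master seed.
#' @param ... further arguments passed to [clhs()].
#' @return data.frame of class `size_sweep` with columns `size`, `mean_kl`,
#'   `sd_kl`; per-rep values in the `reps` attribute (matrix, sizes x reps).
#' @export
run_sweep <- function(stack, size_min = 10L, size_max = 500L, step = 10L,
                      reps = 10L, nbins = 25L, metric = "kl",
                      iterations = 10000L, seed = 1L, ...) {
  stopifnot(size_min >= 1L, step >= 1L, reps >= 1L)
  if (size_max > stack$r)
    stop("size_max = ", size_max, " exceeds the ", stack$r, " valid cells",
         call. = FALSE)
  sizes <- seq.int(size_min, size_max, by = step)
  set.seed(seed)
  run_seeds <- matrix(sample.int(.Machine$integer.max, length(sizes) * reps),
                      nrow = length(sizes))
  vals <- matrix(NA_real_, length(sizes), reps)
  for (i in seq_along(sizes)) {
    for (j in seq_len(reps)) {
      res <- tryCatch(
        clhs(stack, n = sizes[i], iterations = iterations,
             seed = run_seeds[i, j], ...),
        error = function(e) stop("cLHS failed at size ", sizes[i], ", rep ",
                                 j, ": ", conditionMessage(e), call. = FALSE))
      vals[i, j] <- mean_divergence(stack, res$design, nbins = nbins,
                                    metric = metric)$mean
    }
  }
  out <- data.frame(size = sizes,
                    mean_kl = rowMeans(vals),
                    sd_kl = apply(vals, 1L, stats::sd))
  attr(out, "reps") <- vals
  attr(out, "metric") <- metric
  class(out) <- c("size_sweep", "data.frame")
  out
}

#' Fit an exponential decay to divergence-vs-size data
#'
#' Nonlinear least squares for `y = b1 * exp(-k * x) + b0` with starting
#' values `b0 = min(y)`, `b1 = max(y) - min(y)`, `k = 1 / mean(x)` and the
#' bounds `b1 >= 0`, `k > 0` (port algorithm). A flat or non-decreasing
#' series fails to converge; the error carries the starting values.
#'
#' @param sizes sample sizes (>= 4 points).
#' @param mean_kl mean divergence at each size.
#' @return list of class `decay_fit` with `b0`, `b1`, `k`, `se` (named
#'   standard errors), `residuals`, `fitted`, and the `nls` object in
#'   `model`.
#' @export
fit_decay <- function(sizes, mean_kl) {
  stopifnot(length(sizes) == length(mean_kl), length(sizes) >= 4L)
  start <- list(b0 = min(mean_kl), b1 = max(mean_kl) - min(mean_kl),
                k = 1 / mean(sizes))
  dat <- data.frame(x = sizes, y = mean_kl)
  fit <- tryCatch(
    stats::nls(y ~ b0 + b1 * exp(-k * x), data = dat, start = start,
               algorithm = "port",
               lower = c(b0 = -Inf, b1 = 0, k = 1e-10),
               control = stats::nls.control(maxiter = 200,
                                            scaleOffset = 1)),
    error = function(e)
      stop("decay fit did not converge (start b0=", signif(start$b0, 4),
           ", b1=", signif(start$b1, 4), ", k=", signif(start$k, 4), "): ",
           conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3L))
  structure(list(b0 = unname(cf["b0"]), b1 = unname(cf["b1"]),
                 k = unname(cf["k"]),
                 se = stats::setNames(as.numeric(se), names(cf)),
                 residuals = stats::residuals(fit),
                 fitted = stats::fitted(fit), model = fit),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> y = %.4g * exp(-%.4g x) + %.4g  (RSS %.3g)\n",
              x$b1, x$k, x$b0, sum(x$residuals^2)))
  invisible(x)
}

#' Optimal sample size from a fitted decay
#'
#' The captured fraction of covariate-space information at size `x` is the
#' normalised decay `C(x) = 1 - exp(-k x)` (any constant scaling of the
#' divergence cancels). The optimal size is the smallest grid size whose
#' captured fraction reaches `coverage`; the exact continuous solution
#' `x* = -ln(1 - coverage) / k` is reported alongside.
#'
#' @param fit a [fit_decay()] result, or any list with element `k > 0`.
#' @param coverage target captured fraction, in (0, 1) (default 0.95).
#' @param grid candidate sizes (default `seq(10, 500, 10)`, the sweep grid).
#' @return list with `size` (chosen grid size), `x_star` (continuous
#'   solution) and `coverage`.
#' @export
optimal_size <- function(fit, coverage = 0.95, grid = seq(10L, 500L, 10L)) {
  k <- fit$k
  stopifnot(is.numeric(k), k > 0, coverage > 0, coverage < 1)
  x_star <- -log(1 - coverage) / k
  captured <- 1 - exp(-k * grid)
  ok <- which(captured >= coverage)
  if (length(ok) == 0L)
    stop("coverage ", coverage, " unreachable on the grid (continuous ",
         "solution x* = ", round(x_star, 2), ")", call. = FALSE)
  list(size = grid[ok[1L]], x_star = x_star, coverage = coverage)
}
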