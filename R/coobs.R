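# whitening transform: rows of X %*% solve(chol(sigma)) have unit
# covariance, so Euclidean distance in the whitened space equals the
# Mahalanobis distance under sigma
whiten <- function(X, sigma) {
  as.matrix(X) %*% solve(chol(sigma))
}

cross_dist2 <- function(A, B) {
  # squared Euclidean distances between rows of A (n x k) and B (m x k);
  # in whitened coordinates these are squared Mahalanobis distances
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Per-pixel maximum multivariate distance (magpd)
#'
#' For each valid cell, the maximum squared Mahalanobis distance
#' (continuous covariates, full-raster covariance; the squared scale is
#' shared with [relocate()]) to the other valid cells. Exact mode
#' computes all pairwise distances (O(r^2), intended for small rasters and
#' tests); approximate mode maximises over a seeded random subset of
#' `approx_sample` cells, which biases magpd downward (documented; the
#' subset always includes each pixel's own comparisons, not itself).
#'
#' @param stack a [covariate_stack()] with >= 2 valid cells.
#' @param mode `"exact"` or `"approximate"`.
#' @param approx_sample subset size in approximate mode (default
#'   `min(r, 2000)`); `approx_sample = r` reproduces exact mode.
#' @param seed seed for the subset draw.
#' @param sigma optional precomputed [stack_covariance()].
#' @return numeric vector of magpd per valid cell (aligned with
#'   [valid_cells()]). A constant stack (all distances zero) is an error.
#' @export
magpd_map <- function(stack, mode = c("approximate", "exact"),
                      approx_sample = NULL, seed = NULL, sigma = NULL) {
  mode <- match.arg(mode)
  if (stack$r < 2L) stop("need >= 2 valid cells", call. = FALSE)
  if (is.null(sigma)) sigma <- stack_covariance(stack)
  cn <- continuous_names(stack)
  X <- whiten(cell_values(stack)[cn], sigma)
  if (mode == "approximate") {
    if (is.null(approx_sample)) approx_sample <- min(stack$r, 2000L)
    stopifnot(approx_sample >= 2L)
    if (!is.null(seed)) set.seed(seed)
    idx <- sort(sample.int(stack$r, min(approx_sample, stack$r)))
  } else {
    idx <- seq_len(stack$r)
  }
  D <- cross_dist2(X, X[idx, , drop = FALSE])
  magpd <- apply(D, 1L, max)
  if (all(magpd == 0))
    stop("degenerate stack: all covariate vectors identical", call. = FALSE)
  magpd
}

#' Count-of-observations (COOBS) coverage map
#'
#' For each valid pixel `i`, the data distance `dd_j` (squared Mahalanobis,
#' same scale as [magpd_map()]) to every legacy point
#' `j` is standardised by the pixel's maximum distance,
#' `sdd_j = 1 - dd_j / magpd_i`, and the COOBS value is the number of
#' legacy points with `sdd_j >= threshold`. Values near `o` mark pixels
#' whose covariate combination is already well observed; low values mark
#' coverage gaps. Pixels with `magpd = 0` are flagged and counted by exact
#' covariate match.
#'
#' @param stack a [covariate_stack()].
#' @param legacy a non-empty [sample_design()].
#' @param threshold similarity threshold close to 1 (default 0.975).
#' @param mode,approx_sample,seed passed to [magpd_map()].
#' @return list of class `coverage_map` with `coobs` and `magpd` (matrices
#'   in grid shape, `NA` off-mask), `threshold`, `o`, and `flagged`
#'   (cell indices with zero magpd).
#' @export
coobs_map <- function(stack, legacy, threshold = 0.975,
                      mode = c("approximate", "exact"),
                      approx_sample = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(legacy) || nrow(legacy) == 0L)
    stop("legacy design is empty", call. = FALSE)
  sigma <- stack_covariance(stack)
  cn <- continuous_names(stack)
  magpd <- magpd_map(stack, mode = mode, approx_sample = approx_sample,
                     seed = seed, sigma = sigma)
  X <- whiten(cell_values(stack)[cn], sigma)
  L <- whiten(design_values(legacy)[cn], sigma)
  dd <- cross_dist2(X, L)                      # r x o, squared scale
  zero <- magpd == 0
  counts <- integer(stack$r)
  if (any(!zero)) {
    sdd <- 1 - dd[!zero, , drop = FALSE] / magpd[!zero]
    counts[!zero] <- rowSums(sdd >= threshold)
  }
  if (any(zero))
    counts[zero] <- rowSums(dd[zero, , drop = FALSE] == 0)
  cells <- valid_cells(stack)
  cm <- matrix(NA_real_, nrow(stack$mask), ncol(stack$mask))
  mm <- cm
  cm[cells] <- counts
  mm[cells] <- magpd
  structure(list(coobs = cm, magpd = mm, threshold = threshold,
                 o = nrow(legacy), flagged = cells[zero]),
            class = "coverage_map")
}

#' Cross-tabulate site locations against coverage classes
#'
#' Proportion of a design's sites falling in each COOBS class. Classes are
#' half-open `[low, high)` with the last class closed above by `o`; the
#' defaults follow the conventional banding 0-5, 5-10, 10-20, 20-40, >40.
#'
#' @param coverage a [coobs_map()] result.
#' @param sites a [sample_design()] on the same stack.
#' @param breaks lower class edges (default `c(0, 5, 10, 20, 40)`).
#' @return data.frame with `class` labels and `proportion` (sums to 1).
#' @export
coverage_crosstab <- function(coverage, sites,
                              breaks = c(0, 5, 10, 20, 40)) {
  v <- coverage$coobs[sites$cell]
  if (anyNA(v))
    stop("site(s) off the coverage map's valid mask", call. = FALSE)
  idx <- findInterval(v, breaks)
  labels <- c(paste(breaks[-length(breaks)], breaks[-1L], sep = "-"),
              paste0(">", breaks[length(breaks)]))
  counts <- tabulate(idx, nbins = length(breaks))
  data.frame(class = labels, proportion = counts / length(v))
}
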