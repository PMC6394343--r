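# Gaussian smoothing of a matrix by separable convolution with reflected
# edges; `range` is the kernel standard deviation in cells
smooth_field <- function(m, range) {
  if (range <= 0) return(m)
  half <- max(1L, ceiling(3 * range))
  kern <- stats::dnorm(seq(-half, half), sd = range)
  kern <- kern / sum(kern)
  conv1 <- function(v) {
    n <- length(v)
    pad <- c(v[pmin(half:1, n)], v, v[pmax(n - (1:half) + 1L, 1L)])
    stats::filter(pad, kern, sides = 2)[(half + 1L):(half + n)]
  }
  m <- apply(m, 2L, conv1)
  t(apply(t(m), 2L, conv1))
}

#' Generate a synthetic covariate landscape
#'
#' Seeded stand-in for a real terrain/sensor covariate stack: independent
#' Gaussian white-noise fields are linearly mixed through the Cholesky
#' factor of a target correlation matrix, then each layer is smoothed with
#' a Gaussian kernel (spatial autocorrelation) and standardised. Because
#' the same smoothing is applied to every mixed layer, the realised
#' inter-layer Pearson correlation approximates the target (tests use a
#' +/- 0.1 tolerance). Categorical layers are quantile cuts of additional
#' smoothed fields, so classes form spatially coherent patches.
#'
#' What this emulates: several co-registered, spatially autocorrelated,
#' cross-correlated continuous covariates, coarse categorical maps, and
#' optional nodata. What it does not: variogram-exact spatial structure,
#' skewed/multimodal sensor distributions, or real terrain derivatives.
#'
#' @param nrow,ncol grid shape (default 100 x 100).
#' @param n_continuous number of continuous covariates (default 5).
#' @param correlation target correlation matrix (`n_continuous` square,
#'   unit diagonal, positive semi-definite); default identity.
#' @param range smoothing kernel sd in cells, recycled per layer
#'   (default 5).
#' @param n_categorical number of categorical layers (default 0).
#' @param n_classes classes per categorical layer (default 3).
#' @param nodata_fraction fraction of cells masked in all layers
#'   (default 0).
#' @param cellsize cell size in meters (default 25, a typical DEM
#'   resolution).
#' @param seed integer seed; identical seeds give identical stacks.
#' @return a [covariate_stack()] with layers `cov1..covk`, `cat1..`.
#' @export
make_landscape <- function(nrow = 100L, ncol = 100L, n_continuous = 5L,
                           correlation = NULL, range = 5,
                           n_categorical = 0L, n_classes = 3L,
                           nodata_fraction = 0, cellsize = 25,
                           seed = NULL) {
  stopifnot(nrow >= 2L, ncol >= 2L, n_continuous >= 1L,
            nodata_fraction >= 0, nodata_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(correlation)) correlation <- diag(n_continuous)
  if (!isSymmetric(unname(correlation)) ||
      any(abs(diag(correlation) - 1) > 1e-8))
    stop("`correlation` must be symmetric with unit diagonal", call. = FALSE)
  ch <- tryCatch(chol(correlation),
                 error = function(e)
                   stop("`correlation` is not positive semi-definite",
                        call. = FALSE))
  range <- rep_len(range, n_continuous)
  ncell <- nrow * ncol
  Z <- matrix(stats::rnorm(ncell * n_continuous), ncell) %*% ch
  layers <- list()
  for (i in seq_len(n_continuous)) {
    f <- smooth_field(matrix(Z[, i], nrow, ncol), range[i])
    layers[[paste0("cov", i)]] <- (f - mean(f)) / stats::sd(f)
  }
  kinds <- rep("continuous", n_continuous)
  for (i in seq_len(n_categorical)) {
    f <- smooth_field(matrix(stats::rnorm(ncell), nrow, ncol), range[1L])
    cuts <- stats::quantile(f, probs = seq(0, 1, length.out = n_classes + 1L))
    codes <- bin_index(as.vector(f), cuts)
    layers[[paste0("cat", i)]] <- matrix(as.numeric(codes), nrow, ncol)
    kinds <- c(kinds, "categorical")
  }
  if (nodata_fraction > 0) {
    hole <- sample.int(ncell, round(nodata_fraction * ncell))
    for (nm in names(layers)) layers[[nm]][hole] <- NA_real_
  }
  covariate_stack(layers, kinds, cellsize = cellsize,
                  crs = "local projected (m)")
}

#' Generate a legacy sample design with known bias
#'
#' Emulates pre-existing survey data whose covariate-space coverage a new
#' survey must complement: `"none"` draws cells uniformly;
#' `"spatial_corner"` confines sites to the top-left map quadrant;
#' `"covariate_low_tail"` draws with probability proportional to the
#' rank-inverse of the first continuous covariate, concentrating sites in
#' its low values and starving the upper strata.
#'
#' @param stack a [covariate_stack()].
#' @param n number of legacy sites, `<= r` (and `<=` eligible cells for the
#'   corner bias).
#' @param bias `"none"`, `"spatial_corner"` or `"covariate_low_tail"`.
#' @param seed integer seed.
#' @return a [sample_design()] with provenance `"legacy"`.
#' @export
make_legacy <- function(stack, n,
                        bias = c("none", "spatial_corner",
                                 "covariate_low_tail"),
                        seed = NULL) {
  bias <- match.arg(bias)
  if (!is.null(seed)) set.seed(seed)
  cells <- valid_cells(stack)
  d <- dim(stack$mask)
  eligible <- cells
  prob <- NULL
  if (bias == "spatial_corner") {
    rw <- ((cells - 1L) %% d[1L]) + 1L
    cl <- ((cells - 1L) %/% d[1L]) + 1L
    eligible <- cells[rw <= ceiling(d[1L] / 2) & cl <= ceiling(d[2L] / 2)]
  } else if (bias == "covariate_low_tail") {
    v <- stack$layers[[continuous_names(stack)[1L]]][cells]
    prob <- length(v) - rank(v, ties.method = "first") + 1
  }
  if (n > length(eligible))
    stop("n = ", n, " exceeds the ", length(eligible), " eligible cells",
         call. = FALSE)
  picked <- sample(eligible, n, prob = prob)
  sample_design(stack, picked, provenance = "legacy")
}

#' Regular-grid design of approximately n sites
#'
#' Rounds the grid spacing so that about `n` cell centers fall on the valid
#' mask; used as the benchmark design that cLHS is compared against.
#'
#' @param stack a [covariate_stack()].
#' @param n target number of sites.
#' @return a [sample_design()] with provenance `"grid"`.
#' @export
make_grid_design <- function(stack, n) {
  d <- dim(stack$mask)
  spacing <- max(1L, floor(sqrt(prod(d) / n)))
  repeat {
    rws <- seq.int(ceiling(spacing / 2), d[1L], by = spacing)
    cls <- seq.int(ceiling(spacing / 2), d[2L], by = spacing)
    cells <- as.integer(outer(rws, (cls - 1L) * d[1L], `+`))
    cells <- cells[stack$mask[cells]]
    if (length(cells) >= n || spacing == 1L) break
    spacing <- spacing - 1L
  }
  if (length(cells) > n) cells <- cells[round(seq(1, length(cells), length.out = n))]
  sample_design(stack, cells, provenance = "grid")
}
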