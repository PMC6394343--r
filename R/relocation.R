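#' Covariance of the continuous covariates over the whole valid raster
#'
#' Shared by the relocation and coverage-map modules so that Mahalanobis
#' distances are comparable across them. A near-singular matrix is repaired
#' by ridge inflation (`1e-8 * mean(diag)` added to the diagonal) with a
#' warning; if it is still singular the collinear layer pairs are named in
#' the error.
#'
#' @param stack a [covariate_stack()].
#' @return positive-definite covariance matrix of the continuous layers.
#' @export
stack_covariance <- function(stack) {
  cn <- continuous_names(stack)
  if (length(cn) == 0L)
    stop("no continuous covariates in the stack", call. = FALSE)
  X <- as.matrix(cell_values(stack)[cn])
  sigma <- stats::cov(X)
  if (all(diag(sigma) == 0))
    stop("degenerate stack: every continuous covariate is constant",
         call. = FALSE)
  ok <- function(s) is.finite(rcond(s)) && rcond(s) > 1e-12
  if (!ok(sigma)) {
    warning("near-singular covariance: ridge repair applied", call. = FALSE)
    sigma <- sigma + diag(1e-8 * mean(diag(sigma)), nrow(sigma))
    if (!ok(sigma)) {
      cc <- stats::cor(X)
      pairs <- which(abs(cc) > 0.999999 & upper.tri(cc), arr.ind = TRUE)
      stop("singular covariance; collinear layers: ",
           paste(cn[pairs[, 1L]], cn[pairs[, 2L]], sep = "~",
                 collapse = ", "), call. = FALSE)
    }
  }
  dimnames(sigma) <- list(cn, cn)
  sigma
}

#' Mahalanobis distances to a site in covariate space
#'
#' `d(x, s) = sqrt((x - s)' Sigma^-1 (x - s))` over the continuous
#' covariates.
#'
#' @param values matrix or data.frame of candidate covariate vectors (rows).
#' @param site numeric vector, the site's covariate values (same order).
#' @param sigma covariance matrix (see [stack_covariance()]).
#' @return numeric vector of distances (0 iff the candidate equals the site).
#' @export
mahalanobis_distance <- function(values, site, sigma) {
  sqrt(stats::mahalanobis(as.matrix(values), center = as.numeric(site),
                          cov = sigma))
}

#' Sigmoid similarity of a Mahalanobis distance
#'
#' `S = 1 / (1 + exp(slope * (dist - dist_med)))`: a strictly decreasing
#' map from distance to (0, 1), anchored so that the median distance within
#' the buffer scores exactly 0.5 (the median is used because it is less
#' outlier-sensitive than the mean). The qualifier set at threshold `t` is
#' exactly `{dist <= dist_med + log(1/t - 1) / slope}`.
#'
#' @param dist Mahalanobis distance(s), `>= 0`.
#' @param dist_med median Mahalanobis distance over the candidate zone.
#' @param slope sigmoid steepness (default 1; exposed for sensitivity
#'   analysis only).
#' @return similarity value(s) in (0, 1).
#' @export
similarity <- function(dist, dist_med, slope = 1) {
  1 / (1 + exp(slope * (dist - dist_med)))
}

#' Candidate cells for relocating a site
#'
#' All valid cells whose centers lie within `radius` meters of the site's
#' center, excluding the site itself, and -- for every categorical layer --
#' keeping only cells whose class matches the site's class.
#'
#' @param stack a [covariate_stack()].
#' @param site linear cell index of the (inaccessible) site; must be valid.
#' @param radius buffer radius in meters (default 500).
#' @return integer vector of candidate cell indices; an empty zone is an
#'   error (condition class `hypersample_empty_zone`).
#' @export
candidate_zone <- function(stack, site, radius = 500) {
  stopifnot(radius > 0, length(site) == 1L)
  if (!stack$mask[site]) stop("site is not on the valid mask", call. = FALSE)
  cells <- valid_cells(stack)
  xy <- cell_xy(stack, cells)
  s <- cell_xy(stack, site)
  d2 <- (xy$x - s$x)^2 + (xy$y - s$y)^2
  keep <- d2 <= radius^2 & cells != site
  for (nm in categorical_names(stack)) {
    keep <- keep & stack$layers[[nm]][cells] == stack$layers[[nm]][site]
  }
  out <- cells[keep]
  if (length(out) == 0L)
    stop(structure(class = c("hypersample_empty_zone", "error", "condition"),
                   list(message = paste0("empty candidate zone around cell ",
                                         site, " at radius ", radius, " m"),
                        call = NULL)))
  out
}

#' Relocate an inaccessible site to a similar nearby cell
#'
#' Builds the buffered, categorically masked candidate zone, computes
#' squared Mahalanobis distances from each candidate to the site over the
#' continuous covariates (full-raster covariance), converts them to sigmoid
#' similarities anchored at the zone's median distance, and picks among the
#' cells whose similarity reaches `threshold`:
#' `"random"` draws one qualifier uniformly (seeded), `"nearest"` takes the
#' geographically closest qualifier, `"ranked"` returns qualifiers ordered
#' by increasing covariate distance and selects the first.
#'
#' The sigmoid operates on the *squared* Mahalanobis scale: a similarity
#' threshold `t` admits candidates with squared distance below
#' `dist_med + log(1/t - 1)`, and only on the squared scale do local-buffer
#' medians clear the ~3.66 gap that `t = 0.975` implies.
#'
#' @param stack a [covariate_stack()].
#' @param site linear cell index of the inaccessible site.
#' @param radius buffer radius in meters (default 500).
#' @param threshold similarity threshold in (0, 1) (default 0.975).
#' @param strategy `"random"`, `"nearest"` or `"ranked"`.
#' @param slope sigmoid steepness passed to [similarity()].
#' @param seed seed for the random strategy.
#' @param grow if `TRUE`, an empty zone or empty qualifier set doubles the
#'   radius (up to `grow_cap` times the original) before failing; off by
#'   default to honour a fixed survey buffer.
#' @param grow_cap maximum radius multiple when growing.
#' @param sigma optional precomputed [stack_covariance()] (saves time when
#'   relocating many sites).
#' @return list of class `relocation` with `site` (new cell index), `xy`,
#'   `surface` (data.frame: cell, dist = squared Mahalanobis distance,
#'   similarity over the zone), `dist_med`, `qualifiers` (ordered by
#'   distance), and `radius` actually used. No qualifier is an error
#'   (class `hypersample_no_qualifier`) reporting the best similarity
#'   attained.
#' @export
relocate <- function(stack, site, radius = 500, threshold = 0.975,
                     strategy = c("random", "nearest", "ranked"), slope = 1,
                     seed = NULL, grow = FALSE, grow_cap = 4,
                     sigma = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(sigma)) sigma <- stack_covariance(stack)
  if (!is.null(seed)) set.seed(seed)
  cn <- continuous_names(stack)
  site_vals <- as.numeric(cell_values(stack, site)[cn])
  rad <- radius
  repeat {
    zone <- tryCatch(candidate_zone(stack, site, rad), error = function(e) e)
    if (!inherits(zone, "error")) {
      dist <- stats::mahalanobis(as.matrix(cell_values(stack, zone)[cn]),
                                 center = site_vals, cov = sigma)
      dist_med <- stats::median(dist)
      sim <- similarity(dist, dist_med, slope)
      qual <- zone[sim >= threshold]
      if (length(qual) > 0L) break
      err <- structure(
        class = c("hypersample_no_qualifier", "error", "condition"),
        list(message = sprintf(
          "no candidate reaches similarity %.4g (best attained %.4g)",
          threshold, max(sim)), call = NULL))
    } else err <- zone
    if (!grow || rad >= radius * grow_cap) stop(err)
    rad <- min(rad * 2, radius * grow_cap)
  }
  ord <- order(dist[match(qual, zone)])
  qualifiers <- qual[ord]
  new_site <- switch(strategy,
    random = qual[sample.int(length(qual), 1L)],
    nearest = {
      qxy <- cell_xy(stack, qual)
      sxy <- cell_xy(stack, site)
      qual[which.min((qxy$x - sxy$x)^2 + (qxy$y - sxy$y)^2)]
    },
    ranked = qualifiers[1L])
  structure(list(site = new_site, xy = cell_xy(stack, new_site),
                 surface = data.frame(cell = zone, dist = dist,
                                      similarity = sim),
                 dist_med = dist_med, qualifiers = qualifiers,
                 radius = rad),
            class = "relocation")
}

#' Relocate every site of a design
#'
#' @param stack a [covariate_stack()].
#' @param design a [sample_design()] whose sites are all deemed
#'   inaccessible.
#' @param seed master seed; one sub-seed per site.
#' @param ... passed to [relocate()].
#' @return a [sample_design()] with provenance `"relocated"`, same size and
#'   order as `design`.
#' @export
relocate_design <- function(stack, design, seed = NULL, ...) {
  sigma <- stack_covariance(stack)
  if (!is.null(seed)) set.seed(seed)
  site_seeds <- sample.int(.Machine$integer.max, nrow(design))
  new_cells <- vapply(seq_len(nrow(design)), function(i) {
    relocate(stack, design$cell[i], seed = site_seeds[i], sigma = sigma,
             ...)$site
  }, integer(1))
  sample_design(stack, new_cells, provenance = "relocated")
}

#' Compare original and relocated designs by per-covariate divergence
#'
#' @param stack a [covariate_stack()].
#' @param original,relocated same-size [sample_design()]s.
#' @param nbins histogram bins (default 25).
#' @return data.frame with one row per covariate plus a `"Mean"` row:
#'   `covariate`, `kl_original`, `kl_relocated`, `delta`.
#' @export
evaluate_relocation <- function(stack, original, relocated, nbins = 25L) {
  if (nrow(original) != nrow(relocated))
    stop("designs differ in size (", nrow(original), " vs ",
         nrow(relocated), ")", call. = FALSE)
  a <- mean_divergence(stack, original, nbins = nbins)
  b <- mean_divergence(stack, relocated, nbins = nbins)
  out <- data.frame(covariate = c(names(a$per_covariate), "Mean"),
                    kl_original = c(a$per_covariate, a$mean),
                    kl_relocated = c(b$per_covariate, b$mean))
  out$delta <- out$kl_relocated - out$kl_original
  rownames(out) <- NULL
  out
}
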