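#' Histogram bin specifications
#'
#' Equal-width bins spanning the population range of a continuous
#' covariate. Sample and population are always binned against the *same*
#' population-derived edges, otherwise their distributions are not
#' comparable. Values equal to the maximum fall in the last bin.
#'
#' @param values population values (>= 2 distinct values expected).
#' @param nbins number of bins (default 25).
#' @return list of class `bin_spec` with `edges` (length `nbins + 1`,
#'   strictly increasing) and `nbins`. A constant covariate yields a
#'   single-bin spec with a warning.
#' @export
make_bins <- function(values, nbins = 25L) {
  stopifnot(nbins >= 1L)
  values <- values[!is.na(values)]
  rng <- range(values)
  if (rng[1L] == rng[2L]) {
    warning("constant covariate: single-bin spec", call. = FALSE)
    return(structure(list(edges = c(rng[1L], rng[1L] + 1), nbins = 1L),
                     class = "bin_spec"))
  }
  structure(list(edges = seq(rng[1L], rng[2L], length.out = nbins + 1L),
                 nbins = as.integer(nbins)),
            class = "bin_spec")
}

#' Binned proportions of a set of values
#'
#' @param values numeric values (continuous covariate) or class codes
#'   (categorical, with `categories` given).
#' @param spec a [make_bins()] spec, or `NULL` for categorical use.
#' @param categories category list for categorical covariates; proportions
#'   are reported per category in this order.
#' @return numeric vector of proportions (sums to 1).
#' @export
bin_proportions <- function(values, spec = NULL, categories = NULL) {
  values <- values[!is.na(values)]
  if (!is.null(categories)) {
    p <- table(factor(as.character(values), levels = as.character(categories)))
    return(as.numeric(p) / length(values))
  }
  idx <- bin_index(values, spec$edges)
  tabulate(idx, nbins = spec$nbins) / length(values)
}

#' Kullback-Leibler divergence between binned distributions
#'
#' `KL = sum_i O_i (ln O_i - ln E_i)` over shared bins, with the limit
#' convention `0 * log 0 = 0`. If the sample places mass on a bin where the
#' population has none (possible only through numerically empty population
#' bins), the population distribution is eps-smoothed (1e-6 added to every
#' bin, renormalised) with a warning so the divergence stays finite.
#'
#' Unlike the total absolute deviation, KL penalises mass missing from the
#' distribution tails (low-`E` bins) more than the same mass missing near
#' the mode.
#'
#' @param O sample proportions.
#' @param E population proportions (same bin spec, same length).
#' @return nonnegative scalar; 0 iff `O == E` on the support of `E`.
#' @export
kl_divergence <- function(O, E) {
  if (length(O) != length(E))
    stop("O and E have different lengths (", length(O), " vs ", length(E),
         ")", call. = FALSE)
  if (any(O > 0 & E == 0)) {
    warning("sample mass on empty population bins: eps-smoothing E",
            call. = FALSE)
    E <- E + 1e-6
    E <- E / sum(E)
  }
  keep <- O > 0
  sum(O[keep] * (log(O[keep]) - log(E[keep])))
}

#' Total absolute deviation between binned distributions
#'
#' `sum_i |O_i - E_i|`; bounded by 2; penalises all departures equally.
#'
#' @inheritParams kl_divergence
#' @return scalar in `[0, 2]`.
#' @export
abs_deviation <- function(O, E) {
  if (length(O) != length(E))
    stop("O and E have different lengths (", length(O), " vs ", length(E),
         ")", call. = FALSE)
  sum(abs(O - E))
}

#' Per-covariate divergence of a design from the population
#'
#' Continuous covariates are compared through `nbins` equal-width bins over
#' the population range; categorical covariates through raw class
#' proportions. The per-covariate divergences are averaged without weights.
#'
#' @param stack a [covariate_stack()].
#' @param design a non-empty [sample_design()].
#' @param nbins histogram bins for continuous covariates (default 25).
#' @param metric `"kl"` or `"absdev"`.
#' @return list with `per_covariate` (named numeric) and `mean`.
#' @export
mean_divergence <- function(stack, design, nbins = 25L,
                            metric = c("kl", "absdev")) {
  metric <- match.arg(metric)
  if (is.null(design) || nrow(design) == 0L)
    stop("empty design", call. = FALSE)
  fn <- if (metric == "kl") kl_divergence else abs_deviation
  pop <- cell_values(stack)
  smp <- design_values(design)
  out <- numeric(0)
  for (nm in names(stack$layers)) {
    if (stack$kinds[[nm]] == "continuous") {
      spec <- make_bins(pop[[nm]], nbins)
      E <- bin_proportions(pop[[nm]], spec)
      O <- bin_proportions(smp[[nm]], spec)
    } else {
      cats <- sort(unique(pop[[nm]]))
      E <- bin_proportions(pop[[nm]], categories = cats)
      O <- bin_proportions(smp[[nm]], categories = cats)
    }
    out[nm] <- fn(O, E)
  }
  list(per_covariate = out, mean = mean(out))
}
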