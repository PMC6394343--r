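#' Equal-probability strata and population summaries for cLHS
#'
#' For each continuous covariate the empirical distribution over the valid
#' cells is cut into `n` equi-probable strata (n+1 empirical quantiles,
#' linear interpolation). For each categorical covariate the population
#' class proportions are recorded. Strata are half-open `[low, high)` with
#' the last stratum closed; duplicated quantile edges (possible when `n`
#' exceeds the number of distinct values) are kept, and the resulting
#' zero-width strata are flagged with a warning.
#'
#' @param stack a [covariate_stack()].
#' @param n number of strata (the target sample size), `>= 1`.
#' @return list with `n`, `continuous` (named list of length-(n+1) edge
#'   vectors) and `categorical` (named list of class-proportion tables).
#' @export
build_strata <- function(stack, n) {
  stopifnot(n >= 1, n <= stack$r)
  tab <- cell_values(stack)
  cont <- lapply(tab[continuous_names(stack)], function(v) {
    e <- stats::quantile(v, probs = seq(0, 1, length.out = n + 1L),
                         names = FALSE, type = 7)
    if (anyDuplicated(e))
      warning("degenerate strata: duplicated quantile edges (n exceeds ",
              "distinct values)", call. = FALSE)
    e
  })
  cat_ <- lapply(tab[categorical_names(stack)], function(v) {
    p <- table(v) / length(v)
    stats::setNames(as.numeric(p), names(p))
  })
  list(n = as.integer(n), continuous = cont, categorical = cat_)
}

# half-open bin membership [e_i, e_{i+1}), last bin closed above
bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  pmin.int(pmax.int(i, 1L), length(edges) - 1L)
}

#' cLHS objective function
#'
#' Three additive criteria: `O1` matches the sample to the equal-probability
#' strata of each continuous covariate (`sum |count_in_stratum - 1|`), `O2`
#' matches categorical class proportions (`sum |sample - population|`), and
#' `O3` matches the Pearson correlation matrix of the continuous covariates
#' (`sum` of absolute elementwise deviations over the upper triangle).
#'
#' A covariate that is constant within the sample has an undefined sample
#' correlation; its entries are treated as zero deviation and the covariate
#' is reported in the `constant` element.
#'
#' @param sample_table data.frame of covariate values for the sampled cells
#'   (same columns as the stack).
#' @param strata output of [build_strata()]; the sample size must equal
#'   `strata$n`.
#' @param pop_cor population Pearson correlation matrix of the continuous
#'   covariates (see [population_correlation()]).
#' @param weights numeric length 3, nonnegative, not all zero.
#' @return list `O1`, `O2`, `O3`, `total`, `constant` (names of sample-
#'   constant covariates, possibly empty).
#' @export
clhs_objective <- function(sample_table, strata, pop_cor,
                           weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3L, all(weights >= 0), any(weights > 0))
  if (nrow(sample_table) != strata$n)
    stop("sample size ", nrow(sample_table), " != strata n ", strata$n,
         call. = FALSE)
  o1 <- 0
  for (nm in names(strata$continuous)) {
    idx <- bin_index(sample_table[[nm]], strata$continuous[[nm]])
    cnt <- tabulate(idx, nbins = strata$n)
    o1 <- o1 + sum(abs(cnt - 1L))
  }
  o2 <- 0
  for (nm in names(strata$categorical)) {
    pop <- strata$categorical[[nm]]
    sm <- table(factor(as.character(sample_table[[nm]]), levels = names(pop)))
    o2 <- o2 + sum(abs(as.numeric(sm) / nrow(sample_table) - pop))
  }
  o3 <- 0
  constant <- character()
  cn <- names(strata$continuous)
  if (length(cn) >= 2L) {
    sub <- as.matrix(sample_table[cn])
    sds <- apply(sub, 2L, stats::sd)
    constant <- cn[sds == 0 | is.na(sds)]
    sc <- suppressWarnings(stats::cor(sub))
    dev <- abs(pop_cor[cn, cn] - sc)
    dev[is.na(dev)] <- 0  # constant-in-sample covariates: zero deviation
    o3 <- sum(dev[upper.tri(dev)])
  }
  list(O1 = o1, O2 = o2, O3 = o3,
       total = weights[1L] * o1 + weights[2L] * o2 + weights[3L] * o3,
       constant = constant)
}

#' Population correlation matrix of the continuous covariates
#' @param stack a [covariate_stack()].
#' @return Pearson correlation matrix over valid cells (1x1 identity-like
#'   matrix when fewer than two continuous covariates).
#' @export
population_correlation <- function(stack) {
  cn <- continuous_names(stack)
  if (length(cn) < 2L) {
    m <- diag(length(cn))
    dimnames(m) <- list(cn, cn)
    return(m)
  }
  stats::cor(as.matrix(cell_values(stack)[cn]))
}

#' Conditioned Latin hypercube sampling by simulated annealing
#'
#' Draws a random initial sample of `n` valid cells and anneals it toward
#' the cLHS objective: at each iteration one sampled cell is swapped for a
#' random unsampled cell -- with probability `swap_prob` a uniformly random
#' sampled cell, otherwise the cell contributing worst to the continuous
#' stratum criterion -- and the move is accepted by the Metropolis rule
#' `exp(-delta/T)`. Temperature starts at `temp_start` and is multiplied by
#' `cooling` every `chain_length` iterations. The best design seen is
#' returned, so more iterations never worsen the result for a fixed seed.
#'
#' @param stack a [covariate_stack()].
#' @param n sample size, `1 <= n <= r`.
#' @param iterations annealing iterations (default 10000).
#' @param weights objective weights `(w1, w2, w3)`.
#' @param temp_start,cooling,chain_length annealing schedule.
#' @param swap_prob probability of swapping a uniformly random sampled cell
#'   (vs the worst-stratum cell), in (0, 1].
#' @param seed integer seed; identical seeds give identical designs.
#' @return list of class `clhs_result`: `design` (a [sample_design()]),
#'   `objective` (the final [clhs_objective()] of the best design),
#'   `objective_trace` (accepted-state total per iteration),
#'   `initial_objective`, and `strata`.
#' @export
clhs <- function(stack, n, iterations = 10000L, weights = c(1, 1, 1),
                 temp_start = 1, cooling = 0.95, chain_length = 10L,
                 swap_prob = 0.5, seed = NULL) {
  if (n > stack$r)
    stop("infeasible: n = ", n, " exceeds the ", stack$r, " valid cells",
         call. = FALSE)
  stopifnot(n >= 1L, iterations >= 1L, swap_prob > 0, swap_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  cells <- valid_cells(stack)
  pop_tab <- cell_values(stack)
  strata <- build_strata(stack, n)
  pop_cor <- population_correlation(stack)
  cn <- names(strata$continuous)

  state <- sample.int(length(cells), n)   # positions into `cells`
  obj <- clhs_objective(pop_tab[state, , drop = FALSE], strata, pop_cor,
                        weights)
  initial <- obj
  best_state <- state
  best_obj <- obj
  trace <- numeric(iterations)

  in_sample <- logical(length(cells))
  in_sample[state] <- TRUE
  temp <- temp_start

  worst_point <- function(state) {
    # the sampled point sitting in the most over-full continuous strata
    load <- numeric(length(state))
    for (nm in cn) {
      idx <- bin_index(pop_tab[[nm]][state], strata$continuous[[nm]])
      cnt <- tabulate(idx, nbins = strata$n)
      load <- load + (cnt[idx] - 1L)
    }
    which.max(load)
  }

  for (it in seq_len(iterations)) {
    if (it > 1L && (it - 1L) %% chain_length == 0L) temp <- temp * cooling
    pos <- if (length(cn) && stats::runif(1) > swap_prob)
      worst_point(state) else sample.int(n, 1L)
    repl <- sample.int(length(cells), 1L)
    if (in_sample[repl]) { trace[it] <- obj$total; next }
    cand <- state
    cand[pos] <- repl
    cobj <- clhs_objective(pop_tab[cand, , drop = FALSE], strata, pop_cor,
                           weights)
    delta <- cobj$total - obj$total
    if (delta <= 0 || stats::runif(1) < exp(-delta / temp)) {
      in_sample[state[pos]] <- FALSE
      in_sample[repl] <- TRUE
      state <- cand
      obj <- cobj
      if (obj$total < best_obj$total) { best_obj <- obj; best_state <- state }
    }
    trace[it] <- obj$total
  }

  design <- sample_design(stack, cells[best_state], provenance = "clhs")
  structure(list(design = design, objective = best_obj,
                 objective_trace = trace, initial_objective = initial,
                 strata = strata, n = as.integer(n), seed = seed),
            class = "clhs_result")
}

#' @export
print.clhs_result <- function(x, ...) {
  cat("<clhs_result> n =", x$n, "\n")
  cat(sprintf("  objective: total %.4f (O1 %.3f, O2 %.4f, O3 %.4f)\n",
              x$objective$total, x$objective$O1, x$objective$O2,
              x$objective$O3))
  cat(sprintf("  initial objective: %.4f\n", x$initial_objective$total))
  invisible(x)
}
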