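#' Quantile matrix for the adapted-HELS algorithm
#'
#' Per continuous covariate, the `s + 1` empirical quantiles at
#' probabilities `0, 1/s, ..., 1` (linear interpolation, same convention as
#' [build_strata()]). Categorical covariates are excluded: the marginal
#' strata of aHELS are quantile-based. Duplicated edges (possible when `s`
#' exceeds the number of distinct values) yield zero-width strata, which
#' are flagged with a warning.
#'
#' @param stack a [covariate_stack()].
#' @param s number of strata per covariate (the sample budget), `>= 1`.
#' @return `(s + 1) x k` matrix; columns named by covariate, each column
#'   non-decreasing from the covariate minimum to its maximum.
#' @export
quantile_matrix <- function(stack, s) {
  stopifnot(s >= 1L)
  cn <- continuous_names(stack)
  if (length(cn) == 0L)
    stop("aHELS needs at least one continuous covariate", call. = FALSE)
  tab <- cell_values(stack)[cn]
  qm <- vapply(tab, stats::quantile,
               probs = seq(0, 1, length.out = s + 1L), names = FALSE,
               type = 7, FUN.VALUE = numeric(s + 1L))
  qm <- matrix(qm, nrow = s + 1L, dimnames = list(NULL, cn))
  if (any(apply(qm, 2L, anyDuplicated) > 0L))
    warning("zero-width strata: s exceeds distinct values in some covariate",
            call. = FALSE)
  qm
}

# s x k tally of values (data.frame, continuous columns of qm) into the
# half-open strata of the quantile matrix (last stratum closed)
strata_tally <- function(values, qm) {
  s <- nrow(qm) - 1L
  vapply(colnames(qm), function(nm)
    tabulate(bin_index(values[[nm]], qm[, nm]), nbins = s),
    FUN.VALUE = numeric(s))
}

#' Grid and legacy data densities over the aHELS strata
#'
#' For each stratum of each covariate: the grid density is the pixel tally
#' divided by `r`, the data density the legacy tally divided by `o`, and
#' the ratio is data density / grid density (0/0 reported as 0 and flagged
#' in the `empty` element). Ratios below 1 mark under-sampled strata.
#'
#' @param stack a [covariate_stack()].
#' @param legacy a non-empty [sample_design()] of existing sites extracted
#'   from the same stack.
#' @param qm a [quantile_matrix()].
#' @return list of class `ahels_densities`: `grid_density`, `data_density`,
#'   `ratio` (all `s x k`), `o`, `r`, `empty` (logical matrix of 0/0
#'   strata).
#' @export
ahels_densities <- function(stack, legacy, qm) {
  if (is.null(legacy) || nrow(legacy) == 0L)
    stop("legacy design is empty", call. = FALSE)
  off <- which(!stack$mask[legacy$cell])
  if (length(off))
    stop("legacy point(s) off the valid mask: ",
         paste(off, collapse = ", "), call. = FALSE)
  pop <- cell_values(stack)
  o <- nrow(legacy)
  grid_t <- strata_tally(pop, qm)
  data_t <- strata_tally(design_values(legacy), qm)
  grid_d <- grid_t / stack$r
  data_d <- data_t / o
  ratio <- data_d / grid_d
  empty <- grid_t == 0 & data_t == 0
  ratio[grid_d == 0] <- 0      # 0/0 -> 0, flagged via `empty`
  structure(list(grid_density = grid_d, data_density = data_d,
                 ratio = ratio, o = o, r = stack$r, empty = empty),
            class = "ahels_densities")
}

#' Allocate additional sites to under-sampled strata (adapted HELS)
#'
#' Ranks the `s x k` density ratios from smallest (most under-sampled) to
#' largest -- ties broken deterministically by (covariate column, stratum
#' row) -- and walks the ranking, drawing for each stratum
#' `m = max(1, ceiling(o * grid_density - data_tally))` cells uniformly at
#' random (seeded) from the unselected valid cells whose covariate value
#' lies in that stratum, capped at the remaining budget and at the cells
#' available. Newly drawn sites are tallied into every covariate's strata
#' before the next ranking entry is consumed, so parity is not overshot.
#' The walk repeats over the ranking until the budget `s` is spent; if no
#' progress is possible a partial design is returned with a warning.
#'
#' @param stack a [covariate_stack()].
#' @param legacy a non-empty [sample_design()] of existing sites.
#' @param s number of additional sites wanted.
#' @param seed integer seed for the random draws.
#' @param m_rule `"subtract"` (default: required count minus the sites the
#'   stratum already holds) or `"literal"` (`o * grid_density` regardless
#'   of current occupancy).
#' @return a [sample_design()] with provenance `"ahels"` and exactly `s`
#'   rows (fewer only in the warned partial case); the triggering stratum
#'   of each site is recorded in the `stratum` column
#'   (`"<covariate>[q<row>]"`).
#' @export
ahels_allocate <- function(stack, legacy, s, seed = NULL,
                           m_rule = c("subtract", "literal")) {
  m_rule <- match.arg(m_rule)
  stopifnot(s >= 1L)
  if (!is.null(seed)) set.seed(seed)
  qm <- quantile_matrix(stack, s)
  dens <- ahels_densities(stack, legacy, qm)
  o <- dens$o
  k <- ncol(qm)
  ns <- nrow(qm) - 1L
  cells <- valid_cells(stack)
  pop <- cell_values(stack)[colnames(qm)]
  # per-covariate stratum membership of every valid cell
  memb <- vapply(colnames(qm), function(nm) bin_index(pop[[nm]], qm[, nm]),
                 FUN.VALUE = integer(stack$r))
  # column-major order of the ratio matrix == (covariate, stratum) tie-break
  ranking <- order(as.vector(dens$ratio))
  data_tally <- dens$data_density * o   # running tallies incl. new sites
  taken <- logical(stack$r)
  taken[match(legacy$cell, cells)] <- TRUE  # legacy cells are not re-drawn
  sel <- integer(0)
  sel_stratum <- character(0)
  remaining <- s
  repeat {
    progress <- FALSE
    for (el in ranking) {
      if (remaining == 0L) break
      i <- ((el - 1L) %% ns) + 1L     # stratum row
      j <- ((el - 1L) %/% ns) + 1L    # covariate column
      need <- if (m_rule == "subtract")
        ceiling(o * dens$grid_density[i, j] - data_tally[i, j])
      else
        ceiling(o * dens$grid_density[i, j])
      m <- min(max(1L, need), remaining)
      elig <- which(memb[, j] == i & !taken)
      if (length(elig) == 0L) next
      m <- min(m, length(elig))
      pick <- if (length(elig) == 1L) elig else sample(elig, m)
      pick <- pick[seq_len(m)]
      taken[pick] <- TRUE
      sel <- c(sel, pick)
      sel_stratum <- c(sel_stratum,
                       rep(sprintf("%s[q%d]", colnames(qm)[j], i), m))
      remaining <- remaining - m
      progress <- TRUE
      # re-tally the new sites into every covariate's strata
      for (jj in seq_len(k)) {
        tt <- tabulate(memb[pick, jj], nbins = ns)
        data_tally[, jj] <- data_tally[, jj] + tt
      }
      if (remaining == 0L) break
    }
    if (remaining == 0L || !progress) break
  }
  if (remaining > 0L)
    warning("budget unfillable: only ", s - remaining, " of ", s,
            " sites allocated", call. = FALSE)
  design <- sample_design(stack, cells[sel], provenance = "ahels")
  design$stratum <- sel_stratum
  design
}
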