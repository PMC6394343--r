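# Independent oracle implementations: naive loops, no shared code paths
# with the package internals they check.

# literal term-by-term evaluation of the KL sum
oracle_kl <- function(O, E) {
  s <- 0
  for (i in seq_along(O)) {
    if (O[i] > 0) s <- s + O[i] * (log(O[i]) - log(E[i]))
  }
  s
}

# naive cLHS objective: per-stratum counts by explicit loops
oracle_objective <- function(sample_table, strata, pop_cor,
                             weights = c(1, 1, 1)) {
  o1 <- 0
  for (nm in names(strata$continuous)) {
    e <- strata$continuous[[nm]]
    n <- length(e) - 1L
    for (j in seq_len(n)) {
      lo <- e[j]; hi <- e[j + 1L]
      v <- sample_table[[nm]]
      inb <- if (j == n) v >= lo & v <= hi else v >= lo & v < hi
      # half-open convention with clamping of below-range values into bin 1
      if (j == 1L) inb <- inb | v < lo
      o1 <- o1 + abs(sum(inb) - 1L)
    }
  }
  o2 <- 0
  for (nm in names(strata$categorical)) {
    pop <- strata$categorical[[nm]]
    for (cl in names(pop)) {
      p <- mean(as.character(sample_table[[nm]]) == cl)
      o2 <- o2 + abs(p - pop[[cl]])
    }
  }
  o3 <- 0
  cn <- names(strata$continuous)
  if (length(cn) >= 2L) {
    sc <- suppressWarnings(stats::cor(as.matrix(sample_table[cn])))
    for (a in seq_along(cn)) for (b in seq_along(cn)) {
      if (a < b) {
        d <- abs(pop_cor[cn[a], cn[b]] - sc[a, b])
        if (is.na(d)) d <- 0
        o3 <- o3 + d
      }
    }
  }
  weights[1] * o1 + weights[2] * o2 + weights[3] * o3
}

# brute-force COOBS: double loop over pixels and legacy points, squared
# Mahalanobis distances via solve() per pair
oracle_coobs <- function(stack, legacy, threshold) {
  cn <- names(stack$kinds)[stack$kinds == "continuous"]
  X <- as.matrix(cell_values(stack)[cn])
  L <- as.matrix(design_values(legacy)[cn])
  si <- solve(stats::cov(X))
  r <- nrow(X)
  d2 <- function(a, b) { v <- a - b; drop(t(v) %*% si %*% v) }
  counts <- integer(r)
  for (i in seq_len(r)) {
    magpd <- 0
    for (j in seq_len(r)) magpd <- max(magpd, d2(X[i, ], X[j, ]))
    if (magpd == 0) {
      for (j in seq_len(nrow(L))) if (d2(X[i, ], L[j, ]) == 0)
        counts[i] <- counts[i] + 1L
    } else {
      for (j in seq_len(nrow(L))) {
        sdd <- 1 - d2(X[i, ], L[j, ]) / magpd
        if (sdd >= threshold) counts[i] <- counts[i] + 1L
      }
    }
  }
  counts
}

# small helper: stack from plain matrices
tiny_stack <- function(..., kinds = "continuous", cellsize = 1) {
  layers <- list(...)
  if (is.null(names(layers)))
    names(layers) <- paste0("v", seq_along(layers))
  covariate_stack(layers, kinds = kinds, cellsize = cellsize)
}

# deterministic 1-layer stack whose values are 1..n laid on a grid
seq_stack <- function(nr, nc, cellsize = 1) {
  tiny_stack(a = matrix(seq_len(nr * nc), nr, nc), cellsize = cellsize)
}

# random proportion vector of length n (positive, sums to 1)
rand_props <- function(n, zeros = 0L) {
  p <- stats::rexp(n) + 1e-4
  if (zeros > 0L) p[sample.int(n, zeros)] <- 0
  p / sum(p)
}
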