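test_that("quantile_matrix matches the quantile oracle and edge shapes", {
  st <- seq_stack(10, 10)  # 1..100
  qm <- quantile_matrix(st, 4)
  expect_equal(dim(qm), c(5L, 1L))
  expect_equal(qm[, "a"], unname(quantile(1:100, seq(0, 1, 0.25))))
  qm1 <- quantile_matrix(st, 1)
  expect_equal(qm1[, "a"], c(1, 100))
  st2 <- tiny_stack(a = matrix(rnorm(64), 8), b = matrix(rnorm(64), 8))
  expect_equal(ncol(quantile_matrix(st2, 3)), 2L)
  # repeated values force duplicate edges
  st3 <- tiny_stack(a = matrix(rep(1:2, 8), 4))
  expect_warning(quantile_matrix(st3, 6), "zero-width")
})

test_that("densities reproduce a hand-tallied toy example", {
  # 20 cells valued 1..20; legacy at cells 1, 2, 3, 11; s = 2 strata
  st <- seq_stack(4, 5)
  legacy <- sample_design(st, c(1L, 2L, 3L, 11L), "legacy")
  qm <- quantile_matrix(st, 2)
  d <- ahels_densities(st, legacy, qm)
  # strata split at the median 10.5: cells 1..10 | 11..20
  expect_equal(unname(d$grid_density[, "a"]), c(0.5, 0.5))
  expect_equal(unname(d$data_density[, "a"]), c(0.75, 0.25))
  expect_equal(unname(d$ratio[, "a"]), c(1.5, 0.5))
  expect_equal(d$o, 4L)
  expect_equal(colSums(d$grid_density), c(a = 1))
  expect_equal(colSums(d$data_density), c(a = 1))
})

test_that("proportional legacy data gives ratios near 1, gaps give 0", {
  st <- make_landscape(nrow = 20, ncol = 20, n_continuous = 2, range = 2,
                       seed = 44)
  big <- make_legacy(st, 350, bias = "none", seed = 1)
  qm <- quantile_matrix(st, 4)
  d <- ahels_densities(st, big, qm)
  expect_true(all(abs(d$ratio - 1) < 0.35))
  # a stratum with no legacy points has ratio 0
  low <- design_values(big)$cov1 <= qm[2, "cov1"]
  half <- big[low, ]
  d2 <- ahels_densities(st, half, qm)
  expect_equal(unname(d2$ratio[3:4, "cov1"]), c(0, 0))
  # off-mask legacy points are rejected upstream by sample_design
  expect_error(sample_design(st, c(valid_cells(st)[1], -5L)), "off the valid")
})

test_that("allocation conserves the budget without duplicates", {
  st <- make_landscape(nrow = 20, ncol = 20, n_continuous = 2, range = 3,
                       seed = 12)
  legacy <- make_legacy(st, 40, bias = "covariate_low_tail", seed = 5)
  al <- ahels_allocate(st, legacy, s = 25, seed = 7)
  expect_equal(nrow(al), 25L)
  expect_equal(anyDuplicated(al$cell), 0L)
  expect_false(any(al$cell %in% legacy$cell))
  expect_true(all(al$provenance == "ahels"))
  expect_match(al$stratum, "^cov[12]\\[q[0-9]+\\]$")
  # every returned site's covariate value lies in its triggering stratum
  qm <- quantile_matrix(st, 25)
  parts <- strsplit(al$stratum, "[", fixed = TRUE)
  nm <- vapply(parts, `[`, "", 1)
  rw <- as.integer(gsub("[^0-9]", "", vapply(parts, `[`, "", 2)))
  v <- vapply(seq_len(25), function(i) al[[nm[i]]][i], numeric(1))
  expect_true(all(v >= qm[cbind(rw, match(nm, colnames(qm)))] - 1e-12))
  expect_true(all(v <= qm[cbind(rw + 1L, match(nm, colnames(qm)))] + 1e-12))
  # same seed, same allocation
  al2 <- ahels_allocate(st, legacy, s = 25, seed = 7)
  expect_identical(al$cell, al2$cell)
})

test_that("allocation targets under-sampled strata and lifts the worst ratio", {
  st <- make_landscape(nrow = 25, ncol = 25, n_continuous = 2, range = 3,
                       seed = 18)
  legacy <- make_legacy(st, 60, bias = "covariate_low_tail", seed = 4)
  s <- 40
  qm <- quantile_matrix(st, s)
  before <- ahels_densities(st, legacy, qm)
  al <- ahels_allocate(st, legacy, s = s, seed = 11)
  combined <- sample_design(st, c(legacy$cell, al$cell), "legacy")
  after <- ahels_densities(st, combined, qm)
  expect_gte(min(after$ratio), min(before$ratio))
  # the upper strata of the biased covariate receive most of the new sites
  upper <- design_values(al)$cov1 > stats::median(cell_values(st)$cov1)
  expect_gte(mean(upper), 0.6)
})

test_that("the literal m rule is exposed and allocates the full budget too", {
  st <- make_landscape(nrow = 15, ncol = 15, n_continuous = 2, range = 2,
                       seed = 27)
  legacy <- make_legacy(st, 30, bias = "spatial_corner", seed = 2)
  al <- ahels_allocate(st, legacy, s = 20, seed = 3, m_rule = "literal")
  expect_equal(nrow(al), 20L)
})
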