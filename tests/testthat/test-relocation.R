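test_that("mahalanobis_distance matches hand-evaluated cases", {
  expect_equal(mahalanobis_distance(rbind(c(3, 4)), c(0, 0), diag(2)), 5)
  expect_equal(mahalanobis_distance(rbind(c(2, 1)), c(0, 0),
                                    diag(c(4, 1))), sqrt(2))
  expect_equal(mahalanobis_distance(rbind(c(1.3, -2)), c(1.3, -2),
                                    diag(2)), 0)
  # with a single covariate it reduces to |x - s| / sigma
  sd1 <- 2.5
  expect_equal(mahalanobis_distance(rbind(7), 2, matrix(sd1^2)),
               abs(7 - 2) / sd1)
})

test_that("similarity is the anchored decreasing sigmoid", {
  expect_equal(similarity(4, 4), 0.5)
  expect_equal(similarity(4 - 3.6636, 4), 0.975, tolerance = 1e-4)
  expect_equal(similarity(1e6, 4), 0)
  d <- seq(0, 10, 0.25)
  expect_true(all(diff(similarity(d, 5)) < 0))
  expect_true(all(similarity(d, 5) > 0 & similarity(d, 5) < 1))
  # closed-form qualifier set: S(d) >= t iff d <= d_med + log(1/t - 1)/slope
  for (t in c(0.6, 0.9, 0.975)) {
    cut <- 5 + log(1 / t - 1)
    expect_equal(similarity(d, 5) >= t, d <= cut + 1e-12)
  }
})

test_that("candidate_zone buffers, masks categories and can be empty", {
  st <- make_landscape(nrow = 10, ncol = 10, n_continuous = 2, range = 2,
                       cellsize = 1, seed = 2)
  site <- valid_cells(st)[45]
  # radius covering the whole raster, no categorical layers
  z <- candidate_zone(st, site, radius = 100)
  expect_setequal(z, setdiff(valid_cells(st), site))
  # a sub-cell radius leaves nothing
  expect_error(candidate_zone(st, site, radius = 0.4),
               class = "hypersample_empty_zone")
  # categorical masking keeps only the site's class
  stc <- make_landscape(nrow = 12, ncol = 12, n_continuous = 2,
                        n_categorical = 1, range = 3, cellsize = 1, seed = 6)
  site2 <- valid_cells(stc)[60]
  z2 <- candidate_zone(stc, site2, radius = 100)
  expect_true(all(stc$layers$cat1[z2] == stc$layers$cat1[site2]))
  expect_lt(length(z2), stc$r - 1L)
})

test_that("relocate honours the threshold, the seed and the strategies", {
  st <- make_landscape(nrow = 30, ncol = 30, n_continuous = 4, range = 2,
                       cellsize = 25, seed = 14)
  site <- clhs(st, n = 10, iterations = 300, seed = 3)$design$cell[1]
  r1 <- relocate(st, site, radius = 500, threshold = 0.9, seed = 77)
  expect_true(all(r1$surface$similarity[match(r1$qualifiers,
                                              r1$surface$cell)] >= 0.9))
  expect_true(r1$site %in% r1$qualifiers)
  expect_false(r1$site == site)
  r2 <- relocate(st, site, radius = 500, threshold = 0.9, seed = 77)
  expect_identical(r1$site, r2$site)
  # ranked returns the smallest-distance qualifier first
  rr <- relocate(st, site, radius = 500, threshold = 0.9,
                 strategy = "ranked")
  dq <- r1$surface$dist[match(rr$qualifiers, r1$surface$cell)]
  expect_true(all(diff(dq) >= 0))
  expect_equal(rr$site, rr$qualifiers[1])
  # nearest picks the geographically closest qualifier
  rn <- relocate(st, site, radius = 500, threshold = 0.9,
                 strategy = "nearest")
  sxy <- cell_xy(st, site)
  qxy <- cell_xy(st, r1$qualifiers)
  d2 <- (qxy$x - sxy$x)^2 + (qxy$y - sxy$y)^2
  nxy <- cell_xy(st, rn$site)
  expect_equal((nxy$x - sxy$x)^2 + (nxy$y - sxy$y)^2, min(d2))
  # an absurd threshold finds no qualifier and reports the best similarity
  expect_error(relocate(st, site, radius = 500, threshold = 0.999999),
               class = "hypersample_no_qualifier")
  # grow doubles the radius instead of failing on an empty zone
  rg <- relocate(st, site, radius = 20, threshold = 0.9, grow = TRUE,
                 grow_cap = 16, seed = 1)
  expect_gt(rg$radius, 20)
})

test_that("similarity surface anchors 0.5 at the median distance", {
  st <- make_landscape(nrow = 20, ncol = 20, n_continuous = 3, range = 2,
                       cellsize = 25, seed = 31)
  site <- valid_cells(st)[200]
  r <- relocate(st, site, radius = 400, threshold = 0.6, seed = 5)
  expect_equal(stats::median(r$surface$dist), r$dist_med)
  expect_equal(similarity(r$dist_med, r$dist_med), 0.5)
})

test_that("evaluate_relocation reports per-covariate rows plus a mean row", {
  st <- make_landscape(nrow = 15, ncol = 15, n_continuous = 3, range = 2,
                       seed = 9)
  d <- clhs(st, n = 12, iterations = 200, seed = 2)$design
  ev <- evaluate_relocation(st, d, d)
  expect_equal(ev$covariate, c(names(st$layers), "Mean"))
  expect_equal(ev$delta, rep(0, 4))
  expect_equal(ev$kl_original[4], mean(ev$kl_original[1:3]))
  expect_error(evaluate_relocation(st, d, d[1:5, ]), "size")
})
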