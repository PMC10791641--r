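# NCP labeling, duplicate averaging, summer medians, normalization, z-scoring,
# training-table construction and transition summaries.

test_that("classify_ncp implements the quadrant rule with >= as the high side", {
  expect_identical(classify_ncp(10, 5), "oligotrophic")
  expect_identical(classify_ncp(50, 5), "eutrophic")
  expect_identical(classify_ncp(10, 50), "dystrophic")
  expect_identical(classify_ncp(50, 50), "mixotrophic")
  # boundary values count as high on both axes
  expect_identical(classify_ncp(30, 20), "mixotrophic")
  expect_identical(classify_ncp(30, 5), "eutrophic")
  expect_identical(classify_ncp(10, 20), "dystrophic")
  expect_error(classify_ncp(-1, 5), "nonnegative")
  expect_error(classify_ncp(NA_real_, 5), "finite")
})

test_that("classify_ncp equals a brute-force quadrant lookup on a dense grid", {
  grid <- expand.grid(tp = seq(0, 100, length.out = 101),
                      color = seq(0, 100, length.out = 101))
  got <- classify_ncp(grid$tp, grid$color)
  lookup <- matrix(c("oligotrophic", "dystrophic", "eutrophic", "mixotrophic"),
                   2, 2, byrow = TRUE)   # rows: tp low/high, cols: color low/high
  expected <- lookup[cbind(1L + (grid$tp >= 30), 1L + (grid$color >= 20))]
  expect_identical(got, expected)
})

test_that("merge_eumixo collapses the two productive quadrants only", {
  expect_identical(merge_eumixo(c("eutrophic", "mixotrophic", "oligotrophic",
                                  "dystrophic")),
                   c("eu/mixo", "eu/mixo", "oligo", "dys"))
  expect_error(merge_eumixo("blue"), "unknown")
})

test_that("average_duplicates takes unweighted means and the earliest date", {
  ins <- data.frame(lake_id = c(1L, 1L, 2L, 3L, 3L, 3L),
                    date = as.Date(c("2007-07-10", "2007-06-02", "2007-06-15",
                                     "2007-06-01", "2007-07-01", "2007-08-01")),
                    tp_ugL = c(20, 40, 10, 5, 5, 5),
                    color_pcu = c(4, 6, 8, 10, 30, 50))
  out <- average_duplicates(ins)
  expect_identical(nrow(out), 3L)
  expect_equal(out$tp_ugL[out$lake_id == 1], 30)
  expect_equal(out$color_pcu[out$lake_id == 3], 30)
  expect_identical(out$date[out$lake_id == 1], as.Date("2007-06-02"))
  expect_equal(out[out$lake_id == 2, c("tp_ugL", "color_pcu")],
               data.frame(tp_ugL = 10, color_pcu = 8), ignore_attr = TRUE)
  expect_error(average_duplicates(ins[0, ]), "empty")
})

test_that("summer medians use June-August only and the even-count convention", {
  ov <- data.frame(lake_id = 1L,
                   date = as.Date(c("2007-06-10", "2007-07-10", "2007-08-10",
                                    "2007-05-10")),
                   red = c(0.1, 0.2, 0.3, 0.9), green = c(1, 1, 1, 9),
                   blue = c(2, 2, 2, 9), nir = c(3, 3, 3, 9))
  s <- summer_median_spectrum(ov)
  expect_equal(unname(s$medians["red"]), 0.2)
  expect_identical(s$n_images, 3L)
  # even count: mean of the middle pair
  s2 <- summer_median_spectrum(ov[c(1, 2), ])
  expect_equal(unname(s2$medians["red"]), 0.15)
  # all off-summer: no output
  expect_null(summer_median_spectrum(ov[4, , drop = FALSE]))
  # order invariance and insensitivity to non-summer rows
  s3 <- summer_median_spectrum(ov[c(4, 3, 1, 2), ])
  expect_equal(s3, s)
})

test_that("relative_normalize emits unit-sum vectors and rejects degenerate input", {
  expect_equal(unname(relative_normalize(c(0.1, 0.1, 0.1, 0.1))),
               rep(0.25, 4))
  expect_equal(unname(relative_normalize(c(0.02, 0.03, 0.04, 0.01))),
               c(0.2, 0.3, 0.4, 0.1))
  expect_error(relative_normalize(c(0, 0, 0, 0)), "degenerate")
  expect_error(relative_normalize(c(1, 2, 3)), "length 4")
})

test_that("aggregate_overpasses matches the one-lake-year operation and shrinks with summer", {
  sim <- small_sim()
  feat <- aggregate_overpasses(sim$overpasses)
  expect_true(all(abs(rowSums(feat[, paste0("rel_", c("red", "green", "blue",
                                                      "nir"))]) - 1) < 1e-9))
  expect_true(all(feat$n_images >= 1))
  # spot-check three lake-years against the scalar operation
  for (i in c(1L, 10L, nrow(feat))) {
    sub <- sim$overpasses[sim$overpasses$lake_id == feat$lake_id[i] &
                            format(as.Date(sim$overpasses$date), "%Y") ==
                              feat$year[i], ]
    s <- summer_median_spectrum(sub)
    expect_identical(feat$n_images[i], s$n_images)
    expect_equal(as.numeric(feat[i, paste0("rel_", c("red", "green", "blue", "nir"))]),
                 unname(relative_normalize(s$medians)), tolerance = 1e-12)
  }
  # monotonicity: a narrower summer never increases n_images
  feat_jul <- aggregate_overpasses(sim$overpasses, summer_months = 7L)
  m <- merge(feat, feat_jul, by = c("lake_id", "year"))
  expect_true(all(m$n_images.y <= m$n_images.x))
  expect_true(nrow(feat_jul) <= nrow(feat))
})

test_that("z-scoring reproduces fit-time statistics and flags zero variance", {
  tab <- data.frame(rel_red = c(0.2, 0.3, 0.4), rel_green = c(0.1, 0.2, 0.3),
                    rel_blue = c(0.3, 0.2, 0.1), rel_nir = c(0.4, 0.3, 0.2))
  sc <- zscore_fit(tab)
  z <- zscore_apply(sc, tab)
  expect_equal(z$z_red, c(-1, 0, 1))
  # applying to a new value equal to the fit mean gives 0
  new <- tab[1, ]; new[1, ] <- as.list(sc$mean)
  expect_equal(as.numeric(zscore_apply(sc, new)[paste0("z_", c("red", "green",
                                                               "blue", "nir"))]),
               rep(0, 4))
  tab$rel_red <- 0.5
  expect_error(zscore_fit(tab), "rel_red")
  expect_error(zscore_fit(tab[1, ]), "2 rows")
})

test_that("the training table joins, filters, labels and standardizes correctly", {
  sim <- small_sim()
  feat <- aggregate_overpasses(sim$overpasses)
  tab <- build_training_table(sim$insitu, feat, lakes = sim$lakes)
  zc <- paste0("z_", c("red", "green", "blue", "nir"))
  expect_true(all(abs(colMeans(tab[, zc])) < 1e-9))
  expect_true(all(abs(apply(tab[, zc], 2, sd) - 1) < 1e-9))
  expect_s3_class(tab$trophic_state, "factor")
  expect_identical(levels(tab$trophic_state), lts_classes())
  # area filter: all training lakes are at least 10 ha
  small <- sim$lakes$lake_id[sim$lakes$area_km2 < 0.1]
  expect_false(any(tab$lake_id %in% small))
  dropped <- attr(tab, "dropped")
  avg <- average_duplicates(sim$insitu)
  expect_identical(unname(dropped["small_lake"]), sum(avg$lake_id %in% small))
  # inner-join count: labeled lake-campaigns without features are dropped
  expect_true(nrow(tab) <= nrow(feat))
  # duplicate feature keys are an error
  expect_error(build_training_table(sim$insitu, rbind(feat, feat[1, ])),
               "duplicate")
  # disjoint keys are an empty join
  feat2 <- feat; feat2$lake_id <- feat2$lake_id + 10000L
  expect_error(build_training_table(sim$insitu, feat2), "empty join")
})

test_that("transition_summary reproduces a hand-enumerated example", {
  # 4 duplicated lakes: 3 stable, 1 oligo -> eu/mixo
  ins <- data.frame(
    lake_id = rep(1:4, each = 2),
    date = rep(as.Date(c("2007-06-10", "2007-08-10")), 4),
    tp_ugL = c(10, 10, 50, 55, 10, 10, 10, 60),
    color_pcu = c(5, 6, 5, 5, 50, 55, 5, 5))
  tr <- transition_summary(ins)
  expect_identical(tr$n_multi, 4L)
  expect_equal(tr$frac_stable, 0.75)
  chg <- tr$paths[tr$paths$count > 0, ]
  expect_identical(nrow(chg), 1L)
  expect_identical(chg$from, "oligo")
  expect_identical(chg$to, "eu/mixo")
  expect_equal(chg$frac_of_changing, 1)
  expect_equal(chg$frac_of_all, 0.25)
  # all-stable input: identity matrix structure
  ins2 <- ins; ins2$tp_ugL <- 10; ins2$color_pcu <- 5
  tr2 <- transition_summary(ins2)
  expect_equal(tr2$frac_stable, 1)
  expect_true(all(tr2$transition_matrix[upper.tri(tr2$transition_matrix)] == 0))
  expect_true(all(tr2$transition_matrix[lower.tri(tr2$transition_matrix)] == 0))
})
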