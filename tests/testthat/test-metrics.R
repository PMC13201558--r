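test_that("segment thirds partition the extent with the documented boundaries", {
  s <- segment_stats(1:9, positions = 1:9, extent = 9)
  expect_equal(s$segment, c("proximal", "middle", "distal"))
  expect_equal(s$mean, c(2, 5, 8))
  expect_equal(s$n, c(3L, 3L, 3L))
  # extent 30 -> boundaries at 10 and 20, right-closed
  s30 <- segment_stats(rep(1, 5), positions = c(5, 10, 10.001, 20, 25), extent = 30)
  expect_equal(s30$n, c(2L, 2L, 1L))
  # constant values: mean reproduced, sd zero
  sc <- segment_stats(rep(0.1, 9), positions = 1:9, extent = 9)
  expect_equal(sc$mean, rep(0.1, 3))
  expect_equal(sc$sd, rep(0, 3))
})

test_that("MAPE matches hand computations and scaling identities", {
  expect_equal(as.numeric(mape(c(1, 2, 3), c(2, 2, 2))), 100 * mean(c(0.5, 0, 0.5)))
  expect_equal(as.numeric(mape(c(1, 2, 3), c(1, 2, 3))), 0)
  ref <- c(1.2, 3.4, 0.7, 2.2)
  expect_equal(as.numeric(mape(1.1 * ref, ref)), 10, tolerance = 1e-10)
  # common positive rescaling leaves MAPE unchanged
  expect_equal(as.numeric(mape(3 * 1.1 * ref, 3 * ref)), 10, tolerance = 1e-10)
  # near-zero references are excluded and counted
  m <- mape(c(1, 1, 1), c(1, 1, 1e-9))
  expect_equal(attr(m, "n_excluded"), 1L)
})

test_that("Spearman correlation matches hand values and monotone invariance", {
  expect_equal(as.numeric(spearman_rho(1:5, c(1, 3, 2, 5, 4))), 0.8)
  expect_equal(as.numeric(spearman_rho(1:6, (1:6)^3)), 1)
  expect_equal(as.numeric(spearman_rho(1:6, -(1:6))), -1)
  a <- c(0.3, 1.2, 0.8, 2.0, 1.6)
  expect_equal(as.numeric(spearman_rho(a, exp(a))), 1)
  expect_error(spearman_rho(1:5, rep(1, 5)), "zero-variance")
})

test_that("spatial variance matches hand computation and quadratic scaling", {
  expect_equal(spatial_variance(c(0.1, 0.2, 0.3)), 0.01)
  v <- c(0.05, 0.11, 0.08, 0.21)
  expect_equal(spatial_variance(2 * v), 4 * spatial_variance(v))
  expect_equal(spatial_variance(rep(0.3, 5)), 0)
  expect_error(spatial_variance(0.1), "at least 2")
})

test_that("Welch group test returns t = 0, p = 1 for identical groups", {
  r <- group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  r2 <- group_test(c(0.08, 0.081, 0.079), c(0.13, 0.131, 0.133))
  expect_lt(r2$p_value, 0.01)
})

test_that("map comparison is exact for self-comparison and asymmetric in its inputs", {
  pos <- seq(0.5, 8.5, by = 0.5)
  val <- 0.05 + 0.01 * sin(pos)
  rep1 <- compare_maps(pos, val, pos, val, extent = 9)
  expect_equal(rep1$mape_pct, 0)
  expect_equal(rep1$spearman, 1)
  expect_equal(rep1$segments$pct_diff, rep(0, 3))
  expect_equal(rep1$p_value, 1)
  # asymmetry: MAPE normalizes by the reference
  a <- compare_maps(pos, 1.2 * val, pos, val, extent = 9)$mape_pct
  b <- compare_maps(pos, val, pos, 1.2 * val, extent = 9)$mape_pct
  expect_gt(a, b)
})

test_that("nearest-neighbor resampling from a finer grid keeps MAPE below 1%", {
  fine <- seq(0, 9, by = 0.05)
  coarse <- seq(0.2, 8.8, by = 0.4)
  f <- function(p) 0.08 + 0.02 * sin(p / 2)
  rep1 <- compare_maps(coarse, f(coarse), fine, f(fine), extent = 9)
  expect_lt(rep1$mape_pct, 1)
})

test_that("rigid offset search recovers a known axial shift", {
  pos <- seq(0, 9, by = 0.05)
  f <- function(p) 0.08 + 0.03 * sin(p)
  off <- align_offset(pos, f(pos), pos + 0.25, f(pos), search = 0.5, step = 0.05)
  expect_equal(off, -0.25, tolerance = 1e-9)
})

test_that("comparison reports round-trip to JSON and CSV", {
  pos <- seq(0.5, 8.5, by = 0.5)
  val <- 0.05 + 0.01 * sin(pos)
  rep1 <- compare_maps(pos, 1.05 * val, pos, val, extent = 9)
  path <- file.path(tempdir(), "report_test.json")
  write_report(rep1, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$mape_pct, rep1$mape_pct, tolerance = 1e-12)
  expect_named(j$segments, c("proximal", "middle", "distal"))
  segs <- utils::read.csv(sub("json$", "csv", path))
  expect_equal(segs$mean_pred, rep1$segments$mean_pred, tolerance = 1e-12)
})
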