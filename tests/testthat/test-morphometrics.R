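# Quadratic-surface morphometry and six-type terrain classification.

grid_from <- function(f, n = 15, cell = 2) {
  # heights z(x, y) on an n x n grid, x east, y north, row 1 = north
  h <- (n - 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) f((j - h - 1) * cell, (h + 1 - i) * cell))
}

test_that("local quadratic fit reproduces analytic surfaces", {
  plane <- grid_from(function(x, y) 0.1 * x + 3, n = 5)
  fit <- fit_local_quadratic(plane, cell_size = 2)
  expect_equal(unname(fit$coef), c(0, 0, 0, 0.1, 0, 3), tolerance = 1e-9)
  expect_equal(fit$rmse, 0, tolerance = 1e-9)

  bowl <- grid_from(function(x, y) x^2 + y^2, n = 5)
  fit <- fit_local_quadratic(bowl, cell_size = 2)
  expect_equal(unname(fit$coef[1:2]), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(fit$coef[3:5]), c(0, 0, 0), tolerance = 1e-9)

  # noisy plane: coefficients match explicit normal equations
  set.seed(5)
  w <- 5; cellsz <- 2
  z <- grid_from(function(x, y) 0.3 * x - 0.2 * y + 1, n = w) +
    matrix(rnorm(w * w, 0, 0.1), w)
  fit <- fit_local_quadratic(z, cell_size = cellsz)
  hh <- (w - 1) / 2
  jj <- rep(seq_len(w), each = w); ii <- rep(seq_len(w), times = w)
  x <- (jj - hh - 1) * cellsz; y <- (hh + 1 - ii) * cellsz
  X <- cbind(x^2, y^2, x * y, x, y, 1)
  beta <- solve(t(X) %*% X, t(X) %*% as.vector(z))
  expect_equal(unname(fit$coef), as.numeric(beta), tolerance = 1e-9)

  z[2, 2] <- NA
  expect_null(fit_local_quadratic(z))
})

test_that("morphometric stack has 12 layers with correct analytic anchors", {
  ms <- morpho_stack(matrix(5, 10, 10), is_depth = TRUE)
  expect_length(ms$layers, 12)
  expect_equal(names(ms$layers), morpho_layer_names())
  expect_lt(max(ms$layers$slope), 1e-9)
  expect_true(all(ms$layers$abs_roughness == 0))
  expect_lt(max(ms$layers$local_roughness), 1e-9)
  expect_true(all(ms$layers$rmse < 1e-12))
  expect_true(all(is.na(ms$layers$aspect)))

  # depth plane dipping due east at 10% grade: downslope aspect 90 degrees
  n <- 11
  depth <- outer(seq_len(n), seq_len(n), function(i, j) 5 + 0.1 * (j * 2))
  ms <- morpho_stack(depth, is_depth = TRUE)
  inner <- 2:(n - 1)
  expect_equal(max(abs(ms$layers$slope[inner, inner] -
                         atan(0.1) * 180 / pi)), 0, tolerance = 1e-9)
  expect_equal(max(abs(ms$layers$aspect[inner, inner] - 90)), 0,
               tolerance = 1e-9)
  expect_true(all(ms$layers$shaded_relief >= 0 & ms$layers$shaded_relief <= 1))
  expect_error(morpho_stack(matrix(1, 2, 2)), "smaller")
})

test_that("rotating the grid rotates aspect by 90 degrees and preserves
           slope and curvature", {
  set.seed(8)
  z <- grid_from(function(x, y) 0.02 * x^2 - 0.015 * y^2 + 0.3 * x + 0.1 * y,
                 n = 11) + matrix(rnorm(121, 0, 0.05), 11)
  a <- morpho_stack(z, is_depth = FALSE)
  # 90-degree clockwise rotation of the height field
  zr <- t(z)[, rev(seq_len(nrow(z)))]
  b <- morpho_stack(zr, is_depth = FALSE)
  inner <- 3:9
  map_back <- function(m) t(m[, rev(seq_len(ncol(m)))])
  expect_equal(map_back(b$layers$slope)[inner, inner],
               a$layers$slope[inner, inner], tolerance = 1e-9)
  expect_equal(map_back(b$layers$min_curvature)[inner, inner],
               a$layers$min_curvature[inner, inner], tolerance = 1e-9)
  expect_equal(map_back(b$layers$max_curvature)[inner, inner],
               a$layers$max_curvature[inner, inner], tolerance = 1e-9)
  da <- (map_back(b$layers$aspect) - a$layers$aspect)[inner, inner] %% 360
  expect_true(all(abs(da - 90) < 1e-6))
})

test_that("terrain classification labels analytic landforms and swaps under
           sign change", {
  legend <- terrain_classes()
  flat <- classify_terrain(matrix(3, 12, 12), 6)
  expect_true(all(flat$legend[flat$codes] == "plane"))

  # a shoal (depth minimum) is a peak; a deep hole is a pit
  n <- 13; ctr <- 7
  bump <- outer(seq_len(n), seq_len(n), function(i, j)
    10 - 6 * exp(-((i - ctr)^2 + (j - ctr)^2) / 8))
  tm <- classify_terrain(bump, 6)
  expect_equal(tm$legend[tm$codes[ctr, ctr]], "peak")
  hole <- 20 - bump
  tm2 <- classify_terrain(hole, 6)
  expect_equal(tm2$legend[tm2$codes[ctr, ctr]], "pit")

  # multiplying depths by -1 swaps peak<->pit and ridge<->channel
  set.seed(13)
  z <- matrix(cumsum(rnorm(15 * 15, 0, 0.3)), 15, 15)
  t1 <- classify_terrain(z, 6)
  t2 <- classify_terrain(-z, 6)
  swap <- c(peak = "pit", ridge = "channel", pass = "pass", plane = "plane",
            channel = "ridge", pit = "peak")
  expect_equal(unname(swap[t1$legend[t1$codes]]),
               unname(t2$legend[t2$codes]))

  # both window scales are supported on the 2-m grid
  expect_equal(attr(classify_terrain(bump, 12), "scale_m"), 12)
  expect_error(classify_terrain(bump, 2), "unsupported scale")
})

test_that("slope correction makes local roughness at most absolute roughness
           on tilted noisy planes", {
  set.seed(21)
  n <- 12
  depth <- outer(seq_len(n), seq_len(n), function(i, j) 4 + 0.5 * i) +
    matrix(rnorm(n * n, 0, 0.05), n)
  ms <- morpho_stack(depth)
  expect_true(all(ms$layers$local_roughness <=
                    ms$layers$abs_roughness + 1e-12))
})
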