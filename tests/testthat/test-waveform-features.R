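# Waveform segmentation and the 16 per-sounding statistics, checked against
# brute-force oracles.

test_that("segmentation finds surface and benthic peaks and orders the
           intervals", {
  w <- two_peak_waveform(t1 = 10, t2 = 50)
  seg <- segment_waveform(w)
  expect_true(seg$surface[1] <= 11 && 11 <= seg$surface[2])  # sample of t=10
  expect_true(seg$benthic[1] <= 51 && 51 <= seg$benthic[2])
  expect_lt(seg$surface[2], seg$benthic[1])
  expect_lte(seg$column[2], seg$transition[1])
  expect_lte(seg$transition[2], seg$benthic[1])

  # idempotence
  expect_identical(seg, segment_waveform(w))

  # monotone decay has no benthic return
  mono <- as_waveform(100 * exp(-(0:80) / 15))
  expect_error(segment_waveform(mono), "bottom signal lost",
               class = "bs_bottom_lost")
})

test_that("benthic statistics match their definitions on constructed pulses", {
  # symmetric triangular pulse: zero skewness
  tri <- c(0:10, 10:0)  # every value appears twice: symmetric multiset
  b <- benthic_statistics(manual_segments(c(1, length(tri))), as_waveform(tri))
  expect_equal(unname(b["b_skew"]), 0, tolerance = 1e-12)

  # constant segment: variance 0, skewness/kurtosis 0 by convention;
  # trapezoidal AUC of constant c over m samples is c * (m - 1)
  const <- rep(7, 30)
  b <- benthic_statistics(manual_segments(c(1, 30)), as_waveform(const))
  expect_equal(unname(b["b_var"]), 0)
  expect_equal(unname(b["b_skew"]), 0)
  expect_equal(unname(b["b_kurt"]), 0)
  expect_equal(unname(b["b_auc"]), 7 * 29)
  expect_equal(unname(b["b_irange"]), 0)

  # time range: |t(max) - t(min)| with max at 52 ns and min at 48 ns
  y <- rep(5, 60)
  y[49] <- 1    # t = 48
  y[53] <- 20   # t = 52
  b <- benthic_statistics(manual_segments(c(1, 60)), as_waveform(y))
  expect_equal(unname(b["b_trange"]), 4)
})

test_that("moment statistics agree with a naive two-pass oracle", {
  set.seed(42)
  for (rep in 1:20) {
    y <- rexp(sample(10:80, 1), rate = 0.1)
    w <- as_waveform(y)
    b <- benthic_statistics(manual_segments(c(1, length(y))), w)
    mu <- sum(y) / length(y)
    m2 <- sum((y - mu)^2) / length(y)
    m3 <- sum((y - mu)^3) / length(y)
    m4 <- sum((y - mu)^4) / length(y)
    expect_equal(unname(b["b_mean"]), mu, tolerance = 1e-9)
    expect_equal(unname(b["b_var"]), m2, tolerance = 1e-9)
    expect_equal(unname(b["b_skew"]), m3 / m2^1.5, tolerance = 1e-9)
    expect_equal(unname(b["b_kurt"]), m4 / m2^2, tolerance = 1e-9)
    expect_equal(unname(b["b_mad"]), mean(abs(y - mu)), tolerance = 1e-9)
  }
})

test_that("decile Shannon index matches its anchors and a brute-force
           percentile oracle", {
  expect_equal(decile_shannon(rep(4, 25)), log(10), tolerance = 1e-12)

  # one decile dominating: entropy collapses to 0
  expect_equal(decile_shannon(c(rep(0, 95), rep(100, 5))), 0)

  # brute-force oracle: linear interpolation between order statistics
  y <- as.numeric(1:100)
  dec <- vapply(seq(0.1, 1, 0.1), function(p) {
    h <- (length(y) - 1) * p + 1
    lo <- floor(h)
    sort(y)[lo] + (h - lo) * (sort(y)[min(lo + 1, length(y))] - sort(y)[lo])
  }, numeric(1))
  q <- dec / sum(dec)
  expect_equal(decile_shannon(y), -sum(q * log(q)), tolerance = 1e-12)

  expect_error(decile_shannon(rep(0, 20)), "all-zero")
  expect_error(decile_shannon(1:5), "10 samples")
})

test_that("transition statistics cover the symmetric, constant and linear
           cases", {
  hump <- c(1, 3, 5, 5, 3, 1)   # paired values: symmetric multiset
  s <- transition_statistics(manual_segments(c(10, 12), c(1, 6)),
                             as_waveform(c(hump, rep(1, 10))))
  expect_equal(unname(s["t_skew"]), 0, tolerance = 1e-12)

  s <- transition_statistics(manual_segments(c(10, 12), c(1, 6)),
                             as_waveform(rep(3, 20)))
  expect_equal(unname(s["t_var"]), 0)

  # linear ramp a + b t: mean equals the midpoint value
  ramp <- 2 + 0.5 * (0:10)
  s <- transition_statistics(manual_segments(c(15, 16), c(1, 11)),
                             as_waveform(c(ramp, rep(0, 10))))
  expect_equal(unname(s["t_mean"]), 2 + 0.5 * 5, tolerance = 1e-12)
})

test_that("feature table has 16 columns, conserves rows and flags lost
           bottoms", {
  ws <- lapply(c(3, 7, 12), function(d) simulate_waveform(d, 0.5, 0))
  ft <- extract_feature_table(ws, depths = c(3, 7, 12))
  expect_equal(sum(names(ft) %in% waveform_feature_names()), 16)
  expect_equal(nrow(ft), 3)
  expect_equal(attr(ft, "n_lost"), 0L)

  empty <- extract_feature_table(list())
  expect_equal(nrow(empty), 0)

  ws_bad <- c(ws, list(as_waveform(100 * exp(-(0:80) / 15))))
  expect_message(ft2 <- extract_feature_table(ws_bad, depths = rep(5, 4)),
                 "bottom signal lost")
  expect_equal(nrow(ft2), 3)
  expect_equal(attr(ft2, "n_lost"), 1L)
})

test_that("extracted benthic skewness decreases strictly with seabed
           complexity at zero noise", {
  for (d in c(4, 9, 14)) {
    sk <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(cx) {
      w <- simulate_waveform(d, cx, 0)
      benthic_statistics(segment_waveform(w), w)["b_skew"]
    }, numeric(1))
    expect_true(all(diff(sk) < 0))
  }
})

test_that("depth normalization removes polynomial depth trends", {
  set.seed(7)
  d <- runif(40, 2, 16)
  ft <- data.frame(sounding_id = as.character(1:40), depth = d)
  ft$b_mean <- 3 - 2 * d + 0.5 * d^2            # exactly quadratic
  ft$b_var <- 5 + d + rnorm(40)
  res <- depth_normalize(ft, feature_cols = c("b_mean", "b_var"))
  expect_true(all(res$b_mean == 0))
  expect_equal(mean(res$b_var), 0, tolerance = 1e-9)

  # 5-point parabola: residuals match explicit normal equations
  d5 <- c(2, 5, 8, 11, 14)
  f5 <- c(1.2, 0.7, 2.9, 3.1, 4.0)
  X <- cbind(1, d5, d5^2)
  beta <- solve(t(X) %*% X, t(X) %*% f5)
  r5 <- f5 - as.numeric(X %*% beta)
  tab <- data.frame(sounding_id = as.character(1:5), depth = d5, b_mean = f5)
  out <- depth_normalize(tab, feature_cols = "b_mean")
  expect_equal(out$b_mean, r5 / sd(r5), tolerance = 1e-9)
})

test_that("PCA reduction keeps the smallest component set reaching the
           variance target", {
  set.seed(9)
  n <- 60
  # orthogonal columns with known variances 4, 1, 0.25: eigenvalues by hand
  z1 <- rep(c(-1, 1), n / 2)
  z2 <- rep(c(-1, -1, 1, 1), n / 4)
  z3 <- rep(c(-1, 1, 1, -1), n / 4)
  x <- data.frame(a = 2 * z1, b = 1 * z2, c = 0.5 * z3)
  sc <- n / (n - 1)  # population -> sample variance factor
  p <- pca_reduce(x, variance_kept = 0.95, feature_cols = c("a", "b", "c"))
  ev <- attr(p, "sdev")^2
  expect_equal(sort(ev, decreasing = TRUE), sc * c(4, 1, 0.25),
               tolerance = 1e-9)
  # 4 + 1 of 5.25 total = 0.952 >= 0.95: two components suffice
  expect_equal(attr(p, "n_kept"), 2)

  # duplicated column: shared variance loads on one component
  x2 <- data.frame(a = rnorm(30))
  x2$b <- x2$a
  x2$c <- rnorm(30)
  p2 <- pca_reduce(x2, variance_kept = 0.95,
                   feature_cols = c("a", "b", "c"))
  expect_lt(attr(p2, "n_kept"), 3)

  # reconstruction error bounded by the discarded eigenvalue sum
  tot <- sum(attr(p, "sdev")^2)
  kept <- sum(attr(p, "sdev")[seq_len(attr(p, "n_kept"))]^2)
  expect_lte(tot - kept, 0.05 * tot + 1e-9)
})
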