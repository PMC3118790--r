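# Synthetic benthoscape generator: seeded determinism, gradient structure,
# waveform pulse physics and quadrat cover protocol.

test_that("generator is bit-identical across runs with the same seed", {
  cfg <- tiny_config(seed = 11)
  a <- generate_benthoscape(cfg)
  b <- generate_benthoscape(cfg)
  expect_identical(a$depth$values, b$depth$values)
  expect_identical(a$complexity$values, b$complexity$values)
  expect_identical(a$substratum$codes, b$substratum$codes)

  st1 <- sample_stations(a, 25, seed = 5)
  st2 <- sample_stations(b, 25, seed = 5)
  expect_identical(st1, st2)
  st3 <- sample_stations(a, 25, seed = 6)
  expect_false(identical(st1$row, st3$row))

  q1 <- generate_quadrats(st1, cfg)
  q2 <- generate_quadrats(st2, cfg)
  expect_identical(q1, q2)

  cfg2 <- tiny_config(seed = 12)
  expect_false(identical(generate_benthoscape(cfg2)$depth$values,
                         a$depth$values))
})

test_that("depth model has a shore-normal gradient, stays in range, and the
           embayment is shallower than its threshold", {
  cfg <- tiny_config(depth_noise_sd = 0, complexity_noise_sd = 0, seed = 3)
  scape <- generate_benthoscape(cfg)
  d <- scape$depth$values
  # zero-noise: every column strictly increases seaward (down rows)
  expect_true(all(apply(d, 2, function(col) all(diff(col) > 0))))
  expect_true(all(d >= cfg$depth_range[1] & d <= cfg$depth_range[2]))
  # embayment: the shallowest shore cells sit below the threshold
  expect_lt(min(d[1, ]), cfg$embayment_depth_threshold)
  # complexity bounded and positively associated with hard substrata
  cx <- scape$complexity$values
  expect_true(all(cx >= 0 & cx <= 1))
  hard <- scape$substratum$codes >= 3
  if (any(hard) && any(!hard)) expect_gt(mean(cx[hard]), mean(cx[!hard]))
})

test_that("generator rejects invalid configurations", {
  expect_error(benthoscape_config(grid_shape = c(0, 5)), "grid_shape")
  expect_error(benthoscape_config(depth_range = c(5, 2)), "depth_range")
  expect_error(benthoscape_config(species_pool = letters[1:5]), "12")
  expect_error(benthoscape_config(abiotic_pool = letters[1:3]), "4")
})

test_that("benthic pulse peaks at kappa * depth after the surface and its
           temporal skew follows the complexity scenario", {
  # closed form: noiseless pulse maximum at t_surface + 8.9 ns/m * depth
  w <- simulate_waveform(4.5, 0.2, noise_sd = 0)
  seg <- segment_waveform(w)
  bi <- seg$benthic[1]:seg$benthic[2]
  t_peak <- (bi[which.max(w$intensities[bi])] - 1) * w$dt
  expect_lt(abs(t_peak - (15 + kappa_ns_per_m() * 4.5)), 1)

  # flat simple bottom: right-skewed return; complex bottom: left-skewed
  expect_gt(benthic_temporal_m3(simulate_waveform(6, 0, 0)), 0)
  expect_lt(benthic_temporal_m3(simulate_waveform(6, 1, 0)), 0)

  expect_error(simulate_waveform(-1, 0.5), "non-negative")
  expect_error(simulate_waveform(5, 1.5), "complexity")
  expect_true(all(simulate_waveform(3, 0.5, noise_sd = 5,
                                    seed = 1)$intensities >= 0))
  expect_gte(length(simulate_waveform(2, 0, 0)$intensities), 50)
})

test_that("travel time recovers depth to within one sample at zero noise", {
  for (d in seq(2.5, 15.5, by = 1.3)) for (cx in c(0, 0.5, 1)) {
    w <- simulate_waveform(d, cx, 0)
    seg <- segment_waveform(w)
    x <- w$intensities
    si <- seg$surface[1]:seg$surface[2]
    bi <- seg$benthic[1]:seg$benthic[2]
    t_s <- (si[which.max(x[si])] - 1) * w$dt
    t_b <- (bi[which.max(x[bi])] - 1) * w$dt
    expect_lt(abs((t_b - t_s) / kappa_ns_per_m() - d), 1 / kappa_ns_per_m() +
                1e-9)
  }
})

test_that("station sampling is uniform, bounded and reproducible", {
  scape <- generate_benthoscape(benthoscape_config(seed = 4))
  st <- sample_stations(scape)          # default survey size
  expect_equal(nrow(st), 300)
  expect_true(all(st$row >= 1 & st$row <= 60 & st$col >= 1 & st$col <= 80))
  expect_false(any(duplicated(st$station_id)))

  one <- sample_stations(scape, 1, seed = 9)
  expect_equal(nrow(one), 1)

  small <- generate_benthoscape(tiny_config(seed = 2))
  expect_error(sample_stations(small, 1e5), "exceeds")
})

test_that("quadrat covers honour the 100-cell quantization and conserve
           image area", {
  cfg <- tiny_config(seed = 21)
  scape <- generate_benthoscape(cfg)
  st <- sample_stations(scape, 40, seed = 22)
  q <- generate_quadrats(st, cfg)
  covers <- as.matrix(q[, -1])
  expect_equal(ncol(covers), 16)   # 12 biotic + 4 abiotic
  expect_true(all(covers >= 0 & covers <= 100))
  expect_true(all(covers == round(covers)))   # integer percents
  biotic <- covers[, benthic_species_pool()]
  expect_true(all(rowSums(covers) <= 100 + 1e-9))

  # layered canopies may push summed biotic cover past 100%
  cfgL <- tiny_config(seed = 21, layered_cover = TRUE, depth_effect = 3,
                      complexity_effect = 3)
  qL <- generate_quadrats(st, cfgL)
  expect_gt(max(rowSums(qL[, benthic_species_pool()])), 100)
})

test_that("diversity responds positively to the depth gradient under a
           noise-free, strong-effect configuration", {
  cfg <- benthoscape_config(grid_shape = c(30, 30), n_stations = 150,
                            depth_noise_sd = 0, complexity_noise_sd = 0,
                            quadrat_noise_sd = 0, depth_effect = 2.5,
                            complexity_effect = 2.5, seed = 31)
  scape <- generate_benthoscape(cfg)
  st <- sample_stations(scape, 150, seed = 32)
  ix <- index_table(generate_quadrats(st, cfg))
  expect_gt(cor(st$depth, ix$D, method = "spearman"), 0)
})
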