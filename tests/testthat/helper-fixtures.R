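# Shared fixtures: hand-built waveforms, tiny survey configs, and a cached
# reference pipeline run reused across test files.

# waveform made of two well-separated Gaussian peaks (surface at t1, benthic
# at t2), zero noise
two_peak_waveform <- function(t1 = 10, t2 = 50, a1 = 100, a2 = 80,
                              sigma = 2, n = 90) {
  t <- 0:(n - 1)
  structure(list(t0 = 0, dt = 1,
                 intensities = a1 * exp(-(t - t1)^2 / (2 * sigma^2)) +
                   a2 * exp(-(t - t2)^2 / (2 * sigma^2)),
                 sounding_id = "toy", easting = 0, northing = 0),
            class = "bs_waveform")
}

# hand-made segments object, for unit-testing the statistics in isolation
manual_segments <- function(benthic, transition = c(1, 2)) {
  structure(list(surface = c(1, 2), column = c(2, transition[1]),
                 transition = transition, benthic = benthic,
                 noise_floor = 0, noise_sd = 0),
            class = "bs_segments")
}

# wrap a plain intensity vector as a waveform
as_waveform <- function(y, dt = 1) {
  structure(list(t0 = 0, dt = dt, intensities = y, sounding_id = "v",
                 easting = 0, northing = 0),
            class = "bs_waveform")
}

tiny_config <- function(...) {
  benthoscape_config(grid_shape = c(15, 20), n_stations = 40, ...)
}

# temporal skewness ingredients of the benthic return: the pulse treated as
# a density over time
benthic_temporal_m3 <- function(w) {
  seg <- segment_waveform(w)
  idx <- seg$benthic[1]:seg$benthic[2]
  y <- w$intensities[idx]
  tt <- w$t0 + (idx - 1) * w$dt
  p <- y / sum(y)
  mu <- sum(p * tt)
  sum(p * (tt - mu)^3)
}

# cached full pipeline runs (Simpson response, random forest, terciles) so
# the benchmark tests do not repeat the expensive stages
.run_cache <- new.env(parent = emptyenv())
reference_run <- function(seed) {
  key <- as.character(seed)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_pipeline(benthoscape_config(seed = seed),
                                      responses = "D",
                                      learners = "random_forest", ks = 3)
  }
  .run_cache[[key]]
}
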