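#' Survey configuration for the synthetic benthoscape generator
#'
#' Bundles every tunable of the synthetic survey: grid geometry, depth range,
#' embayment structure, station and quadrat protocol, the fixed 12-taxon
#' biotic pool and 4-class substratum pool, effect sizes linking depth and
#' structural complexity to community composition, and noise levels.
#'
#' @param grid_shape integer vector (rows, cols) of the 2-m depth grid. Rows
#'   run shore (row 1) to sea.
#' @param cell_size cell edge length in meters.
#' @param depth_range numeric (min, max) water depth in meters, positive down.
#' @param embayment_depth_threshold depth (m) shallower than which the
#'   sheltered embayment lies; also the ecological boundary the depth model
#'   encodes.
#' @param embayment_strength fractional shallowing at the embayment centre,
#'   in \[0, 1); 0 disables the embayment and leaves a pure shore-normal
#'   gradient.
#' @param n_stations number of photo-quadrat stations.
#' @param quadrat_area quadrat footprint in square meters.
#' @param grid_cells_per_quadrat number of grid squares used to quantize
#'   covers on each photograph (percent covers are multiples of
#'   100 / grid_cells_per_quadrat).
#' @param species_pool character vector of exactly 12 biotic labels.
#' @param abiotic_pool character vector of exactly 4 substratum labels,
#'   ordered soft to hard.
#' @param depth_effect,complexity_effect effect sizes (logit scale) of scaled
#'   depth and structural complexity on taxon occurrence, cover and evenness.
#' @param depth_noise_sd standard deviation (m) of the smooth bathymetric
#'   noise field.
#' @param complexity_noise_sd standard deviation of the smooth noise added to
#'   the structural-complexity field.
#' @param quadrat_noise_sd station-level noise (logit scale) on the community
#'   linear predictor.
#' @param waveform_noise_sd additive Gaussian noise (photo counts) on
#'   simulated waveforms.
#' @param layered_cover logical; if TRUE biotic canopies may overlap so that
#'   summed biotic cover can exceed 100%.
#' @param seed integer seed governing every random draw of the generator.
#'
#' @return An object of class `benthoscape_config` (a validated list).
#' @export
#' @examples
#' cfg <- benthoscape_config(grid_shape = c(30, 40), n_stations = 50)
#' cfg$depth_range
benthoscape_config <- function(grid_shape = c(60, 80),
                               cell_size = 2,
                               depth_range = c(2, 16),
                               embayment_depth_threshold = 6.25,
                               embayment_strength = 0.45,
                               n_stations = 300,
                               quadrat_area = 0.16,
                               grid_cells_per_quadrat = 100,
                               species_pool = benthic_species_pool(),
                               abiotic_pool = substratum_pool(),
                               depth_effect = 1.6,
                               complexity_effect = 1.6,
                               depth_noise_sd = 0.3,
                               complexity_noise_sd = 0.2,
                               quadrat_noise_sd = 0.4,
                               waveform_noise_sd = 2,
                               layered_cover = FALSE,
                               seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2 || any(!is.finite(grid_shape)) ||
      any(grid_shape <= 0)) {
    stop("`grid_shape` must be two positive integers (rows, cols)",
         call. = FALSE)
  }
  if (length(depth_range) != 2 || any(depth_range <= 0) ||
      diff(depth_range) <= 0) {
    stop("`depth_range` must be positive and increasing", call. = FALSE)
  }
  if (n_stations < 1) stop("`n_stations` must be >= 1", call. = FALSE)
  if (length(species_pool) != 12) {
    stop("`species_pool` must contain exactly 12 biotic labels",
         call. = FALSE)
  }
  if (length(abiotic_pool) != 4) {
    stop("`abiotic_pool` must contain exactly 4 substratum labels",
         call. = FALSE)
  }
  if (embayment_strength < 0 || embayment_strength >= 1) {
    stop("`embayment_strength` must be in [0, 1)", call. = FALSE)
  }
  if (cell_size <= 0) stop("`cell_size` must be positive", call. = FALSE)
  cfg <- list(
    grid_shape = grid_shape, cell_size = cell_size,
    depth_range = as.numeric(depth_range),
    embayment_depth_threshold = embayment_depth_threshold,
    embayment_strength = embayment_strength,
    n_stations = as.integer(n_stations),
    quadrat_area = quadrat_area,
    grid_cells_per_quadrat = as.integer(grid_cells_per_quadrat),
    species_pool = species_pool, abiotic_pool = abiotic_pool,
    depth_effect = depth_effect, complexity_effect = complexity_effect,
    depth_noise_sd = depth_noise_sd,
    complexity_noise_sd = complexity_noise_sd,
    quadrat_noise_sd = quadrat_noise_sd,
    waveform_noise_sd = waveform_noise_sd,
    layered_cover = isTRUE(layered_cover),
    seed = as.integer(seed)
  )
  class(cfg) <- "benthoscape_config"
  cfg
}

#' Default biotic and substratum label pools
#'
#' The 12 epi-macrobenthic cover variables (taxa, macroalgae and dead shells)
#' and the 4 substratum grain-size classes scored on each photo quadrat.
#'
#' @return Character vector of labels.
#' @export
benthic_species_pool <- function() {
  c("Crustacea", "Echinoidea", "Annelida", "Gastropoda", "Asteroidea",
    "Dead_shells", "Fucus", "Zostera_marina", "Chondrus_crispus",
    "Laminaria", "Chorda_tomentosa", "Polysiphonia")
}

#' @rdname benthic_species_pool
#' @export
substratum_pool <- function() {
  c("Fine_sand", "Pebbles", "Cobbles", "Boulders")
}

#' Two-way travel-time constant for green LiDAR in water
#'
#' Nanoseconds of round-trip delay per meter of water depth (speed of light
#' in water close to 0.225 m/ns gives 2 / 0.225 = 8.9 ns/m, rounded to the
#' design constant used consistently by the simulator and the feature stage).
#'
#' @return Numeric scalar, ns per meter.
#' @export
kappa_ns_per_m <- function() 8.9
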