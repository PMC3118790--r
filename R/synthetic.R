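# Synthetic benthoscape surveys: depth model, structural-complexity field,
# substratum truth, green-channel waveforms and station photo-quadrats with
# the gradient structure the downstream analysis assumes.

#' Run an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not perturb the
#' caller's random stream.
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Smooth Gaussian random field: white noise blurred by a separable Gaussian
# kernel (replicate padding), rescaled to the requested marginal sd.
smooth_noise <- function(nrow, ncol, sd, sigma_cells = 2) {
  if (sd <= 0) return(matrix(0, nrow, ncol))
  z <- matrix(rnorm(nrow * ncol), nrow, ncol)
  half <- max(1L, ceiling(3 * sigma_cells))
  k <- exp(-((-half:half)^2) / (2 * sigma_cells^2))
  k <- k / sum(k)
  blur1d <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], half), v, rep(v[n], half))
    as.numeric(stats::filter(vp, k, sides = 2))[(half + 1):(half + n)]
  }
  z <- apply(z, 2, blur1d)
  z <- t(apply(z, 1, blur1d))
  s <- sd(as.vector(z))
  if (s == 0) return(matrix(0, nrow, ncol))
  z * (sd / s)
}

new_grid <- function(values, cell_size, origin = NULL) {
  if (is.null(origin)) origin <- c(0, nrow(values) * cell_size)
  structure(list(values = values, cell_size = cell_size,
                 origin = origin),  # (easting, northing) of NW corner
            class = "bs_grid")
}

new_categorical_raster <- function(codes, legend, cell_size, origin = NULL) {
  if (is.null(origin)) origin <- c(0, nrow(codes) * cell_size)
  stopifnot(all(codes[!is.na(codes)] %in% seq_along(legend)))
  structure(list(codes = codes, legend = legend, cell_size = cell_size,
                 origin = origin),
            class = "bs_raster_cat")
}

# Cell-centre coordinates; row 1 is the north (shore) edge.
cell_coords <- function(grid, row, col) {
  list(easting = grid$origin[1] + (col - 0.5) * grid$cell_size,
       northing = grid$origin[2] - (row - 0.5) * grid$cell_size)
}

#' Generate a synthetic benthoscape
#'
#' Builds the latent physical template of a survey: a depth grid with a
#' shore-normal gradient (row 1 shallow, deepening seaward) plus a sheltered
#' embayment shallower than the configured threshold, a structural-complexity
#' field in \[0, 1\] that rises with depth (soft nourished sands inshore,
#' hard complex bottoms offshore) plus smooth spatial noise, and a
#' substratum-truth raster whose grain-size classes coarsen with complexity.
#'
#' All draws are governed by `config$seed`; identical configs give
#' bit-identical grids.
#'
#' @param config a [benthoscape_config()].
#' @return A list of class `benthoscape` with elements `depth` (a grid of
#'   meters, positive down), `complexity` (grid in \[0, 1\]), `substratum`
#'   (categorical raster over `config$abiotic_pool`), and `config`.
#' @export
#' @examples
#' scape <- generate_benthoscape(benthoscape_config(grid_shape = c(20, 30)))
#' range(scape$depth$values)
generate_benthoscape <- function(config) {
  stopifnot(inherits(config, "benthoscape_config"))
  R <- config$grid_shape[1]; C <- config$grid_shape[2]
  dmin <- config$depth_range[1]; dmax <- config$depth_range[2]

  with_seed(config$seed, {
    r <- if (R > 1) (seq_len(R) - 1) / (R - 1) else 0
    base <- dmin + (dmax - dmin) * r                 # shore-normal gradient
    base_m <- matrix(base, R, C)
    # Embayment: a smooth shallowing bump anchored on the shore edge; the
    # multiplicative form keeps every column strictly increasing seaward.
    cidx <- (seq_len(C) - 1)
    c0 <- (C - 1) / 2
    sr <- max(0.35 * R, 1); sc <- max(0.18 * C, 1)
    bump <- outer((seq_len(R) - 1)^2 / (2 * sr^2),
                  (cidx - c0)^2 / (2 * sc^2), "+")
    f <- 1 - config$embayment_strength * exp(-bump)
    raw <- base_m * f + smooth_noise(R, C, config$depth_noise_sd)
    rng <- range(raw)
    depth_vals <- if (diff(rng) > 0) {
      dmin + (raw - rng[1]) / diff(rng) * (dmax - dmin)
    } else matrix(dmin, R, C)

    d01 <- (depth_vals - dmin) / (dmax - dmin)
    comp <- 0.15 + 0.6 * d01 + smooth_noise(R, C, config$complexity_noise_sd)
    comp <- pmin(pmax(comp, 0), 1)

    codes <- matrix(findInterval(comp, c(0.3, 0.5, 0.65)) + 1L, R, C)
    structure(list(
      depth = new_grid(depth_vals, config$cell_size),
      complexity = new_grid(comp, config$cell_size),
      substratum = new_categorical_raster(codes, config$abiotic_pool,
                                          config$cell_size),
      config = config
    ), class = "benthoscape")
  })
}

#' Simulate a green-channel full-waveform LiDAR return
#'
#' The noiseless trace is the sum of three components: a Gaussian water
#' surface peak, an exponentially decaying water-column return, and a benthic
#' pulse whose maximum sits at `t_surface + kappa * depth` with
#' `kappa = ` [kappa_ns_per_m()] ns/m. The benthic pulse is an asymmetric
#' Gaussian whose rise/fall widths are driven by seabed structural
#' complexity: over a flat simple bottom the return decays slowly (long right
#' tail, positive temporal skew), while a structurally complex bottom
#' reflects and absorbs photons before the peak, shortening the tail
#' (left-skewed, tighter pulse). Gaussian noise is added and intensities are
#' clipped at zero.
#'
#' @param depth water depth in meters (>= 0).
#' @param complexity structural complexity in \[0, 1\].
#' @param noise_sd additive Gaussian noise, photo counts.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param sounding_id identifier carried on the waveform.
#' @param easting,northing sounding position, meters.
#' @param t_surface surface-peak time, ns.
#' @param dt sampling interval, ns.
#' @return Object of class `bs_waveform`: list with `t0`, `dt`,
#'   `intensities`, `sounding_id`, `easting`, `northing`.
#' @export
#' @examples
#' w <- simulate_waveform(4.5, complexity = 0.2, noise_sd = 0)
#' length(w$intensities) >= 50
simulate_waveform <- function(depth, complexity, noise_sd = 0, seed = NULL,
                              sounding_id = "s1", easting = 0, northing = 0,
                              t_surface = 15, dt = 1) {
  if (!is.finite(depth) || depth < 0) {
    stop("`depth` must be non-negative", call. = FALSE)
  }
  if (complexity < 0 || complexity > 1) {
    stop("`complexity` must lie in [0, 1]", call. = FALSE)
  }
  kappa <- kappa_ns_per_m()
  t_b <- t_surface + kappa * depth
  tau <- 2 + 10 * (1 - complexity)   # afterglow decay time, ns
  n <- max(150, ceiling((t_b + 40 + 12 * tau) / dt))
  t <- (seq_len(n) - 1) * dt

  surface <- 180 * exp(-(t - t_surface)^2 / (2 * 2.5^2))
  column <- ifelse(t >= t_surface,
                   35 * exp(-0.08 * (t - t_surface)), 0)
  sigma_r <- 1.2 + 1.8 * complexity   # rise width grows with complexity
  sigma_f <- 5.0 - 3.0 * complexity   # fall steepens with complexity
  amp <- 40 + 60 * exp(-0.1 * depth)
  sig <- ifelse(t <= t_b, sigma_r, sigma_f)
  benthic <- amp * exp(-(t - t_b)^2 / (2 * sig^2))
  # elongated low-intensity afterglow trailing the benthic peak over flat
  # simple bottoms; both its amplitude and its decay time shrink as
  # complexity rises (photons absorbed/reflected before the peak instead of
  # trailing behind it). The gamma-like shape has zero value and slope at
  # the peak, so the pulse maximum stays at t_surface + kappa * depth.
  dtb <- pmax(t - t_b, 0) / tau
  tail <- (1 - complexity) * 0.35 * amp * dtb^2 * exp(-dtb)

  # constant dark-count baseline keeps the additive noise from clipping at
  # zero in the signal region
  intens <- 8 + surface + column + benthic + tail
  if (noise_sd > 0) {
    intens <- with_seed(seed, intens + rnorm(n, 0, noise_sd))
  }
  structure(list(t0 = 0, dt = dt, intensities = pmax(intens, 0),
                 sounding_id = sounding_id,
                 easting = easting, northing = northing),
            class = "bs_waveform")
}

#' Sample photo-quadrat stations over a benthoscape
#'
#' Stations are placed uniformly at random over grid cells, without
#' replacement and without any substratum stratification, mimicking a survey
#' spread across the study area with no prior knowledge of the seabed.
#'
#' @param scape a `benthoscape` from [generate_benthoscape()].
#' @param n_stations number of stations; must not exceed the cell count.
#' @param seed integer seed (RNG state restored afterwards).
#' @return A data.frame with columns `station_id`, `row`, `col`, `easting`,
#'   `northing`, `depth`, `complexity`.
#' @export
sample_stations <- function(scape, n_stations = scape$config$n_stations,
                            seed = scape$config$seed) {
  stopifnot(inherits(scape, "benthoscape"))
  ncell <- prod(dim(scape$depth$values))
  if (n_stations > ncell) {
    stop("`n_stations` exceeds the number of grid cells", call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(ncell, n_stations))
  R <- nrow(scape$depth$values)
  row <- ((idx - 1) %% R) + 1L
  col <- ((idx - 1) %/% R) + 1L
  xy <- cell_coords(scape$depth, row, col)
  data.frame(
    station_id = sprintf("st%04d", seq_len(n_stations)),
    row = row, col = col,
    easting = xy$easting, northing = xy$northing,
    depth = scape$depth$values[cbind(row, col)],
    complexity = scape$complexity$values[cbind(row, col)],
    stringsAsFactors = FALSE
  )
}

#' Generate station photo-quadrat cover matrices
#'
#' Simulates the percent-cover scoring of one photograph per station on a
#' grid of `grid_cells_per_quadrat` uniformly distributed squares (covers are
#' integer multiples of the grid unit). Taxon occurrence follows logistic
#' responses to scaled depth and structural complexity; covers of present
#' taxa are allocated by a Dirichlet draw whose concentration (evenness)
#' rises along the same gradient, so richness, abundance and evenness -- and
#' hence Simpson diversity -- all increase with depth and complexity.
#' Substratum classes fill the residual (non-biotic) image area, weighted
#' toward the station's true substratum. With `layered_cover = TRUE` biotic
#' canopies may overlap and summed biotic cover can exceed 100%.
#'
#' @param stations data.frame from [sample_stations()].
#' @param config the survey [benthoscape_config()].
#' @param seed integer seed; defaults to a fixed offset of `config$seed`.
#' @return Data.frame: `station_id` plus 12 biotic and 4 abiotic percent
#'   columns (in `config` pool order).
#' @export
generate_quadrats <- function(stations, config,
                              seed = (config$seed + 99991L) %% 2147483647L) {
  stopifnot(inherits(config, "benthoscape_config"))
  n <- nrow(stations)
  unit <- 100 / config$grid_cells_per_quadrat
  alpha <- seq(0.5, -2.5, length.out = 12)
  dmin <- config$depth_range[1]; dmax <- config$depth_range[2]

  with_seed(seed, {
    biotic <- matrix(0, n, 12, dimnames = list(NULL, config$species_pool))
    abiotic <- matrix(0, n, 4, dimnames = list(NULL, config$abiotic_pool))
    for (i in seq_len(n)) {
      zd <- 2 * (stations$depth[i] - dmin) / (dmax - dmin) - 1
      zc <- 2 * stations$complexity[i] - 1
      eta <- config$depth_effect * zd + config$complexity_effect * zc +
        rnorm(1, 0, config$quadrat_noise_sd)

      occ <- rbinom(12, 1, plogis(alpha + eta)) == 1
      if (any(occ)) {
        theta <- exp(0.8 + 0.8 * eta)
        w <- rgamma(sum(occ), shape = theta, rate = 1)
        if (sum(w) == 0) w <- rep(1, sum(occ))
        props <- w / sum(w)
        a_tot <- 100 * plogis(-0.3 + 0.9 * eta)
        if (config$layered_cover) a_tot <- a_tot * (1 + 1.5 * plogis(eta))
        cov <- round(a_tot * props / unit) * unit
        if (!config$layered_cover) {
          while (sum(cov) > 100) cov[which.max(cov)] <- cov[which.max(cov)] - unit
        }
        biotic[i, occ] <- cov
      }
      residual <- max(0, 100 - min(100, sum(biotic[i, ])))
      if (residual > 0) {
        wsub <- rep(1, 4)
        sub_code <- findInterval(stations$complexity[i], c(0.3, 0.5, 0.65)) + 1L
        wsub[sub_code] <- 6
        units_left <- round(residual / unit)
        counts <- as.vector(rmultinom(1, units_left, wsub / sum(wsub)))
        abiotic[i, ] <- counts * unit
      }
    }
    data.frame(station_id = stations$station_id, biotic, abiotic,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
}
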