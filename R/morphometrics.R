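# Terrain morphometry: local quadratic surface fits on the depth grid, the
# 12 derived bathymetric features, and six-type terrain classification at
# two window scales.

#' Names of the 12 morphometric layers
#' @return Character vector.
#' @export
morpho_layer_names <- function() {
  c("abs_roughness", "local_roughness", "slope", "aspect", "shaded_relief",
    "profile_convexity", "plan_convexity", "longitudinal_convexity",
    "cross_sectional_convexity", "min_curvature", "max_curvature", "rmse")
}

#' Terrain class legend
#' @return Character vector of the six terrain types.
#' @export
terrain_classes <- function() {
  c("peak", "ridge", "pass", "plane", "channel", "pit")
}

# design matrix for z = a x^2 + b y^2 + c xy + d x + e y + f on an odd
# square window; x east, y north (row 1 = north), cell-centred coordinates
quad_design <- function(w, cell_size) {
  h <- (w - 1) / 2
  j <- rep(seq_len(w), each = w)   # column index, column-major stacking
  i <- rep(seq_len(w), times = w)  # row index
  x <- (j - h - 1) * cell_size
  y <- (h + 1 - i) * cell_size
  cbind(x2 = x^2, y2 = y^2, xy = x * y, x = x, y = y, one = 1)
}

#' Fit a local quadratic surface to a window of grid values
#'
#' Least-squares fit of z = a x^2 + b y^2 + c xy + d x + e y + f in
#' cell-centred local coordinates (x east, y north, meters).
#'
#' @param window odd square matrix of surface values (heights).
#' @param cell_size cell edge, meters.
#' @return List with `coef` (named a..f) and `rmse` (root mean squared
#'   residual). Windows containing missing values return NULL (no-data).
#' @export
fit_local_quadratic <- function(window, cell_size = 2) {
  w <- nrow(window)
  stopifnot(w == ncol(window), w %% 2 == 1)
  z <- as.vector(window)
  if (anyNA(z)) return(NULL)
  X <- quad_design(w, cell_size)
  cf <- qr.coef(qr(X), z)
  res <- z - X %*% cf
  list(coef = setNames(as.numeric(cf), c("a", "b", "c", "d", "e", "f")),
       rmse = sqrt(mean(res^2)))
}

# derived quantities from quadratic coefficients
quad_derivatives <- function(a, b, cc, d, e) {
  g2 <- d^2 + e^2
  slope <- atan(sqrt(g2)) * 180 / pi
  aspect <- if (g2 < 1e-24) NA_real_ else (atan2(-d, -e) * 180 / pi) %% 360
  if (g2 < 1e-24) {
    profc <- planc <- longc <- crosc <- 0
  } else {
    num <- a * d^2 + b * e^2 + cc * d * e
    numx <- b * d^2 + a * e^2 - cc * d * e
    profc <- -200 * num / (g2 * (1 + g2)^1.5)
    planc <- 200 * numx / g2^1.5
    longc <- -2 * num / g2
    crosc <- -2 * numx / g2
  }
  disc <- sqrt((a - b)^2 + cc^2)
  list(slope = slope, aspect = aspect, profc = profc, planc = planc,
       longc = longc, crosc = crosc,
       minc = -a - b - disc, maxc = -a - b + disc)
}

# replicate-padded window extraction
pad_window <- function(m, i, j, h) {
  R <- nrow(m); C <- ncol(m)
  ri <- pmin(pmax(i + (-h:h), 1), R)
  cj <- pmin(pmax(j + (-h:h), 1), C)
  m[ri, cj, drop = FALSE]
}

#' Morphometric feature stack of a depth grid
#'
#' Fits a quadratic surface in a 3x3 window around every cell of the digital
#' depth model (depths are converted to heights, z = -depth, so that shoals
#' are peaks and aspect is the downslope compass direction) and derives the
#' 12 layers of [morpho_layer_names()]: absolute roughness (SD of the 3x3
#' depths), local roughness (SD of residuals about the best-fit 3x3 plane),
#' slope (degrees), aspect (degrees clockwise from north, downslope; NA on
#' flats), Lambertian shaded relief in \[0, 1\], profile / plan /
#' longitudinal / cross-sectional convexity (+ convex, - concave), minimum
#' and maximum curvature (-a-b -/+ sqrt((a-b)^2 + c^2)), and the RMSE of the
#' quadratic fit. Edge cells use nearest-valid padding.
#'
#' @param depth a `bs_grid` of depths (positive down) or a numeric matrix of
#'   heights when `is_depth = FALSE`.
#' @param sun_azimuth,sun_elevation illumination for shaded relief, degrees.
#' @param is_depth if TRUE (default) values are depths and are negated to
#'   heights before fitting.
#' @return Object of class `bs_morpho`: list with `layers` (named list of 12
#'   matrices), `bathymetry` (the input depth matrix), `cell_size`.
#' @export
morpho_stack <- function(depth, sun_azimuth = 315, sun_elevation = 45,
                         is_depth = TRUE) {
  if (inherits(depth, "bs_grid")) {
    vals <- depth$values; cs <- depth$cell_size
  } else {
    vals <- depth; cs <- 2
  }
  R <- nrow(vals); C <- ncol(vals)
  if (R < 3 || C < 3) stop("grid smaller than the 3x3 window", call. = FALSE)
  z <- if (is_depth) -vals else vals

  X <- quad_design(3, cs)
  Pq <- solve(crossprod(X), t(X))          # quadratic projector
  Xp <- X[, 4:6]                           # plane terms x, y, 1
  Pp <- solve(crossprod(Xp), t(Xp))
  Hq <- X %*% Pq
  Hp <- Xp %*% Pp

  azr <- sun_azimuth * pi / 180; elr <- sun_elevation * pi / 180
  sun <- c(sin(azr) * cos(elr), cos(azr) * cos(elr), sin(elr))

  nm <- morpho_layer_names()
  layers <- setNames(lapply(nm, function(x) matrix(NA_real_, R, C)), nm)
  for (i in seq_len(R)) for (j in seq_len(C)) {
    win <- pad_window(z, i, j, 1L)
    zz <- as.vector(win)
    cf <- Pq %*% zz
    a <- cf[1]; b <- cf[2]; cc <- cf[3]; d <- cf[4]; e <- cf[5]
    qd <- quad_derivatives(a, b, cc, d, e)
    res_q <- zz - Hq %*% zz
    res_p <- zz - Hp %*% zz
    nrm <- c(-d, -e, 1) / sqrt(1 + d^2 + e^2)
    layers$abs_roughness[i, j] <- sd(zz)
    layers$local_roughness[i, j] <- sd(res_p)
    layers$slope[i, j] <- qd$slope
    layers$aspect[i, j] <- qd$aspect
    layers$shaded_relief[i, j] <- min(max(sum(nrm * sun), 0), 1)
    layers$profile_convexity[i, j] <- qd$profc
    layers$plan_convexity[i, j] <- qd$planc
    layers$longitudinal_convexity[i, j] <- qd$longc
    layers$cross_sectional_convexity[i, j] <- qd$crosc
    layers$min_curvature[i, j] <- qd$minc
    layers$max_curvature[i, j] <- qd$maxc
    layers$rmse[i, j] <- sqrt(mean(res_q^2))
  }
  structure(list(layers = layers, bathymetry = vals, cell_size = cs),
            class = "bs_morpho")
}

#' Classify terrain into the six morphometric types
#'
#' Fits the local quadratic at the window size matching the requested spatial
#' scale (scale in meters / cell size, rounded up to an odd cell count: 6 m
#' on a 2-m grid gives 3x3, 12 m gives 7x7) and applies the slope/curvature
#' decision rules: on sloping cells the cross-sectional convexity separates
#' ridge (convex), channel (concave) and inclined plane; on level cells the
#' signs of minimum and maximum curvature distinguish peak (both convex),
#' pit (both concave), pass (saddle), ridge or channel (one flat) and plane.
#'
#' @inheritParams morpho_stack
#' @param scale_m window scale, meters (any scale giving an odd window >= 3).
#' @param slope_tol slope tolerance, degrees.
#' @param curv_tol curvature tolerance (per unit).
#' @return A categorical raster (`bs_raster_cat`) over [terrain_classes()],
#'   with attribute `scale_m`.
#' @export
classify_terrain <- function(depth, scale_m = 6, slope_tol = 1,
                             curv_tol = 0.005, is_depth = TRUE) {
  if (inherits(depth, "bs_grid")) {
    vals <- depth$values; cs <- depth$cell_size
  } else {
    vals <- depth; cs <- 2
  }
  w <- round(scale_m / cs)
  if (w %% 2 == 0) w <- w + 1L
  if (w < 3) stop("unsupported scale: window smaller than 3 cells",
                  call. = FALSE)
  R <- nrow(vals); C <- ncol(vals)
  if (R < 3 || C < 3) stop("grid smaller than the window", call. = FALSE)
  z <- if (is_depth) -vals else vals

  X <- quad_design(w, cs)
  Pq <- solve(crossprod(X), t(X))
  h <- (w - 1) %/% 2
  legend <- terrain_classes()
  codes <- matrix(NA_integer_, R, C)
  for (i in seq_len(R)) for (j in seq_len(C)) {
    zz <- as.vector(pad_window(z, i, j, h))
    if (anyNA(zz)) next
    cf <- Pq %*% zz
    qd <- quad_derivatives(cf[1], cf[2], cf[3], cf[4], cf[5])
    cls <- if (qd$slope > slope_tol) {
      if (qd$crosc > curv_tol) "ridge"
      else if (qd$crosc < -curv_tol) "channel"
      else "plane"
    } else {
      if (qd$maxc > curv_tol) {
        if (qd$minc > curv_tol) "peak"
        else if (qd$minc < -curv_tol) "pass"
        else "ridge"
      } else if (qd$maxc < -curv_tol) {
        "pit"
      } else {
        if (qd$minc < -curv_tol) "channel" else "plane"
      }
    }
    codes[i, j] <- match(cls, legend)
  }
  out <- new_categorical_raster(codes, legend, cs)
  attr(out, "scale_m") <- scale_m
  out
}

#' Inverse-distance gridding of scattered soundings
#'
#' Simple utility to grid scattered (easting, northing, depth) soundings onto
#' a regular cell grid by inverse-distance-squared weighting of the `k`
#' nearest soundings, for feeding real point data into the raster stages.
#'
#' @param soundings data.frame with `easting`, `northing`, `depth`.
#' @param cell_size output cell size, meters.
#' @param k number of neighbours.
#' @return A `bs_grid` of depths.
#' @export
grid_soundings <- function(soundings, cell_size = 2, k = 6) {
  e <- soundings$easting; n <- soundings$northing; d <- soundings$depth
  e0 <- min(e); n1 <- max(n)
  C <- max(1L, ceiling((max(e) - e0) / cell_size))
  R <- max(1L, ceiling((n1 - min(n)) / cell_size))
  vals <- matrix(NA_real_, R, C)
  for (i in seq_len(R)) for (j in seq_len(C)) {
    cx <- e0 + (j - 0.5) * cell_size
    cy <- n1 - (i - 0.5) * cell_size
    dist2 <- (e - cx)^2 + (n - cy)^2
    nb <- order(dist2)[seq_len(min(k, length(d)))]
    w <- 1 / pmax(dist2[nb], 1e-9)
    vals[i, j] <- sum(w * d[nb]) / sum(w)
  }
  new_grid(vals, cell_size, origin = c(e0, n1))
}
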