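# Spatial autocorrelation (Moran's I with permutation inference) and
# application of the selected model across the predictor raster stack.

#' Spatial weights for stations or raster cells
#'
#' Supported schemes: `knn` (k-nearest neighbours by Euclidean distance,
#' default k = 8, row-standardized), `distance_band` (all neighbours within
#' `band` meters, row-standardized), and `rook` / `queen` contiguity for
#' regular grids (coordinates are then interpreted as (row, col) indices).
#' Self-weights are always zero.
#'
#' @param coords two-column matrix/data.frame of point coordinates (easting,
#'   northing), or (row, col) for grid schemes.
#' @param scheme one of "knn", "distance_band", "rook", "queen".
#' @param k neighbours for knn.
#' @param band distance band, meters.
#' @param row_standardize divide each row by its sum (default TRUE).
#' @return An n x n weight matrix of class `bs_weights`.
#' @export
spatial_weights <- function(coords, scheme = c("knn", "distance_band",
                                               "rook", "queen"),
                            k = 8, band = NULL, row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  w <- matrix(0, n, n)
  if (scheme %in% c("knn", "distance_band")) {
    d <- as.matrix(dist(coords))
    diag(d) <- Inf
    if (scheme == "knn") {
      if (k >= n) stop("k must be smaller than n", call. = FALSE)
      for (i in seq_len(n)) w[i, order(d[i, ])[seq_len(k)]] <- 1
    } else {
      if (is.null(band)) stop("`band` required", call. = FALSE)
      w[d <= band] <- 1
    }
  } else {
    dr <- abs(outer(coords[, 1], coords[, 1], "-"))
    dc <- abs(outer(coords[, 2], coords[, 2], "-"))
    w[if (scheme == "rook") (dr + dc) == 1 else (pmax(dr, dc) == 1)] <- 1
  }
  diag(w) <- 0
  if (row_standardize) {
    rs <- rowSums(w)
    w[rs > 0, ] <- w[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  structure(w, class = c("bs_weights", "matrix"))
}

#' Moran's I with permutation inference
#'
#' Global spatial autocorrelation:
#' I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2
#' with S0 the sum of all weights. Its expectation under no autocorrelation
#' is -1/(n - 1). The pseudo p-value is one-sided (positive autocorrelation)
#' from `n_perm` random permutations of the values over the locations.
#'
#' @param values numeric vector (non-constant, n >= 3).
#' @param coords point coordinates (used to build weights when `weights` is
#'   NULL).
#' @param weights a `bs_weights` matrix; built as row-standardized 8-nearest
#'   neighbours from `coords` when NULL.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return List: `I`, `expectation`, `p_value`, `n_perm`.
#' @export
morans_i <- function(values, coords = NULL, weights = NULL, n_perm = 999,
                     seed = 1) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values", call. = FALSE)
  if (var(values) == 0) stop("Moran's I undefined for constant values",
                             call. = FALSE)
  if (is.null(weights)) {
    if (is.null(coords)) stop("supply `coords` or `weights`", call. = FALSE)
    weights <- spatial_weights(coords, "knn", k = min(8, n - 1))
  }
  w <- unclass(weights)
  s0 <- sum(w)
  stat <- function(x) {
    z <- x - mean(x)
    (n / s0) * as.numeric(t(z) %*% w %*% z) / sum(z^2)
  }
  i_obs <- stat(values)
  perms <- with_seed(seed,
    vapply(seq_len(n_perm), function(i) stat(sample(values)), numeric(1)))
  list(I = i_obs, expectation = -1 / (n - 1),
       p_value = (1 + sum(perms >= i_obs)) / (n_perm + 1),
       n_perm = n_perm)
}

#' Predict the diversity class map from a raster predictor stack
#'
#' Applies a trained learner to every valid cell of the predictor stack and
#' returns the categorical class map together with per-class probability
#' layers (so users can re-threshold) and the discretization edges defining
#' the legend.
#'
#' @param learner one of [learner_names()].
#' @param x_train,y_train,k,seed training data as in [train_and_predict()].
#' @param stack_cells data.frame with `row`, `col` and the predictor columns
#'   (one row per valid cell).
#' @param grid_shape (rows, cols) of the raster.
#' @param edges discretization edges labelling the classes.
#' @param cell_size cell edge, meters.
#' @return List of class `bs_predicted_map`: `class_map` (a
#'   `bs_raster_cat`), `prob` (list of k probability matrices), `edges`.
#' @export
predict_map <- function(learner, x_train, y_train, k, stack_cells,
                        grid_shape, edges = NULL, cell_size = 2, seed = 1) {
  feat <- setdiff(names(stack_cells), c("row", "col"))
  miss <- setdiff(names(as.data.frame(x_train)), feat)
  if (length(miss) > 0) {
    stop("stack is missing training predictors: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  prob <- train_and_predict(learner, x_train, y_train,
                            stack_cells[names(as.data.frame(x_train))],
                            k, seed = seed)
  cls <- max.col(prob, ties.method = "first")
  codes <- matrix(NA_integer_, grid_shape[1], grid_shape[2])
  codes[cbind(stack_cells$row, stack_cells$col)] <- cls
  legend <- if (k == 3) c("low", "medium", "high") else
    paste0("class", seq_len(k) - 1)
  players <- lapply(seq_len(k), function(c) {
    m <- matrix(NA_real_, grid_shape[1], grid_shape[2])
    m[cbind(stack_cells$row, stack_cells$col)] <- prob[, c]
    m
  })
  names(players) <- legend
  structure(list(class_map = new_categorical_raster(codes, legend, cell_size),
                 prob = players, edges = edges,
                 model = attr(prob, "model")),
            class = "bs_predicted_map")
}
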