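# Supervised substratum-type mapping from waveform principal components, and
# kernel beta-diversity rasters (Bray-Curtis dissimilarity, Pielou evenness)
# over the resulting categorical map.

#' Sample ground-truth pixels from a substratum raster
#'
#' Draws labelled pixels per class and tags them as training (2/3) or
#' validation (1/3); the two sets are disjoint by construction.
#'
#' @param truth a `bs_raster_cat` of true substratum classes.
#' @param n_per_class pixels to sample per class (capped at availability).
#' @param seed integer seed.
#' @return Data.frame: `row`, `col`, `label`, `split` ("train"/"valid").
#' @export
sample_ground_truth <- function(truth, n_per_class = 60, seed = 1) {
  codes <- truth$codes
  with_seed(seed, {
    out <- lapply(seq_along(truth$legend), function(k) {
      idx <- which(codes == k)
      if (length(idx) == 0) return(NULL)
      take <- sample(idx, min(n_per_class, length(idx)))
      n_tr <- floor(2 * length(take) / 3)
      data.frame(row = ((take - 1) %% nrow(codes)) + 1L,
                 col = ((take - 1) %/% nrow(codes)) + 1L,
                 label = truth$legend[k],
                 split = c(rep("train", n_tr),
                           rep("valid", length(take) - n_tr)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Train the substratum classifier
#'
#' A margin-maximizing classifier with a radial kernel on standardized
#' inputs. Hyperparameters (cost, kernel width) are chosen by a small grid
#' search with stratified cross-validation on the training pixels.
#'
#' @param x matrix or data.frame of predictors (waveform PC scores).
#' @param y class labels (factor or character); at least two classes.
#' @param seed integer seed (cross-validation folds).
#' @param cost_grid,gamma_grid hyperparameter candidates; `gamma_grid`
#'   defaults to (0.5, 1, 2) / ncol(x).
#' @param folds cross-validation folds.
#' @return A fitted `e1071::svm` model (with probability support) carrying
#'   the chosen hyperparameters in attributes `cost` and `gamma`.
#' @export
train_substratum_classifier <- function(x, y, seed = 1,
                                        cost_grid = c(1, 10, 100),
                                        gamma_grid = NULL, folds = 3) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) {
    stop("training data must contain at least two classes", call. = FALSE)
  }
  if (is.null(gamma_grid)) gamma_grid <- c(0.5, 1, 2) / ncol(x)
  with_seed(seed, {
    # stratified fold assignment
    fold <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    best <- NULL; best_acc <- -1
    for (cst in cost_grid) for (gm in gamma_grid) {
      acc <- 0
      for (f in seq_len(folds)) {
        tr <- fold != f
        if (nlevels(droplevels(y[tr])) < 2) next
        m <- e1071::svm(x[tr, , drop = FALSE], droplevels(y[tr]),
                        kernel = "radial", cost = cst, gamma = gm,
                        scale = TRUE)
        acc <- acc + mean(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
      }
      if (acc > best_acc) { best_acc <- acc; best <- c(cst, gm) }
    }
    model <- e1071::svm(x, y, kernel = "radial", cost = best[1],
                        gamma = best[2], scale = TRUE, probability = TRUE)
    attr(model, "cost") <- best[1]
    attr(model, "gamma") <- best[2]
    model
  })
}

#' Classify the seafloor from per-cell predictor scores
#'
#' Applies the trained classifier to every valid cell; no post-classification
#' resampling or smoothing is applied.
#'
#' @param model from [train_substratum_classifier()].
#' @param pc_cells data.frame with `row`, `col` and the predictor columns the
#'   model was trained on.
#' @param grid_shape (rows, cols) of the output raster.
#' @param cell_size cell edge, meters.
#' @return A `bs_raster_cat` over the model's class levels.
#' @export
classify_seafloor <- function(model, pc_cells, grid_shape, cell_size = 2) {
  feat_cols <- setdiff(names(pc_cells), c("row", "col", "sounding_id", "depth"))
  pred <- predict(model, as.matrix(pc_cells[feat_cols]))
  codes <- matrix(NA_integer_, grid_shape[1], grid_shape[2])
  codes[cbind(pc_cells$row, pc_cells$col)] <- as.integer(pred)
  new_categorical_raster(codes, levels(pred), cell_size)
}

#' Confusion matrix and accuracies on validation pixels
#'
#' @param predicted,truth label vectors of equal length (validation pixels).
#' @param classes class order for the matrix (default union of labels).
#' @return List: `confusion` (rows = true, cols = predicted),
#'   `overall_accuracy`, `per_class_accuracy` (recall per true class).
#' @export
confusion_matrix <- function(predicted, truth, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(as.character(predicted),
                                                 as.character(truth))))
  cm <- table(factor(truth, classes), factor(predicted, classes))
  names(dimnames(cm)) <- c("true", "predicted")
  list(confusion = unclass(cm),
       overall_accuracy = sum(diag(cm)) / sum(cm),
       per_class_accuracy = diag(cm) / pmax(rowSums(cm), 1))
}

disc_offsets <- function(radius_cells) {
  h <- floor(radius_cells)
  g <- expand.grid(di = -h:h, dj = -h:h)
  g$dist <- sqrt(g$di^2 + g$dj^2)
  g[g$dist <= radius_cells, ]
}

# class-composition proportions of the map cells at (row+di, col+dj)
kernel_composition <- function(codes, i, j, offs, n_classes) {
  ri <- i + offs$di; cj <- j + offs$dj
  ok <- ri >= 1 & ri <= nrow(codes) & cj >= 1 & cj <= ncol(codes)
  v <- codes[cbind(ri[ok], cj[ok])]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NULL)
  tabulate(v, nbins = n_classes) / length(v)
}

#' Kernel Bray-Curtis dissimilarity raster
#'
#' For every cell, the Bray-Curtis percent dissimilarity between the
#' substratum class composition of an inner disc kernel and that of a
#' surrounding annulus of (at least) equal area:
#' BC = 100 * sum(|x_i - y_i|) / sum(x_i + y_i). Values near 0 mark locally
#' homogeneous seafloor; 100 marks two entirely different compositions.
#' With `reference = "global"` the comparison is against the whole-map
#' composition instead of the annulus.
#'
#' @param map a `bs_raster_cat` substratum map.
#' @param radius_m kernel radius, meters (>= cell size).
#' @param reference "annulus" (default) or "global".
#' @return Numeric matrix in \[0, 100\] (NA where the kernel has no data).
#' @export
kernel_braycurtis <- function(map, radius_m = 6,
                              reference = c("annulus", "global")) {
  reference <- match.arg(reference)
  if (radius_m < map$cell_size) stop("radius must be >= cell size",
                                     call. = FALSE)
  rc <- radius_m / map$cell_size
  inner <- disc_offsets(rc)
  n_inner <- nrow(inner)
  K <- length(map$legend)
  codes <- map$codes

  if (reference == "annulus") {
    r2 <- rc + 0.5
    repeat {
      outer_disc <- disc_offsets(r2)
      ann <- outer_disc[outer_disc$dist > rc, ]
      if (nrow(ann) >= n_inner) break
      r2 <- r2 + 0.5
    }
  } else {
    glob <- tabulate(codes[!is.na(codes)], nbins = K)
    glob <- glob / sum(glob)
  }

  out <- matrix(NA_real_, nrow(codes), ncol(codes))
  for (i in seq_len(nrow(codes))) for (j in seq_len(ncol(codes))) {
    x <- kernel_composition(codes, i, j, inner, K)
    if (is.null(x)) next
    y <- if (reference == "annulus") {
      kernel_composition(codes, i, j, ann, K)
    } else glob
    if (is.null(y)) next
    out[i, j] <- 100 * sum(abs(x - y)) / sum(x + y)
  }
  out
}

#' Kernel Pielou evenness raster
#'
#' For every cell, the Shannon evenness of the substratum classes within a
#' disc kernel: J' = -sum(p_i log p_i) / log(R) over the R classes present
#' (J' = 0 when a single class covers the kernel, 1 when all present classes
#' are equally represented).
#'
#' @inheritParams kernel_braycurtis
#' @return Numeric matrix in \[0, 1\] (NA where the kernel has no data).
#' @export
kernel_evenness <- function(map, radius_m = 6) {
  if (radius_m < map$cell_size) stop("radius must be >= cell size",
                                     call. = FALSE)
  inner <- disc_offsets(radius_m / map$cell_size)
  K <- length(map$legend)
  codes <- map$codes
  out <- matrix(NA_real_, nrow(codes), ncol(codes))
  for (i in seq_len(nrow(codes))) for (j in seq_len(ncol(codes))) {
    p <- kernel_composition(codes, i, j, inner, K)
    if (is.null(p)) next
    p <- p[p > 0]
    out[i, j] <- if (length(p) < 2) 0 else -sum(p * log(p)) / log(length(p))
  }
  out
}
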