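# Response discretization, train/test protocol, and the seven-learner bench.

#' Names of the seven learners
#' @return Character vector in fixed (tie-breaking) order.
#' @export
learner_names <- function() {
  c("naive_bayes", "regression_tree", "classification_tree", "c45",
    "random_forest", "svm", "cn2")
}

#' Printed learner settings
#'
#' The benchmark defaults: naive Bayes with relative-frequency priors and
#' classification threshold 0.5; trees with binary splits, pre-pruning at a
#' minimum of 10 samples per split and m-estimate post-pruning with m = 5;
#' classification tree splitting on information gain with same-majority leaf
#' merging; the gain-ratio tree pre-pruned at 10 and post-pruned at
#' confidence 25; a random forest of 10 trees with 6-variable split subsets
#' (recomputed as round(sqrt(p)) when the predictor table is not the standard
#' 34 columns) and a 10-sample minimum per split, majority vote; a radial
#' kernel SVM on standardized inputs; and a covering-rule inducer with
#' Laplace rule evaluation, a beam of 5 rules, likelihood-ratio alpha 0.05
#' and stopping alpha 0.2, exclusive covering.
#'
#' @return Named list of per-learner settings.
#' @export
learner_settings <- function() {
  list(
    naive_bayes = list(prior = "relative_frequency", threshold = 0.5),
    regression_tree = list(binarization = TRUE, min_split = 10,
                           m_estimate = 5),
    classification_tree = list(criterion = "information_gain",
                               min_split = 10, m_estimate = 5,
                               merge_same_majority = TRUE),
    c45 = list(criterion = "gain_ratio", min_split = 10, confidence = 25),
    random_forest = list(n_trees = 10, split_subset = 6, min_split = 10,
                         vote = "majority"),
    svm = list(kernel = "radial", normalize = TRUE),
    cn2 = list(evaluation = "laplace", beam = 5, lrs_alpha = 0.05,
               stopping_alpha = 0.2, covering = "exclusive")
  )
}

#' Equal-width discretization of a response
#'
#' Partitions `values` into `k` classes of identical width over `range`
#' (observed range by default; bounded indices such as Simpson D may use
#' their theoretical interval, e.g. \[0, 1\], which for k = 3 gives the
#' tercile cuts 1/3 and 2/3). Bins are right-open except the last; values
#' outside `range` are clamped into the end bins.
#'
#' @param values numeric response vector.
#' @param k number of classes (>= 2).
#' @param range (min, max) interval to partition; default the observed range.
#' @return Object of class `bs_discretized`: list with `k`, `edges` (k + 1
#'   cut points), `labels` (integers in 0..k-1), `range`.
#' @export
#' @examples
#' d <- equal_width_discretize(runif(50), 3, range = c(0, 1))
#' d$edges   # 0, 1/3, 2/3, 1
equal_width_discretize <- function(values, k, range = NULL) {
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (is.null(range)) range <- c(min(values), max(values))
  if (diff(range) <= 0) {
    stop("degenerate range: response is constant", call. = FALSE)
  }
  edges <- seq(range[1], range[2], length.out = k + 1)
  lab <- findInterval(values, edges, rightmost.closed = TRUE)
  lab <- pmin(pmax(lab, 1L), k) - 1L
  structure(list(k = as.integer(k), edges = edges, labels = as.integer(lab),
                 range = range),
            class = "bs_discretized")
}

#' Random train/test split
#'
#' Draws a test set of exactly `test_n` stations; train and test are
#' disjoint and exhaustive.
#'
#' @param n total number of stations (or a data.frame, whose row count is
#'   used).
#' @param test_n test-set size (default 100, the 34% protocol on 300
#'   stations).
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(n, test_n = 100, seed = 1) {
  if (is.data.frame(n)) n <- nrow(n)
  if (test_n >= n) stop("`test_n` must be smaller than n", call. = FALSE)
  test <- sort(with_seed(seed, sample.int(n, test_n)))
  list(train = setdiff(seq_len(n), test), test = test)
}

# sanitize a probability matrix: fill non-finite rows with the priors and
# renormalize every row to 1
fix_prob_rows <- function(p, priors) {
  bad <- !is.finite(rowSums(p))
  if (any(bad)) p[bad, ] <- matrix(priors, sum(bad), length(priors),
                                   byrow = TRUE)
  rs <- rowSums(p)
  zero <- rs <= 0
  if (any(zero)) { p[zero, ] <- 1 / ncol(p); rs[zero] <- 1 }
  p / rowSums(p)
}

#' Train a learner and predict class probabilities on a test set
#'
#' Class labels are the integer codes of a [equal_width_discretize()]
#' response (0..k-1). The returned matrix has one column per class (columns
#' named "0".."k-1"); classes absent from training receive probability zero.
#' Rows sum to 1. Training requires at least two classes present.
#'
#' @param learner one of [learner_names()].
#' @param x_train,x_test data.frames/matrices of numeric predictors.
#' @param y_train integer class labels (0-based) for the training rows.
#' @param k total number of classes.
#' @param seed integer seed (bootstraps, tie-breaking).
#' @return Probability matrix (rows = test samples) with attributes `model`
#'   and `learner`; for the random forest the attribute `importance` carries
#'   the per-variable split importance.
#' @export
train_and_predict <- function(learner, x_train, y_train, x_test, k,
                              seed = 1) {
  learner <- match.arg(learner, learner_names())
  x_train <- as.data.frame(x_train)
  x_test <- as.data.frame(x_test)
  lev <- as.character(0:(k - 1))
  yf <- factor(as.character(y_train), levels = lev)
  present <- levels(droplevels(yf))
  if (length(present) < 2) {
    stop("training labels must contain at least two classes", call. = FALSE)
  }
  yd <- droplevels(yf)
  priors_present <- as.numeric(table(yd)) / length(yd)
  # constant columns break scaling-based learners; drop them consistently
  keep <- vapply(x_train, function(v) sd(v) > 0, logical(1))
  if (!any(keep)) keep[1] <- TRUE
  xtr <- x_train[, keep, drop = FALSE]
  xte <- x_test[, keep, drop = FALSE]

  prob_present <- with_seed(seed, switch(
    learner,
    naive_bayes = {
      m <- e1071::naiveBayes(xtr, yd)
      p <- predict(m, xte, type = "raw")
      attr(p, "model") <- m
      p
    },
    regression_tree = {
      df <- cbind(xtr, .y = as.numeric(as.character(yd)))
      m <- rpart::rpart(.y ~ ., data = df, method = "anova",
                        control = rpart::rpart.control(minsplit = 10,
                                                       xval = 0))
      pr <- predict(m, xte)
      cls <- pmin(pmax(round(pr), 0), k - 1)
      p <- matrix(0, nrow(xte), length(levels(yd)),
                  dimnames = list(NULL, levels(yd)))
      ci <- match(as.character(cls), levels(yd))
      # predictions falling on an absent class snap to the nearest present one
      if (anyNA(ci)) {
        pres_num <- as.numeric(levels(yd))
        ci[is.na(ci)] <- vapply(cls[is.na(ci)], function(v)
          which.min(abs(pres_num - v)), integer(1))
      }
      p[cbind(seq_len(nrow(p)), ci)] <- 1
      attr(p, "model") <- m
      p
    },
    classification_tree = {
      df <- cbind(xtr, .y = yd)
      m <- rpart::rpart(.y ~ ., data = df, method = "class",
                        parms = list(split = "information"),
                        control = rpart::rpart.control(minsplit = 10,
                                                       xval = 0))
      p <- predict(m, xte, type = "prob")
      attr(p, "model") <- m
      p
    },
    c45 = {
      m <- c45_train(xtr, yd, min_split = 10, confidence = 0.25)
      p <- predict(m, xte)
      attr(p, "model") <- m
      p
    },
    random_forest = {
      mtry <- if (ncol(xtr) == 34) 6 else max(1, round(sqrt(ncol(xtr))))
      m <- randomForest::randomForest(
        xtr, yd, ntree = 10, mtry = mtry, nodesize = 9, importance = TRUE)
      p <- predict(m, xte, type = "prob")
      attr(p, "model") <- m
      attr(p, "importance") <- m$importance[, "MeanDecreaseGini"]
      p
    },
    svm = {
      m <- e1071::svm(as.matrix(xtr), yd, kernel = "radial", scale = TRUE,
                      probability = TRUE)
      pr <- predict(m, as.matrix(xte), probability = TRUE)
      p <- attr(pr, "probabilities")[, levels(yd), drop = FALSE]
      attr(p, "model") <- m
      p
    },
    cn2 = {
      m <- cn2_train(xtr, yd)
      p <- predict(m, xte)
      attr(p, "model") <- m
      p
    }
  ))

  model <- attr(prob_present, "model")
  imp <- attr(prob_present, "importance")
  pm <- matrix(prob_present[, levels(yd), drop = FALSE], nrow = nrow(xte))
  pm <- fix_prob_rows(pm, priors_present)
  out <- matrix(0, nrow(xte), k, dimnames = list(NULL, lev))
  out[, levels(yd)] <- pm
  attr(out, "model") <- model
  attr(out, "learner") <- learner
  if (!is.null(imp)) attr(out, "importance") <- imp
  out
}

#' Training-set class priors
#'
#' Relative class frequencies over the k classes (0..k-1).
#' @param y_train integer class labels (0-based).
#' @param k number of classes.
#' @return Numeric vector of length k summing to 1.
#' @export
class_priors <- function(y_train, k) {
  tabulate(y_train + 1L, k) / length(y_train)
}
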