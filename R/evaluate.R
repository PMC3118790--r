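# Evaluation of probabilistic classifiers (CA, AUC, information score,
# Brier score), the learners x classes benchmark sweep, inverse-class-count
# trend fits, model selection, ROC/confusion reporting and binned trends.

#' Score a set of probabilistic predictions
#'
#' Four evaluators:
#' \describe{
#'   \item{CA}{classification accuracy of the argmax decision (ties broken
#'     toward the lower class code).}
#'   \item{AUC}{macro-averaged one-vs-rest probability that a randomly chosen
#'     positive is ranked above a randomly chosen negative (ties count 0.5);
#'     classes without both positives and negatives in the test set are
#'     skipped.}
#'   \item{IS}{Kononenko-Bratko information score, bits: per sample with true
#'     class c, prior P(c) and predicted P'(c), the score is
#'     -log2 P(c) + log2 P'(c) when P'(c) >= P(c) and
#'     -(-log2(1 - P(c)) + log2(1 - P'(c))) otherwise, averaged. Credits only
#'     probability assigned beyond the prior; a predictor emitting the priors
#'     scores 0. Priors are clamped away from 0/1 for classes unseen in
#'     training.}
#'   \item{Bs}{Brier score halved, (1 / 2N) sum over samples and classes of
#'     (P' - y)^2, so that confidently wrong classification of every sample
#'     scores 1 and perfect prediction 0.}
#' }
#'
#' @param prob probability matrix (test samples x k classes); rows must sum
#'   to 1 within 1e-6.
#' @param y_true integer true labels, 0-based.
#' @param priors training class priors over the k classes
#'   (see [class_priors()]).
#' @return Named numeric vector c(CA, AUC, IS, Bs).
#' @export
evaluate_predictions <- function(prob, y_true, priors) {
  prob <- as.matrix(prob)
  k <- ncol(prob)
  n <- nrow(prob)
  if (any(abs(rowSums(prob) - 1) > 1e-6)) {
    stop("probability rows must sum to 1", call. = FALSE)
  }
  if (length(y_true) != n) stop("label/probability size mismatch",
                                call. = FALSE)
  yc <- y_true + 1L

  ca <- mean(max.col(prob, ties.method = "first") == yc)

  aucs <- numeric(0)
  for (c in seq_len(k)) {
    pos <- yc == c
    if (!any(pos) || all(pos)) next
    r <- rank(prob[, c])
    aucs <- c(aucs, (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
                (sum(pos) * sum(!pos)))
  }
  auc <- if (length(aucs)) mean(aucs) else NA_real_

  pr <- pmin(pmax(priors, 1e-6), 1 - 1e-6)
  pt <- prob[cbind(seq_len(n), yc)]
  p0 <- pr[yc]
  is_i <- ifelse(pt >= p0,
                 -log2(p0) + log2(pmax(pt, 1e-12)),
                 -(-log2(1 - p0) + log2(pmax(1 - pt, 1e-12))))
  is <- mean(is_i)

  y1 <- matrix(0, n, k)
  y1[cbind(seq_len(n), yc)] <- 1
  bs <- sum((prob - y1)^2) / (2 * n)

  c(CA = ca, AUC = auc, IS = is, Bs = bs)
}

#' Benchmark sweep over responses, learners and class counts
#'
#' Discretizes each response into k = `ks` equal-width classes, splits the
#' stations once into train/test, trains every learner and scores it with
#' the four evaluators on the held-out test set. Failures (e.g. a class
#' missing from the training labels) are logged in the `error` column, not
#' fatal.
#'
#' @param predictors data.frame of per-station numeric predictors.
#' @param responses data.frame of response columns (e.g. from
#'   [index_table()]).
#' @param learners subset of [learner_names()].
#' @param ks class counts to sweep.
#' @param test_n held-out test size.
#' @param seed integer seed governing the split and the learners.
#' @param ranges named list of fixed discretization intervals per response;
#'   defaults to the theoretical \[0, 1\] for the bounded Simpson index D,
#'   observed range otherwise.
#' @return Data.frame of class `bs_evalcube`: response, learner, k, CA, AUC,
#'   IS, Bs, error.
#' @export
sweep_learners <- function(predictors, responses,
                           learners = learner_names(), ks = 2:10,
                           test_n = 100, seed = 1,
                           ranges = list(D = c(0, 1))) {
  split <- split_train_test(nrow(predictors), test_n = test_n, seed = seed)
  rows <- list()
  for (resp in names(responses)) {
    vals <- responses[[resp]]
    rng <- ranges[[resp]]
    for (k in ks) {
      disc <- tryCatch(equal_width_discretize(vals, k, range = rng),
                       error = function(e) e)
      for (ln in learners) {
        res <- if (inherits(disc, "error")) disc else tryCatch({
          y_tr <- disc$labels[split$train]
          p <- train_and_predict(ln, predictors[split$train, , drop = FALSE],
                                 y_tr,
                                 predictors[split$test, , drop = FALSE],
                                 k, seed = seed)
          evaluate_predictions(p, disc$labels[split$test],
                               class_priors(y_tr, k))
        }, error = function(e) e)
        rows[[length(rows) + 1]] <- if (inherits(res, "error")) {
          data.frame(response = resp, learner = ln, k = k, CA = NA,
                     AUC = NA, IS = NA, Bs = NA,
                     error = conditionMessage(res),
                     stringsAsFactors = FALSE)
        } else {
          data.frame(response = resp, learner = ln, k = k, CA = res["CA"],
                     AUC = res["AUC"], IS = res["IS"], Bs = res["Bs"],
                     error = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bs_evalcube", "data.frame")
  out
}

#' Inverse-class-count trend fit
#'
#' Ordinary least squares of an evaluator series on the inverse of the class
#' count: metric = a + b / k, with the adjusted coefficient of determination
#' R2adj = 1 - (1 - R2) (n - 1) / (n - 2). A constant series has R2 = 0 by
#' convention (hence R2adj = -1/(n - 2)).
#'
#' @param metric evaluator values.
#' @param k matching class counts.
#' @return List: `a`, `b`, `r2`, `r2_adj`, `fitted`.
#' @export
inverse_trend_fit <- function(metric, k) {
  ok <- is.finite(metric)
  metric <- metric[ok]; k <- k[ok]
  n <- length(metric)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (var(metric) == 0) {
    return(list(a = mean(metric), b = 0, r2 = 0,
                r2_adj = 1 - (n - 1) / (n - 2),
                fitted = rep(mean(metric), n)))
  }
  x <- 1 / k
  fit <- lm(metric ~ x)
  r2 <- summary(fit)$r.squared
  list(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]), r2 = r2,
       r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
       fitted = unname(fitted(fit)))
}

#' Select the best non-binary model from an evaluation cube
#'
#' Binary discretizations oversimplify the ecology and are excluded; among
#' the remaining cells the model with maximal CA is chosen, ties broken by
#' lower Brier score, then by the fixed learner order, response order and
#' smaller k (fully deterministic).
#'
#' @param cube a `bs_evalcube` from [sweep_learners()].
#' @param exclude_k class counts to exclude (default 2).
#' @return One-row data.frame: response, learner, k, CA, AUC, IS, Bs.
#' @export
select_model <- function(cube, exclude_k = 2) {
  x <- cube[!(cube$k %in% exclude_k) & !is.na(cube$CA), , drop = FALSE]
  if (nrow(x) == 0) stop("no evaluable cells", call. = FALSE)
  x$learner_rank <- match(x$learner, learner_names())
  x$response_rank <- match(x$response, unique(cube$response))
  o <- order(-x$CA, x$Bs, x$learner_rank, x$response_rank, x$k)
  x[o[1], c("response", "learner", "k", "CA", "AUC", "IS", "Bs")]
}

#' One-vs-rest ROC curves, optimal thresholds and confusion matrix
#'
#' For each class, the ROC staircase over all score thresholds, the area
#' under it, and the equal-cost optimal operating point (maximal
#' TPR - FPR, the tangency of the unit-slope iso-performance line). The
#' confusion matrix uses the argmax decision, with per-class predicted
#' proportions (correct / predicted, i.e. precision) and true proportions
#' (correct / actual, i.e. recall).
#'
#' @param prob probability matrix (test samples x k).
#' @param y_true integer true labels, 0-based.
#' @return List: `roc` (per-class data.frames with threshold, fpr, tpr),
#'   `auc`, `optimal_threshold`, `confusion`, `predicted_prop`, `true_prop`.
#' @export
roc_and_confusion <- function(prob, y_true) {
  prob <- as.matrix(prob)
  k <- ncol(prob)
  yc <- y_true + 1L
  roc <- vector("list", k)
  auc <- opt <- rep(NA_real_, k)
  for (c in seq_len(k)) {
    pos <- yc == c
    sc <- prob[, c]
    thr <- c(Inf, sort(unique(sc), decreasing = TRUE))
    tpr <- fpr <- numeric(length(thr))
    for (i in seq_along(thr)) {
      call_pos <- sc >= thr[i]
      tpr[i] <- if (any(pos)) sum(call_pos & pos) / sum(pos) else NA
      fpr[i] <- if (any(!pos)) sum(call_pos & !pos) / sum(!pos) else NA
    }
    roc[[c]] <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
    if (any(pos) && any(!pos)) {
      auc[c] <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
      opt[c] <- thr[which.max(tpr - fpr)]
    }
  }
  pred <- max.col(prob, ties.method = "first")
  cm <- table(factor(yc, seq_len(k)), factor(pred, seq_len(k)))
  names(dimnames(cm)) <- c("true", "predicted")
  list(roc = roc, auc = auc, optimal_threshold = opt,
       confusion = unclass(cm),
       predicted_prop = diag(cm) / pmax(colSums(cm), 1),
       true_prop = diag(cm) / pmax(rowSums(cm), 1))
}

#' Binned response trend along a predictor gradient
#'
#' Stations are sorted by the predictor and averaged in consecutive blocks of
#' `bin_size`; a trend model (degree-2 or -3 polynomial, or natural-log
#' regression) is then fitted to the block means.
#'
#' @param response,predictor numeric vectors of equal length.
#' @param bin_size stations per block (default 20).
#' @param model "poly2", "poly3" or "log".
#' @return List: `bins` (data.frame of block means), `coef`, `r2`, `fitted`.
#' @export
binned_trend <- function(response, predictor, bin_size = 20,
                         model = c("poly2", "poly3", "log")) {
  model <- match.arg(model)
  n <- length(response)
  nb <- floor(n / bin_size)
  if (nb < 2) stop("need at least 2 full bins", call. = FALSE)
  o <- order(predictor)
  idx <- o[seq_len(nb * bin_size)]
  grp <- rep(seq_len(nb), each = bin_size)
  bins <- data.frame(
    predictor = tapply(predictor[idx], grp, mean),
    response = tapply(response[idx], grp, mean))
  fit <- switch(model,
    poly2 = lm(response ~ predictor + I(predictor^2), data = bins),
    poly3 = lm(response ~ predictor + I(predictor^2) + I(predictor^3),
               data = bins),
    log = {
      if (any(bins$predictor <= 0)) {
        stop("log trend requires positive predictor means", call. = FALSE)
      }
      lm(response ~ log(predictor), data = bins)
    })
  list(bins = bins, coef = coef(fit), r2 = summary(fit)$r.squared,
       fitted = unname(fitted(fit)))
}
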