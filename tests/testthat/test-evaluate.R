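# The four evaluators, the benchmark cube machinery, trend fits, model
# selection, ROC/confusion and binned trends.

one_hot <- function(y, k) {
  m <- matrix(0, length(y), k)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

test_that("evaluators hit their analytic anchors", {
  y <- c(0L, 1L, 2L, 0L, 1L)
  p <- one_hot(y, 3)
  pri <- class_priors(y, 3)
  s <- evaluate_predictions(p, y, pri)
  expect_equal(unname(s["CA"]), 1)
  expect_equal(unname(s["Bs"]), 0)

  # a predictor emitting the priors carries no information
  pp <- matrix(rep(pri, 5), 5, 3, byrow = TRUE)
  s <- evaluate_predictions(pp, y, pri)
  expect_equal(unname(s["IS"]), 0, tolerance = 1e-12)

  # two equiprobable classes, certain and correct: one full bit
  y2 <- rep(c(0L, 1L), 5)
  s2 <- evaluate_predictions(one_hot(y2, 2), y2, c(0.5, 0.5))
  expect_equal(unname(s2["IS"]), 1, tolerance = 1e-9)

  # perfect ranking on a 3+/3- binary toy
  y3 <- c(1L, 1L, 1L, 0L, 0L, 0L)
  p3 <- cbind(1 - c(.9, .8, .7, .3, .2, .1), c(.9, .8, .7, .3, .2, .1))
  s3 <- evaluate_predictions(p3, y3, c(0.5, 0.5))
  expect_equal(unname(s3["AUC"]), 1)

  # confidently wrong everywhere: Brier reaches its upper bound 1
  ywrong <- c(0L, 1L)
  pwrong <- one_hot(c(1L, 0L), 2)
  expect_equal(unname(evaluate_predictions(pwrong, ywrong,
                                           c(0.5, 0.5))["Bs"]), 1)

  expect_error(evaluate_predictions(matrix(c(0.5, 0.4), 1, 2), 0L,
                                    c(0.5, 0.5)), "sum to 1")
})

test_that("evaluators equal brute-force computation on a 10-sample set", {
  p <- matrix(c(
    0.70, 0.20, 0.10,
    0.10, 0.60, 0.30,
    0.25, 0.25, 0.50,
    0.40, 0.35, 0.25,
    0.05, 0.80, 0.15,
    0.33, 0.33, 0.34,
    0.60, 0.10, 0.30,
    0.20, 0.50, 0.30,
    0.15, 0.15, 0.70,
    0.45, 0.45, 0.10), 10, 3, byrow = TRUE)
  y <- c(0L, 1L, 2L, 1L, 1L, 2L, 0L, 0L, 2L, 0L)
  pri <- c(0.4, 0.3, 0.3)
  s <- evaluate_predictions(p, y, pri)

  # CA: explicit argmax loop (ties toward the lower class)
  ca <- mean(vapply(1:10, function(i) which.max(p[i, ]) - 1L == y[i],
                    logical(1)))
  expect_equal(unname(s["CA"]), ca, tolerance = 1e-9)

  # AUC: explicit positive/negative pair counting with ties at 0.5
  aucs <- c()
  for (cls in 1:3) {
    pos <- which(y == cls - 1L); neg <- which(y != cls - 1L)
    tot <- 0
    for (i in pos) for (j in neg) {
      tot <- tot + (p[i, cls] > p[j, cls]) + 0.5 * (p[i, cls] == p[j, cls])
    }
    aucs <- c(aucs, tot / (length(pos) * length(neg)))
  }
  expect_equal(unname(s["AUC"]), mean(aucs), tolerance = 1e-9)

  # IS: per-sample information gained relative to the prior
  is_i <- vapply(1:10, function(i) {
    pc <- pri[y[i] + 1L]; ppr <- p[i, y[i] + 1L]
    if (ppr >= pc) -log2(pc) + log2(ppr)
    else -(-log2(1 - pc) + log2(1 - ppr))
  }, numeric(1))
  expect_equal(unname(s["IS"]), mean(is_i), tolerance = 1e-9)

  # Brier: halved mean squared deviation from the one-hot outcomes
  bs <- sum((p - one_hot(y, 3))^2) / (2 * 10)
  expect_equal(unname(s["Bs"]), bs, tolerance = 1e-9)

  # independent cross-check of the binary rank AUC against pROC
  skip_if_not_installed("pROC")
  yb <- as.integer(y == 0L)
  ref <- as.numeric(pROC::auc(pROC::roc(yb, p[, 1], quiet = TRUE,
                                        direction = "<")))
  expect_equal(aucs[1], ref, tolerance = 1e-9)
})

test_that("inverse class-count trend fit matches normal equations and its
           degenerate conventions", {
  k <- 2:10
  y <- 0.3 + 1.2 / k
  f <- suppressWarnings(inverse_trend_fit(y, k))  # exact fit warns in summary.lm
  expect_equal(f$a, 0.3, tolerance = 1e-9)
  expect_equal(f$b, 1.2, tolerance = 1e-9)
  expect_equal(f$r2_adj, 1, tolerance = 1e-9)

  fc <- inverse_trend_fit(rep(0.5, 9), k)
  expect_equal(fc$r2, 0)
  expect_equal(fc$r2_adj, -1 / 7, tolerance = 1e-12)

  set.seed(3)
  y2 <- 0.2 + 0.9 / k + rnorm(9, 0, 0.05)
  f2 <- inverse_trend_fit(y2, k)
  X <- cbind(1, 1 / k)
  beta <- solve(t(X) %*% X, t(X) %*% y2)
  expect_equal(c(f2$a, f2$b), as.numeric(beta), tolerance = 1e-9)
})

test_that("model selection excludes binary cells and breaks ties as
           stated", {
  cube <- data.frame(
    response = rep("D", 5),
    learner = c("svm", "random_forest", "svm", "cn2", "naive_bayes"),
    k = c(2L, 3L, 3L, 4L, 3L),
    CA = c(0.95, 0.70, 0.70, 0.70, 0.60),
    AUC = 0.8, IS = 0.5,
    Bs = c(0.01, 0.20, 0.25, 0.20, 0.30),
    error = NA_character_)
  class(cube) <- c("bs_evalcube", "data.frame")
  sel <- select_model(cube)
  # the binary 0.95 cell is excluded; CA ties at 0.70 resolved by lower Bs,
  # then by the fixed learner order (random forest before cn2)
  expect_equal(sel$learner, "random_forest")
  expect_equal(sel$k, 3L)
})

test_that("ROC staircase, optimal threshold and confusion proportions match
           hand enumeration", {
  # 6-point binary toy, scores fixed
  y <- c(1L, 1L, 0L, 1L, 0L, 0L)
  sc <- c(0.9, 0.7, 0.6, 0.4, 0.3, 0.1)
  p <- cbind(1 - sc, sc)
  rc <- roc_and_confusion(p, y)
  r <- rc$roc[[2]]
  # hand enumeration: thresholds Inf,.9,.7,.6,.4,.3,.1
  expect_equal(r$tpr, c(0, 1, 2, 2, 3, 3, 3) / 3)
  expect_equal(r$fpr, c(0, 0, 0, 1, 1, 2, 3) / 3)
  expect_equal(rc$auc[2], 8 / 9, tolerance = 1e-9)  # 8 of 9 pairs ranked right
  # both 0.7 and 0.4 attain the maximal TPR - FPR of 2/3
  expect_true(rc$optimal_threshold[2] %in% c(0.7, 0.4))

  # perfect scores: the curve passes through (0, 1)
  rc2 <- roc_and_confusion(one_hot(y, 2), y)
  expect_true(any(rc2$roc[[2]]$fpr == 0 & rc2$roc[[2]]$tpr == 1))
  expect_equal(rc2$auc[2], 1)

  # random scores hover near the diagonal
  set.seed(8)
  n <- 400
  yr <- sample(0:1, n, replace = TRUE)
  pr <- runif(n)
  rc3 <- roc_and_confusion(cbind(1 - pr, pr), yr)
  expect_lt(abs(rc3$auc[2] - 0.5), 0.12)

  cm <- roc_and_confusion(p, y)
  expect_equal(sum(cm$confusion), 6)
})

test_that("binned trends average consecutive blocks and fit the block
           means", {
  x <- seq_len(100)
  y <- 2 + 3 * x
  bt <- suppressWarnings(binned_trend(y, x, bin_size = 20, model = "poly2"))
  expect_equal(nrow(bt$bins), 5)    # floor(100 / 20)
  expect_equal(bt$r2, 1, tolerance = 1e-9)

  set.seed(4)
  xp <- runif(87); yp <- rnorm(87)
  bt2 <- binned_trend(yp, xp, bin_size = 20, model = "poly2")
  expect_equal(nrow(bt2$bins), 4)
  o <- order(xp)
  grp <- rep(1:4, each = 20)
  expect_equal(as.numeric(bt2$bins$response),
               as.numeric(tapply(yp[o][1:80], grp, mean)), tolerance = 1e-12)
})

test_that("the benchmark sweep logs failures instead of aborting", {
  tp <- data.frame(x1 = rnorm(60), x2 = rnorm(60))
  resp <- data.frame(D = c(rep(0.1, 59), 0.9))  # k = 9 leaves empty classes
  cube <- sweep_learners(tp, resp, learners = "classification_tree",
                         ks = c(2, 9), test_n = 20, seed = 2)
  expect_equal(nrow(cube), 2)
  expect_true(all(is.na(cube$CA) | (cube$CA >= 0 & cube$CA <= 1)))
})
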