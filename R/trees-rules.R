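# In-repo learners: a gain-ratio decision tree with pessimistic-error
# pruning (C4.5 style) and an ordered-rule covering inducer (CN2 style,
# beam search with Laplace accuracy and likelihood-ratio significance).

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Upper confidence limit of the binomial error rate (C4.5 pessimistic
# estimate): number of predicted errors among n cases having observed e.
pessimistic_errors <- function(e, n, cf = 0.25) {
  if (n == 0) return(0)
  if (e >= n) return(n)
  n * qbeta(1 - cf, e + 1, n - e)
}

#' Gain-ratio decision tree
#'
#' A decision tree for numeric predictors using binary threshold splits
#' chosen by the gain ratio (information gain divided by split information),
#' pre-pruned by a minimum node size for splitting and post-pruned by
#' subtree replacement under the pessimistic (upper binomial confidence)
#' error estimate.
#'
#' @param x numeric matrix or data.frame of predictors.
#' @param y factor of class labels.
#' @param min_split minimum samples in a node for it to be split.
#' @param confidence confidence level for pessimistic pruning (0.25 = the
#'   conventional 25).
#' @param max_depth recursion cap.
#' @return Object of class `bs_c45`.
#' @export
c45_train <- function(x, y, min_split = 10, confidence = 0.25,
                      max_depth = 30) {
  x <- as.matrix(x)
  y <- factor(y)
  K <- nlevels(y)
  yi <- as.integer(y)

  best_split <- function(idx) {
    n <- length(idx)
    h0 <- entropy_bits(tabulate(yi[idx], K))
    best <- NULL; best_gr <- 1e-9
    for (j in seq_len(ncol(x))) {
      xs <- x[idx, j]
      u <- sort(unique(xs))
      if (length(u) < 2) next
      thr <- if (length(u) > 33) {
        unique(quantile(xs, seq(0.03, 0.97, length.out = 32), names = FALSE))
      } else (u[-1] + u[-length(u)]) / 2
      for (tv in thr) {
        left <- xs <= tv
        nl <- sum(left)
        if (nl < 2 || n - nl < 2) next
        cl <- tabulate(yi[idx][left], K)
        cr <- tabulate(yi[idx][!left], K)
        gain <- h0 - (nl / n) * entropy_bits(cl) -
          ((n - nl) / n) * entropy_bits(cr)
        si <- entropy_bits(c(nl, n - nl))
        if (si <= 0) next
        gr <- gain / si
        if (gain > 1e-9 && gr > best_gr) {
          best_gr <- gr
          best <- list(attr = j, thr = tv)
        }
      }
    }
    best
  }

  build <- function(idx, depth) {
    counts <- tabulate(yi[idx], K)
    n <- length(idx)
    if (n < min_split || max(counts) == n || depth >= max_depth) {
      return(list(leaf = TRUE, counts = counts))
    }
    sp <- best_split(idx)
    if (is.null(sp)) return(list(leaf = TRUE, counts = counts))
    left <- x[idx, sp$attr] <= sp$thr
    list(leaf = FALSE, counts = counts, attr = sp$attr, thr = sp$thr,
         left = build(idx[left], depth + 1),
         right = build(idx[!left], depth + 1))
  }

  prune <- function(node) {
    n <- sum(node$counts)
    leaf_est <- pessimistic_errors(n - max(node$counts), n, confidence)
    if (node$leaf) { node$est <- leaf_est; return(node) }
    node$left <- prune(node$left)
    node$right <- prune(node$right)
    sub_est <- node$left$est + node$right$est
    if (leaf_est <= sub_est + 0.1) {
      return(list(leaf = TRUE, counts = node$counts, est = leaf_est))
    }
    node$est <- sub_est
    node
  }

  structure(list(root = prune(build(seq_along(yi), 0)), levels = levels(y),
                 K = K),
            class = "bs_c45")
}

#' @rdname c45_train
#' @param object fitted `bs_c45` tree.
#' @param newdata predictor matrix/data.frame.
#' @param ... unused.
#' @return For `predict`: matrix of Laplace-corrected class probabilities.
#' @export
predict.bs_c45 <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  K <- object$K
  route <- function(node, row) {
    while (!node$leaf) {
      node <- if (row[node$attr] <= node$thr) node$left else node$right
    }
    (node$counts + 1) / (sum(node$counts) + K)
  }
  out <- t(apply(newdata, 1, function(r) route(object$root, r)))
  colnames(out) <- object$levels
  out
}

#' Ordered-rule covering classifier
#'
#' Induces an ordered list of if-then rules by general-to-specific beam
#' search. Complexes (conjunctions of threshold tests on the predictors) are
#' scored by the Laplace accuracy of their majority class; a candidate rule
#' must differ significantly from the class distribution of the remaining
#' (uncovered) examples under the likelihood-ratio statistic at
#' `alpha`, and each specialization step must itself pass `stop_alpha`.
#' The `beam` best complexes survive each round. Covered examples are
#' removed after each accepted rule (exclusive covering); a default rule
#' over the remaining examples closes the list.
#'
#' @param x numeric matrix or data.frame of predictors.
#' @param y factor of class labels.
#' @param beam beam width (number of best complexes kept).
#' @param alpha required significance of an accepted rule.
#' @param stop_alpha significance each specialization must reach.
#' @param max_len maximum number of conjuncts per rule.
#' @param n_thresholds candidate thresholds per predictor (deciles).
#' @return Object of class `bs_cn2` with elements `rules` (list of tests,
#'   class, prob) and `default_prob`.
#' @export
cn2_train <- function(x, y, beam = 5, alpha = 0.05, stop_alpha = 0.2,
                      max_len = 4, n_thresholds = 9) {
  x <- as.matrix(x)
  y <- factor(y)
  K <- nlevels(y)
  yi <- as.integer(y)
  n <- length(yi)

  tests <- list()
  for (j in seq_len(ncol(x))) {
    thr <- unique(quantile(x[, j], seq_len(n_thresholds) / (n_thresholds + 1),
                           names = FALSE))
    for (tv in thr) {
      tests[[length(tests) + 1]] <- c(attr = j, op = 1, thr = tv)  # <=
      tests[[length(tests) + 1]] <- c(attr = j, op = 2, thr = tv)  # >
    }
  }
  tmat <- vapply(tests, function(ts) {
    if (ts["op"] == 1) x[, ts["attr"]] <= ts["thr"] else x[, ts["attr"]] > ts["thr"]
  }, logical(n))
  if (n == 1) tmat <- matrix(tmat, nrow = 1)

  crit_alpha <- qchisq(1 - alpha, K - 1)
  crit_stop <- qchisq(1 - stop_alpha, K - 1)
  laplace <- function(counts) (max(counts) + 1) / (sum(counts) + K)
  lrs <- function(counts, base_prop) {
    ncov <- sum(counts)
    keep <- counts > 0 & base_prop > 0
    if (any(counts > 0 & base_prop == 0)) return(Inf)
    2 * sum(counts[keep] * log(counts[keep] / (ncov * base_prop[keep])))
  }

  find_rule <- function(remaining) {
    base_counts <- tabulate(yi[remaining], K)
    base_prop <- base_counts / sum(base_counts)
    cover0 <- rep(FALSE, n); cover0[remaining] <- TRUE
    beam_set <- list(list(tests = integer(0), cover = cover0))
    best <- NULL; best_lap <- laplace(base_counts)
    for (len in seq_len(max_len)) {
      cands <- list(); sigs <- character(0)
      for (bm in beam_set) {
        avail <- setdiff(seq_along(tests), bm$tests)
        for (ti in avail) {
          cov <- bm$cover & tmat[, ti]
          ncov <- sum(cov)
          if (ncov == 0 || ncov == sum(bm$cover)) next
          key <- paste(which(cov), collapse = ",")
          if (key %in% sigs) next
          counts <- tabulate(yi[cov], K)
          stat <- lrs(counts, base_prop)
          if (stat < crit_stop) next
          cand <- list(tests = c(bm$tests, ti), cover = cov,
                       lap = laplace(counts), counts = counts, stat = stat)
          cands[[length(cands) + 1]] <- cand
          sigs <- c(sigs, key)
          if (stat >= crit_alpha && cand$lap > best_lap) {
            best <- cand; best_lap <- cand$lap
          }
        }
      }
      if (length(cands) == 0) break
      ord <- order(vapply(cands, `[[`, numeric(1), "lap"), decreasing = TRUE)
      beam_set <- cands[ord[seq_len(min(beam, length(cands)))]]
    }
    best
  }

  rules <- list()
  remaining <- seq_len(n)
  while (length(remaining) >= 2 && length(unique(yi[remaining])) >= 1) {
    r <- find_rule(remaining)
    if (is.null(r)) break
    rules[[length(rules) + 1]] <- list(
      tests = lapply(r$tests, function(ti) tests[[ti]]),
      class = which.max(r$counts),
      prob = (r$counts + 1) / (sum(r$counts) + K))
    remaining <- remaining[!r$cover[remaining]]
    if (length(remaining) == 0) break
  }
  def_counts <- if (length(remaining) > 0) tabulate(yi[remaining], K)
                else tabulate(yi, K)
  structure(list(rules = rules,
                 default_prob = (def_counts + 1) / (sum(def_counts) + K),
                 levels = levels(y), K = K),
            class = "bs_cn2")
}

#' @rdname cn2_train
#' @param object fitted `bs_cn2` rule list.
#' @param newdata predictor matrix/data.frame.
#' @param ... unused.
#' @return For `predict`: matrix of Laplace-corrected class probabilities
#'   from the first matching rule (default rule otherwise).
#' @export
predict.bs_cn2 <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- matrix(NA_real_, nrow(newdata), object$K,
                dimnames = list(NULL, object$levels))
  for (i in seq_len(nrow(newdata))) {
    p <- object$default_prob
    for (r in object$rules) {
      ok <- all(vapply(r$tests, function(ts) {
        v <- newdata[i, ts["attr"]]
        if (ts["op"] == 1) v <= ts["thr"] else v > ts["thr"]
      }, logical(1)))
      if (ok) { p <- r$prob; break }
    }
    out[i, ] <- p
  }
  out
}
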