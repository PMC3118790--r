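# Segmentation of full waveforms into surface / column / transition / benthic
# parts and the 16 per-sounding shape statistics, with depth normalization
# and PCA reduction.

#' Canonical waveform feature column order
#'
#' Twelve benthic-return statistics followed by four transition statistics.
#' @return Character vector of 16 names.
#' @export
waveform_feature_names <- function() {
  c("b_mean", "b_var", "b_skew", "b_kurt", "b_median", "b_mad",
    "b_min", "b_max", "b_auc", "b_irange", "b_trange", "b_hdec",
    "t_mean", "t_var", "t_skew", "t_kurt")
}

# Population moments of a sample treated as an empirical distribution.
# Skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 (non-excess); both 0 by
# convention when the segment is constant.
moment_stats <- function(y) {
  mu <- mean(y)
  m2 <- mean((y - mu)^2)
  if (m2 < 1e-24) {
    return(c(mean = mu, var = 0, skew = 0, kurt = 0))
  }
  m3 <- mean((y - mu)^3)
  m4 <- mean((y - mu)^4)
  c(mean = mu, var = m2, skew = m3 / m2^1.5, kurt = m4 / m2^2)
}

trapezoid <- function(t, y) {
  n <- length(y)
  if (n < 2) return(0)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

#' Segment a waveform into surface, column, transition and benthic intervals
#'
#' Peaks are detected on a lightly smoothed trace (3-sample moving average)
#' as local maxima whose height and prominence exceed the noise floor by
#' three noise standard deviations; the noise floor is the median of the
#' first five pre-surface samples and its SD is estimated from the same
#' samples (with a small relative floor for noiseless traces). The first
#' prominent peak is the water surface; the last is the benthic return. The
#' benthic interval runs from the trough preceding the benthic peak to the
#' return to noise floor (or trace end). The water column between surface end
#' and trough is fitted by a straight line; the column ends where residuals
#' rise persistently above three residual SDs (the onset of the benthic
#' rise), and the transition interval spans column end to benthic start. If
#' the detected column end leaves fewer than three transition samples it is
#' pulled back to guarantee a non-degenerate transition.
#'
#' @param w a `bs_waveform`.
#' @return Object of class `bs_segments`: sample-index intervals `surface`,
#'   `column`, `transition`, `benthic`, plus `noise_floor` and `noise_sd`.
#'   Throws an error of class `bs_bottom_lost` when no benthic peak is
#'   detectable (the bottom-signal detection limit).
#' @export
segment_waveform <- function(w) {
  stopifnot(inherits(w, "bs_waveform"))
  x <- w$intensities
  n <- length(x)
  if (n < 50) stop("waveform must have at least 50 samples", call. = FALSE)

  noise_floor <- median(x[1:5])
  noise_sd <- sd(x[1:5])
  eps <- 1e-3 * max(max(x) - noise_floor, 1e-12)
  thr_sd <- max(3 * noise_sd, eps)

  # smoothed trace for detection only
  xs <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
  xs[1] <- x[1]; xs[n] <- x[n]

  cand <- which(diff(sign(diff(xs))) < 0) + 1L
  cand <- cand[xs[cand] > noise_floor + thr_sd]
  prominence <- function(i) {
    lj <- i
    while (lj > 1 && xs[lj] <= xs[i]) lj <- lj - 1L
    left_min <- min(xs[lj:i])
    rj <- i
    while (rj < n && xs[rj] <= xs[i]) rj <- rj + 1L
    right_min <- min(xs[i:rj])
    xs[i] - max(left_min, right_min)
  }
  peaks <- cand[vapply(cand, prominence, numeric(1)) >= thr_sd]
  if (length(peaks) < 2) {
    stop(structure(class = c("bs_bottom_lost", "error", "condition"),
                   list(message = "bottom signal lost: no benthic peak detected",
                        call = NULL)))
  }
  s <- peaks[1]
  b <- peaks[length(peaks)]

  # surface interval: enclosing region where the trace exceeds 10% of the
  # surface amplitude above the noise floor
  lvl <- noise_floor + 0.1 * (x[s] - noise_floor)
  s1 <- s; while (s1 > 1 && x[s1 - 1] > lvl) s1 <- s1 - 1L
  s2 <- s; while (s2 < b && x[s2 + 1] > lvl && (s2 + 1) < b) {
    s2 <- s2 + 1L
    if (xs[s2] > xs[s2 - 1]) { s2 <- s2 - 1L; break }  # rising again
  }

  # benthic start: last return to the noise floor before the benthic peak
  # (the onset of the benthic rise); if the return rides on an elevated
  # column that never reaches the floor, the trough between the peaks
  below <- if (b - s2 > 1) {
    which(xs[(s2 + 1):(b - 1)] <= noise_floor + thr_sd)
  } else integer(0)
  m <- if (length(below) > 0) s2 + max(below)
       else if (b - s2 > 1) s2 + which.min(xs[(s2 + 1):(b - 1)])
       else s2 + 1L

  # benthic end: return to the noise floor (smoothed trace at or below the
  # pre-surface median) or trace end; the interval is widened to at least 10
  # samples so decile statistics are always defined
  e <- b
  while (e < n && xs[e + 1] > noise_floor + eps) e <- e + 1L
  if (e - m < 9) e <- min(n, m + 9L)
  if (e - m < 9) m <- max(s2 + 1L, e - 9L)

  # column: straight-line fit from surface end to trough; residual breakout
  # marks the onset of the benthic rise
  col_end <- m
  if (m - s2 >= 6) {
    ci <- s2:m
    nfit <- max(4, floor(0.6 * length(ci)))
    fit_i <- ci[seq_len(nfit)]
    cf <- stats::lsfit(fit_i, x[fit_i])$coefficients
    resid_all <- x[ci] - (cf[1] + cf[2] * ci)
    sig <- max(sd(resid_all[seq_len(nfit)]), eps)
    out <- which(resid_all > 3 * sig)
    out <- out[out > 1 & out < length(ci)]
    brk <- NA_integer_
    for (j in out) {
      if (j + 1 <= length(ci) && resid_all[j + 1] > 3 * sig) { brk <- j; break }
    }
    if (!is.na(brk)) col_end <- ci[brk]
  }
  if (col_end > m - 3) col_end <- max(s2 + 1L, m - 3L)

  structure(list(surface = c(s1, s2),
                 column = c(s2, col_end),
                 transition = c(col_end, m),
                 benthic = c(m, e),
                 noise_floor = noise_floor,
                 noise_sd = noise_sd),
            class = "bs_segments")
}

#' Benthic-return statistics
#'
#' The 12 statistics of the benthic interval: moments of the empirical
#' distribution of intensity samples (mean, variance, skewness, kurtosis),
#' median, mean absolute deviation, minimum, maximum, trapezoidal area under
#' the curve, intensity range (max - min), time range (ns between the global
#' maximum and global minimum of the interval), and the decile Shannon index
#' [decile_shannon()].
#'
#' @param seg segments from [segment_waveform()].
#' @param w the waveform the segments came from.
#' @return Named numeric vector of 12 values (see [waveform_feature_names()]).
#' @export
benthic_statistics <- function(seg, w) {
  idx <- seg$benthic[1]:seg$benthic[2]
  y <- w$intensities[idx]
  tt <- w$t0 + (idx - 1) * w$dt
  ms <- moment_stats(y)
  c(b_mean = unname(ms["mean"]), b_var = unname(ms["var"]),
    b_skew = unname(ms["skew"]), b_kurt = unname(ms["kurt"]),
    b_median = median(y), b_mad = mean(abs(y - mean(y))),
    b_min = min(y), b_max = max(y),
    b_auc = trapezoid(tt, y),
    b_irange = max(y) - min(y),
    b_trange = abs(tt[which.max(y)] - tt[which.min(y)]),
    b_hdec = decile_shannon(y))
}

#' Decile Shannon index of benthic intensities
#'
#' The ten deciles (10th to 100th percentiles, linear interpolation between
#' order statistics) of the benthic intensity samples are normalized to
#' proportions and their Shannon entropy returned: identical deciles give
#' ln(10), a single dominating decile tends to 0.
#'
#' @param y benthic intensity samples (>= 10 values, not all zero).
#' @return H'dec in \[0, ln 10\].
#' @export
decile_shannon <- function(y) {
  if (length(y) < 10) stop("need at least 10 samples", call. = FALSE)
  q <- quantile(y, probs = seq(0.1, 1, by = 0.1), names = FALSE, type = 7)
  tot <- sum(q)
  if (tot <= 0) stop("decile Shannon undefined for all-zero intensities",
                     call. = FALSE)
  p <- q / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Transition-waveform statistics
#'
#' Mean, variance, skewness and kurtosis of the intensity samples between
#' water-column end and benthic start.
#'
#' @inheritParams benthic_statistics
#' @return Named numeric vector of 4 values.
#' @export
transition_statistics <- function(seg, w) {
  y <- w$intensities[seg$transition[1]:seg$transition[2]]
  ms <- moment_stats(y)
  c(t_mean = unname(ms["mean"]), t_var = unname(ms["var"]),
    t_skew = unname(ms["skew"]), t_kurt = unname(ms["kurt"]))
}

#' Extract the per-sounding waveform feature table
#'
#' Segments every waveform and computes the 16 statistics; soundings whose
#' bottom signal is lost are excluded and counted (attribute `n_lost`, plus a
#' message when any are dropped).
#'
#' @param waveforms list of `bs_waveform` objects.
#' @param depths optional numeric vector of per-sounding mean bathymetry (m).
#' @return Data.frame with `sounding_id`, `depth`, and the 16 feature
#'   columns in [waveform_feature_names()] order; attribute `n_lost` counts
#'   excluded soundings.
#' @export
extract_feature_table <- function(waveforms, depths = NULL) {
  nm <- waveform_feature_names()
  if (length(waveforms) == 0) {
    out <- cbind(data.frame(sounding_id = character(0), depth = numeric(0)),
                 as.data.frame(matrix(numeric(0), 0, 16,
                                      dimnames = list(NULL, nm))))
    attr(out, "n_lost") <- 0L
    return(out)
  }
  if (is.null(depths)) depths <- rep(NA_real_, length(waveforms))
  rows <- vector("list", length(waveforms))
  lost <- 0L
  for (i in seq_along(waveforms)) {
    w <- waveforms[[i]]
    seg <- tryCatch(segment_waveform(w), bs_bottom_lost = function(e) NULL)
    if (is.null(seg)) { lost <- lost + 1L; next }
    rows[[i]] <- c(benthic_statistics(seg, w), transition_statistics(seg, w))
  }
  keep <- !vapply(rows, is.null, logical(1))
  feat <- do.call(rbind, rows[keep])
  out <- cbind(
    data.frame(
      sounding_id = vapply(waveforms[keep], function(w) as.character(w$sounding_id),
                           character(1)),
      depth = depths[keep], stringsAsFactors = FALSE),
    as.data.frame(feat)[nm])
  rownames(out) <- NULL
  attr(out, "n_lost") <- lost
  if (lost > 0) message(lost, " sounding(s) excluded: bottom signal lost")
  out
}

#' Remove the depth trend from waveform features
#'
#' Each feature is regressed on depth with a second-degree polynomial
#' (ordinary least squares) and replaced by its standardized residual, so the
#' remaining variation reflects bottom character rather than water depth.
#' Features whose residual variance vanishes (e.g. exactly quadratic in
#' depth) become all-zero columns.
#'
#' @param features table from [extract_feature_table()] (needs a `depth`
#'   column).
#' @param feature_cols columns to normalize; defaults to the 16 standard
#'   features present in the table.
#' @return The table with feature columns replaced by standardized residuals.
#' @export
depth_normalize <- function(features,
                            feature_cols = intersect(waveform_feature_names(),
                                                     names(features))) {
  stopifnot("depth" %in% names(features))
  d <- features$depth
  out <- features
  for (cl in feature_cols) {
    f <- features[[cl]]
    r <- stats::residuals(lm(f ~ d + I(d^2)))
    s <- sd(r)
    out[[cl]] <- if (is.na(s) || s < 1e-12) rep(0, length(f)) else r / s
  }
  out
}

#' PCA reduction of the residual feature table
#'
#' Principal components of the (centered) residual features, ordered by
#' eigenvalue; the smallest leading set whose cumulative variance fraction
#' reaches `variance_kept` is retained.
#'
#' @param residuals table from [depth_normalize()] (or any data.frame whose
#'   numeric feature columns should be reduced).
#' @param variance_kept fraction of total variance to keep (default 0.95).
#' @param feature_cols columns entering the PCA.
#' @return Data.frame of PC scores (`PC1`, `PC2`, ...; id/depth columns are
#'   carried through), with attributes `rotation`, `center`, `sdev` and
#'   `n_kept` so new soundings can be projected.
#' @export
pca_reduce <- function(residuals, variance_kept = 0.95,
                       feature_cols = intersect(waveform_feature_names(),
                                                names(residuals))) {
  x <- as.matrix(residuals[feature_cols])
  keep_cols <- apply(x, 2, function(v) sd(v) > 0)
  p <- prcomp(x[, keep_cols, drop = FALSE], center = TRUE, scale. = FALSE)
  vfrac <- cumsum(p$sdev^2) / sum(p$sdev^2)
  m <- which(vfrac >= variance_kept)[1]
  scores <- as.data.frame(p$x[, seq_len(m), drop = FALSE])
  meta <- residuals[setdiff(names(residuals), feature_cols)]
  out <- cbind(meta, scores)
  attr(out, "rotation") <- p$rotation[, seq_len(m), drop = FALSE]
  attr(out, "center") <- p$center
  attr(out, "sdev") <- p$sdev
  attr(out, "n_kept") <- m
  attr(out, "feature_cols") <- feature_cols[keep_cols]
  out
}

#' Project new residual features onto retained principal components
#'
#' @param pcs output of [pca_reduce()].
#' @param newdata data.frame containing the same feature columns.
#' @return Matrix of PC scores for `newdata`.
#' @export
pca_project <- function(pcs, newdata) {
  rot <- attr(pcs, "rotation")
  ctr <- attr(pcs, "center")
  cols <- attr(pcs, "feature_cols")
  x <- as.matrix(newdata[cols])
  sweep(x, 2, ctr) %*% rot
}
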