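# RReliefF feature scoring and negative-score elimination.
#
# The regression Relief estimator weighs each feature by how much its
# differences co-occur with target differences among nearest neighbors:
#   W[f] = P(diff f | diff y, near) adjusted as
#        = NdCdF[f]/NdC - (NdF[f] - NdCdF[f]) / (m - NdC)
# with "difference" the range-normalized absolute difference and neighbor
# contributions weighted by exp(-(rank/sigma)^2), normalized over the k
# nearest neighbors (Manhattan distance on range-scaled features).

#' RReliefF feature scores for a continuous target
#'
#' Every instance is used as an anchor in deterministic order (optionally a
#' seeded random subset via `m_anchors`); its `k` nearest neighbors by
#' Manhattan distance on range-scaled features contribute with
#' distance-rank weights `exp(-(rank/sigma)^2)` normalized to sum 1.
#'
#' @param x Numeric matrix or data frame of features (instances x features),
#'   typically z-scored; no missing values.
#' @param y Numeric target, length `nrow(x)`.
#' @param k Neighbor count (default 10).
#' @param sigma Rank-decay scale (default 50).
#' @param m_anchors Number of random anchor instances; `NULL` (default) uses
#'   all instances deterministically.
#' @param seed Seed for anchor sampling when `m_anchors` is given.
#' @param target,phase Optional labels stored with the scores.
#' @return A `rrelieff_scores` tibble: `feature`, `weight`; attributes `k`,
#'   `sigma`, `target`, `phase`.
#' @export
rrelieff <- function(x, y, k = 10, sigma = 50, m_anchors = NULL, seed = 1L,
                     target = NA_character_, phase = NA_character_) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); f <- ncol(x)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (length(y) != n) stop("y length must match nrow(x)", call. = FALSE)
  if (n <= k) stop(sprintf("need more than k = %d instances, got %d", k, n), call. = FALSE)

  feat_names <- colnames(x)
  if (is.null(feat_names)) feat_names <- paste0("f", seq_len(f))

  rng_f <- apply(x, 2, function(v) diff(range(v)))
  rng_y <- diff(range(y))
  if (rng_y == 0) {
    warning("constant target: all RReliefF weights are 0", call. = FALSE)
    return(new_rrelieff_scores(feat_names, rep(0, f), k, sigma, target, phase))
  }
  scale_f <- ifelse(rng_f == 0, 1, rng_f)
  xs <- sweep(x, 2, scale_f, "/")      # range-scaled features
  ys <- y / rng_y

  anchors <- seq_len(n)
  if (!is.null(m_anchors)) {
    anchors <- with_local_seed(seed, sort(sample.int(n, min(m_anchors, n))))
  }
  m <- length(anchors)

  rank_w <- exp(-(seq_len(k) / sigma)^2)
  n_dc <- 0
  n_df <- numeric(f)
  n_dcdf <- numeric(f)
  # precompute the full Manhattan distance matrix when it fits comfortably
  D <- NULL
  if (n <= 2000) {
    D <- matrix(0, n, n)
    for (j in seq_len(f)) D <- D + abs(outer(xs[, j], xs[, j], "-"))
  }
  for (i in anchors) {
    d <- if (is.null(D)) colSums(abs(t(xs) - xs[i, ])) else D[, i]
    d[i] <- Inf
    nb <- order(d)[seq_len(k)]           # stable tie-break: by index
    w <- rank_w / sum(rank_w)
    dy <- abs(ys[nb] - ys[i])
    dfm <- abs(xs[nb, , drop = FALSE] -
                 matrix(xs[i, ], nrow = k, ncol = f, byrow = TRUE))
    n_dc <- n_dc + sum(w * dy)
    n_df <- n_df + colSums(w * dfm)
    n_dcdf <- n_dcdf + colSums((w * dy) * dfm)
  }
  if (n_dc == 0 || n_dc >= m) {
    warning("degenerate target differences: weights set to 0", call. = FALSE)
    return(new_rrelieff_scores(feat_names, rep(0, f), k, sigma, target, phase))
  }
  weight <- n_dcdf / n_dc - (n_df - n_dcdf) / (m - n_dc)
  new_rrelieff_scores(feat_names, weight, k, sigma, target, phase)
}

new_rrelieff_scores <- function(feature, weight, k, sigma, target, phase) {
  out <- tibble::tibble(feature = feature, weight = unname(weight))
  attr(out, "k") <- k
  attr(out, "sigma") <- sigma
  attr(out, "target") <- target
  attr(out, "phase") <- phase
  class(out) <- c("rrelieff_scores", class(out))
  out
}

#' Eliminate negative-score features
#'
#' Keeps features whose RReliefF weight is non-negative (zero weights are
#' kept: elimination is strictly of negative scores).
#'
#' @param scores A [rrelieff()] result (or tibble with `feature`, `weight`).
#' @return Character vector of retained feature names, with the logical
#'   keep mask as attribute `"mask"`. Errors if every score is negative.
#' @export
select_nonnegative <- function(scores) {
  mask <- scores$weight >= 0
  if (!any(mask)) {
    stop("degenerate selection: all feature scores are negative", call. = FALSE)
  }
  out <- scores$feature[mask]
  attr(out, "mask") <- mask
  out
}

#' Score features per phase and target
#'
#' Convenience wrapper mirroring the per-phase, per-target scoring layout:
#' z-scores the features within each phase and runs [rrelieff()] against the
#' chosen reference-BP target.
#'
#' @param features Feature table from [extract_beat_features()].
#' @param target `"sbp"` or `"dbp"`.
#' @param k,sigma Passed to [rrelieff()].
#' @return Tibble with `phase`, `feature`, `weight`.
#' @export
score_features_by_phase <- function(features, target = c("sbp", "dbp"),
                                    k = 10, sigma = 50) {
  target <- match.arg(target)
  ycol <- paste0(target, "_ref")
  purrr::map_dfr(split(features, features$phase), function(fp) {
    st <- zscore_fit(fp)
    fp_z <- suppressWarnings(zscore_apply(fp, st))
    cols <- intersect(feature_names(), names(fp_z))
    sc <- rrelieff(as.matrix(fp_z[, cols]), fp_z[[ycol]], k = k, sigma = sigma,
                   target = target, phase = fp$phase[1])
    tibble::tibble(phase = fp$phase[1], feature = sc$feature, weight = sc$weight)
  })
}
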