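# Feature-level quality control, replicate summarization, transformation and
# imputation.
#
# Filters follow standard untargeted-HRM practice: a feature is kept when
# fewer than 30% of samples are missing (a sample counts as missing only when
# all three replicate injections are absent), the median across-sample
# coefficient of variation among technical replicates is < 30%, and the
# median replicate-pair Pearson correlation is > 0.7. Retained features are
# median-summarized over replicates, log2 transformed, per-batch median
# centered, auto-scaled and kNN-imputed (k = 10).

#' Default QC thresholds
#'
#' @param max_missing_frac Maximum sample-level missing fraction (exclusive).
#' @param max_median_cv Maximum median replicate CV (exclusive).
#' @param min_median_pearson Minimum median replicate-pair Pearson
#'   correlation (exclusive).
#' @param knn_k Number of neighbours for kNN imputation.
#' @return list of thresholds.
#' @export
qc_thresholds <- function(max_missing_frac = 0.30, max_median_cv = 0.30,
                          min_median_pearson = 0.70, knn_k = 10L) {
  stopifnot(max_missing_frac > 0, max_missing_frac <= 1, knn_k >= 1)
  list(max_missing_frac = max_missing_frac, max_median_cv = max_median_cv,
       min_median_pearson = min_median_pearson, knn_k = as.integer(knn_k))
}

# features x samples x 3 array of replicate intensities
replicate_array <- function(table) {
  idx <- replicate_index(table)
  a <- array(NA_real_, dim = c(nrow(table$features), nrow(idx), 3),
             dimnames = list(table$features$feature_id, rownames(idx), NULL))
  for (r in 1:3) a[, , r] <- table$intensities[, idx[, r], drop = FALSE]
  a
}

row_mins <- function(x) {
  x0 <- x
  x0[is.na(x)] <- Inf
  out <- do.call(pmin, as.data.frame(x0))
  out[is.infinite(out)] <- NA_real_
  out
}

# row medians tolerating NAs, via a single row-wise sort (NAs last)
row_medians <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  n_obs <- rowSums(!is.na(x))
  s <- matrix(x[order(row(x), x, na.last = TRUE)],
              nrow(x), ncol(x), byrow = TRUE)
  lo <- (n_obs + 1L) %/% 2L
  hi <- n_obs %/% 2L + 1L
  out <- rep(NA_real_, nrow(x))
  ok <- n_obs > 0
  i <- which(ok)
  out[ok] <- (s[cbind(i, lo[ok])] + s[cbind(i, hi[ok])]) / 2
  out
}

#' Per-sample replicate coefficients of variation for one feature
#'
#' CV is sd/mean of the observed raw replicate intensities of a sample,
#' using the sample (n-1) standard deviation; samples with fewer than two
#' observed replicates are skipped (NA).
#'
#' @param table A `feature_table`.
#' @param feature_id Feature identifier.
#' @return list with `cv` (per-sample vector) and `median_cv` (NA when no
#'   sample has >= 2 observed replicates).
#' @export
replicate_cv <- function(table, feature_id) {
  i <- match(feature_id, table$features$feature_id)
  if (is.na(i)) stop("unknown feature: ", feature_id)
  cvm <- feature_cv_matrix(table, rows = i)
  cv <- cvm[1, ]
  list(cv = cv, median_cv = stats::median(cv, na.rm = TRUE))
}

# vectorized per-sample CVs: features x samples matrix
feature_cv_matrix <- function(table, rows = NULL, a = replicate_array(table)) {
  if (!is.null(rows)) a <- a[rows, , , drop = FALSE]
  obs <- !is.na(a)
  n <- obs[, , 1] + obs[, , 2] + obs[, , 3]
  a0 <- a; a0[!obs] <- 0
  s1 <- a0[, , 1] + a0[, , 2] + a0[, , 3]
  s2 <- a0[, , 1]^2 + a0[, , 2]^2 + a0[, , 3]^2
  mean_ <- s1 / n
  var_ <- (s2 - n * mean_^2) / (n - 1)
  var_[var_ < 0] <- 0  # numerical guard
  cv <- sqrt(var_) / mean_
  cv[n < 2] <- NA_real_
  if (is.null(dim(cv))) cv <- matrix(cv, nrow = dim(a)[1])
  cv
}

#' Median replicate-pair Pearson correlation for one feature
#'
#' For each of the three replicate pairs (1-2, 1-3, 2-3) the Pearson
#' correlation is computed across samples, using samples where both members
#' of the pair are observed; the median of the three pair correlations is
#' returned. Fewer than 3 usable samples for a pair makes that pair NA.
#'
#' @inheritParams replicate_cv
#' @return list with `pair_r` (length 3) and `median_r`.
#' @export
replicate_pearson <- function(table, feature_id) {
  i <- match(feature_id, table$features$feature_id)
  if (is.na(i)) stop("unknown feature: ", feature_id)
  pm <- feature_pearson_matrix(table, rows = i)
  list(pair_r = pm$pairs[1, ], median_r = pm$median[1])
}

feature_pearson_matrix <- function(table, rows = NULL,
                                   a = replicate_array(table)) {
  if (!is.null(rows)) a <- a[rows, , , drop = FALSE]
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  out <- matrix(NA_real_, dim(a)[1], 3)
  for (pi in seq_along(pairs)) {
    x <- a[, , pairs[[pi]][1], drop = FALSE][, , 1, drop = TRUE]
    y <- a[, , pairs[[pi]][2], drop = FALSE][, , 1, drop = TRUE]
    if (is.null(dim(x))) { x <- matrix(x, 1); y <- matrix(y, 1) }
    ok <- !is.na(x) & !is.na(y)
    x0 <- ifelse(ok, x, 0); y0 <- ifelse(ok, y, 0)
    n <- rowSums(ok)
    sx <- rowSums(x0); sy <- rowSums(y0)
    sxx <- rowSums(x0^2); syy <- rowSums(y0^2); sxy <- rowSums(x0 * y0)
    num <- sxy - sx * sy / n
    den <- sqrt(pmax(sxx - sx^2 / n, 0) * pmax(syy - sy^2 / n, 0))
    r <- num / den
    r[n < 3 | den == 0] <- NA_real_
    out[, pi] <- r
  }
  list(pairs = out, median = row_medians(out))
}

#' Apply feature-level QC filters
#'
#' Retains features with sample-level missing fraction below
#' `max_missing_frac`, median replicate CV below `max_median_cv` and median
#' replicate Pearson correlation above `min_median_pearson` (all strict
#' inequalities). Features with undefined CV or Pearson fail QC.
#'
#' @param table A `feature_table`.
#' @param thresholds A [qc_thresholds] list.
#' @return list with `table` (filtered) and `report` (per-feature metrics,
#'   pass flag and comma-joined rejection reasons).
#' @export
apply_qc <- function(table, thresholds = qc_thresholds()) {
  nf <- nrow(table$features)
  if (nf == 0L) {
    return(list(table = table,
                report = data.frame(feature_id = character(),
                                    missing_frac = numeric(),
                                    median_cv = numeric(),
                                    median_pearson = numeric(),
                                    pass = logical(), reason = character())))
  }
  a <- replicate_array(table)
  all_absent <- is.na(a[, , 1, drop = FALSE]) &
    is.na(a[, , 2, drop = FALSE]) & is.na(a[, , 3, drop = FALSE])
  missing_frac <- rowMeans(all_absent[, , 1, drop = FALSE])
  cvm <- feature_cv_matrix(table, a = a)
  if (is.null(dim(cvm))) cvm <- matrix(cvm, nrow = nf)
  median_cv <- row_medians(cvm)
  median_pearson <- feature_pearson_matrix(table, a = a)$median

  fail_miss <- missing_frac >= thresholds$max_missing_frac
  fail_cv <- is.na(median_cv) | median_cv >= thresholds$max_median_cv
  fail_r <- is.na(median_pearson) |
    median_pearson <= thresholds$min_median_pearson
  pass <- !fail_miss & !fail_cv & !fail_r
  reason <- vapply(seq_len(nf), function(i) {
    paste(c(if (fail_miss[i]) "missing",
            if (fail_cv[i]) "cv",
            if (fail_r[i]) "pearson"), collapse = ",")
  }, "")
  report <- data.frame(feature_id = table$features$feature_id,
                       missing_frac = missing_frac, median_cv = median_cv,
                       median_pearson = median_pearson, pass = pass,
                       reason = reason, stringsAsFactors = FALSE)
  keep <- which(pass)
  out <- table
  out$features <- table$features[keep, , drop = FALSE]
  rownames(out$features) <- NULL
  out$intensities <- table$intensities[keep, , drop = FALSE]
  list(table = out, report = report)
}

#' Summarize triplicate injections to a sample-level matrix
#'
#' Per (feature, sample): median of the observed replicates; NA when all
#' three are absent.
#'
#' @param table A `feature_table`.
#' @return list of class `sample_matrix` with `features`, `sample_id`,
#'   `batch` (one per sample) and `intensities` (features x samples).
#' @export
summarize_replicates <- function(table) {
  a <- replicate_array(table)
  flat <- cbind(as.vector(a[, , 1]), as.vector(a[, , 2]),
                as.vector(a[, , 3]))
  m <- matrix(row_medians(flat), dim(a)[1], dim(a)[2])
  sids <- table_samples(table)
  batch <- table$injections$batch[match(sids, table$injections$sample_id)]
  dimnames(m) <- list(table$features$feature_id, sids)
  structure(list(features = table$features, sample_id = sids,
                 batch = batch, intensities = m),
            class = "sample_matrix")
}

#' Log2 transform, per-batch median centering and auto-scaling
#'
#' Zero intensities are replaced by half the smallest positive observed
#' intensity of the feature before log2 (half-minimum substitution). After
#' log2, the per-batch median (over observed entries) is subtracted per
#' feature, then each feature is standardized to mean 0, sd 1 over observed
#' entries. Features that are constant after centering are dropped.
#'
#' @param sm A `sample_matrix` (see [summarize_replicates]).
#' @return list with `scaled` (sample_matrix of auto-scaled values),
#'   `centered` (sample_matrix of log2 batch-centered values, pre-scaling),
#'   `center` and `scale` (per-feature mean/sd used), and `dropped`
#'   (feature ids removed as constant).
#' @export
log2_batch_center_autoscale <- function(sm) {
  m <- sm$intensities
  if (any(m < 0, na.rm = TRUE)) stop("negative intensity before log2")
  if (any(m == 0, na.rm = TRUE)) {
    mpos <- m
    mpos[!is.na(m) & m == 0] <- NA_real_
    half_min <- row_mins(mpos) / 2
    zero <- which(!is.na(m) & m == 0, arr.ind = TRUE)
    m[zero] <- half_min[zero[, 1]]  # NA when the feature is all-zero
  }
  lg <- log2(m)
  for (b in unique(sm$batch)) {
    cols <- which(sm$batch == b)
    med <- row_medians(lg[, cols, drop = FALSE])
    lg[, cols] <- lg[, cols, drop = FALSE] - med
  }
  n_obs <- rowSums(!is.na(lg))
  lg0 <- lg; lg0[is.na(lg)] <- 0
  mu <- rowSums(lg0) / n_obs
  sd_ <- sqrt(pmax(rowSums(lg0^2) - n_obs * mu^2, 0) / (n_obs - 1))
  sd_[n_obs < 2] <- NA_real_
  keep <- which(!is.na(sd_) & sd_ > 0)
  dropped <- sm$features$feature_id[setdiff(seq_len(nrow(lg)), keep)]
  lg <- lg[keep, , drop = FALSE]
  scaled <- (lg - mu[keep]) / sd_[keep]
  feats <- sm$features[keep, , drop = FALSE]
  rownames(feats) <- NULL
  mk <- function(x) structure(list(features = feats,
                                   sample_id = sm$sample_id,
                                   batch = sm$batch, intensities = x),
                              class = "sample_matrix")
  list(scaled = mk(scaled), centered = mk(lg),
       center = mu[keep], scale = sd_[keep], dropped = dropped)
}

#' k-nearest-neighbour imputation in feature space
#'
#' For a feature f missing at sample s, candidate neighbours are features
#' observed at s sharing at least one co-observed sample with f. The
#' distance is the Euclidean distance over co-observed samples divided by
#' the square root of their count; the imputed value is the
#' inverse-distance-weighted mean of the k nearest candidates' values at s.
#' A zero-distance candidate is used directly. With no candidates the
#' feature mean (0 after auto-scaling) is used and a warning is issued.
#' Observed entries are never altered.
#'
#' @param x features x samples numeric matrix with NAs (auto-scaled).
#' @param k Number of neighbours (default 10).
#' @return Complete matrix of the same shape.
#' @export
knn_impute <- function(x, k = 10L) {
  stopifnot(is.matrix(x), k >= 1)
  if (!anyNA(x)) return(x)
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0
  rows_missing <- which(rowSums(!obs) > 0)
  mode(obs) <- "numeric"
  # sum over co-observed samples of (x_i - x_j)^2, computed by masked
  # crossproducts; n_co = number of co-observed samples
  xm <- x0[rows_missing, , drop = FALSE]
  om <- obs[rows_missing, , drop = FALSE]
  s_xy <- xm %*% t(x0)
  s_xx <- (xm^2) %*% t(obs)
  s_yy <- om %*% t(x0^2)
  n_co <- om %*% t(obs)
  d2 <- (s_xx + s_yy - 2 * s_xy) / n_co
  d2[n_co == 0] <- Inf
  d2[d2 < 0] <- 0
  out <- x
  any_mean_fallback <- FALSE
  feat_means <- rowSums(x0) / pmax(rowSums(obs), 1)
  for (ri in seq_along(rows_missing)) {
    f <- rows_missing[ri]
    d <- sqrt(d2[ri, ])
    d[f] <- Inf  # not its own neighbour
    ord <- order(d)
    ord <- ord[is.finite(d[ord])]
    for (s in which(is.na(x[f, ]))) {
      cand <- ord[obs[ord, s] == 1]
      if (!length(cand)) {
        out[f, s] <- feat_means[f]
        any_mean_fallback <- TRUE
        next
      }
      use <- cand[seq_len(min(k, length(cand)))]
      du <- d[use]
      if (any(du == 0)) {
        out[f, s] <- mean(x[use[du == 0], s])
      } else {
        w <- 1 / du
        out[f, s] <- sum(w * x[use, s]) / sum(w)
      }
    }
  }
  if (any_mean_fallback) {
    warning("knn_impute: no candidate neighbours for some entries; ",
            "feature mean used")
  }
  out
}
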