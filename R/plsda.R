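# PLS-DA via NIPALS PLS1 on a centered class indicator, VIP scoring and
# discriminative-feature selection.
#
# PLS1 with a single centered y column gives the same discriminant
# direction as two-class PLS-DA with a dummy Y matrix while avoiding the
# dummy-coding ambiguity. Weight vectors are sign-fixed so that each score
# vector correlates non-negatively with y, making output stable across
# runs.

#' Fit PLS-DA (NIPALS PLS1)
#'
#' For components a = 1..A on the deflated matrices:
#' `w_a = X'y / ||X'y||`, `t_a = X w_a`, `p_a = X't_a / (t_a't_a)`,
#' `b_a = y't_a / (t_a't_a)`, then `X <- X - t_a p_a'` and
#' `y <- y - b_a t_a`. The explained-Y sum of squares of component a is
#' `SSY_a = b_a^2 (t_a't_a)`.
#'
#' @param X samples x features complete matrix (columns = features). X and
#'   y are centered internally.
#' @param y Binary class vector (smoker indicator), both classes present.
#' @param A Number of components (default 2).
#' @return `plsda_model` list: `W`, `P` (features x A), `Tm` (scores,
#'   samples x A), `b`, `ssy`, `x_var_explained`, `feature_ids`, `y_centered`.
#' @export
fit_plsda <- function(X, y, A = 2L) {
  stopifnot(is.matrix(X), !anyNA(X))
  y <- as.numeric(y)
  if (length(unique(y)) != 2L) stop("y must contain exactly two classes")
  if (A >= min(dim(X))) stop("A must be below rank of X")
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  y0 <- yc
  totSSX <- sum(Xc^2)
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  b <- ssy <- xvar <- numeric(A)
  Xa <- Xc; ya <- yc
  for (a in seq_len(A)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("degenerate component ", a, ": X'y is zero")
    w <- w / nw
    t_ <- Xa %*% w
    tt <- sum(t_^2)
    p_ <- crossprod(Xa, t_) / tt
    b_ <- sum(ya * t_) / tt
    # sign convention: score correlates non-negatively with the original y
    if (sum(t_ * y0) < 0) {
      w <- -w; t_ <- -t_; p_ <- -p_; b_ <- -b_
    }
    W[, a] <- w; Tm[, a] <- t_; P[, a] <- p_
    b[a] <- b_
    ssy[a] <- b_^2 * tt
    xvar[a] <- tt * sum(p_^2) / totSSX
    Xa <- Xa - tcrossprod(t_, p_)
    ya <- ya - b_ * t_
  }
  structure(list(W = W, P = P, Tm = Tm, b = b, ssy = ssy,
                 x_var_explained = xvar,
                 feature_ids = colnames(X), sample_ids = rownames(X),
                 y_centered = yc, A = A),
            class = "plsda_model")
}

#' Variable Importance in Projection
#'
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )` with p the number
#' of features and unit-norm weight vectors, so that `sum_j VIP_j^2 = p`.
#'
#' @param model A fitted [fit_plsda] model.
#' @return Named numeric vector of per-feature VIP scores.
#' @export
vip <- function(model) {
  if (all(model$ssy == 0)) stop("all components explain zero Y variance")
  p <- nrow(model$W)
  num <- (model$W^2) %*% model$ssy
  v <- sqrt(p * num / sum(model$ssy))
  stats::setNames(as.numeric(v), model$feature_ids)
}

#' Select discriminative features by VIP cutoff and compute fold changes
#'
#' Fold change is `2^(mean_smokers - mean_nonsmokers)` of the
#' covariate-adjusted log2-scale intensity of the feature.
#'
#' @param model A fitted [fit_plsda] model.
#' @param adjusted_log2 features x samples matrix of covariate-adjusted
#'   log2-scale intensities (pre-auto-scaling back-mapped), rownames =
#'   feature ids.
#' @param smoker Logical vector aligned to the matrix columns.
#' @param vip_cutoff Selection threshold (default 2).
#' @return data.frame: `feature_id`, `vip`, `selected`, `fold_change`.
#' @export
select_features <- function(model, adjusted_log2, smoker, vip_cutoff = 2) {
  v <- vip(model)
  fc <- fold_change(adjusted_log2, smoker)
  data.frame(feature_id = names(v), vip = as.numeric(v),
             selected = as.numeric(v) >= vip_cutoff,
             fold_change = as.numeric(fc[names(v)]),
             stringsAsFactors = FALSE)
}

#' Per-feature fold change between smokers and non-smokers
#'
#' @param adjusted_log2 features x samples matrix of adjusted log2-scale
#'   intensities.
#' @param smoker Logical vector aligned to columns.
#' @return Named vector of `2^(mean difference)` fold changes.
#' @export
fold_change <- function(adjusted_log2, smoker) {
  smoker <- as.logical(smoker)
  if (!any(smoker) || all(smoker)) stop("both classes must be present")
  d <- rowMeans(adjusted_log2[, smoker, drop = FALSE]) -
    rowMeans(adjusted_log2[, !smoker, drop = FALSE])
  2^d
}

#' Score-plot table with 95% confidence ellipses
#'
#' Exports the first two score vectors per sample with class labels, plus
#' per-class ellipse parameters (mean, covariance of scores, chi-squared
#' 95% radius on 2 df).
#'
#' @param model A fitted [fit_plsda] model with `A >= 2`.
#' @param smoker Logical class vector aligned to samples.
#' @return list with `scores` data.frame and `ellipses` list.
#' @export
export_scores <- function(model, smoker) {
  if (model$A < 2L) stop("need at least 2 components for a score plot")
  sc <- data.frame(sample_id = model$sample_ids %||%
                     seq_len(nrow(model$Tm)),
                   t1 = model$Tm[, 1], t2 = model$Tm[, 2],
                   class = ifelse(as.logical(smoker), "smoker",
                                  "non-smoker"),
                   stringsAsFactors = FALSE)
  r2 <- stats::qchisq(0.95, df = 2)
  ellipses <- lapply(split(sc[, c("t1", "t2")], sc$class), function(d) {
    list(center = colMeans(d), cov = stats::cov(d), radius2 = r2)
  })
  list(scores = sc, ellipses = ellipses)
}

#' Plot PLS-DA scores with class ellipses
#' @param scores Output of [export_scores].
#' @param model The fitted model (for axis variance labels).
#' @param file Optional PNG path; plots to the active device otherwise.
#' @export
plot_scores <- function(scores, model, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 700)
    on.exit(grDevices::dev.off())
  }
  sc <- scores$scores
  cls <- factor(sc$class)
  cols <- c("steelblue", "darkorange")[as.integer(cls)]
  graphics::plot(sc$t1, sc$t2, col = cols,
                 pch = c(1, 17)[as.integer(cls)],
                 xlab = sprintf("X-variate 1 (%.1f%%)",
                                100 * model$x_var_explained[1]),
                 ylab = sprintf("X-variate 2 (%.1f%%)",
                                100 * model$x_var_explained[2]))
  th <- seq(0, 2 * pi, length.out = 181)
  for (i in seq_along(scores$ellipses)) {
    e <- scores$ellipses[[i]]
    ch <- chol(e$cov)
    pts <- cbind(cos(th), sin(th)) %*% (ch * sqrt(e$radius2))
    graphics::lines(pts[, 1] + e$center[1], pts[, 2] + e$center[2],
                    col = c("steelblue", "darkorange")[i])
  }
  graphics::legend("topright", legend = levels(cls), col =
                     c("steelblue", "darkorange"), pch = c(1, 17))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
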