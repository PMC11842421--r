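# Per-feature univariate logistic regression of smoking status on adjusted
# intensity, with Benjamini-Hochberg FDR. Confounders enter through the
# prior residualization stage, not as model terms.

#' Univariate logistic regression by IRLS
#'
#' Maximum-likelihood fit of `logit P(y = 1) = alpha + beta x` by
#' iteratively reweighted least squares; convergence when `|delta beta|`
#' falls below `tol` (default 1e-8), at most `max_iter` iterations. Wald p
#' from `beta / se` against the standard normal. A constant `x` returns
#' `beta = 0, p = 1`; (quasi-)perfect separation is flagged and the fit
#' reported with `separation = TRUE` (such rows are excluded from FDR).
#'
#' @param y Binary outcome with both classes present.
#' @param x Finite numeric predictor.
#' @param tol,max_iter IRLS convergence controls.
#' @return list: `beta`, `se`, `p`, `alpha`, `converged`, `separation`.
#' @export
logistic_fit <- function(y, x, tol = 1e-8, max_iter = 100L) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), all(is.finite(x)),
            length(x) == length(y))
  if (length(unique(y)) != 2L) stop("y must contain both classes")
  if (stats::sd(x) == 0) {
    return(list(beta = 0, se = NA_real_, p = 1,
                alpha = stats::qlogis(mean(y)), converged = TRUE,
                separation = FALSE))
  }
  X <- cbind(1, unname(x))
  beta <- c(stats::qlogis(mean(y)), 0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    fit <- solve(XtW %*% X, XtW %*% z)
    delta <- abs(fit[2] - beta[2])
    beta <- unname(drop(fit))
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  cov_ <- solve(t(X * w) %*% X)
  se <- sqrt(cov_[2, 2])
  separation <- !converged || abs(beta[2]) > 1e3 ||
    max(abs(eta)) > 30 && all(round(mu) == y)
  p <- 2 * stats::pnorm(-abs(beta[2] / se))
  list(beta = beta[2], se = se, p = p, alpha = beta[1],
       converged = converged, separation = separation)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_{j >= i} m p_(j) / j`, clipped to 1 and mapped back to the
#' input order.
#'
#' @param p Vector of p-values in `[0, 1]` (NAs passed through).
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values outside [0, 1]")
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m) {
    o <- order(pp)
    qq <- pmin(1, cummin(rev(m * pp[o] / seq_len(m))))
    q[ok][o] <- rev(qq)
  }
  q
}

#' Association testing over selected features
#'
#' Fits [logistic_fit] of smoking status on each selected feature's
#' adjusted intensity and applies [bh_fdr] over the non-separated fits
#' (within the table's single chromatography mode).
#'
#' @param adjusted features x samples matrix (rownames = feature ids).
#' @param smoker Logical vector aligned to columns.
#' @param features Feature metadata data.frame (`feature_id`, `mz`, `rt`,
#'   `mode`).
#' @param feature_ids Features to test (default: all rows of `adjusted`).
#' @return data.frame of association rows sorted as input: `feature_id`,
#'   `mz`, `rt`, `mode`, `beta`, `se`, `p`, `fdr_q`, `direction`,
#'   `separation`.
#' @export
associate_features <- function(adjusted, smoker, features,
                               feature_ids = rownames(adjusted)) {
  y <- as.numeric(as.logical(smoker))
  rows <- lapply(feature_ids, function(fid) {
    fit <- logistic_fit(y, adjusted[fid, ])
    data.frame(feature_id = fid, beta = fit$beta, se = fit$se, p = fit$p,
               separation = fit$separation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  meta <- features[match(out$feature_id, features$feature_id),
                   c("mz", "rt", "mode")]
  out <- cbind(out[1], meta, out[-1])
  out$fdr_q <- NA_real_
  usable <- !out$separation
  out$fdr_q[usable] <- bh_fdr(out$p[usable])
  out$direction <- sign(out$beta)
  rownames(out) <- NULL
  out
}

#' Manhattan-style export
#'
#' Type-2 Manhattan table: retention time against -log10 p with direction
#' sign; the 20 smallest p-values are flagged for labeling and rows at
#' p < 0.001 marked significant.
#'
#' @param rows Association data.frame from [associate_features].
#' @param n_label Number of top features to label (default 20).
#' @param p_signif Significance annotation threshold (default 0.001).
#' @return data.frame with `feature_id`, `mz`, `rt`, `neg_log10_p`,
#'   `direction`, `labeled`, `significant`.
#' @export
manhattan_export <- function(rows, n_label = 20L, p_signif = 1e-3) {
  if (!nrow(rows)) stop("no association rows")
  ord <- order(rows$p)
  labeled <- logical(nrow(rows))
  labeled[ord[seq_len(min(n_label, nrow(rows)))]] <- TRUE
  data.frame(feature_id = rows$feature_id, mz = rows$mz, rt = rows$rt,
             neg_log10_p = -log10(rows$p), direction = rows$direction,
             labeled = labeled, significant = rows$p < p_signif,
             stringsAsFactors = FALSE)
}
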