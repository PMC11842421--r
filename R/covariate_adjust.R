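# Confounder residualization: every metabolite feature (other than the two
# smoking biomarkers) is regressed on maternal race/ethnicity, maternal age
# band, birth-year band, infant sex and neighbourhood SES; downstream
# discovery runs on the OLS residuals.

#' Build the confounder design matrix
#'
#' Treatment (reference-level) indicator coding with an intercept; the first
#' listed level of each factor is the reference. Errors when the design is
#' rank deficient, naming the aliased columns.
#'
#' @param samples Validated sample covariate data.frame.
#' @return numeric matrix, samples x columns.
#' @export
design_matrix <- function(samples) {
  df <- data.frame(
    race = factor(samples$race_ethnicity, levels = RACE_LEVELS),
    age = factor(samples$maternal_age, levels = AGE_LEVELS),
    byear = factor(samples$birth_year_band, levels = BIRTHYEAR_LEVELS),
    sex = factor(samples$sex, levels = SEX_LEVELS),
    ses = factor(samples$ses, levels = SES_LEVELS)
  )
  X <- stats::model.matrix(~ race + age + byear + sex + ses, df)
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    aliased <- colnames(X)[qr_$pivot[(qr_$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  rownames(X) <- samples$sample_id
  X
}

#' Residualize features against confounders
#'
#' Ordinary least squares of each feature (row of `x`) on `design`; the
#' output row is the residual vector. Features listed in `exclude` are
#' passed through untouched and flagged non-discoverable.
#'
#' @param x features x samples complete numeric matrix (rownames =
#'   feature ids).
#' @param design Design matrix from [design_matrix] (samples x columns).
#' @param exclude Character vector of feature ids to pass through.
#' @return list with `residuals` (same shape as `x`) and `excluded`
#'   (feature ids passed through).
#' @export
residualize <- function(x, design, exclude = character()) {
  stopifnot(is.matrix(x), ncol(x) == nrow(design), !anyNA(x))
  qr_ <- qr(design)
  if (qr_$rank < ncol(design)) {
    aliased <- colnames(design)[qr_$pivot[(qr_$rank + 1):ncol(design)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  res <- t(qr.resid(qr_, t(x)))
  excl_idx <- which(rownames(x) %in% exclude)
  if (length(excl_idx)) res[excl_idx, ] <- x[excl_idx, , drop = FALSE]
  dimnames(res) <- dimnames(x)
  list(residuals = res, excluded = rownames(x)[excl_idx])
}
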