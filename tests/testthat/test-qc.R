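test_that("replicate_cv matches hand computations", {
  # samples: (2,2,2) -> 0; (1,2,3) -> sd 1 / mean 2 = 0.5
  vals <- rbind(c(2, 2, 2, 1, 2, 3))
  tab <- make_table(vals)
  out <- replicate_cv(tab, "F001")
  expect_equal(unname(out$cv), c(0, 0.5))
  expect_equal(out$median_cv, 0.25)
  # all samples identical CV c -> median c
  vals2 <- rbind(c(1, 2, 3, 10, 20, 30, 100, 200, 300))
  out2 <- replicate_cv(make_table(vals2), "F001")
  expect_equal(out2$median_cv, 0.5)
  # < 2 observed replicates -> sample skipped
  vals3 <- rbind(c(5, NA, NA, 1, 2, 3))
  out3 <- replicate_cv(make_table(vals3), "F001")
  expect_true(is.na(out3$cv[1]))
  expect_equal(out3$median_cv, 0.5)
})

test_that("replicate_pearson agrees with a brute-force oracle", {
  # identical replicates -> all pair correlations 1
  tru <- matrix(seq(2, 40, length.out = 10), 1)
  out <- replicate_pearson(make_table(triplicate(tru)), "F001")
  expect_equal(unname(out$pair_r), rep(1, 3))
  # anti-correlated pair
  n <- 8
  base <- seq_len(n) * 10
  vals <- numeric(0)
  for (s in seq_len(n)) vals <- c(vals, base[s], 100 - base[s], base[s])
  out2 <- replicate_pearson(make_table(matrix(vals, 1)), "F001")
  expect_equal(unname(out2$pair_r[1]), -1)   # rep1 vs rep2
  expect_equal(unname(out2$pair_r[2]), 1)    # rep1 vs rep3
  # random seeded case with missing entries vs cor() oracle
  set.seed(31)
  a <- matrix(runif(30, 50, 150), 10, 3)
  a[sample(30, 4)] <- NA
  vals3 <- as.vector(t(a))
  out3 <- replicate_pearson(make_table(matrix(vals3, 1)), "F001")
  oracle <- sapply(list(c(1, 2), c(1, 3), c(2, 3)), function(pr) {
    ok <- !is.na(a[, pr[1]]) & !is.na(a[, pr[2]])
    if (sum(ok) < 3) NA_real_ else cor(a[ok, pr[1]], a[ok, pr[2]])
  })
  expect_equal(unname(out3$pair_r), oracle, tolerance = 1e-12)
  expect_equal(out3$median_r, median(oracle, na.rm = TRUE))
})

test_that("apply_qc filters by engineered failure reason", {
  set.seed(5)
  n <- 10
  good <- function() triplicate(matrix(runif(n, 100, 200), 1))
  rows <- list()
  for (i in 1:5) rows[[i]] <- good()
  # fails missing only: 4 of 10 samples fully absent
  r <- good(); r[1, 1:12] <- NA; rows[[6]] <- r
  # fails cv only: replicates (v, 2v, 3v) -> CV 0.5, Pearson 1
  base <- runif(n, 100, 200)
  rows[[7]] <- matrix(rbind(base, 2 * base, 3 * base), 1)
  # fails pearson only: within-sample noise dominates across-sample signal
  base2 <- 1000 + runif(n)
  rows[[8]] <- matrix(rbind(base2 + runif(n, -20, 20),
                            base2 + runif(n, -20, 20),
                            base2 + runif(n, -20, 20)), 1)
  vals <- do.call(rbind, rows)
  tab <- make_table(vals)
  out <- apply_qc(tab)
  expect_equal(sum(out$report$pass), 5)
  expect_equal(out$report$reason[6], "missing")
  expect_equal(out$report$reason[7], "cv")
  expect_equal(out$report$reason[8], "pearson")
  expect_identical(out$table$features$feature_id,
                   sprintf("F%03d", 1:5))
  # vacuous thresholds retain everything
  lax <- qc_thresholds(max_missing_frac = 1.0, max_median_cv = Inf,
                       min_median_pearson = -2)
  expect_true(all(apply_qc(tab, lax)$report$pass))
  # empty table passes through
  empty <- tab
  empty$features <- tab$features[0, ]
  empty$intensities <- tab$intensities[0, , drop = FALSE]
  expect_equal(nrow(apply_qc(empty)$report), 0)
})

test_that("QC report is equivariant under feature permutation", {
  set.seed(8)
  vals <- matrix(runif(10 * 18, 50, 500), 10, 18)
  vals[sample(length(vals), 20)] <- NA
  tab <- make_table(vals)
  perm <- sample(10)
  tab2 <- tab
  tab2$features <- tab$features[perm, ]
  tab2$intensities <- tab$intensities[perm, , drop = FALSE]
  r1 <- apply_qc(tab)$report
  r2 <- apply_qc(tab2)$report
  expect_equal(r2, r1[perm, ], ignore_attr = TRUE)
})

test_that("summarize_replicates takes the median of observed replicates", {
  vals <- rbind(c(1, 2, 4, NA, 3, 5, NA, NA, NA))
  sm <- summarize_replicates(make_table(vals))
  expect_equal(unname(sm$intensities[1, ]), c(2, 4, NA))
})

test_that("log2/batch-centering/auto-scaling identities hold", {
  set.seed(9)
  tru <- matrix(2^runif(40, 8, 15), 4, 10)
  # identical within-batch values, +5 log2 offset on batch 2
  batch <- rep(c("b1", "b2"), each = 5)
  tru2 <- cbind(tru[, 1:5], tru[, 1:5] * 2^5)
  sm <- summarize_replicates(make_table(triplicate(tru2),
                                        batch = batch))
  tr <- log2_batch_center_autoscale(sm)
  cen <- tr$centered$intensities
  for (i in 1:4) {
    expect_equal(mean(cen[i, 1:5]), mean(cen[i, 6:10]), tolerance = 1e-8)
  }
  sc <- tr$scaled$intensities
  expect_equal(unname(rowMeans(sc)), rep(0, 4), tolerance = 1e-8)
  expect_equal(unname(apply(sc, 1, sd)), rep(1, 4), tolerance = 1e-8)
  # oracle recomputation, one batch
  sm1 <- summarize_replicates(make_table(triplicate(tru)))
  got <- log2_batch_center_autoscale(sm1)$scaled$intensities
  lg <- log2(tru)
  lg <- lg - apply(lg, 1, median)
  want <- t(scale(t(lg)))
  expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-10)
  # constant features are dropped with a report entry
  trc <- rbind(tru, 7)
  smc <- summarize_replicates(make_table(triplicate(trc)))
  outc <- log2_batch_center_autoscale(smc)
  expect_equal(outc$dropped, "F005")
  expect_equal(nrow(outc$scaled$intensities), 4)
})

test_that("zeros get half-minimum substitution before log2", {
  tru <- rbind(c(0, 4, 8, 16))
  sm <- summarize_replicates(make_table(triplicate(tru)))
  tr <- log2_batch_center_autoscale(sm)
  # zero replaced by 2 (= min positive 4 / 2), so the centered value is
  # log2(2) - median(log2(c(2, 4, 8, 16)))
  expect_equal(tr$centered$intensities[1, 1],
               1 - median(log2(c(2, 4, 8, 16))), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("knn imputation matches the brute-force all-pairs oracle", {
  set.seed(17)
  x <- matrix(rnorm(200), 20, 10)
  x <- t(scale(t(x)))
  masked <- x
  idx <- cbind(sample(20, 5), sample(10, 5, replace = TRUE))
  masked[idx] <- NA
  got <- knn_impute(masked, k = 4)
  # observed entries never altered
  expect_identical(got[!is.na(masked)], masked[!is.na(masked)])
  want <- knn_oracle(masked, k = 4)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("knn imputation handles zero-distance and k clamping", {
  set.seed(21)
  base <- rnorm(8)
  x <- rbind(base, base, rnorm(8), rnorm(8))
  rownames(x) <- NULL
  m <- x; m[1, 3] <- NA
  out <- knn_impute(m, k = 10)   # k larger than candidate count
  expect_equal(out[1, 3], base[3])  # exact duplicate wins at distance 0
})

test_that("knn falls back to the feature mean when no candidate exists", {
  x <- rbind(c(NA, 1, 2, 3), c(NA, 2, 1, 3))  # nothing observed at s = 1
  expect_warning(out <- knn_impute(x, k = 2), "no candidate")
  expect_equal(out[1, 1], mean(c(1, 2, 3)))
  expect_equal(out[2, 1], mean(c(2, 1, 3)))
})

test_that("knn beats mean imputation on structured data", {
  set.seed(33)
  n <- 40; p <- 30
  f <- matrix(rnorm(n * 3), n, 3)
  x <- tcrossprod(matrix(rnorm(p * 3), p, 3), f) +
    0.3 * matrix(rnorm(p * n), p, n)
  x <- t(scale(t(x)))
  masked <- x
  hide <- which(matrix(runif(p * n) < 0.05, p, n))
  masked[hide] <- NA
  imp <- knn_impute(masked, k = 10)
  rmse_knn <- sqrt(mean((imp[hide] - x[hide])^2))
  rmse_mean <- sqrt(mean((0 - x[hide])^2))  # feature means are ~0
  expect_lt(rmse_knn, rmse_mean)
})
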