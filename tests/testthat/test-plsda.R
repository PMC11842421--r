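test_that("a single informative feature takes all the weight", {
  set.seed(14)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x2 <- rnorm(n)
  x2 <- residuals(lm(x2 ~ y))          # exactly orthogonal noise
  X <- cbind(f1 = y - mean(y), f2 = x2)
  m <- fit_plsda(X, y, A = 1)
  expect_equal(abs(m$W[, 1]), c(1, 0), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unname(vip(m)), c(sqrt(2), 0), tolerance = 1e-8)
})

test_that("first PLS direction equals the dominant eigenvector oracle", {
  set.seed(15)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rbinom(30, 1, 0.5)
  m <- fit_plsda(X, y, A = 1)
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  M <- crossprod(Xc, yc) %*% crossprod(yc, Xc)  # X'y y'X
  ev <- eigen(M, symmetric = TRUE)$vectors[, 1]
  ev <- ev / sqrt(sum(ev^2))
  expect_equal(abs(as.numeric(m$W[, 1])), abs(ev), tolerance = 1e-8)
})

test_that("NIPALS scores are orthogonal across components", {
  set.seed(16)
  X <- matrix(rnorm(40 * 12), 40, 12)
  y <- rbinom(40, 1, 0.4)
  m <- fit_plsda(X, y, A = 3)
  Tm <- m$Tm
  expect_lt(abs(sum(Tm[, 1] * Tm[, 2])), 1e-8)
  expect_lt(abs(sum(Tm[, 1] * Tm[, 3])), 1e-8)
  expect_lt(abs(sum(Tm[, 2] * Tm[, 3])), 1e-8)
  # sign convention: every score correlates non-negatively with y
  for (a in 1:3) expect_gte(sum(Tm[, a] * (y - mean(y))), 0)
})

test_that("VIP normalization and formula oracle", {
  set.seed(18)
  X <- matrix(rnorm(50 * 9), 50, 9)
  y <- rbinom(50, 1, 0.5)
  m <- fit_plsda(X, y, A = 2)
  v <- vip(m)
  expect_equal(sum(v^2), 9, tolerance = 1e-6)
  # independent re-implementation of the formula
  p <- 9
  want <- sqrt(p * rowSums(sweep(m$W^2, 2, m$ssy, `*`)) / sum(m$ssy))
  expect_equal(unname(v), unname(want), tolerance = 1e-10)
  # uniform weights give VIP 1 everywhere (single component)
  m1 <- list(W = matrix(1 / sqrt(p), p, 1), ssy = 2,
             feature_ids = NULL)
  expect_equal(unname(vip(m1)), rep(1, p), tolerance = 1e-12)
})

test_that("fold change follows the log2 mean difference", {
  m <- rbind(a = c(1, 1, 2, 2), b = c(3, 3, 3, 3))
  smoker <- c(FALSE, FALSE, TRUE, TRUE)
  fc <- fold_change(m, smoker)
  expect_equal(unname(fc), c(2, 1))
  expect_error(fold_change(m, rep(TRUE, 4)), "both classes")
  # seeded hand oracle
  set.seed(19)
  x <- matrix(rnorm(40), 2, 20)
  s <- rep(c(TRUE, FALSE), 10)
  expect_equal(unname(fold_change(x, s)),
               unname(2^(rowMeans(x[, s]) - rowMeans(x[, !s]))))
})

test_that("score export separates planted classes and is deterministic", {
  run1 <- local({
    sim <- simulate_mwas(sim_config(seed = 23, n_samples = 200,
                                    n_features = 150, n_planted = 15,
                                    plant_pathway = FALSE))
    sm <- summarize_replicates(apply_qc(sim$hilic)$table)
    tr <- log2_batch_center_autoscale(sm)
    X <- t(knn_impute(tr$scaled$intensities))
    list(m = fit_plsda(X, as.numeric(sim$truth$exposed), 2),
         y = sim$truth$exposed)
  })
  sc <- export_scores(run1$m, run1$y)
  t1s <- sc$scores$t1[sc$scores$class == "smoker"]
  t1n <- sc$scores$t1[sc$scores$class == "non-smoker"]
  expect_lt(t.test(t1s, t1n)$p.value, 0.01)
  expect_named(sc$ellipses, c("non-smoker", "smoker"))
  # deterministic refit
  sc2 <- export_scores(run1$m, run1$y)
  expect_identical(sc, sc2)
  expect_error(export_scores(fit_plsda(matrix(rnorm(80), 20, 4),
                                       rbinom(20, 1, 0.5), 1),
                             rep(c(TRUE, FALSE), 10)), "2 components")
})

test_that("score plots render to file", {
  set.seed(77)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- rep(c(0, 1), 20)
  m <- fit_plsda(X, y, 2)
  sc <- export_scores(m, y == 1)
  f <- withr::local_tempfile(fileext = ".png")
  plot_scores(sc, m, f)
  expect_true(file.exists(f) && file.size(f) > 1000)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fit_plsda(X, rep(1, 10), 1), "two classes")
  expect_error(fit_plsda(X, rbinom(10, 1, 0.5), 8), "rank")
})
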