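test_that("EASE equals 1 whenever k <= 1 (exhaustive, small N)", {
  for (N in c(3, 8, 15)) {
    for (m in 0:N) {
      for (n in 0:N) {
        expect_equal(ease_score(0, m, n, N), 1)
        if (m >= 1 && n >= 1) expect_equal(ease_score(1, m, n, N), 1)
      }
    }
  }
})

test_that("EASE matches exhaustive hypergeometric enumeration", {
  # oracle: direct sum of choose() mass over the support
  ease_oracle <- function(k, m, n, N) {
    if (k <= 1) return(1)
    j <- max(0, n - (N - m)):min(m, n)
    mass <- choose(m, j) * choose(N - m, n - j) / choose(N, n)
    sum(mass[j >= k - 1])
  }
  expect_equal(ease_score(4, 10, 10, 100), ease_oracle(4, 10, 10, 100),
               tolerance = 1e-12)
  expect_equal(ease_score(5, 5, 5, 5), 1)  # certain event
  set.seed(51)
  for (rep in 1:200) {
    N <- sample(2:30, 1)
    m <- sample(0:N, 1)
    n <- sample(0:N, 1)
    kmax <- min(m, n)
    k <- sample(0:kmax, 1)
    if (k > 0 && k < max(0, n - (N - m))) next
    k <- max(k, n - (N - m))
    expect_equal(ease_score(k, m, n, N), ease_oracle(k, m, n, N),
                 tolerance = 1e-12)
  }
  expect_error(ease_score(5, 4, 10, 20))
})

test_that("EASE is non-increasing in overlap k", {
  for (cfg in list(c(12, 9, 25), c(5, 5, 30), c(20, 10, 40))) {
    m <- cfg[1]; n <- cfg[2]; N <- cfg[3]
    ks <- max(0, n - (N - m)):min(m, n)
    ps <- vapply(ks, ease_score, 0, m = m, n = n, N = N)
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("m/z mapping preserves ambiguity and empties cleanly", {
  pdb <- make_pdb(c(A = 3, B = 3))
  # two isobaric metabolites
  pdb$metabolite_masses[c("A_M01", "B_M01")] <- 200.0
  feats <- data.frame(feature_id = c("f1", "f2"),
                      mz = c(adduct_mz(200, "M+H", "HILIC_pos"), 1100),
                      mode = "HILIC_pos", stringsAsFactors = FALSE)
  out <- map_mz_to_metabolites(feats, pdb, tol_ppm = 10)
  expect_setequal(out$map$f1, c("A_M01", "B_M01"))
  expect_null(out$map$f2)
  # brute-force oracle over all (feature, metabolite, adduct) triples
  set.seed(52)
  pdb2 <- make_pdb(c(A = 6, B = 9), seed = 99)
  feats2 <- data.frame(
    feature_id = sprintf("g%02d", 1:40),
    mz = runif(40, 90, 700),
    mode = sample(c("HILIC_pos", "C18_neg"), 40, TRUE),
    stringsAsFactors = FALSE)
  # put some features exactly on adduct masses
  feats2$mz[1:5] <- adduct_mz(pdb2$metabolite_masses[1:5], "M+Na",
                              "HILIC_pos")
  feats2$mode[1:5] <- "HILIC_pos"
  got <- map_mz_to_metabolites(feats2, pdb2, tol_ppm = 10)
  for (i in 1:40) {
    want <- character()
    for (met in names(pdb2$metabolite_masses)) {
      for (ad in mode_adducts(feats2$mode[i])) {
        theo <- adduct_mz(pdb2$metabolite_masses[[met]], ad,
                          feats2$mode[i])
        if (abs(1e6 * (feats2$mz[i] - theo) / theo) <= 10) {
          want <- c(want, met)
        }
      }
    }
    have <- got$map[[feats2$feature_id[i]]]
    expect_setequal(if (is.null(have)) character() else have,
                    unique(want))
  }
})

test_that("permutation null is seed-deterministic and gamma fit sane", {
  pdb <- make_pdb(c(A = 15, B = 20, C = 25), seed = 7)
  set.seed(61)
  feats <- data.frame(feature_id = sprintf("d%03d", 1:150),
                      mz = runif(150, 90, 700), mode = "HILIC_pos",
                      stringsAsFactors = FALSE)
  feats$mz[1:30] <- adduct_mz(sample(pdb$metabolite_masses, 30), "M+H",
                              "HILIC_pos") * (1 + runif(30, -5e-6, 5e-6))
  set.seed(101)
  n1 <- permutation_null(feats, pdb, n_sig = 30, P = 40)
  set.seed(101)
  n2 <- permutation_null(feats, pdb, n_sig = 30, P = 40)
  expect_identical(n1, n2)
  expect_length(n1$pool, 3 * 40)
  if (n1$method == "gamma") {
    expect_gt(n1$shape, 0)
    expect_gt(n1$rate, 0)
  }
})

test_that("gamma adjustment is a CDF: median to 0.5, monotone, ranking-safe", {
  null <- structure(list(method = "gamma", shape = 3, rate = 9,
                         pool = numeric(0)), class = "null_model")
  med <- qgamma(0.5, 3, 9)
  expect_equal(gamma_adjust(med, null), 0.5, tolerance = 1e-12)
  expect_equal(gamma_adjust(0, null), 0)
  grid <- seq(0, 1, by = 0.01)
  adj <- gamma_adjust(grid, null)
  expect_true(all(diff(adj) >= 0))
  expect_equal(adj, pgamma(grid, 3, 9))  # oracle CDF
  expect_error(gamma_adjust(0.5, list(shape = 3)), "unfitted")
})

test_that("gamma goodness of fit: good on gamma-like pools, misfit on atoms", {
  set.seed(81)
  pool <- rgamma(500, shape = 2.5, rate = 6)
  pool <- pmin(pool, 1)
  nm <- mwasdbs:::fit_null_model(pool)
  expect_identical(nm$method, "gamma")
  expect_lt(null_model_ks(nm), 0.15)
  # an EASE pool dominated by the atom at 1 cannot be matched by any
  # continuous gamma: the diagnostic detects (and documents) the misfit
  atom <- c(rep(1, 480), runif(20, 0.2, 0.9))
  nm2 <- mwasdbs:::fit_null_model(atom)
  expect_gt(null_model_ks(nm2), 0.15)
})

test_that("degenerate pools fall back to the empirical null", {
  nm <- mwasdbs:::fit_null_model(rep(1, 50))
  expect_identical(nm$method, "empirical")
  expect_equal(gamma_adjust(1, nm), 1)
  expect_equal(gamma_adjust(0.2, nm), 0)
})

test_that("enrich recovers a constructed enriched pathway", {
  pdb <- make_pdb(c(Target = 8, Bg1 = 20, Bg2 = 25), seed = 13)
  set.seed(71)
  detected <- data.frame(feature_id = sprintf("d%03d", 1:300),
                         mz = runif(300, 90, 700), mode = "HILIC_pos",
                         stringsAsFactors = FALSE)
  # target pathway metabolites present among detected; 6 of them selected
  tmz <- adduct_mz(pdb$metabolite_masses[pdb$pathways$Target], "M+H",
                   "HILIC_pos")
  detected$mz[1:8] <- tmz
  # background mappable features so the universe is not only the target
  bgm <- sample(pdb$metabolite_masses[c(pdb$pathways$Bg1,
                                        pdb$pathways$Bg2)], 25)
  detected$mz[9:33] <- adduct_mz(bgm, "M+H", "HILIC_pos")
  selected <- detected[c(1:6, 40:73), ]
  set.seed(72)
  out <- enrich(selected, detected, pdb, P = 60)
  tgt <- out[out$pathway == "Target", ]
  expect_equal(nrow(tgt), 1)
  expect_gte(tgt$overlap_size, 6)
  expect_lt(tgt$ease_p, 0.05)
  expect_true(tgt$significant)
  # empty selected list -> empty output
  expect_equal(nrow(enrich(detected[0, ], detected, pdb, P = 5)), 0)
  expect_error(enrich(data.frame(feature_id = "zz", mz = 100,
                                 mode = "HILIC_pos"),
                      detected, pdb), "subset")
})
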