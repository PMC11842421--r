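small_cfg <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_samples = 150, n_features = 120, n_planted = 10),
    list(...))
  do.call(sim_config, args)
}

test_that("the generator is bit-identical under the same seed", {
  s1 <- simulate_mwas(small_cfg(99))
  s2 <- simulate_mwas(small_cfg(99))
  expect_identical(s1, s2)
  s3 <- simulate_mwas(small_cfg(100))
  expect_false(identical(s1$hilic$intensities, s3$hilic$intensities))
})

test_that("zero planted effect leaves planted features null", {
  sim <- simulate_mwas(small_cfg(7, planted_effect = c(0, 0),
                                 n_features = 400, n_planted = 40))
  sm <- summarize_replicates(sim$hilic)
  lg <- log2(sm$intensities)
  y <- sim$truth$exposed
  pvals <- apply(lg, 1, function(v) {
    ok <- !is.na(v)
    if (sum(ok & y) < 5 || sum(ok & !y) < 5) return(NA_real_)
    t.test(v[ok & y], v[ok & !y])$p.value
  })
  planted <- sim$truth$planted$HILIC_pos$feature_id
  rej <- mean(pvals[planted] < 0.001, na.rm = TRUE)
  expect_lte(rej, 0.05 + 1e-9)  # ~0.1% expected under the null
})

test_that("missingness is monotone non-increasing in intensity decile", {
  sim <- simulate_mwas(small_cfg(3, n_samples = 250, n_features = 500))
  tab <- sim$hilic
  keep <- -(1:2)  # biomarker channels are exempt from censoring
  obs_rate <- rowMeans(!is.na(tab$intensities[keep, ]))
  mu_proxy <- rowMeans(log2(tab$intensities[keep, ]), na.rm = TRUE)
  dec <- cut(mu_proxy, quantile(mu_proxy, 0:10 / 10), include.lowest = TRUE)
  miss_by_dec <- tapply(1 - obs_rate, dec, mean)
  # allow tiny sampling wiggle between adjacent deciles
  expect_true(all(diff(miss_by_dec) <= 0.03))
  expect_gt(miss_by_dec[1], miss_by_dec[10])
})

test_that("realized replicate CVs straddle the 30% QC threshold", {
  sim <- simulate_mwas(small_cfg(5, n_features = 300, n_samples = 200))
  rep_qc <- apply_qc(sim$hilic)$report
  cvs <- rep_qc$median_cv[!is.na(rep_qc$median_cv)]
  # the median-of-samples CV of triplicates underestimates the generating
  # CV (~0.8x), so the realized upper tail is thin but non-empty: the
  # 30% filter rejects some but not all features
  expect_gt(mean(cvs < 0.30), 0.5)
  expect_gte(sum(cvs > 0.30), 5)
})

test_that("pathway planting closes the loop through mapping", {
  pdb <- read_pathway_db(default_pathway_db_path())
  sim <- simulate_mwas(small_cfg(13))
  pw <- sim$truth$pathway
  expect_gte(nrow(pw), 4)
  feats <- sim$hilic$features
  planted_feats <- feats[feats$feature_id %in% pw$feature_id, ]
  got <- map_mz_to_metabolites(planted_feats, pdb, tol_ppm = 1)
  mapped <- unique(unlist(got$map))
  expect_gte(length(intersect(
    mapped, pdb$pathways[[sim_config()$planted_pathway]])), 4)
  # planting into a small custom pathway errors below 4 metabolites
  tiny <- make_pdb(c(Solo = 1))
  expect_error(plan_pathway_features(tiny, "Solo"), "fewer than 4")
  expect_error(plan_pathway_features(pdb, "No such pathway"),
               "not in database")
})

test_that("biomarker channels behave as specified", {
  sim <- simulate_mwas(small_cfg(17))
  tab <- sim$hilic
  expect_equal(tab$features$mz[1:2], c(177.1023, 193.0973))
  # cotinine present only for samples with the cotinine indicator
  sm <- summarize_replicates(tab)
  cot <- sm$intensities[1, ]
  expect_identical(unname(!is.na(cot)),
                   unname(sim$truth$indicators$cotinine))
})
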