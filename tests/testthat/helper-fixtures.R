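# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# minimal well-formed feature table: `values` is features x (3 * n_samples)
# in injection order (sample-major, replicates 1..3)
make_table <- function(values, mz = NULL, rt = NULL, mode = "HILIC_pos",
                       batch = NULL) {
  values <- as.matrix(values)
  stopifnot(ncol(values) %% 3 == 0)
  n <- ncol(values) / 3
  p <- nrow(values)
  sid <- sprintf("S%03d", seq_len(n))
  if (is.null(mz)) mz <- seq(100, 200, length.out = p)
  if (is.null(rt)) rt <- seq(30, 300, length.out = p)
  if (is.null(batch)) batch <- rep("b1", n)
  injections <- data.frame(
    injection_id = paste0(rep(sid, each = 3), ".", rep(1:3, n)),
    sample_id = rep(sid, each = 3), replicate = rep(1:3, n),
    batch = rep(batch, each = 3), stringsAsFactors = FALSE)
  features <- data.frame(feature_id = sprintf("F%03d", seq_len(p)),
                         mz = mz, rt = rt, mode = mode,
                         stringsAsFactors = FALSE)
  feature_table(features, injections, values)
}

# replicate triplets per sample from a features x samples "true" matrix,
# with identical replicates (CV 0, Pearson 1)
triplicate <- function(m) {
  m <- as.matrix(m)
  m[, rep(seq_len(ncol(m)), each = 3), drop = FALSE]
}

make_samples <- function(n, reported = rep(FALSE, n), seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    reported_smoker = reported,
    race_ethnicity = sample(c("white_nonhispanic", "hispanic", "other"),
                            n, TRUE),
    maternal_age = sample(c("<20", "20-24", "25-29", "30-34", "35+"),
                          n, TRUE),
    birth_year_band = sample(c("1983-1990", "1991-2000", "2001-2011"),
                             n, TRUE),
    sex = sample(c("male", "female"), n, TRUE),
    ses = sample(as.character(1:5), n, TRUE),
    stringsAsFactors = FALSE)
}

# small pathway database with controllable sizes
make_pdb <- function(sizes = c(A = 5, B = 8), mass_range = c(100, 600),
                     seed = 42) {
  set.seed(seed)
  pathways <- list(); masses <- c()
  for (pw in names(sizes)) {
    ids <- sprintf("%s_M%02d", pw, seq_len(sizes[[pw]]))
    pathways[[pw]] <- ids
    masses[ids] <- runif(length(ids), mass_range[1], mass_range[2])
  }
  list(pathways = pathways, metabolite_masses = masses)
}

# brute-force kNN imputation oracle: all-pairs loops, no shortcuts
knn_oracle <- function(x, k) {
  out <- x
  p <- nrow(x)
  for (f in seq_len(p)) {
    for (s in which(is.na(x[f, ]))) {
      cand <- c(); dist <- c()
      for (g in seq_len(p)) {
        if (g == f || is.na(x[g, s])) next
        co <- which(!is.na(x[f, ]) & !is.na(x[g, ]))
        if (!length(co)) next
        cand <- c(cand, g)
        dist <- c(dist, sqrt(sum((x[f, co] - x[g, co])^2) / length(co)))
      }
      if (!length(cand)) { out[f, s] <- 0; next }
      ord <- order(dist)
      use <- ord[seq_len(min(k, length(ord)))]
      if (any(dist[use] == 0)) {
        out[f, s] <- mean(x[cand[use][dist[use] == 0], s])
      } else {
        w <- 1 / dist[use]
        out[f, s] <- sum(w * x[cand[use], s]) / sum(w)
      }
    }
  }
  out
}

# classify exposure from a simulated study (shared pipeline front end)
classify_sim <- function(sim, rule = exposure_rule()) {
  smr <- summarize_replicates(sim$hilic)
  cot <- extract_biomarker(smr, rule$cotinine_mz, rule$mz_tol_ppm)
  hyd <- extract_biomarker(smr, rule$hydroxycotinine_mz, rule$mz_tol_ppm)
  classify_exposure(sim$samples, cot$intensity, hyd$intensity, rule)
}
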