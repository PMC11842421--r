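# Seeded synthetic dried-blood-spot data with the statistical structure the
# analysis assumes: dual chromatography modes, triplicate injections in
# batches of 40, intensity-dependent (left-censoring) missingness,
# per-feature replicate CVs straddling the 30% QC threshold, overlapping
# smoking indicators calibrated so the union rule yields ~17% prevalence,
# planted log2-scale exposure effects on a subset of features, and a
# planted enriched pathway whose metabolite adduct masses are written onto
# planted feature m/z values.
#
# The two biomarker channels (cotinine, hydroxycotinine) are simulated
# noise-free: their replicates are identical, they receive no batch offset
# and no censoring noise, so exposure classification recovers the generated
# truth exactly. Every stochastic draw comes from the single R RNG stream
# keyed by the seed.

#' Synthetic-data configuration
#'
#' Defaults emulate the study design: 900 samples, 2000 features per mode,
#' a 17% target smoking prevalence driven by three overlapping indicators,
#' 60 planted features per mode with log2 effects in `[0.5, 1.5]`,
#' per-feature replicate CVs in `[0.10, 0.40]` and batches of 40.
#'
#' @param seed Integer seed for the single RNG stream.
#' @param n_samples Number of newborns.
#' @param n_features Features per chromatography mode.
#' @param smoker_fraction Target prevalence of the indicator union.
#' @param n_planted Planted exposure-affected features per mode.
#' @param planted_effect Range (lo, hi) of planted |log2| mean shifts;
#'   `c(0, 0)` disables effects (global null).
#' @param replicate_cv Range of per-feature technical-replicate CVs.
#' @param missing_a,missing_b Intercept/slope of the logistic
#'   left-censoring curve `P(missing) = plogis(a - b * log2 intensity)`.
#' @param batch_size Samples per analytical batch.
#' @param plant_pathway Plant the enriched pathway? (default TRUE)
#' @param planted_pathway Pathway name to plant.
#' @param n_pathway_features Planted features carrying pathway adduct
#'   masses (>= 4 metabolites required).
#' @param p_latent,p_report,p_cotinine Latent smoker fraction and
#'   per-indicator conditional probabilities (calibrated once so the union
#'   hits `smoker_fraction`).
#' @param hydroxy_shift Log2 shift of hydroxycotinine in latent smokers.
#' @param modes Chromatography modes to generate (both by default;
#'   generating only `"HILIC_pos"` leaves the HILIC stream unchanged and
#'   skips the C18 table — a compute knob for test loops).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_samples = 900L, n_features = 2000L,
                       smoker_fraction = 0.17, n_planted = 60L,
                       planted_effect = c(0.5, 1.5),
                       replicate_cv = c(0.10, 0.40),
                       missing_a = 11, missing_b = 0.8,
                       batch_size = 40L, plant_pathway = TRUE,
                       planted_pathway = "Vitamin A (retinol) metabolism",
                       n_pathway_features = 6L,
                       p_latent = 0.165, p_report = 0.12,
                       p_cotinine = 0.50, hydroxy_shift = 3,
                       modes = c("HILIC_pos", "C18_neg")) {
  stopifnot(n_planted < n_features, smoker_fraction > 0,
            smoker_fraction < 1, batch_size >= 1,
            length(planted_effect) == 2, planted_effect[1] >= 0,
            diff(planted_effect) >= 0, length(replicate_cv) == 2,
            all(modes %in% FEATURE_MODES), "HILIC_pos" %in% modes,
            !plant_pathway || n_planted >= 4L)
  structure(as.list(environment()), class = "sim_config")
}

#' Choose pathway metabolites to plant onto feature m/z values
#'
#' Picks `n` metabolites of the pathway (all of them when the pathway is
#' smaller than `n`) and computes their `[M+H]+` m/z; at least 4 plantable
#' metabolites are required.
#'
#' @param pdb Pathway database.
#' @param pathway Pathway name present in `pdb`.
#' @param n Number of metabolites to plant (default 6).
#' @return data.frame: `metabolite`, `mass`, `mz`.
#' @export
plan_pathway_features <- function(pdb, pathway, n = 6L) {
  if (!pathway %in% names(pdb$pathways)) {
    stop("pathway not in database: ", pathway)
  }
  mets <- pdb$pathways[[pathway]]
  usable <- mets[pdb$metabolite_masses[mets] + PROTON_MASS >= MZ_RANGE[1] &
                 pdb$metabolite_masses[mets] + PROTON_MASS <= MZ_RANGE[2]]
  if (length(usable) < 4L) {
    stop("pathway '", pathway, "' has fewer than 4 plantable metabolites")
  }
  pick <- usable[seq_len(min(n, length(usable)))]
  data.frame(metabolite = pick,
             mass = unname(pdb$metabolite_masses[pick]),
             mz = unname(adduct_mz(pdb$metabolite_masses[pick], "M+H",
                                   "HILIC_pos")),
             stringsAsFactors = FALSE)
}

# Table-1-like covariate frequencies by smoking stratum
.COV_FREQ <- list(
  race_ethnicity = list(
    levels = RACE_LEVELS,
    smoker = c(74, 49, 30), nonsmoker = c(225, 370, 135)),
  maternal_age = list(
    levels = AGE_LEVELS,
    smoker = c(18, 38, 44, 43, 10), nonsmoker = c(81, 181, 193, 170, 105)),
  birth_year_band = list(
    levels = BIRTHYEAR_LEVELS,
    smoker = c(63, 66, 24), nonsmoker = c(121, 281, 328)),
  sex = list(levels = SEX_LEVELS,
             smoker = c(87, 66), nonsmoker = c(346, 384)),
  ses = list(levels = SES_LEVELS,
             smoker = c(30, 40, 47, 18, 18),
             nonsmoker = c(163, 208, 145, 117, 97))
)

#' Generate a synthetic study
#'
#' @param cfg A [sim_config].
#' @param pdb Pathway database for planting (default: packaged synthetic
#'   database).
#' @return list: `hilic` and `c18` (feature tables), `samples` (covariate
#'   data.frame) and `truth` (planted features and effects per mode,
#'   planted-pathway metabolites/features, per-sample true exposure and
#'   indicators).
#' @export
simulate_mwas <- function(cfg = sim_config(), pdb = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(pdb)) pdb <- read_pathway_db(default_pathway_db_path())
  set.seed(cfg$seed)
  n <- cfg$n_samples
  sid <- sprintf("S%04d", seq_len(n))
  batch <- sprintf("b%02d", ((seq_len(n) - 1) %/% cfg$batch_size) + 1L)

  ## exposure indicators --------------------------------------------------
  latent <- stats::rbinom(n, 1, cfg$p_latent) == 1
  report <- latent & stats::rbinom(n, 1, cfg$p_report) == 1
  cot_present <- latent & stats::rbinom(n, 1, cfg$p_cotinine) == 1
  hyd_log2 <- stats::rnorm(n, 10, 1.2) + cfg$hydroxy_shift * latent
  hyd_detected <- hyd_log2 > 11.7   # ~20% detected overall
  h0 <- ifelse(hyd_detected, 2^hyd_log2, 0)
  cutoff <- stats::quantile(h0, 1 - 0.14, names = FALSE)
  hyd_flag <- h0 >= cutoff & h0 > 0
  exposed <- report | cot_present | hyd_flag

  ## covariates from Table-1-like stratum frequencies ---------------------
  samples <- data.frame(sample_id = sid, reported_smoker = report,
                        stringsAsFactors = FALSE)
  for (cv in names(.COV_FREQ)) {
    fr <- .COV_FREQ[[cv]]
    out <- character(n)
    out[exposed] <- sample(fr$levels, sum(exposed), replace = TRUE,
                           prob = fr$smoker / sum(fr$smoker))
    out[!exposed] <- sample(fr$levels, sum(!exposed), replace = TRUE,
                            prob = fr$nonsmoker / sum(fr$nonsmoker))
    samples[[cv]] <- out
  }
  samples <- validate_samples(samples)

  ## per-mode feature tables ----------------------------------------------
  cot_log2 <- stats::rnorm(n, 12, 1)
  biomarkers <- list(
    list(mz = 177.1023, rt = 150, present = cot_present,
         log2 = cot_log2),
    list(mz = 193.0973, rt = 140, present = hyd_detected,
         log2 = hyd_log2))
  pw_plan <- NULL
  if (cfg$plant_pathway) {
    pw_plan <- plan_pathway_features(pdb, cfg$planted_pathway,
                                     min(cfg$n_pathway_features,
                                         cfg$n_planted))
  }
  truth <- list(exposed = stats::setNames(exposed, sid),
                latent = stats::setNames(latent, sid),
                indicators = data.frame(sample_id = sid, report = report,
                                        cotinine = cot_present,
                                        hydroxycotinine = hyd_flag,
                                        stringsAsFactors = FALSE),
                hydroxycotinine_cutoff = cutoff,
                planted = list(), pathway = NULL)
  tables <- list()
  for (mode in cfg$modes) {
    gen <- simulate_mode(cfg, mode, sid, batch, exposed,
                         biomarkers = if (mode == "HILIC_pos") biomarkers,
                         pw_plan = if (mode == "HILIC_pos") pw_plan)
    tables[[mode]] <- gen$table
    truth$planted[[mode]] <- gen$planted
    if (!is.null(gen$pathway)) truth$pathway <- gen$pathway
  }
  list(hilic = tables$HILIC_pos, c18 = tables$C18_neg,
       samples = samples, truth = truth)
}

simulate_mode <- function(cfg, mode, sid, batch, exposed, biomarkers = NULL,
                          pw_plan = NULL) {
  n <- length(sid)
  p <- cfg$n_features
  n_bio <- length(biomarkers)
  mz <- stats::runif(p, MZ_RANGE[1], MZ_RANGE[2])
  rt <- stats::runif(p, 10, 700)
  if (n_bio) {
    for (i in seq_len(n_bio)) {
      mz[i] <- biomarkers[[i]]$mz
      rt[i] <- biomarkers[[i]]$rt
    }
  }
  fid <- sprintf("%s_F%04d", mode, seq_len(p))

  planted_idx <- sample(setdiff(seq_len(p), seq_len(n_bio)),
                        cfg$n_planted)
  lo <- cfg$planted_effect[1]; hi <- cfg$planted_effect[2]
  sgn <- ifelse(stats::runif(cfg$n_planted) < 0.8, 1, -1)
  effect <- sgn * stats::runif(cfg$n_planted, lo, hi)
  pathway_out <- NULL
  if (!is.null(pw_plan)) {
    # pathway features are a subset of the planted set: strong positive
    # effects (upper part of the configured range) and m/z set to the
    # metabolite [M+H]+ mass so annotation and enrichment can recover them
    npw <- nrow(pw_plan)
    stopifnot(npw <= cfg$n_planted)
    mz[planted_idx[seq_len(npw)]] <- pw_plan$mz
    effect[seq_len(npw)] <- if (hi <= 0) 0 else
      stats::runif(npw, max(lo, 2 / 3 * hi), hi)
    pathway_out <- data.frame(pw_plan,
                              feature_id = fid[planted_idx[seq_len(npw)]],
                              stringsAsFactors = FALSE)
  }

  mu <- stats::rnorm(p, 17, 2.5)
  sigma <- stats::runif(p, 0.4, 1.2)
  cv <- stats::runif(p, cfg$replicate_cv[1], cfg$replicate_cv[2])
  sdlog2 <- sqrt(log(1 + cv^2)) / log(2)
  batch_levels <- unique(batch)
  boff <- stats::setNames(stats::rnorm(length(batch_levels), 0, 0.3),
                          batch_levels)

  # sample-level true log2 intensity
  L <- matrix(mu, p, n) + matrix(stats::rnorm(p * n, 0, 1), p, n) * sigma
  if (cfg$n_planted) {
    L[planted_idx, exposed] <- L[planted_idx, exposed] + effect
  }
  L <- L + rep(boff[batch], each = p)

  intens <- matrix(NA_real_, p, 3 * n)
  inj_id <- character(3 * n)
  inj_sample <- character(3 * n)
  inj_rep <- integer(3 * n)
  for (r in 1:3) {
    cols <- 3 * (seq_len(n) - 1) + r
    rep_log2 <- L + matrix(stats::rnorm(p * n, 0, 1), p, n) * sdlog2
    vals <- 2^rep_log2
    pmiss <- stats::plogis(cfg$missing_a - cfg$missing_b * L)
    vals[matrix(stats::runif(p * n), p, n) < pmiss] <- NA_real_
    intens[, cols] <- vals
    inj_id[cols] <- paste0(sid, ".", r)
    inj_sample[cols] <- sid
    inj_rep[cols] <- r
  }
  # biomarker channels: noise-free, uncensored, no batch offset
  if (n_bio) {
    for (i in seq_len(n_bio)) {
      v <- ifelse(biomarkers[[i]]$present, 2^biomarkers[[i]]$log2,
                  NA_real_)
      for (r in 1:3) intens[i, 3 * (seq_len(n) - 1) + r] <- v
    }
  }
  features <- data.frame(feature_id = fid, mz = mz, rt = rt, mode = mode,
                         stringsAsFactors = FALSE)
  injections <- data.frame(injection_id = inj_id, sample_id = inj_sample,
                           replicate = inj_rep,
                           batch = batch[match(inj_sample, sid)],
                           stringsAsFactors = FALSE)
  tab <- feature_table(features, injections, intens)
  planted <- data.frame(feature_id = fid[planted_idx], effect = effect,
                        stringsAsFactors = FALSE)
  list(table = tab, planted = planted, pathway = pathway_out)
}
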