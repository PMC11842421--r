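# Shared data model and on-disk formats.
#
# A feature table holds injection-level ion intensities for one
# chromatography mode: rows are (m/z, retention time) features, columns are
# injections (three technical replicates per sample, batches of <= 40
# samples). Missing intensities are NA internally and empty cells on disk;
# zero is a legitimate measured intensity and is never used as a sentinel.

FEATURE_MODES <- c("HILIC_pos", "C18_neg")

RACE_LEVELS <- c("white_nonhispanic", "hispanic", "other")
AGE_LEVELS <- c("<20", "20-24", "25-29", "30-34", "35+")
BIRTHYEAR_LEVELS <- c("1983-1990", "1991-2000", "2001-2011")
SEX_LEVELS <- c("male", "female")
SES_LEVELS <- as.character(1:5)

MZ_RANGE <- c(85, 1275)  # instrument scan range

#' Construct a feature table
#'
#' @param features data.frame with columns `feature_id`, `mz`, `rt`, `mode`.
#' @param injections data.frame with columns `injection_id`, `sample_id`,
#'   `replicate` (1..3) and `batch`.
#' @param intensities numeric matrix, `nrow(features)` x `nrow(injections)`,
#'   non-negative, `NA` = missing.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, injections, intensities) {
  stopifnot(is.data.frame(features), is.data.frame(injections),
            is.matrix(intensities))
  need_f <- c("feature_id", "mz", "rt", "mode")
  if (!all(need_f %in% names(features))) {
    stop("features must have columns: ", paste(need_f, collapse = ", "))
  }
  need_i <- c("injection_id", "sample_id", "replicate", "batch")
  if (!all(need_i %in% names(injections))) {
    stop("injections must have columns: ", paste(need_i, collapse = ", "))
  }
  x <- structure(
    list(features = features[need_f], injections = injections[need_i],
         intensities = intensities),
    class = "feature_table"
  )
  validate_feature_table(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "feature_table: %d features x %d injections (%d samples, %d batches), mode %s\n",
    nrow(x$features), nrow(x$injections),
    length(unique(x$injections$sample_id)),
    length(unique(x$injections$batch)),
    paste(unique(x$features$mode), collapse = "/")))
  invisible(x)
}

validate_feature_table <- function(x) {
  f <- x$features; inj <- x$injections; m <- x$intensities
  if (anyDuplicated(f$feature_id)) {
    stop("duplicate feature_id: ",
         paste(unique(f$feature_id[duplicated(f$feature_id)]), collapse = ", "))
  }
  if (any(f$mz < MZ_RANGE[1] | f$mz > MZ_RANGE[2])) {
    bad <- f$feature_id[f$mz < MZ_RANGE[1] | f$mz > MZ_RANGE[2]]
    stop("m/z outside instrument range [", MZ_RANGE[1], ", ", MZ_RANGE[2],
         "] for feature(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(f$rt < 0)) stop("negative retention time")
  if (!all(f$mode %in% FEATURE_MODES)) stop("unknown mode in features")
  reps <- table(inj$sample_id)
  if (any(reps != 3L)) {
    bad <- names(reps)[reps != 3L]
    stop("sample(s) without exactly 3 replicate injections: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  per_batch <- tapply(inj$sample_id, inj$batch,
                      function(s) length(unique(s)))
  if (any(per_batch > 40L)) {
    stop("batch with more than 40 samples: ",
         paste(names(per_batch)[per_batch > 40L], collapse = ", "))
  }
  if (nrow(m) != nrow(f) || ncol(m) != nrow(inj)) {
    stop("intensity matrix is ", nrow(m), "x", ncol(m),
         " but expected ", nrow(f), "x", nrow(inj))
  }
  if (any(m < 0, na.rm = TRUE)) stop("negative intensity")
  x
}

#' Sample identifiers of a feature table, in first-injection order
#' @param table A `feature_table`.
#' @export
table_samples <- function(table) {
  unique(table$injections$sample_id)
}

# column indices of the 3 replicate injections per sample:
# samples x 3 integer matrix, rows named by sample_id
replicate_index <- function(table) {
  inj <- table$injections
  sids <- table_samples(table)
  idx <- matrix(NA_integer_, length(sids), 3,
                dimnames = list(sids, NULL))
  for (r in 1:3) {
    sel <- which(inj$replicate == r)
    idx[match(inj$sample_id[sel], sids), r] <- sel
  }
  if (anyNA(idx)) stop("sample missing a replicate index")
  idx
}

#' Read a feature table from TSV
#'
#' The TSV has header columns `mz`, `time`, then one intensity column per
#' injection named `<sample_id>.<replicate>`. Missing intensities are empty
#' cells. Batches are given in a separate two-column TSV
#' (`injection_id`, `batch`); with `batch_path = NULL` all injections fall
#' into one batch.
#'
#' @param path Feature-table TSV path.
#' @param mode Chromatography/ionization mode of the table.
#' @param batch_path Optional batch-map TSV path.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, mode = c("HILIC_pos", "C18_neg"),
                               batch_path = NULL) {
  mode <- match.arg(mode)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3 || names(df)[1] != "mz" || names(df)[2] != "time") {
    stop("malformed header in ", path,
         ": expected columns mz, time, <sample>.<rep>...")
  }
  inj_names <- names(df)[-(1:2)]
  parts <- regmatches(inj_names, regexec("^(.*)\\.([0-9]+)$", inj_names))
  bad <- inj_names[lengths(parts) != 3L]
  if (length(bad)) {
    stop("injection column(s) not of the form <sample>.<rep>: ",
         paste(bad, collapse = ", "))
  }
  sample_id <- vapply(parts, `[`, "", 2L)
  replicate <- as.integer(vapply(parts, `[`, "", 3L))
  batch <- rep("b1", length(inj_names))
  if (!is.null(batch_path)) {
    bm <- utils::read.delim(batch_path, colClasses = "character")
    if (!all(c("injection_id", "batch") %in% names(bm))) {
      stop("batch map must have columns injection_id, batch")
    }
    hit <- match(inj_names, bm$injection_id)
    if (anyNA(hit)) {
      stop("injection(s) missing from batch map: ",
           paste(inj_names[is.na(hit)], collapse = ", "))
    }
    batch <- bm$batch[hit]
  }
  raw <- as.matrix(df[, -(1:2), drop = FALSE])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  nonnum <- nzchar(trimws(raw)) & is.na(num)
  if (any(nonnum)) {
    w <- which(nonnum, arr.ind = TRUE)[1, ]
    stop("non-numeric intensity at row ", w[1], ", column '",
         inj_names[w[2]], "' in ", path)
  }
  num[!nzchar(trimws(raw))] <- NA_real_
  features <- data.frame(
    feature_id = sprintf("%s_F%04d", mode, seq_len(nrow(df))),
    mz = as.numeric(df$mz), rt = as.numeric(df$time), mode = mode,
    stringsAsFactors = FALSE
  )
  injections <- data.frame(injection_id = inj_names, sample_id = sample_id,
                           replicate = replicate, batch = batch,
                           stringsAsFactors = FALSE)
  feature_table(features, injections, num)
}

#' Write a feature table (and its batch map) to TSV
#' @param table A `feature_table`.
#' @param path Output TSV path.
#' @param batch_path Optional batch-map TSV path.
#' @export
write_feature_table <- function(table, path, batch_path = NULL) {
  m <- table$intensities
  chr <- matrix(format_num(m), nrow = nrow(m))
  chr[is.na(m)] <- ""
  out <- cbind(mz = format_num(table$features$mz),
               time = format_num(table$features$rt), chr)
  colnames(out) <- c("mz", "time", table$injections$injection_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(batch_path)) {
    utils::write.table(
      data.frame(injection_id = table$injections$injection_id,
                 batch = table$injections$batch),
      batch_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

format_num <- function(x) {
  out <- formatC(x, format = "g", digits = 15)
  out[is.na(x)] <- NA_character_
  out
}

#' Read the sample covariate table
#'
#' TSV with one row per sample and columns `sample_id`, `reported_smoker`
#' (TRUE/FALSE), `race_ethnicity`, `maternal_age`, `birth_year_band`, `sex`,
#' `ses`. Categorical values are validated against their fixed domains.
#'
#' @param path Covariate TSV path.
#' @return data.frame of validated sample records.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  validate_samples(df)
}

validate_samples <- function(df) {
  need <- c("sample_id", "reported_smoker", "race_ethnicity",
            "maternal_age", "birth_year_band", "sex", "ses")
  if (!all(need %in% names(df))) {
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[need]
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  rs <- as.character(df$reported_smoker)
  if (!all(toupper(rs) %in% c("TRUE", "FALSE"))) {
    stop("reported_smoker must be TRUE/FALSE")
  }
  df$reported_smoker <- toupper(rs) == "TRUE"
  domains <- list(race_ethnicity = RACE_LEVELS, maternal_age = AGE_LEVELS,
                  birth_year_band = BIRTHYEAR_LEVELS, sex = SEX_LEVELS,
                  ses = SES_LEVELS)
  for (col in names(domains)) {
    vals <- as.character(df[[col]])
    bad <- setdiff(unique(vals), domains[[col]])
    if (length(bad)) {
      stop("unknown ", col, " level(s): ", paste(bad, collapse = ", "))
    }
    df[[col]] <- vals
  }
  df
}

#' Write the sample covariate table
#' @param samples data.frame as returned by [read_samples].
#' @param path Output TSV path.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an authentic-standard reference library (JSON)
#'
#' Entries carry `name`, `formula`, `adduct`, `mz` (library m/z of the ion),
#' `rt` (library retention time, seconds) and `mode`. The neutral
#' monoisotopic mass is recomputed from the formula.
#'
#' @param path JSON path.
#' @return data.frame with one row per library entry.
#' @export
read_reference_library <- function(path) {
  lib <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  df <- if (is.data.frame(lib)) lib else lib$entries
  need <- c("name", "formula", "adduct", "mz", "rt", "mode")
  if (!all(need %in% names(df))) {
    stop("reference library must provide fields: ",
         paste(need, collapse = ", "))
  }
  df$neutral_mass <- vapply(df$formula, monoisotopic_mass, 0)
  if (any(df$neutral_mass <= 0)) stop("non-positive neutral mass in library")
  df
}

#' Read a pathway database (JSON)
#'
#' JSON object with `pathways` (pathway name -> array of metabolite ids) and
#' `metabolite_masses` (metabolite id -> neutral monoisotopic mass).
#'
#' @param path JSON path.
#' @return list with elements `pathways` (named list of character vectors)
#'   and `metabolite_masses` (named numeric vector).
#' @export
read_pathway_db <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  pdb <- list(pathways = lapply(obj$pathways, as.character),
              metabolite_masses = unlist(obj$metabolite_masses))
  validate_pathway_db(pdb)
}

validate_pathway_db <- function(pdb) {
  if (!length(pdb$pathways)) stop("empty pathway database")
  if (any(lengths(pdb$pathways) == 0)) stop("empty pathway in database")
  mets <- unique(unlist(pdb$pathways))
  missing_mass <- setdiff(mets, names(pdb$metabolite_masses))
  if (length(missing_mass)) {
    stop("metabolite(s) without mass entry: ",
         paste(utils::head(missing_mass, 5), collapse = ", "))
  }
  if (any(pdb$metabolite_masses <= 0)) stop("non-positive metabolite mass")
  pdb
}

#' Write a pathway database to JSON
#' @param pdb Pathway database list (see [read_pathway_db]).
#' @param path Output JSON path.
#' @export
write_pathway_db <- function(pdb, path) {
  jsonlite::write_json(
    list(pathways = pdb$pathways,
         metabolite_masses = as.list(pdb$metabolite_masses)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
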