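#' Construct a feature table
#'
#' The central container of the pipeline: one row per LC-MS m/z feature
#' (defined by m/z and retention time) and one intensity column per sample.
#' Intensities are non-negative; missing measurements are `NA` (distinct from
#' numeric zero). Duplicate m/z values are permitted only at distinct
#' retention times; feature ids are `mz@rt` strings.
#'
#' @param mz numeric vector of mass-to-charge values (Da, positive-mode,
#'   singly charged), all > 0.
#' @param rt numeric vector of retention times (seconds).
#' @param intensity numeric matrix, features x samples; values >= 0 or `NA`.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   intensity column.
#' @param feature_id optional character vector of feature ids; defaults to
#'   `mz@rt`.
#' @return an object of class `feature_table` with elements `features`
#'   (data.frame: feature_id, mz, rt) and `intensity` (matrix with feature ids
#'   as rownames and sample ids as colnames).
#' @export
feature_table <- function(mz, rt, intensity, sample_ids, feature_id = NULL) {
  mz <- as.numeric(mz)
  rt <- as.numeric(rt)
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (length(mz) != length(rt))
    stop("mz and rt must have equal length")
  if (nrow(intensity) != length(mz))
    stop("intensity must have one row per feature")
  if (ncol(intensity) != length(sample_ids))
    stop("intensity must have one column per sample id")
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique")
  if (any(!is.finite(mz)) || any(mz <= 0))
    stop("every mz must be a finite positive number")
  bad <- which(intensity < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative intensity at feature row %d, sample '%s'",
                 bad[1, 1], sample_ids[bad[1, 2]]))
  if (is.null(feature_id))
    feature_id <- paste0(format(mz, trim = TRUE, digits = 15), "@",
                         format(rt, trim = TRUE, digits = 15))
  feature_id <- as.character(feature_id)
  if (anyDuplicated(feature_id))
    stop("duplicate (mz, rt) feature rows are not allowed")
  features <- data.frame(feature_id = feature_id, mz = mz, rt = rt,
                         stringsAsFactors = FALSE)
  dimnames(intensity) <- list(feature_id, as.character(sample_ids))
  structure(list(features = features, intensity = intensity),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples, m/z %.3f-%.3f\n",
              nrow(x$features), ncol(x$intensity),
              min(x$features$mz), max(x$features$mz)))
  invisible(x)
}

#' Number of features / samples in a feature table
#' @param table a `feature_table`
#' @return integer count
#' @export
n_features <- function(table) nrow(table$features)

#' @rdname n_features
#' @export
n_samples <- function(table) ncol(table$intensity)

#' Read a feature table from TSV
#'
#' Expects the table shape emitted by apLCMS-style peak extraction: columns
#' `mz`, `rt` (or `time`), then one intensity column per sample. By default
#' zeros are coerced to missing, since peak-extraction software emits 0 for
#' features undetected in a sample and the downstream presence filter needs a
#' presence/absence notion.
#'
#' @param path path to a tab-separated file.
#' @param zero_as_missing coerce 0 intensities to `NA` (default `TRUE`).
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path, zero_as_missing = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  mz_col <- which(tolower(nm) == "mz")
  rt_col <- which(tolower(nm) %in% c("rt", "time", "retention_time"))
  if (length(mz_col) != 1)
    stop("malformed header: need exactly one 'mz' column")
  if (length(rt_col) != 1)
    stop("malformed header: need exactly one 'rt' (or 'time') column")
  sample_cols <- setdiff(seq_along(nm), c(mz_col, rt_col))
  if (length(sample_cols) == 0)
    stop("malformed header: no sample columns found")
  intensity <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(intensity) <- "double"
  neg <- which(apply(intensity < 0, 1, any, na.rm = TRUE))
  if (length(neg) > 0)
    stop(sprintf("negative intensity in row %d of %s", neg[1], path))
  if (zero_as_missing) intensity[intensity == 0] <- NA_real_
  feature_table(df[[mz_col]], df[[rt_col]], intensity, nm[sample_cols])
}

#' Write a feature table to TSV
#'
#' Inverse of [read_feature_table()]: columns `mz`, `rt`, then one per sample.
#' Missing intensities are written as empty cells (not 0), so a round trip
#' preserves the missingness pattern.
#'
#' @param table a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(mz = table$features$mz, rt = table$features$rt,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(table$intensity, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Columns: `sample_id`, `group` (levels `case` / `control`), plus any
#' covariate columns.
#'
#' @param path path to a tab-separated file.
#' @return a data.frame with factor-free character columns.
#' @export
read_sample_info <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_info(df)
}

#' Validate a sample metadata data.frame
#' @param samples data.frame with `sample_id` and `group` columns.
#' @return the validated data.frame.
#' @export
validate_sample_info <- function(samples) {
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("sample info needs 'sample_id' and 'group' columns")
  if (anyDuplicated(samples$sample_id))
    stop("sample_id values must be unique")
  if (!all(samples$group %in% c("case", "control")))
    stop("group must be 'case' or 'control'")
  samples
}

#' Write sample metadata to TSV
#' @param samples validated sample info data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_info <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a metabolite mass database from TSV
#'
#' Columns `id`, `name`, `formula`, `mass` (`pathway` optional). Each record
#' needs a formula and/or a monoisotopic mass; missing masses are filled from
#' the formula via [monoisotopic_mass()], and when both are present they must
#' agree within 1e-4 Da.
#'
#' @param path path to a tab-separated file.
#' @return data.frame with columns id, name, formula, mass, pathway.
#' @export
read_metabolite_db <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(formula = "character"))
  if (nrow(df) == 0)
    return(data.frame(id = character(), name = character(),
                      formula = character(), mass = numeric(),
                      pathway = character(), stringsAsFactors = FALSE))
  validate_metabolite_db(df)
}

#' Validate (and mass-fill) a metabolite database data.frame
#' @param db data.frame with at least `id`, `name`, and `formula` and/or
#'   `mass` columns.
#' @return validated data.frame with every `mass` resolved.
#' @export
validate_metabolite_db <- function(db) {
  if (!all(c("id", "name") %in% names(db)))
    stop("metabolite db needs 'id' and 'name' columns")
  if (!"formula" %in% names(db)) db$formula <- NA_character_
  if (!"mass" %in% names(db)) db$mass <- NA_real_
  if (!"pathway" %in% names(db)) db$pathway <- NA_character_
  db$formula[!is.na(db$formula) & !nzchar(db$formula)] <- NA_character_
  db$mass <- as.numeric(db$mass)
  neither <- is.na(db$formula) & is.na(db$mass)
  if (any(neither))
    stop(sprintf("record '%s' has neither formula nor mass", db$id[which(neither)[1]]))
  has_f <- !is.na(db$formula)
  fm <- rep(NA_real_, nrow(db))
  fm[has_f] <- vapply(db$formula[has_f], monoisotopic_mass, numeric(1))
  both <- has_f & !is.na(db$mass)
  off <- both & abs(fm - db$mass) > 1e-4
  if (any(off))
    stop(sprintf("record '%s': formula mass %.6f disagrees with stated mass %.6f",
                 db$id[which(off)[1]], fm[which(off)[1]], db$mass[which(off)[1]]))
  db$mass[is.na(db$mass)] <- fm[is.na(db$mass)]
  if (any(db$mass <= 0)) stop("monoisotopic mass must be positive")
  db[, c("id", "name", "formula", "mass", "pathway")]
}

#' Write a metabolite database to TSV
#' @param db validated metabolite database data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metabolite_db <- function(db, path) {
  out <- db
  out$mass <- formatC(out$mass, format = "f", digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "mwaskit")
  if (!nzchar(p)) stop("packaged fixture not found: ", file)
  p
}

#' Transcribed cluster table of discriminating m/z features
#'
#' The published table of 21 discriminating m/z features with one or more
#' Pearson correlations at r > 0.81: 17 features in four clusters plus 4
#' independent features, each with its printed correlated-feature m/z list.
#' m/z values are kept at the printed 3-decimal precision. Two cluster-1 rows
#' share m/z 341.192 (same m/z, distinct retention times).
#'
#' @return data.frame with columns `cluster` (character: "1".."4" or
#'   "Independent"), `mz` (numeric), and `correlated` (comma-separated m/z
#'   string as printed).
#' @export
load_table1_fixture <- function() {
  df <- utils::read.delim(extdata_path("table1_clusters.tsv"),
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "character"))
  df
}

#' Transcribed annotation table of clustered discriminating features
#'
#' The published annotation table for the 17 clustered features: per-feature
#' direction of change in cases (Higher/Lower) and database matches.
#'
#' @return data.frame with columns `cluster`, `mz`, `presence`,
#'   `metlin_match`, `correlated_matches`.
#' @export
load_table2_fixture <- function() {
  utils::read.delim(extdata_path("table2_annotations.tsv"),
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "numeric", "character",
                                   "character", "character"))
}

#' Cohort demographics fixture
#'
#' 2x2 comorbidity / exposure counts for the 26-case / 19-control cohort,
#' reconstructed from the published percentages, plus the continuous age
#' summaries. Printed p-values are carried along for comparison.
#'
#' @return list with elements `categorical` (variable, case_with,
#'   case_without, control_with, control_without, printed_p) and `continuous`
#'   (variable, case_mean, case_sd, case_n, control_mean, control_sd,
#'   control_n, printed_p).
#' @export
load_demographics_fixture <- function() {
  list(
    categorical = utils::read.delim(extdata_path("demographics_categorical.tsv"),
                                    stringsAsFactors = FALSE),
    continuous = utils::read.delim(extdata_path("demographics_continuous.tsv"),
                                   stringsAsFactors = FALSE)
  )
}
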