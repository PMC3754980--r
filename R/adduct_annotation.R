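# Monoisotopic element masses (Da), most-abundant isotope.
ELEMENT_MASSES <- c(
  C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  S = 31.97207069, P = 30.97376151, Na = 22.98976928, K = 38.9637069,
  Cl = 34.96885271
)

# Cation masses are electron-corrected (mass of H/Na/K minus one electron).
PROTON_MASS <- 1.007276

#' Positive-mode adduct table
#'
#' The five singly-charged positive-mode adduct forms used for database
#' matching: M+H, M+Na, M+K, the water-loss protonated form M+H-H2O, and the
#' water-cluster form M+H+2H2O. `mass_shift` is added to the neutral
#' monoisotopic mass M to obtain the theoretical m/z.
#'
#' @param preset `"default"` (all five) or `"metlin-batch"` (the four forms
#'   used in batch searches: no M+K).
#' @return data.frame with columns `name` and `mass_shift` (Da).
#' @export
adduct_table <- function(preset = c("default", "metlin-batch")) {
  preset <- match.arg(preset)
  tab <- data.frame(
    name = c("M+H", "M+Na", "M+K", "M+H-H2O", "M+H+2H2O"),
    mass_shift = c(1.007276, 22.989218, 38.963158,
                   1.007276 - 18.010565, 1.007276 + 36.021130),
    stringsAsFactors = FALSE
  )
  if (preset == "metlin-batch") tab <- tab[tab$name != "M+K", ]
  tab
}

#' Monoisotopic mass of a chemical formula
#'
#' Sums most-abundant-isotope element masses over a Hill-style formula such
#' as `"C26H43NO6"`. Supported elements: C, H, N, O, S, P, Na, K, Cl.
#'
#' @param formula formula string; element symbols with optional positive
#'   integer counts.
#' @return monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("H2O")        # 18.010565
#' monoisotopic_mass("C26H43NO6")  # glycocholic acid, 465.309038
monoisotopic_mass <- function(formula) {
  if (!is.character(formula) || length(formula) != 1 || !nzchar(formula))
    stop("formula must be a single non-empty string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("malformed formula: ", formula)
  syms <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(syms, names(ELEMENT_MASSES))
  if (length(unknown) > 0)
    stop("unknown element symbol: ", unknown[1])
  if (any(counts < 1)) stop("malformed formula: ", formula)
  sum(ELEMENT_MASSES[syms] * counts)
}

#' Theoretical adduct m/z of a neutral mass
#'
#' @param M neutral monoisotopic mass (Da), > 0.
#' @param adduct adduct name (row of [adduct_table()]) or a one-row
#'   data.frame with a `mass_shift` column.
#' @return theoretical m/z (singly charged).
#' @export
adduct_mz <- function(M, adduct) {
  if (any(M <= 0)) stop("neutral mass must be positive")
  if (is.character(adduct)) {
    tab <- adduct_table()
    shift <- tab$mass_shift[match(adduct, tab$name)]
    if (any(is.na(shift))) stop("unknown adduct: ", adduct[is.na(shift)][1])
  } else {
    shift <- adduct$mass_shift
  }
  M + shift
}

#' Annotation search settings
#'
#' @param ppm_tolerance maximum |mass error| in parts per million (default
#'   10, the database search tolerance; the instrument's nominal accuracy is
#'   5 ppm and a 9 ppm preset matches the pathway-database searches).
#' @param adducts adduct data.frame from [adduct_table()] or a preset name.
#' @param mz_range numeric length-2 acquisition window (Da).
#' @return list of validated settings.
#' @export
annotation_config <- function(ppm_tolerance = 10, adducts = "default",
                              mz_range = c(85, 850)) {
  if (is.character(adducts)) adducts <- adduct_table(adducts)
  stopifnot(ppm_tolerance > 0, nrow(adducts) >= 1,
            length(mz_range) == 2, mz_range[1] < mz_range[2])
  list(ppm_tolerance = ppm_tolerance, adducts = adducts, mz_range = mz_range)
}

#' Match one observed m/z against a metabolite database
#'
#' Enumerates every (record, adduct) pair whose theoretical m/z lies within
#' the ppm tolerance of the observed value. The signed ppm error is
#' `1e6 * (observed - theoretical) / theoretical`; matching uses its absolute
#' value. Hits are sorted by |ppm| ascending; exact ties keep the adduct
#' order of the adduct table.
#'
#' @param mz_observed observed m/z (Da).
#' @param db validated metabolite database (see [read_metabolite_db()]).
#' @param config settings from [annotation_config()].
#' @return data.frame of hits: `record_id`, `name`, `adduct`,
#'   `theoretical_mz`, `ppm_error` (possibly zero rows).
#' @export
annotate_feature <- function(mz_observed, db, config = annotation_config()) {
  empty <- data.frame(record_id = character(), name = character(),
                      adduct = character(), theoretical_mz = numeric(),
                      ppm_error = numeric(), stringsAsFactors = FALSE)
  if (nrow(db) == 0) return(empty)
  theo <- outer(db$mass, config$adducts$mass_shift, `+`)  # records x adducts
  ppm <- 1e6 * (mz_observed - theo) / theo
  hit <- which(abs(ppm) <= config$ppm_tolerance, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  out <- data.frame(
    record_id = db$id[hit[, 1]],
    name = db$name[hit[, 1]],
    adduct = config$adducts$name[hit[, 2]],
    theoretical_mz = theo[hit],
    ppm_error = ppm[hit],
    stringsAsFactors = FALSE
  )
  out <- out[order(abs(out$ppm_error), hit[, 2]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate every feature of an ion cluster
#'
#' Batch search: annotates the cluster's seed features and its correlated
#' satellite features against the database, and summarises which distinct
#' records were matched and which features had no match (the batch analogue
#' of searching a correlated feature group together).
#'
#' @param cluster an `ion_cluster` (see [build_clusters()]), or any list with
#'   `seed_mz` and `satellite_mz` numeric vectors.
#' @param db validated metabolite database.
#' @param config settings from [annotation_config()].
#' @return list with `hits` (per-feature annotation data.frame with a `role`
#'   column), `matched_records` (distinct record ids), `unmatched_mz`
#'   (features with no hit).
#' @export
annotate_cluster <- function(cluster, db, config = annotation_config()) {
  mzs <- c(cluster$seed_mz, cluster$satellite_mz)
  roles <- c(rep("seed", length(cluster$seed_mz)),
             rep("satellite", length(cluster$satellite_mz)))
  hits <- vector("list", length(mzs))
  unmatched <- numeric(0)
  for (i in seq_along(mzs)) {
    h <- annotate_feature(mzs[i], db, config)
    if (nrow(h) == 0) {
      unmatched <- c(unmatched, mzs[i])
    } else {
      h$mz <- mzs[i]
      h$role <- roles[i]
      hits[[i]] <- h
    }
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(record_id = character(), name = character(),
                       adduct = character(), theoretical_mz = numeric(),
                       ppm_error = numeric(), mz = numeric(),
                       role = character(), stringsAsFactors = FALSE)
  list(hits = hits,
       matched_records = unique(hits$record_id),
       unmatched_mz = unmatched)
}

#' Background match rate of random m/z values
#'
#' Fraction of m/z values drawn uniformly over the acquisition range that
#' match at least one database record within the ppm tolerance — the chance
#' level against which real annotation yields should be judged.
#'
#' @param db validated metabolite database.
#' @param config settings from [annotation_config()].
#' @param n_draws number of random m/z values (>= 100).
#' @param seed RNG seed for reproducibility.
#' @return fraction in [0, 1].
#' @export
background_match_rate <- function(db, config = annotation_config(),
                                  n_draws = 1000, seed = 1) {
  if (n_draws < 100) stop("n_draws must be >= 100")
  draws <- local_rng(seed, stats::runif(n_draws, config$mz_range[1],
                                        config$mz_range[2]))
  if (nrow(db) == 0) return(0)
  # a draw matches if any theoretical m/z lies within ppm window
  theo <- sort(as.vector(outer(db$mass, config$adducts$mass_shift, `+`)))
  hitone <- function(mz) {
    i <- findInterval(mz, theo)
    cand <- theo[pmax(1, i):pmin(length(theo), i + 1)]
    any(abs(1e6 * (mz - cand) / cand) <= config$ppm_tolerance)
  }
  mean(vapply(draws, hitone, logical(1)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
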