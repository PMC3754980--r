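#' Synthetic cohort settings
#'
#' Defaults emulate the study conditions the pipeline is designed for: a
#' 26-case / 19-control positive-mode ESI dataset over m/z 85-850 with about
#' 1680 features (560 chemicals x 3 adducts), within-chemical correlated
#' features, log-normal intensities, and limit-of-detection plus random
#' missingness.
#'
#' @param n_cases,n_controls group sizes (default 26 / 19).
#' @param n_chemicals number of latent chemicals (default 560).
#' @param adducts_per_chemical ion forms emitted per chemical (default 3).
#' @param differential_fraction fraction of chemicals with a true group
#'   difference (default 0.1).
#' @param effect_size_log2 case-vs-control shift of the latent log2
#'   abundance for differential chemicals (default 1).
#' @param sigma_between SD of the latent log2 abundance across samples
#'   (default 1.0).
#' @param sigma_adduct SD of per-feature log2 noise around the latent
#'   abundance (default 0.2; at this level features of one chemical
#'   typically correlate above 0.81).
#' @param dropout_rate random (MCAR) missingness rate (default 0.05).
#' @param lod_quantile global intensity quantile below which values are
#'   censored as missing (default 0.10).
#' @param mz_error_ppm_sd SD of the m/z measurement error in ppm (default 3).
#' @param mz_range acquisition window in Da (default c(85, 850)).
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-chemical
#'   baseline log2 abundance (default 17 +/- 2, a typical ion-count scale).
#' @param seed RNG seed; the same config + seed reproduces the dataset
#'   bit-for-bit.
#' @return list of validated settings.
#' @export
simulation_config <- function(n_cases = 26, n_controls = 19,
                              n_chemicals = 560, adducts_per_chemical = 3,
                              differential_fraction = 0.1,
                              effect_size_log2 = 1, sigma_between = 1.0,
                              sigma_adduct = 0.2, dropout_rate = 0.05,
                              lod_quantile = 0.10, mz_error_ppm_sd = 3,
                              mz_range = c(85, 850),
                              baseline_log2_mean = 17, baseline_log2_sd = 2,
                              seed = 1) {
  stopifnot(n_cases + n_controls >= 4, n_chemicals >= 1,
            adducts_per_chemical >= 1,
            differential_fraction >= 0, differential_fraction <= 1,
            sigma_between >= 0, sigma_adduct >= 0,
            dropout_rate >= 0, dropout_rate <= 1,
            lod_quantile >= 0, lod_quantile <= 1,
            mz_error_ppm_sd >= 0, length(mz_range) == 2,
            mz_range[1] < mz_range[2])
  as.list(environment())
}

#' Synthetic metabolite mass database
#'
#' Random records with masses spaced so that adduct windows of distinct
#' records do not collide: neutral masses are drawn on a grid over the mass
#' range with at least `min_spacing_ppm` relative separation. Intended for
#' simulation and annotation round-trip studies; records are synthetic, not
#' real compounds.
#'
#' @param n number of records.
#' @param mass_range neutral-mass range in Da.
#' @param min_spacing_ppm minimum relative spacing between masses (default
#'   50 ppm).
#' @param seed RNG seed.
#' @return validated metabolite database data.frame.
#' @export
synthetic_metabolite_db <- function(n, mass_range = c(90, 800),
                                    min_spacing_ppm = 50, seed = 1) {
  local_rng(seed, {
    lo <- log(mass_range[1]); hi <- log(mass_range[2])
    step <- min_spacing_ppm * 1e-6
    grid <- exp(seq(lo, hi, by = step))
    if (length(grid) < n)
      stop("mass range too narrow for ", n, " records at this spacing")
    masses <- sort(sample(grid, n))
    # jitter within a third of the spacing so masses are not exactly gridded
    masses <- masses * exp(stats::runif(n, -step / 3, step / 3))
    data.frame(id = sprintf("syn%04d", seq_len(n)),
               name = sprintf("synthetic metabolite %d", seq_len(n)),
               formula = NA_character_, mass = masses,
               pathway = NA_character_, stringsAsFactors = FALSE)
  })
}

#' Simulate a case-control LC-MS feature table with ground truth
#'
#' Generative model: each chemical j has latent log2 abundance
#' `a[j, i] = mu_j + beta_j * 1(case_i) + eps`, `eps ~ N(0, sigma_between^2)`;
#' it emits one feature per adduct with log2 intensity
#' `a[j, i] + log2(f_k) + eta`, `eta ~ N(0, sigma_adduct^2)`, where the
#' per-chemical ionization efficiencies `f` are a Dirichlet draw over the
#' adduct set (so one chemical's features share the latent signal and hence
#' correlate). Feature m/z is the record's adduct m/z perturbed by
#' `N(0, (ppm * mz / 1e6)^2)` measurement error; records whose perturbed m/z
#' falls outside the acquisition window are replaced by a resampled record.
#' Intensities below the `lod_quantile` of the pooled intensity
#' distribution, plus a random `dropout_rate` subset, are set missing.
#'
#' @param config settings from [simulation_config()].
#' @param db metabolite database with at least `n_chemicals` rows (default: a
#'   synthetic db of the right size).
#' @return list with `table` (`feature_table`), `samples` (sample info
#'   data.frame), and `truth` (see below). `truth` has `chemicals`
#'   (chemical_id, record_id, differential, effect_size_log2),
#'   `features` (feature_id, chemical_id, record_id, adduct), and
#'   `resampled` (record ids swapped out for falling off-range).
#' @export
simulate_dataset <- function(config = simulation_config(), db = NULL) {
  if (is.null(db))
    db <- synthetic_metabolite_db(config$n_chemicals,
                                  mass_range = config$mz_range * c(1.05, 0.9),
                                  seed = config$seed + 1L)
  if (nrow(db) < config$n_chemicals)
    stop("db has fewer records than n_chemicals")
  local_rng(config$seed, simulate_dataset_impl(config, db))
}

simulate_dataset_impl <- function(config, db) {
  n <- config$n_cases + config$n_controls
  is_case <- c(rep(TRUE, config$n_cases), rep(FALSE, config$n_controls))
  sample_ids <- sprintf("S%02d", seq_len(n))
  adducts <- adduct_table()
  adducts <- adducts[seq_len(min(config$adducts_per_chemical, nrow(adducts))), ,
                     drop = FALSE]
  ad_per <- config$adducts_per_chemical
  if (ad_per > nrow(adducts))
    adducts <- adducts[rep(seq_len(nrow(adducts)), length.out = ad_per), ]

  nchem <- config$n_chemicals
  pick <- sample(nrow(db), nchem)
  n_diff <- round(config$differential_fraction * nchem)
  differential <- seq_len(nchem) <= n_diff  # first chemicals carry the effect
  beta <- ifelse(differential,
                 config$effect_size_log2 * sample(c(-1, 1), nchem, TRUE), 0)
  mu <- stats::rnorm(nchem, config$baseline_log2_mean, config$baseline_log2_sd)

  # resample records whose adduct m/z would leave the window
  feasible <- function(mass) {
    mzs <- mass + adducts$mass_shift
    all(mzs > config$mz_range[1] & mzs < config$mz_range[2])
  }
  resampled <- character(0)
  pool <- setdiff(seq_len(nrow(db)), pick)
  for (j in seq_len(nchem)) {
    tries <- 0
    while (!feasible(db$mass[pick[j]]) && length(pool) > 0 && tries < 1000) {
      resampled <- c(resampled, db$id[pick[j]])
      cand <- sample(length(pool), 1)
      pick[j] <- pool[cand]
      pool <- pool[-cand]
      tries <- tries + 1
    }
    if (!feasible(db$mass[pick[j]]))
      stop("could not place chemical ", j, " inside the m/z window")
  }

  chem_ids <- sprintf("chem%04d", seq_len(nchem))
  nfeat <- nchem * ad_per
  mz <- rt <- numeric(nfeat)
  feat_chem <- integer(nfeat)
  feat_adduct <- character(nfeat)
  log2I <- matrix(NA_real_, nfeat, n)
  rt_chem <- stats::runif(nchem, 30, 570)

  for (j in seq_len(nchem)) {
    a <- mu[j] + beta[j] * is_case + stats::rnorm(n, 0, config$sigma_between)
    f <- stats::rgamma(ad_per, shape = 2)
    f <- f / sum(f)
    for (k in seq_len(ad_per)) {
      i <- (j - 1) * ad_per + k
      theo <- db$mass[pick[j]] + adducts$mass_shift[k]
      mz[i] <- theo + stats::rnorm(1, 0, config$mz_error_ppm_sd * theo / 1e6)
      rt[i] <- rt_chem[j] + stats::rnorm(1, 0, 0.5)
      feat_chem[i] <- j
      feat_adduct[i] <- adducts$name[k]
      log2I[i, ] <- a + log2(f[k]) +
        stats::rnorm(n, 0, config$sigma_adduct)
    }
  }
  intensity <- 2^log2I
  # LOD censoring on the pooled distribution, then MCAR dropout
  if (config$lod_quantile > 0) {
    lod <- stats::quantile(intensity, config$lod_quantile, na.rm = TRUE)
    intensity[intensity < lod] <- NA_real_
  }
  if (config$dropout_rate > 0) {
    drop <- stats::runif(length(intensity)) < config$dropout_rate
    intensity[drop] <- NA_real_
  }
  tab <- feature_table(mz, rt, intensity, sample_ids)
  samples <- data.frame(sample_id = sample_ids,
                        group = ifelse(is_case, "case", "control"),
                        stringsAsFactors = FALSE)
  truth <- list(
    chemicals = data.frame(chemical_id = chem_ids,
                           record_id = db$id[pick],
                           differential = differential,
                           effect_size_log2 = beta,
                           stringsAsFactors = FALSE),
    features = data.frame(feature_id = tab$features$feature_id,
                          chemical_id = chem_ids[feat_chem],
                          record_id = db$id[pick[feat_chem]],
                          adduct = feat_adduct,
                          stringsAsFactors = FALSE),
    resampled = resampled
  )
  list(table = tab, samples = samples, truth = truth)
}

#' Recovery report against simulation ground truth
#'
#' Scores a pipeline run on a simulated dataset: sensitivity and false
#' discovery proportion of differential-chemical detection (a chemical
#' counts as detected if any of its features is in the chosen significant
#' set), adjusted Rand agreement between the recovered ion clusters and the
#' true chemical partition, and the fraction of features whose top
#' annotation hit is the generating record.
#'
#' @param truth the `truth` element of [simulate_dataset()] output.
#' @param mwas_result an `mwas_result`, or `NULL` to skip.
#' @param siglist which significant set defines detection: `"raw"`,
#'   `"log2"`, or `"intersection"`.
#' @param clusters output of [build_clusters()], or `NULL` to skip.
#' @param annotations data.frame mapping `feature_id` to the top-hit
#'   `record_id` (e.g. assembled from [annotate_feature()]), or `NULL`.
#' @return one-row data.frame with `sensitivity`, `fdp`, `n_detected`,
#'   `cluster_ari`, `annotation_top_hit_rate` (NA where skipped).
#' @export
truth_recovery_report <- function(truth, mwas_result = NULL,
                                  siglist = c("raw", "log2", "intersection"),
                                  clusters = NULL, annotations = NULL) {
  siglist <- match.arg(siglist)
  sens <- fdp <- ndet <- ari <- tophit <- NA_real_
  if (!is.null(mwas_result)) {
    if (!all(mwas_result$feature_id %in% truth$features$feature_id))
      stop("mwas result features do not match the simulated feature universe")
    sig <- switch(siglist, raw = mwas_result$sig_raw,
                  log2 = mwas_result$sig_log2,
                  intersection = mwas_result$in_intersection)
    sig_feats <- mwas_result$feature_id[sig]
    det_chem <- unique(truth$features$chemical_id[
      truth$features$feature_id %in% sig_feats])
    truly_diff <- truth$chemicals$chemical_id[truth$chemicals$differential]
    ndet <- length(det_chem)
    sens <- if (length(truly_diff) > 0)
      length(intersect(det_chem, truly_diff)) / length(truly_diff)
    else NA_real_
    fdp <- if (ndet > 0)
      length(setdiff(det_chem, truly_diff)) / ndet else 0
  }
  if (!is.null(clusters)) {
    assigned <- unlist(lapply(clusters$clusters, function(cl) {
      stats::setNames(rep(cl$cluster_id, length(cl$seed_features)),
                      cl$seed_features)
    }))
    if (length(assigned) >= 2) {
      true_part <- truth$features$chemical_id[
        match(names(assigned), truth$features$feature_id)]
      ari <- mclust::adjustedRandIndex(unname(assigned), true_part)
    }
  }
  if (!is.null(annotations)) {
    m <- match(annotations$feature_id, truth$features$feature_id)
    if (any(is.na(m)))
      stop("annotated features do not match the simulated feature universe")
    tophit <- mean(annotations$record_id == truth$features$record_id[m])
  }
  data.frame(sensitivity = sens, fdp = fdp, n_detected = ndet,
             cluster_ari = ari, annotation_top_hit_rate = tophit)
}
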