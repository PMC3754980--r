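#' Default pipeline configuration
#'
#' Nested stage settings with the published defaults (50% presence, FDR
#' q = 0.05 raw / 0.2 log2, r > 0.81 clustering, 10 ppm annotation, top 5%
#' loadings, stratified 10-fold CV).
#'
#' @param seed global seed; stage seeds derive from it.
#' @return nested configuration list.
#' @export
pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    simulation = simulation_config(seed = seed),
    mwas = mwas_config(),
    correlation = correlation_config(),
    annotation = annotation_config(),
    panel = panel_config(seed = seed)
  )
}

#' Run the end-to-end MWAS pipeline
#'
#' Stage order: load or simulate inputs, presence filter, dual-scale MWAS
#' with FDR, correlation clustering of the intersection features, adduct
#' annotation of the clusters, OPLS-DA/LDA panel. Writes
#' `feature_table.tsv` (when simulated), `samples.tsv`, `mwas_results.tsv`,
#' `manhattan.tsv`, `clusters.tsv`, `annotations.tsv`, `panel.json`,
#' `scores.tsv`, and `manifest.json` (config echo, seed, per-stage row
#' counts) into `out_dir`. A rerun with the same config and inputs is
#' bit-identical.
#'
#' @param config nested configuration from [pipeline_config()], or a path to
#'   a YAML file with the same structure.
#' @param out_dir output directory (created if needed).
#' @param feature_table_path,samples_path input paths; when `NULL` the
#'   synthetic generator supplies the cohort.
#' @param db_path metabolite database path; when `NULL` and simulating, the
#'   simulation's synthetic database is used.
#' @return invisibly, a list of the in-memory stage results plus the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         feature_table_path = NULL, samples_path = NULL,
                         db_path = NULL) {
  if (is.character(config)) config <- config_from_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "mwaskit",
                   version = as.character(utils::packageVersion("mwaskit")),
                   seed = config$seed, config = config_echo(config))

  if (is.null(feature_table_path)) {
    db <- if (!is.null(db_path)) read_metabolite_db(db_path) else
      synthetic_metabolite_db(config$simulation$n_chemicals,
                              mass_range = config$simulation$mz_range *
                                c(1.05, 0.9),
                              seed = config$simulation$seed + 1L)
    sim <- simulate_dataset(config$simulation, db)
    tab <- sim$table; samples <- sim$samples; truth <- sim$truth
    write_feature_table(tab, file.path(out_dir, "feature_table.tsv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         dataframe = "columns", digits = NA)
  } else {
    if (is.null(samples_path))
      stop("configuration error: samples_path required with feature_table_path")
    tab <- read_feature_table(feature_table_path)
    samples <- read_sample_info(samples_path)
    truth <- NULL
    if (!is.null(db_path)) {
      if (!file.exists(db_path))
        stop("configuration error: metabolite db not found: ", db_path)
      db <- read_metabolite_db(db_path)
    } else db <- NULL
  }
  write_sample_info(samples, file.path(out_dir, "samples.tsv"))

  filtered <- presence_filter(tab, config$mwas$presence_threshold)
  mwas <- run_mwas(filtered, samples, config$mwas)
  utils::write.table(mwas, file.path(out_dir, "mwas_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(manhattan_export(mwas),
                     file.path(out_dir, "manhattan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cmat <- correlation_matrix(filtered, config$correlation)
  seeds <- mwas$feature_id[mwas$in_intersection]
  built <- build_clusters(seeds, cmat, filtered, config$correlation)
  utils::write.table(cluster_report(built),
                     file.path(out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ann <- NULL
  if (!is.null(db)) {
    groups <- c(built$clusters, built$independent)
    ann <- do.call(rbind, lapply(groups, function(cl) {
      res <- annotate_cluster(cl, db, config$annotation)
      if (nrow(res$hits) == 0) return(NULL)
      cbind(cluster = cl$cluster_id, res$hits)
    }))
    if (is.null(ann))
      ann <- data.frame(cluster = character(), record_id = character(),
                        name = character(), adduct = character(),
                        theoretical_mz = numeric(), ppm_error = numeric(),
                        mz = numeric(), role = character())
    utils::write.table(ann, file.path(out_dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  panel <- panel_report(filtered, samples, config$panel)
  jsonlite::write_json(
    list(selected_features = panel$selected,
         variance_explained = as.list(panel$variance_explained),
         resubstitution_accuracy = panel$resubstitution_accuracy,
         cv_scheme = config$panel$cv_scheme,
         cv_accuracy = panel$cv_accuracy),
    file.path(out_dir, "panel.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(panel$scores, file.path(out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest$counts <- list(
    total_features = n_features(tab),
    filtered_features = n_features(filtered),
    significant_raw = sum(mwas$sig_raw),
    significant_log2 = sum(mwas$sig_log2),
    intersection = sum(mwas$in_intersection),
    clusters = length(built$clusters),
    clustered_seeds = sum(vapply(built$clusters,
                                 function(cl) length(cl$seed_features),
                                 integer(1))),
    independent_seeds = length(built$independent),
    annotation_hits = if (is.null(ann)) NA else nrow(ann),
    panel_size = length(panel$selected)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(table = tab, filtered = filtered, samples = samples,
                 truth = truth, mwas = mwas, clusters = built,
                 annotations = ann, panel = panel, manifest = manifest))
}

config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(seed = if (!is.null(raw$seed)) raw$seed else 1)
  for (stage in c("simulation", "mwas", "correlation", "annotation",
                  "panel")) {
    if (!is.null(raw[[stage]])) {
      unknown <- setdiff(names(raw[[stage]]), names(cfg[[stage]]))
      if (length(unknown) > 0)
        stop("configuration error: unknown ", stage, " setting: ",
             unknown[1])
      cfg[[stage]][names(raw[[stage]])] <- raw[[stage]]
    }
  }
  # re-validate through the constructors
  cfg$simulation <- do.call(simulation_config, cfg$simulation)
  cfg$mwas <- do.call(mwas_config, cfg$mwas)
  cfg$correlation <- do.call(correlation_config, cfg$correlation)
  cfg$annotation <- do.call(
    annotation_config,
    cfg$annotation[intersect(names(cfg$annotation),
                             names(formals(annotation_config)))])
  cfg$panel <- do.call(panel_config, cfg$panel)
  cfg
}

config_echo <- function(config) {
  rapply(config, function(x)
    if (is.data.frame(x)) NULL else x, how = "replace")
}

#' Human-readable pipeline summary
#'
#' Plain-text report over a pipeline output directory: the feature-count
#' cascade (total >= filtered >= significant >= intersection), the cluster
#' table, the annotation table, and panel accuracies.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return the report lines, invisibly; printed to the console.
#' @export
pipeline_report <- function(out_dir) {
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  cn <- manifest$counts
  lines <- c(
    "MWAS pipeline summary",
    "=====================",
    sprintf("features: %d total -> %d after presence filter", cn$total_features,
            cn$filtered_features),
    sprintf("significant: %d raw, %d log2, %d intersection",
            cn$significant_raw, cn$significant_log2, cn$intersection))
  if (cn$intersection == 0)
    lines <- c(lines, "no discriminatory features")
  lines <- c(lines, sprintf("clusters: %d (seeds %d), independent seeds %d",
                            cn$clusters, cn$clustered_seeds,
                            cn$independent_seeds))
  cl_path <- file.path(out_dir, "clusters.tsv")
  if (file.exists(cl_path)) {
    cl <- utils::read.delim(cl_path, stringsAsFactors = FALSE)
    if (nrow(cl) > 0) {
      lines <- c(lines, "", "Cluster | m/z | Correlated m/z Features",
                 sprintf("%s | %.3f | %s", cl$cluster, cl$mz, cl$correlated))
    }
  }
  ann_path <- file.path(out_dir, "annotations.tsv")
  if (file.exists(ann_path)) {
    ann <- utils::read.delim(ann_path, stringsAsFactors = FALSE)
    lines <- c(lines, "", sprintf("annotation hits: %d", nrow(ann)))
  }
  panel_path <- file.path(out_dir, "panel.json")
  if (file.exists(panel_path)) {
    pj <- jsonlite::read_json(panel_path)
    lines <- c(lines, "",
               sprintf("panel: %d features; resubstitution %.3f; %s CV %.3f",
                       length(pj$selected_features),
                       pj$resubstitution_accuracy, pj$cv_scheme,
                       pj$cv_accuracy))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
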