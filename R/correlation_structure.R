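#' Ion-clustering settings
#'
#' @param r_threshold Pearson correlation threshold, strict `>` (default
#'   0.81, the empirical level at which features derived from the same
#'   chemical correlate).
#' @param scale correlation scale, `"log2"` (default) or `"raw"`.
#' @param min_overlap minimum paired non-missing samples per correlation
#'   (default 10; pairs below it get `NA`).
#' @return list of validated settings.
#' @export
correlation_config <- function(r_threshold = 0.81, scale = c("log2", "raw"),
                               min_overlap = 10) {
  stopifnot(r_threshold > 0, r_threshold < 1, min_overlap >= 3)
  list(r_threshold = r_threshold, scale = match.arg(scale),
       min_overlap = min_overlap)
}

#' Feature-feature Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations between all features of a table,
#' on the configured scale. Pairs with fewer than `min_overlap` shared
#' non-missing samples, and pairs involving a constant feature, are `NA`.
#'
#' @param table a `feature_table`.
#' @param config settings from [correlation_config()].
#' @return symmetric matrix of correlations with unit diagonal, feature ids
#'   as dimnames.
#' @export
correlation_matrix <- function(table, config = correlation_config()) {
  X <- t(table$intensity)  # samples x features
  if (config$scale == "log2") {
    X[!is.na(X) & X <= 0] <- NA_real_
    X <- log2(X)
  }
  suppressWarnings(R <- stats::cor(X, use = "pairwise.complete.obs"))
  overlap <- crossprod(!is.na(X))
  R[overlap < config$min_overlap] <- NA_real_
  diag(R) <- 1
  dimnames(R) <- list(table$features$feature_id, table$features$feature_id)
  R
}

#' Cluster discriminatory features by correlation
#'
#' Implements the published cluster construction: among the discriminatory
#' (seed) features, keep those with at least one correlation above the
#' threshold to any feature of the full filtered table; connect seeds that
#' correlate with each other above the threshold; connected components of
#' two or more seeds are clusters, seeds with correlates but no seed-seed
#' edge are "independent". Every non-seed feature correlated above threshold
#' with a cluster seed is attached as a satellite, ranked by decreasing r.
#' Cluster labels are assigned in order of the smallest seed m/z.
#'
#' @param discriminatory character vector of seed feature ids (e.g. the
#'   intersection features of an [run_mwas()] result).
#' @param matrix correlation matrix over the full filtered table, from
#'   [correlation_matrix()].
#' @param full_table the `feature_table` the matrix was computed on (for m/z
#'   and canonical ordering).
#' @param config settings from [correlation_config()].
#' @return list with `clusters` (list of `ion_cluster` objects with
#'   `cluster_id`, `seed_features`, `seed_mz`, `satellite_features`,
#'   `satellite_mz`, `seed_edges`) and `independent` (same shape, one seed
#'   each).
#' @export
build_clusters <- function(discriminatory, matrix, full_table,
                           config = correlation_config()) {
  feats <- full_table$features
  # canonical order: m/z ascending, then rt
  discriminatory <- intersect(
    feats$feature_id[order(feats$mz, feats$rt)], discriminatory)
  if (length(discriminatory) == 0)
    return(list(clusters = list(), independent = list()))
  if (!all(discriminatory %in% rownames(matrix)))
    stop("discriminatory features missing from the correlation matrix")
  thr <- config$r_threshold
  corr_of <- function(id) {
    r <- matrix[id, ]
    r <- r[!is.na(r) & names(r) != id & r > thr]
    sort(r, decreasing = TRUE)
  }
  correlates <- lapply(discriminatory, corr_of)
  names(correlates) <- discriminatory
  retained <- discriminatory[vapply(correlates, length, integer(1)) > 0]
  if (length(retained) == 0)
    return(list(clusters = list(), independent = list()))
  # seed-seed edges
  sub <- matrix[retained, retained, drop = FALSE]
  edge_idx <- which(upper.tri(sub) & !is.na(sub) & sub > thr, arr.ind = TRUE)
  edges <- data.frame(from = retained[edge_idx[, 1]],
                      to = retained[edge_idx[, 2]],
                      r = sub[edge_idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = retained))
  comp <- igraph::components(g)
  membership <- comp$membership[retained]
  mzs <- feats$mz[match(retained, feats$feature_id)]
  mk <- function(seed_ids, cid) {
    sat <- sort(unlist(unname(lapply(correlates[seed_ids], function(r) {
      r[setdiff(names(r), retained)]
    }))), decreasing = TRUE)
    sat <- sat[!duplicated(names(sat))]
    seed_sub <- edges[edges$from %in% seed_ids & edges$to %in% seed_ids, ,
                      drop = FALSE]
    structure(list(
      cluster_id = cid,
      seed_features = seed_ids,
      seed_mz = feats$mz[match(seed_ids, feats$feature_id)],
      satellite_features = names(sat),
      satellite_mz = feats$mz[match(names(sat), feats$feature_id)],
      satellite_r = unname(sat),
      seed_edges = seed_sub,
      correlates = lapply(correlates[seed_ids], function(r) {
        data.frame(feature_id = names(r),
                   mz = feats$mz[match(names(r), feats$feature_id)],
                   r = unname(r), stringsAsFactors = FALSE)
      })
    ), class = "ion_cluster")
  }
  comp_ids <- unique(membership)
  comp_seeds <- lapply(comp_ids, function(k) retained[membership == k])
  multi <- vapply(comp_seeds, length, integer(1)) >= 2
  clusters <- comp_seeds[multi]
  singles <- comp_seeds[!multi]
  # order clusters by smallest seed m/z
  ord <- order(vapply(clusters, function(s) min(mzs[match(s, retained)]),
                      numeric(1)))
  clusters <- clusters[ord]
  clusters <- lapply(seq_along(clusters),
                     function(i) mk(clusters[[i]], as.character(i)))
  singles <- singles[order(vapply(singles,
                                  function(s) mzs[match(s, retained)],
                                  numeric(1)))]
  independent <- lapply(singles, function(s) mk(s, "Independent"))
  list(clusters = clusters, independent = independent)
}

#' Cluster table in published layout
#'
#' One row per retained seed feature: cluster label (or "Independent"), the
#' seed m/z, and its correlated features above threshold, ranked by
#' decreasing correlation, formatted at the given precision.
#'
#' @param built output of [build_clusters()], or a data.frame already in
#'   (cluster, mz, correlated) shape (passed through, which makes the
#'   formatter the identity on a transcribed fixture).
#' @param digits m/z print precision (default 3, the published precision).
#' @return data.frame with columns `cluster`, `mz`, `correlated`.
#' @export
cluster_report <- function(built, digits = 3) {
  if (is.data.frame(built)) {
    out <- built[, c("cluster", "mz", "correlated")]
    rownames(out) <- NULL
    return(out)
  }
  fmt <- function(x) formatC(x, format = "f", digits = digits)
  rows <- list()
  for (cl in c(built$clusters, built$independent)) {
    for (i in seq_along(cl$seed_features)) {
      id <- cl$seed_features[i]
      cr <- cl$correlates[[id]]
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl$cluster_id,
        mz = cl$seed_mz[i],
        correlated = paste(fmt(cr$mz), collapse = ", "),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(cluster = character(), mz = numeric(),
                      correlated = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
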