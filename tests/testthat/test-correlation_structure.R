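# naive two-pass pairwise-complete Pearson correlation
cor_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

test_that("correlation matrix matches the naive formula and handles degeneracy", {
  set.seed(40)
  n <- 20
  intens <- matrix(2^rnorm(8 * n, 15, 2), 8, n)
  intens[sample(length(intens), 25)] <- NA
  intens[7, ] <- intens[1, ]              # duplicated feature
  intens[8, ] <- rep(1000, n)             # constant on log2 scale
  tab <- feature_table(101:108, 1:8, intens, sprintf("S%d", 1:n))
  cfg <- correlation_config(min_overlap = 5)
  R <- correlation_matrix(tab, cfg)
  expect_equal(diag(R), rep(1, 8), ignore_attr = TRUE)
  expect_equal(R, t(R))
  L <- log2(intens)
  for (i in 1:6) for (j in 1:6) {
    if (sum(!is.na(L[i, ]) & !is.na(L[j, ])) >= 5)
      expect_equal(R[i, j], cor_oracle(L[i, ], L[j, ]), tolerance = 1e-12)
  }
  expect_equal(R[1, 7], 1)                    # duplicate rows correlate at 1
  expect_true(all(is.na(R[8, -8])))           # constant feature flagged NA
  # anti-correlated profiles on the raw scale
  tab2 <- feature_table(c(1, 2), c(1, 2),
                        rbind(1:10, 10:1), sprintf("S%d", 1:10))
  R2 <- correlation_matrix(tab2, correlation_config(scale = "raw",
                                                    min_overlap = 5))
  expect_equal(R2[1, 2], -1)
  # pairs below min_overlap are missing
  sparse <- matrix(NA_real_, 2, 20)
  sparse[1, 1:8] <- 2^rnorm(8, 10)
  sparse[2, 5:12] <- 2^rnorm(8, 10)
  tab3 <- feature_table(c(5, 6), c(1, 2), sparse, sprintf("S%d", 1:20))
  R3 <- correlation_matrix(tab3, correlation_config(min_overlap = 5))
  expect_true(is.na(R3[1, 2]))
})

test_that("cluster construction recovers planted adduct groups", {
  bt <- block_table(n_chem = 3, k = 3, n = 24, sigma = 0.01, seed = 41)
  R <- correlation_matrix(bt$table, correlation_config())
  all_ids <- bt$table$features$feature_id
  built <- build_clusters(all_ids, R, bt$table)
  expect_length(built$clusters, 3)
  expect_length(built$independent, 0)
  sizes <- vapply(built$clusters, function(cl) length(cl$seed_features),
                  integer(1))
  expect_equal(sizes, c(3L, 3L, 3L))
  # recovered partition equals the generating chemical partition
  for (cl in built$clusters) {
    chem <- bt$chem[match(cl$seed_features, all_ids)]
    expect_length(unique(chem), 1)
  }
  # clusters ordered by smallest seed m/z; seeds/satellites disjoint
  first_mz <- vapply(built$clusters, function(cl) min(cl$seed_mz), numeric(1))
  expect_true(!is.unsorted(first_mz))
  for (cl in built$clusters)
    expect_length(intersect(cl$seed_features, cl$satellite_features), 0)
})

test_that("seed-edge rule separates independents and satellite-only links", {
  # two seeds correlated only through a shared satellite stay independent
  set.seed(42)
  n <- 30
  shared <- rnorm(n)
  a <- shared + rnorm(n, 0, 1.6)          # weakly tied to the satellite hub
  b <- -shared + rnorm(n, 0, 1.6)
  hub <- shared
  ab_r <- cor(a, b)
  expect_lt(abs(ab_r), 0.81)
  intens <- 2^rbind(a + 15, b + 15, hub + 15)
  tab <- feature_table(c(100, 200, 300), 1:3, intens, sprintf("S%d", 1:n))
  R <- correlation_matrix(tab, correlation_config(scale = "log2"))
  # force the seed-satellite links above threshold by thresholding directly
  R[1, 3] <- R[3, 1] <- 0.95
  R[2, 3] <- R[3, 2] <- 0.95
  R[1, 2] <- R[2, 1] <- 0.2
  built <- build_clusters(c("100@1", "200@2"), R, tab)
  expect_length(built$clusters, 0)
  expect_length(built$independent, 2)
  expect_equal(built$independent[[1]]$satellite_features, "300@3")
  # one seed with no correlations above threshold is dropped entirely
  R[1, 3] <- R[3, 1] <- 0.5
  R[2, 3] <- R[3, 2] <- 0.5
  built2 <- build_clusters(c("100@1"), R, tab)
  expect_length(built2$clusters, 0)
  expect_length(built2$independent, 0)
  # empty discriminatory set
  built3 <- build_clusters(character(0), R, tab)
  expect_length(built3$clusters, 0)
})

test_that("cluster output is invariant to seed input order and threshold-monotone", {
  bt <- block_table(n_chem = 4, k = 3, n = 30, sigma = 0.15, seed = 43)
  R <- correlation_matrix(bt$table, correlation_config())
  ids <- bt$table$features$feature_id
  b1 <- build_clusters(ids, R, bt$table)
  b2 <- build_clusters(rev(ids), R, bt$table)
  expect_equal(lapply(b1$clusters, `[[`, "seed_features"),
               lapply(b2$clusters, `[[`, "seed_features"))
  # raising the threshold can only split or shrink merged components
  n_big <- function(thr) {
    b <- build_clusters(ids, R, bt$table,
                        correlation_config(r_threshold = thr))
    max(0, vapply(b$clusters, function(cl) length(cl$seed_features),
                  integer(1)))
  }
  expect_gte(n_big(0.5), n_big(0.95))
})

test_that("satellites are rank-ordered by correlation with strict threshold", {
  bt <- block_table(n_chem = 2, k = 4, n = 30, sigma = 0.2, seed = 44)
  R <- correlation_matrix(bt$table, correlation_config())
  ids <- bt$table$features$feature_id
  built <- build_clusters(ids[c(1, 5)], R, bt$table)
  for (cl in c(built$clusters, built$independent)) {
    expect_true(all(diff(cl$satellite_r) <= 0))
    expect_true(all(cl$satellite_r > 0.81))
    for (cr in cl$correlates) expect_true(all(diff(cr$r) <= 0))
  }
  # a tie exactly at the threshold is excluded (strict >)
  Rt <- matrix(c(1, 0.81, 0.81, 1), 2,
               dimnames = list(ids[1:2], ids[1:2]))
  tab2 <- feature_table(bt$table$features$mz[1:2], bt$table$features$rt[1:2],
                        bt$table$intensity[1:2, ], colnames(bt$table$intensity))
  bt2 <- build_clusters(ids[1:2], Rt, tab2)
  expect_length(bt2$clusters, 0)
  expect_length(bt2$independent, 0)
})

test_that("cluster report reproduces the published table shape", {
  t1 <- load_table1_fixture()
  # the formatter is the identity on rows already in published shape
  out <- cluster_report(t1)
  expect_equal(out$cluster, t1$cluster)
  expect_equal(out$mz, t1$mz)
  expect_equal(out$correlated, t1$correlated)
  # empty input gives a header-only frame
  empty <- cluster_report(list(clusters = list(), independent = list()))
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty), c("cluster", "mz", "correlated"))
  # synthetic clusters: one row per retained seed, m/z at 3 decimals
  bt <- block_table(n_chem = 2, k = 3, n = 24, sigma = 0.05, seed = 45)
  R <- correlation_matrix(bt$table, correlation_config())
  built <- build_clusters(bt$table$features$feature_id, R, bt$table)
  rep_ <- cluster_report(built)
  expect_equal(nrow(rep_), 6)
  expect_true(all(grepl("^\\d+\\.\\d{3}(, \\d+\\.\\d{3})*$", rep_$correlated)))
})
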