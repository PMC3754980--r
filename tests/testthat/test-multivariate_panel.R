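# independent single-y NIPALS PLS, written against the textbook recursion
pls_oracle <- function(X, y, ncomp) {
  Xs <- scale(X)
  yc <- y - mean(y)
  W <- T_ <- P <- NULL
  for (k in seq_len(ncomp)) {
    w <- drop(crossprod(Xs, yc)); w <- w / sqrt(sum(w^2))
    t <- drop(Xs %*% w)
    p <- drop(crossprod(Xs, t)) / sum(t^2)
    cc <- sum(yc * t) / sum(t^2)
    Xs <- Xs - tcrossprod(t, p)
    yc <- yc - cc * t
    W <- cbind(W, w); T_ <- cbind(T_, t); P <- cbind(P, p)
  }
  list(weights = W, scores = T_, loadings = P)
}

sep_data <- function(n = 40, p = 12, delta = 3, seed = 70) {
  set.seed(seed)
  y <- rep(c("case", "control"), c(ceiling(n / 2), floor(n / 2)))
  X <- matrix(rnorm(n * p), n, p)
  X[y == "case", 1] <- X[y == "case", 1] + delta
  list(X = X, y = y)
}

test_that("OPLS with zero orthogonal components is plain PLS-DA", {
  d <- sep_data()
  m <- fit_opls(d$X, d$y, panel_config(n_orthogonal = 0, n_predictive = 2))
  ref <- pls_oracle(d$X, ifelse(d$y == "case", 1, -1), 2)
  expect_equal(unname(m$scores), unname(ref$scores), tolerance = 1e-10)
  expect_equal(unname(m$weights), unname(ref$weights), tolerance = 1e-10)
  expect_equal(unname(m$loadings), unname(ref$loadings), tolerance = 1e-10)
})

test_that("first predictive weight recovers a planted discriminant direction", {
  set.seed(71)
  n <- 60; p <- 30
  y <- rep(c(1, -1), each = n / 2)
  disc <- c(1, rep(0, p - 1))                 # class split along feature 1
  orth <- c(0, 1, rep(0, p - 2))              # strong orthogonal variation
  z <- rnorm(n, 0, 4)
  z <- z - y * sum(z * y) / sum(y * y)  # nuisance scores orthogonal to class
  X <- 1.5 * outer(y, disc) + outer(z, orth) +
    matrix(rnorm(n * p, 0, 0.1), n, p)
  m <- fit_opls(X, y, panel_config(n_orthogonal = 1, n_predictive = 1,
                                   scaling = "mean_center"))
  w1 <- m$weights[, 1]
  cosine <- abs(sum(w1 * disc) / sqrt(sum(w1^2)))
  expect_gte(cosine, 0.99)
  # the orthogonal component's scores absorb the planted nuisance variation
  expect_gte(abs(cor(m$scores_orth[, 1], z)), 0.99)
})

test_that("OPLS variance bookkeeping and score orthogonality hold", {
  d <- sep_data(n = 30, p = 40, seed = 72)
  m <- fit_opls(d$X, d$y, panel_config(n_orthogonal = 2, n_predictive = 2))
  ve <- m$variance_explained
  expect_true(all(ve >= 0))
  expect_lte(sum(ve), 1 + 1e-8)
  S <- cbind(m$scores_orth, m$scores)
  G <- crossprod(S)
  offdiag <- G[upper.tri(G)]
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
  # constant feature under autoscale is refused
  X2 <- d$X; X2[, 3] <- 5
  expect_error(fit_opls(X2, d$y), "constant feature")
  expect_error(fit_opls(cbind(d$X, NA), d$y), "missing")
})

test_that("panel selection ranks by variance-weighted squared loadings", {
  d <- sep_data(n = 40, p = 20, delta = 4, seed = 73)
  m <- fit_opls(d$X, d$y, panel_config(n_orthogonal = 0))
  # the single dominant feature ranks first
  expect_equal(unname(select_top_loadings(m, 0.05)[1]), 1L)
  expect_length(select_top_loadings(m, 1), 20)
  expect_error(select_top_loadings(m, 1.2), "fraction")
  # ceil(0.05 * 1168) = 59 features on a study-sized table
  set.seed(74)
  Xbig <- matrix(rnorm(20 * 1168), 20, 1168)
  ybig <- rep(c("case", "control"), each = 10)
  mbig <- fit_opls(Xbig, ybig, panel_config(n_orthogonal = 0,
                                            n_predictive = 1))
  expect_length(select_top_loadings(mbig, 0.05), 59)
})

test_that("LDA separates well-separated Gaussians and matches MASS when regular", {
  d <- sep_data(n = 60, p = 4, delta = 6, seed = 75)
  m <- fit_lda(d$X, d$y, shrinkage = 0)
  acc <- classification_accuracy(predict_lda(m, d$X), d$y)
  expect_gte(acc, 0.98)
  ref <- MASS::lda(d$X, grouping = d$y)
  expect_equal(as.character(predict(ref, d$X)$class),
               predict_lda(m, d$X),
               tolerance = 0)
  # single feature, equal variances: boundary at the midpoint of class means
  x1 <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  y1 <- rep(c("a", "b"), each = 3)
  m1 <- fit_lda(x1, y1, shrinkage = 0)
  mid <- mean(c(1, 11))
  expect_equal(predict_lda(m1, matrix(mid + 0.01)), "b")
  expect_equal(predict_lda(m1, matrix(mid - 0.01)), "a")
})

test_that("LDA shrinkage keeps p > n fits defined and flags singularity", {
  set.seed(76)
  X <- matrix(rnorm(20 * 50), 20, 50)
  y <- rep(c("case", "control"), each = 10)
  expect_error(fit_lda(X, y, shrinkage = 0), "shrinkage")
  m <- fit_lda(X, y, shrinkage = "auto")
  expect_gt(m$shrinkage, 0)
  expect_length(predict_lda(m, X), 20)
})

test_that("cross-validation schemes partition correctly", {
  d <- sep_data(n = 45, p = 6, delta = 5, seed = 77)
  trainer <- function(X, y) {
    m <- fit_lda(X, y, shrinkage = 0.1)
    function(Xn) predict_lda(m, Xn)
  }
  loo <- cross_validate(d$X, d$y, trainer, "loo")
  expect_length(loo$predictions, 45)
  expect_false(anyNA(loo$predictions))
  expect_gte(loo$accuracy, 0.95)
  cv <- cross_validate(d$X, d$y, trainer, "kfold10_stratified", seed = 7)
  expect_equal(sort(unique(cv$fold)), 1:10)
  # stratification: fold class ratios within one sample of the global ratio
  tab <- table(cv$fold, d$y)
  expect_true(all(abs(tab[, 1] - tab[, 2]) <= 2))
  # a perfect oracle classifier scores 1 under any scheme
  oracle <- function(X, y) { ys <- d$y; function(Xn) ys[match(Xn[, 1], d$X[, 1])] }
  expect_equal(cross_validate(d$X, d$y, oracle, "loo")$accuracy, 1)
})

test_that("identical class distributions give chance-level CV accuracy", {
  set.seed(78)
  X <- matrix(rnorm(44 * 10), 44, 10)
  y <- rep(c("case", "control"), each = 22)
  trainer <- function(Xt, yt) {
    m <- fit_lda(Xt, yt, shrinkage = 0.2)
    function(Xn) predict_lda(m, Xn)
  }
  accs <- sapply(1:10, function(i) {
    cross_validate(X, sample(y), trainer, "kfold10_stratified", seed = i)$accuracy
  })
  # binomial null: mean 0.5, sd ~ 0.075 per run
  expect_lt(abs(mean(accs) - 0.5), 3 * 0.075 / sqrt(10))
})

test_that("CV accuracy does not beat resubstitution on average", {
  set.seed(79)
  diffs <- replicate(8, {
    n <- 40
    y <- rep(c("case", "control"), each = n / 2)
    X <- matrix(rnorm(n * 15), n, 15)
    X[y == "case", 1] <- X[y == "case", 1] + 1
    m <- fit_lda(X, y, shrinkage = 0.1)
    resub <- classification_accuracy(predict_lda(m, X), y)
    trainer <- function(Xt, yt) {
      mm <- fit_lda(Xt, yt, shrinkage = 0.1)
      function(Xn) predict_lda(mm, Xn)
    }
    cv <- cross_validate(X, y, trainer, "kfold10_stratified", seed = 2)
    resub - cv$accuracy
  })
  expect_gte(mean(diffs), 0)
})

test_that("panel pipeline keeps selection inside folds and is column-permutation invariant", {
  sim <- simulate_dataset(simulation_config(n_chemicals = 25,
                                            differential_fraction = 0.2,
                                            effect_size_log2 = 2, seed = 80))
  f <- presence_filter(sim$table)
  X <- t(log2(f$intensity))
  y <- sim$samples$group
  cfg <- panel_config(loading_fraction = 0.2, seed = 3)
  acc1 <- cross_validate(X, y, panel_trainer(cfg), "kfold10_stratified",
                         seed = 3)$accuracy
  set.seed(81)
  perm <- sample(ncol(X))
  acc2 <- cross_validate(X[, perm], y, panel_trainer(cfg),
                         "kfold10_stratified", seed = 3)$accuracy
  expect_equal(acc1, acc2)
})

test_that("panel report returns coherent accuracies and scores", {
  sim <- simulate_dataset(simulation_config(n_chemicals = 30,
                                            differential_fraction = 0.2,
                                            effect_size_log2 = 2.5, seed = 82))
  f <- presence_filter(sim$table)
  pr <- panel_report(f, sim$samples,
                     panel_config(loading_fraction = 0.1, seed = 4))
  expect_length(pr$selected, ceiling(0.1 * sum(apply(
    impute_median(t(log2(f$intensity))), 2, sd) > 0)))
  expect_gte(pr$resubstitution_accuracy, pr$cv_accuracy - 0.1)
  expect_true(all(pr$scores$sample_id == sim$samples$sample_id))
  expect_true(all(c("predictive1", "predictive2", "orthogonal1") %in%
                  names(pr$scores)))
  expect_true(all(pr$variance_explained >= 0) &&
              sum(pr$variance_explained) <= 1 + 1e-8)
})

test_that("PLS-DA scores agree with an established implementation", {
  skip_if_not_installed("mixOmics")
  d <- sep_data(n = 40, p = 12, delta = 3, seed = 70)
  m <- fit_opls(d$X, d$y, panel_config(n_orthogonal = 0, n_predictive = 2))
  ref <- mixOmics::plsda(d$X, factor(d$y), ncomp = 2, scale = TRUE)
  expect_gt(abs(cor(m$scores[, 1], ref$variates$X[, 1])), 1 - 1e-8)
  expect_gt(abs(cor(m$scores[, 2], ref$variates$X[, 2])), 1 - 1e-8)
})
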