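#' Panel-selection settings
#'
#' @param n_orthogonal orthogonal components removed before the predictive
#'   fit (default 1).
#' @param n_predictive predictive components (default 2).
#' @param scaling `"autoscale"` (center + unit variance, the metabolomics
#'   default) or `"mean_center"`.
#' @param loading_fraction fraction of features kept as the panel
#'   (default 0.05).
#' @param cv_scheme `"kfold10_stratified"` or `"loo"`.
#' @param shrinkage LDA covariance shrinkage in [0, 1], or `"auto"`.
#' @param seed RNG seed for fold assignment.
#' @return list of validated settings.
#' @export
panel_config <- function(n_orthogonal = 1, n_predictive = 2,
                         scaling = c("autoscale", "mean_center"),
                         loading_fraction = 0.05,
                         cv_scheme = c("kfold10_stratified", "loo"),
                         shrinkage = "auto", seed = 1) {
  stopifnot(n_orthogonal >= 0, n_predictive >= 1,
            loading_fraction > 0, loading_fraction <= 1)
  list(n_orthogonal = n_orthogonal, n_predictive = n_predictive,
       scaling = match.arg(scaling), loading_fraction = loading_fraction,
       cv_scheme = match.arg(cv_scheme), shrinkage = shrinkage, seed = seed)
}

scale_matrix <- function(X, scaling) {
  ctr <- colMeans(X)
  if (scaling == "autoscale") {
    scl <- apply(X, 2, stats::sd)
    if (any(scl == 0)) {
      bad <- colnames(X)[which(scl == 0)[1]]
      stop("constant feature under autoscaling: ",
           if (is.null(bad)) which(scl == 0)[1] else bad)
    }
  } else {
    scl <- rep(1, ncol(X))
  }
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Fit an orthogonal PLS discriminant model
#'
#' O-PLS with single-y NIPALS: the y-predictive weight direction is
#' `w = X'y / |X'y|`; each orthogonal component is the part of the X loading
#' orthogonal to `w` (`w_o = p - (w'p) w`, normalized), whose scores are
#' removed from X before the predictive PLS components are extracted by
#' NIPALS deflation. Per-component fractions of the total (scaled) X sum of
#' squares are recorded, so the usual "orthogonal removed x%, predictive 1
#' and 2 explain y%/z%" accounting can be read off the model.
#'
#' @param X numeric matrix, samples x features, no missing values.
#' @param y group coding: +1 / -1, or a `"case"`/`"control"` vector.
#' @param config settings from [panel_config()].
#' @param feature_mz optional m/z per feature, used for deterministic
#'   tie-breaks in [select_top_loadings()].
#' @return an `opls_model`: scaling parameters, orthogonal and predictive
#'   weights/scores/loadings, `variance_explained` (named per component),
#'   and the fitted y-regression for prediction.
#' @export
fit_opls <- function(X, y, config = panel_config(), feature_mz = NULL) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must have no missing values (impute upstream)")
  if (is.character(y) || is.factor(y))
    y <- ifelse(as.character(y) == "case", 1, -1)
  stopifnot(length(y) == nrow(X), all(y %in% c(-1, 1)))
  if (min(table(y)) < 2) stop("need >= 2 samples per class")
  sc <- scale_matrix(X, config$scaling)
  Xs <- sc$X
  yc <- y - mean(y)
  ss_total <- sum(Xs^2)
  p_feat <- ncol(Xs)

  W_o <- T_o <- P_o <- NULL
  var_o <- numeric(0)
  Xd <- Xs
  for (k in seq_len(config$n_orthogonal)) {
    w <- drop(crossprod(Xd, yc)); w <- w / sqrt(sum(w^2))
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    w_o <- p - drop(crossprod(w, p)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break  # no orthogonal variation left
    w_o <- w_o / nw
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); T_o <- cbind(T_o, t_o); P_o <- cbind(P_o, p_o)
    var_o <- c(var_o, sum(t_o^2) * sum(p_o^2) / ss_total)
  }

  W <- T_p <- P <- NULL
  cvec <- numeric(0)
  var_p <- numeric(0)
  yd <- yc
  for (k in seq_len(config$n_predictive)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(Xd %*% w)
    cc <- sum(yd * t) / sum(t^2)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    Xd <- Xd - tcrossprod(t, p)
    yd <- yd - cc * t
    W <- cbind(W, w); T_p <- cbind(T_p, t); P <- cbind(P, p)
    cvec <- c(cvec, cc)
    var_p <- c(var_p, sum(t^2) * sum(p^2) / ss_total)
  }
  ve <- c(if (length(var_o)) stats::setNames(var_o,
             paste0("orthogonal", seq_along(var_o))),
          if (length(var_p)) stats::setNames(var_p,
             paste0("predictive", seq_along(var_p))))
  structure(list(
    center = sc$center, scale = sc$scale, scaling = config$scaling,
    weights_orth = W_o, scores_orth = T_o, loadings_orth = P_o,
    weights = W, scores = T_p, loadings = P, y_loadings = cvec,
    y_mean = mean(y), variance_explained = ve,
    feature_mz = feature_mz, feature_names = colnames(X)
  ), class = "opls_model")
}

#' Project new samples onto an OPLS model
#'
#' Applies the training scaling, removes the orthogonal components, and
#' returns predictive scores plus the regression prediction of the group
#' code.
#'
#' @param model an `opls_model`.
#' @param X new samples x features matrix (same feature order as training).
#' @return list with `scores` (predictive), `scores_orth`, and `y_hat`.
#' @export
predict_opls <- function(model, X) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  T_o <- NULL
  if (!is.null(model$weights_orth)) {
    for (k in seq_len(ncol(model$weights_orth))) {
      t_o <- drop(Xs %*% model$weights_orth[, k])
      Xs <- Xs - tcrossprod(t_o, model$loadings_orth[, k])
      T_o <- cbind(T_o, t_o)
    }
  }
  T_p <- NULL
  y_hat <- rep(model$y_mean, nrow(X))
  if (!is.null(model$weights)) {
    for (k in seq_len(ncol(model$weights))) {
      t <- drop(Xs %*% model$weights[, k])
      Xs <- Xs - tcrossprod(t, model$loadings[, k])
      y_hat <- y_hat + model$y_loadings[k] * t
      T_p <- cbind(T_p, t)
    }
  }
  list(scores = T_p, scores_orth = T_o, y_hat = y_hat)
}

#' Select the top-loading panel features
#'
#' Ranks features by the variance-weighted squared predictive loadings
#' (sum over predictive components of loading^2 times that component's
#' explained-variance fraction) and returns the top `ceil(fraction * p)`.
#' Ties are broken by m/z ascending (when the model carries feature m/z),
#' then by feature order.
#'
#' @param model an `opls_model`.
#' @param fraction fraction of features to keep, in (0, 1].
#' @return integer vector of feature column indices, ranked; feature names
#'   attached as names when available.
#' @export
select_top_loadings <- function(model, fraction = 0.05) {
  if (fraction > 1 || fraction <= 0) stop("fraction must be in (0, 1]")
  P <- model$loadings
  if (is.null(P)) stop("model has no predictive components")
  vp <- model$variance_explained[grep("^predictive",
                                      names(model$variance_explained))]
  score <- drop(P^2 %*% vp)
  p <- length(score)
  tie <- if (!is.null(model$feature_mz)) model$feature_mz else seq_len(p)
  ord <- order(-score, tie, seq_len(p))
  keep <- ord[seq_len(ceiling(fraction * p))]
  if (!is.null(model$feature_names)) names(keep) <- model$feature_names[keep]
  keep
}

#' Linear discriminant analysis with shrinkage covariance
#'
#' Two-class Gaussian LDA on the pooled within-class covariance, with
#' optional shrinkage toward the scaled identity
#' `S_lambda = (1 - lambda) S + lambda * mean(diag(S)) I`, which keeps the
#' rule defined when features outnumber samples. Equal class priors (the
#' decision boundary for one feature with equal variances is the midpoint of
#' the class means).
#'
#' @param X training matrix, samples x features, complete.
#' @param y class labels (two classes).
#' @param shrinkage lambda in [0, 1], or `"auto"`: 0 when the pooled
#'   covariance is comfortably full rank (n - 2 > 2 p), else 0.5.
#' @return an `lda_model`.
#' @export
fit_lda <- function(X, y, shrinkage = "auto") {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("exactly two classes required")
  n1 <- sum(y == classes[1]); n2 <- sum(y == classes[2])
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per class")
  p <- ncol(X)
  if (identical(shrinkage, "auto"))
    shrinkage <- if (nrow(X) - 2 > 2 * p) 0 else 0.5
  mu1 <- colMeans(X[y == classes[1], , drop = FALSE])
  mu2 <- colMeans(X[y == classes[2], , drop = FALSE])
  Xc <- X
  Xc[y == classes[1], ] <- sweep(X[y == classes[1], , drop = FALSE], 2, mu1)
  Xc[y == classes[2], ] <- sweep(X[y == classes[2], , drop = FALSE], 2, mu2)
  S <- crossprod(Xc) / (nrow(X) - 2)
  if (shrinkage > 0)
    S <- (1 - shrinkage) * S + shrinkage * mean(diag(S)) * diag(p)
  a <- tryCatch(solve(S, mu1 - mu2), error = function(e)
    stop("singular pooled covariance; use shrinkage > 0"))
  structure(list(classes = classes, direction = a,
                 midpoint = (mu1 + mu2) / 2, shrinkage = shrinkage),
            class = "lda_model")
}

#' @rdname fit_lda
#' @param model an `lda_model`.
#' @param X matrix of samples to classify.
#' @return `predict_lda`: character vector of predicted class labels.
#' @export
predict_lda <- function(model, X) {
  X <- as.matrix(X)
  score <- drop(sweep(X, 2, model$midpoint) %*% model$direction)
  ifelse(score >= 0, model$classes[1], model$classes[2])
}

#' Classification accuracy
#' @param predicted,actual label vectors of equal length.
#' @return fraction correct.
#' @export
classification_accuracy <- function(predicted, actual) {
  mean(as.character(predicted) == as.character(actual))
}

#' Cross-validate a classifier pipeline
#'
#' Runs stratified 10-fold or leave-one-out cross-validation. The
#' `trainer` receives only the training fold (so any scaling, imputation or
#' feature selection it performs stays inside the fold) and must return a
#' prediction function over new rows.
#'
#' @param X samples x features matrix (missing values allowed if the trainer
#'   handles them).
#' @param y class labels.
#' @param trainer `function(X_train, y_train)` returning
#'   `function(X_new) -> labels`.
#' @param scheme `"kfold10_stratified"` or `"loo"`.
#' @param seed RNG seed for fold assignment.
#' @return list with `predictions` (per sample), `fold` (assignment),
#'   `fold_accuracy`, `accuracy` (pooled), `n_invalid_folds`.
#' @export
cross_validate <- function(X, y, trainer,
                           scheme = c("kfold10_stratified", "loo"),
                           seed = 1) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  fold <- integer(n)
  if (scheme == "loo") {
    fold <- seq_len(n)
  } else {
    k <- 10
    fold <- local_rng(seed, {
      f <- integer(n)
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        f[idx] <- rep_len(seq_len(k), length(idx))
      }
      f
    })
  }
  preds <- rep(NA_character_, n)
  invalid <- 0
  for (f in sort(unique(fold))) {
    test <- which(fold == f)
    train <- which(fold != f)
    if (length(unique(y[train])) < 2) {
      invalid <- invalid + 1
      next
    }
    fit <- trainer(X[train, , drop = FALSE], y[train])
    preds[test] <- fit(X[test, , drop = FALSE])
  }
  ok <- !is.na(preds)
  fold_acc <- vapply(sort(unique(fold)), function(f) {
    i <- fold == f & ok
    if (!any(i)) NA_real_ else mean(preds[i] == y[i])
  }, numeric(1))
  list(predictions = preds, fold = fold, fold_accuracy = fold_acc,
       accuracy = mean(preds[ok] == y[ok]), n_invalid_folds = invalid)
}

#' Median-impute missing values, feature-wise
#'
#' Column medians are taken from `stats_from` (the training fold) and
#' applied to `X`, so imputation never leaks test-fold information.
#'
#' @param X matrix to impute.
#' @param stats_from matrix whose column medians are used (default `X`).
#' @return imputed matrix.
#' @export
impute_median <- function(X, stats_from = X) {
  med <- apply(stats_from, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- med[j]
  }
  X
}

#' Standard OPLS + LDA panel trainer for cross-validation
#'
#' Inside each training fold: median-impute, fit the OPLS model, select the
#' top-loading panel, then fit shrinkage LDA on the panel columns. The
#' returned predictor applies the same imputation statistics and panel.
#'
#' @param config settings from [panel_config()].
#' @return a trainer function for [cross_validate()].
#' @export
panel_trainer <- function(config = panel_config()) {
  function(X_train, y_train) {
    Xi <- impute_median(X_train)
    keep_var <- apply(Xi, 2, stats::sd) > 0
    Xi <- Xi[, keep_var, drop = FALSE]
    model <- fit_opls(Xi, y_train, config)
    panel <- select_top_loadings(model, config$loading_fraction)
    lda <- fit_lda(Xi[, panel, drop = FALSE], y_train,
                   shrinkage = config$shrinkage)
    ref <- X_train
    function(X_new) {
      Xn <- impute_median(X_new, stats_from = ref)[, keep_var, drop = FALSE]
      predict_lda(lda, Xn[, panel, drop = FALSE])
    }
  }
}

#' Fit the full multivariate panel report
#'
#' The group-wise half of the pipeline: impute, fit OPLS-DA, take the
#' top-loading panel, fit LDA on it, and report resubstitution plus
#' cross-validated accuracy under the configured scheme.
#'
#' @param table a filtered `feature_table`.
#' @param samples sample info data.frame.
#' @param config settings from [panel_config()].
#' @return list with `model` (`opls_model`), `selected` (panel feature ids),
#'   `variance_explained`, `resubstitution_accuracy`, `cv_accuracy`,
#'   `cv` (full [cross_validate()] output), and per-sample `scores`.
#' @export
panel_report <- function(table, samples, config = panel_config()) {
  samples <- validate_sample_info(samples)
  X <- t(table$intensity)
  X[!is.na(X) & X <= 0] <- NA_real_
  X <- log2(X)
  y <- samples$group[match(rownames(X), samples$sample_id)]
  Xi <- impute_median(X)
  keep_var <- apply(Xi, 2, stats::sd) > 0
  Xi <- Xi[, keep_var, drop = FALSE]
  mzs <- table$features$mz[keep_var]
  model <- fit_opls(Xi, y, config, feature_mz = mzs)
  panel <- select_top_loadings(model, config$loading_fraction)
  lda <- fit_lda(Xi[, panel, drop = FALSE], y, shrinkage = config$shrinkage)
  resub <- classification_accuracy(predict_lda(lda, Xi[, panel, drop = FALSE]),
                                   y)
  cv <- cross_validate(X, y, panel_trainer(config),
                       scheme = config$cv_scheme, seed = config$seed)
  scores <- data.frame(sample_id = rownames(X), group = y,
                       model$scores,
                       check.names = FALSE, stringsAsFactors = FALSE)
  names(scores)[-(1:2)] <- paste0("predictive", seq_len(ncol(model$scores)))
  if (!is.null(model$scores_orth)) {
    so <- as.data.frame(model$scores_orth)
    names(so) <- paste0("orthogonal", seq_len(ncol(so)))
    scores <- cbind(scores, so)
  }
  list(model = model,
       selected = table$features$feature_id[keep_var][panel],
       variance_explained = model$variance_explained,
       resubstitution_accuracy = resub,
       cv_accuracy = cv$accuracy, cv = cv, scores = scores)
}
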