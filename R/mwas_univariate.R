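#' MWAS screening settings
#'
#' @param presence_threshold minimum fraction of samples in which a feature
#'   must be detected to be tested (default 0.50).
#' @param q_raw FDR level for the non-transformed analysis (default 0.05).
#' @param q_log2 FDR level for the log2-transformed analysis (default 0.2).
#' @param test_variant `"welch"` or `"pooled"` two-sample t-test.
#' @param log2_offset non-negative offset added before log2 (default 0:
#'   non-positive values stay missing).
#' @return list of validated settings.
#' @export
mwas_config <- function(presence_threshold = 0.50, q_raw = 0.05,
                        q_log2 = 0.2, test_variant = "welch",
                        log2_offset = 0) {
  stopifnot(presence_threshold > 0, presence_threshold < 1,
            q_raw > 0, q_raw < 1, q_log2 > 0, q_log2 < 1, log2_offset >= 0)
  list(presence_threshold = presence_threshold, q_raw = q_raw,
       q_log2 = q_log2, test_variant = match.arg(test_variant,
                                                 c("welch", "pooled")),
       log2_offset = log2_offset)
}

#' Drop features detected in too few samples
#'
#' Keeps features whose non-missing intensity count over all samples is at
#' least `threshold` of the sample count; feature order is preserved.
#'
#' @param table a `feature_table`.
#' @param threshold presence fraction in (0, 1), default 0.5.
#' @return the filtered `feature_table`.
#' @export
presence_filter <- function(table, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  if (n_features(table) == 0) return(table)
  frac <- rowSums(!is.na(table$intensity)) / n_samples(table)
  subset_features(table, frac >= threshold)
}

subset_features <- function(table, keep) {
  feature_table(table$features$mz[keep], table$features$rt[keep],
                table$intensity[keep, , drop = FALSE],
                colnames(table$intensity),
                feature_id = table$features$feature_id[keep])
}

#' Feature-wise two-group t-tests
#'
#' Two-tailed t-test per feature on the chosen scale. On the log2 scale only
#' positive intensities are transformed (after the configured offset);
#' non-positive and missing values are excluded pairwise. Features with fewer
#' than two present values in either group are untestable: their statistics
#' are `NA` and they are excluded from the multiple-testing denominator.
#'
#' @param table a (filtered) `feature_table`.
#' @param groups character vector over samples, `"case"` / `"control"`, in
#'   the table's sample order.
#' @param scale `"raw"` or `"log2"`.
#' @param variant t-test variant, see [t_test_two_sided()].
#' @param log2_offset offset added before the log2 transform (log2 scale
#'   only).
#' @return data.frame: `feature_id`, `t`, `p`, `testable`, `mean_case`,
#'   `mean_control`.
#' @export
feature_tests <- function(table, groups, scale = c("raw", "log2"),
                          variant = "welch", log2_offset = 0) {
  scale <- match.arg(scale)
  stopifnot(length(groups) == n_samples(table))
  is_case <- groups == "case"
  X <- table$intensity
  if (scale == "log2") {
    X <- X + log2_offset
    X[!is.na(X) & X <= 0] <- NA_real_
    X <- log2(X)
  }
  nfeat <- nrow(X)
  t_ <- p_ <- mc <- mk <- rep(NA_real_, nfeat)
  testable <- rep(FALSE, nfeat)
  for (i in seq_len(nfeat)) {
    xc <- X[i, is_case]; xk <- X[i, !is_case]
    xc <- xc[!is.na(xc)]; xk <- xk[!is.na(xk)]
    if (length(xc) >= 2 && length(xk) >= 2 &&
        (stats::sd(xc) > 0 || stats::sd(xk) > 0)) {
      tt <- t_test_two_sided(xc, xk, variant = variant)
      t_[i] <- tt$t; p_[i] <- tt$p
      mc[i] <- tt$mean_x; mk[i] <- tt$mean_y
      testable[i] <- TRUE
    } else if (length(xc) >= 2 && length(xk) >= 2) {
      # both groups constant
      tt <- t_test_two_sided(xc, xk, variant = variant)
      t_[i] <- tt$t; p_[i] <- tt$p
      mc[i] <- mean(xc); mk[i] <- mean(xk)
      testable[i] <- is.finite(tt$t)
    }
  }
  data.frame(feature_id = table$features$feature_id, t = t_, p = p_,
             testable = testable, mean_case = mc, mean_control = mk,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up false discovery rate control
#'
#' Step-up rule at level `q`: with the m non-missing p-values sorted
#' ascending, reject hypotheses 1..k where k is the largest i with
#' p(i) <= i*q/m. Adjusted q-values are the monotone minimum of p(i)*m/i,
#' capped at 1; rejection flags come from the step-up definition itself (they
#' coincide with `q_adj <= q` by construction).
#'
#' @param pvalues numeric vector in [0, 1]; `NA` entries are excluded from m
#'   and never rejected.
#' @param q FDR level in (0, 1).
#' @return list with `q_adj` (same length as input) and `reject` (logical).
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  n <- length(pvalues)
  q_adj <- rep(NA_real_, n)
  reject <- rep(FALSE, n)
  ok <- which(!is.na(pvalues))
  m <- length(ok)
  if (m == 0) return(list(q_adj = q_adj, reject = reject))
  o <- ok[order(pvalues[ok])]
  ps <- pvalues[o]
  adj <- rev(cummin(rev(ps * m / seq_len(m))))
  q_adj[o] <- pmin(adj, 1)
  k <- which(ps <= seq_len(m) * q / m)
  if (length(k) > 0) reject[o[seq_len(max(k))]] <- TRUE
  list(q_adj = q_adj, reject = reject)
}

#' Run the full univariate MWAS screen
#'
#' Composes the per-feature tests at both scales with BH FDR control at the
#' two configured levels, flags the intersection (features significant on
#' both scales), and records the direction of change in cases.
#'
#' @param table a presence-filtered `feature_table`.
#' @param samples sample info data.frame (`sample_id`, `group`).
#' @param config settings from [mwas_config()].
#' @return an `mwas_result`: data.frame with per-feature columns `feature_id`,
#'   `mz`, `rt`, `n_present`, `t_raw`, `p_raw`, `q_raw_adj`, `sig_raw`,
#'   `t_log2`, `p_log2`, `q_log2_adj`, `sig_log2`, `in_intersection`,
#'   `direction`; the config is attached as attribute `config`.
#' @export
run_mwas <- function(table, samples, config = mwas_config()) {
  samples <- validate_sample_info(samples)
  idx <- match(colnames(table$intensity), samples$sample_id)
  if (any(is.na(idx)))
    stop("intensity columns and sample_id do not match")
  groups <- samples$group[idx]
  raw <- feature_tests(table, groups, "raw", config$test_variant)
  lg2 <- feature_tests(table, groups, "log2", config$test_variant,
                       log2_offset = config$log2_offset)
  bh_raw <- bh_fdr(ifelse(raw$testable, raw$p, NA_real_), config$q_raw)
  bh_lg2 <- bh_fdr(ifelse(lg2$testable, lg2$p, NA_real_), config$q_log2)
  direction <- ifelse(is.na(raw$mean_case) | is.na(raw$mean_control), NA,
                      ifelse(raw$mean_case >= raw$mean_control,
                             "higher", "lower"))
  out <- data.frame(
    feature_id = table$features$feature_id,
    mz = table$features$mz, rt = table$features$rt,
    n_present = rowSums(!is.na(table$intensity)),
    t_raw = raw$t, p_raw = raw$p, q_raw_adj = bh_raw$q_adj,
    sig_raw = bh_raw$reject,
    t_log2 = lg2$t, p_log2 = lg2$p, q_log2_adj = bh_lg2$q_adj,
    sig_log2 = bh_lg2$reject,
    in_intersection = bh_raw$reject & bh_lg2$reject,
    direction = direction,
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- config
  class(out) <- c("mwas_result", "data.frame")
  out
}

#' Manhattan-plot data export
#'
#' One row per tested feature, ordered by m/z ascending: m/z, -log10 p on the
#' chosen scale, and the significance flag — the data behind the usual MWAS
#' Manhattan plot.
#'
#' @param result an `mwas_result` from [run_mwas()].
#' @param scale which analysis to plot, `"raw"` (default) or `"log2"`.
#' @return data.frame with columns `mz`, `neg_log10_p`, `significant`.
#' @export
manhattan_export <- function(result, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  p <- if (scale == "raw") result$p_raw else result$p_log2
  sig <- if (scale == "raw") result$sig_raw else result$sig_log2
  keep <- !is.na(p)
  out <- data.frame(mz = result$mz[keep], neg_log10_p = -log10(p[keep]),
                    significant = sig[keep])
  out[order(out$mz), , drop = FALSE]
}
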