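#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test on a 2x2 contingency table (cases with / without,
#' controls with / without). The two-sided p-value follows the
#' point-probability convention: sum the hypergeometric probabilities of all
#' tables with the observed margins whose point probability does not exceed
#' that of the observed table, with a relative tie tolerance of 1e-7. Point
#' probabilities are computed on the log scale (log-gamma via `lchoose`) so
#' large counts cannot overflow.
#'
#' @param a,b,c,d non-negative integer cell counts: cases with the attribute,
#'   cases without, controls with, controls without. A 2x2 matrix may be
#'   passed as `a` instead.
#' @return the two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  m1 <- a + b   # cases
  m2 <- c + d   # controls
  k <- a + c    # total with attribute
  n <- m1 + m2
  if (m1 == 0 || m2 == 0 || k == 0 || k == n) {
    warning("degenerate margin; p = 1")
    return(1)
  }
  support <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, support) + lchoose(m2, k - support) - lchoose(n, k)
  obs <- logp[support == a]
  # relative tie tolerance on the probability scale
  p <- sum(exp(logp)[logp <= obs + log1p(1e-7)])
  min(p, 1)
}

#' Two-sided two-sample t-test, from raw values or group summaries
#'
#' Welch (default) or pooled-variance two-sample t-test. Either raw vectors or
#' `group_summary()` objects (mean, sd, n) may be supplied, so published
#' summary statistics can be tested without the underlying values.
#'
#' @param x,y numeric vectors, or objects from [group_summary()].
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return list with `t`, `df`, `p`, and the two group means.
#' @export
t_test_two_sided <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  sx <- if (inherits(x, "group_summary")) x else group_summary_from(x)
  sy <- if (inherits(y, "group_summary")) y else group_summary_from(y)
  if (sx$n < 2 || sy$n < 2) stop("each group needs n >= 2")
  v1 <- sx$sd^2; v2 <- sy$sd^2
  delta <- sx$mean - sy$mean
  if (v1 == 0 && v2 == 0) {
    if (delta == 0)
      return(list(t = 0, df = sx$n + sy$n - 2, p = 1,
                  mean_x = sx$mean, mean_y = sy$mean))
    return(list(t = sign(delta) * Inf, df = sx$n + sy$n - 2, p = 0,
                mean_x = sx$mean, mean_y = sy$mean))
  }
  if (variant == "welch") {
    se2 <- v1 / sx$n + v2 / sy$n
    tstat <- delta / sqrt(se2)
    df <- se2^2 / (v1^2 / (sx$n^2 * (sx$n - 1)) + v2^2 / (sy$n^2 * (sy$n - 1)))
  } else {
    sp2 <- ((sx$n - 1) * v1 + (sy$n - 1) * v2) / (sx$n + sy$n - 2)
    tstat <- delta / sqrt(sp2 * (1 / sx$n + 1 / sy$n))
    df <- sx$n + sy$n - 2
  }
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df),
       mean_x = sx$mean, mean_y = sy$mean)
}

#' Group summary statistics for summary-based t-tests
#' @param mean group mean (units of the variable).
#' @param sd group standard deviation (same units), >= 0.
#' @param n group size, >= 2.
#' @return a `group_summary` object.
#' @export
group_summary <- function(mean, sd, n) {
  if (sd < 0) stop("sd must be >= 0")
  if (n < 2) stop("n must be >= 2")
  structure(list(mean = mean, sd = sd, n = n), class = "group_summary")
}

group_summary_from <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("each group needs n >= 2 non-missing values")
  group_summary(mean(x), stats::sd(x), length(x))
}

#' Case/control balance table for cohort covariates
#'
#' One row per covariate: Fisher exact test for categorical (logical or
#' two-level) covariates, t-test for continuous ones, mirroring the usual
#' "Table 1" of a case-control study.
#'
#' @param samples sample info data.frame with `sample_id`, `group`, and
#'   covariate columns.
#' @param variant t-test variant, see [t_test_two_sided()].
#' @return data.frame with columns `variable`, `type`, `case_stat`,
#'   `control_stat`, `p`.
#' @export
cohort_balance_table <- function(samples, variant = "welch") {
  samples <- validate_sample_info(samples)
  covars <- setdiff(names(samples), c("sample_id", "group"))
  is_case <- samples$group == "case"
  rows <- list()
  for (v in covars) {
    x <- samples[[v]]
    if (all(is.na(x))) {
      warning("covariate '", v, "' missing for all samples; skipped")
      next
    }
    if (is.numeric(x) && length(unique(stats::na.omit(x))) > 2) {
      tt <- t_test_two_sided(x[is_case], x[!is_case], variant = variant)
      rows[[v]] <- data.frame(
        variable = v, type = "continuous",
        case_stat = sprintf("%.1f±%.1f", tt$mean_x,
                            stats::sd(x[is_case], na.rm = TRUE)),
        control_stat = sprintf("%.1f±%.1f", tt$mean_y,
                               stats::sd(x[!is_case], na.rm = TRUE)),
        p = tt$p, stringsAsFactors = FALSE)
    } else {
      xb <- as.logical(x)
      a <- sum(xb & is_case, na.rm = TRUE)
      b <- sum(!xb & is_case, na.rm = TRUE)
      cc <- sum(xb & !is_case, na.rm = TRUE)
      dd <- sum(!xb & !is_case, na.rm = TRUE)
      p <- fisher_exact_two_sided(a, b, cc, dd)
      rows[[v]] <- data.frame(
        variable = v, type = "categorical",
        case_stat = sprintf("%d/%d", a, a + b),
        control_stat = sprintf("%d/%d", cc, cc + dd),
        p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
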