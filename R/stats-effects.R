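#' Partial eta-squared from an F statistic
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`, the exact SS-based value for any
#' single-error-term ANOVA effect.
#'
#' @param F F statistic (>= 0); vectorised.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Partial eta-squared in `[0, 1)`.
#' @examples
#' partial_eta_squared(41.41, 1, 33)  # 0.56 to two decimals
#' @export
partial_eta_squared <- function(F, df1, df2) {
  if (any(F < 0) || any(df1 <= 0) || any(df2 <= 0))
    stop("F must be >= 0 and degrees of freedom positive", call. = FALSE)
  F * df1 / (F * df1 + df2)
}

#' Confidence interval for partial eta-squared
#'
#' Noncentrality pivot: the bounds are the noncentrality parameters
#' `lambda` at which the observed F sits at the `1 - alpha/2` and
#' `alpha/2` quantiles of the noncentral F distribution, converted via
#' `eta_p^2 = lambda / (lambda + df1 + df2 + 1)`. The lower bound is
#' truncated at 0 when the observed F is below the corresponding central
#' quantile. The default 90% level is the convention that makes the
#' interval consistent with the two-sided 0.05 F test.
#'
#' @param F Observed F statistic.
#' @param df1,df2 Degrees of freedom (possibly non-integer, e.g. after a
#'   sphericity correction).
#' @param level Confidence level (default 0.90).
#' @return Numeric `c(lo, hi)`.
#' @examples
#' round(eta_squared_ci(41.41, 1, 33), 2)  # 0.35 0.67
#' @export
eta_squared_ci <- function(F, df1, df2, level = 0.90) {
  stopifnot(F >= 0, df1 > 0, df2 > 0, level > 0, level < 1)
  alpha <- (1 - level) / 2
  to_eta <- function(ncp) ncp / (ncp + df1 + df2 + 1)
  pnf <- function(ncp) suppressWarnings(stats::pf(F, df1, df2, ncp = ncp))
  pivot <- function(prob) {
    # largest ncp with pf(F | ncp) >= prob is the bound; 0 when even the
    # central distribution puts F below prob
    if (pnf(0) < prob) return(0)
    upper <- max(10, 4 * (F * df1 + df1 + df2))
    while (pnf(upper) > prob) {
      upper <- upper * 2
      if (upper > 1e8)
        stop("numeric failure: noncentrality inversion did not bracket",
             call. = FALSE)
    }
    suppressWarnings(stats::uniroot(function(l) pnf(l) - prob,
                                    c(0, upper), tol = 1e-8)$root)
  }
  c(to_eta(pivot(1 - alpha)), to_eta(pivot(alpha)))
}

#' Paired t-test with Cohen's d and noncentral confidence interval
#'
#' Standard paired t on the difference scores (via [stats::t.test()]),
#' plus the difference-score-standardised Cohen's d, which satisfies
#' `d = t / sqrt(n)` exactly, with its confidence interval by
#' noncentral-t inversion.
#'
#' @param x,y Paired observations (equal length, n >= 2).
#' @param d_ci_level Confidence level of the d interval (default 0.95).
#' @return One-row data frame of class `paired_test`: `t`, `df`, `p`,
#'   `mean_diff`, `d`, `d_ci_lo`, `d_ci_hi`.
#' @export
paired_t <- function(x, y, d_ci_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need n >= 2 pairs", call. = FALSE)
  dif <- x - y
  if (stats::sd(dif) == 0)
    stop("undefined statistic: zero variance of differences", call. = FALSE)
  tt <- stats::t.test(x, y, paired = TRUE)
  tv <- unname(tt$statistic)
  ci <- cohens_d_ci(tv, n, level = d_ci_level)
  structure(data.frame(t = tv, df = n - 1L, p = tt$p.value,
                       mean_diff = unname(tt$estimate),
                       d = tv / sqrt(n),
                       d_ci_lo = ci[1], d_ci_hi = ci[2]),
            class = c("paired_test", "data.frame"))
}

#' Noncentral-t confidence interval for paired Cohen's d
#'
#' Inverts the noncentral t distribution at the observed statistic:
#' bounds are `ncp / sqrt(n)` with `ncp` solving
#' `pt(t, df, ncp) = 1 - alpha/2` (lower) and `alpha/2` (upper).
#'
#' @param t Observed paired t statistic.
#' @param n Number of pairs (df = n - 1).
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lo, hi)`.
#' @examples
#' round(cohens_d_ci(8.53, 34), 2)  # 0.97 1.94
#' @export
cohens_d_ci <- function(t, n, level = 0.95) {
  stopifnot(n >= 2, level > 0, level < 1)
  alpha <- (1 - level) / 2
  df <- n - 1
  bound <- function(prob) {
    lim <- abs(t) + 20 + 5 * sqrt(n)
    stats::uniroot(function(ncp) stats::pt(t, df, ncp) - prob,
                   c(-lim, lim), tol = 1e-8, extendInt = "downX")$root
  }
  suppressWarnings(c(bound(1 - alpha), bound(alpha)) / sqrt(n))
}

#' Within-subject (Cousineau-Morey) confidence intervals
#'
#' Descriptive condition-mean intervals corrected for within-subject
#' designs: each participant's scores are normalised by subtracting the
#' participant mean and adding the grand mean; per-cell variances of the
#' normalised scores are inflated by Morey's factor `M / (M - 1)` for `M`
#' cells, then a t-based interval is computed per cell.
#'
#' @param scores n x M matrix/data frame of per-participant cell means
#'   (complete).
#' @param level Confidence level (default 0.95).
#' @return Data frame: `cell`, `mean`, `ci_half_width`, `lo`, `hi`.
#' @export
within_subject_ci <- function(scores, level = 0.95) {
  scores <- as.matrix(scores)
  M <- ncol(scores)
  if (M < 2) stop("invalid input: need at least 2 cells", call. = FALSE)
  if (any(is.na(scores))) stop("scores must be complete", call. = FALSE)
  n <- nrow(scores)
  norm <- scores - rowMeans(scores) + mean(scores)
  half <- apply(norm, 2, function(v)
    sqrt(M / (M - 1)) * stats::sd(v) / sqrt(n) *
      stats::qt(1 - (1 - level) / 2, n - 1))
  mu <- colMeans(scores)
  data.frame(cell = if (is.null(colnames(scores))) as.character(seq_len(M))
                    else colnames(scores),
             mean = unname(mu), ci_half_width = unname(half),
             lo = unname(mu - half), hi = unname(mu + half),
             stringsAsFactors = FALSE)
}

#' Pearson correlation with residual-based outlier screening
#'
#' Fits the least-squares line of `y` on `x`, removes (in a single pass)
#' points whose residuals lie more than `sd_threshold` standard deviations
#' from the line, and recomputes the correlation on the remainder.
#'
#' @param x,y Numeric vectors, equal length, n >= 3.
#' @param sd_threshold Residual threshold in residual SDs (default 3).
#' @param screen Disable to get the plain Pearson correlation on all
#'   points (default `TRUE`).
#' @return List of class `robust_pearson`: `r`, `p`, `n_used`,
#'   `removed_points` (indices into the input), `sd_threshold`.
#' @export
robust_pearson <- function(x, y, sd_threshold = 3, screen = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  removed <- integer(0)
  use <- which(ok)
  if (screen) {
    fit <- stats::lm(y[use] ~ x[use])
    res <- stats::resid(fit)
    out <- abs(res) > sd_threshold * stats::sd(res)
    removed <- use[out]
    use <- use[!out]
    if (length(use) < 3)
      stop("undefined statistic: fewer than 3 points after screening",
           call. = FALSE)
  }
  ct <- stats::cor.test(x[use], y[use])
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 n_used = length(use), removed_points = removed,
                 sd_threshold = if (screen) sd_threshold else NA_real_),
            class = "robust_pearson")
}

#' @export
print.robust_pearson <- function(x, ...) {
  cat(sprintf("r = %.3f, p = %.4g, n = %d (%d point(s) removed)\n",
              x$r, x$p, x$n_used, length(x$removed_points)))
  invisible(x)
}

#' Per-participant CS+ minus CS- differential scores
#'
#' Collapses a long cell-mean table to one differential per participant
#' and measure: cell means are first averaged within CS type across all
#' other cells (positions, test phases), then differenced. A missing CS
#' marginal propagates `NA`.
#'
#' @param cell_means Long data frame with columns `participant`,
#'   `cs_type`, `measure`, `mean` (e.g. from [aggregate_conditions()];
#'   any extra columns such as `phase`/`position` are averaged over).
#' @return Wide data frame: `participant` plus one differential column
#'   per measure.
#' @export
differential_scores <- function(cell_means) {
  need <- c("participant", "cs_type", "measure", "mean")
  miss <- setdiff(need, names(cell_means))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  marg <- stats::aggregate(list(mean = cell_means$mean),
                           by = list(participant = cell_means$participant,
                                     cs_type = cell_means$cs_type,
                                     measure = cell_means$measure),
                           FUN = function(v) mean(v))  # NA propagates
  plus <- marg[marg$cs_type == "CS+", ]
  minus <- marg[marg$cs_type == "CS-", ]
  m <- merge(plus, minus, by = c("participant", "measure"),
             suffixes = c("_plus", "_minus"), all = TRUE)
  m$differential <- m$mean_plus - m$mean_minus
  out <- stats::reshape(m[, c("participant", "measure", "differential")],
                        idvar = "participant", timevar = "measure",
                        direction = "wide")
  names(out) <- sub("^differential\\.", "diff_", names(out))
  rownames(out) <- NULL
  out[order(out$participant), ]
}
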