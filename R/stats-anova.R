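#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Univariate within-subject decomposition for fully crossed balanced
#' designs with one observation per participant and cell (condition
#' means). For every main effect and interaction the error term is the
#' corresponding effect-by-participant interaction. For effects with more
#' than one numerator degree of freedom the Greenhouse-Geisser epsilon is
#' computed from the covariance of the effect's contrast scores and, when
#' Mauchly's sphericity test rejects at `mauchly_alpha`, the
#' epsilon-corrected degrees of freedom and p-value are adopted; both the
#' corrected and uncorrected rows are always reported. Partial eta-squared
#' and its confidence interval (noncentral-F pivot, 90% by default) are
#' attached per effect.
#'
#' @param data Long data frame with a participant column, the factor
#'   columns and a value column.
#' @param dv Name of the value column.
#' @param within Character vector of within-subject factor column names.
#' @param participant Name of the participant column.
#' @param mauchly_alpha Significance level of Mauchly's test that triggers
#'   the correction (default 0.05).
#' @param eta_ci_level Confidence level for the partial eta-squared
#'   interval (default 0.90).
#' @return Data frame of class `rm_anova` with one row per effect:
#'   `effect`, `df1`, `df2`, `SS_effect`, `SS_error`, `F`, `p_uncorrected`,
#'   `gg_epsilon`, `mauchly_p`, `df1_corr`, `df2_corr`, `p` (corrected
#'   when the correction was applied, see `gg_applied`), `partial_eta_sq`,
#'   `eta_ci_lo`, `eta_ci_hi`.
#' @examples
#' d <- expand.grid(participant = 1:8, position = c("low", "middle", "high"))
#' d$y <- rnorm(nrow(d)) + as.integer(d$position)
#' rm_anova(d, dv = "y", within = "position")
#' @export
rm_anova <- function(data, dv, within, participant = "participant",
                     mauchly_alpha = 0.05, eta_ci_level = 0.90) {
  cols <- c(participant, within, dv)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(is.na(data[[dv]])))
    stop("incomplete design: missing values in `", dv, "`", call. = FALSE)
  d <- data[, cols]
  d[[participant]] <- factor(d[[participant]])
  for (w in within) d[[w]] <- factor(d[[w]])
  n <- nlevels(d[[participant]])
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  k_lev <- vapply(within, function(w) nlevels(d[[w]]), 0L)

  # completeness: exactly one observation per participant x cell
  tab <- table(d[, c(participant, within)])
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)[1, ]
    stop("incomplete design: participant ",
         dimnames(tab)[[1]][bad[1]], " does not have exactly one ",
         "observation in every cell", call. = FALSE)
  }

  # cell-mean array: participants x cells (cells in factor-crossing order)
  cell_key <- interaction(d[rev(within)], sep = ":", lex.order = TRUE)
  y <- tapply(d[[dv]], list(d[[participant]], cell_key), mean)
  grand <- mean(y)

  effects <- unlist(lapply(seq_along(within), function(m)
    utils::combn(within, m, simplify = FALSE)), recursive = FALSE)

  rows <- lapply(effects, function(eff) {
    df1 <- prod(k_lev[eff] - 1L)
    # per-participant means over the effect's cells (averaging the others)
    ym <- effect_cell_means(d, dv, participant, eff)
    M <- orthonormal_contrasts(k_lev[eff])   # cells x df1
    Z <- ym %*% M                            # participants x df1
    zbar <- colMeans(Z)
    reps <- prod(k_lev[setdiff(within, eff)])
    ss_eff <- n * reps * sum(zbar^2)
    ss_err <- reps * sum(sweep(Z, 2, zbar)^2)
    df2 <- df1 * (n - 1L)
    Fv <- (ss_eff / df1) / (ss_err / df2)
    p_unc <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    if (df1 > 1L) {
      S <- stats::cov(Z) * reps
      eps <- gg_epsilon_from_contrast_cov(S, df1)
      mau <- mauchly_p(S, df1, n)
    } else {
      eps <- 1; mau <- NA_real_
    }
    applied <- df1 > 1L && !is.na(mau) && mau < mauchly_alpha
    df1c <- eps * df1
    df2c <- eps * df2
    p_corr <- stats::pf(Fv, df1c, df2c, lower.tail = FALSE)
    pes <- partial_eta_squared(Fv, df1, df2)
    ci <- eta_squared_ci(Fv, df1, df2, level = eta_ci_level)
    data.frame(effect = paste(eff, collapse = ":"),
               df1 = df1, df2 = df2,
               SS_effect = ss_eff, SS_error = ss_err,
               F = Fv, p_uncorrected = p_unc,
               gg_epsilon = eps, mauchly_p = mau,
               df1_corr = df1c, df2_corr = df2c,
               gg_applied = applied,
               p = if (applied) p_corr else p_unc,
               p_gg = p_corr,
               partial_eta_sq = pes,
               eta_ci_lo = ci[1], eta_ci_hi = ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n") <- n
  attr(out, "grand_mean") <- grand
  class(out) <- c("rm_anova", "data.frame")
  out
}

# participants x (cells of `eff`) matrix of means, averaging other factors.
effect_cell_means <- function(d, dv, participant, eff) {
  key <- interaction(d[rev(eff)], sep = ":", lex.order = TRUE)
  tapply(d[[dv]], list(d[[participant]], key), mean)
}

# Kronecker product of per-factor orthonormal (Helmert-based) contrasts.
orthonormal_contrasts <- function(k_lev) {
  mats <- lapply(k_lev, function(k) {
    C <- stats::contr.helmert(k)
    sweep(C, 2, sqrt(colSums(C^2)), "/")
  })
  Reduce(function(a, b) kronecker(b, a), mats)
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-correction factor for a within-subject factor with `k`
#' levels, computed from the covariance matrix of the condition scores:
#' with `S_c` the covariance of the orthonormal contrast scores and
#' `lambda` its eigenvalues, `epsilon = (sum lambda)^2 /
#' ((k - 1) * sum lambda^2)`, clamped to `[1/(k-1), 1]`. Equals 1 under
#' compound symmetry and approaches the lower bound as the covariance
#' degenerates to rank one.
#'
#' @param scores An n x k matrix of per-participant condition scores, or a
#'   k x k covariance matrix (then `n` is only needed for validation).
#' @param k Number of levels (inferred from the input when omitted).
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(scores, k = ncol(scores)) {
  scores <- as.matrix(scores)
  if (nrow(scores) == ncol(scores) && isTRUE(all.equal(scores, t(scores),
                                                       tolerance = 1e-8))) {
    S <- scores
  } else {
    if (nrow(scores) < 2)
      stop("invalid input: need at least 2 participants", call. = FALSE)
    S <- stats::cov(scores)
  }
  if (k < 3) stop("epsilon is defined for k >= 3 levels", call. = FALSE)
  C <- orthonormal_contrasts(k)
  gg_epsilon_from_contrast_cov(t(C) %*% S %*% C, k - 1L)
}

gg_epsilon_from_contrast_cov <- function(Sc, df) {
  tr <- sum(diag(Sc))
  tr2 <- sum(Sc * t(Sc))  # = tr(Sc %*% Sc) for symmetric Sc
  if (tr2 <= .Machine$double.eps) return(1)  # zero contrast variance:
                                             # sphericity trivially holds
  eps <- tr^2 / (df * tr2)
  min(1, max(1 / df, eps))
}

# Mauchly's sphericity test on the contrast-score covariance (p = df1).
mauchly_p <- function(Sc, p, n) {
  if (n - 1L <= p) return(NA_real_)  # test undefined, too few subjects
  ev <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return(0)
  W <- prod(ev) / (mean(ev))^p
  f <- (2 * p^2 + p + 2) / (6 * p)
  chi <- -(n - 1 - f) * log(W)
  df <- p * (p + 1) / 2 - 1
  stats::pchisq(chi, df, lower.tail = FALSE)
}

#' Helmert contrasts on a 3-level within-subject factor
#'
#' Planned contrasts after a repeated-measures ANOVA: level 1 against the
#' mean of levels 2 and 3 (weights 1, -1/2, -1/2) and level 2 against
#' level 3 (weights 0, 1, -1). By default both are tested against the
#' pooled factor-by-participant error term, giving `df = 2 * (n - 1)`
#' (66 for n = 34); `pooled_error = FALSE` uses each contrast's own
#' difference-score variance with `df = n - 1`.
#'
#' @param scores n x 3 matrix (or data frame) of per-participant level
#'   means, columns in factor-level order.
#' @param pooled_error Use the pooled error term (default `TRUE`).
#' @return Data frame with one row per contrast: `label`, `estimate`,
#'   `se`, `t`, `df`, `p`.
#' @export
helmert_contrasts <- function(scores, pooled_error = TRUE) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 3L)
    stop("invalid input: exactly 3 factor levels required", call. = FALSE)
  n <- nrow(scores)
  weights <- list(`1 vs 2+3` = c(1, -0.5, -0.5),
                  `2 vs 3` = c(0, 1, -1))
  if (pooled_error) {
    ybar_s <- rowMeans(scores)
    ybar_l <- colMeans(scores)
    resid <- sweep(sweep(scores, 1, ybar_s), 2, ybar_l) + mean(scores)
    ss_err <- sum(resid^2)
    df <- 2L * (n - 1L)
    mse <- ss_err / df
  }
  rows <- lapply(names(weights), function(lab) {
    w <- weights[[lab]]
    est <- sum(w * colMeans(scores))
    if (pooled_error) {
      se <- sqrt(mse * sum(w^2) / n)
      dfi <- df
    } else {
      cs <- scores %*% w
      se <- stats::sd(cs) / sqrt(n)
      dfi <- n - 1L
    }
    tv <- est / se
    data.frame(label = lab, estimate = est, se = se, t = tv, df = dfi,
               p = 2 * stats::pt(abs(tv), dfi, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
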