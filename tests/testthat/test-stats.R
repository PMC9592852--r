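test_that("rm_anova reproduces the classical univariate decomposition", {
  set.seed(101)
  for (rep in 1:4) {
    d <- expand.grid(participant = 1:7,
                     A = c("a1", "a2"), B = c("b1", "b2", "b3"),
                     stringsAsFactors = FALSE)
    d$y <- rnorm(nrow(d)) + as.integer(factor(d$B)) * 0.8 +
      rnorm(7)[d$participant]
    out <- rm_anova(d, dv = "y", within = c("A", "B"))

    dd <- d
    dd$participant <- factor(dd$participant)
    dd$A <- factor(dd$A); dd$B <- factor(dd$B)
    ao <- summary(aov(y ~ A * B + Error(participant / (A * B)), data = dd))
    ref <- rbind(
      A = ao[["Error: participant:A"]][[1]]["A", c("Df", "F value")],
      B = ao[["Error: participant:B"]][[1]]["B", c("Df", "F value")],
      `A:B` = ao[["Error: participant:A:B"]][[1]]["A:B", c("Df", "F value")])
    for (eff in rownames(ref)) {
      row <- out[out$effect == eff, ]
      expect_equal(row$F, ref[eff, "F value"], tolerance = 1e-8,
                   label = paste("F for", eff))
      expect_equal(row$df1, ref[eff, "Df"])
    }
    # the eta identity holds to machine precision per effect
    expect_equal(out$partial_eta_sq,
                 out$SS_effect / (out$SS_effect + out$SS_error),
                 tolerance = 1e-12)
  }
})

test_that("a 2-level factor reduces exactly to the paired t-test", {
  set.seed(7)
  for (rep in 1:5) {
    x <- rnorm(12); y <- rnorm(12, 0.4)
    d <- data.frame(participant = rep(1:12, 2),
                    cond = rep(c("A", "B"), each = 12), y = c(x, y))
    a <- rm_anova(d, dv = "y", within = "cond")
    tt <- paired_t(x, y)
    expect_equal(a$F, tt$t^2, tolerance = 1e-10)
    expect_equal(a$p_uncorrected, tt$p, tolerance = 1e-10)
  }
})

test_that("rm_anova rejects incomplete or missing-value designs", {
  d <- expand.grid(participant = 1:4, cond = c("a", "b", "c"),
                   stringsAsFactors = FALSE)
  d$y <- rnorm(12)
  expect_error(rm_anova(d[-1, ], dv = "y", within = "cond"),
               "incomplete design")
  d2 <- d; d2$y[3] <- NA
  expect_error(rm_anova(d2, dv = "y", within = "cond"), "missing values")
  expect_error(rm_anova(d[d$participant == 1, ], dv = "y",
                        within = "cond"), "2 participants")
})

test_that("Greenhouse-Geisser epsilon matches the eigenvalue formula", {
  # compound symmetry: epsilon is exactly 1
  n <- 40; k <- 4
  set.seed(3)
  subj <- rnorm(n, sd = 2)
  cs <- sapply(1:k, function(j) subj + rnorm(n))
  expect_gt(gg_epsilon(cs), 0.85)
  # all variance in one contrast: the 1/(k-1) lower bound
  v <- c(1, -1, 0)
  expect_equal(gg_epsilon(tcrossprod(v), k = 3), 0.5)

  for (seed in 1:25) {
    set.seed(seed)
    sc <- matrix(rnorm(6 * 3), 6, 3) %*% matrix(runif(9, -1, 1), 3, 3)
    eps <- gg_epsilon(sc)
    expect_equal(eps, max(0.5, min(1, oracle_gg_epsilon(sc))),
                 tolerance = 1e-8)
    expect_gte(eps, 0.5); expect_lte(eps, 1)
  }
  expect_error(gg_epsilon(matrix(1, 1, 3)), "2 participants")
  expect_error(gg_epsilon(matrix(rnorm(8), 4, 2)), "k >= 3")
})

test_that("Helmert contrasts use the pooled error term with df 2(n-1)", {
  # equal level means: both contrasts are null
  set.seed(4)
  eq <- matrix(rnorm(15), 5, 3)
  eq <- sweep(eq, 2, colMeans(eq)) + 2  # force identical level means
  hc0 <- helmert_contrasts(eq)
  expect_equal(hc0$t, c(0, 0), tolerance = 1e-10)

  # n = 34 gives the conventional df = 66
  set.seed(5)
  hc34 <- helmert_contrasts(matrix(rnorm(34 * 3), 34, 3))
  expect_equal(hc34$df, c(66, 66))

  # hand-computed contrast on a 5-participant table
  sc <- matrix(c(1, 2, 3,
                 2, 3, 4,
                 1.5, 2, 3.5,
                 1, 2.5, 3,
                 2, 2, 4), ncol = 3, byrow = TRUE)
  n <- nrow(sc)
  res <- sweep(sweep(sc, 1, rowMeans(sc)), 2, colMeans(sc)) + mean(sc)
  mse <- sum(res^2) / (2 * (n - 1))
  w1 <- c(1, -0.5, -0.5)
  t1 <- sum(w1 * colMeans(sc)) / sqrt(mse * sum(w1^2) / n)
  w2 <- c(0, 1, -1)
  t2 <- sum(w2 * colMeans(sc)) / sqrt(mse * sum(w2^2) / n)
  hc <- helmert_contrasts(sc)
  expect_equal(hc$t, c(t1, t2), tolerance = 1e-10)
  expect_error(helmert_contrasts(matrix(1, 4, 2)), "3 factor levels")
})

test_that("paired tests report d = t / sqrt(n) with a noncentral CI", {
  set.seed(11)
  x <- rnorm(20, 1); y <- rnorm(20)
  res <- paired_t(x, y)
  expect_equal(res$d, res$t / sqrt(20), tolerance = 1e-12)
  expect_equal(sign(res$d), sign(res$t))
  expect_true(res$d_ci_lo < res$d && res$d < res$d_ci_hi)
  # a mean-matched pair with residual variance keeps t and d at zero
  z <- y + scale(rnorm(20), center = TRUE, scale = FALSE)
  resn <- paired_t(as.numeric(z), y)
  expect_equal(resn$t, 0, tolerance = 1e-10)
  expect_equal(resn$d, 0, tolerance = 1e-10)
  expect_error(paired_t(x, x), "zero variance")
  expect_error(paired_t(x, y[1:5]), "equal length")
})

test_that("eta-squared helpers respect their boundary behaviour", {
  expect_equal(partial_eta_squared(0, 1, 33), 0)
  expect_error(partial_eta_squared(-1, 1, 33), ">= 0")
  ci0 <- eta_squared_ci(0, 1, 33)
  expect_equal(ci0[1], 0)
  # bounds bracket the point estimate when F clears the critical value
  set.seed(13)
  for (i in 1:10) {
    df1 <- sample(1:3, 1); df2 <- sample(20:60, 1)
    F <- runif(1, 0, 30)
    ci <- eta_squared_ci(F, df1, df2)
    pes <- partial_eta_squared(F, df1, df2)
    if (F > qf(0.95, df1, df2)) {
      expect_gt(ci[1], 0)
      expect_true(ci[1] <= pes && pes <= ci[2])
    }
  }
})

test_that("within-subject intervals strip between-participant variance", {
  # identical condition profiles with participant offsets: widths collapse
  prof <- c(1, 2, 3, 4)
  offs <- rnorm(10, sd = 5)
  sc <- outer(offs, rep(1, 4)) + matrix(prof, 10, 4, byrow = TRUE)
  ci <- within_subject_ci(sc)
  expect_true(all(ci$ci_half_width < 1e-8))
  expect_equal(ci$mean, prof + mean(offs))
  expect_error(within_subject_ci(matrix(1:5, 5, 1)), "2 cells")

  # corrected width does not exceed the naive width when offsets dominate
  set.seed(17)
  wins <- replicate(50, {
    sc <- outer(rnorm(8, sd = 4), rep(1, 3)) + matrix(rnorm(24, sd = 0.5), 8, 3)
    corr <- within_subject_ci(sc)$ci_half_width
    naive <- apply(sc, 2, function(v) sd(v) / sqrt(8) * qt(0.975, 7))
    all(corr <= naive)
  })
  expect_gt(mean(wins), 0.9)
})

test_that("residual screening removes gross outliers and only those", {
  x <- seq_len(30)
  y <- 2 * x
  r0 <- robust_pearson(x, y)
  expect_equal(r0$r, 1, tolerance = 1e-12)
  expect_length(r0$removed_points, 0)

  # 67 collinear points plus one planted gross outlier
  set.seed(23)
  x2 <- rnorm(67); y2 <- 3 * x2 + rnorm(67, sd = 0.05)
  x2 <- c(x2, 0); y2 <- c(y2, 10)
  r1 <- robust_pearson(x2, y2)
  expect_equal(r1$removed_points, 68L)
  expect_equal(r1$n_used, 67)
  expect_gt(r1$r, 0.99)

  # disabling the screen reproduces the plain Pearson correlation
  r2 <- robust_pearson(x2, y2, screen = FALSE)
  expect_equal(r2$r, unname(cor(x2, y2)), tolerance = 1e-12)
  expect_length(r2$removed_points, 0)
  expect_error(robust_pearson(1:2, 1:2), "3 complete pairs")
})

test_that("differential scores average positions and phases before the CS difference", {
  cm <- expand.grid(participant = 1:3, phase = c("test_safety", "test_threat"),
                    cs_type = c("CS+", "CS-"),
                    position = c("low", "middle", "high"),
                    measure = "peak_velocity", stringsAsFactors = FALSE)
  cm$mean <- ifelse(cm$cs_type == "CS+", 310, 300)
  d <- differential_scores(cm)
  expect_equal(d$diff_peak_velocity, rep(10, 3))

  cm0 <- cm; cm0$mean <- 250
  expect_equal(differential_scores(cm0)$diff_peak_velocity, rep(0, 3))

  # a missing marginal propagates NA rather than silently dropping
  cmna <- cm
  cmna$mean[cmna$participant == 2 & cmna$cs_type == "CS-"] <- NA
  dna <- differential_scores(cmna)
  expect_true(is.na(dna$diff_peak_velocity[dna$participant == 2]))
  expect_false(anyNA(dna$diff_peak_velocity[dna$participant != 2]))
})
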