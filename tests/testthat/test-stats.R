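makeLongData <- function(nDev = 8, grid = c(7, 10, 14, 17, 21),
                         traj = function(t, g) 10 + 2 * t,
                         reSD = 0.5, residSD = 0.2) {
  df <- expand.grid(device = sprintf("d%02d", seq_len(nDev)),
                    session = grid, stringsAsFactors = FALSE)
  df$culture <- ifelse(as.integer(sub("d", "", df$device)) <= nDev / 2,
                       "co", "tri")
  re <- rnorm(nDev, 0, reSD)
  names(re) <- sprintf("d%02d", seq_len(nDev))
  df$y <- traj(df$session, df$culture) + re[df$device] +
    rnorm(nrow(df), 0, residSD)
  df
}

test_that("saturated spline model interpolates noise-free trajectories", {
  grid <- c(7, 10, 14, 17, 21)
  traj <- c(3, 9, 4, 12, 8)  # deliberately non-monotone
  df <- expand.grid(device = sprintf("d%d", 1:6), session = grid,
                    stringsAsFactors = FALSE)
  df$culture <- ifelse(df$device %in% c("d1", "d2", "d3"), "co", "tri")
  df$y <- traj[match(df$session, grid)] +
    ifelse(df$culture == "tri", 2.5, 0)
  fit <- fitSplineLme(df, "y", group = "culture")
  em <- estimatedMarginalMeans(fit)
  want <- traj[match(em$timepoint, grid)] +
    ifelse(em$group == "tri", 2.5, 0)
  expect_lt(max(abs(em$emmean - want)), 1e-8)
  # permuting row order leaves the fit unchanged
  fit2 <- fitSplineLme(df[sample(nrow(df)), ], "y", group = "culture")
  em2 <- estimatedMarginalMeans(fit2)
  expect_equal(em2$emmean, em$emmean, tolerance = 1e-10)
})

test_that("spline mixed model recovers simulated fixed effects without bias", {
  set.seed(71)
  grid <- c(7, 10, 14, 17, 21)
  nrep <- 60
  est21 <- numeric(nrep)
  cover <- logical(nrep)
  trueDiff <- 28  # DIV21-vs-DIV7 within-culture difference: 2 * (21 - 7)
  for (r in seq_len(nrep)) {
    df <- makeLongData(nDev = 8, grid = grid)
    fit <- fitSplineLme(df, "y", group = "culture")
    ct <- emmContrastsHolm(fit, comparisons = "vs-baseline")
    row <- ct[ct$group == "co" & ct$timepoint == 21, ]
    est21[r] <- row$estimate
    ci <- row$estimate + c(-1, 1) * qt(0.975, row$df) * row$se
    cover[r] <- ci[1] <= trueDiff && trueDiff <= ci[2]
  }
  mcse <- sd(est21) / sqrt(nrep)
  expect_lt(abs(mean(est21) - trueDiff), 4 * mcse + 0.02)
  expect_gte(mean(cover), 0.88)
  expect_lte(mean(cover), 1.00)
})

test_that("marginal means and SEs match the emmeans reference", {
  set.seed(73)
  df <- makeLongData(nDev = 6)
  fit <- fitSplineLme(df, "y", group = "culture")
  em <- estimatedMarginalMeans(fit)
  m <- lme4::lmer(
    y ~ 0 + culture + culture:splines::bs(session, knots = 14,
                                          Boundary.knots = c(7, 21),
                                          degree = 3) + (1 | device),
    data = df,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  ref <- as.data.frame(suppressMessages(
    emmeans::emmeans(m, ~ culture | session,
                     at = list(session = c(7, 10, 14, 17, 21)),
                     lmer.df = "asymptotic")))
  ref <- ref[order(ref$culture, ref$session), ]
  em <- em[order(em$group, em$timepoint), ]
  expect_equal(em$emmean, ref$emmean, tolerance = 1e-6)
  expect_equal(em$se, ref$SE, tolerance = 1e-6)
})

test_that("Holm step-down adjustment matches the hand computation", {
  # raw {0.01, 0.03, 0.04} -> multiply by {3, 2, 2} with running max:
  # {0.03, 0.06, 0.06}
  expect_equal(p.adjust(c(0.01, 0.03, 0.04), "holm"),
               c(0.03, 0.06, 0.06))
  set.seed(79)
  df <- makeLongData(nDev = 6)
  fit <- fitSplineLme(df, "y", group = "culture")
  ct <- emmContrastsHolm(fit)
  # monotone in the raw ordering, never below raw, in [0, 1]
  expect_true(all(ct$pAdjusted >= ct$p - 1e-15))
  expect_true(all(ct$pAdjusted <= 1))
  o <- order(ct$p)
  expect_true(all(diff(ct$pAdjusted[o]) >= -1e-15))
  # m = 1: adjusted equals raw
  one <- ct[1, , drop = FALSE]
  expect_equal(p.adjust(one$p, "holm"), one$p)
})

test_that("null longitudinal data keep family-wise error controlled", {
  set.seed(83)
  nrep <- 120
  anyRej <- vapply(seq_len(nrep), function(r) {
    df <- makeLongData(nDev = 8, traj = function(t, g) 5)
    fit <- fitSplineLme(df, "y", group = "culture")
    ct <- emmContrastsHolm(fit)
    any(ct$pAdjusted < 0.05)
  }, logical(1))
  fwer <- mean(anyRej)
  margin <- 3 * sqrt(0.05 * 0.95 / nrep)
  expect_lte(fwer, 0.05 + margin)
})

test_that("pooled-variance t-test handles standard and degenerate input", {
  x <- c(1, 2, 3)
  r <- twoSampleTtest(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r2 <- twoSampleTtest(x, x + 10)
  expect_lt(r2$p, 0.01)
  # agreement with the closed-form pooled t
  set.seed(5)
  a <- rnorm(10); b <- rnorm(12, 0.5)
  r3 <- twoSampleTtest(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(r3$t, unname(ref$statistic))
  expect_equal(r3$p, ref$p.value)
  # zero pooled variance
  expect_equal(twoSampleTtest(c(2, 2, 2), c(2, 2))$p, 1)
  expect_equal(twoSampleTtest(c(2, 2, 2), c(3, 3))$p, 0)
  expect_error(twoSampleTtest(1, c(1, 2)), "at least two")
})

test_that("equal-variance null t-test calibrates near the nominal level", {
  set.seed(89)
  rej <- mean(vapply(seq_len(2000), function(i) {
    twoSampleTtest(rnorm(8), rnorm(8))$p < 0.05
  }, logical(1)))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("non-convergent or invalid fits are reported, contrasts suppressed", {
  df <- data.frame(device = "d1", session = c(1, 2), culture = "co",
                   y = c(1, 2))
  expect_error(fitSplineLme(df, "z"), "missing columns")
  fit <- suppressWarnings(fitSplineLme(df, "y"))
  if (!isTRUE(fit$converged)) {
    expect_error(emmContrastsHolm(fit), "converge")
  } else {
    succeed()
  }
})
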