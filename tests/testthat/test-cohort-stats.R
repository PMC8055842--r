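test_that("covariate adjustment leaves residuals orthogonal to covariates", {
  set.seed(31)
  n <- 60
  age <- rnorm(n, 67, 6); edu <- rnorm(n, 17, 3); gen <- rbinom(n, 1, 0.4)
  y <- 2 - 0.05 * age + 0.02 * edu + 0.3 * gen + rnorm(n, 0, 0.4)
  adj <- adjust_covariates(y, age, edu, gen)
  expect_lt(abs(cor(adj, age)), 1e-10)
  expect_lt(abs(cor(adj, edu)), 1e-10)
  expect_lt(abs(cor(adj, gen)), 1e-10)
  expect_equal(mean(adj), mean(y))
  expect_error(adjust_covariates(y, age, age, gen), "collinear")
  expect_error(adjust_covariates(y[1:3], age[1:3], edu[1:3], gen[1:3]),
               "at least 5")
})

test_that("adjustment with null covariate effects changes values little and
           recovers an injected age slope", {
  set.seed(32)
  # null: covariates carry no signal -> mean absolute change shrinks with n
  ch <- vapply(c(50, 1000), function(n) {
    age <- rnorm(n, 67, 6); edu <- rnorm(n, 17, 3); gen <- rbinom(n, 1, .4)
    y <- rnorm(n)
    mean(abs(adjust_covariates(y, age, edu, gen) - y))
  }, numeric(1))
  expect_lt(ch[2], ch[1])
  expect_lt(ch[2], 0.06)

  # injected 0.5/year slope: adjusted group contrast recovers the designed
  # group effect across replicates
  nrep <- 100L
  hits <- 0L
  for (r in seq_len(nrep)) {
    grp <- rep(c(0, 1), each = 25)
    age <- rnorm(50, 67 + 3 * grp, 5)   # confounded with group
    edu <- rnorm(50, 17, 3); gen <- rbinom(50, 1, 0.4)
    y <- 1.0 * grp + 0.5 * age + rnorm(50, 0, 1)
    adj <- adjust_covariates(y, age, edu, gen)
    est <- mean(adj[grp == 1]) - mean(adj[grp == 0])
    se <- sqrt(var(adj[grp == 1]) / 25 + var(adj[grp == 0]) / 25)
    if (abs(est - 1.0) <= 2.2 * se) hits <- hits + 1L
  }
  expect_gte(hits / nrep, 0.9)
})

test_that("shifted log picks the branch by skew sign and symmetrizes", {
  set.seed(33)
  pos <- rlnorm(200, 0, 0.8)
  tp <- shifted_log(pos)
  expect_identical(tp$spec$direction, "positive_skew")
  expect_lt(tp$spec$a, min(pos))
  expect_lt(abs(tp$spec$skew_after), 0.1)
  expect_lte(abs(tp$spec$skew_after), abs(tp$spec$skew_before))

  neg <- -rlnorm(200, 0, 0.8)
  tn <- shifted_log(neg)
  expect_identical(tn$spec$direction, "negative_skew")
  expect_gt(tn$spec$a, max(neg))
  expect_lte(abs(tn$spec$skew_after), abs(tn$spec$skew_before))
  expect_error(shifted_log(rep(1, 10)), "constant")
})

test_that("common-variance scaling normalizes columns and keeps structure", {
  set.seed(34)
  X <- data.frame(a = rnorm(30, 5, 3), b = rlnorm(30), c = rnorm(30, -2, .2))
  S <- scale_common_variance(X)
  expect_true(all(abs(vapply(S, var, numeric(1)) - 1) < 1e-12))
  S2 <- scale_common_variance(S)
  expect_equal(as.matrix(S2), as.matrix(S), tolerance = 1e-12)
  expect_equal(cor(as.matrix(S)), cor(as.matrix(X)), tolerance = 1e-12)
  X$d <- 1
  expect_error(scale_common_variance(X), "constant")
})

test_that("one-way ANOVA matches the textbook decomposition", {
  set.seed(35)
  g <- factor(rep(c("CN", "aMCI", "AD"), c(15, 15, 11)),
              levels = c("CN", "aMCI", "AD"))
  y <- rnorm(41) + c(CN = 0, aMCI = 0.4, AD = -0.2)[as.character(g)]
  res <- anova_oneway(y, g)
  expect_identical(res$df, c(2, 38))
  # brute-force sums of squares
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  Fbrute <- (ssb / 2) / (ssw / 38)
  expect_lt(abs(res$F - Fbrute), 1e-12)
  expect_equal(res$p, stats::pf(Fbrute, 2, 38, lower.tail = FALSE))
  expect_error(anova_oneway(y, factor(rep("a", 41))), "2 groups")
})

test_that("Tukey HSD adjusts upward and matches the studentized range", {
  set.seed(36)
  g <- factor(rep(c("CN", "aMCI", "AD"), c(15, 15, 11)),
              levels = c("CN", "aMCI", "AD"))
  y <- rnorm(41) + c(CN = 0, aMCI = 0.7, AD = -0.3)[as.character(g)]
  tk <- tukey_hsd(y, g)
  expect_setequal(tk$pair, c("aMCI-CN", "AD-CN", "AD-aMCI"))
  expect_true(all(tk$p_adj >= tk$p_unadj - 1e-12))
  # independent oracle: ptukey on the pairwise studentized statistic
  mse <- anova_oneway(y, g)$ss_within / 38
  d <- mean(y[g == "aMCI"]) - mean(y[g == "CN"])
  se <- sqrt(mse / 2 * (1 / 15 + 1 / 15))
  p_oracle <- stats::ptukey(abs(d) / se, 3, 38, lower.tail = FALSE)
  expect_equal(tk$p_adj[tk$pair == "aMCI-CN"], p_oracle, tolerance = 1e-10)
})

test_that("interaction model: design, centering identity, known-coefficient
           recovery", {
  set.seed(37)
  g <- factor(rep(c("CN", "aMCI", "AD"), c(15, 15, 11)),
              levels = c("CN", "aMCI", "AD"))
  x <- rnorm(41, 2, 1)
  xc <- x - mean(x)
  y <- 0.5 - 0.3 * (g == "aMCI") - 1 * (g == "AD") + 0.4 * xc +
    0.2 * xc * (g == "aMCI") - 0.5 * xc * (g == "AD") + rnorm(41, 0, 0.3)
  im <- interaction_model(y, x, g)
  expect_identical(im$coefficients$term, paste0("b", 0:5))
  # CN is the reference level and x is centered: b0 estimates the CN mean
  # outcome at the average marker value
  fitted_cn_at_mean <- im$coefficients$estimate[1]
  expect_lt(abs(fitted_cn_at_mean - 0.5), 0.25)
  expect_lt(abs(im$coefficients$estimate[4] - 0.4), 0.3)
  expect_identical(im$interaction_df[1], 2)
  expect_error(interaction_model(y[g != "AD"], x[g != "AD"],
                                 droplevels(g[g != "AD"])), "three groups")

  # b3 +/- 2 SE covers the truth at about the nominal rate
  nrep <- 200L
  cover <- 0L
  for (r in seq_len(nrep)) {
    xr <- rnorm(41, 2, 1); xcr <- xr - mean(xr)
    yr <- 0.5 + 0.4 * xcr + rnorm(41, 0, 0.5)
    imr <- interaction_model(yr, xr, g)
    b3 <- imr$coefficients$estimate[4]; se <- imr$coefficients$se[4]
    if (abs(b3 - 0.4) <= 2 * se) cover <- cover + 1L
  }
  expect_gte(cover / nrep, 0.88)
})

test_that("cohort generator is deterministic with the published sizes and
           holds its type-I error under the null", {
  d <- cohort_design(seed = 41)
  s1 <- simulate_cohort(d, spectra = FALSE)
  s2 <- simulate_cohort(d, spectra = FALSE)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(nrow(s1$cohort), 41L)
  expect_identical(as.integer(table(s1$cohort$group)), c(15L, 15L, 11L))

  # null cohort: zero group effects -> adjusted ANOVA rejects at ~alpha
  ge0 <- default_group_effects()
  ge0$amci <- 0; ge0$ad <- 0
  nrep <- 400L
  rej <- 0L
  for (r in seq_len(nrep)) {
    sim <- simulate_cohort(cohort_design(group_effects = ge0,
                                         seed = 10000 + r),
                           spectra = FALSE)
    co <- sim$cohort
    adj <- adjust_covariates(co$energy_reserve_temporal, co$age,
                             co$education, co$gender)
    tv <- shifted_log(adj)$values
    if (anova_oneway(tv, co$group)$p <= 0.10) rej <- rej + 1L
  }
  expect_lt(abs(rej / nrep - 0.10), 0.035)
})
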