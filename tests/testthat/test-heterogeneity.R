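# Respondent-utility tables for these tests are generated directly from the
# normal sampling model the screen assumes; the HB stage is exercised in its
# own tests.
sim_utilities <- function(n, k = 5, sd = 0.5, shift = NULL, groups = NULL,
                          seed = 1) {
  withr::with_seed(seed, {
    u <- matrix(rnorm(n * k, mean = -4, sd = sd), n, k)
    colnames(u) <- paste0("out", seq_len(k))
    if (!is.null(shift)) u[groups == 1L, 1] <- u[groups == 1L, 1] + shift
    cbind(data.frame(respondent = seq_len(n)), as.data.frame(u))
  })
}

test_that("screening detects a real one-outcome shift", {
  hits <- 0L
  for (s in 1:20) {
    g <- rep(c(0L, 1L), length.out = 396)
    ru <- sim_utilities(396, shift = 1.0, groups = g, seed = s)
    cov <- data.frame(respondent = ru$respondent, grp = g)
    sc <- screen_interactions(ru, cov, n_covariates = 10)
    hits <- hits + ("grp" %in% sc$screened_in)
  }
  expect_gte(hits, 19L)
})

test_that("screening holds its Bonferroni-level type-I error under the null", {
  n_sim <- 1000L
  false_pos <- 0L
  for (s in seq_len(n_sim)) {
    g <- rep(c(0L, 1L), length.out = 120)
    ru <- sim_utilities(120, k = 4, seed = 10000 + s)
    cov <- data.frame(respondent = ru$respondent, grp = g)
    sc <- screen_interactions(ru, cov, n_covariates = 10)
    false_pos <- false_pos + length(sc$screened_in)
  }
  rate <- false_pos / n_sim
  se <- sqrt(0.005 * 0.995 / n_sim)
  expect_lte(rate, 0.005 + 3 * se)
})

test_that("constant covariates are skipped, not tested", {
  ru <- sim_utilities(50, seed = 3)
  cov <- data.frame(respondent = ru$respondent, fixed = "x",
                    real = rep(c("a", "b"), 25))
  expect_warning(sc <- screen_interactions(ru, cov), "single level")
  expect_identical(sc$skipped, "fixed")
  expect_true(is.na(sc$p_values[["fixed"]]))
  expect_false(is.na(sc$p_values[["real"]]))
  expect_equal(sc$alpha_adj, 0.05 / 2)
})

test_that("stratified ANOVA matches the textbook formula on a hand example", {
  ru <- data.frame(respondent = 1:6, out1 = c(1, 2, 3, 4, 5, 6))
  g <- c("a", "a", "b", "b", "c", "c")
  sa <- stratified_anova(ru, g, "out1")
  # by hand: SSB = 16, SSW = 1.5 -> F = (16/2)/(1.5/3) = 16
  expect_equal(sa$f_statistic, 16, tolerance = 1e-12)
  expect_equal(sa$p_value, stats::pf(16, 2, 3, lower.tail = FALSE))
  expect_equal(sa$strata$mean, c(1.5, 3.5, 5.5))
})

test_that("stratified ANOVA null p-values are uniform", {
  ps <- vapply(1:1000, function(s) {
    ru <- sim_utilities(40, k = 1, seed = 20000 + s)
    names(ru)[2] <- "out1"
    stratified_anova(ru, rep(c("a", "b"), 20), "out1")$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("degenerate strata are rejected", {
  ru <- data.frame(respondent = 1:6, out1 = rep(c(1, 2), 3))
  expect_error(stratified_anova(ru, rep("a", 6), "out1"), "at least 2 strata")
  ru0 <- data.frame(respondent = 1:6, out1 = rep(5, 6))
  expect_error(stratified_anova(ru0, rep(c("a", "b"), 3), "out1"),
               "undefined")
})

test_that("Tukey-Kramer reduces to the pooled t-test with two strata", {
  ru <- sim_utilities(30, k = 1, seed = 7)
  names(ru)[2] <- "out1"
  g <- rep(c("a", "b"), c(12, 18))      # unequal sizes on purpose
  tk <- tukey_kramer(ru, g, "out1")
  tt <- stats::t.test(ru$out1[g == "a"], ru$out1[g == "b"], var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-10)
  expect_equal(abs(tk$diff), abs(diff(rev(tapply(ru$out1, g, mean)))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Tukey-Kramer agrees with a direct studentized-range computation", {
  ru <- data.frame(respondent = 1:9,
                   out1 = c(1.1, 0.8, 1.3, 2.2, 2.4, 1.9, 3.0, 3.3, 2.8))
  g <- rep(c("g1", "g2", "g3"), each = 3)
  tk <- tukey_kramer(ru, g, "out1")
  # oracle: q statistic and ptukey by hand for one pair
  fit <- stats::aov(out1 ~ gg, data = data.frame(out1 = ru$out1, gg = factor(g)))
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  m <- tapply(ru$out1, g, mean)
  q13 <- abs(m["g3"] - m["g1"]) / sqrt(mse / 3)  # balanced groups of 3
  p13 <- stats::ptukey(q13, 3, 6, lower.tail = FALSE)
  row13 <- tk[tk$comparison == "g3-g1", ]
  expect_equal(row13$p_adj, unname(p13), tolerance = 1e-10)
})

test_that("identical strata give zero differences and p = 1", {
  g <- rep(c("a", "b", "c"), each = 3)
  ru <- data.frame(respondent = 1:9, out1 = c(1, 2, 3, 1, 2, 3, 1, 2, 3))
  tk <- tukey_kramer(ru, g, "out1")
  expect_equal(tk$diff, rep(0, 3), tolerance = 1e-12)
  expect_equal(tk$p_adj, rep(1, 3), tolerance = 1e-12)
})

test_that("experienced-vs-not compares groups with a Student t-test", {
  # identical groups: zero difference, p = 1
  ru <- data.frame(respondent = 1:20, out1 = rep(c(-4, -5), 10))
  fl <- rep(c(TRUE, FALSE), each = 10)
  ru$out1 <- c(rep(c(-4, -5), 5), rep(c(-4, -5), 5))
  r0 <- experienced_vs_not(ru, fl, "out1")
  expect_equal(r0$difference, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)
  # swapping labels flips the sign, p unchanged
  r1 <- experienced_vs_not(ru, !fl, "out1")
  expect_equal(r1$difference, -r0$difference)
  expect_equal(r1$p_value, r0$p_value)
  expect_error(experienced_vs_not(ru, rep(TRUE, 20), "out1"), "non-empty")
})

test_that("a -0.6 shift at 50 vs 346 respondents is reliably detected", {
  hits <- 0L
  for (s in 1:20) {
    withr::with_seed(30000 + s, {
      u <- c(rnorm(50, -5.6, 0.3), rnorm(346, -5.0, 0.3))
    })
    ru <- data.frame(respondent = 1:396, out1 = u)
    fl <- rep(c(TRUE, FALSE), c(50, 346))
    hits <- hits + (experienced_vs_not(ru, fl, "out1")$p_value < 0.05)
  }
  expect_gte(hits, 19L)
})

test_that("the heterogeneity report lays out stratum summaries", {
  g <- rep(c("young", "old"), 30)
  ru <- sim_utilities(60, k = 2, shift = 0.8, groups = as.integer(g == "old"),
                      seed = 12)
  cov <- data.frame(respondent = ru$respondent, age = g)
  rep_tab <- heterogeneity_report(ru, cov)
  expect_setequal(unique(rep_tab$stratum), c("young", "old"))
  expect_setequal(unique(rep_tab$outcome), c("out1", "out2"))
  expect_true(all(rep_tab$stars %in% c("", "*", "**", "***")))
})
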