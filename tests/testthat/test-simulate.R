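test_that("simulated responses respect the design and are deterministic", {
  d <- small_design()
  tp <- true_preferences(small_catalog(), mu = c(-2, -3, -4, -5), sigma = 0.2)
  r1 <- simulate_choices(d, tp, n_respondents = 20, seed = 9)
  r2 <- simulate_choices(d, tp, n_respondents = 20, seed = 9)
  r3 <- simulate_choices(d, tp, n_respondents = 20, seed = 10)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))
  shown <- as.matrix(r1[paste0("item", 1:3)])
  expect_true(all(r1$best != r1$worst))
  expect_true(all(mapply(function(i, b) b %in% shown[i, ], seq_len(nrow(r1)), r1$best)))
  expect_true(all(mapply(function(i, w) w %in% shown[i, ], seq_len(nrow(r1)), r1$worst)))
  expect_false(anyDuplicated(r1[c("respondent", "task")]) > 0)
  # round-robin version assignment
  expect_equal(unique(r1$version[r1$respondent == 1]), 1L)
  expect_equal(unique(r1$version[r1$respondent == 2]), 2L)
})

test_that("equal part-worths give uniform best-choice shares", {
  # adverse-only design: the reference (utility 0) would dominate any triple
  d <- generate_design(small_catalog(), n_versions = 2, tasks_per_version = 5,
                       items_per_task = 3, seed = 1, include_reference = FALSE,
                       n_restarts = 5)
  tp <- true_preferences(small_catalog(), mu = rep(-3, 4), sigma = 0)
  r <- simulate_choices(d, tp, n_respondents = 2000, seed = 4)
  shown <- as.matrix(r[paste0("item", 1:3)])
  items <- unique(as.vector(shown))
  for (it in items) {
    n_shown <- sum(shown == it)
    share <- sum(r$best == it) / n_shown
    se <- sqrt((1 / 3) * (2 / 3) / n_shown)
    expect_lt(abs(share - 1 / 3), 3 * se)
  }
})

test_that("best-choice frequencies follow the softmax of the truth", {
  # chi-square goodness of fit per task, aggregated over tasks
  d <- generate_design(default_catalog(), n_versions = 1, tasks_per_version = 8,
                       items_per_task = 3, seed = 2)
  u <- fracture_outcome_utilities()
  tp <- true_preferences(default_catalog(), mu = u, sigma = 0)
  r <- simulate_choices(d, tp, n_respondents = 5000, seed = 6)
  mu_full <- c(stats::setNames(u$mean, u$outcome))
  chi2 <- 0; df <- 0
  for (tk in unique(r$task)) {
    sub <- r[r$task == tk, ]
    s <- unlist(sub[1, paste0("item", 1:3)], use.names = FALSE)
    p <- exp(mu_full[s] - max(mu_full[s]))
    p <- p / sum(p)
    obs <- table(factor(sub$best, levels = s))
    exp_n <- p * nrow(sub)
    keep <- exp_n >= 5
    chi2 <- chi2 + sum((obs[keep] - exp_n[keep])^2 / exp_n[keep])
    df <- df + max(sum(keep) - 1, 0)
  }
  expect_gt(stats::pchisq(chi2, df, lower.tail = FALSE), 0.01)
})

test_that("the most severe outcome is chosen best least often", {
  d <- generate_design(default_catalog(), seed = 1)
  r <- simulate_choices(d, default_truth(), n_respondents = 396, seed = 13)
  shown <- as.matrix(r[paste0("item", 1:3)])
  rate <- function(it) sum(r$best == it) / sum(shown == it)
  rates <- vapply(adverse_outcomes(default_catalog()), rate, numeric(1))
  expect_equal(names(which.min(rates)), "Death")
})

test_that("covariate effects shift the simulated preferences", {
  d <- small_design()
  cov <- data.frame(grp = rep(c(0, 1), each = 100))
  tp <- true_preferences(
    small_catalog(), mu = rep(-3, 4), sigma = 0,
    covariate_effects = list(grp = function(v) c(worst = -2 * v)))
  r <- simulate_choices(d, tp, n_respondents = 200, seed = 21, covariates = cov)
  shown <- as.matrix(r[paste0("item", 1:3)])
  in_grp <- r$cov_grp == 1
  rate <- function(sel) sum(r$best[sel] == "worst") / sum(shown[sel, ] == "worst")
  expect_lt(rate(in_grp), rate(!in_grp))
})

test_that("trial simulation honors its probabilities and degenerate cases", {
  probs0 <- list(A = c(x = 0, y = 0), B = c(x = 0, y = 0))
  t0 <- simulate_trial(c(50, 50), probs0, seed = 1)
  expect_equal(nrow(t0$events), 0L)
  probs1 <- list(A = c(x = 1), B = c(x = 0))
  t1 <- simulate_trial(c(40, 60), probs1, seed = 2)
  expect_equal(sum(t1$events$patient %in%
                     t1$patients$patient[t1$patients$arm == "A"]), 40L)
  expect_true(all(t1$events$event_time <= 365))
  # at most one event per patient-component pair
  tr <- simulate_trial(seed = 3)
  expect_false(anyDuplicated(tr$events[c("patient", "component")]) > 0)
  # per-component counts within binomial 95% bounds of their expectation
  probs <- pilon_trial_probs()
  for (arm in c("A", "B")) {
    n_arm <- c(A = 498, B = 502)[[arm]]
    ids <- tr$patients$patient[tr$patients$arm == arm]
    for (comp in names(probs[[arm]])) {
      cnt <- sum(tr$events$component == comp & tr$events$patient %in% ids)
      p <- probs[[arm]][[comp]]
      expect_lt(abs(cnt - n_arm * p), 1.96 * sqrt(n_arm * p * (1 - p)) + 1)
    }
  }
  expect_identical(simulate_trial(seed = 9)$events, simulate_trial(seed = 9)$events)
  expect_error(simulate_trial(c(-1, 10), probs0), "positive")
  expect_error(simulate_trial(c(10, 10), list(A = c(x = 2), B = c(x = 0))),
               "\\[0, 1\\]")
})

test_that("trial data round-trips through long and wide CSV", {
  tr <- simulate_trial(c(30, 30),
                       list(A = c(u = .4, v = .2), B = c(u = .2, v = .4)),
                       seed = 8)
  long <- withr::local_tempfile(fileext = ".csv")
  wide <- withr::local_tempfile(fileext = ".csv")
  write_trial_long(tr, long)
  back <- read_trial_long(long)
  expect_equal(back$patients, tr$patients)
  expect_equal(back$events[order(back$events$patient, back$events$event_time), ],
               tr$events, ignore_attr = TRUE)
  write_trial_wide(tr, wide)
  backw <- read_trial_wide(wide, components = c(u = "u", v = "v"))
  expect_equal(nrow(backw$events), nrow(tr$events))
  expect_equal(sort(backw$events$event_time), sort(tr$events$event_time))
})
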