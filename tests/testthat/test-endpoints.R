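test_that("Fisher's exact composite test behaves on symmetric and known tables", {
  # 10 events / 10 non-events in each arm of 20
  tr <- two_arm_trial(c(rep(100, 10), rep(NA, 10)), c(rep(100, 10), rep(NA, 10)))
  res <- fisher_composite(tr)
  expect_equal(res$estimate, 1, tolerance = 1e-9)
  expect_equal(res$p_value, 1)
  expect_equal(res$measure, "odds ratio")

  # event-count profile of the hypothetical 1000-patient trial
  tr2 <- two_arm_trial(c(rep(50, 168), rep(NA, 330)), c(rep(50, 174), rep(NA, 328)))
  res2 <- fisher_composite(tr2)
  # independent oracle: two-sided exact p by hypergeometric enumeration
  m <- 168 + 174; n_tot <- 1000; nA <- 498
  dens <- stats::dhyper(0:m, m, n_tot - m, nA)
  p_or <- sum(dens[dens <= stats::dhyper(168, m, n_tot - m, nA) * (1 + 1e-7)])
  expect_equal(res2$p_value, p_or, tolerance = 1e-8)

  # doubling every cell keeps the sample odds ratio; the conditional MLE
  # moves only marginally
  tr3 <- two_arm_trial(c(rep(50, 2 * 168), rep(NA, 2 * 330)),
                       c(rep(50, 2 * 174), rep(NA, 2 * 328)))
  expect_equal(fisher_composite(tr3)$estimate, res2$estimate, tolerance = 0.02)
})

test_that("time to first event ignores later events and mirrors symmetry", {
  times <- c(30, 90, 150, NA, NA, NA)
  tr <- two_arm_trial(times, times)
  res <- time_to_first_event(tr)
  expect_equal(res$estimate, 1, tolerance = 1e-6)

  # adding a later second event to a patient changes nothing
  tr2 <- tr
  tr2$events <- rbind(tr2$events,
                      data.frame(patient = 1L, component = "c2",
                                 event_time = 200))
  res2 <- time_to_first_event(tr2)
  expect_equal(res2$estimate, res$estimate, tolerance = 1e-12)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)
})

test_that("the Cox hazard ratio recovers a doubled exponential hazard", {
  withr::with_seed(41, {
    n <- 4000
    tA <- rexp(n, rate = 2 / 365)       # doubled hazard in arm A
    tB <- rexp(n, rate = 1 / 365)
    tA[tA > 365] <- NA; tB[tB > 365] <- NA
  })
  tr <- two_arm_trial(tA, tB)
  res <- time_to_first_event(tr)
  expect_lt(abs(res$estimate - 2), 0.2)
})

test_that("weighted recurrent analysis reduces to time-to-first in exit layout", {
  withr::with_seed(77, {
    tA <- ifelse(runif(150) < .3, runif(150, 1, 300), NA)
    tB <- ifelse(runif(150) < .4, runif(150, 1, 300), NA)
  })
  tr <- two_arm_trial(tA, tB)                     # single events only
  w <- c(c1 = 1)
  ttf <- time_to_first_event(tr)
  rec <- weighted_recurrent_tte(tr, w, risk = "exit")
  expect_equal(rec$estimate, ttf$estimate, tolerance = 1e-6)
})

test_that("swapping the arms inverts the recurrent-event hazard ratio", {
  tr <- simulate_trial(c(150, 150), pilon_trial_probs(), seed = 19)
  w <- compute_weights(fracture_outcome_utilities(), table3_composite)
  for (layout in c("cohort", "exit")) {
    res <- weighted_recurrent_tte(tr, w, risk = layout)
    tr_sw <- tr
    tr_sw$patients$arm <- c(A = "B", B = "A")[tr_sw$patients$arm]
    res_sw <- weighted_recurrent_tte(tr_sw, w, risk = layout)
    expect_equal(res_sw$estimate, 1 / res$estimate, tolerance = 1e-6)
  }
  expect_error(weighted_recurrent_tte(tr, c(zz = 1)), "no weight")
})

test_that("trading severe for mild events pulls the weighted hazard below the unweighted", {
  w <- compute_weights(fracture_outcome_utilities(), table3_composite)
  tr <- simulate_trial(seed = 2)
  unw <- time_to_first_event(tr)
  wt <- weighted_recurrent_tte(tr, w)
  expect_lt(wt$estimate, unw$estimate)
})

test_that("the probability index counts cross-arm pairs exactly", {
  # 4-patient toy instance, scores: A = {0, w1}, B = {w1, w1+w2}
  tr <- make_trial(
    events = data.frame(patient = c(2L, 3L, 4L, 4L),
                        component = c("c1", "c1", "c1", "c2"),
                        event_time = c(10, 20, 30, 40)),
    patients = data.frame(patient = 1:4, arm = c("A", "A", "B", "B"),
                          followup = 365))
  w <- c(c1 = 0.8, c2 = 0.5)
  res <- global_rank_test(tr, w)
  # brute force over the 4 cross-arm pairs: scores A = {0, .8}, B = {.8, 1.3}
  # pairs (0,.8)<, (0,1.3)<, (.8,.8)=, (.8,1.3)<  -> (3 + 0.5) / 4
  expect_equal(res$estimate, 3.5 / 4, tolerance = 1e-12)
  # cross-check against the rank-sum statistic: U = nA*nB - W(A over B)
  wt <- stats::wilcox.test(c(0, .8), c(.8, 1.3), exact = FALSE)
  expect_equal(res$estimate * 4, 4 - unname(wt$statistic), tolerance = 1e-12)
})

test_that("probability index hits its boundary and null values", {
  tr_eq <- make_trial(
    events = data.frame(patient = c(1L, 3L), component = "c1",
                        event_time = c(5, 5)),
    patients = data.frame(patient = 1:4, arm = c("A", "A", "B", "B"),
                          followup = 365))
  res <- global_rank_test(tr_eq, c(c1 = 1))
  expect_equal(res$estimate, 0.5)
  expect_equal(res$p_value, 1, tolerance = 1e-9)

  # arm A uniformly better (no events) than arm B (all events)
  tr_ext <- make_trial(
    events = data.frame(patient = 3:4, component = "c1", event_time = c(5, 6)),
    patients = data.frame(patient = 1:4, arm = c("A", "A", "B", "B"),
                          followup = 365))
  expect_equal(global_rank_test(tr_ext, c(c1 = 1))$estimate, 1)
})

test_that("sum scoring counts repeat events where max scoring does not", {
  tr <- make_trial(
    events = data.frame(patient = c(1L, 1L, 3L), component = c("c1", "c2", "c1"),
                        event_time = c(5, 10, 5)),
    patients = data.frame(patient = 1:4, arm = c("A", "A", "B", "B"),
                          followup = 365))
  w <- c(c1 = 0.9, c2 = 0.2)
  s_sum <- global_rank_test(tr, w, score = "sum")
  s_max <- global_rank_test(tr, w, score = "max")
  expect_false(isTRUE(all.equal(s_sum$estimate, s_max$estimate)))
})

test_that("random-effects model reduces to its marginal and unweighted forms", {
  tr <- simulate_trial(c(400, 400),
                       list(A = c(x = 0.15, y = 0.3), B = c(x = 0.3, y = 0.15)),
                       seed = 23)
  # constant weights match the unweighted fit exactly after normalization
  unw <- random_effects_composite(tr)
  wconst <- random_effects_composite(
    tr, weights = c(x = 0.7, y = 0.7), components = c("x", "y"))
  expect_equal(wconst$estimate, unw$estimate, tolerance = 1e-6)
  expect_equal(wconst$lower95, unw$lower95, tolerance = 1e-5)

  # independence between components (no patient effect): GLMM ~ marginal GLM
  counts <- table(tr$patients$arm[match(tr$events$patient,
                                        tr$patients$patient)])
  n_rows <- 2 * 400
  or_marg <- (counts[["A"]] / (n_rows - counts[["A"]])) /
             (counts[["B"]] / (n_rows - counts[["B"]]))
  expect_lt(abs(unw$estimate - or_marg) / or_marg, 0.10)
})

test_that("the full battery emits one row per configured method", {
  tr <- simulate_trial(seed = 4)
  w <- compute_weights(fracture_outcome_utilities(), table3_composite)
  res <- analyze_all(tr, w)
  expect_equal(nrow(res), 7L)
  expect_setequal(unique(res$weighted), c(TRUE, FALSE))
  expect_true(all(res$lower95 <= res$estimate & res$estimate <= res$upper95))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))

  # unit weights collapse the weighted global rank onto the unweighted one
  unit <- stats::setNames(rep(1, 3), table3_composite)
  g1 <- global_rank_test(tr, unit)
  w1 <- structure(data.frame(component = table3_composite, utility = -1,
                             weight = 1),
                  class = c("component_weights", "data.frame"))
  g2 <- global_rank_test(tr, w1)
  expect_equal(g2$estimate, g1$estimate, tolerance = 1e-12)
  expect_equal(g2$p_value, g1$p_value, tolerance = 1e-12)
})

test_that("survival-curve coordinates are monotone within arms", {
  tr <- simulate_trial(c(100, 100), pilon_trial_probs(), seed = 31)
  for (kc in list(km_curves(tr),
                  km_curves(tr, compute_weights(fracture_outcome_utilities(),
                                                table3_composite)))) {
    for (a in unique(kc$arm)) {
      s <- kc$surv[kc$arm == a]
      expect_true(all(diff(s) <= 1e-12))
    }
  }
})
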