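# Uniform result container for the trial analyses.
trial_result <- function(method, measure, estimate, lower95, upper95, p_value,
                         n_events, weighted) {
  structure(list(method = method, measure = measure, estimate = estimate,
                 lower95 = lower95, upper95 = upper95, p_value = p_value,
                 n_events = n_events, weighted = weighted),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("%s%s: %s = %.3f (95%% CI %.3f-%.3f), p = %.4g [%d events]\n",
              x$method, if (x$weighted) " (weighted)" else "",
              x$measure, x$estimate, x$lower95, x$upper95, x$p_value,
              x$n_events))
  invisible(x)
}

#' @export
as.data.frame.trial_result <- function(x, ...) {
  data.frame(method = x$method, measure = x$measure, estimate = x$estimate,
             lower95 = x$lower95, upper95 = x$upper95, p_value = x$p_value,
             n_events = x$n_events, weighted = x$weighted)
}

check_two_arms <- function(trial) {
  arms <- table(factor(trial$patients$arm, levels = c("A", "B")))
  if (any(arms == 0L)) stop_bad_arg("both arms must contain patients")
  arms
}

# Arm factor with B as reference, so effects are A versus B (HR/OR < 1
# favors treatment A).
arm_factor <- function(arm) factor(arm, levels = c("B", "A"))

#' Fisher's exact test on the unweighted composite
#'
#' Classifies each patient as having at least one component event or none,
#' forms the 2x2 arm-by-event table, and applies Fisher's exact test:
#' exact hypergeometric p-value and conditional maximum-likelihood odds
#' ratio (A versus B) with an exact confidence interval.
#'
#' @param trial A `trial_data` object.
#' @return A `trial_result` with an odds-ratio effect measure.
#' @export
fisher_composite <- function(trial) {
  check_two_arms(trial)
  has_event <- trial$patients$patient %in% trial$events$patient
  tab <- table(arm = arm_factor(trial$patients$arm),
               event = factor(has_event, levels = c(TRUE, FALSE)))
  # orient as rows A,B for an A-vs-B odds ratio
  tab <- tab[c("A", "B"), ]
  ft <- stats::fisher.test(tab)
  trial_result("Fisher exact (any event)", "odds ratio",
               unname(ft$estimate), ft$conf.int[1], ft$conf.int[2],
               ft$p.value, sum(has_event), weighted = FALSE)
}

#' Unweighted time-to-first-event analysis
#'
#' Reduces each patient to the earliest event time across all composite
#' components (censoring at follow-up when event-free) and fits a Cox
#' proportional-hazards model on the arm indicator. Later events are
#' discarded, which is exactly the limitation weighted recurrent-event
#' analyses address.
#'
#' @param trial A `trial_data` object.
#' @return A `trial_result` with a hazard ratio (A versus B), Wald interval
#'   and p-value.
#' @export
time_to_first_event <- function(trial) {
  check_two_arms(trial)
  if (!nrow(trial$events)) stop_bad_arg("no events in the trial data")
  first <- stats::aggregate(event_time ~ patient, trial$events, min)
  p <- trial$patients
  t_first <- first$event_time[match(p$patient, first$patient)]
  status <- as.integer(!is.na(t_first))
  time <- ifelse(is.na(t_first), p$followup, t_first)
  fit <- survival::coxph(survival::Surv(time, status) ~ arm,
                         data = data.frame(time = time, status = status,
                                           arm = arm_factor(p$arm)))
  cox_result(fit, "time to first event", sum(status), weighted = FALSE)
}

cox_result <- function(fit, method, n_events, weighted) {
  s <- summary(fit)
  co <- s$coefficients
  se_col <- if ("robust se" %in% colnames(co)) "robust se" else "se(coef)"
  est <- co[1, "coef"]; se <- co[1, se_col]
  trial_result(method, "hazard ratio",
               exp(est), exp(est - 1.96 * se), exp(est + 1.96 * se),
               2 * stats::pnorm(-abs(est / se)), n_events, weighted)
}

#' Weighted recurrent-event time-to-event analysis
#'
#' Counting-process Cox model allowing several events per patient, each
#' component event carrying its composite weight as an observation weight
#' in the partial likelihood, with variance cluster-robust by patient. Two
#' risk-set layouts are offered:
#'
#' * `risk = "cohort"` (default): every patient stays at risk for the whole
#'   follow-up through a weight-1 baseline record, and each event enters as
#'   an instantaneous weighted record at its event time. Events thus count
#'   fractionally (by severity weight) against the full cohort at risk —
#'   the layout of weighted composite endpoint analyses, and the one that
#'   turns an event profile where one arm trades severe events for mild
#'   ones into a hazard ratio well below 1.
#' * `risk = "exit"`: each event contributes its own record from
#'   randomization to the event and patients leave the risk set with their
#'   events; event-free patients are censored at follow-up. With all
#'   weights equal to 1 and at most one event per patient this layout
#'   reduces exactly to [time_to_first_event()].
#'
#' @param trial A `trial_data` object.
#' @param weights A `component_weights` table covering every component with
#'   events.
#' @param risk Risk-set layout, see Details.
#' @return A `trial_result` with a hazard ratio (A versus B) using the
#'   robust standard error.
#' @export
weighted_recurrent_tte <- function(trial, weights,
                                   risk = c("cohort", "exit")) {
  risk <- match.arg(risk)
  check_two_arms(trial)
  if (!nrow(trial$events)) stop_bad_arg("no events in the trial data")
  w <- weight_lookup(weights)
  missing <- setdiff(unique(trial$events$component), names(w))
  if (length(missing))
    stop_bad_arg("no weight for component(s): ", paste(missing, collapse = ", "))
  p <- trial$patients
  ev <- merge(trial$events, p, by = "patient")
  if (risk == "cohort") {
    eps <- 1e-6
    rows <- rbind(
      data.frame(patient = ev$patient, arm = ev$arm,
                 t0 = ev$event_time - eps, t1 = ev$event_time,
                 status = 1L, w = unname(w[ev$component])),
      data.frame(patient = p$patient, arm = p$arm,
                 t0 = 0, t1 = p$followup, status = 0L, w = 1))
    rows$arm <- arm_factor(rows$arm)
    fit <- survival::coxph(
      survival::Surv(t0, t1, status) ~ arm, data = rows, weights = rows$w,
      cluster = rows$patient, robust = TRUE,
      control = survival::coxph.control(timefix = FALSE))
  } else {
    rows <- data.frame(patient = ev$patient, arm = ev$arm,
                       time = ev$event_time, status = 1L,
                       w = unname(w[ev$component]))
    none <- p[!p$patient %in% ev$patient, ]
    if (nrow(none))
      rows <- rbind(rows, data.frame(patient = none$patient, arm = none$arm,
                                     time = none$followup, status = 0L, w = 1))
    rows$arm <- arm_factor(rows$arm)
    fit <- survival::coxph(survival::Surv(time, status) ~ arm,
                           data = rows, weights = rows$w,
                           cluster = rows$patient, robust = TRUE)
  }
  cox_result(fit, "weighted recurrent events", nrow(ev), weighted = TRUE)
}

weight_lookup <- function(weights) {
  if (is.data.frame(weights) && all(c("component", "weight") %in% names(weights)))
    return(stats::setNames(weights$weight, weights$component))
  if (is.numeric(weights) && !is.null(names(weights))) return(weights)
  stop_bad_arg("weights must be a component_weights table or a named vector")
}

#' Global-rank Wilcoxon test with a Probability Index
#'
#' Scores each patient by the sum of the composite weights of their events
#' (0 when event-free), ranks the scores across arms with midranks for
#' ties, and reports the Wilcoxon rank-sum test together with the
#' Probability Index \eqn{PI = P(S_A < S_B) + P(S_A = S_B)/2}, estimated as
#' `U / (n_A * n_B)` over all cross-arm pairs. A lower score means less
#' severe outcomes, so PI above 0.5 favors arm A. The confidence interval
#' uses the placement (DeLong-type) variance of the index.
#'
#' @param trial A `trial_data` object.
#' @param weights A `component_weights` table or named vector covering all
#'   components with events; use unit weights for the unweighted test.
#' @param score `"sum"` (default: weights of all events add up) or `"max"`
#'   (worst single event).
#' @return A `trial_result` with the Probability Index as effect measure;
#'   `p_value` is the normal-approximation Wilcoxon p-value with tie
#'   correction.
#' @export
global_rank_test <- function(trial, weights, score = c("sum", "max")) {
  score <- match.arg(score)
  check_two_arms(trial)
  w <- weight_lookup(weights)
  missing <- setdiff(unique(trial$events$component), names(w))
  if (length(missing))
    stop_bad_arg("no weight for component(s): ", paste(missing, collapse = ", "))
  sc <- patient_scores(trial, w, score)
  a <- sc$score[sc$arm == "A"]; b <- sc$score[sc$arm == "B"]
  nA <- length(a); nB <- length(b)
  # U counts pairs where the A patient fares worse (higher burden) ... PI is
  # oriented so that PI > 0.5 means A patients have LOWER severity scores.
  grid <- outer(a, b, function(x, y) (x < y) + 0.5 * (x == y))
  pi_hat <- mean(grid)
  # placement variance (Hanley-McNeil / DeLong)
  v10 <- rowMeans(grid); v01 <- colMeans(grid)
  se <- sqrt(stats::var(v10) / nA + stats::var(v01) / nB)
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  trial_result("global rank (Wilcoxon)", "probability index",
               pi_hat,
               max(0, pi_hat - 1.96 * se), min(1, pi_hat + 1.96 * se),
               wt$p.value, nrow(trial$events),
               weighted = !isTRUE(all(w == 1)))
}

patient_scores <- function(trial, w, score) {
  p <- trial$patients
  s <- rep(0, nrow(p))
  if (nrow(trial$events)) {
    ew <- unname(w[trial$events$component])
    agg <- tapply(ew, trial$events$patient, if (score == "sum") sum else max)
    s[match(as.numeric(names(agg)), p$patient)] <- as.numeric(agg)
  }
  data.frame(patient = p$patient, arm = p$arm, score = s)
}

#' Random-effects logistic model on the composite components
#'
#' Expands the trial into one binary row per patient and component and fits
#' a logistic mixed model with a treatment fixed effect and a patient-level
#' random intercept. When component weights are supplied, each row carries
#' its component's weight as an observation weight (normalized to mean 1, so
#' constant weights reproduce the unweighted fit exactly).
#'
#' @param trial A `trial_data` object.
#' @param weights Optional `component_weights` table or named vector; `NULL`
#'   fits the unweighted model.
#' @param components Components modelled; defaults to those in `weights`,
#'   falling back to all components with events.
#' @return A `trial_result` with an odds ratio (A versus B).
#' @export
random_effects_composite <- function(trial, weights = NULL, components = NULL) {
  check_two_arms(trial)
  if (is.null(components)) {
    components <- if (!is.null(weights)) names(weight_lookup(weights))
                  else sort(unique(trial$events$component))
  }
  if (!length(components)) stop_bad_arg("no components to model")
  p <- trial$patients
  long <- expand.grid(patient = p$patient, component = components,
                      stringsAsFactors = FALSE)
  long$arm <- arm_factor(p$arm[match(long$patient, p$patient)])
  key <- paste(trial$events$patient, trial$events$component)
  long$event <- as.integer(paste(long$patient, long$component) %in% key)
  if (!is.null(weights)) {
    w <- weight_lookup(weights)
    missing <- setdiff(components, names(w))
    if (length(missing))
      stop_bad_arg("no weight for component(s): ",
                   paste(missing, collapse = ", "))
    long$w <- unname(w[long$component])
    long$w <- long$w / mean(long$w)
  } else {
    long$w <- 1
  }
  # fractional observation weights are intentional; muffle the binomial
  # integer-count warning only
  fit <- withCallingHandlers(
    glmmTMB::glmmTMB(event ~ arm + (1 | patient), data = long,
                     family = stats::binomial(), weights = long$w),
    warning = function(w) {
      if (grepl("non-integer", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!fit$sdr$pdHess || !is.finite(fit$fit$objective))
    stop_bad_arg("random-effects model did not converge (",
                 "non-positive-definite Hessian); check event sparsity")
  co <- summary(fit)$coefficients$cond
  est <- co["armA", "Estimate"]; se <- co["armA", "Std. Error"]
  trial_result("random effects logistic", "odds ratio",
               exp(est), exp(est - 1.96 * se), exp(est + 1.96 * se),
               2 * stats::pnorm(-abs(est / se)), sum(long$event),
               weighted = !is.null(weights))
}

#' Run the full unweighted and weighted analysis battery
#'
#' Applies all configured analyses to one trial: the unweighted battery
#' (Fisher's exact test, time to first event, unweighted global rank,
#' unweighted random effects) and the weighted battery (weighted
#' recurrent-event Cox, weighted global rank, weighted random effects),
#' mirroring a side-by-side comparison of how component weighting changes
#' the estimated treatment effect.
#'
#' @param trial A `trial_data` object.
#' @param weights A `component_weights` table for the weighted analyses.
#' @return A data.frame with one row per method: `method`, `measure`,
#'   `estimate`, `lower95`, `upper95`, `p_value`, `n_events`, `weighted`.
#' @export
analyze_all <- function(trial, weights) {
  w <- weight_lookup(weights)
  unit <- stats::setNames(rep(1, length(w)), names(w))
  results <- list(
    fisher_composite(trial),
    time_to_first_event(trial),
    global_rank_test(trial, unit),
    random_effects_composite(trial, weights = NULL, components = names(w)),
    weighted_recurrent_tte(trial, weights),
    global_rank_test(trial, weights),
    random_effects_composite(trial, weights = weights)
  )
  out <- do.call(rbind, lapply(results, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier-style curve coordinates
#'
#' Survival-curve coordinates per arm for plotting or plain-text export:
#' either time to first event, or the weighted recurrent-event layout (one
#' record per event).
#'
#' @param trial A `trial_data` object.
#' @param weights Optional weights; when supplied the recurrent-event
#'   layout is used.
#' @return A data.frame `arm`, `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_curves <- function(trial, weights = NULL) {
  p <- trial$patients
  if (is.null(weights)) {
    first <- stats::aggregate(event_time ~ patient, trial$events, min)
    t_first <- first$event_time[match(p$patient, first$patient)]
    status <- as.integer(!is.na(t_first))
    dat <- data.frame(time = ifelse(is.na(t_first), p$followup, t_first),
                      status = status, arm = p$arm)
    fit <- survival::survfit(survival::Surv(time, status) ~ arm, data = dat)
  } else {
    w <- weight_lookup(weights)
    ev <- merge(trial$events, p, by = "patient")
    rows <- data.frame(time = ev$event_time, status = 1L, arm = ev$arm,
                       w = unname(w[ev$component]))
    none <- p[!p$patient %in% ev$patient, ]
    if (nrow(none))
      rows <- rbind(rows, data.frame(time = none$followup, status = 0L,
                                     arm = none$arm, w = 1))
    fit <- survival::survfit(survival::Surv(time, status) ~ arm, data = rows,
                             weights = rows$w)
  }
  arms <- rep(sub("^arm=", "", names(fit$strata)), fit$strata)
  data.frame(arm = arms, time = fit$time, surv = fit$surv,
             n_risk = fit$n.risk, n_event = fit$n.event)
}

#' Write trial analysis results as JSON or CSV
#'
#' @param results Data frame from [analyze_all()].
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else
    utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
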