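#' Specify a data-generating preference truth
#'
#' Bundles the population mean part-worths, the between-respondent
#' covariance, and optional covariate shifts that drive the choice
#' simulator. The reference level's utility is fixed at zero.
#'
#' @param catalog An [outcome_catalog()].
#' @param mu Named numeric vector of mean part-worths for non-reference
#'   outcomes (the reference is fixed at 0). Unnamed vectors are matched to
#'   the catalog's non-reference outcomes in order.
#' @param sigma Between-respondent covariance: a PSD matrix over the
#'   non-reference outcomes, or a single scalar `s` meaning `s * I`.
#' @param covariate_effects Optional named list: for each covariate name, a
#'   function of the respondent's covariate value returning an additive
#'   shift vector on `mu` (named or full-length).
#' @return A `true_preferences` object.
#' @examples
#' tp <- true_preferences(default_catalog(),
#'                        mu = fracture_outcome_utilities(), sigma = 0.25)
#' @export
true_preferences <- function(catalog, mu, sigma = 0, covariate_effects = NULL) {
  stopifnot(inherits(catalog, "outcome_catalog"))
  adverse <- adverse_outcomes(catalog)
  mu <- as_utility_vector(mu)
  if (is.null(names(mu))) {
    if (length(mu) != length(adverse))
      stop_bad_arg("mu has length ", length(mu), ", expected ", length(adverse))
    names(mu) <- adverse
  }
  mu <- mu[adverse]
  if (anyNA(mu)) stop_bad_arg("mu is missing values for some non-reference outcomes")
  k <- length(adverse)
  if (length(sigma) == 1L) sigma <- diag(as.numeric(sigma), k)
  sigma <- as.matrix(sigma)
  if (!isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-8)) ||
      any(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
    stop_bad_arg("sigma must be a symmetric positive semi-definite matrix")
  if (nrow(sigma) != k) stop_bad_arg("sigma dimension does not match the catalog")
  dimnames(sigma) <- list(adverse, adverse)
  structure(list(catalog = catalog, mu = mu, sigma = sigma,
                 covariate_effects = covariate_effects),
            class = "true_preferences")
}

#' Default data-generating truth for the shipped catalog
#'
#' Population means equal to the elicited utilities of
#' [fracture_outcome_utilities()] and moderate between-respondent
#' heterogeneity (`0.25 * I`).
#'
#' @return A [true_preferences()] object.
#' @export
default_truth <- function() {
  true_preferences(default_catalog(), mu = fracture_outcome_utilities(),
                   sigma = 0.25)
}

#' Simulate best-worst scaling responses
#'
#' Draws each respondent's part-worth vector from the multivariate normal
#' population of a [true_preferences()] truth (reference utility fixed at
#' zero) and generates best and worst picks for every task of their assigned
#' questionnaire version under the sequential best-worst logit:
#' the best item `b` is drawn with probability
#' `exp(beta_b) / sum_{j in S} exp(beta_j)` over the shown set `S`, then the
#' worst `w` with probability `exp(-beta_w) / sum_{j in S \ b} exp(-beta_j)`.
#' Versions are assigned round-robin by respondent index.
#'
#' @param design A `bws_design`.
#' @param truth A [true_preferences()] whose catalog matches the design.
#' @param n_respondents Number of respondents (default 396).
#' @param seed Integer seed; output is a pure function of inputs and seed.
#' @param covariates Optional data.frame of respondent covariates with
#'   `n_respondents` rows; columns are stored as `cov_*` and, when named in
#'   the truth's `covariate_effects`, shift that respondent's mean.
#' @return A `bws_responses` data.frame: `respondent`, `version`, `task`,
#'   `item1..item<m>`, `best`, `worst`, plus any `cov_*` columns, with the
#'   catalog attached as an attribute.
#' @export
simulate_choices <- function(design, truth, n_respondents = 396L, seed = 1L,
                             covariates = NULL) {
  stopifnot(inherits(design, "bws_design"), inherits(truth, "true_preferences"))
  if (n_respondents < 1L) stop_bad_arg("n_respondents must be at least 1")
  if (!identical(sort(truth$catalog$outcomes), sort(design$catalog$outcomes)))
    stop_bad_arg("truth and design use different catalogs")
  if (!is.null(covariates) && nrow(covariates) != n_respondents)
    stop_bad_arg("covariates must have one row per respondent")

  adverse <- names(truth$mu)
  k <- length(adverse)
  versions <- sort(unique(design$tasks$version))
  item_cols <- grep("^item", names(design$tasks), value = TRUE)
  m <- length(item_cols)

  withr::with_seed(as.integer(seed), {
    # Respondent part-worths on the full catalog scale (reference = 0).
    mu_mat <- matrix(truth$mu, n_respondents, k, byrow = TRUE)
    if (!is.null(truth$covariate_effects)) {
      for (nm in names(truth$covariate_effects)) {
        if (is.null(covariates) || !nm %in% names(covariates))
          stop_bad_arg("covariate_effects names covariate '", nm,
                       "' absent from the covariates table")
        shifts <- t(vapply(covariates[[nm]], function(v) {
          s <- truth$covariate_effects[[nm]](v)
          out <- stats::setNames(numeric(k), adverse)
          if (is.null(names(s))) out[] <- s else out[names(s)] <- s
          out
        }, numeric(k)))
        mu_mat <- mu_mat + shifts
      }
    }
    beta <- mu_mat + MASS::mvrnorm(n_respondents, mu = rep(0, k),
                                   Sigma = truth$sigma)
    colnames(beta) <- adverse
    beta_full <- cbind(beta,
                       stats::setNames(data.frame(rep(0, n_respondents)),
                                       truth$catalog$reference))
    beta_full <- as.matrix(beta_full)

    rows <- vector("list", n_respondents)
    for (r in seq_len(n_respondents)) {
      v <- versions[((r - 1L) %% length(versions)) + 1L]
      vt <- design$tasks[design$tasks$version == v, , drop = FALSE]
      shown <- as.matrix(vt[item_cols])
      b_r <- beta_full[r, ]
      best <- character(nrow(vt))
      worst <- character(nrow(vt))
      for (t_i in seq_len(nrow(vt))) {
        s <- shown[t_i, ]
        pb <- exp(b_r[s] - max(b_r[s]))
        best[t_i] <- sample(s, 1L, prob = pb)
        rest <- s[s != best[t_i]]
        pw <- exp(-b_r[rest] + min(b_r[rest]))
        worst[t_i] <- sample(rest, 1L, prob = pw)
      }
      rows[[r]] <- data.frame(respondent = r, version = v, task = vt$task,
                              vt[item_cols], best = best, worst = worst,
                              row.names = NULL)
    }
    out <- do.call(rbind, rows)
    if (!is.null(covariates)) {
      cv <- covariates
      names(cv) <- paste0("cov_", names(cv))
      out <- cbind(out, cv[out$respondent, , drop = FALSE])
      rownames(out) <- NULL
    }
    structure(out, catalog = truth$catalog,
              class = c("bws_responses", "data.frame"))
  })
}

#' Read or write choice responses as CSV
#'
#' @param responses A `bws_responses` data.frame.
#' @param path File path.
#' @param catalog Catalog attached on reading.
#' @return `write_responses()` returns `path` invisibly; `read_responses()`
#'   a `bws_responses`.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path, catalog) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, catalog = catalog, class = c("bws_responses", "data.frame"))
}

#' Simulate a two-arm trial with multi-component events
#'
#' Each patient independently experiences each composite component with the
#' arm-specific probability given in `component_probs`; several distinct
#' components may occur for the same patient (at most one event per
#' component). Event times are drawn uniformly over follow-up by default, or
#' from a truncated exponential with the stated rate.
#'
#' The default probabilities correspond to the event profile of a
#' hypothetical 1000-patient pilon fracture trial with a three-component
#' composite (deep SSI, bone healing complication, superficial SSI): arm A
#' (n = 498) has fewer severe events but more superficial infections than
#' arm B (n = 502).
#'
#' @param arm_sizes Integer pair: patients in arms A and B.
#' @param component_probs Named list with elements `A` and `B`, each a named
#'   vector of per-component event probabilities in `[0, 1]`.
#' @param followup_days Follow-up horizon (> 0), default 365.
#' @param time_model `"uniform"` (default) or `"exponential"`.
#' @param rate Event rate per day for the exponential model.
#' @param seed Integer seed.
#' @return A `trial_data` object: list with `events` (data.frame `patient`,
#'   `component`, `event_time`) and `patients` (data.frame `patient`, `arm`,
#'   `followup`).
#' @examples
#' tr <- simulate_trial(seed = 7)
#' table(tr$patients$arm)
#' @export
simulate_trial <- function(arm_sizes = c(A = 498L, B = 502L),
                           component_probs = pilon_trial_probs(),
                           followup_days = 365,
                           time_model = c("uniform", "exponential"),
                           rate = NULL, seed = 1L) {
  time_model <- match.arg(time_model)
  arm_sizes <- as.integer(arm_sizes)
  if (length(arm_sizes) != 2L || any(arm_sizes < 1L))
    stop_bad_arg("arm_sizes must be two positive integers")
  if (followup_days <= 0) stop_bad_arg("followup_days must be positive")
  probs <- lapply(component_probs[c("A", "B")], unlist)
  if (any(vapply(probs, is.null, logical(1))))
    stop_bad_arg("component_probs needs elements 'A' and 'B'")
  if (any(unlist(probs) < 0 | unlist(probs) > 1))
    stop_bad_arg("event probabilities must lie in [0, 1]")
  if (time_model == "exponential" && (is.null(rate) || rate <= 0))
    stop_bad_arg("the exponential time model needs a positive rate")

  withr::with_seed(as.integer(seed), {
    n <- sum(arm_sizes)
    patients <- data.frame(patient = seq_len(n),
                           arm = rep(c("A", "B"), arm_sizes),
                           followup = followup_days)
    ev <- list()
    for (arm in c("A", "B")) {
      idx <- patients$patient[patients$arm == arm]
      for (comp in names(probs[[arm]])) {
        hit <- idx[stats::runif(length(idx)) < probs[[arm]][comp]]
        if (!length(hit)) next
        t_ev <- switch(time_model,
          uniform = stats::runif(length(hit), 0, followup_days),
          exponential = {
            # truncated exponential on (0, followup]
            u <- stats::runif(length(hit))
            -log(1 - u * (1 - exp(-rate * followup_days))) / rate
          })
        ev[[length(ev) + 1L]] <- data.frame(patient = hit, component = comp,
                                            event_time = t_ev)
      }
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(patient = integer(), component = character(),
                 event_time = numeric())
    events <- events[order(events$patient, events$event_time), , drop = FALSE]
    rownames(events) <- NULL
    structure(list(events = events, patients = patients), class = "trial_data")
  })
}

#' Event probabilities of the hypothetical pilon fracture trial
#'
#' Per-arm, per-component event probabilities implied by the event counts of
#' the hypothetical trial (arm A, n = 498: 61 deep SSI, 30 bone healing
#' complications, 98 superficial SSI; arm B, n = 502: 91, 55 and 42).
#'
#' @return Named list with elements `A` and `B`.
#' @export
pilon_trial_probs <- function() {
  comps <- c("Deep surgical site infection", "Bone healing complication",
             "Superficial surgical site infection")
  list(A = stats::setNames(c(61, 30, 98) / 498, comps),
       B = stats::setNames(c(91, 55, 42) / 502, comps))
}

#' @export
print.trial_data <- function(x, ...) {
  cat("Two-arm trial:", nrow(x$patients), "patients (",
      paste(table(x$patients$arm), collapse = " + "), "),",
      nrow(x$events), "component events\n")
  invisible(x)
}

#' Read or write trial data (long and wide CSV)
#'
#' The long format has one row per component event
#' (`patient,arm,component,event_time,followup`) plus one row with an empty
#' component for each event-free patient. The wide format has one row per
#' patient with an event-time column per component (empty when no event).
#'
#' @param trial A `trial_data` object.
#' @param path File path.
#' @return Writers return `path` invisibly; readers a `trial_data`.
#' @export
write_trial_long <- function(trial, path) {
  ev <- merge(trial$events, trial$patients, by = "patient")
  ev <- ev[, c("patient", "arm", "component", "event_time", "followup")]
  none <- trial$patients[!trial$patients$patient %in% trial$events$patient, ]
  if (nrow(none))
    ev <- rbind(ev, data.frame(patient = none$patient, arm = none$arm,
                               component = "", event_time = NA_real_,
                               followup = none$followup))
  ev <- ev[order(ev$patient), ]
  utils::write.csv(ev, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_long
#' @export
read_trial_long <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  patients <- unique(df[, c("patient", "arm", "followup")])
  patients <- patients[order(patients$patient), ]
  rownames(patients) <- NULL
  events <- df[!is.na(df$event_time) & nzchar(df$component),
               c("patient", "component", "event_time")]
  rownames(events) <- NULL
  structure(list(events = events, patients = patients), class = "trial_data")
}

#' @rdname write_trial_long
#' @export
write_trial_wide <- function(trial, path) {
  comps <- sort(unique(trial$events$component))
  wide <- trial$patients
  for (comp in comps) {
    ev <- trial$events[trial$events$component == comp, ]
    wide[[make.names(comp)]] <- ev$event_time[match(wide$patient, ev$patient)]
  }
  utils::write.csv(wide, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_long
#' @param components For the wide reader: mapping from column names to
#'   component labels; defaults to the syntactic column names themselves.
#' @export
read_trial_wide <- function(path, components = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fixed <- c("patient", "arm", "followup")
  comp_cols <- setdiff(names(df), fixed)
  if (is.null(components))
    components <- stats::setNames(comp_cols, comp_cols)
  ev <- list()
  for (col in comp_cols) {
    has <- !is.na(df[[col]])
    if (any(has))
      ev[[col]] <- data.frame(patient = df$patient[has],
                              component = components[[col]],
                              event_time = df[[col]][has])
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(patient = integer(), component = character(),
               event_time = numeric())
  events <- events[order(events$patient, events$event_time), ]
  rownames(events) <- NULL
  structure(list(events = events, patients = df[, fixed]), class = "trial_data")
}
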