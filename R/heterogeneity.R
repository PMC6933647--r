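#' Screen covariates for preference heterogeneity
#'
#' First stage of the heterogeneity cascade: each covariate is tested
#' independently for a joint shift of the respondent-level utility vector
#' (a multivariate linear model of the posterior-mean utilities on the
#' covariate, Pillai/Wilks F test of the joint null). A covariate is
#' screened in when its p-value falls below the Bonferroni threshold
#' `alpha / n_covariates` (0.05 / 10 = 0.005 for the default ten-covariate
#' screen). Screened covariates are then re-tested jointly in a single
#' multivariate model at the same threshold (type-II tests).
#'
#' @param respondent_utilities Data frame from [respondent_utilities()]:
#'   `respondent` plus one utility column per outcome.
#' @param covariates Data frame keyed by a `respondent` column, one column
#'   per covariate.
#' @param alpha Familywise level before Bonferroni division (default 0.05).
#' @param n_covariates Divisor for the Bonferroni threshold; defaults to the
#'   number of covariate columns supplied.
#' @param outcomes Utility columns to include; defaults to all non-reference
#'   columns present.
#' @return A `heterogeneity_screen` list: `p_values` (named, marginal),
#'   `screened_in` (names), `joint_p_values` (named, NA when nothing
#'   screened in), `jointly_significant`, `alpha_adj`, `skipped`.
#' @export
screen_interactions <- function(respondent_utilities, covariates,
                                alpha = 0.05, n_covariates = NULL,
                                outcomes = NULL) {
  merged <- merge(respondent_utilities, covariates, by = "respondent")
  cov_names <- setdiff(names(covariates), "respondent")
  if (!length(cov_names)) stop_bad_arg("no covariates supplied")
  if (is.null(n_covariates)) n_covariates <- length(cov_names)
  if (n_covariates < 1L) stop_bad_arg("n_covariates must be at least 1")
  alpha_adj <- alpha / n_covariates
  if (is.null(outcomes))
    outcomes <- setdiff(names(respondent_utilities), "respondent")
  Y <- as.matrix(merged[outcomes])

  skipped <- character()
  p_values <- stats::setNames(rep(NA_real_, length(cov_names)), cov_names)
  for (cv in cov_names) {
    x <- merged[[cv]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      warning("covariate '", cv, "' has a single level; skipped")
      skipped <- c(skipped, cv)
      next
    }
    fit <- stats::lm(Y ~ x, data = data.frame(x = x))
    an <- stats::anova(fit, test = "Pillai")
    p_values[cv] <- an[["Pr(>F)"]][rownames(an) == "x"]
  }
  screened <- names(p_values)[!is.na(p_values) & p_values < alpha_adj]

  joint_p <- stats::setNames(rep(NA_real_, length(screened)), screened)
  if (length(screened) > 1L) {
    dat <- merged[screened]
    fit <- stats::lm(Y ~ ., data = dat)
    an <- car::Anova(fit, test.statistic = "Pillai", type = 2)
    sm <- summary(an)$multivariate.tests
    for (cv in screened) {
      tb <- sm[[cv]]
      if (!is.null(tb)) {
        st <- stats::pf(tb$approx.F, tb$num.df, tb$den.df, lower.tail = FALSE)
        joint_p[cv] <- st
      }
    }
  } else if (length(screened) == 1L) {
    joint_p[screened] <- p_values[screened]
  }

  structure(list(p_values = p_values,
                 screened_in = screened,
                 joint_p_values = joint_p,
                 jointly_significant = names(joint_p)[!is.na(joint_p) &
                                                        joint_p < alpha_adj],
                 alpha_adj = alpha_adj,
                 skipped = skipped),
            class = "heterogeneity_screen")
}

#' @export
print.heterogeneity_screen <- function(x, ...) {
  cat("Heterogeneity screen at adjusted alpha =", format(x$alpha_adj), "\n")
  print(round(x$p_values, 5))
  cat("screened in:",
      if (length(x$screened_in)) paste(x$screened_in, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Stratified one-way ANOVA of respondent utilities
#'
#' Compares the respondent-level posterior-mean utility of one outcome
#' across the strata of a covariate with a classical one-way ANOVA,
#' reporting per-stratum means and standard deviations alongside the F test.
#'
#' @param respondent_utilities Data frame from [respondent_utilities()].
#' @param covariate Stratum membership: either a covariate data.frame with a
#'   `respondent` column and one stratum column, or a vector aligned with
#'   the respondents.
#' @param outcome Name of the utility column to analyze.
#' @return A `stratified_anova` list: `p_value`, `f_statistic`, `df`,
#'   `strata` (data.frame `stratum`, `n`, `mean`, `sd`).
#' @export
stratified_anova <- function(respondent_utilities, covariate, outcome) {
  dat <- align_covariate(respondent_utilities, covariate, outcome)
  tab <- table(dat$g)
  if (length(tab) < 2L || any(tab < 2L))
    stop_bad_arg("need at least 2 strata with at least 2 respondents each")
  fit <- stats::aov(u ~ g, data = dat)
  an <- summary(fit)[[1]]
  if (an["Residuals", "Sum Sq"] < 1e-12 * max(1, an["g", "Sum Sq"]))
    stop_bad_arg("zero within-stratum variance: the F statistic is undefined")
  strata <- do.call(rbind, lapply(split(dat$u, dat$g), function(v)
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v))))
  strata <- cbind(data.frame(stratum = rownames(strata)), strata)
  rownames(strata) <- NULL
  structure(list(outcome = outcome,
                 p_value = an["g", "Pr(>F)"],
                 f_statistic = an["g", "F value"],
                 df = c(an["g", "Df"], an["Residuals", "Df"]),
                 strata = strata,
                 fit = fit),
            class = "stratified_anova")
}

#' Tukey-Kramer pairwise stratum comparisons
#'
#' All pairwise differences in mean respondent utility between strata, with
#' studentized-range adjusted p-values that honor unequal group sizes
#' (the Kramer modification). With exactly two strata the adjusted p-value
#' coincides with the pooled two-sample t-test.
#'
#' @inheritParams stratified_anova
#' @return A data.frame with columns `comparison`, `diff`, `lower`, `upper`,
#'   `p_adj`.
#' @export
tukey_kramer <- function(respondent_utilities, covariate, outcome) {
  dat <- align_covariate(respondent_utilities, covariate, outcome)
  if (length(unique(dat$g)) < 2L) stop_bad_arg("need at least 2 strata")
  fit <- stats::aov(u ~ g, data = dat)
  tk <- stats::TukeyHSD(fit)$g
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lower = tk[, "lwr"], upper = tk[, "upr"],
             p_adj = tk[, "p adj"], row.names = NULL)
}

#' Compare utilities between outcome experiencers and non-experiencers
#'
#' Two-sample Student's t-test (equal variances) of the respondent-level
#' utility of an outcome between respondents who experienced that outcome
#' during their clinical course and those who did not.
#'
#' @inheritParams stratified_anova
#' @param experience_flags Logical vector (or data.frame with `respondent`
#'   and one flag column) marking experiencers.
#' @return A list: `mean_experienced`, `mean_not`, `difference`, `t`, `df`,
#'   `p_value`, `n` (pair of group sizes).
#' @export
experienced_vs_not <- function(respondent_utilities, experience_flags, outcome) {
  dat <- align_covariate(respondent_utilities, experience_flags, outcome)
  dat$g <- as.logical(dat$g)
  n1 <- sum(dat$g); n0 <- sum(!dat$g)
  if (n1 == 0L || n0 == 0L)
    stop_bad_arg("both experiencer and non-experiencer groups must be non-empty")
  tt <- stats::t.test(dat$u[dat$g], dat$u[!dat$g], var.equal = TRUE)
  list(outcome = outcome,
       mean_experienced = mean(dat$u[dat$g]),
       mean_not = mean(dat$u[!dat$g]),
       difference = mean(dat$u[dat$g]) - mean(dat$u[!dat$g]),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n = c(experienced = n1, not = n0))
}

# Align a covariate/flag argument with the respondent utility table and
# return data.frame(u, g) for one outcome.
align_covariate <- function(respondent_utilities, covariate, outcome) {
  if (!outcome %in% names(respondent_utilities))
    stop_bad_arg("outcome '", outcome, "' not found in respondent utilities")
  if (is.data.frame(covariate)) {
    stopifnot("respondent" %in% names(covariate))
    gcol <- setdiff(names(covariate), "respondent")[1]
    merged <- merge(respondent_utilities[c("respondent", outcome)], covariate,
                    by = "respondent")
    dat <- data.frame(u = merged[[outcome]], g = merged[[gcol]])
  } else {
    if (length(covariate) != nrow(respondent_utilities))
      stop_bad_arg("covariate length does not match the respondent table")
    dat <- data.frame(u = respondent_utilities[[outcome]], g = covariate)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat$g <- factor(dat$g)
  dat
}

#' Stratified heterogeneity report
#'
#' Convenience wrapper producing a stratum-by-outcome table of mean (SD)
#' respondent utilities with ANOVA significance stars (* p < 0.05,
#' ** p < 0.01, *** p < 0.001), one block per covariate.
#'
#' @param respondent_utilities Data frame from [respondent_utilities()].
#' @param covariates Data frame keyed by `respondent`.
#' @param outcomes Utility columns to report; defaults to all.
#' @return A data.frame `covariate`, `stratum`, `n`, `outcome`, `mean`,
#'   `sd`, `p_value`, `stars`.
#' @export
heterogeneity_report <- function(respondent_utilities, covariates,
                                 outcomes = NULL) {
  if (is.null(outcomes))
    outcomes <- setdiff(names(respondent_utilities), "respondent")
  rows <- list()
  for (cv in setdiff(names(covariates), "respondent")) {
    for (oc in outcomes) {
      sa <- tryCatch(stratified_anova(respondent_utilities,
                                      covariates[c("respondent", cv)], oc),
                     error = function(e) NULL)
      if (is.null(sa)) next
      stars <- if (sa$p_value < 0.001) "***" else if (sa$p_value < 0.01) "**"
        else if (sa$p_value < 0.05) "*" else ""
      rows[[length(rows) + 1L]] <-
        data.frame(covariate = cv, stratum = sa$strata$stratum,
                   n = sa$strata$n, outcome = oc, mean = sa$strata$mean,
                   sd = sa$strata$sd, p_value = sa$p_value, stars = stars)
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
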