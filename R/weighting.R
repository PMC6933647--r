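#' Composite endpoint component weights from utilities
#'
#' Converts mean outcome utilities into component weights for a composite
#' endpoint. For component `a` of a composite with components `j = 1..k`,
#'
#' \deqn{W_a = \frac{\sum_{j \ne a} e^{u_j}}{\sum_j e^{u_j}}
#'           = 1 - \mathrm{softmax}_a(u),}
#'
#' a modified conditional-logit share: the more severe (more negative
#' utility) a component, the closer its weight is to 1. With three
#' components this is `(e^{u_b} + e^{u_i}) / (e^{u_a} + e^{u_b} + e^{u_i})`.
#' The denominator runs over the composite's components only; weights sum to
#' `k - 1` exactly and are invariant to adding a constant to all utilities.
#' Computation is log-sum-exp stabilized; rounding (e.g. to 2 decimals) is
#' left to presentation.
#'
#' @param utilities A `utility_estimates` table or a named numeric vector of
#'   mean utilities.
#' @param components Character vector (length >= 2) of component labels.
#' @return A `component_weights` data.frame with columns `component`,
#'   `utility`, `weight`.
#' @examples
#' u <- c("Deep surgical site infection" = -5.69,
#'        "Bone healing complication" = -5.20,
#'        "Superficial surgical site infection" = -3.29)
#' compute_weights(u, names(u))   # 0.93, 0.88, 0.19 at 2 decimals
#' @export
compute_weights <- function(utilities, components) {
  u_all <- as_utility_vector(utilities)
  components <- as.character(components)
  if (length(components) < 2L)
    stop_bad_arg("a composite needs at least 2 components")
  missing <- setdiff(components, names(u_all))
  if (length(missing))
    stop_bad_arg("no utility available for component(s): ",
                 paste(missing, collapse = ", "))
  u <- u_all[components]
  w <- 1 - exp(u - lse(u))
  structure(data.frame(component = components, utility = unname(u),
                       weight = unname(w), stringsAsFactors = FALSE),
            utilities_used = u,
            class = c("component_weights", "data.frame"))
}

#' @export
print.component_weights <- function(x, ...) {
  cat("Composite endpoint weights (", nrow(x), " components )\n", sep = "")
  print.data.frame(data.frame(component = x$component,
                              utility = x$utility,
                              weight = round(x$weight, 2)),
                   row.names = FALSE)
  invisible(x)
}

#' Subgroup-adjusted component weights
#'
#' Recomputes composite weights after substituting subgroup-specific mean
#' utilities (e.g. the utility of an above-knee amputation among
#' respondents aged 65 or older) for selected outcomes.
#'
#' @inheritParams compute_weights
#' @param overrides Named numeric vector or list: outcome label to subgroup
#'   mean utility. Labels must be known outcomes.
#' @return A `component_weights` data.frame; the labels whose utilities were
#'   overridden are recorded in the `"overridden"` attribute.
#' @export
subgroup_adjusted_weights <- function(utilities, components, overrides = NULL) {
  u <- as_utility_vector(utilities)
  overrides <- unlist(overrides)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(u))
    if (length(unknown))
      stop_bad_arg("override for unknown outcome(s): ",
                   paste(unknown, collapse = ", "))
    u[names(overrides)] <- overrides
  }
  out <- compute_weights(u, components)
  attr(out, "overridden") <- intersect(names(overrides), components)
  out
}

#' Sensitivity intervals for component weights
#'
#' Propagates utility uncertainty into the weights: each component's utility
#' is drawn independently from a normal distribution matched to its mean and
#' 95% interval (sd = interval width / (2 * 1.96)), the weights are
#' recomputed per draw, and 2.5/97.5 percentile intervals are reported.
#' Posterior correlations between utilities are not modelled, so the
#' intervals are approximate.
#'
#' @param utilities A `utility_estimates` table carrying `lower95`/`upper95`.
#' @param components Character vector of component labels.
#' @param n_draws Monte Carlo draws (>= 100).
#' @param seed Integer seed; deterministic given the seed.
#' @return A data.frame `component`, `weight` (point weight), `lower95`,
#'   `upper95`.
#' @export
weight_sensitivity <- function(utilities, components, n_draws = 10000L,
                               seed = 1L) {
  if (!is.data.frame(utilities) ||
      !all(c("outcome", "mean", "lower95", "upper95") %in% names(utilities)))
    stop_bad_arg("utilities must carry mean, lower95 and upper95 columns")
  if (n_draws < 100L) stop_bad_arg("n_draws must be at least 100")
  point <- compute_weights(utilities, components)
  rows <- match(components, utilities$outcome)
  mu <- utilities$mean[rows]
  sd <- (utilities$upper95[rows] - utilities$lower95[rows]) / (2 * stats::qnorm(0.975))
  if (anyNA(sd)) stop_bad_arg("missing interval for some components")
  k <- length(components)
  wmat <- withr::with_seed(as.integer(seed), {
    u_draws <- matrix(stats::rnorm(n_draws * k, mean = rep(mu, each = n_draws),
                                   sd = rep(sd, each = n_draws)), n_draws, k)
    e <- exp(u_draws - apply(u_draws, 1, max))
    1 - e / rowSums(e)
  })
  data.frame(component = components,
             weight = point$weight,
             lower95 = apply(wmat, 2, stats::quantile, 0.025),
             upper95 = apply(wmat, 2, stats::quantile, 0.975),
             row.names = NULL)
}

#' Read or write component weights as JSON
#'
#' Mirrors the outcome/utility/weight presentation of a composite endpoint
#' table.
#'
#' @param weights A `component_weights` data.frame.
#' @param path File path.
#' @return `write_weights()` returns `path` invisibly; `read_weights()` a
#'   `component_weights`.
#' @export
write_weights <- function(weights, path) {
  jsonlite::write_json(as.data.frame(weights), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(df, class = c("component_weights", "data.frame"))
}
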