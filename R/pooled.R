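# Anchoring contrast: maps the reduced parameter vector theta to utilities
# on the full item scale, beta = C %*% theta.
#   fixed:   beta[ref] = 0, identity rows elsewhere (dummy coding).
#   shifted: effects coding, sum(beta) = 0 over the item pool; reported
#            utilities are later re-anchored at the reference's posterior mean.
# When the reference item was never shown, utilities are identified only up
# to a common shift; we fall back to one free parameter per item and warn.
anchor_contrast <- function(items, reference, anchor = c("shifted", "fixed")) {
  anchor <- match.arg(anchor)
  k <- length(items)
  ref_i <- match(reference, items)
  if (is.na(ref_i)) {
    warning("reference level '", reference, "' does not appear in the choice ",
            "tasks; utilities are identified only up to a common shift")
    C <- diag(k)
    dimnames(C) <- list(items, items)
    return(C)
  }
  C <- matrix(0, k, k - 1L, dimnames = list(items, items[-ref_i]))
  C[cbind(seq_len(k)[-ref_i], seq_len(k - 1L))] <- 1
  if (anchor == "shifted") C[ref_i, ] <- -1
  C
}

#' Pooled multinomial-logit fit of best-worst responses
#'
#' Maximizes the product of sequential best-worst task likelihoods over all
#' respondents with one shared part-worth vector (no heterogeneity), via
#' quasi-Newton iteration. The reference outcome's utility is fixed at zero
#' (it must appear in the tasks for the location to be data-identified).
#' Confidence intervals are Wald intervals from the observed information.
#'
#' This fit serves as a fast point-estimate oracle for the hierarchical
#' Bayesian model of [fit_hb_mnl()] and as its initializer.
#'
#' @param responses A `bws_responses` data.frame.
#' @param catalog An [outcome_catalog()]; defaults to the one attached to
#'   `responses`.
#' @return A `utility_estimates` data frame with one row per item seen in
#'   the tasks (the reference, if shown, has a degenerate zero interval).
#' @export
fit_pooled_mnl <- function(responses, catalog = attr(responses, "catalog")) {
  if (is.null(catalog)) stop_bad_arg("no catalog attached to the responses")
  idx <- index_responses(responses,
                         items = catalog$outcomes[
                           catalog$outcomes %in%
                             unlist(responses[grep("^item", names(responses))],
                                    use.names = FALSE)])
  C <- anchor_contrast(idx$items, catalog$reference, anchor = "fixed")
  p <- ncol(C)
  fit <- stats::optim(rep(0, p), bw_pooled_negll, idx = idx, C = C,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  theta <- fit$par
  if (fit$convergence != 0 || any(abs(theta) > 15)) {
    worst_dir <- colnames(C)[which.max(abs(theta))]
    stop_bad_arg("finite maximum-likelihood estimate does not exist: the ",
                 "likelihood is unbounded in the direction of '", worst_dir,
                 "' (complete separation)")
  }
  V <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V)) || any(diag(V) < 0)) {
    worst_dir <- colnames(C)[which.max(abs(theta))]
    stop_bad_arg("singular information matrix (separation or unidentified ",
                 "utilities); largest estimate is for '", worst_dir, "'")
  }
  u <- as.numeric(C %*% theta)
  se_u <- sqrt(pmax(0, diag(C %*% V %*% t(C))))
  df <- data.frame(outcome = idx$items, mean = u,
                   lower95 = u - 1.96 * se_u, upper95 = u + 1.96 * se_u,
                   stringsAsFactors = FALSE)
  new_utility_estimates(df, reference = catalog$reference,
                        n_respondents = idx$n_resp, method = "pooled MNL")
}
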