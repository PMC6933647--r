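#' Hierarchical Bayesian multinomial logit for best-worst responses
#'
#' Estimates outcome utilities from best-worst scaling data with a mixed
#' logit: respondent part-worth vectors `beta_r` are drawn from a
#' multivariate normal population `N(mu, Sigma)`, and each respondent's
#' picks follow the sequential best-worst logit of [bw_task_likelihood()].
#' The sampler alternates
#' (1) a conjugate normal draw of `mu` given the part-worths and `Sigma`,
#' (2) a conjugate inverse-Wishart draw of `Sigma`, and
#' (3) one random-walk Metropolis-Hastings step per respondent with a
#' proposal covariance proportional to the current `Sigma`, its scale
#' adapted toward roughly 30% acceptance during burn-in and frozen after,
#' and two joint moves that repair the chain's slowest directions:
#' (4) a location move shifting every part-worth vector and `mu` by a
#' common constant (the reference-to-adverse gap is informed only by the
#' minority of tasks showing the reference, so respondent-wise random
#' walks traverse it extremely slowly), and (5) a scale move contracting or
#' expanding all part-worths around `mu` jointly with `Sigma` (Gibbs
#' updates alone change the overall heterogeneity scale only geometrically
#' slowly). Both are plain Metropolis-Hastings steps on the exact
#' posterior, with scales adapted during burn-in like the respondent
#' proposals.
#'
#' Priors are weakly informative: `mu ~ N(0, prior_mu_var * I)` and
#' `Sigma ~ InverseWishart(d + 2, I)` with `d` the parameter dimension.
#'
#' Anchoring: with `anchor = "fixed"` (default) the reference outcome's
#' utility is pinned to zero in the likelihood for the population and every
#' respondent — the anchor is a common fixed point, respondent
#' heterogeneity attaches to the adverse outcomes, and the reference's
#' reported interval is degenerate. With `anchor = "shifted"` the model is
#' effects-coded (utilities of all shown items sum to zero per draw) and
#' reported utilities are shifted by a constant so the reference's
#' posterior mean is exactly zero, leaving it a non-degenerate interval;
#' this coding also grants the anchor its own between-respondent variance,
#' which the choice data barely constrain, and can widen the anchor gap
#' noticeably — use it for presentation, not for recovery benchmarks.
#' Respondents missing a best or worst pick on any task are dropped
#' entirely.
#'
#' @param responses A `bws_responses` data.frame.
#' @param n_iter Total MCMC iterations (default 10000).
#' @param burn_in Burn-in iterations discarded (default 5000; must be
#'   smaller than `n_iter`).
#' @param seed Integer seed; draws are a pure function of inputs and seed.
#' @param anchor `"shifted"` or `"fixed"`, see Details.
#' @param catalog An [outcome_catalog()]; defaults to the attached one.
#' @param prior_mu_var Prior variance of each component of `mu`.
#' @param keep_beta_draws Store full per-respondent draws (memory permitting)
#'   in addition to their running means.
#' @param verbose Print progress every 1000 iterations.
#' @return A list of class `hb_fit` with elements `draws` (a
#'   `posterior_draws` object: `mu` and `utility` draw matrices, `sigma`
#'   array, `beta_mean`, acceptance trace, iteration counts, seed) and
#'   `estimates` (a `utility_estimates` data frame of posterior means and
#'   2.5/97.5 percentiles).
#' @export
fit_hb_mnl <- function(responses, n_iter = 10000L, burn_in = 5000L, seed = 1L,
                       anchor = c("fixed", "shifted"),
                       catalog = attr(responses, "catalog"),
                       prior_mu_var = 100, keep_beta_draws = FALSE,
                       verbose = FALSE) {
  anchor <- match.arg(anchor)
  if (is.null(catalog)) stop_bad_arg("no catalog attached to the responses")
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  if (burn_in >= n_iter) stop_bad_arg("burn_in must be smaller than n_iter")
  if (!nrow(responses)) stop_bad_arg("responses are empty")

  idx <- index_responses(responses,
                         items = catalog$outcomes[
                           catalog$outcomes %in%
                             unlist(responses[grep("^item", names(responses))],
                                    use.names = FALSE)])
  C <- anchor_contrast(idx$items, catalog$reference, anchor = anchor)
  d <- ncol(C)
  N <- idx$n_resp
  k <- length(idx$items)

  init <- tryCatch(
    {
      mle <- fit_pooled_mnl(responses, catalog = catalog)
      # project MLE utilities onto the theta scale: theta = (C'C)^-1 C' u
      as.numeric(solve(crossprod(C), crossprod(C, mle$mean[match(idx$items, mle$outcome)])))
    },
    error = function(e) rep(0, d))

  nu0 <- d + 2
  S0 <- diag(d)
  retained <- n_iter - burn_in

  res <- withr::with_seed(as.integer(seed), {
    # overdispersed start at the prior scale: launching every respondent at
    # the same point collapses the first Sigma draw toward zero and the
    # hierarchy re-inflates only slowly
    theta <- matrix(rep(init, each = N), N, d) +
      matrix(stats::rnorm(N * d), N, d)
    mu <- init
    sigma <- diag(d)
    rho <- 0.1
    rho_loc <- 0.1
    ll_cur <- bw_loglik_by_respondent(theta %*% t(C), idx)

    mu_draws <- matrix(NA_real_, retained, d)
    sigma_draws <- array(NA_real_, c(d, d, retained))
    beta_sum <- matrix(0, N, d)
    beta_draws <- if (keep_beta_draws && retained * N * d <= 5e6)
      array(NA_real_, c(N, d, retained)) else NULL
    acc_trace <- numeric(n_iter)
    rho_trace <- numeric(n_iter)
    acc_window <- rep(0.3, 25L)
    loc_window <- rep(0.35, 25L)
    loc_trace <- numeric(n_iter)
    scl_window <- rep(0.35, 25L)
    scl_trace <- numeric(n_iter)
    rho_scl <- 0.1

    for (it in seq_len(n_iter)) {
      ## (1) mu | theta, sigma  --  conjugate normal
      mu <- draw_mu(theta, sigma, prior_mu_var)
      ## (2) sigma | theta, mu  --  conjugate inverse-Wishart
      sigma <- draw_sigma(theta, mu, S0, nu0)

      ## (3) theta_r | mu, sigma, data  --  random-walk MH, all respondents
      L <- chol(sigma)
      prop <- theta + rho * (matrix(stats::rnorm(N * d), N, d) %*% L)
      ll_prop <- bw_loglik_by_respondent(prop %*% t(C), idx)
      Si <- chol2inv(L)
      qc <- theta - matrix(mu, N, d, byrow = TRUE)
      qp <- prop - matrix(mu, N, d, byrow = TRUE)
      lp_cur <- -0.5 * rowSums((qc %*% Si) * qc)
      lp_prop <- -0.5 * rowSums((qp %*% Si) * qp)
      accept <- log(stats::runif(N)) < (ll_prop + lp_prop - ll_cur - lp_cur)
      theta[accept, ] <- prop[accept, , drop = FALSE]
      ll_cur[accept] <- ll_prop[accept]
      if (any(!is.finite(ll_cur)))
        stop("non-finite likelihood for respondent ",
             idx$resp_ids[which(!is.finite(ll_cur))[1]], call. = FALSE)

      ## (4) joint location move: shift every theta_r and mu by a common
      ## delta. The theta_r | mu, Sigma prior terms cancel; only tasks
      ## showing the reference change the likelihood.
      delta <- rho_loc * stats::rnorm(1L)
      ll_loc <- bw_loglik_by_respondent((theta + delta) %*% t(C), idx)
      lp_delta <- (sum(mu^2) - sum((mu + delta)^2)) / (2 * prior_mu_var)
      loc_ok <- log(stats::runif(1L)) < sum(ll_loc - ll_cur) + lp_delta
      if (loc_ok) {
        theta <- theta + delta
        mu <- mu + delta
        ll_cur <- ll_loc
      }
      loc_window[(it - 1L) %% 25L + 1L] <- as.numeric(loc_ok)
      if (it < burn_in) {
        rho_loc <- rho_loc * if (mean(loc_window) > 0.35) 1.1 else 0.9
        loc_trace[it] <- rho_loc
      } else if (it == burn_in && burn_in >= 10L) {
        tail_n <- min(500L, burn_in - 1L)
        rho_loc <- exp(mean(log(loc_trace[(burn_in - tail_n):(burn_in - 1L)])))
      }

      ## (5) joint scale move: contract or expand all part-worths around mu
      ## together with Sigma (theta_r -> mu + g(theta_r - mu), Sigma ->
      ## g^2 Sigma). The hierarchical density change cancels against the
      ## theta Jacobian, leaving the likelihood, the inverse-Wishart prior
      ## and the Sigma Jacobian. Gibbs updates alone traverse the overall
      ## heterogeneity scale only geometrically slowly.
      g <- exp(rho_scl * stats::rnorm(1L))
      mu_mat <- matrix(mu, N, d, byrow = TRUE)
      prop_s <- mu_mat + g * (theta - mu_mat)
      ll_scl <- bw_loglik_by_respondent(prop_s %*% t(C), idx)
      Si_s <- chol2inv(chol(sigma))
      d_prior <- -(nu0 + d + 1) * d * log(g) -
        0.5 * sum(diag(Si_s)) * (1 / g^2 - 1)
      scl_ok <- log(stats::runif(1L)) <
        sum(ll_scl - ll_cur) + d_prior + d * (d + 1) * log(g)
      if (scl_ok) {
        theta <- prop_s
        sigma <- g^2 * sigma
        ll_cur <- ll_scl
      }
      scl_window[(it - 1L) %% 25L + 1L] <- as.numeric(scl_ok)
      if (it < burn_in) {
        rho_scl <- rho_scl * if (mean(scl_window) > 0.35) 1.1 else 0.9
        scl_trace[it] <- rho_scl
      } else if (it == burn_in && burn_in >= 10L) {
        tail_n <- min(500L, burn_in - 1L)
        rho_scl <- exp(mean(log(scl_trace[(burn_in - tail_n):(burn_in - 1L)])))
      }

      afrac <- mean(accept)
      acc_trace[it] <- afrac
      acc_window[(it - 1L) %% 25L + 1L] <- afrac
      if (it < burn_in) {
        rho <- rho * if (mean(acc_window) > 0.30) 1.1 else 0.9
      } else if (it == burn_in && burn_in >= 10L) {
        # the multiplicative rule makes log(rho) a random walk around its
        # equilibrium; freeze at the geometric mean of the recent trajectory
        # rather than at whatever excursion burn-in happens to end on
        tail_n <- min(500L, burn_in - 1L)
        rho <- exp(mean(log(rho_trace[(burn_in - tail_n):(burn_in - 1L)])))
      }
      rho_trace[it] <- rho

      if (it > burn_in) {
        s <- it - burn_in
        mu_draws[s, ] <- mu
        sigma_draws[, , s] <- sigma
        beta_sum <- beta_sum + theta
        if (!is.null(beta_draws)) beta_draws[, , s] <- theta
      }
      if (verbose && it %% 1000L == 0L)
        message("iteration ", it, "/", n_iter,
                "  acceptance ", round(mean(acc_window), 2))
    }
    list(mu_draws = mu_draws, sigma_draws = sigma_draws,
         beta_mean = beta_sum / retained, beta_draws = beta_draws,
         acc_trace = acc_trace, rho_trace = rho_trace)
  })

  # utilities on the full item scale, one row per retained draw
  util_draws <- res$mu_draws %*% t(C)
  colnames(util_draws) <- idx$items
  shift <- 0
  ref <- catalog$reference
  if (anchor == "shifted" && ref %in% idx$items) {
    shift <- mean(util_draws[, ref])
    util_draws <- util_draws - shift
  }
  est_mean <- colMeans(util_draws)
  if (ref %in% idx$items && anchor == "shifted") est_mean[ref] <- 0
  qs <- apply(util_draws, 2, stats::quantile, probs = c(0.025, 0.975))
  est <- new_utility_estimates(
    data.frame(outcome = idx$items, mean = unname(est_mean),
               lower95 = pmin(unname(qs[1, ]), unname(est_mean)),
               upper95 = pmax(unname(qs[2, ]), unname(est_mean)),
               stringsAsFactors = FALSE),
    reference = ref, n_respondents = N, method = "hierarchical Bayes MNL")

  draws <- structure(
    list(mu = res$mu_draws, utility = util_draws, sigma = res$sigma_draws,
         beta_mean = res$beta_mean, beta_draws = res$beta_draws,
         contrast = C, items = idx$items, respondent_ids = idx$resp_ids,
         anchor = anchor, anchor_shift = shift,
         acceptance = res$acc_trace, proposal_scale = res$rho_trace,
         n_iter = n_iter, burn_in = burn_in, seed = as.integer(seed)),
    class = "posterior_draws")

  structure(list(draws = draws, estimates = est), class = "hb_fit")
}

# mu full conditional: precision = N * Sigma^-1 + I / prior_var,
# mean = precision^-1 Sigma^-1 sum(theta_r). Used by the sampler and
# directly unit-testable against its closed-form moments.
draw_mu <- function(theta, sigma, prior_var) {
  N <- nrow(theta); d <- ncol(theta)
  Si <- chol2inv(chol(sigma))
  P <- N * Si + diag(d) / prior_var
  Lp <- chol(P)
  m <- backsolve(Lp, forwardsolve(t(Lp), Si %*% colSums(theta)))
  as.numeric(m + backsolve(Lp, stats::rnorm(d)))
}

mu_conditional_moments <- function(theta, sigma, prior_var) {
  N <- nrow(theta); d <- ncol(theta)
  Si <- chol2inv(chol(sigma))
  P <- N * Si + diag(d) / prior_var
  V <- chol2inv(chol(P))
  list(mean = as.numeric(V %*% (Si %*% colSums(theta))), cov = V)
}

# Sigma full conditional: InverseWishart(nu0 + N, S0 + scatter about mu).
draw_sigma <- function(theta, mu, S0, nu0) {
  N <- nrow(theta)
  q <- theta - matrix(mu, N, ncol(theta), byrow = TRUE)
  S <- S0 + crossprod(q)
  W <- stats::rWishart(1L, nu0 + N, chol2inv(chol(S)))[, , 1L]
  chol2inv(chol(W))
}

#' @export
print.hb_fit <- function(x, ...) {
  cat("Hierarchical Bayes MNL fit:", x$draws$n_iter, "iterations (",
      x$draws$burn_in, "burn-in ),",
      length(x$draws$respondent_ids), "respondents\n")
  cat("mean MH acceptance after burn-in:",
      round(mean(x$draws$acceptance[-seq_len(x$draws$burn_in)]), 3), "\n\n")
  print(x$estimates)
  invisible(x)
}

#' Respondent-level posterior mean utilities
#'
#' Posterior means of each respondent's part-worth vector over the retained
#' draws, mapped to the full outcome scale and re-anchored the same way as
#' the population estimates. These feed the heterogeneity analyses.
#'
#' @param draws A `posterior_draws` object (or an `hb_fit`).
#' @return A data.frame with column `respondent` followed by one utility
#'   column per outcome.
#' @export
respondent_utilities <- function(draws) {
  if (inherits(draws, "hb_fit")) draws <- draws$draws
  stopifnot(inherits(draws, "posterior_draws"))
  u <- draws$beta_mean %*% t(draws$contrast) - draws$anchor_shift
  colnames(u) <- draws$items
  cbind(data.frame(respondent = draws$respondent_ids), as.data.frame(u))
}
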