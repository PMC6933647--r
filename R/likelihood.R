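#' Likelihood of one best-worst pick
#'
#' Probability of observing the pair (`best`, `worst`) in one choice set
#' under the sequential (exploded) best-worst logit: the best item is a
#' multinomial-logit draw over the shown set with utilities `beta`, and the
#' worst is a draw over the remaining items with negated utilities,
#'
#' \deqn{P(b, w \mid S) = \frac{e^{\beta_b}}{\sum_{j \in S} e^{\beta_j}}
#'       \cdot \frac{e^{-\beta_w}}{\sum_{j \in S \setminus b} e^{-\beta_j}}.}
#'
#' @param beta Named numeric utility vector covering the shown items, or an
#'   unnamed vector matched to `shown` by position.
#' @param shown Character (or index) vector of the items in the choice set.
#' @param best,worst The picked items; must be distinct members of `shown`.
#' @return The probability, a number in (0, 1).
#' @examples
#' bw_task_likelihood(c(a = 0, b = 0, c = 0), c("a", "b", "c"), "a", "c")  # 1/6
#' @export
bw_task_likelihood <- function(beta, shown, best, worst) {
  if (length(best) != 1L || length(worst) != 1L || identical(best, worst))
    stop_bad_arg("best and worst must be a single pair of distinct items")
  if (is.null(names(beta))) {
    if (length(beta) != length(shown))
      stop_bad_arg("unnamed beta must have one entry per shown item")
    names(beta) <- shown
  }
  if (!all(c(best, worst) %in% shown))
    stop_bad_arg("best and worst must both be among the shown items")
  b <- beta[as.character(shown)]
  if (anyNA(b)) stop_bad_arg("beta does not cover all shown items")
  p_best <- exp(b[[as.character(best)]] - lse(b))
  rest <- b[names(b) != as.character(best)]
  p_worst <- exp(-rest[[as.character(worst)]] - lse(-rest))
  p_best * p_worst
}

# ---- vectorized internal engine shared by the pooled MLE and HB sampler ----

# Index a response table against an item vector. Returns a list with
#   resp (int), shown (M x m index matrix), best_pos/worst_pos (column of the
#   pick within shown), n_resp, items.
# Respondents missing a best or worst pick on any task are dropped entirely.
index_responses <- function(responses, items = NULL) {
  item_cols <- grep("^item", names(responses), value = TRUE)
  if (!length(item_cols) || !all(c("best", "worst") %in% names(responses)))
    stop_bad_arg("responses must have item*, best and worst columns")
  bad <- is.na(responses$best) | is.na(responses$worst) |
    responses$best == "" | responses$worst == ""
  if (any(bad)) {
    drop_resp <- unique(responses$respondent[bad])
    warning("dropping ", length(drop_resp),
            " respondent(s) with incomplete best/worst picks")
    responses <- responses[!responses$respondent %in% drop_resp, , drop = FALSE]
  }
  if (!nrow(responses)) stop_bad_arg("no complete responses left")
  shown_lab <- as.matrix(responses[item_cols])
  if (is.null(items))
    items <- sort(unique(as.vector(shown_lab)))
  shown <- matrix(match(as.vector(shown_lab), items), nrow = nrow(responses))
  if (anyNA(shown)) stop_bad_arg("responses contain items outside the catalog")
  best_pos <- max.col(shown_lab == responses$best, ties.method = "first")
  worst_pos <- max.col(shown_lab == responses$worst, ties.method = "first")
  if (any(rowSums(shown_lab == responses$best) != 1L) ||
      any(rowSums(shown_lab == responses$worst) != 1L))
    stop_bad_arg("every best/worst pick must match exactly one shown item")
  if (any(best_pos == worst_pos))
    stop_bad_arg("best and worst picks coincide in some tasks")
  resp_ids <- unique(responses$respondent)
  list(resp = match(responses$respondent, resp_ids),
       resp_ids = resp_ids,
       shown = shown,
       best_pos = best_pos, worst_pos = worst_pos,
       n_resp = length(resp_ids), items = items,
       m = length(item_cols))
}

# Per-respondent log-likelihood for a beta matrix (n_resp x n_items, full
# item scale). Returns a numeric vector of length n_resp.
bw_loglik_by_respondent <- function(beta_mat, idx) {
  m <- idx$m
  M <- length(idx$resp)
  eta <- matrix(0, M, m)
  for (j in seq_len(m))
    eta[, j] <- beta_mat[cbind(idx$resp, idx$shown[, j])]
  ll_best <- eta[cbind(seq_len(M), idx$best_pos)] - row_lse(eta)
  # worst over the shown set minus the best, with negated utilities
  neg <- -eta
  neg[cbind(seq_len(M), idx$best_pos)] <- -Inf
  ll_worst <- neg[cbind(seq_len(M), idx$worst_pos)] - row_lse(neg)
  as.numeric(rowsum(ll_best + ll_worst, idx$resp, reorder = TRUE))
}

# Pooled (single shared beta) negative log-likelihood and its value for a
# parameter vector theta on the reduced scale beta = C %*% theta.
bw_pooled_negll <- function(theta, idx, C) {
  beta <- as.numeric(C %*% theta)
  beta_mat <- matrix(beta, 1L, length(beta))
  idx1 <- idx
  idx1$resp <- rep(1L, length(idx$resp))
  -sum(bw_loglik_by_respondent(beta_mat, idx1))
}
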