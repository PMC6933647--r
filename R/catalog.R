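#' Define an outcome catalog
#'
#' An outcome catalog is the ordered list of clinical outcomes (attribute
#' levels) that can appear in a best-worst scaling questionnaire, together
#' with one designated reference level whose reported mean utility is
#' anchored at zero. All other outcomes are interpreted relative to it.
#'
#' @param outcomes Character vector of unique outcome labels (at least 3).
#' @param reference The label used as the zero-utility anchor. Must be one of
#'   `outcomes`. Defaults to `"Perfect health"`.
#' @return An object of class `outcome_catalog`: a list with elements
#'   `outcomes` and `reference`.
#' @examples
#' cat3 <- outcome_catalog(c("Perfect health", "Mild pain", "Deep SSI"))
#' cat3
#' @export
outcome_catalog <- function(outcomes, reference = "Perfect health") {
  outcomes <- as.character(outcomes)
  if (anyDuplicated(outcomes)) stop_bad_arg("outcome labels must be unique")
  if (length(outcomes) < 3L) stop_bad_arg("an outcome catalog needs at least 3 outcomes")
  if (!reference %in% outcomes)
    stop_bad_arg("reference level '", reference, "' is not in the outcome list")
  structure(list(outcomes = outcomes, reference = reference),
            class = "outcome_catalog")
}

#' @export
print.outcome_catalog <- function(x, ...) {
  cat("Outcome catalog:", length(x$outcomes), "outcomes\n")
  marks <- ifelse(x$outcomes == x$reference, " (reference)", "")
  cat(paste0("  - ", x$outcomes, marks, collapse = "\n"), "\n")
  invisible(x)
}

#' Non-reference outcomes of a catalog
#' @param catalog An [outcome_catalog()].
#' @return Character vector of outcome labels excluding the reference level.
#' @export
adverse_outcomes <- function(catalog) {
  setdiff(catalog$outcomes, catalog$reference)
}

#' Default orthopaedic trauma outcome catalog
#'
#' The ten clinical outcomes commonly reported after surgically treated
#' fractures that ship as the package default: death, above/below knee
#' amputation, three pain severities, deep and superficial surgical site
#' infection (SSI), bone healing complications, and perfect health (the
#' reference level).
#'
#' @return An [outcome_catalog()] of ten outcomes with `"Perfect health"` as
#'   reference.
#' @export
default_catalog <- function() {
  outcome_catalog(
    c("Death",
      "Above knee amputation",
      "Below knee amputation",
      "Severe pain",
      "Deep surgical site infection",
      "Bone healing complication",
      "Moderate pain",
      "Mild pain",
      "Superficial surgical site infection",
      "Perfect health"),
    reference = "Perfect health"
  )
}

#' Reference utility estimates for the default catalog
#'
#' Mean utilities with 95% intervals for the ten orthopaedic trauma outcomes,
#' as elicited from a best-worst scaling survey of 396 surgically treated
#' fracture patients and estimated with a hierarchical Bayesian multinomial
#' logit (10,000 iterations, 5,000 burn-in), scaled so perfect health has
#' mean utility zero. These serve as ready-made inputs for weight
#' calculation and as a realistic truth for the simulators.
#'
#' @return A [utility_estimates] data frame (outcome, mean, lower95, upper95).
#' @examples
#' u <- fracture_outcome_utilities()
#' compute_weights(u, c("Deep surgical site infection",
#'                      "Bone healing complication",
#'                      "Superficial surgical site infection"))
#' @export
fracture_outcome_utilities <- function() {
  df <- data.frame(
    outcome = default_catalog()$outcomes,
    mean    = c(-8.91, -7.66, -6.97, -5.90, -5.69, -5.20, -4.59, -3.30, -3.29, 0.00),
    lower95 = c(-9.23, -7.83, -7.14, -6.00, -5.81, -5.31, -4.69, -3.46, -3.39, -0.37),
    upper95 = c(-8.65, -7.48, -6.85, -5.80, -5.60, -5.09, -4.57, -3.13, -3.16, 0.44),
    stringsAsFactors = FALSE
  )
  new_utility_estimates(df, reference = "Perfect health", n_respondents = 396L,
                        method = "reference table")
}

#' Read or write an outcome catalog as JSON
#'
#' The on-disk format is `{"outcomes": [...], "reference": "..."}`.
#'
#' @param path File path.
#' @param catalog An [outcome_catalog()].
#' @return `read_catalog()` returns an [outcome_catalog()];
#'   `write_catalog()` returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  outcome_catalog(x$outcomes, reference = x$reference %||% "Perfect health")
}

#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  jsonlite::write_json(list(outcomes = catalog$outcomes,
                            reference = catalog$reference),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
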