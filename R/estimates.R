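# The utility_estimates container shared by the pooled MLE, the HB sampler
# and the shipped reference table.

new_utility_estimates <- function(df, reference, n_respondents, method) {
  stopifnot(all(c("outcome", "mean", "lower95", "upper95") %in% names(df)))
  structure(df,
            reference = reference,
            n_respondents = n_respondents,
            method = method,
            class = c("utility_estimates", "data.frame"))
}

#' @export
print.utility_estimates <- function(x, digits = 3, ...) {
  cat("Outcome utilities (", attr(x, "method"), ", n = ",
      attr(x, "n_respondents"), " respondents, reference: ",
      attr(x, "reference"), ")\n", sep = "")
  print.data.frame(data.frame(outcome = x$outcome,
                              mean = round(x$mean, digits),
                              lower95 = round(x$lower95, digits),
                              upper95 = round(x$upper95, digits)),
                   row.names = FALSE)
  invisible(x)
}

# Coerce a named numeric vector, a utility_estimates object, or any
# data.frame with outcome/mean columns to a named utility vector.
as_utility_vector <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.data.frame(x) && all(c("outcome", "mean") %in% names(x)))
    return(stats::setNames(x$mean, x$outcome))
  stop_bad_arg("cannot interpret utilities: supply a named numeric vector ",
               "or a utility estimates table")
}

#' Read or write utility estimates as JSON
#'
#' The format is an array of `{outcome, mean, lower95, upper95}` records
#' plus a small metadata object.
#'
#' @param estimates A `utility_estimates` object.
#' @param path File path.
#' @return `write_utilities()` returns `path` invisibly; `read_utilities()`
#'   a `utility_estimates`.
#' @export
write_utilities <- function(estimates, path) {
  jsonlite::write_json(
    list(meta = list(reference = attr(estimates, "reference"),
                     n_respondents = attr(estimates, "n_respondents"),
                     method = attr(estimates, "method")),
         utilities = as.data.frame(estimates)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_utilities
#' @export
read_utilities <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_utility_estimates(x$utilities, reference = x$meta$reference,
                        n_respondents = x$meta$n_respondents,
                        method = x$meta$method)
}
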