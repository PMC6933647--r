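# Small fixtures shared across tests; everything is built in code.

small_catalog <- function() {
  outcome_catalog(c("well", "ache", "infection", "fracture", "worst"),
                  reference = "well")
}

# A tiny deterministic design over the small catalog (reference included).
small_design <- function(seed = 1L) {
  generate_design(small_catalog(), n_versions = 2L, tasks_per_version = 5L,
                  items_per_task = 3L, seed = seed, n_restarts = 5L)
}

# Hand-built response table: two respondents, two tasks each, over items
# a/b/c (no reference shown).
toy_responses <- function() {
  cat <- outcome_catalog(c("ref", "a", "b", "c"), reference = "ref")
  df <- data.frame(
    respondent = c(1L, 1L, 2L, 2L),
    version = 1L,
    task = c(1L, 2L, 1L, 2L),
    item1 = "a", item2 = "b", item3 = "c",
    best = c("a", "a", "b", "a"),
    worst = c("c", "b", "c", "c"),
    stringsAsFactors = FALSE
  )
  structure(df, catalog = cat, class = c("bws_responses", "data.frame"))
}

# Build a trial_data object directly from per-patient event lists.
make_trial <- function(events, patients) {
  structure(list(events = events, patients = patients), class = "trial_data")
}

# Two balanced arms, one component, with given event times (NA = censored).
two_arm_trial <- function(times_a, times_b, followup = 365,
                          component = "c1") {
  nA <- length(times_a); nB <- length(times_b)
  patients <- data.frame(patient = seq_len(nA + nB),
                         arm = rep(c("A", "B"), c(nA, nB)),
                         followup = followup)
  tt <- c(times_a, times_b)
  has <- !is.na(tt)
  events <- data.frame(patient = patients$patient[has],
                       component = component, event_time = tt[has])
  make_trial(events, patients)
}

table3_composite <- c("Deep surgical site infection",
                      "Bone healing complication",
                      "Superficial surgical site infection")
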