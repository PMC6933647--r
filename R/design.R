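#' Construct a blocked, balanced best-worst scaling design
#'
#' Builds a blocked fractional design for an object-case (Case 1) best-worst
#' scaling experiment: `n_versions` questionnaire versions, each with
#' `tasks_per_version` choice sets of `items_per_task` distinct outcomes.
#' Within each version a randomized greedy swap optimizer equalizes per-item
#' appearance counts (primary criterion) and breaks ties by the D-efficiency
#' of the dummy-coded design matrix; the best of `n_restarts` restarts is
#' returned. The default geometry (4 versions of 10 triples) matches a
#' questionnaire in which each respondent sees 10 sets of 3 outcomes drawn
#' from a 10-outcome catalog.
#'
#' By default the reference level is part of the item pool: respondents can
#' be shown "perfect health" next to adverse outcomes, which is what makes
#' all utilities identifiable on the reference-anchored scale (the
#' best-worst logit is invariant to a common shift of the utilities of the
#' items actually shown). Set `include_reference = FALSE` for a design over
#' adverse outcomes only; utilities estimated from such a design are
#' identified only up to a common additive constant.
#'
#' @param catalog An [outcome_catalog()].
#' @param n_versions Number of questionnaire versions (blocks).
#' @param tasks_per_version Choice sets per version.
#' @param items_per_task Items shown per choice set (>= 2).
#' @param seed Integer seed; the design is a pure function of the inputs and
#'   this seed.
#' @param include_reference Should the reference level be in the item pool?
#' @param n_restarts Random restarts of the greedy optimizer.
#' @return A `bws_design`: list with `tasks` (data.frame `version`, `task`,
#'   `item1..item<m>`), `items` (the pool), `catalog`, `seed`, and
#'   `diagnostics_note` (non-NULL if exact balance was infeasible).
#' @examples
#' d <- generate_design(default_catalog(), n_versions = 4,
#'                      tasks_per_version = 10, items_per_task = 3, seed = 1)
#' head(d$tasks)
#' @export
generate_design <- function(catalog, n_versions = 4L, tasks_per_version = 10L,
                            items_per_task = 3L, seed = 1L,
                            include_reference = TRUE, n_restarts = 50L) {
  stopifnot(inherits(catalog, "outcome_catalog"))
  pool <- if (include_reference) catalog$outcomes else adverse_outcomes(catalog)
  k <- length(pool)
  if (items_per_task < 2L) stop_bad_arg("items_per_task must be at least 2")
  if (items_per_task > k)
    stop_bad_arg("catalog too small: ", k, " eligible outcomes for ",
                 items_per_task, " items per task")
  if (n_versions < 1L || tasks_per_version < 1L)
    stop_bad_arg("n_versions and tasks_per_version must be at least 1")

  note <- NULL
  slots_per_version <- items_per_task * tasks_per_version
  # Exact within-version balance needs counts in {floor, ceil} of slots/k,
  # which is always arithmetically reachable here; record a note if a version
  # cannot host every item at least once when slots < k.
  if (slots_per_version < k)
    note <- sprintf("only %d item slots per version for %d items; some items absent from some versions",
                    slots_per_version, k)

  tasks <- withr::with_seed(as.integer(seed), {
    # versions are optimized sequentially; each sees the appearance counts
    # accumulated so far, so the blocked design is balanced overall as well
    # as within every version
    base_counts <- integer(k)
    out <- vector("list", n_versions)
    for (v in seq_len(n_versions)) {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        cand <- optimize_version(k, tasks_per_version, items_per_task,
                                 base_counts)
        if (is.null(best) || better_design(cand, best)) best <- cand
      }
      base_counts <- base_counts + tabulate(best$mat, nbins = k)
      out[[v]] <- data.frame(version = v, task = seq_len(tasks_per_version),
                             matrix(best$mat, nrow = tasks_per_version,
                                    dimnames = list(NULL,
                                      paste0("item", seq_len(items_per_task)))))
    }
    do.call(rbind, out)
  })
  for (j in seq_len(items_per_task))
    tasks[[paste0("item", j)]] <- pool[tasks[[paste0("item", j)]]]

  structure(list(tasks = tasks, items = pool, catalog = catalog,
                 seed = as.integer(seed), n_restarts = as.integer(n_restarts),
                 diagnostics_note = note),
            class = "bws_design")
}

# One greedy-optimized version block. base_counts carries the appearance
# counts of previously fixed versions so overall balance is optimized too.
# Returns list(mat = T x m index matrix, global_balance, balance, deff).
# Randomness comes from the caller's RNG state.
optimize_version <- function(k, n_tasks, m, base_counts = integer(k)) {
  mat <- t(vapply(seq_len(n_tasks), function(i) sort(sample.int(k, m)),
                  integer(m)))
  score <- version_score(mat, k, base_counts)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    counts <- base_counts + tabulate(mat, nbins = k)
    for (t_i in sample.int(n_tasks)) {
      for (s_i in seq_len(m)) {
        cur <- mat[t_i, s_i]
        for (repl in order(counts)) {        # try globally rare items first
          if (repl == cur || repl %in% mat[t_i, ]) next
          cand <- mat
          cand[t_i, s_i] <- repl
          cand_score <- version_score(cand, k, base_counts)
          if (score_better(cand_score, score)) {
            mat <- cand
            score <- cand_score
            counts <- base_counts + tabulate(mat, nbins = k)
            improved <- TRUE
            break
          }
        }
      }
    }
  }
  c(list(mat = mat), score)
}

version_score <- function(mat, k, base_counts = integer(k)) {
  counts <- tabulate(mat, nbins = k)
  total <- base_counts + counts
  list(global_balance = max(total) - min(total),
       balance = max(counts) - min(counts),
       deff = d_efficiency(mat, k))
}

# Lexicographic: global balance, then within-version balance, then
# D-efficiency as tiebreaker.
score_better <- function(a, b) {
  if (a$global_balance != b$global_balance)
    return(a$global_balance < b$global_balance)
  if (a$balance != b$balance) return(a$balance < b$balance)
  a$deff > b$deff + 1e-12
}
better_design <- score_better

# D-efficiency of the column-centered task-by-item incidence matrix:
# det(X'X)^(1/p) / n with p = k - 1 (one column dropped after centering).
d_efficiency <- function(mat, k) {
  n <- nrow(mat)
  x <- matrix(0, n, k)
  x[cbind(rep(seq_len(n), ncol(mat)), as.vector(mat))] <- 1
  x <- scale(x, center = TRUE, scale = FALSE)[, -k, drop = FALSE]
  xtx <- crossprod(x)
  d <- suppressWarnings(determinant(xtx, logarithm = TRUE))
  if (d$sign <= 0) return(0)
  exp(as.numeric(d$modulus) / ncol(x)) / n
}

#' Diagnose a best-worst design
#'
#' Computes per-item appearance counts, the pairwise co-occurrence matrix,
#' the frequency-balance score (max minus min appearance count) and the
#' relative D-efficiency of the dummy-coded design matrix, normalized
#' against the best design found over `n_restarts` fresh optimizer restarts
#' on the same geometry.
#'
#' @param design A `bws_design` from [generate_design()].
#' @param catalog An [outcome_catalog()]; defaults to the one stored in the
#'   design.
#' @param n_restarts Restarts used to compute the normalization reference.
#' @param seed Seed for the reference restarts.
#' @return A `bws_design_diagnostics` list: `appearance_counts` (named),
#'   `cooccurrence` (symmetric matrix, zero diagonal), `balance_score`,
#'   `d_efficiency`, `relative_d_efficiency` and `note`.
#' @export
diagnose_design <- function(design, catalog = design$catalog,
                            n_restarts = 50L, seed = 1L) {
  stopifnot(inherits(design, "bws_design"))
  items <- design$items
  im <- design_index_matrix(design)
  if (any(is.na(im))) stop_bad_arg("design contains items not in its item pool")
  k <- length(items)
  counts <- tabulate(as.vector(im), nbins = k)
  names(counts) <- items
  co <- matrix(0L, k, k, dimnames = list(items, items))
  m <- ncol(im)
  for (r in seq_len(nrow(im))) {
    pr <- utils::combn(im[r, ], 2L)
    for (j in seq_len(ncol(pr))) {
      co[pr[1, j], pr[2, j]] <- co[pr[1, j], pr[2, j]] + 1L
      co[pr[2, j], pr[1, j]] <- co[pr[2, j], pr[1, j]] + 1L
    }
  }
  deff <- d_efficiency(im, k)
  ref <- withr::with_seed(as.integer(seed), {
    best <- 0
    tv <- nrow(im) / length(unique(design$tasks$version))
    for (r in seq_len(n_restarts)) {
      cand <- optimize_version(k, nrow(im), m)
      if (cand$deff > best) best <- cand$deff
    }
    best
  })
  structure(list(appearance_counts = counts,
                 cooccurrence = co,
                 balance_score = max(counts) - min(counts),
                 d_efficiency = deff,
                 relative_d_efficiency = if (ref > 0) min(1, deff / ref) else 1,
                 note = design$diagnostics_note),
            class = "bws_design_diagnostics")
}

#' @export
print.bws_design_diagnostics <- function(x, ...) {
  cat("BWS design diagnostics\n")
  cat("  balance score (max-min appearances):", x$balance_score, "\n")
  cat("  relative D-efficiency:", format(x$relative_d_efficiency, digits = 4), "\n")
  cat("  appearance counts:\n")
  print(x$appearance_counts)
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
print.bws_design <- function(x, ...) {
  cat("BWS choice design:",
      length(unique(x$tasks$version)), "versions x",
      sum(x$tasks$version == x$tasks$version[1]), "tasks,",
      ncol(x$tasks) - 2L, "items per task,",
      length(x$items), "items in pool\n")
  invisible(x)
}

# Tasks as an integer index matrix into design$items.
design_index_matrix <- function(design) {
  item_cols <- grep("^item", names(design$tasks), value = TRUE)
  matrix(match(as.vector(as.matrix(design$tasks[item_cols])), design$items),
         nrow = nrow(design$tasks))
}

#' Read or write a design as CSV
#'
#' Columns `version,task,item1,...` with item labels.
#'
#' @param design A `bws_design`.
#' @param path File path.
#' @param catalog Catalog used to rebuild the object when reading.
#' @return `write_design()` returns `path` invisibly; `read_design()` a
#'   `bws_design`.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design$tasks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, catalog) {
  tasks <- utils::read.csv(path, stringsAsFactors = FALSE)
  item_cols <- grep("^item", names(tasks), value = TRUE)
  items <- catalog$outcomes[catalog$outcomes %in%
                              unique(unlist(tasks[item_cols], use.names = FALSE))]
  structure(list(tasks = tasks, items = items, catalog = catalog,
                 seed = NA_integer_, diagnostics_note = NULL),
            class = "bws_design")
}
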