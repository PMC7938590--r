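#' Bucket ranks into a summary
#'
#' Collapses per-query ranks into ordered buckets. With the default edges
#' `c(1, 3, 10)` the buckets are `1`, `2-3`, `4-10`, `>10` and `missing`
#' (`NA` ranks — the query compound was absent from the database). Bucket
#' counts always sum to the number of ranks supplied.
#'
#' @param ranks Integer vector of ranks, `NA` for missing.
#' @param edges Increasing integer vector of upper bucket edges.
#' @return A tibble of class `rank_summary` with `bucket` (ordered factor)
#'   and `count`; the total is stored as an attribute.
#' @export
bucket_ranks <- function(ranks, edges = c(1, 3, 10)) {
  edges <- sort(unique(as.integer(edges)))
  if (any(edges < 1L)) abort("Bucket edges must be >= 1.")
  lows <- c(1L, head(edges, -1) + 1L)
  labels <- ifelse(lows == edges, as.character(edges),
                   paste0(lows, "-", edges))
  labels <- c(labels, paste0(">", edges[length(edges)]), "missing")
  bucket_of <- function(r) {
    if (is.na(r)) return("missing")
    i <- which(r <= edges)
    if (length(i)) labels[i[1]] else paste0(">", edges[length(edges)])
  }
  b <- vapply(ranks, bucket_of, character(1))
  counts <- unname(vapply(labels, function(l) sum(b == l), integer(1)))
  out <- tibble(bucket = factor(labels, levels = labels), count = counts)
  structure(out, class = c("rank_summary", class(out)),
            total = length(ranks))
}

#' Run a ranking benchmark
#'
#' For each benchmark entry the database is queried by exact mass within a
#' ppm window, candidates are scored with the supplied terms (external
#' per-candidate scores restricted to the entry's query), and the rank of
#' the true compound (by IKFB) is recorded — `NA` when the compound is not
#' retrieved. Ranks are bucketed into a [bucket_ranks()] summary. Terms
#' referencing absent database columns fail before any query runs.
#'
#' @param db A lite-entry tibble.
#' @param benchmark Tibble with `name`, `ikfb`, `neutral_mass` columns.
#' @param terms Scoring terms as in [score_candidates()].
#' @param external Optional tibble `(query, term, ikfb, value)`; rows are
#'   matched to benchmark entries by `query == name`.
#' @param ppm Mass tolerance (default 5).
#' @param edges Bucket edges passed to [bucket_ranks()].
#' @return An object of class `benchmark_result`: list with `summary` (a
#'   `rank_summary`) and `ranks` (per-entry tibble `name`, `ikfb`,
#'   `n_candidates`, `rank`). [tidy()] returns the per-entry table,
#'   [glance()] one row of bucket fractions.
#' @export
run_benchmark <- function(db, benchmark, terms, external = NULL, ppm = 5,
                          edges = c(1, 3, 10)) {
  db_terms <- terms$source[terms$source != "external"]
  missing_cols <- setdiff(db_terms, names(db))
  if (length(missing_cols)) {
    abort(paste0("Scoring term column(s) absent from the database: ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  n <- nrow(benchmark)
  ranks <- integer(n)
  ncand <- integer(n)
  for (i in seq_len(n)) {
    cands <- candidates_by_mass(db, benchmark$neutral_mass[i], ppm)
    ncand[i] <- nrow(cands)
    if (nrow(cands) == 0L) {
      ranks[i] <- NA_integer_
      next
    }
    ext <- if (!is.null(external)) {
      external[external$query == benchmark$name[i], , drop = FALSE]
    }
    scored <- score_candidates(cands, terms, ext)
    ranks[i] <- rank_of(scored, benchmark$ikfb[i])
  }
  per_entry <- tibble(name = benchmark$name, ikfb = benchmark$ikfb,
                      n_candidates = ncand, rank = ranks)
  structure(list(summary = bucket_ranks(ranks, edges), ranks = per_entry),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  tot <- attr(x$summary, "total")
  cat("<benchmark_result> ", tot, " queries\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s %5d (%.1f%%)\n", as.character(s$bucket[i]),
                s$count[i], if (tot) 100 * s$count[i] / tot else 0))
  }
  invisible(x)
}

#' @rdname run_benchmark
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @export
tidy.benchmark_result <- function(x, ...) x$ranks

#' @rdname run_benchmark
#' @export
glance.benchmark_result <- function(x, ...) {
  s <- x$summary
  tot <- attr(s, "total")
  out <- tibble(total = tot)
  for (i in seq_len(nrow(s))) {
    out[[paste0("frac_", as.character(s$bucket[i]))]] <-
      if (tot) s$count[i] / tot else 0
  }
  out
}

#' Subset a benchmark by annotation category
#'
#' Keeps benchmark entries whose matching database entry (by IKFB) has a
#' positive score in the given top category — the protocol used to restrict
#' an evaluation to, say, compounds with agrochemical annotation. Entries
#' absent from the database are excluded.
#'
#' @inheritParams run_benchmark
#' @param top Short name of a top category present as a score column of
#'   `db`.
#' @return The benchmark subset.
#' @export
subset_benchmark_by_category <- function(benchmark, db, top) {
  if (!top %in% names(db)) {
    abort(paste0("Category '", top, "' is not a score column of the database."))
  }
  score <- db[[top]][match(benchmark$ikfb, db$ikfb)]
  benchmark[!is.na(score) & score > 0, , drop = FALSE]
}

#' Gap report against a compound list
#'
#' Partitions a suspect or benchmark list by presence of its IKFB in the
#' database, quantifying coverage gaps.
#'
#' @param list_tbl Tibble with `name` and `ikfb` (or full `inchikey`).
#' @param db A lite-entry tibble.
#' @return An object of class `gap_report`: list with `present`,
#'   `missing_count` and `missing` (tibble of absent `name`/`ikfb`);
#'   `present + missing_count` equals the list size.
#' @export
gap_report <- function(list_tbl, db) {
  ikfb <- if ("ikfb" %in% names(list_tbl) && !all(is.na(list_tbl$ikfb))) {
    list_tbl$ikfb
  } else if ("inchikey" %in% names(list_tbl)) {
    substr(list_tbl$inchikey, 1, 14)
  } else {
    abort("`list_tbl` needs an `ikfb` or `inchikey` column.")
  }
  present <- ikfb %in% db$ikfb
  structure(list(
    present = sum(present),
    missing_count = sum(!present),
    missing = tibble(name = list_tbl$name[!present], ikfb = ikfb[!present])),
    class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap_report> ", x$present, " present, ", x$missing_count,
      " missing of ", x$present + x$missing_count, "\n", sep = "")
  invisible(x)
}

#' @rdname gap_report
#' @param x A `gap_report`.
#' @param ... Unused.
#' @export
tidy.gap_report <- function(x, ...) x$missing

#' @rdname gap_report
#' @export
glance.gap_report <- function(x, ...) {
  tibble(present = x$present, missing_count = x$missing_count,
         total = x$present + x$missing_count)
}

#' Transformation-product statements
#'
#' Renders predecessor/successor mappings as human-readable annotation
#' statements, one per predecessor, successors grouped in input order:
#' `"<P> has known environmental transformation products that include
#' <list>"`. The list uses a serial comma for three or more items and a
#' bare `and` for two.
#'
#' @param mappings Tibble as returned by [read_transformation_list()].
#' @return Tibble with `predecessor_name` and `statement`.
#' @export
transformation_statements <- function(mappings) {
  if (nrow(mappings) == 0L) {
    return(tibble(predecessor_name = character(0), statement = character(0)))
  }
  preds <- unique(mappings$predecessor_name)
  rows <- lapply(preds, function(p) {
    succ <- mappings$successor_name[mappings$predecessor_name == p]
    listed <- if (length(succ) == 1L) {
      succ
    } else if (length(succ) == 2L) {
      paste(succ, collapse = " and ")
    } else {
      paste0(paste(head(succ, -1), collapse = ", "), ", and ",
             succ[length(succ)])
    }
    tibble(predecessor_name = p,
           statement = paste0(p, " has known environmental transformation",
                              " products that include ", listed))
  })
  bind_rows(rows)
}
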