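#' Candidate retrieval by exact mass
#'
#' Returns database entries whose monoisotopic mass lies within a
#' symmetric ppm window of the query mass:
#' `|m_entry - m_query| / m_query * 1e6 <= ppm`. Results are ordered by
#' ascending absolute mass deviation (stable), with the deviation reported
#' in `ppm_error`.
#'
#' @param db A lite-entry tibble ([build_lite()] entries or
#'   [read_lite_csv()] output).
#' @param mass Neutral monoisotopic query mass in Da (> 0).
#' @param ppm Mass tolerance in parts per million (default 5).
#' @return The matching rows of `db` plus a `ppm_error` column.
#' @export
candidates_by_mass <- function(db, mass, ppm = 5) {
  if (!is.numeric(mass) || length(mass) != 1L || is.na(mass) || mass <= 0) {
    abort("`mass` must be a single positive number.")
  }
  if (!is.numeric(ppm) || ppm < 0) abort("`ppm` must be non-negative.")
  dev <- abs(db$monoisotopic_mass - mass) / mass * 1e6
  hits <- db[dev <= ppm, , drop = FALSE]
  hits$ppm_error <- dev[dev <= ppm]
  hits[order(hits$ppm_error), , drop = FALSE]
}

#' Candidate retrieval by molecular formula
#'
#' Returns entries whose neutralised formula equals the query formula by
#' element-count equality (string order is irrelevant).
#'
#' @inheritParams candidates_by_mass
#' @param formula A neutral formula string or `mol_formula`.
#' @return The matching rows of `db`.
#' @export
candidates_by_formula <- function(db, formula) {
  q <- format_formula(neutralize_formula(as_mol_formula(formula)))
  canon <- vapply(db$formula, function(s)
    format_formula(neutralize_formula(parse_formula(s))), character(1),
    USE.NAMES = FALSE)
  db[canon == q, , drop = FALSE]
}

#' Score and rank a candidate set
#'
#' Weighted, max-normalized multi-term scoring: each term's raw values
#' (taken from a database column or an external per-candidate table keyed
#' by IKFB) are divided by the maximum raw value within the candidate set
#' (0 when the maximum is 0), and the combined score is the weighted sum of
#' the normalized terms. Candidates are returned in descending combined
#' order; tied candidates share the best rank (`tie_mode = "optimistic"`,
#' rank = 1 + number strictly better) or the worst (`"pessimistic"`).
#'
#' @param cands Candidate tibble (rows of a lite database).
#' @param terms Tibble with columns `name`, `weight` (>= 0, not all 0) and
#'   `source` — either a column of `cands` or `"external"`.
#' @param external Optional tibble `(term, ikfb, value)` supplying raw
#'   values for external terms; candidates absent from it score 0.
#' @param tie_mode `"optimistic"` (default) or `"pessimistic"`.
#' @return `cands` plus `raw_<term>`, `norm_<term>`, `combined` and `rank`
#'   columns, sorted by descending `combined`.
#' @export
score_candidates <- function(cands, terms, external = NULL,
                             tie_mode = c("optimistic", "pessimistic")) {
  tie_mode <- match.arg(tie_mode)
  if (!all(c("name", "weight", "source") %in% names(terms))) {
    abort("`terms` needs columns name, weight, source.")
  }
  if (any(terms$weight < 0)) abort("Term weights must be non-negative.")
  if (all(terms$weight == 0)) abort("All term weights are zero: no ranking signal.")

  out <- cands
  combined <- rep(0, nrow(cands))
  for (i in seq_len(nrow(terms))) {
    nm <- terms$name[i]
    src <- terms$source[i]
    raw <- if (identical(src, "external")) {
      if (is.null(external)) {
        rep(0, nrow(cands))
      } else {
        ext <- external[external$term == nm, , drop = FALSE]
        v <- ext$value[match(cands$ikfb, ext$ikfb)]
        dplyr::coalesce(v, 0)
      }
    } else {
      if (!src %in% names(cands)) {
        abort(paste0("Scoring term '", nm, "' references absent column '", src, "'."))
      }
      as.numeric(cands[[src]])
    }
    mx <- if (nrow(cands)) max(raw) else 0
    norm <- if (mx > 0) raw / mx else rep(0, length(raw))
    out[[paste0("raw_", nm)]] <- raw
    out[[paste0("norm_", nm)]] <- norm
    combined <- combined + terms$weight[i] * norm
  }
  out$combined <- combined
  ties <- if (tie_mode == "optimistic") "min" else "max"
  out$rank <- as.integer(rank(-combined, ties.method = ties))
  out[order(-out$combined, out$ikfb), , drop = FALSE]
}

#' Rank of a target candidate
#'
#' @param scored Output of [score_candidates()].
#' @param target_ikfb InChIKey first block of the sought compound.
#' @return The target's rank, or `NA_integer_` when the target is missing
#'   from the candidate set.
#' @export
rank_of <- function(scored, target_ikfb) {
  i <- match(target_ikfb, scored$ikfb)
  if (is.na(i)) NA_integer_ else scored$rank[i]
}
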