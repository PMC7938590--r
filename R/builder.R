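#' Keep only records annotated in the selected categories
#'
#' Rule 1 of the construction pipeline: a record survives iff its
#' fingerprint intersects the selected categories (top-level or subcategory
#' bits).
#'
#' @param records A compound record tibble (see [read_compound_dump()]).
#' @param sel A `category_selection` or built-in selection name.
#' @param idx A `category_index`.
#' @return The filtered record tibble.
#' @export
filter_annotated <- function(records, sel, idx) {
  bits <- selection_bits(sel, idx)
  keep <- vapply(records$fingerprint, function(fp) any(fp %in% bits), logical(1))
  records[keep, , drop = FALSE]
}

#' Map records onto their parent compounds
#'
#' Rule 2: each record with a parent CID is merged into that parent — the
#' child's fingerprint is unioned into the parent's and its literature and
#' patent counts are summed onto it — so the neutral (parent) form carries
#' the family's annotation. Parent chains are resolved transitively; a
#' parent CID with no record of its own is materialised as a stub from its
#' lowest-CID child's structure fields. Cycles in the parent relation are an
#' error.
#'
#' @inheritParams filter_annotated
#' @return A record tibble with one row per (ultimate) parent.
#' @export
map_to_parent <- function(records) {
  if (nrow(records) == 0L) return(records)
  parent <- setNames(records$parent_cid, as.character(records$cid))
  root_of <- function(cid) {
    cur <- cid
    seen <- character(0)
    repeat {
      key <- as.character(cur)
      if (key %in% seen) {
        abort(paste0("Parent cycle detected involving CID ", cid, "."))
      }
      seen <- c(seen, key)
      if (!key %in% names(parent)) return(cur)   # stub parent
      p <- parent[[key]]
      if (is.na(p)) return(cur)
      cur <- p
    }
  }
  roots <- vapply(records$cid, root_of, numeric(1))

  out <- vector("list", length(unique(roots)))
  i <- 0L
  for (r in sort(unique(roots))) {
    members <- records[roots == r, , drop = FALSE]
    own <- members[members$cid == r, , drop = FALSE]
    base <- if (nrow(own)) own[1, ] else {
      stub <- members[order(members$cid), ][1, ]
      stub$cid <- as.integer(r)
      stub$pubmed_count <- 0L
      stub$patent_count <- 0L
      stub$fingerprint <- list(integer(0))
      stub
    }
    base$parent_cid <- NA_integer_
    base$fingerprint <- list(sort(unique(unlist(members$fingerprint))))
    base$pubmed_count <- sum(members$pubmed_count)
    base$patent_count <- sum(members$patent_count)
    i <- i + 1L
    out[[i]] <- base
  }
  bind_rows(out)
}

#' Collapse records by InChIKey first block
#'
#' Rule 3: stereoisomers (and other records sharing a structural skeleton)
#' are merged into one entry per InChIKey first block (IKFB). The retained
#' "best" CID is the most annotated record in the group — fingerprint
#' cardinality restricted to the active selection when one is given — with
#' ties broken towards the lowest CID. Counts are summed and fingerprints
#' unioned over the group; all member CIDs are listed in `related_cids`.
#'
#' @inheritParams filter_annotated
#' @param sel,idx Optional; when supplied, "most annotated" counts only
#'   bits of the selected categories.
#' @return A lite-entry tibble (without score columns yet): `ikfb`, `cid`,
#'   identity fields from the best CID, summed counts, union
#'   `fingerprint`, `related_cids`.
#' @export
collapse_by_ikfb <- function(records, sel = NULL, idx = NULL) {
  if (nrow(records) == 0L) {
    return(tibble(
      ikfb = character(0), cid = integer(0), name = character(0),
      smiles = character(0), inchi = character(0), inchikey = character(0),
      formula = character(0), monoisotopic_mass = numeric(0),
      pubmed_count = integer(0), patent_count = integer(0),
      fingerprint = list(), related_cids = list()))
  }
  records$ikfb <- substr(records$inchikey, 1, 14)
  bits <- if (!is.null(sel) && !is.null(idx)) selection_bits(sel, idx) else NULL
  n_bits <- vapply(records$fingerprint, function(fp) {
    if (is.null(bits)) length(fp) else sum(fp %in% bits)
  }, integer(1))

  groups <- split(seq_len(nrow(records)), records$ikfb)
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    ord <- rows[order(-n_bits[rows], records$cid[rows])]
    best <- records[ord[1], , drop = FALSE]
    out[[g]] <- tibble(
      ikfb = best$ikfb, cid = best$cid, name = best$name,
      smiles = best$smiles, inchi = best$inchi, inchikey = best$inchikey,
      formula = best$formula, monoisotopic_mass = best$monoisotopic_mass,
      pubmed_count = sum(records$pubmed_count[rows]),
      patent_count = sum(records$patent_count[rows]),
      fingerprint = list(sort(unique(unlist(records$fingerprint[rows])))),
      related_cids = list(sort(records$cid[rows])))
  }
  arrange(bind_rows(out), .data$ikfb)
}

#' Element, mixture and charge filters
#'
#' Rules 4-6, applied after collapsing so eliminations are accounted per
#' IKFB: entries whose formula contains a blacklisted element are
#' eliminated (reason `"element"`); multi-component entries — mixtures,
#' salts, disconnected structures — are eliminated (reason
#' `"disconnected"`); charged formulas are kept with the charge token
#' stripped from the formula string (the structure strings are left
#' untouched). Every input entry lands in exactly one partition.
#'
#' @param entries A collapsed lite-entry tibble.
#' @param blacklist Character vector of excluded element symbols.
#' @return List with `kept` (entries, formulas neutralised) and
#'   `eliminated` (entries plus a `reason` column).
#' @export
apply_structure_filters <- function(entries, blacklist = default_element_blacklist()) {
  if (nrow(entries) == 0L) {
    return(list(kept = entries,
                eliminated = mutate(entries, reason = character(0))))
  }
  parsed <- lapply(entries$formula, parse_formula)
  reason <- rep(NA_character_, nrow(entries))
  for (i in seq_len(nrow(entries))) {
    if (contains_excluded_element(parsed[[i]], blacklist)) {
      reason[i] <- "element"
    } else if (is_multicomponent(entries$smiles[i], entries$inchi[i])) {
      reason[i] <- "disconnected"
    }
  }
  kept <- entries[is.na(reason), , drop = FALSE]
  if (nrow(kept)) {
    kept$formula <- vapply(parsed[is.na(reason)], function(f)
      format_formula(neutralize_formula(f)), character(1))
  }
  eliminated <- entries[!is.na(reason), , drop = FALSE]
  eliminated$reason <- reason[!is.na(reason)]
  list(kept = kept, eliminated = eliminated)
}

score_entries <- function(entries, sel, idx) {
  sel <- as_selection(sel)
  for (cc in sel$top_categories) {
    entries[[cc]] <- vapply(entries$fingerprint, category_score,
                            integer(1), top = cc, idx = idx)
  }
  entries$anno_total_count <- vapply(entries$fingerprint, anno_total_count,
                                     integer(1), sel = sel, idx = idx)
  entries
}

#' Build a compact candidate database
#'
#' Runs the full six-rule construction over raw compound records: (1) keep
#' records annotated in the selected categories, (2) map onto parent
#' compounds, (3) collapse by InChIKey first block retaining the best CID,
#' (4) drop entries with blacklisted elements, (5) drop disconnected
#' structures and mixtures, (6) neutralise charged formulas. Per-category
#' score columns and the total annotation count are then populated, and an
#' accounting report is produced satisfying
#' `kept_ikfb + eliminated_ikfb = total_ikfb`.
#'
#' @inheritParams filter_annotated
#' @param blacklist Character vector of excluded element symbols.
#' @return An object of class `lite_build`: list with `entries` (the kept
#'   lite-entry tibble with score columns), `eliminated` (tibble with
#'   `reason`), `report` (accounting list), `selection`, `index`.
#'   [tidy()] returns the entries, [glance()] the report as a one-row
#'   tibble.
#' @examples
#' \dontrun{
#' idx <- default_category_index()
#' fx <- generate_fixture(tempfile("fx"), seed = 1, idx = idx)
#' rec <- read_compound_dump(fx$paths$compounds, fx$paths$counts,
#'                           fx$paths$toc, idx)
#' b <- build_lite(rec, "tier0", idx)
#' glance(b)
#' }
#' @export
build_lite <- function(records, sel, idx, blacklist = default_element_blacklist()) {
  sel <- as_selection(sel)
  annotated <- filter_annotated(records, sel, idx)
  parents <- map_to_parent(annotated)
  collapsed <- collapse_by_ikfb(parents, sel, idx)
  parts <- apply_structure_filters(collapsed, blacklist)
  entries <- score_entries(parts$kept, sel, idx)

  reasons <- as.list(table(parts$eliminated$reason))
  report <- list(
    kept_ikfb = nrow(parts$kept),
    eliminated_ikfb = nrow(parts$eliminated),
    total_ikfb = nrow(collapsed),
    parent_cids = nrow(parents),
    annotated_cids = nrow(annotated),
    eliminated_reasons = lapply(reasons, as.integer))
  structure(list(entries = entries, eliminated = parts$eliminated,
                 report = report, selection = sel, index = idx),
            class = "lite_build")
}

#' @export
print.lite_build <- function(x, ...) {
  r <- x$report
  cat("<lite_build> selection ", x$selection$name, ": ",
      r$kept_ikfb, " kept + ", r$eliminated_ikfb, " eliminated = ",
      r$total_ikfb, " IKFB (", r$annotated_cids, " annotated CIDs, ",
      r$parent_cids, " parents)\n", sep = "")
  invisible(x)
}

#' @rdname build_lite
#' @param x A `lite_build`.
#' @param ... Unused.
#' @export
tidy.lite_build <- function(x, ...) x$entries

#' @rdname build_lite
#' @export
glance.lite_build <- function(x, ...) {
  r <- x$report
  tibble(selection = x$selection$name,
         kept_ikfb = r$kept_ikfb, eliminated_ikfb = r$eliminated_ikfb,
         total_ikfb = r$total_ikfb, parent_cids = r$parent_cids,
         annotated_cids = r$annotated_cids)
}

#' Per-category content summary
#'
#' Tabulates, for every category index row (top categories and their
#' subcategories), how many entries (IKFB) carry the bit and how many
#' related CIDs those entries account for. Annotation is imputed to the
#' whole collapsed group, so a CID annotated in several subcategories is
#' counted once per subcategory — the totals deliberately include this
#' duplication, matching how the content of such databases is usually
#' visualised.
#'
#' @param entries A built lite-entry tibble (or a `lite_build`).
#' @param idx A `category_index`; defaults to the index stored on a
#'   `lite_build`.
#' @return Tibble with `top_name`, `short_name`, `sub_name`, `ikfb_count`,
#'   `cid_count`, one row per index bit with a non-zero count.
#' @export
category_summary <- function(entries, idx = NULL) {
  if (inherits(entries, "lite_build")) {
    if (is.null(idx)) idx <- entries$index
    entries <- entries$entries
  }
  if (is.null(idx)) abort("`idx` is required when `entries` is a tibble.")
  n_related <- vapply(entries$related_cids, length, integer(1))
  rows <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    b <- idx$bit[i]
    has <- vapply(entries$fingerprint, function(fp) b %in% fp, logical(1))
    rows[[i]] <- tibble(
      top_name = idx$top_name[i], short_name = idx$short_name[i],
      sub_name = idx$sub_name[i],
      ikfb_count = sum(has), cid_count = sum(n_related[has]))
  }
  filter(bind_rows(rows), .data$ikfb_count > 0L)
}
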