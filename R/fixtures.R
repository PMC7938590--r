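#' Generate a synthetic compound dump fixture
#'
#' Writes a deterministic, fully synthetic annotation dump (compounds /
#' counts / fingerprint TSVs in the [read_compound_dump()] dialect) with
#' known ground truth. The generator emulates the structural features the
#' construction rules act on: stereoisomer groups sharing an InChIKey first
#' block, sparse multi-category annotation (with occasional
#' subcategory-without-top bits to exercise normalisation), heavy-tailed
#' (discretised log-normal) literature and patent counts, parent-child CID
#' relationships within a group, and controllable fractions of
#' disconnected, blacklisted-element and charged records. Identifiers are
#' valid-pattern synthetic InChIKeys, not hashes of real structures, and
#' SMILES/InChI strings are schematic — faithful only in the properties the
#' filters inspect (component separators, element sets).
#'
#' Formulas are drawn from a small pool so that several IKFB groups share
#' an exact mass, giving multi-member candidate sets in downstream ppm
#' queries.
#'
#' The returned `truth` is computed by [oracle_build()], an independent
#' straight-line implementation of the construction rules that shares no
#' code with the builder pipeline, and is also written as JSON beside the
#' dump files.
#'
#' @param out_dir Directory for the dump files (created if needed).
#' @param n_compounds,n_ikfb_groups Fixture size; every group gets at least
#'   one compound, so `n_ikfb_groups <= n_compounds` is required.
#' @param annotation_density Probability a (compound, top category) pair is
#'   annotated.
#' @param sub_density Probability each subcategory of an annotated top is
#'   also present.
#' @param fraction_disconnected,fraction_blacklisted Per-group
#'   probabilities of mixture structures / blacklisted-element formulas.
#' @param fraction_charged Per-compound probability of a charged formula.
#' @param fraction_with_parent Per-group probability that the group's
#'   non-minimal CIDs point to its lowest CID as parent.
#' @param count_meanlog,count_sdlog Log-normal parameters of the
#'   literature/patent count model.
#' @param n_formula_pool Number of distinct base formulas to draw from.
#' @param seed Integer seed; identical seeds give byte-identical files.
#' @param idx Governing `category_index`.
#' @param sel Selection used for the ground truth (default `"tier0"`).
#' @return List with `paths` (compounds/counts/toc/truth), `records` (the
#'   generated table, raw fingerprints) and `truth` (an [oracle_build()]
#'   result).
#' @export
generate_fixture <- function(out_dir,
                             n_compounds = 60, n_ikfb_groups = 25,
                             annotation_density = 0.35, sub_density = 0.35,
                             fraction_disconnected = 0.10,
                             fraction_blacklisted = 0.08,
                             fraction_charged = 0.10,
                             fraction_with_parent = 0.25,
                             count_meanlog = 2, count_sdlog = 2,
                             n_formula_pool = max(8L, n_ikfb_groups %/% 8L),
                             seed = 1L,
                             idx = default_category_index(),
                             sel = "tier0") {
  if (n_ikfb_groups > n_compounds) {
    abort("`n_ikfb_groups` must not exceed `n_compounds`.")
  }
  probs <- c(annotation_density, sub_density, fraction_disconnected,
             fraction_blacklisted, fraction_charged, fraction_with_parent)
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0, 1].")
  sel <- as_selection(sel)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  records <- withr::with_seed(as.integer(seed), {
    rand_block <- function(n, k) {
      vapply(seq_len(n), function(i)
        paste(sample(LETTERS, k, replace = TRUE), collapse = ""), character(1))
    }
    ikfb <- unique(rand_block(n_ikfb_groups * 3L, 14L))[seq_len(n_ikfb_groups)]

    # group membership: one compound per group, remainder assigned randomly
    group <- c(seq_len(n_ikfb_groups),
               sample(n_ikfb_groups, n_compounds - n_ikfb_groups, replace = TRUE))
    group <- sample(group)

    pool <- lapply(seq_len(n_formula_pool), function(i) {
      c(C = sample(4:20, 1), H = sample(5:30, 1), N = sample(0:3, 1),
        O = sample(0:4, 1), Cl = sample(0:2, 1))
    })
    fmt_counts <- function(cnt) {
      cnt <- cnt[cnt > 0]
      paste0(names(cnt), ifelse(cnt > 1, cnt, ""), collapse = "")
    }
    grp_formula_id <- sample(n_formula_pool, n_ikfb_groups, replace = TRUE)
    grp_blacklisted <- runif(n_ikfb_groups) < fraction_blacklisted
    grp_disconnected <- runif(n_ikfb_groups) < fraction_disconnected
    bl_pool <- c("Ti", "Ag", "Pt", "W", "Sc")
    grp_formula <- vapply(seq_len(n_ikfb_groups), function(g) {
      cnt <- pool[[grp_formula_id[g]]]
      s <- fmt_counts(cnt)
      if (grp_blacklisted[g]) s <- paste0(s, bl_pool[sample(length(bl_pool), 1)])
      s
    }, character(1))
    grp_smiles <- vapply(seq_len(n_ikfb_groups), function(g) {
      base <- paste0("CC", strrep("C", sample(1:6, 1)), "O")
      if (grp_disconnected[g]) paste0(base, ".[Na+]") else base
    }, character(1))
    grp_inchi <- vapply(seq_len(n_ikfb_groups), function(g) {
      f <- grp_formula[g]
      if (grp_disconnected[g]) f <- paste0(f, ".Na")
      paste0("InChI=1S/", f, "/c1-2")
    }, character(1))

    cid <- sort(sample(1:5000000, n_compounds))
    charged <- runif(n_compounds) < fraction_charged
    formula <- grp_formula[group]
    formula[charged] <- paste0(formula[charged], "+")

    suffix <- rand_block(n_compounds, 10L)
    inchikey <- paste0(ikfb[group], "-", suffix, "-N")
    while (anyDuplicated(inchikey)) {
      d <- duplicated(inchikey)
      inchikey[d] <- paste0(ikfb[group[d]], "-", rand_block(sum(d), 10L), "-N")
    }

    parent_cid <- rep(NA_integer_, n_compounds)
    for (g in seq_len(n_ikfb_groups)) {
      members <- which(group == g)
      if (length(members) > 1L && runif(1) < fraction_with_parent) {
        p <- members[which.min(cid[members])]
        parent_cid[setdiff(members, p)] <- cid[p]
      }
    }

    tops <- unique(idx$short_name)
    fingerprint <- lapply(seq_len(n_compounds), function(i) {
      bits <- integer(0)
      for (s in tops) {
        if (runif(1) < annotation_density) {
          tb <- idx$bit[idx$short_name == s & idx$sub_name == ""]
          sb <- idx$bit[idx$short_name == s & idx$sub_name != ""]
          present_subs <- sb[runif(length(sb)) < sub_density]
          # occasionally drop the top bit to exercise roll-up normalisation
          if (length(present_subs) && runif(1) < 0.1) {
            bits <- c(bits, present_subs)
          } else {
            bits <- c(bits, tb, present_subs)
          }
        }
      }
      sort(unique(bits))
    })

    has_counts <- runif(n_compounds) > 0.15
    pubmed <- ifelse(has_counts,
                     as.integer(floor(rlnorm(n_compounds, count_meanlog, count_sdlog))), 0L)
    patent <- ifelse(has_counts,
                     as.integer(floor(rlnorm(n_compounds, count_meanlog + 1, count_sdlog))), 0L)
    mass_blank <- runif(n_compounds) < 0.1

    tibble(
      cid = cid, parent_cid = parent_cid,
      name = paste0("Compound_", cid),
      smiles = grp_smiles[group], inchi = grp_inchi[group],
      inchikey = inchikey, formula = formula,
      monoisotopic_mass = formula_mass(formula),
      pubmed_count = pubmed, patent_count = patent,
      fingerprint = fingerprint,
      .has_counts = has_counts, .mass_blank = mass_blank)
  })

  paths <- list(compounds = file.path(out_dir, "compounds.tsv"),
                counts = file.path(out_dir, "counts.tsv"),
                toc = file.path(out_dir, "toc.tsv"),
                truth = file.path(out_dir, "truth.json"))
  comp <- tibble(
    CID = records$cid,
    ParentCID = records$parent_cid,
    Name = records$name, SMILES = records$smiles, InChI = records$inchi,
    InChIKey = records$inchikey, Formula = records$formula,
    MonoisotopicMass = ifelse(records$.mass_blank, NA_real_,
                              records$monoisotopic_mass))
  readr::write_tsv(comp, paths$compounds, na = "")
  readr::write_tsv(
    tibble(CID = records$cid, PubMedCount = records$pubmed_count,
           PatentCount = records$patent_count)[records$.has_counts, ],
    paths$counts, na = "")
  readr::write_tsv(
    tibble(CID = records$cid,
           FingerprintHex = vapply(records$fingerprint, fp_to_hex, character(1))),
    paths$toc, na = "")

  records <- select(records, -".has_counts", -".mass_blank")
  truth <- oracle_build(records, sel, idx)
  jsonlite::write_json(
    list(kept_ikfb = truth$entries$ikfb,
         eliminated = truth$eliminated, report = truth$report),
    paths$truth, auto_unbox = TRUE, digits = NA)
  list(paths = paths, records = records, truth = truth)
}

#' Reference implementation of the construction rules
#'
#' A deliberately plain, loop-based implementation of the six construction
#' rules, written independently of the builder pipeline and sharing no code
#' with it. It exists to provide ground truth for generated fixtures and an
#' equivalence oracle in the test suite; it is not optimised and should not
#' be used on large inputs.
#'
#' @inheritParams build_lite
#' @return List with `entries` (tibble: `ikfb`, `cid`, `related_cids`,
#'   `pubmed_count`, `patent_count`, per-category scores,
#'   `anno_total_count`, `formula`), `eliminated` (tibble: `ikfb`,
#'   `reason`) and `report` (accounting list).
#' @export
oracle_build <- function(records, sel, idx, blacklist = default_element_blacklist()) {
  sel <- as_selection(sel)

  # selected bits, top bits and subcategory bits, by plain scans
  sel_bits <- c()
  top_of <- list()
  subs_of <- list()
  for (s in sel$top_categories) {
    rows <- which(idx$short_name == s)
    sel_bits <- c(sel_bits, idx$bit[rows])
    top_of[[s]] <- idx$bit[rows[idx$sub_name[rows] == ""]]
    subs_of[[s]] <- idx$bit[rows[idx$sub_name[rows] != ""]]
  }

  # roll-up: a subcategory bit implies its top bit
  normalize <- function(bits) {
    extra <- c()
    for (b in bits) {
      s <- idx$short_name[idx$bit == b]
      extra <- c(extra, idx$bit[idx$short_name == s & idx$sub_name == ""])
    }
    sort(unique(c(bits, extra)))
  }
  fps <- lapply(records$fingerprint, normalize)

  # rule 1: annotated in the selection
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) keep[i] <- length(intersect(fps[[i]], sel_bits)) > 0
  rec <- records[keep, , drop = FALSE]
  fps <- fps[keep]
  n_annotated <- nrow(rec)

  # rule 2: resolve to ultimate parents, merging annotation and counts
  root <- numeric(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    cur <- rec$cid[i]
    hops <- 0
    repeat {
      j <- which(rec$cid == cur)
      nxt <- if (length(j)) rec$parent_cid[j[1]] else NA
      if (is.na(nxt)) break
      cur <- nxt
      hops <- hops + 1
      if (hops > nrow(rec)) abort("Parent cycle detected.")
    }
    root[i] <- cur
  }
  proots <- sort(unique(root))
  pr <- list()
  for (r in proots) {
    members <- which(root == r)
    j <- which(rec$cid == r)
    base_i <- if (length(j)) j[1] else members[which.min(rec$cid[members])]
    fp <- sort(unique(unlist(fps[members])))
    pr[[length(pr) + 1]] <- list(
      cid = r, inchikey = rec$inchikey[base_i], smiles = rec$smiles[base_i],
      inchi = rec$inchi[base_i], formula = rec$formula[base_i],
      pubmed = sum(rec$pubmed_count[members]),
      patent = sum(rec$patent_count[members]),
      fp = fp)
  }
  n_parents <- length(pr)

  # rule 3: collapse by IKFB, best = most selected-category bits, tie lowest CID
  blocks <- unique(vapply(pr, function(p) substr(p$inchikey, 1, 14), character(1)))
  blocks <- sort(blocks)
  entries <- list()
  eliminated <- list()
  for (b in blocks) {
    members <- Filter(function(p) substr(p$inchikey, 1, 14) == b, pr)
    nbits <- vapply(members, function(p) length(intersect(p$fp, sel_bits)), integer(1))
    cids <- vapply(members, function(p) p$cid, numeric(1))
    best <- members[[order(-nbits, cids)[1]]]
    fp <- sort(unique(unlist(lapply(members, function(p) p$fp))))
    e <- list(ikfb = b, cid = best$cid, related = sort(cids),
              pubmed = sum(vapply(members, function(p) p$pubmed, numeric(1))),
              patent = sum(vapply(members, function(p) p$patent, numeric(1))),
              smiles = best$smiles, inchi = best$inchi,
              formula = best$formula, fp = fp)

    # rules 4-6 on the collapsed entry
    elems <- unique(stringr::str_extract_all(
      sub("[+-][0-9]*$", "", e$formula), "[A-Z][a-z]?")[[1]])
    smi_nobracket <- gsub("\\[[^]]*\\]", "", e$smiles)
    inchi_layer <- strsplit(e$inchi, "/", fixed = TRUE)[[1]]
    if (any(elems %in% blacklist)) {
      eliminated[[length(eliminated) + 1]] <- tibble(ikfb = b, reason = "element")
    } else if (grepl(".", smi_nobracket, fixed = TRUE) ||
               (length(inchi_layer) >= 2 && grepl(".", inchi_layer[2], fixed = TRUE))) {
      eliminated[[length(eliminated) + 1]] <- tibble(ikfb = b, reason = "disconnected")
    } else {
      e$formula <- sub("[+-][0-9]*$", "", e$formula)
      entries[[length(entries) + 1]] <- e
    }
  }

  rows <- lapply(entries, function(e) {
    out <- tibble(ikfb = e$ikfb, cid = e$cid, related_cids = list(e$related),
                  pubmed_count = e$pubmed, patent_count = e$patent,
                  formula = e$formula)
    total <- 0L
    for (s in sel$top_categories) {
      score <- if (top_of[[s]] %in% e$fp) 1L + sum(subs_of[[s]] %in% e$fp) else 0L
      out[[s]] <- score
      if (top_of[[s]] %in% e$fp) total <- total + 1L
    }
    out$anno_total_count <- total
    out
  })
  entries_tbl <- if (length(rows)) bind_rows(rows) else
    tibble(ikfb = character(0), cid = numeric(0), related_cids = list(),
           pubmed_count = numeric(0), patent_count = numeric(0),
           formula = character(0), anno_total_count = integer(0))
  elim_tbl <- if (length(eliminated)) bind_rows(eliminated) else
    tibble(ikfb = character(0), reason = character(0))

  list(entries = entries_tbl, eliminated = elim_tbl,
       report = list(kept_ikfb = nrow(entries_tbl),
                     eliminated_ikfb = nrow(elim_tbl),
                     total_ikfb = length(blocks),
                     parent_cids = n_parents,
                     annotated_cids = n_annotated))
}

#' Generate a synthetic ranking benchmark
#'
#' Draws queries from database entries and fabricates an external
#' per-candidate scoring term (e.g. a spectral-similarity stand-in) with a
#' controllable information content: with probability `informativeness` a
#' query's correct candidate receives the strict maximum score (1.0, all
#' competitors below 0.9); otherwise all candidates in the retrieval window
#' — including the correct one — receive iid uniform scores, so the score
#' carries no information about correctness. The expected rank-1 fraction
#' under scoring by this term alone is therefore `informativeness` plus a
#' small chance-win excess from the uninformative draws.
#'
#' @param db A lite-entry tibble (non-empty).
#' @param n_queries Number of queries; must not exceed `nrow(db)`
#'   (sampling is without replacement).
#' @param informativeness Probability in `[0, 1]` that a query's external
#'   score identifies the correct candidate.
#' @param seed Integer seed.
#' @param ppm Retrieval window used when fabricating competitor scores.
#' @param term_name Name of the external scoring term.
#' @return List with `benchmark` (tibble `name`, `ikfb`, `neutral_mass`),
#'   `external` (tibble `query`, `term`, `ikfb`, `value`) and `terms` (a
#'   one-row terms tibble scoring by the external term alone).
#' @export
generate_benchmark <- function(db, n_queries, informativeness, seed = 1L,
                               ppm = 5, term_name = "SpecSim") {
  if (nrow(db) == 0L) abort("`db` must be non-empty.")
  if (n_queries > nrow(db)) {
    abort("`n_queries` must not exceed the number of database entries.")
  }
  if (informativeness < 0 || informativeness > 1) {
    abort("`informativeness` must lie in [0, 1].")
  }
  withr::with_seed(as.integer(seed), {
    picks <- sort(sample(nrow(db), n_queries))
    bench <- vector("list", n_queries)
    ext <- vector("list", n_queries)
    for (i in seq_len(n_queries)) {
      row <- db[picks[i], ]
      qname <- paste0("Q", i, "_", row$ikfb)
      cands <- candidates_by_mass(db, row$monoisotopic_mass, ppm)
      informative <- runif(1) < informativeness
      value <- if (informative) {
        ifelse(cands$ikfb == row$ikfb, 1.0, runif(nrow(cands), 0, 0.9))
      } else {
        runif(nrow(cands))
      }
      bench[[i]] <- tibble(name = qname, ikfb = row$ikfb,
                           neutral_mass = row$monoisotopic_mass)
      ext[[i]] <- tibble(query = qname, term = term_name,
                         ikfb = cands$ikfb, value = value)
    }
    list(benchmark = bind_rows(bench), external = bind_rows(ext),
         terms = tibble(name = term_name, weight = 1, source = "external"))
  })
}
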