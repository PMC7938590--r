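#' Read a compound annotation dump
#'
#' Reads the three-file dump dialect into one tidy compound table. The dump
#' consists of `compounds.tsv` (CID, ParentCID, Name, SMILES, InChI,
#' InChIKey, Formula, MonoisotopicMass), `counts.tsv` (CID, PubMedCount,
#' PatentCount) and `toc.tsv` (CID, FingerprintHex), all keyed by CID.
#' Missing count rows default to 0, a missing fingerprint row to the empty
#' fingerprint, and a blank mass column is computed from the formula.
#' Count/fingerprint rows whose CID has no compound row are orphans: they
#' are dropped with a warning reporting how many were seen. Fingerprints are
#' normalised so any subcategory bit implies its top-category bit.
#'
#' @param compounds,counts,toc Paths to the three TSV files.
#' @param idx A `category_index` governing the fingerprints.
#' @return A tibble with one row per compound: `cid`, `parent_cid`, `name`,
#'   `smiles`, `inchi`, `inchikey`, `formula`, `monoisotopic_mass`,
#'   `pubmed_count`, `patent_count` and a `fingerprint` list-column of
#'   integer bit positions.
#' @export
read_compound_dump <- function(compounds, counts, toc, idx) {
  comp <- readr::read_tsv(compounds, col_types = readr::cols(
    CID = readr::col_character(), ParentCID = readr::col_character(),
    Name = readr::col_character(), SMILES = readr::col_character(),
    InChI = readr::col_character(), InChIKey = readr::col_character(),
    Formula = readr::col_character(), MonoisotopicMass = readr::col_double()))
  cnt <- readr::read_tsv(counts, col_types = readr::cols(
    CID = readr::col_character(), PubMedCount = readr::col_integer(),
    PatentCount = readr::col_integer()))
  fps <- readr::read_tsv(toc, col_types = readr::cols(
    CID = readr::col_character(), FingerprintHex = readr::col_character()))

  parse_cid <- function(x, file, required = TRUE) {
    out <- suppressWarnings(as.integer(x))
    bad <- which(if (required) is.na(out) | out <= 0L
                 else (!is.na(x) & nzchar(x)) & (is.na(out) | out <= 0L))
    if (length(bad)) {
      abort(paste0("Malformed CID '", x[bad[1]], "' in ", file,
                   " line ", bad[1] + 1L, "."))
    }
    out
  }
  cid <- parse_cid(comp$CID, compounds)
  parent_cid <- parse_cid(comp$ParentCID, compounds, required = FALSE)

  bad_key <- which(is.na(comp$InChIKey) |
                     !grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", comp$InChIKey))
  if (length(bad_key)) {
    abort(paste0("Bad InChIKey '", comp$InChIKey[bad_key[1]], "' in ",
                 compounds, " line ", bad_key[1] + 1L, "."))
  }

  mass <- comp$MonoisotopicMass
  blank <- which(is.na(mass))
  if (length(blank)) mass[blank] <- formula_mass(comp$Formula[blank])

  records <- tibble(
    cid = cid, parent_cid = parent_cid,
    name = comp$Name, smiles = dplyr::coalesce(comp$SMILES, ""),
    inchi = dplyr::coalesce(comp$InChI, ""), inchikey = comp$InChIKey,
    formula = comp$Formula, monoisotopic_mass = mass)

  n_orphans <- sum(!cnt$CID %in% comp$CID) + sum(!fps$CID %in% comp$CID)
  if (n_orphans > 0) {
    warn(paste0("Dropped ", n_orphans,
                " orphan count/fingerprint row(s) with no compound row."))
  }

  cnt$cid <- parse_cid(cnt$CID, counts)
  records <- left_join(records,
                       select(cnt, "cid", pubmed_count = "PubMedCount",
                              patent_count = "PatentCount"),
                       by = "cid") %>%
    mutate(pubmed_count = dplyr::coalesce(.data$pubmed_count, 0L),
           patent_count = dplyr::coalesce(.data$patent_count, 0L))

  fps$cid <- parse_cid(fps$CID, toc)
  fp_list <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) fp_list[[i]] <- integer(0)
  hit <- match(fps$cid, records$cid)
  for (j in seq_len(nrow(fps))) {
    if (is.na(hit[j])) next
    fp <- tryCatch(hex_to_fp(fps$FingerprintHex[j], idx), error = function(e) {
      abort(paste0(conditionMessage(e), " (", toc, " line ", j + 1L, ")"))
    })
    fp_list[[hit[j]]] <- normalize_fingerprint(fp, idx)
  }
  records$fingerprint <- fp_list
  records
}

lite_fixed_cols <- c("Identifier", "CompoundName", "MolecularFormula",
                     "MonoisotopicMass", "SMILES", "InChI", "InChIKey",
                     "InChIKeyFirstBlock", "PubMed_Count", "Patent_Count",
                     "AnnoTypeCount")

#' Write / read the compact candidate database CSV
#'
#' The on-disk form consumed by downstream identification tools: fixed
#' columns `Identifier` (best CID), `CompoundName`, `MolecularFormula`,
#' `MonoisotopicMass`, `SMILES`, `InChI`, `InChIKey`, `InChIKeyFirstBlock`,
#' `PubMed_Count`, `Patent_Count`, `AnnoTypeCount`, then one score column
#' per selected top category (short name), then `RelatedCIDs`
#' (ascending, semicolon-joined). UTF-8, RFC 4180 quoting.
#'
#' @param entries A lite-entry tibble as produced by [build_lite()].
#' @param sel The `category_selection` the entries were built under.
#' @param path Output CSV path.
#' @return `write_lite_csv()` returns the number of data rows written;
#'   `read_lite_csv()` returns the entries tibble (without fingerprints,
#'   which are not serialised).
#' @export
write_lite_csv <- function(entries, sel, path) {
  sel <- as_selection(sel)
  cats <- sel$top_categories
  out <- tibble(
    Identifier = entries$cid,
    CompoundName = entries$name,
    MolecularFormula = entries$formula,
    MonoisotopicMass = entries$monoisotopic_mass,
    SMILES = entries$smiles,
    InChI = entries$inchi,
    InChIKey = entries$inchikey,
    InChIKeyFirstBlock = entries$ikfb,
    PubMed_Count = entries$pubmed_count,
    Patent_Count = entries$patent_count,
    AnnoTypeCount = entries$anno_total_count)
  for (cc in cats) out[[cc]] <- entries[[cc]]
  out$RelatedCIDs <- vapply(entries$related_cids, function(v)
    paste(sort(v), collapse = ";"), character(1))
  readr::write_csv(out, path)
  nrow(out)
}

#' @rdname write_lite_csv
#' @export
read_lite_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    Identifier = readr::col_integer(),
    MonoisotopicMass = readr::col_double(),
    PubMed_Count = readr::col_integer(),
    Patent_Count = readr::col_integer(),
    AnnoTypeCount = readr::col_integer(),
    RelatedCIDs = readr::col_character(),
    .default = readr::col_guess()))
  missing <- setdiff(lite_fixed_cols, names(raw))
  if (length(missing)) {
    abort(paste0("Lite CSV is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  cats <- setdiff(names(raw), c(lite_fixed_cols, "RelatedCIDs"))
  out <- tibble(
    ikfb = raw$InChIKeyFirstBlock,
    cid = raw$Identifier,
    name = raw$CompoundName,
    smiles = as.character(raw$SMILES),
    inchi = as.character(raw$InChI),
    inchikey = raw$InChIKey,
    formula = raw$MolecularFormula,
    monoisotopic_mass = raw$MonoisotopicMass,
    pubmed_count = raw$PubMed_Count,
    patent_count = raw$Patent_Count,
    anno_total_count = raw$AnnoTypeCount)
  for (cc in cats) out[[cc]] <- as.integer(raw[[cc]])
  out$related_cids <- lapply(strsplit(
    dplyr::coalesce(raw$RelatedCIDs, ""), ";", fixed = TRUE),
    function(v) as.integer(v[nzchar(v)]))
  out
}

#' Read a suspect list
#'
#' Suspect lists are CSVs with a name column and at least one identifier
#' column among InChIKey (full or first block), formula and neutral
#' monoisotopic mass. Column headers are matched case-insensitively
#' (`name`; `inchikey`; `formula`; `neutral_mass`/`mass`/
#' `monoisotopicmass`). InChIKeys are trimmed and upper-cased; duplicates
#' are preserved (de-duplication is the caller's choice).
#'
#' @param path CSV path.
#' @return Tibble with `name`, `inchikey`, `ikfb`, `formula`,
#'   `neutral_mass`.
#' @export
read_suspect_list <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  lc <- tolower(names(raw))
  pick <- function(opts) {
    i <- which(lc %in% opts)
    if (length(i)) raw[[i[1]]] else rep(NA_character_, nrow(raw))
  }
  if (!"name" %in% lc) abort("Suspect list needs a 'Name' column.")
  name <- pick("name")
  id_cols <- c("inchikey", "formula", "molecularformula", "neutral_mass",
               "mass", "monoisotopicmass")
  if (!any(id_cols %in% lc)) {
    abort("Suspect list needs at least one identifier column (InChIKey, Formula or Neutral_Mass).")
  }
  key <- toupper(trimws(pick("inchikey")))
  formula <- pick(c("formula", "molecularformula"))
  mass <- suppressWarnings(as.numeric(pick(c("neutral_mass", "mass", "monoisotopicmass"))))
  bad <- which(is.na(key) & is.na(formula) & is.na(mass))
  if (length(bad)) {
    abort(paste0("Suspect list row ", bad[1] + 1L,
                 " has neither InChIKey, formula nor mass."))
  }
  tibble(name = name, inchikey = key,
         ikfb = ifelse(is.na(key), NA_character_, substr(key, 1, 14)),
         formula = formula, neutral_mass = mass)
}

#' Read a transformation (predecessor/successor) list
#'
#' Parent-to-transformation-product mappings, one row per edge, with
#' provenance carried through. A row mapping a compound to itself is an
#' error.
#'
#' @param path CSV path with columns `predecessor_cid`, `predecessor_name`,
#'   `successor_cid`, `successor_name`, `source` (case-insensitive).
#' @return Tibble of mappings.
#' @export
read_transformation_list <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  lc <- tolower(names(raw))
  need <- c("predecessor_cid", "predecessor_name", "successor_cid",
            "successor_name", "source")
  miss <- setdiff(need, lc)
  if (length(miss)) {
    abort(paste0("Transformation list is missing column(s): ",
                 paste(miss, collapse = ", "), "."))
  }
  out <- tibble(
    predecessor_cid = as.integer(raw[[which(lc == "predecessor_cid")[1]]]),
    predecessor_name = raw[[which(lc == "predecessor_name")[1]]],
    successor_cid = as.integer(raw[[which(lc == "successor_cid")[1]]]),
    successor_name = raw[[which(lc == "successor_name")[1]]],
    source = raw[[which(lc == "source")[1]]])
  self <- which(out$predecessor_cid == out$successor_cid)
  if (length(self)) {
    abort(paste0("Transformation list row ", self[1] + 1L,
                 " maps CID ", out$predecessor_cid[self[1]], " to itself."))
  }
  out
}
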