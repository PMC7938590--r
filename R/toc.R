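#' Annotation category index
#'
#' The category index describes the annotation classification tree governing
#' compound fingerprints: one row per fingerprint bit, either a top-level
#' category or one of its subcategories (one nesting level; deeper trees are
#' flattened to their top-level subcategory). Bits must be unique and
#' contiguous from 0, and every subcategory row must share its `top_name`
#' with a top-level row. Short names (e.g. `AgroChemInfo`) are fixed aliases
#' used as column names in the compact database.
#'
#' `default_category_index()` loads the reference index shipped with the
#' package: a synthetic, frozen stand-in for a live classification browser
#' tree, holding the ten exposomics-relevant top categories with plausible
#' subcategory sets. Real trees change over time, so the index is always an
#' input, never hard-coded logic.
#'
#' @param path Path to a TSV with columns `bit`, `top_name`, `short_name`,
#'   `sub_name` (`sub_name` empty on top-level rows).
#' @param version Optional version label stored on the index.
#' @return A tibble of class `category_index`.
#' @examples
#' idx <- default_category_index()
#' dplyr::count(idx, short_name)
#' @export
read_category_index <- function(path, version = basename(path)) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    bit = readr::col_integer(),
    top_name = readr::col_character(),
    short_name = readr::col_character(),
    sub_name = readr::col_character()))
  if (nrow(raw) == 0L) abort("Category index file is empty.")
  raw$sub_name[is.na(raw$sub_name)] <- ""

  bad <- which(is.na(raw$bit) | is.na(raw$top_name) | !nzchar(raw$top_name) |
                 is.na(raw$short_name) | !nzchar(raw$short_name))
  if (length(bad)) {
    abort(paste0("Malformed category index row at line ", bad[1] + 1L, "."))
  }
  dup <- raw$bit[duplicated(raw$bit)]
  if (length(dup)) {
    abort(paste0("Duplicated bit position(s): ", paste(unique(dup), collapse = ", "), "."))
  }
  if (!setequal(raw$bit, seq_len(nrow(raw)) - 1L)) {
    abort("Bit positions must be contiguous from 0.")
  }
  tops <- raw$top_name[raw$sub_name == ""]
  orphan <- which(raw$sub_name != "" & !(raw$top_name %in% tops))
  if (length(orphan)) {
    abort(paste0("Orphan subcategory at line ", orphan[1] + 1L,
                 ": no top-level row for '", raw$top_name[orphan[1]], "'."))
  }
  idx <- arrange(as_tibble(raw), .data$bit)
  structure(idx, class = c("category_index", class(idx)),
            version = version)
}

#' @rdname read_category_index
#' @export
default_category_index <- function() {
  read_category_index(
    system.file("extdata", "category_index.tsv", package = "annolite"),
    version = "annolite-reference-1")
}

index_width <- function(idx) nrow(idx)

# top-level bit for each short name
top_bit <- function(idx, short) {
  row <- which(idx$short_name == short & idx$sub_name == "")
  if (!length(row)) abort(paste0("Unknown top category: '", short, "'."))
  idx$bit[row]
}

sub_bits <- function(idx, short) {
  idx$bit[idx$short_name == short & idx$sub_name != ""]
}

#' Built-in category selections
#'
#' The named selections of top-level annotation categories used to build the
#' compact database tiers: `tier0` is the seven environmental categories
#' (AgroChemInfo, DrugMedicInfo, FoodRelated, PharmacoInfo, SafetyInfo,
#' ToxicityInfo, KnownUse); `tier1` adds BioPathway; `exposomics` adds
#' Identification and DisorderDisease on top of tier1. Selections are
#' nested: tier0 < tier1 < exposomics.
#'
#' @param name One of `"tier0"`, `"tier1"`, `"exposomics"`.
#' @return A `category_selection`: list with `name` and `top_categories`
#'   (ordered character vector of short names).
#' @examples
#' builtin_selection("tier0")$top_categories
#' @export
builtin_selection <- function(name) {
  tier0 <- c("AgroChemInfo", "DrugMedicInfo", "FoodRelated", "PharmacoInfo",
             "SafetyInfo", "ToxicityInfo", "KnownUse")
  sels <- list(
    tier0 = tier0,
    tier1 = c(tier0, "BioPathway"),
    exposomics = c(tier0, "BioPathway", "Identification", "DisorderDisease"))
  if (!is.character(name) || length(name) != 1L || !name %in% names(sels)) {
    abort(paste0("Unknown selection '", paste(name, collapse = ","),
                 "'. Valid names: ", paste(names(sels), collapse = ", "), "."))
  }
  structure(list(name = name, top_categories = sels[[name]]),
            class = "category_selection")
}

#' @export
print.category_selection <- function(x, ...) {
  cat("<category_selection> ", x$name, ": ",
      paste(x$top_categories, collapse = ", "), "\n", sep = "")
  invisible(x)
}

as_selection <- function(sel) {
  if (inherits(sel, "category_selection")) return(sel)
  if (is.character(sel) && length(sel) == 1L) return(builtin_selection(sel))
  abort("Expected a category_selection or a built-in selection name.")
}

# all bits (top + sub) belonging to the selected top categories
selection_bits <- function(sel, idx) {
  sel <- as_selection(sel)
  missing <- setdiff(sel$top_categories, idx$short_name)
  if (length(missing)) {
    abort(paste0("Selection references unknown categories: ",
                 paste(missing, collapse = ", "), "."))
  }
  sort(idx$bit[idx$short_name %in% sel$top_categories])
}

#' Category score of a fingerprint
#'
#' Per-category annotation score: 0 when the top-level bit is absent,
#' otherwise 1 (the category itself) plus the number of distinct subcategory
#' bits of that category present in the fingerprint. Used to populate the
#' per-category columns of the compact database so annotation richness can
#' act as a ranking term.
#'
#' @param fp Integer vector of fingerprint bit positions.
#' @param top Short name of a top-level category.
#' @param idx A `category_index`.
#' @return Non-negative integer.
#' @export
category_score <- function(fp, top, idx) {
  tb <- top_bit(idx, top)
  if (!(tb %in% fp)) return(0L)
  1L + length(intersect(sub_bits(idx, top), fp))
}

#' Total annotation count of a fingerprint
#'
#' Number of selected top-level categories whose top bit is present; the
#' `AnnoTypeCount` column of the compact database. Bounded by the selection
#' size (7 for tier0, 8 for tier1, 10 for exposomics).
#'
#' @inheritParams category_score
#' @param sel A `category_selection` or built-in selection name.
#' @return Non-negative integer, at most `length(sel$top_categories)`.
#' @export
anno_total_count <- function(fp, sel, idx) {
  sel <- as_selection(sel)
  tops <- vapply(sel$top_categories, function(s) top_bit(idx, s), integer(1))
  sum(tops %in% fp)
}

# subcategory bits imply their top-category bit
normalize_fingerprint <- function(fp, idx) {
  if (!length(fp)) return(integer(0))
  shorts <- unique(idx$short_name[match(fp, idx$bit)])
  tops <- vapply(shorts, function(s) top_bit(idx, s), integer(1))
  sort(unique(c(as.integer(fp), tops)))
}

#' Fingerprint hex serialisation
#'
#' Fingerprints travel in dump files as hexadecimal strings; bit 0 is the
#' least-significant bit of the value the string encodes. `hex_to_fp()`
#' validates against the governing index: strings wider than the index, or
#' set bits at positions outside it, are errors.
#'
#' @param fp Integer vector of set bit positions.
#' @param hex A hexadecimal string.
#' @param idx Optional `category_index` governing the width.
#' @return `fp_to_hex()` a string; `hex_to_fp()` a sorted integer vector.
#' @examples
#' fp_to_hex(c(0, 4))      # "11"
#' hex_to_fp("11")         # 0 4
#' @export
fp_to_hex <- function(fp) {
  fp <- as.integer(fp)
  if (!length(fp)) return("0")
  if (any(fp < 0L)) abort("Fingerprint bits must be non-negative.")
  n_nib <- max(fp) %/% 4L + 1L
  nib <- integer(n_nib)
  for (b in unique(fp)) {
    i <- b %/% 4L + 1L
    nib[i] <- bitwOr(nib[i], bitwShiftL(1L, b %% 4L))
  }
  paste(sprintf("%X", rev(nib)), collapse = "")
}

#' @rdname fp_to_hex
#' @export
hex_to_fp <- function(hex, idx = NULL) {
  hex <- toupper(trimws(hex))
  if (!nzchar(hex) || grepl("[^0-9A-F]", hex)) {
    abort(paste0("Invalid fingerprint hex string: '", hex, "'."))
  }
  if (!is.null(idx) && nchar(hex) > ceiling(index_width(idx) / 4)) {
    abort(paste0("Fingerprint hex '", hex, "' is wider than the ",
                 index_width(idx), "-bit category index."))
  }
  digits <- rev(strsplit(hex, "")[[1]])
  bits <- integer(0)
  for (i in seq_along(digits)) {
    v <- strtoi(digits[i], 16L)
    for (j in 0:3) {
      if (bitwAnd(v, bitwShiftL(1L, j)) != 0L) bits <- c(bits, (i - 1L) * 4L + j)
    }
  }
  if (!is.null(idx) && length(bits) && max(bits) >= index_width(idx)) {
    abort(paste0("Fingerprint bit ", max(bits), " is outside the ",
                 index_width(idx), "-bit category index."))
  }
  sort(bits)
}
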