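#' Molecular formulas
#'
#' A `mol_formula` is a parsed molecular formula: a named integer vector of
#' element counts plus a formal charge in elementary units. Formula strings
#' follow Hill convention with an optional trailing charge token written
#' sign-first (`+`, `-`, `+2`, `-3`, ...), the form large compound
#' databases print (`C2H3O2-`, `O4P-3`): a magnitude digit before the sign
#' would be ambiguous with a trailing element count (`C9H13N2+` is
#' N\eqn{_2}, charge +1). Embedded charges are rejected. Element symbols
#' are validated against the shipped periodic table.
#'
#' @param text A single formula string, e.g. `"C10H14N2"` or `"C6H5O-"`.
#' @return `parse_formula()` returns a `mol_formula` object: a list with
#'   `counts` (named integer vector) and `charge` (integer).
#' @examples
#' f <- parse_formula("C10H14N2")
#' monoisotopic_mass(f)
#' format_formula(neutralize_formula(parse_formula("C9H13N2+")))
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort("`text` must be a single formula string.")
  }
  text <- trimws(text)
  if (!nzchar(text)) abort("Cannot parse an empty formula string.")

  charge <- 0L
  m <- stringr::str_match(text, "^(.*?)([+-])([0-9]*)$")
  if (!is.na(m[1, 1])) {
    n <- m[1, 4]
    charge <- if (nzchar(n)) as.integer(n) else 1L
    if (m[1, 3] == "-") charge <- -charge
    text <- m[1, 2]
    if (!nzchar(text)) abort("Formula has a charge token but no elements.")
  }
  if (stringr::str_detect(text, "[+-]")) {
    abort("Embedded charge tokens are not supported; use a trailing token.")
  }

  toks <- stringr::str_match_all(text, "([A-Z][a-z]?)([0-9]*)")[[1]]
  if (sum(nchar(toks[, 1])) != nchar(text)) {
    bad <- stringr::str_remove_all(text, "([A-Z][a-z]?)([0-9]*)")
    abort(paste0("Cannot parse formula token(s): '", bad, "' in '", text, "'."))
  }
  syms <- toks[, 2]
  unknown <- setdiff(syms, element_symbols())
  if (length(unknown)) {
    abort(paste0("Unknown element symbol(s): ", paste(unknown, collapse = ", "), "."))
  }
  cnt <- ifelse(nzchar(toks[, 3]), suppressWarnings(as.integer(toks[, 3])), 1L)
  if (any(is.na(cnt)) || any(cnt < 1L)) abort("Element counts must be positive integers.")
  counts <- vapply(split(cnt, syms), sum, integer(1))
  new_mol_formula(counts[hill_order(names(counts))], charge)
}

new_mol_formula <- function(counts, charge = 0L) {
  structure(list(counts = counts, charge = as.integer(charge)),
            class = "mol_formula")
}

hill_order <- function(syms) {
  if ("C" %in% syms) {
    rest <- sort(setdiff(syms, c("C", "H")))
    c("C", intersect("H", syms), rest)
  } else {
    sort(syms)
  }
}

#' @rdname parse_formula
#' @param f A `mol_formula`, or a formula string (coerced with
#'   [parse_formula()]).
#' @return `format_formula()` returns the canonical Hill-order string with a
#'   trailing charge token when the charge is non-zero.
#' @export
format_formula <- function(f) {
  f <- as_mol_formula(f)
  cnt <- f$counts
  body <- paste0(names(cnt), ifelse(cnt > 1L, cnt, ""), collapse = "")
  if (f$charge == 0L) return(body)
  n <- abs(f$charge)
  paste0(body, if (f$charge > 0L) "+" else "-", if (n > 1L) n else "")
}

as_mol_formula <- function(f) {
  if (inherits(f, "mol_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  abort("Expected a mol_formula or a formula string.")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

isotope_table <- function() {
  if (is.null(the$isotopes)) {
    path <- system.file("extdata", "isotope_masses.tsv", package = "annolite")
    tab <- readr::read_tsv(path, col_types = readr::cols(
      symbol = readr::col_character(), mass = readr::col_double()))
    the$isotopes <- setNames(tab$mass, tab$symbol)
  }
  the$isotopes
}

element_symbols <- function() names(isotope_table())

#' Monoisotopic mass of a formula
#'
#' Sum of count times most-abundant-isotope mass over the elements of the
#' formula. The electron mass is neglected (charge is ignored); the effect is
#' well below one ppm and is irrelevant at the 5 ppm retrieval windows used
#' downstream. An empty formula has mass 0.
#'
#' @inheritParams format_formula
#' @return Mass in Da (double).
#' @export
monoisotopic_mass <- function(f) {
  f <- as_mol_formula(f)
  if (!length(f$counts)) return(0)
  iso <- isotope_table()
  missing <- setdiff(names(f$counts), names(iso))
  if (length(missing)) {
    abort(paste0("No isotope mass tabulated for: ", paste(missing, collapse = ", "), "."))
  }
  sum(f$counts * iso[names(f$counts)])
}

#' Vectorised monoisotopic mass over formula strings
#'
#' @param x Character vector of formula strings.
#' @return Double vector of masses in Da.
#' @export
formula_mass <- function(x) {
  vapply(x, function(s) monoisotopic_mass(parse_formula(s)), numeric(1),
         USE.NAMES = FALSE)
}

#' Strip the charge from a formula
#'
#' Sets the formal charge to zero without touching element counts: this is a
#' notational normalisation (no hydrogen adjustment), so the corresponding
#' structure strings are deliberately left unchanged by callers.
#'
#' @inheritParams format_formula
#' @return A neutral `mol_formula`.
#' @export
neutralize_formula <- function(f) {
  f <- as_mol_formula(f)
  new_mol_formula(f$counts, 0L)
}

#' Element blacklist for database construction
#'
#' The default exclusion list used by the structure filters: entries whose
#' formula contains any of these (mostly metallic, rare-earth, noble-gas and
#' synthetic) elements are removed from the compact database, since such
#' species are not usefully processed by in-silico fragmentation workflows.
#'
#' @return Character vector of element symbols.
#' @export
default_element_blacklist <- function() {
  c("Kr", "Dy", "Ir", "La", "Lu", "Nd", "Nb", "Os", "Pd", "Pt", "Pu", "Pr",
    "Re", "Rh", "Ru", "Sm", "Sc", "Ag", "Ta", "Tc", "Tb", "Th", "Tm", "Ti",
    "W", "Ac", "Am", "Er", "Eu", "Gd", "Hf", "Ho", "Xe", "Yb", "Rn", "Sr",
    "Be", "Cm", "Cf", "Cs", "Md", "Pm", "Fr", "Pa", "Np", "Bk", "Es", "Fm",
    "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds", "Rg", "Cn", "Nh",
    "Fl", "Mc", "Lv", "Ts", "Og")
}

#' @rdname default_element_blacklist
#' @inheritParams format_formula
#' @param blacklist Character vector of excluded element symbols.
#' @return `contains_excluded_element()` returns `TRUE` iff any element of
#'   `f` is blacklisted.
#' @export
contains_excluded_element <- function(f, blacklist = default_element_blacklist()) {
  f <- as_mol_formula(f)
  any(names(f$counts) %in% blacklist)
}

#' Detect multi-component (disconnected) structures
#'
#' A purely lexical check: a SMILES with a component separator `.` outside
#' square brackets, or an InChI whose formula layer contains a `.`, denotes a
#' mixture/salt/disconnected structure, which cannot be observed at the
#' neutral mass of a single-component query.
#'
#' @param smiles,inchi Structure identifier strings; at least one must be
#'   non-empty.
#' @return `TRUE` iff either identifier indicates multiple components.
#' @export
is_multicomponent <- function(smiles = "", inchi = "") {
  smiles <- if (is.null(smiles) || is.na(smiles)) "" else smiles
  inchi <- if (is.null(inchi) || is.na(inchi)) "" else inchi
  if (!nzchar(smiles) && !nzchar(inchi)) {
    abort("At least one of `smiles`/`inchi` must be non-empty.")
  }
  if (nzchar(smiles)) {
    chars <- strsplit(smiles, "")[[1]]
    depth <- 0L
    for (ch in chars) {
      if (ch == "[") depth <- depth + 1L
      else if (ch == "]") depth <- max(0L, depth - 1L)
      else if (ch == "." && depth == 0L) return(TRUE)
    }
  }
  if (nzchar(inchi)) {
    layers <- strsplit(inchi, "/", fixed = TRUE)[[1]]
    if (length(layers) >= 2 && grepl(".", layers[2], fixed = TRUE)) return(TRUE)
  }
  FALSE
}
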