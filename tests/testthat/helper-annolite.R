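# shared fixtures for the suite: a tiny record constructor and the shipped
# reference index (loaded once)

ref_idx <- default_category_index()

# one-row compound record in the read_compound_dump() shape
rec_row <- function(cid, inchikey, formula = "C10H14N2", fp = integer(0),
                    parent_cid = NA_integer_, name = paste0("cmp", cid),
                    smiles = "CCO", inchi = NULL,
                    pubmed = 0L, patent = 0L, mass = NULL) {
  if (is.null(inchi)) inchi <- paste0("InChI=1S/", sub("[+-][0-9]*$", "", formula), "/c1-2")
  if (is.null(mass)) mass <- monoisotopic_mass(parse_formula(formula))
  tibble::tibble(
    cid = as.integer(cid), parent_cid = as.integer(parent_cid), name = name,
    smiles = smiles, inchi = inchi, inchikey = inchikey, formula = formula,
    monoisotopic_mass = mass, pubmed_count = as.integer(pubmed),
    patent_count = as.integer(patent), fingerprint = list(sort(as.integer(fp))))
}

# a valid-pattern synthetic InChIKey with the given first block
ikey <- function(block, suffix = "AAAAAAAAAA") paste0(block, "-", suffix, "-N")

# random raw fingerprint over the reference index
random_fp <- function(idx = ref_idx, density = 0.15) {
  idx$bit[stats::runif(nrow(idx)) < density]
}

top_bit_of <- function(idx, short) idx$bit[idx$short_name == short & idx$sub_name == ""]
sub_bits_of <- function(idx, short) idx$bit[idx$short_name == short & idx$sub_name != ""]
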