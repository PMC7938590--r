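agro_top <- top_bit_of(ref_idx, "AgroChemInfo")
agro_subs <- sub_bits_of(ref_idx, "AgroChemInfo")
tox_top <- top_bit_of(ref_idx, "ToxicityInfo")
ident_top <- top_bit_of(ref_idx, "Identification")

test_that("annotation filtering keeps records intersecting the selection", {
  recs <- dplyr::bind_rows(
    rec_row(1, ikey("AAAAAAAAAAAAAA"), fp = ident_top),      # outside tier0
    rec_row(2, ikey("BBBBBBBBBBBBBB"), fp = agro_subs[1]),   # selected subcategory
    rec_row(3, ikey("CCCCCCCCCCCCCC"), fp = integer(0)))
  kept <- filter_annotated(recs, "tier0", ref_idx)
  expect_identical(kept$cid, 2L)
  expect_identical(filter_annotated(recs, "exposomics", ref_idx)$cid, c(1L, 2L))
  expect_equal(nrow(filter_annotated(recs[0, ], "tier0", ref_idx)), 0)
})

test_that("parent mapping imputes child annotation and counts to the parent", {
  child <- rec_row(2, ikey("AAAAAAAAAAAAAA", "CHILDAAAAA"), fp = c(agro_top, agro_subs[1]),
                   parent_cid = 1, pubmed = 3, patent = 10)
  parent <- rec_row(1, ikey("AAAAAAAAAAAAAA"), fp = integer(0), pubmed = 1, patent = 2)
  lone <- rec_row(9, ikey("ZZZZZZZZZZZZZZ"), fp = tox_top, pubmed = 4)

  mapped <- map_to_parent(dplyr::bind_rows(child, parent, lone))
  expect_setequal(mapped$cid, c(1L, 9L))
  p <- mapped[mapped$cid == 1L, ]
  expect_identical(p$fingerprint[[1]], sort(c(agro_top, agro_subs[1])))
  expect_equal(p$pubmed_count, 4L)
  expect_equal(p$patent_count, 12L)
  expect_identical(mapped[mapped$cid == 9L, ]$pubmed_count, 4L)  # pass-through

  # two children of one parent: union of fingerprints, sum of counts
  c1 <- rec_row(11, ikey("AAAAAAAAAAAAAA", "CHILDBBBBB"), fp = agro_top,
                parent_cid = 1, pubmed = 5)
  c2 <- rec_row(12, ikey("AAAAAAAAAAAAAA", "CHILDCCCCC"), fp = tox_top,
                parent_cid = 1, patent = 6)
  m2 <- map_to_parent(dplyr::bind_rows(parent, c1, c2))
  expect_identical(m2$fingerprint[[1]], sort(c(agro_top, tox_top)))
  expect_equal(m2$pubmed_count, 6L)
  expect_equal(m2$patent_count, 8L)

  # absent parent is materialised as a stub from the child
  orphan <- rec_row(21, ikey("QQQQQQQQQQQQQQ"), fp = agro_top, parent_cid = 20,
                    pubmed = 2)
  stub <- map_to_parent(orphan)
  expect_identical(stub$cid, 20L)
  expect_identical(stub$fingerprint[[1]], agro_top)
  expect_equal(stub$pubmed_count, 2L)

  # cycles are an error
  a <- rec_row(1, ikey("AAAAAAAAAAAAAA"), parent_cid = 2)
  bb <- rec_row(2, ikey("BBBBBBBBBBBBBB"), parent_cid = 1)
  expect_error(map_to_parent(dplyr::bind_rows(a, bb)), "cycle")
})

test_that("IKFB collapse retains the most annotated CID with lowest-CID ties", {
  blk <- "HXKKHQJGJAFBHI"
  grp <- dplyr::bind_rows(
    rec_row(100, ikey(blk, "AAAAAAAAAB"), fp = c(agro_top, agro_subs[1:2]), pubmed = 1),
    rec_row(50, ikey(blk, "AAAAAAAAAC"), fp = agro_top, patent = 4),
    rec_row(200, ikey(blk, "AAAAAAAAAD"), fp = tox_top, pubmed = 2))
  e <- collapse_by_ikfb(grp, "tier0", ref_idx)
  expect_equal(nrow(e), 1)
  expect_identical(e$cid, 100L)                 # 3 selected bits beats 1
  expect_identical(e$related_cids[[1]], c(50L, 100L, 200L))
  expect_equal(e$pubmed_count, 3L)
  expect_equal(e$patent_count, 4L)
  expect_identical(e$fingerprint[[1]], sort(c(agro_top, agro_subs[1:2], tox_top)))

  # equal annotation: lowest CID wins
  tie <- dplyr::bind_rows(
    rec_row(7, ikey(blk, "AAAAAAAAAB"), fp = agro_top),
    rec_row(3, ikey(blk, "AAAAAAAAAC"), fp = tox_top))
  expect_identical(collapse_by_ikfb(tie, "tier0", ref_idx)$cid, 3L)

  single <- collapse_by_ikfb(rec_row(5, ikey("AAAAAAAAAAAAAA"), fp = agro_top))
  expect_identical(single$related_cids[[1]], 5L)
})

test_that("structure filters partition entries with reasons and neutralise charges", {
  entries <- collapse_by_ikfb(dplyr::bind_rows(
    rec_row(1, ikey("AAAAAAAAAAAAAA"), formula = "C6H12PtN2", fp = agro_top),
    rec_row(2, ikey("BBBBBBBBBBBBBB"), smiles = "CC(=O)[O-].[Na+]", fp = agro_top),
    rec_row(3, ikey("CCCCCCCCCCCCCC"), formula = "C9H13N2+", smiles = "C[N+]1CC1",
            fp = agro_top),
    rec_row(4, ikey("DDDDDDDDDDDDDD"), fp = agro_top)))
  parts <- apply_structure_filters(entries)

  expect_equal(nrow(parts$kept) + nrow(parts$eliminated), nrow(entries))
  expect_identical(sort(parts$eliminated$reason), c("disconnected", "element"))
  expect_identical(parts$eliminated$reason[parts$eliminated$cid == 1L], "element")
  expect_identical(parts$eliminated$reason[parts$eliminated$cid == 2L], "disconnected")

  charged <- parts$kept[parts$kept$cid == 3L, ]
  expect_identical(charged$formula, "C9H13N2")   # charge token stripped
  expect_identical(charged$smiles, "C[N+]1CC1")  # structure untouched
})

test_that("full build is deterministic, accounts exactly, and handles empty input", {
  fx <- generate_fixture(withr::local_tempdir(), n_compounds = 80,
                         n_ikfb_groups = 35, seed = 12)
  b1 <- build_lite(fx$records, "tier0", ref_idx)
  b2 <- build_lite(fx$records, "tier0", ref_idx)
  expect_identical(b1$entries, b2$entries)
  expect_identical(b1$report, b2$report)

  r <- b1$report
  expect_identical(r$kept_ikfb + r$eliminated_ikfb, r$total_ikfb)
  expect_equal(sum(unlist(r$eliminated_reasons)), r$eliminated_ikfb)

  b0 <- build_lite(fx$records[0, ], "tier0", ref_idx)
  expect_equal(nrow(b0$entries), 0)
  expect_identical(b0$report$total_ikfb, 0L)

  g <- glance(b1)
  expect_identical(g$kept_ikfb, r$kept_ikfb)
  expect_identical(tidy(b1), b1$entries)
})

test_that("adding an annotation bit never shrinks the kept set or any score", {
  withr::with_seed(77, {
    for (trial in 1:5) {
      fx <- generate_fixture(withr::local_tempdir(), n_compounds = 40,
                             n_ikfb_groups = 18, seed = 300 + trial)
      recs <- fx$records
      base <- build_lite(recs, "tier0", ref_idx)

      i <- sample(nrow(recs), 1)
      missing_bits <- setdiff(ref_idx$bit, recs$fingerprint[[i]])
      if (!length(missing_bits)) next
      recs$fingerprint[[i]] <- sort(c(recs$fingerprint[[i]], sample(missing_bits, 1)))
      more <- build_lite(recs, "tier0", ref_idx)

      expect_true(all(base$entries$ikfb %in% more$entries$ikfb))
      shared <- intersect(base$entries$ikfb, more$entries$ikfb)
      for (cc in c(builtin_selection("tier0")$top_categories, "anno_total_count")) {
        expect_true(all(
          more$entries[[cc]][match(shared, more$entries$ikfb)] >=
            base$entries[[cc]][match(shared, base$entries$ikfb)]), label = cc)
      }
    }
  })
})

test_that("kept sets nest across tier0, tier1 and exposomics", {
  for (seed in c(41, 42)) {
    fx <- generate_fixture(withr::local_tempdir(), n_compounds = 70,
                           n_ikfb_groups = 30, seed = seed)
    k0 <- build_lite(fx$records, "tier0", ref_idx)$entries$ikfb
    k1 <- build_lite(fx$records, "tier1", ref_idx)$entries$ikfb
    kx <- build_lite(fx$records, "exposomics", ref_idx)$entries$ikfb
    expect_true(all(k0 %in% k1))
    expect_true(all(k1 %in% kx))
  }
})

test_that("category summary equals a brute-force tally and duplicates by design", {
  blk1 <- ikey("AAAAAAAAAAAAAA")
  blk2 <- ikey("BBBBBBBBBBBBBB")
  recs <- dplyr::bind_rows(
    rec_row(1, blk1, fp = c(agro_top, agro_subs[1:2])),
    rec_row(2, ikey("AAAAAAAAAAAAAA", "BBBBBBBBBB"), fp = tox_top),
    rec_row(3, blk2, fp = c(agro_top, agro_subs[1])))
  b <- build_lite(recs, "tier0", ref_idx)
  cs <- category_summary(b)

  # one entry annotated in 2 subcategories appears in both subcategory rows
  sub_rows <- cs[cs$short_name == "AgroChemInfo" & cs$sub_name != "", ]
  expect_equal(nrow(sub_rows), 2)
  expect_true(all(sub_rows$ikfb_count >= 1))

  # brute-force tally over the union fingerprints
  for (j in seq_len(nrow(cs))) {
    bit <- ref_idx$bit[ref_idx$short_name == cs$short_name[j] &
                         ref_idx$sub_name == cs$sub_name[j]]
    has <- vapply(b$entries$fingerprint, function(fp) bit %in% fp, logical(1))
    expect_equal(cs$ikfb_count[j], sum(has))
    expect_equal(cs$cid_count[j],
                 sum(lengths(b$entries$related_cids)[has]))
  }

  expect_equal(nrow(category_summary(b$entries[0, ], ref_idx)), 0)
})
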