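test_that("rank bucketing conserves totals and honours custom edges", {
  s <- bucket_ranks(c(1L, 1L, 2L, 5L, 40L, NA))
  expect_identical(as.character(s$bucket), c("1", "2-3", "4-10", ">10", "missing"))
  expect_identical(s$count, c(2L, 1L, 1L, 1L, 1L))
  expect_equal(sum(s$count), attr(s, "total"))

  s2 <- bucket_ranks(c(1L, 4L, 6L), edges = c(3, 5))
  expect_identical(as.character(s2$bucket), c("1-3", "4-5", ">5", "missing"))
  expect_identical(s2$count, c(1L, 1L, 1L, 0L))

  withr::with_seed(15, {
    for (i in 1:10) {
      ranks <- sample(c(1:30, NA), sample(1:50, 1), replace = TRUE)
      s <- bucket_ranks(ranks)
      expect_equal(sum(s$count), length(ranks))
    }
  })
})

test_that("benchmark runs bucket ranks, flag missing compounds, and validate terms", {
  fx <- generate_fixture(withr::local_tempdir(), n_compounds = 100,
                         n_ikfb_groups = 50, seed = 61)
  db <- build_lite(fx$records, "tier0", ref_idx)$entries
  bm <- generate_benchmark(db, 25, informativeness = 1.0, seed = 62)

  # a perfectly informative external term dominates: everything ranks first
  res <- run_benchmark(db, bm$benchmark, bm$terms, bm$external)
  s <- res$summary
  expect_equal(s$count[s$bucket == "1"], 25L)
  expect_equal(sum(s$count), 25)
  expect_identical(tidy(res)$rank, rep(1L, 25))
  expect_equal(glance(res)$frac_1, 1)

  # empty benchmark: all buckets zero
  empty <- run_benchmark(db, bm$benchmark[0, ], bm$terms, bm$external)
  expect_true(all(empty$summary$count == 0L))

  # a query compound absent from the database lands in "missing"
  ghost <- tibble::tibble(name = "ghost", ikfb = "GGGGGGGGGGGGGG",
                          neutral_mass = db$monoisotopic_mass[1])
  res_g <- run_benchmark(db, ghost, bm$terms, bm$external)
  expect_equal(res_g$summary$count[res_g$summary$bucket == "missing"], 1L)

  bad_terms <- tibble::tibble(name = "x", weight = 1, source = "no_such_col")
  expect_error(run_benchmark(db, bm$benchmark, bad_terms), "no_such_col")
})

test_that("an uninformative term never beats an informative one on rank-1 counts", {
  fx <- generate_fixture(withr::local_tempdir(), n_compounds = 120,
                         n_ikfb_groups = 60, seed = 71)
  db <- build_lite(fx$records, "tier0", ref_idx)$entries
  const_ext <- function(bm) dplyr::mutate(bm$external, value = 0.5)
  for (seed in c(72, 73, 74)) {
    bm <- generate_benchmark(db, 30, informativeness = 1.0, seed = seed)
    informative <- run_benchmark(db, bm$benchmark, bm$terms, bm$external)
    constant <- run_benchmark(db, bm$benchmark, bm$terms, const_ext(bm))
    n1 <- function(r) r$summary$count[r$summary$bucket == "1"]
    expect_lte(n1(constant), n1(informative))
  }
})

test_that("category subsetting equals a brute-force filter", {
  fx <- generate_fixture(withr::local_tempdir(), n_compounds = 100,
                         n_ikfb_groups = 50, seed = 81)
  db <- build_lite(fx$records, "tier0", ref_idx)$entries
  bm <- generate_benchmark(db, 30, informativeness = 1.0, seed = 82)
  bench <- dplyr::bind_rows(
    bm$benchmark,
    tibble::tibble(name = "ghost", ikfb = "GGGGGGGGGGGGGG", neutral_mass = 100))

  sub <- subset_benchmark_by_category(bench, db, "AgroChemInfo")
  brute <- bench[vapply(bench$ikfb, function(k) {
    j <- which(db$ikfb == k)
    length(j) > 0 && db$AgroChemInfo[j] > 0
  }, logical(1)), ]
  expect_identical(sub, brute)
  expect_false("ghost" %in% sub$name)           # entries missing from db excluded
  expect_error(subset_benchmark_by_category(bench, db, "NotACol"), "NotACol")
})

test_that("gap reports partition a list by database presence", {
  db <- dplyr::bind_rows(
    collapse_by_ikfb(rec_row(1, ikey("AAAAAAAAAAAAAA"))),
    collapse_by_ikfb(rec_row(2, ikey("BBBBBBBBBBBBBB"))))
  lst <- tibble::tibble(
    name = c("a", "b", "c", "d"),
    ikfb = c("AAAAAAAAAAAAAA", "BBBBBBBBBBBBBB", "XXXXXXXXXXXXXX",
             "YYYYYYYYYYYYYY"))
  g <- gap_report(lst, db)
  expect_equal(g$present, 2)
  expect_equal(g$missing_count, 2)
  expect_equal(g$present + g$missing_count, nrow(lst))
  expect_setequal(tidy(g)$name, c("c", "d"))

  expect_equal(gap_report(lst, db[0, ])$missing_count, 4)
  expect_equal(gap_report(lst[1:2, ], db)$missing_count, 0)
  expect_identical(glance(g)$total, 4L)
})

test_that("transformation statements follow the serial-comma grammar", {
  maps <- tibble::tibble(
    predecessor_cid = c(8607L, 8607L, 8607L, 5L),
    predecessor_name = c("Folpet", "Folpet", "Folpet", "Atrazine"),
    successor_cid = c(1L, 2L, 3L, 6L),
    successor_name = c("Phthalimide", "Phthalamic acid", "Phthalic acid",
                       "Desethylatrazine"),
    source = "S60")
  st <- transformation_statements(maps)
  expect_equal(nrow(st), 2)
  expect_identical(
    st$statement[st$predecessor_name == "Folpet"],
    paste0("Folpet has known environmental transformation products that ",
           "include Phthalimide, Phthalamic acid, and Phthalic acid"))
  expect_identical(
    st$statement[st$predecessor_name == "Atrazine"],
    paste0("Atrazine has known environmental transformation products that ",
           "include Desethylatrazine"))

  two <- transformation_statements(maps[1:2, ])
  expect_match(two$statement, "include Phthalimide and Phthalamic acid$")

  expect_equal(nrow(transformation_statements(maps[0, ])), 0)
})

test_that("rank-1 recovery tracks the informativeness of the external term", {
  fx <- generate_fixture(withr::local_tempdir(), n_compounds = 200,
                         n_ikfb_groups = 110, seed = 91,
                         fraction_disconnected = 0.05, fraction_blacklisted = 0.05)
  db <- build_lite(fx$records, "tier0", ref_idx)$entries
  n <- 80
  for (p in c(0.5, 0.9, 1.0)) {
    bm <- generate_benchmark(db, n, informativeness = p, seed = 900 + p * 10)
    res <- run_benchmark(db, bm$benchmark, bm$terms, bm$external)
    frac <- glance(res)$frac_1
    # expected rank-1 fraction: p plus chance wins among k iid-scored candidates
    if (p == 1.0) {
      expect_equal(frac, 1)
    } else {
      k <- tidy(res)$n_candidates
      expected <- p + (1 - p) * mean(1 / k)
      se <- sqrt(expected * (1 - expected) / n)
      expect_lte(abs(frac - expected), 4 * se)
    }
  }
})
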