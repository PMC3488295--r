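write_gb <- function(lines) {
  tf <- withr::local_tempfile(fileext = ".gb", .local_envir = parent.frame())
  writeLines(lines, tf)
  tf
}

stub_record <- function(acc = "AB000001", authors = "Smith,J., Jones,K.",
                        date = "03-JAN-2002", with_pub = TRUE,
                        submitted = TRUE) {
  c(sprintf("LOCUS       %s  600 bp mRNA linear VRT %s", acc, date),
    sprintf("ACCESSION   %s", acc),
    if (with_pub) c(
      "REFERENCE   1  (bases 1 to 600)",
      sprintf("  AUTHORS   %s", authors),
      "  TITLE     A study of amphibian transcripts",
      "  JOURNAL   Genome Res. 12, 1-10 (2002)"),
    sprintf("REFERENCE   %d  (bases 1 to 600)", if (with_pub) 2L else 1L),
    "  AUTHORS   Smith,J.",
    "  TITLE     Direct Submission",
    if (submitted)
      sprintf("  JOURNAL   Submitted (%s) Some Institute", date)
    else "  JOURNAL   Unpublished",
    "//")
}

test_that("last author and submission date are mined from stub records", {
  path <- write_gb(stub_record())
  rec <- parse_flatfile(path)
  expect_equal(rec$last_author, "Jones,K.")
  expect_equal(rec$submit_date, as.Date("2002-01-03"))

  # 'and' before the final name
  path2 <- write_gb(stub_record(authors = "Smith,J., Roe,R. and Doe,J.A."))
  expect_equal(parse_flatfile(path2)$last_author, "Doe,J.A.")

  # only a Direct Submission reference: its author is used
  path3 <- write_gb(stub_record(with_pub = FALSE))
  expect_equal(parse_flatfile(path3)$last_author, "Smith,J.")

  # no Submitted line: null date with a warning? date NA but author present
  path4 <- write_gb(stub_record(submitted = FALSE))
  rec4 <- parse_flatfile(path4)
  expect_true(is.na(rec4$submit_date))
  expect_equal(rec4$last_author, "Jones,K.")
})

test_that("unterminated records and duplicate accessions are errors", {
  bad <- stub_record()
  path <- write_gb(bad[-length(bad)])          # drop the trailing //
  expect_error(parse_flatfile(path), "unterminated")
  path2 <- write_gb(c(stub_record("AB1"), stub_record("AB1")))
  expect_error(parse_flatfile(path2), "duplicate accession")
})

test_that("monthly pooling follows individual and library conventions", {
  recs <- tibble::tibble(
    accession = c("a", "b", "c"),
    submit_date = as.Date(c("2002-01-03", "2002-01-15", "2002-02-02")),
    last_author = "X", library_id = NA_character_)
  mc <- monthly_counts(recs)
  expect_equal(mc$month, c("2002-01", "2002-02"))
  expect_equal(mc$count, c(2L, 1L))
  expect_equal(attr(mc, "n_undated"), 0L)

  # library mode pools at the library's earliest month
  lib_recs <- tibble::tibble(
    accession = c("a", "b"),
    submit_date = as.Date(c("2004-03-10", "2004-01-20")),
    last_author = "X", library_id = "L")
  ml <- monthly_counts(lib_recs, group_by_library = TRUE)
  expect_equal(ml$month, "2004-01")
  expect_equal(ml$count, 2L)

  # undated records excluded but reported; totals conserve
  recs$submit_date[2] <- NA
  mc2 <- monthly_counts(recs)
  expect_equal(sum(mc2$count) + attr(mc2, "n_undated"), nrow(recs))

  empty <- monthly_counts(recs[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("author ranking is order-invariant with alphabetical ties", {
  recs <- tibble::tibble(
    accession = sprintf("a%d", 1:5),
    submit_date = as.Date("2004-01-01"),
    last_author = c("B", "A", "A", NA, "C"), library_id = NA_character_)
  rk <- rank_last_authors(recs)
  expect_equal(rk$last_author, c("A", "B", "C"))
  expect_equal(rk$count, c(2L, 1L, 1L))
  expect_equal(attr(rk, "n_unattributed"), 1L)
  rk2 <- rank_last_authors(recs[sample(5), ])
  expect_equal(rk2$last_author, rk$last_author)
  expect_equal(rank_last_authors(recs, top_n = 1)$last_author, "A")
})

test_that("generated flatfiles round-trip through the parser", {
  ff <- make_flatfiles(12, authors = c("Zorn,A.M.", "Richardson,P.",
                                       "Gilchrist,M.J."),
                       seed = 19, libraries = c("NICHD_XGC1", "THdA"))
  path <- write_gb(ff$text)
  rec <- parse_flatfile(path)
  expect_equal(rec$accession, ff$truth$accession)
  expect_equal(rec$submit_date, ff$truth$submit_date)
  expect_equal(rec$last_author, ff$truth$last_author)
  expect_equal(rec$library_id, ff$truth$library_id)
  # determinism and the empty case
  expect_identical(make_flatfiles(12, "A,B.", seed = 19),
                   make_flatfiles(12, "A,B.", seed = 19))
  expect_equal(nrow(make_flatfiles(0, "A,B.")$truth), 0L)
  expect_error(make_flatfiles(3, "Zorn, A. M."), "canonical")
})
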