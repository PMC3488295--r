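orf_of <- function(seq, min_len = 6) find_longest_orf(seq, min_len_nt = min_len)

test_that("UTR presence maps to the complete-ORF subclasses", {
  seq <- "GGATGAAATAGCC"
  expect_equal(as.character(classify_completeness(seq, orf_of(seq))),
               "COMPLETE_WITH_UTRS")
  seq <- "ATGAAATAGCC"
  expect_equal(as.character(classify_completeness(seq, orf_of(seq))),
               "COMPLETE_NO_5UTR")
  seq <- "GGATGAAATAG"
  expect_equal(as.character(classify_completeness(seq, orf_of(seq))),
               "COMPLETE_NO_3UTR")
  seq <- "ATGAAATAG"
  expect_equal(as.character(classify_completeness(seq, orf_of(seq))),
               "COMPLETE_NO_UTRS")
})

test_that("missing stop codon means 3'-truncation", {
  seq <- "GGATGAAAAAA"
  expect_equal(as.character(classify_completeness(seq, orf_of(seq))),
               "TRUNC_3")
})

test_that("protein evidence upstream of the ORF start means 5'-truncation", {
  # ORF starts at 50; evidence interval [10, 45) sits strictly upstream
  seq <- paste0(strrep("C", 50), "ATG", strrep("AAA", 20), "TAG",
                strrep("C", 20))
  orf <- orf_of(seq)
  expect_equal(orf$start, 50L)
  ev <- data.frame(start = 10L, end = 45L)
  expect_equal(
    as.character(classify_completeness(seq, orf, protein_evidence = ev)),
    "TRUNC_5")
  # evidence downstream of the start is not truncation evidence
  ev2 <- data.frame(start = 60L, end = 90L)
  expect_equal(
    as.character(classify_completeness(seq, orf, protein_evidence = ev2)),
    "COMPLETE_WITH_UTRS")
})

test_that("heuristic mode calls putative 5'-truncation from open upstream", {
  # 36 nt of open in-frame sequence upstream of the ATG, no stop
  seq <- paste0(strrep("CCA", 12), "ATG", strrep("AAA", 20), "TAGCC")
  orf <- orf_of(seq)
  cls <- classify_completeness(seq, orf)
  expect_equal(as.character(cls), "TRUNC_5")
  expect_true(attr(cls, "putative"))
  # an in-frame stop upstream blocks the call
  seq2 <- paste0("TAA", strrep("CCA", 11), "ATG", strrep("AAA", 20), "TAGCC")
  expect_equal(as.character(classify_completeness(seq2, orf_of(seq2))),
               "COMPLETE_WITH_UTRS")
  # short upstream region is not called
  seq3 <- paste0(strrep("CCA", 5), "ATG", strrep("AAA", 20), "TAGCC")
  expect_equal(as.character(classify_completeness(seq3, orf_of(seq3))),
               "COMPLETE_WITH_UTRS")
})

test_that("both truncations combine, and repeat content dominates all", {
  # open upstream and no stop
  seq <- paste0(strrep("CCA", 12), "ATG", strrep("AAA", 20))
  expect_equal(as.character(classify_completeness(seq, orf_of(seq))),
               "TRUNC_BOTH")
  # repeat precedence regardless of ORF structure
  expect_equal(
    as.character(classify_completeness(seq, orf_of(seq),
                                       repeat_fraction = 0.81)),
    "HIGH_COPY_REPEAT")
  expect_equal(
    as.character(classify_completeness("GGATGAAATAGCC",
                                       orf_of("GGATGAAATAGCC"),
                                       repeat_fraction = 0.81)),
    "HIGH_COPY_REPEAT")
  expect_error(classify_completeness(seq, orf_of(seq), repeat_fraction = 1.2),
               "\\[0, 1\\]")
})

test_that("no ORF and sub-threshold repeat coverage yield NO_ORF", {
  expect_equal(as.character(
    classify_completeness("GGGCCC", NULL, repeat_fraction = 0.80)),
    "NO_ORF")
})

test_that("crossing the repeat threshold only ever flips to HIGH_COPY_REPEAT", {
  withr::local_seed(33)
  for (i in 1:50) {
    seq <- rand_dna(sample(30:200, 1))
    orf <- find_longest_orf(seq, min_len_nt = 30)
    below <- classify_completeness(seq, orf, repeat_fraction = 0.80)
    above <- classify_completeness(seq, orf, repeat_fraction = 0.801)
    expect_equal(as.character(above), "HIGH_COPY_REPEAT")
    expect_false(as.character(below) == "HIGH_COPY_REPEAT")
  }
})

test_that("classification is total over random sequences", {
  withr::local_seed(44)
  for (i in 1:100) {
    seq <- rand_dna(sample(10:150, 1), alphabet = c("A", "C", "G", "T", "N"))
    orf <- find_longest_orf(seq, min_len_nt = 30)
    cls <- classify_completeness(seq, orf)
    expect_length(as.character(cls), 1L)
    expect_true(as.character(cls) %in% completeness_classes())
  }
})

test_that("tallies conserve counts and reject duplicate ids", {
  tly <- tally_classes(data.frame(
    id = c("t1", "t2", "t3"),
    class = c("TRUNC_3", "TRUNC_3", "COMPLETE_NO_UTRS")), label = "demo")
  expect_equal(tly$total, 3L)
  expect_equal(tly$counts[["TRUNC_3"]], 2L)
  expect_equal(sum(tly$counts), tly$total)

  expect_error(tally_classes(data.frame(id = c("a", "a"),
                                        class = c("NO_ORF", "NO_ORF"))),
               "duplicate")
  empty <- tally_classes(data.frame(id = character(), class = character()))
  expect_equal(empty$total, 0L)
  expect_true(all(empty$counts == 0L))
})
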