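test_that("translation follows the standard code with X for fuzzy codons", {
  expect_equal(translate_dna("ATGAAA"), "MK")
  expect_equal(translate_dna("ATGAAN"), "MX")
  expect_equal(translate_dna("ATGTAA"), "M*")
  expect_equal(translate_dna("ATGAAAT"), "MK")     # partial codon dropped
  expect_equal(translate_dna("GATGAAA", offset = 1), "MK")
  expect_equal(translate_dna("AT"), "")
})

test_that("longest ORF is found with stop handling and tie rules", {
  o <- find_longest_orf("GGATGAAATAGCC", min_len_nt = 6)
  expect_equal(c(o$start, o$end), c(2L, 11L))
  expect_true(o$has_start && o$has_stop)
  expect_equal(o$protein, "MK")

  # two ORFs of equal length: 5'-most start wins
  o2 <- find_longest_orf("ATGAAATAGATGCCCTAG", min_len_nt = 6)
  expect_equal(o2$start, 0L)

  expect_null(find_longest_orf("GGGCCCGGGCCC", min_len_nt = 6))

  # open ORF runs to the last complete codon
  o3 <- find_longest_orf("GGATGAAAAAA", min_len_nt = 6)
  expect_equal(c(o3$start, o3$end), c(2L, 11L))
  expect_false(o3$has_stop)

  # below the length floor
  expect_null(find_longest_orf("GGATGAAATAGCC", min_len_nt = 12))
  expect_error(find_longest_orf(""), "empty")
})

test_that("reverse-strand scanning reports forward coordinates", {
  fwd <- "GGATGAAATAGCC"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  o <- find_longest_orf(rc, min_len_nt = 6, scan_reverse = TRUE)
  expect_equal(o$strand, "-")
  n <- nchar(rc)
  expect_equal(c(o$start, o$end), c(n - 11L, n - 2L))
  expect_equal(o$protein, "MK")
  # without the flag the reverse ORF is invisible
  expect_null(find_longest_orf(rc, min_len_nt = 9))
})

test_that("scanner agrees with the brute-force oracle on random input", {
  withr::local_seed(2024)
  n_agree <- 0L
  for (i in 1:1000) {
    len <- sample(1:90, 1)
    seq <- rand_dna(len, alphabet = c("A", "C", "G", "T",
                                      if (i %% 7 == 0) "N"))
    min_len <- sample(c(3, 6, 30, 90), 1)
    got <- find_longest_orf(seq, min_len_nt = min_len)
    want <- oracle_longest_orf(seq, min_len_nt = min_len)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$has_stop, want$has_stop)
    }
    n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, 1000L)
})

test_that("orf_call invariants hold on scanner output", {
  withr::local_seed(7)
  for (i in 1:50) {
    seq <- rand_dna(sample(30:300, 1))
    o <- find_longest_orf(seq, min_len_nt = 30)
    if (is.null(o)) next
    expect_equal((o$end - o$start) %% 3L, 0L)
    expect_lte(o$end, nchar(seq))
    expect_gte(o$start, 0L)
    if (o$strand == "+") {
      expect_equal(substr(seq, o$start + 1, o$start + 3), "ATG")
      if (o$has_stop) {
        expect_true(substr(seq, o$end - 2, o$end) %in% c("TAA", "TAG", "TGA"))
      }
    }
    expect_equal(nchar(o$protein),
                 (o$end - o$start) / 3 - as.integer(o$has_stop))
  }
})
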