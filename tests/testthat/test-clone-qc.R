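# a coding contig: 60 nt 5' UTR, 180-codon ORF, 120 nt 3' UTR
demo_contig <- function(seed = 21) {
  withr::with_seed(seed, {
    orf <- paste0("ATG", paste(replicate(178, {
      repeat {
        cod <- rand_dna(3)
        if (!cod %in% c("TAA", "TAG", "TGA")) break
      }
      cod
    }), collapse = ""), "TAA")
    list(id = "ctgA", seq = paste0(rand_dna(60), orf, rand_dna(120)),
         orf_start = 60L, orf_end = 60L + 540L)
  })
}

test_that("alignment of identical and reverse-complement sequences", {
  ct <- demo_contig()
  aln <- align_to_contig(list(id = "c1", seq = ct$seq), ct)
  expect_equal(aln$identity, 1.0)
  expect_equal(aln$q_cov, 1.0)
  expect_equal(aln$t_cov, 1.0)
  expect_equal(aln$strand, "+")
  expect_equal(nrow(aln$blocks), 1L)
  expect_equal(nrow(aln$indels), 0L)

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ct$seq)))
  aln2 <- align_to_contig(list(id = "c2", seq = rc), ct)
  expect_equal(aln2$strand, "-")
  expect_equal(aln2$identity, 1.0)
})

test_that("a single deleted base is recovered as a 1 nt deletion", {
  ct <- demo_contig()
  mutant <- paste0(substr(ct$seq, 1, 250), substr(ct$seq, 252, nchar(ct$seq)))
  aln <- align_to_contig(list(id = "c3", seq = mutant), ct)
  dels <- aln$indels[aln$indels$kind == "deletion_from_query", ]
  expect_equal(nrow(dels), 1L)
  expect_equal(dels$length, 1L)
  # homopolymer slippage can shift the reported position slightly
  expect_lt(abs(dels$t_pos - 250L), 10L)
})

test_that("alignment is refused for mostly-N queries", {
  ct <- demo_contig()
  expect_error(
    align_to_contig(list(id = "bad", seq = strrep("N", 500)), ct),
    "refused")
})

test_that("frameshift detection respects frame and the ORF interval", {
  aln <- list(indels = data.frame(
    q_pos = c(100L, 200L, 650L), t_pos = c(100L, 200L, 650L),
    length = c(1L, 3L, 1L),
    kind = c("deletion_from_query", "deletion_from_query",
             "insertion_in_query"),
    inserted = c(NA, NA, "T")))
  fs <- detect_frameshifts(aln, c(60L, 600L))
  expect_equal(nrow(fs), 1L)       # the in-frame 3 nt and the UTR indel pass
  expect_equal(fs$t_pos, 100L)
  expect_equal(nrow(detect_frameshifts(aln, NULL)), 0L)
})

test_that("clone codes are recovered for engineered single defects", {
  cs <- make_clone_set(c("perfect", "t5", "t3", "fs", "chi", "imm",
                         "short_del", "low_identity", "noncoding_target",
                         "unknown"), seed = 77)
  res <- classify_clones(cs$clones, cs$contigs, cs$orfs)
  m <- merge(res, cs$truth, by = "clone_id")
  expect_equal(m$code.x, m$code.y)
  expect_equal(length(unique(m$code.x)), 10L)  # all codes exercised
})

test_that("a contig aligned to itself is always full-length", {
  cs <- make_clone_set(c("perfect", "perfect"), seed = 3)
  for (i in seq_len(nrow(cs$orfs))) {
    ct <- cs$contigs[cs$contigs$id == cs$orfs$contig_id[i], ]
    code <- classify_clone(list(id = ct$id, seq = ct$seq),
                           xenqc:::merge_contig_orfs(cs$contigs, cs$orfs))
    expect_equal(code$value, "FL")
  }
})

test_that("candidate order never changes the call", {
  cs <- make_clone_set(c("chi", "t5", "imm"), seed = 13)
  cand <- xenqc:::merge_contig_orfs(cs$contigs, cs$orfs)
  withr::local_seed(1)
  for (i in seq_len(nrow(cs$clones))) {
    base <- classify_clone(cs$clones[i, ], cand)$value
    for (r in 1:3) {
      perm <- cand[sample(nrow(cand)), ]
      expect_equal(classify_clone(cs$clones[i, ], perm)$value, base)
    }
  }
})

test_that("qc_summary conserves counts and rejects duplicates", {
  tly <- qc_summary(data.frame(clone_id = c("a", "b", "c"),
                               code = c("FL", "FL", "FS")), "demo")
  expect_equal(tly$total, 3L)
  expect_equal(tly$counts[["FL"]], 2L)
  expect_error(qc_summary(data.frame(clone_id = c("a", "a"),
                                     code = c("FL", "FS"))), "duplicate")
  expect_equal(qc_summary(data.frame(clone_id = character(),
                                     code = character()))$total, 0L)
  expect_error(classify_clone(list(id = "x", seq = "ACGT"), list()),
               "no candidate")
})
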