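test_that("set summaries count clones, genes and unmapped accessions", {
  clones <- tibble::tibble(
    clone_id = c("c1", "c2", "c3", "c4", "c5"),
    accession = c("a1", "a2", "a3", "a4", "a5"))
  gmap <- tibble::tibble(accession = c("a1", "a2", "a3"),
                         gene_id = c("g1", "g1", "g2"))
  s <- summarize_set(clones, gmap, plates = 1, fl_rate = 1.0)
  expect_equal(s$distinct_clones, 5L)
  expect_equal(s$distinct_genes, 2L)
  expect_equal(s$unmapped_accessions, 2L)
  expect_equal(s$wells, 96L)
  expect_equal(s$est_fl_genes, 2L)

  # clones without accessions don't count as distinct clones
  clones$accession[5] <- NA
  s2 <- summarize_set(clones, gmap, plates = 1, fl_rate = 0.5)
  expect_equal(s2$distinct_clones, 4L)

  empty <- summarize_set(clones[0, ], gmap, plates = 1, fl_rate = 0.9)
  expect_equal(empty$distinct_genes, 0L)
  expect_equal(empty$est_fl_genes, 0L)
  expect_error(summarize_set(clones, gmap, plates = 0, fl_rate = 1), "plates")
})

test_that("set summary is invariant to clone order", {
  withr::local_seed(8)
  clones <- tibble::tibble(clone_id = sprintf("c%d", 1:50),
                           accession = sprintf("a%d", sample(1:30, 50, TRUE)))
  gmap <- tibble::tibble(accession = sprintf("a%d", 1:25),
                         gene_id = sprintf("g%d", sample(1:12, 25, TRUE)))
  s1 <- summarize_set(clones, gmap, plates = 2, fl_rate = 0.7)
  s2 <- summarize_set(clones[sample(50), ], gmap, plates = 2, fl_rate = 0.7)
  expect_equal(s1, s2)
})

test_that("the full-length estimator rounds halves away from zero", {
  expect_equal(est_fl_genes(4973, 0.90), 4476L)
  expect_equal(est_fl_genes(5, 0.5), 3L)
  expect_equal(est_fl_genes(0, 0.9), 0L)
  # monotone in both arguments
  expect_gte(est_fl_genes(4973, 0.91), est_fl_genes(4973, 0.90))
  expect_gte(est_fl_genes(5000, 0.90), est_fl_genes(4973, 0.90))
  expect_error(est_fl_genes(10, 1.2), "\\[0, 1\\]")
})

test_that("full-length rate excludes unsequenced clones from the denominator", {
  w <- fl_rate_from_qc(xen_fixture("table2_wellcome"))
  expect_equal(w, 4585 / (9216 - 2772))
  i <- fl_rate_from_qc(xen_fixture("table2_image"))
  expect_equal(i, 1795 / (1920 - 4))
  one <- tally_classes(c(x = "FL"), levels = clone_qc_codes())
  expect_equal(fl_rate_from_qc(one), 1.0)
  all_unknown <- tally_classes(c(x = "?"), levels = clone_qc_codes())
  expect_error(fl_rate_from_qc(all_unknown), "no sequenced")
})

test_that("combining sets deduplicates genes but not clones", {
  gmap <- tibble::tibble(accession = c("a1", "a2", "a3", "a4"),
                         gene_id = c("g1", "g2", "g2", "g3"))
  t1 <- tibble::tibble(clone_id = c("c1", "c2"), accession = c("a1", "a2"))
  t2 <- tibble::tibble(clone_id = c("c1", "c2"), accession = c("a3", "a4"))
  s1 <- summarize_set(t1, gmap, plates = 1, fl_rate = 1, set_name = "A",
                      species = "X. tropicalis")
  s2 <- summarize_set(t2, gmap, plates = 2, fl_rate = 1, set_name = "B",
                      species = "X. tropicalis")
  comb <- combine_sets(list(s1, s2), list(t1, t2), gmap)
  expect_equal(comb$plates, 3L)
  expect_equal(comb$wells, 288L)
  expect_equal(comb$distinct_clones, 4L)   # clone ids are per-set
  expect_equal(comb$distinct_genes, 3L)    # g2 shared, counted once
  expect_true(is.na(comb$est_fl_genes))

  # disjoint gene sets: combined equals the sum
  gmap2 <- tibble::tibble(accession = c("a1", "a2", "a3", "a4"),
                          gene_id = c("g1", "g2", "g3", "g4"))
  comb2 <- combine_sets(list(s1, s2), list(t1, t2), gmap2)
  expect_equal(comb2$distinct_genes, 4L)

  s3 <- summarize_set(t2, gmap, plates = 2, fl_rate = 1, set_name = "C",
                      species = "X. laevis")
  expect_error(combine_sets(list(s1, s3), list(t1, t2), gmap), "species")
  expect_error(combine_sets(list(s1), list(t1), gmap), "at least two")
})

test_that("coverage percentages match the printed gene-count arithmetic", {
  expect_equal(coverage_percent(10549, 22472), 46.9)
  expect_equal(coverage_percent(10549, 20000), 52.7)
  expect_equal(coverage_percent(0, 100), 0.0)
  expect_error(coverage_percent(5, 0), "positive")
  expect_error(coverage_percent(101, 100), "exceeds")
})
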