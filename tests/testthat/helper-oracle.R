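# Independent brute-force oracle for the longest-ORF scanner: enumerate
# every ATG position, extend codon by codon to the first stop or the last
# complete codon, and apply the tie rules (longest, then 5'-most start,
# then lowest frame) by explicit sort. Written directly from the contract,
# separately from the package internals.
oracle_longest_orf <- function(seq, min_len_nt = 90L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  cand <- list()
  for (i in seq_len(max(0L, n - 2L))) {
    if (substr(seq, i, i + 2L) != "ATG") next
    end <- NA
    has_stop <- FALSE
    j <- i + 3L
    while (j + 2L <= n) {
      cod <- substr(seq, j, j + 2L)
      if (cod %in% stops) {
        end <- j + 2L
        has_stop <- TRUE
        break
      }
      j <- j + 3L
    }
    if (!has_stop) end <- j - 1L
    cand[[length(cand) + 1L]] <- data.frame(
      start = i - 1L, end = end, has_stop = has_stop, frame = (i - 1L) %% 3L)
  }
  if (length(cand) == 0L) return(NULL)
  cand <- do.call(rbind, cand)
  cand <- cand[cand$end - cand$start >= min_len_nt, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  len <- cand$end - cand$start
  cand[order(-len, cand$start, cand$frame)[1L], , drop = FALSE]
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
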