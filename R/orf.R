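STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a nucleotide sequence with the standard genetic code
#'
#' Standard nuclear code; a trailing partial codon is dropped; any codon
#' containing a character outside A/C/G/T translates to `X`; stop codons
#' translate to `*`. Ambiguity-tolerant by design: gapped assemblies inject
#' N runs into transcripts and a hard failure there would be worse than an
#' `X` residue.
#'
#' @param seq Nucleotide string.
#' @param offset Reading-frame offset, 0, 1 or 2 bases from the 5' end.
#' @return Amino-acid string (possibly empty).
#' @examples
#' translate_dna("ATGAAATAG")   # "MK*"
#' translate_dna("ATGAAN")      # "MX"
#' @export
translate_dna <- function(seq, offset = 0L) {
  stopifnot(length(seq) == 1L, offset %in% 0:2)
  seq <- toupper(seq)
  n <- nchar(seq)
  starts <- seq.int(offset + 1L, by = 3L,
                    length.out = max(0L, (n - offset) %/% 3L))
  if (length(starts) == 0L) return("")
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

orf_call <- function(start, end, has_start, has_stop, strand = "+",
                     frame = start %% 3L, seq = NULL, transcript_id = NA_character_) {
  protein <- NULL
  structure(
    list(transcript_id = transcript_id, strand = strand, frame = as.integer(frame),
         start = as.integer(start), end = as.integer(end),
         has_start = has_start, has_stop = has_stop, protein = NA_character_),
    class = "orf_call")
}

#' @export
print.orf_call <- function(x, ...) {
  cat(sprintf("ORF [%d,%d) strand %s frame %d  start:%s stop:%s  %d aa\n",
              x$start, x$end, x$strand, x$frame,
              if (x$has_start) "ATG" else "-",
              if (x$has_stop) "yes" else "open",
              nchar(x$protein)))
  invisible(x)
}

# All ATG-initiated candidate ORFs on the forward strand of `seq`.
# Returns a data.frame with 0-based half-open coordinates; end includes the
# stop codon when present, else runs to the last complete codon in frame.
orf_candidates_fwd <- function(seq) {
  n <- nchar(seq)
  out <- vector("list", 3L)
  for (f in 0:2) {
    starts1 <- seq.int(f + 1L, by = 3L, length.out = max(0L, (n - f) %/% 3L))
    if (length(starts1) == 0L) next
    codons <- substring(seq, starts1, starts1 + 2L)
    atg_i <- which(codons == "ATG")
    if (length(atg_i) == 0L) next
    stop_i <- which(codons %in% STOP_CODONS)
    # first stop at or after each ATG (strictly after the start codon itself)
    nxt <- stop_i[findInterval(atg_i, stop_i) + 1L]
    has_stop <- !is.na(nxt)
    end0 <- ifelse(has_stop,
                   starts1[ifelse(is.na(nxt), 1L, nxt)] + 2L,   # stop codon last base
                   starts1[length(starts1)] + 2L)               # last complete codon
    start0 <- starts1[atg_i] - 1L
    out[[f + 1L]] <- data.frame(start = start0, end = end0,
                                has_stop = has_stop, frame = f)
  }
  cand <- do.call(rbind, out)
  if (is.null(cand)) {
    return(data.frame(start = integer(), end = integer(),
                      has_stop = logical(), frame = integer()))
  }
  cand
}

# Brute-force reference enumeration of ATG-initiated ORFs, by direct
# substring inspection. Used by the synthetic-data generator for rejection
# sampling; deliberately simple and independent of the vectorised scanner.
orf_enumerate_slow <- function(seq) {
  n <- nchar(seq)
  rows <- list()
  for (i in seq_len(max(0L, n - 2L))) {
    if (substr(seq, i, i + 2L) != "ATG") next
    j <- i + 3L
    end0 <- NA_integer_
    has_stop <- FALSE
    while (j + 2L <= n) {
      if (substr(seq, j, j + 2L) %in% STOP_CODONS) {
        end0 <- j + 2L
        has_stop <- TRUE
        break
      }
      j <- j + 3L
    }
    if (!has_stop) end0 <- j - 1L  # last complete codon already consumed
    rows[[length(rows) + 1L]] <-
      data.frame(start = i - 1L, end = end0, has_stop = has_stop,
                 frame = (i - 1L) %% 3L)
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      has_stop = logical(), frame = integer()))
  }
  do.call(rbind, rows)
}

pick_best_orf <- function(cand) {
  if (nrow(cand) == 0L) return(NULL)
  len <- cand$end - cand$start
  ord <- order(-len, cand$start, cand$frame)
  cand[ord[1L], , drop = FALSE]
}

#' Find the longest ORF in a transcript
#'
#' Scans for the longest ATG-initiated reading frame, extended to the first
#' in-frame stop codon (TAA/TAG/TGA), or to the last complete in-frame codon
#' when no stop is reached (`has_stop = FALSE`). Ties on length are broken by
#' 5'-most start, then lowest frame index. Codons containing non-ACGT
#' characters are neither start nor stop codons; ORFs may run through them.
#'
#' Gene-model transcripts are sense-strand, so only the forward strand is
#' scanned unless `scan_reverse = TRUE`, in which case both strands are
#' scanned, coordinates are reported on the forward transcript, and `strand`
#' records the orientation (the forward strand wins length ties).
#'
#' @param seq Nucleotide string (non-empty).
#' @param min_len_nt Minimum ORF length in nucleotides, measured start
#'   through stop (stop included when present). Candidates shorter than this
#'   are discarded; if none remain the function returns `NULL`.
#' @param scan_reverse Also scan the reverse complement.
#' @return An `orf_call` (0-based half-open `start`/`end` on the forward
#'   transcript, `frame` on the scanned strand, `has_start`/`has_stop` flags,
#'   translated `protein` without the stop) or `NULL` if no qualifying ORF.
#' @examples
#' find_longest_orf("GGATGAAATAGCC", min_len_nt = 6)
#' @export
find_longest_orf <- function(seq, min_len_nt = 90L, scan_reverse = FALSE) {
  stopifnot(length(seq) == 1L)
  if (is.na(seq) || !nzchar(seq)) {
    stop("cannot scan an empty sequence")
  }
  seq <- toupper(seq)
  n <- nchar(seq)
  cand <- orf_candidates_fwd(seq)
  if (nrow(cand) > 0L) cand$strand <- "+"
  if (scan_reverse) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      chartr("URYSWKMBDHV", "TNNNNNNNNNN", seq))))
    rcand <- orf_candidates_fwd(rc)
    if (nrow(rcand) > 0L) {
      rcand$strand <- "-"
      cand <- rbind(cand, rcand)
    }
  }
  if (nrow(cand) == 0L) return(NULL)
  cand <- cand[cand$end - cand$start >= min_len_nt, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  len <- cand$end - cand$start
  ord <- order(-len, cand$strand != "+", cand$start, cand$frame)
  best <- cand[ord[1L], , drop = FALSE]
  scanned <- if (best$strand == "+") seq else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      chartr("URYSWKMBDHV", "TNNNNNNNNNN", seq))))
  orf_seq <- substr(scanned, best$start + 1L, best$end)
  prot <- translate_dna(orf_seq, 0L)
  if (best$has_stop) prot <- substr(prot, 1L, nchar(prot) - 1L)
  call <- orf_call(
    start = if (best$strand == "+") best$start else n - best$end,
    end = if (best$strand == "+") best$end else n - best$start,
    has_start = TRUE, has_stop = best$has_stop,
    strand = best$strand, frame = best$frame)
  call$protein <- prot
  call
}

#' Default thresholds for completeness classification
#'
#' @param min_upstream_open Minimum length (nt) of an open in-frame region
#'   reaching the transcript 5' end for the heuristic 5'-truncation call.
#' @param repeat_threshold Repeat-coverage fraction above which (strictly) a
#'   transcript is classed as high-copy repeat.
#' @return Named list of thresholds.
#' @export
completeness_params <- function(min_upstream_open = 30L,
                                repeat_threshold = 0.80) {
  list(min_upstream_open = as.integer(min_upstream_open),
       repeat_threshold = repeat_threshold)
}

#' Classify transcript completeness
#'
#' Applies the severity-ordered category scheme: high-copy repeat content
#' (repeat coverage strictly above the threshold) takes precedence over ORF
#' truncation calls, which take precedence over the UTR-presence subclasses.
#' A 3'-truncation is called when the ORF has no stop codon (it runs off the
#' transcript end). A 5'-truncation is called either from evidence (a protein
#' match interval starting strictly upstream of the ORF start) or, when no
#' evidence is supplied, heuristically: the in-frame region upstream of the
#' ORF start reaches the transcript 5' end with no in-frame stop codon and
#' spans at least `params$min_upstream_open` nt. Heuristic calls carry a
#' `putative` attribute. Otherwise the class records which UTRs are present:
#' a 5' UTR iff the ORF starts after position 0, a 3' UTR iff it ends before
#' the transcript end.
#'
#' @param seq The transcript sequence the ORF was derived from.
#' @param orf An [find_longest_orf()] result, or `NULL` (no qualifying ORF).
#' @param protein_evidence Optional matrix/data.frame of 0-based half-open
#'   intervals (`start`, `end`) of protein matches on the transcript.
#' @param repeat_fraction Optional repeat-coverage fraction in \[0, 1\].
#' @param params Thresholds from [completeness_params()].
#' @return A single class label from [completeness_classes()]; heuristic
#'   5'-truncation calls have `attr(, "putative") = TRUE`.
#' @export
classify_completeness <- function(seq, orf, protein_evidence = NULL,
                                  repeat_fraction = NULL,
                                  params = completeness_params()) {
  if (!is.null(repeat_fraction)) {
    if (is.na(repeat_fraction) || repeat_fraction < 0 || repeat_fraction > 1) {
      stop("repeat_fraction must lie in [0, 1]")
    }
    if (is_high_copy_repeat(repeat_fraction, params$repeat_threshold)) {
      return("HIGH_COPY_REPEAT")
    }
  }
  if (is.null(orf)) return("NO_ORF")
  seq <- toupper(seq)
  n <- nchar(seq)
  stopifnot(orf$end <= n, orf$start >= 0L)

  trunc3 <- !orf$has_stop
  putative <- FALSE
  if (!is.null(protein_evidence) && NROW(protein_evidence) > 0L) {
    ev_start <- if (is.data.frame(protein_evidence)) protein_evidence$start
                else protein_evidence[, 1L]
    trunc5 <- any(ev_start < orf$start)
  } else {
    trunc5 <- upstream_open(seq, orf, params$min_upstream_open)
    putative <- trunc5
  }
  cls <- if (trunc5 && trunc3) "TRUNC_BOTH"
    else if (trunc5) "TRUNC_5"
    else if (trunc3) "TRUNC_3"
    else {
      utr5 <- orf$start > 0L
      utr3 <- orf$end < n
      if (utr5 && utr3) "COMPLETE_WITH_UTRS"
      else if (utr5) "COMPLETE_NO_3UTR"
      else if (utr3) "COMPLETE_NO_5UTR"
      else "COMPLETE_NO_UTRS"
    }
  if (putative && cls %in% c("TRUNC_5", "TRUNC_BOTH")) {
    attr(cls, "putative") <- TRUE
  }
  cls
}

# TRUE when the in-frame region upstream of the ORF start reaches the
# transcript 5' end with no in-frame stop codon and spans >= min_open nt.
upstream_open <- function(seq, orf, min_open) {
  if (orf$strand == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      chartr("URYSWKMBDHV", "TNNNNNNNNNN", toupper(seq)))))
    orf <- list(start = nchar(seq) - orf$end)  # start on the scanned strand
  }
  if (orf$start < min_open) return(FALSE)
  lead <- orf$start %% 3L  # incomplete leading bases, ignored
  starts1 <- seq.int(lead + 1L, by = 3L,
                     length.out = (orf$start - lead) %/% 3L)
  if (length(starts1) == 0L) return(orf$start >= min_open)
  codons <- substring(seq, starts1, starts1 + 2L)
  !any(codons %in% STOP_CODONS)
}

#' Scan and classify a set of transcripts
#'
#' Convenience pipeline over [find_longest_orf()], [repeat_coverage()] and
#' [classify_completeness()] for a table of sequence records.
#'
#' @param records Tibble from [read_fasta()] (columns `id`, `seq`).
#' @param repeat_lib Optional repeat library as a tibble of records; when
#'   supplied, repeat coverage is computed per transcript.
#' @param evidence Optional tibble of protein-evidence intervals with columns
#'   `transcript_id`, `ev_start`, `ev_end` (0-based half-open).
#' @param min_len_nt Minimum ORF length passed to [find_longest_orf()].
#' @param params Classification thresholds.
#' @return Tibble with columns `id`, `class`, `putative`, `orf_start`,
#'   `orf_end`, `has_stop`, `repeat_fraction`.
#' @export
scan_transcripts <- function(records, repeat_lib = NULL, evidence = NULL,
                             min_len_nt = 90L,
                             params = completeness_params()) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    seq <- records$seq[i]
    rf <- if (is.null(repeat_lib)) NULL else
      repeat_coverage(seq, repeat_lib)$fraction
    orf <- find_longest_orf(seq, min_len_nt = min_len_nt)
    ev <- NULL
    if (!is.null(evidence)) {
      sel <- evidence[evidence$transcript_id == records$id[i], , drop = FALSE]
      if (nrow(sel) > 0L) {
        ev <- data.frame(start = sel$ev_start, end = sel$ev_end)
      }
    }
    cls <- classify_completeness(seq, orf, protein_evidence = ev,
                                 repeat_fraction = rf, params = params)
    tibble::tibble(
      id = records$id[i],
      class = as.character(cls),
      putative = isTRUE(attr(cls, "putative")),
      orf_start = if (is.null(orf)) NA_integer_ else orf$start,
      orf_end = if (is.null(orf)) NA_integer_ else orf$end,
      has_stop = if (is.null(orf)) NA else orf$has_stop,
      repeat_fraction = if (is.null(rf)) NA_real_ else rf)
  })
  dplyr::bind_rows(rows)
}
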