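#' @importFrom Biostrings pairwiseAlignment pattern subject nmatch score
#' @importFrom IRanges IRanges reduce start end width
NULL

# Substitution matrix over A/C/G/T/N: match +1, mismatch -2. N never matches
# anything (including N), so N-masked regions cannot seed or extend hits.
acgtn_matrix <- function(match = 1, mismatch = -2) {
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(mismatch, 5L, 5L, dimnames = list(letters, letters))
  diag(mat)[1:4] <- match
  mat
}

# Collapse every non-ACGT character (IUPAC ambiguity, U) to N for alignment.
to_acgtn <- function(seq) {
  chartr("URYSWKMBDHV", "NNNNNNNNNNN", toupper(seq))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(seq))))
}

#' Default alignment scoring for clone QC
#'
#' @return Named list: `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @export
align_scoring <- function() {
  list(match = 1, mismatch = -2, gap_open = -5, gap_extend = -1)
}

# Optimal local affine-gap alignment of (oriented) query vs target with
# block/indel recovery from the aligned strings. Coordinates are 0-based
# half-open; q coordinates refer to the oriented query as supplied.
local_align <- function(qseq, tseq, scoring = align_scoring()) {
  aln <- pairwiseAlignment(
    to_acgtn(qseq), to_acgtn(tseq), type = "local",
    substitutionMatrix = acgtn_matrix(scoring$match, scoring$mismatch),
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
  p <- strsplit(as.character(pattern(aln)), "", fixed = TRUE)[[1L]]
  s <- strsplit(as.character(subject(aln)), "", fixed = TRUE)[[1L]]
  ncol <- length(p)
  if (ncol == 0L) {
    return(list(score = score(aln), identity = 0, ncol = 0L,
                blocks = empty_blocks(), indels = empty_indels(),
                q_start = 0L, q_end = 0L, t_start = 0L, t_end = 0L))
  }
  state <- ifelse(p == "-", "D", ifelse(s == "-", "I", "M"))
  runs <- rle(state)
  q <- start(pattern(aln)) - 1L   # 0-based cursors
  t <- start(subject(aln)) - 1L
  q0 <- q
  t0 <- t
  blocks <- list()
  indels <- list()
  col <- 1L
  n_match <- 0L
  for (k in seq_along(runs$lengths)) {
    len <- runs$lengths[k]
    cols <- col:(col + len - 1L)
    if (runs$values[k] == "M") {
      n_match <- n_match + sum(p[cols] == s[cols])
      blocks[[length(blocks) + 1L]] <- data.frame(
        q_start = q, q_end = q + len, t_start = t, t_end = t + len)
      q <- q + len
      t <- t + len
    } else if (runs$values[k] == "I") {   # insertion in query
      indels[[length(indels) + 1L]] <- data.frame(
        q_pos = q, t_pos = t, length = len, kind = "insertion_in_query",
        inserted = paste(p[cols], collapse = ""))
      q <- q + len
    } else {                              # deletion from query
      indels[[length(indels) + 1L]] <- data.frame(
        q_pos = q, t_pos = t, length = len, kind = "deletion_from_query",
        inserted = NA_character_)
      t <- t + len
    }
    col <- col + len
  }
  list(score = score(aln),
       identity = n_match / ncol,
       ncol = ncol,
       blocks = do.call(rbind, blocks),
       indels = if (length(indels) > 0L) do.call(rbind, indels) else empty_indels(),
       q_start = q0, q_end = q, t_start = t0, t_end = t)
}

empty_blocks <- function() {
  data.frame(q_start = integer(), q_end = integer(),
             t_start = integer(), t_end = integer())
}
empty_indels <- function() {
  data.frame(q_pos = integer(), t_pos = integer(), length = integer(),
             kind = character(), inserted = character())
}

#' Align a cDNA clone sequence to a reference contig
#'
#' Optimal local affine-gap alignment, both orientations tried and the best
#' strand kept. Gapless blocks and indels are recovered from the traceback.
#' Query coordinates on the minus strand refer to the reverse-complemented
#' query; target coordinates always refer to the contig as supplied.
#'
#' @param cdna A record (list or one-row data.frame with `id`, `seq`) or a
#'   plain sequence string.
#' @param contig A contig reference: list with `id`, `seq` and optionally
#'   `orf_start`/`orf_end` (0-based half-open; `NULL`/`NA` when non-coding).
#' @param scoring Scoring scheme, see [align_scoring()].
#' @param max_n_frac Refuse alignment (error) when the query exceeds this
#'   fraction of N; such clones are pre-classified `?` by [classify_clone()].
#' @return A `pairwise_alignment`: list with `q_id`, `t_id`, `strand`,
#'   `score`, `identity` (matches over aligned columns), `q_cov`/`t_cov`,
#'   `blocks`, `indels`, and 0-based half-open aligned spans `q_start`,
#'   `q_end`, `t_start`, `t_end`.
#' @export
align_to_contig <- function(cdna, contig, scoring = align_scoring(),
                            max_n_frac = 0.5) {
  q_id <- NA_character_
  qseq <- cdna
  if (is.list(cdna) || is.data.frame(cdna)) {
    q_id <- as.character(cdna$id[[1L]])
    qseq <- as.character(cdna$seq[[1L]])
  }
  tseq <- as.character(contig$seq[[1L]])
  if (!nzchar(qseq) || !nzchar(tseq)) stop("cannot align an empty sequence")
  if (n_fraction(qseq) > max_n_frac) {
    stop("alignment refused: query is more than ", round(100 * max_n_frac),
         "% N")
  }
  fwd <- local_align(qseq, tseq, scoring)
  rev <- local_align(revcomp(to_acgtn(qseq)), tseq, scoring)
  best <- if (rev$score > fwd$score) rev else fwd
  strand <- if (rev$score > fwd$score) "-" else "+"
  structure(
    list(q_id = q_id, t_id = as.character(contig$id[[1L]]), strand = strand,
         score = best$score, identity = best$identity,
         q_cov = (best$q_end - best$q_start) / nchar(qseq),
         t_cov = (best$t_end - best$t_start) / nchar(tseq),
         q_len = nchar(qseq), t_len = nchar(tseq),
         blocks = best$blocks, indels = best$indels,
         q_start = best$q_start, q_end = best$q_end,
         t_start = best$t_start, t_end = best$t_end),
    class = "pairwise_alignment")
}

n_fraction <- function(seq) {
  if (!nzchar(seq)) return(1)
  lengths(regmatches(seq, gregexpr("N", to_acgtn(seq)))) / nchar(seq)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "%s vs %s (%s): score %.0f, identity %.3f, q[%d,%d) t[%d,%d), %d indel(s)\n",
    x$q_id, x$t_id, x$strand, x$score, x$identity,
    x$q_start, x$q_end, x$t_start, x$t_end, nrow(x$indels)))
  invisible(x)
}
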