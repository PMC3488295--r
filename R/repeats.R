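#' Default parameters for repeat-coverage scanning
#'
#' @param min_identity Minimum identity (over aligned columns) for a hit.
#' @param min_hit_len Minimum transcript span (nt) of a hit.
#' @return Named list of parameters.
#' @export
repeat_params <- function(min_identity = 0.80, min_hit_len = 50L) {
  list(min_identity = min_identity, min_hit_len = as.integer(min_hit_len))
}

#' Fraction of a transcript covered by repeat-library matches
#'
#' Collects local alignments between the transcript and every library entry
#' (both strands) passing the identity and length cutoffs, merges overlapping
#' transcript intervals, and reports merged covered bases over transcript
#' length. Multiple hits per library entry are recovered by iteratively
#' masking each best hit (with N, which matches nothing) and re-aligning, so
#' tandem or dispersed repeat copies are all counted. Coverage is invariant
#' to library order and to duplicated library entries.
#'
#' @param seq Transcript sequence (non-empty).
#' @param repeat_lib Repeat library as a tibble of records (`id`, `seq`),
#'   possibly empty.
#' @param params See [repeat_params()].
#' @param max_hits_per_entry Safety cap on the masking iteration.
#' @return List with `fraction` (merged coverage in \[0, 1\]) and `hits`
#'   (tibble: `q_start`, `q_end` 0-based half-open on the transcript,
#'   `library_id`, `strand`, `identity`).
#' @export
repeat_coverage <- function(seq, repeat_lib, params = repeat_params(),
                            max_hits_per_entry = 64L) {
  stopifnot(length(seq) == 1L)
  if (is.na(seq) || !nzchar(seq)) stop("cannot scan an empty sequence")
  seq <- toupper(seq)
  hits <- list()
  if (!is.null(repeat_lib) && nrow(repeat_lib) > 0L) {
    for (i in seq_len(nrow(repeat_lib))) {
      for (strand in c("+", "-")) {
        lib_seq <- repeat_lib$seq[i]
        if (!nzchar(lib_seq)) next
        if (strand == "-") lib_seq <- revcomp(to_acgtn(lib_seq))
        masked <- seq
        for (iter in seq_len(max_hits_per_entry)) {
          aln <- local_align(masked, lib_seq)
          span <- aln$q_end - aln$q_start
          if (aln$score <= 0 || span < params$min_hit_len ||
              aln$identity < params$min_identity) {
            break
          }
          hits[[length(hits) + 1L]] <- tibble::tibble(
            q_start = aln$q_start, q_end = aln$q_end,
            library_id = repeat_lib$id[i], strand = strand,
            identity = aln$identity)
          substr(masked, aln$q_start + 1L, aln$q_end) <-
            strrep("N", span)
        }
      }
    }
  }
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0L) {
    return(list(fraction = 0,
                hits = tibble::tibble(q_start = integer(), q_end = integer(),
                                      library_id = character(),
                                      strand = character(),
                                      identity = double())))
  }
  merged <- IRanges::reduce(IRanges::IRanges(start = hits$q_start + 1L,
                                             end = hits$q_end))
  list(fraction = sum(IRanges::width(merged)) / nchar(seq), hits = hits)
}

#' Apply the high-copy-repeat coverage rule
#'
#' A transcript is flagged as high-copy repeat content when strictly more
#' than `threshold` of its length is covered by repeat matches; such
#' transcripts are treated as probably not from true protein-coding genes.
#'
#' @param fraction Coverage fraction in \[0, 1\].
#' @param threshold Coverage threshold (strict inequality).
#' @return Logical flag.
#' @examples
#' is_high_copy_repeat(0.81)  # TRUE
#' is_high_copy_repeat(0.80)  # FALSE: the rule is strictly "more than"
#' @export
is_high_copy_repeat <- function(fraction, threshold = 0.80) {
  if (any(is.na(fraction)) || any(fraction < 0) || any(fraction > 1)) {
    stop("coverage fraction must lie in [0, 1]")
  }
  fraction > threshold
}
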