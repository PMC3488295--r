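#' Contiguous non-gap sections of a scaffold
#'
#' Gaps within assembly scaffolds are represented as runs of N between
#' sections of real sequence. A run of at least `min_gap_run` N's counts as a
#' gap; shorter N runs are treated as ordinary ambiguous bases inside a
#' section, since real assemblies contain isolated ambiguity calls that are
#' not structural gaps.
#'
#' @param seq Scaffold sequence (non-empty).
#' @param min_gap_run Minimum N-run length that constitutes a gap.
#' @return Data.frame of 0-based half-open `start`/`end` section intervals
#'   (zero rows for an all-gap scaffold).
#' @export
scaffold_sections <- function(seq, min_gap_run = 10L) {
  stopifnot(length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  n <- nchar(seq)
  runs <- gregexpr(sprintf("N{%d,}", as.integer(min_gap_run)), seq)[[1L]]
  if (runs[1L] == -1L) {
    return(data.frame(start = 0L, end = n))
  }
  gap_start <- as.integer(runs) - 1L
  gap_end <- gap_start + attr(runs, "match.length")
  sec_start <- c(0L, gap_end)
  sec_end <- c(gap_start, n)
  keep <- sec_end > sec_start
  data.frame(start = sec_start[keep], end = sec_end[keep])
}

#' Gap statistics for an assembly
#'
#' Aggregates section and gap tallies across scaffolds. `assembled_bases`
#' counts every base inside sections (including sub-threshold N runs);
#' `gap_bases` counts only bases inside qualifying N runs, so the two always
#' sum to the total residue count.
#'
#' @param scaffolds Tibble of scaffold records (`id`, `seq`).
#' @param min_gap_run Minimum N-run length that constitutes a gap.
#' @return List of class `gap_stats`: `n_scaffolds`, `n_sections`,
#'   `assembled_bases`, `gap_bases`, `mean_section_len`.
#' @export
compute_gap_stats <- function(scaffolds, min_gap_run = 10L) {
  stopifnot(is.data.frame(scaffolds))
  if (nrow(scaffolds) == 0L) stop("no scaffolds supplied")
  n_sections <- 0L
  assembled <- 0
  total <- 0
  for (i in seq_len(nrow(scaffolds))) {
    sec <- scaffold_sections(scaffolds$seq[i], min_gap_run)
    n_sections <- n_sections + nrow(sec)
    assembled <- assembled + sum(sec$end - sec$start)
    total <- total + nchar(scaffolds$seq[i])
  }
  structure(
    list(n_scaffolds = nrow(scaffolds),
         n_sections = n_sections,
         assembled_bases = assembled,
         gap_bases = total - assembled,
         mean_section_len = if (n_sections > 0L) assembled / n_sections
                            else NA_real_),
    class = "gap_stats")
}

#' @export
print.gap_stats <- function(x, ...) {
  cat(sprintf(
    "%d scaffold(s), %d section(s); %s assembled + %s gap bases; mean section %.1f nt\n",
    x$n_scaffolds, x$n_sections, format(x$assembled_bases, big.mark = ","),
    format(x$gap_bases, big.mark = ","), x$mean_section_len))
  invisible(x)
}

#' Mean distance between scaffold gaps, in kb
#'
#' The average length of a contiguous section — equivalently the mean
#' distance between gaps within scaffolds — from the assembled-base total and
#' the section count, reported to one decimal in kb.
#'
#' @param assembled_bases Total assembled (non-gap) bases.
#' @param n_sections Number of contiguous sections (at least 1).
#' @return Mean section length in kb, rounded to one decimal.
#' @examples
#' mean_intergap_kb(1.5e9, 175000)  # 8.6
#' @export
mean_intergap_kb <- function(assembled_bases, n_sections) {
  if (length(n_sections) != 1L || is.na(n_sections) || n_sections < 1L) {
    stop("n_sections must be a positive count")
  }
  round(assembled_bases / n_sections / 1000, 1L)
}
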