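#' Default thresholds for clone QC classification
#'
#' The code set and the evidence axes (extent vs the contig ORF, frameshift,
#' divergence, chimerism, retained introns) are fixed; these operational
#' thresholds are surfaced so every call can be audited via its rationale.
#'
#' @param chimera_seg Minimum length (nt) of each of the two disjoint query
#'   segments for a chimera call.
#' @param chimera_identity Minimum identity of each chimera segment.
#' @param chimera_max_overlap Maximum overlap (nt) tolerated between the two
#'   segments' query spans.
#' @param min_intron Minimum query-insertion length (nt) for a retained
#'   intron (immature/mis-spliced) call; the inserted sequence must begin GT
#'   and end AG.
#' @param min_short_del Minimum in-frame deletion (nt) inside the ORF for an
#'   odd-short-form call.
#' @param fl_identity Identity at or above which a full-ORF clone is called
#'   full-length rather than possibly-full-length.
#' @param min_orf_nt ORF length below which the best contig is treated as
#'   probably non-coding.
#' @param max_n_frac Query N fraction above which no alignment is attempted.
#' @return Named list of thresholds.
#' @export
clone_qc_params <- function(chimera_seg = 100L, chimera_identity = 0.95,
                            chimera_max_overlap = 30L, min_intron = 60L,
                            min_short_del = 60L, fl_identity = 0.97,
                            min_orf_nt = 90L, max_n_frac = 0.5) {
  list(chimera_seg = as.integer(chimera_seg),
       chimera_identity = chimera_identity,
       chimera_max_overlap = as.integer(chimera_max_overlap),
       min_intron = as.integer(min_intron),
       min_short_del = as.integer(min_short_del),
       fl_identity = fl_identity,
       min_orf_nt = as.integer(min_orf_nt),
       max_n_frac = max_n_frac)
}

#' Detect frameshift indels within a contig ORF
#'
#' An indel causes a frameshift when its length is not divisible by 3 and it
#' falls inside the coding region of the reference contig.
#'
#' @param aln A [align_to_contig()] result.
#' @param orf Numeric vector `c(orf_start, orf_end)` (0-based half-open) on
#'   the contig, or `NULL` for a non-coding contig (returns no frameshifts).
#' @return The subset of `aln$indels` that shift the frame.
#' @export
detect_frameshifts <- function(aln, orf) {
  if (is.null(orf) || any(is.na(orf))) return(empty_indels())
  ind <- aln$indels
  if (nrow(ind) == 0L) return(ind)
  ind[ind$t_pos >= orf[1L] & ind$t_pos < orf[2L] & ind$length %% 3L != 0L, ,
      drop = FALSE]
}

contig_orf <- function(contig) {
  os <- contig$orf_start
  oe <- contig$orf_end
  if (is.null(os) || is.null(oe) || is.na(os) || is.na(oe)) return(NULL)
  c(as.integer(os), as.integer(oe))
}

# Map a query span to forward-clone coordinates (minus-strand alignments
# report q coordinates on the reverse-complemented query).
fwd_q_span <- function(aln) {
  if (aln$strand == "+") c(aln$q_start, aln$q_end)
  else c(aln$q_len - aln$q_end, aln$q_len - aln$q_start)
}

#' Classify a full-insert cDNA clone against reference contigs
#'
#' Aligns the clone to every candidate contig and applies the code set in
#' fixed decreasing precedence: `?` (no usable sequence) over `CHI` (two
#' mostly disjoint clone segments aligning best to different contigs) over
#' `FLx` (best contig non-coding) over `IMM` (retained-intron-like insertion
#' bounded by GT...AG) over `FS` (frameshifting indel inside the ORF) over
#' `FLsh` (large in-frame deletion inside a fully covered ORF) over `FLt5` /
#' `FLt3` (alignment misses the ORF 5' / 3' end; a clone truncated at both
#' ends reports `FLt5`, the more damaging defect for start-codon-anchored
#' applications) over `FLq` (ORF covered but identity below the full-length
#' band) over `FL`. Precedence is total, so permuting candidates never
#' changes the call.
#'
#' @param cdna A record (list/one-row data.frame with `id`, `seq`).
#' @param candidates A data.frame of contig references (columns `id`, `seq`,
#'   `orf_start`, `orf_end`; `NA` ORF = non-coding), or a list of such
#'   references. Must be non-empty.
#' @param params Thresholds from [clone_qc_params()].
#' @return List with `value` (one code from [clone_qc_codes()]), `rationale`
#'   (free text naming the triggering evidence), `best_contig`.
#' @export
classify_clone <- function(cdna, candidates, params = clone_qc_params()) {
  cand <- as_contig_list(candidates)
  if (length(cand) == 0L) stop("no candidate contigs supplied")
  qseq <- as.character(cdna$seq[[1L]])
  q_id <- as.character(cdna$id[[1L]])

  if (!nzchar(qseq) || n_fraction(qseq) > params$max_n_frac) {
    return(qc_code("?", sprintf(
      "no usable sequence (%s)",
      if (!nzchar(qseq)) "empty" else
        sprintf("%.0f%% N", 100 * n_fraction(qseq))), NA_character_))
  }

  alns <- lapply(cand, function(ct)
    align_to_contig(cdna, ct, max_n_frac = params$max_n_frac))
  scores <- vapply(alns, function(a) a$score, numeric(1L))
  best_i <- order(-scores, vapply(cand, function(ct) ct$id, character(1L)))[1L]
  best <- alns[[best_i]]
  best_ct <- cand[[best_i]]

  # chimera: a second contig explains a mostly disjoint part of the clone
  strong <- which(vapply(alns, function(a) {
    a$identity >= params$chimera_identity &&
      (a$q_end - a$q_start) >= params$chimera_seg
  }, logical(1L)))
  strong <- strong[order(-scores[strong])]
  if (length(strong) >= 2L) {
    s1 <- fwd_q_span(alns[[strong[1L]]])
    for (j in strong[-1L]) {
      if (alns[[j]]$t_id == alns[[strong[1L]]]$t_id) next
      s2 <- fwd_q_span(alns[[j]])
      overlap <- max(0L, min(s1[2L], s2[2L]) - max(s1[1L], s2[1L]))
      if (overlap <= params$chimera_max_overlap) {
        return(qc_code("CHI", sprintf(
          "segments [%d,%d) -> %s and [%d,%d) -> %s align to different contigs",
          s1[1L], s1[2L], alns[[strong[1L]]]$t_id,
          s2[1L], s2[2L], alns[[j]]$t_id), best_ct$id))
      }
    }
  }

  orf <- contig_orf(best_ct)
  if (is.null(orf) || (orf[2L] - orf[1L]) < params$min_orf_nt) {
    return(qc_code("FLx", sprintf(
      "best contig %s is %s", best_ct$id,
      if (is.null(orf)) "non-coding (no annotated ORF)"
      else sprintf("near non-coding (ORF %d nt < %d)",
                   orf[2L] - orf[1L], params$min_orf_nt)), best_ct$id))
  }

  ins <- best$indels[best$indels$kind == "insertion_in_query", , drop = FALSE]
  if (nrow(ins) > 0L) {
    retained <- ins[ins$length >= params$min_intron &
                      startsWith(ins$inserted, "GT") &
                      endsWith(ins$inserted, "AG"), , drop = FALSE]
    if (nrow(retained) > 0L) {
      return(qc_code("IMM", sprintf(
        "%d nt GT...AG insertion at contig position %d (retained intron)",
        retained$length[1L], retained$t_pos[1L]), best_ct$id))
    }
  }

  fs <- detect_frameshifts(best, orf)
  if (nrow(fs) > 0L) {
    return(qc_code("FS", sprintf(
      "%d nt %s at contig position %d shifts the reading frame",
      fs$length[1L], gsub("_", " ", fs$kind[1L]), fs$t_pos[1L]), best_ct$id))
  }

  orf_covered <- best$t_start <= orf[1L] && best$t_end >= orf[2L]
  if (orf_covered) {
    del <- best$indels[best$indels$kind == "deletion_from_query" &
                         best$indels$length %% 3L == 0L &
                         best$indels$length >= params$min_short_del &
                         best$indels$t_pos >= orf[1L] &
                         best$indels$t_pos < orf[2L], , drop = FALSE]
    if (nrow(del) > 0L) {
      return(qc_code("FLsh", sprintf(
        "in-frame %d nt deletion inside the ORF at contig position %d",
        del$length[1L], del$t_pos[1L]), best_ct$id))
    }
  }
  if (best$t_start > orf[1L]) {
    return(qc_code("FLt5", sprintf(
      "alignment starts at contig position %d, downstream of the ORF start %d",
      best$t_start, orf[1L]), best_ct$id))
  }
  if (best$t_end < orf[2L]) {
    return(qc_code("FLt3", sprintf(
      "alignment ends at contig position %d, upstream of the ORF end %d",
      best$t_end, orf[2L]), best_ct$id))
  }
  if (best$identity < params$fl_identity) {
    return(qc_code("FLq", sprintf(
      "ORF covered but identity %.3f below the full-length band (%.2f)",
      best$identity, params$fl_identity), best_ct$id))
  }
  qc_code("FL", sprintf(
    "ORF fully covered at identity %.3f with no defect", best$identity),
    best_ct$id)
}

qc_code <- function(value, rationale, best_contig) {
  structure(list(value = value, rationale = rationale,
                 best_contig = best_contig),
            class = "clone_qc_code")
}

#' @export
print.clone_qc_code <- function(x, ...) {
  cat(sprintf("%-4s %s\n", x$value, x$rationale))
  invisible(x)
}

as_contig_list <- function(candidates) {
  if (is.data.frame(candidates)) {
    lapply(seq_len(nrow(candidates)), function(i) {
      list(id = candidates$id[i], seq = candidates$seq[i],
           orf_start = if ("orf_start" %in% names(candidates))
             candidates$orf_start[i] else NA,
           orf_end = if ("orf_end" %in% names(candidates))
             candidates$orf_end[i] else NA)
    })
  } else {
    candidates
  }
}

#' Classify a table of clones against reference contigs
#'
#' @param clones Tibble of clone records (`id`, `seq`).
#' @param contigs Tibble of contig sequences (`id`, `seq`).
#' @param orfs Tibble with columns `contig_id`, `orf_start`, `orf_end`
#'   (0-based half-open); contigs absent from it are treated as non-coding.
#' @param params Thresholds from [clone_qc_params()].
#' @return Tibble with columns `clone_id`, `code`, `rationale`,
#'   `best_contig`.
#' @export
classify_clones <- function(clones, contigs, orfs = NULL,
                            params = clone_qc_params()) {
  cand <- merge_contig_orfs(contigs, orfs)
  rows <- lapply(seq_len(nrow(clones)), function(i) {
    call <- classify_clone(clones[i, ], cand, params)
    tibble::tibble(clone_id = clones$id[i], code = call$value,
                   rationale = call$rationale,
                   best_contig = call$best_contig)
  })
  dplyr::bind_rows(rows)
}

merge_contig_orfs <- function(contigs, orfs) {
  out <- tibble::tibble(id = contigs$id, seq = contigs$seq,
                        orf_start = NA_integer_, orf_end = NA_integer_)
  if (!is.null(orfs) && nrow(orfs) > 0L) {
    m <- match(out$id, orfs$contig_id)
    out$orf_start <- as.integer(orfs$orf_start[m])
    out$orf_end <- as.integer(orfs$orf_end[m])
  }
  out
}

#' Tally clone QC codes for a clone set
#'
#' @param codes Data.frame with columns `clone_id` (or `id`) and `code`, or
#'   a named character vector.
#' @param set_name Label for the clone set.
#' @return A `category_tally` over [clone_qc_codes()].
#' @export
qc_summary <- function(codes, set_name = "") {
  if (is.data.frame(codes)) {
    idcol <- if ("clone_id" %in% names(codes)) "clone_id" else "id"
    codes <- stats::setNames(as.character(codes$code),
                             as.character(codes[[idcol]]))
  }
  tally_classes(codes, label = set_name, levels = clone_qc_codes())
}
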