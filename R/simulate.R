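#' @importFrom withr with_seed
NULL

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# Random DNA guaranteed to contain no ATG: occurrences are rewritten
# A(C)G, which cannot create a new ATG (no T is introduced).
random_dna_no_atg <- function(n) {
  s <- random_dna(n)
  while (grepl("ATG", s, fixed = TRUE)) {
    p <- regexpr("ATG", s, fixed = TRUE)
    substr(s, p + 1L, p + 1L) <- "C"
  }
  s
}

NONSTOP_CODONS <- setdiff(
  apply(expand.grid(BASES, BASES, BASES), 1L, paste, collapse = ""),
  STOP_CODONS)

random_codons <- function(n, exclude_atg = FALSE) {
  pool <- if (exclude_atg) setdiff(NONSTOP_CODONS, "ATG") else NONSTOP_CODONS
  if (n <= 0L) return("")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# A 5' UTR of length n with no ATG and, when room allows, a stop codon
# placed in frame with the downstream ORF, so a genuinely complete
# transcript is never mistaken for a 5'-truncated one by the
# open-upstream heuristic.
make_utr5 <- function(n) {
  if (n < 3L) return(random_dna_no_atg(n))
  s <- random_dna_no_atg(n)
  pos <- n %% 3L  # 0-based start of the first full codon in ORF frame
  substr(s, pos + 1L, pos + 3L) <- "TAA"
  s
}

#' Generate labelled synthetic transcripts
#'
#' Builds transcripts with a designed 5' UTR / ORF / 3' UTR structure and an
#' optional engineered defect, together with the true completeness class of
#' each. Rejection sampling against a brute-force ORF enumeration guarantees
#' the designed ORF is the unique longest one, so the truth labels are exact
#' by construction. Deterministic for a given `seed`.
#'
#' Supported defects and their truth labels:
#' \describe{
#'   \item{none}{intact transcript, `COMPLETE_WITH_UTRS`}
#'   \item{drop_5utr / drop_3utr / drop_both}{UTR(s) removed,
#'     `COMPLETE_NO_5UTR` / `COMPLETE_NO_3UTR` / `COMPLETE_NO_UTRS`}
#'   \item{truncate_5}{5' UTR and the ORF start lost; an internal in-frame
#'     ATG at least `defect_arg` nt (default 30) into the remaining open
#'     region becomes the apparent start, `TRUNC_5`}
#'   \item{truncate_3_remove_stop}{3' UTR and stop codon lost, `TRUNC_3`}
#'   \item{frameshift}{1-nt deletion at codon `defect_arg` (default mid-ORF);
#'     the shifted frame soon meets a stop, so the transcript presents a
#'     shorter but complete ORF — transcript-level scanning cannot see
#'     frameshifts, `COMPLETE_WITH_UTRS`}
#'   \item{repeat_fill}{fraction `defect_arg` (default 0.9, must exceed 0.85)
#'     of the transcript taken from a repeat element, `HIGH_COPY_REPEAT`}
#'   \item{no_orf}{ATG-free sequence, `NO_ORF`}
#' }
#'
#' @param specs Tibble with columns `id`, `utr5_len`, `orf_codons` (total
#'   codons including start and stop, at least 2), `utr3_len`, `defect`, and
#'   optionally `defect_arg`.
#' @param seed Integer seed; same seed, same output.
#' @param min_len_nt The ORF-length floor the downstream scanner will use
#'   (the designed ORF is kept comfortably above it).
#' @return List with `records` (tibble `id`, `desc`, `seq`), `truth` (tibble
#'   `id`, `class`, `defect`) and `repeat_lib` (tibble of the repeat record
#'   used by `repeat_fill`, empty if unused).
#' @export
make_transcripts <- function(specs, seed = 1L, min_len_nt = 90L) {
  stopifnot(is.data.frame(specs),
            all(c("id", "utr5_len", "orf_codons", "utr3_len", "defect")
                %in% names(specs)))
  if (anyDuplicated(specs$id) > 0L) stop("duplicate transcript spec ids")
  withr::with_seed(as.integer(seed), {
    repeat_unit <- random_dna(400L)
    rows <- lapply(seq_len(nrow(specs)), function(i) {
      make_one_transcript(specs[i, ], repeat_unit, min_len_nt)
    })
    records <- dplyr::bind_rows(lapply(rows, function(r) r$record))
    truth <- dplyr::bind_rows(lapply(rows, function(r) r$truth))
    list(records = records, truth = truth,
         repeat_lib = tibble::tibble(id = "rep_unit", desc = NA_character_,
                                     seq = repeat_unit))
  })
}

make_one_transcript <- function(sp, repeat_unit, min_len_nt) {
  defect <- as.character(sp$defect)
  arg <- if ("defect_arg" %in% names(sp)) sp$defect_arg else NA_real_
  u5 <- as.integer(sp$utr5_len)
  u3 <- as.integer(sp$utr3_len)
  nc <- as.integer(sp$orf_codons)
  if (nc < 2L) stop("orf_codons must be at least 2 (spec ", sp$id, ")")
  if (3L * nc < min_len_nt + 6L && !(defect %in% c("no_orf", "repeat_fill"))) {
    stop("designed ORF too short relative to the scanner floor (spec ",
         sp$id, ")")
  }

  build <- function() {
    switch(defect,
      none = ,
      drop_5utr = ,
      drop_3utr = ,
      drop_both = build_intact(u5, nc, u3, defect),
      truncate_5 = build_trunc5(u5, nc, u3,
                                if (is.na(arg)) 30L else as.integer(arg)),
      truncate_3_remove_stop = build_trunc3(u5, nc),
      frameshift = build_frameshift(u5, nc, u3,
                                    if (is.na(arg)) nc %/% 2L
                                    else as.integer(arg), min_len_nt),
      repeat_fill = build_repeat(u5, nc, u3, repeat_unit,
                                 if (is.na(arg)) 0.9 else arg),
      no_orf = build_no_orf(u5, nc, u3),
      stop("unknown defect: ", defect)
    )
  }
  for (attempt in 1:200) {
    cand <- build()
    if (accept_transcript(cand, min_len_nt)) {
      return(list(
        record = tibble::tibble(id = as.character(sp$id),
                                desc = paste("synthetic", defect),
                                seq = cand$seq),
        truth = tibble::tibble(id = as.character(sp$id), class = cand$class,
                               defect = defect)))
    }
  }
  stop("could not realise transcript spec '", sp$id,
       "' (defect ", defect, ") after 200 attempts")
}

# The designed structure must be what a scanner will see: the expected ORF
# is the unique winner by (length, 5'-most, frame) among all brute-force
# candidates. Checked with the slow enumerator, not the production scanner.
accept_transcript <- function(cand, min_len_nt) {
  if (isTRUE(cand$skip_orf_check)) return(TRUE)
  all_orfs <- orf_enumerate_slow(cand$seq)
  all_orfs <- all_orfs[all_orfs$end - all_orfs$start >= min_len_nt, ,
                       drop = FALSE]
  if (is.null(cand$exp_start)) {        # no qualifying ORF expected
    return(nrow(all_orfs) == 0L)
  }
  if (nrow(all_orfs) == 0L) return(FALSE)
  best <- pick_best_orf(all_orfs)
  ok <- best$start == cand$exp_start && best$end == cand$exp_end
  if (!ok) return(FALSE)
  # and the winner must be strictly longest (no length ties)
  len <- all_orfs$end - all_orfs$start
  sum(len == max(len)) == 1L
}

build_intact <- function(u5, nc, u3, defect) {
  if (defect %in% c("drop_5utr", "drop_both")) u5 <- 0L
  if (defect %in% c("drop_3utr", "drop_both")) u3 <- 0L
  if (defect == "none" && (u5 == 0L || u3 == 0L)) {
    stop("defect 'none' requires both UTRs to be non-empty")
  }
  orf <- paste0("ATG", random_codons(nc - 2L), sample(STOP_CODONS, 1L))
  seq <- paste0(make_utr5(u5), orf, random_dna_no_atg(u3))
  cls <- if (u5 > 0L && u3 > 0L) "COMPLETE_WITH_UTRS"
    else if (u5 > 0L) "COMPLETE_NO_3UTR"
    else if (u3 > 0L) "COMPLETE_NO_5UTR"
    else "COMPLETE_NO_UTRS"
  list(seq = seq, class = cls, exp_start = u5, exp_end = u5 + 3L * nc)
}

build_trunc5 <- function(u5, nc, u3, min_upstream) {
  # internal ATG at codon j; everything upstream of codon 2 is cut away,
  # leaving >= min_upstream nt of open in-frame sequence before the ATG
  j <- 2L + ceiling(min_upstream / 3L) + sample(0:3, 1L)
  if (nc - j < 20L) stop("truncate_5 needs a longer ORF (orf_codons >= ",
                         j + 20L, ")")
  body <- random_codons(j - 2L, exclude_atg = TRUE)        # codons 2..j-1
  rest <- random_codons(nc - 1L - j)                        # j+1..nc-1
  seq <- paste0(body, "ATG", rest, sample(STOP_CODONS, 1L),
                random_dna_no_atg(u3))
  exp_start <- 3L * (j - 2L)
  exp_end <- exp_start + 3L * (nc - j + 1L)
  list(seq = seq, class = "TRUNC_5", exp_start = exp_start, exp_end = exp_end)
}

build_trunc3 <- function(u5, nc) {
  seq <- paste0(make_utr5(u5), "ATG", random_codons(nc - 2L))
  list(seq = seq, class = "TRUNC_3", exp_start = u5,
       exp_end = u5 + 3L * (nc - 1L))
}

# Delete one base mid-ORF of an intact transcript. Reading in the start
# codon's frame, the sequence downstream of the deletion is frame-random,
# so a stop usually appears within a few codons; the builder verifies with
# the brute-force enumeration that the apparent ORF is start-intact,
# stopped, shorter than designed, and flanked on both sides — i.e. the
# mutant presents as an ordinary complete transcript.
build_frameshift <- function(u5, nc, u3, at_codon, min_len_nt) {
  if (at_codon < ceiling(min_len_nt / 3) + 2L || at_codon > nc - 4L) {
    stop("frameshift position must leave an apparent ORF above the ",
         "scanner floor and sit inside the ORF")
  }
  orf <- paste0("ATG", random_codons(nc - 2L), sample(STOP_CODONS, 1L))
  full <- paste0(make_utr5(u5), orf, random_dna_no_atg(u3))
  pos <- u5 + 3L * (at_codon - 1L) + 1L  # first base of codon `at_codon`
  seq <- paste0(substr(full, 1L, pos - 1L),
                substr(full, pos + 1L, nchar(full)))
  cand <- orf_enumerate_slow(seq)
  cand <- cand[cand$end - cand$start >= min_len_nt, , drop = FALSE]
  best <- pick_best_orf(cand)
  ok <- !is.null(best) && best$start == u5 && best$has_stop &&
    best$end < u5 + 3L * nc - 1L && best$end < nchar(seq)
  if (!ok) {
    # force rejection; the caller retries with fresh random content
    return(list(seq = seq, class = "COMPLETE_WITH_UTRS",
                exp_start = -1L, exp_end = -1L))
  }
  list(seq = seq, class = "COMPLETE_WITH_UTRS",
       exp_start = best$start, exp_end = best$end)
}

build_repeat <- function(u5, nc, u3, repeat_unit, fraction) {
  if (is.na(fraction) || fraction <= 0.85 || fraction > 1) {
    stop("repeat_fill fraction must lie in (0.85, 1] so the truth label ",
         "is unambiguous against the 0.80 coverage rule")
  }
  total <- u5 + 3L * nc + u3
  n_rep <- ceiling(fraction * total)
  reps <- strrep(repeat_unit, ceiling(n_rep / nchar(repeat_unit)))
  seq <- paste0(substr(reps, 1L, n_rep), random_dna(total - n_rep))
  list(seq = seq, class = "HIGH_COPY_REPEAT", exp_start = NULL,
       exp_end = NULL, skip_orf_check = TRUE)
}

build_no_orf <- function(u5, nc, u3) {
  list(seq = random_dna_no_atg(u5 + 3L * nc + u3), class = "NO_ORF",
       exp_start = NULL, exp_end = NULL)
}

#' Generate a labelled synthetic clone set
#'
#' Builds coding reference contigs (5' UTR + ORF + 3' UTR), one clone per
#' requested defect, and the true QC code of each clone. Defect magnitudes
#' sit strictly beyond the classifier thresholds (the unambiguous regime)
#' unless `include_boundary = TRUE`, which adds one clone whose deletion is
#' exactly at threshold, flagged `ambiguous` in the truth table and meant to
#' be excluded from recovery scoring. Deterministic for a given `seed`.
#'
#' Defects: `perfect` (FL), `t5` (FLt5), `t3` (FLt3), `fs` (FS), `chi`
#' (CHI), `imm` (IMM), `short_del` (FLsh), `low_identity` (FLq),
#' `noncoding_target` (FLx), `unknown` (`?`).
#'
#' @param defects Character vector of defect names, one clone each (values
#'   may repeat).
#' @param seed Integer seed.
#' @param orf_codons,utr5_len,utr3_len Contig architecture.
#' @param include_boundary Add the threshold-boundary clone.
#' @return List with `contigs` (tibble `id`, `seq`), `orfs` (tibble
#'   `contig_id`, `orf_start`, `orf_end`; non-coding contigs absent),
#'   `clones` (tibble `id`, `seq`) and `truth` (tibble `clone_id`, `code`,
#'   `defect`, `ambiguous`).
#' @export
make_clone_set <- function(defects, seed = 1L, orf_codons = 180L,
                           utr5_len = 60L, utr3_len = 120L,
                           include_boundary = FALSE) {
  known <- c("perfect", "t5", "t3", "fs", "chi", "imm", "short_del",
             "low_identity", "noncoding_target", "unknown")
  bad <- setdiff(defects, known)
  if (length(bad) > 0L) stop("unknown clone defect: ", bad[1L])
  if (orf_codons < 80L) stop("orf_codons must be at least 80")
  params <- clone_qc_params()
  withr::with_seed(as.integer(seed), {
    n <- length(defects)
    contig_seq <- function() {
      paste0(random_dna(utr5_len), "ATG", random_codons(orf_codons - 2L),
             sample(STOP_CODONS, 1L), random_dna(utr3_len))
    }
    contigs <- tibble::tibble(
      id = sprintf("contig_%03d", seq_len(n + 1L)),
      seq = vapply(seq_len(n + 1L), function(i) contig_seq(), character(1L)))
    noncoding <- tibble::tibble(id = "contig_nc", seq = random_dna(
      utr5_len + 3L * orf_codons + utr3_len))
    orf_start <- utr5_len
    orf_end <- utr5_len + 3L * orf_codons
    clone_rows <- list()
    truth_rows <- list()
    emit <- function(id, seq, code, defect, ambiguous = FALSE) {
      clone_rows[[length(clone_rows) + 1L]] <<-
        tibble::tibble(id = id, seq = seq)
      truth_rows[[length(truth_rows) + 1L]] <<-
        tibble::tibble(clone_id = id, code = code, defect = defect,
                       ambiguous = ambiguous)
    }
    spare <- contigs$seq[n + 1L]  # chimera partner
    for (i in seq_len(n)) {
      d <- defects[i]
      ct <- contigs$seq[i]
      id <- sprintf("clone_%03d", i)
      len <- nchar(ct)
      if (d == "perfect") {
        emit(id, ct, "FL", d)
      } else if (d == "t5") {
        emit(id, substr(ct, orf_start + 31L + 3L * sample(0:10, 1L), len),
             "FLt5", d)
      } else if (d == "t3") {
        emit(id, substr(ct, 1L, orf_end - 30L - 3L * sample(0:10, 1L)),
             "FLt3", d)
      } else if (d == "fs") {
        pos <- orf_start + 30L + 3L * sample(0:20, 1L)
        emit(id, paste0(substr(ct, 1L, pos), substr(ct, pos + 2L, len)),
             "FS", d)
      } else if (d == "chi") {
        seg <- 150L + 3L * sample(0:20, 1L)
        emit(id, paste0(substr(ct, 1L, seg),
                        substr(spare, nchar(spare) - seg + 1L, nchar(spare))),
             "CHI", d)
      } else if (d == "imm") {
        pos <- intron_site(ct, orf_start, orf_end)
        insert <- paste0("GT", random_dna(116L), "AG")
        emit(id, paste0(substr(ct, 1L, pos), insert,
                        substr(ct, pos + 1L, len)), "IMM", d)
      } else if (d == "short_del") {
        # flanks must out-score the affine gap cost (open 5 + extend 90),
        # or the optimal local alignment drops a flank instead of opening
        # the deletion and the clone presents as truncated
        dlen <- 90L
        pos <- orf_start + 60L + 3L * sample(0:10, 1L)
        emit(id, paste0(substr(ct, 1L, pos), substr(ct, pos + dlen + 1L, len)),
             "FLsh", d)
      } else if (d == "low_identity") {
        emit(id, mutate_seq(ct, rate = 0.04, margin = 30L), "FLq", d)
      } else if (d == "noncoding_target") {
        emit(id, noncoding$seq, "FLx", d)
      } else if (d == "unknown") {
        emit(id, paste0(strrep("N", 400L), random_dna(200L)), "?", d)
      }
    }
    if (include_boundary) {
      ct <- contigs$seq[n + 1L]
      pos <- orf_start + 60L
      dlen <- params$min_short_del  # exactly at threshold: ambiguous
      emit("clone_boundary",
           paste0(substr(ct, 1L, pos), substr(ct, pos + dlen + 1L, nchar(ct))),
           "FLsh", "short_del_boundary", ambiguous = TRUE)
    }
    used_coding <- contigs[seq_len(n + 1L), ]
    list(
      contigs = dplyr::bind_rows(used_coding, noncoding),
      orfs = tibble::tibble(contig_id = used_coding$id,
                            orf_start = orf_start, orf_end = orf_end),
      clones = dplyr::bind_rows(clone_rows),
      truth = dplyr::bind_rows(truth_rows))
  })
}

# An insertion site inside the ORF whose flanking contig bases are not G:
# affine-gap traceback could otherwise slide the gap and carry the GT/AG
# dinucleotides out of the inserted segment. The site also keeps both
# flanks long enough (> 125 nt of matches) that opening the 120 nt
# insertion gap out-scores dropping a flank.
intron_site <- function(ct, orf_start, orf_end) {
  lo <- orf_start + 90L
  hi <- orf_end - 30L
  for (k in 1:200) {
    pos <- lo + 3L * sample.int((hi - lo) %/% 3L, 1L)
    if (substr(ct, pos, pos) != "G" && substr(ct, pos + 1L, pos + 1L) != "G") {
      return(pos)
    }
  }
  stop("could not place an unambiguous intron insertion site")
}

# Substitute `rate` of the bases, each to a different base, leaving
# `margin` nt untouched at both ends so local alignment keeps full extent.
mutate_seq <- function(seq, rate, margin) {
  n <- nchar(seq)
  k <- max(1L, floor(rate * n))
  pos <- sample((margin + 1L):(n - margin), k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  chars[pos] <- vapply(chars[pos], function(b)
    sample(setdiff(BASES, b), 1L), character(1L))
  paste(chars, collapse = "")
}

#' Generate a synthetic gapped scaffold with known gap statistics
#'
#' Interleaves random ACGT sections with N runs. The truth statistics are
#' computed from the requested lengths, independently of any scanner.
#'
#' @param section_lens Positive section lengths (nt).
#' @param gap_lens N-run lengths, one fewer than sections; each at least
#'   `min_gap_run` so the truth is unambiguous.
#' @param seed Integer seed.
#' @param id Scaffold id.
#' @param min_gap_run The gap-run convention the truth assumes.
#' @return List with `record` (tibble `id`, `desc`, `seq`) and `truth`
#'   (list: `n_sections`, `assembled_bases`, `gap_bases`,
#'   `mean_section_len`).
#' @export
make_scaffolds <- function(section_lens, gap_lens, seed = 1L,
                           id = "scaffold_1", min_gap_run = 10L) {
  section_lens <- as.integer(section_lens)
  gap_lens <- as.integer(gap_lens)
  if (length(gap_lens) != length(section_lens) - 1L) {
    stop("need exactly one gap between consecutive sections")
  }
  if (any(section_lens <= 0L)) stop("section lengths must be positive")
  if (length(gap_lens) > 0L && any(gap_lens < min_gap_run)) {
    stop("gap runs below min_gap_run (", min_gap_run,
         ") would merge sections; not representable")
  }
  withr::with_seed(as.integer(seed), {
    pieces <- character(0L)
    for (i in seq_along(section_lens)) {
      sec <- random_dna(section_lens[i])
      # a section must not itself contain a qualifying N run (it cannot:
      # random_dna draws from ACGT only)
      pieces <- c(pieces, sec)
      if (i <= length(gap_lens)) pieces <- c(pieces, strrep("N", gap_lens[i]))
    }
    seq <- paste(pieces, collapse = "")
    list(
      record = tibble::tibble(id = id, desc = "synthetic scaffold", seq = seq),
      truth = list(n_sections = length(section_lens),
                   assembled_bases = sum(section_lens),
                   gap_bases = sum(gap_lens),
                   mean_section_len = sum(section_lens) / length(section_lens)))
  })
}

#' Generate minimal GenBank flatfile records with known metadata
#'
#' Writes syntactically minimal records (LOCUS/ACCESSION/FEATURES/REFERENCE
#' blocks, `//` terminators) with controlled author lists, submission dates
#' and optional cDNA library annotations, plus the truth table of what was
#' written. Roughly half the records carry a publication reference ahead of
#' the Direct Submission reference; the rest have only the Direct
#' Submission. Deterministic for a given `seed`.
#'
#' @param n Number of records (0 gives an empty file).
#' @param authors Character vector of last-author names to draw from.
#' @param date_range Length-2 `Date` (or coercible) vector of submission
#'   date bounds.
#' @param seed Integer seed.
#' @param libraries Optional character vector of library ids to draw from
#'   (`NULL` for no library annotation).
#' @return List with `text` (character vector of flatfile lines) and `truth`
#'   (tibble `accession`, `submit_date`, `last_author`, `library_id`).
#' @export
make_flatfiles <- function(n, authors, date_range = c("2002-01-01",
                                                      "2007-12-31"),
                           seed = 1L, libraries = NULL) {
  stopifnot(n >= 0L, length(authors) >= 1L)
  if (any(grepl(",\\s", authors) | grepl("\\sand\\s", authors))) {
    stop("author names must be canonical flatfile tokens ",
         "(\"Surname,I.N.\", no space after the comma)")
  }
  date_range <- as.Date(date_range)
  if (n == 0L) {
    return(list(text = character(),
                truth = tibble::tibble(accession = character(),
                                       submit_date = as.Date(character()),
                                       last_author = character(),
                                       library_id = character())))
  }
  withr::with_seed(as.integer(seed), {
    days <- as.integer(date_range[2L] - date_range[1L])
    text <- character()
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      acc <- sprintf("XSY%06d", i)
      date <- date_range[1L] + sample.int(days + 1L, 1L) - 1L
      author <- sample(authors, 1L)
      lib <- if (is.null(libraries)) NA_character_ else sample(libraries, 1L)
      with_pub <- stats::runif(1L) < 0.5
      text <- c(text, gb_record(acc, date, author, lib, with_pub))
      truth[[i]] <- tibble::tibble(accession = acc, submit_date = date,
                                   last_author = author, library_id = lib)
    }
    list(text = text, truth = dplyr::bind_rows(truth))
  })
}

gb_record <- function(acc, date, last_author, library_id, with_pub) {
  datestr <- sprintf("%02d-%s-%s", as.integer(format(date, "%d")),
                     names(MONTHS)[as.integer(format(date, "%m"))],
                     format(date, "%Y"))
  lines <- c(
    sprintf("LOCUS       %s               600 bp    mRNA    linear   VRT %s",
            acc, datestr),
    "DEFINITION  Xenopus tropicalis cDNA clone, complete cds.",
    sprintf("ACCESSION   %s", acc),
    "FEATURES             Location/Qualifiers",
    "     source          1..600",
    '                     /organism="Xenopus tropicalis"')
  if (!is.na(library_id)) {
    lines <- c(lines, sprintf('                     /clone_lib="%s"',
                              library_id))
  }
  ref_no <- 1L
  if (with_pub) {
    lines <- c(lines,
      sprintf("REFERENCE   %d  (bases 1 to 600)", ref_no),
      sprintf("  AUTHORS   Doe,J., Roe,R.S. and %s", last_author),
      "  TITLE     Systematic sequencing of full-length cDNA clones",
      "  JOURNAL   Genome Res. 14, 1-10 (2004)")
    ref_no <- ref_no + 1L
  }
  direct_author <- if (with_pub) "Doe,J." else last_author
  lines <- c(lines,
    sprintf("REFERENCE   %d  (bases 1 to 600)", ref_no),
    sprintf("  AUTHORS   %s", direct_author),
    "  TITLE     Direct Submission",
    sprintf("  JOURNAL   Submitted (%s) Institute of Amphibian Genomics",
            datestr),
    "//")
  lines
}
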