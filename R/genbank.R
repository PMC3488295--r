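MONTHS <- c(JAN = 1L, FEB = 2L, MAR = 3L, APR = 4L, MAY = 5L, JUN = 6L,
            JUL = 7L, AUG = 8L, SEP = 9L, OCT = 10L, NOV = 11L, DEC = 12L)

# Parse DD-MON-YYYY without locale dependence.
parse_gb_date <- function(x) {
  m <- regmatches(x, regexec("^(\\d{2})-([A-Z]{3})-(\\d{4})$", x))[[1L]]
  if (length(m) == 0L) return(as.Date(NA))
  mon <- MONTHS[m[3L]]
  if (is.na(mon)) return(as.Date(NA))
  as.Date(sprintf("%s-%02d-%s", m[4L], mon, m[2L]))
}

#' Mine submission metadata from a GenBank flatfile
#'
#' Parses a multi-record GenBank flatfile (records end with `//`) and
#' extracts, per record: the accession, the submission date (the
#' `Submitted (DD-MON-YYYY)` date in the first JOURNAL line carrying one,
#' normally the Direct Submission reference), the last author of the first
#' listed publication reference (falling back to the Direct Submission
#' reference when the record has no publication), and the cDNA library
#' (`/clone_lib` qualifier) when annotated. Records yielding neither a date
#' nor an author are kept with `NA`s and flagged by a warning.
#'
#' @param path Path to a GenBank flatfile.
#' @return Tibble with columns `accession`, `submit_date` (Date),
#'   `last_author`, `library_id`.
#' @export
parse_flatfile <- function(path) {
  if (!file.exists(path)) stop("flatfile not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "//")
  if (length(lines) > 0L) {
    tail_start <- if (length(ends) > 0L) max(ends) + 1L else 1L
    if (tail_start <= length(lines) &&
        any(nzchar(trimws(lines[tail_start:length(lines)])))) {
      stop("unterminated flatfile record (record index ",
           length(ends) + 1L, "): no closing '//'")
    }
  }
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  rows <- lapply(seq_along(ends), function(i) {
    parse_gb_record(lines[starts[i]:(ends[i] - 1L)], i)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0L) {
    bad <- is.na(out$submit_date) & is.na(out$last_author)
    if (any(bad)) {
      warning(sum(bad), " record(s) with neither a submission date nor ",
              "an extractable author: ",
              paste(out$accession[bad], collapse = ", "))
    }
    if (anyDuplicated(out$accession[!is.na(out$accession)]) > 0L) {
      stop("duplicate accession in flatfile: ",
           out$accession[anyDuplicated(out$accession)])
    }
  }
  out
}

parse_gb_record <- function(lines, index) {
  field_at <- function(pat) {
    hit <- grep(pat, lines)
    if (length(hit) == 0L) NA_character_ else lines[hit[1L]]
  }
  acc_line <- field_at("^ACCESSION")
  accession <- if (is.na(acc_line)) {
    loc <- field_at("^LOCUS")
    if (is.na(loc)) NA_character_ else strsplit(trimws(sub("^LOCUS", "", loc)),
                                                "\\s+")[[1L]][1L]
  } else {
    strsplit(trimws(sub("^ACCESSION", "", acc_line)), "\\s+")[[1L]][1L]
  }

  lib_line <- grep("/clone_lib=", lines, value = TRUE)
  library_id <- NA_character_
  if (length(lib_line) > 0L) {
    m <- regmatches(lib_line[1L],
                    regexec('/clone_lib="?([^"]+)"?', lib_line[1L]))[[1L]]
    if (length(m) > 0L) library_id <- m[2L]
  }

  refs <- parse_references(lines)
  submit_date <- as.Date(NA)
  for (r in refs) {
    m <- regmatches(r$journal,
                    regexec("Submitted\\s+\\((\\d{2}-[A-Z]{3}-\\d{4})\\)",
                            r$journal))[[1L]]
    if (length(m) > 0L) {
      submit_date <- parse_gb_date(m[2L])
      break
    }
  }

  is_direct <- vapply(refs, function(r)
    grepl("Direct Submission", r$title, fixed = TRUE), logical(1L))
  pick <- if (any(!is_direct)) which(!is_direct)[1L]
          else if (length(refs) > 0L) 1L else NA_integer_
  last_author <- if (is.na(pick)) NA_character_ else last_author_of(refs[[pick]]$authors)

  tibble::tibble(accession = accession, submit_date = submit_date,
                 last_author = last_author, library_id = library_id)
}

# Split a record into REFERENCE blocks with collapsed AUTHORS/TITLE/JOURNAL.
parse_references <- function(lines) {
  ref_starts <- grep("^REFERENCE", lines)
  if (length(ref_starts) == 0L) return(list())
  top_level <- grep("^[A-Z]", lines)  # any new top-level keyword ends a block
  lapply(seq_along(ref_starts), function(i) {
    from <- ref_starts[i] + 1L
    nxt <- top_level[top_level > ref_starts[i]]
    to <- if (length(nxt) > 0L) nxt[1L] - 1L else length(lines)
    block <- if (from <= to) lines[from:to] else character()
    list(authors = collapse_field(block, "AUTHORS"),
         title = collapse_field(block, "TITLE"),
         journal = collapse_field(block, "JOURNAL"))
  })
}

collapse_field <- function(block, key) {
  starts <- grep(sprintf("^\\s{1,4}%s\\b", key), block)
  if (length(starts) == 0L) return(NA_character_)
  i <- starts[1L]
  out <- trimws(sub(sprintf("^\\s*%s\\s*", key), "", block[i]))
  j <- i + 1L
  while (j <= length(block) && grepl("^\\s{6,}", block[j])) {
    out <- paste(out, trimws(block[j]))
    j <- j + 1L
  }
  out
}

# The final name in an AUTHORS list. Canonical flatfile name tokens carry
# no space after their internal comma ("Jones,K."), so ", " and " and "
# are unambiguous separators.
last_author_of <- function(authors) {
  if (is.na(authors) || !nzchar(authors)) return(NA_character_)
  parts <- strsplit(trimws(authors), "\\s+and\\s+")[[1L]]
  last <- trimws(parts[length(parts)])
  entries <- strsplit(last, ",\\s+")[[1L]]  # "Smith,J., Jones,K." style
  trimws(entries[length(entries)])
}

#' Monthly submission counts
#'
#' Pools dated records by calendar month of submission. In library mode all
#' records of a cDNA library are pooled at the month of the library's
#' earliest submission date (the convention for EST time series, where a
#' library's ESTs arrive in batches long after the library was made);
#' records without a library annotation count as singleton libraries.
#' Undated records are excluded from the series and reported via the
#' `n_undated` attribute, so series total + undated = record count.
#'
#' @param records Tibble from [parse_flatfile()].
#' @param group_by_library Pool by library at the earliest library date.
#' @return Tibble `month` ("YYYY-MM"), `count`, ordered by month, with
#'   attribute `n_undated`.
#' @export
monthly_counts <- function(records, group_by_library = FALSE) {
  undated <- is.na(records$submit_date)
  dated <- records[!undated, , drop = FALSE]
  if (nrow(dated) == 0L) {
    out <- tibble::tibble(month = character(), count = integer())
    attr(out, "n_undated") <- sum(undated)
    return(out)
  }
  if (group_by_library) {
    lib <- ifelse(is.na(dated$library_id),
                  paste0(".singleton.", seq_len(nrow(dated))),
                  dated$library_id)
    earliest <- stats::aggregate(dated$submit_date, by = list(lib = lib), FUN = min)
    month <- format(earliest$x[match(lib, earliest$lib)], "%Y-%m")
  } else {
    month <- format(dated$submit_date, "%Y-%m")
  }
  tab <- table(month)
  out <- tibble::tibble(month = names(tab), count = as.integer(tab))
  out <- out[order(out$month), ]
  attr(out, "n_undated") <- sum(undated)
  out
}

#' Rank last authors by submission count
#'
#' Counts distinct last-author strings (exact match after whitespace
#' trimming — name variants are deliberately kept distinct) and returns the
#' most prolific submitters. Ties are broken alphabetically. Records with no
#' extractable author are excluded and reported via the `n_unattributed`
#' attribute.
#'
#' @param records Tibble from [parse_flatfile()].
#' @param top_n Number of rows to keep.
#' @return Tibble `count`, `last_author`, descending by count, with
#'   attribute `n_unattributed`.
#' @export
rank_last_authors <- function(records, top_n = 25L) {
  known <- records$last_author[!is.na(records$last_author)]
  known <- trimws(known)
  if (length(known) == 0L) {
    out <- tibble::tibble(count = integer(), last_author = character())
    attr(out, "n_unattributed") <- nrow(records)
    return(out)
  }
  tab <- table(known)
  out <- tibble::tibble(count = as.integer(tab), last_author = names(tab))
  out <- out[order(-out$count, out$last_author), ]
  out <- utils::head(out, top_n)
  attr(out, "n_unattributed") <- sum(is.na(records$last_author))
  out
}
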