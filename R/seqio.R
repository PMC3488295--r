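#' @importFrom tibble tibble as_tibble
#' @importFrom Biostrings BStringSet readBStringSet writeXStringSet
NULL

# IUPAC nucleotide alphabet accepted on input (after uppercasing)
IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Read a multi-record FASTA file
#'
#' Parses a (optionally gzip-compressed) FASTA file into a tibble of sequence
#' records. Sequences are uppercased on read, so any soft-masking (lowercase)
#' in the input is lost. Characters outside the IUPAC nucleotide alphabet are
#' rejected with an error reporting the offending record and position.
#'
#' @param path Path to a FASTA file.
#' @param allow_empty Permit records with an empty sequence (they are always
#'   flagged with a warning).
#' @return A tibble with columns `id` (first word of the header),
#'   `desc` (remainder of the header, `NA` if none) and `seq` (uppercase
#'   nucleotide string), one row per record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a first record", "ACGTacgt", ">b", "NNN"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, allow_empty = TRUE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  non_blank <- which(nzchar(trimws(lines)))
  if (length(non_blank) > 0L && !startsWith(trimws(lines[non_blank[1L]]), ">")) {
    stop("malformed FASTA: sequence line before any '>' header at line ",
         non_blank[1L], " of ", path)
  }
  n_headers <- sum(startsWith(trimws(lines), ">"))
  if (n_headers == 0L) {
    return(tibble(id = character(), desc = character(), seq = character()))
  }
  set <- readBStringSet(path)
  if (length(set) != n_headers) {
    stop("FASTA parse dropped records: ", n_headers, " headers but ",
         length(set), " records read from ", path)
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), NA_character_)
  seq <- toupper(gsub("[[:space:]]", "", as.character(set)))
  bad_id <- which(!nzchar(id))
  if (length(bad_id) > 0L) {
    stop("FASTA record ", bad_id[1L], " has an empty id")
  }
  check_iupac(seq, id)
  empty <- which(!nzchar(seq))
  if (length(empty) > 0L) {
    if (!allow_empty) {
      stop("empty sequence for record(s): ", paste(id[empty], collapse = ", "))
    }
    warning("empty sequence for record(s): ", paste(id[empty], collapse = ", "))
  }
  tibble(id = id, desc = desc, seq = unname(seq))
}

check_iupac <- function(seq, id) {
  pat <- sprintf("[^%s]", paste(IUPAC_CHARS, collapse = ""))
  hit <- regexpr(pat, seq)
  bad <- which(hit > 0L)
  if (length(bad) > 0L) {
    i <- bad[1L]
    stop(sprintf(
      "non-IUPAC character '%s' in record '%s' at sequence position %d",
      substr(seq[i], hit[i], hit[i]), id[i], hit[i]))
  }
  invisible(TRUE)
}

#' Write sequence records as FASTA
#'
#' @param records A tibble/data.frame with columns `id`, `seq` and optionally
#'   `desc`, as returned by [read_fasta()].
#' @param path Output path.
#' @param wrap Line width for the sequence lines (positive integer).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (!is.numeric(wrap) || length(wrap) != 1L || wrap < 1L) {
    stop("`wrap` must be a positive integer")
  }
  if (nrow(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  desc <- if ("desc" %in% names(records)) records$desc
          else rep(NA_character_, nrow(records))
  headers <- ifelse(is.na(desc) | !nzchar(desc),
                    records$id, paste(records$id, desc))
  set <- BStringSet(records$seq)
  names(set) <- headers
  writeXStringSet(set, path, width = as.integer(wrap))
  invisible(path)
}

#' Read a TSV table with a header row
#'
#' Thin wrapper around [readr::read_tsv()] that enforces the presence of
#' required columns. Missing cells become `NA`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param required_columns Character vector of column names that must be
#'   present; a schema error names the first missing one.
#' @return A tibble, zero rows if the file holds only a header.
#' @export
read_tsv_table <- function(path, required_columns = character()) {
  if (!file.exists(path)) {
    stop("TSV file not found: ", path)
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required_columns, names(tab))
  if (length(missing) > 0L) {
    stop("required column '", missing[1L], "' absent from ", path)
  }
  as_tibble(tab)
}
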