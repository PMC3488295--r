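#' Transcript completeness categories
#'
#' The category scheme used for gene-model transcript audits, in decreasing
#' severity order: high-copy repeat content, ORF truncated at both ends, 5'
#' only, 3' only, then the four complete-ORF subclasses distinguished by which
#' UTRs are present, plus `NO_ORF` for transcripts in which no qualifying ORF
#' was found (reported separately from the error categories).
#'
#' @return Character vector of class labels.
#' @export
completeness_classes <- function() {
  c("HIGH_COPY_REPEAT", "TRUNC_BOTH", "TRUNC_5", "TRUNC_3",
    "COMPLETE_NO_UTRS", "COMPLETE_NO_5UTR", "COMPLETE_NO_3UTR",
    "COMPLETE_WITH_UTRS", "NO_ORF")
}

#' Full-insert cDNA clone QC codes
#'
#' The clone QC code set: `?` (no usable full-insert sequence), `CHI`
#' (chimeric clone), `FL` (full-length), `FLq` (possibly full-length), `FLsh`
#' (odd short form), `FLt3`/`FLt5` (truncated 3'/5'), `FLx` (probably
#' non-coding), `FS` (frame shifted), `IMM` (immature/mis-spliced mRNA).
#'
#' @return Character vector of code values.
#' @export
clone_qc_codes <- function() {
  c("?", "CHI", "FL", "FLq", "FLsh", "FLt3", "FLt5", "FLx", "FS", "IMM")
}

new_tally <- function(counts, label, levels) {
  full <- stats::setNames(integer(length(levels)), levels)
  full[names(counts)] <- as.integer(counts)
  structure(
    list(label = label, counts = full, total = sum(full)),
    class = "category_tally")
}

#' Tally classification results into a category summary
#'
#' Counts one classification per item and checks conservation (counts sum to
#' the number of inputs). Items must be unique; a duplicated id is an error,
#' since no sequence may be reported in more than one category.
#'
#' @param classes A data.frame with columns `id` and `class`, or a named
#'   character vector (names are ids).
#' @param label Label for the tally (e.g. an assembly or clone-set name).
#' @param levels The category universe; defaults to [completeness_classes()].
#' @return A `category_tally`: list with `label`, named integer `counts`
#'   (every level present), and `total`.
#' @export
tally_classes <- function(classes, label = "",
                          levels = completeness_classes()) {
  if (is.data.frame(classes)) {
    stopifnot(all(c("id", "class") %in% names(classes)))
    ids <- as.character(classes$id)
    cls <- as.character(classes$class)
  } else {
    ids <- names(classes)
    cls <- as.character(classes)
  }
  if (!is.null(ids) && anyDuplicated(ids) > 0L) {
    stop("duplicate id in classification input: ",
         ids[anyDuplicated(ids)])
  }
  unknown <- setdiff(unique(cls), levels)
  if (length(unknown) > 0L) {
    stop("class outside the category universe: ", unknown[1L])
  }
  counts <- table(factor(cls, levels = levels))
  new_tally(as.integer(counts) |> stats::setNames(levels), label, levels)
}

#' @export
print.category_tally <- function(x, ...) {
  cat(sprintf("Category tally%s: %d item(s)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$total))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-20s %8d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}
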