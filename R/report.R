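COMPLETE_CLASSES <- c("COMPLETE_NO_UTRS", "COMPLETE_NO_5UTR",
                      "COMPLETE_NO_3UTR", "COMPLETE_WITH_UTRS")

TABLE4_LABELS <- c(
  HIGH_COPY_REPEAT = "80% high copy number repeat",
  TRUNC_BOTH = "ORF truncated both ends",
  TRUNC_5 = "ORF truncated 5'",
  TRUNC_3 = "ORF truncated 3'",
  COMPLETE_NO_UTRS = "No UTRs",
  COMPLETE_NO_5UTR = "No 5' UTR",
  COMPLETE_NO_3UTR = "No 3' UTR",
  COMPLETE_WITH_UTRS = "OK transcripts with UTRs")

#' Render a transcript-completeness tally as a report
#'
#' Emits the standard completeness layout (total, then categories in
#' decreasing severity, with a subtotal of complete-ORF transcripts) plus
#' the headline complete-ORF percentage: the four complete subclasses over
#' the total, rounded to the nearest integer for display (the raw fraction
#' is retained). Transcripts with no qualifying ORF, an artifact-side
#' category absent from the published layout, are appended as their own row
#' so totals still reconcile.
#'
#' @param tally A `category_tally` over [completeness_classes()].
#' @return List of class `completeness_report`: `label`, `rows` (tibble
#'   `key`, `label`, `count`), `total`, `complete_total`,
#'   `complete_orf_fraction`, `complete_orf_percent`.
#' @examples
#' render_completeness_report(xen_fixture("table4_v41"))$complete_orf_percent
#' @export
render_completeness_report <- function(tally) {
  stopifnot(inherits(tally, "category_tally"))
  if (tally$total <= 0L) stop("empty tally")
  cnt <- tally$counts
  complete_total <- sum(cnt[COMPLETE_CLASSES])
  keys <- names(TABLE4_LABELS)
  rows <- tibble::tibble(key = keys, label = unname(TABLE4_LABELS[keys]),
                         count = unname(cnt[keys]))
  if (cnt[["NO_ORF"]] > 0L) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      key = "NO_ORF", label = "No qualifying ORF", count = cnt[["NO_ORF"]]))
  }
  frac <- complete_total / tally$total
  structure(
    list(label = tally$label, rows = rows, total = tally$total,
         complete_total = complete_total,
         complete_orf_fraction = frac,
         complete_orf_percent = round(100 * frac)),
    class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("Gene model transcript completeness [%s]\n", x$label))
  cat(sprintf("  %-28s %8s\n", "Total transcripts", format(x$total, big.mark = ",")))
  for (i in seq_len(nrow(x$rows))) {
    cat(sprintf("  %-28s %8s\n", x$rows$label[i],
                format(x$rows$count[i], big.mark = ",")))
  }
  cat(sprintf("  %-28s %8s\n", "Total complete ORF",
              format(x$complete_total, big.mark = ",")))
  cat(sprintf("  Complete-ORF percentage: %d%%\n", x$complete_orf_percent))
  invisible(x)
}

TABLE2_LABELS <- c(
  "?" = "(lacks full-length sequencing result)",
  CHI = "Chimeric Clone",
  FL = "Full-Length",
  FLq = "Possibly Full-Length",
  FLsh = "Odd Short Form",
  FLt3 = "Truncated 3-prime",
  FLt5 = "Truncated 5-prime",
  FLx = "Probably Non-Coding",
  FS = "Frame Shifted",
  IMM = "Immature/mis-spliced mRNA")

#' Render a clone QC tally as a report
#'
#' Emits the standard clone QC layout plus two headline figures: the failure
#' percentage (clones with no full-insert sequencing result over all clones,
#' nearest integer) and the full-length rate among successfully sequenced
#' clones (via [fl_rate_from_qc()]).
#'
#' @param tally A `category_tally` over [clone_qc_codes()].
#' @return List of class `qc_report`: `label`, `rows` (tibble `code`,
#'   `label`, `count`), `total`, `failure_percent`, `fl_rate`,
#'   `fl_percent` (one decimal).
#' @examples
#' render_qc_report(xen_fixture("table2_wellcome"))$failure_percent
#' @export
render_qc_report <- function(tally) {
  stopifnot(inherits(tally, "category_tally"))
  if (tally$total <= 0L) stop("empty tally")
  cnt <- tally$counts
  codes <- names(TABLE2_LABELS)
  rows <- tibble::tibble(code = codes, label = unname(TABLE2_LABELS[codes]),
                         count = unname(cnt[codes]))
  rate <- fl_rate_from_qc(tally)
  structure(
    list(label = tally$label, rows = rows, total = tally$total,
         failure_percent = round(100 * cnt[["?"]] / tally$total),
         fl_rate = rate, fl_percent = round(100 * rate, 1L)),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Full-insert clone QC [%s]\n", x$label))
  for (i in seq_len(nrow(x$rows))) {
    cat(sprintf("  %6s  %-40s %6s\n", x$rows$code[i], x$rows$label[i],
                format(x$rows$count[i], big.mark = ",")))
  }
  cat(sprintf("  Total %s; failed %d%%; full-length of sequenced %.1f%%\n",
              format(x$total, big.mark = ","), x$failure_percent,
              x$fl_percent))
  invisible(x)
}

#' Serialise a report to JSON
#'
#' JSON is the stable machine-readable interface of the report module; the
#' printed layouts are for eyes only.
#'
#' @param report A `completeness_report` or `qc_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
report_json <- function(report, path = NULL) {
  payload <- unclass(report)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
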