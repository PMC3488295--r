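#' Round to the nearest integer, halves away from zero
#'
#' The rounding convention for estimated full-length gene counts
#' (e.g. 4973 x 0.90 = 4475.7 -> 4476).
#' @param x Numeric vector.
#' @return Integer vector.
#' @keywords internal
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Estimated number of genes with a full-length cDNA
#'
#' @param distinct_genes Number of distinct genes with at least one clone.
#' @param fl_rate Full-length rate in \[0, 1\] (explicit or sampled).
#' @return Integer estimate, rounded half away from zero.
#' @examples
#' est_fl_genes(4973, 0.90)  # 4476
#' @export
est_fl_genes <- function(distinct_genes, fl_rate) {
  if (any(fl_rate < 0) || any(fl_rate > 1)) stop("fl_rate must lie in [0, 1]")
  round_half_away(distinct_genes * fl_rate)
}

#' Summarise a clone set against a gene map
#'
#' Counts the distinct clones with accessions, maps accessions to gene ids
#' (many accessions may map to one gene), and estimates the number of genes
#' for which the set holds a full-length cDNA. Accessions absent from the
#' gene map are reported, never silently dropped.
#'
#' @param clones Tibble of clone records with columns `clone_id`,
#'   `accession` (NA when the clone has no sequence), and optionally
#'   `set_name`, `species`.
#' @param gene_map Tibble with columns `accession`, `gene_id` (an accession
#'   maps to at most one gene).
#' @param plates Number of 96-well plates in the set (positive).
#' @param fl_rate Full-length rate in \[0, 1\] used for the estimate.
#' @param set_name,species Labels (defaulted from the clone table if present).
#' @return One-row tibble: `set_name`, `species`, `plates`, `wells`,
#'   `distinct_clones`, `distinct_genes`, `est_fl_genes`,
#'   `unmapped_accessions`.
#' @export
summarize_set <- function(clones, gene_map, plates, fl_rate,
                          set_name = NULL, species = NULL) {
  if (length(plates) != 1L || is.na(plates) || plates <= 0) {
    stop("plates must be a positive count")
  }
  if (fl_rate < 0 || fl_rate > 1) stop("fl_rate must lie in [0, 1]")
  check_gene_map(gene_map)
  set_name <- set_name %||% first_or(clones, "set_name")
  species <- species %||% first_or(clones, "species")
  with_acc <- clones[!is.na(clones$accession) & nzchar(clones$accession), ,
                     drop = FALSE]
  accs <- unique(with_acc$accession)
  genes <- unique(gene_map$gene_id[match(accs, gene_map$accession)])
  genes <- genes[!is.na(genes)]
  unmapped <- sum(!(accs %in% gene_map$accession))
  tibble::tibble(
    set_name = set_name, species = species,
    plates = as.integer(plates), wells = as.integer(plates) * 96L,
    distinct_clones = length(unique(with_acc$clone_id)),
    distinct_genes = length(genes),
    est_fl_genes = est_fl_genes(length(genes), fl_rate),
    unmapped_accessions = unmapped)
}

check_gene_map <- function(gene_map) {
  stopifnot(all(c("accession", "gene_id") %in% names(gene_map)))
  dup <- gene_map$accession[duplicated(gene_map$accession)]
  if (length(dup) > 0L) {
    conflicting <- vapply(unique(dup), function(a) {
      length(unique(gene_map$gene_id[gene_map$accession == a])) > 1L
    }, logical(1L))
    if (any(conflicting)) {
      stop("accession maps to more than one gene id: ",
           unique(dup)[conflicting][1L])
    }
  }
  invisible(TRUE)
}

first_or <- function(tab, col, default = "") {
  if (!col %in% names(tab) || nrow(tab) == 0L) default
  else as.character(tab[[col]][[1L]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full-length rate from a clone QC tally
#'
#' The proportion of successfully sequenced clones classified full-length:
#' `FL / (total - ?)`. Clones lacking a full-insert sequencing result (`?`)
#' are excluded from the denominator.
#'
#' @param tally A `category_tally` over [clone_qc_codes()].
#' @return Fraction in \[0, 1\].
#' @export
fl_rate_from_qc <- function(tally) {
  stopifnot(inherits(tally, "category_tally"))
  if (tally$total <= 0L) stop("empty tally")
  sequenced <- tally$total - tally$counts[["?"]]
  if (sequenced <= 0L) stop("no sequenced clones in tally")
  tally$counts[["FL"]] / sequenced
}

#' Combine clone-set summaries with cross-set gene deduplication
#'
#' Plates and wells are summed; distinct clones and genes are recomputed from
#' the pooled clone tables, so genes shared between sets are counted once.
#' The combined full-length estimate is reported as `NA`: per-set estimates
#' mix explicit and sampled rates and do not determine a combined value.
#'
#' @param summaries List (or row-bound tibble) of [summarize_set()] outputs,
#'   at least two, all for the same species.
#' @param clone_tables List of the corresponding clone tables.
#' @param gene_map The shared accession-to-gene map.
#' @return One-row tibble in the [summarize_set()] layout.
#' @export
combine_sets <- function(summaries, clone_tables, gene_map) {
  if (is.data.frame(summaries)) {
    summaries <- split(summaries, seq_len(nrow(summaries)))
  }
  if (length(summaries) < 2L) {
    stop("need at least two sets to combine")
  }
  species <- unique(vapply(summaries, function(s) as.character(s$species),
                           character(1L)))
  if (length(species) > 1L) {
    stop("species mismatch across sets: ", paste(species, collapse = ", "))
  }
  check_gene_map(gene_map)
  pooled <- dplyr::bind_rows(lapply(seq_along(clone_tables), function(i) {
    tab <- clone_tables[[i]]
    tab$set_name <- summaries[[i]]$set_name
    tab
  }))
  with_acc <- pooled[!is.na(pooled$accession) & nzchar(pooled$accession), ,
                     drop = FALSE]
  accs <- unique(with_acc$accession)
  genes <- unique(gene_map$gene_id[match(accs, gene_map$accession)])
  genes <- genes[!is.na(genes)]
  tibble::tibble(
    set_name = "(combined sources)", species = species,
    plates = sum(vapply(summaries, function(s) s$plates, integer(1L))),
    wells = sum(vapply(summaries, function(s) s$wells, integer(1L))),
    distinct_clones = nrow(unique(with_acc[, c("set_name", "clone_id")])),
    distinct_genes = length(genes),
    est_fl_genes = NA_integer_,
    unmapped_accessions = sum(!(accs %in% gene_map$accession)))
}

#' Gene coverage percentage
#'
#' @param genes_with_data Genes with at least one cDNA accession attached.
#' @param gene_total_estimate Estimated total protein-coding genes
#'   (positive, at least `genes_with_data`).
#' @return Percentage to one decimal.
#' @examples
#' coverage_percent(10549, 22472)  # 46.9
#' @export
coverage_percent <- function(genes_with_data, gene_total_estimate) {
  if (gene_total_estimate <= 0) stop("gene_total_estimate must be positive")
  if (genes_with_data > gene_total_estimate) {
    stop("genes_with_data exceeds the total estimate")
  }
  round(100 * genes_with_data / gene_total_estimate, 1L)
}
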