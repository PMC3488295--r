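#' Packaged reference tallies and assembly totals
#'
#' Published audit tables for the Xenopus tropicalis expressed-sequence
#' resources, shipped as fixtures so the report arithmetic can be checked
#' without any download:
#' \describe{
#'   \item{table4_v41, table4_v71}{gene-model transcript completeness
#'     tallies for the v4.1 and v7.1 genome assemblies (`category_tally`
#'     over [completeness_classes()]; totals 27,653 and 43,436)}
#'   \item{table2_wellcome, table2_image}{full-insert clone QC tallies for
#'     the Wellcome/Sanger set (9,216 clones) and the analysed IMAGE/XGC
#'     sample (1,920 clones, data incomplete)}
#'   \item{table3}{clone-set gene accounting rows (plates, wells, distinct
#'     clones/genes, estimated full-length genes)}
#'   \item{assembly_v41}{the v4.1 assembly totals: 19,759 scaffolds,
#'     ~175,000 contiguous sections, ~1.5 billion assembled bases}
#' }
#'
#' @param name One of the fixture names above.
#' @return A `category_tally`, tibble, or list depending on the fixture.
#' @export
xen_fixture <- function(name) {
  switch(name,
    table4_v41 = new_tally(c(
      HIGH_COPY_REPEAT = 868, TRUNC_BOTH = 3536, TRUNC_5 = 2307,
      TRUNC_3 = 9594, COMPLETE_NO_UTRS = 4020, COMPLETE_NO_5UTR = 399,
      COMPLETE_NO_3UTR = 3230, COMPLETE_WITH_UTRS = 3699),
      label = "v4.1", levels = completeness_classes()),
    table4_v71 = new_tally(c(
      HIGH_COPY_REPEAT = 1056, TRUNC_BOTH = 486, TRUNC_5 = 1262,
      TRUNC_3 = 2798, COMPLETE_NO_UTRS = 4610, COMPLETE_NO_5UTR = 2920,
      COMPLETE_NO_3UTR = 3396, COMPLETE_WITH_UTRS = 26908),
      label = "v7.1", levels = completeness_classes()),
    table2_wellcome = new_tally(c(
      "?" = 2772, CHI = 64, FL = 4585, FLq = 256, FLsh = 147, FLt3 = 715,
      FLt5 = 335, FLx = 228, FS = 96, IMM = 18),
      label = "Wellcome/Sanger", levels = clone_qc_codes()),
    table2_image = new_tally(c(
      "?" = 4, CHI = 8, FL = 1795, FLq = 31, FLsh = 35, FLt3 = 0,
      FLt5 = 3, FLx = 3, FS = 37, IMM = 4),
      label = "IMAGE/XGC (24-plate sample)", levels = clone_qc_codes()),
    table3 = tibble::tribble(
      ~species, ~set_name, ~plates, ~wells, ~distinct_clones,
        ~distinct_genes, ~est_fl_genes,
      "X. tropicalis", "IMAGE/XGC",          54L,  5184L,  5165L, 4973L, 4476L,
      "X. tropicalis", "Wellcome/Sanger",    96L,  9216L,  5293L, 4911L, 3904L,
      "X. tropicalis", "(combined sources)", 150L, 14400L, 10458L, 7681L, 6619L,
      "X. laevis",     "IMAGE/XGC",         104L,  9984L,  9671L, 9256L, 8381L),
    assembly_v41 = list(n_scaffolds = 19759L, n_sections = 175000L,
                        assembled_bases = 1.5e9),
    stop("unknown fixture: ", name)
  )
}
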