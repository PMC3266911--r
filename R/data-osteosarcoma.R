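#' Published 17p11.2-p12 top-gene amplification/overexpression counts
#'
#' The eleven genes most frequently overexpressed through amplification in
#' the 17p11.2-p12 amplicon of a published osteosarcoma cohort (20 tumours
#' with both SNP-array and expression data). Columns: `band` (cytoband),
#' `mb` (position on chromosome 17 in Mb), `A` (tumours with the gene
#' amplified), `O` (tumours with the gene overexpressed), `OA` (tumours with
#' both). The published percentage column is recomputed by
#' [summarize_oa()]-style arithmetic, not stored.
#'
#' @return data.frame(gene, band, mb, A, O, OA)
#' @export
os17p_top_genes <- function() {
  data.frame(
    gene = c("SHMT1", "PMP22", "RASD1", "TOP3A", "PRPSAP2", "COPS3", "GRAP",
             "C17orf39", "RICH2", "ALKBH5", "C17orf45"),
    band = c("p11.2", "p12", "p11.2", "p11.2", "p11.2", "p11.2", "p11.2",
             "p11.2", "p12", "p11.2", "p11.2"),
    mb = c(18.25, 15.15, 17.39, 19.5, 17.8, 17.17, 18.94, 17.95, 12.75,
           18.1, 16.34),
    A = c(17L, 16L, 18L, 17L, 16L, 18L, 17L, 18L, 17L, 17L, 18L),
    O = c(15L, 14L, 13L, 12L, 10L, 12L, 12L, 10L, 11L, 10L, 10L),
    OA = c(13L, 12L, 12L, 11L, 10L, 11L, 10L, 10L, 9L, 9L, 9L),
    stringsAsFactors = FALSE
  )
}

#' Published copy-number/expression correlations for the top genes
#'
#' Pearson correlation R between gene copy number (qPCR) and expression
#' level (qRT-PCR), with two-sided p-values, as published for the eleven
#' top-ranked 17p11.2-p12 genes.
#'
#' @return data.frame(gene, r, p)
#' @export
os17p_correlations <- function() {
  data.frame(
    gene = c("C17orf39", "RICH2", "C17orf45", "TOP3A", "COPS3", "SHMT1",
             "PRPSAP2", "PMP22", "RASD1", "GRAP", "ALKBH5"),
    r = c(0.77, 0.75, 0.74, 0.73, 0.72, 0.67, 0.64, 0.62, 0.49, -0.13, -0.16),
    p = c(3e-05, 9e-05, 1e-04, 1e-04, 2e-04, 7e-04, 1e-03, 2e-03, 0.02,
          0.6, 0.5),
    stringsAsFactors = FALSE
  )
}
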