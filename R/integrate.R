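#' Gene-level copy number from probe-level calls
#'
#' Copy number of a gene is the lower median of the copy numbers of SNP
#' probes overlapping its coding interval `[start, end)`; when no probe
#' overlaps, the copy number of the probe nearest to the closer gene
#' boundary is used (ties resolve to the lower coordinate). The lower median
#' keeps integer inputs integral.
#'
#' @param gene one-row data.frame or list with `chrom`, `start`, `end`.
#' @param cn numeric copy number per probe (one sample).
#' @param probes probe data.frame (`chrom`, `pos`), positions sorted within
#'   chromosome.
#' @return scalar copy number.
#' @export
gene_copy_number <- function(gene, cn, probes) {
  if (nrow(probes) == 0) stop("empty probe list")
  on_chrom <- which(probes$chrom == gene$chrom)
  if (!length(on_chrom))
    stop("no probes on chromosome '", gene$chrom, "'")
  pos <- probes$pos[on_chrom]
  inside <- on_chrom[pos >= gene$start & pos < gene$end]
  if (length(inside)) {
    x <- sort(cn[inside])
    return(x[ceiling(length(x) / 2)])          # lower median
  }
  d <- ifelse(pos < gene$start, gene$start - pos, pos - gene$end + 1)
  nearest <- on_chrom[which.min(d)]            # which.min: ties -> first
  cn[nearest]
}

#' Gene x sample copy-number matrix
#'
#' Applies [gene_copy_number()] to every gene and sample.
#'
#' @param genes gene models data.frame (`name`, `chrom`, `start`, `end`).
#' @param cn_matrix probes x samples copy-number matrix.
#' @param probes probe data.frame.
#' @return numeric matrix genes x samples.
#' @export
gene_cn_matrix <- function(genes, cn_matrix, probes) {
  out <- matrix(NA_real_, nrow(genes), ncol(cn_matrix),
                dimnames = list(genes$name, colnames(cn_matrix)))
  for (g in seq_len(nrow(genes)))
    for (s in seq_len(ncol(cn_matrix)))
      out[g, s] <- gene_copy_number(genes[g, ], cn_matrix[, s], probes)
  out
}

#' Average multiple expression probes per gene
#'
#' Arithmetic mean of linear-scale probe signals mapping to the same gene.
#'
#' @param expr probe x sample matrix (linear scale), rownames = probe ids.
#' @param probe_map data.frame(probe_id, gene).
#' @return gene x sample matrix.
#' @export
collapse_expression <- function(expr, probe_map) {
  miss <- setdiff(rownames(expr), probe_map$probe_id)
  if (length(miss)) stop("unmapped expression probe(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  gene <- probe_map$gene[match(rownames(expr), probe_map$probe_id)]
  rowsum(expr, gene) / as.vector(table(gene)[sort(unique(gene))])
}

#' Per-gene, per-sample amplification and overexpression status
#'
#' Fold change is the tumour's linear expression signal over the osteoblast
#' reference signal for the same gene. A gene is amplified in a sample when
#' its copy number strictly exceeds `amp_cn` (3.5) and overexpressed when the
#' fold change is at least `over_fc` (2). Only samples present in both the
#' copy-number and expression matrices are scored.
#'
#' @param gene_cn gene x sample copy-number matrix ([gene_cn_matrix()]).
#' @param expr gene x sample linear expression matrix.
#' @param reference named numeric vector (or one-column matrix) of reference
#'   signals per gene; must be strictly positive.
#' @param amp_cn,over_fc thresholds.
#' @return long data.frame(gene, sample, copy_number, amplified, fold_change,
#'   overexpressed).
#' @export
status_matrix <- function(gene_cn, expr, reference, amp_cn = 3.5, over_fc = 2) {
  if (is.matrix(reference)) reference <- stats::setNames(reference[, 1], rownames(reference))
  genes <- intersect(rownames(gene_cn), rownames(expr))
  if (!length(genes)) stop("no shared genes between copy number and expression")
  samples <- intersect(colnames(gene_cn), colnames(expr))
  if (!length(samples)) stop("no shared samples between copy number and expression")
  ref <- reference[genes]
  if (any(is.na(ref))) stop("reference signal missing for gene(s): ",
                            paste(genes[is.na(ref)][1:min(5, sum(is.na(ref)))],
                                  collapse = ", "))
  bad <- ref <= 0
  if (any(bad)) stop("zero/negative reference signal for gene '",
                     genes[bad][1], "'")
  fc <- sweep(expr[genes, samples, drop = FALSE], 1, ref, "/")
  cn <- gene_cn[genes, samples, drop = FALSE]
  out <- data.frame(
    gene = rep(genes, times = length(samples)),
    sample = rep(samples, each = length(genes)),
    copy_number = as.vector(cn),
    amplified = as.vector(cn > amp_cn),
    fold_change = as.vector(fc),
    overexpressed = as.vector(fc >= over_fc),
    stringsAsFactors = FALSE
  )
  out
}

#' Overexpression-given-amplification summary per gene
#'
#' Counts, per gene: `A` tumours with amplification, `O` tumours with
#' overexpression, `OA` tumours with both, and `pct = 100 * OA / A` (the
#' percentage of tumours in which the amplified gene is also overexpressed).
#' `pct` is undefined (NA) when `A = 0`; such genes are ineligible for
#' ranking. `pct_reported` is rounded to one decimal for display; `pct`
#' keeps full precision.
#'
#' @param status long status data.frame ([status_matrix()]) or any data.frame
#'   with `gene`, `amplified`, `overexpressed`.
#' @return data.frame(gene, A, O, OA, pct, pct_reported), one row per gene.
#' @export
summarize_oa <- function(status) {
  stopifnot(all(c("gene", "amplified", "overexpressed") %in% names(status)))
  genes <- unique(status$gene)
  rows <- lapply(genes, function(g) {
    st <- status[status$gene == g, , drop = FALSE]
    A <- sum(st$amplified)
    O <- sum(st$overexpressed)
    OA <- sum(st$amplified & st$overexpressed)
    stopifnot(OA <= min(A, O))
    pct <- if (A > 0) 100 * OA / A else NA_real_
    data.frame(gene = g, A = A, O = O, OA = OA, pct = pct,
               pct_reported = round(pct, 1), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Rank candidate genes by overexpression-given-amplification
#'
#' Keeps genes whose `pct` is defined and at least `min_pct` (inclusive:
#' a gene overexpressed in exactly half of its amplified tumours makes the
#' list), sorted by `pct` descending; ties resolve to larger `OA`, then
#' gene name, so the order is deterministic.
#'
#' @param summaries data.frame from [summarize_oa()].
#' @param min_pct inclusive percentage threshold (default 50).
#' @return the surviving rows, ranked.
#' @export
rank_candidates <- function(summaries, min_pct = 50) {
  keep <- !is.na(summaries$pct) & summaries$pct >= min_pct
  top <- summaries[keep, , drop = FALSE]
  top <- top[order(-top$pct, -top$OA, top$gene), , drop = FALSE]
  rownames(top) <- NULL
  top
}

#' Pearson correlation filter between copy number and expression
#'
#' Product-moment correlation R with a two-sided p-value from
#' `t = R * sqrt(n-2) / sqrt(1-R^2)` on `n - 2` degrees of freedom.
#' A gene passes when `R > min_r` and `P <= alpha`: amplification-driven
#' overexpression implies a positive dosage-expression association. A
#' constant input vector leaves R undefined; the gene is reported as
#' non-passing with `degenerate = TRUE` rather than raising an error.
#'
#' @param cn,expr paired per-sample values (same length, n >= 3).
#' @param alpha two-sided significance threshold (inclusive).
#' @param min_r lower bound on R (strict; default 0 requires positivity).
#' @return data.frame(r, p, n, passes, degenerate), one row.
#' @export
pearson_filter <- function(cn, expr, alpha = 0.05, min_r = 0) {
  if (length(cn) != length(expr)) stop("cn and expr must have equal length")
  n <- length(cn)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(cn) == 0 || stats::sd(expr) == 0)
    return(data.frame(r = NA_real_, p = NA_real_, n = n, passes = FALSE,
                      degenerate = TRUE))
  r <- stats::cor(cn, expr)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  data.frame(r = r, p = p, n = n, passes = r > min_r && p <= alpha,
             degenerate = FALSE)
}

#' Apply the correlation filter to a ranked candidate list
#'
#' Partitions correlation results into passing and discarded genes,
#' preserving the input order in both lists.
#'
#' @param results data.frame with columns `gene` and `passes` (one row per
#'   top-ranked gene, e.g. built with [pearson_filter()]).
#' @return list(`passing`, `discarded`): complementary row subsets.
#' @export
apply_table2_filter <- function(results) {
  stopifnot(all(c("gene", "passes") %in% names(results)))
  pass <- results[results$passes, , drop = FALSE]
  fail <- results[!results$passes, , drop = FALSE]
  rownames(pass) <- rownames(fail) <- NULL
  list(passing = pass, discarded = fail)
}
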