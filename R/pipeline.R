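#' Pipeline configuration
#'
#' Collects every threshold of the analysis in one place: amplification calls
#' at copy number > 3.5, overexpression at fold change >= 2, significant
#' regions at q < 0.25, candidate ranking at pct >= 50, correlation filter at
#' two-sided P <= 0.05 with R > `min_r`.
#'
#' Exactly one of `sim` (a [sim_config()]: the cohort is generated and its
#' input files written under `out_dir`) or `inputs` (named list of paths:
#' `probes`, `lrr`, `baf`, `genes`, `expr`, `ref`, optional `ct_table`) must
#' be supplied.
#'
#' @param out_dir output directory (created if needed).
#' @param sim optional [sim_config()].
#' @param inputs optional named list of input paths.
#' @param seed seed for the permutation null (and simulation, when `sim` is
#'   given without its own seed).
#' @param n_perm permutations for the G-score null.
#' @param q_cutoff,amplification_cn,overexpression_fc,min_pct,alpha,min_r
#'   decision thresholds.
#' @param c_max,penalty copy-number caller settings.
#' @param n_genes_per_chrom gene models per chromosome when simulating.
#' @export
pipeline_config <- function(out_dir, sim = NULL, inputs = NULL, seed = 1L,
                            n_perm = 1000L, q_cutoff = 0.25,
                            amplification_cn = 3.5, overexpression_fc = 2,
                            min_pct = 50, alpha = 0.05, min_r = 0,
                            c_max = 12L, penalty = NULL,
                            n_genes_per_chrom = 20L) {
  if (is.null(sim) == is.null(inputs))
    stop("supply exactly one of 'sim' or 'inputs'")
  if (q_cutoff <= 0 || q_cutoff >= 1) stop("q_cutoff must be in (0,1)")
  if (amplification_cn <= 0 || overexpression_fc <= 0 || min_pct < 0)
    stop("thresholds must be positive")
  structure(list(out_dir = out_dir, sim = sim, inputs = inputs,
                 seed = as.integer(seed), n_perm = as.integer(n_perm),
                 q_cutoff = q_cutoff, amplification_cn = amplification_cn,
                 overexpression_fc = overexpression_fc, min_pct = min_pct,
                 alpha = alpha, min_r = min_r, c_max = as.integer(c_max),
                 penalty = penalty,
                 n_genes_per_chrom = as.integer(n_genes_per_chrom)),
            class = "pipeline_config")
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

with_stage <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  log_stage(stage, "done in %.1fs", proc.time()[["elapsed"]] - t0)
  res
}

#' Run the full amplicon-to-candidate-oncogene pipeline
#'
#' Stages, in order: (optional) qPCR cohort screen; absolute copy-number
#' calling from LRR/BAF; G-score scan for significantly amplified regions;
#' copy-number/expression integration and candidate ranking. Every output is
#' a text file under `config$out_dir`; `manifest.json` lists each artifact
#' with its md5 checksum, so a rerun with the same seed is verifiably
#' identical. Logs go to stderr; results never do.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the manifest as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  artifacts <- character(0)
  add <- function(p) artifacts <<- c(artifacts, p)

  if (!is.null(config$sim)) {
    sim_out <- with_stage("simulate", {
      cohort <- simulate_cohort(config$sim)
      genes <- synthetic_gene_models(config$sim, config$n_genes_per_chrom)
      expr <- simulate_expression(config$sim, cohort$truth, genes)
      add(write_probes_tsv(cohort$data$probes, path("probes.tsv")))
      add(write_matrix_tsv(cohort$data$lrr, path("lrr.tsv")))
      add(write_matrix_tsv(cohort$data$baf, path("baf.tsv")))
      add(write_genes_bed(genes, path("genes.bed")))
      add(write_matrix_tsv(expr$tumour, path("expression.tsv")))
      add(write_matrix_tsv(expr$reference, path("expression_reference.tsv")))
      add(write_json_file(list(ploidy = as.list(cohort$truth$ploidy)),
                          path("truth.json")))
      list(probes = cohort$data$probes, lrr = cohort$data$lrr,
           baf = cohort$data$baf, sample_ids = cohort$data$sample_ids,
           genes = genes, expr = expr$tumour, ref = expr$reference)
    })
    probes <- sim_out$probes; lrr <- sim_out$lrr; baf <- sim_out$baf
    sample_ids <- sim_out$sample_ids; genes <- sim_out$genes
    expr <- sim_out$expr; ref <- sim_out$ref
    screen_res <- NULL
  } else {
    inp <- config$inputs
    loaded <- with_stage("load", {
      need <- c("probes", "lrr", "baf", "genes", "expr", "ref")
      miss <- setdiff(need, names(inp))
      if (length(miss)) stop("missing input path(s): ", paste(miss, collapse = ", "))
      for (f in need) if (!file.exists(inp[[f]]))
        stop("input file not found: ", inp[[f]])
      list(probes = read_probes_tsv(inp$probes),
           lrr = read_matrix_tsv(inp$lrr), baf = read_matrix_tsv(inp$baf),
           genes = read_genes_bed(inp$genes),
           expr = read_matrix_tsv(inp$expr), ref = read_matrix_tsv(inp$ref))
    })
    probes <- loaded$probes; lrr <- loaded$lrr; baf <- loaded$baf
    sample_ids <- colnames(lrr); genes <- loaded$genes
    expr <- loaded$expr; ref <- loaded$ref

    screen_res <- NULL
    if (!is.null(inp$ct_table)) {
      screen_res <- with_stage("screen", {
        ct <- as.data.frame(data.table::fread(inp$ct_table, sep = "\t"))
        calls <- dosage_calls_from_ct(aggregate_ct(ct))
        res <- screen_cohort(calls)
        utils::write.table(res$summary, path("screen_summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        add(path("screen_summary.tsv"))
        res
      })
    }
  }

  profiles <- with_stage("callcn", {
    data <- list(probes = probes, lrr = lrr, baf = baf,
                 sample_ids = sample_ids)
    profs <- call_cohort_cn(data, penalty = config$penalty,
                            c_max = config$c_max)
    add(write_segments_tsv(profs, path("segments.tsv")))
    cnm <- vapply(profs, `[[`, numeric(nrow(probes)), "cn")
    rownames(cnm) <- probes$probe_id
    add(write_matrix_tsv(cnm, path("cn_matrix.tsv")))
    pl <- data.frame(sample = names(profs),
                     ploidy = vapply(profs, `[[`, 0L, "ploidy"))
    utils::write.table(pl, path("ploidy.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(path("ploidy.tsv"))
    profs
  })

  scores <- with_stage("regions", {
    A <- build_amplitude_matrix(profiles, probes)
    sc <- score_markers(A, probes, n_perm = config$n_perm, seed = config$seed)
    utils::write.table(sc, path("marker_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add(path("marker_scores.tsv"))
    regs <- significant_regions(sc, cutoff = config$q_cutoff)
    utils::write.table(regs, path("regions.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(path("regions.tsv"))
    list(markers = sc, regions = regs)
  })

  integration <- with_stage("integrate", {
    cnm <- vapply(profiles, `[[`, numeric(nrow(probes)), "cn")
    rownames(cnm) <- probes$probe_id
    gcn <- gene_cn_matrix(genes, cnm, probes)
    status <- status_matrix(gcn, expr, ref,
                            amp_cn = config$amplification_cn,
                            over_fc = config$overexpression_fc)
    status$code <- ifelse(status$amplified & status$overexpressed, "AO",
                   ifelse(status$amplified, "A",
                   ifelse(status$overexpressed, "O", "none")))
    utils::write.table(status, path("status_matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add(path("status_matrix.tsv"))
    oa <- summarize_oa(status)
    utils::write.table(oa, path("oa_summary.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(path("oa_summary.tsv"))
    top <- rank_candidates(oa, min_pct = config$min_pct)
    cors <- do.call(rbind, lapply(top$gene, function(g) {
      samples <- intersect(colnames(gcn), colnames(expr))
      cbind(gene = g, pearson_filter(gcn[g, samples], expr[g, samples],
                                     alpha = config$alpha,
                                     min_r = config$min_r))
    }))
    if (is.null(cors))
      cors <- data.frame(gene = character(0), r = numeric(0), p = numeric(0),
                         n = integer(0), passes = logical(0),
                         degenerate = logical(0))
    utils::write.table(cors, path("correlations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add(path("correlations.tsv"))
    part <- apply_table2_filter(cors)
    add(write_json_file(list(candidates = part$passing$gene,
                             discarded = part$discarded$gene,
                             ranking = top),
                        path("candidates.json")))
    list(status = status, oa = oa, top = top, correlations = cors,
         filtered = part)
  })

  manifest <- list(
    out_dir = config$out_dir,
    seed = config$seed,
    status = "complete",
    artifacts = lapply(unique(artifacts), function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
  )
  write_json_file(manifest, path("manifest.json"))
  log_stage("pipeline", "complete: %d artifacts", length(manifest$artifacts))
  invisible(list(manifest = manifest, screen = screen_res,
                 scores = scores, integration = integration))
}
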