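#' Simulation configuration for a synthetic SNP-array tumour cohort
#'
#' Builds the parameter object consumed by [simulate_cohort()] and
#' [simulate_expression()]. The generator emulates the data structure of an
#' Illumina-style SNP array cohort of osteosarcomas carrying focal 17p
#' amplicons: per-probe LogR ratio (LRR) centred on `log2(CN/2)` and B-allele
#' frequency (BAF) centred on `b/CN` for the sample's allele split, with
#' focal amplicons of fixed integer copy number superimposed on a variable
#' whole-genome ploidy, and expression in which a configurable fraction of
#' amplified gene--sample pairs responds to gene dosage.
#'
#' Defaults describe a desk-scale cohort (about 5,000 probes over three
#' chromosomes, 20 tumours, two chr17 amplicons of copy number 6 at 13.5 and
#' 17.2 Mb with 50\% penetrance). A full-size array (~370k probes) is reached
#' by enlarging `chrom_layout`; nothing else changes.
#'
#' @param n_tumours number of tumour samples.
#' @param chrom_layout data.frame with columns `chrom`, `n_probes` (>= 2),
#'   `length_bp`. Probes are evenly spaced along each chromosome.
#' @param ploidy_dist named numeric vector: probabilities over integer
#'   ploidies (names are the ploidies). Must sum to 1.
#' @param amplicons list of amplicon specifications from [amplicon_spec()].
#' @param lrr_sd,baf_sd Gaussian noise standard deviations for LRR and BAF.
#' @param pop_allele_freq population B-allele frequency in (0,1) used to draw
#'   germline genotypes (one draw per probe per sample).
#' @param expr_baseline_mean,expr_baseline_sd log2-scale mean/sd of per-gene
#'   baseline expression.
#' @param dosage_slope log2 expression change per log2 copy-number ratio for
#'   dosage-coupled gene--sample pairs.
#' @param dosage_coupling probability that an amplified gene responds to
#'   dosage in a given sample. Scalar, or a vector recycled over genes (named
#'   by gene to be explicit).
#' @param expr_sd log2-scale expression noise sd.
#' @param seed integer root seed; per-sample child seeds are derived by fixed
#'   arithmetic so cohorts are reproducible under subsetting.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_tumours = 20,
                       chrom_layout = data.frame(
                         chrom = c("chr17", "chr1", "chr2"),
                         n_probes = c(2500L, 1500L, 1000L),
                         length_bp = c(81e6, 249e6, 243e6)
                       ),
                       ploidy_dist = c("2" = 0.6, "3" = 0.3, "4" = 0.1),
                       amplicons = list(
                         amplicon_spec("chr17", center_bp = 13.5e6, width_bp = 3e6,
                                       copy_number = 6L, penetrance = 0.5),
                         amplicon_spec("chr17", center_bp = 17.2e6, width_bp = 2e6,
                                       copy_number = 6L, penetrance = 0.5)
                       ),
                       lrr_sd = 0.15, baf_sd = 0.03,
                       pop_allele_freq = 0.5,
                       expr_baseline_mean = 8, expr_baseline_sd = 1,
                       dosage_slope = 1, dosage_coupling = 0.65,
                       expr_sd = 0.25,
                       seed = 1L) {
  stopifnot(is.data.frame(chrom_layout),
            all(c("chrom", "n_probes", "length_bp") %in% names(chrom_layout)))
  if (n_tumours < 1) stop("n_tumours must be >= 1")
  if (any(chrom_layout$n_probes < 2)) stop("each chromosome needs >= 2 probes")
  if (abs(sum(ploidy_dist) - 1) > 1e-8) stop("ploidy_dist probabilities must sum to 1")
  if (is.null(names(ploidy_dist))) stop("ploidy_dist must be named by integer ploidy")
  if (lrr_sd < 0 || baf_sd < 0 || expr_sd < 0) stop("noise sds must be >= 0")
  if (pop_allele_freq <= 0 || pop_allele_freq >= 1) stop("pop_allele_freq must be in (0,1)")
  if (any(dosage_coupling < 0) || any(dosage_coupling > 1))
    stop("dosage_coupling must be in [0,1]")
  for (a in amplicons) {
    row <- match(a$chrom, chrom_layout$chrom)
    if (is.na(row)) stop("amplicon on unknown chromosome '", a$chrom, "'")
    lo <- a$center_bp - a$width_bp / 2
    hi <- a$center_bp + a$width_bp / 2
    if (lo < 0 || hi > chrom_layout$length_bp[row])
      stop(sprintf(
        "amplicon %s:%g+/-%g (CN %d) extends outside chromosome bounds [0, %g)",
        a$chrom, a$center_bp, a$width_bp / 2, a$copy_number,
        chrom_layout$length_bp[row]))
  }
  cfg <- list(n_tumours = as.integer(n_tumours), chrom_layout = chrom_layout,
              ploidy_dist = ploidy_dist, amplicons = amplicons,
              lrr_sd = lrr_sd, baf_sd = baf_sd,
              pop_allele_freq = pop_allele_freq,
              expr_baseline_mean = expr_baseline_mean,
              expr_baseline_sd = expr_baseline_sd,
              dosage_slope = dosage_slope, dosage_coupling = dosage_coupling,
              expr_sd = expr_sd, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Focal amplicon specification
#'
#' @param chrom chromosome label (must appear in the cohort layout).
#' @param center_bp,width_bp amplicon centre and width in bp; the amplicon
#'   covers `[center - width/2, center + width/2)`.
#' @param copy_number integer total copy number (>= 3) in carrier samples.
#' @param penetrance fraction of tumours carrying the amplicon, in [0,1].
#' @export
amplicon_spec <- function(chrom, center_bp, width_bp, copy_number, penetrance) {
  if (width_bp <= 0) stop("amplicon width must be > 0")
  if (copy_number < 3) stop("amplicon copy_number must be >= 3")
  if (penetrance < 0 || penetrance > 1) stop("penetrance must be in [0,1]")
  list(chrom = chrom, center_bp = center_bp, width_bp = width_bp,
       copy_number = as.integer(copy_number), penetrance = penetrance)
}

# Child seed for sample i (or any derived stream), kept below 2^31.
child_seed <- function(root, i) as.integer((as.numeric(root) + 104729 * i) %% 2147483647)

probe_table <- function(chrom_layout) {
  out <- do.call(rbind, lapply(seq_len(nrow(chrom_layout)), function(r) {
    n <- chrom_layout$n_probes[r]
    pos <- floor((seq_len(n) - 0.5) * chrom_layout$length_bp[r] / n)
    data.frame(probe_id = sprintf("%s_p%05d", chrom_layout$chrom[r], seq_len(n)),
               chrom = chrom_layout$chrom[r], pos = pos,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a SNP-array cohort with known copy-number truth
#'
#' For every probe of every tumour: germline genotype is drawn once with the
#' population B-allele frequency; total copy number is the sample's ploidy
#' except inside amplicons the sample carries, where it is overwritten by the
#' amplicon copy number; for heterozygous probes one haplotype is picked
#' uniformly to carry all extra copies, so the B-allele count is 1 or CN-1.
#' Observed signals are `LRR = log2(CN/2) + N(0, lrr_sd)` and
#' `BAF = b/CN + N(0, baf_sd)` truncated to [0,1]. Copy-number-zero probes
#' emit no allelic signal: BAF uniform on [0,1], LRR floored at -5.
#'
#' @param config a [sim_config()] object.
#' @return list with elements
#'   \item{data}{list: `probes` (probe_id/chrom/pos), `lrr` and `baf`
#'     matrices (probes x samples), `sample_ids`}
#'   \item{truth}{list: `ploidy` (named integer per sample), `cn` and
#'     `minor` matrices (true total CN and minor-allele count per probe),
#'     `carriers` (amplicon x sample logical), `probes`}
#' Deterministic given `config$seed`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  probes <- probe_table(config$chrom_layout)
  M <- nrow(probes)
  S <- config$n_tumours
  sample_ids <- sprintf("OS%02d", seq_len(S))
  ploidies <- as.integer(names(config$ploidy_dist))

  # amplicon probe index sets (fixed geometry)
  amp_idx <- lapply(config$amplicons, function(a) {
    which(probes$chrom == a$chrom &
          probes$pos >= a$center_bp - a$width_bp / 2 &
          probes$pos <  a$center_bp + a$width_bp / 2)
  })

  lrr <- matrix(NA_real_, M, S, dimnames = list(probes$probe_id, sample_ids))
  baf <- lrr
  cn_true <- matrix(NA_integer_, M, S, dimnames = dimnames(lrr))
  minor_true <- cn_true
  carriers <- matrix(FALSE, length(config$amplicons), S,
                     dimnames = list(NULL, sample_ids))
  ploidy_vec <- stats::setNames(integer(S), sample_ids)

  for (s in seq_len(S)) {
    set.seed(child_seed(config$seed, s))
    ploidy <- ploidies[sample.int(length(ploidies), 1L,
                                  prob = config$ploidy_dist)]
    ploidy_vec[s] <- ploidy
    carry <- vapply(config$amplicons,
                    function(a) stats::runif(1) < a$penetrance, logical(1))
    carriers[, s] <- carry

    cn <- rep.int(ploidy, M)
    for (j in seq_along(config$amplicons)) {
      if (carry[j]) cn[amp_idx[[j]]] <- config$amplicons[[j]]$copy_number
    }

    # germline genotype: B copies out of 2 haplotypes
    geno <- stats::rbinom(M, 2L, config$pop_allele_freq)
    # allele split at CN c: hom keeps 0 or c B copies; het puts the extra
    # copies on one haplotype chosen uniformly -> b in {1, c-1}
    hap_coin <- stats::runif(M) < 0.5
    b <- integer(M)
    b[geno == 2L] <- cn[geno == 2L]
    het <- geno == 1L & cn >= 1L
    b[het] <- ifelse(hap_coin[het], cn[het] - 1L, 1L)
    b[cn == 0L] <- 0L

    lrr_mu <- ifelse(cn > 0L, log2(cn / 2), -5)
    lrr[, s] <- lrr_mu + stats::rnorm(M, 0, config$lrr_sd)
    baf_mu <- ifelse(cn > 0L, b / pmax(cn, 1L), NA_real_)
    noise <- stats::rnorm(M, 0, config$baf_sd)
    b_obs <- ifelse(cn > 0L, baf_mu + noise, stats::runif(M))
    baf[, s] <- pmin(1, pmax(0, b_obs))

    cn_true[, s] <- cn
    minor_true[, s] <- pmin(b, cn - b)
  }
  list(
    data = list(probes = probes, lrr = lrr, baf = baf, sample_ids = sample_ids),
    truth = list(ploidy = ploidy_vec, cn = cn_true, minor = minor_true,
                 carriers = carriers, probes = probes)
  )
}

#' Evenly spaced synthetic gene models
#'
#' Places `n_per_chrom` non-overlapping genes per chromosome (width = one
#' third of the spacing), named `<chrom>_g<k>`. Coordinates are 0-based
#' half-open, matching BED.
#'
#' @param config a [sim_config()].
#' @param n_per_chrom genes per chromosome.
#' @return data.frame(name, chrom, start, end)
#' @export
synthetic_gene_models <- function(config, n_per_chrom = 20L) {
  cl <- config$chrom_layout
  out <- do.call(rbind, lapply(seq_len(nrow(cl)), function(r) {
    spacing <- cl$length_bp[r] / n_per_chrom
    start <- floor((seq_len(n_per_chrom) - 1) * spacing + spacing / 3)
    end <- floor(start + spacing / 3)
    data.frame(name = sprintf("%s_g%02d", cl$chrom[r], seq_len(n_per_chrom)),
               chrom = cl$chrom[r], start = start, end = end,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate expression for tumours and an osteoblast-like reference
#'
#' log2 expression of gene g in sample s is
#' `baseline(g) + dosage_slope * log2(CN(g,s)/2) * coupled(g,s) + N(0, expr_sd)`;
#' the reference column is `baseline(g) + N(0, expr_sd)`. `coupled(g,s)` is a
#' Bernoulli(dosage_coupling) draw: it models the observation that only a
#' fraction of amplified tumours overexpress a given amplified gene. Gene
#' copy number is read from the truth matrix with the same
#' median/nearest-probe rule the integration stage uses
#' ([gene_copy_number()]). Matrices are returned on the linear scale.
#'
#' @param config a [sim_config()].
#' @param truth truth component returned by [simulate_cohort()].
#' @param genes gene models (data.frame name/chrom/start/end), e.g. from
#'   [synthetic_gene_models()].
#' @return list: `tumour` (genes x samples, linear), `reference` (genes x 1,
#'   linear), `coupled` (logical genes x samples), `log2_mean` (noise-free
#'   log2 means), `gene_cn` (true gene-level CN used).
#' @export
simulate_expression <- function(config, truth, genes) {
  stopifnot(inherits(config, "sim_config"))
  bad <- !genes$chrom %in% config$chrom_layout$chrom
  if (any(bad)) stop("gene(s) outside chrom_layout: ",
                     paste(genes$name[bad], collapse = ", "))
  G <- nrow(genes)
  S <- ncol(truth$cn)
  gene_cn <- gene_cn_matrix(genes, truth$cn, truth$probes)

  set.seed(child_seed(config$seed, 0) )
  baseline <- stats::rnorm(G, config$expr_baseline_mean, config$expr_baseline_sd)

  coupling <- rep_len(config$dosage_coupling, G)
  set.seed(child_seed(config$seed, -1))
  coupled <- matrix(stats::runif(G * S) < coupling, G, S,
                    dimnames = dimnames(gene_cn))

  set.seed(child_seed(config$seed, -2))
  dosage <- config$dosage_slope * log2(pmax(gene_cn, 0.5) / 2) * coupled
  log2_mean <- baseline + dosage
  tumour <- 2 ^ (log2_mean + matrix(stats::rnorm(G * S, 0, config$expr_sd), G, S))
  reference <- matrix(2 ^ (baseline + stats::rnorm(G, 0, config$expr_sd)), G, 1,
                      dimnames = list(genes$name, "osteoblast"))
  dimnames(tumour) <- dimnames(gene_cn)
  dimnames(log2_mean) <- dimnames(gene_cn)
  list(tumour = tumour, reference = reference, coupled = coupled,
       log2_mean = log2_mean, gene_cn = gene_cn)
}
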