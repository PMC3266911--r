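#' Amplification amplitude matrix
#'
#' Per marker and sample, the amplitude of amplification above the sample's
#' own ploidy: `a(m, s) = max(0, CN(m, s) - ploidy(s))`. Losses are ignored.
#' Measuring against per-sample ploidy (not 2) is the aneuploidy correction:
#' whole-genome triploidy contributes no amplitude, focal peaks on top of it
#' do.
#'
#' @param profiles list of `cn_profile` objects sharing one probe list.
#' @param probes the shared probe data.frame.
#' @return numeric matrix (markers x samples).
#' @export
build_amplitude_matrix <- function(profiles, probes) {
  M <- nrow(probes)
  for (p in profiles) {
    if (length(p$cn) != M)
      stop(sprintf("probe mismatch: sample '%s' has %d probes, expected %d",
                   p$sample_id, length(p$cn), M))
  }
  A <- vapply(profiles, function(p) pmax(0, p$cn - p$ploidy), numeric(M))
  dimnames(A) <- list(probes$probe_id,
                      vapply(profiles, `[[`, "", "sample_id"))
  A
}

#' Per-marker G-score
#'
#' Mean amplification amplitude across samples, `G(m) = sum_s a(m,s) / N`.
#' A marker amplified in many samples or at high amplitude (or both) scores
#' high: the score jointly encodes frequency and amplitude of aberration.
#'
#' @param A amplitude matrix (markers x samples), entries >= 0.
#' @return numeric vector of G-scores.
#' @export
gscore <- function(A) {
  if (any(A < 0)) stop("amplitudes must be >= 0")
  rowMeans(A)
}

#' Permutation p-values for G-scores under a cyclic-shift null
#'
#' Each permutation independently rotates every sample's amplitude vector by
#' a uniform random offset within each chromosome, preserving each sample's
#' amplitude content and segment lengths while destroying cross-sample
#' positional alignment. Permuted G values are pooled across all markers and
#' permutations (a genome-wide null), and
#' `p(m) = (1 + #\{pooled >= G_obs(m)\}) / (1 + n_perm * M)`.
#'
#' Implementation note: the null accumulates only the non-zero amplitude
#' runs, so cost scales with the amplified fraction of the genome rather
#' than the marker count.
#'
#' @param A amplitude matrix (markers x samples).
#' @param chrom chromosome label per marker (row order of `A`).
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed; results are reproducible given the seed.
#' @return numeric vector of p-values in (0, 1].
#' @export
permutation_null <- function(A, chrom, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  M <- nrow(A); S <- ncol(A)
  stopifnot(length(chrom) == M)
  g_obs <- gscore(A)

  chr_levels <- unique(as.character(chrom))
  chr_idx <- lapply(chr_levels, function(ch) which(chrom == ch))

  # sparse support: per (sample, chromosome) the local offsets and values of
  # non-zero amplitudes
  supports <- list()
  for (s in seq_len(S)) {
    for (ci in seq_along(chr_idx)) {
      gi <- chr_idx[[ci]]
      v <- A[gi, s]
      nz <- which(v > 0)
      if (length(nz))
        supports[[length(supports) + 1L]] <-
          list(local = nz, val = v[nz], L = length(gi), offset0 = gi[1] - 1L)
    }
  }

  set.seed(seed)
  total <- as.numeric(n_perm) * M
  nz_perm <- vector("list", n_perm)
  for (p in seq_len(n_perm)) {
    if (!length(supports)) break
    idx_all <- integer(0); val_all <- numeric(0)
    for (sp in supports) {
      off <- sample.int(sp$L, 1L) - 1L
      idx_all <- c(idx_all, sp$offset0 + ((sp$local - 1L + off) %% sp$L) + 1L)
      val_all <- c(val_all, sp$val)
    }
    agg <- rowsum(val_all, idx_all)   # sum across samples at each marker
    nz_perm[[p]] <- agg[, 1] / S
  }
  pooled <- sort(unlist(nz_perm, use.names = FALSE))

  p <- vapply(g_obs, function(g) {
    n_ge <- if (g <= 0) total
            else length(pooled) - findInterval(g, pooled, left.open = TRUE)
    (1 + n_ge) / (1 + total)
  }, numeric(1))
  names(p) <- rownames(A)
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j` (cumulative
#' minimum from the largest p), capped at 1 and returned in input order.
#'
#' @param p numeric p-values in [0, 1].
#' @return q-values in [0, 1].
#' @export
fdr_q <- function(p) {
  if (any(p < 0 | p > 1 | !is.finite(p))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Score a marker set: G, permutation p and BH q per marker
#'
#' @param A amplitude matrix.
#' @param probes probe data.frame (row order of `A`).
#' @inheritParams permutation_null
#' @return data.frame(probe_id, chrom, pos, g, p, q)
#' @export
score_markers <- function(A, probes, n_perm = 1000L, seed = 1L) {
  g <- gscore(A)
  p <- permutation_null(A, probes$chrom, n_perm = n_perm, seed = seed)
  data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
             pos = probes$pos, g = g, p = unname(p), q = fdr_q(unname(p)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Significantly amplified regions at a q-value cutoff
#'
#' Maximal runs of consecutive markers (within a chromosome) with
#' `q < cutoff`; each region reports one peak, the marker of maximal G
#' (leftmost on ties). Region coordinates are half-open: `start` is the first
#' significant marker's position and `end` the last's position + 1.
#'
#' @param marker_scores data.frame from [score_markers()] (columns `chrom`,
#'   `pos`, `g`, `q`).
#' @param cutoff q-value threshold (strict `<`); the conventional value
#'   is 0.25.
#' @return data.frame(chrom, start, end, n_markers, peak_pos, peak_g,
#'   peak_q), possibly with zero rows.
#' @export
significant_regions <- function(marker_scores, cutoff = 0.25) {
  out <- list()
  for (ch in unique(marker_scores$chrom)) {
    sub <- marker_scores[marker_scores$chrom == ch, , drop = FALSE]
    sig <- sub$q < cutoff
    if (!any(sig)) next
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      run <- starts[j]:ends[j]
      peak <- run[which.max(sub$g[run])]   # ties -> leftmost
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = sub$pos[starts[j]],
        end = sub$pos[ends[j]] + 1,
        n_markers = length(run),
        peak_pos = sub$pos[peak],
        peak_g = sub$g[peak],
        peak_q = sub$q[peak],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_markers = integer(0),
                      peak_pos = numeric(0), peak_g = numeric(0),
                      peak_q = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
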