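#' Greedy binary segmentation of an LRR vector
#'
#' Recursively splits the vector at the position that most reduces the
#' within-segment sum of squared error; a split is accepted iff the SSE
#' reduction strictly exceeds `penalty`. Ties go to the smallest index, so
#' the result is deterministic. Operates on one chromosome at a time.
#'
#' @param x numeric LRR values (finite).
#' @param penalty positive acceptance penalty. `NULL` uses a BIC-like default
#'   `2 * sigma^2 * log(n)` with `sigma` estimated robustly from median
#'   absolute successive differences (see [bic_penalty()]).
#' @param probe_ids optional ids used in error messages for non-finite input.
#' @return sorted integer vector of breakpoints `k`: each segment ends at `k`
#'   and the next begins at `k + 1`. Empty vector when no split is accepted.
#' @export
segment_profile <- function(x, penalty = NULL, probe_ids = NULL) {
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x))
    ids <- if (is.null(probe_ids)) as.character(bad) else probe_ids[bad]
    stop("non-finite LRR at probe(s): ", paste(utils::head(ids, 10), collapse = ", "))
  }
  n <- length(x)
  if (is.null(penalty)) penalty <- bic_penalty(x)
  if (penalty <= 0) stop("penalty must be > 0")
  if (n < 2) return(integer(0))

  s <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x * x))
  seg_cost <- function(a, b) (s2[b + 1] - s2[a]) - (s[b + 1] - s[a])^2 / (b - a + 1)

  breaks <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    rg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- rg[1]; hi <- rg[2]
    if (hi - lo < 1L) next
    k <- lo:(hi - 1L)
    nl <- k - lo + 1; nr <- hi - k
    sl <- s[k + 1] - s[lo]; sr <- s[hi + 1] - s[k + 1]
    cost_l <- (s2[k + 1] - s2[lo]) - sl^2 / nl
    cost_r <- (s2[hi + 1] - s2[k + 1]) - sr^2 / nr
    red <- seg_cost(lo, hi) - (cost_l + cost_r)
    i <- which.max(red)                     # ties -> smallest index
    if (red[i] > penalty) {
      breaks <- c(breaks, k[i])
      stack[[length(stack) + 1L]] <- c(lo, k[i])
      stack[[length(stack) + 1L]] <- c(k[i] + 1L, hi)
    }
  }
  sort(breaks)
}

#' BIC-like segmentation penalty
#'
#' `2 * sigma^2 * log(n)`, with `sigma` from the median absolute successive
#' difference scaled to a Gaussian sd (`/ (sqrt(2) * qnorm(0.75))`). Floored
#' at `1e-8` so that noise-free input still splits only at exact steps.
#'
#' @param x numeric vector.
#' @export
bic_penalty <- function(x) {
  n <- length(x)
  sigma <- stats::median(abs(diff(x))) / (sqrt(2) * stats::qnorm(0.75))
  max(2 * sigma^2 * log(max(n, 2)), 1e-8)
}

#' Fit integer copy number and minor-allele count to segment means
#'
#' Grid search over total copy number `c` in `0..c_max` and B-allele count
#' `b` in `0..floor(c/2)` minimising
#' `w_lrr * (meanLRR - log2(max(c, 0.5)/2))^2 + w_baf * (mBAF - target)^2`
#' where the mirrored-BAF target is `b/c` (0.5 for `c = 0`, which carries no
#' allelic signal). Ties resolve to the smaller `c`, then smaller `b`. When
#' `mean_mbaf` is `NA` (no allelically informative probe in the segment) the
#' BAF term is dropped and the tie-break returns `b = 0`.
#'
#' @param mean_lrr segment mean LRR.
#' @param mean_mbaf segment mean mirrored BAF (`min(BAF, 1-BAF)`), or `NA`.
#' @param c_max maximum copy number considered (>= 2).
#' @param w_lrr,w_baf objective weights.
#' @return named integer vector `c(cn = , b = )`.
#' @export
fit_segment_cn <- function(mean_lrr, mean_mbaf, c_max = 12L, w_lrr = 1, w_baf = 1) {
  if (c_max < 2) stop("c_max must be >= 2")
  best <- c(cn = NA_integer_, b = NA_integer_)
  best_obj <- Inf
  for (cc in 0:c_max) {
    lrr_target <- log2(max(cc, 0.5) / 2)
    for (bb in 0:(cc %/% 2)) {
      baf_target <- if (cc > 0) bb / cc else 0.5
      obj <- w_lrr * (mean_lrr - lrr_target)^2
      if (!is.na(mean_mbaf)) obj <- obj + w_baf * (mean_mbaf - baf_target)^2
      if (obj < best_obj) {           # strict: ties keep smaller c, then b
        best_obj <- obj
        best <- c(cn = cc, b = bb)
      }
    }
  }
  best
}

#' Probe-weighted modal ploidy of a segmented profile
#'
#' The sample ploidy is the copy number covering the largest number of probes
#' genome-wide; ties resolve to the smaller ploidy. Used to correct for
#' aneuploidy: gained/lost labels and amplification amplitudes are relative
#' to this baseline, so focal peaks on a triploid background are still seen
#' as gains.
#'
#' @param segments data.frame with columns `cn` and `n_probes`.
#' @return integer ploidy.
#' @export
estimate_ploidy <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0) stop("empty profile: no segments")
  w <- tapply(segments$n_probes, segments$cn, sum)
  cns <- as.integer(names(w))
  cns[order(-w, cns)][1]
}

#' Label segments relative to sample ploidy
#'
#' @param segments segment data.frame with a `cn` column.
#' @param ploidy integer >= 1.
#' @return `segments` with a `label` column in
#'   `{"normal", "gained", "lost"}`: gained iff `cn > ploidy`, lost iff
#'   `cn < ploidy`.
#' @export
label_segments <- function(segments, ploidy) {
  if (ploidy < 1) stop("ploidy must be >= 1")
  segments$label <- ifelse(segments$cn > ploidy, "gained",
                    ifelse(segments$cn < ploidy, "lost", "normal"))
  segments
}

#' Absolute integer copy-number profile of one sample
#'
#' Segments the LRR genome-wide (per chromosome), fits integer copy number
#' and allele count to each segment from its mean LRR and mean mirrored BAF,
#' estimates ploidy as the probe-weighted modal copy number, and labels each
#' segment gained/lost/normal relative to ploidy. Probes with mirrored BAF
#' below `min_mbaf` (effectively homozygous, hence uninformative about
#' allelic imbalance) are excluded from the segment's mBAF mean.
#'
#' @param lrr,baf numeric vectors over probes (one sample).
#' @param probes data.frame(probe_id, chrom, pos), positions sorted within
#'   chromosome.
#' @param sample_id sample label.
#' @param penalty segmentation penalty; `NULL` = per-chromosome BIC default.
#' @param c_max maximum fitted copy number.
#' @param min_mbaf homozygosity exclusion threshold for the mBAF mean.
#' @return object of class `cn_profile`: list with `sample_id`, `segments`
#'   (chrom, start, end (bp, half-open), start_idx, end_idx, n_probes,
#'   mean_lrr, mean_mbaf, cn, b, label), `cn` (integer per probe), `ploidy`.
#' @export
call_cn_profile <- function(lrr, baf, probes, sample_id = "S1", penalty = NULL,
                            c_max = 12L, min_mbaf = 0.05) {
  stopifnot(length(lrr) == nrow(probes), length(baf) == nrow(probes))
  mbaf <- pmin(baf, 1 - baf)
  chroms <- unique(probes$chrom)
  seg_rows <- list()
  for (ch in chroms) {
    idx <- which(probes$chrom == ch)
    bp <- segment_profile(lrr[idx], penalty, probe_ids = probes$probe_id[idx])
    starts <- c(1L, bp + 1L)
    ends <- c(bp, length(idx))
    for (j in seq_along(starts)) {
      gi <- idx[starts[j]:ends[j]]          # global probe indices
      mb <- mbaf[gi]
      mb_inf <- mb[mb >= min_mbaf]
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        chrom = ch,
        start = probes$pos[gi[1]],
        end = probes$pos[gi[length(gi)]] + 1,
        start_idx = gi[1], end_idx = gi[length(gi)] + 1L,
        n_probes = length(gi),
        mean_lrr = mean(lrr[gi]),
        mean_mbaf = if (length(mb_inf)) mean(mb_inf) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  segments <- do.call(rbind, seg_rows)
  fits <- t(vapply(seq_len(nrow(segments)),
                   function(i) fit_segment_cn(segments$mean_lrr[i],
                                              segments$mean_mbaf[i], c_max),
                   c(cn = 0L, b = 0L)))
  segments$cn <- as.integer(fits[, "cn"])
  segments$b <- as.integer(fits[, "b"])
  ploidy <- estimate_ploidy(segments)
  segments <- label_segments(segments, ploidy)

  cn <- integer(nrow(probes))
  for (i in seq_len(nrow(segments)))
    cn[segments$start_idx[i]:(segments$end_idx[i] - 1L)] <- segments$cn[i]

  structure(list(sample_id = sample_id, segments = segments, cn = cn,
                 ploidy = ploidy),
            class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("<cn_profile> sample %s: ploidy %d, %d segments, %d probes\n",
              x$sample_id, x$ploidy, nrow(x$segments), length(x$cn)))
  invisible(x)
}

#' Copy-number profiles for every sample of a cohort
#'
#' @param data cohort data list (`probes`, `lrr`, `baf`, `sample_ids`), as
#'   produced by [simulate_cohort()] or read from disk.
#' @param ... passed to [call_cn_profile()].
#' @return named list of `cn_profile` objects.
#' @export
call_cohort_cn <- function(data, ...) {
  profs <- lapply(seq_along(data$sample_ids), function(s) {
    call_cn_profile(data$lrr[, s], data$baf[, s], data$probes,
                    sample_id = data$sample_ids[s], ...)
  })
  names(profs) <- data$sample_ids
  profs
}
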