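# Independent brute-force oracles. These deliberately avoid the package's
# optimised code paths (prefix sums, pooled sorting, vectorised grids) so a
# shared bug cannot hide.

# within-segment SSE by direct summation
oracle_sse <- function(x) sum((x - mean(x))^2)

# best single split of x[lo:hi] by trying every k; returns NULL if no split
oracle_best_split <- function(x, lo, hi) {
  if (hi - lo < 1) return(NULL)
  best_k <- NA_integer_; best_red <- -Inf
  total <- oracle_sse(x[lo:hi])
  for (k in lo:(hi - 1)) {
    red <- total - oracle_sse(x[lo:k]) - oracle_sse(x[(k + 1):hi])
    if (red > best_red + 1e-12) {  # strict improvement: ties keep smallest k
      best_red <- red
      best_k <- k
    }
  }
  list(k = best_k, red = best_red)
}

# greedy binary segmentation, recursive, O(n^2) per level
oracle_segment <- function(x, penalty) {
  rec <- function(lo, hi) {
    sp <- oracle_best_split(x, lo, hi)
    if (is.null(sp) || sp$red <= penalty) return(integer(0))
    c(rec(lo, sp$k), sp$k, rec(sp$k + 1, hi))
  }
  sort(rec(1, length(x)))
}

# integer CN fit by naive double loop, evaluating the objective verbatim
oracle_fit_cn <- function(mean_lrr, mean_mbaf, c_max = 12, w_lrr = 1, w_baf = 1) {
  results <- data.frame()
  for (cc in 0:c_max) {
    for (bb in 0:floor(cc / 2)) {
      obj <- w_lrr * (mean_lrr - log2(max(cc, 0.5) / 2))^2
      if (!is.na(mean_mbaf)) {
        target <- if (cc > 0) bb / cc else 0.5
        obj <- obj + w_baf * (mean_mbaf - target)^2
      }
      results <- rbind(results, data.frame(cn = cc, b = bb, obj = obj))
    }
  }
  results <- results[order(results$obj, results$cn, results$b), ]
  c(cn = results$cn[1], b = results$b[1])
}

# G-score by explicit double loop
oracle_gscore <- function(A) {
  g <- numeric(nrow(A))
  for (m in seq_len(nrow(A))) {
    acc <- 0
    for (s in seq_len(ncol(A))) acc <- acc + A[m, s]
    g[m] <- acc / ncol(A)
  }
  g
}

# Pearson R and two-sided p by direct summation
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  r <- num / den
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# Benjamini-Hochberg by hand: sort, p * m / rank, cumulative min from the top
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  q <- numeric(m)
  q[o] <- pmin(adj, 1)
  q
}

# small single-chromosome layout used across tests
small_layout <- function(n17 = 400L, n1 = 300L) {
  data.frame(chrom = c("chr17", "chr1"), n_probes = c(n17, n1),
             length_bp = c(81e6, 249e6))
}

# build per-gene status rows realising printed (A, O, OA) counts over n samples
status_from_counts <- function(gene, A, O, OA, n = 20L) {
  amp <- c(rep(TRUE, OA), rep(TRUE, A - OA), rep(FALSE, O - OA),
           rep(FALSE, n - A - (O - OA)))
  over <- c(rep(TRUE, OA), rep(FALSE, A - OA), rep(TRUE, O - OA),
            rep(FALSE, n - A - (O - OA)))
  data.frame(gene = gene, sample = sprintf("T%02d", seq_len(n)),
             amplified = amp, overexpressed = over,
             stringsAsFactors = FALSE)
}
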