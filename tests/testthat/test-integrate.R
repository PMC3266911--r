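test_that("gene copy number: lower median of overlapping probes, else nearest", {
  probes <- data.frame(probe_id = paste0("p", 1:5), chrom = "chr17",
                       pos = c(100, 200, 300, 1000, 2000))
  gene <- list(chrom = "chr17", start = 50, end = 350)
  expect_equal(gene_copy_number(gene, c(4, 4, 6, 8, 8), probes), 4)
  # even count -> lower median keeps integers integral
  gene2 <- list(chrom = "chr17", start = 50, end = 1100)
  expect_equal(gene_copy_number(gene2, c(2, 4, 6, 8, 8), probes), 4)
  # no overlap -> nearest probe
  gene3 <- list(chrom = "chr17", start = 1400, end = 1500)
  expect_equal(gene_copy_number(gene3, c(2, 2, 2, 8, 3), probes), 8)
  # equidistant probes -> lower coordinate wins
  probes4 <- data.frame(probe_id = c("a", "b"), chrom = "chr17",
                        pos = c(100, 500))
  gene4 <- list(chrom = "chr17", start = 300, end = 301)
  # distances: 300-100 = 200 ; 500-301+1 = 200
  expect_equal(gene_copy_number(gene4, c(2, 6), probes4), 2)
  expect_error(gene_copy_number(gene, c(1), probes[0, ]), "empty probe list")
  expect_error(gene_copy_number(list(chrom = "chr9", start = 1, end = 2),
                                c(2, 2, 2, 2, 2), probes), "chr9")
})

test_that("status matrix computes fold change against the reference", {
  gcn <- matrix(c(2, 6, 2, 2), 2, 2,
                dimnames = list(c("gA", "gB"), c("T1", "T2")))
  expr <- matrix(c(10, 40, 20, 10), 2, 2,
                 dimnames = list(c("gA", "gB"), c("T1", "T2")))
  ref <- c(gA = 10, gB = 10)
  st <- status_matrix(gcn, expr, ref)
  a <- st[st$gene == "gA" & st$sample == "T1", ]
  expect_equal(a$fold_change, 1)
  expect_false(a$overexpressed)
  expect_false(a$amplified)
  # overexpressed without amplification: independent flags
  b <- st[st$gene == "gA" & st$sample == "T2", ]
  expect_equal(b$fold_change, 2)
  expect_true(b$overexpressed)
  expect_false(b$amplified)
  c_ <- st[st$gene == "gB" & st$sample == "T1", ]
  expect_true(c_$amplified)
  expect_true(c_$overexpressed)
  expect_error(status_matrix(gcn, expr, c(gA = 0, gB = 10)), "gA")
})

test_that("amplified genes under full coupling are all overexpressed", {
  cfg <- sim_config(n_tumours = 6, chrom_layout = small_layout(),
                    ploidy_dist = c("2" = 1), lrr_sd = 0, baf_sd = 0,
                    amplicons = list(amplicon_spec("chr17", 13.5e6, 4e6, 6L, 1)),
                    dosage_coupling = 1, dosage_slope = 1, expr_sd = 0,
                    seed = 3)
  sim <- simulate_cohort(cfg)
  genes <- data.frame(name = c("in1", "in2", "out"), chrom = "chr17",
                      start = c(12.5e6, 14e6, 40e6),
                      end = c(12.6e6, 14.1e6, 40.1e6))
  expr <- simulate_expression(cfg, sim$truth, genes)
  st <- status_matrix(expr$gene_cn, expr$tumour, expr$reference)
  amp <- st[st$amplified, ]
  expect_gt(nrow(amp), 0)
  expect_true(all(amp$overexpressed))          # fold 3 >= 2 at CN 6, slope 1
  expect_true(all(st$gene[st$amplified] %in% c("in1", "in2")))
})

test_that("O/A summary reproduces printed-count arithmetic", {
  st <- rbind(status_from_counts("SHMT1", 17, 15, 13),
              status_from_counts("PMP22", 16, 14, 12),
              status_from_counts("noamp", 0, 5, 0))
  oa <- summarize_oa(st)
  expect_equal(oa$pct_reported[oa$gene == "SHMT1"], 76.5)
  expect_equal(oa$pct_reported[oa$gene == "PMP22"], 75)
  expect_true(is.na(oa$pct[oa$gene == "noamp"]))
  expect_true(all(oa$OA <= pmin(oa$A, oa$O)))
})

test_that("OA <= min(A, O) on arbitrary random status tables", {
  set.seed(10)
  for (i in 1:10) {
    st <- data.frame(gene = sample(letters[1:4], 60, TRUE),
                     sample = sprintf("T%02d", 1:60),
                     amplified = runif(60) < 0.4,
                     overexpressed = runif(60) < 0.5)
    oa <- summarize_oa(st)
    expect_true(all(oa$OA <= pmin(oa$A, oa$O)))
    expect_true(all(is.na(oa$pct) | (oa$pct >= 0 & oa$pct <= 100)))
  }
})

test_that("candidate ranking keeps pct >= 50 sorted with stable tie-breaks", {
  tab <- os17p_top_genes()
  st <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    status_from_counts(tab$gene[i], tab$A[i], tab$O[i], tab$OA[i])))
  oa <- summarize_oa(st)
  top <- rank_candidates(oa, min_pct = 50)
  expect_equal(nrow(top), 11L)
  expect_equal(top$gene[1], "SHMT1")
  expect_equal(top$gene[11], "C17orf45")
  expect_true(all(diff(top$pct) <= 0))         # non-increasing
  # the two genes tied at 52.9 with equal OA sort alphabetically
  tied <- top$gene[round(top$pct, 1) == 52.9]
  expect_equal(tied, sort(tied))

  none <- rank_candidates(data.frame(gene = "g", A = 10L, O = 2L, OA = 2L,
                                     pct = 20, pct_reported = 20))
  expect_equal(nrow(none), 0L)
})

test_that("pearson filter: sign rule, significance rule, oracle agreement", {
  cn <- c(2, 2, 4, 6, 8)
  perfect <- pearson_filter(cn, 2 * cn)
  expect_equal(perfect$r, 1)
  expect_true(perfect$passes)
  anti <- pearson_filter(cn, -cn)
  expect_equal(anti$r, -1)
  expect_false(anti$passes)

  got <- pearson_filter(cn, c(1, 2, 2, 5, 7))
  want <- oracle_pearson(cn, c(1, 2, 2, 5, 7))
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  set.seed(2)
  for (i in 1:15) {
    n <- sample(5:50, 1)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    got <- pearson_filter(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }

  flat <- pearson_filter(rep(2, 5), rnorm(5))
  expect_true(flat$degenerate)
  expect_false(flat$passes)
  expect_error(pearson_filter(1:2, 1:2), "at least 3")
})

test_that("the correlation filter separates published passers and failures", {
  tab <- os17p_correlations()
  res <- data.frame(gene = tab$gene, r = tab$r, p = tab$p,
                    passes = tab$r > 0 & tab$p <= 0.05)
  part <- apply_table2_filter(res)
  expect_equal(nrow(part$passing), 9L)
  expect_setequal(part$discarded$gene, c("GRAP", "ALKBH5"))
  # marginal positive correlation still passes (R = 0.49, P = 0.02)
  expect_true("RASD1" %in% part$passing$gene)
  # input order preserved in both partitions
  expect_equal(part$passing$gene, tab$gene[tab$r > 0 & tab$p <= 0.05])

  allneg <- data.frame(gene = c("x", "y"), passes = c(FALSE, FALSE))
  expect_equal(nrow(apply_table2_filter(allneg)$passing), 0L)
})

test_that("O/A pct recovers per-gene coupling within binomial error", {
  couplings <- c(0.3, 0.5, 0.7, 0.9)
  genes <- data.frame(name = paste0("g", 1:4), chrom = "chr17",
                      start = 12.2e6 + (0:3) * 6e5,
                      end = 12.4e6 + (0:3) * 6e5)
  OA <- A <- numeric(4)
  for (seed in 1:20) {
    cfg <- sim_config(n_tumours = 20, chrom_layout = small_layout(),
                      ploidy_dist = c("2" = 1), lrr_sd = 0, baf_sd = 0,
                      amplicons = list(
                        amplicon_spec("chr17", 13.5e6, 4e6, 6L, 1)),
                      dosage_coupling = couplings, expr_sd = 0.15,
                      seed = 1000 + seed)
    sim <- simulate_cohort(cfg)
    expr <- simulate_expression(cfg, sim$truth, genes)
    st <- status_matrix(expr$gene_cn, expr$tumour, expr$reference)
    oa <- summarize_oa(st)
    oa <- oa[match(genes$name, oa$gene), ]
    OA <- OA + oa$OA
    A <- A + oa$A
  }
  phat <- OA / A
  se <- sqrt(couplings * (1 - couplings) / A)
  expect_true(all(abs(phat - couplings) <= 3 * se + 0.02))
})
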