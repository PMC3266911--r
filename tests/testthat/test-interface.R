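test_that("matrix TSV round-trips exactly", {
  m <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("p", 1:4), paste0("S", 1:3)))
  f <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, f)
  expect_equal(read_matrix_tsv(f), m, tolerance = 1e-12)
})

test_that("malformed matrix cells are reported with row and column", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\tS1\tS2", "p1\t1.5\t2.0", "p2\toops\t3.0"), f)
  expect_error(read_matrix_tsv(f), "row 2.*column 'S1'|row 2, column 'S1'")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("probe\tS1", "p1\t1"), f2)
  expect_error(read_matrix_tsv(f2), "first column must be 'id'")
})

test_that("probe and BED files round-trip under half-open convention", {
  probes <- data.frame(probe_id = c("a", "b"), chrom = "chr17",
                       pos = c(10L, 20L), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_probes_tsv(probes, f)
  expect_equal(read_probes_tsv(f), probes)

  genes <- data.frame(name = "g1", chrom = "chr17", start = 100L,
                      end = 200L, stringsAsFactors = FALSE)
  fb <- tempfile(fileext = ".bed")
  write_genes_bed(genes, fb)
  back <- read_genes_bed(fb)
  expect_equal(back$end - back$start, 100L)   # half-open interval length
  expect_equal(back, genes[, c("name", "chrom", "start", "end")])

  bad <- tempfile(fileext = ".bed")
  writeLines("chr17\t200\t100\tg1", bad)
  expect_error(read_genes_bed(bad), "end <= start")
})

test_that("pipeline produces a complete manifest and is seed-deterministic", {
  cfg_for <- function(dir) pipeline_config(
    out_dir = dir,
    sim = sim_config(n_tumours = 6, chrom_layout = small_layout(),
                     seed = 4),
    seed = 4, n_perm = 100)
  d1 <- tempfile("run1"); d2 <- tempfile("run2")
  r1 <- suppressMessages(run_pipeline(cfg_for(d1)))
  r2 <- suppressMessages(run_pipeline(cfg_for(d2)))

  files <- vapply(r1$manifest$artifacts, `[[`, "", "file")
  expect_true(all(c("segments.tsv", "marker_scores.tsv", "regions.tsv",
                    "candidates.json", "cn_matrix.tsv") %in% files))
  expect_equal(r1$manifest$status, "complete")
  md5 <- function(r) vapply(r$manifest$artifacts, `[[`, "", "md5")
  expect_identical(md5(r1), md5(r2))          # identical checksums
})

test_that("a missing input file fails with the stage named", {
  cfg <- pipeline_config(
    out_dir = tempfile(),
    inputs = list(probes = "nope.tsv", lrr = "nope.tsv", baf = "nope.tsv",
                  genes = "nope.bed", expr = "missing_expression.tsv",
                  ref = "nope.tsv"))
  expect_error(suppressMessages(run_pipeline(cfg)), "stage 'load' failed")
})

test_that("CLI subcommands exit 0 on valid input and 1 on errors", {
  dir <- tempfile("cli")
  status <- suppressMessages(oncoamp_main(
    c("simulate", "--out-dir", dir, "--seed", "2", "--n-tumours", "5")))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(dir, "lrr.tsv")))

  cn_dir <- file.path(dir, "cn")
  expect_identical(suppressMessages(oncoamp_main(
    c("callcn", "--probes", file.path(dir, "probes.tsv"),
      "--lrr", file.path(dir, "lrr.tsv"),
      "--baf", file.path(dir, "baf.tsv"),
      "--out-dir", cn_dir))), 0L)

  reg_dir <- file.path(dir, "reg")
  expect_identical(suppressMessages(oncoamp_main(
    c("regions", "--probes", file.path(dir, "probes.tsv"),
      "--cn", file.path(cn_dir, "cn_matrix.tsv"),
      "--ploidy", file.path(cn_dir, "ploidy.tsv"),
      "--n-perm", "50", "--seed", "2", "--out-dir", reg_dir))), 0L)
  expect_true(file.exists(file.path(reg_dir, "regions.tsv")))

  int_dir <- file.path(dir, "int")
  expect_identical(suppressMessages(oncoamp_main(
    c("integrate", "--genes", file.path(dir, "genes.bed"),
      "--probes", file.path(dir, "probes.tsv"),
      "--cn", file.path(cn_dir, "cn_matrix.tsv"),
      "--expr", file.path(dir, "expression.tsv"),
      "--ref", file.path(dir, "expression_reference.tsv"),
      "--out-dir", int_dir))), 0L)
  expect_true(file.exists(file.path(int_dir, "candidates.json")))

  # documented error cases -> nonzero with a diagnostic
  expect_identical(suppressMessages(oncoamp_main(
    c("callcn", "--probes", "does_not_exist.tsv",
      "--lrr", "x", "--baf", "y"))), 1L)
  expect_identical(suppressMessages(oncoamp_main("frobnicate")), 1L)
  expect_identical(suppressMessages(oncoamp_main(
    c("screen", "--ct-table", "absent.tsv"))), 1L)
})

test_that("screen subcommand runs on a Ct table fixture", {
  ct <- rbind(
    data.frame(sample = "T1", gene = "COPS3",
               role = rep(c("target", "reference"), each = 3),
               context = "test", ct = c(23, 23, 23, 25, 25, 25)),
    data.frame(sample = "T2", gene = "COPS3",
               role = rep(c("target", "reference"), each = 3),
               context = "test", ct = c(25, 25, 25, 25, 25, 25)),
    data.frame(sample = "blood", gene = "COPS3",
               role = c("target", "reference"),
               context = "calibrator", ct = c(25, 25)))
  for (g in marker_panel()$gene[-7]) {    # remaining panel genes: diploid
    ct <- rbind(ct,
      data.frame(sample = rep(c("T1", "T2"), each = 2), gene = g,
                 role = rep(c("target", "reference"), 2),
                 context = "test", ct = 25),
      data.frame(sample = "blood", gene = g,
                 role = c("target", "reference"),
                 context = "calibrator", ct = 25))
  }
  f <- tempfile(fileext = ".tsv")
  utils::write.table(ct, f, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- tempfile("screen")
  expect_identical(suppressMessages(oncoamp_main(
    c("screen", "--ct-table", f, "--out-dir", out))), 0L)
  summ <- read.delim(file.path(out, "screen_summary.tsv"))
  expect_true(summ$selected[summ$sample == "T1"])    # COPS3 at CN 8
  expect_false(summ$selected[summ$sample == "T2"])
})
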