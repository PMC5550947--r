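# Count-track I/O, 3'-end filters, pairing and context windows.

genes3 <- function() gene_models(c("g1", "g2"), c("ACGTACGT", "GGGGCCCCAAAA"))

test_that("count tables are zero-filled, validated and round-tripped", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tstrand\tposition\tsample_id\tcount",
               "g1\tantisense\t0\ts1\t5",
               "g1\tantisense\t2\ts1\t1"), tmp)
  genes <- gene_models("g1", "ACGT")
  cts <- load_counts_table(tmp, genes)
  expect_length(cts, 1L)
  expect_equal(cts[[1]]$counts, c(5, 0, 1, 0))

  # empty file: empty collection with a warning
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene_id\tstrand\tposition\tsample_id\tcount", tmp2)
  expect_warning(empty <- load_counts_table(tmp2, genes), "empty")
  expect_length(empty, 0L)

  # negative counts are a format error
  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tstrand\tposition\tsample_id\tcount",
               "g1\tantisense\t1\ts1\t-1"), tmp3)
  expect_error(load_counts_table(tmp3, genes), "negative")

  # unknown sample vs the sample sheet is a configuration error
  ss <- data.frame(sample_id = "sX", group = "a")
  expect_error(load_counts_table(tmp, genes, ss), "sample")

  # write/load round trip conserves every track
  tracks <- list()
  set.seed(3)
  g <- genes3()
  for (s in c("s1", "s2")) {
    for (i in 1:2) {
      cnt <- rpois(g$length[i], 2)
      tracks[[bbdisp:::counts_key(g$gene_id[i], "antisense", s)]] <-
        base_start_counts(g$gene_id[i], s, "antisense", cnt)
    }
  }
  tmp4 <- withr::local_tempfile(fileext = ".tsv.gz")
  write_counts_table(tracks, tmp4)
  back <- load_counts_table(tmp4, g)
  for (key in names(tracks)) {
    expect_equal(back[[key]]$counts, tracks[[key]]$counts)
  }
})

test_that("3'-end filters remove exactly the configured tail", {
  g <- gene_models("g1", paste(rep("ACGT", 75), collapse = ""))  # 300 nt
  bc <- base_start_counts("g1", "s1", "antisense", rep(1, 300))
  expect_length(apply_filters(bc, g[1, ], filter_config(76, 0))$counts, 224)
  expect_length(apply_filters(bc, g[1, ], filter_config(35, 200))$counts, 65)
  expect_equal(apply_filters(bc, g[1, ], filter_config(0, 0))$counts, bc$counts)
  # trimming removes trailing positions, never alters the head
  f <- apply_filters(bc, g[1, ], filter_config(10, 5))
  expect_equal(f$counts, bc$counts[1:285])
  # trims consuming the gene exclude it
  expect_warning(out <- apply_filters(bc, g[1, ], filter_config(200, 200)),
                 "excluded")
  expect_null(out)
})

test_that("context windows cover K/2 bases each side and mark boundaries", {
  # K = 2 around position 1 of ACGT: one base either side
  expect_equal(position_contexts("ACGT", 1L, 2L), "AG")
  # window reaching past the start is missing
  expect_true(is.na(position_contexts(paste(rep("A", 300), collapse = ""),
                                      10L, 80L)))
  # interior window of a long gene is complete and excludes the start base
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  ctx <- position_contexts(s, 100L, 80L)
  expect_equal(nchar(ctx), 80L)
  expect_equal(ctx, paste0(substr(s, 61, 100), substr(s, 102, 141)))
})

test_that("pairing aligns counts, depth and contexts", {
  g <- genes3()[1, ]
  a <- base_start_counts("g1", "s1", "antisense", c(1, 2, 0, 4, 0, 0, 1, 0))
  b <- base_start_counts("g1", "s2", "antisense", c(3, 4, 1, 0, 0, 2, 0, 0))
  pc <- pair_counts(a, b, g, K = 2L)
  expect_equal(pc$depth, pc$n + pc$m)
  expect_equal(pc$depth[1:2], c(4, 6))
  # totals are conserved
  expect_equal(sum(pc$n) + sum(pc$m), sum(a$counts) + sum(b$counts))
  # mismatched position sets are an alignment error
  short <- base_start_counts("g1", "s2", "antisense", c(1, 1))
  expect_error(pair_counts(a, short, g, K = 2L), "alignment")
})

test_that("BAM extraction reproduces simulator counts and honours the
           uniqueness filter", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(G = 4, gene_length = 120, depth_meanlog = log(3),
                    depth_sdlog = 0.5, seed = 5)
  sim <- simulate_pair(cfg)
  paths <- emit_fixtures(sim, dir, bam = TRUE)
  cts <- counts_from_bam(paths$bam_s1, sim$genes)
  for (g in names(sim$pairs)) {
    key <- bbdisp:::counts_key(g, "antisense", "s1")
    expect_equal(cts[[key]]$counts, sim$pairs[[g]]$n)
  }
  # total reads in the BAM equal the summed counts
  n_reads <- Rsamtools::countBam(paths$bam_s1)$records
  expect_equal(n_reads, sum(vapply(sim$pairs, function(pc) sum(pc$n), numeric(1))))

  # a low-MAPQ (non-unique) read is not counted
  sam <- file.path(dir, "multi.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               "@SQ\tSN:gX\tLN:50",
               "r1\t0\tgX\t11\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
               "r2\t0\tgX\t11\t0\t10M\t*\t0\t0\tACGTACGTAC\t*"), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "multi"), overwrite = TRUE,
                          indexDestination = TRUE)
  gX <- gene_models("gX", paste(rep("ACGTA", 10), collapse = ""))
  cts2 <- counts_from_bam(bam, gX, mapq_min = 10)
  expect_equal(cts2[[1]]$counts[11], 1)  # only the MAPQ-60 read
  expect_equal(sum(cts2[[1]]$counts), 1)
  # missing index is an I/O error
  expect_error(counts_from_bam(file.path(dir, "nope.bam"), gX), "index")
})

test_that("FASTA round trip preserves sequences", {
  g <- genes3()
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_gene_fasta(g, tmp)
  back <- read_gene_fasta(tmp)
  expect_equal(back$sequence, g$sequence)
  expect_equal(back$gene_id, g$gene_id)
})
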