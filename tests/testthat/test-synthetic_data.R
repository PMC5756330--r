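# The synthetic generator and the truth scorer.

test_that("generation is a deterministic function of the seed", {
  d1 <- generate_dataset(synthetic_config(seed = 4))
  d2 <- generate_dataset(synthetic_config(seed = 4))
  expect_identical(d1$genome$chr1$sequence, d2$genome$chr1$sequence)
  expect_identical(d1$profiles, d2$profiles)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$reads, d2$reads)
  d3 <- generate_dataset(synthetic_config(seed = 5))
  expect_false(identical(d1$genome$chr1$sequence, d3$genome$chr1$sequence))
})

test_that("the planted TSS census matches the configuration", {
  ds <- generate_dataset(synthetic_config(seed = 1))
  tr <- ds$truth$tss
  expect_equal(nrow(tr), 50L)
  base_cat <- vapply(strsplit(tr$category, ","), function(x)
    setdiff(x, "asTSS")[1], character(1))
  cnt <- table(base_cat)
  expect_equal(unname(cnt["pTSS"]), 5L)
  expect_equal(unname(cnt["iTSS"]), 5L)
  expect_equal(unname(cnt["nsTSS"]), 3L)
  expect_equal(unname(cnt["nTSS"]), 4L)
  expect_true(all(tr$strength >= 40L))
  expect_true(all(tr$position >= 1 & tr$position <= ds$genome$chr1$length))
  expect_equal(nrow(ds$annotation), 80L)
  expect_true(all(c("rRNA", "tRNA") %in% ds$annotation$feature_type))
})

test_that("barcode read counts are binomial around the configured rate", {
  ds <- generate_dataset(synthetic_config(seed = 6, n_reads = 1000L,
                                          fp_read_fraction = 0.6))
  n_fp <- length(ds$truth$barcode_read_ids)
  sigma <- sqrt(1000 * 0.6 * 0.4)
  expect_lt(abs(n_fp - 600), 3 * sigma)
  expect_true(all(startsWith(ds$reads[ds$truth$barcode_read_ids],
                             "TACCCTAG")))
  kept <- filter_barcoded_reads(ds$reads)
  expect_equal(kept$n_discarded, n_fp)
})

test_that("planted read-start strength sits on Poisson background", {
  cfg <- synthetic_config(seed = 2)
  ds <- generate_dataset(cfg)
  rs <- ds$profiles$chr1$read_starts
  for (i in seq_len(nrow(ds$truth$tss))) {
    t <- ds$truth$tss[i, ]
    expect_gte(rs[[t$strand]][t$position], t$strength)
  }
  # background positions: mean close to lambda
  bg <- rs[["+"]][-(ds$truth$tss$position[ds$truth$tss$strand == "+"])]
  expect_lt(abs(mean(bg) - cfg$noise_lambda), 0.05)
})

test_that("each planted category is re-derivable from the geometry", {
  ds <- generate_dataset(synthetic_config(seed = 3))
  utrs <- local({
    tr <- ds$truth$tss
    sp <- tr[grepl("sTSS|pTSS", tr$category) & !is.na(tr$gene_id), ]
    gi <- match(sp$gene_id, ds$annotation$gene_id)
    g5 <- ifelse(ds$annotation$strand[gi] == "+", ds$annotation$start[gi],
                 ds$annotation$end[gi])
    data.frame(replicon_id = "chr1",
               start = ifelse(sp$strand == "+", sp$position, g5 + 1L),
               end = ifelse(sp$strand == "+", g5 - 1L, sp$position),
               strand = sp$strand, gene_id = sp$gene_id)
  })
  for (i in seq_len(nrow(ds$truth$tss))) {
    t <- ds$truth$tss[i, ]
    got <- classify_tss_one(t$replicon_id, t$position, t$strand,
                            ds$annotation, detected_utrs = utrs)
    expect_equal(paste(sort(unique(got$category)), collapse = ","),
                 t$category, info = paste("TSS at", t$position, t$strand))
  }
})

test_that("the scorer applies matching and degenerate-case conventions", {
  truth <- list(tss = data.frame(replicon_id = "chr1",
                                 position = c(100L, 500L), strand = "+",
                                 category = "sTSS", stringsAsFactors = FALSE))
  mk_result <- function(pos) list(
    tss = data.frame(replicon_id = rep("chr1", length(pos)),
                     position = pos, strand = rep("+", length(pos)),
                     stringsAsFactors = FALSE),
    transcripts = data.frame(kind = character(0), start = integer(0),
                             end = integer(0), strand = character(0)))
  r <- truth_scorer(mk_result(c(100L, 500L)), truth)
  expect_equal(r$tss$sensitivity, 1.0)
  expect_equal(r$tss$precision, 1.0)

  r0 <- truth_scorer(mk_result(integer(0)), truth)
  expect_equal(r0$tss$sensitivity, 0.0)
  expect_equal(r0$tss$precision, 1.0)
  expect_true(r0$tss$zero_calls)

  r2 <- truth_scorer(mk_result(102L), truth, tolerance_nt = 3L)
  expect_equal(r2$tss$sensitivity, 0.5)
  expect_equal(r2$tss$precision, 1.0)
  r3 <- truth_scorer(mk_result(102L), truth, tolerance_nt = 1L)
  expect_equal(r3$tss$sensitivity, 0.0)
  expect_equal(r3$tss$precision, 0.0)
})

test_that("written datasets read back into equivalent objects", {
  ds <- generate_dataset(synthetic_config(seed = 9))
  d <- tempfile()
  write_dataset(ds, d)
  g <- read_genome(file.path(d, "genome.fasta"))
  expect_identical(g$chr1$sequence, ds$genome$chr1$sequence)
  ann <- read_annotation(file.path(d, "annotation.gff3"), g,
                         types = c("CDS", "rRNA", "tRNA"))
  expect_equal(nrow(ann), nrow(ds$annotation))
  expect_equal(ann$start, ds$annotation$start)
  expect_equal(ann$strand, ds$annotation$strand)
  p <- read_stranded_bedgraph(file.path(d, "depth_fwd.bedgraph"),
                              file.path(d, "depth_rev.bedgraph"),
                              file.path(d, "starts_fwd.bedgraph"),
                              file.path(d, "starts_rev.bedgraph"), g)
  expect_identical(p$chr1$depth, ds$profiles$chr1$depth)
  expect_identical(p$chr1$read_starts, ds$profiles$chr1$read_starts)
  reads <- read_fastq(file.path(d, "reads.fastq"))
  expect_identical(reads, ds$reads)
})
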