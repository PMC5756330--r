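# Operon joining, sub-operon derivation, coverage-extension transcripts.

span_df <- function(...) {
  x <- list(...)
  do.call(rbind, lapply(x, function(p)
    data.frame(gene_a = p[[1]], gene_b = p[[2]],
               count = as.integer(p[[3]]), stringsAsFactors = FALSE)))
}

lay_genes <- function(n, strand = "+", start = 1000L, len = 300L,
                      gap = 100L) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    s <- start + (i - 1L) * (len + gap)
    toy_gene(paste0("g", i), s, s + len - 1L, strand)
  }))
}

test_that("spanning-read joining thresholds at 10 and respects strand", {
  ann <- lay_genes(3)
  jo <- join_operons(ann, span_df(list("g1", "g2", 12), list("g2", "g3", 9)))
  expect_equal(unname(jo$operon_genes), list(c("g1", "g2")))
  expect_equal(jo$monocistronic, "g3")

  jo10 <- join_operons(ann, span_df(list("g1", "g2", 10),
                                    list("g2", "g3", 10)))
  expect_equal(unname(jo10$operon_genes), list(c("g1", "g2", "g3")))

  mixed <- lay_genes(2)
  mixed$strand[2] <- "-"
  jm <- join_operons(mixed, span_df(list("g1", "g2", 50)))
  expect_equal(length(jm$operon_genes), 0L)   # opposite strands never join
  expect_setequal(jm$monocistronic, c("g1", "g2"))
})

test_that("a 14-gene run with all counts >= 10 forms one operon", {
  ann <- lay_genes(14)
  pairs <- lapply(1:13, function(i)
    list(paste0("g", i), paste0("g", i + 1), 10 + i))
  jo <- join_operons(ann, do.call(span_df, pairs))
  expect_equal(length(jo$operon_genes), 1L)
  expect_equal(jo$operon_genes[[1]], paste0("g", 1:14))
  expect_equal(jo$operons$n_genes, 14L)
})

test_that("minus-strand operons are listed in transcription order", {
  ann <- lay_genes(3, strand = "-")
  # transcription order on "-" is right to left: g3, g2, g1
  jo <- join_operons(ann, span_df(list("g3", "g2", 15), list("g2", "g1", 15)))
  expect_equal(jo$operon_genes[[1]], c("g3", "g2", "g1"))
})

test_that("sub-operons are contiguous suffixes anchored at internal TSSs", {
  op <- c("g1", "g2", "g3", "g4")
  tss <- data.frame(tss_id = c("t1", "t2", "t3", "t4"),
                    read_start_count = c(100L, 40L, 60L, 25L),
                    stringsAsFactors = FALSE)
  asn <- function(ids, genes) data.frame(
    tss_id = ids, category = "sTSS", gene_id = genes,
    distance_nt = 50L, stringsAsFactors = FALSE)

  d1 <- derive_suboperons("OP1", op, asn("t3", "g3"), tss)
  expect_equal(d1$suboperons$gene_ids, "g3,g4")
  expect_true(is.na(d1$primary_tss))

  d2 <- derive_suboperons("OP1", op, asn("t1", "g1"), tss)
  expect_equal(d2$primary_tss, "t1")
  expect_equal(nrow(d2$suboperons), 0L)

  d3 <- derive_suboperons("OP1", op, asn(c("t2", "t3"), c("g2", "g3")), tss)
  expect_equal(d3$suboperons$gene_ids, c("g2,g3,g4", "g3,g4"))

  # two TSSs on the same internal gene collapse, keeping the stronger
  d4 <- derive_suboperons("OP1", op, asn(c("t2", "t4"), c("g3", "g3")), tss)
  expect_equal(nrow(d4$suboperons), 1L)
  expect_equal(d4$suboperons$tss_id, "t2")

  # suffix property: every sub-operon list is a suffix of the parent
  for (d in list(d1, d3, d4)) {
    for (gl in strsplit(d$suboperons$gene_ids, ",")) {
      k <- match(gl[1], op)
      expect_equal(gl, op[k:length(op)])
    }
  }
})

test_that("antisense extension applies the 15/20/500/40/80 rules exactly", {
  g <- toy_genome(2000)
  mk <- function(dep) toy_profiles(g, depth_fwd = dep)
  cfg <- antisense_config()

  dep <- integer(2000); dep[100:219] <- 20L; dep[220] <- 14L
  tr <- call_antisense_transcript(100L, "+", "chr1", mk(dep), cfg)
  expect_equal(tr$length_nt, 120L)        # stops where depth drops below 15
  expect_equal(c(tr$start, tr$end), c(100L, 219L))

  dep <- integer(2000); dep[100:114] <- 30L
  expect_null(call_antisense_transcript(100L, "+", "chr1", mk(dep), cfg))

  dep <- integer(2000); dep[100:119] <- 15L   # exactly 20 nt at exactly 15
  tr20 <- call_antisense_transcript(100L, "+", "chr1", mk(dep), cfg)
  expect_equal(tr20$length_nt, 20L)

  long <- function(start_cov) {
    dep <- numeric(2000)
    dep[100:699] <- 50
    dep[100] <- start_cov
    as.integer(round(dep))
  }
  expect_null(call_antisense_transcript(100L, "+", "chr1",
                                        mk(long(75)), cfg))
  tr80 <- call_antisense_transcript(100L, "+", "chr1", mk(long(85)), cfg)
  expect_equal(tr80$length_nt, 600L)

  # minus strand: extension runs toward smaller coordinates
  dep <- integer(2000); dep[481:600] <- 25L
  trm <- call_antisense_transcript(600L, "-", "chr1",
                                   toy_profiles(g, depth_rev = dep), cfg)
  expect_equal(c(trm$start, trm$end), c(481L, 600L))

  # reported transcripts satisfy the per-position coverage contract
  for (tr in list(tr, tr20, tr80)) {
    expect_true(tr$mean_depth >= cfg$min_pos_coverage)
    expect_gte(tr$length_nt, cfg$min_length_nt)
  }
})

test_that("ORF scanning reports the longest qualifying frame", {
  body26 <- paste(rep("CAC", 25), collapse = "")
  seq <- paste0(paste(rep("C", 12), collapse = ""), "ATG", body26, "TAA",
                paste(rep("C", 10), collapse = ""))
  orf <- find_longest_orf(seq, 25L)
  expect_equal(orf$aa, 26L)
  expect_equal(orf$start_off, 13L)
  expect_equal(orf$start_codon, "ATG")
  expect_null(find_longest_orf(seq, 27L))

  # 24-aa ORF rejected at the 25-aa floor
  short <- paste0("ATG", paste(rep("CAC", 23), collapse = ""), "TAA")
  expect_null(find_longest_orf(short, 25L))
  expect_equal(find_longest_orf(short, 24L)$aa, 24L)

  # alternative start codons count
  gtg <- paste0("GTG", paste(rep("CAC", 25), collapse = ""), "TAG")
  expect_equal(find_longest_orf(gtg, 25L)$start_codon, "GTG")
})

test_that("overlapping intergenic extensions merge as alternative TSSs", {
  g <- toy_genome(3000, seed = 8)
  dep <- integer(3000)
  dep[500:829] <- 30L       # shared extent for two TSSs 30 nt apart
  dep[1500:1799] <- 30L     # separate transcript
  p <- toy_profiles(g, depth_fwd = dep)
  ntss <- data.frame(tss_id = c("n1", "n2", "n3"), replicon_id = "chr1",
                     position = c(500L, 530L, 1500L), strand = "+",
                     stringsAsFactors = FALSE)
  nov <- find_novel_transcripts(ntss, p, g)
  expect_equal(nrow(nov), 2L)
  expect_equal(nov$n_alt_tss[nov$start == 500], 2L)
  expect_equal(nov$tss_ids[nov$start == 500], "n1,n2")
  expect_equal(nov$n_alt_tss[nov$start == 1500], 1L)
  expect_true(all(nov$kind == "intergenic"))
})
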