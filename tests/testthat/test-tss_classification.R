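# Genomic-context classification, start-codon revision, ranking, UTRs.

test_that("sense/distal windows have inclusive boundaries at 300 and 600", {
  g <- toy_genome(3000)
  ann <- toy_gene("g1", 1001, 1600, "+")
  cat_at <- function(pos) {
    a <- classify_tss_one("chr1", pos, "+", ann)
    paste(sort(a$category), collapse = ",")
  }
  expect_equal(cat_at(1001 - 120), "sTSS")    # 120 nt upstream
  expect_equal(cat_at(1001 - 300), "sTSS")    # boundary: 300 inclusive
  expect_equal(cat_at(1001 - 301), "pTSS")    # just past the sense window
  expect_equal(cat_at(1001 - 450), "pTSS")
  expect_equal(cat_at(1001 - 600), "pTSS")    # boundary: 600 inclusive
  expect_equal(cat_at(1001 - 601), "nTSS")    # beyond assignment range
  expect_equal(cat_at(1001), "sTSS")          # at the start codon: UTR 0
  a <- classify_tss_one("chr1", 1001 - 120, "+", ann)
  expect_equal(a$distance_nt, 120L)
})

test_that("inside-ORF TSSs split at 200 nt into revision route vs internal", {
  ann <- toy_gene("g1", 1001, 2200, "+")
  a200 <- classify_tss_one("chr1", 1201, "+", ann)   # 200 nt into ORF
  expect_equal(a200$category, "nsTSS")
  a201 <- classify_tss_one("chr1", 1202, "+", ann)   # 201 nt into ORF
  expect_equal(a201$category, "iTSS")
  expect_equal(a201$distance_nt, 201L)
})

test_that("internal TSS near the ORF end loses iTSS when sense of next gene", {
  ann <- rbind(toy_gene("g1", 1001, 2000, "+"),
               toy_gene("g2", 2101, 2700, "+"))
  # 979 nt into g1, 20 nt from its end, 121 nt upstream of g2
  a <- classify_tss_one("chr1", 1980, "+", ann)
  expect_equal(sort(a$category), "sTSS")
  expect_equal(a$gene_id[a$category == "sTSS"], "g2")
  # same geometry but no downstream gene: plain internal
  b <- classify_tss_one("chr1", 1980, "+", toy_gene("g1", 1001, 2000, "+"))
  expect_equal(b$category, "iTSS")
  # internal, > 300 nt from the end, also sense of an overlapping next
  # gene: keeps both labels
  ann2 <- rbind(toy_gene("g1", 1001, 2000, "+"),
                toy_gene("g2", 1900, 2600, "+"))
  cc <- classify_tss_one("chr1", 1650, "+", ann2)
  expect_setequal(cc$category, c("iTSS", "sTSS"))
})

test_that("antisense labels come from opposite-strand ORFs and 5'-UTRs", {
  ann <- rbind(toy_gene("g_a", 1001, 1600, "-"),
               toy_gene("g_b", 1450 + 150 + 1, 2300, "+"))
  # inside g_a (antisense) and 150 nt upstream of g_b (sense)
  a <- classify_tss_one("chr1", 1451, "+", ann)
  expect_setequal(a$category, c("asTSS", "sTSS"))
  expect_equal(a$gene_id[a$category == "asTSS"], "g_a")
  expect_equal(a$gene_id[a$category == "sTSS"], "g_b")

  utrs <- data.frame(replicon_id = "chr1", start = 2500, end = 2600,
                     strand = "-", gene_id = "g_c")
  b <- classify_tss_one("chr1", 2550, "+", toy_gene("g_x", 10, 60, "+"),
                        detected_utrs = utrs)
  expect_true("asTSS" %in% b$category)
  b2 <- classify_tss_one("chr1", 2550, "+", toy_gene("g_x", 10, 60, "+"),
                         detected_utrs = utrs,
                         config = classification_config(
                           as_utr_extension = FALSE))
  expect_false("asTSS" %in% b2$category)
})

test_that("classification on a minus-strand gene mirrors plus geometry", {
  ann <- toy_gene("g1", 1001, 1600, "-")       # 5' start at 1600
  a <- classify_tss_one("chr1", 1600 + 120, "-", ann)
  expect_equal(a$category, "sTSS")
  expect_equal(a$distance_nt, 120L)
  expect_equal(classify_tss_one("chr1", 1600 + 301, "-", ann)$category,
               "pTSS")
  expect_equal(classify_tss_one("chr1", 1600 - 250, "-", ann)$category,
               "iTSS")
})

test_that("start-codon revision finds the first in-frame start with an RBS", {
  L <- 3000L
  seqv <- rep("C", L)
  # gene on +: ATG at 1001, interior free of in-frame starts, stop at 2198
  seqv[1001:1003] <- c("A", "T", "G")
  seqv[2196:2198] <- c("T", "A", "A")
  # planted revised start 180 nt downstream (in frame), RBS 8 nt upstream
  seqv[1181:1183] <- c("A", "T", "G")
  seqv[(1181 - 13):(1181 - 9)] <- c("A", "G", "G", "A", "G")
  g <- make_genome(c(chr1 = paste(seqv, collapse = "")))
  gene <- toy_gene("g1", 1001, 2198, "+")
  rv <- revise_start_codon(1151, "+", "chr1", gene, g)   # TSS at +150
  expect_equal(rv$new_start, 1181L)
  expect_equal(rv$shortening_aa, 60L)
  expect_equal(rv$new_utr_nt, 30L)
  expect_true(rv$rbs_found)

  # no downstream in-frame start codon at all -> NULL (caller -> iTSS)
  seqv2 <- rep("C", L)
  seqv2[1001:1003] <- c("A", "T", "G")
  seqv2[2196:2198] <- c("T", "A", "A")
  g2 <- make_genome(c(chr1 = paste(seqv2, collapse = "")))
  expect_null(revise_start_codon(1151, "+", "chr1", gene, g2))

  # large shortening is accepted: next start 74 codons in
  seqv3 <- rep("C", L)
  seqv3[1001:1003] <- c("A", "T", "G")
  seqv3[2196:2198] <- c("T", "A", "A")
  seqv3[(1001 + 222):(1003 + 222)] <- c("G", "T", "G")
  g3 <- make_genome(c(chr1 = paste(seqv3, collapse = "")))
  rv3 <- revise_start_codon(1180, "+", "chr1", gene, g3)
  expect_equal(rv3$shortening_aa, 74L)
  expect_false(rv3$rbs_found)
  expect_error(revise_start_codon(1151, "+", "chr1",
                                  toy_gene("r1", 1001, 2198, "+", "rRNA"),
                                  g), "CDS")
})

test_that("start-codon revision mirrors on the minus strand", {
  L <- 3000L
  seqv <- rep("C", L)
  # gene on -: 5' start (ATG) at 2198 reading leftwards
  seqv[2196:2198] <- c("C", "A", "T")      # revcomp(ATG)
  seqv[1001:1003] <- c("T", "T", "A")      # revcomp(TAA) stop
  seqv[2106:2108] <- c("C", "A", "T")      # revised start at 2108, -90
  g <- make_genome(c(chr1 = paste(seqv, collapse = "")))
  gene <- toy_gene("g1", 1001, 2198, "-")
  rv <- revise_start_codon(2198 - 60, "-", "chr1", gene, g)
  expect_equal(rv$new_start, 2108L)
  expect_equal(rv$shortening_aa, 30L)
  expect_equal(rv$new_utr_nt, (2198 - 60) - 2108)
})

test_that("primary/secondary ranking follows read starts with tie-breaks", {
  tss <- data.frame(
    tss_id = c("A", "B", "C", "D", "E"),
    replicon_id = "chr1", position = c(880, 940, 1500, 1560, 3000),
    strand = "+", read_start_count = c(150L, 30L, 40L, 40L, 25L),
    stringsAsFactors = FALSE)
  asn <- data.frame(
    tss_id = c("A", "B", "C", "D", "E"),
    category = c("sTSS", "sTSS", "sTSS", "sTSS", "sTSS"),
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    distance_nt = c(120L, 60L, 120L, 60L, 10L),
    stringsAsFactors = FALSE)
  r <- rank_primary_secondary(asn, tss)
  expect_equal(r$rank[r$tss_id == "A"], "primary")     # highest count
  expect_equal(r$rank[r$tss_id == "B"], "secondary")
  expect_equal(r$rank[r$tss_id == "D"], "primary")     # tie: closer wins
  expect_equal(r$rank[r$tss_id == "C"], "secondary")
  expect_equal(r$rank[r$tss_id == "E"], "primary")     # singleton
  for (g in unique(r$gene_id)) {
    expect_equal(sum(r$rank[r$gene_id == g] == "primary"), 1L)
  }
})

test_that("leaderless boundary is 3 nt and the histogram uses 5-nt bins", {
  asn <- data.frame(tss_id = sprintf("t%d", 1:6),
                    category = "sTSS", gene_id = sprintf("g%d", 1:6),
                    distance_nt = c(3L, 4L, 2L, 12L, 14L, 33L),
                    rank = "primary", stringsAsFactors = FALSE)
  ul <- compute_utr_and_leaderless(asn)
  expect_equal(ul$utr$leaderless,
               c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  h <- ul$histogram
  expect_equal(h$count[h$bin_start == 0], 3L)    # 2, 3, 4
  expect_equal(h$count[h$bin_start == 10], 2L)   # 12, 14
  expect_equal(h$count[h$bin_start == 30], 1L)   # 33
})

test_that("structural-RNA TSSs are tagged and kept out of classification", {
  ann <- rbind(toy_gene("rrn1", 1001, 2500, "+", "rRNA"),
               toy_gene("g1", 3001, 3600, "+"))
  a <- classify_tss_one("chr1", 1001 - 50, "+", ann)
  expect_equal(a$category, "structural")
  b <- classify_tss_one("chr1", 3001 - 50, "+", ann)
  expect_equal(b$category, "sTSS")
})
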