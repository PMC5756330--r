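# Readthrough ratios, Fisher enrichment, initiation statistics.

test_that("readthrough ratio separates termination from readthrough", {
  g <- toy_genome(2000)
  gene <- toy_gene("gx", 1001, 1400, "+")
  el <- data.frame(name = "FMN-like", replicon_id = "chr1", start = 820,
                   end = 940, strand = "+", downstream_gene_id = "gx",
                   stringsAsFactors = FALSE)
  dep <- numeric(2000); dep[801:1000] <- 6000; dep[1001:1400] <- 60
  p <- toy_profiles(g, depth_fwd = as.integer(dep))
  tssr <- data.frame(replicon_id = "chr1", position = 801L, strand = "+",
                     stringsAsFactors = FALSE)
  rt <- readthrough_ratio(el, gene, p, tssr)
  expect_true(rt$tss_found)
  expect_equal(rt$ratio, 100)
  expect_equal(rt$verdict, "termination-like")

  dep2 <- numeric(2000); dep2[801:1400] <- 55
  p2 <- toy_profiles(g, depth_fwd = as.integer(dep2))
  rt2 <- readthrough_ratio(el, gene, p2, NULL)     # no TSS: element start
  expect_false(rt2$tss_found)
  expect_equal(rt2$ratio, 1)
  expect_equal(rt2$verdict, "readthrough-like")

  dep3 <- numeric(2000); dep3[801:1000] <- 50
  p3 <- toy_profiles(g, depth_fwd = as.integer(dep3))
  rt3 <- readthrough_ratio(el, gene, p3, NULL)     # zero-depth ORF
  expect_true(rt3$flagged)
  expect_equal(rt3$verdict, "termination-like")
})

test_that("Fisher enrichment matches brute-force hypergeometric sums", {
  genes <- sprintf("g%03d", 1:100)
  cats <- rep(c("catA", "catB"), c(13, 87))
  names(cats) <- genes
  subset <- genes[c(1:3, 14:20)]                  # a=3 b=7 c=10 d=80
  res <- fisher_enrichment(subset, genes, cats)
  a_row <- res[res$category == "catA", ]
  expect_equal(a_row[, c("a", "b", "c", "d")],
               data.frame(a = 3L, b = 7L, c = 10L, d = 80L),
               ignore_attr = TRUE)
  expect_equal(a_row$p_value, brute_fisher(3, 7, 10, 80), tolerance = 1e-9)

  # subset == universe: every table degenerates, p = 1
  res_all <- fisher_enrichment(genes, genes, cats)
  expect_true(all(res_all$p_value == 1))
  expect_error(fisher_enrichment(character(0), character(0), cats),
               "empty")
})

test_that("Fisher p equals enumeration for random tables with margins <= 30", {
  set.seed(12)
  for (i in 1:20) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if (a + b == 0 || c_ + d == 0) next
    genes <- sprintf("g%d", seq_len(a + b + c_ + d))
    cats <- rep(c("hit", "other"), c(a + c_, b + d))
    names(cats) <- c(genes[seq_len(a)],
                     genes[a + b + seq_len(c_)],
                     genes[a + seq_len(b)],
                     genes[a + b + c_ + seq_len(d)])
    subset <- genes[seq_len(a + b)]
    res <- fisher_enrichment(subset, genes, cats[genes])
    hit <- res[res$category == "hit", ]
    expect_equal(hit$p_value, brute_fisher(hit$a, hit$b, hit$c, hit$d),
                 tolerance = 1e-9)
  }
})

test_that("initiation statistics are strand-aware with proper deciles", {
  # genome where every planted +1 is G on the requested strand
  seqv <- rep("A", 400)
  pos_plus <- seq(20, 200, by = 20)
  seqv[pos_plus] <- "G"
  pos_minus <- seq(220, 380, by = 20)
  seqv[pos_minus] <- "C"          # complement reads G on "-"
  g <- make_genome(c(chr1 = paste(seqv, collapse = "")))
  tss <- data.frame(
    replicon_id = "chr1",
    position = c(pos_plus, pos_minus),
    strand = rep(c("+", "-"), c(length(pos_plus), length(pos_minus))),
    read_start_count = seq(10L, by = 10L,
                           length.out = length(pos_plus) +
                             length(pos_minus)),
    categories = "sTSS", stringsAsFactors = FALSE)
  st <- initiation_stats(tss, g)
  p1 <- st[st$position == "+1" & st$stratum == "all", ]
  expect_equal(p1$frequency[p1$base == "G"], 1)
  expect_equal(sum(p1$frequency), 1)
  # 19 TSSs -> decile size ceil(19/10) = 2; top decile holds the 2 largest
  top <- st[st$stratum == "top10", ]
  expect_equal(unique(top$n), 2L)
  expect_equal(unique(top$mean_read_starts), mean(c(190, 180)))
  # every frequency vector sums to 1
  agg <- aggregate(frequency ~ group + stratum + position, st, sum)
  expect_true(all(abs(agg$frequency - 1) < 1e-9))
})

test_that("small categories skip deciles and context mirrors strands", {
  g <- make_genome(c(chr1 = "AACGTACGTACGTAAA"))
  tss <- data.frame(replicon_id = "chr1", position = c(5L, 5L),
                    strand = c("+", "-"), read_start_count = c(10L, 20L),
                    categories = c("sTSS", "iTSS"), stringsAsFactors = FALSE)
  ctx <- tss_context(tss, g)
  expect_equal(ctx$base_p1, c("T", "A"))     # genome[5] = T; complement A
  expect_equal(ctx$base_m1, c("G", "T"))     # -1 is 4 on "+", 6 on "-"
  expect_equal(ctx$base_p2, c("A", "C"))
  st <- initiation_stats(tss, g)
  expect_false(any(st$stratum %in% c("top10", "low10")))
})

test_that("gene mean depth is the arithmetic mean over the gene body", {
  g <- toy_genome(1000)
  ann <- rbind(toy_gene("u", 101, 200, "+"),
               toy_gene("z", 301, 400, "+"),
               toy_gene("h", 501, 600, "+"))
  dep <- numeric(1000)
  dep[101:200] <- 10
  dep[501:550] <- 0; dep[551:600] <- 20
  p <- toy_profiles(g, depth_fwd = as.integer(dep))
  md <- gene_mean_depth(ann, p)
  expect_equal(md$mean_depth[md$gene_id == "u"], 10)
  expect_equal(md$mean_depth[md$gene_id == "z"], 0)
  expect_equal(md$mean_depth[md$gene_id == "h"], 10)
})
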