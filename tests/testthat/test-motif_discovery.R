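# ZOOPS EM motif discovery, promoter/RBS search, purine profiling.

plant_in_windows <- function(n, len, motif, rate, seed,
                             offsets = NULL) {
  set.seed(seed)
  w <- nchar(motif)
  seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), len, TRUE),
                             collapse = ""))
  planted <- runif(n) < rate
  off <- integer(n)
  for (i in which(planted)) {
    o <- if (is.null(offsets)) sample(len - w + 1L, 1L) else
      sample(offsets, 1L)
    substr(seqs[i], o, o + w - 1L) <- motif
    off[i] <- o
  }
  list(seqs = seqs, planted = planted, offsets = off)
}

consensus_hits <- function(consensus, target) {
  a <- strsplit(toupper(consensus), "")[[1]]
  b <- strsplit(toupper(target), "")[[1]]
  sum(a == b)
}

test_that("EM input validation and PWM normalization hold", {
  expect_error(em_motif(c("ACGTA"), 6), "2 sequences")
  expect_error(em_motif(c("ACGTA", "ACGTACGT"), 6), "shorter than width")
  m <- em_motif(c("ACGTACGTAA", "TTACGTACGT", "ACGTTTTTAC"), 4, seed = 3,
                n_restarts = 2)
  expect_equal(rowSums(m$pwm), rep(1, 4), tolerance = 1e-9)
  expect_equal(sum(m$background), 1, tolerance = 1e-9)
})

test_that("EM log-likelihood is monotone non-decreasing on every run", {
  set.seed(13)
  for (rep in 1:4) {
    seqs <- replicate(15, paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                                collapse = ""))
    m <- em_motif(seqs, 5, seed = rep, n_restarts = 3)
    expect_true(all(diff(m$loglik_trace) >= -1e-8))
  }
})

test_that("a planted TATAAT motif is recovered from random 50-mers", {
  pw <- plant_in_windows(20, 50, "TATAAT", rate = 1, seed = 7)
  m <- em_motif(pw$seqs, 6, seed = 7, n_restarts = 8)
  expect_gte(consensus_hits(m$consensus, "TATAAT"), 5L)
})

test_that("EM reaches at least the best hard-assignment likelihood", {
  pw <- plant_in_windows(4, 8, "GGCA", rate = 1, seed = 21)
  bg <- rep(0.25, 4)
  brute <- brute_zoops_loglik(pw$seqs, 4, bg)
  m <- em_motif(pw$seqs, 4, background = bg, seed = 2, n_restarts = 20)
  expect_gte(m$loglik, brute - 1e-6)
})

test_that("column-shuffled input loses the planted occurrence signal", {
  pw <- plant_in_windows(40, 50, "TATAAT", rate = 0.95, seed = 15,
                         offsets = 34:42)
  m <- em_motif(pw$seqs, 6, seed = 4, n_restarts = 5, offsets = 34:42)
  frac_planted <- mean(m$per_sequence$bayes_factor >= 4)
  set.seed(16)
  mat <- do.call(rbind, strsplit(pw$seqs, ""))
  for (j in seq_len(ncol(mat))) mat[, j] <- sample(mat[, j])
  shuffled <- apply(mat, 1, paste, collapse = "")
  m2 <- em_motif(shuffled, 6, seed = 4, n_restarts = 5, offsets = 34:42)
  frac_shuf <- mean(m2$per_sequence$bayes_factor >= 4)
  expect_gte(frac_planted - frac_shuf, 0.3)
})

test_that("consensus casing thresholds are applied per column", {
  pwm <- rbind(c(0.9, 0.04, 0.03, 0.03),
               c(0.2, 0.2, 0.1, 0.5),
               c(0.25, 0.25, 0.25, 0.25))
  colnames(pwm) <- c("A", "C", "G", "T")
  expect_equal(consensus_string(pwm), "Atn")
  expect_equal(consensus_string(pwm, upper_threshold = 0.5), "ATn")
  expect_equal(consensus_string(pwm, lower_threshold = 0.2), "Ata")
})

test_that("purine profile indexes positions -20..-1 and extracts by region", {
  allA <- rep(paste(rep("A", 20), collapse = ""), 5)
  pp <- purine_profile(allA)
  expect_equal(pp$profile$position, -(20:1))
  expect_true(all(pp$profile$purine_fraction == 1))
  expect_true(all(pp$extracted))
  allC <- rep(paste(rep("C", 20), collapse = ""), 5)
  expect_false(any(purine_profile(allC)$extracted))
  expect_error(purine_profile(c("ACGT")), "exactly 20")

  # AGGAG planted at -12..-8 in 80% of 100 windows
  pw <- plant_in_windows(100, 20, "AGGAG", rate = 0.8, seed = 5,
                         offsets = 9)       # window pos 9..13 = -12..-8
  pp2 <- purine_profile(pw$seqs)
  at <- pp2$profile$position %in% -12:-8
  expect_true(all(pp2$profile$purine_fraction[at] > 0.55))
})

test_that("RBS discovery recovers the motif with legal spacers only", {
  pw <- plant_in_windows(60, 20, "AGGAG", rate = 0.95, seed = 9,
                         offsets = 4:11)    # 3' end 5-12 nt before codon
  r <- find_rbs(pw$seqs, start_codons = rep("ATG", 60), seed = 9)
  expect_gte(consensus_hits(r$model$consensus, "AGGAG"), 4L)
  sp <- r$calls$spacer[r$calls$has_rbs]
  expect_true(all(sp >= 3 & sp <= 14))
  expect_false(is.na(r$spacer_mean))
  expect_equal(unname(r$start_codon_usage["ATG"]), 60L)

  # an occurrence ending 2 nt before the start codon is outside the legal
  # offsets and cannot be called there
  w <- paste0(paste(rep("C", 13), collapse = ""), "AGGAG", "CC")
  r2 <- find_rbs(c(w, w), seed = 1)
  expect_true(all(is.na(r2$calls$spacer) | r2$calls$spacer >= 3))
})

test_that("promoter search respects the -10 and -35 spacer windows", {
  # 60 TSSs on a constructed genome: 50-nt upstream windows with TATAAT
  # ending 7 nt before +1 in 90% of them, TTGACA 18 nt upstream of that
  set.seed(3)
  n <- 60
  seg <- 120L
  seqv <- sample(c("A", "C", "G", "T"), n * seg, TRUE)
  tss <- data.frame(replicon_id = "chr1",
                    position = seg * (seq_len(n) - 1L) + 100L,
                    strand = "+", stringsAsFactors = FALSE)
  planted <- runif(n) < 0.9
  for (i in which(planted)) {
    p <- tss$position[i]
    seqv[(p - 7 - 6):(p - 7 - 1)] <- strsplit("TATAAT", "")[[1]]
    m10s <- p - 7 - 6
    seqv[(m10s - 18 - 6):(m10s - 18 - 1)] <- strsplit("TTGACA", "")[[1]]
  }
  g <- make_genome(c(chr1 = paste(seqv, collapse = "")))
  pr <- find_promoters(tss, g, seed = 3)
  expect_gte(consensus_hits(pr$minus10$consensus, "TATAAT"), 5L)
  expect_gte(pr$fraction_minus10, 0.85)
  expect_lte(pr$fraction_minus10, 0.97)
  sp10 <- pr$calls$minus10_spacer[pr$calls$has_minus10]
  expect_true(all(sp10 >= 3 & sp10 <= 11))
  expect_equal(sort(unique(sp10))[1], 7L)
  expect_gte(consensus_hits(pr$minus35$consensus, "TTGACA"), 4L)
  gaps <- pr$calls$minus35_gap[pr$calls$has_minus35]
  expect_true(all(gaps >= 16 & gaps <= 23))
  expect_true(any(gaps == 18L))
})

test_that("PWM scanning and the canonical RBS check agree on plain cases", {
  pwm <- pwm_from_consensus("AGGAG")
  sc <- scan_pwm("CCCAGGAGCCC", pwm)
  expect_equal(unname(which.max(sc)), 4L)
  g <- make_genome(c(chr1 = paste0(paste(rep("C", 30), collapse = ""),
                                   "AGGAG", "CCCCCCCC", "ATG",
                                   paste(rep("C", 30), collapse = ""))))
  expect_true(rbs_present(g, "chr1", 44L, "+"))   # spacer 8
  g2 <- make_genome(c(chr1 = paste(rep("C", 80), collapse = "")))
  expect_false(rbs_present(g2, "chr1", 44L, "+"))
})
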