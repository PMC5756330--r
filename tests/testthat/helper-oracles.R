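# Independent oracles and small fixture builders used across the suite.

# Two-sided Fisher exact p-value by direct hypergeometric enumeration over
# all tables with the observed margins.
brute_fisher <- function(a, b, c, d) {
  m <- a + b            # subset size
  n <- c + d
  k <- a + c            # category total
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive ZOOPS objective bound: maximize the pseudocount-penalized
# mixture log-likelihood (the quantity em_motif reports) over all hard
# single-offset-or-none assignments, with parameters set to the
# assignment's pseudocounted maximum-likelihood estimates.
brute_zoops_loglik <- function(seqs, width, background, pseudocount = 0.25) {
  enc <- lapply(seqs, function(s)
    match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")))
  n <- length(enc)
  offs <- lapply(enc, function(x) 0:(length(x) - width + 1L)) # 0 = none
  grid <- do.call(expand.grid, offs)
  logbg <- log(background)
  bg_ll <- vapply(enc, function(x) sum(logbg[x]), numeric(1))
  mix_ll <- function(pwm, gamma) {
    tot <- 0
    for (i in seq_len(n)) {
      x <- enc[[i]]
      no <- length(x) - width + 1L
      lr <- vapply(seq_len(no), function(j) {
        sum(log(pwm[cbind(seq_len(width), x[j:(j + width - 1L)])])) -
          sum(logbg[x[j:(j + width - 1L)]])
      }, numeric(1))
      tot <- tot + log((gamma / no) * sum(exp(lr)) + (1 - gamma)) + bg_ll[i]
    }
    tot
  }
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    asg <- as.integer(grid[r, ])
    counts <- matrix(pseudocount, width, 4L)
    used <- 0L
    for (i in seq_len(n)) {
      if (asg[i] > 0L) {
        used <- used + 1L
        w <- enc[[i]][asg[i]:(asg[i] + width - 1L)]
        for (k in seq_len(width)) counts[k, w[k]] <- counts[k, w[k]] + 1
      }
    }
    pwm <- counts / rowSums(counts)
    gamma <- min(max(used / n, 1e-6), 1 - 1e-6)
    ll <- mix_ll(pwm, gamma) + pseudocount * sum(log(pwm))
    if (ll > best) best <- ll
  }
  best
}

# small linear genome with one configurable gene, for classification tests
toy_genome <- function(len = 3000L, seed = 5L) {
  set.seed(seed)
  make_genome(c(chr1 = paste(sample(c("A", "C", "G", "T"), len,
                                    replace = TRUE), collapse = "")))
}

toy_gene <- function(gene_id, start, end, strand = "+",
                     feature_type = "CDS", replicon_id = "chr1") {
  data.frame(gene_id = gene_id, replicon_id = replicon_id, start = start,
             end = end, strand = strand, feature_type = feature_type,
             product = NA_character_, functional_category = NA_character_,
             stringsAsFactors = FALSE)
}

# profiles with explicit vectors on one replicon
toy_profiles <- function(genome, starts_fwd = NULL, starts_rev = NULL,
                         depth_fwd = NULL, depth_rev = NULL) {
  p <- new_profiles(genome)
  r <- names(genome)[1]
  L <- genome[[r]]$length
  fill <- function(v) if (is.null(v)) integer(L) else {
    stopifnot(length(v) == L); as.integer(v)
  }
  p[[r]]$read_starts[["+"]] <- fill(starts_fwd)
  p[[r]]$read_starts[["-"]] <- fill(starts_rev)
  p[[r]]$depth[["+"]] <- fill(depth_fwd)
  p[[r]]$depth[["-"]] <- fill(depth_rev)
  p
}

# memoized default synthetic run shared by the acceptance tests
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_run <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.acceptance_cache[[key]])) {
    .acceptance_cache[[key]] <- simulate_and_score(synthetic_config(seed = seed))
  }
  .acceptance_cache[[key]]
}
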