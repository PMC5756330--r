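# Fixed-width motif discovery by expectation maximization under a ZOOPS
# (zero-or-one occurrence per sequence) model, with positional constraints
# doing the work of the promoter/RBS spacer rules: the offset prior is
# uniform over the legal spacer window. N bases contribute background
# probability (log-ratio 0) in scoring and are skipped in re-estimation.

BASES <- c("A", "C", "G", "T")

encode_seq <- function(s) {
  x <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]],
             c(BASES, "N"))
  if (anyNA(x)) stop("sequence contains characters outside A/C/G/T/N")
  x
}

#' Promoter search configuration
#'
#' @param upstream_window_nt length of the extracted upstream window (50).
#' @param minus10_width width of the -10 element (6).
#' @param minus10_spacer_to_tss legal nt between the -10 3' end and the +1
#'   site (3 to 11).
#' @param minus35_width width of the -35 element (6).
#' @param spacer_10_35 legal nt between the -35 3' end and the -10 5' end
#'   (16 to 23).
#' @return list of class `promoter_config`.
#' @export
promoter_config <- function(upstream_window_nt = 50L, minus10_width = 6L,
                            minus10_spacer_to_tss = c(3L, 11L),
                            minus35_width = 6L,
                            spacer_10_35 = c(16L, 23L)) {
  stopifnot(minus10_width + max(minus10_spacer_to_tss) <= upstream_window_nt)
  structure(list(upstream_window_nt = upstream_window_nt,
                 minus10_width = minus10_width,
                 minus10_spacer_to_tss = minus10_spacer_to_tss,
                 minus35_width = minus35_width,
                 spacer_10_35 = spacer_10_35),
            class = "promoter_config")
}

#' RBS search configuration
#'
#' @param utr_min_nt minimal UTR length for inclusion (20).
#' @param window_nt window upstream of the start codon (20).
#' @param purine_threshold purine fraction defining enrichment (0.55).
#' @param purine_region positions (relative to the start codon) over which
#'   the per-sequence purine fraction is averaged (-15 to -6).
#' @param rbs_width motif width (5).
#' @param spacer_to_start legal nt between the motif 3' end and the start
#'   codon (3 to 14).
#' @return list of class `rbs_config`.
#' @export
rbs_config <- function(utr_min_nt = 20L, window_nt = 20L,
                       purine_threshold = 0.55,
                       purine_region = c(-15L, -6L),
                       rbs_width = 5L, spacer_to_start = c(3L, 14L)) {
  stopifnot(purine_threshold > 0, purine_threshold < 1)
  structure(list(utr_min_nt = utr_min_nt, window_nt = window_nt,
                 purine_threshold = purine_threshold,
                 purine_region = purine_region,
                 rbs_width = rbs_width, spacer_to_start = spacer_to_start),
            class = "rbs_config")
}

#' ZOOPS EM motif discovery
#'
#' Learns a fixed-width position weight matrix under a zero-or-one
#' occurrence-per-sequence model. The E-step computes per-offset occurrence
#' posteriors against the background; the M-step re-estimates the PWM from
#' posterior-weighted counts with pseudocounts and the occurrence prior
#' from the mean posterior. The log-likelihood is non-decreasing within a
#' run; the best of `n_restarts` seeded restarts is returned.
#'
#' @param sequences character vector (>= 2 sequences, each at least
#'   `width` long).
#' @param width motif width.
#' @param background length-4 base probability vector (A,C,G,T); default
#'   estimated from the input composition.
#' @param seed integer seed for the restarts.
#' @param n_restarts number of EM restarts (default 5).
#' @param max_iter maximal EM iterations per restart (default 200).
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param offsets legal motif start offsets: NULL (all), an integer vector
#'   applied to every sequence, or a list with one vector per sequence.
#' @param pseudocount per-base pseudocount (default 0.25).
#' @return object of class `motif_model`: width, pwm (width x 4), background,
#'   pseudocount, gamma (occurrence prior), per_sequence (data.frame:
#'   offset, posterior), consensus, loglik, loglik_trace.
#' @export
em_motif <- function(sequences, width, background = NULL, seed = 1L,
                     n_restarts = 5L, max_iter = 200L, tol = 1e-6,
                     offsets = NULL, pseudocount = 0.25) {
  if (length(sequences) < 2L) stop("need at least 2 sequences")
  lens <- nchar(sequences)
  if (any(lens < width)) {
    stop("sequence ", which(lens < width)[1], " shorter than width ", width)
  }
  enc <- lapply(sequences, encode_seq)
  n <- length(enc)
  if (is.null(offsets)) {
    offs <- lapply(lens, function(L) seq_len(L - width + 1L))
  } else if (!is.list(offsets)) {
    offs <- lapply(lens, function(L) {
      o <- offsets[offsets >= 1L & offsets <= L - width + 1L]
      if (!length(o)) stop("no legal offsets for a sequence")
      o
    })
  } else {
    stopifnot(length(offsets) == n)
    offs <- offsets
  }
  # per-sequence window base-code matrices (n_offsets x width)
  W <- lapply(seq_len(n), function(i) {
    o <- offs[[i]]
    m <- matrix(0L, length(o), width)
    for (k in seq_len(width)) m[, k] <- enc[[i]][o + k - 1L]
    m
  })
  if (is.null(background)) {
    cnt <- tabulate(unlist(enc), nbins = 5L)[1:4] + 1
    background <- cnt / sum(cnt)
  }
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-6)
  logbg <- log(background)
  # constant background log-likelihood of each full sequence (N -> 0)
  bg_ll <- vapply(enc, function(x) sum(logbg[x[x <= 4L]]), numeric(1))

  run_em <- function(rseed) {
    set.seed(rseed)
    # seed the PWM from a random legal window
    i0 <- sample.int(n, 1L)
    j0 <- sample(seq_len(nrow(W[[i0]])), 1L)
    pwm <- matrix(1, width, 4L)
    for (k in seq_len(width)) {
      b <- W[[i0]][j0, k]
      if (b <= 4L) pwm[k, b] <- pwm[k, b] + 4
    }
    pwm <- pwm / rowSums(pwm)
    gamma <- 0.5
    trace <- numeric(0)
    ll_prev <- -Inf
    z <- vector("list", n)
    for (iter in seq_len(max_iter)) {
      LT <- cbind(log(pwm) - matrix(logbg, width, 4L, byrow = TRUE), 0)
      ll <- 0
      for (i in seq_len(n)) {
        m <- W[[i]]
        sc <- numeric(nrow(m))
        for (k in seq_len(width)) sc <- sc + LT[k, m[, k]]
        li <- (gamma / nrow(m)) * exp(sc)
        denom <- sum(li) + (1 - gamma)
        z[[i]] <- li / denom
        ll <- ll + log(denom) + bg_ll[i]
      }
      # MAP objective: data log-likelihood plus the Dirichlet log-prior
      # implied by the pseudocounts (monotone under the EM updates)
      ll <- ll + pseudocount * sum(log(pwm))
      trace <- c(trace, ll)
      if (is.finite(ll_prev) && ll - ll_prev < tol) break
      ll_prev <- ll
      counts <- matrix(pseudocount, width, 4L)
      tot <- 0
      for (i in seq_len(n)) {
        m <- W[[i]]; zi <- z[[i]]
        tot <- tot + sum(zi)
        for (k in seq_len(width)) {
          b <- m[, k]
          ok <- b <= 4L
          if (any(ok)) {
            add <- rowsum(zi[ok], b[ok])
            counts[k, as.integer(rownames(add))] <-
              counts[k, as.integer(rownames(add))] + add[, 1]
          }
        }
      }
      pwm <- counts / rowSums(counts)
      gamma <- min(max(tot / n, 1e-6), 1 - 1e-6)
    }
    list(pwm = pwm, gamma = gamma, loglik = trace[length(trace)],
         trace = trace, z = z)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- run_em(as.integer(seed) + r - 1L)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  # per-sequence Bayes factor at the final parameters: the mean per-offset
  # motif-vs-background likelihood ratio. Occurrence calls threshold this
  # rather than the ZOOPS posterior, whose occurrence prior degenerates
  # toward 1 on motif-free input.
  LTf <- cbind(log(best$pwm) - matrix(logbg, width, 4L, byrow = TRUE), 0)
  bf <- vapply(seq_len(n), function(i) {
    m <- W[[i]]
    sc <- numeric(nrow(m))
    for (k in seq_len(width)) sc <- sc + LTf[k, m[, k]]
    mean(exp(sc))
  }, numeric(1))
  per_seq <- data.frame(
    offset = vapply(seq_len(n), function(i)
      offs[[i]][which.max(best$z[[i]])], integer(1)),
    posterior = vapply(best$z, sum, numeric(1)),
    bayes_factor = bf
  )
  colnames(best$pwm) <- BASES
  structure(list(width = width, pwm = best$pwm, background = background,
                 pseudocount = pseudocount, gamma = best$gamma,
                 per_sequence = per_seq,
                 consensus = consensus_string(best$pwm),
                 loglik = best$loglik, loglik_trace = best$trace),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model: width", x$width, " consensus", x$consensus,
      " loglik", format(x$loglik), "\n")
  invisible(x)
}

#' Consensus string with conservation casing
#'
#' Per PWM column: uppercase letter when the maximal base frequency reaches
#' `upper_threshold`, lowercase when it reaches `lower_threshold`, else "n".
#'
#' @param pwm width x 4 probability matrix (columns A,C,G,T).
#' @param upper_threshold,lower_threshold casing thresholds (0.7 / 0.4).
#' @return character scalar.
#' @export
consensus_string <- function(pwm, upper_threshold = 0.7,
                             lower_threshold = 0.4) {
  stopifnot(ncol(pwm) == 4L, all(abs(rowSums(pwm) - 1) < 1e-6))
  out <- character(nrow(pwm))
  for (k in seq_len(nrow(pwm))) {
    j <- which.max(pwm[k, ])
    f <- pwm[k, j]
    out[k] <- if (f >= upper_threshold) BASES[j]
              else if (f >= lower_threshold) tolower(BASES[j])
              else "n"
  }
  paste(out, collapse = "")
}

#' Build a PWM from a consensus string
#'
#' @param consensus DNA string over A/C/G/T.
#' @param strength probability of the consensus base per column (0.85).
#' @return width x 4 probability matrix.
#' @export
pwm_from_consensus <- function(consensus, strength = 0.85) {
  b <- encode_seq(consensus)
  stopifnot(all(b <= 4L))
  pwm <- matrix((1 - strength) / 3, length(b), 4L,
                dimnames = list(NULL, BASES))
  for (k in seq_along(b)) pwm[k, b[k]] <- strength
  pwm
}

#' Log-odds scores of a PWM along a sequence
#'
#' @param seq DNA string.
#' @param pwm width x 4 probability matrix.
#' @param background length-4 base probabilities (default uniform).
#' @return numeric vector of scores, one per start offset (N scores 0).
#' @export
scan_pwm <- function(seq, pwm, background = rep(0.25, 4)) {
  x <- encode_seq(seq)
  w <- nrow(pwm)
  n_off <- length(x) - w + 1L
  if (n_off < 1L) return(numeric(0))
  LT <- cbind(log(pwm) - matrix(log(background), w, 4L, byrow = TRUE), 0)
  sc <- numeric(n_off)
  for (k in seq_len(w)) sc <- sc + LT[k, x[seq_len(n_off) + k - 1L]]
  sc
}

default_rbs_model <- function() {
  pwm <- pwm_from_consensus("AGGAG")
  structure(list(width = 5L, pwm = pwm, background = rep(0.25, 4),
                 pseudocount = 0.25, gamma = 0.9,
                 per_sequence = NULL, consensus = "AGGAG",
                 loglik = NA_real_, loglik_trace = numeric(0)),
            class = "motif_model")
}

#' Is an RBS motif present upstream of a start codon?
#'
#' Scans the 20 nt upstream of the codon (strand-aware) for a placement of
#' the RBS motif whose 3' end lies within the legal spacer of the codon
#' and whose log-odds score is positive.
#'
#' @param genome a `tss_genome`.
#' @param replicon_id replicon.
#' @param codon_start genome coordinate of the first codon base (on "-",
#'   the larger coordinate).
#' @param strand "+" or "-".
#' @param rbs_model a `motif_model` (default: canonical AGGAG matrix).
#' @param spacer legal nt between motif 3' end and codon (default 3-14).
#' @return logical.
#' @export
rbs_present <- function(genome, replicon_id, codon_start, strand,
                        rbs_model = NULL, spacer = c(3L, 14L)) {
  if (is.null(rbs_model)) rbs_model <- default_rbs_model()
  w <- rbs_model$width
  win <- if (strand == "+") {
    extract_seq(genome, replicon_id, codon_start - 20L, codon_start - 1L, "+")
  } else {
    extract_seq(genome, replicon_id, codon_start + 1L, codon_start + 20L, "-")
  }
  if (is.na(win)) return(FALSE)
  sc <- scan_pwm(win, rbs_model$pwm, rbs_model$background)
  if (!length(sc)) return(FALSE)
  # offset o has its 3' end at window position o+w-1; spacer to the codon
  # is 20 - (o+w-1)
  sp <- nchar(win) - (seq_along(sc) + w - 1L)
  legal <- sp >= spacer[1] & sp <= spacer[2]
  any(legal & sc > 0)
}

extract_upstream_windows <- function(tss, genome, width) {
  win <- rep(NA_character_, nrow(tss))
  for (i in seq_len(nrow(tss))) {
    r <- tss$replicon_id[i]; p <- tss$position[i]; s <- tss$strand[i]
    win[i] <- if (s == "+") {
      extract_seq(genome, r, p - width, p - 1L, "+")
    } else {
      extract_seq(genome, r, p + 1L, p + width, "-")
    }
  }
  win
}

#' Discover -10/-35 promoter motifs upstream of TSSs
#'
#' Extracts the 50 nt upstream of each TSS (truncated windows are skipped
#' and reported), learns the -10 element by ZOOPS EM restricted to offsets
#' placing its 3' end 3-11 nt upstream of the +1 site, then learns the -35
#' element only over TSSs with a -10 call, restricted to a 16-23 nt gap
#' between the -35 3' end and the -10 5' end. A TSS "has" an element when
#' its occurrence posterior reaches 0.5.
#'
#' @param tss TSS data.frame (tss_id, replicon_id, position, strand).
#' @param genome a `tss_genome`.
#' @param config a [promoter_config()].
#' @param seed EM seed.
#' @param n_restarts EM restarts.
#' @param occurrence_bf motif-vs-background Bayes factor at or above which
#'   a sequence is counted as carrying the element (default 4).
#' @return list: `minus10`, `minus35` (motif_model or NULL), `calls`
#'   (data.frame: tss_id, has_minus10, minus10_spacer, has_minus35,
#'   minus35_gap), `fraction_minus10`, `fraction_minus35`, `skipped`
#'   (tss_ids without a full window).
#' @export
find_promoters <- function(tss, genome, config = promoter_config(),
                           seed = 1L, n_restarts = 5L,
                           occurrence_bf = 4) {
  if (!("tss_id" %in% names(tss))) {
    tss$tss_id <- tss_id_of(tss$replicon_id, tss$position, tss$strand)
  }
  Wn <- config$upstream_window_nt
  w10 <- config$minus10_width
  win <- extract_upstream_windows(tss, genome, Wn)
  ok <- !is.na(win)
  skipped <- tss$tss_id[!ok]
  seqs <- win[ok]
  ids <- tss$tss_id[ok]
  empty_calls <- data.frame(tss_id = character(0), has_minus10 = logical(0),
                            minus10_spacer = integer(0),
                            has_minus35 = logical(0),
                            minus35_gap = integer(0))
  if (length(seqs) < 2L) {
    return(list(minus10 = NULL, minus35 = NULL, calls = empty_calls,
                fraction_minus10 = NA_real_, fraction_minus35 = NA_real_,
                skipped = skipped))
  }
  sp <- config$minus10_spacer_to_tss
  # offset o puts the 3' end at o+w10-1; spacer to +1 is Wn-(o+w10-1)
  o10 <- (Wn - w10 + 1L - sp[2]):(Wn - w10 + 1L - sp[1])
  m10 <- em_motif(seqs, w10, seed = seed, n_restarts = n_restarts,
                  offsets = o10)
  has10 <- m10$per_sequence$bayes_factor >= occurrence_bf
  off10 <- m10$per_sequence$offset
  spacer10 <- Wn - (off10 + w10 - 1L)
  calls <- data.frame(tss_id = ids, has_minus10 = has10,
                      minus10_spacer = ifelse(has10, spacer10, NA_integer_),
                      has_minus35 = FALSE, minus35_gap = NA_integer_,
                      stringsAsFactors = FALSE)
  m35 <- NULL
  if (sum(has10) >= 2L) {
    w35 <- config$minus35_width
    g <- config$spacer_10_35
    idx35 <- which(has10)
    offs35 <- lapply(idx35, function(i) {
      o <- (off10[i] - g[2] - w35):(off10[i] - g[1] - w35)
      o[o >= 1L]
    })
    usable <- lengths(offs35) > 0L
    if (sum(usable) >= 2L) {
      m35 <- em_motif(seqs[idx35[usable]], w35, seed = seed + 1L,
                      n_restarts = n_restarts, offsets = offs35[usable])
      has35 <- m35$per_sequence$bayes_factor >= occurrence_bf
      off35 <- m35$per_sequence$offset
      gap <- off10[idx35[usable]] - (off35 + w35 - 1L) - 1L
      calls$has_minus35[idx35[usable]] <- has35
      calls$minus35_gap[idx35[usable]] <- ifelse(has35, gap, NA_integer_)
    }
  }
  list(minus10 = m10, minus35 = m35, calls = calls,
       fraction_minus10 = mean(calls$has_minus10),
       fraction_minus35 = if (any(calls$has_minus10))
         sum(calls$has_minus35) / sum(calls$has_minus10) else NA_real_,
       skipped = skipped)
}

#' Per-position purine profile of start-codon-proximal windows
#'
#' Windows are exactly `window_nt` long and end immediately before the
#' start codon; position indices run -window_nt ... -1. A sequence is
#' extracted (RBS candidate) when its mean purine (A+G) fraction over the
#' configured region (-15 ... -6 by default) exceeds the threshold.
#'
#' @param windows character vector of windows (all `window_nt` long).
#' @param config an [rbs_config()].
#' @return list: `profile` (data.frame: position, purine_fraction),
#'   `extracted` (logical per window).
#' @export
purine_profile <- function(windows, config = rbs_config()) {
  Wn <- config$window_nt
  if (any(nchar(windows) != Wn)) {
    stop("all windows must be exactly ", Wn, " nt")
  }
  m <- do.call(rbind, lapply(windows, encode_seq))
  pur <- m == 1L | m == 3L                       # A or G
  prof <- data.frame(position = -(Wn:1),
                     purine_fraction = colMeans(pur))
  reg <- config$purine_region
  cols <- (Wn + reg[1] + 1L):(Wn + reg[2] + 1L)  # -15..-6 -> 6..15
  extracted <- rowMeans(pur[, cols, drop = FALSE]) > config$purine_threshold
  list(profile = prof, extracted = extracted)
}

#' Discover the ribosome-binding-site motif
#'
#' Runs ZOOPS EM (width 5) on purine-enriched upstream windows, with
#' occurrences legal only when the motif 3' end lies 3-14 nt upstream of
#' the start codon. Reports per-gene calls, spacer mean/SD, and start-codon
#' usage.
#'
#' @param windows extracted windows (from [purine_profile()]).
#' @param start_codons character vector of the genes' start codons
#'   (parallel to `windows`; optional).
#' @param config an [rbs_config()].
#' @param seed,n_restarts EM control.
#' @param occurrence_bf Bayes-factor threshold for occurrence calls (4).
#' @return list: `model` (motif_model), `calls` (data.frame: window,
#'   has_rbs, rbs_seq, spacer), `spacer_mean`, `spacer_sd`,
#'   `start_codon_usage` (table).
#' @export
find_rbs <- function(windows, start_codons = NULL, config = rbs_config(),
                     seed = 1L, n_restarts = 5L, occurrence_bf = 4) {
  Wn <- config$window_nt
  w <- config$rbs_width
  sp <- config$spacer_to_start
  offs <- (Wn - w + 1L - sp[2]):(Wn - w + 1L - sp[1])
  model <- em_motif(windows, w, seed = seed, n_restarts = n_restarts,
                    offsets = offs)
  has <- model$per_sequence$bayes_factor >= occurrence_bf
  off <- model$per_sequence$offset
  spacer <- Wn - (off + w - 1L)
  calls <- data.frame(
    window = windows, has_rbs = has,
    rbs_seq = ifelse(has, substr(windows, off, off + w - 1L), NA_character_),
    spacer = ifelse(has, spacer, NA_integer_), stringsAsFactors = FALSE)
  usage <- if (!is.null(start_codons)) table(toupper(start_codons)) else NULL
  list(model = model, calls = calls,
       spacer_mean = mean(spacer[has]), spacer_sd = sd(spacer[has]),
       start_codon_usage = usage)
}
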