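# Synthetic bacterial transcriptome with planted ground truth.
#
# The generator lays out a single ~100 kb replicon with 80 genes (operon
# runs, antisense-host blocks, riboswitch loci, standalone genes) and
# plants TSSs of every category, promoter/RBS motifs, spanning-read
# counts, antisense and novel transcripts, and barcode-flagged
# false-positive 5' reads. Depth is a block model (flat or gently tapered
# plateaus over planted transcripts); read-start noise is Poisson per
# position. Every planted element's category is enforced geometrically at
# planting time, so the classification rules can re-derive it exactly.

#' Synthetic dataset configuration
#'
#' Defaults are the desk-scale study conditions used throughout the test
#' suite: one 100 kb replicon, 80 genes, 50 planted TSSs of strength
#' 40-200 over Poisson(0.2) read-start noise.
#'
#' @param seed RNG seed; the dataset is a deterministic function of it.
#' @param replicon_length replicon length in nt (100000).
#' @param tss_spec named integer vector: number of planted standalone
#'   sense TSSs (`sTSS`), distal (`pTSS`), internal (`iTSS`), and
#'   revision-route (`nsTSS`) TSSs. Antisense and intergenic TSS counts
#'   follow `antisense_spec` and the fixed novel-transcript design (4
#'   intergenic TSSs); riboswitch, operon-first and sub-operon sense TSSs
#'   are added on top of `sTSS` (defaults total 50 planted TSSs).
#' @param strength_range read-start strength range of planted TSSs
#'   (c(40, 200)).
#' @param operon_spec list of integer vectors: spanning-read counts
#'   between transcription-adjacent genes of each laid-out gene run (a
#'   count below the joining threshold splits the run in truth).
#' @param minus10_consensus,minus35_consensus,rbs_consensus planted motif
#'   consensus strings.
#' @param motif_plant_rate fraction of eligible sites receiving the
#'   planted motif (0.9).
#' @param noise_lambda Poisson mean of background read starts (0.2).
#' @param barcode false-positive 5'-end barcode ("TACCCTAG").
#' @param n_reads number of simulated primary-library reads (1000).
#' @param fp_read_fraction probability a read carries the barcode (0.605).
#' @param antisense_spec data.frame(length, mean_cov, start_cov, accept):
#'   planted antisense transcripts straddling the calling thresholds.
#' @param riboswitch_spec data.frame(utr_cov, orf_cov, has_tss): planted
#'   cis-regulatory loci and their UTR/ORF coverage plateaus.
#' @param fp_spike_n,fp_spike_strength processed-end read-start spikes
#'   planted in coverage deserts (removed by curation).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             replicon_length = 100000L,
                             tss_spec = c(sTSS = 19L, pTSS = 5L,
                                          iTSS = 5L, nsTSS = 3L),
                             strength_range = c(40L, 200L),
                             operon_spec = list(
                               op1 = c(25L, 30L, 18L, 12L),
                               op2 = c(14L, 22L),
                               op3 = c(12L, 15L, 11L),
                               op4 = c(10L),
                               op5 = c(9L),
                               op6 = c(20L, 9L, 13L)),
                             minus10_consensus = "TATAAT",
                             minus35_consensus = "TTGACA",
                             rbs_consensus = "AGGAG",
                             motif_plant_rate = 0.9,
                             noise_lambda = 0.2,
                             barcode = "TACCCTAG",
                             n_reads = 1000L,
                             fp_read_fraction = 0.605,
                             antisense_spec = data.frame(
                               length = c(120L, 15L, 600L, 600L, 40L, 30L),
                               mean_cov = c(25, 30, 50, 50, 14, 20),
                               start_cov = c(25, 30, 85, 75, 14, 20),
                               accept = c(TRUE, FALSE, TRUE, FALSE,
                                          FALSE, TRUE)),
                             riboswitch_spec = data.frame(
                               utr_cov = c(6000, 3000, 2600, 2000, 100, 80),
                               orf_cov = c(60, 50, 100, 100, 100, 80),
                               has_tss = c(TRUE, TRUE, TRUE, TRUE,
                                           FALSE, FALSE)),
                             fp_spike_n = 5L,
                             fp_spike_strength = 35L) {
  stopifnot(motif_plant_rate >= 0, motif_plant_rate <= 1,
            fp_read_fraction >= 0, fp_read_fraction <= 1,
            noise_lambda >= 0, all(strength_range > 0),
            grepl("^[ACGT]+$", minus10_consensus),
            grepl("^[ACGT]+$", minus35_consensus),
            grepl("^[ACGT]+$", rbs_consensus))
  structure(as.list(environment()), class = "synthetic_config")
}

rand_len <- function(lo, hi) {            # gene length, multiple of 3
  3L * sample(seq(ceiling(lo / 3), floor(hi / 3)), 1L)
}

#' Generate a synthetic dataset with planted truth
#'
#' @param config a [synthetic_config()].
#' @return list: `genome` (tss_genome), `annotation` (data.frame),
#'   `profiles` (stranded_profiles), `reads` (named character vector),
#'   `spanning_counts` (data.frame), `cis_elements` (data.frame), `truth`
#'   (list of planted elements), `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  set.seed(config$seed)
  L <- config$replicon_length
  rep_id <- "chr1"
  GAP <- 320L; OP_GAP <- 150L

  # ---- unit plan ----------------------------------------------------------
  units <- list()
  add_unit <- function(type, n_genes, strand, lens = NULL, ...) {
    if (is.null(lens)) lens <- vapply(seq_len(n_genes), function(i)
      rand_len(450, 750), integer(1))
    units[[length(units) + 1L]] <<- c(list(type = type, n_genes = n_genes,
                                           strand = strand, lens = lens),
                                      list(...))
  }
  rs <- function() sample(c("+", "-"), 1L)
  ts <- config$tss_spec

  add_unit("operon", 5L, "+", name = "op1",
           counts = config$operon_spec$op1, first_tss = TRUE, sub_gene = 3L)
  for (i in seq_len(2L)) add_unit("plain", 1L, rs())
  add_unit("operon", 2L, rs(), name = "op5", counts = config$operon_spec$op5)
  # antisense host blocks: hosts flanked by same-strand plain genes so the
  # opposite-strand TSS has no same-strand gene start within 600 nt
  n_as <- nrow(config$antisense_spec)
  as_plus_hosts <- ceiling(n_as / 2)      # hosts on "-", TSS on "+"
  add_unit("plain", 1L, "-")
  for (i in seq_len(as_plus_hosts))
    add_unit("as_host", 1L, "-", lens = 600L, as_entry = i)
  add_unit("plain", 1L, "-")
  if (n_as > as_plus_hosts) {
    add_unit("plain", 1L, "+")
    for (i in seq(as_plus_hosts + 1L, n_as))
      add_unit("as_host", 1L, "+", lens = 600L, as_entry = i)
    add_unit("plain", 1L, "+")
  }
  for (i in seq_len(nrow(config$riboswitch_spec)))
    add_unit("riboswitch", 1L, "+", lens = 450L, rs_entry = i)
  n_leaderless <- min(2L, ts[["sTSS"]])
  for (i in seq_len(ts[["sTSS"]]))
    add_unit("s_gene", 1L, rs(), leaderless = i <= n_leaderless)
  for (i in seq_len(ts[["pTSS"]])) add_unit("p_gene", 1L, rs())
  for (i in seq_len(ts[["iTSS"]])) add_unit("i_gene", 1L, rs(), lens = 600L)
  for (i in seq_len(ts[["nsTSS"]])) add_unit("ns_gene", 1L, rs(), lens = 600L)
  add_unit("operon", 3L, rs(), name = "op2", counts = config$operon_spec$op2)
  add_unit("operon", 4L, "+", name = "op3",
           counts = config$operon_spec$op3, first_tss = TRUE, sub_gene = 2L)
  add_unit("operon", 2L, rs(), name = "op4", counts = config$operon_spec$op4)
  add_unit("operon", 4L, rs(), name = "op6", counts = config$operon_spec$op6)
  n_struct <- 4L
  for (i in seq_len(n_struct))
    add_unit("structural", 1L, rs(), lens = 120L,
             ftype = if (i %% 2L) "rRNA" else "tRNA")
  n_plain_left <- 80L - sum(vapply(units, function(u) u$n_genes,
                                   integer(1)))
  if (n_plain_left < 0L) stop("unit plan exceeds requested gene count")
  for (i in seq_len(n_plain_left)) add_unit("plain", 1L, rs())

  # ---- layout -------------------------------------------------------------
  draw_strength <- function() {
    sr <- config$strength_range
    sample(seq(sr[1], sr[2]), 1L)
  }
  ann <- list(); gmeta <- list()
  cursor <- 400L
  for (ui in seq_along(units)) {
    u <- units[[ui]]
    # upstream-side space requirement (5' gap) by unit type and strand
    utr_d <- NA_integer_
    need <- GAP
    if (u$type == "p_gene") { utr_d <- sample(330:560, 1L); need <- utr_d + 80L }
    if (u$type == "s_gene") {
      utr_d <- if (isTRUE(u$leaderless)) sample(0:3, 1L) else
        sample(25:250, 1L)
      need <- max(GAP, utr_d + 60L)
    }
    if (u$type == "riboswitch") need <- GAP + 150L   # UTR lives in the gap
    gap <- if (u$strand == "+") need else GAP
    # a "-" unit needs its 5' space on the right; widen the *next* gap then
    cursor <- cursor + gap
    starts <- integer(u$n_genes)
    for (k in seq_len(u$n_genes)) {
      starts[k] <- cursor
      cursor <- cursor + u$lens[k] - 1L
      if (k < u$n_genes) cursor <- cursor + 1L + OP_GAP
    }
    ends <- starts + u$lens - 1L
    cursor <- ends[u$n_genes] + 1L
    if (u$strand == "-") cursor <- cursor + need - GAP
    gid <- sprintf("g%03d_%s", ui, u$type)
    ids <- if (u$n_genes == 1L) gid else paste0(gid, "_", seq_len(u$n_genes))
    ftype <- if (u$type == "structural") u$ftype else "CDS"
    ann[[ui]] <- data.frame(
      gene_id = ids, replicon_id = rep_id, start = starts, end = ends,
      strand = u$strand, feature_type = ftype,
      product = paste("synthetic", u$type),
      functional_category = NA_character_, stringsAsFactors = FALSE)
    gmeta[[ui]] <- c(u, list(gene_ids = ids, starts = starts, ends = ends,
                             utr_d = utr_d))
  }
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  if (cursor + 8000L > L) {
    stop("replicon too short for the requested genes/operons: need > ",
         cursor + 8000L, " nt")
  }
  desert <- cursor + 1500L

  # assign functional categories to CDS genes (20 roles, round-robin with
  # jitter) so enrichment statistics have a universe to work with
  is_cds <- annotation$feature_type == "CDS"
  roles <- sprintf("role_%02d", 1:20)
  annotation$functional_category[is_cds] <-
    sample(roles, sum(is_cds), replace = TRUE)

  # ---- genome sequence ----------------------------------------------------
  seqv <- sample(BASES, L, replace = TRUE, prob = c(.3, .2, .2, .3))
  wr <- function(from, to, motif, strand = "+") {
    s <- if (strand == "+") motif else revcomp(motif)
    stopifnot(to - from + 1L == nchar(s), from >= 1L, to <= L)
    seqv[from:to] <<- strsplit(s, "", fixed = TRUE)[[1]]
  }
  for (i in which(is_cds)) {
    s <- annotation$start[i]; e <- annotation$end[i]
    if (annotation$strand[i] == "+") {
      wr(s, s + 2L, "ATG"); wr(e - 2L, e, "TAA")
    } else {
      wr(e - 2L, e, "ATG", "-"); wr(s, s + 2L, "TAA", "-")
    }
  }

  # ---- plant TSSs ---------------------------------------------------------
  truth_tss <- list(); motif_truth <- list()
  add_tss <- function(position, strand, category, strength, gene_id = NA,
                      utr = NA, extra = list()) {
    truth_tss[[length(truth_tss) + 1L]] <<- c(list(
      replicon_id = rep_id, position = as.integer(position),
      strand = strand, category = category,
      strength = as.integer(strength), gene_id = as.character(gene_id),
      utr = as.integer(utr)), extra)
  }
  plant_promoter <- function(p, strand) {
    if (runif(1) > config$motif_plant_rate) return(invisible(NULL))
    sp <- sample(5:9, 1L)
    w10 <- nchar(config$minus10_consensus)
    w35 <- nchar(config$minus35_consensus)
    g <- sample(16:20, 1L)
    if (strand == "+") {
      m10 <- c(p - sp - w10, p - sp - 1L)
      m35 <- c(m10[1] - g - w35, m10[1] - g - 1L)
    } else {
      m10 <- c(p + sp + 1L, p + sp + w10)
      m35 <- c(m10[2] + g + 1L, m10[2] + g + w35)
    }
    wr(m10[1], m10[2], config$minus10_consensus, strand)
    wr(m35[1], m35[2], config$minus35_consensus, strand)
    motif_truth[[length(motif_truth) + 1L]] <<- data.frame(
      kind = "minus10", start = m10[1], end = m10[2], strand = strand,
      spacer = sp, stringsAsFactors = FALSE)
    motif_truth[[length(motif_truth) + 1L]] <<- data.frame(
      kind = "minus35", start = m35[1], end = m35[2], strand = strand,
      spacer = g, stringsAsFactors = FALSE)
  }
  plant_rbs <- function(codon_first, strand, force = FALSE) {
    if (!force && runif(1) > config$motif_plant_rate)
      return(invisible(NULL))
    sp <- sample(6:10, 1L)
    w <- nchar(config$rbs_consensus)
    iv <- if (strand == "+") c(codon_first - sp - w, codon_first - sp - 1L)
          else c(codon_first + sp + 1L, codon_first + sp + w)
    wr(iv[1], iv[2], config$rbs_consensus, strand)
    motif_truth[[length(motif_truth) + 1L]] <<- data.frame(
      kind = "rbs", start = iv[1], end = iv[2], strand = strand,
      spacer = sp, stringsAsFactors = FALSE)
  }
  tss_at_utr <- function(gstart, gend, strand, d) {
    if (strand == "+") gstart - d else gend + d
  }

  suboperon_truth <- list(); operon_truth <- list()
  spanning <- list()
  # transcript plateaus to add to depth: list(strand, from, to, level)
  plateaus <- list()
  add_plateau <- function(strand, from, to, level, taper = TRUE) {
    plateaus[[length(plateaus) + 1L]] <<- list(
      strand = strand, from = as.integer(from), to = as.integer(to),
      level = level, taper = taper)
  }
  gene5 <- function(i) if (annotation$strand[i] == "+") annotation$start[i]
                       else annotation$end[i]

  for (ui in seq_along(units)) {
    u <- gmeta[[ui]]
    g1 <- match(u$gene_ids[1], annotation$gene_id)
    st <- u$strand
    if (u$type %in% c("plain", "structural")) {
      if (u$type == "plain") {
        add_plateau(st, annotation$start[g1], annotation$end[g1], 8)
      }
      next
    }
    if (u$type == "s_gene") {
      d <- u$utr_d
      p <- tss_at_utr(annotation$start[g1], annotation$end[g1], st, d)
      str_ <- draw_strength()
      add_tss(p, st, "sTSS", str_, u$gene_ids[1], d)
      plant_promoter(p, st)
      if (d >= 20L) plant_rbs(gene5(g1), st)
      lv <- max(8, round(str_ / 3))
      if (st == "+") add_plateau(st, p, annotation$end[g1], lv)
      else add_plateau(st, annotation$start[g1], p, lv)
    } else if (u$type == "p_gene") {
      d <- u$utr_d
      p <- tss_at_utr(annotation$start[g1], annotation$end[g1], st, d)
      str_ <- draw_strength()
      add_tss(p, st, "pTSS", str_, u$gene_ids[1], d)
      plant_promoter(p, st)
      lv <- max(8, round(str_ / 3))
      if (st == "+") add_plateau(st, p, annotation$end[g1], lv)
      else add_plateau(st, annotation$start[g1], p, lv)
    } else if (u$type == "i_gene") {
      off <- sample(201:290, 1L)
      p <- if (st == "+") annotation$start[g1] + off else
        annotation$end[g1] - off
      str_ <- draw_strength()
      add_tss(p, st, "iTSS", str_, u$gene_ids[1], off)
      add_plateau(st, annotation$start[g1], annotation$end[g1], 8)
      lv <- max(8, round(str_ / 3))
      if (st == "+") add_plateau(st, p, annotation$end[g1], lv)
      else add_plateau(st, annotation$start[g1], p, lv)
    } else if (u$type == "ns_gene") {
      off <- sample(c(90L, 120L, 150L), 1L)        # multiple of 3
      gs <- gene5(g1)
      p <- if (st == "+") gs + off else gs - off
      new_off <- off + 30L
      # scrub in-frame start codons between the annotated and revised start
      for (k3 in seq(3L, new_off - 3L, by = 3L)) {
        iv <- if (st == "+") c(gs + k3, gs + k3 + 2L) else
          c(gs - k3 - 2L, gs - k3)
        cod <- if (st == "+") paste(seqv[iv[1]:iv[2]], collapse = "") else
          revcomp(paste(seqv[iv[1]:iv[2]], collapse = ""))
        if (cod %in% START_CODONS) wr(iv[1], iv[2], "CCA", st)
      }
      new_start <- if (st == "+") gs + new_off else gs - new_off
      if (st == "+") wr(new_start, new_start + 2L, "ATG", "+")
      else wr(new_start - 2L, new_start, "ATG", "-")
      plant_rbs(new_start, st, force = TRUE)
      str_ <- draw_strength()
      add_tss(p, st, "nsTSS", str_, u$gene_ids[1], NA, extra = list(
        new_start = as.integer(new_start),
        shortening_aa = as.integer(new_off / 3L), new_utr = 30L))
      add_plateau(st, annotation$start[g1], annotation$end[g1], 8)
      lv <- max(8, round(str_ / 3))
      if (st == "+") add_plateau(st, p, annotation$end[g1], lv)
      else add_plateau(st, annotation$start[g1], p, lv)
    } else if (u$type == "operon") {
      idx <- match(u$gene_ids, annotation$gene_id)
      tx_ids <- if (st == "+") u$gene_ids else rev(u$gene_ids)
      counts <- u$counts
      for (k in seq_along(counts)) {
        spanning[[length(spanning) + 1L]] <- data.frame(
          gene_a = tx_ids[k], gene_b = tx_ids[k + 1L],
          count = counts[k], stringsAsFactors = FALSE)
      }
      # truth operons: split the run where the count drops below 10
      brk <- c(0L, which(counts < 10L), length(counts) + 1L)
      for (b in seq_len(length(brk) - 1L)) {
        span <- (brk[b] + 1L):(brk[b + 1L] - 1L + 1L)
        span <- span[span <= length(tx_ids)]
        if (length(span) >= 2L) {
          operon_truth[[length(operon_truth) + 1L]] <- tx_ids[span]
        }
      }
      for (i in idx) add_plateau(st, annotation$start[i],
                                 annotation$end[i], 8)
      if (isTRUE(u$first_tss)) {
        fg <- match(tx_ids[1], annotation$gene_id)
        d <- sample(40:120, 1L)
        p <- tss_at_utr(annotation$start[fg], annotation$end[fg], st, d)
        str_ <- draw_strength()
        add_tss(p, st, "sTSS", str_, tx_ids[1], d)
        plant_promoter(p, st)
        plant_rbs(gene5(fg), st)
        lv <- max(8, round(str_ / 3))
        if (st == "+") add_plateau(st, p, max(annotation$end[idx]), lv)
        else add_plateau(st, min(annotation$start[idx]), p, lv)
      }
      if (!is.null(u$sub_gene)) {
        sg <- match(tx_ids[u$sub_gene], annotation$gene_id)
        d <- sample(30:110, 1L)
        p <- tss_at_utr(annotation$start[sg], annotation$end[sg], st, d)
        str_ <- draw_strength()
        add_tss(p, st, "sTSS", str_, tx_ids[u$sub_gene], d)
        plant_promoter(p, st)
        plant_rbs(gene5(sg), st)
        suboperon_truth[[length(suboperon_truth) + 1L]] <- list(
          operon = tx_ids, first_gene = tx_ids[u$sub_gene],
          tss_position = as.integer(p))
        lv <- max(8, round(str_ / 3))
        if (st == "+") add_plateau(st, p, max(annotation$end[idx]), lv)
        else add_plateau(st, min(annotation$start[idx]), p, lv)
      }
    }
  }
  # other adjacent same-strand CDS pairs get sub-threshold counts
  cds <- annotation[is_cds, , drop = FALSE]
  have <- if (length(spanning)) do.call(rbind, spanning) else
    data.frame(gene_a = character(0), gene_b = character(0),
               count = integer(0))
  for (i in seq_len(nrow(cds) - 1L)) {
    if (cds$strand[i] == cds$strand[i + 1L]) {
      a <- cds$gene_id[i]; b <- cds$gene_id[i + 1L]
      if (cds$strand[i] == "-") { tmp <- a; a <- b; b <- tmp }
      if (!any((have$gene_a == a & have$gene_b == b) |
                 (have$gene_a == b & have$gene_b == a))) {
        have <- rbind(have, data.frame(gene_a = a, gene_b = b,
                                       count = sample(0:5, 1L),
                                       stringsAsFactors = FALSE))
      }
    }
  }
  spanning_counts <- have

  # ---- antisense transcripts ---------------------------------------------
  as_truth <- list()
  as_sets <- list()     # exact depth assignments applied after plateaus
  for (ui in seq_along(units)) {
    u <- gmeta[[ui]]
    if (u$type != "as_host") next
    e <- config$antisense_spec[u$as_entry, ]
    host <- match(u$gene_ids[1], annotation$gene_id)
    add_plateau(u$strand, annotation$start[host], annotation$end[host], 8)
    tstrand <- if (u$strand == "+") "-" else "+"
    p <- if (tstrand == "+") annotation$start[host] + 150L else
      annotation$end[host] - 150L
    str_ <- draw_strength()
    add_tss(p, tstrand, "asTSS", str_, u$gene_ids[1], NA)
    lvl <- rep(e$mean_cov, e$length)
    lvl[1] <- e$start_cov
    # preserve the intended mean under the start-coverage override
    if (e$length > 1L) {
      lvl[-1] <- (e$mean_cov * e$length - e$start_cov) / (e$length - 1L)
    }
    iv <- if (tstrand == "+") c(p, p + e$length - 1L) else
      c(p - e$length + 1L, p)
    as_sets[[length(as_sets) + 1L]] <- list(strand = tstrand, from = iv[1],
                                            to = iv[2],
                                            values = if (tstrand == "+") lvl
                                                     else rev(lvl))
    as_truth[[length(as_truth) + 1L]] <- data.frame(
      tss_position = as.integer(p), strand = tstrand,
      start = as.integer(iv[1]), end = as.integer(iv[2]),
      length = e$length, mean_cov = e$mean_cov, accept = e$accept,
      stringsAsFactors = FALSE)
  }

  # ---- riboswitch loci ----------------------------------------------------
  rs_truth <- list(); cis <- list()
  rs_sets <- list()
  ri <- 0L
  for (ui in seq_along(units)) {
    u <- gmeta[[ui]]
    if (u$type != "riboswitch") next
    ri <- ri + 1L
    e <- config$riboswitch_spec[u$rs_entry, ]
    g1 <- match(u$gene_ids[1], annotation$gene_id)
    gs <- annotation$start[g1]; ge <- annotation$end[g1]
    utr_start <- gs - 150L
    el <- data.frame(name = sprintf("element_%d", ri),
                     rfam_accession = sprintf("RFSYN%04d", ri),
                     replicon_id = rep_id, start = utr_start + 20L,
                     end = utr_start + 110L, strand = "+",
                     downstream_gene_id = u$gene_ids[1],
                     stringsAsFactors = FALSE)
    cis[[ri]] <- el
    if (e$has_tss) {
      add_tss(utr_start, "+", "sTSS", 300L, u$gene_ids[1], 150L)
      plant_promoter(utr_start, "+")
      plant_rbs(gs, "+")
    }
    rs_sets[[length(rs_sets) + 1L]] <- list(
      strand = "+", from = utr_start, to = gs - 1L, value = e$utr_cov)
    rs_sets[[length(rs_sets) + 1L]] <- list(
      strand = "+", from = gs, to = ge, value = e$orf_cov)
    rs_truth[[ri]] <- data.frame(
      name = el$name, has_tss = e$has_tss,
      tss_position = if (e$has_tss) as.integer(utr_start) else NA_integer_,
      utr_cov = e$utr_cov, orf_cov = e$orf_cov,
      expected_verdict = if (e$utr_cov / e$orf_cov >= 10)
        "termination-like" else "readthrough-like",
      stringsAsFactors = FALSE)
  }
  cis_elements <- do.call(rbind, cis)

  # ---- novel intergenic transcripts --------------------------------------
  nov_truth <- list(); nov_sets <- list()
  scrub_orfs <- function(from, to, strand, min_aa) {
    for (it in seq_len(100L)) {
      s <- extract_seq_chars(seqv, from, to, strand)
      orf <- find_longest_orf(s, min_aa)
      if (is.null(orf)) return(invisible(NULL))
      iv <- if (strand == "+") c(from + orf$start_off - 1L,
                                 from + orf$start_off + 1L) else
        c(to - orf$start_off - 1L, to - orf$start_off + 1L)
      wr(iv[1], iv[2], "CCC", strand)
    }
    stop("could not scrub open reading frames from planted ncRNA")
  }
  t1 <- desert + 500L
  t2 <- t1 + 30L
  nov_sets[[1]] <- list(strand = "+", from = t1, to = t1 + 329L, value = 30)
  scrub_orfs(t1, t1 + 329L, "+", 25L)
  add_tss(t1, "+", "nTSS", draw_strength(), NA, NA)
  add_tss(t2, "+", "nTSS", draw_strength(), NA, NA)
  nov_truth[[1]] <- data.frame(start = t1, end = t1 + 329L, strand = "+",
                               n_alt_tss = 2L, has_orf = FALSE,
                               orf_aa = NA_integer_,
                               stringsAsFactors = FALSE)
  t3 <- desert + 2500L
  # transcript with a planted 26-aa ORF: C-scrubbed prefix (no start
  # codons in any frame), RBS, ATG, 25 CAC codons (start- and stop-free in
  # every frame), TAA, then a tail kept too short to host a 25-aa ORF
  wr(t3, t3 + 23L, paste(rep("C", 24), collapse = ""))
  orf_start <- t3 + 24L
  wr(orf_start, orf_start + 2L, "ATG")
  wr(orf_start + 3L, orf_start + 77L, paste(rep("CAC", 25L), collapse = ""))
  wr(orf_start + 78L, orf_start + 80L, "TAA")
  plant_rbs(orf_start, "+", force = TRUE)
  nov_sets[[2]] <- list(strand = "+", from = t3, to = t3 + 149L, value = 30)
  add_tss(t3, "+", "nTSS", draw_strength(), NA, NA)
  nov_truth[[2]] <- data.frame(start = t3, end = t3 + 149L, strand = "+",
                               n_alt_tss = 1L, has_orf = TRUE, orf_aa = 26L,
                               stringsAsFactors = FALSE)
  t4 <- desert + 4500L
  nov_sets[[3]] <- list(strand = "-", from = t4 - 249L, to = t4, value = 30)
  scrub_orfs(t4 - 249L, t4, "-", 25L)
  add_tss(t4, "-", "nTSS", draw_strength(), NA, NA)
  nov_truth[[3]] <- data.frame(start = t4 - 249L, end = t4, strand = "-",
                               n_alt_tss = 1L, has_orf = FALSE,
                               orf_aa = NA_integer_, stringsAsFactors = FALSE)

  # ---- processed-end spikes (curation fodder) ----------------------------
  fp_positions <- desert + 5200L + 60L * seq_len(config$fp_spike_n)
  fp_strands <- rep(c("+", "-"), length.out = config$fp_spike_n)

  # ---- profiles -----------------------------------------------------------
  genome <- make_genome(stats::setNames(paste(seqv, collapse = ""), rep_id))
  profiles <- new_profiles(genome)
  depth <- list("+" = numeric(L), "-" = numeric(L))
  for (pl in plateaus) {
    n <- pl$to - pl$from + 1L
    vals <- if (isTRUE(pl$taper) && n > 1L)
      seq(pl$level * 1.05, pl$level * 0.95, length.out = n)
    else rep(pl$level, n)
    if (pl$strand == "-") vals <- rev(vals)
    depth[[pl$strand]][pl$from:pl$to] <-
      depth[[pl$strand]][pl$from:pl$to] + vals
  }
  for (s in c(as_sets, nov_sets)) {
    v <- if (!is.null(s$values)) s$values else
      rep(s$value, s$to - s$from + 1L)
    depth[[s$strand]][s$from:s$to] <- v
    # hard stop just past the extent so coverage extension terminates
    stop_iv <- if (s$strand == "+") (s$to + 1L):min(L, s$to + 5L) else
      max(1L, s$from - 5L):(s$from - 1L)
    depth[[s$strand]][stop_iv] <- 0
  }
  for (s in rs_sets) {
    depth[[s$strand]][s$from:s$to] <- s$value
  }
  tss_df <- do.call(rbind, lapply(truth_tss, function(x)
    data.frame(replicon_id = x$replicon_id, position = x$position,
               strand = x$strand, category = x$category,
               strength = x$strength, gene_id = x$gene_id, utr = x$utr,
               new_start = if (!is.null(x$new_start)) x$new_start
                           else NA_integer_,
               shortening_aa = if (!is.null(x$shortening_aa))
                 x$shortening_aa else NA_integer_,
               new_utr = if (!is.null(x$new_utr)) x$new_utr
                         else NA_integer_,
               stringsAsFactors = FALSE)))
  # a planted TSS lying inside the 5'-UTR of an opposite-strand sense or
  # distal TSS additionally carries the antisense label (the UTR-antisense
  # classification rule, re-derived from planted coordinates)
  sp_rows <- which(tss_df$category %in% c("sTSS", "pTSS"))
  g5v <- integer(0); utr_iv <- NULL
  if (length(sp_rows)) {
    gi <- match(tss_df$gene_id[sp_rows], annotation$gene_id)
    g5v <- ifelse(annotation$strand[gi] == "+", annotation$start[gi],
                  annotation$end[gi])
    utr_iv <- data.frame(
      from = ifelse(tss_df$strand[sp_rows] == "+",
                    tss_df$position[sp_rows], g5v + 1L),
      to = ifelse(tss_df$strand[sp_rows] == "+", g5v - 1L,
                  tss_df$position[sp_rows]),
      strand = tss_df$strand[sp_rows])
  }
  for (i in seq_len(nrow(tss_df))) {
    cats <- tss_df$category[i]
    if (!is.null(utr_iv)) {
      hit <- utr_iv$strand != tss_df$strand[i] &
        utr_iv$from <= tss_df$position[i] &
        utr_iv$to >= tss_df$position[i]
      if (any(hit)) cats <- union(strsplit(cats, ",")[[1]], "asTSS")
    }
    tss_df$category[i] <- paste(sort(unique(unlist(strsplit(cats, ",")))),
                                collapse = ",")
  }
  rstarts <- list("+" = rpois(L, config$noise_lambda),
                  "-" = rpois(L, config$noise_lambda))
  for (i in seq_len(nrow(tss_df))) {
    s <- tss_df$strand[i]; p <- tss_df$position[i]
    rstarts[[s]][p] <- rstarts[[s]][p] + tss_df$strength[i]
  }
  for (i in seq_along(fp_positions)) {
    rstarts[[fp_strands[i]]][fp_positions[i]] <-
      rstarts[[fp_strands[i]]][fp_positions[i]] + config$fp_spike_strength
  }
  profiles[[rep_id]]$depth[["+"]] <- as.integer(round(depth[["+"]]))
  profiles[[rep_id]]$depth[["-"]] <- as.integer(round(depth[["-"]]))
  profiles[[rep_id]]$read_starts[["+"]] <- as.integer(rstarts[["+"]])
  profiles[[rep_id]]$read_starts[["-"]] <- as.integer(rstarts[["-"]])

  # ---- primary-library reads ---------------------------------------------
  n_reads <- config$n_reads
  fp <- runif(n_reads) < config$fp_read_fraction
  ids <- sprintf("read_%05d", seq_len(n_reads))
  reads <- character(n_reads)
  for (i in seq_len(n_reads)) {
    if (fp[i]) {
      at <- sample(L - 60L, 1L)
      reads[i] <- paste0(config$barcode,
                         substr(genome[[rep_id]]$sequence, at, at + 39L))
    } else {
      j <- sample(nrow(tss_df), 1L, prob = tss_df$strength)
      p <- tss_df$position[j]
      reads[i] <- if (tss_df$strand[j] == "+")
        substr(genome[[rep_id]]$sequence, p, min(L, p + 39L))
      else revcomp(substr(genome[[rep_id]]$sequence, max(1L, p - 39L), p))
    }
  }
  names(reads) <- ids

  truth <- list(
    tss = tss_df,
    operons = operon_truth,
    suboperon_tss = suboperon_truth,
    antisense = do.call(rbind, as_truth),
    novel = do.call(rbind, nov_truth),
    riboswitch = do.call(rbind, rs_truth),
    motif_offsets = do.call(rbind, motif_truth),
    barcode_read_ids = ids[fp],
    fp_spikes = data.frame(position = fp_positions, strand = fp_strands,
                           stringsAsFactors = FALSE))
  list(genome = genome, annotation = annotation, profiles = profiles,
       reads = reads, spanning_counts = spanning_counts,
       cis_elements = cis_elements, truth = truth, config = config)
}

# strand-aware extraction from a character vector of bases
extract_seq_chars <- function(seqv, from, to, strand) {
  s <- paste(seqv[from:to], collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Write a synthetic dataset to standard files
#'
#' Emits genome.fasta, annotation.gff3, four BedGraph files (depth and
#' read starts per strand), reads.fastq, spanning_counts.tsv,
#' cis_elements.tsv, and truth.json.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  con <- file(fa, "w")
  for (r in dataset$genome) {
    writeLines(paste0(">", r$id), con)
    writeLines(substring(r$sequence, seq(1, r$length, 70),
                         pmin(seq(1, r$length, 70) + 69, r$length)), con)
  }
  close(con)
  a <- dataset$annotation
  gff <- c("##gff-version 3",
           sprintf("%s\ttsscall\t%s\t%d\t%d\t.\t%s\t0\tID=%s;product=%s%s",
                   a$replicon_id, a$feature_type, a$start, a$end, a$strand,
                   a$gene_id, gsub("[;=]", "_", a$product),
                   ifelse(is.na(a$functional_category), "",
                          paste0(";functional_category=",
                                 a$functional_category))))
  writeLines(gff, file.path(dir, "annotation.gff3"))
  for (r in names(dataset$profiles)) {
    pr <- dataset$profiles[[r]]
    write_bedgraph(pr$depth[["+"]], r, file.path(dir, "depth_fwd.bedgraph"))
    write_bedgraph(pr$depth[["-"]], r, file.path(dir, "depth_rev.bedgraph"))
    write_bedgraph(pr$read_starts[["+"]], r,
                   file.path(dir, "starts_fwd.bedgraph"))
    write_bedgraph(pr$read_starts[["-"]], r,
                   file.path(dir, "starts_rev.bedgraph"))
  }
  write_fastq(dataset$reads, file.path(dir, "reads.fastq"))
  write_one_table(dataset$spanning_counts,
                  file.path(dir, "spanning_counts.tsv"))
  write_one_table(dataset$cis_elements, file.path(dir, "cis_elements.tsv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Score pipeline calls against planted truth
#'
#' TSS matching is greedy one-to-one by distance: a called TSS matches a
#' planted one when strands agree and the positional difference is at most
#' `tolerance_nt`. With zero calls, precision is reported as 1.0 and
#' `zero_calls` is flagged.
#'
#' @param result a pipeline result bundle (see [run_pipeline()]).
#' @param truth the `truth` element of [generate_dataset()].
#' @param tolerance_nt positional matching tolerance (default 0).
#' @return list of class `recovery_report`: per-class sensitivity and
#'   precision plus detail tables.
#' @export
truth_scorer <- function(result, truth, tolerance_nt = 0L) {
  called <- result$tss
  planted <- truth$tss
  n_called <- nrow(called); n_planted <- nrow(planted)
  pairs <- list()
  if (n_called && n_planted) {
    for (i in seq_len(n_called)) {
      d <- abs(planted$position - called$position[i])
      ok <- planted$strand == called$strand[i] &
        planted$replicon_id == called$replicon_id[i] & d <= tolerance_nt
      if (any(ok)) {
        for (j in which(ok)) {
          pairs[[length(pairs) + 1L]] <- c(i, j, d[j])
        }
      }
    }
  }
  matched_c <- logical(n_called); matched_p <- logical(n_planted)
  match_of <- rep(NA_integer_, n_called)
  if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(pm[, 3]), , drop = FALSE]
    for (k in seq_len(nrow(pm))) {
      i <- pm[k, 1]; j <- pm[k, 2]
      if (!matched_c[i] && !matched_p[j]) {
        matched_c[i] <- TRUE; matched_p[j] <- TRUE
        match_of[i] <- j
      }
    }
  }
  sens <- if (n_planted) sum(matched_p) / n_planted else NA_real_
  prec <- if (n_called) sum(matched_c) / n_called else 1.0

  # category agreement over matched pairs (pre-revision labels)
  cat_ok <- NA_real_
  if (any(matched_c) && "categories_initial" %in% names(called)) {
    agree <- vapply(which(matched_c), function(i) {
      called$categories_initial[i] == planted$category[match_of[i]]
    }, logical(1))
    cat_ok <- mean(agree)
  }

  op_called <- if (!is.null(result$operon_genes))
    lapply(result$operon_genes, paste, collapse = ",") else list()
  op_truth <- lapply(truth$operons, paste, collapse = ",")
  op_exact <- setequal(unlist(op_called), unlist(op_truth))

  sub_ok <- NA
  if (!is.null(result$suboperons) && length(truth$suboperon_tss)) {
    want <- vapply(truth$suboperon_tss, function(x) x$first_gene,
                   character(1))
    gotten <- result$suboperons$first_gene_id
    sub_ok <- all(want %in% gotten)
  }

  as_ok <- NA
  if (!is.null(truth$antisense)) {
    tr <- result$transcripts
    as_called <- tr[tr$kind == "antisense", , drop = FALSE]
    agree <- vapply(seq_len(nrow(truth$antisense)), function(i) {
      e <- truth$antisense[i, ]
      hit <- any(as_called$start == e$start & as_called$end == e$end &
                   as_called$strand == e$strand)
      hit == e$accept
    }, logical(1))
    as_ok <- all(agree)
  }

  nov_ok <- NA
  if (!is.null(truth$novel)) {
    tr <- result$transcripts
    nv <- tr[tr$kind == "intergenic", , drop = FALSE]
    agree <- vapply(seq_len(nrow(truth$novel)), function(i) {
      e <- truth$novel[i, ]
      j <- which(nv$start == e$start & nv$end == e$end &
                   nv$strand == e$strand)
      if (!length(j)) return(FALSE)
      nv$n_alt_tss[j[1]] == e$n_alt_tss &&
        (if (e$has_orf) !is.na(nv$orf_aa[j[1]]) &&
           nv$orf_aa[j[1]] == e$orf_aa else is.na(nv$orf_aa[j[1]]))
    }, logical(1))
    nov_ok <- all(agree)
  }

  structure(list(
    tss = list(sensitivity = sens, precision = prec,
               n_planted = n_planted, n_called = n_called,
               zero_calls = n_called == 0L),
    category_agreement = cat_ok,
    operons_exact = op_exact,
    suboperons_recovered = sub_ok,
    antisense_agreement = as_ok,
    novel_agreement = nov_ok),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    paste0("recovery_report\n  TSS: sensitivity %.3f precision %.3f",
           " (%d planted, %d called)\n  category agreement: %s\n",
           "  operons exact: %s  suboperons: %s\n",
           "  antisense agreement: %s  novel agreement: %s\n"),
    x$tss$sensitivity, x$tss$precision, x$tss$n_planted, x$tss$n_called,
    format(x$category_agreement), x$operons_exact,
    x$suboperons_recovered, x$antisense_agreement, x$novel_agreement))
  invisible(x)
}
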