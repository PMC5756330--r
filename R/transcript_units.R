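# Operon and sub-operon inference from spanning-read counts plus TSSs, and
# coverage-extension calling of antisense and novel intergenic transcripts.

#' Operon inference configuration
#'
#' @param min_spanning_reads minimal sense-orientation spanning reads to
#'   join two neighboring genes into one transcript (10).
#' @param expression_floor minimal mean gene-body depth for a gene to count
#'   as expressed in the mono/polycistronic census (5).
#' @return list of class `operon_config`.
#' @export
operon_config <- function(min_spanning_reads = 10L, expression_floor = 5) {
  stopifnot(min_spanning_reads >= 1)
  structure(list(min_spanning_reads = as.integer(min_spanning_reads),
                 expression_floor = expression_floor),
            class = "operon_config")
}

#' Antisense / novel transcript calling configuration
#'
#' @param min_pos_coverage minimal per-position depth inside a transcript
#'   (15).
#' @param min_length_nt minimal transcript length (20).
#' @param long_length_nt length above which the high-coverage start rule
#'   applies (500).
#' @param long_mean_cov mean-coverage bound of that rule (40).
#' @param long_start_cutoff required depth at the TSS for long,
#'   high-coverage transcripts (80).
#' @param min_orf_aa minimal ORF length in amino acids for novel
#'   transcripts (25).
#' @return list of class `antisense_config`.
#' @export
antisense_config <- function(min_pos_coverage = 15, min_length_nt = 20L,
                             long_length_nt = 500L, long_mean_cov = 40,
                             long_start_cutoff = 80, min_orf_aa = 25L) {
  stopifnot(min_pos_coverage > 0, min_length_nt > 0, long_length_nt > 0,
            long_mean_cov > 0, long_start_cutoff > 0)
  structure(list(min_pos_coverage = min_pos_coverage,
                 min_length_nt = as.integer(min_length_nt),
                 long_length_nt = as.integer(long_length_nt),
                 long_mean_cov = long_mean_cov,
                 long_start_cutoff = long_start_cutoff,
                 min_orf_aa = as.integer(min_orf_aa)),
            class = "antisense_config")
}

#' Join neighboring genes into operons by spanning-read counts
#'
#' Adjacent same-strand genes (consecutive CDS features on a replicon) are
#' joined when their spanning-read count reaches the minimum; maximal runs
#' form operons, listed in transcription order. Opposite-strand neighbors
#' are never joined. All other expressed genes are monocistronic.
#'
#' @param annotation annotation data.frame (CDS rows are used).
#' @param spanning_counts data.frame (gene_a, gene_b, count) keyed by
#'   genomically ordered adjacent gene pairs.
#' @param config an [operon_config()].
#' @param expressed_gene_ids genes counting as expressed (default: all CDS).
#' @return list: `operons` (data.frame: operon_id, replicon_id, strand,
#'   gene_ids comma-joined in transcription order, n_genes, start, end),
#'   `operon_genes` (named list of gene-id vectors), `monocistronic`
#'   (character vector).
#' @export
join_operons <- function(annotation, spanning_counts,
                         config = operon_config(),
                         expressed_gene_ids = NULL) {
  cds <- annotation[annotation$feature_type == "CDS", , drop = FALSE]
  cds <- cds[order(cds$replicon_id, cds$start), , drop = FALSE]
  if (is.null(expressed_gene_ids)) expressed_gene_ids <- cds$gene_id
  key <- paste(spanning_counts$gene_a, spanning_counts$gene_b, sep = "\r")
  getcount <- function(a, b) {
    i <- match(paste(a, b, sep = "\r"), key)
    j <- match(paste(b, a, sep = "\r"), key)
    if (!is.na(i)) spanning_counts$count[i]
    else if (!is.na(j)) spanning_counts$count[j] else 0L
  }
  runs <- list(); run <- integer(0)
  flush <- function() {
    if (length(run) >= 2L) runs[[length(runs) + 1L]] <<- run
    run <<- integer(0)
  }
  for (i in seq_len(nrow(cds))) {
    if (!length(run)) { run <- i; next }
    prev <- run[length(run)]
    joined <- cds$replicon_id[i] == cds$replicon_id[prev] &&
      cds$strand[i] == cds$strand[prev] &&
      getcount(cds$gene_id[prev], cds$gene_id[i]) >=
        config$min_spanning_reads
    if (joined) run <- c(run, i) else { flush(); run <- i }
  }
  flush()
  op_genes <- list(); rows <- list()
  for (k in seq_along(runs)) {
    idx <- runs[[k]]
    strand <- cds$strand[idx[1]]
    ids <- cds$gene_id[idx]
    if (strand == "-") ids <- rev(ids)     # transcription order
    oid <- sprintf("OP_%04d", k)
    op_genes[[oid]] <- ids
    rows[[k]] <- data.frame(
      operon_id = oid, replicon_id = cds$replicon_id[idx[1]],
      strand = strand, gene_ids = paste(ids, collapse = ","),
      n_genes = length(ids), start = min(cds$start[idx]),
      end = max(cds$end[idx]), stringsAsFactors = FALSE)
  }
  operons <- if (length(rows)) do.call(rbind, rows) else
    data.frame(operon_id = character(0), replicon_id = character(0),
               strand = character(0), gene_ids = character(0),
               n_genes = integer(0), start = integer(0), end = integer(0))
  in_op <- unlist(op_genes, use.names = FALSE)
  mono <- setdiff(intersect(expressed_gene_ids, cds$gene_id), in_op)
  list(operons = operons, operon_genes = op_genes, monocistronic = mono)
}

#' Derive sub-operons from TSSs internal to a primary operon
#'
#' A TSS assigned to the operon's first gene is the operon's primary TSS; a
#' TSS assigned to gene k > 1 defines a sub-operon comprising that gene and
#' all downstream genes (a contiguous suffix in transcription order). One
#' sub-operon per distinct internal first gene; multiple TSSs on the same
#' gene collapse, keeping the one with the most read starts.
#'
#' @param operon_id operon id.
#' @param operon_gene_ids gene ids in transcription order.
#' @param assignments ranked assignment data.frame (tss_id, category,
#'   gene_id) restricted to gene-assigned categories (sTSS/pTSS).
#' @param tss classified TSS data.frame (tss_id, read_start_count).
#' @return list: `primary_tss` (tss_id or NA), `suboperons` (data.frame:
#'   parent_operon_id, first_gene_id, gene_ids, n_genes, tss_id).
#' @export
derive_suboperons <- function(operon_id, operon_gene_ids, assignments,
                              tss) {
  a <- assignments[assignments$category %in% c("sTSS", "pTSS") &
                     assignments$gene_id %in% operon_gene_ids, ,
                   drop = FALSE]
  counts <- tss$read_start_count[match(a$tss_id, tss$tss_id)]
  best_tss <- function(rows) {
    rows$tss_id[order(-counts[match(rows$tss_id, a$tss_id)])][1]
  }
  first <- operon_gene_ids[1]
  primary <- if (any(a$gene_id == first)) {
    best_tss(a[a$gene_id == first, , drop = FALSE])
  } else NA_character_
  internal <- setdiff(unique(a$gene_id), first)
  internal <- internal[order(match(internal, operon_gene_ids))]
  subs <- lapply(seq_along(internal), function(i) {
    g <- internal[i]
    k <- match(g, operon_gene_ids)
    suffix <- operon_gene_ids[k:length(operon_gene_ids)]
    data.frame(parent_operon_id = operon_id, first_gene_id = g,
               gene_ids = paste(suffix, collapse = ","),
               n_genes = length(suffix),
               tss_id = best_tss(a[a$gene_id == g, , drop = FALSE]),
               stringsAsFactors = FALSE)
  })
  suboperons <- if (length(subs)) do.call(rbind, subs) else
    data.frame(parent_operon_id = character(0), first_gene_id = character(0),
               gene_ids = character(0), n_genes = integer(0),
               tss_id = character(0))
  list(primary_tss = primary, suboperons = suboperons)
}

extend_coverage <- function(position, strand, depth, min_cov) {
  n <- length(depth)
  if (position < 1L || position > n || depth[position] < min_cov) {
    return(NULL)
  }
  if (strand == "+") {
    end <- position
    while (end < n && depth[end + 1L] >= min_cov) end <- end + 1L
    c(position, end)
  } else {
    start <- position
    while (start > 1L && depth[start - 1L] >= min_cov) start <- start - 1L
    c(start, position)
  }
}

#' Call an antisense transcript by coverage extension
#'
#' Extends downstream from the TSS while the per-position depth stays at or
#' above the minimum (15); the transcript is reported only if at least 20
#' nt long. A transcript longer than 500 nt with mean depth above 40 must
#' additionally have depth at the TSS of at least 80 ("high-coverage start"
#' rule), else no transcript is called.
#'
#' @param position,strand,replicon_id the antisense TSS.
#' @param profiles a `stranded_profiles` object.
#' @param config an [antisense_config()].
#' @return NULL or a one-row data.frame: replicon_id, start, end, strand,
#'   length_nt, mean_depth.
#' @export
call_antisense_transcript <- function(position, strand, replicon_id,
                                      profiles,
                                      config = antisense_config()) {
  depth <- profiles[[replicon_id]]$depth[[strand]]
  ext <- extend_coverage(position, strand, depth, config$min_pos_coverage)
  if (is.null(ext)) return(NULL)
  len <- ext[2] - ext[1] + 1L
  if (len < config$min_length_nt) return(NULL)
  mc <- mean(depth[ext[1]:ext[2]])
  if (len > config$long_length_nt && mc > config$long_mean_cov &&
      depth[position] < config$long_start_cutoff) {
    return(NULL)
  }
  data.frame(replicon_id = replicon_id, start = ext[1], end = ext[2],
             strand = strand, length_nt = len, mean_depth = mc,
             stringsAsFactors = FALSE)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest qualifying ORF within a transcript
#'
#' Scans all three frames of the transcript sequence (already in
#' transcription orientation) for start codons (ATG/GTG/TTG/CTG) with an
#' in-frame stop inside the transcript; reports the longest ORF of at
#' least `min_aa` codons (stop codon excluded from the length).
#'
#' @param seq transcript sequence, 5' to 3'.
#' @param min_aa minimal protein length in aa.
#' @return NULL or list(start_off, stop_off, aa, start_codon): 1-based
#'   offsets of the first start-codon base and first stop-codon base within
#'   `seq`.
#' @export
find_longest_orf <- function(seq, min_aa = 25L) {
  n <- nchar(seq)
  codon_at <- function(i) substr(seq, i, i + 2L)
  best <- NULL
  for (frame in 0:2) {
    i <- 1L + frame
    open <- NULL
    while (i + 2L <= n) {
      cod <- codon_at(i)
      if (is.null(open) && cod %in% START_CODONS) open <- i
      if (!is.null(open) && cod %in% STOP_CODONS) {
        aa <- (i - open) / 3L
        if (aa >= min_aa && (is.null(best) || aa > best$aa)) {
          best <- list(start_off = open, stop_off = i, aa = as.integer(aa),
                       start_codon = codon_at(open))
        }
        open <- NULL
      }
      i <- i + 3L
    }
  }
  best
}

#' Find novel intergenic transcripts from unassigned TSSs
#'
#' Each intergenic TSS is extended by the same coverage rule as antisense
#' calls; TSSs whose extents overlap on the same strand merge as
#' alternative TSSs of a single transcript. Within each transcript, all
#' three frames are scanned for ORFs; the longest ORF of at least
#' `min_orf_aa` is reported together with the presence of an RBS motif
#' 3-14 nt upstream of its start. Transcripts without a qualifying ORF are
#' putative non-coding RNAs.
#'
#' @param n_tss data.frame of intergenic TSSs (tss_id, replicon_id,
#'   position, strand).
#' @param profiles a `stranded_profiles` object.
#' @param genome a `tss_genome`.
#' @param rbs_model optional `motif_model` for the RBS check.
#' @param config an [antisense_config()].
#' @return data.frame: transcript_id, kind, replicon_id, start, end,
#'   strand, tss_ids, n_alt_tss, mean_depth, orf_start, orf_end,
#'   orf_start_codon, orf_aa, rbs_found.
#' @export
find_novel_transcripts <- function(n_tss, profiles, genome,
                                   rbs_model = NULL,
                                   config = antisense_config()) {
  empty <- data.frame(transcript_id = character(0), kind = character(0),
                      replicon_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      tss_ids = character(0), n_alt_tss = integer(0),
                      mean_depth = numeric(0), orf_start = integer(0),
                      orf_end = integer(0), orf_start_codon = character(0),
                      orf_aa = integer(0), rbs_found = logical(0))
  if (!nrow(n_tss)) return(empty)
  exts <- list()
  for (i in seq_len(nrow(n_tss))) {
    depth <- profiles[[n_tss$replicon_id[i]]]$depth[[n_tss$strand[i]]]
    e <- extend_coverage(n_tss$position[i], n_tss$strand[i], depth,
                         config$min_pos_coverage)
    if (is.null(e)) next
    if (e[2] - e[1] + 1L < config$min_length_nt) next
    exts[[length(exts) + 1L]] <- data.frame(
      tss_id = n_tss$tss_id[i], replicon_id = n_tss$replicon_id[i],
      strand = n_tss$strand[i], start = e[1], end = e[2],
      stringsAsFactors = FALSE)
  }
  if (!length(exts)) return(empty)
  ex <- do.call(rbind, exts)
  ex <- ex[order(ex$replicon_id, ex$strand, ex$start), , drop = FALSE]
  # merge overlapping extents on the same replicon and strand
  grp <- integer(nrow(ex)); g <- 0L; cur_end <- -Inf
  for (i in seq_len(nrow(ex))) {
    if (i == 1L || ex$replicon_id[i] != ex$replicon_id[i - 1L] ||
        ex$strand[i] != ex$strand[i - 1L] || ex$start[i] > cur_end) {
      g <- g + 1L
      cur_end <- ex$end[i]
    } else {
      cur_end <- max(cur_end, ex$end[i])
    }
    grp[i] <- g
  }
  out <- list()
  for (gg in unique(grp)) {
    rows <- ex[grp == gg, , drop = FALSE]
    r <- rows$replicon_id[1]; s <- rows$strand[1]
    start <- min(rows$start); end <- max(rows$end)
    depth <- profiles[[r]]$depth[[s]]
    seq <- extract_seq(genome, r, start, end, s)
    orf <- find_longest_orf(seq, config$min_orf_aa)
    if (!is.null(orf)) {
      # map transcript offsets back to genome coordinates
      if (s == "+") {
        ostart <- start + orf$start_off - 1L
        oend <- start + orf$stop_off + 2L - 1L
        codon_first <- ostart
      } else {
        ostart <- end - (orf$stop_off + 2L) + 1L
        oend <- end - orf$start_off + 1L
        codon_first <- oend
      }
      rbs <- rbs_present(genome, r, codon_first, s, rbs_model = rbs_model)
    }
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = sprintf("NOVEL_%s_%d_%s", r, start,
                              ifelse(s == "+", "fwd", "rev")),
      kind = "intergenic", replicon_id = r, start = start, end = end,
      strand = s, tss_ids = paste(rows$tss_id, collapse = ","),
      n_alt_tss = nrow(rows), mean_depth = mean(depth[start:end]),
      orf_start = if (is.null(orf)) NA_integer_ else ostart,
      orf_end = if (is.null(orf)) NA_integer_ else oend,
      orf_start_codon = if (is.null(orf)) NA_character_ else orf$start_codon,
      orf_aa = if (is.null(orf)) NA_integer_ else orf$aa,
      rbs_found = if (is.null(orf)) NA else rbs,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
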