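# Genomic-context classification of verified TSSs.
#
# Distances are measured from the +1 site to the first base of the start
# codon, in transcribed nucleotides, so the UTR length equals the distance
# and a TSS sitting on the A of ATG has UTR 0. Boundary semantics: the
# sense window is [0, 300] inclusive, the putative (distal) window is
# (300, 600], an internal TSS lies > 200 nt into the ORF, and the
# revision route covers (0, 200] into the ORF.

#' Classification configuration
#'
#' @param s_max_nt maximal TSS-to-start distance for a sense TSS (300).
#' @param ns_downstream_max_nt maximal distance into an ORF for the
#'   start-codon revision route (200).
#' @param p_min_nt,p_max_nt distal ("putative") window: (p_min, p_max]
#'   (300, 600].
#' @param i_min_into_orf_nt internal TSSs lie strictly more than this far
#'   into the ORF (200).
#' @param i_near_end_nt internal TSSs within this distance of the ORF end
#'   that are simultaneously sense TSSs of the next gene are removed from
#'   the internal category (300).
#' @param leaderless_max_nt maximal UTR length of a leaderless transcript (3).
#' @param as_utr_extension also count TSSs antisense to detected 5'-UTRs
#'   as antisense (default TRUE).
#' @return list of class `classification_config`.
#' @export
classification_config <- function(s_max_nt = 300L,
                                  ns_downstream_max_nt = 200L,
                                  p_min_nt = 300L, p_max_nt = 600L,
                                  i_min_into_orf_nt = 200L,
                                  i_near_end_nt = 300L,
                                  leaderless_max_nt = 3L,
                                  as_utr_extension = TRUE) {
  stopifnot(s_max_nt <= p_max_nt, s_max_nt >= 0, p_min_nt >= 0)
  structure(list(s_max_nt = s_max_nt,
                 ns_downstream_max_nt = ns_downstream_max_nt,
                 p_min_nt = p_min_nt, p_max_nt = p_max_nt,
                 i_min_into_orf_nt = i_min_into_orf_nt,
                 i_near_end_nt = i_near_end_nt,
                 leaderless_max_nt = leaderless_max_nt,
                 as_utr_extension = as_utr_extension),
            class = "classification_config")
}

gene_tx_start <- function(ann) ifelse(ann$strand == "+", ann$start, ann$end)
gene_tx_end <- function(ann) ifelse(ann$strand == "+", ann$end, ann$start)

tss_id_of <- function(replicon_id, position, strand) {
  sprintf("TSS_%s_%d_%s", replicon_id, position,
          ifelse(strand == "+", "fwd", "rev"))
}

#' Classify one TSS by genomic context
#'
#' Returns the set of (category, gene) assignments for a single TSS.
#' Categories: `sTSS` (sense, 0-300 nt upstream of a same-strand ORF
#' start), `nsTSS` (inside a same-strand ORF at most 200 nt past its start;
#' routed to start-codon revision), `pTSS` (300-600 nt upstream), `iTSS`
#' (more than 200 nt into a same-strand ORF), `asTSS` (inside an
#' opposite-strand ORF or, optionally, its detected 5'-UTR), `nTSS`
#' (intergenic, none of the above). Multiple categories are allowed; an
#' internal TSS within 300 nt of the ORF end that is also the sense TSS of
#' the next gene loses the internal label.
#'
#' @param replicon_id,position,strand the TSS (+1 site, 1-based).
#' @param annotation annotation data.frame (CDS features are classified
#'   against; rRNA/tRNA features flag the TSS as structural instead).
#' @param detected_utrs optional data.frame (replicon_id, start, end,
#'   strand) of detected 5'-UTR extents for the antisense rule.
#' @param config a [classification_config()].
#' @return data.frame with columns category, gene_id, distance_nt. A
#'   structural-RNA TSS returns the single pseudo-category `structural`.
#' @export
classify_tss_one <- function(replicon_id, position, strand, annotation,
                             detected_utrs = NULL,
                             config = classification_config()) {
  ann <- annotation[annotation$replicon_id == replicon_id, , drop = FALSE]
  out <- data.frame(category = character(0), gene_id = character(0),
                    distance_nt = integer(0), stringsAsFactors = FALSE)
  add <- function(cat, gene, d) rbind(out, data.frame(
    category = cat, gene_id = gene, distance_nt = as.integer(d),
    stringsAsFactors = FALSE))

  # structural-RNA tagging: within the sense window of, or inside, an
  # rRNA/tRNA feature on the same strand
  struct <- ann[ann$feature_type %in% c("rRNA", "tRNA", "RNase_P"), ,
                drop = FALSE]
  if (nrow(struct)) {
    g5 <- gene_tx_start(struct)
    same <- struct$strand == strand
    d <- if (strand == "+") g5 - position else position - g5
    inside <- struct$start <= position & position <= struct$end
    if (any(same & ((d >= 0 & d <= config$s_max_nt) | inside))) {
      i <- which(same & ((d >= 0 & d <= config$s_max_nt) | inside))[1]
      return(add("structural", struct$gene_id[i], max(d[i], 0L)))
    }
  }

  cds <- ann[ann$feature_type == "CDS", , drop = FALSE]
  if (!nrow(cds)) return(add("nTSS", NA_character_, NA_integer_))
  g5 <- gene_tx_start(cds)
  same <- cds$strand == strand
  inside <- cds$start <= position & position <= cds$end

  # inside a same-strand ORF: revision route or internal
  itss_gene <- NULL
  for (i in which(same & inside)) {
    off <- if (strand == "+") position - g5[i] else g5[i] - position
    if (off > 0 && off <= config$ns_downstream_max_nt) {
      out <- add("nsTSS", cds$gene_id[i], off)
    } else if (off > config$i_min_into_orf_nt) {
      out <- add("iTSS", cds$gene_id[i], off)
      itss_gene <- i
    }
  }

  # distance to the nearest downstream same-strand ORF start
  d <- if (strand == "+") g5 - position else position - g5
  dn <- which(same & d >= 0)
  if (length(dn)) {
    j <- dn[which.min(d[dn])]
    dj <- d[j]
    if (dj <= config$s_max_nt) {
      out <- add("sTSS", cds$gene_id[j], dj)
    } else if (dj > config$p_min_nt && dj <= config$p_max_nt) {
      out <- add("pTSS", cds$gene_id[j], dj)
    }
  }

  # internal-near-end exception
  if (!is.null(itss_gene) && "sTSS" %in% out$category) {
    g3 <- gene_tx_end(cds)[itss_gene]
    dend <- if (strand == "+") g3 - position else position - g3
    if (dend <= config$i_near_end_nt) {
      out <- out[!(out$category == "iTSS" &
                     out$gene_id == cds$gene_id[itss_gene]), , drop = FALSE]
    }
  }

  # antisense to opposite-strand ORFs (and, optionally, detected 5'-UTRs)
  for (i in which(!same & inside)) {
    off <- if (cds$strand[i] == "+") position - cds$start[i] else
      cds$end[i] - position
    out <- add("asTSS", cds$gene_id[i], off)
  }
  if (config$as_utr_extension && !is.null(detected_utrs) &&
      nrow(detected_utrs)) {
    u <- detected_utrs[detected_utrs$replicon_id == replicon_id &
                         detected_utrs$strand != strand &
                         detected_utrs$start <= position &
                         detected_utrs$end >= position, , drop = FALSE]
    for (i in seq_len(nrow(u))) {
      if (!any(out$category == "asTSS" & out$gene_id == u$gene_id[i])) {
        out <- add("asTSS", u$gene_id[i], NA_integer_)
      }
    }
  }

  if (!nrow(out)) out <- add("nTSS", NA_character_, NA_integer_)
  rownames(out) <- NULL
  out
}

#' Classify all verified TSSs
#'
#' @param tss data.frame of verified TSSs (replicon_id, position, strand,
#'   read_start_count).
#' @param annotation annotation data.frame.
#' @param detected_utrs optional 5'-UTR extents (see [classify_tss_one()]).
#' @param config a [classification_config()].
#' @return list with `assignments` (long data.frame: tss_id, category,
#'   gene_id, distance_nt) and `tss` (the input with tss_id and a
#'   comma-collapsed `categories` column).
#' @export
classify_tss <- function(tss, annotation, detected_utrs = NULL,
                         config = classification_config()) {
  if (!nrow(tss)) {
    tss$tss_id <- character(0)
    tss$categories <- character(0)
    return(list(assignments = data.frame(
      tss_id = character(0), category = character(0),
      gene_id = character(0), distance_nt = integer(0),
      stringsAsFactors = FALSE), tss = tss))
  }
  tss$tss_id <- tss_id_of(tss$replicon_id, tss$position, tss$strand)
  asn <- vector("list", nrow(tss))
  for (i in seq_len(nrow(tss))) {
    a <- classify_tss_one(tss$replicon_id[i], tss$position[i],
                          tss$strand[i], annotation, detected_utrs, config)
    if (nrow(a)) a$tss_id <- tss$tss_id[i]
    asn[[i]] <- a
  }
  assignments <- do.call(rbind, asn)
  assignments <- assignments[, c("tss_id", "category", "gene_id",
                                 "distance_nt")]
  tss$categories <- vapply(tss$tss_id, function(id) {
    paste(sort(unique(assignments$category[assignments$tss_id == id])),
          collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  list(assignments = assignments, tss = tss)
}

START_CODONS <- c("ATG", "GTG", "TTG", "CTG")

#' Revise a translation start codon from an internal sense TSS
#'
#' For a TSS lying at most 200 nt downstream of an annotated start codon in
#' sense orientation, scans downstream of the TSS for the first start codon
#' (ATG/GTG/TTG/CTG) in frame with the annotated stop codon. If found, the
#' gene start is revised and the presence of a ribosome-binding-site motif
#' 3-14 nt upstream of the new start is recorded; if no in-frame start
#' codon exists downstream, NULL is returned and the TSS should be
#' relabelled internal.
#'
#' @param position,strand,replicon_id the TSS.
#' @param gene one-row annotation data.frame (a CDS).
#' @param genome a `tss_genome`.
#' @param rbs_model optional `motif_model` used for the RBS check; when
#'   NULL a canonical Shine-Dalgarno matrix (AGGAG) is used.
#' @param rbs_spacer legal spacer range (nt between motif 3' end and the
#'   start codon), default 3-14.
#' @return NULL, or a one-row data.frame: gene_id, old_start, new_start,
#'   shortening_aa, new_utr_nt, rbs_found.
#' @export
revise_start_codon <- function(position, strand, replicon_id, gene, genome,
                               rbs_model = NULL, rbs_spacer = c(3L, 14L)) {
  if (gene$feature_type != "CDS") stop("start revision requires a CDS")
  stopifnot(gene$strand == strand, gene$replicon_id == replicon_id)
  if (strand == "+") {
    old <- gene$start
    k <- ceiling(max(position - old, 3) / 3)
    cand <- old + 3L * k
    while (cand <= gene$end - 5L) {
      codon <- extract_seq(genome, replicon_id, cand, cand + 2L, "+")
      if (codon %in% START_CODONS) break
      cand <- cand + 3L
    }
    if (cand > gene$end - 5L) return(NULL)
    new_start <- cand
    shortening <- (new_start - old) / 3
    new_utr <- new_start - position
  } else {
    old <- gene$end
    k <- ceiling(max(old - position, 3) / 3)
    cand <- old - 3L * k
    while (cand >= gene$start + 5L) {
      codon <- extract_seq(genome, replicon_id, cand - 2L, cand, "-")
      if (codon %in% START_CODONS) break
      cand <- cand - 3L
    }
    if (cand < gene$start + 5L) return(NULL)
    new_start <- cand
    shortening <- (old - new_start) / 3
    new_utr <- position - new_start
  }
  rbs <- rbs_present(genome, replicon_id, new_start, strand,
                     rbs_model = rbs_model, spacer = rbs_spacer)
  data.frame(gene_id = gene$gene_id, old_start = old,
             new_start = new_start, shortening_aa = as.integer(shortening),
             new_utr_nt = as.integer(new_utr), rbs_found = rbs,
             stringsAsFactors = FALSE)
}

#' Rank TSS-to-gene assignments as primary or secondary
#'
#' Within each gene (over sense and distal assignments), the TSS with the
#' highest read-start count is primary; all others are secondary. Ties are
#' broken toward the TSS closest to the start codon, then toward the
#' smaller genome coordinate.
#'
#' @param assignments long assignment data.frame from [classify_tss()].
#' @param tss the classified TSS data.frame (with tss_id and
#'   read_start_count).
#' @param categories categories participating in ranking (default sTSS and
#'   pTSS).
#' @return `assignments` with a `rank` column ("primary"/"secondary"; NA
#'   for non-ranked categories).
#' @export
rank_primary_secondary <- function(assignments, tss,
                                   categories = c("sTSS", "pTSS")) {
  assignments$rank <- rep(NA_character_, nrow(assignments))
  idx <- which(assignments$category %in% categories &
                 !is.na(assignments$gene_id))
  if (!length(idx)) return(assignments)
  counts <- tss$read_start_count[match(assignments$tss_id, tss$tss_id)]
  pos <- tss$position[match(assignments$tss_id, tss$tss_id)]
  for (g in unique(assignments$gene_id[idx])) {
    rows <- idx[assignments$gene_id[idx] == g]
    o <- order(-counts[rows], assignments$distance_nt[rows], pos[rows])
    assignments$rank[rows[o[1]]] <- "primary"
    if (length(rows) > 1L) {
      assignments$rank[rows[o[-1]]] <- "secondary"
    }
  }
  assignments
}

#' 5'-UTR lengths, leaderless calls, and the UTR length histogram
#'
#' UTR length equals the TSS-to-start-codon distance already stored on the
#' sense/distal assignments. A transcript is leaderless when the UTR of its
#' TSS is at most `leaderless_max_nt` (3 nt). The histogram uses 5-nt bins
#' ([0-4], [5-9], ...) over primary plus secondary assignments.
#'
#' @param assignments ranked assignment data.frame.
#' @param config a [classification_config()].
#' @param bin_nt histogram bin width (default 5).
#' @return list with `utr` (data.frame: tss_id, gene_id, rank,
#'   utr_length_nt, leaderless) and `histogram` (data.frame: bin_start,
#'   bin_end, count).
#' @export
compute_utr_and_leaderless <- function(assignments,
                                       config = classification_config(),
                                       bin_nt = 5L) {
  sel <- assignments[assignments$category %in% c("sTSS", "pTSS") &
                       !is.na(assignments$rank), , drop = FALSE]
  utr <- data.frame(tss_id = sel$tss_id, gene_id = sel$gene_id,
                    rank = sel$rank, utr_length_nt = sel$distance_nt,
                    leaderless = sel$distance_nt <= config$leaderless_max_nt,
                    stringsAsFactors = FALSE)
  if (nrow(utr)) {
    b <- utr$utr_length_nt %/% bin_nt
    tab <- table(b)
    hist <- data.frame(bin_start = as.integer(names(tab)) * bin_nt,
                       bin_end = as.integer(names(tab)) * bin_nt + bin_nt - 1L,
                       count = as.integer(tab))
  } else {
    hist <- data.frame(bin_start = integer(0), bin_end = integer(0),
                       count = integer(0))
  }
  list(utr = utr, histogram = hist)
}

#' Initiation context bases at -1, +1, +2
#'
#' Strand-aware: on the minus strand bases are complemented and positions
#' mirrored so that +1 is always the first transcribed base.
#'
#' @param tss TSS data.frame (replicon_id, position, strand).
#' @param genome a `tss_genome`.
#' @return the input with character columns base_m1, base_p1, base_p2.
#' @export
tss_context <- function(tss, genome) {
  n <- nrow(tss)
  m1 <- p1 <- p2 <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    r <- tss$replicon_id[i]; p <- tss$position[i]; s <- tss$strand[i]
    if (s == "+") {
      m1[i] <- extract_seq(genome, r, p - 1L, p - 1L, "+")
      p1[i] <- extract_seq(genome, r, p, p, "+")
      p2[i] <- extract_seq(genome, r, p + 1L, p + 1L, "+")
    } else {
      m1[i] <- extract_seq(genome, r, p + 1L, p + 1L, "-")
      p1[i] <- extract_seq(genome, r, p, p, "-")
      p2[i] <- extract_seq(genome, r, p - 1L, p - 1L, "-")
    }
  }
  tss$base_m1 <- m1; tss$base_p1 <- p1; tss$base_p2 <- p2
  tss
}
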