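# Riboswitch readthrough ratios, functional-category enrichment, and
# transcription-initiation nucleotide statistics.

#' Riboswitch / cis-element readthrough ratio
#'
#' The 5'-UTR region runs from the detected TSS (or, absent one, the
#' element start) to the base before the downstream gene start; the ratio
#' is mean UTR depth over mean ORF depth. High ratios indicate premature
#' transcription termination at the element (riboswitch "off"); ratios
#' near 1 indicate readthrough. The verdict threshold defaults to 10.
#'
#' @param element one-row data.frame: name, replicon_id, start, end,
#'   strand, downstream_gene_id.
#' @param downstream_gene one-row annotation data.frame.
#' @param profiles a `stranded_profiles` object.
#' @param tss_records verified TSS data.frame used to locate the element's
#'   TSS (same strand, upstream of the gene start, within 600 nt).
#' @param verdict_threshold ratio at or above which the element is called
#'   termination-like (10).
#' @param eps floor for the ORF mean (1e-6); a zero-depth ORF is flagged.
#' @return one-row data.frame: name, tss_found, tss_position, utr_start,
#'   utr_end, utr_mean_depth, orf_mean_depth, ratio, verdict, flagged.
#' @export
readthrough_ratio <- function(element, downstream_gene, profiles,
                              tss_records = NULL, verdict_threshold = 10,
                              eps = 1e-6) {
  g <- downstream_gene
  stopifnot(g$replicon_id == element$replicon_id,
            g$strand == element$strand)
  s <- g$strand
  gstart <- if (s == "+") g$start else g$end
  tss_pos <- NA_integer_
  if (!is.null(tss_records) && nrow(tss_records)) {
    cand <- tss_records[tss_records$replicon_id == g$replicon_id &
                          tss_records$strand == s, , drop = FALSE]
    d <- if (s == "+") gstart - cand$position else cand$position - gstart
    cand <- cand[d > 0 & d <= 600, , drop = FALSE]
    d <- d[d > 0 & d <= 600]
    if (nrow(cand)) tss_pos <- cand$position[which.min(d)]
  }
  from <- if (!is.na(tss_pos)) tss_pos else
    (if (s == "+") element$start else element$end)
  if (s == "+") {
    utr <- c(from, g$start - 1L); orf <- c(g$start, g$end)
  } else {
    utr <- c(g$end + 1L, from); orf <- c(g$start, g$end)
  }
  if (utr[1] > utr[2]) stop("zero-length UTR region for ", element$name)
  depth <- profiles[[g$replicon_id]]$depth[[s]]
  utr_mean <- mean(depth[utr[1]:utr[2]])
  orf_mean <- mean(depth[orf[1]:orf[2]])
  flagged <- orf_mean <= 0
  ratio <- utr_mean / max(orf_mean, eps)
  data.frame(name = element$name, tss_found = !is.na(tss_pos),
             tss_position = tss_pos, utr_start = utr[1], utr_end = utr[2],
             utr_mean_depth = utr_mean, orf_mean_depth = orf_mean,
             ratio = ratio,
             verdict = if (ratio >= verdict_threshold) "termination-like"
                       else "readthrough-like",
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Functional-category enrichment by Fisher's exact test
#'
#' For each category, tests whether genes in the subset carry the category
#' more often than the remaining genes (two-sided by default, matching the
#' reporting of raw p-values; a Benjamini-Hochberg column is added).
#'
#' @param genes_in_subset character vector of gene ids (subset of
#'   `all_genes`).
#' @param all_genes character vector of all gene ids (the universe).
#' @param categories named character vector or list mapping gene_id ->
#'   functional category (NA allowed), or a data.frame (gene_id, category).
#' @param alternative "two.sided" (default), "greater", or "less".
#' @return data.frame: category, a (subset with category), b (subset
#'   without), c (rest with), d (rest without), odds_ratio, p_value, p_bh.
#' @export
fisher_enrichment <- function(genes_in_subset, all_genes, categories,
                              alternative = "two.sided") {
  if (!length(all_genes)) stop("empty gene universe")
  stopifnot(all(genes_in_subset %in% all_genes))
  if (is.data.frame(categories)) {
    cats <- categories$category
    names(cats) <- categories$gene_id
  } else cats <- unlist(categories)
  cat_of <- cats[all_genes]
  in_sub <- all_genes %in% genes_in_subset
  out <- list()
  for (cc in sort(unique(stats::na.omit(cat_of)))) {
    has <- !is.na(cat_of) & cat_of == cc
    a <- sum(in_sub & has); b <- sum(in_sub & !has)
    c_ <- sum(!in_sub & has); d <- sum(!in_sub & !has)
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                      alternative = alternative)
    out[[cc]] <- data.frame(category = cc, a = a, b = b, c = c_, d = d,
                            odds_ratio = unname(ft$estimate),
                            p_value = ft$p.value, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_bh <- p.adjust(res$p_value, method = "BH")
  res
}

#' Transcription-initiation nucleotide statistics
#'
#' Base frequencies at positions -1, +1 and +2 (strand-aware) per TSS
#' category, for all TSSs and for the top and bottom deciles by read-start
#' count (decile size ceil(n/10); ties broken by genome position for
#' determinism). Categories with fewer than 10 members skip the deciles.
#'
#' @param tss classified TSS data.frame with `categories` and
#'   `read_start_count` (context bases are added if absent).
#' @param genome a `tss_genome`.
#' @param groups named list mapping a reported group to the categories it
#'   pools. By default the sense group pools sTSS, nsTSS and nTSS
#'   (intergenic TSSs are treated as sense TSSs downstream), and pTSS,
#'   iTSS, asTSS are reported alone.
#' @return data.frame: group, stratum (all/top10/low10), n,
#'   mean_read_starts, position (-1/+1/+2), base, frequency.
#' @export
initiation_stats <- function(tss, genome,
                             groups = list(sTSS = c("sTSS", "nsTSS", "nTSS"),
                                           pTSS = "pTSS", iTSS = "iTSS",
                                           asTSS = "asTSS")) {
  if (!all(c("base_m1", "base_p1", "base_p2") %in% names(tss))) {
    tss <- tss_context(tss, genome)
  }
  catlist <- strsplit(tss$categories, ",", fixed = TRUE)
  rows <- list()
  freq_rows <- function(sub, group, stratum) {
    n <- nrow(sub)
    res <- list()
    for (posname in c("-1" = "base_m1", "+1" = "base_p1",
                      "+2" = "base_p2")) {
      pos <- names(which(c("-1" = "base_m1", "+1" = "base_p1",
                           "+2" = "base_p2") == posname))
      b <- factor(sub[[posname]], levels = BASES)
      f <- table(b) / max(n, 1L)
      res[[posname]] <- data.frame(
        group = group, stratum = stratum, n = n,
        mean_read_starts = mean(sub$read_start_count),
        position = pos, base = BASES, frequency = as.numeric(f),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, res)
  }
  for (g in names(groups)) {
    in_g <- vapply(catlist, function(x) any(x %in% groups[[g]]), logical(1))
    sub <- tss[in_g, , drop = FALSE]
    if (!nrow(sub)) next
    rows[[paste(g, "all")]] <- freq_rows(sub, g, "all")
    if (nrow(sub) >= 10L) {
      k <- ceiling(nrow(sub) / 10)
      o <- order(-sub$read_start_count, sub$replicon_id, sub$position)
      rows[[paste(g, "top")]] <- freq_rows(sub[o[seq_len(k)], , drop = FALSE],
                                           g, "top10")
      ol <- order(sub$read_start_count, sub$replicon_id, sub$position)
      rows[[paste(g, "low")]] <- freq_rows(sub[ol[seq_len(k)], , drop = FALSE],
                                           g, "low10")
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Mean whole-transcriptome depth per gene body
#'
#' Arithmetic mean of same-strand depth over the gene body.
#'
#' @param annotation annotation data.frame.
#' @param profiles a `stranded_profiles` object.
#' @return data.frame: gene_id, mean_depth.
#' @export
gene_mean_depth <- function(annotation, profiles) {
  md <- numeric(nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    depth <- profiles[[annotation$replicon_id[i]]]$depth[[
      annotation$strand[i]]]
    md[i] <- mean(depth[annotation$start[i]:annotation$end[i]])
  }
  data.frame(gene_id = annotation$gene_id, mean_depth = md,
             stringsAsFactors = FALSE)
}
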