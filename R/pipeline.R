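# End-to-end orchestration: barcode filter -> detect -> curate ->
# classify/revise -> rank/UTR -> motifs -> operons/sub-operons ->
# antisense/novel transcripts -> statistics.

#' Run the full primary-transcriptome analysis
#'
#' @param genome a `tss_genome`.
#' @param annotation annotation data.frame.
#' @param profiles a `stranded_profiles` object.
#' @param spanning_counts data.frame (gene_a, gene_b, count) of sense
#'   spanning reads between adjacent genes (optional; operon stage skipped
#'   without it).
#' @param reads optional named character vector of primary-library reads
#'   (barcode filter stage).
#' @param cis_elements optional data.frame of predicted cis-regulatory
#'   elements (name, replicon_id, start, end, strand, downstream_gene_id).
#' @param detection a [detection_config()].
#' @param classification a [classification_config()].
#' @param promoter a [promoter_config()].
#' @param rbs a [rbs_config()].
#' @param operon an [operon_config()].
#' @param antisense an [antisense_config()].
#' @param seed global seed; per-stage seeds are derived from it by fixed
#'   offsets and recorded in the manifest.
#' @return result bundle (list): `tss`, `assignments`, `revised_starts`,
#'   `utr`, `utr_histogram`, `promoters`, `rbs`, `operons`,
#'   `operon_genes`, `monocistronic`, `suboperons`, `transcripts`,
#'   `initiation`, `readthrough`, `enrichment`, `motifs`, `manifest`.
#' @export
run_pipeline <- function(genome, annotation, profiles,
                         spanning_counts = NULL, reads = NULL,
                         cis_elements = NULL,
                         detection = detection_config(),
                         classification = classification_config(),
                         promoter = promoter_config(),
                         rbs = rbs_config(),
                         operon = operon_config(),
                         antisense = antisense_config(),
                         seed = 1L) {
  seed <- as.integer(seed)
  manifest <- list(seed = seed,
                   stage_seeds = list(minus10 = seed + 101L,
                                      rbs = seed + 202L))

  # 1. barcode filter (optional; detection uses the profile signal, so the
  # filter is reported rather than re-counted into read_starts)
  if (!is.null(reads)) {
    fb <- filter_barcoded_reads(reads, detection$barcode)
    manifest$reads_total <- length(reads)
    manifest$reads_discarded_barcode <- fb$n_discarded
  }

  # 2. detect + curate
  cands <- detect_tss(profiles, detection)
  cur <- if (detection$curate) curate_tss(cands, profiles, detection) else
    list(verified = cands,
         removed = cbind(cands[0, ], reason = character(0)))
  verified <- cur$verified
  manifest$n_candidates <- nrow(cands)
  manifest$n_removed_curation <- nrow(cur$removed)
  manifest$n_verified <- nrow(verified)

  # 3. classify (two passes: the second counts TSSs antisense to 5'-UTRs
  # detected in the first)
  cl <- classify_tss(verified, annotation, NULL, classification)
  utr_extents <- utr_extents_from(cl$assignments, cl$tss, annotation)
  if (classification$as_utr_extension && nrow(utr_extents)) {
    cl <- classify_tss(verified, annotation, utr_extents, classification)
  }
  tss <- cl$tss
  assignments <- cl$assignments
  tss$categories_initial <- tss$categories

  # 4. start-codon revision for the nsTSS route
  revised <- list()
  ns <- which(assignments$category == "nsTSS")
  for (k in ns) {
    i <- match(assignments$tss_id[k], tss$tss_id)
    gene <- annotation[annotation$gene_id == assignments$gene_id[k], ,
                       drop = FALSE]
    rv <- revise_start_codon(tss$position[i], tss$strand[i],
                             tss$replicon_id[i], gene, genome)
    if (is.null(rv)) {
      assignments$category[k] <- "iTSS"
    } else {
      assignments$category[k] <- "sTSS"
      assignments$distance_nt[k] <- rv$new_utr_nt
      rv$tss_id <- assignments$tss_id[k]
      revised[[length(revised) + 1L]] <- rv
    }
  }
  revised_starts <- if (length(revised)) do.call(rbind, revised) else
    data.frame(gene_id = character(0), old_start = integer(0),
               new_start = integer(0), shortening_aa = integer(0),
               new_utr_nt = integer(0), rbs_found = logical(0),
               tss_id = character(0))
  tss$categories <- vapply(tss$tss_id, function(id) {
    paste(sort(unique(assignments$category[assignments$tss_id == id])),
          collapse = ",")
  }, character(1), USE.NAMES = FALSE)

  # 5. ranking and UTR/leaderless
  assignments <- rank_primary_secondary(assignments, tss)
  ul <- compute_utr_and_leaderless(assignments, classification)
  tss <- tss_context(tss, genome)

  # 6. motifs: -10/-35 over primary sense TSSs with UTR < 300; RBS over
  # genes whose s/p TSS leaves a UTR of at least 20 nt
  prim_s <- assignments$tss_id[assignments$category == "sTSS" &
                                 !is.na(assignments$rank) &
                                 assignments$rank == "primary" &
                                 assignments$distance_nt < 300]
  promoters <- NULL
  if (length(prim_s) >= 2L) {
    promoters <- find_promoters(tss[tss$tss_id %in% prim_s, , drop = FALSE],
                                genome, promoter,
                                seed = manifest$stage_seeds$minus10)
  }
  rbs_res <- NULL
  uok <- ul$utr[ul$utr$utr_length_nt >= rbs$utr_min_nt, , drop = FALSE]
  if (nrow(uok) >= 2L) {
    g <- annotation[match(uok$gene_id, annotation$gene_id), , drop = FALSE]
    win <- character(nrow(g)); cod <- character(nrow(g))
    for (i in seq_len(nrow(g))) {
      if (g$strand[i] == "+") {
        win[i] <- extract_seq(genome, g$replicon_id[i],
                              g$start[i] - rbs$window_nt, g$start[i] - 1L,
                              "+")
        cod[i] <- extract_seq(genome, g$replicon_id[i], g$start[i],
                              g$start[i] + 2L, "+")
      } else {
        win[i] <- extract_seq(genome, g$replicon_id[i], g$end[i] + 1L,
                              g$end[i] + rbs$window_nt, "-")
        cod[i] <- extract_seq(genome, g$replicon_id[i], g$end[i] - 2L,
                              g$end[i], "-")
      }
    }
    ok <- !is.na(win) & !duplicated(uok$gene_id)
    if (sum(ok) >= 2L) {
      pp <- purine_profile(win[ok], rbs)
      if (sum(pp$extracted) >= 2L) {
        rbs_res <- find_rbs(win[ok][pp$extracted],
                            cod[ok][pp$extracted], rbs,
                            seed = manifest$stage_seeds$rbs)
        rbs_res$purine <- pp$profile
        rbs_res$n_windows <- sum(ok)
        rbs_res$n_extracted <- sum(pp$extracted)
      }
    }
  }

  # 7. operons and sub-operons
  operons <- NULL; operon_genes <- NULL; mono <- NULL; subops <- NULL
  if (!is.null(spanning_counts)) {
    cds <- annotation[annotation$feature_type == "CDS", , drop = FALSE]
    expr <- gene_mean_depth(cds, profiles)
    expressed <- expr$gene_id[expr$mean_depth >= operon$expression_floor]
    jo <- join_operons(annotation, spanning_counts, operon, expressed)
    operons <- jo$operons; operon_genes <- jo$operon_genes
    mono <- jo$monocistronic
    sub_list <- list(); ptss <- character(0)
    for (oid in names(operon_genes)) {
      ds <- derive_suboperons(oid, operon_genes[[oid]], assignments, tss)
      ptss[oid] <- ds$primary_tss
      if (nrow(ds$suboperons)) sub_list[[oid]] <- ds$suboperons
    }
    operons$primary_tss <- unname(ptss[operons$operon_id])
    subops <- if (length(sub_list)) do.call(rbind, sub_list) else
      data.frame(parent_operon_id = character(0),
                 first_gene_id = character(0), gene_ids = character(0),
                 n_genes = integer(0), tss_id = character(0))
    rownames(subops) <- NULL
  }

  # 8. antisense and novel transcripts
  txs <- list()
  catlist <- strsplit(tss$categories, ",", fixed = TRUE)
  as_idx <- which(vapply(catlist, function(x) "asTSS" %in% x, logical(1)))
  for (i in as_idx) {
    tr <- call_antisense_transcript(tss$position[i], tss$strand[i],
                                    tss$replicon_id[i], profiles, antisense)
    if (!is.null(tr)) {
      tr <- cbind(transcript_id = sprintf("AS_%s", tss$tss_id[i]),
                  kind = "antisense", tss_ids = tss$tss_id[i], tr)
      txs[[length(txs) + 1L]] <- tr
    }
  }
  as_tx <- if (length(txs)) do.call(rbind, txs) else NULL
  n_idx <- which(vapply(catlist, function(x) identical(x, "nTSS"),
                        logical(1)))
  nov <- find_novel_transcripts(tss[n_idx, , drop = FALSE], profiles,
                                genome, rbs_model = if (!is.null(rbs_res))
                                  rbs_res$model else NULL,
                                config = antisense)
  transcripts <- merge_transcript_tables(as_tx, nov)

  # 9. statistics
  initiation <- initiation_stats(tss, genome)
  readthrough <- NULL
  if (!is.null(cis_elements) && nrow(cis_elements)) {
    rt <- list()
    for (i in seq_len(nrow(cis_elements))) {
      el <- cis_elements[i, , drop = FALSE]
      gde <- annotation[annotation$gene_id == el$downstream_gene_id, ,
                        drop = FALSE]
      rt[[i]] <- readthrough_ratio(el, gde, profiles, tss)
    }
    readthrough <- do.call(rbind, rt)
  }
  enrichment <- NULL
  if (any(!is.na(annotation$functional_category))) {
    cds <- annotation[annotation$feature_type == "CDS", , drop = FALSE]
    long_utr <- unique(ul$utr$gene_id[ul$utr$utr_length_nt >= 100 &
                                        ul$utr$utr_length_nt <= 300])
    long_utr <- intersect(long_utr, cds$gene_id)
    if (length(long_utr)) {
      enrichment <- fisher_enrichment(
        long_utr, cds$gene_id,
        data.frame(gene_id = cds$gene_id,
                   category = cds$functional_category))
    }
  }

  motifs <- motif_table(list(minus10 = if (!is.null(promoters))
    promoters$minus10 else NULL,
    minus35 = if (!is.null(promoters)) promoters$minus35 else NULL,
    rbs = if (!is.null(rbs_res)) rbs_res$model else NULL))

  # census of final category labels (a TSS can be in several categories)
  cats <- unlist(strsplit(tss$categories, ",", fixed = TRUE))
  manifest$category_counts <- as.list(table(cats))
  manifest$n_revised_starts <- nrow(revised_starts)
  manifest$n_leaderless <- sum(ul$utr$leaderless)
  manifest$n_operons <- if (!is.null(operons)) nrow(operons) else NA_integer_
  manifest$n_monocistronic <- if (!is.null(mono)) length(mono) else
    NA_integer_
  manifest$n_suboperons <- if (!is.null(subops)) nrow(subops) else
    NA_integer_
  manifest$n_transcripts <- nrow(transcripts)

  list(tss = tss, assignments = assignments,
       revised_starts = revised_starts, utr = ul$utr,
       utr_histogram = ul$histogram, promoters = promoters, rbs = rbs_res,
       operons = operons, operon_genes = operon_genes,
       monocistronic = mono, suboperons = subops,
       transcripts = transcripts, initiation = initiation,
       readthrough = readthrough, enrichment = enrichment, motifs = motifs,
       manifest = manifest)
}

utr_extents_from <- function(assignments, tss, annotation) {
  sel <- assignments[assignments$category %in% c("sTSS", "pTSS") &
                       !is.na(assignments$gene_id), , drop = FALSE]
  if (!nrow(sel)) {
    return(data.frame(replicon_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gene_id = character(0)))
  }
  i <- match(sel$tss_id, tss$tss_id)
  g <- match(sel$gene_id, annotation$gene_id)
  pos <- tss$position[i]; strand <- tss$strand[i]
  g5 <- ifelse(annotation$strand[g] == "+", annotation$start[g],
               annotation$end[g])
  start <- ifelse(strand == "+", pos, g5 + 1L)
  end <- ifelse(strand == "+", g5 - 1L, pos)
  keep <- start <= end
  data.frame(replicon_id = tss$replicon_id[i], start = start, end = end,
             strand = strand, gene_id = sel$gene_id,
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

merge_transcript_tables <- function(as_tx, nov) {
  cols <- c("transcript_id", "kind", "replicon_id", "start", "end",
            "strand", "tss_ids", "n_alt_tss", "length_nt", "mean_depth",
            "orf_start", "orf_end", "orf_start_codon", "orf_aa",
            "rbs_found")
  fix <- function(df) {
    if (is.null(df) || !nrow(df)) return(NULL)
    for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
    if (all(is.na(df$n_alt_tss))) df$n_alt_tss <- 1L
    if (all(is.na(df$length_nt))) df$length_nt <- df$end - df$start + 1L
    df[, cols]
  }
  out <- rbind(fix(as_tx), fix(nov))
  if (is.null(out)) {
    out <- as.data.frame(stats::setNames(rep(list(logical(0)),
                                             length(cols)), cols))
  }
  rownames(out) <- NULL
  out
}

motif_table <- function(models) {
  rows <- list()
  for (nm in names(models)) {
    m <- models[[nm]]
    if (is.null(m)) next
    rows[[nm]] <- data.frame(
      motif = nm, position = seq_len(m$width),
      A = m$pwm[, "A"], C = m$pwm[, "C"], G = m$pwm[, "G"],
      T = m$pwm[, "T"], consensus = m$consensus,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(0), position = integer(0),
               A = numeric(0), C = numeric(0), G = numeric(0),
               T = numeric(0), consensus = character(0))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic dataset, run the pipeline, and score recovery
#'
#' @param config a [synthetic_config()].
#' @param tolerance_nt TSS matching tolerance for scoring (0).
#' @param ... further arguments passed to [run_pipeline()].
#' @return list with `dataset`, `result`, and `report` (a
#'   `recovery_report`).
#' @export
simulate_and_score <- function(config = synthetic_config(),
                               tolerance_nt = 0L, ...) {
  dataset <- generate_dataset(config)
  result <- run_pipeline(dataset$genome, dataset$annotation,
                         dataset$profiles, dataset$spanning_counts,
                         reads = dataset$reads,
                         cis_elements = dataset$cis_elements,
                         seed = config$seed, ...)
  report <- truth_scorer(result, dataset$truth, tolerance_nt)
  list(dataset = dataset, result = result, report = report)
}
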