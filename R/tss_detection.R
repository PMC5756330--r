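# TSS detection from primary-library read-start profiles.
#
# A position is a candidate TSS when its read-start count reaches the
# minimum (default 20) and the percent increase over the upstream neighbor
# reaches the minimum (default 250%). "Upstream neighbor" is strand-aware:
# p-1 on "+", p+1 on "-". The denominator is floored at 1 so that a zero
# upstream count yields a finite, very large increase.

#' Detection configuration
#'
#' @param min_increase_percent minimum percent coverage increase over the
#'   upstream neighbor (default 250).
#' @param min_read_starts minimum read-start count at the TSS (default 20).
#' @param assignment_window_nt maximal distance upstream of a start codon
#'   for gene assignment (default 600).
#' @param barcode 5'-barcode marking false-positive primary ends.
#' @param signal which signal the increase rule uses: "read_starts"
#'   (default) or "depth".
#' @param local_max_window_nt curation: window (+/- nt) within which a
#'   verified TSS must be the read-start local maximum (default 3).
#' @param downstream_window_nt curation: downstream window over which mean
#'   transcriptome depth is required (default 20).
#' @param min_downstream_depth curation: minimum mean depth over that
#'   window (default 5).
#' @param curate logical; apply the curation rules (default TRUE).
#' @return a list of class `detection_config`.
#' @export
detection_config <- function(min_increase_percent = 250,
                             min_read_starts = 20L,
                             assignment_window_nt = 600L,
                             barcode = "TACCCTAG",
                             signal = c("read_starts", "depth"),
                             local_max_window_nt = 3L,
                             downstream_window_nt = 20L,
                             min_downstream_depth = 5,
                             curate = TRUE) {
  signal <- match.arg(signal)
  stopifnot(min_increase_percent > 0, min_read_starts > 0,
            assignment_window_nt > 0, local_max_window_nt > 0,
            downstream_window_nt > 0, min_downstream_depth > 0)
  structure(list(min_increase_percent = min_increase_percent,
                 min_read_starts = as.integer(min_read_starts),
                 assignment_window_nt = as.integer(assignment_window_nt),
                 barcode = toupper(barcode),
                 signal = signal,
                 local_max_window_nt = as.integer(local_max_window_nt),
                 downstream_window_nt = as.integer(downstream_window_nt),
                 min_downstream_depth = min_downstream_depth,
                 curate = curate),
            class = "detection_config")
}

#' Remove reads whose 5' end carries the false-positive barcode
#'
#' dRNA-seq protocols can tag non-primary (5'-monophosphate) transcript
#' ends with a barcode during library preparation; reads beginning with the
#' exact barcode are false-positive primary ends and are discarded.
#' Matching is exact, 5'-anchored, case-insensitive, no mismatches.
#'
#' @param reads character vector of read sequences, or a FASTQ file path.
#' @param barcode barcode string (default "TACCCTAG").
#' @return list with `kept` (read sequences; names preserved),
#'   `n_discarded`, and `discarded_ids` (names of removed reads, if named).
#' @export
filter_barcoded_reads <- function(reads, barcode = "TACCCTAG") {
  stopifnot(nzchar(barcode))
  if (length(reads) == 1L && file.exists(reads[1]) &&
      grepl("\\.(fastq|fq)$", reads[1])) {
    reads <- read_fastq(reads[1])
  }
  if (!length(reads)) {
    return(list(kept = character(0), n_discarded = 0L,
                discarded_ids = character(0)))
  }
  pre <- toupper(substr(reads, 1L, nchar(barcode)))
  bad <- pre == toupper(barcode)
  list(kept = reads[!bad],
       n_discarded = sum(bad),
       discarded_ids = if (!is.null(names(reads))) names(reads)[bad]
                       else character(0))
}

#' Read a (plain-text) FASTQ file into a named character vector
#'
#' @param path FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1, length(lines), 4)]))
  seqs <- lines[seq(2, length(lines), 4)]
  names(seqs) <- ids
  seqs
}

#' Write reads as FASTQ (constant quality)
#'
#' @param reads named character vector of sequences.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads),
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

detect_tss_one <- function(rs, depth, replicon_id, strand, config) {
  sig <- if (config$signal == "read_starts") rs else depth
  n <- length(rs)
  p <- which(rs >= config$min_read_starts)
  if (!length(p)) {
    return(data.frame(replicon_id = character(0), position = integer(0),
                      strand = character(0), read_start_count = integer(0),
                      local_increase_percent = numeric(0)))
  }
  q <- if (strand == "+") p - 1L else p + 1L
  upstream <- ifelse(q >= 1L & q <= n, sig[pmin(pmax(q, 1L), n)], 0L)
  inc <- 100 * (sig[p] - upstream) / pmax(upstream, 1)
  keep <- inc >= config$min_increase_percent
  data.frame(replicon_id = replicon_id, position = p[keep], strand = strand,
             read_start_count = rs[p][keep],
             local_increase_percent = inc[keep],
             stringsAsFactors = FALSE)
}

#' Detect candidate TSSs from read-start profiles
#'
#' Applies the minimum read-start and percent-increase rules per position
#' on both strands of every replicon.
#'
#' @param profiles a `stranded_profiles` object.
#' @param config a [detection_config()].
#' @return data.frame of candidates sorted by (replicon, position, strand)
#'   with columns replicon_id, position, strand, read_start_count,
#'   local_increase_percent.
#' @export
detect_tss <- function(profiles, config = detection_config()) {
  out <- list()
  for (r in names(profiles)) {
    for (s in c("+", "-")) {
      out[[paste(r, s)]] <- detect_tss_one(
        profiles[[r]]$read_starts[[s]], profiles[[r]]$depth[[s]],
        r, s, config)
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$replicon_id, df$position, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Curate candidate TSSs
#'
#' Automated surrogate for manual inspection: a candidate is removed if
#' (a) it is not the read-start local maximum within +/- `local_max_window_nt`
#' (ties kept at the smaller coordinate), or (b) the mean whole-transcriptome
#' depth over the next `downstream_window_nt` nt downstream is below
#' `min_downstream_depth` (no supporting transcript). Every removal carries
#' a reason.
#'
#' @param candidates data.frame from [detect_tss()].
#' @param profiles a `stranded_profiles` object.
#' @param config a [detection_config()].
#' @return list with `verified` (data.frame) and `removed` (data.frame with
#'   a `reason` column).
#' @export
curate_tss <- function(candidates, profiles, config = detection_config()) {
  if (!nrow(candidates)) {
    return(list(verified = candidates,
                removed = cbind(candidates, reason = character(0))))
  }
  w <- config$local_max_window_nt
  d <- config$downstream_window_nt
  reason <- rep(NA_character_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    r <- candidates$replicon_id[i]; s <- candidates$strand[i]
    p <- candidates$position[i]
    rs <- profiles[[r]]$read_starts[[s]]
    n <- length(rs)
    win <- max(1L, p - w):min(n, p + w)
    higher <- rs[win] > rs[p] | (rs[win] == rs[p] & win < p)
    if (any(higher)) {
      reason[i] <- "not local maximum"
      next
    }
    dep <- profiles[[r]]$depth[[s]]
    dwin <- if (s == "+") (p + 1L):min(n, p + d) else max(1L, p - d):(p - 1L)
    dwin <- dwin[dwin >= 1L & dwin <= n]
    if (!length(dwin) || mean(dep[dwin]) < config$min_downstream_depth) {
      reason[i] <- "no downstream transcript"
    }
  }
  keep <- is.na(reason)
  list(verified = {
    v <- candidates[keep, , drop = FALSE]; rownames(v) <- NULL; v
  }, removed = {
    rm <- cbind(candidates[!keep, , drop = FALSE],
                reason = reason[!keep])
    rownames(rm) <- NULL; rm
  })
}
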