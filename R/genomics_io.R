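#' @importFrom stats rpois runif sd p.adjust fisher.test dhyper
#' @importFrom utils write.table read.table head tail
NULL

# Coordinate conventions used throughout the package:
#  * all in-memory coordinates are 1-based inclusive (IRanges convention);
#  * BedGraph I/O converts from that format's 0-based half-open standard;
#  * a TSS position is the +1 nucleotide itself (first transcribed base);
#  * on the "-" strand, "upstream" means larger coordinates and extracted
#    sequences are reverse-complemented.

IUPAC_OK <- c("A", "C", "G", "T", "N", "U",
              "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes other than N are not expected here; N maps to N.
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a genome from FASTA
#'
#' Sequences are uppercased, U is converted to T, and IUPAC ambiguity codes
#' other than A/C/G/T are collapsed to N (they receive background
#' probability in motif scoring). Duplicate record ids and non-IUPAC
#' characters are errors naming the offending record.
#'
#' @param path FASTA file.
#' @param circular logical; whether replicons are circular (recycled).
#'   Distance computations never wrap across the origin.
#' @return an object of class `tss_genome`: a named list of replicons, each
#'   with `id`, `sequence` (character), `length`, `circular`.
#' @export
read_genome <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id: ", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(ss))
  circular <- rep_len(circular, length(seqs))
  reps <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    bad <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1]]), IUPAC_OK)
    if (length(bad)) {
      stop("non-IUPAC character(s) ", paste(bad, collapse = ","),
           " in record '", ids[i], "'")
    }
    s <- chartr("U", "T", s)
    s <- chartr("RYSWKMBDHV", "NNNNNNNNNN", s)
    reps[[i]] <- list(id = ids[i], sequence = s, length = nchar(s),
                      circular = circular[i])
  }
  names(reps) <- ids
  structure(reps, class = "tss_genome")
}

#' Build a genome object from in-memory sequences
#'
#' @param seqs named character vector of replicon sequences.
#' @param circular logical, recycled.
#' @return a `tss_genome`.
#' @export
make_genome <- function(seqs, circular = TRUE) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  circular <- rep_len(circular, length(seqs))
  reps <- lapply(seq_along(seqs), function(i) {
    s <- toupper(seqs[[i]])
    list(id = names(seqs)[i], sequence = s, length = nchar(s),
         circular = circular[i])
  })
  names(reps) <- names(seqs)
  structure(reps, class = "tss_genome")
}

#' @export
print.tss_genome <- function(x, ...) {
  cat("tss_genome:", length(x), "replicon(s)\n")
  for (r in x) cat(sprintf("  %s  %d nt%s\n", r$id, r$length,
                           if (r$circular) " (circular)" else ""))
  invisible(x)
}

#' Extract genomic sequence, strand-aware
#'
#' For strand "-" the reverse complement is returned, so the result always
#' reads 5' to 3' on the requested strand.
#'
#' @param genome a `tss_genome`.
#' @param replicon_id replicon id.
#' @param start,end 1-based inclusive coordinates, start <= end.
#' @param strand "+" or "-".
#' @return character scalar, or NA if the interval exceeds the replicon.
#' @export
extract_seq <- function(genome, replicon_id, start, end, strand = "+") {
  rep <- genome[[replicon_id]]
  if (is.null(rep)) stop("unknown replicon: ", replicon_id)
  if (start < 1L || end > rep$length || start > end) return(NA_character_)
  s <- substr(rep$sequence, start, end)
  if (strand == "-") s <- revcomp(s) else s
}

#' Read gene annotation from GFF3
#'
#' Keeps features of the requested types; coordinates are validated against
#' the genome. Features are returned sorted by (replicon, start, end).
#'
#' @param path GFF3 file.
#' @param genome a `tss_genome`.
#' @param types feature types to keep.
#' @param category_attr GFF attribute carrying the functional category.
#' @return data.frame with columns gene_id, replicon_id, start, end, strand,
#'   feature_type, product, functional_category.
#' @export
read_annotation <- function(path, genome, types = c("CDS", "rRNA", "tRNA"),
                            category_attr = "functional_category") {
  gr <- rtracklayer::import(path)
  gr <- gr[as.character(gr$type) %in% types]
  seqid <- as.character(GenomicRanges::seqnames(gr))
  bad <- setdiff(unique(seqid), names(genome))
  if (length(bad)) stop("GFF3 seqid(s) not in genome: ",
                        paste(bad, collapse = ","))
  md <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
  if ("locus_tag" %in% names(md)) {
    lt <- as.character(md$locus_tag)
    ids <- ifelse(is.na(ids), lt, ids)
  }
  if (any(is.na(ids))) ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  prod <- if ("product" %in% names(md)) as.character(md$product) else NA_character_
  fcat <- if (category_attr %in% names(md))
    as.character(md[[category_attr]]) else NA_character_
  ann <- data.frame(
    gene_id = ids,
    replicon_id = seqid,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_type = as.character(gr$type),
    product = if (length(prod) == length(gr)) prod else NA_character_,
    functional_category = if (length(fcat) == length(gr)) fcat else NA_character_,
    stringsAsFactors = FALSE
  )
  validate_annotation(ann, genome)
}

#' Validate and sort an annotation table
#'
#' @param ann annotation data.frame (see [read_annotation()]).
#' @param genome a `tss_genome`.
#' @return the sorted, validated annotation.
#' @export
validate_annotation <- function(ann, genome) {
  stopifnot(all(c("gene_id", "replicon_id", "start", "end", "strand",
                  "feature_type") %in% names(ann)))
  for (i in seq_len(nrow(ann))) {
    rep <- genome[[ann$replicon_id[i]]]
    if (is.null(rep)) stop("feature ", ann$gene_id[i],
                           " on unknown replicon ", ann$replicon_id[i])
    if (ann$start[i] < 1L || ann$end[i] > rep$length ||
        ann$start[i] > ann$end[i]) {
      stop("feature ", ann$gene_id[i], " has coordinates [", ann$start[i],
           ",", ann$end[i], "] outside replicon ", rep$id,
           " (length ", rep$length, ")")
    }
  }
  if (!all(ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  ann <- ann[order(ann$replicon_id, ann$start, ann$end), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

# --- stranded profiles -----------------------------------------------------

#' Create empty stranded profiles for a genome
#'
#' A profiles object holds, per replicon and strand, a dense integer vector
#' of whole-transcriptome depth and one of primary-library 5'-end
#' (read-start) counts, each of replicon length.
#'
#' @param genome a `tss_genome`.
#' @return object of class `stranded_profiles`.
#' @export
new_profiles <- function(genome) {
  p <- lapply(genome, function(r) {
    z <- integer(r$length)
    list(depth = list("+" = z, "-" = z),
         read_starts = list("+" = z, "-" = z))
  })
  structure(p, class = "stranded_profiles")
}

parse_bedgraph_into <- function(path, vecs, what, strand, genome) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(vecs)
  parts <- strsplit(lines, "[ \t]+")
  for (p in parts) {
    if (length(p) < 4L) stop("malformed BedGraph line in ", path)
    chrom <- p[1]
    from0 <- as.integer(p[2]); to0 <- as.integer(p[3])
    val <- as.numeric(p[4])
    rep <- genome[[chrom]]
    if (is.null(rep)) stop("BedGraph replicon not in genome: ", chrom)
    if (from0 < 0L || to0 > rep$length || from0 >= to0) {
      stop("BedGraph interval [", from0, ",", to0, ") out of range for ",
           chrom, " (length ", rep$length, ")")
    }
    idx <- (from0 + 1L):to0   # 0-based half-open -> 1-based inclusive
    cur <- vecs[[chrom]][[what]][[strand]][idx]
    seen <- attr(vecs[[chrom]][[what]][[strand]], "seen")
    if (is.null(seen)) seen <- logical(rep$length)
    conflict <- seen[idx] & cur != val
    if (any(conflict)) {
      stop("conflicting BedGraph values at ", chrom, ":",
           idx[which(conflict)[1]], " (", cur[which(conflict)[1]],
           " vs ", val, ")")
    }
    vecs[[chrom]][[what]][[strand]][idx] <- as.integer(round(val))
    seen[idx] <- TRUE
    attr(vecs[[chrom]][[what]][[strand]], "seen") <- seen
  }
  vecs
}

#' Read stranded depth and read-start profiles from BedGraph
#'
#' BedGraph intervals are 0-based half-open; positions absent from a file
#' are zero. Overlapping intervals with conflicting values are an error.
#'
#' @param depth_fwd,depth_rev BedGraph files of whole-transcriptome depth.
#' @param starts_fwd,starts_rev BedGraph files of primary 5'-end counts.
#' @param genome a `tss_genome`.
#' @return a `stranded_profiles` object with dense per-base vectors.
#' @export
read_stranded_bedgraph <- function(depth_fwd, depth_rev,
                                   starts_fwd, starts_rev, genome) {
  vecs <- new_profiles(genome)
  vecs <- parse_bedgraph_into(depth_fwd, vecs, "depth", "+", genome)
  vecs <- parse_bedgraph_into(depth_rev, vecs, "depth", "-", genome)
  vecs <- parse_bedgraph_into(starts_fwd, vecs, "read_starts", "+", genome)
  vecs <- parse_bedgraph_into(starts_rev, vecs, "read_starts", "-", genome)
  for (r in names(vecs)) for (w in c("depth", "read_starts"))
    for (s in c("+", "-")) attr(vecs[[r]][[w]][[s]], "seen") <- NULL
  vecs
}

#' Write a dense per-base vector as BedGraph
#'
#' Zero runs are omitted; emitted intervals are 0-based half-open.
#'
#' @param vec integer vector (1-based per-base values).
#' @param replicon_id replicon id for the first BedGraph column.
#' @param path output file.
#' @export
write_bedgraph <- function(vec, replicon_id, path) {
  r <- rle(as.integer(vec))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths        # already 0-based
  keep <- r$values != 0L
  df <- data.frame(chrom = replicon_id, start = starts[keep],
                   end = ends[keep], value = r$values[keep])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# --- flat result tables ----------------------------------------------------

write_one_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

read_one_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = "NA", colClasses = NA, check.names = FALSE,
             comment.char = "")
}

#' Write pipeline result tables
#'
#' Emits `tss.tsv`, `operons.tsv`, `suboperons.tsv`, `transcripts.tsv`,
#' `motifs.tsv`, and a GFF3 of called features, all with 1-based inclusive
#' coordinates and deterministic row order (replicon, position, strand).
#'
#' @param results a pipeline result bundle (see [run_pipeline()]), or a list
#'   with any subset of elements `tss`, `operons`, `suboperons`,
#'   `transcripts`, `motifs`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_tables <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ord <- function(df) {
    if (!nrow(df)) return(df)
    key <- intersect(c("replicon_id", "position", "start", "strand",
                       "gene_id", "operon_id"), names(df))
    if (length(key)) df <- df[do.call(order, df[key]), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  for (nm in c("tss", "operons", "suboperons", "transcripts", "motifs")) {
    if (!is.null(results[[nm]])) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      write_one_table(ord(results[[nm]]), f)
      written <- c(written, f)
    }
  }
  if (!is.null(results$tss) && nrow(results$tss)) {
    gff <- file.path(out_dir, "called_features.gff3")
    df <- ord(results$tss)
    lines <- c("##gff-version 3",
               sprintf("%s\ttsscall\tTSS\t%d\t%d\t%s\t%s\t.\tID=%s;categories=%s",
                       df$replicon_id, df$position, df$position,
                       df$read_start_count, df$strand, df$tss_id,
                       df$categories))
    writeLines(lines, gff)
    written <- c(written, gff)
  }
  invisible(written)
}

#' Read back a result table written by [write_tables()]
#'
#' @param path a .tsv written by [write_tables()].
#' @return data.frame.
#' @export
read_table_back <- function(path) read_one_table(path)
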