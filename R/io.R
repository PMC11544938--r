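#' Write a genome to FASTA
#' @param genome Named character vector of chromosome sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(genome)), path, width = 70L)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write an annotation to GTF
#'
#' Emits one `transcript` and per-exon `exon` features per model, 1-based
#' inclusive coordinates, with `gene_id`, `transcript_id` and `gene_biotype`
#' attributes. Output ordering is deterministic (chrom, start, transcript id).
#'
#' @param annotation List of [transcript_model()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  ord <- order(vapply(annotation, function(t) t$chrom, ""),
               vapply(annotation, function(t) tm_span(t)[1L], 0L),
               vapply(annotation, function(t) t$transcript_id, ""))
  lines <- character(0)
  for (tm in annotation[ord]) {
    biotype <- if (tm$biotype == "lncRNA") "lncRNA" else "protein_coding"
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                     tm$gene_id, tm$transcript_id, biotype)
    span <- tm_span(tm)
    lines <- c(lines, paste(tm$chrom, "isohybrid", "transcript",
                            span[1L] + 1L, span[2L], ".", tm$strand, ".", attrs,
                            sep = "\t"))
    for (i in seq_len(nrow(tm$exons))) {
      lines <- c(lines, paste(tm$chrom, "isohybrid", "exon",
                              tm$exons[i, 1L] + 1L, tm$exons[i, 2L], ".",
                              tm$strand, ".", attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an annotation from GTF
#'
#' Uses rtracklayer for parsing; exon features are grouped by transcript and
#' returned as [transcript_model()] objects (coordinates converted back to
#' 0-based half-open).
#'
#' @param path GTF file.
#' @return List of `transcript_model`s, sorted by (chrom, start, id).
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   gene_id = gr$gene_id, transcript_id = gr$transcript_id,
                   biotype = if (!is.null(gr$gene_biotype)) gr$gene_biotype else "protein_coding",
                   stringsAsFactors = FALSE)
  out <- lapply(split(df, df$transcript_id), function(d) {
    d <- d[order(d$start), ]
    transcript_model(d$transcript_id[1L], d$gene_id[1L], d$chrom[1L], d$strand[1L],
                     cbind(d$start, d$end),
                     biotype = if (d$biotype[1L] == "lncRNA") "lncRNA" else "coding")
  })
  out <- unname(out)
  ord <- order(vapply(out, function(t) t$chrom, ""),
               vapply(out, function(t) tm_span(t)[1L], 0L),
               vapply(out, function(t) t$transcript_id, ""))
  out[ord]
}

#' Write simulated long reads to FASTQ
#'
#' The read header carries the pass count and read quality as `np=` / `rq=`
#' tags; the per-base quality string is a constant Phred character derived
#' from the read accuracy.
#'
#' @param reads Data frame with columns `read_id`, `sequence`, `n_passes`,
#'   `quality`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  q <- pmin(pmax(round(-10 * log10(pmax(1 - reads$quality, 1e-4))), 2L), 40L)
  qchar <- vapply(seq_len(nrow(reads)), function(i) rawToChar(as.raw(33L + q[i])), "")
  lines <- character(4L * nrow(reads))
  lines[seq(1L, length(lines), 4L)] <-
    sprintf("@%s np=%d rq=%.4f", reads$read_id, reads$n_passes, reads$quality)
  lines[seq(2L, length(lines), 4L)] <- reads$sequence
  lines[seq(3L, length(lines), 4L)] <- "+"
  lines[seq(4L, length(lines), 4L)] <-
    vapply(seq_len(nrow(reads)),
           function(i) strrep(qchar[i], nchar(reads$sequence[i])), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read simulated long reads from FASTQ
#' @param path FASTQ file written by [write_reads_fastq()].
#' @return Data frame with `read_id`, `sequence`, `n_passes`, `quality`.
#' @export
read_reads_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("read_reads_fastq: truncated FASTQ")
  hdr <- lines[seq(1L, length(lines), 4L)]
  data.frame(
    read_id = sub("^@(\\S+).*$", "\\1", hdr),
    sequence = lines[seq(2L, length(lines), 4L)],
    n_passes = as.integer(sub(".*np=(\\d+).*", "\\1", hdr)),
    quality = as.numeric(sub(".*rq=([0-9.]+).*", "\\1", hdr)),
    stringsAsFactors = FALSE
  )
}

#' Write aligned isoforms to BED12
#'
#' One line per isoform; `score` holds the full-length read support and the
#' block fields encode the exon chain (0-based half-open).
#'
#' @param isoforms List of [aligned_isoform()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_isoforms_bed12 <- function(isoforms, path) {
  lines <- vapply(isoforms, function(iso) {
    tm <- iso$model
    span <- tm_span(tm)
    sizes <- tm$exons[, 2L] - tm$exons[, 1L]
    starts <- tm$exons[, 1L] - span[1L]
    paste(tm$chrom, span[1L], span[2L], iso$isoform_id, iso$fl_support, tm$strand,
          span[1L], span[2L], "0,0,0", nrow(tm$exons),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","), sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read aligned isoforms from BED12
#' @param path BED12 file; `name` is the isoform id, `score` the FL support.
#' @param gene_ids Optional named vector mapping isoform id to gene id.
#' @return List of `aligned_isoform`s.
#' @export
read_isoforms_bed12 <- function(path, gene_ids = NULL) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    chrom_start <- as.integer(tab[i, 2L])
    sizes <- as.integer(strsplit(sub(",$", "", tab[i, 11L]), ",")[[1L]])
    starts <- as.integer(strsplit(sub(",$", "", tab[i, 12L]), ",")[[1L]])
    ex_start <- chrom_start + starts
    id <- tab[i, 4L]
    gid <- if (!is.null(gene_ids) && id %in% names(gene_ids)) gene_ids[[id]] else NA_character_
    aligned_isoform(id,
                    transcript_model(id, gid, tab[i, 1L], tab[i, 6L],
                                     cbind(ex_start, ex_start + sizes)),
                    fl_support = max(1L, as.integer(tab[i, 5L])))
  })
}

#' Write a data frame as TSV
#' @param df Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path File path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
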