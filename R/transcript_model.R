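#' Transcript models
#'
#' A transcript model is a strand-aware exon chain on a chromosome and is the
#' universal currency passed between the annotation, simulation, collapse and
#' classification stages. Exons are stored as 0-based half-open `[start, end)`
#' genomic intervals, sorted and non-adjacent (gap of at least 1 bp between
#' consecutive exons, i.e. a real intron). On-disk formats use their native
#' conventions: GTF is written 1-based inclusive, BED12 0-based half-open.
#'
#' @param transcript_id,gene_id Character identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column integer matrix of `[start, end)` intervals, one row
#'   per exon, sorted by start.
#' @param cds Optional length-2 vector: CDS `[start, end)` in *transcript*
#'   coordinates. For a coding biotype its length must be divisible by 3.
#' @param biotype `"coding"` or `"lncRNA"`.
#'
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL, biotype = "coding") {
  if (!is.matrix(exons)) exons <- matrix(as.integer(exons), ncol = 2L)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (nrow(exons) < 1L) stop("transcript_model: at least one exon required")
  if (any(exons[, 2L] <= exons[, 1L])) stop("transcript_model: empty exon interval")
  if (nrow(exons) > 1L) {
    gaps <- exons[-1L, 1L] - exons[-nrow(exons), 2L]
    if (any(gaps < 1L)) {
      stop("transcript_model: exons must be strictly increasing and non-adjacent")
    }
  }
  if (!strand %in% c("+", "-")) stop("transcript_model: strand must be '+' or '-'")
  if (!biotype %in% c("coding", "lncRNA")) {
    stop("transcript_model: biotype must be 'coding' or 'lncRNA'")
  }
  if (!is.null(cds)) {
    cds <- as.integer(cds)
    if (length(cds) != 2L || cds[2L] <= cds[1L]) stop("transcript_model: bad cds")
    if (biotype == "coding" && (cds[2L] - cds[1L]) %% 3L != 0L) {
      stop("transcript_model: coding cds length must be divisible by 3")
    }
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons, cds = cds, biotype = biotype),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d [%s] %d exon(s), %d nt, %s\n",
              x$transcript_id, x$gene_id, x$chrom, tm_span(x)[1L], tm_span(x)[2L],
              x$strand, nrow(x$exons), tm_length(x), x$biotype))
  invisible(x)
}

#' Spliced length of a transcript model (nt)
#' @param tm A `transcript_model`.
#' @return Integer number of exonic bases.
#' @export
tm_length <- function(tm) sum(tm$exons[, 2L] - tm$exons[, 1L])

#' Genomic span of a transcript model
#' @param tm A `transcript_model`.
#' @return `c(start, end)`, 0-based half-open.
#' @export
tm_span <- function(tm) c(tm$exons[1L, 1L], tm$exons[nrow(tm$exons), 2L])

#' Splice junctions of a transcript model
#'
#' Junction k is the intron `[exon_k.end, exon_{k+1}.start)`; the first column
#' ("donor") is the genomic-left boundary and the second ("acceptor") the
#' genomic-right boundary. On the minus strand the biological donor/acceptor
#' roles are reversed; callers that need transcriptional orientation resolve
#' it from `strand`.
#'
#' @param tm A `transcript_model`.
#' @return Integer matrix with columns `donor`, `acceptor` (0 rows for
#'   mono-exon models).
#' @export
tm_junctions <- function(tm) {
  n <- nrow(tm$exons)
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("donor", "acceptor"))))
  }
  cbind(donor = tm$exons[-n, 2L], acceptor = tm$exons[-1L, 1L])
}

#' Canonical string key of a junction chain
#' @param tm A `transcript_model`.
#' @return A single string, `""` for mono-exon models.
#' @export
tm_chain_key <- function(tm) {
  j <- tm_junctions(tm)
  if (nrow(j) == 0L) return("")
  paste(sprintf("%d-%d", j[, 1L], j[, 2L]), collapse = ";")
}

junction_keys <- function(j) {
  if (nrow(j) == 0L) return(character(0))
  sprintf("%d-%d", j[, 1L], j[, 2L])
}

#' Spliced transcript sequence from a genome
#'
#' Concatenates exonic genome sequence in genomic order and reverse-complements
#' for minus-strand models, so the result reads 5' to 3' in transcript
#' orientation.
#'
#' @param tm A `transcript_model`.
#' @param genome Named character vector of chromosome sequences.
#' @return DNA string (character scalar).
#' @export
tm_sequence <- function(tm, genome) {
  chrom_seq <- genome[[tm$chrom]]
  if (is.null(chrom_seq)) stop("tm_sequence: unknown chromosome ", tm$chrom)
  parts <- substring(chrom_seq, tm$exons[, 1L] + 1L, tm$exons[, 2L])
  s <- paste(parts, collapse = "")
  if (tm$strand == "-") s <- revcomp_dna(s) else s
}

#' Reverse complement of a DNA string
#' @param s DNA string over `{A,C,G,T,N}`.
#' @return Reverse complement, same case.
#' @export
revcomp_dna <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Aligned isoform: a transcript model plus full-length read support
#'
#' @param isoform_id Identifier (`PB.<locus>.<n>` style after renumbering).
#' @param model A `transcript_model`.
#' @param fl_support Count of supporting full-length non-chimeric reads
#'   (must be >= 1).
#' @return An object of class `aligned_isoform`.
#' @export
aligned_isoform <- function(isoform_id, model, fl_support = 1L) {
  stopifnot(inherits(model, "transcript_model"))
  fl_support <- as.integer(fl_support)
  if (is.na(fl_support) || fl_support < 1L) stop("aligned_isoform: fl_support must be >= 1")
  structure(list(isoform_id = isoform_id, model = model, fl_support = fl_support),
            class = "aligned_isoform")
}

#' @export
print.aligned_isoform <- function(x, ...) {
  cat(sprintf("<aligned_isoform> %s fl_support=%d\n", x$isoform_id, x$fl_support))
  print(x$model)
  invisible(x)
}

# exonic overlap (bp) between two exon matrices on the same chromosome
exonic_overlap_bp <- function(ex1, ex2) {
  total <- 0L
  for (i in seq_len(nrow(ex1))) {
    o <- pmin(ex1[i, 2L], ex2[, 2L]) - pmax(ex1[i, 1L], ex2[, 1L])
    total <- total + sum(o[o > 0L])
  }
  total
}
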