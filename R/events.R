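#' Enumerate alternative-splicing events among a gene's isoforms
#'
#' Pairwise comparison of junction chains, deduplicated by event
#' coordinates. Exon skipping: an internal exon of one isoform spanned by a
#' single junction of another (inclusion junctions = the two flanking
#' junctions, LI = 2; skipping junction = the spanning one, LS = 1). Intron
#' retention: one isoform's exon fully contains another's junction
#' (inclusion side = the retained intron body, LI = 1). Alternative
#' 5'/3' splice sites: two junctions sharing one boundary with the other
#' boundary differing, provided the longer exon genuinely extends across
#' the alternative boundary (which excludes exon-skipping artifacts);
#' 5' vs 3' is resolved by strand. The inclusion junction of an alt event
#' is the shorter intron (more exonic sequence retained).
#'
#' @param gene_isoforms List of [transcript_model()]s (or
#'   [aligned_isoform()]s) of one gene.
#' @return Data frame with `event_id`, `gene_id`, `event_type`, `chrom`,
#'   `strand`, `coordinates`, `inclusion_junctions`, `skipping_junctions`,
#'   `LI`, `LS`; zero rows for a single-isoform gene.
#' @export
detect_as_events <- function(gene_isoforms) {
  tms <- lapply(gene_isoforms, function(x) if (inherits(x, "aligned_isoform")) x$model else x)
  empty <- data.frame(event_id = character(0), gene_id = character(0),
                      event_type = character(0), chrom = character(0),
                      strand = character(0), coordinates = character(0),
                      inclusion_junctions = character(0),
                      skipping_junctions = character(0),
                      LI = integer(0), LS = integer(0), stringsAsFactors = FALSE)
  if (length(tms) < 2L) return(empty)
  gene_id <- tms[[1L]]$gene_id
  chrom <- tms[[1L]]$chrom
  strand <- tms[[1L]]$strand

  seen <- new.env(parent = emptyenv())
  rows <- list()
  note <- function(type, coordinates, inclusion, skipping, LI, LS) {
    key <- paste(type, coordinates, paste(inclusion, collapse = ";"),
                 paste(skipping, collapse = ";"), sep = "|")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    rows[[length(rows) + 1L]] <<- data.frame(
      event_id = NA_character_, gene_id = gene_id, event_type = type,
      chrom = chrom, strand = strand, coordinates = coordinates,
      inclusion_junctions = paste(inclusion, collapse = ";"),
      skipping_junctions = paste(skipping, collapse = ";"),
      LI = LI, LS = LS, stringsAsFactors = FALSE)
  }

  for (ai in seq_along(tms)) {
    for (bi in seq_along(tms)) {
      if (ai == bi) next
      A <- tms[[ai]]; B <- tms[[bi]]
      ja <- tm_junctions(A); jb <- tm_junctions(B)
      na <- nrow(A$exons)

      # exon skipping: internal exon of A spanned by one junction of B
      if (na >= 3L && nrow(jb) > 0L) {
        for (k in 2:(na - 1L)) {
          e <- A$exons[k, ]
          hit <- which(jb[, 1L] <= e[1L] & e[2L] <= jb[, 2L])
          for (h in hit) {
            note("exon_skipping", sprintf("%d-%d", e[1L], e[2L]),
                 sprintf("%d-%d", c(A$exons[k - 1L, 2L], e[2L]),
                         c(e[1L], A$exons[k + 1L, 1L])),
                 sprintf("%d-%d", jb[h, 1L], jb[h, 2L]), 2L, 1L)
          }
        }
      }

      # intron retention: exon of A strictly contains a junction of B
      if (nrow(jb) > 0L) {
        for (x in seq_len(nrow(A$exons))) {
          e <- A$exons[x, ]
          hit <- which(e[1L] < jb[, 1L] & jb[, 2L] < e[2L])
          for (h in hit) {
            d <- jb[h, 1L]; a <- jb[h, 2L]
            note("intron_retention", sprintf("%d-%d", d, a),
                 sprintf("body:%d-%d", d, a), sprintf("%d-%d", d, a), 1L, 1L)
          }
        }
      }

      # alternative 5'/3' splice sites
      if (nrow(ja) > 0L && nrow(jb) > 0L) {
        for (p in seq_len(nrow(ja))) {
          for (q in seq_len(nrow(jb))) {
            d1 <- ja[p, 1L]; a1 <- ja[p, 2L]
            d2 <- jb[q, 1L]; a2 <- jb[q, 2L]
            if (a1 == a2 && d1 != d2) {
              # genomic-left boundary differs
              big <- if (d1 > d2) list(t = A, d = d1) else list(t = B, d = d2)
              d_small <- min(d1, d2)
              ex <- big$t$exons
              s_big <- ex[which(ex[, 2L] == big$d)[1L], 1L]
              if (!is.na(s_big) && s_big < d_small) {
                j_incl <- sprintf("%d-%d", max(d1, d2), a1)
                j_skip <- sprintf("%d-%d", d_small, a1)
                type <- if (strand == "+") "alt_5prime" else "alt_3prime"
                note(type, paste(j_incl, j_skip, sep = "|"), j_incl, j_skip, 1L, 1L)
              }
            } else if (d1 == d2 && a1 != a2) {
              # genomic-right boundary differs
              small <- if (a1 < a2) list(t = A, a = a1) else list(t = B, a = a2)
              a_big <- max(a1, a2)
              ex <- small$t$exons
              e_small <- ex[which(ex[, 1L] == small$a)[1L], 2L]
              if (!is.na(e_small) && e_small > a_big) {
                j_incl <- sprintf("%d-%d", d1, min(a1, a2))
                j_skip <- sprintf("%d-%d", d1, a_big)
                type <- if (strand == "+") "alt_3prime" else "alt_5prime"
                note(type, paste(j_incl, j_skip, sep = "|"), j_incl, j_skip, 1L, 1L)
              }
            }
          }
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$event_type, out$coordinates,
                   out$inclusion_junctions, out$skipping_junctions), ]
  out$event_id <- sprintf("AS.%s.%d", gene_id, seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Cluster polyadenylation sites per gene
#'
#' Positions with zero read support are dropped; the remainder are
#' clustered per gene by single linkage, joining adjacent positions closer
#' than `min_distance` (15 bp by default), so cluster representatives of
#' one gene are always at least `min_distance` apart. The representative is
#' the highest-support member, ties broken by the most distal position
#' (strand-aware: downstream-most).
#'
#' @param three_prime_ends Data frame with `gene_id`, `position`, `support`
#'   and optionally `strand` (default `+`).
#' @param min_distance Minimum distance between adjacent sites (bases).
#' @return List with `clusters` (data frame `gene_id`,
#'   `representative_position`, `members`, `support`, `n_members`) and
#'   `histogram` (sites-per-gene tally over bins 1..5 and `>5`).
#' @export
call_apa_sites <- function(three_prime_ends, min_distance = 15L) {
  df <- three_prime_ends
  if (any(df$support < 0)) stop("validation error: negative poly(A) site support")
  if (is.null(df$strand)) df$strand <- "+"
  df <- df[df$support > 0, , drop = FALSE]
  rows <- list()
  for (g in split(df, df$gene_id)) {
    g <- g[order(g$position), ]
    brk <- c(0L, which(diff(g$position) >= min_distance), nrow(g))
    for (ci in seq_len(length(brk) - 1L)) {
      m <- g[(brk[ci] + 1L):brk[ci + 1L], , drop = FALSE]
      distal <- if (m$strand[1L] == "+") -m$position else m$position
      rep_pos <- m$position[order(-m$support, distal)][1L]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = m$gene_id[1L], representative_position = rep_pos,
        members = paste(m$position, collapse = ";"),
        support = sum(m$support), n_members = nrow(m), stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), representative_position = integer(0),
               members = character(0), support = numeric(0), n_members = integer(0))
  clusters <- clusters[order(clusters$gene_id, clusters$representative_position), , drop = FALSE]
  rownames(clusters) <- NULL
  per_gene <- table(clusters$gene_id)
  bins <- cut(as.integer(per_gene), breaks = c(0:5, Inf),
              labels = c("1", "2", "3", "4", "5", ">5"))
  list(clusters = clusters,
       histogram = table(factor(bins, levels = c("1", "2", "3", "4", "5", ">5"))))
}

#' Detect fusion-transcript candidates from split alignments
#'
#' A read is fusion evidence iff its alignment splits into >= 2 segments
#' hitting >= 2 distinct gene loci, every segment covers at least
#' `min_segment_fraction` of the read, and the segments together cover at
#' least `min_total_coverage` of it. Reads with identical ordered locus
#' pairs and breakpoints within `breakpoint_window` are grouped into one
#' candidate; candidates need `min_support` reads. Each end is labelled
#' with the known gene it falls in, or `novel` otherwise.
#'
#' @param split_alignments Data frame from [simulate_split_alignments()]
#'   (columns `read_id`, `segment`, `chrom`, `gstart`, `gend`,
#'   `read_start`, `read_end`, `read_length`).
#' @param annotation Annotation list or [annotation_index()].
#' @param min_support Minimum supporting reads per candidate.
#' @param min_segment_fraction Minimum per-segment read coverage.
#' @param min_total_coverage Minimum total read coverage.
#' @param breakpoint_window Breakpoint clustering window (bases).
#' @return List with `candidates` (data frame `fusion_id`, `gene_a`,
#'   `gene_b`, `chrom_a`, `chrom_b`, `breakpoint_a`, `breakpoint_b`,
#'   `same_chromosome`, `support`) and `tally` (known/novel four-way
#'   counts).
#' @export
detect_fusions <- function(split_alignments, annotation, min_support = 2L,
                           min_segment_fraction = 0.05,
                           min_total_coverage = 0.95,
                           breakpoint_window = 50L) {
  index <- if (inherits(annotation, "annotation_index")) annotation else
    annotation_index(annotation)
  gene_of <- function(chrom, gstart, gend) {
    for (g in index$genes) {
      if (g$chrom == chrom && gstart < g$span[2L] && g$span[1L] < gend) {
        return(g$gene_id)
      }
    }
    "novel"
  }
  evidence <- list()
  for (rd in split(split_alignments, split_alignments$read_id)) {
    if (nrow(rd) < 2L) next
    rd <- rd[order(rd$read_start), ]
    L <- rd$read_length[1L]
    fr <- (rd$read_end - rd$read_start) / L
    if (any(fr < min_segment_fraction)) next
    if (sum(fr) < min_total_coverage) next
    loci <- vapply(seq_len(nrow(rd)),
                   function(i) gene_of(rd$chrom[i], rd$gstart[i], rd$gend[i]), "")
    locus_keys <- paste(rd$chrom, loci)
    if (length(unique(locus_keys)) < 2L) next
    evidence[[length(evidence) + 1L]] <- data.frame(
      read_id = rd$read_id[1L],
      gene_a = loci[1L], gene_b = loci[nrow(rd)],
      chrom_a = rd$chrom[1L], chrom_b = rd$chrom[nrow(rd)],
      breakpoint_a = rd$gend[1L], breakpoint_b = rd$gstart[nrow(rd)],
      stringsAsFactors = FALSE)
  }
  empty <- list(candidates = data.frame(fusion_id = character(0),
                                        gene_a = character(0), gene_b = character(0),
                                        chrom_a = character(0), chrom_b = character(0),
                                        breakpoint_a = integer(0), breakpoint_b = integer(0),
                                        same_chromosome = logical(0), support = integer(0)),
                tally = c(both_known = 0L, both_novel = 0L,
                          novel_front = 0L, novel_rear = 0L))
  if (length(evidence) == 0L) return(empty)
  ev <- do.call(rbind, evidence)
  cands <- list()
  for (g in split(ev, paste(ev$chrom_a, ev$gene_a, ev$chrom_b, ev$gene_b))) {
    g <- g[order(g$breakpoint_a, g$breakpoint_b), ]
    cl <- cumsum(c(1L, as.integer(diff(g$breakpoint_a) > breakpoint_window |
                                    abs(diff(g$breakpoint_b)) > breakpoint_window)))
    for (sub in split(g, cl)) {
      if (nrow(sub) < min_support) next
      cands[[length(cands) + 1L]] <- data.frame(
        fusion_id = NA_character_,
        gene_a = sub$gene_a[1L], gene_b = sub$gene_b[1L],
        chrom_a = sub$chrom_a[1L], chrom_b = sub$chrom_b[1L],
        breakpoint_a = sub$breakpoint_a[1L], breakpoint_b = sub$breakpoint_b[1L],
        same_chromosome = sub$chrom_a[1L] == sub$chrom_b[1L],
        support = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  if (length(cands) == 0L) return(empty)
  out <- do.call(rbind, cands)
  out <- out[order(out$chrom_a, out$breakpoint_a, out$chrom_b, out$breakpoint_b), ]
  out$fusion_id <- sprintf("FUSION.%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  ka <- out$gene_a != "novel"
  kb <- out$gene_b != "novel"
  list(candidates = out,
       tally = c(both_known = sum(ka & kb), both_novel = sum(!ka & !kb),
                 novel_front = sum(!ka & kb), novel_rear = sum(ka & !kb)))
}
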