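#' Build a reference index for structural classification
#'
#' Precomputes, per reference transcript, the chain key and span, and per
#' gene the donor/acceptor site sets, junction sets, exon tables and spans,
#' plus chromosome/strand-wide splice-site and junction catalogs.
#'
#' @param annotation List of reference [transcript_model()]s.
#' @return An opaque index object for [classify_isoform()].
#' @export
annotation_index <- function(annotation) {
  tx <- lapply(annotation, function(tm) {
    list(transcript_id = tm$transcript_id, gene_id = tm$gene_id, chrom = tm$chrom,
         strand = tm$strand, exons = tm$exons, span = tm_span(tm),
         junctions = junction_keys(tm_junctions(tm)),
         n_exons = nrow(tm$exons), biotype = tm$biotype)
  })
  genes <- lapply(split(tx, vapply(tx, `[[`, "", "gene_id")), function(ts) {
    ex <- do.call(rbind, lapply(ts, `[[`, "exons"))
    j <- unique(unlist(lapply(ts, `[[`, "junctions")))
    sites <- unique(unlist(lapply(ts, function(t) {
      jm <- t$exons
      n <- nrow(jm)
      if (n < 2L) return(integer(0))
      c(jm[-n, 2L], jm[-1L, 1L])
    })))
    list(gene_id = ts[[1L]]$gene_id, chrom = ts[[1L]]$chrom,
         strand = ts[[1L]]$strand, transcripts = ts,
         exons = ex, span = c(min(ex[, 1L]), max(ex[, 2L])),
         junctions = j, sites = sites)
  })
  site_catalog <- new.env(parent = emptyenv())
  junction_catalog <- new.env(parent = emptyenv())
  for (g in genes) {
    skey <- paste(g$chrom, g$strand)
    site_catalog[[skey]] <- c(site_catalog[[skey]], g$sites)
    junction_catalog[[skey]] <- c(junction_catalog[[skey]], g$junctions)
  }
  structure(list(transcripts = tx, genes = genes, site_catalog = site_catalog,
                 junction_catalog = junction_catalog,
                 chroms = unique(vapply(tx, `[[`, "", "chrom"))),
            class = "annotation_index")
}

#' Classify one isoform into the eight structural categories
#'
#' Ordered decision procedure: (1) a multi-exon isoform with same-strand
#' exonic gene overlap is FSM if its junction chain equals some reference
#' transcript's chain; else ISM if the chain is a consecutive sub-chain of
#' a reference chain; else NNC if at least one splice site is absent from
#' the same-strand annotation catalog (or borrowed from a different gene);
#' else NIC (all sites annotated for the associated gene, combination
#' novel). (2) With no same-strand overlap but exonic overlap on the
#' opposite strand: Antisense. (3) Contained within a same-strand gene
#' span without touching its exons: Genic_Intron. (4) Other same-strand
#' gene-span overlap: Genic_Genomic. (5) Otherwise Intergenic. Mono-exon
#' isoforms are FSM when contained in a mono-exon reference's span, ISM
#' when contained within a single exon of a multi-exon reference, and
#' positional otherwise.
#'
#' @param isoform An [aligned_isoform()] or [transcript_model()].
#' @param index An [annotation_index()] (or an annotation list, which is
#'   indexed on the fly).
#' @return One-row data frame: `isoform_id`, `category`, `associated_gene`,
#'   `associated_transcript`, `novel_junctions`, `novel_splice_sites`.
#' @export
classify_isoform <- function(isoform, index) {
  if (!inherits(index, "annotation_index")) index <- annotation_index(index)
  tm <- if (inherits(isoform, "aligned_isoform")) isoform$model else isoform
  if (!tm$chrom %in% index$chroms) {
    stop("validation error: isoform on unknown chromosome ", tm$chrom)
  }
  id <- tm$transcript_id
  jkeys <- junction_keys(tm_junctions(tm))
  span <- tm_span(tm)
  multi <- length(jkeys) > 0L

  res <- function(category, gene = NA_character_, transcript = NA_character_,
                  novel_j = 0L, novel_s = 0L) {
    data.frame(isoform_id = id, category = category, associated_gene = gene,
               associated_transcript = transcript, novel_junctions = novel_j,
               novel_splice_sites = novel_s, stringsAsFactors = FALSE)
  }

  same <- Filter(function(g) g$chrom == tm$chrom && g$strand == tm$strand &&
                   exonic_overlap_bp(tm$exons, g$exons) > 0L, index$genes)
  scat_key <- paste(tm$chrom, tm$strand)
  sites <- if (multi) {
    jm <- tm_junctions(tm)
    unique(c(jm[, 1L], jm[, 2L]))
  } else integer(0)
  novel_s <- sum(!sites %in% index$site_catalog[[scat_key]])
  novel_j <- sum(!jkeys %in% index$junction_catalog[[scat_key]])

  if (multi && length(same) > 0L) {
    cand_tx <- unlist(lapply(same, `[[`, "transcripts"), recursive = FALSE)
    chain_eq <- vapply(cand_tx, function(t) identical(t$junctions, jkeys), FALSE)
    if (any(chain_eq)) {
      hit <- cand_tx[chain_eq][[order(vapply(cand_tx[chain_eq], `[[`, "", "transcript_id"))[1L]]]
      return(res("FSM", hit$gene_id, hit$transcript_id, novel_j, novel_s))
    }
    sub <- vapply(cand_tx, function(t) is_consecutive_subchain(jkeys, t$junctions), FALSE)
    if (any(sub)) {
      hit <- cand_tx[sub][[order(vapply(cand_tx[sub], `[[`, "", "transcript_id"))[1L]]]
      return(res("ISM", hit$gene_id, hit$transcript_id, novel_j, novel_s))
    }
    ov <- vapply(same, function(g) exonic_overlap_bp(tm$exons, g$exons), 0L)
    assoc <- same[[which.max(ov)]]
    if (novel_s > 0L) return(res("NNC", assoc$gene_id, novel_j = novel_j, novel_s = novel_s))
    if (all(sites %in% assoc$sites)) {
      return(res("NIC", assoc$gene_id, novel_j = novel_j, novel_s = novel_s))
    }
    # every site is annotated somewhere, but not all for this gene:
    # cross-gene site borrowing does not mask novelty
    return(res("NNC", assoc$gene_id, novel_j = novel_j, novel_s = novel_s))
  }

  if (!multi && length(same) > 0L) {
    cand_tx <- unlist(lapply(same, `[[`, "transcripts"), recursive = FALSE)
    mono_hit <- Filter(function(t) t$n_exons == 1L && t$span[1L] <= span[1L] &&
                         span[2L] <= t$span[2L], cand_tx)
    if (length(mono_hit)) {
      hit <- mono_hit[[order(vapply(mono_hit, `[[`, "", "transcript_id"))[1L]]]
      return(res("FSM", hit$gene_id, hit$transcript_id))
    }
    exon_hit <- Filter(function(t) {
      t$n_exons > 1L && any(t$exons[, 1L] <= span[1L] & span[2L] <= t$exons[, 2L])
    }, cand_tx)
    if (length(exon_hit)) {
      hit <- exon_hit[[order(vapply(exon_hit, `[[`, "", "transcript_id"))[1L]]]
      return(res("ISM", hit$gene_id, hit$transcript_id))
    }
  }

  anti <- Filter(function(g) g$chrom == tm$chrom && g$strand != tm$strand &&
                   exonic_overlap_bp(tm$exons, g$exons) > 0L, index$genes)
  if (length(same) == 0L && length(anti) > 0L) {
    ov <- vapply(anti, function(g) exonic_overlap_bp(tm$exons, g$exons), 0L)
    return(res("Antisense", anti[[which.max(ov)]]$gene_id))
  }

  span_genes <- Filter(function(g) g$chrom == tm$chrom && g$strand == tm$strand &&
                         span[1L] < g$span[2L] && g$span[1L] < span[2L], index$genes)
  intronic <- Filter(function(g) g$span[1L] <= span[1L] && span[2L] <= g$span[2L] &&
                       exonic_overlap_bp(tm$exons, g$exons) == 0L, span_genes)
  if (length(intronic)) return(res("Genic_Intron", intronic[[1L]]$gene_id))
  if (length(same) > 0L || length(span_genes) > 0L) {
    g <- if (length(same)) same[[1L]] else span_genes[[1L]]
    return(res("Genic_Genomic", g$gene_id))
  }
  res("Intergenic")
}

# is `sub` a consecutive (contiguous) strict sub-chain of `full`?
is_consecutive_subchain <- function(sub, full) {
  ns <- length(sub)
  nf <- length(full)
  if (ns == 0L || ns >= nf) return(FALSE)
  for (off in 0:(nf - ns)) {
    if (identical(full[off + seq_len(ns)], sub)) return(TRUE)
  }
  FALSE
}

#' Classify a set of isoforms
#' @param isoforms List of [aligned_isoform()]s.
#' @param annotation Annotation list or [annotation_index()].
#' @return Data frame, one row per isoform (see [classify_isoform()]).
#' @export
classify_isoforms <- function(isoforms, annotation) {
  index <- if (inherits(annotation, "annotation_index")) annotation else
    annotation_index(annotation)
  do.call(rbind, lapply(isoforms, classify_isoform, index = index))
}

#' Category tally and length-binned tally
#' @param classifications Data frame from [classify_isoforms()].
#' @param isoforms Matching list of isoforms (for spliced lengths).
#' @return List with `categories` (named counts over the eight labels,
#'   summing to the isoform count) and `length_bins` (1 kb bins).
#' @export
tally_categories <- function(classifications, isoforms = NULL) {
  lv <- c("FSM", "ISM", "NIC", "NNC", "Antisense", "Genic_Intron",
          "Genic_Genomic", "Intergenic")
  categories <- table(factor(classifications$category, levels = lv))
  out <- list(categories = categories)
  if (!is.null(isoforms)) {
    lens <- vapply(isoforms, function(x) tm_length(x$model), 0L)
    bin <- paste0(floor(lens / 1000L), "-", floor(lens / 1000L) + 1L, " kb")
    out$length_bins <- table(bin, factor(classifications$category, levels = lv))
  }
  out
}

#' Assign isoforms to known genes and novel-gene clusters
#'
#' Known-gene hits are genes with at least one isoform classified FSM, ISM,
#' NIC, NNC or Genic_Genomic. Isoforms in the positional categories
#' Intergenic, Antisense and Genic_Intron are clustered into novel genes by
#' single-linkage exonic overlap on the same chromosome and strand.
#'
#' @param classifications Data frame from [classify_isoforms()].
#' @param isoforms Matching list of [aligned_isoform()]s.
#' @return List with `known_gene_hits` (character vector) and
#'   `novel_gene_clusters` (data frame `cluster_id`, `isoform_id`).
#' @export
assign_genes <- function(classifications, isoforms) {
  known_cat <- c("FSM", "ISM", "NIC", "NNC", "Genic_Genomic")
  known <- sort(unique(classifications$associated_gene[
    classifications$category %in% known_cat &
      !is.na(classifications$associated_gene)]))
  novel_idx <- which(classifications$category %in%
                       c("Intergenic", "Antisense", "Genic_Intron"))
  if (length(novel_idx) == 0L) {
    return(list(known_gene_hits = known,
                novel_gene_clusters = data.frame(cluster_id = character(0),
                                                 isoform_id = character(0))))
  }
  sub <- isoforms[novel_idx]
  comp <- overlap_components(sub)
  starts <- vapply(sub, function(x) tm_span(x$model)[1L], 0L)
  chroms <- vapply(sub, function(x) x$model$chrom, "")
  comp_groups <- split(seq_along(sub), comp)
  keys <- vapply(comp_groups, function(g) sprintf("%s:%012d", chroms[g[1L]], min(starts[g])), "")
  rank <- match(keys, sort(keys))
  rows <- list()
  for (ci in seq_along(comp_groups)) {
    for (i in comp_groups[[ci]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = sprintf("NOVELG.%d", rank[ci]),
        isoform_id = sub[[i]]$isoform_id, stringsAsFactors = FALSE)
    }
  }
  cl <- do.call(rbind, rows)
  cl <- cl[order(cl$cluster_id, cl$isoform_id), ]
  rownames(cl) <- NULL
  list(known_gene_hits = known, novel_gene_clusters = cl)
}

#' Count reference genes whose locus boundaries the isoforms extend
#'
#' A gene is "updated" iff some FSM/ISM/NIC/NNC isoform associated with it
#' extends the annotated gene span by at least `min_extension` bases at
#' either end.
#'
#' @param isoforms List of [aligned_isoform()]s.
#' @param classifications Data frame from [classify_isoforms()].
#' @param annotation Annotation list or [annotation_index()].
#' @param min_extension Minimum extension in bases (default 100).
#' @return List with `n_updated` and `records` (data frame `gene_id`,
#'   `side`, `extension`).
#' @export
count_locus_updates <- function(isoforms, classifications, annotation,
                                min_extension = 100L) {
  index <- if (inherits(annotation, "annotation_index")) annotation else
    annotation_index(annotation)
  spans <- lapply(index$genes, `[[`, "span")
  names(spans) <- vapply(index$genes, `[[`, "", "gene_id")
  rows <- list()
  for (i in seq_along(isoforms)) {
    cl <- classifications[i, ]
    if (!cl$category %in% c("FSM", "ISM", "NIC", "NNC")) next
    gspan <- spans[[cl$associated_gene]]
    if (is.null(gspan)) next
    ispan <- tm_span(isoforms[[i]]$model)
    if (gspan[1L] - ispan[1L] >= min_extension) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = cl$associated_gene, side = "left",
        extension = gspan[1L] - ispan[1L], stringsAsFactors = FALSE)
    }
    if (ispan[2L] - gspan[2L] >= min_extension) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = cl$associated_gene, side = "right",
        extension = ispan[2L] - gspan[2L], stringsAsFactors = FALSE)
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), side = character(0), extension = integer(0))
  list(n_updated = length(unique(records$gene_id)), records = records)
}
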