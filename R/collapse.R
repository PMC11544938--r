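#' Collapse redundant aligned isoforms
#'
#' Two isoforms merge iff they share chromosome and strand, have identical
#' junction chains, and both genomic termini lie within `end_tolerance`;
#' the merge relation is closed transitively. Optionally, a multi-exon
#' isoform whose junction chain is a strict consecutive 3'-anchored
#' sub-chain of a surviving isoform's chain (a 5'-degraded fragment) is
#' absorbed into it. Full-length support is summed across merges; the kept
#' model in each group is the one with the largest support (ties: longer
#' spliced length, then lexicographically smaller id), so the result does
#' not depend on input order.
#'
#' @param isoforms List of [aligned_isoform()]s on one genome.
#' @param end_tolerance Maximum terminal difference in bases (>= 0).
#' @param collapse_degraded_5prime Absorb 5'-degraded sub-chain isoforms.
#' @return List with `isoforms` (collapsed list) and `report` (list with
#'   `n_input`, `n_output`, `merges` data frame of `kept_id`,
#'   `absorbed_id`).
#' @export
collapse_isoforms <- function(isoforms, end_tolerance = 50L,
                              collapse_degraded_5prime = TRUE) {
  if (end_tolerance < 0L) stop("validation error: end_tolerance must be >= 0")
  n <- length(isoforms)
  if (n == 0L) {
    return(list(isoforms = list(),
                report = list(n_input = 0L, n_output = 0L,
                              merges = data.frame(kept_id = character(0),
                                                  absorbed_id = character(0)))))
  }
  ids <- vapply(isoforms, function(x) x$isoform_id, "")
  ord <- order(ids)
  isoforms <- isoforms[ord]
  ids <- ids[ord]
  chroms <- vapply(isoforms, function(x) x$model$chrom, "")
  strands <- vapply(isoforms, function(x) x$model$strand, "")
  chains <- vapply(isoforms, function(x) tm_chain_key(x$model), "")
  starts <- vapply(isoforms, function(x) tm_span(x$model)[1L], 0L)
  ends <- vapply(isoforms, function(x) tm_span(x$model)[2L], 0L)
  support <- vapply(isoforms, function(x) x$fl_support, 0L)
  splen <- vapply(isoforms, function(x) tm_length(x$model), 0L)

  # exact merge: transitive closure within (chrom, strand, chain) groups
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) { parent[find(i)] <<- find(j) }
  groups <- split(seq_len(n), paste(chroms, strands, chains, sep = "\r"))
  for (g in groups) {
    if (length(g) < 2L) next
    for (a in seq_along(g)[-1L]) {
      for (b in seq_len(a - 1L)) {
        i <- g[a]; j <- g[b]
        if (abs(starts[i] - starts[j]) <= end_tolerance &&
            abs(ends[i] - ends[j]) <= end_tolerance) union2(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  merges <- list()
  keep <- integer(0)
  agg_support <- integer(0)
  for (g in split(seq_len(n), roots)) {
    best <- g[order(-support[g], -splen[g], ids[g])][1L]
    keep <- c(keep, best)
    agg_support <- c(agg_support, sum(support[g]))
    for (m in setdiff(g, best)) {
      merges[[length(merges) + 1L]] <- data.frame(kept_id = ids[best],
                                                  absorbed_id = ids[m],
                                                  stringsAsFactors = FALSE)
    }
  }
  o <- order(ids[keep])
  keep <- keep[o]
  agg_support <- agg_support[o]

  if (collapse_degraded_5prime) {
    # absorb strict consecutive 3'-anchored sub-chains; process shorter
    # chains first so fragments funnel into their ultimate container
    alive <- rep(TRUE, length(keep))
    njunc <- vapply(keep, function(i) length(strsplit(chains[i], ";", fixed = TRUE)[[1L]]), 0L)
    njunc[chains[keep] == ""] <- 0L
    proc <- order(njunc, ids[keep])
    for (pi in proc) {
      i <- keep[pi]
      if (njunc[pi] < 1L) next
      ji <- strsplit(chains[i], ";", fixed = TRUE)[[1L]]
      cand <- which(alive & seq_along(keep) != pi)
      containers <- cand[vapply(cand, function(pj) {
        j <- keep[pj]
        if (chroms[j] != chroms[i] || strands[j] != strands[i]) return(FALSE)
        jj <- strsplit(chains[j], ";", fixed = TRUE)[[1L]]
        if (length(jj) <= length(ji)) return(FALSE)
        anchored <- if (strands[i] == "+") jj[(length(jj) - length(ji) + 1L):length(jj)]
                    else jj[seq_along(ji)]
        identical(anchored, ji)
      }, FALSE)]
      if (length(containers) == 0L) next
      best <- containers[order(-agg_support[containers],
                               -splen[keep[containers]], ids[keep[containers]])][1L]
      agg_support[best] <- agg_support[best] + agg_support[pi]
      alive[pi] <- FALSE
      merges[[length(merges) + 1L]] <- data.frame(kept_id = ids[keep[best]],
                                                  absorbed_id = ids[i],
                                                  stringsAsFactors = FALSE)
    }
    keep <- keep[alive]
    agg_support <- agg_support[alive]
  }

  out <- lapply(seq_along(keep), function(k) {
    iso <- isoforms[[keep[k]]]
    iso$fl_support <- agg_support[k]
    iso
  })
  merges_df <- if (length(merges)) do.call(rbind, merges) else
    data.frame(kept_id = character(0), absorbed_id = character(0))
  merges_df <- merges_df[order(merges_df$kept_id, merges_df$absorbed_id), , drop = FALSE]
  rownames(merges_df) <- NULL
  list(isoforms = out,
       report = list(n_input = n, n_output = length(out), merges = merges_df))
}

#' Filter low-confidence isoforms by short-read junction support
#'
#' A multi-exon isoform is retained iff every junction either has short-read
#' support of at least `min_support` or exists in the reference annotation
#' (annotation rescue). Mono-exon isoforms, having no junctions to
#' validate, are retained iff their full-length support is at least 2.
#'
#' @param isoforms List of [aligned_isoform()]s.
#' @param junction_support Data frame `chrom`, `donor`, `acceptor`, `count`.
#' @param annotation List of reference [transcript_model()]s.
#' @param min_support Minimum short-read count per novel junction.
#' @return Filtered list of `aligned_isoform`s.
#' @export
filter_low_confidence <- function(isoforms, junction_support, annotation,
                                  min_support = 1L) {
  sup <- new.env(parent = emptyenv())
  if (nrow(junction_support) > 0L) {
    for (i in seq_len(nrow(junction_support))) {
      sup[[sprintf("%s:%d-%d", junction_support$chrom[i],
                   junction_support$donor[i], junction_support$acceptor[i])]] <-
        junction_support$count[i]
    }
  }
  ann <- new.env(parent = emptyenv())
  for (tm in annotation) {
    j <- tm_junctions(tm)
    for (k in seq_len(nrow(j))) {
      ann[[sprintf("%s:%s:%d-%d", tm$chrom, tm$strand, j[k, 1L], j[k, 2L])]] <- TRUE
    }
  }
  Filter(function(iso) {
    j <- tm_junctions(iso$model)
    if (nrow(j) == 0L) return(iso$fl_support >= 2L)
    for (k in seq_len(nrow(j))) {
      skey <- sprintf("%s:%d-%d", iso$model$chrom, j[k, 1L], j[k, 2L])
      akey <- sprintf("%s:%s:%d-%d", iso$model$chrom, iso$model$strand,
                      j[k, 1L], j[k, 2L])
      supported <- !is.null(sup[[skey]]) && sup[[skey]] >= min_support
      if (!supported && is.null(ann[[akey]])) return(FALSE)
    }
    TRUE
  }, isoforms)
}

#' Renumber isoforms with PB-style locus identifiers
#'
#' Groups isoforms into loci by single-linkage exonic overlap on the same
#' chromosome and strand, orders loci by genomic position, and assigns ids
#' `PB.<locus>.<n>` (isoforms within a locus ordered by descending
#' full-length support, then id).
#'
#' @param isoforms List of [aligned_isoform()]s.
#' @return The same isoforms with `isoform_id` (and model ids) replaced.
#' @export
assign_pb_ids <- function(isoforms) {
  if (length(isoforms) == 0L) return(isoforms)
  comp <- overlap_components(isoforms)
  starts <- vapply(isoforms, function(x) tm_span(x$model)[1L], 0L)
  chroms <- vapply(isoforms, function(x) x$model$chrom, "")
  comp_key <- vapply(split(seq_along(isoforms), comp), function(g) {
    sprintf("%s:%012d", chroms[g[1L]], min(starts[g]))
  }, "")
  locus_rank <- match(comp_key, sort(comp_key))
  support <- vapply(isoforms, function(x) x$fl_support, 0L)
  ids <- vapply(isoforms, function(x) x$isoform_id, "")
  out <- isoforms
  for (ci in seq_along(comp_key)) {
    g <- which(comp == names(comp_key)[ci])
    g <- g[order(-support[g], ids[g])]
    for (k in seq_along(g)) {
      new_id <- sprintf("PB.%d.%d", locus_rank[ci], k)
      out[[g[k]]]$isoform_id <- new_id
      out[[g[k]]]$model$transcript_id <- new_id
    }
  }
  out
}

# single-linkage exonic-overlap components (same chrom + strand)
overlap_components <- function(isoforms) {
  n <- length(isoforms)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  key <- vapply(isoforms, function(x) paste(x$model$chrom, x$model$strand), "")
  for (g in split(seq_len(n), key)) {
    if (length(g) < 2L) next
    for (a in seq_along(g)[-1L]) {
      for (b in seq_len(a - 1L)) {
        if (exonic_overlap_bp(isoforms[[g[a]]]$model$exons,
                              isoforms[[g[b]]]$model$exons) > 0L) {
          parent[find(g[a])] <- find(g[b])
        }
      }
    }
  }
  as.character(vapply(seq_len(n), find, 0L))
}
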