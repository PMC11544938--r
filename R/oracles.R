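#' Brute-force reference implementations
#'
#' Deliberately naive, unoptimized re-derivations of the core operations,
#' kept independent of the production code paths. They exist so the test
#' suite and the acceptance script can confront the efficient
#' implementations with exhaustive enumeration on small inputs.
#'
#' @name oracles
NULL

#' @describeIn oracles Exhaustive structural classifier: compares the
#'   isoform against every reference transcript and site individually,
#'   following the same ordered decision rules as [classify_isoform()].
#' @param isoform An [aligned_isoform()] or [transcript_model()].
#' @param annotation List of reference [transcript_model()]s.
#' @export
classify_isoform_exhaustive <- function(isoform, annotation) {
  tm <- if (inherits(isoform, "aligned_isoform")) isoform$model else isoform
  my_j <- tm_junctions(tm)
  my_keys <- junction_keys(my_j)
  my_span <- tm_span(tm)
  overlaps_exons <- function(ref) {
    if (ref$chrom != tm$chrom) return(FALSE)
    for (i in seq_len(nrow(tm$exons))) {
      for (k in seq_len(nrow(ref$exons))) {
        if (tm$exons[i, 1L] < ref$exons[k, 2L] &&
            ref$exons[k, 1L] < tm$exons[i, 2L]) return(TRUE)
      }
    }
    FALSE
  }
  gene_ids <- unique(vapply(annotation, function(t) t$gene_id, ""))
  gene_tx <- lapply(gene_ids, function(g) Filter(function(t) t$gene_id == g, annotation))
  names(gene_tx) <- gene_ids
  gene_overlap_bp <- vapply(gene_ids, function(g) {
    sum(vapply(gene_tx[[g]], function(ref) {
      if (ref$strand != tm$strand) return(0L)
      if (!overlaps_exons(ref)) return(0L)
      1L
    }, 0L))
  }, 0L)
  same_genes <- gene_ids[vapply(gene_ids, function(g) {
    any(vapply(gene_tx[[g]], function(ref) ref$strand == tm$strand && overlaps_exons(ref), FALSE))
  }, FALSE)]
  anti_genes <- gene_ids[vapply(gene_ids, function(g) {
    any(vapply(gene_tx[[g]], function(ref) ref$strand != tm$strand && overlaps_exons(ref), FALSE))
  }, FALSE)]

  out <- function(category, gene = NA_character_, transcript = NA_character_) {
    data.frame(isoform_id = tm$transcript_id, category = category,
               associated_gene = gene, associated_transcript = transcript,
               stringsAsFactors = FALSE)
  }

  if (nrow(my_j) > 0L && length(same_genes) > 0L) {
    cand <- Filter(function(ref) ref$strand == tm$strand && ref$gene_id %in% same_genes,
                   annotation)
    cand <- cand[order(vapply(cand, function(t) t$transcript_id, ""))]
    for (ref in cand) {
      if (identical(junction_keys(tm_junctions(ref)), my_keys)) {
        return(out("FSM", ref$gene_id, ref$transcript_id))
      }
    }
    for (ref in cand) {
      rk <- junction_keys(tm_junctions(ref))
      if (length(my_keys) < length(rk)) {
        for (off in 0:(length(rk) - length(my_keys))) {
          if (all(rk[off + seq_along(my_keys)] == my_keys)) {
            return(out("ISM", ref$gene_id, ref$transcript_id))
          }
        }
      }
    }
    # sites annotated anywhere on this chromosome and strand?
    all_sites <- integer(0)
    for (ref in annotation) {
      if (ref$chrom == tm$chrom && ref$strand == tm$strand) {
        rj <- tm_junctions(ref)
        all_sites <- c(all_sites, rj[, 1L], rj[, 2L])
      }
    }
    my_sites <- c(my_j[, 1L], my_j[, 2L])
    # associated gene = largest exonic overlap, computed pairwise
    ov <- vapply(same_genes, function(g) {
      ex <- do.call(rbind, lapply(gene_tx[[g]], function(t) t$exons))
      tot <- 0L
      for (i in seq_len(nrow(tm$exons))) {
        for (k in seq_len(nrow(ex))) {
          tot <- tot + max(0L, min(tm$exons[i, 2L], ex[k, 2L]) -
                             max(tm$exons[i, 1L], ex[k, 1L]))
        }
      }
      tot
    }, 0L)
    assoc <- same_genes[which.max(ov)]
    if (any(!my_sites %in% all_sites)) return(out("NNC", assoc))
    gene_sites <- integer(0)
    for (ref in gene_tx[[assoc]]) {
      rj <- tm_junctions(ref)
      gene_sites <- c(gene_sites, rj[, 1L], rj[, 2L])
    }
    if (all(my_sites %in% gene_sites)) return(out("NIC", assoc))
    return(out("NNC", assoc))
  }

  if (nrow(my_j) == 0L && length(same_genes) > 0L) {
    cand <- Filter(function(ref) ref$strand == tm$strand && ref$gene_id %in% same_genes,
                   annotation)
    cand <- cand[order(vapply(cand, function(t) t$transcript_id, ""))]
    for (ref in cand) {
      rs <- tm_span(ref)
      if (nrow(ref$exons) == 1L && rs[1L] <= my_span[1L] && my_span[2L] <= rs[2L]) {
        return(out("FSM", ref$gene_id, ref$transcript_id))
      }
    }
    for (ref in cand) {
      if (nrow(ref$exons) > 1L) {
        for (k in seq_len(nrow(ref$exons))) {
          if (ref$exons[k, 1L] <= my_span[1L] && my_span[2L] <= ref$exons[k, 2L]) {
            return(out("ISM", ref$gene_id, ref$transcript_id))
          }
        }
      }
    }
  }

  if (length(same_genes) == 0L && length(anti_genes) > 0L) {
    ov <- vapply(anti_genes, function(g) {
      ex <- do.call(rbind, lapply(gene_tx[[g]], function(t) t$exons))
      tot <- 0L
      for (i in seq_len(nrow(tm$exons))) {
        for (k in seq_len(nrow(ex))) {
          tot <- tot + max(0L, min(tm$exons[i, 2L], ex[k, 2L]) -
                             max(tm$exons[i, 1L], ex[k, 1L]))
        }
      }
      tot
    }, 0L)
    return(out("Antisense", anti_genes[which.max(ov)]))
  }

  for (g in gene_ids) {
    ts <- gene_tx[[g]]
    if (ts[[1L]]$chrom != tm$chrom || ts[[1L]]$strand != tm$strand) next
    gspan <- range(unlist(lapply(ts, function(t) tm_span(t))))
    if (gspan[1L] <= my_span[1L] && my_span[2L] <= gspan[2L] &&
        !any(vapply(ts, overlaps_exons, FALSE))) {
      return(out("Genic_Intron", g))
    }
  }
  for (g in gene_ids) {
    ts <- gene_tx[[g]]
    if (ts[[1L]]$chrom != tm$chrom || ts[[1L]]$strand != tm$strand) next
    gspan <- range(unlist(lapply(ts, function(t) tm_span(t))))
    if (my_span[1L] < gspan[2L] && gspan[1L] < my_span[2L]) {
      return(out("Genic_Genomic", g))
    }
  }
  out("Intergenic")
}

#' @describeIn oracles Transitive-closure collapse oracle: builds the full
#'   pairwise mergeable relation, closes it with repeated boolean matrix
#'   expansion, aggregates components, then absorbs 5'-degraded sub-chains
#'   by repeated full rescans until a fixed point.
#' @param isoforms List of [aligned_isoform()]s.
#' @param end_tolerance,collapse_degraded_5prime See [collapse_isoforms()].
#' @export
collapse_oracle <- function(isoforms, end_tolerance = 50L,
                            collapse_degraded_5prime = TRUE) {
  n <- length(isoforms)
  if (n == 0L) return(list())
  ids <- vapply(isoforms, function(x) x$isoform_id, "")
  isoforms <- isoforms[order(ids)]
  ids <- sort(ids)
  M <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- isoforms[[i]]$model; b <- isoforms[[j]]$model
      if (a$chrom == b$chrom && a$strand == b$strand &&
          identical(tm_chain_key(a), tm_chain_key(b)) &&
          abs(tm_span(a)[1L] - tm_span(b)[1L]) <= end_tolerance &&
          abs(tm_span(a)[2L] - tm_span(b)[2L]) <= end_tolerance) {
        M[i, j] <- TRUE
      }
    }
  }
  repeat {
    M2 <- (M %*% M) > 0
    if (identical(M2, M)) break
    M <- M2
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[which(M[i, ])] <- cid
    }
  }
  support <- vapply(isoforms, function(x) x$fl_support, 0L)
  splen <- vapply(isoforms, function(x) tm_length(x$model), 0L)
  survivors <- list()
  for (c0 in unique(comp)) {
    g <- which(comp == c0)
    best <- g[order(-support[g], -splen[g], ids[g])][1L]
    iso <- isoforms[[best]]
    iso$fl_support <- sum(support[g])
    survivors[[length(survivors) + 1L]] <- iso
  }
  survivors <- survivors[order(vapply(survivors, function(x) x$isoform_id, ""))]

  if (collapse_degraded_5prime) {
    repeat {
      nj <- vapply(survivors, function(x) nrow(tm_junctions(x$model)), 0L)
      sid <- vapply(survivors, function(x) x$isoform_id, "")
      done <- TRUE
      for (i in order(nj, sid)) {
        if (nj[i] < 1L) next
        a <- survivors[[i]]$model
        ka <- junction_keys(tm_junctions(a))
        conts <- integer(0)
        for (j in seq_along(survivors)) {
          if (i == j) next
          b <- survivors[[j]]$model
          if (b$chrom != a$chrom || b$strand != a$strand) next
          kb <- junction_keys(tm_junctions(b))
          if (length(kb) <= length(ka)) next
          anch <- if (a$strand == "+") kb[(length(kb) - length(ka) + 1L):length(kb)]
                  else kb[seq_along(ka)]
          if (identical(anch, ka)) conts <- c(conts, j)
        }
        if (length(conts)) {
          sup <- vapply(survivors[conts], function(x) x$fl_support, 0L)
          ln <- vapply(survivors[conts], function(x) tm_length(x$model), 0L)
          nm <- vapply(survivors[conts], function(x) x$isoform_id, "")
          best <- conts[order(-sup, -ln, nm)][1L]
          survivors[[best]]$fl_support <-
            survivors[[best]]$fl_support + survivors[[i]]$fl_support
          survivors <- survivors[-i]
          done <- FALSE
          break
        }
      }
      if (done) break
    }
  }
  survivors
}

#' @describeIn oracles Exhaustive ORF finder: enumerates every candidate
#'   (start, stop) pair in every forward frame directly.
#' @param sequence DNA string.
#' @param min_aa Minimum protein length (aa).
#' @export
find_best_orf_exhaustive <- function(sequence, min_aa = 100L) {
  if (nchar(sequence) < 3L) stop("validation error: sequence shorter than one codon")
  if (grepl("[^ACGT]", sequence)) stop("validation error: non-ACGT characters in sequence")
  stops <- c("TAA", "TAG", "TGA")
  cands <- list()
  for (frame in 0:2) {
    nc <- (nchar(sequence) - frame) %/% 3L
    if (nc < 1L) next
    cod <- vapply(seq_len(nc),
                  function(k) substr(sequence, frame + 3L * k - 2L, frame + 3L * k), "")
    atg_at <- which(cod == "ATG")
    stop_at <- which(cod %in% stops)
    # complete: every (ATG, stop) pair with no intervening stop
    for (a in atg_at) {
      for (s in stop_at) {
        # valid ORF: stop after the ATG with no intervening stop codon
        if (s > a && !any(stop_at >= a & stop_at < s)) {
          cands[[length(cands) + 1L]] <-
            list(start = frame + 3L * (a - 1L), end = frame + 3L * s,
                 length = 3L * (s - a + 1L), completeness = "complete",
                 protein_length = s - a, frame = frame)
        }
      }
    }
    # three_prime_partial: ATG with no downstream stop, runs to the end
    for (a in atg_at) {
      if (!any(stop_at >= a)) {
        cands[[length(cands) + 1L]] <-
          list(start = frame + 3L * (a - 1L), end = frame + 3L * nc,
               length = 3L * (nc - a + 1L), completeness = "three_prime_partial",
               protein_length = nc - a + 1L, frame = frame)
      }
    }
    # five_prime_partial: frame start to its first stop, no upstream ATG
    for (s in stop_at) {
      if (!any(stop_at < s) && !any(atg_at < s)) {
        cands[[length(cands) + 1L]] <-
          list(start = frame, end = frame + 3L * s,
               length = 3L * s, completeness = "five_prime_partial",
               protein_length = s - 1L, frame = frame)
      }
    }
    # internal: a frame devoid of both ATG and stop codons
    if (length(atg_at) == 0L && length(stop_at) == 0L) {
      cands[[length(cands) + 1L]] <-
        list(start = frame, end = frame + 3L * nc, length = 3L * nc,
             completeness = "internal", protein_length = nc, frame = frame)
    }
  }
  cands <- Filter(function(c) c$protein_length >= min_aa, cands)
  if (length(cands) == 0L) return(NULL)
  rank <- c(complete = 1L, five_prime_partial = 2L,
            three_prime_partial = 3L, internal = 4L)
  ord <- order(-vapply(cands, `[[`, 0L, "length"),
               rank[vapply(cands, `[[`, "", "completeness")],
               vapply(cands, `[[`, 0L, "start"))
  cands[[ord[1L]]]
}

#' @describeIn oracles Naive agglomerative single-linkage clustering of
#'   poly(A) sites: repeatedly merges the closest cluster pair under
#'   `min_distance` until none remain.
#' @param three_prime_ends Data frame with `gene_id`, `position`,
#'   `support`, optional `strand`.
#' @param min_distance Minimum between-site distance.
#' @export
call_apa_sites_oracle <- function(three_prime_ends, min_distance = 15L) {
  df <- three_prime_ends
  if (any(df$support < 0)) stop("validation error: negative poly(A) site support")
  if (is.null(df$strand)) df$strand <- "+"
  df <- df[df$support > 0, , drop = FALSE]
  rows <- list()
  for (g in split(df, df$gene_id)) {
    clusters <- lapply(seq_len(nrow(g)), function(i) g[i, , drop = FALSE])
    repeat {
      best <- NULL
      bd <- Inf
      if (length(clusters) > 1L) {
        for (i in seq_along(clusters)[-1L]) {
          for (j in seq_len(i - 1L)) {
            d <- min(abs(outer(clusters[[i]]$position, clusters[[j]]$position, "-")))
            if (d < min_distance && d < bd) { bd <- d; best <- c(i, j) }
          }
        }
      }
      if (is.null(best)) break
      clusters[[best[2L]]] <- rbind(clusters[[best[2L]]], clusters[[best[1L]]])
      clusters <- clusters[-best[1L]]
    }
    for (m in clusters) {
      distal <- if (m$strand[1L] == "+") -m$position else m$position
      rep_pos <- m$position[order(-m$support, distal)][1L]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = m$gene_id[1L], representative_position = rep_pos,
        members = paste(sort(m$position), collapse = ";"),
        support = sum(m$support), n_members = nrow(m), stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), representative_position = integer(0),
               members = character(0), support = numeric(0), n_members = integer(0))
  clusters <- clusters[order(clusters$gene_id, clusters$representative_position), , drop = FALSE]
  rownames(clusters) <- NULL
  clusters
}

#' @describeIn oracles Plain pairwise AS-event enumerator used to check
#'   [detect_as_events()]; loops over ordered isoform pairs and re-derives
#'   each event definition with explicit scans.
#' @param gene_isoforms List of [transcript_model()]s of one gene.
#' @export
detect_as_events_oracle <- function(gene_isoforms) {
  tms <- lapply(gene_isoforms, function(x) if (inherits(x, "aligned_isoform")) x$model else x)
  if (length(tms) < 2L) {
    return(detect_as_events(gene_isoforms))  # shares only the empty schema
  }
  strand <- tms[[1L]]$strand
  found <- list()
  push <- function(type, coordinates, inclusion, skipping, LI, LS) {
    found[[length(found) + 1L]] <<- data.frame(
      event_type = type, coordinates = coordinates,
      inclusion_junctions = inclusion, skipping_junctions = skipping,
      LI = LI, LS = LS, stringsAsFactors = FALSE)
  }
  for (A in tms) {
    for (B in tms) {
      if (identical(A, B)) next
      exA <- A$exons; exB <- B$exons
      nA <- nrow(exA)
      # exon skipping
      if (nA >= 3L && nrow(exB) >= 2L) {
        for (k in 2:(nA - 1L)) {
          for (q in seq_len(nrow(exB) - 1L)) {
            d <- exB[q, 2L]; a <- exB[q + 1L, 1L]
            if (d <= exA[k, 1L] && exA[k, 2L] <= a) {
              push("exon_skipping", sprintf("%d-%d", exA[k, 1L], exA[k, 2L]),
                   paste(sprintf("%d-%d", c(exA[k - 1L, 2L], exA[k, 2L]),
                                 c(exA[k, 1L], exA[k + 1L, 1L])), collapse = ";"),
                   sprintf("%d-%d", d, a), 2L, 1L)
            }
          }
        }
      }
      # intron retention
      for (x in seq_len(nA)) {
        if (nrow(exB) < 2L) next
        for (q in seq_len(nrow(exB) - 1L)) {
          d <- exB[q, 2L]; a <- exB[q + 1L, 1L]
          if (exA[x, 1L] < d && a < exA[x, 2L]) {
            push("intron_retention", sprintf("%d-%d", d, a),
                 sprintf("body:%d-%d", d, a), sprintf("%d-%d", d, a), 1L, 1L)
          }
        }
      }
      # alternative donor/acceptor sides
      if (nA >= 2L && nrow(exB) >= 2L) {
        for (p in seq_len(nA - 1L)) {
          for (q in seq_len(nrow(exB) - 1L)) {
            d1 <- exA[p, 2L]; a1 <- exA[p + 1L, 1L]
            d2 <- exB[q, 2L]; a2 <- exB[q + 1L, 1L]
            if (a1 == a2 && d1 != d2) {
              dbig <- max(d1, d2); dsml <- min(d1, d2)
              exo <- if (d1 > d2) exA else exB
              srow <- which(exo[, 2L] == dbig)
              if (length(srow) && exo[srow[1L], 1L] < dsml) {
                type <- if (strand == "+") "alt_5prime" else "alt_3prime"
                ji <- sprintf("%d-%d", dbig, a1); js <- sprintf("%d-%d", dsml, a1)
                push(type, paste(ji, js, sep = "|"), ji, js, 1L, 1L)
              }
            }
            if (d1 == d2 && a1 != a2) {
              abig <- max(a1, a2); asml <- min(a1, a2)
              exo <- if (a1 < a2) exA else exB
              erow <- which(exo[, 1L] == asml)
              if (length(erow) && exo[erow[1L], 2L] > abig) {
                type <- if (strand == "+") "alt_3prime" else "alt_5prime"
                ji <- sprintf("%d-%d", d1, asml); js <- sprintf("%d-%d", d1, abig)
                push(type, paste(ji, js, sep = "|"), ji, js, 1L, 1L)
              }
            }
          }
        }
      }
    }
  }
  if (length(found) == 0L) return(detect_as_events(gene_isoforms))
  out <- unique(do.call(rbind, found))
  out <- out[order(out$event_type, out$coordinates,
                   out$inclusion_junctions, out$skipping_junctions), ]
  rownames(out) <- NULL
  out
}
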