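#' Planted isoforms with known structural categories
#'
#' Constructs isoforms whose structural category relative to the truth-set
#' annotation is known by design: FSM copies a reference chain with terminal
#' jitter; ISM keeps a consecutive sub-chain; NIC recombines annotated
#' donors/acceptors into an unannotated junction; NNC shifts one splice site
#' off every annotated position; Antisense mirrors reference exons on the
#' opposite strand; Genic_Intron and Genic_Genomic sit inside an intron or
#' straddle an exonic-union boundary; Intergenic isoforms live in the empty
#' chromosome tails, > 2 kb from any gene.
#'
#' @param truth A `truth_set` from [build_truth_set()].
#' @param n_per_category Number of isoforms planted per category.
#' @param seed RNG seed.
#' @return List with `isoforms` (list of [aligned_isoform()]) and `truth`
#'   (data frame `isoform_id`, `category`).
#' @export
simulate_isoform_plants <- function(truth, n_per_category = 20L, seed = 1L) {
  set.seed(seed)
  genes <- gene_structures(truth)
  multi <- Filter(function(g) nrow(g$primary$exons) >= 4L, genes)
  tails <- chromosome_tails(truth)

  isoforms <- list()
  labels <- list()
  k <- 0L
  add <- function(category, tm) {
    k <<- k + 1L
    id <- sprintf("plant%04d", k)
    tm$transcript_id <- id
    isoforms[[k]] <<- aligned_isoform(id, tm)
    labels[[k]] <<- data.frame(isoform_id = id, category = category,
                               stringsAsFactors = FALSE)
  }

  for (i in seq_len(n_per_category)) {
    g <- multi[[1L + (i - 1L) %% length(multi)]]
    t0 <- g$primary
    ex <- t0$exons
    n <- nrow(ex)

    # FSM: identical chain, jittered termini
    e <- ex
    e[1L, 1L] <- e[1L, 1L] + sample(1:30, 1L)
    e[n, 2L] <- e[n, 2L] - sample(1:30, 1L)
    add("FSM", transcript_model("x", NA, t0$chrom, t0$strand, e))

    # ISM: drop one junction from a random end
    if (sample(c(TRUE, FALSE), 1L)) e <- ex[-1L, , drop = FALSE] else
      e <- ex[-n, , drop = FALSE]
    e[1L, 1L] <- e[1L, 1L] + sample(0:20, 1L)
    add("ISM", transcript_model("x", NA, t0$chrom, t0$strand, e))

    # NIC: skip an internal exon whose skip junction is unannotated
    ki <- if (n >= 5L) sample(3:(n - 1L), 1L) else 3L
    add("NIC", transcript_model("x", NA, t0$chrom, t0$strand,
                                ex[-ki, , drop = FALSE]))

    # NNC: shift one acceptor 4 bp off every annotated site
    e <- ex
    e[3L, 1L] <- e[3L, 1L] + 4L
    add("NNC", transcript_model("x", NA, t0$chrom, t0$strand, e))

    # Antisense: reference exon pair on the opposite strand
    add("Antisense",
        transcript_model("x", NA, t0$chrom, if (t0$strand == "+") "-" else "+",
                         ex[1:2, , drop = FALSE]))

    # Genic_Intron: mono-exon inside an exonic-union gap
    gap <- g$intron_gaps[which(g$intron_gaps[, 2L] - g$intron_gaps[, 1L] >= 250L)[1L], ]
    add("Genic_Intron",
        transcript_model("x", NA, t0$chrom, t0$strand,
                         matrix(c(gap[1L] + 40L, gap[1L] + 190L), ncol = 2L)))

    # Genic_Genomic: mono-exon straddling the last exonic-union boundary
    u_end <- g$union[nrow(g$union), 2L]
    add("Genic_Genomic",
        transcript_model("x", NA, t0$chrom, t0$strand,
                         matrix(c(u_end - 60L, u_end + 80L), ncol = 2L)))

    # Intergenic: chromosome tail, far from every gene
    tail <- tails[[1L + (i - 1L) %% length(tails)]]
    s <- tail$start + sample(0:40000, 1L)
    add("Intergenic",
        transcript_model("x", NA, tail$chrom, sample(c("+", "-"), 1L),
                         matrix(c(s, s + 200L, s + 500L, s + 700L),
                                ncol = 2L, byrow = TRUE)))
  }
  list(isoforms = isoforms, truth = do.call(rbind, labels))
}

#' Random structurally diverse isoforms (no truth label)
#'
#' Mutates reference transcripts with random edits (terminal jitter, exon
#' drops, site shifts, intron retention, strand flips, intergenic moves) to
#' fuzz the structural classifier against its exhaustive comparator.
#'
#' @param truth A `truth_set`.
#' @param n Number of isoforms.
#' @param seed RNG seed.
#' @return List of [aligned_isoform()]s.
#' @export
simulate_random_isoforms <- function(truth, n = 1000L, seed = 1L) {
  set.seed(seed)
  genes <- gene_structures(truth)
  multi <- Filter(function(g) nrow(g$primary$exons) >= 4L, genes)
  tails <- chromosome_tails(truth)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- multi[[sample(length(multi), 1L)]]
    t0 <- g$primary
    ex <- t0$exons
    strand <- t0$strand
    op <- sample(c("jitter", "subchain", "skip", "shift", "retain",
                   "flip", "intergenic", "mono"), 1L)
    e <- switch(op,
      jitter = {
        e <- ex
        e[1L, 1L] <- max(0L, e[1L, 1L] + sample(-300:60, 1L))
        e[nrow(e), 2L] <- e[nrow(e), 2L] + sample(-60:300, 1L)
        if (e[1L, 1L] >= e[1L, 2L] - 10L) e[1L, 1L] <- e[1L, 2L] - 10L
        if (e[nrow(e), 2L] <= e[nrow(e), 1L] + 10L) e[nrow(e), 2L] <- e[nrow(e), 1L] + 10L
        e
      },
      subchain = {
        d <- sample(1:(nrow(ex) - 2L), 1L)
        if (sample(c(TRUE, FALSE), 1L)) ex[-seq_len(d), , drop = FALSE] else
          ex[seq_len(nrow(ex) - d), , drop = FALSE]
      },
      skip = ex[-sample(2:(nrow(ex) - 1L), 1L), , drop = FALSE],
      shift = {
        e <- ex
        j <- sample(2:(nrow(e) - 1L), 1L)
        if (sample(c(TRUE, FALSE), 1L)) e[j, 1L] <- e[j, 1L] + sample(c(-7L, 4L, 7L), 1L)
        else e[j, 2L] <- e[j, 2L] + sample(c(-7L, -4L, 7L), 1L)
        e
      },
      retain = {
        j <- sample(seq_len(nrow(ex) - 1L), 1L)
        rbind(ex[seq_len(j - 1L), , drop = FALSE],
              c(ex[j, 1L], ex[j + 1L, 2L]),
              if (j + 2L <= nrow(ex)) ex[(j + 2L):nrow(ex), , drop = FALSE])
      },
      flip = {
        strand <- if (strand == "+") "-" else "+"
        ex[sample(seq_len(nrow(ex) - 1L), 1L) + 0:1, , drop = FALSE]
      },
      intergenic = {
        tail <- tails[[sample(length(tails), 1L)]]
        s <- tail$start + sample(0:40000, 1L)
        strand <- sample(c("+", "-"), 1L)
        matrix(c(s, s + sample(80:400, 1L)), ncol = 2L)
      },
      mono = {
        span <- tm_span(t0)
        s <- max(0L, span[1L] + sample(-500:2000, 1L))
        matrix(c(s, s + sample(80:600, 1L)), ncol = 2L)
      })
    id <- sprintf("rand%05d", i)
    out[[i]] <- aligned_isoform(
      id, transcript_model(id, NA, t0$chrom, strand, e))
  }
  out
}

# per-gene structure summaries used by the plant generators
gene_structures <- function(truth) {
  by_gene <- split(truth$annotation,
                   vapply(truth$annotation, function(t) t$gene_id, ""))
  lapply(by_gene, function(ts) {
    n_ex <- vapply(ts, function(t) nrow(t$exons), 0L)
    primary <- ts[[which.max(n_ex)]]
    all_ex <- do.call(rbind, lapply(ts, function(t) t$exons))
    u <- merge_intervals(all_ex)
    gaps <- if (nrow(u) > 1L) cbind(u[-nrow(u), 2L], u[-1L, 1L]) else
      matrix(integer(0), ncol = 2L)
    list(gene_id = primary$gene_id, chrom = primary$chrom,
         strand = primary$strand, primary = primary, union = u,
         intron_gaps = gaps)
  })
}

chromosome_tails <- function(truth) {
  lapply(names(truth$genome), function(ch) {
    list(chrom = ch, start = nchar(truth$genome[[ch]]) - 50000L)
  })
}

merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(x)
  x <- x[order(x[, 1L], x[, 2L]), , drop = FALSE]
  out <- x[1L, , drop = FALSE]
  for (i in seq_len(nrow(x))[-1L]) {
    if (x[i, 1L] <= out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], x[i, 2L])
    } else out <- rbind(out, x[i, , drop = FALSE])
  }
  out
}
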