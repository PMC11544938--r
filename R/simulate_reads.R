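#' Synthetic cDNA primer sequences
#'
#' Fixed 20-mer 5' and 3' primers used by the simulator and, by default, by
#' the read classifier. They are distinct from each other and from each
#' other's reverse complements, so exact-match classification on synthetic
#' reads is unambiguous.
#' @format Character scalars.
#' @export
PRIMER5 <- "CACTGGCCGTCGTTTTACAA"

#' @rdname PRIMER5
#' @export
PRIMER3 <- "AGGAAACAGCTATGACCATG"

#' Simulate long reads with primer/poly(A) structure
#'
#' Each read is drawn from an expressed isoform and given one of three
#' ground-truth labels: `FLNC` (5' primer + insert + optional poly(A) + 3'
#' primer), `FL_chimeric` (an additional internal 5'-primer copy splitting
#' two inserts), or `non_full_length` (missing at least one terminal
#' primer). A fraction `polya_absent_rate` of full-length reads lacks the
#' poly(A) tract. Per-read pass counts and read qualities (accuracy in
#' `[0.95, 1]`, the regime of circular-consensus reads) are recorded.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param truth A `truth_set` from [build_truth_set()].
#' @param config A [sim_config()]; `n_long_reads`, `chimera_rate`,
#'   `non_full_length_rate` and `polya_absent_rate` apply.
#' @return Data frame with `read_id`, `isoform_id`, `truth_category`,
#'   `truth_polya`, `n_passes`, `quality`, `sequence`.
#' @export
simulate_long_reads <- function(genome, truth, config) {
  if (length(truth$expressed) == 0L) stop("configuration error: empty truth set")
  set.seed(config$seed + 101L)
  n <- config$n_long_reads
  iso_seqs <- vapply(truth$expressed, function(t) tm_sequence(t, genome), "")
  iso_ids <- vapply(truth$expressed, function(t) t$transcript_id, "")
  wts <- truth$abundance$ck + truth$abundance$w
  wts <- wts[match(iso_ids, truth$abundance$isoform_id)]
  wts[is.na(wts)] <- 1

  pick <- sample(seq_along(iso_ids), n, replace = TRUE, prob = wts)
  category <- sample(c("FLNC", "FL_chimeric", "non_full_length"), n, replace = TRUE,
                     prob = c(1 - config$chimera_rate - config$non_full_length_rate,
                              config$chimera_rate, config$non_full_length_rate))
  polya_absent <- stats::runif(n) < config$polya_absent_rate
  tail_len <- sample(20:35, n, replace = TRUE)
  nfl_variant <- sample(1:3, n, replace = TRUE)
  pick2 <- sample(seq_along(iso_ids), n, replace = TRUE, prob = wts)

  sequence <- character(n)
  truth_polya <- rep(NA, n)
  for (i in seq_len(n)) {
    ins <- iso_seqs[pick[i]]
    tail <- if (polya_absent[i]) "" else strrep("A", tail_len[i])
    if (category[i] == "FLNC") {
      sequence[i] <- paste0(PRIMER5, ins, tail, PRIMER3)
      truth_polya[i] <- !polya_absent[i]
    } else if (category[i] == "FL_chimeric") {
      sequence[i] <- paste0(PRIMER5, ins, PRIMER5, iso_seqs[pick2[i]], tail, PRIMER3)
      truth_polya[i] <- !polya_absent[i]
    } else {
      sequence[i] <- switch(nfl_variant[i],
                            paste0(ins, tail, PRIMER3),
                            paste0(PRIMER5, ins),
                            ins)
    }
  }
  data.frame(read_id = sprintf("read%05d", seq_len(n)),
             isoform_id = iso_ids[pick],
             truth_category = category,
             truth_polya = truth_polya,
             n_passes = sample(3:40, n, replace = TRUE),
             quality = round(stats::runif(n, 0.95, 1), 4),
             sequence = sequence,
             stringsAsFactors = FALSE)
}

#' Simulate redundant spliced alignments for the collapse stage
#'
#' Every expressed (non-fusion) isoform is emitted as one or more aligned
#' copies with terminal jitter well inside the default collapse tolerance,
#' plus occasional 5'-degraded copies whose junction chain is a 3'-anchored
#' sub-chain of the full model (the dominant long-read artifact). Collapsing
#' the result should recover exactly one model per expressed isoform.
#'
#' @param truth A `truth_set`.
#' @param config A [sim_config()].
#' @return List of [aligned_isoform()]s.
#' @export
simulate_aligned_isoforms <- function(truth, config) {
  set.seed(config$seed + 202L)
  out <- list()
  k <- 0L
  for (tm in truth$expressed) {
    wt <- truth$abundance$ck[match(tm$transcript_id, truth$abundance$isoform_id)] +
      truth$abundance$w[match(tm$transcript_id, truth$abundance$isoform_id)]
    if (is.na(wt)) wt <- 2L
    n_copies <- 1L + stats::rbinom(1L, 2L, 0.4)
    supports <- as.integer(stats::rmultinom(1L, max(wt, n_copies), rep(1, n_copies)))
    supports <- pmax(supports, 1L)
    first_w <- tm$exons[1L, 2L] - tm$exons[1L, 1L]
    last_w <- tm$exons[nrow(tm$exons), 2L] - tm$exons[nrow(tm$exons), 1L]
    for (cpy in seq_len(n_copies)) {
      ex <- tm$exons
      j5 <- sample(0:min(20L, first_w - 50L), 1L)
      j3 <- sample(0:min(20L, last_w - 50L), 1L)
      ex[1L, 1L] <- ex[1L, 1L] + j5
      ex[nrow(ex), 2L] <- ex[nrow(ex), 2L] - j3
      k <- k + 1L
      out[[k]] <- aligned_isoform(
        sprintf("aln%04d", k),
        transcript_model(sprintf("aln%04d", k), tm$gene_id, tm$chrom, tm$strand,
                         ex, biotype = tm$biotype),
        fl_support = supports[cpy])
    }
    if (nrow(tm$exons) >= 3L && stats::runif(1L) < 0.3) {
      # 5'-degraded copy: drop one junction from the transcriptional 5' end
      ex <- if (tm$strand == "+") tm$exons[-1L, , drop = FALSE] else
        tm$exons[-nrow(tm$exons), , drop = FALSE]
      ex[1L, 1L] <- ex[1L, 1L] + sample(0:20, 1L)
      k <- k + 1L
      out[[k]] <- aligned_isoform(
        sprintf("aln%04d", k),
        transcript_model(sprintf("aln%04d", k), tm$gene_id, tm$chrom, tm$strand,
                         ex, biotype = tm$biotype),
        fl_support = 1L)
    }
  }
  out
}

#' Simulate per-read split alignments for fusion detection
#'
#' Planted fusion transcripts produce reads whose alignments split into two
#' segments on two distinct gene loci; all other reads align as a single
#' full-coverage segment inside one gene.
#'
#' @param truth A `truth_set`.
#' @param config A [sim_config()]; `n_single_gene_alignments` background
#'   reads are drawn.
#' @return Data frame with `read_id`, `segment`, `chrom`, `gstart`, `gend`,
#'   `read_start`, `read_end`, `read_length`.
#' @export
simulate_split_alignments <- function(truth, config) {
  set.seed(config$seed + 303L)
  rows <- list()
  fus <- truth$planted_fusions
  if (nrow(fus) > 0L) {
    for (f in seq_len(nrow(fus))) {
      for (r in seq_len(fus$support[f])) {
        rid <- sprintf("fusread_%s_%d", fus$fusion_id[f], r)
        L <- fus$len_a[f] + fus$len_b[f]
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = rid, segment = 1:2,
          chrom = c(fus$chrom_a[f], fus$chrom_b[f]),
          gstart = c(fus$start_a[f], fus$breakpoint_b[f]),
          gend = c(fus$breakpoint_a[f], fus$end_b[f]),
          read_start = c(0L, fus$len_a[f]),
          read_end = c(fus$len_a[f], L),
          read_length = L, stringsAsFactors = FALSE)
      }
    }
  }
  n_bg <- config$n_single_gene_alignments
  iso <- truth$expressed
  pick <- sample(seq_along(iso), n_bg, replace = TRUE)
  for (i in seq_len(n_bg)) {
    tm <- iso[[pick[i]]]
    L <- tm_length(tm)
    span <- tm_span(tm)
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = sprintf("bgread%05d", i), segment = 1L,
      chrom = tm$chrom, gstart = span[1L], gend = span[2L],
      read_start = 0L, read_end = L, read_length = L,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Transcript 3'-end table for APA calling
#'
#' Returns the planted per-gene polyadenylation-site observations
#' (strand-resolved genomic positions with read support, including
#' zero-support decoys that the caller must drop).
#'
#' @param truth A `truth_set`.
#' @return Data frame with `gene_id`, `strand`, `position`, `support`.
#' @export
simulate_three_prime_ends <- function(truth) {
  truth$planted_apa
}
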