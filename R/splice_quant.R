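#' Exon inclusion level
#'
#' `phi = (I/LI) / (I/LI + S/LS)`: the inclusion and skipping junction-read
#' totals are normalized by the number of junctions each class of molecule
#' can contribute to (`LI`, `LS` junction multiplicities), making phi the
#' estimated fraction of the gene's transcripts that include the
#' alternative region.
#'
#' @param I Inclusion junction reads (>= 0).
#' @param S Skipping junction reads (>= 0).
#' @param LI,LS Junction multiplicities (integers >= 1).
#' @return phi in `[0, 1]`, or `NA` when `I + S == 0` (undefined).
#' @export
compute_phi <- function(I, S, LI = 1L, LS = 1L) {
  if (any(LI < 1L) || any(LS < 1L)) stop("validation error: LI and LS must be >= 1")
  if (any(I < 0) || any(S < 0)) stop("validation error: negative junction counts")
  ifelse(I + S == 0, NA_real_, (I / LI) / (I / LI + S / LS))
}

#' Count reads supporting one junction
#'
#' From a junction-count table (exact-match on chromosome, donor, acceptor
#' and condition), or from gapped read alignments via
#' [read_supports_junction()].
#'
#' @param junction_table Data frame with `chrom`, `donor`, `acceptor`,
#'   `condition`, `count` (donor < acceptor).
#' @param chrom,donor,acceptor Junction coordinates (genome space).
#' @param condition Condition label.
#' @return Total read count (0 if absent).
#' @export
count_junction_reads <- function(junction_table, chrom, donor, acceptor, condition) {
  if (!chrom %in% junction_table$chrom) {
    stop("validation error: unknown chromosome ", chrom)
  }
  hit <- junction_table$chrom == chrom & junction_table$donor == donor &
    junction_table$acceptor == acceptor & junction_table$condition == condition
  sum(junction_table$count[hit])
}

#' Does a gapped read alignment support a junction?
#'
#' A read supports the junction iff its alignment contains a gap whose
#' boundaries equal `(donor, acceptor)` exactly. For intron retention the
#' inclusion evidence is instead a read whose aligned blocks overlap the
#' retained intron body by at least `min_overlap` bases without a gap
#' there ([read_supports_intron_body()]).
#'
#' @param blocks Two-column matrix of the read's aligned blocks
#'   (`[start, end)` genomic intervals, sorted).
#' @param donor,acceptor Junction coordinates.
#' @return Logical.
#' @export
read_supports_junction <- function(blocks, donor, acceptor) {
  n <- nrow(blocks)
  if (n < 2L) return(FALSE)
  any(blocks[-n, 2L] == donor & blocks[-1L, 1L] == acceptor)
}

#' @rdname read_supports_junction
#' @param min_overlap Minimum block overlap with the intron body (default 6).
#' @export
read_supports_intron_body <- function(blocks, donor, acceptor, min_overlap = 6L) {
  if (read_supports_junction(blocks, donor, acceptor)) return(FALSE)
  ov <- pmin(blocks[, 2L], acceptor) - pmax(blocks[, 1L], donor)
  sum(ov[ov > 0L]) >= min_overlap
}

#' Per-event inclusion statistics from a simulated junction-count table
#'
#' Sums inclusion- and skipping-role counts per event and condition and
#' computes phi with the event's junction multiplicities.
#'
#' @param events Data frame of events (needs `event_id`, `LI`, `LS`).
#' @param junction_counts Data frame from [simulate_junction_counts()].
#' @return Data frame with `event_id`, `condition`, `I`, `S`, `LI`, `LS`,
#'   `phi`.
#' @export
quantify_events <- function(events, junction_counts) {
  rows <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events$event_id[i]
    sub <- junction_counts[junction_counts$event_id == ev, , drop = FALSE]
    for (cond in sort(unique(junction_counts$condition))) {
      s2 <- sub[sub$condition == cond, , drop = FALSE]
      I <- sum(s2$count[s2$role == "inclusion"])
      S <- sum(s2$count[s2$role == "skipping"])
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = ev, condition = cond, I = I, S = S,
        LI = events$LI[i], LS = events$LS[i],
        phi = compute_phi(I, S, events$LI[i], events$LS[i]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Differential splicing between two groups
#'
#' Per event, computes group inclusion levels phi1/phi2 and
#' `delta_phi = |phi1 - phi2|`, a two-sided exact test (Fisher) on the 2x2
#' junction-count table `[[I1, S1], [I2, S2]]`, and Benjamini-Hochberg FDR
#' across all testable events. An event is called significant iff
#' `delta_phi > 0.05` and `FDR <= 0.01`. Events with `I + S == 0` in
#' either group are untestable and excluded from the FDR computation.
#'
#' @param counts Data frame with one row per event: `event_id`, `I1`,
#'   `S1`, `I2`, `S2`, `LI`, `LS`.
#' @param delta_threshold Minimum |delta phi| (default 0.05).
#' @param fdr_threshold Maximum FDR (default 0.01).
#' @return Data frame with `event_id`, `phi1`, `phi2`, `delta_phi`,
#'   `p_value`, `fdr`, `significant`, `testable`.
#' @export
diff_splicing <- function(counts, delta_threshold = 0.05, fdr_threshold = 0.01) {
  n <- nrow(counts)
  phi1 <- phi2 <- delta <- p <- rep(NA_real_, n)
  testable <- rep(FALSE, n)
  for (i in seq_len(n)) {
    I1 <- counts$I1[i]; S1 <- counts$S1[i]
    I2 <- counts$I2[i]; S2 <- counts$S2[i]
    phi1[i] <- compute_phi(I1, S1, counts$LI[i], counts$LS[i])
    phi2[i] <- compute_phi(I2, S2, counts$LI[i], counts$LS[i])
    testable[i] <- (I1 + S1 > 0L) && (I2 + S2 > 0L)
    if (testable[i]) {
      delta[i] <- abs(phi1[i] - phi2[i])
      p[i] <- stats::fisher.test(matrix(c(I1, S1, I2, S2), 2L, byrow = TRUE))$p.value
    }
  }
  fdr <- rep(NA_real_, n)
  fdr[testable] <- stats::p.adjust(p[testable], method = "BH")
  data.frame(event_id = counts$event_id, phi1 = phi1, phi2 = phi2,
             delta_phi = delta, p_value = p, fdr = fdr,
             significant = testable & !is.na(delta) & delta > delta_threshold &
               fdr <= fdr_threshold,
             testable = testable, stringsAsFactors = FALSE)
}

#' Assign junction reads to the splice variants of one gene
#'
#' Each junction read is assigned to the variants containing that junction:
#' reads on a junction unique to one variant accrue to it alone; reads on a
#' junction shared by k variants are split equally (1/k each). Junctions
#' matching no variant are ignored.
#'
#' @param gene_isoforms List of [aligned_isoform()]s or
#'   [transcript_model()]s of a single gene.
#' @param junction_counts Data frame with `chrom`, `donor`, `acceptor`,
#'   `count` (already restricted to one condition).
#' @param condition Condition label attached to the output.
#' @param lib_factor Library scaling factor for `relative_level` (e.g. a
#'   reference-gene read count); default 1.
#' @return Data frame with `isoform_id`, `gene_id`, `condition`,
#'   `assigned_reads`, `relative_level`.
#' @export
quantify_variants <- function(gene_isoforms, junction_counts, condition = "CK",
                              lib_factor = 1) {
  tms <- lapply(gene_isoforms, function(x) if (inherits(x, "aligned_isoform")) x$model else x)
  gid <- unique(vapply(tms, function(t) t$gene_id, ""))
  if (length(gid) > 1L) stop("validation error: isoforms from more than one gene")
  ids <- vapply(tms, function(t) t$transcript_id, "")
  jsets <- lapply(tms, function(t) {
    sprintf("%s:%s", t$chrom, junction_keys(tm_junctions(t)))
  })
  assigned <- stats::setNames(numeric(length(tms)), ids)
  for (i in seq_len(nrow(junction_counts))) {
    key <- sprintf("%s:%d-%d", junction_counts$chrom[i],
                   junction_counts$donor[i], junction_counts$acceptor[i])
    compat <- which(vapply(jsets, function(js) key %in% js, FALSE))
    if (length(compat) == 0L) next
    assigned[compat] <- assigned[compat] + junction_counts$count[i] / length(compat)
  }
  data.frame(isoform_id = ids, gene_id = gid, condition = condition,
             assigned_reads = as.numeric(assigned),
             relative_level = as.numeric(assigned) / lib_factor,
             stringsAsFactors = FALSE)
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target_sample - Ct_ref_sample) -
#'         (Ct_target_calibrator - Ct_ref_calibrator)`; returns
#' `2^-ddCt`, the expression of the target in the sample relative to the
#' calibrator, both normalized to the reference gene.
#'
#' @param ct_target_sample,ct_ref_sample Sample threshold cycles.
#' @param ct_target_calibrator,ct_ref_calibrator Calibrator threshold
#'   cycles.
#' @return Positive fold change.
#' @export
ddct_relative_expression <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_calibrator, ct_ref_calibrator) {
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

#' Summarize a qPCR plate into relative expression per sample
#'
#' Computes `delta_ct = ct_target - ct_ref` per sample, references the
#' mean delta Ct of the calibrator group, and reports `2^-ddCt`.
#'
#' @param samples Data frame with `sample_id`, `group`, `ct_target`,
#'   `ct_ref`.
#' @param calibrator_group Group used as calibrator (default `"CK"`).
#' @return Input with `delta_ct`, `delta_delta_ct`, `relative_expression`
#'   columns appended.
#' @export
qpcr_summary <- function(samples, calibrator_group = "CK") {
  if (!calibrator_group %in% samples$group) {
    stop("validation error: calibrator group absent")
  }
  dct <- samples$ct_target - samples$ct_ref
  cal <- mean(dct[samples$group == calibrator_group])
  ddct <- dct - cal
  cbind(samples, delta_ct = dct, delta_delta_ct = ddct,
        relative_expression = 2^(-ddct))
}

#' Read-ratio relative expression from RNA-seq counts
#'
#' Gene reads divided by reference-gene (e.g. GAPDH) reads, relative to the
#' control-group ratio. Returns `NA` (untestable) when the reference-gene
#' count is zero.
#'
#' @param gene_reads Reads mapped to the candidate gene.
#' @param gapdh_reads Reads mapped to the reference gene (> 0).
#' @param calibrator_ratio Control-group `gene/reference` ratio (> 0).
#' @return Fold change, or `NA_real_` when untestable.
#' @export
rnaseq_relative_expression <- function(gene_reads, gapdh_reads, calibrator_ratio = 1) {
  if (is.na(gapdh_reads) || gapdh_reads <= 0) {
    warning("reference gene has zero reads; expression untestable")
    return(NA_real_)
  }
  if (calibrator_ratio <= 0) stop("validation error: calibrator_ratio must be > 0")
  (gene_reads / gapdh_reads) / calibrator_ratio
}
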