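# Small shared fixtures. The default truth set is expensive enough to build
# once per test run; sub-sampled configs are built inline where a test needs
# different conditions.

small_config <- function(...) {
  args <- utils::modifyList(list(n_long_reads = 800L,
                                 n_single_gene_alignments = 500L), list(...))
  do.call(sim_config, args)
}

.fixture_env <- new.env()

fixture_truth <- function() {
  if (is.null(.fixture_env$truth)) .fixture_env$truth <- build_truth_set(small_config())
  .fixture_env$truth
}

# quick transcript constructor for hand-built cases
tm <- function(id, exons, strand = "+", chrom = "chr1", gene = "G",
               biotype = "coding") {
  transcript_model(id, gene, chrom, strand,
                   matrix(as.integer(exons), ncol = 2L, byrow = TRUE),
                   biotype = biotype)
}

ai <- function(id, exons, strand = "+", chrom = "chr1", gene = "G", support = 1L) {
  aligned_isoform(id, tm(id, exons, strand, chrom, gene), fl_support = support)
}

# expand a junction-count table into unit reads and assign each one equally
# among compatible variants: the brute-force counterpart of quantify_variants
quantify_variants_bruteforce <- function(gene_isoforms, junction_counts) {
  tms <- lapply(gene_isoforms,
                function(x) if (inherits(x, "aligned_isoform")) x$model else x)
  ids <- vapply(tms, function(t) t$transcript_id, "")
  total <- stats::setNames(numeric(length(ids)), ids)
  for (i in seq_len(nrow(junction_counts))) {
    for (r in seq_len(junction_counts$count[i])) {
      compat <- character(0)
      for (t in tms) {
        j <- tm_junctions(t)
        for (k in seq_len(nrow(j))) {
          if (t$chrom == junction_counts$chrom[i] &&
              j[k, 1L] == junction_counts$donor[i] &&
              j[k, 2L] == junction_counts$acceptor[i]) {
            compat <- c(compat, t$transcript_id)
          }
        }
      }
      if (length(compat)) total[compat] <- total[compat] + 1 / length(compat)
    }
  }
  total
}
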