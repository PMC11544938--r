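#!/usr/bin/env Rscript
# Simulate the study conditions: a two-chromosome toy genome, a reference
# annotation with multi-isoform genes hosting planted splicing events,
# long reads with primer/poly(A) structure, and two-condition junction
# counts. Writes every artifact under results/sim/.

suppressPackageStartupMessages(library(isohybrid))

outdir <- "results/sim"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

config <- sim_config()
write_sim_config(config, file.path(outdir, "config.yaml"))
truth <- build_truth_set(config)

write_genome_fasta(truth$genome, file.path(outdir, "genome.fa"))
write_annotation_gtf(truth$annotation, file.path(outdir, "annotation.gtf"))

reads <- simulate_long_reads(truth$genome, truth, config)
write_reads_fastq(reads, file.path(outdir, "long_reads.fastq"))
write_tsv(reads[, c("read_id", "isoform_id", "truth_category", "truth_polya")],
          file.path(outdir, "read_truth.tsv"))

aligned <- simulate_aligned_isoforms(truth, config)
write_isoforms_bed12(aligned, file.path(outdir, "aligned_isoforms.bed12"))

write_tsv(simulate_junction_counts(truth, config),
          file.path(outdir, "junction_counts.tsv"))
write_tsv(simulate_junction_support(truth),
          file.path(outdir, "junction_support.tsv"))
write_tsv(truth$planted_events, file.path(outdir, "truth_events.tsv"))
write_tsv(truth$planted_fusions, file.path(outdir, "truth_fusions.tsv"))
write_tsv(truth$planted_apa, file.path(outdir, "truth_apa_sites.tsv"))
write_tsv(simulate_split_alignments(truth, config),
          file.path(outdir, "split_alignments.tsv"))

message(sprintf("Simulated %d chromosomes (%s bp), %d annotated transcripts, %d expressed isoforms.",
                length(truth$genome),
                paste(nchar(truth$genome), collapse = " + "),
                length(truth$annotation), length(truth$expressed)))
message(sprintf("Planted: %d AS events (delta-phi %s), %d fusions, %d genes with APA sites, %d long reads.",
                nrow(truth$planted_events),
                paste(unique(abs(truth$planted_events$phi_ck - truth$planted_events$phi_w)),
                      collapse = "/"),
                nrow(truth$planted_fusions),
                length(unique(truth$planted_apa$gene_id)), nrow(reads)))
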