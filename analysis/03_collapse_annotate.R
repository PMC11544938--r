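#!/usr/bin/env Rscript
# Collapse redundant spliced alignments into unique isoform models, filter
# them with short-read junction support, and classify each survivor into
# the eight structural categories against the reference annotation.

suppressPackageStartupMessages(library(isohybrid))

simdir <- "results/sim"
outdir <- "results/isoforms"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

aligned <- read_isoforms_bed12(file.path(simdir, "aligned_isoforms.bed12"))
annotation <- read_annotation_gtf(file.path(simdir, "annotation.gtf"))
support <- read_tsv(file.path(simdir, "junction_support.tsv"))

col <- collapse_isoforms(aligned, end_tolerance = 50L,
                         collapse_degraded_5prime = TRUE)
message(sprintf("Collapse: %d aligned models -> %d unique isoforms (%d merges).",
                col$report$n_input, col$report$n_output, nrow(col$report$merges)))

filtered <- filter_low_confidence(col$isoforms, support, annotation,
                                  min_support = 1L)
message(sprintf("Short-read filter retained %d of %d isoforms.",
                length(filtered), length(col$isoforms)))
isoforms <- assign_pb_ids(filtered)
write_isoforms_bed12(isoforms, file.path(outdir, "isoforms.bed12"))

cls <- classify_isoforms(isoforms, annotation)
write_tsv(cls, file.path(outdir, "structural_classifications.tsv"))
tal <- tally_categories(cls, isoforms)
write_tsv(as.data.frame(tal$categories), file.path(outdir, "category_tally.tsv"))

genes <- assign_genes(cls, isoforms)
write_tsv(genes$novel_gene_clusters, file.path(outdir, "novel_gene_clusters.tsv"))
upd <- count_locus_updates(isoforms, cls, annotation, min_extension = 100L)
write_tsv(upd$records, file.path(outdir, "locus_updates.tsv"))

message(sprintf("Categories: %s.",
                paste(names(tal$categories), as.integer(tal$categories),
                      sep = "=", collapse = ", ")))
message(sprintf("%d known genes hit; %d novel gene clusters; %d loci with boundary extensions >= 100 bp.",
                length(genes$known_gene_hits),
                length(unique(genes$novel_gene_clusters$cluster_id)),
                upd$n_updated))
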