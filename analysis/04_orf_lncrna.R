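#!/usr/bin/env Rscript
# Predict ORFs with completeness classes for every isoform and call known
# and novel lncRNAs with the length / ORF / coding-potential filters.

suppressPackageStartupMessages(library(isohybrid))

simdir <- "results/sim"
outdir <- "results/orf"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

genome <- read_genome_fasta(file.path(simdir, "genome.fa"))
annotation <- read_annotation_gtf(file.path(simdir, "annotation.gtf"))
isoforms <- read_isoforms_bed12("results/isoforms/isoforms.bed12")
cls <- read_tsv("results/isoforms/structural_classifications.tsv")

orfs <- predict_orfs(isoforms, genome, min_aa = 100L)
write_tsv(orfs, file.path(outdir, "orf_predictions.tsv"))
tal <- tally_orf_classes(orfs)
write_tsv(data.frame(class = names(tal), count = as.integer(tal)),
          file.path(outdir, "orf_class_tally.tsv"))

lnc <- call_lncrnas(cls, orfs, annotation)
write_tsv(lnc, file.path(outdir, "lncrna_calls.tsv"))

message(sprintf("ORFs: %d of %d isoforms carry a significant ORF (%s).",
                tal[["with_orf"]], nrow(orfs),
                paste(names(tal)[2:5], as.integer(tal)[2:5], sep = "=",
                      collapse = ", ")))
message(sprintf("lncRNAs: %d known, %d novel; %d coding isoforms.",
                sum(lnc$status == "known_lncRNA"),
                sum(lnc$status == "novel_lncRNA"),
                sum(lnc$status == "coding")))
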