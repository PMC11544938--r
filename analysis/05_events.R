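#!/usr/bin/env Rscript
# Enumerate alternative-splicing events per gene, cluster alternative
# polyadenylation sites with the 15 bp single-linkage rule, and detect
# fusion-transcript candidates from split alignments.

suppressPackageStartupMessages(library(isohybrid))

simdir <- "results/sim"
outdir <- "results/events"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

annotation <- read_annotation_gtf(file.path(simdir, "annotation.gtf"))
isoforms <- read_isoforms_bed12("results/isoforms/isoforms.bed12")
cls <- read_tsv("results/isoforms/structural_classifications.tsv")

# group isoforms by associated gene (novel isoforms fall back to their own id)
assoc <- ifelse(is.na(cls$associated_gene), cls$isoform_id, cls$associated_gene)
events <- list()
for (g in split(seq_along(isoforms), assoc)) {
  if (length(g) < 2L) next
  models <- lapply(isoforms[g], function(x) {
    m <- x$model
    m$gene_id <- assoc[g[1L]]
    m
  })
  ev <- detect_as_events(models)
  if (nrow(ev) > 0L) events[[length(events) + 1L]] <- ev
}
events <- if (length(events)) do.call(rbind, events) else detect_as_events(list())
write_tsv(events, file.path(outdir, "as_events.tsv"))
message(sprintf("AS events: %d total (%s).", nrow(events),
                paste(names(table(events$event_type)),
                      as.integer(table(events$event_type)),
                      sep = "=", collapse = ", ")))

apa <- call_apa_sites(read_tsv(file.path(simdir, "truth_apa_sites.tsv")),
                      min_distance = 15L)
write_tsv(apa$clusters, file.path(outdir, "apa_clusters.tsv"))
write_tsv(as.data.frame(apa$histogram), file.path(outdir, "apa_histogram.tsv"))
message(sprintf("APA: %d genes with poly(A) site clusters; sites-per-gene histogram %s.",
                length(unique(apa$clusters$gene_id)),
                paste(names(apa$histogram), as.integer(apa$histogram),
                      sep = ":", collapse = " ")))

fus <- detect_fusions(read_tsv(file.path(simdir, "split_alignments.tsv")),
                      annotation, min_support = 2L)
write_tsv(fus$candidates, file.path(outdir, "fusion_candidates.tsv"))
truth_fus <- read_tsv(file.path(simdir, "truth_fusions.tsv"))
hit <- merge(fus$candidates, truth_fus, by = c("gene_a", "gene_b"))
message(sprintf("Fusions: %d candidates (%d intra-, %d inter-chromosomal); %d of %d plants recovered.",
                nrow(fus$candidates), sum(fus$candidates$same_chromosome),
                sum(!fus$candidates$same_chromosome), nrow(hit), nrow(truth_fus)))
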