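#' Run the full hybrid-transcriptome pipeline on synthetic data
#'
#' Executes every stage in order — simulate truth, simulate and classify
#' long reads, collapse and filter aligned isoforms, structural annotation,
#' ORF/lncRNA calling, AS/APA/fusion event detection, and hybrid
#' differential-splicing quantification — and assembles a run report whose
#' tallies all conserve their stage's input counts. The run is a pure
#' function of the config (seeded), so re-runs are byte-identical.
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory; when given, every intermediate table
#'   is written as TSV plus a JSON manifest.
#' @param inputs Optional named list of input file paths (e.g. a
#'   pre-simulated FASTQ); all paths are checked before any stage runs.
#' @return A `run_report` (list; see Details) with the truth set and all
#'   stage outputs attached.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL, inputs = NULL) {
  for (p in unlist(inputs)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  truth <- build_truth_set(config)

  # stage: long reads -> classification -> ROI summary
  reads <- if (!is.null(inputs$fastq)) read_reads_fastq(inputs$fastq) else
    simulate_long_reads(truth$genome, truth, config)
  read_cls <- classify_reads(reads)
  roi_summary <- summarize_rois(reads)
  flnc_tally <- tally_classifications(read_cls)

  # stage: collapse + short-read filter
  aligned <- simulate_aligned_isoforms(truth, config)
  collapsed <- collapse_isoforms(aligned)
  support <- simulate_junction_support(truth)
  filtered <- filter_low_confidence(collapsed$isoforms, support, truth$annotation)
  isoforms <- assign_pb_ids(filtered)

  # stage: structural annotation
  index <- annotation_index(truth$annotation)
  struct_cls <- classify_isoforms(isoforms, index)
  cat_tally <- tally_categories(struct_cls, isoforms)
  gene_assign <- assign_genes(struct_cls, isoforms)
  locus_updates <- count_locus_updates(isoforms, struct_cls, index)

  # stage: ORF / lncRNA
  orfs <- predict_orfs(isoforms, truth$genome)
  orf_tally <- tally_orf_classes(orfs)
  lncrnas <- call_lncrnas(struct_cls, orfs, truth$annotation)
  lnc_counts <- c(known = sum(lncrnas$status == "known_lncRNA"),
                  novel = sum(lncrnas$status == "novel_lncRNA"))

  # stage: events
  assoc <- ifelse(is.na(struct_cls$associated_gene),
                  struct_cls$isoform_id, struct_cls$associated_gene)
  as_events <- list()
  for (g in split(seq_along(isoforms), assoc)) {
    if (length(g) < 2L) next
    models <- lapply(isoforms[g], function(x) {
      m <- x$model
      m$gene_id <- assoc[g[1L]]
      m
    })
    ev <- detect_as_events(models)
    if (nrow(ev) > 0L) as_events[[length(as_events) + 1L]] <- ev
  }
  as_events <- if (length(as_events)) do.call(rbind, as_events) else
    detect_as_events(list())
  as_tally <- table(factor(as_events$event_type, levels = EVENT_TYPES))
  apa <- call_apa_sites(simulate_three_prime_ends(truth))
  fusions <- detect_fusions(simulate_split_alignments(truth, config),
                            truth$annotation)

  # stage: hybrid quantification + differential splicing
  counts <- simulate_junction_counts(truth, config)
  quants <- quantify_events(truth$planted_events, counts)
  wide <- merge(quants[quants$condition == "CK", c("event_id", "I", "S", "LI", "LS")],
                quants[quants$condition == "W", c("event_id", "I", "S")],
                by = "event_id", suffixes = c("1", "2"))
  diff <- diff_splicing(wide)
  diff <- merge(diff, truth$planted_events[, c("event_id", "gene_id", "event_type")],
                by = "event_id")

  # per-variant expression of the first event gene ("hub gene" analog)
  hub_gene <- truth$planted_events$gene_id[1L]
  hub_iso <- Filter(function(t) identical(t$gene_id, hub_gene), truth$expressed)
  hub_counts <- junction_counts_to_genomic(counts, truth)
  variant_expr <- do.call(rbind, lapply(c("CK", "W"), function(cond) {
    quantify_variants(hub_iso,
                      hub_counts[hub_counts$condition == cond &
                                   hub_counts$gene_id == hub_gene, ],
                      condition = cond)
  }))

  variant_tables <- lapply(unique(truth$planted_events$gene_id), function(g) {
    emit_variant_structure_table(g, isoforms, struct_cls, orfs, as_events)
  })
  names(variant_tables) <- unique(truth$planted_events$gene_id)

  report <- structure(list(
    config = config, truth = truth,
    roi_summary = roi_summary, read_classifications = read_cls,
    flnc_tally = flnc_tally,
    collapse_report = collapsed$report, isoforms = isoforms,
    structural = struct_cls, category_tally = cat_tally,
    gene_assignment = gene_assign, locus_updates = locus_updates,
    orfs = orfs, orf_tally = orf_tally, lncrnas = lncrnas,
    lncrna_counts = lnc_counts,
    as_events = as_events, as_tally = as_tally,
    apa = apa, fusions = fusions,
    junction_counts = counts, splicing_quant = quants,
    diff_splicing = diff, variant_expression = variant_expr,
    variant_tables = variant_tables), class = "run_report")
  validate_run_report(report)
  if (!is.null(outdir)) write_run_report(report, outdir)
  report
}

# map the event-keyed junction-count table to genomic junction rows
junction_counts_to_genomic <- function(counts, truth) {
  sub <- counts[!startsWith(counts$junction, "body:"), , drop = FALSE]
  parts <- regmatches(sub$junction, regexec("^(\\d+)-(\\d+)$", sub$junction))
  data.frame(gene_id = sub$gene_id, chrom = sub$chrom,
             donor = as.integer(vapply(parts, `[`, "", 2L)),
             acceptor = as.integer(vapply(parts, `[`, "", 3L)),
             condition = sub$condition, count = sub$count,
             stringsAsFactors = FALSE)
}

#' Check the internal count conservation of a run report
#' @param report A `run_report`.
#' @return `TRUE` invisibly; stops if a tally does not conserve counts.
#' @export
validate_run_report <- function(report) {
  ft <- report$flnc_tally
  if (ft$FLNC + ft$FL_chimeric + ft$non_full_length != ft$total) {
    stop("run report: read category tally does not conserve the read count")
  }
  if (ft$FLNC_with_polyA + ft$FLNC_without_polyA != ft$FLNC) {
    stop("run report: poly(A) split does not conserve the FLNC count")
  }
  cr <- report$collapse_report
  if (cr$n_output + nrow(cr$merges) != cr$n_input) {
    stop("run report: collapse report does not conserve the isoform count")
  }
  if (sum(report$category_tally$categories) != length(report$isoforms)) {
    stop("run report: structural categories do not sum to the isoform count")
  }
  if (sum(report$as_tally) != nrow(report$as_events)) {
    stop("run report: AS tally does not sum to the event count")
  }
  invisible(TRUE)
}

#' Write the run report to a directory
#' @param report A `run_report`.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_run_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) write_tsv(df, file.path(outdir, name))
  w(report$read_classifications, "read_classifications.tsv")
  w(report$structural, "structural_classifications.tsv")
  w(as.data.frame(report$category_tally$categories), "category_tally.tsv")
  w(report$orfs, "orfs.tsv")
  w(report$lncrnas, "lncrna_calls.tsv")
  w(report$as_events, "as_events.tsv")
  w(report$apa$clusters, "apa_clusters.tsv")
  w(as.data.frame(report$apa$histogram), "apa_histogram.tsv")
  w(report$fusions$candidates, "fusion_candidates.tsv")
  w(report$junction_counts, "junction_counts.tsv")
  w(report$splicing_quant, "splicing_quant.tsv")
  w(report$diff_splicing, "diff_splicing.tsv")
  w(report$variant_expression, "variant_expression.tsv")
  write_isoforms_bed12(report$isoforms, file.path(outdir, "isoforms.bed12"))
  manifest <- list(
    n_reads = report$flnc_tally$total,
    flnc = report$flnc_tally$FLNC,
    fl_chimeric = report$flnc_tally$FL_chimeric,
    non_full_length = report$flnc_tally$non_full_length,
    roi_summary = report$roi_summary,
    n_isoforms = length(report$isoforms),
    categories = as.list(report$category_tally$categories),
    known_genes_hit = length(report$gene_assignment$known_gene_hits),
    novel_gene_clusters =
      length(unique(report$gene_assignment$novel_gene_clusters$cluster_id)),
    locus_updates = report$locus_updates$n_updated,
    orf_classes = as.list(report$orf_tally),
    lncrnas = as.list(report$lncrna_counts),
    as_events = as.list(report$as_tally),
    apa_genes = length(unique(report$apa$clusters$gene_id)),
    fusion_candidates = nrow(report$fusions$candidates),
    fusion_tally = as.list(report$fusions$tally),
    significant_events = sum(report$diff_splicing$significant))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  reads: %d (FLNC %d, chimeric %d, non-FL %d)\n",
              x$flnc_tally$total, x$flnc_tally$FLNC, x$flnc_tally$FL_chimeric,
              x$flnc_tally$non_full_length))
  cat(sprintf("  isoforms after collapse+filter: %d\n", length(x$isoforms)))
  cat(sprintf("  AS events: %d; APA genes: %d; fusions: %d\n",
              nrow(x$as_events), length(unique(x$apa$clusters$gene_id)),
              nrow(x$fusions$candidates)))
  cat(sprintf("  differentially spliced events: %d of %d testable\n",
              sum(x$diff_splicing$significant), sum(x$diff_splicing$testable)))
  invisible(x)
}

#' Variant structure table for one gene
#'
#' One row per splice variant with the vocabulary used in isoform reports:
#' alignment status "Fully spliced match" (FSM), "Partial splice match"
#' (ISM) or "Unmatched" (novel), and a splicing form noting novel splice
#' sites, intron retention, or variable termini.
#'
#' @param gene_id Gene identifier.
#' @param isoforms List of [aligned_isoform()]s.
#' @param classifications Data frame from [classify_isoforms()].
#' @param orfs Data frame from [predict_orfs()].
#' @param as_events Optional AS-event data frame (to label intron
#'   retention forms).
#' @return Data frame with `variant_id`, `total_length_bp`, `n_exons`,
#'   `cds_length_bp`, `aligned_genome`, `splicing_form`.
#' @export
emit_variant_structure_table <- function(gene_id, isoforms, classifications,
                                         orfs, as_events = NULL) {
  idx <- which(classifications$associated_gene %in% gene_id)
  if (length(idx) == 0L) stop("validation error: no isoforms for gene ", gene_id)
  retained <- character(0)
  if (!is.null(as_events) && nrow(as_events) > 0L) {
    ir <- as_events[as_events$event_type == "intron_retention" &
                      as_events$gene_id == gene_id, , drop = FALSE]
    if (nrow(ir) > 0L) {
      for (i in idx) {
        ex <- isoforms[[i]]$model$exons
        for (e in seq_len(nrow(ir))) {
          co <- as.integer(strsplit(ir$coordinates[e], "-", fixed = TRUE)[[1L]])
          if (any(ex[, 1L] < co[1L] & co[2L] < ex[, 2L])) {
            retained <- c(retained, isoforms[[i]]$isoform_id)
          }
        }
      }
    }
  }
  rows <- lapply(idx, function(i) {
    iso <- isoforms[[i]]
    cl <- classifications[i, ]
    o <- orfs[orfs$isoform_id == iso$isoform_id, ]
    aligned <- switch(cl$category, FSM = "Fully spliced match",
                      ISM = "Partial splice match", "Unmatched")
    form <- if (cl$category == "NNC") "At least one novel splice site"
      else if (iso$isoform_id %in% retained) "Intron retention"
      else if (cl$category == "FSM") "Variable 5' and 3' ends"
      else if (cl$category == "ISM") "Truncated ends"
      else "Novel combination of known splice sites"
    data.frame(variant_id = iso$isoform_id, total_length_bp = tm_length(iso$model),
               n_exons = nrow(iso$model$exons),
               cds_length_bp = if (nrow(o) && !is.na(o$orf_length[1L]))
                 o$orf_length[1L] else NA_integer_,
               aligned_genome = aligned, splicing_form = form,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$variant_id), , drop = FALSE]
}
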