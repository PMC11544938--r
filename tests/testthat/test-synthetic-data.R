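test_that("generation is deterministic under a fixed seed and varies across seeds", {
  cfg <- small_config()
  a <- build_toy_genome(cfg)
  b <- build_toy_genome(cfg)
  fa <- tempfile(); fb <- tempfile(); ga <- tempfile(); gb <- tempfile()
  write_genome_fasta(a$genome, fa); write_genome_fasta(b$genome, fb)
  write_annotation_gtf(a$annotation, ga); write_annotation_gtf(b$annotation, gb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(readLines(ga), readLines(gb))

  other <- build_toy_genome(small_config(seed = 2L))
  expect_false(identical(a$annotation[[1L]]$exons, other$annotation[[1L]]$exons))
})

test_that("degenerate configs are rejected", {
  expect_error(sim_config(n_genes = 0L), "n_genes")
  expect_error(sim_config(chimera_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(polya_absent_rate = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(delta_phi_effects = c(0.3, 1.5)), "delta_phi")
  expect_error(build_truth_set(sim_config(n_genes = 5L)), "configuration error")
})

test_that("annotation satisfies the documented structural guarantees", {
  truth <- fixture_truth()
  ann <- truth$annotation
  gene_ids <- vapply(ann, function(t) t$gene_id, "")
  strands <- vapply(ann, function(t) t$strand, "")
  expect_true(any(table(gene_ids) >= 2L))           # multi-isoform genes
  expect_setequal(unique(strands), c("+", "-"))     # both strands
  expect_true(any(vapply(ann, function(t) t$biotype == "lncRNA", FALSE)))
  expect_true(all(vapply(ann, function(t) nchar(truth$genome[[t$chrom]]) >= 1000L, FALSE)))

  # intergenic gaps >= 2 kb between gene spans per chromosome
  gt <- truth$gene_table
  for (ch in unique(gt$chrom)) {
    g <- gt[gt$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1L) expect_true(all(g$start[-1L] - g$end[-nrow(g)] >= 2000L))
  }

  # every planted event type exists and is recovered by the event detector
  by_gene <- split(ann, gene_ids)
  ev <- do.call(rbind, lapply(by_gene[vapply(by_gene, length, 0L) > 1L],
                              detect_as_events))
  pe <- truth$planted_events
  expect_setequal(unique(pe$event_type),
                  c("exon_skipping", "intron_retention", "alt_5prime", "alt_3prime"))
  hit <- merge(pe, ev, by = c("event_type", "coordinates"))
  expect_equal(nrow(hit), nrow(pe))
  expect_true(all(hit$LI.x == hit$LI.y & hit$LS.x == hit$LS.y))
})

test_that("GTF round-trips without loss", {
  truth <- fixture_truth()
  path <- tempfile(fileext = ".gtf")
  write_annotation_gtf(truth$annotation, path)
  back <- read_annotation_gtf(path)
  orig <- truth$annotation[order(vapply(truth$annotation, function(t) t$chrom, ""),
                                 vapply(truth$annotation, function(t) tm_span(t)[1L], 0L),
                                 vapply(truth$annotation, function(t) t$transcript_id, ""))]
  expect_equal(length(back), length(orig))
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$exons, orig[[i]]$exons)
    expect_identical(back[[i]]$strand, orig[[i]]$strand)
    expect_identical(back[[i]]$gene_id, orig[[i]]$gene_id)
    expect_identical(back[[i]]$biotype, orig[[i]]$biotype)
  }
})

test_that("read labels follow the configured rates", {
  truth <- fixture_truth()
  pure <- small_config(chimera_rate = 0, non_full_length_rate = 0,
                       polya_absent_rate = 0)
  reads <- simulate_long_reads(truth$genome, truth, pure)
  expect_true(all(reads$truth_category == "FLNC"))
  expect_true(all(reads$truth_polya))

  cfg <- sim_config(n_long_reads = 5000L, chimera_rate = 0.1)
  big <- simulate_long_reads(truth$genome, build_truth_set(cfg), cfg)
  frac <- mean(big$truth_category == "FL_chimeric")
  sd3 <- 3 * sqrt(0.1 * 0.9 / 5000)
  expect_lt(abs(frac - 0.1), sd3)
  # label conservation
  expect_equal(sum(table(big$truth_category)), nrow(big))
  # determinism
  again <- simulate_long_reads(truth$genome, build_truth_set(cfg), cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_reads_fastq(big, f1); write_reads_fastq(again, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("junction counts follow the binomial inclusion model", {
  truth <- fixture_truth()
  cfg <- small_config()
  counts <- simulate_junction_counts(truth, cfg)
  expect_setequal(unique(counts$condition), c("CK", "W"))
  expect_true(all(counts$count >= 0))

  # phi = 1 forces S = 0 in every draw
  t2 <- truth
  t2$planted_events$phi_ck <- 1
  t2$planted_events$phi_w <- 1
  c2 <- simulate_junction_counts(t2, cfg)
  expect_true(all(c2$count[c2$role == "skipping"] == 0L))

  # estimator recovery at phi = 0.7, LI = 2, LS = 1, n = 2000
  set.seed(99)
  d <- simulate_event_counts(0.7, 2000L, LI = 2L, LS = 1L)
  expect_equal(d$I, 2L * d$X)
  expect_equal(d$S, 2000L - d$X)
  expect_lt(abs(compute_phi(d$I, d$S, 2L, 1L) - 0.7), 0.03)

  t3 <- truth
  t3$planted_events <- t3$planted_events[0, ]
  expect_error(simulate_junction_counts(t3, cfg), "validation error")
  expect_error(simulate_event_counts(1.2, 100L), "validation error")
})
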