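test_that("hand-built cases hit the documented category definitions", {
  ann <- list(tm("t1", c(100, 200, 300, 400, 500, 600, 700, 800, 900, 1000,
                         1100, 1200), gene = "G1"),
              tm("lnc1", c(5000, 5400), gene = "L1", biotype = "lncRNA"))
  idx <- annotation_index(ann)

  # FSM: identical chain, different ends
  r <- classify_isoform(tm("x", c(150, 200, 300, 400, 500, 600, 700, 800,
                                  900, 1000, 1100, 1150)), idx)
  expect_equal(r$category, "FSM")
  expect_equal(r$associated_transcript, "t1")

  # ISM: last 3 of 5 junctions
  r <- classify_isoform(tm("x", c(520, 600, 700, 800, 900, 1000, 1100, 1200)), idx)
  expect_equal(r$category, "ISM")

  # NIC: known donors/acceptors recombined into an unannotated junction
  r <- classify_isoform(tm("x", c(100, 200, 300, 400, 500, 600, 900, 1000,
                                  1100, 1200)), idx)
  expect_equal(r$category, "NIC")
  expect_equal(r$novel_splice_sites, 0L)

  # NNC: same chain with one acceptor shifted +4 (unannotated site)
  r <- classify_isoform(tm("x", c(100, 200, 300, 400, 500, 600, 904, 1000,
                                  1100, 1200)), idx)
  expect_equal(r$category, "NNC")
  expect_gt(r$novel_splice_sites, 0L)

  # Antisense / Genic_Intron / Genic_Genomic / Intergenic
  expect_equal(classify_isoform(tm("x", c(100, 200, 300, 400), strand = "-"), idx)$category,
               "Antisense")
  expect_equal(classify_isoform(tm("x", c(210, 280)), idx)$category, "Genic_Intron")
  expect_equal(classify_isoform(tm("x", c(150, 250)), idx)$category, "Genic_Genomic")
  expect_equal(classify_isoform(tm("x", c(8000, 8500)), idx)$category, "Intergenic")

  # mono-exon FSM within a mono-exon reference's span
  r <- classify_isoform(tm("x", c(5100, 5300)), idx)
  expect_equal(r$category, "FSM")
  expect_equal(r$associated_transcript, "lnc1")
  # mono-exon within a single exon of a multi-exon reference: ISM
  expect_equal(classify_isoform(tm("x", c(110, 190)), idx)$category, "ISM")

  expect_error(classify_isoform(tm("x", c(1, 100), chrom = "chrX"), idx),
               "unknown chromosome")
})

test_that("planted categories are reproduced exactly", {
  truth <- fixture_truth()
  plants <- simulate_isoform_plants(truth, n_per_category = 20L, seed = 5L)
  got <- classify_isoforms(plants$isoforms, truth$annotation)
  expect_identical(got$category, plants$truth$category)
  # partition: tallies sum to the isoform count
  tal <- tally_categories(got)
  expect_equal(sum(tal$categories), length(plants$isoforms))
})

test_that("classifier agrees with the exhaustive comparator on random isoforms", {
  truth <- fixture_truth()
  rand <- simulate_random_isoforms(truth, n = 200L, seed = 17L)
  idx <- annotation_index(truth$annotation)
  got <- classify_isoforms(rand, idx)
  oracle <- do.call(rbind, lapply(rand, classify_isoform_exhaustive,
                                  annotation = truth$annotation))
  expect_identical(got$category, oracle$category)
  expect_identical(got$associated_gene, oracle$associated_gene)
})

test_that("adding a matching reference never makes an isoform more novel", {
  truth <- fixture_truth()
  iso <- simulate_isoform_plants(truth, n_per_category = 3L, seed = 9L)
  nnc <- iso$isoforms[iso$truth$category == "NNC"]
  for (x in nnc) {
    before <- classify_isoform(x, truth$annotation)$category
    expect_equal(before, "NNC")
    new_ref <- x$model
    new_ref$transcript_id <- paste0(x$isoform_id, ".ref")
    new_ref$gene_id <- "GNEW"
    after <- classify_isoform(x, c(truth$annotation, list(new_ref)))$category
    expect_equal(after, "FSM")
  }
})

test_that("gene assignment separates known hits from novel clusters", {
  # 3 intergenic isoforms, two overlapping each other: 2 clusters
  ann <- list(tm("t1", c(100, 200, 300, 400), gene = "G1"))
  isos <- list(ai("a", c(50000, 50400)), ai("b", c(50300, 50700)),
               ai("c", c(90000, 90500)))
  cls <- classify_isoforms(isos, ann)
  expect_true(all(cls$category == "Intergenic"))
  res <- assign_genes(cls, isos)
  expect_equal(length(unique(res$novel_gene_clusters$cluster_id)), 2L)
  expect_length(res$known_gene_hits, 0L)

  # all-FSM input: zero novel genes
  fsm <- list(ai("f", c(100, 200, 300, 400)))
  cls2 <- classify_isoforms(fsm, ann)
  res2 <- assign_genes(cls2, fsm)
  expect_equal(nrow(res2$novel_gene_clusters), 0L)
  expect_equal(res2$known_gene_hits, "G1")

  # simulator plants: novel loci recovered as one cluster each
  truth <- fixture_truth()
  cfg <- small_config()
  col <- collapse_isoforms(simulate_aligned_isoforms(truth, cfg))
  flt <- filter_low_confidence(col$isoforms, simulate_junction_support(truth),
                               truth$annotation)
  cls3 <- classify_isoforms(flt, truth$annotation)
  res3 <- assign_genes(cls3, flt)
  expect_equal(length(unique(res3$novel_gene_clusters$cluster_id)),
               cfg$n_novel_genes + cfg$n_lncrnas)
})

test_that("locus updates count span extensions beyond the threshold", {
  ann <- list(tm("t1", c(1000, 1200, 1400, 1600), gene = "G1"))
  ext <- list(ai("e", c(1000, 1200, 1400, 1800)))   # 3' extension of 200
  cls <- classify_isoforms(ext, ann)
  r <- count_locus_updates(ext, cls, ann, min_extension = 100L)
  expect_equal(r$n_updated, 1L)
  expect_equal(r$records$side, "right")
  expect_equal(r$records$extension, 200L)
  r2 <- count_locus_updates(ext, cls, ann, min_extension = 300L)
  expect_equal(r2$n_updated, 0L)

  within <- list(ai("w", c(1050, 1200, 1400, 1550)))
  clw <- classify_isoforms(within, ann)
  expect_equal(count_locus_updates(within, clw, ann)$n_updated, 0L)

  # random set equals brute-force span comparison
  truth <- fixture_truth()
  rand <- simulate_random_isoforms(truth, n = 120L, seed = 3L)
  cls <- classify_isoforms(rand, truth$annotation)
  r <- count_locus_updates(rand, cls, truth$annotation, min_extension = 100L)
  spans <- lapply(split(truth$annotation,
                        vapply(truth$annotation, function(t) t$gene_id, "")),
                  function(ts) range(unlist(lapply(ts, tm_span))))
  manual <- character(0)
  for (i in seq_along(rand)) {
    if (!cls$category[i] %in% c("FSM", "ISM", "NIC", "NNC")) next
    gs <- spans[[cls$associated_gene[i]]]
    is_ <- tm_span(rand[[i]]$model)
    if (gs[1L] - is_[1L] >= 100L || is_[2L] - gs[2L] >= 100L) {
      manual <- c(manual, cls$associated_gene[i])
    }
  }
  expect_equal(r$n_updated, length(unique(manual)))
})
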