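test_that("canonical event fixtures produce the expected types and multiplicities", {
  # e1-e2-e3 vs e1-e3: one exon_skipping with LI=2, LS=1
  full <- tm("a", c(100, 200, 300, 400, 500, 600))
  skip <- tm("b", c(100, 200, 500, 600))
  ev <- detect_as_events(list(full, skip))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "exon_skipping")
  expect_equal(ev$LI, 2L)
  expect_equal(ev$LS, 1L)
  expect_equal(ev$coordinates, "300-400")
  expect_equal(ev$inclusion_junctions, "200-300;400-500")
  expect_equal(ev$skipping_junctions, "200-500")

  # merged exon vs spliced pair: intron retention
  spliced <- tm("a", c(100, 200, 300, 400))
  merged <- tm("b", c(100, 400))
  ev <- detect_as_events(list(spliced, merged))
  expect_equal(ev$event_type, "intron_retention")
  expect_equal(ev$coordinates, "200-300")

  # shared acceptor, shifted donor: alt 5' on "+", alt 3' on "-"
  a <- tm("a", c(100, 200, 300, 400))
  b <- tm("b", c(100, 170, 300, 400))
  expect_equal(detect_as_events(list(a, b))$event_type, "alt_5prime")
  am <- tm("a", c(100, 200, 300, 400), strand = "-")
  bm <- tm("b", c(100, 170, 300, 400), strand = "-")
  expect_equal(detect_as_events(list(am, bm))$event_type, "alt_3prime")
  # the inclusion junction is the shorter intron
  expect_equal(detect_as_events(list(a, b))$inclusion_junctions, "200-300")

  # single isoform: empty, not an error
  expect_equal(nrow(detect_as_events(list(full))), 0L)
})

test_that("event sets equal the pairwise oracle and are order/duplicate invariant", {
  set.seed(21)
  cols <- c("event_type", "coordinates", "inclusion_junctions",
            "skipping_junctions", "LI", "LS")
  for (rep in 1:50) {
    nex <- sample(4:7, 1L)
    starts <- cumsum(c(100L, rep(300L, nex - 1L)))
    base <- transcript_model("t1", "G", "chr1", sample(c("+", "-"), 1L),
                             cbind(starts, starts + 150L))
    isos <- list(base)
    for (k in seq_len(sample(1:4, 1L))) {
      ex <- base$exons
      op <- sample(c("skip", "retain", "alt", "sub"), 1L)
      if (op == "skip") ex <- ex[-sample(2:(nex - 1L), 1L), , drop = FALSE]
      if (op == "retain") {
        j <- sample(nex - 1L, 1L)
        ex <- rbind(ex[seq_len(j - 1L), , drop = FALSE],
                    c(ex[j, 1L], ex[j + 1L, 2L]),
                    if (j + 2L <= nex) ex[(j + 2L):nex, , drop = FALSE])
      }
      if (op == "alt") {
        j <- sample(nex - 1L, 1L)
        if (sample(c(TRUE, FALSE), 1L)) ex[j, 2L] <- ex[j, 2L] - sample(c(20L, 40L), 1L)
        else ex[j + 1L, 1L] <- ex[j + 1L, 1L] + sample(c(20L, 40L), 1L)
      }
      if (op == "sub") ex <- ex[-1L, , drop = FALSE]
      isos[[k + 1L]] <- transcript_model(paste0("t", k + 1L), "G", "chr1",
                                         base$strand, ex)
    }
    a <- detect_as_events(isos)
    b <- detect_as_events_oracle(isos)
    expect_equal(a[, cols], b[, cols], ignore_attr = TRUE)
    # order invariance and duplicate invariance
    a2 <- detect_as_events(rev(isos))
    expect_equal(a[, cols], a2[, cols], ignore_attr = TRUE)
    a3 <- detect_as_events(c(isos, isos[1L]))
    expect_equal(a[, cols], a3[, cols], ignore_attr = TRUE)
    # type tallies sum to the event count
    expect_equal(sum(table(a$event_type)), nrow(a))
  }
})

test_that("APA clustering follows the 15 bp single-linkage rule", {
  one <- data.frame(gene_id = "g", position = 500L, support = 3L)
  expect_equal(nrow(call_apa_sites(one)$clusters), 1L)

  three <- data.frame(gene_id = "g", position = c(100L, 110L, 130L),
                      support = c(5L, 2L, 4L))
  cl <- call_apa_sites(three)$clusters
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$representative_position, c(100L, 130L))
  expect_equal(cl$n_members, c(2L, 1L))

  # zero-support positions are excluded; negative support errors
  dz <- data.frame(gene_id = "g", position = c(100L, 300L), support = c(5L, 0L))
  expect_equal(nrow(call_apa_sites(dz)$clusters), 1L)
  expect_error(call_apa_sites(data.frame(gene_id = "g", position = 1L,
                                         support = -1L)), "validation error")

  # representative tie: most distal (strand-aware)
  tie <- data.frame(gene_id = "g", position = c(100L, 105L), support = c(5L, 5L),
                    strand = "+")
  expect_equal(call_apa_sites(tie)$clusters$representative_position, 105L)
  tie$strand <- "-"
  expect_equal(call_apa_sites(tie)$clusters$representative_position, 100L)
})

test_that("APA equals the brute-force oracle, is idempotent, and spaces representatives", {
  set.seed(31)
  for (rep in 1:80) {
    n <- sample(2:12, 1L)
    df <- data.frame(gene_id = "g",
                     position = sort(sample(1000:1400, n)),
                     support = sample(0:20, n, replace = TRUE))
    got <- call_apa_sites(df)$clusters
    orc <- call_apa_sites_oracle(df)
    expect_equal(got[, c("gene_id", "representative_position", "support", "n_members")],
                 orc[, c("gene_id", "representative_position", "support", "n_members")],
                 ignore_attr = TRUE)
    # every positive-support position in exactly one cluster
    expect_equal(sum(got$n_members), sum(df$support > 0))
    # representatives >= 15 bp apart
    if (nrow(got) > 1L) expect_true(all(diff(got$representative_position) >= 15L))
    # idempotence: re-clustering the representatives changes nothing
    again <- call_apa_sites(data.frame(gene_id = "g",
                                       position = got$representative_position,
                                       support = got$support))$clusters
    expect_equal(again$representative_position, got$representative_position)
  }
})

test_that("fusion detection recovers plants with zero false positives", {
  truth <- fixture_truth()
  cfg <- sim_config(n_single_gene_alignments = 5000L)
  splits <- simulate_split_alignments(truth, cfg)
  res <- detect_fusions(splits, truth$annotation)
  pf <- truth$planted_fusions
  expect_equal(nrow(res$candidates), nrow(pf))
  m <- merge(res$candidates, pf, by = c("gene_a", "gene_b"))
  expect_equal(nrow(m), nrow(pf))
  expect_equal(m$same_chromosome.x, m$same_chromosome.y)
  expect_true(all(m$support.x >= 2L))
  expect_equal(sum(res$tally), nrow(res$candidates))

  # single-gene reads alone yield no candidates
  bg <- splits[grepl("^bgread", splits$read_id), ]
  expect_equal(nrow(detect_fusions(bg, truth$annotation)$candidates), 0L)

  # explicit two-read toy case across chromosomes
  toy <- do.call(rbind, lapply(1:2, function(r) {
    data.frame(read_id = paste0("r", r), segment = 1:2,
               chrom = c("chr1", "chr2"),
               gstart = c(100L, 5000L), gend = c(600L, 5500L),
               read_start = c(0L, 500L), read_end = c(500L, 1000L),
               read_length = 1000L)
  }))
  ann <- list(tm("a1", c(50, 700), gene = "GA"),
              tm("b1", c(4900, 5600), chrom = "chr2", gene = "GB"))
  r <- detect_fusions(toy, ann, min_support = 2L)
  expect_equal(nrow(r$candidates), 1L)
  expect_false(r$candidates$same_chromosome)
  # a read fully contained in one gene is never evidence
  solo <- toy[toy$read_id == "r1" & toy$segment == 1L, ]
  expect_equal(nrow(detect_fusions(solo, ann)$candidates), 0L)
})
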