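test_that("compute_phi matches the closed form and its boundary behavior", {
  expect_equal(compute_phi(30, 10, 2L, 1L), 0.6)
  expect_equal(compute_phi(10, 0, 2L, 1L), 1)
  expect_equal(compute_phi(0, 7, 2L, 1L), 0)
  expect_true(is.na(compute_phi(0, 0, 2L, 1L)))
  expect_error(compute_phi(1, 1, 0L, 1L), "validation error")
  expect_error(compute_phi(-1, 1, 1L, 1L), "validation error")
})

test_that("phi is monotone, scale invariant and bounded (property check)", {
  set.seed(77)
  for (rep in 1:1000) {
    I <- sample(0:500, 1L); S <- sample(0:500, 1L)
    LI <- sample(1:4, 1L); LS <- sample(1:4, 1L)
    if (I + S == 0L) next
    p <- compute_phi(I, S, LI, LS)
    expect_gte(p, 0); expect_lte(p, 1)
    k <- sample(2:9, 1L)
    expect_equal(compute_phi(k * I, k * S, LI, LS), p)
    expect_gte(compute_phi(I + 1L, S, LI, LS), p)
    expect_lte(compute_phi(I, S + 1L, LI, LS), p)
  }
})

test_that("junction-read counting is coordinate-exact; IR uses body overlap", {
  tab <- data.frame(chrom = "chr1", donor = c(200L, 400L), acceptor = c(300L, 500L),
                    condition = c("CK", "CK"), count = c(12L, 3L))
  expect_equal(count_junction_reads(tab, "chr1", 200L, 300L, "CK"), 12L)
  expect_equal(count_junction_reads(tab, "chr1", 201L, 300L, "CK"), 0L)
  expect_error(count_junction_reads(tab, "chrX", 200L, 300L, "CK"), "unknown chromosome")

  blocks_gap <- cbind(c(100L, 300L), c(200L, 400L))
  expect_true(read_supports_junction(blocks_gap, 200L, 300L))
  expect_false(read_supports_junction(blocks_gap, 201L, 300L))
  # intron-retention inclusion: >= 6 bp block overlap with the body, no gap
  blocks_through <- cbind(100L, 400L)
  expect_true(read_supports_intron_body(blocks_through, 200L, 300L))
  expect_false(read_supports_intron_body(blocks_gap, 200L, 300L))
  expect_false(read_supports_intron_body(cbind(100L, 204L), 200L, 300L))

  # simulated table: event quantification reproduces the emitted truth counts
  truth <- fixture_truth()
  cfg <- small_config()
  counts <- simulate_junction_counts(truth, cfg)
  q <- quantify_events(truth$planted_events, counts)
  for (i in seq_len(nrow(q))) {
    sub <- counts[counts$event_id == q$event_id[i] & counts$condition == q$condition[i], ]
    expect_equal(q$I[i], sum(sub$count[sub$role == "inclusion"]))
    expect_equal(q$S[i], sum(sub$count[sub$role == "skipping"]))
  }
})

test_that("differential splicing applies the exact test, BH and the decision rule", {
  # identical counts: delta 0, never significant
  d <- diff_splicing(data.frame(event_id = "e", I1 = 50L, S1 = 50L,
                                I2 = 50L, S2 = 50L, LI = 1L, LS = 1L))
  expect_equal(d$delta_phi, 0)
  expect_false(d$significant)

  # strong swap: phi1 = 45/55, phi2 = 5/95, delta ~ 0.766, significant
  d <- diff_splicing(data.frame(event_id = "e", I1 = 90L, S1 = 10L,
                                I2 = 10L, S2 = 90L, LI = 2L, LS = 1L))
  expect_equal(d$phi1, 45 / 55)
  expect_equal(d$phi2, 5 / 95)
  expect_equal(d$delta_phi, 45 / 55 - 5 / 95)
  expect_equal(d$p_value,
               stats::fisher.test(matrix(c(90, 10, 10, 90), 2, byrow = TRUE))$p.value)
  expect_equal(d$fdr, d$p_value)  # independent BH on one test
  expect_true(d$significant)

  # delta below 5% is never significant, however small the p-value
  n <- 1e6L
  d <- diff_splicing(data.frame(event_id = "e", I1 = as.integer(0.52 * n),
                                S1 = as.integer(0.48 * n),
                                I2 = as.integer(0.48 * n),
                                S2 = as.integer(0.52 * n), LI = 1L, LS = 1L))
  expect_lt(d$p_value, 1e-10)
  expect_false(d$significant)

  # a group with I + S = 0 is untestable and excluded from the FDR
  d <- diff_splicing(data.frame(event_id = c("a", "b"),
                                I1 = c(0L, 40L), S1 = c(0L, 10L),
                                I2 = c(10L, 10L), S2 = c(10L, 40L),
                                LI = 1L, LS = 1L))
  expect_false(d$testable[1L])
  expect_true(is.na(d$fdr[1L]))
  expect_equal(d$fdr[2L], d$p_value[2L])

  # BH recomputed independently over a batch
  set.seed(8)
  batch <- data.frame(event_id = sprintf("e%03d", 1:50),
                      I1 = rbinom(50, 200, 0.5), S1 = rbinom(50, 200, 0.5),
                      I2 = rbinom(50, 200, 0.5), S2 = rbinom(50, 200, 0.5),
                      LI = 2L, LS = 1L)
  d <- diff_splicing(batch)
  expect_equal(d$fdr, stats::p.adjust(d$p_value, "BH"))
})

test_that("variant quantification assigns unique and shared junction reads correctly", {
  a <- tm("va", c(100, 200, 300, 400, 500, 600))
  b <- tm("vb", c(100, 200, 500, 600))
  # junction 400-500 unique to va; 10 reads all to va
  jc <- data.frame(chrom = "chr1", donor = 400L, acceptor = 500L, count = 10L)
  q <- quantify_variants(list(a, b), jc)
  expect_equal(q$assigned_reads[q$isoform_id == "va"], 10)
  expect_equal(q$assigned_reads[q$isoform_id == "vb"], 0)
  # no junction shared by both here except none; add a shared one
  shared <- data.frame(chrom = "chr1", donor = c(400L, 200L),
                       acceptor = c(500L, 300L), count = c(10L, 8L))
  # 200-300 belongs only to va as well; craft a real shared junction
  c2 <- tm("vc", c(100, 200, 300, 350, 500, 600))
  shared2 <- data.frame(chrom = "chr1", donor = 200L, acceptor = 300L, count = 8L)
  q <- quantify_variants(list(a, c2), shared2)
  expect_equal(q$assigned_reads, c(4, 4))

  expect_error(quantify_variants(list(a, tm("x", c(1, 50), gene = "H")),
                                 shared2), "validation error")

  # three-variant toy gene equals the per-read brute-force assignment
  set.seed(12)
  v1 <- tm("v1", c(100, 200, 300, 400, 500, 600, 700, 800))
  v2 <- tm("v2", c(100, 200, 500, 600, 700, 800))
  v3 <- tm("v3", c(100, 200, 300, 400, 500, 600))
  jc <- data.frame(chrom = "chr1",
                   donor = c(200L, 400L, 600L, 200L), acceptor = c(300L, 500L, 700L, 500L),
                   count = sample(1:20, 4L))
  q <- quantify_variants(list(v1, v2, v3), jc)
  brute <- quantify_variants_bruteforce(list(v1, v2, v3), jc)
  expect_equal(stats::setNames(q$assigned_reads, q$isoform_id), brute)
  # read conservation: all counted junctions belong to >= 1 variant
  expect_equal(sum(q$assigned_reads), sum(jc$count))
})

test_that("qPCR and read-ratio expression math is exact", {
  expect_equal(ddct_relative_expression(10, 5, 9, 4), 1)
  expect_equal(ddct_relative_expression(10, 5, 9, 5), 0.5)
  expect_equal(ddct_relative_expression(8, 5, 10, 5), 4)

  plate <- data.frame(sample_id = c("ck1", "ck2", "w1"),
                      group = c("CK", "CK", "W"),
                      ct_target = c(20, 20, 18), ct_ref = c(15, 15, 15))
  r <- qpcr_summary(plate)
  expect_equal(r$relative_expression, c(1, 1, 4))
  expect_error(qpcr_summary(plate[plate$group == "W", ]), "calibrator")

  expect_equal(rnaseq_relative_expression(100, 100, 1), 1)
  expect_equal(rnaseq_relative_expression(200, 100, 1), 2)
  expect_warning(res <- rnaseq_relative_expression(200, 0, 1), "untestable")
  expect_true(is.na(res))
})
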