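random_cds_free <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("completeness classes come out of constructed fixtures", {
  # complete: smallest ORF incl. stop
  r <- find_best_orf("ATGAAATAG", min_aa = 1L)
  expect_equal(r$completeness, "complete")
  expect_equal(r$length, 9L)
  expect_equal(r$protein_length, 2L)

  # three_prime_partial: ATG + 150 non-stop codons, no stop
  seq3p <- paste0("ATG", strrep("GCT", 150))
  r <- find_best_orf(seq3p, min_aa = 100L)
  expect_equal(r$completeness, "three_prime_partial")
  expect_equal(r$protein_length, 151L)

  # five_prime_partial: codons then a stop, no upstream ATG in frame
  seq5p <- paste0(strrep("GCT", 150), "TAA")
  r <- find_best_orf(seq5p, min_aa = 100L)
  expect_equal(r$completeness, "five_prime_partial")
  expect_equal(r$protein_length, 150L)

  # internal: neither ATG nor stop in the frame
  seqint <- strrep("GCT", 150)
  r <- find_best_orf(seqint, min_aa = 100L)
  expect_equal(r$completeness, "internal")
  expect_equal(r$protein_length, 150L)

  expect_error(find_best_orf("AC"), "validation error")
  expect_error(find_best_orf("ATGNNN"), "validation error")
})

test_that("find_best_orf equals the exhaustive enumeration oracle", {
  set.seed(123)
  for (rep in 1:30) {
    s <- random_cds_free(sample(300:1200, 1L))
    for (min_aa in c(1L, 30L)) {
      a <- find_best_orf(s, min_aa)
      b <- find_best_orf_exhaustive(s, min_aa)
      expect_identical(a, b)
    }
  }
  # CDS length of a complete ORF is divisible by 3 and protein matches
  set.seed(5)
  for (rep in 1:20) {
    s <- random_cds_free(900)
    a <- find_best_orf(s, 1L)
    if (!is.null(a) && a$completeness == "complete") {
      expect_equal(a$length %% 3L, 0L)
      expect_equal(a$protein_length, a$length / 3L - 1L)
    }
  }
})

test_that("coding score is a bounded logistic of coverage and protein length", {
  expect_equal(coding_score("ACGT", NULL), 0)
  s <- paste0("ATG", strrep("GCT", 298), "TAA")  # 900 nt, ORF covers 100%
  orf <- find_best_orf(s, 1L)
  expect_equal(orf$length, 900L)
  expect_gt(coding_score(s, orf), 0.5)
  # documented closed form at stated inputs
  expect_equal(coding_score(s, orf),
               1 / (1 + exp(-(4 * 1 + 0.02 * orf$protein_length - 3))))
  set.seed(1)
  for (rep in 1:200) {
    s <- random_cds_free(sample(200:1500, 1L))
    sc <- coding_score(s, find_best_orf(s, 1L))
    expect_gte(sc, 0)
    expect_lte(sc, 1)
  }
})

test_that("lncRNA calling applies the length/ORF/score filters", {
  truth <- fixture_truth()
  ann <- truth$annotation

  # 180 nt isoform with no ORF: fails the > 200 nt filter
  short_cls <- data.frame(isoform_id = "s", category = "Intergenic",
                          associated_gene = NA, associated_transcript = NA,
                          stringsAsFactors = FALSE)
  short_orf <- data.frame(isoform_id = "s", transcript_length = 180L,
                          max_orf_aa = 10L, coding_score = 0.1,
                          stringsAsFactors = FALSE)
  r <- call_lncrnas(short_cls, short_orf, ann)
  expect_equal(r$status, "undetermined")

  # pipeline: known lncRNAs via FSM, planted novel lncRNAs all recovered
  cfg <- small_config()
  col <- collapse_isoforms(simulate_aligned_isoforms(truth, cfg))
  flt <- filter_low_confidence(col$isoforms, simulate_junction_support(truth),
                               truth$annotation)
  cls <- classify_isoforms(flt, ann)
  orfs <- predict_orfs(flt, truth$genome)
  calls <- call_lncrnas(cls, orfs, ann)

  lnc_ref <- vapply(Filter(function(t) t$biotype == "lncRNA", ann),
                    function(t) t$transcript_id, "")
  known <- calls$isoform_id[calls$status == "known_lncRNA"]
  expect_equal(sort(cls$associated_transcript[match(known, cls$isoform_id)]),
               sort(lnc_ref))

  # all planted novel lncRNA models called novel_lncRNA
  planted <- vapply(Filter(function(t) t$biotype == "lncRNA" &&
                             startsWith(t$gene_id, "NLNC"), truth$expressed),
                    function(t) tm_chain_key(t), "")
  chains <- vapply(flt, function(x) tm_chain_key(x$model), "")
  planted_ids <- vapply(flt[chains %in% planted], function(x) x$isoform_id, "")
  expect_true(all(calls$status[match(planted_ids, calls$isoform_id)] == "novel_lncRNA"))

  # disjointness invariants
  expect_false(any(calls$status == "coding" & calls$max_orf_aa < 100L))
  expect_false(any(calls$status == "novel_lncRNA" & calls$max_orf_aa >= 100L))
})
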