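test_that("identical chains merge within tolerance and junction matching is exact", {
  a <- ai("a", c(100, 200, 300, 400, 500, 600), support = 3L)
  b <- ai("b", c(110, 200, 300, 400, 500, 590), support = 2L)
  res <- collapse_isoforms(list(a, b), end_tolerance = 50L)
  expect_equal(res$report$n_output, 1L)
  expect_equal(res$isoforms[[1L]]$fl_support, 5L)
  expect_equal(res$isoforms[[1L]]$isoform_id, "a")  # larger support kept

  # one junction off by 1 bp: no merge
  c1 <- ai("c", c(100, 200, 301, 400, 500, 600))
  res <- collapse_isoforms(list(a, c1), end_tolerance = 50L)
  expect_equal(res$report$n_output, 2L)
  expect_error(collapse_isoforms(list(a), end_tolerance = -1L), "validation error")
})

test_that("5'-degraded sub-chains are absorbed strand-awarely", {
  full <- ai("full", c(100, 200, 300, 400, 500, 600, 700, 800), support = 5L)
  deg_plus <- ai("deg", c(320, 400, 500, 600, 700, 800))   # missing first junction
  res <- collapse_isoforms(list(full, deg_plus))
  expect_equal(res$report$n_output, 1L)
  expect_equal(res$isoforms[[1L]]$fl_support, 6L)
  # on "-" the 5' end is the genomic right: a genomic-prefix chain absorbs
  fullm <- ai("fullm", c(100, 200, 300, 400, 500, 600, 700, 800), strand = "-", support = 5L)
  degm <- ai("degm", c(100, 200, 300, 400, 500, 580), strand = "-")
  res <- collapse_isoforms(list(fullm, degm))
  expect_equal(res$report$n_output, 1L)
  # with the flag off both survive
  res <- collapse_isoforms(list(full, deg_plus), collapse_degraded_5prime = FALSE)
  expect_equal(res$report$n_output, 2L)
})

test_that("collapse matches the transitive-closure oracle and its invariants", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(8:20, 1L)
    isos <- lapply(seq_len(n), function(i) {
      base <- sample(c(1000L, 5000L), 1L)
      nex <- sample(2:5, 1L)
      starts <- base + cumsum(c(sample(0:60, 1L), rep(300L, nex - 1L)))
      ends <- starts + 150L + c(rep(0L, nex - 1L), sample(0:60, 1L))
      if (sample(c(TRUE, FALSE), 1L) && nex >= 3L) {
        starts <- starts[-1L]; ends <- ends[-1L]
      }
      aligned_isoform(sprintf("i%02d", i),
                      transcript_model(sprintf("i%02d", i), "G", "chr1",
                                       sample(c("+", "-"), 1L),
                                       cbind(starts, ends)),
                      fl_support = sample(1:9, 1L))
    })
    res <- collapse_isoforms(isos)
    orc <- collapse_oracle(isos)
    key <- function(l) sort(vapply(l, function(x)
      paste(x$isoform_id, x$fl_support, tm_chain_key(x$model)), ""))
    expect_identical(key(res$isoforms), key(orc))

    # support conservation
    expect_equal(sum(vapply(res$isoforms, function(x) x$fl_support, 0L)),
                 sum(vapply(isos, function(x) x$fl_support, 0L)))
    # conservation of counts in the report
    expect_equal(res$report$n_output + nrow(res$report$merges), res$report$n_input)
    # idempotence
    res2 <- collapse_isoforms(res$isoforms)
    expect_identical(key(res2$isoforms), key(res$isoforms))
    expect_equal(nrow(res2$report$merges), 0L)
    # input-order invariance
    res3 <- collapse_isoforms(rev(isos))
    expect_identical(key(res3$isoforms), key(res$isoforms))
  }
})

test_that("low-confidence filtering applies the support and annotation-rescue rules", {
  ann <- list(tm("ref", c(100, 200, 300, 400), gene = "G1"))
  sup0 <- data.frame(chrom = "chr1", donor = 200L, acceptor = 300L, count = 0)
  supported <- data.frame(chrom = "chr1", donor = 500L, acceptor = 600L, count = 7)

  novel <- ai("novel", c(450, 500, 600, 700))
  expect_length(filter_low_confidence(list(novel), sup0, ann, min_support = 1L), 0L)
  expect_length(filter_low_confidence(list(novel), supported, ann, min_support = 1L), 1L)

  # all junctions annotated, zero short-read support: rescued
  known <- ai("known", c(110, 200, 300, 390))
  expect_length(filter_low_confidence(list(known), sup0, ann, min_support = 1L), 1L)

  # mono-exon: retained iff fl_support >= 2
  mono1 <- ai("m1", c(100, 400), support = 1L)
  mono2 <- ai("m2", c(100, 400), support = 2L)
  kept <- filter_low_confidence(list(mono1, mono2), sup0, ann)
  expect_equal(vapply(kept, function(x) x$isoform_id, ""), "m2")

  # mixed random set equals rule-by-rule reapplication
  set.seed(7)
  truth <- fixture_truth()
  isos <- simulate_aligned_isoforms(truth, small_config())
  sup <- simulate_junction_support(truth)
  sup$count[sample(nrow(sup), 5L)] <- 0
  got <- filter_low_confidence(isos, sup, truth$annotation, min_support = 1L)
  skey <- sprintf("%s:%d-%d", sup$chrom, sup$donor, sup$acceptor)
  akey <- unlist(lapply(truth$annotation, function(t) {
    j <- tm_junctions(t)
    sprintf("%s:%s:%d-%d", t$chrom, t$strand, j[, 1L], j[, 2L])
  }))
  manual <- Filter(function(iso) {
    j <- tm_junctions(iso$model)
    if (nrow(j) == 0L) return(iso$fl_support >= 2L)
    all(vapply(seq_len(nrow(j)), function(k) {
      key <- sprintf("%s:%d-%d", iso$model$chrom, j[k, 1L], j[k, 2L])
      (key %in% skey && sup$count[match(key, skey)] >= 1) ||
        sprintf("%s:%s:%d-%d", iso$model$chrom, iso$model$strand,
                j[k, 1L], j[k, 2L]) %in% akey
    }, FALSE))
  }, isos)
  expect_identical(vapply(got, function(x) x$isoform_id, ""),
                   vapply(manual, function(x) x$isoform_id, ""))
})
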