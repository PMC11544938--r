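STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find the best open reading frame of a transcript
#'
#' Scans the three forward frames (transcripts are strand-resolved cDNA).
#' Candidate ORFs are: ATG to stop codon (`complete`, the stop is included
#' in the ORF); ATG to the end of the frame with no downstream stop
#' (`three_prime_partial`); frame start to the first stop with no upstream
#' in-frame ATG (`five_prime_partial`); and a whole frame containing
#' neither ATG nor stop (`internal`). Returns the longest candidate whose
#' protein length is at least `min_aa`, ties broken by completeness rank
#' (complete > 5'-partial > 3'-partial > internal), then by leftmost
#' start.
#'
#' @param sequence DNA string over `{A,C,G,T}` of length >= 3.
#' @param min_aa Minimum protein length in amino acids (default 100, the
#'   conventional significance bound; the stop codon never counts toward
#'   protein length).
#' @return List with `start`, `end` (0-based half-open transcript
#'   coordinates), `length` (nt), `completeness`, `protein_length` (aa),
#'   `frame`; or `NULL` when no candidate reaches `min_aa`.
#' @export
find_best_orf <- function(sequence, min_aa = 100L) {
  if (nchar(sequence) < 3L) stop("validation error: sequence shorter than one codon")
  if (grepl("[^ACGT]", sequence)) stop("validation error: non-ACGT characters in sequence")
  cands <- list()
  for (frame in 0:2) {
    n_codons <- (nchar(sequence) - frame) %/% 3L
    if (n_codons < 1L) next
    codons <- substring(sequence, frame + 1L + 3L * (seq_len(n_codons) - 1L),
                        frame + 3L * seq_len(n_codons))
    stops <- which(codons %in% STOP_CODONS)
    atgs <- which(codons == "ATG")
    add <- function(a, b, completeness, protein) {
      cands[[length(cands) + 1L]] <<- list(
        start = frame + 3L * (a - 1L), end = frame + 3L * b,
        length = 3L * (b - a + 1L), completeness = completeness,
        protein_length = protein, frame = frame)
    }
    for (a in atgs) {
      nxt <- stops[stops >= a]
      if (length(nxt)) {
        s <- nxt[1L]
        if (s > a) add(a, s, "complete", s - a)
      } else {
        add(a, n_codons, "three_prime_partial", n_codons - a + 1L)
      }
    }
    if (length(stops)) {
      s1 <- stops[1L]
      if (!any(atgs < s1)) add(1L, s1, "five_prime_partial", s1 - 1L)
    } else if (length(atgs) == 0L) {
      add(1L, n_codons, "internal", n_codons)
    }
  }
  cands <- Filter(function(c) c$protein_length >= min_aa, cands)
  if (length(cands) == 0L) return(NULL)
  rank <- c(complete = 1L, five_prime_partial = 2L,
            three_prime_partial = 3L, internal = 4L)
  ord <- order(-vapply(cands, `[[`, 0L, "length"),
               rank[vapply(cands, `[[`, "", "completeness")],
               vapply(cands, `[[`, 0L, "start"))
  cands[[ord[1L]]]
}

#' Intrinsic coding-potential score
#'
#' A documented logistic combination of ORF coverage (ORF length over
#' transcript length) and predicted protein length:
#' `score = 1 / (1 + exp(-(4 * coverage + 0.02 * protein_aa - 3)))`,
#' and exactly 0 when no ORF was found. A complete ORF covering a whole
#' transcript of typical mRNA length scores close to 1; the short, sparse
#' ORFs of noncoding transcripts stay below 0.5.
#'
#' @param sequence Transcript DNA string.
#' @param orf Result of [find_best_orf()] (or `NULL`).
#' @return Score in `[0, 1]`.
#' @export
coding_score <- function(sequence, orf) {
  if (is.null(orf)) return(0)
  coverage <- orf$length / nchar(sequence)
  1 / (1 + exp(-(4 * coverage + 0.02 * orf$protein_length - 3)))
}

#' Predict ORFs for a set of isoforms
#' @param isoforms List of [aligned_isoform()]s.
#' @param genome Named character vector of chromosome sequences.
#' @param min_aa Minimum protein length (aa) for [find_best_orf()]; the
#'   table also records the best ORF of any length for lncRNA filtering.
#' @return Data frame with `isoform_id`, `transcript_length`, `orf_start`,
#'   `orf_end`, `orf_length`, `completeness`, `protein_length`,
#'   `max_orf_aa`, `coding_score`.
#' @export
predict_orfs <- function(isoforms, genome, min_aa = 100L) {
  rows <- lapply(isoforms, function(iso) {
    s <- tm_sequence(iso$model, genome)
    best_any <- find_best_orf(s, min_aa = 1L)
    best <- find_best_orf(s, min_aa = min_aa)
    data.frame(
      isoform_id = iso$isoform_id, transcript_length = nchar(s),
      orf_start = if (is.null(best)) NA_integer_ else best$start,
      orf_end = if (is.null(best)) NA_integer_ else best$end,
      orf_length = if (is.null(best)) NA_integer_ else best$length,
      completeness = if (is.null(best)) NA_character_ else best$completeness,
      protein_length = if (is.null(best)) NA_integer_ else best$protein_length,
      max_orf_aa = if (is.null(best_any)) 0L else best_any$protein_length,
      coding_score = coding_score(s, best_any),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tally ORF completeness classes
#' @param orfs Data frame from [predict_orfs()].
#' @return Named counts: with_orf, complete, five_prime_partial,
#'   three_prime_partial, internal, none.
#' @export
tally_orf_classes <- function(orfs) {
  cl <- factor(orfs$completeness,
               levels = c("complete", "five_prime_partial",
                          "three_prime_partial", "internal"))
  c(with_orf = sum(!is.na(orfs$completeness)), table(cl),
    none = sum(is.na(orfs$completeness)))
}

#' Call known and novel lncRNAs
#'
#' Known lncRNAs are isoforms matching (FSM/ISM) a reference transcript of
#' lncRNA biotype. Isoforms assigned to novel-gene clusters are candidate
#' novel lncRNAs when they pass the length filter (> `min_length` nt),
#' lack a significant ORF (< `orf_aa_threshold` aa) and score below
#' `score_threshold` on coding potential; isoforms with a significant ORF
#' are called coding, everything else undetermined.
#'
#' @param classifications Data frame from [classify_isoforms()].
#' @param orfs Data frame from [predict_orfs()].
#' @param annotation Annotation list (for reference biotypes).
#' @param min_length Minimum lncRNA length in nt (default 200; the filter
#'   requires strictly greater).
#' @param orf_aa_threshold Significant-ORF bound in aa (default 100).
#' @param score_threshold Coding-potential bound (default 0.5).
#' @return Data frame with `isoform_id`, `status` (`known_lncRNA`,
#'   `novel_lncRNA`, `coding`, `undetermined`), `transcript_length`,
#'   `max_orf_aa`, `coding_score`.
#' @export
call_lncrnas <- function(classifications, orfs, annotation,
                         min_length = 200L, orf_aa_threshold = 100L,
                         score_threshold = 0.5) {
  lnc_tx <- vapply(Filter(function(t) t$biotype == "lncRNA", annotation),
                   function(t) t$transcript_id, "")
  novel_cat <- c("Intergenic", "Antisense", "Genic_Intron")
  rows <- lapply(seq_len(nrow(classifications)), function(i) {
    cl <- classifications[i, ]
    o <- orfs[orfs$isoform_id == cl$isoform_id, ]
    status <- if (cl$category %in% c("FSM", "ISM") &&
                  !is.na(cl$associated_transcript) &&
                  cl$associated_transcript %in% lnc_tx) {
      "known_lncRNA"
    } else if (o$max_orf_aa >= orf_aa_threshold) {
      "coding"
    } else if (cl$category %in% novel_cat && o$transcript_length > min_length &&
               o$coding_score < score_threshold) {
      "novel_lncRNA"
    } else {
      "undetermined"
    }
    data.frame(isoform_id = cl$isoform_id, status = status,
               transcript_length = o$transcript_length,
               max_orf_aa = o$max_orf_aa, coding_score = o$coding_score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
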