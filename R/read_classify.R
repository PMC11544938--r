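#' Classify a long read by terminal primers and poly(A)
#'
#' A read is full-length iff the 5' primer occurs (exact match) within the
#' first `window` bases and the 3' primer within the last `window` bases;
#' a full-length read is chimeric iff an additional primer copy occurs
#' strictly inside the insert. The poly(A) flag requires at least
#' `polya_min` trailing adenines immediately before the 3' primer, allowing
#' at most one non-A per 10 scanned bases. The insert is the sequence
#' between the primers with the poly(A) tract removed; non-full-length
#' reads carry no insert. Full-length status is decided by the primers
#' alone — full-length non-chimeric (FLNC) reads without a poly(A) tract
#' exist and keep their category.
#'
#' @param sequence Read sequence (character scalar), or a list/one-row data
#'   frame with `read_id` and `sequence`.
#' @param primer5,primer3 Primer sequences (non-empty, distinct).
#' @param polya_min Minimum poly(A) tract length (default 20).
#' @param window Terminal search window in bases (default 100).
#' @param read_id Identifier attached to the result.
#' @return List with `read_id`, `category` (`FLNC`, `FL_chimeric`,
#'   `non_full_length`), `has_polyA` (NA for non-full-length), `insert`
#'   (NA for non-full-length).
#' @export
classify_read <- function(sequence, primer5 = PRIMER5, primer3 = PRIMER3,
                          polya_min = 20L, window = 100L, read_id = NA_character_) {
  if (is.list(sequence)) {
    read_id <- sequence$read_id
    sequence <- sequence$sequence
  }
  if (is.na(sequence) || !nzchar(sequence)) stop("validation error: empty read")
  if (!nzchar(primer5) || !nzchar(primer3) || primer5 == primer3) {
    stop("validation error: primers must be non-empty and distinct")
  }
  len <- nchar(sequence)
  p5_hits <- find_all(sequence, primer5)
  p3_hits <- find_all(sequence, primer3)
  p5 <- p5_hits[p5_hits <= window - nchar(primer5) + 1L][1L]
  p3_ok <- p3_hits[p3_hits + nchar(primer3) - 1L >= len - window + 1L]
  p3 <- if (length(p3_ok)) p3_ok[length(p3_ok)] else NA_integer_

  if (is.na(p5) || is.na(p3) || p3 <= p5 + nchar(primer5)) {
    return(list(read_id = read_id, category = "non_full_length",
                has_polyA = NA, insert = NA_character_))
  }
  ins_start <- p5 + nchar(primer5)
  ins_end <- p3 - 1L
  internal <- c(p5_hits[p5_hits > ins_start & p5_hits + nchar(primer5) - 1L <= ins_end],
                p3_hits[p3_hits > ins_start & p3_hits + nchar(primer3) - 1L <= ins_end])
  category <- if (length(internal)) "FL_chimeric" else "FLNC"

  tail_len <- polya_tail_length(sequence, ins_end)
  has_polyA <- tail_len >= polya_min
  insert_end <- if (has_polyA) ins_end - tail_len else ins_end
  insert <- if (insert_end >= ins_start) substr(sequence, ins_start, insert_end) else ""
  list(read_id = read_id, category = category, has_polyA = has_polyA,
       insert = insert)
}

# all start positions (1-based) of exact occurrences of pat in s
find_all <- function(s, pat) {
  hits <- gregexpr(pat, s, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

# length of the maximal A-tract ending at position `end`, allowing at most
# one non-A per 10 scanned bases; trimmed so the tract starts and ends on A
polya_tail_length <- function(sequence, end) {
  if (end < 1L) return(0L)
  chars <- strsplit(substr(sequence, 1L, end), "")[[1L]]
  scanned <- 0L
  non_a <- 0L
  best <- 0L
  for (i in seq(end, 1L)) {
    scanned <- scanned + 1L
    if (chars[i] != "A") {
      non_a <- non_a + 1L
      if (non_a * 10L > scanned) break
    } else {
      best <- scanned
    }
  }
  best
}

#' Classify a table of reads
#' @param reads Data frame with `read_id` and `sequence` (e.g. from
#'   [simulate_long_reads()] or [read_reads_fastq()]).
#' @inheritParams classify_read
#' @return Data frame with `read_id`, `category`, `has_polyA`,
#'   `insert_length`.
#' @export
classify_reads <- function(reads, primer5 = PRIMER5, primer3 = PRIMER3,
                           polya_min = 20L, window = 100L) {
  res <- lapply(seq_len(nrow(reads)), function(i) {
    cl <- classify_read(reads$sequence[i], primer5, primer3, polya_min, window,
                        read_id = reads$read_id[i])
    data.frame(read_id = cl$read_id, category = cl$category,
               has_polyA = cl$has_polyA,
               insert_length = if (is.na(cl$insert)) NA_integer_ else nchar(cl$insert),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Summary statistics of a set of reads of insert
#'
#' @param reads Data frame with `sequence` (or `length`), `quality`,
#'   `n_passes`.
#' @return List with `n_reads`, `total_bases`, `mean_length` (rounded to
#'   the nearest integer), `mean_quality` and `mean_passes` (2 decimals).
#' @export
summarize_rois <- function(reads) {
  if (is.null(reads) || nrow(reads) == 0L) stop("validation error: no reads to summarize")
  lens <- if ("length" %in% names(reads)) reads$length else nchar(reads$sequence)
  total <- sum(as.numeric(lens))
  list(n_reads = nrow(reads), total_bases = total,
       mean_length = round(total / nrow(reads)),
       mean_quality = round(mean(reads$quality), 2L),
       mean_passes = round(mean(reads$n_passes), 2L))
}

#' Tally read classifications
#'
#' @param classifications Data frame from [classify_reads()].
#' @return Named list of counts: `FLNC`, `FL_chimeric`, `non_full_length`,
#'   `FLNC_with_polyA`, `FLNC_without_polyA`, `total`. The three categories
#'   always sum to `total` and the two poly(A) splits to `FLNC`.
#' @export
tally_classifications <- function(classifications) {
  cat_counts <- table(factor(classifications$category,
                             levels = c("FLNC", "FL_chimeric", "non_full_length")))
  flnc <- classifications$category == "FLNC"
  list(FLNC = as.integer(cat_counts[["FLNC"]]),
       FL_chimeric = as.integer(cat_counts[["FL_chimeric"]]),
       non_full_length = as.integer(cat_counts[["non_full_length"]]),
       FLNC_with_polyA = sum(flnc & classifications$has_polyA %in% TRUE),
       FLNC_without_polyA = sum(flnc & classifications$has_polyA %in% FALSE),
       total = nrow(classifications))
}
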