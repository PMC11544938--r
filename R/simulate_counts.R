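#' Simulate per-event inclusion/skipping transcript counts
#'
#' For one event with true inclusion level `phi`, draws the number of
#' inclusion *transcripts* `X ~ Binomial(n, phi)` among `n` informative
#' molecules. Each inclusion molecule spans every one of the event's `LI`
#' inclusion junctions and each skipping molecule its `LS` skipping
#' junctions, so the junction-read totals are `I = LI * X` and
#' `S = LS * (n - X)` and the inclusion statistic
#' `(I/LI) / (I/LI + S/LS) = X/n` is an unbiased estimate of `phi`.
#'
#' @param phi True inclusion level in `[0, 1]`.
#' @param n Number of informative molecules.
#' @param LI,LS Inclusion/skipping junction multiplicities (>= 1).
#' @return List with `I`, `S`, `X`.
#' @export
simulate_event_counts <- function(phi, n, LI = 1L, LS = 1L) {
  if (is.na(phi) || phi < 0 || phi > 1) stop("validation error: phi must lie in [0, 1]")
  if (LI < 1L || LS < 1L) stop("validation error: LI and LS must be >= 1")
  X <- stats::rbinom(1L, n, phi)
  list(I = as.integer(LI) * X, S = as.integer(LS) * (n - X), X = X)
}

#' Simulate two-condition junction-count tables
#'
#' For every planted AS event, draws inclusion/skipping junction counts per
#' condition from the binomial model of [simulate_event_counts()] at the
#' event's true condition-specific inclusion levels. The returned table has
#' one row per (event, junction, condition) with `role` either `inclusion`
#' or `skipping`; for intron retention the inclusion row is the retained
#' intron body (`body:donor-acceptor`) counted from reads overlapping it.
#'
#' @param truth A `truth_set` with non-empty `planted_events`.
#' @param config A [sim_config()]; `reads_per_condition` molecules are
#'   allocated to each event's gene and condition.
#' @return Data frame with `gene_id`, `event_id`, `chrom`, `junction`,
#'   `condition`, `count`, `role`.
#' @export
simulate_junction_counts <- function(truth, config) {
  ev <- truth$planted_events
  if (is.null(ev) || nrow(ev) == 0L) {
    stop("validation error: no planted events to simulate counts for")
  }
  if (any(ev$phi_ck < 0 | ev$phi_ck > 1 | ev$phi_w < 0 | ev$phi_w > 1)) {
    stop("validation error: true phi outside [0, 1]")
  }
  set.seed(config$seed + 404L)
  n <- config$reads_per_condition
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    incl <- strsplit(ev$inclusion_junctions[i], ";", fixed = TRUE)[[1L]]
    skip <- strsplit(ev$skipping_junctions[i], ";", fixed = TRUE)[[1L]]
    for (cond in c("CK", "W")) {
      phi <- if (cond == "CK") ev$phi_ck[i] else ev$phi_w[i]
      X <- stats::rbinom(1L, n, phi)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = ev$gene_id[i], event_id = ev$event_id[i], chrom = ev$chrom[i],
        junction = c(incl, skip), condition = cond,
        count = c(rep(X, length(incl)), rep(n - X, length(skip))),
        role = c(rep("inclusion", length(incl)), rep("skipping", length(skip))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Short-read support table for every expressed junction
#'
#' Support for a junction is the summed two-condition abundance of the
#' expressed isoforms containing it; used by [filter_low_confidence()].
#'
#' @param truth A `truth_set`.
#' @return Data frame with `chrom`, `donor`, `acceptor`, `count`.
#' @export
simulate_junction_support <- function(truth) {
  acc <- new.env(parent = emptyenv())
  for (tm in truth$expressed) {
    wt <- truth$abundance$ck[match(tm$transcript_id, truth$abundance$isoform_id)] +
      truth$abundance$w[match(tm$transcript_id, truth$abundance$isoform_id)]
    if (is.na(wt)) wt <- 1
    j <- tm_junctions(tm)
    for (k in seq_len(nrow(j))) {
      key <- sprintf("%s:%d-%d", tm$chrom, j[k, 1L], j[k, 2L])
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + wt
    }
  }
  keys <- sort(ls(acc))
  if (length(keys) == 0L) {
    return(data.frame(chrom = character(0), donor = integer(0),
                      acceptor = integer(0), count = numeric(0)))
  }
  parts <- regmatches(keys, regexec("^(.+):(\\d+)-(\\d+)$", keys))
  data.frame(chrom = vapply(parts, `[`, "", 2L),
             donor = as.integer(vapply(parts, `[`, "", 3L)),
             acceptor = as.integer(vapply(parts, `[`, "", 4L)),
             count = vapply(keys, function(k) acc[[k]], 0), row.names = NULL,
             stringsAsFactors = FALSE)
}
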