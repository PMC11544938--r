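#' @title Toy genome and truth-set generator
#' @description Internal world builder shared by [build_toy_genome()] and
#'   [build_truth_set()]. Everything is derived deterministically from the
#'   config seed so the two entry points always agree.
#' @noRd
NULL

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1L, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

# 12-mer with a stop codon in every reading frame (offsets 0, 4, 8)
STOP_BLOCK <- "TAACTAACTAAC"

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# transcript sequence with a planted complete ORF: 60 nt 5' UTR, ATG,
# sense codons, TAA stop, random 3' UTR
design_coding_seq <- function(len) {
  utr5 <- 60L
  orf_codons <- max(3L, (len - utr5 - 40L) %/% 3L)
  orf <- paste0("ATG", paste(sample(SENSE_CODONS, orf_codons - 2L, replace = TRUE),
                             collapse = ""), "TAA")
  rest <- len - utr5 - nchar(orf)
  paste0(random_dna(utr5), orf, random_dna(rest))
}

# transcript sequence with stop codons every <= 120 nt in all three frames,
# so no ORF can reach the significance threshold
design_lnc_seq <- function(len) {
  s <- random_dna(len)
  pos <- seq(1L, max(1L, len - nchar(STOP_BLOCK)), by = 120L)
  for (p in pos) substr(s, p, p + nchar(STOP_BLOCK) - 1L) <- STOP_BLOCK
  s
}

# write a transcript-orientation sequence into chromosome coordinates
paint_transcript_seq <- function(chrom_seq, tm, tseq) {
  widths <- tm$exons[, 2L] - tm$exons[, 1L]
  stopifnot(nchar(tseq) == sum(widths))
  n <- nrow(tm$exons)
  ord <- if (tm$strand == "+") seq_len(n) else rev(seq_len(n))
  off <- 0L
  for (i in ord) {
    chunk <- substr(tseq, off + 1L, off + widths[i])
    if (tm$strand == "-") chunk <- revcomp_dna(chunk)
    substr(chrom_seq, tm$exons[i, 1L] + 1L, tm$exons[i, 2L]) <- chunk
    off <- off + widths[i]
  }
  chrom_seq
}

EVENT_TYPES <- c("exon_skipping", "intron_retention", "alt_5prime", "alt_3prime")

# build the second isoform of an event gene and describe the event
plant_event <- function(exons, strand, type, shift = 30L) {
  n <- nrow(exons)
  stopifnot(n >= 4L)
  if (type == "exon_skipping") {
    iso2 <- exons[-2L, , drop = FALSE]
    list(exons2 = iso2,
         coordinates = sprintf("%d-%d", exons[2L, 1L], exons[2L, 2L]),
         inclusion = sprintf("%d-%d", c(exons[1L, 2L], exons[2L, 2L]),
                             c(exons[2L, 1L], exons[3L, 1L])),
         skipping = sprintf("%d-%d", exons[1L, 2L], exons[3L, 1L]),
         LI = 2L, LS = 1L, inclusion_isoform = 1L)
  } else if (type == "intron_retention") {
    iso2 <- rbind(exons[1L, ], c(exons[2L, 1L], exons[3L, 2L]))
    if (n > 3L) iso2 <- rbind(iso2, exons[4:n, , drop = FALSE])
    list(exons2 = iso2,
         coordinates = sprintf("%d-%d", exons[2L, 2L], exons[3L, 1L]),
         inclusion = sprintf("body:%d-%d", exons[2L, 2L], exons[3L, 1L]),
         skipping = sprintf("%d-%d", exons[2L, 2L], exons[3L, 1L]),
         LI = 1L, LS = 1L, inclusion_isoform = 2L)
  } else {
    # an alternative donor-side (genomic-left) shift gives alt-5' on "+"
    # and alt-3' on "-"; an acceptor-side shift gives the opposite
    donor_side <- (type == "alt_5prime") == (strand == "+")
    iso2 <- exons
    if (donor_side) {
      iso2[2L, 2L] <- iso2[2L, 2L] - shift
      j_incl <- sprintf("%d-%d", exons[2L, 2L], exons[3L, 1L])
      j_alt <- sprintf("%d-%d", iso2[2L, 2L], exons[3L, 1L])
    } else {
      iso2[3L, 1L] <- iso2[3L, 1L] + shift
      j_incl <- sprintf("%d-%d", exons[2L, 2L], exons[3L, 1L])
      j_alt <- sprintf("%d-%d", exons[2L, 2L], iso2[3L, 1L])
    }
    list(exons2 = iso2,
         coordinates = sprintf("%s|%s", j_incl, j_alt),
         inclusion = j_incl, skipping = j_alt,
         LI = 1L, LS = 1L, inclusion_isoform = 1L)
  }
}

# deterministic single pass that lays out loci, builds isoforms, plants
# events/fusions/APA sites and paints designed sequences into the genome
build_world <- function(config) {
  validate_sim_config(config)
  n_events <- length(config$delta_phi_effects)
  if (n_events > 0L && config$n_genes < n_events + 2L * config$n_fusions) {
    stop("configuration error: n_genes must be >= length(delta_phi_effects) + 2 * n_fusions")
  }
  set.seed(config$seed)

  kinds <- c(rep("coding", config$n_genes),
             rep("lnc_annot", config$n_annotated_lncrnas),
             rep("novel_coding", config$n_novel_genes),
             rep("novel_lnc", config$n_lncrnas))
  n_loci <- length(kinds)
  gene_ids <- character(n_loci)
  gene_ids[kinds == "coding"] <- sprintf("G%03d", seq_len(config$n_genes))
  gene_ids[kinds == "lnc_annot"] <- sprintf("LNCA%d", seq_len(config$n_annotated_lncrnas))
  gene_ids[kinds == "novel_coding"] <- sprintf("NOVG%d", seq_len(config$n_novel_genes))
  gene_ids[kinds == "novel_lnc"] <- sprintf("NLNC%d", seq_len(config$n_lncrnas))

  chroms <- rep(c("chr1", "chr2"), length.out = n_loci)
  # fusion partner pairs: odd pairs intra-chromosomal, even pairs inter-
  if (config$n_fusions > 0L) {
    for (f in seq_len(config$n_fusions)) {
      a <- n_events + 2L * f - 1L
      b <- n_events + 2L * f
      chroms[a] <- "chr1"
      chroms[b] <- if (f %% 2L == 1L) "chr1" else "chr2"
    }
  }
  strands <- rep(c("+", "-"), length.out = n_loci)

  event_types <- if (n_events > 0L) rep(EVENT_TYPES, length.out = n_events) else character(0)

  cursor <- c(chr1 = 5000L, chr2 = 5000L)
  loci <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    kind <- kinds[i]
    lnc <- kind %in% c("lnc_annot", "novel_lnc")
    n_ex <- sample(seq(config$exons_per_gene[1L], config$exons_per_gene[2L]), 1L)
    if (kind == "coding" && i <= n_events) n_ex <- max(n_ex, 4L)
    if (kind == "novel_coding") n_ex <- max(n_ex, 4L)
    if (lnc) n_ex <- if (kinds[i] == "lnc_annot" && gene_ids[i] == "LNCA2") 1L else 2L
    widths <- sample(150:300, n_ex, replace = TRUE)
    introns <- if (n_ex > 1L) sample(300:800, n_ex - 1L, replace = TRUE) else integer(0)
    start <- cursor[[chroms[i]]]
    starts <- start + cumsum(c(0L, widths[-n_ex] + introns))
    exons <- cbind(starts, starts + widths)
    cursor[[chroms[i]]] <- exons[n_ex, 2L] + 2500L
    loci[[i]] <- list(gene_id = gene_ids[i], kind = kind, chrom = chroms[i],
                      strand = strands[i], exons = exons,
                      event_type = if (kind == "coding" && i <= n_events) event_types[i] else NA_character_)
  }
  chrom_len <- cursor + 60000L

  # isoforms, events, truth abundances ------------------------------------
  annotation <- list()
  expressed <- list()
  abund <- list()
  events <- list()
  phi_ck_base <- 0.65
  ev_i <- 0L
  for (i in seq_len(n_loci)) {
    loc <- loci[[i]]
    biotype <- if (loc$kind %in% c("lnc_annot", "novel_lnc")) "lncRNA" else "coding"
    t1_id <- paste0(loc$gene_id, ".t1")
    t1 <- transcript_model(t1_id, loc$gene_id, loc$chrom, loc$strand, loc$exons,
                           biotype = biotype)
    known <- loc$kind %in% c("coding", "lnc_annot")
    if (known) annotation <- c(annotation, list(t1))
    expressed <- c(expressed, list(t1))
    w1 <- 100L

    if (!is.na(loc$event_type)) {
      ev_i <- ev_i + 1L
      pe <- plant_event(loc$exons, loc$strand, loc$event_type)
      t2 <- transcript_model(paste0(loc$gene_id, ".t2"), loc$gene_id, loc$chrom,
                             loc$strand, pe$exons2, biotype = biotype)
      annotation <- c(annotation, list(t2))
      expressed <- c(expressed, list(t2))
      delta <- config$delta_phi_effects[ev_i]
      phi_ck <- phi_ck_base
      phi_w <- max(0, min(1, phi_ck_base - delta))
      incl_id <- if (pe$inclusion_isoform == 1L) t1_id else t2$transcript_id
      skip_id <- if (pe$inclusion_isoform == 1L) t2$transcript_id else t1_id
      events[[ev_i]] <- data.frame(
        event_id = sprintf("EV%03d", ev_i), gene_id = loc$gene_id,
        chrom = loc$chrom, strand = loc$strand, event_type = loc$event_type,
        coordinates = pe$coordinates,
        inclusion_junctions = paste(pe$inclusion, collapse = ";"),
        skipping_junctions = paste(pe$skipping, collapse = ";"),
        LI = pe$LI, LS = pe$LS, phi_ck = phi_ck, phi_w = phi_w,
        inclusion_isoform = incl_id, skipping_isoform = skip_id,
        stringsAsFactors = FALSE)
      w1 <- round(100 * mean(c(phi_ck, phi_w)))
      w2 <- 100L - w1
      if (pe$inclusion_isoform == 2L) { tmp <- w1; w1 <- w2; w2 <- tmp }
      abund[[length(abund) + 1L]] <- data.frame(
        isoform_id = t2$transcript_id, gene_id = loc$gene_id, known = TRUE,
        ck = w2, w = w2, stringsAsFactors = FALSE)
    } else if (loc$kind == "novel_coding" && nrow(loc$exons) >= 4L) {
      # second, exon-skipping isoform so novel loci exercise overlap clustering
      t2 <- transcript_model(paste0(loc$gene_id, ".t2"), loc$gene_id, loc$chrom,
                             loc$strand, loc$exons[-2L, , drop = FALSE],
                             biotype = biotype)
      expressed <- c(expressed, list(t2))
      abund[[length(abund) + 1L]] <- data.frame(
        isoform_id = t2$transcript_id, gene_id = loc$gene_id, known = FALSE,
        ck = 40L, w = 40L, stringsAsFactors = FALSE)
    }
    abund[[length(abund) + 1L]] <- data.frame(
      isoform_id = t1_id, gene_id = loc$gene_id, known = known,
      ck = w1, w = w1, stringsAsFactors = FALSE)
  }
  planted_events <- if (length(events)) do.call(rbind, events) else
    data.frame(event_id = character(0))
  abundance <- do.call(rbind, abund)
  abundance <- abundance[order(abundance$isoform_id), ]
  rownames(abundance) <- NULL

  # genome sequences -------------------------------------------------------
  genome <- vapply(names(chrom_len), function(ch) random_dna(chrom_len[[ch]]), "")
  for (i in seq_len(n_loci)) {
    loc <- loci[[i]]
    t1 <- expressed[[match(paste0(loc$gene_id, ".t1"),
                           vapply(expressed, function(t) t$transcript_id, ""))]]
    len <- tm_length(t1)
    tseq <- if (t1$biotype == "lncRNA") design_lnc_seq(len) else design_coding_seq(len)
    genome[[loc$chrom]] <- paint_transcript_seq(genome[[loc$chrom]], t1, tseq)
  }

  # fusions -----------------------------------------------------------------
  fusions <- list()
  if (config$n_fusions > 0L) {
    for (f in seq_len(config$n_fusions)) {
      la <- loci[[n_events + 2L * f - 1L]]
      lb <- loci[[n_events + 2L * f]]
      na_half <- max(1L, nrow(la$exons) %/% 2L)
      nb_first <- nrow(lb$exons) - max(1L, nrow(lb$exons) %/% 2L) + 1L
      ex_a <- la$exons[seq_len(na_half), , drop = FALSE]
      ex_b <- lb$exons[nb_first:nrow(lb$exons), , drop = FALSE]
      fusions[[f]] <- data.frame(
        fusion_id = sprintf("FUS%d", f),
        gene_a = la$gene_id, gene_b = lb$gene_id,
        chrom_a = la$chrom, chrom_b = lb$chrom,
        start_a = ex_a[1L, 1L], breakpoint_a = ex_a[nrow(ex_a), 2L],
        breakpoint_b = ex_b[1L, 1L], end_b = ex_b[nrow(ex_b), 2L],
        len_a = sum(ex_a[, 2L] - ex_a[, 1L]),
        len_b = sum(ex_b[, 2L] - ex_b[, 1L]),
        same_chromosome = la$chrom == lb$chrom,
        support = 3L, stringsAsFactors = FALSE)
    }
  }
  planted_fusions <- if (length(fusions)) do.call(rbind, fusions) else
    data.frame(fusion_id = character(0))

  # APA sites ---------------------------------------------------------------
  apa_pattern <- c(1L, 2L, 1L, 3L, 2L, 4L, 1L, 5L, 2L, 6L, 3L, 1L)
  n_apa <- min(config$n_genes, length(apa_pattern))
  apa_rows <- list()
  apa_truth <- list()
  for (g in seq_len(n_apa)) {
    loc <- loci[[g]]
    n_sites <- apa_pattern[g]
    base <- if (loc$strand == "+") loc$exons[nrow(loc$exons), 2L] else loc$exons[1L, 1L]
    dirn <- if (loc$strand == "+") 1L else -1L
    primary <- base + dirn * 25L * (seq_len(n_sites) - 1L)
    support <- sample(5:50, n_sites, replace = TRUE)
    rows <- data.frame(gene_id = loc$gene_id, strand = loc$strand,
                       position = primary, support = support,
                       stringsAsFactors = FALSE)
    if (n_sites >= 2L) {
      # satellite within 15 bp of the first site: must merge into its cluster
      rows <- rbind(rows, data.frame(gene_id = loc$gene_id, strand = loc$strand,
                                     position = primary[1L] + dirn * sample(3:10, 1L),
                                     support = sample(1:10, 1L),
                                     stringsAsFactors = FALSE))
    }
    # zero-support decoy: must be dropped before clustering
    rows <- rbind(rows, data.frame(gene_id = loc$gene_id, strand = loc$strand,
                                   position = base - dirn * 200L, support = 0L,
                                   stringsAsFactors = FALSE))
    apa_rows[[g]] <- rows
    apa_truth[[g]] <- data.frame(gene_id = loc$gene_id, n_sites = n_sites,
                                 stringsAsFactors = FALSE)
  }
  planted_apa <- if (length(apa_rows)) do.call(rbind, apa_rows) else
    data.frame(gene_id = character(0))
  apa_site_truth <- if (length(apa_truth)) do.call(rbind, apa_truth) else
    data.frame(gene_id = character(0))
  rownames(planted_apa) <- rownames(apa_site_truth) <- NULL

  gene_table <- do.call(rbind, lapply(loci, function(loc) {
    data.frame(gene_id = loc$gene_id, kind = loc$kind, chrom = loc$chrom,
               strand = loc$strand, start = loc$exons[1L, 1L],
               end = loc$exons[nrow(loc$exons), 2L], stringsAsFactors = FALSE)
  }))

  structure(list(genome = genome, annotation = annotation, expressed = expressed,
                 abundance = abundance, planted_events = planted_events,
                 planted_fusions = planted_fusions, planted_apa = planted_apa,
                 apa_site_truth = apa_site_truth, gene_table = gene_table,
                 config = config),
            class = "truth_set")
}

#' Build the toy genome and reference annotation
#'
#' Generates a two-chromosome genome with multi-isoform coding genes on both
#' strands (hosting planted exon-skipping, intron-retention, alternative-5'
#' and alternative-3' variants), annotated lncRNAs, and >= 2 kb intergenic
#' gaps. Unannotated (novel) loci exist in the full truth set but are absent
#' from the returned annotation.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector) and `annotation`
#'   (list of [transcript_model()]s).
#' @export
build_toy_genome <- function(config) {
  world <- build_world(config)
  list(genome = world$genome, annotation = world$annotation)
}

#' Build the full synthetic truth set
#'
#' @param config A [sim_config()].
#' @return A `truth_set`: genome, annotation (known transcripts), expressed
#'   isoforms (including novel loci), per-condition abundances, planted AS
#'   events with true inclusion levels, planted fusions and poly(A) sites,
#'   and the gene table.
#' @export
build_truth_set <- function(config) build_world(config)

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf(paste0("<truth_set> %d chromosome(s), %d annotated transcripts, ",
                     "%d expressed isoforms, %d AS events, %d fusions\n"),
              length(x$genome), length(x$annotation), length(x$expressed),
              nrow(x$planted_events), nrow(x$planted_fusions)))
  invisible(x)
}
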