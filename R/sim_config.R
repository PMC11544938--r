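#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data generator:
#' a two-condition (CK day-0 control vs W day-5 wounded) skin transcriptome
#' profiled with full-length long reads plus short-read junction counts.
#' Defaults are the conditions every downstream stage is exercised under;
#' see the methods vignette for the rationale behind each value.
#'
#' @param seed Integer RNG seed; the same config (including seed) produces
#'   byte-identical FASTA/GTF/FASTQ/TSV outputs.
#' @param n_genes Number of annotated multi-isoform coding genes (>= 8 +
#'   2 * `n_fusions` so every planted event type and fusion has a host).
#' @param n_novel_genes Expressed coding loci absent from the annotation.
#' @param n_lncrnas Expressed novel lncRNA loci (stop-codon-rich, no
#'   significant ORF, > 200 nt).
#' @param n_annotated_lncrnas Annotated lncRNA genes (recovered as "known").
#' @param n_fusions Planted fusion transcripts; odd indices intra-, even
#'   inter-chromosomal.
#' @param exons_per_gene Length-2 integer range of exon counts per gene.
#' @param chimera_rate,non_full_length_rate,polya_absent_rate Probabilities
#'   in `[0, 1]` of a long read being full-length chimeric, non-full-length,
#'   or (for full-length reads) lacking the poly(A) tract.
#' @param n_long_reads Total simulated long reads.
#' @param reads_per_condition Short-read transcripts sampled per gene and
#'   condition for junction counts.
#' @param delta_phi_effects Target |delta phi| values recycled across the
#'   planted AS events (CK inclusion level 0.65; W = 0.65 - effect).
#' @param n_single_gene_alignments Background single-gene split-alignment
#'   records used to probe fusion-detection specificity.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 24L,
                       n_novel_genes = 4L,
                       n_lncrnas = 3L,
                       n_annotated_lncrnas = 2L,
                       n_fusions = 2L,
                       exons_per_gene = c(3L, 8L),
                       chimera_rate = 0.10,
                       non_full_length_rate = 0.08,
                       polya_absent_rate = 0.01,
                       n_long_reads = 5000L,
                       reads_per_condition = 500L,
                       delta_phi_effects = c(0.3, 0.3, 0.3, 0.3, 0, 0, 0, 0),
                       n_single_gene_alignments = 5000L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_novel_genes = as.integer(n_novel_genes),
              n_lncrnas = as.integer(n_lncrnas),
              n_annotated_lncrnas = as.integer(n_annotated_lncrnas),
              n_fusions = as.integer(n_fusions),
              exons_per_gene = as.integer(exons_per_gene),
              chimera_rate = chimera_rate,
              non_full_length_rate = non_full_length_rate,
              polya_absent_rate = polya_absent_rate,
              n_long_reads = as.integer(n_long_reads),
              reads_per_condition = as.integer(reads_per_condition),
              delta_phi_effects = as.numeric(delta_phi_effects),
              n_single_gene_alignments = as.integer(n_single_gene_alignments))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(chimera = cfg$chimera_rate, non_fl = cfg$non_full_length_rate,
             polya_absent = cfg$polya_absent_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("sim_config: probabilities must lie in [0, 1]")
  }
  if (cfg$chimera_rate + cfg$non_full_length_rate > 1) {
    stop("sim_config: chimera_rate + non_full_length_rate must not exceed 1")
  }
  if (is.na(cfg$n_genes) || cfg$n_genes < 1L) stop("sim_config: n_genes must be >= 1")
  if (cfg$n_novel_genes < 0L || cfg$n_lncrnas < 0L || cfg$n_fusions < 0L) {
    stop("sim_config: counts must be non-negative")
  }
  if (length(cfg$exons_per_gene) != 2L || cfg$exons_per_gene[1L] < 2L ||
      cfg$exons_per_gene[2L] < cfg$exons_per_gene[1L]) {
    stop("sim_config: exons_per_gene must be an increasing range with minimum >= 2")
  }
  if (cfg$n_long_reads < 1L || cfg$reads_per_condition < 1L) {
    stop("sim_config: read counts must be positive")
  }
  if (any(cfg$delta_phi_effects < 0 | cfg$delta_phi_effects > 1)) {
    stop("sim_config: delta_phi_effects must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Write / read a simulation config as YAML
#' @param config A [sim_config()].
#' @param path File path.
#' @return `path` (write) or a `sim_config` (read).
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}
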