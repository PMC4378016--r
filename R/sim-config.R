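#' Simulation configuration
#'
#' Builds and validates the parameter set for the synthetic genome/EST
#' generator. Defaults emulate the gene architecture of the *Volvox carteri*
#' nuclear genome: ~4.6 exons per locus, mean intron length 491 bp with a
#' long right tail, and 56% genomic GC content.
#'
#' @param seed integer seed controlling all randomness of a simulation run.
#' @param n_genes number of gene loci to simulate.
#' @param exons_per_gene_mean mean exon count per locus (shifted-Poisson,
#'   minimum 1 exon; genes hosting a planted event are topped up to the
#'   minimum exon count that event type requires).
#' @param exon_length_range length-2 integer vector, uniform range of exon
#'   lengths in bp.
#' @param intron_length_mean target mean intron length in bp (log-normal).
#' @param intron_length_sdlog sdlog of the log-normal intron length law.
#' @param intron_length_range truncation bounds for intron lengths in bp.
#' @param genome_gc target genomic GC fraction.
#' @param intergenic_min,intergenic_max uniform range of intergenic spacer
#'   lengths in bp (>= 500 so loci never merge by construction).
#' @param as_event_rate fraction of genes carrying one planted alternative
#'   splicing event.
#' @param as_type_mix named probability vector over event types
#'   \code{c(IR=, ES=, Alt5=, Alt3=, MXE=)}; must sum to 1.
#' @param alt_shift_range uniform range (bp) of the donor/acceptor shift for
#'   planted Alt5/Alt3 events (>= 3 bp).
#' @param est_count_per_gene ESTs simulated per gene.
#' @param est_length_range uniform range of partial-read lengths in bp.
#' @param est_partial_fraction fraction of ESTs simulated as partial reads;
#'   the remainder are full isoform length.
#' @param est_error_rate per-base substitution probability in ESTs.
#' @param minor_variant_frequency probability that an EST from a gene with a
#'   planted event is drawn from the alternative (second) isoform.
#'
#' @return An object of class \code{"sim_config"} (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 5)
#' cfg$genome_gc
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 50L,
                       exons_per_gene_mean = 4.6,
                       exon_length_range = c(80L, 300L),
                       intron_length_mean = 491,
                       intron_length_sdlog = 0.8,
                       intron_length_range = c(60L, 20000L),
                       genome_gc = 0.56,
                       intergenic_min = 500L,
                       intergenic_max = 1500L,
                       as_event_rate = 0.5,
                       as_type_mix = c(IR = 0.465, ES = 0.095,
                                       Alt5 = 0.179, Alt3 = 0.219,
                                       MXE = 0.042),
                       alt_shift_range = c(6L, 45L),
                       est_count_per_gene = 20L,
                       est_length_range = c(400L, 800L),
                       est_partial_fraction = 0.6,
                       est_error_rate = 0.01,
                       minor_variant_frequency = 0.5) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene_mean = exons_per_gene_mean,
              exon_length_range = as.integer(exon_length_range),
              intron_length_mean = intron_length_mean,
              intron_length_sdlog = intron_length_sdlog,
              intron_length_range = as.integer(intron_length_range),
              genome_gc = genome_gc,
              intergenic_min = as.integer(intergenic_min),
              intergenic_max = as.integer(intergenic_max),
              as_event_rate = as_event_rate,
              as_type_mix = as_type_mix,
              alt_shift_range = as.integer(alt_shift_range),
              est_count_per_gene = as.integer(est_count_per_gene),
              est_length_range = as.integer(est_length_range),
              est_partial_fraction = est_partial_fraction,
              est_error_rate = est_error_rate,
              minor_variant_frequency = minor_variant_frequency)

  probs <- c(cfg$genome_gc, cfg$as_event_rate, cfg$est_partial_fraction,
             cfg$est_error_rate, cfg$minor_variant_frequency, cfg$as_type_mix)
  if (any(probs < 0 | probs > 1)) .stopf("all probabilities must lie in [0, 1]")
  if (abs(sum(cfg$as_type_mix) - 1) > 1e-8)
    .stopf("as_type_mix must sum to 1 (got %g)", sum(cfg$as_type_mix))
  if (!all(names(cfg$as_type_mix) %in% c("IR", "ES", "Alt5", "Alt3", "MXE")))
    .stopf("as_type_mix names must be among IR, ES, Alt5, Alt3, MXE")
  if (cfg$n_genes < 1L) .stopf("n_genes must be >= 1")
  for (rng in list(cfg$exon_length_range, cfg$intron_length_range,
                   cfg$est_length_range, cfg$alt_shift_range)) {
    if (length(rng) != 2L || any(rng <= 0L) || rng[1] > rng[2])
      .stopf("length ranges must be positive length-2 increasing vectors")
  }
  if (cfg$alt_shift_range[1] < 3L)
    .stopf("alt_shift_range minimum must be >= 3 bp")
  if (cfg$intergenic_min < 500L)
    .stopf("intergenic spacers must be >= 500 bp")
  if (cfg$intron_length_range[1] < 40L)
    .stopf("minimum intron length must be >= 40 bp")
  # a planted event must fit: Alt5/Alt3 shifts carve into the intron, so the
  # host intron is drawn at least alt_shift above the minimum length
  if (cfg$intron_length_range[1] + cfg$alt_shift_range[2] >
      cfg$intron_length_range[2])
    .stopf("intron_length_range too narrow to host alt_shift_range shifts")
  if (cfg$exon_length_range[1] < 40L)
    .stopf("exons must be >= 40 bp for the k-mer seeded aligner")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic splicing simulation config\n")
  cat(sprintf("  %d genes, ~%.1f exons/gene, intron mean %g bp, GC %.2f\n",
              x$n_genes, x$exons_per_gene_mean, x$intron_length_mean,
              x$genome_gc))
  cat(sprintf("  AS rate %.2f; mix: %s\n", x$as_event_rate,
              paste(sprintf("%s=%.3f", names(x$as_type_mix), x$as_type_mix),
                    collapse = " ")))
  cat(sprintf("  %d ESTs/gene, %.0f%% partial (%d-%d bp), error %.3f, minor freq %.2f\n",
              x$est_count_per_gene, 100 * x$est_partial_fraction,
              x$est_length_range[1], x$est_length_range[2],
              x$est_error_rate, x$minor_variant_frequency))
  invisible(x)
}

# minimum reference-isoform exon count needed to host each event type
.min_exons_for <- function(type) {
  switch(type, IR = 2L, Alt5 = 2L, Alt3 = 2L, ES = 3L, MXE = 4L,
         .stopf("unknown event type '%s'", type))
}
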