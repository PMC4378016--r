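#' Simulate ESTs from a synthetic genome
#'
#' Draws single-pass cDNA reads (ESTs) from the spliced isoforms of a
#' simulation: a configurable mixture of full-length and partial reads, from
#' both sequencing orientations, with per-base substitution errors. Every
#' read's source isoform, position, orientation and realized error count are
#' recorded so downstream recovery can be scored against ground truth.
#'
#' For genes with a planted event the source isoform is drawn with
#' \code{minor_variant_frequency} for the alternative form; when that
#' frequency is positive, at least one read per alternative is guaranteed so
#' every planted event is observable in principle.
#'
#' @param sim an \code{"as_simulation"} from \code{\link{simulate_genome}}.
#' @param config optional \code{\link{sim_config}}; defaults to the one the
#'   simulation was built with.
#' @return An object of class \code{"sim_ests"}: list with \code{ests}
#'   (named \code{DNAStringSet}) and \code{reads} (data.frame: est_id,
#'   gene_id, isoform_id, iso_start, length, read_strand relative to the
#'   transcript, genome_strand, n_errors).
#' @examples
#' sim <- simulate_genome(sim_config(seed = 5, n_genes = 3))
#' reads <- simulate_ests(sim)
#' head(reads$reads)
#' @export
simulate_ests <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "as_simulation"))
  cfg <- config
  set.seed(cfg$seed + 1L)

  iso_seqs <- isoform_sequences(sim)
  iso_len <- nchar(iso_seqs)
  if (cfg$est_partial_fraction > 0 && cfg$est_length_range[1] > min(iso_len))
    .stopf("est_length_range minimum (%d) exceeds the shortest isoform (%d bp)",
           cfg$est_length_range[1], min(iso_len))

  seqs <- character(0); rows <- vector("list", nrow(sim$genes))
  for (g in seq_len(nrow(sim$genes))) {
    gene <- sim$genes[g, ]
    isos <- names(sim$isoforms[[gene$gene_id]])
    n <- cfg$est_count_per_gene
    if (length(isos) > 1L) {
      lab <- ifelse(stats::runif(n) < cfg$minor_variant_frequency, 2L, 1L)
      if (cfg$minor_variant_frequency > 0) {   # guarantee both alternatives seen
        if (all(lab == 1L)) lab[1L] <- 2L
        if (all(lab == 2L)) lab[1L] <- 1L
      }
    } else lab <- rep(1L, n)

    gene_rows <- vector("list", n)
    for (j in seq_len(n)) {
      iso_id <- isos[lab[j]]
      tx <- iso_seqs[[iso_id]]
      L <- nchar(tx)
      if (stats::runif(1) < cfg$est_partial_fraction) {
        len <- min(L, .sample_int_range(1L, cfg$est_length_range[1],
                                        cfg$est_length_range[2]))
      } else len <- L
      s0 <- if (len < L) sample.int(L - len + 1L, 1L) - 1L else 0L
      read <- substr(tx, s0 + 1L, s0 + len)

      n_err <- 0L
      if (cfg$est_error_rate > 0) {
        hit <- which(stats::runif(len) < cfg$est_error_rate)
        if (length(hit)) {
          rr <- charToRaw(read)
          for (p in hit) {
            alt <- setdiff(c("A", "C", "G", "T"), rawToChar(rr[p]))
            rr[p] <- charToRaw(.sample1(alt))
          }
          read <- rawToChar(rr)
          n_err <- length(hit)
        }
      }
      read_strand <- sample(c("+", "-"), 1L)
      if (read_strand == "-") read <- .revcomp(read)
      est_id <- sprintf("%s_e%03d", gene$gene_id, j)
      seqs[est_id] <- read
      gene_rows[[j]] <- data.frame(
        est_id = est_id, gene_id = gene$gene_id, isoform_id = iso_id,
        iso_start = s0, length = len, read_strand = read_strand,
        genome_strand = if (gene$strand == read_strand) "+" else "-",
        n_errors = n_err, stringsAsFactors = FALSE)
    }
    rows[[g]] <- do.call(rbind, gene_rows)
  }
  ests <- DNAStringSet(seqs)
  out <- list(ests = ests, reads = do.call(rbind, rows))
  class(out) <- "sim_ests"
  out
}

#' @export
print.sim_ests <- function(x, ...) {
  cat(sprintf("%d simulated ESTs, mean length %.0f bp, %.3f%% substituted bases\n",
              length(x$ests), mean(Biostrings::width(x$ests)),
              100 * sum(x$reads$n_errors) / sum(x$reads$length)))
  invisible(x)
}

#' Spliced isoform sequences of a simulation
#'
#' @param sim an \code{"as_simulation"} object.
#' @return Named character vector of spliced transcript sequences in sense
#'   (transcribed) orientation, one per isoform.
#' @export
isoform_sequences <- function(sim) {
  out <- character(0)
  for (g in seq_len(nrow(sim$genes))) {
    gene <- sim$genes[g, ]
    for (iso_id in names(sim$isoforms[[gene$gene_id]])) {
      bl <- sim$isoforms[[gene$gene_id]][[iso_id]]
      s <- paste(vapply(seq_len(nrow(bl)), function(i)
        .gseq(sim$genome, gene$chrom, bl[i, "start"], bl[i, "end"]), ""),
        collapse = "")
      if (gene$strand == "-") s <- .revcomp(s)
      out[iso_id] <- s
    }
  }
  out
}
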