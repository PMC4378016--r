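#' Run the full alternative-splicing discovery pipeline
#'
#' Chains all stages on a genome and a set of ESTs: spliced alignment,
#' best-hit selection, percent-identity filtering, intron calling with
#' canonical GT/AG enforcement, clustering into loci, splice-graph
#' construction, event classification, the support-ratio quality filter,
#' ORF-based localization and a distribution report. Per-stage EST counts
#' are logged so the filtering funnel is visible.
#'
#' @param genome named \code{DNAStringSet} (or path to a FASTA file).
#' @param ests named \code{DNAStringSet} (or path to a FASTA file).
#' @param k,stride seed parameters of \code{\link{spliced_align}}.
#' @param min_intron,max_intron intron length window in bp.
#' @param min_identity percent-identity threshold (inclusive).
#' @param max_support_ratio support-ratio bound of
#'   \code{\link{apply_support_filter}}.
#' @param verbose log per-stage counts via \code{message()}.
#' @return list of class \code{"as_pipeline"}: alignments (filtered),
#'   clusters, graphs, events (filtered, localized), report.
#' @examples
#' cfg <- sim_config(seed = 11, n_genes = 3, est_count_per_gene = 8,
#'                   est_error_rate = 0, est_partial_fraction = 0)
#' sim <- simulate_genome(cfg)
#' reads <- simulate_ests(sim)
#' res <- run_as_pipeline(sim$genome, reads$ests, verbose = FALSE)
#' res$report
#' @export
run_as_pipeline <- function(genome, ests, k = 16L, stride = 4L,
                            min_intron = 40L, max_intron = 25000L,
                            min_identity = 95.0, max_support_ratio = 10.0,
                            verbose = TRUE) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(ests) && length(ests) == 1L && file.exists(ests))
    ests <- Biostrings::readDNAStringSet(ests)
  say <- function(...) if (verbose) message(sprintf(...))

  say("aligning %d ESTs", length(ests))
  aln <- spliced_align(ests, genome, k = k, stride = stride,
                       min_intron = min_intron, max_intron = max_intron)
  say("  %d candidate alignments for %d ESTs", nrow(aln),
      length(unique(aln$est_id)))
  best <- select_best_alignment(aln)
  say("  best hit kept: %d ESTs aligned, %d unaligned", nrow(best),
      length(ests) - nrow(best))
  ident <- filter_identity(best, min_identity)
  say("  identity >= %.1f%%: %d kept, %d removed", min_identity,
      nrow(ident), nrow(best) - nrow(ident))
  called <- call_introns(ident, genome, min_intron = min_intron)
  canon <- drop_noncanonical(called)
  say("  canonical GT/AG: %d kept, %d removed", nrow(canon),
      nrow(called) - nrow(canon))

  clustered <- cluster_alignments(canon)
  say("clustered into %d loci", nrow(clustered$clusters))
  graphs <- build_splice_graphs(clustered)
  n_flagged <- sum(vapply(graphs, `[[`, TRUE, "flagged"))
  if (n_flagged) say("  %d cluster(s) flagged for strand conflict, excluded",
                     n_flagged)

  events <- classify_events(graphs)
  say("detected %d raw events", nrow(events))
  events <- apply_support_filter(events, max_support_ratio)
  say("  support ratio <= %g: %d events kept", max_support_ratio,
      nrow(events))
  events <- localize_events(events, graphs, genome)

  report <- if (length(graphs)) distribution_report(events, graphs) else NULL
  out <- list(alignments = canon, clusters = clustered, graphs = graphs,
              events = events, report = report)
  class(out) <- "as_pipeline"
  out
}

#' @export
print.as_pipeline <- function(x, ...) {
  cat(sprintf("AS pipeline result: %d alignments, %d loci, %d events\n",
              nrow(x$alignments), length(x$graphs), nrow(x$events)))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Score detected events against simulation ground truth
#'
#' Matches detected events to planted events by type, chromosome and exact
#' variable-region coordinates, and reports precision and recall.
#'
#' @param events an \code{as_events} data.frame.
#' @param truth the \code{truth} data.frame of an \code{"as_simulation"}.
#' @return list with \code{precision}, \code{recall}, \code{n_detected},
#'   \code{n_truth}, \code{n_matched}, and logical vectors
#'   \code{truth_found} / \code{event_matched}.
#' @export
evaluate_events <- function(events, truth) {
  type_map <- c(IR = "intron_retention", ES = "exon_skipping",
                Alt5 = "alt5", Alt3 = "alt3", MXE = "mutually_exclusive")
  tkey <- paste(type_map[truth$event_type], truth$chrom, truth$start,
                truth$end)
  ekey <- paste(events$event_type, events$chrom, events$start, events$end)
  truth_found <- tkey %in% ekey
  event_matched <- ekey %in% tkey
  list(precision = if (nrow(events)) mean(event_matched) else NA_real_,
       recall = if (nrow(truth)) mean(truth_found) else NA_real_,
       n_detected = nrow(events), n_truth = nrow(truth),
       n_matched = sum(truth_found),
       truth_found = truth_found, event_matched = event_matched)
}
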