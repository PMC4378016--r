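# Aggregation of classified events into distribution tables and genome-wide
# summary statistics, with counts always reported alongside percentages.

#' Tabulate event types
#'
#' Counts and one-decimal percentages (rounded half-up, as conventionally
#' printed) per event type, with mutually-exclusive and complex events
#' pooled into \code{"other"}. An empty event set yields a zero table with
#' \code{NA} percentages rather than dividing by zero.
#'
#' @param events an \code{as_events} data.frame.
#' @return data.frame with columns type, count, percent.
#' @export
summarize_event_types <- function(events) {
  lv <- c(intron_retention = "intron_retention",
          exon_skipping = "exon_skipping", alt5 = "alt5", alt3 = "alt3")
  cnt <- c(vapply(lv, function(t) sum(events$event_type == t), 0L),
           other = sum(events$event_type %in% c("mutually_exclusive",
                                                "complex")))
  total <- sum(cnt)
  data.frame(type = c(names(lv), "other"),
             count = as.integer(cnt),
             percent = if (total == 0) NA_real_ else
               round_half_up(100 * cnt / total, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tabulate event localizations
#'
#' Percentages are denominated over localized events only (coding/5' UTR/3'
#' UTR); the count of unclassified events and both denominators are
#' reported, since the localizable subset is generally smaller than the
#' full event set.
#'
#' @param events output of \code{\link{localize_events}}.
#' @return data.frame with columns region, count, percent, plus attributes
#'   \code{n_total} and \code{n_localized}.
#' @export
summarize_regions <- function(events) {
  stopifnot("region" %in% names(events))
  regions <- c("coding", "utr5", "utr3")
  cnt <- vapply(regions, function(r) sum(events$region == r), 0L)
  n_loc <- sum(cnt)
  out <- data.frame(region = regions, count = as.integer(cnt),
                    percent = if (n_loc == 0) NA_real_ else
                      round_half_up(100 * cnt / n_loc, 1),
                    stringsAsFactors = FALSE)
  attr(out, "n_total") <- nrow(events)
  attr(out, "n_localized") <- n_loc
  out
}

#' Loci, exons and mean exons per locus
#'
#' Counts exons of each locus's representative transcript (the
#' highest-supported isoform of its splice graph) and reports the mean per
#' locus to one decimal.
#'
#' @param graphs list of \code{splice_graph}s.
#' @return list with \code{loci}, \code{exons} and \code{mean}.
#' @export
exons_per_locus <- function(graphs) {
  if (!length(graphs)) .stopf("no loci: cannot compute exons per locus")
  ex <- vapply(graphs, function(g) nrow(g$isoforms[[1]]$exons), 0L)
  list(loci = length(graphs), exons = sum(ex),
       mean = mean_exons_per_locus(sum(ex), length(graphs)))
}

#' Mean exons per locus from counts
#' @param exon_count,locus_count totals.
#' @return mean to one decimal (half-up).
#' @export
mean_exons_per_locus <- function(exon_count, locus_count) {
  if (locus_count == 0) .stopf("locus count is zero")
  round_half_up(exon_count / locus_count, 1)
}

#' Fraction of genes subject to alternative splicing
#'
#' @param as_gene_count genes with at least one event.
#' @param total_genes total (protein-coding) genes considered.
#' @return percentage to one decimal (half-up).
#' @export
as_gene_fraction <- function(as_gene_count, total_genes) {
  if (!.is_count(as_gene_count) || !.is_count(total_genes))
    .stopf("counts must be non-negative integers")
  if (total_genes == 0) .stopf("total gene count is zero")
  round_half_up(100 * as_gene_count / total_genes, 1)
}

#' Intron length and composition statistics
#'
#' Summarizes all distinct introns of a set of splice graphs (or of a
#' simulation's gene models): mean length, the length vector (for
#' histograms), and the GC fraction of the pooled intronic sequence.
#'
#' @param x list of \code{splice_graph}s or an \code{"as_simulation"}.
#' @param genome named \code{DNAStringSet} (defaults to \code{x$genome} for
#'   simulations).
#' @return list with \code{n}, \code{mean_length}, \code{lengths},
#'   \code{gc_fraction}.
#' @export
intron_stats <- function(x, genome = NULL) {
  if (inherits(x, "as_simulation")) {
    if (is.null(genome)) genome <- x$genome
    rows <- list()
    for (gid in names(x$isoforms)) {
      chrom <- x$genes$chrom[x$genes$gene_id == gid]
      for (bl in x$isoforms[[gid]]) {
        if (nrow(bl) < 2L) next
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = bl[-nrow(bl), "end"], end = bl[-1L, "start"])
      }
    }
    introns <- unique(do.call(rbind, rows))
  } else {
    introns <- unique(do.call(rbind, lapply(x, function(g)
      if (nrow(g$introns)) data.frame(chrom = g$chrom, start = g$introns$start,
                                      end = g$introns$end) else NULL)))
  }
  if (is.null(introns) || !nrow(introns))
    return(list(n = 0L, mean_length = NA_real_, lengths = integer(0),
                gc_fraction = NA_real_))
  lens <- introns$end - introns$start
  gc <- NA_real_
  if (!is.null(genome)) {
    seqs <- vapply(seq_len(nrow(introns)), function(i)
      .gseq(genome, introns$chrom[i], introns$start[i], introns$end[i]), "")
    pooled <- paste(seqs, collapse = "")
    bases <- table(strsplit(pooled, "")[[1]])
    gc <- sum(bases[names(bases) %in% c("G", "C")]) / sum(bases)
  }
  list(n = nrow(introns), mean_length = mean(lens), lengths = lens,
       gc_fraction = gc)
}

#' Assemble a distribution report
#'
#' Aggregates events, localizations and splice graphs into the summary a
#' genome-wide survey reports: per-type and per-region distributions, locus
#' and exon counts, and the alternatively spliced gene fraction.
#'
#' @param events an \code{as_events} data.frame (localized if available).
#' @param graphs list of \code{splice_graph}s.
#' @param total_genes optional externally known total gene count; defaults
#'   to the number of loci.
#' @return An object of class \code{"distribution_report"}.
#' @export
distribution_report <- function(events, graphs, total_genes = length(graphs)) {
  epl <- exons_per_locus(graphs)
  as_genes <- length(unique(events$cluster_id))
  rep <- list(
    types = summarize_event_types(events),
    regions = if ("region" %in% names(events)) summarize_regions(events)
      else NULL,
    n_events = nrow(events),
    loci = epl$loci, exons = epl$exons, mean_exons_per_locus = epl$mean,
    as_gene_count = as_genes,
    total_genes = total_genes,
    as_gene_percent = as_gene_fraction(as_genes, total_genes))
  class(rep) <- "distribution_report"
  rep
}

#' @export
print.distribution_report <- function(x, ...) {
  cat(sprintf("%d events at %d of %d loci (%s%% of genes); %d exons, %.1f exons/locus\n",
              x$n_events, x$as_gene_count, x$total_genes, x$as_gene_percent,
              x$exons, x$mean_exons_per_locus))
  cat("Event types:\n"); print(x$types)
  if (!is.null(x$regions)) {
    cat(sprintf("Localization (over %d localized of %d events):\n",
                attr(x$regions, "n_localized"), x$n_events))
    print(x$regions)
  }
  invisible(x)
}

#' Write a distribution report as JSON (and optionally TSV tables)
#'
#' @param report a \code{distribution_report}.
#' @param json output JSON path.
#' @param types_tsv,regions_tsv optional TSV paths for the tables.
#' @export
write_report <- function(report, json, types_tsv = NULL, regions_tsv = NULL) {
  x <- unclass(report)
  if (!is.null(x$regions)) {
    x$n_localized <- attr(x$regions, "n_localized")
    attributes(x$regions)[c("n_total", "n_localized")] <- NULL
  }
  jsonlite::write_json(x, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(types_tsv))
    utils::write.table(report$types, types_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(regions_tsv) && !is.null(report$regions))
    utils::write.table(report$regions, regions_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(json)
}
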