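# Longest-ORF annotation of isoforms and localization of events to coding
# region, 5' UTR or 3' UTR on the reference isoform of each locus.

#' Find the longest ATG-initiated open reading frame
#'
#' Scans the three sense frames of a spliced transcript for the longest ORF
#' starting at ATG and ending at the first in-frame stop codon (stop
#' included in the interval). ORFs running off the transcript end without a
#' stop are kept but flagged incomplete (ESTs truncate 3' ends). Ties in
#' length are broken by the 5'-most start.
#'
#' @param seq transcript sequence in sense orientation (character or
#'   \code{DNAString}).
#' @return \code{NULL} when the sequence contains no ATG; otherwise a list
#'   of class \code{"orf_annotation"}: \code{orf_start}, \code{orf_end}
#'   (0-based half-open, stop codon included), \code{protein_length}
#'   (residues, stop excluded), \code{frame} (0-2) and \code{incomplete}.
#' @examples
#' find_longest_orf("ATGAAATAA")  # protein of 2 residues
#' @export
find_longest_orf <- function(seq) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  best <- NULL
  for (f in 0:2) {
    starts <- seq.int(f + 1L, by = 3L, length.out = (n - f) %/% 3L)
    if (!length(starts)) next
    codons <- substring(s, starts, starts + 2L)
    atg <- which(codons == "ATG")
    if (!length(atg)) next
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    for (ai in atg) {
      si <- stops[stops > ai]
      if (length(si)) {
        len <- (si[1] - ai + 1L) * 3L
        cand <- list(orf_start = starts[ai] - 1L,
                     orf_end = starts[ai] - 1L + len,
                     protein_length = si[1] - ai, frame = f,
                     incomplete = FALSE)
      } else {
        len <- (length(codons) - ai + 1L) * 3L
        cand <- list(orf_start = starts[ai] - 1L,
                     orf_end = starts[ai] - 1L + len,
                     protein_length = length(codons) - ai + 1L, frame = f,
                     incomplete = TRUE)
      }
      better <- is.null(best) ||
        (cand$orf_end - cand$orf_start) > (best$orf_end - best$orf_start) ||
        ((cand$orf_end - cand$orf_start) == (best$orf_end - best$orf_start) &&
           cand$orf_start < best$orf_start)
      if (better) best <- cand
    }
  }
  if (!is.null(best)) class(best) <- "orf_annotation"
  best
}

#' @export
print.orf_annotation <- function(x, ...) {
  cat(sprintf("ORF [%d,%d) frame %d: %d residues%s\n", x$orf_start, x$orf_end,
              x$frame, x$protein_length,
              if (x$incomplete) " (no stop; incomplete)" else ""))
  invisible(x)
}

#' Spliced transcript sequence of an isoform
#'
#' @param graph a \code{splice_graph}.
#' @param isoform one element of \code{graph$isoforms}.
#' @param genome named \code{DNAStringSet}.
#' @return Character sequence in sense orientation (reverse-complemented for
#'   minus-strand clusters; unknown strand is treated as '+').
#' @export
transcript_sequence <- function(graph, isoform, genome) {
  ex <- isoform$exons
  s <- paste(vapply(seq_len(nrow(ex)), function(i)
    .gseq(genome, graph$chrom, ex[i, "start"], ex[i, "end"]), ""),
    collapse = "")
  if (!is.na(graph$strand) && graph$strand == "-") s <- .revcomp(s)
  s
}

# project a genomic interval [s,e) onto transcript coordinates of an isoform
# (0-based half-open); a region with no exonic overlap projects to its
# zero-length insertion point. Returns c(ts, te).
.project_to_transcript <- function(isoform, strand, s, e) {
  ex <- isoform$exons
  widths <- ex[, "end"] - ex[, "start"]
  cum <- cumsum(c(0L, widths))
  total <- cum[length(cum)]
  fs <- NA_integer_; fe <- NA_integer_
  for (i in seq_len(nrow(ex))) {
    os <- max(s, ex[i, "start"]); oe <- min(e, ex[i, "end"])
    if (os < oe) {
      ts <- cum[i] + (os - ex[i, "start"])
      te <- cum[i] + (oe - ex[i, "start"])
      fs <- if (is.na(fs)) ts else min(fs, ts)
      fe <- if (is.na(fe)) te else max(fe, te)
    }
  }
  if (is.na(fs)) {             # purely intronic: insertion point
    p <- 0L
    for (i in seq_len(nrow(ex))) {
      if (ex[i, "start"] >= e) break
      p <- cum[i + 1L]
    }
    fs <- fe <- p
  }
  if (!is.na(strand) && strand == "-") c(total - fe, total - fs)
  else c(fs, fe)
}

#' Localize events relative to the longest open reading frame
#'
#' For each cluster the reference isoform is the one with the longest ORF;
#' its transcript divides into 5' UTR, coding region and 3' UTR. Each
#' event's variable region, projected onto that transcript, is labeled
#' coding when it overlaps the ORF by at least one nucleotide (events
#' straddling a UTR boundary therefore count as coding), otherwise 5' or 3'
#' UTR by its position relative to the ORF in transcript orientation. A
#' purely intronic variable region (intron retention against a spliced
#' reference) is localized by its insertion point. Loci whose reference has
#' no ORF yield \code{"unclassified"}.
#'
#' @param events an \code{as_events} data.frame.
#' @param graphs named list of \code{splice_graph}s (names = cluster ids).
#' @param genome named \code{DNAStringSet}.
#' @return The events with added columns \code{region} (\code{"coding"},
#'   \code{"utr5"}, \code{"utr3"} or \code{"unclassified"}) and
#'   \code{basis_isoform}.
#' @export
localize_events <- function(events, graphs, genome) {
  if (!nrow(events)) {
    events$region <- character(0); events$basis_isoform <- character(0)
    return(events)
  }
  region <- character(nrow(events)); basis <- character(nrow(events))
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(events))) {
    cid <- events$cluster_id[i]
    g <- graphs[[cid]]
    if (is.null(g)) { region[i] <- "unclassified"; basis[i] <- NA; next }
    key <- cid
    if (is.null(cache[[key]])) {
      orfs <- lapply(g$isoforms, function(iso)
        find_longest_orf(transcript_sequence(g, iso, genome)))
      lens <- vapply(orfs, function(o)
        if (is.null(o)) -1L else o$orf_end - o$orf_start, 0L)
      cache[[key]] <- list(ref = which.max(lens), orfs = orfs)
    }
    ref_i <- cache[[key]]$ref
    orf <- cache[[key]]$orfs[[ref_i]]
    iso <- g$isoforms[[ref_i]]
    basis[i] <- iso$id
    if (is.null(orf)) { region[i] <- "unclassified"; next }
    tt <- .project_to_transcript(iso, g$strand, events$start[i], events$end[i])
    region[i] <- if (tt[1] == tt[2]) {          # insertion point
      if (tt[1] <= orf$orf_start) "utr5"
      else if (tt[1] >= orf$orf_end) "utr3"
      else "coding"
    } else if (tt[1] < orf$orf_end && tt[2] > orf$orf_start) "coding"
    else if (tt[2] <= orf$orf_start) "utr5"
    else "utr3"
  }
  events$region <- region
  events$basis_isoform <- basis
  events
}
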