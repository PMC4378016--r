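#' Read spliced alignments from a PSL file
#'
#' Parses the 21-column tab-separated PSL format produced by BLAT, with or
#' without the textual header. Block coordinates are kept in the package's
#' internal convention: 0-based half-open, target coordinates always
#' genome-forward, query coordinates in the aligned orientation (for
#' minus-strand records PSL already stores qStarts in reverse-complement
#' query coordinates, which is the aligned orientation).
#'
#' @param path path to a PSL file.
#' @return An \code{est_alignments} data.frame (one row per alignment) with
#'   list-column \code{blocks} (matrix with columns gstart, gend, qstart,
#'   qend) and scalar columns est_id, chrom, read_strand, tx_strand, matches,
#'   mismatches, aligned, identity, score, qsize, tsize, gstart, gend, valid.
#' @export
read_psl <- function(path) {
  lines <- readLines(path)
  # skip the 5-line psLayout header if present, and blank lines
  if (length(lines) && grepl("^psLayout", lines[1])) lines <- lines[-(1:5)]
  lines <- lines[nzchar(lines)]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 21L)
      .stopf("malformed PSL line %d: expected 21 columns, got %d", i, length(f))
    matches <- as.integer(f[1]); mism <- as.integer(f[2])
    rep_m <- as.integer(f[3]); ncount <- as.integer(f[4])
    strand <- substr(f[9], 1L, 1L)
    qname <- f[10]; qsize <- as.integer(f[11])
    tname <- f[14]; tsize <- as.integer(f[15])
    nb <- as.integer(f[18])
    sizes <- as.integer(strsplit(f[19], ",", fixed = TRUE)[[1]])
    qs <- as.integer(strsplit(f[20], ",", fixed = TRUE)[[1]])
    ts <- as.integer(strsplit(f[21], ",", fixed = TRUE)[[1]])
    if (length(sizes) != nb || length(qs) != nb || length(ts) != nb)
      .stopf("malformed PSL line %d: block lists disagree with blockCount", i)
    blocks <- cbind(gstart = ts, gend = ts + sizes,
                    qstart = qs, qend = qs + sizes)
    m_eff <- matches + rep_m
    aligned <- m_eff + mism + ncount
    rows[[i]] <- list(est_id = qname, chrom = tname, read_strand = strand,
                      tx_strand = strand, matches = m_eff, mismatches = mism,
                      aligned = aligned,
                      identity = if (aligned > 0) 100 * m_eff / aligned else 0,
                      score = m_eff - 2L * mism, qsize = qsize, tsize = tsize,
                      gstart = blocks[1, "gstart"], gend = blocks[nb, "gend"],
                      valid = TRUE, blocks = blocks)
  }
  .alignments_df(rows)
}

#' Write spliced alignments to a PSL file
#'
#' Inverse of \code{\link{read_psl}}; emits headerless 21-column PSL.
#'
#' @param alignments an \code{est_alignments} data.frame.
#' @param path output path.
#' @export
write_psl <- function(alignments, path) {
  out <- character(nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    bl <- a$blocks[[1]]
    sizes <- bl[, "gend"] - bl[, "gstart"]
    nb <- nrow(bl)
    q_aln <- c(bl[1, "qstart"], bl[nb, "qend"])   # aligned-orientation coords
    if (a$read_strand == "-") {
      qstart <- a$qsize - q_aln[2]; qend <- a$qsize - q_aln[1]
    } else { qstart <- q_aln[1]; qend <- q_aln[2] }
    tgaps <- if (nb > 1) bl[-1, "gstart"] - bl[-nb, "gend"] else integer(0)
    qgaps <- if (nb > 1) bl[-1, "qstart"] - bl[-nb, "qend"] else integer(0)
    out[i] <- paste(c(a$matches, a$mismatches, 0L, 0L,
                      sum(qgaps > 0), sum(qgaps), sum(tgaps > 0), sum(tgaps),
                      a$read_strand, a$est_id, a$qsize, qstart, qend,
                      a$chrom, a$tsize, bl[1, "gstart"], bl[nb, "gend"], nb,
                      paste0(paste(sizes, collapse = ","), ","),
                      paste0(paste(bl[, "qstart"], collapse = ","), ","),
                      paste0(paste(bl[, "gstart"], collapse = ","), ",")),
                    collapse = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

# assemble an est_alignments data.frame from a list of row lists
.alignments_df <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    df <- data.frame(est_id = character(), chrom = character(),
                     read_strand = character(), tx_strand = character(),
                     matches = integer(), mismatches = integer(),
                     aligned = integer(), identity = numeric(),
                     score = numeric(), qsize = integer(), tsize = integer(),
                     gstart = integer(), gend = integer(), valid = logical(),
                     stringsAsFactors = FALSE)
    df$blocks <- list()
    class(df) <- c("est_alignments", "data.frame")
    return(df)
  }
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(r[setdiff(names(r), c("blocks", "introns"))],
               stringsAsFactors = FALSE)))
  df$blocks <- lapply(rows, `[[`, "blocks")
  if (!is.null(rows[[1]]$introns)) df$introns <- lapply(rows, `[[`, "introns")
  rownames(df) <- NULL
  class(df) <- c("est_alignments", "data.frame")
  df
}

#' @export
print.est_alignments <- function(x, ...) {
  cat(sprintf("%d spliced alignment(s); %d EST(s); %d spliced (>=1 intron)\n",
              nrow(x), length(unique(x$est_id)),
              sum(vapply(x$blocks, nrow, 0L) > 1L)))
  invisible(x)
}

#' Write simulation outputs to disk
#'
#' Writes the genome as FASTA, gene models as GFF3 (1-based inclusive, with
#' ID/Parent attributes for gene/mRNA/exon features) and the planted-event
#' ground truth as TSV (0-based half-open coordinates).
#'
#' @param sim an \code{"as_simulation"} object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  gff <- file.path(dir, "genes.gff3")
  .write_gene_models_gff3(sim, gff)
  tsv <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genome = fa, gff3 = gff, truth = tsv))
}

#' Write simulated ESTs as FASTA
#' @param reads a \code{"sim_ests"} object.
#' @param path output FASTA path.
#' @export
write_ests <- function(reads, path) {
  Biostrings::writeXStringSet(reads$ests, path)
  invisible(path)
}

#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors mcols mcols<-
.write_gene_models_gff3 <- function(sim, path) {
  feats <- list()
  add <- function(chrom, start0, end0, strand, type, id, parent) {
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
    mcols(gr)$type <- type
    mcols(gr)$ID <- id
    mcols(gr)$Parent <- if (is.na(parent)) IRanges::CharacterList(character(0))
      else IRanges::CharacterList(parent)
    gr
  }
  for (g in seq_len(nrow(sim$genes))) {
    gene <- sim$genes[g, ]
    feats[[length(feats) + 1L]] <-
      add(gene$chrom, gene$start, gene$end, gene$strand, "gene",
          gene$gene_id, NA)
    for (iso_id in names(sim$isoforms[[gene$gene_id]])) {
      bl <- sim$isoforms[[gene$gene_id]][[iso_id]]
      feats[[length(feats) + 1L]] <-
        add(gene$chrom, bl[1, "start"], bl[nrow(bl), "end"], gene$strand,
            "mRNA", iso_id, gene$gene_id)
      for (i in seq_len(nrow(bl)))
        feats[[length(feats) + 1L]] <-
          add(gene$chrom, bl[i, "start"], bl[i, "end"], gene$strand, "exon",
              sprintf("%s.exon%d", iso_id, i), iso_id)
    }
  }
  gr <- suppressWarnings(do.call(c, feats))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write classified events as TSV and BED6
#'
#' @param events an event data.frame from \code{\link{classify_events}}.
#' @param tsv,bed output paths (either may be NULL to skip).
#' @export
write_events <- function(events, tsv = NULL, bed = NULL) {
  flat <- events[, setdiff(names(events), c("intervals", "introns_inclusion",
                                            "introns_exclusion"))]
  if (!is.null(tsv))
    utils::write.table(flat, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed)) {
    bed_df <- data.frame(flat$chrom, flat$start, flat$end,
                         paste0(flat$event_type, "_", seq_len(nrow(flat))),
                         pmin(1000L, 100L * pmin(flat$inclusion_support,
                                                 flat$exclusion_support)),
                         ifelse(is.na(flat$strand), ".", flat$strand))
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(events)
}
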