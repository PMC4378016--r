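# Minimal spliced EST-to-genome aligner: exact k-mer seeding (both read
# orientations), diagonal merging into candidate blocks, collinear chaining
# with intron-sized gaps, splice-junction refinement with a canonical GT/AG
# bonus, and terminal extension. Substitution errors only; the minimum intron
# length separates true introns from alignment artefacts.

#' Spliced-align ESTs against a genome
#'
#' Seeds each read with exact k-mers on both orientations, merges seed hits
#' on common diagonals into gapless candidate blocks, chains blocks whose
#' genomic gaps are intron-sized, places each splice junction at the split
#' maximizing matches (with a bonus for canonical GT/AG or CT/AC
#' dinucleotides), and extends terminal blocks to the read ends. Alignment
#' score is \code{matches - 2 * mismatches}; percent identity is computed
#' over aligned read bases (intron gaps excluded), matching PSL
#' matches/misMatches semantics.
#'
#' @param ests named \code{DNAStringSet} (or named character vector) of EST
#'   sequences.
#' @param genome named \code{DNAStringSet} of genome sequences.
#' @param k seed k-mer length.
#' @param stride spacing between seed start positions along each read.
#' @param min_intron minimum genomic gap (bp) interpreted as an intron; a
#'   smaller positive gap invalidates the alignment.
#' @param max_intron maximum intron length considered when chaining.
#' @param min_score minimum alignment score to report a candidate.
#' @return An \code{est_alignments} data.frame with the best candidate per
#'   (EST, orientation, chromosome); apply
#'   \code{\link{select_best_alignment}} to reduce to one per EST. Reads
#'   shorter than \code{k} yield no alignment, with a warning.
#' @examples
#' sim <- simulate_genome(sim_config(seed = 2, n_genes = 2, as_event_rate = 0))
#' reads <- simulate_ests(sim, sim_config(seed = 2, n_genes = 2,
#'   as_event_rate = 0, est_count_per_gene = 2, est_error_rate = 0,
#'   est_partial_fraction = 0))
#' aln <- spliced_align(reads$ests, sim$genome)
#' @importFrom Biostrings PDict matchPDict width
#' @importFrom S4Vectors elementNROWS
#' @export
spliced_align <- function(ests, genome, k = 16L, stride = 4L,
                          min_intron = 40L, max_intron = 25000L,
                          min_score = 30) {
  if (is.character(ests)) ests <- DNAStringSet(ests)
  if (is.null(names(ests)) || anyNA(names(ests)))
    names(ests) <- paste0("est", seq_along(ests))
  est_chr <- as.character(ests)
  too_short <- nchar(est_chr) < k
  if (any(too_short)) {
    warning(sprintf("%d EST(s) shorter than k=%d skipped", sum(too_short), k))
    est_chr <- est_chr[!too_short]
  }
  if (!length(est_chr)) return(.alignments_df(list()))

  chrom_str <- stats::setNames(as.character(genome), names(genome))
  tsizes <- stats::setNames(nchar(chrom_str), names(chrom_str))

  # one combined seed dictionary: both orientations of every read
  seed_tab <- .build_seeds(est_chr, k, stride)
  pd <- PDict(seed_tab$kmers)

  rows <- list()
  for (chrom in names(chrom_str)) {
    m <- matchPDict(pd, genome[[chrom]])
    nhit <- elementNROWS(m)
    if (!sum(nhit)) next
    hit_pat <- rep.int(seq_along(nhit), nhit)
    hit_t <- IRanges::start(unlist(m, use.names = FALSE))
    hits <- data.frame(read = seed_tab$read[hit_pat],
                       orient = seed_tab$orient[hit_pat],
                       qpos = seed_tab$qpos[hit_pat],
                       tpos = hit_t)
    for (grp in split(hits, paste(hits$read, hits$orient))) {
      ri <- grp$read[1]; orient <- grp$orient[1]
      q <- if (orient == "+") est_chr[ri] else .revcomp(est_chr[ri])
      row <- .align_one(q, grp, chrom_str[[chrom]], k, min_intron, max_intron)
      if (is.null(row) || row$score < min_score) next
      row$est_id <- names(est_chr)[ri]
      row$chrom <- chrom
      row$read_strand <- orient
      row$tx_strand <- orient
      row$qsize <- nchar(est_chr[ri])
      row$tsize <- tsizes[[chrom]]
      row$valid <- TRUE
      rows[[length(rows) + 1L]] <- row
    }
  }
  .alignments_df(rows)
}

# enumerate seed k-mers for all reads and both orientations
.build_seeds <- function(est_chr, k, stride) {
  kmers <- character(0); read <- integer(0); orient <- character(0)
  qpos <- integer(0)
  for (i in seq_along(est_chr)) {
    L <- nchar(est_chr[i])
    pos <- unique(c(seq(1L, L - k + 1L, by = stride), L - k + 1L))
    fwd <- substring(est_chr[i], pos, pos + k - 1L)
    rev <- substring(.revcomp(est_chr[i]), pos, pos + k - 1L)
    kmers <- c(kmers, fwd, rev)
    read <- c(read, rep.int(i, 2L * length(pos)))
    orient <- c(orient, rep("+", length(pos)), rep("-", length(pos)))
    qpos <- c(qpos, pos, pos)
  }
  keep <- !grepl("N", kmers, fixed = TRUE)
  list(kmers = DNAStringSet(kmers[keep]), read = read[keep],
       orient = orient[keep], qpos = qpos[keep])
}

# align one read orientation against one chromosome given its seed hits;
# returns a partial alignment row (blocks in 1-based internally, emitted
# 0-based half-open) or NULL
.align_one <- function(q, hits, tstr, k, min_intron, max_intron) {
  L <- nchar(q); tlen <- nchar(tstr)
  diag <- hits$tpos - hits$qpos
  ord <- order(diag, hits$qpos)
  dg <- diag[ord]; qp <- hits$qpos[ord]
  # split same-diagonal runs where seed gaps exceed the error-bridging window
  brk <- c(TRUE, diff(dg) != 0L | diff(qp) > 60L)
  grp <- cumsum(brk)
  bq1 <- tapply(qp, grp, min); bq2 <- tapply(qp, grp, max) + k - 1L
  bdg <- dg[brk]
  blocks <- data.frame(qs = as.integer(bq1), qe = as.integer(bq2),
                       diag = as.integer(bdg))
  blocks <- blocks[order(blocks$qs, blocks$diag), , drop = FALSE]
  B <- nrow(blocks)

  # chain DP: strictly increasing query and diagonal, intron-sized gaps
  len <- blocks$qe - blocks$qs + 1L
  best <- len; prev <- rep.int(0L, B)
  max_qgap <- 2L * k + 8L
  for (j in seq_len(B)) {
    for (i in seq_len(j - 1L)) {
      gap_d <- blocks$diag[j] - blocks$diag[i]
      if (gap_d < min_intron || gap_d > max_intron) next
      if (blocks$qs[j] <= blocks$qs[i] || blocks$qe[j] <= blocks$qe[i]) next
      if (blocks$qs[j] - blocks$qe[i] - 1L > max_qgap) next
      cand <- best[i] + len[j]
      if (cand > best[j]) { best[j] <- cand; prev[j] <- i }
    }
  }
  j <- which.max(best)
  chain <- integer(0)
  while (j != 0L) { chain <- c(j, chain); j <- prev[j] }
  cb <- blocks[chain, , drop = FALSE]
  m <- nrow(cb)

  # junction refinement: choose the query split maximizing matches with a
  # bonus for canonical splice dinucleotides; deterministic tie-break
  splits <- integer(0)
  if (m > 1L) {
    qr <- charToRaw(q); tr <- charToRaw(tstr)
    for (i in seq_len(m - 1L)) {
      lo <- max(cb$qs[i] + 1L, cb$qe[i] - 4L)
      hi <- min(cb$qe[i + 1L], cb$qs[i + 1L] + 4L)
      if (hi < lo) return(NULL)
      s_cand <- lo:hi
      win <- (lo - 1L):hi  # contested query window around the junction
      posL <- win + cb$diag[i]; posR <- win + cb$diag[i + 1L]
      okL <- posL >= 1L & posL <= tlen; okR <- posR >= 1L & posR <= tlen
      mmL <- as.integer(!okL | qr[win] != tr[pmax(posL, 1L)])
      mmR <- as.integer(!okR | qr[win] != tr[pmax(posR, 1L)])
      cumL <- cumsum(mmL); cumR <- rev(cumsum(rev(mmR)))
      # split at s assigns window positions < s left, >= s right
      idx <- s_cand - lo + 2L           # position of s within win
      mm_tot <- cumL[idx - 1L] + cumR[idx]
      # canonical check for each candidate split
      don <- s_cand + cb$diag[i]; acc <- s_cand + cb$diag[i + 1L] - 2L
      dd <- paste0(substring(tstr, don, don), substring(tstr, don + 1L, don + 1L))
      aa <- paste0(substring(tstr, acc, acc), substring(tstr, acc + 1L, acc + 1L))
      canon <- (dd == "GT" & aa == "AG") | (dd == "CT" & aa == "AC")
      sc <- -mm_tot + 3 * canon
      s <- s_cand[order(-sc, !canon, s_cand)][1L]
      splits[i] <- s
    }
    qs <- c(cb$qs[1L], splits)
    qe <- c(splits - 1L, cb$qe[m])
  } else { qs <- cb$qs; qe <- cb$qe }

  # terminal extension to read ends, clamped to chromosome bounds
  qs[1L] <- max(1L, 1L - min(0L, cb$diag[1L]))
  qe[m] <- min(L, tlen - cb$diag[m])
  if (any(qe < qs)) return(NULL)

  # mismatch counting per block
  mm <- 0L
  for (i in seq_len(m)) {
    qseg <- substr(q, qs[i], qe[i])
    tseg <- substr(tstr, qs[i] + cb$diag[i], qe[i] + cb$diag[i])
    mm <- mm + .count_mismatches(qseg, tseg)
  }
  aligned <- sum(qe - qs + 1L)
  matches <- aligned - mm
  # degenerate: refined blocks must keep intron-sized genomic gaps
  if (m > 1L) {
    gs <- qs + cb$diag; ge <- qe + cb$diag
    if (any(gs[-1L] - ge[-m] - 1L < 1L)) return(NULL)
  }
  blocks_out <- cbind(gstart = qs + cb$diag - 1L, gend = qe + cb$diag,
                      qstart = qs - 1L, qend = qe)
  list(matches = matches, mismatches = mm, aligned = aligned,
       identity = if (aligned > 0) 100 * matches / aligned else 0,
       score = matches - 2L * mm,
       gstart = blocks_out[1L, "gstart"], gend = blocks_out[m, "gend"],
       blocks = blocks_out)
}

#' Keep only the best alignment per EST
#'
#' Retains the single highest-scoring alignment for each EST to avoid double
#' counting paralogous loci. Ties are broken deterministically by
#' (chromosome, genomic start), lowest first, so the result is invariant to
#' input order.
#'
#' @param alignments an \code{est_alignments} data.frame.
#' @return The reduced \code{est_alignments} data.frame, ordered by EST id.
#' @export
select_best_alignment <- function(alignments) {
  if (!nrow(alignments)) return(alignments)
  ord <- order(alignments$est_id, -alignments$score, alignments$chrom,
               alignments$gstart)
  a <- alignments[ord, , drop = FALSE]
  a <- a[!duplicated(a$est_id), , drop = FALSE]
  rownames(a) <- NULL
  class(a) <- c("est_alignments", "data.frame")
  a
}

#' Filter alignments by percent identity
#'
#' Removes alignments with identity strictly below the threshold; the
#' boundary is inclusive (exactly 95.0 is kept under the default).
#'
#' @param alignments an \code{est_alignments} data.frame.
#' @param threshold minimum percent identity retained.
#' @export
filter_identity <- function(alignments, threshold = 95.0) {
  keep <- alignments$identity >= threshold
  a <- alignments[keep, , drop = FALSE]
  rownames(a) <- NULL
  class(a) <- c("est_alignments", "data.frame")
  a
}

#' Call introns and infer transcription strand from splice dinucleotides
#'
#' Every genomic gap of at least \code{min_intron} bp between consecutive
#' alignment blocks becomes an intron call with its donor/acceptor
#' dinucleotides looked up in the genome. A GT...AG intron on the forward
#' genome implies transcription on '+'; CT...AC implies '-' (the reverse
#' complement). When all introns of an alignment agree, the inferred strand
#' overrides the read orientation (ESTs may be sequenced from either end).
#' Gaps shorter than \code{min_intron} invalidate the alignment
#' (\code{valid = FALSE}): the substitution-only aligner does not score
#' genomic deletions.
#'
#' @param alignments an \code{est_alignments} data.frame.
#' @param genome named \code{DNAStringSet}.
#' @param min_intron minimum intron length in bp.
#' @return The alignments with an \code{introns} list-column (matrices with
#'   columns start, end and attributes donor/acceptor dinucleotides and
#'   canonical flags), updated \code{tx_strand} and \code{valid}.
#' @export
call_introns <- function(alignments, genome, min_intron = 40L) {
  if (!nrow(alignments)) { alignments$introns <- list(); return(alignments) }
  chrom_str <- stats::setNames(as.character(genome), names(genome))
  introns <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    bl <- alignments$blocks[[i]]
    tstr <- chrom_str[[alignments$chrom[i]]]
    nb <- nrow(bl)
    if (nb < 2L) {
      introns[[i]] <- .intron_matrix(integer(0), integer(0), character(0),
                                     character(0))
      next
    }
    d <- bl[-nb, "gend"]; a <- bl[-1L, "gstart"]
    gap <- a - d
    if (any(gap < min_intron)) {
      alignments$valid[i] <- FALSE
      introns[[i]] <- .intron_matrix(integer(0), integer(0), character(0),
                                     character(0))
      next
    }
    don <- substring(tstr, d + 1L, d + 2L)
    acc <- substring(tstr, a - 1L, a)
    introns[[i]] <- .intron_matrix(d, a, don, acc)
    fwd <- don == "GT" & acc == "AG"
    rev <- don == "CT" & acc == "AC"
    if (all(fwd)) alignments$tx_strand[i] <- "+"
    else if (all(rev)) alignments$tx_strand[i] <- "-"
  }
  alignments$introns <- introns
  alignments
}

.intron_matrix <- function(d, a, don, acc) {
  m <- cbind(start = as.integer(d), end = as.integer(a))
  attr(m, "donor") <- don
  attr(m, "acceptor") <- acc
  attr(m, "canonical") <- (don == "GT" & acc == "AG") |
    (don == "CT" & acc == "AC")
  m
}

#' Drop alignments containing non-canonical introns
#'
#' Removes alignments flagged invalid by \code{\link{call_introns}} and
#' spliced alignments with any intron whose dinucleotides are not GT...AG on
#' the transcribed strand. Unspliced alignments carry no splice-site signal
#' and are kept.
#'
#' @param alignments output of \code{\link{call_introns}}.
#' @export
drop_noncanonical <- function(alignments) {
  if (!nrow(alignments)) return(alignments)
  keep <- vapply(seq_len(nrow(alignments)), function(i) {
    if (!alignments$valid[i]) return(FALSE)
    ii <- alignments$introns[[i]]
    if (nrow(ii) == 0L) return(TRUE)
    canon <- attr(ii, "canonical")
    don <- attr(ii, "donor"); acc <- attr(ii, "acceptor")
    all(canon) && (all(don == "GT" & acc == "AG") ||
                   all(don == "CT" & acc == "AC"))
  }, TRUE)
  a <- alignments[keep, , drop = FALSE]
  rownames(a) <- NULL
  class(a) <- c("est_alignments", "data.frame")
  a
}
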