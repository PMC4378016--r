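# Clustering of filtered alignments into loci and construction of per-locus
# splice graphs: exonic segments, EST-supported intron edges, per-EST paths
# and observed-chain isoforms.

#' Cluster alignments by genomic overlap
#'
#' Single-linkage clustering: two alignments share a cluster iff they are
#' connected by a chain of pairwise genomic interval overlaps on the same
#' chromosome. Each cluster corresponds to one expressed locus.
#'
#' @param alignments an \code{est_alignments} data.frame (one row per EST
#'   after \code{\link{select_best_alignment}}).
#' @return An object of class \code{"est_clusters"}: list with
#'   \code{clusters} (data.frame cluster_id, chrom, start, end, n_members)
#'   and \code{alignments} (the input with a \code{cluster_id} column).
#' @importFrom IRanges IRanges findOverlaps
#' @export
cluster_alignments <- function(alignments) {
  if (!nrow(alignments)) {
    return(structure(list(clusters = data.frame(cluster_id = character(),
                                                chrom = character(),
                                                start = integer(),
                                                end = integer(),
                                                n_members = integer()),
                          alignments = alignments), class = "est_clusters"))
  }
  alignments$cluster_id <- NA_character_
  cl_rows <- list()
  for (chrom in sort(unique(alignments$chrom))) {
    idx <- which(alignments$chrom == chrom)
    ir <- IRanges(alignments$gstart[idx] + 1L, alignments$gend[idx])
    red <- IRanges::reduce(ir)
    hit <- findOverlaps(ir, red)
    comp <- integer(length(idx))
    comp[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
    # order clusters by genomic start for stable ids
    for (ci in seq_along(red)) {
      members <- idx[comp == ci]
      cid <- sprintf("%s:%d-%d", chrom, IRanges::start(red)[ci] - 1L,
                     IRanges::end(red)[ci])
      alignments$cluster_id[members] <- cid
      cl_rows[[length(cl_rows) + 1L]] <-
        data.frame(cluster_id = cid, chrom = chrom,
                   start = IRanges::start(red)[ci] - 1L,
                   end = IRanges::end(red)[ci],
                   n_members = length(members), stringsAsFactors = FALSE)
    }
  }
  structure(list(clusters = do.call(rbind, cl_rows), alignments = alignments),
            class = "est_clusters")
}

#' @export
print.est_clusters <- function(x, ...) {
  cat(sprintf("%d cluster(s) over %d alignment(s) on %d chromosome(s)\n",
              nrow(x$clusters), nrow(x$alignments),
              length(unique(x$clusters$chrom))))
  invisible(x)
}

#' Build a splice graph for one cluster
#'
#' Nodes are exonic segments: the union of aligned blocks split at every
#' observed donor/acceptor position. Edges are distinct canonical introns
#' with EST support counts. Per-EST paths through the graph are retained for
#' event detection. The cluster strand is inferred from splice-site
#' dinucleotides; unspliced ESTs inherit it. Clusters whose spliced members
#' imply conflicting strands are flagged and excluded from event calling.
#'
#' @param members \code{est_alignments} rows belonging to one cluster (after
#'   \code{\link{call_introns}}).
#' @param cluster_id identifier for the cluster.
#' @return An object of class \code{"splice_graph"}.
#' @export
build_splice_graph <- function(members, cluster_id = members$cluster_id[1]) {
  stopifnot(nrow(members) >= 1L)
  chrom <- members$chrom[1]

  # distinct introns with supports
  all_int <- do.call(rbind, lapply(seq_len(nrow(members)), function(i) {
    m <- members$introns[[i]]
    if (nrow(m)) cbind(m, est = i) else NULL
  }))
  if (is.null(all_int)) all_int <- cbind(start = integer(0), end = integer(0),
                                         est = integer(0))
  key <- paste(all_int[, "start"], all_int[, "end"])
  ukey <- unique(key)
  introns <- data.frame(
    start = as.integer(vapply(strsplit(ukey, " "), `[`, "", 1)),
    end = as.integer(vapply(strsplit(ukey, " "), `[`, "", 2)))
  if (nrow(introns)) {
    ord <- order(introns$start, introns$end)
    introns <- introns[ord, , drop = FALSE]
    rownames(introns) <- NULL
    introns$id <- seq_len(nrow(introns))
    introns$support <- vapply(seq_len(nrow(introns)), function(j)
      length(unique(all_int[key == paste(introns$start[j], introns$end[j]),
                            "est"])), 0L)
  } else introns$id <- introns$support <- integer(0)

  # per-EST paths: blocks and ordered intron-id chains
  paths <- lapply(seq_len(nrow(members)), function(i) {
    m <- members$introns[[i]]
    chain <- integer(0)
    if (nrow(m)) {
      chain <- vapply(seq_len(nrow(m)), function(j)
        introns$id[introns$start == m[j, "start"] & introns$end == m[j, "end"]],
        0L)
      chain <- chain[order(introns$start[chain])]
    }
    list(est_id = members$est_id[i], blocks = members$blocks[[i]],
         chain = chain, tx_strand = members$tx_strand[i],
         spliced = nrow(m) > 0L)
  })

  # strand inference: splice-site evidence only; conflict flags the cluster
  ev <- unique(vapply(Filter(function(p) p$spliced, paths),
                      `[[`, "", "tx_strand"))
  strand <- if (length(ev) == 1L) ev else NA_character_
  flagged <- length(ev) > 1L

  # exonic segments: coverage union split at all splice-site positions
  blocks <- do.call(rbind, lapply(paths, `[[`, "blocks"))
  cov <- IRanges::reduce(IRanges(blocks[, "gstart"] + 1L, blocks[, "gend"]))
  cuts <- sort(unique(c(introns$start, introns$end)))
  seg_s <- integer(0); seg_e <- integer(0)
  for (i in seq_along(cov)) {
    s0 <- IRanges::start(cov)[i] - 1L; e0 <- IRanges::end(cov)[i]
    inner <- cuts[cuts > s0 & cuts < e0]
    bnd <- c(s0, inner, e0)
    seg_s <- c(seg_s, bnd[-length(bnd)]); seg_e <- c(seg_e, bnd[-1L])
  }

  g <- list(cluster_id = cluster_id, chrom = chrom, strand = strand,
            flagged = flagged,
            span = c(min(blocks[, "gstart"]), max(blocks[, "gend"])),
            introns = introns,
            segments = data.frame(start = seg_s, end = seg_e),
            paths = paths)
  class(g) <- "splice_graph"
  g$isoforms <- enumerate_isoforms(g)
  g
}

#' Build splice graphs for all clusters
#'
#' @param clustered an \code{"est_clusters"} object.
#' @return Named list of \code{splice_graph} objects, in genomic order.
#' @export
build_splice_graphs <- function(clustered) {
  out <- lapply(seq_len(nrow(clustered$clusters)), function(i) {
    cid <- clustered$clusters$cluster_id[i]
    rows <- clustered$alignments[clustered$alignments$cluster_id == cid, ,
                                 drop = FALSE]
    class(rows) <- c("est_alignments", "data.frame")
    build_splice_graph(rows, cid)
  })
  stats::setNames(out, clustered$clusters$cluster_id)
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(sprintf("Splice graph %s (%s:%d-%d, strand %s)%s\n", x$cluster_id,
              x$chrom, x$span[1], x$span[2],
              ifelse(is.na(x$strand), "?", x$strand),
              if (x$flagged) " [strand conflict]" else ""))
  cat(sprintf("  %d segment(s), %d intron edge(s), %d EST path(s), %d isoform(s)\n",
              nrow(x$segments), nrow(x$introns), length(x$paths),
              length(x$isoforms)))
  invisible(x)
}

#' Enumerate isoforms as distinct observed intron chains
#'
#' Isoforms are the distinct intron chains actually observed in EST paths
#' (never exhaustive graph paths, which would manufacture phantom
#' combinations). Chains that are consecutive sub-runs of a longer observed
#' chain and whose reads do not conflict with it (no exonic coverage across
#' one of its introns) are merged into the longer chain, so truncated reads
#' do not found spurious isoforms. A read consistent with several maximal
#' chains is assigned to the one with the most direct (exact-chain) support,
#' ties broken by chain order.
#'
#' @param graph a \code{splice_graph}.
#' @return List of isoforms: each has \code{id}, \code{chain} (intron ids),
#'   \code{support}, \code{members} (EST ids), \code{span}, and \code{exons}
#'   (genomic block matrix over the isoform span).
#' @export
enumerate_isoforms <- function(graph) {
  paths <- graph$paths
  introns <- graph$introns
  keys <- vapply(paths, function(p) paste(p$chain, collapse = ","), "")
  direct <- table(keys)
  uniq <- names(direct)
  chains <- lapply(uniq, function(k)
    if (nzchar(k)) as.integer(strsplit(k, ",")[[1]]) else integer(0))

  # maximal chains: not a consecutive sub-run of a longer observed chain
  is_subrun <- function(small, big) {
    if (!length(small)) return(TRUE)
    if (length(small) > length(big)) return(FALSE)
    for (s in seq_len(length(big) - length(small) + 1L))
      if (identical(big[s:(s + length(small) - 1L)], small)) return(TRUE)
    FALSE
  }
  maximal <- rep(TRUE, length(chains))
  for (i in seq_along(chains)) for (j in seq_along(chains)) {
    if (i == j || !maximal[i]) next
    if (length(chains[[j]]) > length(chains[[i]]) &&
        is_subrun(chains[[i]], chains[[j]])) { maximal[i] <- FALSE; break }
  }
  max_idx <- which(maximal)
  # deterministic order: by first intron start, then chain length desc
  first_start <- vapply(max_idx, function(i)
    if (length(chains[[i]])) introns$start[chains[[i]][1]] else -1L, 0L)
  max_idx <- max_idx[order(first_start,
                           -vapply(max_idx, function(i) length(chains[[i]]), 0L))]

  conflicts <- function(p, chain) {
    extra <- setdiff(chain, p$chain)
    if (!length(extra)) return(FALSE)
    bl <- p$blocks
    for (t in extra) {
      if (any(.overlaps(bl[, "gstart"], bl[, "gend"],
                        introns$start[t], introns$end[t]))) return(TRUE)
    }
    FALSE
  }

  assign_to <- integer(length(paths))  # index into final isoform list
  iso_chain <- list(); iso_members <- list()
  extra_key_to_iso <- character(0)
  for (pi in seq_along(paths)) {
    p <- paths[[pi]]
    cand <- integer(0)
    for (mi in max_idx) {
      if (is_subrun(p$chain, chains[[mi]]) && !conflicts(p, chains[[mi]]))
        cand <- c(cand, mi)
    }
    if (length(cand)) {
      pick <- cand[order(-as.integer(direct[uniq[cand]]), match(cand, max_idx))][1]
      key <- uniq[pick]
    } else key <- paste(p$chain, collapse = ",")
    key <- paste0("c:", key)  # "" is not addressable as a list name
    if (!key %in% names(iso_chain)) {
      iso_chain[[key]] <- if (nchar(key) > 2L)
        as.integer(strsplit(substring(key, 3L), ",")[[1]]) else integer(0)
      iso_members[[key]] <- integer(0)
    }
    iso_members[[key]] <- c(iso_members[[key]], pi)
  }

  out <- vector("list", length(iso_chain))
  for (i in seq_along(iso_chain)) {
    mem <- iso_members[[i]]
    spans <- vapply(paths[mem], function(p)
      c(min(p$blocks[, "gstart"]), max(p$blocks[, "gend"])), c(0, 0))
    span <- as.integer(c(min(spans[1, ]), max(spans[2, ])))
    ch <- iso_chain[[i]]
    # exon chain over the isoform span: complement of its introns
    if (length(ch)) {
      s <- c(span[1], introns$end[ch]); e <- c(introns$start[ch], span[2])
    } else { s <- span[1]; e <- span[2] }
    out[[i]] <- list(id = sprintf("%s.i%d", graph$cluster_id, i),
                     chain = ch, support = length(mem),
                     members = vapply(paths[mem], `[[`, "", "est_id"),
                     span = span, exons = cbind(start = s, end = e))
  }
  # order isoforms by support desc then genomic span for stable ids
  ord <- order(-vapply(out, `[[`, 0L, "support"),
               vapply(out, function(x) x$span[1], 0L))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$id <- sprintf("%s.i%d", graph$cluster_id, i)
  out
}
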