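# Fixture builders shared across tests. All fixtures are constructed in code;
# coordinates follow the package convention (0-based half-open).

# a genome of background 'A' (or supplied base) with GT/AG (or CT/AC)
# dinucleotides patched at the given intron intervals
fixture_genome <- function(len, introns = NULL, strand = "+",
                           background = "A", name = "chr1") {
  s <- strrep(background, len)
  if (!is.null(introns)) for (i in seq_len(nrow(introns))) {
    d <- introns[i, 1]; a <- introns[i, 2]
    if (strand == "+") {
      substr(s, d + 1, d + 2) <- "GT"
      substr(s, a - 1, a) <- "AG"
    } else {
      substr(s, d + 1, d + 2) <- "CT"
      substr(s, a - 1, a) <- "AC"
    }
  }
  gen <- Biostrings::DNAStringSet(s)
  names(gen) <- name
  gen
}

# hand-built alignment set: blocks_list is a named list (est id ->
# matrix(gstart, gend)); query coordinates are synthesized contiguously
fixture_alignments <- function(blocks_list, genome, chrom = "chr1",
                               cluster_id = "cl1") {
  rows <- lapply(names(blocks_list), function(id) {
    bl <- blocks_list[[id]]
    storage.mode(bl) <- "integer"
    widths <- bl[, 2] - bl[, 1]
    qe <- cumsum(widths); qs <- qe - widths
    blocks <- cbind(gstart = bl[, 1], gend = bl[, 2], qstart = qs, qend = qe)
    aligned <- sum(widths)
    list(est_id = id, chrom = chrom, read_strand = "+", tx_strand = "+",
         matches = aligned, mismatches = 0L, aligned = aligned,
         identity = 100, score = aligned, qsize = aligned,
         tsize = sum(Biostrings::width(genome)),
         gstart = bl[1, 1], gend = bl[nrow(bl), 2], valid = TRUE,
         blocks = blocks)
  })
  aln <- ESTsplice:::.alignments_df(rows)
  aln <- call_introns(aln, genome)
  aln$cluster_id <- cluster_id
  aln
}

# one splice graph from hand-specified member block matrices
fixture_graph <- function(blocks_list, genome = NULL, strand = "+",
                          cluster_id = "cl1") {
  if (is.null(genome)) {
    len <- max(vapply(blocks_list, function(b) max(b[, 2]), 0)) + 100
    introns <- do.call(rbind, lapply(blocks_list, function(b) {
      if (nrow(b) < 2) return(NULL)
      cbind(b[-nrow(b), 2], b[-1, 1])
    }))
    genome <- fixture_genome(len, introns, strand = strand)
  }
  build_splice_graph(fixture_alignments(blocks_list, genome,
                                        cluster_id = cluster_id),
                     cluster_id = cluster_id)
}

# brute-force single-linkage interval clustering (quadratic union-find)
oracle_cluster <- function(start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (start[i] < end[j] && start[j] < end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, 0L)
}

# brute-force longest-ORF scan over every (start, frame) pair
oracle_longest_orf <- function(s) {
  s <- toupper(s); n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (st in seq_len(max(0, n - 2))) {
    if (substr(s, st, st + 2) != "ATG") next
    pos <- st; found <- FALSE
    while (pos + 2 <= n) {
      if (substr(s, pos, pos + 2) %in% stops && pos > st) {
        cand <- list(orf_start = st - 1L, orf_end = pos + 2L,
                     protein_length = (pos - st) / 3, incomplete = FALSE)
        found <- TRUE; break
      }
      pos <- pos + 3
    }
    if (!found) cand <- list(orf_start = st - 1L, orf_end = st - 1L +
                               3 * ((n - st + 1) %/% 3),
                             protein_length = (n - st + 1) %/% 3,
                             incomplete = TRUE)
    if (is.null(best) ||
        (cand$orf_end - cand$orf_start) > (best$orf_end - best$orf_start) ||
        ((cand$orf_end - cand$orf_start) == (best$orf_end - best$orf_start) &&
         cand$orf_start < best$orf_start)) best <- cand
  }
  best
}

random_dna_str <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
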