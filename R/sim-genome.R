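#' Simulate a genome with multi-exon genes and planted splicing events
#'
#' Generates a synthetic chromosome carrying \code{n_genes} multi-exon loci
#' separated by intergenic spacers, with one alternative-splicing event of a
#' randomly drawn type planted in a configurable fraction of genes. Every
#' intron of every isoform is forced to canonical dinucleotides (GT...AG on
#' the transcribed strand), so the downstream canonical-splice-site filter is
#' exercised realistically. The ground truth records each planted event with
#' exact genomic coordinates.
#'
#' Genes hosting a planted event are generated with at least the exon count
#' the event type requires (e.g. exon skipping needs 3 exons, mutually
#' exclusive exons need 4). The terminal exon is extended where necessary so
#' that every isoform is at least as long as the shortest configured EST, so
#' partial-read simulation is always feasible.
#'
#' @param config a \code{\link{sim_config}} object.
#' @return An object of class \code{"as_simulation"}: a list with
#'   \describe{
#'     \item{genome}{\code{DNAStringSet} with one chromosome.}
#'     \item{genes}{data.frame of gene spans (gene_id, chrom, start, end,
#'       strand, n_exons, event_type); coordinates 0-based half-open.}
#'     \item{exons}{data.frame of reference exon coordinates.}
#'     \item{isoforms}{named list (by gene) of isoform block matrices,
#'       columns start/end, 0-based half-open, genome-forward order.}
#'     \item{truth}{data.frame of planted events: gene_id, event_type, chrom,
#'       start, end, strand, inclusion_isoform, exclusion_isoform. The span
#'       is the variable region: the retained intron (IR), the skipped
#'       exon(s) (ES), the donor/acceptor shift segment (Alt5/Alt3), or the
#'       hull of the cassette exons (MXE).}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_genome(sim_config(seed = 3, n_genes = 4))
#' sim$truth
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  genes <- vector("list", cfg$n_genes)
  gene_iso <- vector("list", cfg$n_genes)
  exon_rows <- vector("list", cfg$n_genes)
  truth_rows <- vector("list", cfg$n_genes)
  patches <- vector("list", cfg$n_genes)  # dinucleotide forcing, absolute coords
  cursor <- 0L  # running chromosome length
  chrom <- "chr1"

  for (g in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("g%04d", g)
    strand <- sample(c("+", "-"), 1L)
    has_event <- stats::runif(1) < cfg$as_event_rate
    ev_type <- if (has_event)
      sample(names(cfg$as_type_mix), 1L, prob = cfg$as_type_mix) else NA_character_

    min_ex <- if (has_event) .min_exons_for(ev_type) else 1L
    n_exons <- max(1L + stats::rpois(1L, cfg$exons_per_gene_mean - 1), min_ex)

    exon_len <- .sample_int_range(n_exons, cfg$exon_length_range[1],
                                  cfg$exon_length_range[2])
    shift <- if (has_event && ev_type %in% c("Alt5", "Alt3"))
      .sample_int_range(1L, cfg$alt_shift_range[1], cfg$alt_shift_range[2]) else 0L
    intron_len <- .draw_intron_lengths(n_exons - 1L, cfg,
                                       min_len = cfg$intron_length_range[1] + shift)

    plan <- .plant_event(ev_type, n_exons, exon_len, strand, shift, cfg)

    # extend last exon so both isoforms reach the shortest configured EST
    min_txlen <- cfg$est_length_range[1]
    deficit <- min_txlen - (sum(exon_len) - plan$max_removed_exonic)
    if (deficit > 0L) exon_len[n_exons] <- exon_len[n_exons] + deficit

    # local (gene-relative) exon coordinates, 0-based half-open
    starts <- integer(n_exons); ends <- integer(n_exons)
    pos <- 0L
    for (i in seq_len(n_exons)) {
      starts[i] <- pos; ends[i] <- pos + exon_len[i]
      pos <- ends[i] + if (i < n_exons) intron_len[i] else 0L
    }
    gene_len <- ends[n_exons]

    spacer <- .sample_int_range(1L, cfg$intergenic_min, cfg$intergenic_max)
    offset <- cursor + spacer
    cursor <- offset + gene_len
    starts <- starts + offset; ends <- ends + offset

    iso <- .build_isoforms(plan, n_exons, starts, ends)
    gene_iso[[g]] <- iso$blocks
    names(gene_iso[[g]]) <- paste0(gene_id, ".", seq_along(gene_iso[[g]]))

    # canonical dinucleotides for every intron of every isoform
    pat <- list()
    for (bl in gene_iso[[g]]) {
      if (nrow(bl) < 2L) next
      d <- bl[-nrow(bl), "end"]; a <- bl[-1L, "start"]
      for (j in seq_along(d)) {
        if (strand == "+") {
          pat[[length(pat) + 1L]] <- c(d[j], charToRaw("GT")[1], charToRaw("GT")[2])
          pat[[length(pat) + 1L]] <- c(a[j] - 2L, charToRaw("AG")[1], charToRaw("AG")[2])
        } else {
          pat[[length(pat) + 1L]] <- c(d[j], charToRaw("CT")[1], charToRaw("CT")[2])
          pat[[length(pat) + 1L]] <- c(a[j] - 2L, charToRaw("AC")[1], charToRaw("AC")[2])
        }
      }
    }
    patches[[g]] <- pat

    genes[[g]] <- data.frame(gene_id = gene_id, chrom = chrom,
                             start = starts[1], end = ends[n_exons],
                             strand = strand, n_exons = n_exons,
                             event_type = ev_type,
                             stringsAsFactors = FALSE)
    exon_rows[[g]] <- data.frame(gene_id = gene_id, chrom = chrom,
                                 exon = seq_len(n_exons),
                                 start = starts, end = ends,
                                 stringsAsFactors = FALSE)
    if (has_event) {
      vr <- .event_span(plan, starts, ends)
      truth_rows[[g]] <- data.frame(gene_id = gene_id, event_type = ev_type,
                                    chrom = chrom, start = vr[1], end = vr[2],
                                    strand = strand,
                                    inclusion_isoform = paste0(gene_id, ".", plan$inclusion),
                                    exclusion_isoform = paste0(gene_id, ".", plan$exclusion),
                                    stringsAsFactors = FALSE)
    }
  }

  chrom_len <- cursor + .sample_int_range(1L, cfg$intergenic_min,
                                          cfg$intergenic_max)
  seq_raw <- .random_dna(chrom_len, cfg$genome_gc)
  for (pat in unlist(patches, recursive = FALSE)) {
    seq_raw[pat[1] + 1L] <- as.raw(pat[2])
    seq_raw[pat[1] + 2L] <- as.raw(pat[3])
  }
  genome <- DNAStringSet(rawToChar(seq_raw))
  names(genome) <- chrom

  out <- list(genome = genome,
              genes = do.call(rbind, genes),
              exons = do.call(rbind, exon_rows),
              isoforms = stats::setNames(gene_iso, vapply(genes, `[[`, "", "gene_id")),
              truth = if (length(tr <- Filter(Negate(is.null), truth_rows)))
                do.call(rbind, tr) else
                data.frame(gene_id = character(), event_type = character(),
                           chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           inclusion_isoform = character(),
                           exclusion_isoform = character()),
              config = cfg)
  class(out) <- "as_simulation"
  out
}

#' @export
print.as_simulation <- function(x, ...) {
  cat(sprintf("Synthetic splicing simulation: %d genes on %d chromosome(s), %s bp\n",
              nrow(x$genes), length(x$genome),
              format(sum(Biostrings::width(x$genome)), big.mark = ",")))
  cat(sprintf("  planted events: %d (%s)\n", nrow(x$truth),
              if (nrow(x$truth)) paste(names(table(x$truth$event_type)),
                                       table(x$truth$event_type),
                                       sep = "=", collapse = " ") else "none"))
  invisible(x)
}

# truncated log-normal intron lengths with the configured arithmetic mean
.draw_intron_lengths <- function(n, cfg, min_len = cfg$intron_length_range[1]) {
  if (n == 0L) return(integer(0))
  meanlog <- log(cfg$intron_length_mean) - cfg$intron_length_sdlog^2 / 2
  out <- integer(0)
  while (length(out) < n) {
    x <- round(stats::rlnorm(n, meanlog = meanlog, sdlog = cfg$intron_length_sdlog))
    x <- x[x >= min_len & x <= cfg$intron_length_range[2]]
    out <- c(out, as.integer(x))
  }
  out[seq_len(n)]
}

.random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  charToRaw(paste(sample(names(p), n, replace = TRUE, prob = p), collapse = ""))
}

# Decide which exons/introns the event manipulates. Exon indices are in
# genome-forward order; Alt5/Alt3 semantics are resolved on the transcribed
# strand. Returns a plan consumed by .build_isoforms()/.event_span().
.plant_event <- function(type, n_exons, exon_len, strand, shift, cfg) {
  plan <- list(type = type, max_removed_exonic = 0L, inclusion = 1L, exclusion = 2L)
  if (is.na(type)) return(plan)
  n_introns <- n_exons - 1L
  switch(type,
    IR = {
      plan$intron <- .sample1(seq_len(n_introns))
      plan$inclusion <- 2L; plan$exclusion <- 1L  # isoform 2 retains
    },
    ES = {
      plan$exon <- .sample1(2:(n_exons - 1L))
      plan$max_removed_exonic <- exon_len[plan$exon]
      plan$inclusion <- 1L; plan$exclusion <- 2L
    },
    Alt5 = , Alt3 = {
      plan$intron <- .sample1(seq_len(n_introns))
      plan$shift <- shift
      # donor end is genomic-left on '+', genomic-right on '-'
      donor_left <- (strand == "+")
      plan$shift_at_left <- if (type == "Alt5") donor_left else !donor_left
      plan$inclusion <- 2L; plan$exclusion <- 1L  # isoform 2 retains the segment
    },
    MXE = {
      plan$cassette <- .sample1(2:(n_exons - 2L))  # cassettes: j, j+1
      plan$max_removed_exonic <- max(exon_len[plan$cassette],
                                     exon_len[plan$cassette + 1L])
      plan$inclusion <- 1L; plan$exclusion <- 2L
    })
  plan
}

# isoform exon-block matrices (genome-forward) from a plant plan
.build_isoforms <- function(plan, n_exons, starts, ends) {
  ref <- cbind(start = starts, end = ends)
  if (is.na(plan$type)) return(list(blocks = list(ref)))
  iso2 <- switch(plan$type,
    IR = {
      i <- plan$intron  # merge exons i and i+1 across the retained intron
      keep <- setdiff(seq_len(n_exons), i + 1L)
      m <- ref[keep, , drop = FALSE]
      m[which(keep == plan$intron), "end"] <- ends[i + 1L]
      m
    },
    ES = ref[-plan$exon, , drop = FALSE],
    Alt5 = , Alt3 = {
      i <- plan$intron
      m <- ref
      if (plan$shift_at_left) {
        m[i, "end"] <- ends[i] + plan$shift        # exon grows into intron
      } else {
        m[i + 1L, "start"] <- starts[i + 1L] - plan$shift
      }
      m
    },
    MXE = ref[-(plan$cassette + 1L), , drop = FALSE])
  iso1 <- if (identical(plan$type, "MXE")) ref[-plan$cassette, , drop = FALSE] else ref
  # note: for MXE, isoform 1 keeps cassette j+1... see .plant_event ordering
  if (identical(plan$type, "MXE")) {
    iso1 <- ref[-(plan$cassette + 1L), , drop = FALSE]  # includes cassette j
    iso2 <- ref[-plan$cassette, , drop = FALSE]         # includes cassette j+1
  }
  list(blocks = list(iso1, iso2))
}

# variable-region genomic span of a planted event
.event_span <- function(plan, starts, ends) {
  switch(plan$type,
    IR = c(ends[plan$intron], starts[plan$intron + 1L]),
    ES = c(starts[plan$exon], ends[plan$exon]),
    Alt5 = , Alt3 = {
      i <- plan$intron
      if (plan$shift_at_left) c(ends[i], ends[i] + plan$shift)
      else c(starts[i + 1L] - plan$shift, starts[i + 1L])
    },
    MXE = c(starts[plan$cassette], ends[plan$cassette + 1L]))
}
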