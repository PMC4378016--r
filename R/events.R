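# Pattern-matching of splice graphs into classified alternative splicing
# events. Precedence when patterns overlap: MXE > ES > IR > alt5/alt3 >
# complex; each discordance yields exactly one event. Alternative
# transcription starts/ends are never treated as events.

.EVENT_TYPES <- c("intron_retention", "exon_skipping", "alt5", "alt3",
                  "mutually_exclusive", "complex")

.empty_events <- function() {
  df <- data.frame(cluster_id = character(), chrom = character(),
                   strand = character(), event_type = character(),
                   start = integer(), end = integer(),
                   inclusion_support = integer(), exclusion_support = integer(),
                   shift = integer(), stringsAsFactors = FALSE)
  df$intervals <- list(); df$introns_inclusion <- list()
  df$introns_exclusion <- list()
  class(df) <- c("as_events", "data.frame")
  df
}

.event_row <- function(graph, type, start, end, inc, exc, inc_int, exc_int,
                       shift = NA_integer_, intervals = NULL) {
  df <- data.frame(cluster_id = graph$cluster_id, chrom = graph$chrom,
                   strand = graph$strand, event_type = type,
                   start = as.integer(start), end = as.integer(end),
                   inclusion_support = as.integer(inc),
                   exclusion_support = as.integer(exc),
                   shift = as.integer(shift), stringsAsFactors = FALSE)
  df$intervals <- list(if (is.null(intervals)) cbind(start = start, end = end)
                       else intervals)
  df$introns_inclusion <- list(inc_int)
  df$introns_exclusion <- list(exc_int)
  class(df) <- c("as_events", "data.frame")
  df
}

.bind_events <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
  if (!length(lst)) return(.empty_events())
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  class(out) <- c("as_events", "data.frame")
  out
}

# number of EST paths whose chain contains all given intron ids
.support_all <- function(graph, ids) {
  sum(vapply(graph$paths, function(p) all(ids %in% p$chain), TRUE))
}

# fallback support: paths with >=1 defining intron and none of the rival's
.support_partial <- function(graph, ids, rival) {
  sum(vapply(graph$paths, function(p)
    any(ids %in% p$chain) && !any(rival %in% p$chain), TRUE))
}

.alt_support <- function(graph, ids, rival) {
  s <- .support_all(graph, ids)
  if (s == 0L) s <- .support_partial(graph, ids, rival)
  s
}

# all consecutive sub-runs of observed isoform chains, keyed by their outer
# boundaries (D = first intron start, A = last intron end)
.chain_runs <- function(graph) {
  runs <- list()
  for (iso in graph$isoforms) {
    ch <- iso$chain
    if (!length(ch)) next
    for (i in seq_along(ch)) for (j in i:length(ch)) {
      ids <- ch[i:j]
      key <- paste(graph$introns$start[ids[1]],
                   graph$introns$end[ids[length(ids)]])
      rkey <- paste(ids, collapse = ",")
      if (is.null(runs[[key]])) runs[[key]] <- list()
      runs[[key]][[rkey]] <- ids
    }
  }
  runs
}

# internal exon intervals of a run (between consecutive introns)
.run_exons <- function(graph, ids) {
  if (length(ids) < 2L) return(cbind(start = integer(0), end = integer(0)))
  cbind(start = graph$introns$end[ids[-length(ids)]],
        end = graph$introns$start[ids[-1L]])
}

#' Detect intron retention events
#'
#' An intron retention event is emitted for every intron edge that at least
#' one EST covers exonically without interruption — the retaining read must
#' span the complete intron plus at least one base of both flanking exons,
#' guarding against genomic-DNA-like partial coverage. Inclusion support is
#' the number of retaining ESTs; exclusion support the number splicing the
#' intron.
#'
#' @param graph a \code{splice_graph}.
#' @return An \code{as_events} data.frame.
#' @export
detect_intron_retention <- function(graph) {
  ev <- list()
  for (j in seq_len(nrow(graph$introns))) {
    d <- graph$introns$start[j]; a <- graph$introns$end[j]
    retain <- sum(vapply(graph$paths, function(p)
      any(p$blocks[, "gstart"] <= d - 1L & p$blocks[, "gend"] >= a + 1L), TRUE))
    if (retain >= 1L)
      ev[[length(ev) + 1L]] <- .event_row(graph, "intron_retention", d, a,
                                          inc = retain,
                                          exc = graph$introns$support[j],
                                          inc_int = integer(0), exc_int = j)
  }
  .bind_events(ev)
}

#' Detect exon skipping events
#'
#' Emitted when a long intron edge (D, A) coexists with an observed chain of
#' two or more introns whose outer boundaries are exactly D and A, i.e. an
#' inclusion path through one or more internal exons. Multi-exon skips are a
#' single event.
#'
#' @param graph a \code{splice_graph}.
#' @export
detect_exon_skipping <- function(graph) {
  runs <- .chain_runs(graph)
  ev <- list()
  for (key in names(runs)) {
    rr <- runs[[key]]
    lens <- vapply(rr, length, 0L)
    skips <- rr[lens == 1L]
    if (!length(skips)) next
    skip_id <- skips[[1]][1]
    for (run in rr[lens >= 2L]) {
      exons <- .run_exons(graph, run)
      inc <- .alt_support(graph, run, skip_id)
      exc <- .alt_support(graph, skip_id, run)
      if (inc < 1L || exc < 1L) next
      ev[[length(ev) + 1L]] <- .event_row(
        graph, "exon_skipping", exons[1, "start"],
        exons[nrow(exons), "end"], inc, exc,
        inc_int = run, exc_int = skip_id, intervals = exons)
    }
  }
  .bind_events(ev)
}

#' Detect mutually exclusive exon events
#'
#' Emitted when two or more observed inclusion chains share both flanking
#' splice sites (same D and A), their internal cassette exons are pairwise
#' disjoint, and no observed chain (and no direct D-A skip) joins or skips
#' them — i.e. every transcript contains exactly one of the cassettes.
#'
#' @param graph a \code{splice_graph}.
#' @export
detect_mutually_exclusive <- function(graph) {
  runs <- .chain_runs(graph)
  ev <- list()
  for (key in names(runs)) {
    rr <- runs[[key]]
    lens <- vapply(rr, length, 0L)
    if (any(lens == 1L)) next           # a direct skip makes this ES territory
    multi <- rr[lens >= 2L]
    if (length(multi) < 2L) next
    ex <- lapply(multi, function(run) .run_exons(graph, run))
    disjoint <- TRUE
    for (i in seq_along(ex)) for (j in seq_along(ex)) {
      if (i >= j) next
      for (u in seq_len(nrow(ex[[i]]))) for (v in seq_len(nrow(ex[[j]]))) {
        if (.overlaps(ex[[i]][u, "start"], ex[[i]][u, "end"],
                      ex[[j]][v, "start"], ex[[j]][v, "end"])) disjoint <- FALSE
      }
    }
    if (!disjoint) next
    cass <- do.call(rbind, ex)
    cass <- cass[order(cass[, "start"]), , drop = FALSE]
    sup <- vapply(seq_along(multi), function(i)
      .alt_support(graph, multi[[i]],
                   unlist(multi[-i], use.names = FALSE)), 0L)
    if (any(sup < 1L)) next
    ord <- order(vapply(multi, function(run) .run_exons(graph, run)[1, "start"],
                        0L))
    ev[[length(ev) + 1L]] <- .event_row(
      graph, "mutually_exclusive", min(cass[, "start"]), max(cass[, "end"]),
      inc = sup[ord[1]], exc = sup[ord[2]],
      inc_int = multi[[ord[1]]], exc_int = multi[[ord[2]]], intervals = cass)
  }
  .bind_events(ev)
}

#' Detect alternative 5'/3' splice site events
#'
#' Two intron edges sharing one genomic boundary and differing at the other
#' shift a donor or acceptor site. The label is transcript-orientation
#' aware: a varying genomic-left boundary with a shared right boundary is an
#' alternative 5' site on '+' and an alternative 3' site on '-', and vice
#' versa. With unknown strand the event is classified from the '+'
#' convention and flagged strand-ambiguous via \code{strand = NA}. Pairs
#' already explained by a higher-precedence event may be excluded.
#'
#' @param graph a \code{splice_graph}.
#' @param exclude optional \code{as_events} whose defining intron pairs are
#'   skipped (used by \code{\link{classify_events}} for precedence).
#' @export
detect_alt_splice_sites <- function(graph, exclude = NULL) {
  introns <- graph$introns
  excl_sets <- .defining_sets(exclude)
  ev <- list()
  emit <- function(i, j, varying_left) {
    if (.pair_explained(i, j, excl_sets)) return()
    s <- if (varying_left) sort(c(introns$start[i], introns$start[j]))
         else sort(c(introns$end[i], introns$end[j]))
    shift <- s[2] - s[1]
    type <- if (is.na(graph$strand) || graph$strand == "+") {
      if (varying_left) "alt5" else "alt3"
    } else {
      if (varying_left) "alt3" else "alt5"
    }
    # the retaining alternative (shorter intron) gains the segment as exon
    len_i <- introns$end[i] - introns$start[i]
    len_j <- introns$end[j] - introns$start[j]
    short <- if (len_i < len_j) i else j
    long <- if (len_i < len_j) j else i
    inc <- .alt_support(graph, short, long)
    exc <- .alt_support(graph, long, short)
    if (inc < 1L || exc < 1L) return()
    ev[[length(ev) + 1L]] <<- .event_row(graph, type, s[1], s[2], inc, exc,
                                         inc_int = short, exc_int = long,
                                         shift = shift)
  }
  for (e in unique(introns$end)) {
    ids <- introns$id[introns$end == e]
    if (length(ids) < 2L) next
    ids <- ids[order(introns$start[ids])]
    for (t in seq_len(length(ids) - 1L)) emit(ids[t], ids[t + 1L], TRUE)
  }
  for (s in unique(introns$start)) {
    ids <- introns$id[introns$start == s]
    if (length(ids) < 2L) next
    ids <- ids[order(introns$end[ids])]
    for (t in seq_len(length(ids) - 1L)) emit(ids[t], ids[t + 1L], FALSE)
  }
  .bind_events(ev)
}

.defining_sets <- function(events) {
  if (is.null(events) || !nrow(events)) return(list())
  lapply(seq_len(nrow(events)), function(i)
    c(events$introns_inclusion[[i]], events$introns_exclusion[[i]]))
}

.pair_explained <- function(i, j, sets) {
  for (s in sets) if (i %in% s && j %in% s) return(TRUE)
  FALSE
}

#' Classify remaining discordances as complex events
#'
#' Any pair of overlapping, incompatible intron edges not explained by an
#' already-detected simple or mutually-exclusive event contributes to a
#' complex event; overlapping discordant regions are merged so each yields
#' one event. Supports are the maximum and minimum EST counts over the
#' involved introns.
#'
#' @param graph a \code{splice_graph}.
#' @param simple_events previously detected events (precedence filter).
#' @export
classify_complex <- function(graph, simple_events = NULL) {
  introns <- graph$introns
  n <- nrow(introns)
  if (n < 2L) return(.empty_events())
  sets <- .defining_sets(simple_events)
  pairs <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!.overlaps(introns$start[i], introns$end[i],
                   introns$start[j], introns$end[j])) next
    shared <- introns$start[i] == introns$start[j] ||
      introns$end[i] == introns$end[j]
    if (shared) next                     # alt-site pattern, handled upstream
    if (.pair_explained(i, j, sets)) next
    pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  if (!length(pairs)) return(.empty_events())
  # merge overlapping discordant regions
  regions <- lapply(pairs, function(p)
    c(min(introns$start[p]), max(introns$end[p]), p))
  merged <- list()
  for (r in regions) {
    placed <- FALSE
    for (k in seq_along(merged)) {
      if (.overlaps(r[1], r[2], merged[[k]]$s, merged[[k]]$e)) {
        merged[[k]]$s <- min(merged[[k]]$s, r[1])
        merged[[k]]$e <- max(merged[[k]]$e, r[2])
        merged[[k]]$ids <- union(merged[[k]]$ids, r[-(1:2)])
        placed <- TRUE; break
      }
    }
    if (!placed) merged[[length(merged) + 1L]] <- list(s = r[1], e = r[2],
                                                       ids = r[-(1:2)])
  }
  ev <- lapply(merged, function(m) {
    sup <- introns$support[m$ids]
    .event_row(graph, "complex", m$s, m$e, inc = max(sup), exc = min(sup),
               inc_int = m$ids[which.max(sup)], exc_int = m$ids[which.min(sup)])
  })
  .bind_events(ev)
}

#' Classify all alternative splicing events of a splice graph
#'
#' Runs the detectors in precedence order (mutually exclusive exons, exon
#' skipping, intron retention, alternative 5'/3' sites, complex) so each
#' discordance is assigned exactly one type. Clusters flagged for
#' conflicting strand evidence yield no events.
#'
#' @param graph a \code{splice_graph}, or a list of them.
#' @return An \code{as_events} data.frame over all input graphs.
#' @export
classify_events <- function(graph) {
  if (!inherits(graph, "splice_graph"))
    return(.bind_events(lapply(graph, classify_events)))
  if (graph$flagged) return(.empty_events())
  mxe <- detect_mutually_exclusive(graph)
  es <- detect_exon_skipping(graph)
  ir <- detect_intron_retention(graph)
  alt <- detect_alt_splice_sites(graph, exclude = .bind_events(list(mxe, es)))
  simple <- .bind_events(list(mxe, es, ir, alt))
  cx <- classify_complex(graph, simple)
  .bind_events(list(simple, cx))
}

#' @export
print.as_events <- function(x, ...) {
  cat(sprintf("%d alternative splicing event(s)\n", nrow(x)))
  if (nrow(x)) print(table(factor(x$event_type, levels = .EVENT_TYPES)))
  invisible(x)
}

#' Support-ratio quality filter
#'
#' Keeps only events where the EST evidence for the two splice alternatives
#' is within \code{max_ratio} times of each other (boundary inclusive: a
#' 20:2 event is kept at the default 10, a 21:2 event is dropped). This
#' excludes spurious events backed by a handful of reads against a heavily
#' covered alternative.
#'
#' @param events an \code{as_events} data.frame.
#' @param max_ratio maximum allowed support ratio.
#' @export
apply_support_filter <- function(events, max_ratio = 10.0) {
  if (!nrow(events)) return(events)
  stopifnot(all(events$inclusion_support >= 1L),
            all(events$exclusion_support >= 1L))
  ratio <- pmax(events$inclusion_support, events$exclusion_support) /
    pmin(events$inclusion_support, events$exclusion_support)
  out <- events[ratio <= max_ratio, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("as_events", "data.frame")
  out
}
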