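# Per-gene splice-variant arithmetic and verification utilities: merged
# intron lengths for skipping variants, protein-length deltas, premature
# stop detection, in-silico RT-PCR amplicon prediction and relative
# expression by the 2^-ddCt method.

#' Genomic span removed by an exon-skipping variant
#'
#' When one or more exons are skipped, the upstream intron, the skipped
#' exon(s), any introns between them, and the downstream intron are excised
#' as a single merged intron. Returns its total length.
#'
#' @param upstream_intron,downstream_intron flanking intron lengths in bp.
#' @param skipped_exon_lengths lengths of the skipped exon(s).
#' @param internal_intron_lengths lengths of introns between skipped exons;
#'   must number one fewer than the skipped exons.
#' @return Merged intron length in bp.
#' @examples
#' merged_intron_length(7996, 56, integer(0), 8313)  # 16365
#' @export
merged_intron_length <- function(upstream_intron, skipped_exon_lengths,
                                 internal_intron_lengths = integer(0),
                                 downstream_intron) {
  lens <- c(upstream_intron, skipped_exon_lengths, internal_intron_lengths,
            downstream_intron)
  if (any(lens <= 0)) .stopf("all lengths must be positive")
  if (length(internal_intron_lengths) != length(skipped_exon_lengths) - 1L)
    .stopf("need one internal intron fewer than skipped exons (got %d and %d)",
           length(internal_intron_lengths), length(skipped_exon_lengths))
  sum(lens)
}

#' Protein length after an in-frame removal
#'
#' Removing \code{removed_nt} coding nucleotides shortens the protein by
#' \code{removed_nt / 3} residues when the removal preserves frame;
#' otherwise the variant is frameshifted and its downstream length cannot be
#' derived arithmetically (the sequence is required; see
#' \code{\link{detect_premature_stop}}).
#'
#' @param reference_protein_len reference protein length in residues.
#' @param removed_nt removed coding length in nucleotides.
#' @return list with \code{new_length} (residues, or \code{NA} on
#'   frameshift) and \code{frameshift}.
#' @examples
#' protein_length_change(284, 135)  # 239 residues, no frameshift
#' @export
protein_length_change <- function(reference_protein_len, removed_nt) {
  if (!.is_count(reference_protein_len) || !.is_count(removed_nt))
    .stopf("arguments must be non-negative integers")
  if (removed_nt >= 3 * reference_protein_len)
    .stopf("removed length (%d nt) exceeds the reference coding region",
           removed_nt)
  if (removed_nt %% 3 == 0)
    list(new_length = as.integer(reference_protein_len - removed_nt / 3),
         frameshift = FALSE)
  else
    list(new_length = NA_integer_, frameshift = TRUE)
}

.GENETIC_CODE_STOPS <- c("TAA", "TAG", "TGA")

.translate_to_stop <- function(seq, from) {
  # residues until (excluding) the first stop; NA stop position if none
  n <- nchar(seq)
  starts <- seq.int(from, by = 3L, length.out = (n - from + 1L) %/% 3L)
  codons <- substring(seq, starts, starts + 2L)
  st <- which(codons %in% .GENETIC_CODE_STOPS)
  list(stop_codon_index = if (length(st)) st[1] else NA_integer_,
       n_codons = length(codons))
}

#' Detect a premature termination codon in a splice variant
#'
#' Translates a variant transcript in the reading frame of the reference,
#' starting from the shared start codon, and flags a premature stop when a
#' termination codon occurs 5' of the position homologous to the reference
#' stop (homology accounts for the length difference between the
#' transcripts).
#'
#' @param variant,reference transcript sequences (character or
#'   \code{DNAString}) sharing the reference start codon position, or
#'   transcript-variant lists with a \code{sequence} field.
#' @param orf_start 0-based start of the reference ORF; by default located
#'   with \code{\link{find_longest_orf}} on the reference.
#' @return list with \code{premature} flag, \code{stop_codon} (1-based codon
#'   index of the variant's first stop, counted from the start codon) and
#'   \code{reference_stop_codon}.
#' @export
detect_premature_stop <- function(variant, reference, orf_start = NULL) {
  vs <- toupper(as.character(if (is.list(variant)) variant$sequence else variant))
  rs <- toupper(as.character(if (is.list(reference)) reference$sequence else reference))
  if (is.null(orf_start)) {
    orf <- find_longest_orf(rs)
    if (is.null(orf)) .stopf("reference has no ORF")
    orf_start <- orf$orf_start
  }
  if (substr(rs, orf_start + 1L, orf_start + 3L) != "ATG")
    .stopf("reference ORF does not begin with ATG at position %d", orf_start)
  if (substr(vs, orf_start + 1L, orf_start + 3L) != "ATG")
    .stopf("start codon absent in variant at the shared position")
  ref_tr <- .translate_to_stop(rs, orf_start + 1L)
  var_tr <- .translate_to_stop(vs, orf_start + 1L)
  if (is.na(ref_tr$stop_codon_index))
    .stopf("reference ORF has no stop codon")
  # homologous stop position in the variant, shifted by the length delta
  delta_nt <- nchar(vs) - nchar(rs)
  hom_stop <- ref_tr$stop_codon_index + delta_nt / 3
  premature <- !is.na(var_tr$stop_codon_index) &&
    var_tr$stop_codon_index < hom_stop
  list(premature = premature, stop_codon = var_tr$stop_codon_index,
       reference_stop_codon = ref_tr$stop_codon_index)
}

#' Construct a primer pair
#'
#' @param forward,reverse primer sequences written 5' to 3' (the reverse
#'   primer anneals to the sense strand's reverse complement).
#' @return list of class \code{"primer_pair"}.
#' @export
primer_pair <- function(forward, reverse) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (p in c(forward, reverse))
    if (nchar(p) < 15L || nchar(p) > 35L)
      .stopf("primer length must be 15-35 nt (got %d)", nchar(p))
  structure(list(forward = forward, reverse = reverse),
            class = "primer_pair")
}

#' Predict RT-PCR amplicons on splice variants
#'
#' Exact-match in-silico PCR: the forward primer must occur verbatim on the
#' spliced transcript and the reverse primer's reverse complement downstream
#' of it. A primer spanning an exon-exon junction therefore binds only
#' variants in which that junction sequence is contiguous — the classic
#' discrimination logic for splice variants. A primer with multiple binding
#' sites on a variant makes the prediction ambiguous for that variant.
#'
#' @param variants named character vector (or list with \code{sequence}
#'   fields) of spliced transcript sequences.
#' @param primers a \code{\link{primer_pair}}.
#' @return data.frame: variant_id, product_length (bp; NA when no product),
#'   status ("product", "no_product" or "ambiguous").
#' @examples
#' v <- c(v1 = paste0(strrep("A", 30), "ACGTACGTACGTACGT",
#'                    strrep("G", 60), "CCACGATTAGCATCAC", strrep("C", 30)))
#' pp <- primer_pair("ACGTACGTACGTACGT", "GTGATGCTAATCGTGG")
#' predict_amplicons(v, pp)
#' @export
predict_amplicons <- function(variants, primers) {
  stopifnot(inherits(primers, "primer_pair"))
  if (is.list(variants))
    variants <- vapply(variants, function(v)
      if (is.list(v)) v$sequence else v, "")
  if (is.null(names(variants)))
    names(variants) <- paste0("variant", seq_along(variants))
  rev_site <- .revcomp(primers$reverse)
  out <- lapply(names(variants), function(id) {
    s <- toupper(variants[[id]])
    f_hits <- .find_all(s, primers$forward)
    r_hits <- .find_all(s, rev_site)
    if (length(f_hits) > 1L || length(r_hits) > 1L)
      return(data.frame(variant_id = id, product_length = NA_integer_,
                        status = "ambiguous", stringsAsFactors = FALSE))
    if (length(f_hits) != 1L || length(r_hits) != 1L)
      return(data.frame(variant_id = id, product_length = NA_integer_,
                        status = "no_product", stringsAsFactors = FALSE))
    r_end <- r_hits + nchar(rev_site) - 1L
    if (r_end <= f_hits + nchar(primers$forward) - 1L)
      return(data.frame(variant_id = id, product_length = NA_integer_,
                        status = "no_product", stringsAsFactors = FALSE))
    data.frame(variant_id = id,
               product_length = as.integer(r_end - f_hits + 1L),
               status = "product", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.find_all <- function(subject, pattern) {
  hit <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hit[1] == -1L) integer(0) else as.integer(hit)
}

#' Construct a real-time RT-PCR Ct measurement
#'
#' @param sample sample label (e.g. a condition or timepoint).
#' @param target target label (e.g. a splice variant or reference gene).
#' @param ct numeric vector of replicate threshold cycles, each in (0, 50).
#' @return list of class \code{"ct_measurement"}.
#' @export
ct_measurement <- function(sample, target, ct) {
  if (!length(ct)) .stopf("at least one Ct replicate is required")
  if (any(!is.finite(ct)) || any(ct <= 0) || any(ct >= 50))
    .stopf("Ct values must lie in (0, 50)")
  structure(list(sample = sample, target = target, ct = as.numeric(ct)),
            class = "ct_measurement")
}

#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are averaged; dCt = mean Ct(target) - mean
#' Ct(reference) within a sample; ddCt = dCt(sample) - dCt(calibrator); the
#' fold change is 2^-ddCt. Without a calibrator the relative level within
#' one sample, 2^-dCt against the reference gene (e.g. actin), is reported
#' instead.
#'
#' @param target,reference \code{\link{ct_measurement}}s from the sample of
#'   interest.
#' @param calibrator_target,calibrator_reference optional measurements from
#'   the calibrator sample.
#' @return list of class \code{"relative_expression"}: \code{fold_change},
#'   \code{delta_ct}, \code{delta_delta_ct} (NA without calibrator) and
#'   \code{mode}.
#' @examples
#' t <- ct_measurement("s", "v1", c(24.1, 24.3, 24.2))
#' r <- ct_measurement("s", "actin", c(20.0, 20.1, 19.9))
#' delta_delta_ct(t, r)
#' @export
delta_delta_ct <- function(target, reference, calibrator_target = NULL,
                           calibrator_reference = NULL) {
  stopifnot(inherits(target, "ct_measurement"),
            inherits(reference, "ct_measurement"))
  dct <- mean(target$ct) - mean(reference$ct)
  if (!is.null(calibrator_target) || !is.null(calibrator_reference)) {
    stopifnot(inherits(calibrator_target, "ct_measurement"),
              inherits(calibrator_reference, "ct_measurement"))
    dct_cal <- mean(calibrator_target$ct) - mean(calibrator_reference$ct)
    ddct <- dct - dct_cal
    out <- list(fold_change = 2^(-ddct), delta_ct = dct,
                delta_delta_ct = ddct, mode = "calibrated")
  } else {
    out <- list(fold_change = 2^(-dct), delta_ct = dct,
                delta_delta_ct = NA_real_, mode = "relative_level")
  }
  class(out) <- "relative_expression"
  out
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("%s: fold change %.4g (dCt %.3f%s)\n",
              if (x$mode == "calibrated") "2^-ddCt" else "2^-dCt vs reference",
              x$fold_change, x$delta_ct,
              if (!is.na(x$delta_delta_ct))
                sprintf(", ddCt %.3f", x$delta_delta_ct) else ""))
  invisible(x)
}
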