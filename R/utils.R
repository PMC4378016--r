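# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open; conversion to 1-based happens only at I/O
# boundaries (GFF3, IRanges construction, sequence extraction).

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement subseq
#' @importFrom IRanges IRanges
NULL

# extract genomic subsequence [start, end) (0-based half-open) as character
.gseq <- function(genome, chrom, start, end) {
  if (end <= start) return("")
  as.character(subseq(genome[[chrom]], start = start + 1L, width = end - start))
}

.revcomp <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

# round half up to `digits`, matching the convention of printed percentages
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# per-position mismatch count between two equal-length strings
.count_mismatches <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("internal: unequal lengths in mismatch count")
  if (nchar(a) == 0L) return(0L)
  sum(charToRaw(a) != charToRaw(b))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# 0-based half-open interval overlap
.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

# sample one element of x, robust to length(x) == 1 (where sample(x, 1)
# would draw from 1:x)
.sample1 <- function(x) x[sample.int(length(x), 1L)]

# n uniform integers in [a, b], robust to a == b
.sample_int_range <- function(n, a, b) {
  x <- seq.int(a, b)
  x[sample.int(length(x), n, replace = TRUE)]
}
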