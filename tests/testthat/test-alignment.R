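# a random genome with one two-exon gene; returns genome, EST and the
# planted intron interval
make_two_exon_case <- function(seed = 42, intron = c(400L, 700L),
                               exon1 = c(100L, 400L), exon2 = c(700L, 1100L)) {
  set.seed(seed)
  s <- random_dna_str(3000)
  substr(s, intron[1] + 1, intron[1] + 2) <- "GT"
  substr(s, intron[2] - 1, intron[2]) <- "AG"
  genome <- Biostrings::DNAStringSet(s); names(genome) <- "chr1"
  est <- paste0(substr(s, exon1[1] + 1, exon1[2]),
                substr(s, exon2[1] + 1, exon2[2]))
  list(genome = genome, est = est, intron = intron)
}

test_that("read_psl parses block structure and computes identity", {
  psl1 <- paste(c(600, 0, 0, 0, 0, 0, 0, 0, "+", "q1", 600, 0, 600,
                  "chr1", 5000, 1000, 1600, 1, "600,", "0,", "1000,"),
                collapse = "\t")
  psl2 <- paste(c(500, 0, 0, 0, 0, 0, 1, 500, "+", "q2", 500, 0, 500,
                  "chr1", 5000, 1000, 2000, 2, "200,300,", "0,200,",
                  "1000,1700,"), collapse = "\t")
  path <- withr::local_tempfile(lines = c(psl1, psl2), fileext = ".psl")
  aln <- read_psl(path)
  expect_equal(nrow(aln), 2L)
  expect_equal(aln$identity[1], 100.0)
  expect_equal(unname(aln$blocks[[1]][, "gstart"]), 1000)
  genome <- fixture_genome(5000, introns = rbind(c(1200L, 1700L)))
  called <- call_introns(aln, genome)
  expect_equal(unname(called$introns[[2]][1, ]), c(1200L, 1700L))
})

test_that("malformed PSL lines raise an error naming the line", {
  path <- withr::local_tempfile(lines = "1\t2\t3", fileext = ".psl")
  expect_error(read_psl(path), "line 1")
})

test_that("PSL round-trips block structure losslessly, both strands", {
  case <- make_two_exon_case()
  aln <- select_best_alignment(spliced_align(
    c(fwd = case$est, rev = revcomp_chr(case$est)), case$genome))
  expect_equal(nrow(aln), 2L)
  expect_setequal(aln$read_strand, c("+", "-"))
  path <- withr::local_tempfile(fileext = ".psl")
  write_psl(aln, path)
  back <- read_psl(path)
  for (i in 1:2) {
    j <- match(aln$est_id[i], back$est_id)
    expect_identical(unname(back$blocks[[j]]), unname(aln$blocks[[i]]))
    expect_equal(back$matches[j], aln$matches[i])
    expect_equal(back$read_strand[j], aln$read_strand[i])
  }
})

test_that("spliced_align recovers a planted intron exactly", {
  case <- make_two_exon_case()
  aln <- spliced_align(c(e1 = case$est), case$genome)
  best <- select_best_alignment(aln)
  expect_equal(nrow(best), 1L)
  expect_equal(best$identity, 100)
  called <- call_introns(best, case$genome)
  expect_equal(unname(called$introns[[1]][1, ]), case$intron)
  expect_true(attr(called$introns[[1]], "canonical"))
})

test_that("a foreign sequence yields no alignment", {
  case <- make_two_exon_case()
  set.seed(99)
  stranger <- random_dna_str(500)
  aln <- spliced_align(c(x = stranger), case$genome)
  expect_equal(nrow(aln), 0L)
})

test_that("reads shorter than k are skipped with a warning", {
  case <- make_two_exon_case()
  expect_warning(aln <- spliced_align(c(tiny = "ACGTACGT"), case$genome),
                 "shorter than k")
  expect_equal(nrow(aln), 0L)
})

test_that("reverse-strand reads give the same intron with strand '-'", {
  case <- make_two_exon_case()
  both <- select_best_alignment(spliced_align(
    c(f = case$est, r = revcomp_chr(case$est)), case$genome))
  called <- call_introns(both, case$genome)
  for (i in 1:2)
    expect_equal(unname(called$introns[[i]][1, ]), case$intron)
  # GT..AG on forward genome: transcription strand is '+' for both reads
  expect_true(all(called$tx_strand == "+"))
  expect_setequal(called$read_strand, c("+", "-"))
})

test_that("errored reads still align with the planted junction", {
  case <- make_two_exon_case()
  set.seed(7)
  est <- case$est
  for (p in sample(nchar(est), 6)) {  # ~1% substitutions
    old <- substr(est, p, p)
    substr(est, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  best <- select_best_alignment(spliced_align(c(e = est), case$genome))
  expect_equal(nrow(best), 1L)
  expect_lte(best$mismatches, 6L)
  called <- call_introns(best, case$genome)
  expect_equal(unname(called$introns[[1]][1, ]), case$intron)
})

test_that("best-alignment selection is strict, deterministic and order-invariant", {
  mk <- function(id, chrom, gstart, score) {
    list(est_id = id, chrom = chrom, read_strand = "+", tx_strand = "+",
         matches = score, mismatches = 0L, aligned = score, identity = 100,
         score = score, qsize = score, tsize = 10000L, gstart = gstart,
         gend = gstart + score, valid = TRUE,
         blocks = cbind(gstart = gstart, gend = gstart + score,
                        qstart = 0L, qend = score))
  }
  rows <- list(mk("e1", "chr1", 100L, 600L), mk("e1", "chr2", 900L, 598L),
               mk("e2", "chr2", 500L, 400L), mk("e2", "chr1", 700L, 400L),
               mk("e3", "chr1", 10L, 50L))
  aln <- ESTsplice:::.alignments_df(rows)
  best <- select_best_alignment(aln)
  expect_equal(best$score[best$est_id == "e1"], 600L)
  # exact tie: lowest (chrom, start) kept
  expect_equal(best$chrom[best$est_id == "e2"], "chr1")
  expect_equal(best$gstart[best$est_id == "e2"], 700L)
  # single alignment passes through unchanged
  expect_equal(best$gstart[best$est_id == "e3"], 10L)
  for (perm in list(c(2, 1, 4, 3, 5), 5:1, c(3, 5, 1, 2, 4))) {
    shuf <- ESTsplice:::.alignments_df(rows[perm])
    expect_equal(select_best_alignment(shuf)$gstart, best$gstart)
  }
})

test_that("identity filter boundary is inclusive at the threshold", {
  mk <- function(id, ident) {
    list(est_id = id, chrom = "chr1", read_strand = "+", tx_strand = "+",
         matches = 100L, mismatches = 0L, aligned = 100L, identity = ident,
         score = 100L, qsize = 100L, tsize = 1000L, gstart = 0L, gend = 100L,
         valid = TRUE,
         blocks = cbind(gstart = 0L, gend = 100L, qstart = 0L, qend = 100L))
  }
  aln <- ESTsplice:::.alignments_df(list(mk("a", 94.9), mk("b", 95.0),
                                         mk("c", 99.0), mk("d", 100)))
  kept <- filter_identity(aln)
  expect_setequal(kept$est_id, c("b", "c", "d"))
  expect_equal(nrow(filter_identity(aln, threshold = 0)), 4L)
})

test_that("one mismatch in 100 columns gives 99.0 identity and survives", {
  case <- make_two_exon_case(exon1 = c(100L, 150L), exon2 = c(700L, 750L))
  est <- case$est
  substr(est, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                 substr(est, 30, 30))[1]
  best <- select_best_alignment(spliced_align(c(e = est), case$genome))
  expect_equal(best$aligned, 100L)
  expect_equal(best$mismatches, 1L)
  expect_equal(best$identity, 99.0)
  expect_equal(nrow(filter_identity(best)), 1L)
})

test_that("canonical splice-site enforcement drops GC..AG and keeps CT..AC", {
  set.seed(5)
  s <- random_dna_str(3000)
  # intron 1: GC..AG (non-canonical); intron 2 gene: CT..AC (minus strand)
  substr(s, 401, 402) <- "GC"; substr(s, 699, 700) <- "AG"
  substr(s, 1501, 1502) <- "CT"; substr(s, 1799, 1800) <- "AC"
  genome <- Biostrings::DNAStringSet(s); names(genome) <- "chr1"
  est_gc <- paste0(substr(s, 101, 400), substr(s, 701, 1000))
  est_ctac <- paste0(substr(s, 1201, 1500), substr(s, 1801, 2100))
  aln <- select_best_alignment(spliced_align(
    c(gc = est_gc, ctac = est_ctac), genome))
  called <- call_introns(aln, genome)
  kept <- drop_noncanonical(called)
  expect_false("gc" %in% kept$est_id)
  expect_true("ctac" %in% kept$est_id)
  expect_equal(kept$tx_strand[kept$est_id == "ctac"], "-")
  # surviving spliced alignments carry only canonical introns
  for (i in seq_len(nrow(kept)))
    expect_true(all(attr(kept$introns[[i]], "canonical")))
})

test_that("sub-intron genomic gaps invalidate the alignment", {
  mk <- list(e1 = NULL)
  genome <- fixture_genome(2000)
  rows <- list(list(est_id = "e1", chrom = "chr1", read_strand = "+",
                    tx_strand = "+", matches = 220L, mismatches = 0L,
                    aligned = 220L, identity = 100, score = 220L,
                    qsize = 220L, tsize = 2000L, gstart = 100L, gend = 340L,
                    valid = TRUE,
                    blocks = cbind(gstart = c(100L, 320L),
                                   gend = c(300L, 340L),
                                   qstart = c(0L, 200L),
                                   qend = c(200L, 220L))))
  aln <- ESTsplice:::.alignments_df(rows)
  called <- call_introns(aln, genome)   # 20 bp gap < 40 bp minimum
  expect_false(called$valid[1])
  expect_equal(nrow(drop_noncanonical(called)), 0L)
})

test_that("error-free simulated reads recover every planted intron exactly", {
  cfg <- sim_config(seed = 41, n_genes = 8, est_count_per_gene = 4,
                    est_error_rate = 0, est_partial_fraction = 0,
                    minor_variant_frequency = 0.5)
  sim <- simulate_genome(cfg)
  reads <- simulate_ests(sim, cfg)
  best <- call_introns(select_best_alignment(
    spliced_align(reads$ests, sim$genome)), sim$genome)
  expect_equal(nrow(best), length(reads$ests))
  expect_true(all(best$identity == 100))
  for (i in seq_len(nrow(best))) {
    r <- reads$reads[reads$reads$est_id == best$est_id[i], ]
    bl <- sim$isoforms[[r$gene_id]][[r$isoform_id]]
    want <- if (nrow(bl) > 1)
      cbind(bl[-nrow(bl), "end"], bl[-1, "start"]) else
      matrix(integer(0), ncol = 2)
    got <- best$introns[[i]]
    expect_equal(unname(got[, c("start", "end"), drop = FALSE]),
                 unname(want), ignore_attr = TRUE)
  }
})
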