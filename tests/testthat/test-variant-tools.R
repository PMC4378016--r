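test_that("merged intron length is the sum of its parts", {
  expect_equal(merged_intron_length(7996, 56, integer(0), 8313), 16365)
  expect_equal(merged_intron_length(10, 5, integer(0), 10), 25)
  expect_error(merged_intron_length(10, c(5, 5), integer(0), 10),
               "internal intron")
  expect_error(merged_intron_length(-1, 5, integer(0), 10), "positive")
})

test_that("merged intron length equals coordinate subtraction on gene models", {
  set.seed(127)
  for (i in 1:20) {
    n_skip <- sample(1:4, 1)
    exon_len <- sample(50:200, n_skip + 2, replace = TRUE)
    intron_len <- sample(60:500, n_skip + 1, replace = TRUE)
    # build coordinates: flankL, skipped exons, flankR
    pos <- 0L; starts <- integer(0); ends <- integer(0)
    for (j in seq_along(exon_len)) {
      starts[j] <- pos; ends[j] <- pos + exon_len[j]
      pos <- ends[j] + if (j < length(exon_len)) intron_len[j] else 0L
    }
    want <- starts[n_skip + 2] - ends[1]   # genomic span removed
    got <- merged_intron_length(intron_len[1], exon_len[2:(n_skip + 1)],
                                if (n_skip > 1)
                                  intron_len[2:n_skip] else integer(0),
                                intron_len[n_skip + 1])
    expect_equal(got, want)
  }
})

test_that("in-frame removals shorten the protein; frame breaks are flagged", {
  expect_equal(protein_length_change(284, 135),
               list(new_length = 239L, frameshift = FALSE))
  r <- protein_length_change(453, 510)
  expect_equal(453L - r$new_length, 170L)
  fs <- protein_length_change(100, 56)
  expect_true(fs$frameshift)
  expect_true(is.na(fs$new_length))
  expect_error(protein_length_change(100, 300), "exceeds")
})

test_that("premature stops are found by translation in the reference frame", {
  utr <- "CCACCA"
  core1 <- "ATGGCTGCAGCTGCCGCA"      # 6 codons, no stop
  core2 <- "ATGGCTTAGGCTGCCGCA"      # stop at codon 3
  tail <- "TGACCACCA"                # reference stop + 3' UTR
  ref <- paste0(utr, core1, tail)
  var_stop <- paste0(utr, core2, tail)
  r <- detect_premature_stop(var_stop, ref)
  expect_true(r$premature)
  expect_equal(r$stop_codon, 3L)
  same <- detect_premature_stop(ref, ref)
  expect_false(same$premature)
  # 21 nt in-frame insertion without a stop is not premature
  var_ins <- paste0(utr, "ATGGCTGCAGCTGCC", "GCTGCAGCTGCAGCTGCAGCA",
                    "GCA", tail)
  expect_false(detect_premature_stop(var_ins, ref)$premature)
  no_atg <- paste0(utr, sub("^ATG", "ACG", core1), tail)
  expect_error(detect_premature_stop(no_atg, ref), "start codon absent")
})

test_that("premature stop detection matches a direct codon-scan oracle", {
  set.seed(131)
  stops <- c("TAA", "TAG", "TGA")
  aa_codons <- c("GCT", "GGT", "TGT", "ACT", "CAT", "GAT", "AAA", "CCC")
  for (i in 1:25) {
    n <- sample(10:30, 1)
    core <- paste(sample(aa_codons, n, replace = TRUE), collapse = "")
    ref <- paste0("AAC", "ATG", core, "TAA", "GGG")
    # variant: remove or insert a multiple of 3, maybe insert a stop codon
    ins <- paste(sample(c(aa_codons, stops), sample(1:5, 1), replace = TRUE),
                 collapse = "")
    at <- 3 * sample(2:(n - 2), 1)
    var <- paste0("AAC", "ATG", substr(core, 1, at), ins,
                  substr(core, at + 1, nchar(core)), "TAA", "GGG")
    got <- detect_premature_stop(var, ref)
    # oracle: translate variant from ATG, compare stop to homologous position
    vcore <- substr(var, 7, nchar(var))
    cods <- substring(vcore, seq(1, nchar(vcore) - 2, 3),
                      seq(3, nchar(vcore), 3))
    first_stop <- which(cods %in% stops)[1]
    hom <- (n + 1) + nchar(ins) / 3
    expect_equal(got$premature, first_stop < hom)
  }
})

test_that("primer pairs validate their lengths", {
  expect_error(primer_pair("ACGT", "ACGTACGTACGTACGTAA"), "15-35")
  expect_s3_class(primer_pair("ACGTACGTACGTACGT", "TTTTCCCCGGGGAAAA"),
                  "primer_pair")
})

# two variants differing by one cassette exon, with primers in the flanks
amplicon_case <- function(cassette_len = 135) {
  set.seed(137)
  flank1 <- random_dna_str(120)
  cassette <- random_dna_str(cassette_len)
  flank2 <- random_dna_str(120)
  v1 <- paste0(flank1, cassette, flank2)
  v2 <- paste0(flank1, flank2)
  fwd <- substr(flank1, 21, 40)
  rev_site <- substr(flank2, 81, 100)
  list(variants = c(v1 = v1, v2 = v2),
       primers = primer_pair(fwd, revcomp_chr(rev_site)),
       junction = paste0(substr(flank1, 103, 120), substr(flank2, 1, 2)))
}

test_that("product lengths differ by exactly the cassette length", {
  case <- amplicon_case(135)
  pred <- predict_amplicons(case$variants, case$primers)
  expect_equal(pred$status, c("product", "product"))
  expect_equal(pred$product_length[1] - pred$product_length[2], 135L)
})

test_that("junction-spanning primers discriminate the skip variant", {
  case <- amplicon_case(135)
  jp <- primer_pair(case$junction, case$primers$reverse)
  pred <- predict_amplicons(case$variants, jp)
  expect_equal(pred$status[pred$variant_id == "v1"], "no_product")
  expect_equal(pred$status[pred$variant_id == "v2"], "product")
  # string-search oracle: the junction site is contiguous only in v2
  expect_false(grepl(case$junction, case$variants["v1"], fixed = TRUE))
  expect_true(grepl(case$junction, case$variants["v2"], fixed = TRUE))
})

test_that("missing or repeated primer sites yield none or ambiguous", {
  case <- amplicon_case()
  foreign <- primer_pair(strrep("ACGT", 5), case$primers$reverse)
  pred <- predict_amplicons(case$variants, foreign)
  expect_true(all(pred$status == "no_product"))
  dup <- paste0(case$variants["v1"], case$variants["v1"])
  pred2 <- predict_amplicons(c(dup = dup), case$primers)
  expect_equal(pred2$status, "ambiguous")
})

test_that("amplicon length difference equals cassette length on simulated loci", {
  cfg <- sim_config(seed = 139, n_genes = 12, as_event_rate = 1,
                    as_type_mix = c(IR = 0, ES = 1, Alt5 = 0, Alt3 = 0,
                                    MXE = 0))
  sim <- simulate_genome(cfg)
  iso <- isoform_sequences(sim)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    v1 <- iso[[tr$inclusion_isoform]]; v2 <- iso[[tr$exclusion_isoform]]
    fwd <- substr(v2, 21, 40)
    rev_site <- substr(v2, nchar(v2) - 60, nchar(v2) - 41)
    pred <- predict_amplicons(c(v1 = v1, v2 = v2),
                              primer_pair(fwd, revcomp_chr(rev_site)))
    if (all(pred$status == "product")) {
      expect_equal(pred$product_length[1] - pred$product_length[2],
                   tr$end - tr$start)
    }
  }
})

test_that("ddCt arithmetic matches its closed form and invariants", {
  expect_error(ct_measurement("s", "t", numeric(0)), "at least one")
  expect_error(ct_measurement("s", "t", 55), "0, 50")

  all_eq <- ct_measurement("s", "t", c(20, 20))
  expect_equal(delta_delta_ct(all_eq, all_eq, all_eq, all_eq)$fold_change, 1.0)

  t25 <- ct_measurement("s", "t", 25)
  r20 <- ct_measurement("s", "r", 20)
  cal_t <- ct_measurement("c", "t", 23)
  cal_r <- ct_measurement("c", "r", 20)
  res <- delta_delta_ct(t25, r20, cal_t, cal_r)
  expect_equal(res$delta_delta_ct, 2)
  expect_equal(res$fold_change, 0.25)

  tri_t <- ct_measurement("s", "v1", c(24.1, 24.3, 24.2))
  tri_r <- ct_measurement("s", "actin", c(20.0, 20.1, 19.9))
  rel <- delta_delta_ct(tri_t, tri_r)
  expect_equal(rel$mode, "relative_level")
  expect_equal(rel$fold_change, 2^-(mean(c(24.1, 24.3, 24.2)) -
                                      mean(c(20.0, 20.1, 19.9))))
  # replicate order is irrelevant
  perm <- delta_delta_ct(ct_measurement("s", "v1", c(24.2, 24.1, 24.3)),
                         ct_measurement("s", "actin", c(19.9, 20.0, 20.1)))
  expect_equal(perm$fold_change, rel$fold_change)
  expect_gt(rel$fold_change, 0)
})
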