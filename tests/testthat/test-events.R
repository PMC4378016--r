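test_that("intron retention needs full intron coverage plus flanking bases", {
  g <- fixture_graph(list(s1 = rbind(c(1000, 1200), c(1700, 1900)),
                          s2 = rbind(c(1000, 1200), c(1700, 1900)),
                          s3 = rbind(c(1050, 1200), c(1700, 1850)),
                          ret = rbind(c(1100, 1800))))
  ev <- detect_intron_retention(g)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start, ev$end), c(1200L, 1700L))
  expect_equal(c(ev$inclusion_support, ev$exclusion_support), c(1L, 3L))

  # coverage of the bare intron without flanks is not retention evidence
  g2 <- fixture_graph(list(s1 = rbind(c(1000, 1200), c(1700, 1900)),
                           bare = rbind(c(1200, 1700))))
  expect_equal(nrow(detect_intron_retention(g2)), 0L)
})

test_that("a retained 69 bp first intron is called with its exact length", {
  g <- fixture_graph(list(s1 = rbind(c(100, 500), c(569, 900)),
                          s2 = rbind(c(100, 500), c(569, 900)),
                          ret = rbind(c(450, 650))))
  ev <- classify_events(g)
  ir <- ev[ev$event_type == "intron_retention", ]
  expect_equal(nrow(ir), 1L)
  expect_equal(ir$end - ir$start, 69L)
})

test_that("exon skipping is detected with the variable exon's exact length", {
  # inclusion path exon4-exon5(135 bp)-exon6 vs a skip edge joining 4 to 6
  g <- fixture_graph(list(
    inc1 = rbind(c(1300, 1500), c(2000, 2135), c(2600, 2800)),
    inc2 = rbind(c(1300, 1500), c(2000, 2135), c(2600, 2800)),
    skp1 = rbind(c(1300, 1500), c(2600, 2800))))
  ev <- classify_events(g)
  es <- ev[ev$event_type == "exon_skipping", ]
  expect_equal(nrow(es), 1L)
  expect_equal(c(es$start, es$end), c(2000L, 2135L))
  expect_equal(es$end - es$start, 135L)
  expect_equal(c(es$inclusion_support, es$exclusion_support), c(2L, 1L))
  expect_equal(nrow(ev), 1L)   # nothing else is emitted
})

test_that("a multi-exon skip is one event covering all skipped exons", {
  # eight-exon locus; one edge removes six internal exons at once
  exons <- cbind(seq(1000, 8000, by = 1000), seq(1200, 8200, by = 1000))
  inc <- exons
  skp <- exons[c(1, 8), ]
  g <- fixture_graph(list(i1 = inc, i2 = inc, s1 = skp))
  ev <- classify_events(g)
  es <- ev[ev$event_type == "exon_skipping", ]
  expect_equal(nrow(es), 1L)
  expect_equal(nrow(es$intervals[[1]]), 6L)
  expect_equal(c(es$start, es$end), c(2000L, 7200L))
})

test_that("no shared flanking sites means no exon skipping", {
  g <- fixture_graph(list(a = rbind(c(100, 300), c(700, 900)),
                          b = rbind(c(100, 300), c(700, 900), c(1300, 1500))))
  expect_equal(nrow(detect_exon_skipping(g)), 0L)
})

test_that("alternative donor shifts classify by transcript strand", {
  blocks <- list(long1 = rbind(c(900, 1000), c(2000, 2100)),
                 long2 = rbind(c(900, 1000), c(2000, 2100)),
                 short1 = rbind(c(900, 1021), c(2000, 2100)))
  g_plus <- fixture_graph(blocks, strand = "+")
  ev <- classify_events(g_plus)
  expect_equal(ev$event_type, "alt5")
  expect_equal(c(ev$start, ev$end), c(1000L, 1021L))
  expect_equal(ev$shift, 21L)
  # the retaining (shorter-intron) alternative is the inclusion side
  expect_equal(c(ev$inclusion_support, ev$exclusion_support), c(1L, 2L))

  g_minus <- fixture_graph(blocks, strand = "-")
  ev2 <- classify_events(g_minus)
  expect_equal(ev2$event_type, "alt3")
  expect_equal(c(ev2$start, ev2$end), c(1000L, 1021L))
})

test_that("alternative acceptor shifts mirror the donor logic", {
  blocks <- list(a1 = rbind(c(900, 1000), c(2000, 2100)),
                 a2 = rbind(c(900, 1000), c(1979, 2100)))
  ev_p <- classify_events(fixture_graph(blocks, strand = "+"))
  expect_equal(ev_p$event_type, "alt3")
  expect_equal(ev_p$shift, 21L)
  ev_m <- classify_events(fixture_graph(blocks, strand = "-"))
  expect_equal(ev_m$event_type, "alt5")
})

test_that("edges differing at both ends classify as complex", {
  g <- fixture_graph(list(a = rbind(c(900, 1000), c(2000, 2100)),
                          b = rbind(c(850, 980), c(1950, 2100))))
  expect_equal(nrow(detect_alt_splice_sites(g)), 0L)
  ev <- classify_events(g)
  expect_equal(ev$event_type, "complex")
  expect_equal(nrow(ev), 1L)
})

test_that("two 106 nt cassettes used one-at-a-time form one MXE event", {
  g <- fixture_graph(list(
    v1a = rbind(c(800, 1000), c(1200, 1306), c(2400, 2600)),
    v1b = rbind(c(800, 1000), c(1200, 1306), c(2400, 2600)),
    v2a = rbind(c(800, 1000), c(1800, 1906), c(2400, 2600))))
  ev <- classify_events(g)
  expect_equal(ev$event_type, "mutually_exclusive")
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start, ev$end), c(1200L, 1906L))
  cass <- ev$intervals[[1]]
  expect_equal(unname(cass[, "end"] - cass[, "start"]), c(106L, 106L))
})

test_that("a path containing both cassettes demotes MXE to exon skipping", {
  g <- fixture_graph(list(
    v1 = rbind(c(800, 1000), c(1200, 1306), c(2400, 2600)),
    v2 = rbind(c(800, 1000), c(1800, 1906), c(2400, 2600)),
    both = rbind(c(800, 1000), c(1200, 1306), c(1800, 1906), c(2400, 2600))))
  ev <- classify_events(g)
  expect_equal(sum(ev$event_type == "mutually_exclusive"), 0L)
  expect_equal(sum(ev$event_type == "exon_skipping"), 2L)
})

test_that("three pairwise-exclusive cassettes form one spanning MXE event", {
  g <- fixture_graph(list(
    v1 = rbind(c(800, 1000), c(1200, 1300), c(3000, 3200)),
    v2 = rbind(c(800, 1000), c(1700, 1800), c(3000, 3200)),
    v3 = rbind(c(800, 1000), c(2200, 2300), c(3000, 3200))))
  ev <- classify_events(g)
  mxe <- ev[ev$event_type == "mutually_exclusive", ]
  expect_equal(nrow(mxe), 1L)
  expect_equal(nrow(mxe$intervals[[1]]), 3L)
  expect_equal(c(mxe$start, mxe$end), c(1200L, 2300L))
})

test_that("simple planted events never classify as complex at zero error", {
  cfg <- sim_config(seed = 79, n_genes = 12, as_event_rate = 1,
                    est_count_per_gene = 12, est_error_rate = 0,
                    est_partial_fraction = 0, minor_variant_frequency = 0.5)
  sim <- simulate_genome(cfg)
  reads <- simulate_ests(sim, cfg)
  res <- run_as_pipeline(sim$genome, reads$ests, verbose = FALSE)
  expect_equal(sum(res$events$event_type == "complex"), 0L)
})

test_that("the support-ratio filter bounds evidence imbalance inclusively", {
  g <- fixture_graph(list(a = rbind(c(100, 200), c(300, 400)),
                          b = rbind(c(110, 390))))
  ev <- classify_events(g)
  at_ratio <- function(inc, exc) {
    e <- ev
    e$inclusion_support <- inc; e$exclusion_support <- exc
    nrow(apply_support_filter(e))
  }
  expect_equal(at_ratio(20L, 2L), 1L)   # ratio 10: kept
  expect_equal(at_ratio(2L, 20L), 1L)   # symmetric
  expect_equal(at_ratio(21L, 2L), 0L)   # ratio 10.5: dropped
  expect_equal(at_ratio(1L, 1L), 1L)
  expect_error({e <- ev; e$inclusion_support <- 0L; apply_support_filter(e)})
})

test_that("adding minority support never removes a kept event", {
  g <- fixture_graph(list(a = rbind(c(100, 200), c(300, 400)),
                          b = rbind(c(110, 390))))
  base <- classify_events(g)
  set.seed(83)
  for (i in 1:50) {
    e <- base
    e$inclusion_support <- sample.int(30L, 1L)
    e$exclusion_support <- sample.int(30L, 1L)
    kept_before <- nrow(apply_support_filter(e)) == 1L
    minority <- if (e$inclusion_support <= e$exclusion_support)
      "inclusion_support" else "exclusion_support"
    e[[minority]] <- e[[minority]] + 1L
    kept_after <- nrow(apply_support_filter(e)) == 1L
    if (kept_before) expect_true(kept_after)
  }
})

test_that("each detected event carries exactly one type and counts are order-invariant", {
  cfg <- sim_config(seed = 89, n_genes = 10, as_event_rate = 1,
                    est_count_per_gene = 10, est_error_rate = 0,
                    est_partial_fraction = 0, minor_variant_frequency = 0.5)
  sim <- simulate_genome(cfg)
  reads <- simulate_ests(sim, cfg)
  res1 <- run_as_pipeline(sim$genome, reads$ests, verbose = FALSE)
  perm <- sample(length(reads$ests))
  res2 <- run_as_pipeline(sim$genome, reads$ests[perm], verbose = FALSE)
  expect_true(all(res1$events$event_type %in%
                    c("intron_retention", "exon_skipping", "alt5", "alt3",
                      "mutually_exclusive", "complex")))
  expect_equal(table(res1$events$event_type), table(res2$events$event_type))
  k1 <- with(res1$events, order(chrom, start, end))
  k2 <- with(res2$events, order(chrom, start, end))
  expect_equal(res1$events[k1, c("chrom", "start", "end", "event_type")],
               res2$events[k2, c("chrom", "start", "end", "event_type")],
               ignore_attr = TRUE)
})
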