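# Replication-timing quintiles and kataegis / omikli cluster detection.

test_that("quintile assignment ranks bins earliest-first with stable ties", {
  track <- data.frame(contig = "chr1",
                      start = seq(0, 99000, by = 1000),
                      end = seq(1000, 100000, by = 1000),
                      value = 1:100)
  q <- assign_timing_quintiles(track)           # high value = early
  expect_equal(q$quintile[q$value > 80], rep(1L, 20))
  expect_equal(q$quintile[q$value <= 20], rep(5L, 20))
  q2 <- assign_timing_quintiles(track, early_is_high = FALSE)
  expect_equal(q2$quintile[q2$value <= 20], rep(1L, 20))
  # all-equal values: deterministic genomic-order tie break, 20 bins each
  track$value <- 7
  q3 <- assign_timing_quintiles(track)
  expect_equal(unname(table(q3$quintile)), rep(20L, 5), ignore_attr = TRUE)
  expect_equal(q3$quintile[1:20], rep(1L, 20))
  expect_error(assign_timing_quintiles(track[0, ]), "empty")
})

test_that("generator timing tracks round-trip their intended quintiles", {
  g <- test_genome()
  tr <- generate_timing_track(g, 40L, bias = c(2, 1.5, 1, 0.75, 0.5), seed = 70)
  q <- assign_timing_quintiles(tr)
  expect_identical(q$quintile, attr(tr, "quintile"))
  # quintile assignment is invariant under monotone transforms of the values
  tr2 <- tr; tr2$value <- exp(tr$value / max(tr$value))
  expect_identical(assign_timing_quintiles(tr2)$quintile, q$quintile)
  # and under bin-order permutation
  set.seed(71); perm <- sample(nrow(tr))
  q3 <- assign_timing_quintiles(tr[perm, ])
  expect_identical(q3$quintile, q$quintile[perm])
})

test_that("per-quintile mutation counts normalize to the largest quintile", {
  g <- test_genome(); ix <- test_index(); refs <- test_refs()
  tr <- generate_timing_track(g, 50L, bias = c(2, 1, 1, 1, 1), seed = 72)
  q <- assign_timing_quintiles(tr)
  ps <- plant_sbs_from_signatures(g, 6000L, c(flat = 1), refs, seed = 73,
                                  contigs = "chr1", timing = tr, index = ix)
  mq <- mutations_per_quintile(ps$variants, q)
  expect_equal(max(mq$normalized), 1)
  expect_equal(unname(which.max(mq$counts)), 1L)
  expect_true(all(abs(mq$normalized[2:5] - 0.5) < 0.1))
  # identical planting in both groups: chi-square is calibrated
  set.seed(74)
  hits <- vapply(1:1000, function(i) {
    a <- rmultinom(1, 500, rep(0.2, 5)); b <- rmultinom(1, 500, rep(0.2, 5))
    suppressWarnings(stats::chisq.test(cbind(a, b))$p.value) < 0.05
  }, logical(1))
  expect_true(abs(mean(hits) - 0.05) < 0.02)
})

test_that("TC-to-TT percentages reflect the planted profile", {
  g <- test_genome(); ix <- test_index(); refs <- test_refs()
  tr <- generate_timing_track(g, 40L, seed = 75)
  q <- assign_timing_quintiles(tr)
  # pure SBS2: all quintiles near the TC>TT channel mass of the profile
  ps <- plant_sbs_from_signatures(g, 4000L, c(SBS2 = 1), refs, seed = 76,
                                  contigs = "chr1", index = ix)
  pct <- tcw_to_t_fraction_per_quintile(ps$variants, q, g, index = ix)
  ch <- sbs_channels()
  mass <- 100 * sum(refs[ch$sub == "C>T" & ch$five == "T", "SBS2"])
  expect_true(all(abs(pct - mass) < 8, na.rm = TRUE))
  # a cohort without TC>TT yields zero everywhere
  ps2 <- plant_sbs_from_signatures(g, 1000L, c(SBS13 = 1), refs, seed = 77,
                                   contigs = "chr1", index = ix)
  pct2 <- tcw_to_t_fraction_per_quintile(ps2$variants, q, g, index = ix)
  expect_true(all(pct2 == 0, na.rm = TRUE))
  # empty quintile is NA, not zero
  few <- ps$variants[1:3, ]
  pct3 <- tcw_to_t_fraction_per_quintile(few, q, g, index = ix)
  expect_true(any(is.na(pct3)))
})

test_that("cluster detection partitions variants into the adopted classes", {
  mk <- function(pos) data.frame(contig = "chr1", pos = as.integer(pos),
                                 ref = "C", alt = "T", variant_class = "SBS",
                                 sample_id = "s")
  # six mutations 100 bp apart: one kataegis call
  k <- detect_clusters(mk(seq(1000, by = 100, length.out = 6)))
  expect_equal(nrow(k), 1L)
  expect_equal(k$class, "kataegis")
  expect_equal(k$n_members, 6L)
  # two mutations 5 kb apart, isolated: omikli
  o <- detect_clusters(mk(c(50000, 55000)))
  expect_equal(o$class, "omikli")
  # a 6-member run at 5 kb spacing is neither kataegis nor omikli
  d <- detect_clusters(mk(seq(1e5, by = 5000, length.out = 6)))
  expect_true(all(d$class == "dispersed"))
  # partition property on a mixed set
  v <- mk(c(seq(1000, by = 100, length.out = 7), 30000, 31000, 500000))
  cl <- detect_clusters(v)
  expect_equal(sum(cl$n_members), nrow(v))
})

test_that("genome-density mutations are overwhelmingly dispersed", {
  # uniform mutations at ~1/Mb: the chance of a neighbour within 10 kb is
  # about 1%, so about 98% of mutations stay dispersed
  set.seed(78)
  pos <- sort(sample.int(2e8, 200))
  v <- data.frame(contig = "chr1", pos = pos, ref = "C", alt = "T",
                  variant_class = "SBS", sample_id = "s")
  cl <- detect_clusters(v)
  disp <- sum(cl$n_members[cl$class == "dispersed"])
  expect_gte(disp / nrow(v), 0.97)
})
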