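# TCW enrichment: window census against brute-force oracles, the score
# arithmetic, exact significance, BH adjustment and stratification.

test_that("window censuses match the brute-force oracle on hand-built 41-mers", {
  # a fixed 41-mer with the mutated TCA cytosine at its center
  s41 <- "GGATTTCATTAAGGATTATGTCAGGATTAAGGATTTCTAAG"
  expect_equal(nchar(s41), 41L)
  g <- string_genome(chr1 = s41, chrM = "ACGTACGT")
  v <- data.frame(contig = "chr1", pos = 22L, ref = "C", alt = "T",
                  variant_class = "SBS", sample_id = "s")
  expect_equal(substr(s41, 21, 23), "TCA")
  cnt <- collect_enrichment_counts(v, g)
  oracle <- oracle_window_census(s41, 22L)
  expect_equal(cnt$mut_tcw, 1L)
  expect_equal(cnt$mut_c, 1L)
  expect_equal(cnt$con_tcw, unname(oracle["con_tcw"]))
  expect_equal(cnt$con_c, unname(oracle["con_c"]))

  # a G>A call is counted through the reverse complement: + strand reads WGA
  gg <- string_genome(chr1 = chartr("ACGT", "TGCA", paste(rev(strsplit(s41, "")[[1]]), collapse = "")),
                      chrM = "ACGTACGT")
  vg <- data.frame(contig = "chr1", pos = 20L, ref = "G", alt = "A",
                   variant_class = "SBS", sample_id = "s")
  cg <- collect_enrichment_counts(vg, gg)
  expect_equal(cg$mut_tcw, 1L)
  expect_equal(cg$con_tcw, cnt$con_tcw)
  expect_equal(cg$con_c, cnt$con_c)
})

test_that("overlapping windows double-count by design", {
  g <- test_genome(); ix <- test_index()
  s <- g$contigs[["chr1"]]
  # two informative sites 10 bp apart
  csites <- which(strsplit(s, "")[[1]] %in% c("C", "G"))
  p1 <- csites[500]
  p2 <- csites[csites > p1 & csites <= p1 + 10][1]
  v <- data.frame(contig = "chr1", pos = c(p1, p2), ref = substring(s, c(p1, p2), c(p1, p2)),
                  alt = "N", variant_class = "SBS", sample_id = "s")
  v$alt <- ifelse(v$ref == "C", "T", "A")
  cnt <- collect_enrichment_counts(v, g, index = ix)
  o1 <- oracle_window_census(s, p1); o2 <- oracle_window_census(s, p2)
  expect_equal(cnt$con_c, unname(o1["con_c"] + o2["con_c"]))
  expect_equal(cnt$con_tcw, unname(o1["con_tcw"] + o2["con_tcw"]))
  expect_equal(cnt$mut_c, 2L)
  # aggregation is order-independent
  cnt_rev <- collect_enrichment_counts(v[2:1, ], g, index = ix)
  expect_identical(cnt[c("mut_tcw", "mut_c", "con_tcw", "con_c")],
                   cnt_rev[c("mut_tcw", "mut_c", "con_tcw", "con_c")])
})

test_that("the enrichment score is the printed double ratio", {
  counts <- list(mut_tcw = 10, mut_c = 10, con_tcw = 25, con_c = 100)
  expect_equal(apobec_enrichment_score(counts), 4.0)
  # proportional counts give exactly 1
  expect_equal(apobec_enrichment_score(list(mut_tcw = 5, mut_c = 20,
                                            con_tcw = 25, con_c = 100)), 1.0)
  expect_error(apobec_enrichment_score(list(mut_tcw = 1, mut_c = 0,
                                            con_tcw = 5, con_c = 10)), "undefined")
  expect_error(apobec_enrichment_score(list(mut_tcw = 1, mut_c = 5,
                                            con_tcw = 0, con_c = 10)), "undefined")
})

test_that("one-sided significance equals exact hypergeometric enumeration", {
  cases <- list(c(10, 0, 25, 75), c(5, 15, 25, 75), c(0, 10, 25, 75),
                c(7, 3, 12, 40), c(1, 1, 1, 1))
  for (cs in cases) {
    got <- enrichment_significance(list(mut_tcw = cs[1], mut_c = cs[1] + cs[2],
                                        con_tcw = cs[3], con_c = cs[3] + cs[4]))
    want <- oracle_fisher_greater(cs[1], cs[2], cs[3], cs[4])
    expect_equal(got$p_value, want, tolerance = 1e-12)
  }
  # proportional table: no enrichment, p at least 0.5
  p_prop <- enrichment_significance(list(mut_tcw = 5, mut_c = 20,
                                         con_tcw = 25, con_c = 100))$p_value
  expect_gte(p_prop, 0.5)
  # maximal anti-enrichment
  p_anti <- enrichment_significance(list(mut_tcw = 0, mut_c = 10,
                                         con_tcw = 25, con_c = 100))
  expect_equal(p_anti$p_value, 1)
  expect_equal(p_anti$odds_direction, "depletion")
})

test_that("BH adjustment matches its step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  set.seed(51)
  p <- runif(100)
  expect_equal(adjust_bh(p), oracle_bh(p), tolerance = 1e-12)
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("stratification requires both significance and direction", {
  res <- data.frame(sample_id = c("a", "b", "c"),
                    score = c(1.8, 1.8, 0.7),
                    q_value = c(0.05, 0.5, 0.05))
  out <- stratify_samples(res)
  expect_equal(out$stratum, c("ES_high", "ES_low", "ES_low"))
})

test_that("planted TCW enrichment is recovered, with the small window-census bias", {
  g <- test_genome(); ix <- test_index()
  # null: uniform cytosine mutations. The 41-base window census has a known
  # upward bias of ~5% (positions adjacent to a cytosine can never be TCW
  # centers, which depletes Con_TCW relative to the genome-wide fraction
  # governing Mut_TCW); see the methods vignette.
  scores <- vapply(1:60, function(k) {
    pe <- plant_enriched_cytosine_mutations(g, 800L, fold = 1, seed = 600 + k,
                                            index = ix)
    apobec_enrichment_score(collect_enrichment_counts(pe$variants, g, index = ix))
  }, numeric(1))
  expect_true(abs(mean(scores) - 1.05) < 0.05)
  # planted folds are recovered to within 15% and in order
  got <- vapply(c(1.5, 2, 3), function(f) {
    pe <- plant_enriched_cytosine_mutations(g, 5000L, fold = f, seed = 700, index = ix)
    apobec_enrichment_score(collect_enrichment_counts(pe$variants, g, index = ix))
  }, numeric(1))
  expect_true(all(abs(got / c(1.5, 2, 3) - 1) < 0.15))
  expect_true(all(diff(got) > 0))
})

test_that("the score is invariant under genome-wide reverse complement", {
  g <- test_genome(); ix <- test_index()
  pe <- plant_enriched_cytosine_mutations(g, 1000L, fold = 2, seed = 55, index = ix)
  c1 <- collect_enrichment_counts(pe$variants, g, index = ix)
  grc <- revcomp_genome(g)
  lens <- nchar(g$contigs)
  v <- pe$variants
  v$pos <- lens[v$contig] - v$pos + 1L
  v$ref <- chartr("ACGT", "TGCA", v$ref)
  v$alt <- chartr("ACGT", "TGCA", v$alt)
  c2 <- collect_enrichment_counts(v, grc)
  expect_identical(c1[c("mut_tcw", "mut_c", "con_tcw", "con_c")],
                   c2[c("mut_tcw", "mut_c", "con_tcw", "con_c")])
})

test_that("empty input and the TCA-only mode behave as documented", {
  g <- test_genome()
  expect_error(collect_enrichment_counts(empty_variants_df(), g),
               "no_informative_mutations")
  ix <- test_index()
  pe <- plant_enriched_cytosine_mutations(g, 500L, fold = 1, seed = 56, index = ix)
  tcw <- collect_enrichment_counts(pe$variants, g, index = ix, motif = "TCW")
  tca <- collect_enrichment_counts(pe$variants, g, index = ix, motif = "TCA")
  expect_lte(tca$mut_tcw, tcw$mut_tcw)
  expect_lt(tca$con_tcw, tcw$con_tcw)
})
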