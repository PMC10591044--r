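# Synthetic genome / variant generator: determinism, composition, and
# exact agreement between planted truth and downstream classification.

test_that("generated genomes hit the requested composition", {
  g <- generate_genome(1, 100000L, 0.5, seed = 7)
  s <- g$contigs[["chr1"]]
  expect_equal(nchar(s), 100000L)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  expect_true(abs(gc - 0.5) < 0.02)
  expect_false(grepl("[^ACGT]", s))
  expect_true("chrM" %in% names(g$contigs))

  # trinucleotide frequencies follow the independence expectation
  g2 <- generate_genome(1, 200000L, 0.41, seed = 3)
  tri <- Biostrings::trinucleotideFrequency(
    Biostrings::DNAString(g2$contigs[["chr1"]]))
  expected <- (0.41 / 2) * ((1 - 0.41) / 2)^2 * (200000 - 2)
  expect_true(abs(tri[["TCA"]] / expected - 1) < 0.2)
})

test_that("generation is deterministic and validates its inputs", {
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(generate_genome(2, c(50000L, 1000L), 0.42, seed = 1), f1)
  write_genome_fasta(generate_genome(2, c(50000L, 1000L), 0.42, seed = 1), f2)
  expect_identical(readLines(f1), readLines(f2))
  rt <- read_genome_fasta(f1)
  expect_identical(rt$contigs, generate_genome(2, c(50000L, 1000L), 0.42, seed = 1)$contigs)
  expect_error(generate_genome(1, -5L, 0.5, seed = 1), "length")
  expect_error(generate_genome(1, 100L, 1.2, seed = 1), "gc_fraction")
})

test_that("planted SBS follow the requested signature mixture", {
  g <- test_genome(); ix <- test_index(); refs <- test_refs()
  ps <- plant_sbs_from_signatures(g, 1000L, c(SBS2 = 1), refs, seed = 2, index = ix)
  expect_equal(nrow(ps$variants), 1000L)
  # every event is C>T on the pyrimidine strand at a TC dinucleotide
  chan <- trinucleotide_context(ps$variants, g, index = ix)
  expect_identical(as.integer(chan), ps$ledger$planted_sbs$channel)
  ch <- sbs_channels()
  expect_true(all(ch$sub[chan] == "C>T"))
  # channel counts match the SBS2 multinomial (cells pooled below expected 5)
  p <- as.numeric(refs[, "SBS2"])
  obs <- tabulate(chan, 96)
  big <- p * 1000 >= 5
  o <- c(obs[big], sum(obs[!big])); e <- c(p[big], sum(p[!big]))
  gof <- stats::chisq.test(o, p = e / sum(e))
  expect_gt(gof$p.value, 0.001)
})

test_that("a flat mixture spreads uniformly across channels", {
  g <- test_genome(); ix <- test_index(); refs <- test_refs()
  ps <- plant_sbs_from_signatures(g, 9600L, c(flat = 1), refs, seed = 4, index = ix)
  counts <- tabulate(ps$ledger$planted_sbs$channel, 96)
  expect_true(all(abs(counts - 100) <= 40))
  # positions are unique: a site hosts at most one event
  expect_false(any(duplicated(paste0(ps$variants$contig, ":", ps$variants$pos))))
  # ref base truth: planted ref equals the genome base
  s <- g$contigs[["chr1"]]
  on1 <- ps$variants[ps$variants$contig == "chr1", ]
  expect_identical(substring(s, on1$pos, on1$pos), on1$ref)
})

test_that("planting zero mutations yields an empty, well-formed result", {
  g <- test_genome()
  ps <- plant_sbs_from_signatures(g, 0L, c(flat = 1), test_refs(), seed = 1,
                                  index = test_index())
  expect_equal(nrow(ps$variants), 0L)
  expect_equal(nrow(ps$ledger$planted_sbs), 0L)
})

test_that("read support honours the clean-variant contract and the ledger", {
  g <- test_genome()
  ps <- plant_sbs_from_signatures(g, 1000L, c(flat = 1), test_refs(), seed = 6,
                                  contigs = "chr1", index = test_index())
  clean <- attach_read_support(ps$variants, 30, 0.3, 0, seed = 7)$variants
  expect_true(all(clean$alt_reads >= 3 & clean$total_reads >= 10 & clean$vaf > 0.05))
  # mean depth tracks depth_mean
  big <- attach_read_support(ps$variants[rep(1:1000, 10), ], 10, 0.5, 0, seed = 8)$variants
  expect_true(abs(mean(big$total_reads) / 10 - 1) < 0.1)
  # flagged contaminants are exactly the filter-removed set
  rs <- attach_read_support(ps$variants, 30, 0.3, 0.3, seed = 9, ledger = ps$ledger)
  fl <- apply_quality_filters(rs$variants)
  expect_setequal(paste0(fl$removed$contig, ":", fl$removed$pos),
                  rs$ledger$contaminated)
})

test_that("planted indels classify back to their intended categories", {
  g <- test_genome()
  counts <- c(del_1bp_TA = 25, del_1bp_CG = 15, ins_1bp_TA = 10, ins_1bp_CG = 10,
              indel_2bp = 8, indel_3bp = 8, indel_4bp = 8,
              del_2bp_MH = 10, del_3bp_MH = 20, del_4bp_MH = 10, indel_5plus = 6)
  pi_ <- plant_indels(g, counts, seed = 5)
  expect_identical(classify_indel(pi_$variants, g),
                   pi_$ledger$planted_indels$category)
  cat_ <- build_indel_catalog(pi_$variants, g)
  expect_identical(unname(unclass(cat_)[names(counts)]), unname(as.integer(counts)))
  # empty request
  p0 <- plant_indels(g, c(), seed = 1)
  expect_equal(nrow(p0$variants), 0L)
  expect_error(plant_indels(g, c(bogus = 3), seed = 1), "unknown")
})

test_that("timing track tiles the genome and biases planting as requested", {
  g <- test_genome(); ix <- test_index(); refs <- test_refs()
  tr <- generate_timing_track(g, 50L, bias = rep(1, 5), seed = 10)
  expect_true(all(tr$end - tr$start == tr$end[1] - tr$start[1]))
  expect_false("chrM" %in% tr$contig)
  q <- attr(tr, "quintile")
  expect_true(all(abs(table(q) - nrow(tr) / 5) <= 1))

  # uniform bias: quintile shares 20% +/- 2%
  ps <- plant_sbs_from_signatures(g, 5000L, c(flat = 1), refs, seed = 11,
                                  contigs = "chr1", timing = tr, index = ix)
  qq <- assign_timing_quintiles(tr)
  shares <- mutations_per_quintile(ps$variants, qq)$counts / 5000
  expect_true(all(abs(shares - 0.2) < 0.02))

  # Q1 at twice the rate: share 1/3 +/- 3%
  tr2 <- generate_timing_track(g, 50L, bias = c(2, 1, 1, 1, 1), seed = 12)
  ps2 <- plant_sbs_from_signatures(g, 6000L, c(flat = 1), refs, seed = 13,
                                   contigs = "chr1", timing = tr2, index = ix)
  sh2 <- mutations_per_quintile(ps2$variants, assign_timing_quintiles(tr2))$counts / 6000
  expect_true(abs(sh2[["Q1"]] - 2 / 6) < 0.03)

  # degenerate tiling: 5 bins on a 5 kb contig, one bin per quintile
  g5 <- string_genome(chr1 = strrep("ACGT", 1250), chrM = strrep("ACGT", 100))
  tr5 <- generate_timing_track(g5, 5L, seed = 1)
  expect_equal(nrow(tr5), 5L)
  expect_setequal(attr(tr5, "quintile"), 1:5)
})

test_that("generator output is deterministic down to VCF bytes", {
  g <- test_genome()
  run <- function() {
    ps <- plant_sbs_from_signatures(g, 200L, c(flat = 1), test_refs(), seed = 14,
                                    index = test_index())
    rs <- attach_read_support(ps$variants, 30, 0.3, 0.1, seed = 15)
    f <- tempfile(fileext = ".vcf")
    write_somatic_vcf(rs$variants, f, genome = g)
    readLines(f)
  }
  expect_identical(run(), run())
})
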