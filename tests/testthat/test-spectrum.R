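# SBS-96 catalogs (pyrimidine normalization, strand symmetry), indel
# classification with microhomology, and structural-variant tallies.

test_that("trinucleotide channels are pyrimidine-normalized", {
  g <- string_genome(chr1 = "AATCAGGTGAAA", chrM = "ACGTACGT")
  # + strand: T C A at positions 3-5, C>T -> T[C>T]A
  v1 <- data.frame(contig = "chr1", pos = 4L, ref = "C", alt = "T",
                   variant_class = "SBS", sample_id = "s")
  ch <- sbs_channels()
  expect_equal(ch$channel[trinucleotide_context(v1, g)], "T[C>T]A")
  # purine reference: T G A at 8-10 reverse-complements to T C A; G>A -> T[C>T]A
  v2 <- data.frame(contig = "chr1", pos = 9L, ref = "G", alt = "A",
                   variant_class = "SBS", sample_id = "s")
  expect_equal(ch$channel[trinucleotide_context(v2, g)], "T[C>T]A")
  # contig end and ambiguous context are excluded with reasons
  gn <- string_genome(chr1 = "ACNTA", chrM = "ACGT")
  v3 <- data.frame(contig = "chr1", pos = c(1L, 2L), ref = c("A", "C"),
                   alt = c("T", "T"), variant_class = "SBS", sample_id = "s")
  chan <- trinucleotide_context(v3, gn)
  expect_true(all(is.na(chan)))
  expect_equal(attr(chan, "reason"), c("truncated_context", "ambiguous_context"))
})

test_that("catalogs conserve counts and recover planted spectra", {
  g <- test_genome(); ix <- test_index(); refs <- test_refs()
  ps <- plant_sbs_from_signatures(g, 1000L, c(SBS2 = 1), refs, seed = 30, index = ix)
  cat96 <- build_sbs_catalog(ps$variants, g, index = ix)
  expect_equal(sum(cat96), 1000L)
  expect_gte(cosine_similarity(as.numeric(cat96), as.numeric(refs[, "SBS2"])), 0.97)
  # empty input: valid zero catalog
  z <- build_sbs_catalog(ps$variants[0, ], g, index = ix)
  expect_equal(sum(z), 0L)
  # 50/50 mixture: the SBS2 TCW channels jointly hold about half the SBS2 mass
  ps2 <- plant_sbs_from_signatures(g, 4000L, c(SBS2 = 0.5, flat = 0.5), refs,
                                   seed = 31, index = ix)
  cat2 <- build_sbs_catalog(ps2$variants, g, index = ix)
  ch <- sbs_channels()
  tcw_ch <- ch$sub == "C>T" & ch$five == "T" & ch$three %in% c("A", "T")
  expected <- 4000 * (0.5 * sum(refs[tcw_ch, "SBS2"]) + 0.5 * sum(tcw_ch) / 96)
  expect_true(abs(sum(cat2[tcw_ch]) / expected - 1) < 0.1)
})

test_that("the full catalog is invariant under genome-wide reverse complement", {
  g <- test_genome(); ix <- test_index()
  ps <- plant_sbs_from_signatures(g, 1000L, c(flat = 1), test_refs(), seed = 32,
                                  index = ix)
  cat_f <- build_sbs_catalog(ps$variants, g, index = ix)
  grc <- revcomp_genome(g)
  lens <- nchar(g$contigs)
  vrc <- ps$variants
  vrc$pos <- lens[vrc$contig] - vrc$pos + 1L
  vrc$ref <- chartr("ACGT", "TGCA", vrc$ref)
  vrc$alt <- chartr("ACGT", "TGCA", vrc$alt)
  cat_r <- build_sbs_catalog(vrc, grc)
  expect_identical(unclass(cat_f)[1:96], unclass(cat_r)[1:96])
})

test_that("indel classification follows size, base and microhomology rules", {
  #            123456789012345678
  g <- string_genome(chr1 = "GGTAGACTACGTTTGCAC", chrM = "ACGTACGT")
  del1 <- data.frame(contig = "chr1", pos = 3L, ref = "TA", alt = "T",
                     variant_class = "DEL", sample_id = "s")
  expect_equal(classify_indel(del1, g), "del_1bp_TA")
  # deletion of ACT followed immediately by ACG: 2 bp homology "AC"
  g2 <- string_genome(chr1 = "TTGACTACGTT", chrM = "ACGT")
  del3 <- data.frame(contig = "chr1", pos = 3L, ref = "GACT", alt = "G",
                     variant_class = "DEL", sample_id = "s")
  expect_equal(classify_indel(del3, g2), "del_3bp_MH")
  # 12 bp insertion routes to 5plus
  ins12 <- data.frame(contig = "chr1", pos = 5L, ref = "G",
                      alt = paste0("G", strrep("AT", 6)),
                      variant_class = "INS", sample_id = "s")
  expect_equal(classify_indel(ins12, g), "indel_5plus")
})

test_that("microhomology calls agree with a brute-force span/flank oracle", {
  g <- test_genome()
  s <- g$contigs[["chr1"]]
  set.seed(40)
  for (i in 1:200) {
    L <- sample(2:4, 1)
    p <- sample(100:(nchar(s) - 100), 1)
    anchor <- substr(s, p, p)
    span <- substr(s, p + 1, p + L)
    if (anchor == substr(span, L, L)) next   # avoid shiftable representations
    v <- data.frame(contig = "chr1", pos = p, ref = paste0(anchor, span),
                    alt = anchor, variant_class = "DEL", sample_id = "s")
    got <- classify_indel(v, g)
    mh <- oracle_mh_length(span, substr(s, p + L + 1, p + 2 * L))
    want <- if (mh >= 2) paste0("del_", L, "bp_MH") else paste0("indel_", L, "bp")
    expect_equal(got, want)
  }
})

test_that("structural variants tally by type with breakend deduplication", {
  recs <- data.frame(
    contig = c("chr1", "chr2"), pos = c(100L, 5000L), id = c("b1", "b2"),
    ref = c("A", "T"), alt = c("A[chr2:5000[", "]chr1:100]T"),
    info = c("SVTYPE=BND;MATEID=b2", "SVTYPE=BND;MATEID=b1"),
    stringsAsFactors = FALSE)
  tl <- tally_structural_variants(recs)
  expect_equal(unname(unclass(tl)["translocation"]), 1L)
  expect_equal(attr(tl, "total"), 1L)
  # a 400 bp symbolic deletion is neither indel nor SV deletion
  recs2 <- data.frame(contig = "chr1", pos = 1000L, id = "d1", ref = "A",
                      alt = "<DEL>", info = "SVTYPE=DEL;END=1400")
  tl2 <- tally_structural_variants(recs2)
  expect_equal(attr(tl2, "total"), 0L)
  expect_equal(attr(tl2, "skipped_midsize"), 1L)
  # dangling mate counts once as complex, with a warning
  recs3 <- recs[1, ]; recs3$info <- "SVTYPE=BND;MATEID=zz"
  expect_warning(tl3 <- tally_structural_variants(recs3), "dangling")
  expect_equal(unname(unclass(tl3)["complex"]), 1L)
})

test_that("planted SVs round-trip through VCF into an exact tally", {
  g <- generate_genome(2, c(40000L, 30000L), 0.45, seed = 43)  # 2 autosomes for translocations
  sv <- plant_svs(g, list(deletion = 2, duplication = 1, inversion = 1,
                          translocation = 2, complex = 1), seed = 41)
  f <- tempfile(fileext = ".vcf")
  write_somatic_vcf(empty_variants_df(), f, genome = g, sv_records = sv$records)
  tl <- tally_structural_variants(read_sv_vcf(f))
  expect_equal(attr(tl, "total"), 7L)
  expect_equal(unname(unclass(tl)[c("deletion", "duplication", "inversion",
                                    "translocation", "complex")]),
               c(2L, 1L, 1L, 2L, 1L))
})

test_that("catalog TSVs round-trip in COSMIC layout", {
  g <- test_genome(); ix <- test_index()
  ps <- plant_sbs_from_signatures(g, 300L, c(flat = 1), test_refs(), seed = 42,
                                  index = ix)
  cat96 <- build_sbs_catalog(ps$variants, g, sample_id = "s1", index = ix)
  f <- tempfile(fileext = ".tsv")
  write_catalog_tsv(list(cat96), f)
  back <- read_catalog_tsv(f)[["s1"]]
  expect_identical(unclass(back)[1:96], unclass(cat96)[1:96])
})
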