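test_that("region_set validates, sorts and names BED intervals", {
  rs <- region_set(data.frame(chrom = c("chr2", "chr1", "chr1"),
                              start = c(50, 300, 100),
                              end = c(150, 400, 200)))
  expect_s4_class(rs, "GRanges")
  expect_equal(as.character(GenomicRanges::seqnames(rs)),
               c("chr1", "chr1", "chr2"))
  expect_equal(GenomicRanges::start(rs), c(101, 301, 51))  # 1-based internal
  expect_equal(GenomicRanges::end(rs), c(200, 400, 150))   # end unchanged
  expect_false(anyDuplicated(names(rs)) > 0)

  expect_error(region_set("chr1", start = 10, end = 10), "BED convention")
  expect_error(region_set("chr1", start = -1, end = 10), "BED convention")
  expect_error(region_set(c("chr1", "chr1"), start = c(0, 0),
                          end = c(10, 10), name = c("a", "a")),
               "unique")
  expect_error(region_set("chr1", start = 0, end = 10, summit = 10),
               "summit")
})

test_that("as_bed_df inverts region_set exactly", {
  df <- data.frame(chrom = c("chr1", "chr1"), start = c(100, 500),
                   end = c(200, 900), name = c("a", "b"),
                   score = c(1.5, 2.5), strand = c("+", "-"),
                   stringsAsFactors = FALSE)
  out <- as_bed_df(region_set(df))
  expect_equal(out[, colnames(df)], df)
})

test_that("BED files round-trip through read_bed/write_bed", {
  rs <- region_set(data.frame(chrom = "chr1", start = c(100, 700),
                              end = c(300, 1200), name = c("p1", "p2"),
                              score = c(3, 8), strand = c("+", "-"),
                              summit = c(50, 100)))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(rs, path)
  back <- read_bed(path, summit = TRUE)
  expect_equal(as_bed_df(back), as_bed_df(rs))
})

test_that("consensus footprint matches the worked occupancy example", {
  # replicate A: [100,200); B: [150,250); C: [400,500)
  # core >=2 support is [150,200); footprint is the union of the two
  # supporting peaks, [100,250); the unsupported [400,500) is dropped
  a <- gr("chr1", 100, 200)
  b <- gr("chr1", c(150, 400), c(250, 500))
  out <- consensus_peaks(list(a, b), min_support = 2)
  expect_equal(as_bed_df(out)$start, 100)
  expect_equal(as_bed_df(out)$end, 250)

  core <- consensus_peaks(list(a, b), min_support = 2, footprint = FALSE)
  expect_equal(as_bed_df(core)$start, 150)
  expect_equal(as_bed_df(core)$end, 200)
})

test_that("consensus_peaks validates inputs and handles empties", {
  expect_error(consensus_peaks(list()), "non-empty")
  expect_error(consensus_peaks(list(gr("chr1", 0, 10)), min_support = 2),
               "exceeds")
  expect_length(consensus_peaks(list(gr("chr1", 0, 10),
                                     gr("chr2", 0, 10))), 0)
})

test_that("merge_within is inclusive at exactly the gap", {
  # BED gap between [0,100) and [600,700) is 500
  s <- gr("chr1", c(0, 600), c(100, 700))
  expect_length(merge_within(s, gap = 500), 1)
  expect_length(merge_within(s, gap = 499), 2)
  merged <- merge_within(s, gap = 500)
  expect_equal(as_bed_df(merged)$end - as_bed_df(merged)$start, 700)
  expect_error(merge_within(s, gap = -1), "non-negative")
})

test_that("overlap_counts counts each query once and filters small subjects", {
  q <- gr("chr1", c(0, 1000, 2000), c(500, 1500, 2500))
  s <- gr("chr1", c(100, 200, 2400), c(150, 250, 2450))
  oc <- overlap_counts(q, s)
  expect_equal(oc$k, 2L)  # first query overlaps two subjects, counted once
  expect_equal(oc$n, 3L)
  # subject widths are 50; a 500 bp floor removes them all
  expect_equal(overlap_counts(q, s, min_subject_size = 500)$k, 0L)
  expect_equal(overlap_counts(GenomicRanges::GRanges(), s)$n, 0L)
})

test_that("annotate_regions applies the fixed category priority", {
  genes <- data.frame(
    gene_id = "g1", chrom = "chr1", strand = "+",
    tx_start = 10000, tx_end = 20000, cds_start = 11000, cds_end = 19000,
    exon_starts = "10000,14000,18000", exon_ends = "11500,15000,20000",
    tss = 10000, stringsAsFactors = FALSE)
  # region_set sorts by (chrom, start); starts given in sorted order
  regions <- gr("chr1",
                c(8100, 10400, 10900, 12000, 14200, 19400, 40000),
                c(8300, 10600, 11100, 12200, 14400, 19600, 41000))
  cats <- annotate_regions(regions, genes)
  expect_equal(cats, c("promoter",            # midpoint 8200, within 2 kb
                       "promoter",            # midpoint 10500
                       "promoter",            # promoter beats 5' UTR
                       "intron",              # 12100: gene body, non-exonic
                       "exon",                # 14300, internal exon
                       "three_utr",           # 19500: exonic beyond cds_end
                       "distal_intergenic"))
  # 5' UTR: exonic bp before the CDS, outside the promoter window
  far <- data.frame(genes, stringsAsFactors = FALSE)
  far$cds_start <- 14800
  cats2 <- annotate_regions(gr("chr1", 13000, 13200), far)
  expect_equal(cats2, "intron")  # midpoint 13100: non-exonic gene body
  cats3 <- annotate_regions(gr("chr1", 14300, 14500), far)
  expect_equal(cats3, "five_utr")  # midpoint 14400: exon 2, pre-CDS
})

test_that("annotate_regions warns on unknown chromosomes", {
  genes <- data.frame(
    gene_id = "g1", chrom = "chr1", strand = "+",
    tx_start = 0, tx_end = 1000, cds_start = 100, cds_end = 900,
    exon_starts = "0", exon_ends = "1000", tss = 0, stringsAsFactors = FALSE)
  expect_warning(out <- annotate_regions(gr("chrUn", 0, 100), genes),
                 "absent")
  expect_equal(out, "distal_intergenic")
})

test_that("gene_tss is strand-aware and flankable", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = c("+", "-"),
                      tx_start = c(1000, 5000), tx_end = c(2000, 6000),
                      cds_start = c(1100, 5100), cds_end = c(1900, 5900),
                      exon_starts = c("1000", "5000"),
                      exon_ends = c("2000", "6000"),
                      tss = c(1000, 6000), stringsAsFactors = FALSE)
  tss <- gene_tss(genes)
  expect_equal(GenomicRanges::start(tss), c(1001, 6001))
  expect_equal(names(tss), c("g1", "g2"))
  flanked <- gene_tss(genes, flank = 500)
  expect_equal(GenomicRanges::width(flanked), c(1001, 1001))
  expect_equal(GenomicRanges::start(flanked), c(501, 5501))
})

test_that("gene tables round-trip and derive the strand-aware TSS", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = c("+", "-"),
                      tx_start = c(1000, 5000), tx_end = c(2000, 6000),
                      cds_start = c(1100, 5100), cds_end = c(1900, 5900),
                      exon_starts = c("1000", "5000"),
                      exon_ends = c("2000", "6000"),
                      stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(genes, path)
  back <- read_gene_table(path)
  expect_equal(back$tss, c(1000, 6000))  # plus: tx_start; minus: tx_end
  expect_equal(back[, colnames(genes)], genes)
})
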