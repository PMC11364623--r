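test_that("kmeans cluster labels are ordered by mutant/control ratio", {
  set.seed(1)
  # 30 regions losing signal (ratio ~0.1) and 30 keeping it (~1.0)
  ctl <- matrix(rnorm(60 * 8, 10, 0.1), nrow = 60)
  mut <- rbind(matrix(rnorm(30 * 8, 1, 0.1), nrow = 30),
               matrix(rnorm(30 * 8, 10, 0.1), nrow = 30))
  rownames(ctl) <- rownames(mut) <- paste0("r", 1:60)
  res <- kmeans_cluster_regions(ctl, mut, k = 2, seed = 1)
  expect_equal(unname(res$label[1:30]), rep("Cluster1", 30))
  expect_equal(unname(res$label[31:60]), rep("Cluster2", 30))
  expect_lt(mean(res$ratio[res$label == "Cluster1"]),
            mean(res$ratio[res$label == "Cluster2"]))
  # swapping the halves swaps the assignment but not the label semantics
  res2 <- kmeans_cluster_regions(ctl, mut[60:1, ], k = 2, seed = 1)
  expect_equal(unname(res2$label[1:30]), rep("Cluster2", 30))
})

test_that("kmeans detects degenerate inputs", {
  ctl <- matrix(5, nrow = 4, ncol = 3)
  mut <- matrix(5, nrow = 4, ncol = 3)
  rownames(ctl) <- rownames(mut) <- paste0("r", 1:4)
  res <- kmeans_cluster_regions(ctl, mut, k = 2, seed = 1)
  expect_true(res$degenerate)
  expect_error(kmeans_cluster_regions(ctl[1, , drop = FALSE],
                                      mut[1, , drop = FALSE], k = 2),
               "exceeds")
})

test_that("restarted kmeans attains the brute-force optimum on 6 points", {
  set.seed(3)
  ctl <- matrix(rnorm(6 * 2, 8, 1), nrow = 6)
  mut <- matrix(rnorm(6 * 2, 4, 2), nrow = 6)
  rownames(ctl) <- rownames(mut) <- paste0("r", 1:6)
  res <- kmeans_cluster_regions(ctl, mut, k = 2, restarts = 20, seed = 1)
  # enumerate all 2^5 - 1 nonempty bipartitions on the same feature space
  feats <- log2(cbind(ctl, mut) + 1)
  best <- Inf
  for (code in 1:31) {
    grp <- as.integer(intToBits(code))[1:6]
    if (length(unique(grp)) < 2) next
    ss <- 0
    for (g in 0:1) {
      sub <- feats[grp == g, , drop = FALSE]
      ss <- ss + sum(sweep(sub, 2, colMeans(sub))^2)
    }
    best <- min(best, ss)
  }
  expect_equal(res$withinss, best, tolerance = 1e-8)
})

test_that("adjusted_rand_index matches hand-computed values", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  # one point moved between two equal clusters of 4:
  # contingency 4,0 / 1,3: ARI = (a - e) / (max - e) with
  # a = C(4,2)+C(1,2)+C(3,2) pair agreements = 6+0+3 = 9,
  # rows C(4,2)+C(4,2)=12, cols C(5,2)+C(3,2)=13, N=C(8,2)=28
  # e = 12*13/28 = 39/7; max = (12+13)/2 = 12.5
  a <- c(1, 1, 1, 1, 2, 2, 2, 2)
  b <- c(1, 1, 1, 1, 1, 2, 2, 2)
  expect_equal(adjusted_rand_index(a, b),
               (9 - 39 / 7) / (12.5 - 39 / 7))
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_error(adjusted_rand_index(1:3, 1:4))
})

test_that("bivalent calls follow the documented set pipeline", {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1", strand = "+",
    tx_start = c(10000, 50000, 90000), tx_end = c(20000, 60000, 100000),
    cds_start = c(11000, 51000, 91000), cds_end = c(19000, 59000, 99000),
    exon_starts = c("10000", "50000", "90000"),
    exon_ends = c("20000", "60000", "100000"),
    tss = c(10000, 50000, 90000), stringsAsFactors = FALSE)
  # g1: K4 + K27 + PRC2 -> bivalent. g2: K4 only. g3: both marks, no PRC2.
  k4 <- list(gr("chr1", c(9500, 49500, 89500), c(10500, 50500, 90500)),
             gr("chr1", c(9600, 49600, 89600), c(10600, 50600, 90600)))
  k27 <- list(gr("chr1", c(9500, 89500), c(10500, 90500)),
              gr("chr1", c(9600, 89600), c(10600, 90600)))
  prc2 <- gr("chr1", 9000, 11000)
  out <- call_bivalent_promoters(k4, k27, genes, prc2)
  expect_equal(out$bivalent, c(TRUE, FALSE, FALSE))
  expect_true(attr(out, "refined"))
  # without PRC2 refinement g3 becomes bivalent too, with a warning
  expect_warning(un <- call_bivalent_promoters(k4, k27, genes, NULL),
                 "unrefined")
  expect_equal(un$bivalent, c(TRUE, FALSE, TRUE))
  expect_error(call_bivalent_promoters(k4[1], k27, genes, prc2),
               "replicates")
})

test_that("spreading ratios are exact on constant tracks", {
  # control 4 everywhere; mutant 2 within [2000,3000) and 1 outside
  ctl <- binned_track(list(chr1 = rep(4, 20)), bin_size = 250)
  mutv <- rep(1, 20); mutv[9:12] <- 2
  mut <- binned_track(list(chr1 = mutv), bin_size = 250)
  peak <- region_set(data.frame(chrom = "chr1", start = 2000, end = 3000,
                                name = "p1"))
  sp <- spreading_analysis(peak, list(ctl), list(mut), flank = 1000)
  expect_equal(unname(sp$ratios),
               c(2 / 4, 1 / 4, 1 / 4))  # within, upstream, downstream
  expect_length(sp$narrow_peaks, 0)
  narrow <- region_set(data.frame(chrom = "chr1", start = 2000, end = 2100,
                                  name = "tiny"))
  expect_equal(spreading_analysis(narrow, list(ctl), list(mut))$narrow_peaks,
               "tiny")
  expect_error(spreading_analysis(GenomicRanges::GRanges(), list(ctl),
                                  list(mut)), "empty")
})

test_that("spreading separates flank-specific from uniform loss", {
  g <- default_genome()
  ctl <- lapply(1:3, function(r) simulate_tracks(g, "H3K27me3", "control", r))
  k27a <- lapply(1:3, function(r) simulate_tracks(g, "H3K27me3", "K27A", r))
  k9a <- lapply(1:3, function(r) simulate_tracks(g, "H3K27me3", "K9A", r))
  sp_flank <- spreading_analysis(g$suz12, ctl, k27a)
  sp_unif <- spreading_analysis(g$suz12, ctl, k9a)
  # flank-specific: flanks drop well below the within-peak ratio
  expect_lt(sp_flank$ratios[["upstream"]], sp_flank$ratios[["within"]] - 0.1)
  expect_lt(sp_flank$ratios[["downstream"]],
            sp_flank$ratios[["within"]] - 0.1)
  # uniform: all three zones within a whisker of each other
  expect_lt(diff(range(sp_unif$ratios)), 0.05)
})

test_that("enhancer strata follow quantile boundaries with ties to strong", {
  out <- stratify_enhancers(paste0("e", 1:10), as.numeric(1:10))
  # type-7 quantiles of 1..10 at (0.10, 0.40) are 1.9 and 4.6
  expect_equal(table(out$stratum)[["weak"]], 1)
  expect_equal(table(out$stratum)[["medium"]], 3)
  expect_equal(table(out$stratum)[["strong"]], 6)
  expect_equal(out$stratum[out$rpkm == 1], "weak")
  expect_warning(tied <- stratify_enhancers(paste0("e", 1:5), rep(2, 5)),
                 "one stratum")
  expect_equal(unique(tied$stratum), "strong")
  abs_out <- stratify_enhancers(paste0("e", 1:4), c(0.5, 1.5, 3, 9),
                                boundaries = c(1, 5), absolute = TRUE)
  expect_equal(abs_out$stratum, c("weak", "medium", "medium", "strong"))
  expect_error(stratify_enhancers("e1", 1), "length")
  expect_error(stratify_enhancers(paste0("e", 1:3), c(1, NA, 3)), "finite")
})

test_that("ERV activity groups implement the three-way rule", {
  sub <- c("s1", "s2", "s3", "s4")
  out <- classify_erv_groups(
    sub,
    control_k27ac = c(5, 5, 1, 1),
    control_k9me3 = c(1, 5, 5, 5),
    mutant_k27ac = c(5, 7, 6, 1),
    a = 4, m = 3, d = 1)
  expect_equal(out$group, c("i",    # active, low K9me3
                            "ii",   # dual-marked, gains >= d
                            "iii",  # silent in control, active in mutant
                            "unclassified"))
  # defaults use per-mark medians
  med <- classify_erv_groups(sub, c(5, 5, 1, 1), c(1, 5, 5, 5),
                             c(5, 7, 6, 1))
  expect_equal(med$group[4], "unclassified")
})
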