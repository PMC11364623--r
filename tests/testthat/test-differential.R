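make_sheet <- function(n_per, groups = c("control", "K9A")) {
  data.frame(sample = paste0(rep(groups, each = n_per), "_", seq_len(n_per)),
             genotype = rep(groups, each = n_per),
             replicate = rep(seq_len(n_per), length(groups)),
             batch = "b1", stringsAsFactors = FALSE)
}

test_that("size_factors matches the median-of-ratios hand example", {
  # second sample is the first doubled: geometric-mean reference gives
  # ratios sqrt(1/2) and sqrt(2)
  m <- cbind(s1 = c(10, 20, 40), s2 = c(20, 40, 80))
  f <- size_factors(m)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)))
  # normalization by these factors equalizes the two columns
  norm <- sweep(m, 2, f, "/")
  expect_equal(norm[, 1], norm[, 2])
})

test_that("size_factors falls back to library size with a warning", {
  m <- cbind(s1 = c(5, 0), s2 = c(0, 7))  # no all-positive feature
  expect_warning(f <- size_factors(m), "library-size")
  expect_equal(unname(f), c(5, 7) / exp(mean(log(c(5, 7)))))
})

test_that("contrast resolution validates genotypes and replicate counts", {
  sheet <- make_sheet(3)
  m <- matrix(1:18, nrow = 3,
              dimnames = list(paste0("f", 1:3), sheet$sample))
  expect_error(differential_analysis(m, sheet, "K9A:missing"))
  expect_error(differential_analysis(m, sheet[-(1:2), ], "K9A:control"))
  expect_error(differential_analysis(m, sheet, c("a", "b", "c")),
               "contrast")
})

test_that("log2_fold_change uses pseudocounted normalized means", {
  sheet <- make_sheet(2)
  m <- rbind(f1 = c(10, 10, 70, 70), f2 = c(50, 50, 50, 50))
  colnames(m) <- sheet$sample
  lfc <- log2_fold_change(m, sheet, "K9A:control",
                          factors = rep(1, 4))
  expect_equal(unname(lfc["f1"]), log2(71 / 11))
  expect_equal(unname(lfc["f2"]), 0)
})

test_that("bh_adjust reproduces the worked BH example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.02)),
               c(0.04, 0.04, 0.04, 0.04))
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
})

test_that("permutation branch enumerates assignments and is never zero", {
  set.seed(1)
  sheet <- make_sheet(6)  # choose(12, 6) = 924 assignments, enumerable
  m <- matrix(rpois(50 * 12, 50), nrow = 50,
              dimnames = list(paste0("f", 1:50), sheet$sample))
  m[1, sheet$genotype == "K9A"] <- m[1, sheet$genotype == "K9A"] * 20
  p <- permutation_test(m, sheet, "K9A:control")
  expect_true(all(p > 0 & p <= 1))
  # only the identity assignment and its mirror-image complement reach
  # |t_obs|, so the add-one enumeration p is exactly 2/924
  expect_equal(unname(p[1]), 2 / 924)
  # deterministic: same inputs, same p
  expect_identical(p, permutation_test(m, sheet, "K9A:control"))
})

test_that("constant features always get p = 1", {
  sheet <- make_sheet(3)
  m <- matrix(7, nrow = 2, ncol = 6,
              dimnames = list(c("f1", "f2"), sheet$sample))
  m[2, ] <- c(5, 5, 5, 50, 50, 50)
  p <- permutation_test(m, sheet, "K9A:control", factors = rep(1, 6))
  expect_equal(unname(p["f1"]), 1)
  expect_lt(p[["f2"]], 0.01)
})

test_that("the variance-prior fit recovers known hyperparameters", {
  # draw s2 ~ s0^2 * d0 / chisq(d0) * chisq(d)/d with s0 = 2, d0 = 10, d = 4
  set.seed(42)
  d0 <- 10; s0sq <- 4; d <- 4
  sigma2 <- s0sq * d0 / rchisq(20000, df = d0)
  s2 <- sigma2 * rchisq(20000, df = d) / d
  fit <- ervcre:::fit_variance_prior(s2, d)
  expect_equal(fit$d0, d0, tolerance = 0.1)
  expect_equal(fit$s0sq, s0sq, tolerance = 0.05)
  # log-variance spread below the sampling floor -> infinite prior df
  fith <- ervcre:::fit_variance_prior(rep(2, 100), 1000)
  expect_true(is.infinite(fith$d0))
  expect_equal(fith$s0sq, 2 * exp(-digamma(500) + log(500)))
})

test_that("inv_trigamma inverts trigamma across magnitudes", {
  for (y in c(1e-5, 0.01, 0.5, 2, 50, 1e6)) {
    expect_equal(trigamma(ervcre:::inv_trigamma(y)), y,
                 tolerance = 1e-6)
  }
})

test_that("small-sample branch has calibrated p-values under the null", {
  set.seed(7)
  sheet <- make_sheet(3)
  m <- matrix(rnbinom(2000 * 6, mu = 100, size = 10), nrow = 2000,
              dimnames = list(paste0("f", 1:2000), sheet$sample))
  p <- permutation_test(m, sheet, "K9A:control")
  rate <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lte(rate, 0.05 + 3 * se)
  expect_gte(rate, 0.01)  # and not degenerate
})

test_that("call_differential applies both thresholds", {
  res <- data.frame(feature = c("a", "b", "c", "d"),
                    log2fc = c(2, -2, 2, 0.5),
                    padj = c(0.01, 0.01, 0.5, 0.01))
  out <- call_differential(res, padj_cut = 0.05, lfc_cut = 1)
  expect_equal(out$status, c("up", "down", "ns", "ns"))
  # boundary: lfc exactly at the cut is called, padj exactly at cut is not
  res2 <- data.frame(feature = "e", log2fc = 1, padj = 0.05)
  expect_equal(call_differential(res2)$status, "ns")
  res3 <- data.frame(feature = "e", log2fc = 1, padj = 0.049)
  expect_equal(call_differential(res3)$status, "up")
})

test_that("external size factors override internal estimation", {
  sheet <- make_sheet(3)
  set.seed(2)
  m <- matrix(rnbinom(12 * 6, mu = 200, size = 10), nrow = 12,
              dimnames = list(paste0("f", 1:12), sheet$sample))
  ext <- setNames(rep(1, 6), sheet$sample)
  r1 <- differential_analysis(m, sheet, "K9A:control", factors = ext)
  expect_s3_class(r1, "data.frame")
  expect_error(differential_analysis(m, sheet, "K9A:control",
                                     factors = c(bogus = 1)),
               "cover all samples")
})

test_that("count matrices and sample sheets round-trip", {
  sheet <- make_sheet(2)
  m <- matrix(1:8, nrow = 2,
              dimnames = list(c("f1", "f2"), sheet$sample))
  mp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(m, mp)
  write_sample_sheet(sheet, sp)
  expect_equal(read_count_matrix(mp), m)
  expect_equal(read_sample_sheet(sp), sheet)
})
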