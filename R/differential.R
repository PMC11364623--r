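#' Median-of-ratios size factors
#'
#' For each sample, the median over features (with all-positive counts) of
#' the ratio of the count to the feature's geometric mean across samples.
#' When no feature is positive in every sample, falls back to library-size
#' ratios with a warning.
#'
#' @param matrix features x samples matrix of non-negative counts.
#' @return named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(matrix) {
  mat <- as.matrix(matrix)
  pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(pos)) {
    warning("no feature with all-positive counts; falling back to ",
            "library-size ratios")
    libs <- colSums(mat)
    if (any(libs <= 0)) stop("cannot normalize: empty sample column")
    return(libs / exp(mean(log(libs))))
  }
  logs <- log(mat[pos, , drop = FALSE])
  geo <- rowMeans(logs)
  out <- apply(exp(logs - geo), 2, median)
  setNames(out, colnames(mat))
}

## internal: counts scaled by size factors
normalize_counts <- function(matrix, factors = size_factors(matrix)) {
  sweep(as.matrix(matrix), 2, factors, "/")
}

## internal: resolve a "mutant:control" contrast against a sample sheet
contrast_columns <- function(sheet, contrast) {
  if (is.character(contrast) && length(contrast) == 1L)
    contrast <- strsplit(contrast, ":", fixed = TRUE)[[1]]
  if (length(contrast) != 2L)
    stop("contrast must be c(mutant, control) genotype labels")
  mut <- sheet$sample[sheet$genotype == contrast[1]]
  ctl <- sheet$sample[sheet$genotype == contrast[2]]
  if (length(mut) < 2L || length(ctl) < 2L)
    stop("each contrast side needs >= 2 replicates; got ",
         length(mut), " vs ", length(ctl))
  list(mutant = mut, control = ctl)
}

#' Per-feature log2 fold change for a contrast
#'
#' `log2((mean normalized mutant + pseudocount) /
#' (mean normalized control + pseudocount))`.
#'
#' @param matrix features x samples count matrix.
#' @param sheet sample sheet with `sample` and `genotype` columns.
#' @param contrast `c(mutant, control)` genotype labels or `"mutant:control"`.
#' @param pseudocount added to both group means before the log (default 1).
#' @param factors optional precomputed size factors.
#' @return named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(matrix, sheet, contrast, pseudocount = 1,
                             factors = NULL) {
  cols <- contrast_columns(sheet, contrast)
  norm <- normalize_counts(matrix, factors %||% size_factors(matrix))
  m <- rowMeans(norm[, cols$mutant, drop = FALSE])
  c0 <- rowMeans(norm[, cols$control, drop = FALSE])
  setNames(log2((m + pseudocount) / (c0 + pseudocount)), rownames(matrix))
}

#' Moderated-t permutation test for a two-group contrast
#'
#' Works on `log2(normalized count + 1)`. When at least 100 distinct group
#' assignments exist, two-sided p-values come from the permutation
#' distribution of a moderated t,
#' `t_f = dmean_f / sqrt((s2_f + s0^2) * (1/n1 + 1/n2))` with `s0^2` the
#' median pooled within-group variance over features (all assignments are
#' enumerated up to `max_perms`, beyond which they are sampled).
#' Permutation p-values use the add-one rule
#' `p = (1 + #{|t_perm| >= |t_obs|}) / (1 + n_perm)` and are therefore
#' never zero.
#'
#' With fewer than 100 assignments (e.g. 3 vs 3) the permutation
#' distribution is too coarse, so an empirical-Bayes moderated t is used
#' instead: per-feature variances are shrunk towards a common prior,
#' `s_tilde^2 = (d0 * s0^2 + d * s2) / (d0 + d)` with `d = n1 + n2 - 2`,
#' where the prior df `d0` and prior variance `s0^2` are estimated by
#' moment matching on the log variances (the scaled inverse-chi-square
#' hierarchical model of moderated-t analysis). The reference distribution
#' is t with `d + d0` df, so information borrowed across features buys
#' back degrees of freedom that three replicates cannot supply.
#' All-constant features get p = 1.
#'
#' @inheritParams log2_fold_change
#' @param max_perms cap on the number of permutations (default 2000).
#' @param seed seed for permutation sampling when the assignments are not
#'   fully enumerable.
#' @return named numeric vector of p-values.
#' @export
permutation_test <- function(matrix, sheet, contrast, max_perms = 2000,
                             seed = 1, factors = NULL) {
  cols <- contrast_columns(sheet, contrast)
  norm <- normalize_counts(matrix, factors %||% size_factors(matrix))
  x <- log2(norm[, c(cols$mutant, cols$control), drop = FALSE] + 1)
  n1 <- length(cols$mutant)
  n2 <- length(cols$control)
  n <- n1 + n2
  tstat <- function(assign1) {
    g1 <- x[, assign1, drop = FALSE]
    g2 <- x[, -assign1, drop = FALSE]
    m1 <- rowMeans(g1)
    m2 <- rowMeans(g2)
    s2 <- (rowSums((g1 - m1)^2) + rowSums((g2 - m2)^2)) / (n - 2)
    s0 <- median(s2)
    (m1 - m2) / sqrt((s2 + s0) * (1 / n1 + 1 / n2))
  }
  obs <- tstat(seq_len(n1))
  constant <- apply(x, 1, function(r) all(r == r[1]))
  n_assign <- choose(n, n1)
  if (n_assign >= 100) {
    if (n_assign <= max_perms) {
      perms <- combn(n, n1)
    } else {
      perms <- with_seed(substream_seed(seed, "perms", n, n1), {
        vapply(seq_len(max_perms), function(i) sort(sample.int(n, n1)),
               integer(n1))
      })
    }
    exceed <- rep(0L, nrow(x))
    for (j in seq_len(ncol(perms))) {
      tp <- tstat(perms[, j])
      exceed <- exceed + (abs(tp) >= abs(obs) - 1e-12)
    }
    # the add-one rule; the identity assignment is part of the enumeration
    p <- (1 + exceed - (n_assign <= max_perms)) /
      (1 + ncol(perms) - (n_assign <= max_perms))
  } else {
    g1 <- x[, seq_len(n1), drop = FALSE]
    g2 <- x[, -seq_len(n1), drop = FALSE]
    m1 <- rowMeans(g1)
    m2 <- rowMeans(g2)
    d <- n - 2
    s2 <- (rowSums((g1 - m1)^2) + rowSums((g2 - m2)^2)) / d
    prior <- fit_variance_prior(s2[!constant & s2 > 0], d)
    s_tilde <- if (is.finite(prior$d0))
      (prior$d0 * prior$s0sq + d * s2) / (prior$d0 + d)
    else rep(prior$s0sq, length(s2))
    tmod <- (m1 - m2) / sqrt(s_tilde * (1 / n1 + 1 / n2))
    p <- 2 * pt(abs(tmod), df = d + prior$d0, lower.tail = FALSE)
  }
  p[constant] <- 1
  p <- pmin(p, 1)
  setNames(p, rownames(matrix))
}

## internal: moment-matching fit of the scaled inverse-chi-square variance
## prior. For sample variances s2 on d df, z = log(s2) has
## E[z] = log(sigma^2) + digamma(d/2) - log(d/2) and Var[z] = trigamma(d/2);
## under the hierarchical model the excess variance of z identifies the
## prior df d0 via trigamma(d0/2), and the mean identifies s0^2. When the
## observed spread does not exceed the sampling noise, d0 = Inf (all
## features share one variance).
fit_variance_prior <- function(s2, d) {
  if (length(s2) < 2)
    return(list(d0 = 0, s0sq = if (length(s2)) s2 else 1))
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  excess <- stats::var(z) - trigamma(d / 2)
  if (!is.finite(excess) || excess <= 1e-8)
    return(list(d0 = Inf, s0sq = exp(mean(e))))
  d0 <- 2 * inv_trigamma(excess)
  s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0sq = s0sq)
}

## internal: solve trigamma(x) = y by Newton iteration on 1/trigamma,
## which is nearly linear in x.
inv_trigamma <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < 1e-8 * x) break
  }
  x
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment with monotonicity enforcement;
#' `padj` always lies in `[p, 1]`.
#'
#' @param p vector of p-values.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Run the full differential pipeline on a count matrix
#'
#' Size factors, log2 fold change, moderated-t/permutation p, BH adjustment
#' and threshold calls, returned as one table.
#'
#' @inheritParams permutation_test
#' @param padj_cut,lfc_cut thresholds passed to [call_differential()].
#' @param factors optional externally supplied size factors. Median-of-ratios
#'   assumes most features are unchanged, which fails for small feature sets
#'   with widespread change (e.g. a dozen repeat subfamilies, half of them
#'   de-repressed); supply factors estimated from a large matrix — typically
#'   the gene counts — in that situation.
#' @return data.frame with `feature`, `base_mean`, `log2fc`, `p`, `padj`,
#'   `status`.
#' @export
differential_analysis <- function(matrix, sheet, contrast,
                                  padj_cut = 0.05, lfc_cut = 1,
                                  max_perms = 2000, seed = 1,
                                  factors = NULL) {
  factors <- factors %||% size_factors(matrix)
  if (!is.null(names(factors))) {
    if (!all(colnames(matrix) %in% names(factors)))
      stop("supplied size factors do not cover all samples")
    factors <- factors[colnames(matrix)]
  }
  norm <- normalize_counts(matrix, factors)
  cols <- contrast_columns(sheet, contrast)
  res <- data.frame(
    feature = rownames(matrix),
    base_mean = rowMeans(norm[, c(cols$mutant, cols$control), drop = FALSE]),
    log2fc = log2_fold_change(matrix, sheet, contrast, factors = factors),
    p = permutation_test(matrix, sheet, contrast, max_perms = max_perms,
                         seed = seed, factors = factors),
    stringsAsFactors = FALSE)
  res$padj <- bh_adjust(res$p)
  call_differential(res, padj_cut = padj_cut, lfc_cut = lfc_cut)
}

#' Call up/down/ns status from thresholds
#'
#' `up` iff `padj < padj_cut` and `log2fc >= lfc_cut`; `down` symmetric;
#' otherwise `ns`. Expression analyses use `lfc_cut = 1`, the ERV
#' subfamily analysis `lfc_cut = 1.5`.
#'
#' @param results data.frame with `log2fc` and `padj` columns.
#' @param padj_cut adjusted-p threshold (default 0.05).
#' @param lfc_cut absolute log2 fold-change threshold (default 1).
#' @return the input with a `status` column.
#' @export
call_differential <- function(results, padj_cut = 0.05, lfc_cut = 1) {
  status <- rep("ns", nrow(results))
  sig <- !is.na(results$padj) & results$padj < padj_cut
  status[sig & results$log2fc >= lfc_cut] <- "up"
  status[sig & results$log2fc <= -lfc_cut] <- "down"
  results$status <- status
  rownames(results) <- NULL
  results
}
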