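#' One-sided two-proportion Z-test
#'
#' Pooled-variance Z without continuity correction:
#' `z = (k1/n1 - k2/n2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with
#' `phat = (k1 + k2) / (n1 + n2)`.
#'
#' @param k1,n1 hits and total in the test set.
#' @param k2,n2 hits and total in the background set.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return list with `z`, `p`, the two proportions and a `degenerate` flag
#'   (pooled proportion 0 or 1).
#' @export
two_proportion_z <- function(k1, n1, k2, n2,
                             alternative = c("greater", "less",
                                             "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  phat <- (k1 + k2) / (n1 + n2)
  if (phat == 0 || phat == 1) {
    # all-or-nothing pooled table: p1 == p2 necessarily
    return(list(z = 0, p = switch(alternative, greater = 0.5, less = 0.5,
                                  two.sided = 1),
                p1 = p1, p2 = p2, degenerate = TRUE))
  }
  z <- (p1 - p2) / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  p <- switch(alternative,
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z),
              two.sided = 2 * pnorm(abs(z), lower.tail = FALSE))
  list(z = z, p = p, p1 = p1, p2 = p2, degenerate = FALSE)
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional hypergeometric test (two-sided by summing tables with
#' probability <= the observed, as in [stats::fisher.test()]). A zero
#' row or column gives p = 1 and an undefined (NaN) odds ratio.
#'
#' @param table 2x2 integer matrix.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list with `odds_ratio` (sample odds ratio `ad/bc`) and `p`.
#' @export
fisher_exact <- function(table, alternative = c("two.sided", "greater",
                                                "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(odds_ratio = NaN, p = 1))
  ft <- fisher.test(table, alternative = alternative)
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  list(odds_ratio = unname(or), p = unname(ft$p.value))
}

#' Dual-selection factor enrichment
#'
#' The per-factor occupancy of a cluster is tested twice with Fisher's
#' exact test (one-sided, enrichment): (i) cluster vs background regions
#' and (ii) cluster vs the other cluster. P-values are BH-adjusted across
#' factors within each comparison family, and a factor is selected iff both
#' adjusted p-values fall below `alpha`.
#'
#' @param cluster_hits,other_cluster_hits,background_hits named integer
#'   vectors of per-factor hit counts (same factor names).
#' @param cluster_n,other_n,background_n total region counts of each set.
#' @param alpha selection level (default 0.05).
#' @return data.frame with per-factor odds ratios, p, padj for both
#'   comparisons and a `selected` flag.
#' @export
dual_enrichment_select <- function(cluster_hits, cluster_n,
                                   other_cluster_hits, other_n,
                                   background_hits, background_n,
                                   alpha = 0.05) {
  factors <- names(cluster_hits)
  stopifnot(!is.null(factors),
            identical(factors, names(other_cluster_hits)),
            identical(factors, names(background_hits)))
  test <- function(k1, n1, k2, n2) {
    res <- lapply(seq_along(k1), function(i)
      fisher_exact(matrix(c(k1[i], n1 - k1[i], k2[i], n2 - k2[i]), 2),
                   alternative = "greater"))
    list(or = vapply(res, `[[`, 0, "odds_ratio"),
         p = vapply(res, `[[`, 0, "p"))
  }
  vs_bg <- test(cluster_hits, cluster_n, background_hits, background_n)
  vs_other <- test(cluster_hits, cluster_n, other_cluster_hits, other_n)
  padj_bg <- bh_adjust(vs_bg$p)
  padj_other <- bh_adjust(vs_other$p)
  data.frame(factor = factors,
             or_vs_background = vs_bg$or, p_vs_background = vs_bg$p,
             padj_vs_background = padj_bg,
             or_vs_other = vs_other$or, p_vs_other = vs_other$p,
             padj_vs_other = padj_other,
             selected = padj_bg < alpha & padj_other < alpha,
             stringsAsFactors = FALSE)
}

#' Shuffle-based transposable-element enrichment
#'
#' The observed statistic is the bp overlap between the signal regions and
#' a subfamily's instances. The background re-places the signal regions
#' uniformly at random (length-preserving, within their chromosome) and
#' recomputes the overlap; over `iterations` draws,
#' `log2FC = log2((observed + eps) / (mean background + eps))` and the
#' empirical `p = (1 + #\{background >= observed\}) / (1 + iterations)`
#' (never zero). A subfamily is enriched iff `p < p_cut` and
#' `log2FC > lfc_cut`.
#'
#' @param signal_regions `GRanges` of signal (e.g. H3.3 peak) regions.
#' @param te_instances `GRanges` of TE instances with a `subfamily`
#'   metadata column (a `family` column is carried through when present).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param iterations shuffle iterations (default 20).
#' @param seed RNG seed.
#' @param eps pseudo-bp added to both overlap terms (default 1).
#' @param p_cut,lfc_cut enrichment thresholds (defaults 0.01 and 1).
#' @return data.frame per subfamily: observed bp, background mean, log2fc,
#'   empirical p, `enriched` flag, iterations.
#' @export
te_shuffle_enrichment <- function(signal_regions, te_instances,
                                  chrom_lengths, iterations = 20, seed = 1,
                                  eps = 1, p_cut = 0.01, lfc_cut = 1) {
  if (iterations < 1) stop("iterations must be >= 1")
  chroms <- as.character(GenomicRanges::seqnames(signal_regions))
  widths <- GenomicRanges::width(signal_regions)
  if (any(widths > chrom_lengths[chroms]))
    stop("signal regions larger than their chromosome")
  if (is.null(te_instances$subfamily))
    stop("te_instances must carry a 'subfamily' metadata column")
  subfams <- sort(unique(te_instances$subfamily))
  by_subfam <- lapply(subfams, function(s)
    GenomicRanges::reduce(te_instances[te_instances$subfamily == s],
                          ignore.strand = TRUE))
  names(by_subfam) <- subfams
  overlap_bp <- function(regions, te) {
    if (length(te) == 0L || length(regions) == 0L) return(0)
    sum(GenomicRanges::width(GenomicRanges::intersect(
      GenomicRanges::reduce(regions, ignore.strand = TRUE), te,
      ignore.strand = TRUE)))
  }
  observed <- vapply(by_subfam, overlap_bp, 0, regions = signal_regions)
  bg <- matrix(0, nrow = iterations, ncol = length(subfams),
               dimnames = list(NULL, subfams))
  with_seed(substream_seed(seed, "te_shuffle"), {
    for (it in seq_len(iterations)) {
      new_start <- floor(runif(length(widths)) *
                           (chrom_lengths[chroms] - widths + 1))
      shuffled <- GenomicRanges::GRanges(
        chroms, IRanges::IRanges(new_start + 1, width = widths))
      bg[it, ] <- vapply(by_subfam, overlap_bp, 0, regions = shuffled)
    }
  })
  bg_mean <- colMeans(bg)
  log2fc <- log2((observed + eps) / (bg_mean + eps))
  p <- (1 + colSums(bg >= rep(observed, each = iterations))) /
    (1 + iterations)
  fam <- if (!is.null(te_instances$family))
    te_instances$family[match(subfams, te_instances$subfamily)]
  else NA_character_
  data.frame(subfamily = subfams, family = fam,
             observed_bp = unname(observed), background_mean = bg_mean,
             log2fc = log2fc, p = p,
             enriched = p < p_cut & log2fc > lfc_cut,
             iterations = iterations,
             flagged = unname(observed) == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Printed-percentage formatting
#'
#' `100 * k / n` truncated (floored) at `decimals` decimal places -- the
#' convention that reproduces printed overlap fractions such as
#' "60\%" for 1347/2231 or "83.7\%" for 31/37.
#'
#' @param k,n numerator and denominator counts.
#' @param decimals decimal places (default 0).
#' @return character string ending in `%`. [percent_value()] returns the
#'   same quantity as a number.
#' @export
format_percent <- function(k, n, decimals = 0) {
  sprintf(paste0("%.", decimals, "f%%"), percent_value(k, n, decimals))
}

#' @rdname format_percent
#' @export
percent_value <- function(k, n, decimals = 0) {
  stopifnot(n > 0, k >= 0)
  floor(100 * k / n * 10^decimals) / 10^decimals
}
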