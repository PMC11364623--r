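#' Candidate enhancer-gene pairs by distance
#'
#' All (peak, gene) pairs whose peak-center-to-TSS distance is at most
#' `max_dist`. Distances are signed by gene strand (positive = the peak
#' lies downstream of the TSS in the direction of transcription). No
#' uniqueness constraint: a peak equidistant from two TSSs in range yields
#' two pairs.
#'
#' @param peaks `GRanges` (center = summit if present, else midpoint).
#' @param genes gene table (see [annotate_regions()]).
#' @param max_dist maximum |distance| in bp (default 250000).
#' @return data.frame with `peak_id`, `gene_id`, `distance`.
#' @export
candidate_pairs <- function(peaks, genes, max_dist = 250000) {
  if (length(peaks) == 0L || nrow(genes) == 0L)
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      distance = numeric(0)))
  centers <- region_centers(peaks)
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  rows <- lapply(seq_along(peaks), function(i) {
    cand <- genes[genes$chrom == chroms[i], , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    delta <- centers[i] - cand$tss
    signed <- ifelse(cand$strand == "+", delta, -delta)
    keep <- abs(signed) <= max_dist
    if (!any(keep)) return(NULL)
    data.frame(peak_id = names(peaks)[i], gene_id = cand$gene_id[keep],
               distance = signed[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(peak_id = character(0), gene_id = character(0),
                      distance = numeric(0))
  rownames(out) <- NULL
  out
}

#' Correlate candidate pairs into retained links
#'
#' Pearson correlation between the peak's signal and the gene's expression
#' across shared samples; p from the t-transform of r with n - 2 df,
#' BH-adjusted across all pairs. A link is retained iff `padj < fdr_cut`
#' and `r > 0` (activating links; set `positive_only = FALSE` to admit
#' negative links). Pairs with a zero-variance vector are dropped and
#' counted.
#'
#' @param pairs data.frame from [candidate_pairs()].
#' @param peak_signal peaks x samples matrix (normalized, log scale
#'   upstream).
#' @param expression genes x samples matrix (same sample columns).
#' @param fdr_cut BH FDR threshold for retention (default 0.2).
#' @param positive_only retain only positive correlations (default TRUE).
#' @return data.frame of links with `r`, `p`, `padj`, `retained`; attribute
#'   `"dropped"` counts zero-variance pairs.
#' @export
correlate_links <- function(pairs, peak_signal, expression, fdr_cut = 0.2,
                            positive_only = TRUE) {
  samples <- intersect(colnames(peak_signal), colnames(expression))
  if (length(samples) < 4)
    stop("need >= 4 shared samples; got ", length(samples))
  n <- length(samples)
  ps <- peak_signal[, samples, drop = FALSE]
  ex <- expression[, samples, drop = FALSE]
  keep <- pairs$peak_id %in% rownames(ps) & pairs$gene_id %in% rownames(ex)
  pairs <- pairs[keep, , drop = FALSE]
  x <- ps[pairs$peak_id, , drop = FALSE]
  y <- ex[pairs$gene_id, , drop = FALSE]
  sx <- apply(x, 1, sd)
  sy <- apply(y, 1, sd)
  ok <- sx > 0 & sy > 0
  dropped <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  x <- x[ok, , drop = FALSE]
  y <- y[ok, , drop = FALSE]
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  r <- rowSums(xc * yc) / sqrt(rowSums(xc^2) * rowSums(yc^2))
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  padj <- bh_adjust(p)
  retained <- padj < fdr_cut & (if (positive_only) r > 0 else TRUE)
  out <- data.frame(pairs, r = r, p = p, padj = padj, retained = retained,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Summarize differential expression of linked genes per region class
#'
#' Genes linked to at least one region of a class are counted once per
#' class; the up-fraction is `#up / #linked` using the supplied
#' differential calls.
#'
#' @param links data.frame of retained links (`peak_id`, `gene_id`,
#'   optionally `distance` and `retained`; only retained rows are used when
#'   a `retained` column is present).
#' @param diff data.frame from [differential_analysis()] (`feature`,
#'   `status`).
#' @param region_classes named vector mapping region/peak ids to class
#'   labels (e.g. Cluster1/Cluster2).
#' @return data.frame per class: linked genes, up/down/ns counts, fraction
#'   up, formatted percentage, mean |distance|.
#' @export
link_summary <- function(links, diff, region_classes) {
  if (!is.null(links$retained)) links <- links[links$retained, , drop = FALSE]
  if (nrow(links) == 0L)
    return(data.frame(class = character(0), linked_genes = integer(0),
                      up = integer(0), down = integer(0), ns = integer(0),
                      fraction_up = numeric(0), percent_up = character(0),
                      mean_abs_distance = numeric(0)))
  links$class <- region_classes[links$peak_id]
  links <- links[!is.na(links$class), , drop = FALSE]
  status <- setNames(diff$status, diff$feature)
  rows <- lapply(split(links, links$class), function(df) {
    genes <- unique(df$gene_id)
    st <- status[genes]
    st[is.na(st)] <- "ns"
    data.frame(class = df$class[1], linked_genes = length(genes),
               up = sum(st == "up"), down = sum(st == "down"),
               ns = sum(st == "ns"),
               fraction_up = sum(st == "up") / length(genes),
               percent_up = format_percent(sum(st == "up"), length(genes)),
               mean_abs_distance = if (!is.null(df$distance))
                 mean(abs(df$distance)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
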