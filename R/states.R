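#' k-means clustering of differential H3K9me3 regions
#'
#' Features are the per-region window vectors of control and mutant signal,
#' concatenated row-wise (the degree of loss is only visible with both
#' conditions; set `control_only = TRUE` for control-only features).
#' k-means is run with `restarts` random starts and the best solution by
#' within-cluster sum of squares is kept. Cluster labels are then renamed so
#' that `Cluster1` is the cluster with the lower mean mutant/control region
#' ratio (the "fully lost" class).
#'
#' @param control_matrix,mutant_matrix aligned matrices from
#'   [signal_matrix()] (rows = regions).
#' @param k number of clusters (default 2).
#' @param restarts random restarts (default 10).
#' @param seed RNG seed.
#' @param control_only cluster on control signal only.
#' @param log_transform cluster on `log2(signal + 1)` features (default
#'   TRUE). On the raw scale the heavy right tail of ChIP signal dominates
#'   the within-cluster sum of squares and k-means degenerates into a
#'   magnitude split; the log scale recovers the loss structure.
#' @return list with `label` (named `Cluster1`/`Cluster2`/... vector),
#'   `ratio` (per-region mean mutant / mean control), `control_mean`,
#'   `mutant_mean`, `degenerate` flag.
#' @export
kmeans_cluster_regions <- function(control_matrix, mutant_matrix, k = 2,
                                   restarts = 10, seed = 1,
                                   control_only = FALSE,
                                   log_transform = TRUE) {
  stopifnot(nrow(control_matrix) == nrow(mutant_matrix))
  if (k > nrow(control_matrix))
    stop("k (", k, ") exceeds the number of regions (",
         nrow(control_matrix), ")")
  feats <- if (control_only) control_matrix
           else cbind(control_matrix, mutant_matrix)
  feats[is.na(feats)] <- 0
  if (log_transform) feats <- log2(feats + 1)
  control_mean <- rowMeans(control_matrix, na.rm = TRUE)
  mutant_mean <- rowMeans(mutant_matrix, na.rm = TRUE)
  ratio <- mutant_mean / control_mean
  ids <- rownames(control_matrix) %||% sprintf("region_%d",
                                               seq_len(nrow(control_matrix)))
  if (nrow(unique(feats)) < k) {
    # fewer distinct profiles than clusters: report degeneracy rather than
    # an arbitrary split
    label <- setNames(rep("Cluster1", nrow(feats)), ids)
    return(list(label = label, ratio = setNames(ratio, ids),
                control_mean = setNames(control_mean, ids),
                mutant_mean = setNames(mutant_mean, ids),
                degenerate = TRUE))
  }
  fit <- with_seed(seed, kmeans(feats, centers = k, nstart = restarts,
                                iter.max = 50))
  cluster_ratio <- tapply(ratio, fit$cluster, mean)
  ord <- order(cluster_ratio)
  relabel <- setNames(paste0("Cluster", seq_len(k)), names(cluster_ratio)[ord])
  label <- setNames(unname(relabel[as.character(fit$cluster)]), ids)
  list(label = label, ratio = setNames(ratio, ids),
       control_mean = setNames(control_mean, ids),
       mutant_mean = setNames(mutant_mean, ids),
       degenerate = FALSE, withinss = fit$tot.withinss)
}

#' Call bivalent promoters
#'
#' Pipeline: consensus peaks per mark (>= 2 replicates) -> intersection of
#' the H3K4me3 and H3K27me3 consensus sets -> merge regions within
#' `merge_gap` bp -> keep regions overlapping any TSS +/- `tss_flank` ->
#' keep genes whose retained region also overlaps a PRC2 (e.g. SUZ12) peak.
#'
#' @param k4_reps,k27_reps lists of replicate peak `GRanges` (>= 2 each).
#' @param genes gene table (see [annotate_regions()]).
#' @param prc2_peaks `GRanges` of PRC2-subunit peaks, or NULL to skip the
#'   refinement (output is then flagged unrefined).
#' @param tss_flank promoter half-width for the TSS overlap (default 1000).
#' @param merge_gap merge window in bp (default 500).
#' @param min_support replicate support for the per-mark consensus.
#' @return data.frame with `gene_id`, `tss`, `bivalent`, `region` (the
#'   supporting merged-region coordinates) and a `refined` attribute.
#' @export
call_bivalent_promoters <- function(k4_reps, k27_reps, genes,
                                    prc2_peaks = NULL, tss_flank = 1000,
                                    merge_gap = 500, min_support = 2) {
  if (length(k4_reps) < min_support || length(k27_reps) < min_support)
    stop("need >= ", min_support, " replicates per mark")
  k4 <- consensus_peaks(k4_reps, min_support = min_support)
  k27 <- consensus_peaks(k27_reps, min_support = min_support)
  both <- GenomicRanges::intersect(k4, k27, ignore.strand = TRUE)
  refined <- !is.null(prc2_peaks)
  if (!refined)
    warning("no PRC2 peak set supplied; bivalent calls are unrefined")
  out <- data.frame(gene_id = genes$gene_id, tss = genes$tss,
                    bivalent = FALSE, region = NA_character_,
                    stringsAsFactors = FALSE)
  if (length(both)) {
    merged <- merge_within(both, gap = merge_gap)
    tss <- gene_tss(genes, flank = tss_flank)
    keep <- merged[IRanges::overlapsAny(merged, tss, ignore.strand = TRUE)]
    if (refined && length(keep))
      keep <- keep[IRanges::overlapsAny(keep, prc2_peaks,
                                        ignore.strand = TRUE)]
    if (length(keep)) {
      hits <- GenomicRanges::findOverlaps(tss, keep, ignore.strand = TRUE)
      gid <- names(tss)[S4Vectors::queryHits(hits)]
      reg <- keep[S4Vectors::subjectHits(hits)]
      lab <- sprintf("%s:%d-%d", GenomicRanges::seqnames(reg),
                     GenomicRanges::start(reg) - 1, GenomicRanges::end(reg))
      first <- !duplicated(gid)
      out$bivalent[match(gid[first], out$gene_id)] <- TRUE
      out$region[match(gid[first], out$gene_id)] <- lab[first]
    }
  }
  attr(out, "refined") <- refined
  out
}

#' Polycomb spreading analysis around SUZ12 peaks
#'
#' For each peak, the replicate-averaged H3K27me3 signal within the peak and
#' in the 1.5 kb (by default) zones immediately upstream and downstream is
#' measured per condition; the summary ratio per zone is
#' `mean(mutant) / mean(control)` over peaks. Zones are clipped at
#' chromosome ends; a peak narrower than one bin uses its single covering
#' bin and is flagged.
#'
#' @param suz12 `GRanges` of (non-overlapping) SUZ12 peaks.
#' @param control_tracks,mutant_tracks lists of replicate [binned_track()]s.
#' @param flank flank width in bp (default 1500).
#' @return list with `per_peak` (data.frame of zone means per condition),
#'   `ratios` (named vector: `within`, `upstream`, `downstream`) and
#'   `narrow_peaks` (names of sub-bin peaks).
#' @export
spreading_analysis <- function(suz12, control_tracks, mutant_tracks,
                               flank = 1500) {
  if (length(suz12) == 0L) stop("empty SUZ12 peak set")
  if (!is.list(control_tracks)) control_tracks <- list(control_tracks)
  if (!is.list(mutant_tracks)) mutant_tracks <- list(mutant_tracks)
  bs <- control_tracks[[1]]$bin_size
  narrow <- names(suz12)[GenomicRanges::width(suz12) < bs]
  up <- GenomicRanges::trim(GenomicRanges::flank(suz12, flank, start = TRUE,
                                                 ignore.strand = TRUE))
  down <- GenomicRanges::trim(GenomicRanges::flank(suz12, flank,
                                                   start = FALSE,
                                                   ignore.strand = TRUE))
  zone_mean <- function(tracks, zone) {
    m <- vapply(tracks, function(tr) region_signal(tr, zone, "mean"),
                numeric(length(zone)))
    rowMeans(matrix(m, nrow = length(zone)), na.rm = TRUE)
  }
  per_peak <- data.frame(
    peak = names(suz12),
    control_within = zone_mean(control_tracks, suz12),
    control_up = zone_mean(control_tracks, up),
    control_down = zone_mean(control_tracks, down),
    mutant_within = zone_mean(mutant_tracks, suz12),
    mutant_up = zone_mean(mutant_tracks, up),
    mutant_down = zone_mean(mutant_tracks, down),
    stringsAsFactors = FALSE)
  ratios <- c(
    within = mean(per_peak$mutant_within) / mean(per_peak$control_within),
    upstream = mean(per_peak$mutant_up) / mean(per_peak$control_up),
    downstream = mean(per_peak$mutant_down) / mean(per_peak$control_down))
  list(per_peak = per_peak, ratios = ratios, narrow_peaks = narrow,
       flank = flank)
}

#' Stratify enhancers by control nascent transcription
#'
#' Three strata by control RPKM. Default boundaries are the 0.10 and 0.40
#' quantiles (weak below 0.10, medium below 0.40, the rest strong) -- a
#' proportion-matched heuristic; absolute RPKM thresholds can be supplied
#' instead. Ties are broken deterministically by enhancer id so that the
#' stratum is a monotone function of RPKM.
#'
#' @param enhancers `GRanges` of enhancers (names used as ids) or a
#'   character vector of ids.
#' @param control_rpkm numeric control RPKM per enhancer.
#' @param boundaries two quantiles in (0,1) (default `c(0.10, 0.40)`) or,
#'   with `absolute = TRUE`, two RPKM thresholds.
#' @param absolute interpret `boundaries` as absolute RPKM values.
#' @return data.frame with `enhancer`, `rpkm`, `stratum` (weak/medium/
#'   strong).
#' @export
stratify_enhancers <- function(enhancers, control_rpkm,
                               boundaries = c(0.10, 0.40),
                               absolute = FALSE) {
  ids <- if (is.character(enhancers)) enhancers else names(enhancers)
  stopifnot(length(ids) == length(control_rpkm), length(ids) >= 3)
  if (any(!is.finite(control_rpkm))) stop("control RPKM must be finite")
  if (absolute) {
    cuts <- sort(boundaries)
  } else {
    cuts <- unname(quantile(control_rpkm, sort(boundaries), type = 7))
  }
  # strict comparisons so fully tied inputs resolve upward to "strong"
  stratum <- ifelse(control_rpkm < cuts[1], "weak",
                    ifelse(control_rpkm < cuts[2], "medium", "strong"))
  if (length(unique(stratum)) == 1L)
    warning("all enhancers fall in one stratum")
  data.frame(enhancer = ids, rpkm = control_rpkm, stratum = stratum,
             stringsAsFactors = FALSE)
}

#' Classify ERV subfamilies into activity groups
#'
#' Rule set on per-subfamily signals (common normalized scale, H3K27ac and
#' H3K9me3 in control plus H3K27ac in the mutant):
#' \itemize{
#'   \item group i (constitutively active): control H3K27ac >= `a` and
#'     control H3K9me3 < `m`;
#'   \item group ii (dual-marked, further activated): control H3K27ac >=
#'     `a`, control H3K9me3 >= `m`, and mutant - control H3K27ac >= `d`;
#'   \item group iii (mutant-only activated): control H3K27ac < `a` and
#'     mutant H3K27ac >= `a`;
#'   \item otherwise unclassified.
#' }
#' Default `a` and `m` are the per-mark medians over subfamilies and
#' `d = 1` (log2 units).
#'
#' @param subfamilies character vector of subfamily names.
#' @param control_k27ac,control_k9me3,mutant_k27ac per-subfamily signals.
#' @param a,m,d thresholds (see above); NULL picks the defaults.
#' @return data.frame with `subfamily` and `group` in
#'   `c("i", "ii", "iii", "unclassified")`.
#' @export
classify_erv_groups <- function(subfamilies, control_k27ac, control_k9me3,
                                mutant_k27ac, a = NULL, m = NULL, d = 1) {
  a <- a %||% median(control_k27ac)
  m <- m %||% median(control_k9me3)
  group <- rep("unclassified", length(subfamilies))
  group[control_k27ac >= a & control_k9me3 < m] <- "i"
  group[control_k27ac >= a & control_k9me3 >= m &
          (mutant_k27ac - control_k27ac) >= d] <- "ii"
  group[control_k27ac < a & mutant_k27ac >= a] <- "iii"
  data.frame(subfamily = subfamilies, group = group,
             stringsAsFactors = FALSE)
}
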