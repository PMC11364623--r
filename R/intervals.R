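#' Construct a normalized region set
#'
#' A region set is a `GRanges` built from BED-convention coordinates
#' (0-based start, half-open end). Intervals are validated, sorted by
#' (chromosome, start) and given unique names. An optional `summit` column
#' gives the offset of the peak summit from the interval start.
#'
#' @param chrom character vector of chromosome names, or a data.frame with
#'   columns `chrom`, `start`, `end` and optionally `strand`, `name`,
#'   `score`, `summit`.
#' @param start,end integer BED coordinates (0-based half-open).
#' @param strand strand, one of `"+"`, `"-"`, `"*"`.
#' @param name optional unique labels; autogenerated when missing.
#' @param score optional numeric score.
#' @param summit optional summit offset from `start`, in `[0, end - start)`.
#' @param provenance optional label (mark, sample) carried as metadata.
#' @return A sorted `GRanges` with BED coordinates recoverable via
#'   [as_bed_df()].
#' @export
region_set <- function(chrom, start = NULL, end = NULL, strand = NULL,
                       name = NULL, score = NULL, summit = NULL,
                       provenance = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    chrom <- df$chrom
    start <- df$start
    end <- df$end
    strand <- strand %||% df$strand
    name <- name %||% df$name
    score <- score %||% df$score
    summit <- summit %||% df$summit
  }
  if (length(chrom) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$provenance <- provenance
    return(gr)
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 0) || any(start >= end))
    stop("invalid intervals: need 0 <= start < end (BED convention)")
  strand <- strand %||% "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = strand
  )
  if (!is.null(score)) gr$score <- score
  if (!is.null(summit)) {
    summit <- as.numeric(summit)
    bad <- !is.na(summit) & (summit < 0 | summit >= end - start)
    if (any(bad)) stop("summit offsets must lie in [0, end - start)")
    gr$summit <- summit
  }
  if (is.null(name)) name <- sprintf("region_%d", seq_along(gr))
  if (anyDuplicated(name)) stop("region names must be unique within a set")
  names(gr) <- name
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::metadata(gr)$provenance <- provenance
  gr
}

#' Convert a region set back to a BED-convention data.frame
#'
#' @param gr a `GRanges`.
#' @return data.frame with `chrom`, `start` (0-based), `end` (half-open),
#'   `name`, `score`, `strand` and any extra metadata columns.
#' @export
as_bed_df <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    name = names(gr) %||% sprintf("region_%d", seq_along(gr)),
    score = if (!is.null(gr$score)) gr$score else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(colnames(S4Vectors::mcols(gr)), c("score"))
  for (col in extra) df[[col]] <- S4Vectors::mcols(gr)[[col]]
  rownames(df) <- NULL
  df
}

#' Consensus peaks across replicates
#'
#' A region is retained when at least `min_support` distinct replicate sets
#' contribute an overlapping peak. The output is the merged union footprint
#' of all supporting replicate peaks (occupancy-style consensus), not the
#' >= k-coverage core; set `footprint = FALSE` for the core instead.
#'
#' @param replicate_sets list of `GRanges`, one per replicate.
#' @param min_support minimum number of replicates a region must appear in.
#' @param footprint return the union footprint of supporting peaks (default)
#'   rather than the >= `min_support` coverage core.
#' @return A merged `GRanges` of consensus regions.
#' @export
consensus_peaks <- function(replicate_sets, min_support = 2,
                            footprint = TRUE) {
  if (!is.list(replicate_sets) || length(replicate_sets) == 0L)
    stop("replicate_sets must be a non-empty list of GRanges")
  if (min_support > length(replicate_sets))
    stop("min_support (", min_support, ") exceeds number of replicate sets (",
         length(replicate_sets), ")")
  reduced <- lapply(replicate_sets, function(gr)
    GenomicRanges::reduce(gr, ignore.strand = TRUE))
  pooled <- suppressWarnings(do.call(c, lapply(reduced, unname)))
  if (length(pooled) == 0L) return(GenomicRanges::GRanges())
  cov <- GenomicRanges::coverage(pooled)
  core <- GenomicRanges::GRanges(IRanges::slice(cov, lower = min_support,
                                                rangesOnly = TRUE))
  if (length(core) == 0L) return(GenomicRanges::GRanges())
  if (!footprint) {
    out <- core
  } else {
    support <- pooled[IRanges::overlapsAny(pooled, core, ignore.strand = TRUE)]
    out <- GenomicRanges::reduce(support, ignore.strand = TRUE)
  }
  names(out) <- sprintf("consensus_%d", seq_along(out))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Merge intervals separated by at most a given gap
#'
#' Intervals whose inter-interval gap (`next start - previous end`, BED
#' convention) is less than or equal to `gap` are merged transitively.
#'
#' @param set a `GRanges`.
#' @param gap maximum gap in bp (inclusive; default 500).
#' @return Merged `GRanges`; total covered bp never decreases.
#' @export
merge_within <- function(set, gap = 500) {
  if (gap < 0) stop("gap must be non-negative")
  out <- GenomicRanges::reduce(set, min.gapwidth = gap + 1,
                               ignore.strand = TRUE)
  names(out) <- sprintf("merged_%d", seq_along(out))
  out
}

#' Count query intervals overlapping a subject set
#'
#' @param query,subject `GRanges` sets.
#' @param min_subject_size subject intervals shorter than this many bp are
#'   ignored (default 0; the ERV analyses use 500).
#' @return list with `k` (queries with >= 1 bp overlap, each counted once)
#'   and `n` (total query intervals).
#' @export
overlap_counts <- function(query, subject, min_subject_size = 0) {
  n <- length(query)
  if (length(subject) > 0 && min_subject_size > 0)
    subject <- subject[GenomicRanges::width(subject) >= min_subject_size]
  if (n == 0L || length(subject) == 0L) return(list(k = 0L, n = n))
  k <- sum(IRanges::overlapsAny(query, subject, ignore.strand = TRUE))
  list(k = as.integer(k), n = as.integer(n))
}

#' Assign a genomic category to each region
#'
#' Each region is categorized by its midpoint with the fixed priority
#' promoter (midpoint within `promoter_dist` of a TSS) > 5' UTR > 3' UTR >
#' exon > intron > distal intergenic, so every region gets exactly one
#' category.
#'
#' @param regions a `GRanges`.
#' @param genes a gene table as returned by [build_genome()] or
#'   [read_gene_table()] (refFlat-like: `tx_start`, `tx_end`, `cds_start`,
#'   `cds_end`, `exon_starts`, `exon_ends`, `strand`, `tss`).
#' @param promoter_dist distance from a TSS defining the promoter class
#'   (default 2000 bp).
#' @return character vector of categories, one per region.
#' @export
annotate_regions <- function(regions, genes, promoter_dist = 2000) {
  cats <- c("promoter", "five_utr", "three_utr", "exon", "intron",
            "distal_intergenic")
  if (length(regions) == 0L) return(character(0))
  mid <- floor((GenomicRanges::start(regions) - 1 +
                  GenomicRanges::end(regions)) / 2)
  midpoints <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(regions),
    IRanges::IRanges(mid + 1, width = 1))
  unknown <- !(as.character(GenomicRanges::seqnames(regions)) %in%
                 unique(genes$chrom))
  if (any(unknown))
    warning(sum(unknown), " region(s) on chromosomes absent from the gene ",
            "annotation; categorized as distal_intergenic")
  model <- gene_feature_ranges(genes, promoter_dist)
  out <- rep("distal_intergenic", length(regions))
  remaining <- rep(TRUE, length(regions))
  for (cat in c("promoter", "five_utr", "three_utr", "exon", "intron")) {
    # suppress the harmless Seqinfo merge notice for disjoint seqlevels
    hit <- remaining & suppressWarnings(
      IRanges::overlapsAny(midpoints, model[[cat]], ignore.strand = TRUE))
    out[hit] <- cat
    remaining <- remaining & !hit
  }
  out
}

## internal: explode a refFlat-like gene table into per-category GRanges
gene_feature_ranges <- function(genes, promoter_dist = 2000) {
  empty <- GenomicRanges::GRanges()
  if (nrow(genes) == 0L)
    return(list(promoter = empty, five_utr = empty, three_utr = empty,
                exon = empty, intron = empty))
  mk <- function(chrom, start, end) {
    keep <- end > start
    if (!any(keep)) return(empty)
    GenomicRanges::GRanges(chrom[keep],
                           IRanges::IRanges(start[keep] + 1, end[keep]))
  }
  promoter <- mk(genes$chrom, pmax(0, genes$tss - promoter_dist),
                 genes$tss + promoter_dist)
  ex_start <- lapply(strsplit(as.character(genes$exon_starts), ","),
                     as.numeric)
  ex_end <- lapply(strsplit(as.character(genes$exon_ends), ","), as.numeric)
  n_ex <- lengths(ex_start)
  exon <- mk(rep(genes$chrom, n_ex), unlist(ex_start), unlist(ex_end))
  gene_body <- mk(genes$chrom, genes$tx_start, genes$tx_end)
  intron <- GenomicRanges::setdiff(gene_body, exon, ignore.strand = TRUE)
  # UTR = exonic bp outside the CDS, split by strand into 5'/3'
  left_utr <- mk(genes$chrom, genes$tx_start, genes$cds_start)
  right_utr <- mk(genes$chrom, genes$cds_end, genes$tx_end)
  left_is_five <- genes$strand == "+"
  five_parts <- c(mk(genes$chrom[left_is_five], genes$tx_start[left_is_five],
                     genes$cds_start[left_is_five]),
                  mk(genes$chrom[!left_is_five], genes$cds_end[!left_is_five],
                     genes$tx_end[!left_is_five]))
  three_parts <- c(mk(genes$chrom[!left_is_five],
                      genes$tx_start[!left_is_five],
                      genes$cds_start[!left_is_five]),
                   mk(genes$chrom[left_is_five], genes$cds_end[left_is_five],
                      genes$tx_end[left_is_five]))
  five_utr <- GenomicRanges::intersect(five_parts, exon, ignore.strand = TRUE)
  three_utr <- GenomicRanges::intersect(three_parts, exon,
                                        ignore.strand = TRUE)
  list(promoter = promoter, five_utr = five_utr, three_utr = three_utr,
       exon = exon, intron = intron)
}

#' TSS positions of a gene table as single-bp ranges
#'
#' @param genes gene table (see [annotate_regions()]).
#' @param flank optional symmetric flank in bp (0 returns the TSS bp itself).
#' @return `GRanges` named by `gene_id`, strand-aware.
#' @export
gene_tss <- function(genes, flank = 0) {
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, genes$tss + 1 - flank), genes$tss + 1 + flank),
    strand = genes$strand)
  names(gr) <- genes$gene_id
  gr
}
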