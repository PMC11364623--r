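#' Read a BED file into a region set
#'
#' Understands BED3/BED6 plus an optional 7th `summit` column (offset from
#' start, as written by [write_bed()]).
#'
#' @param path file path.
#' @param summit set `TRUE` if the file carries a 7th summit-offset column.
#' @return A normalized `GRanges` (see [region_set()]).
#' @export
read_bed <- function(path, summit = FALSE) {
  extra <- if (summit) c(summit = "integer") else character(0)
  gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  if (!is.null(gr$name) && !anyDuplicated(gr$name)) df$name <- gr$name
  if (!is.null(gr$score)) df$score <- as.numeric(gr$score)
  if (summit) df$summit <- gr$summit
  region_set(df)
}

#' Write a region set as BED
#'
#' BED6 by default; when the set carries summit offsets they are appended as
#' a 7th column.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  df <- as_bed_df(gr)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (!is.null(df$summit)) cols <- c(cols, "summit")
  df$score[is.na(df$score)] <- 0
  write.table(format(df[, cols], scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a refFlat-like gene table
#'
#' Tab-separated with header: `gene_id`, `chrom`, `strand`, `tx_start`,
#' `tx_end`, `cds_start`, `cds_end`, `exon_starts`, `exon_ends` (comma
#' separated, BED coordinates). A `tss` column is derived from the strand.
#'
#' @param path file path.
#' @return data.frame gene table.
#' @export
read_gene_table <- function(path) {
  genes <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE,
                      colClasses = c(exon_starts = "character",
                                     exon_ends = "character"))
  # TSS as the transcription-start boundary coordinate (BED convention)
  genes$tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  genes
}

#' @rdname read_gene_table
#' @param genes gene table data.frame.
#' @export
write_gene_table <- function(genes, path) {
  cols <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end", "exon_starts", "exon_ends")
  write.table(genes[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a binned track
#'
#' Expects the fixed-step dialect written by [write_bedgraph()]: every
#' record spans one bin of constant width.
#'
#' @param path file path.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param bin_size bin width in bp; inferred from the first record when NULL.
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, chrom_lengths, bin_size = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (is.null(bin_size))
    bin_size <- GenomicRanges::width(gr)[1]
  values <- lapply(names(chrom_lengths), function(chr) {
    n <- ceiling(chrom_lengths[[chr]] / bin_size)
    v <- numeric(n)
    sel <- gr[GenomicRanges::seqnames(gr) == chr]
    if (length(sel)) {
      idx <- (GenomicRanges::start(sel) - 1) %/% bin_size + 1
      v[idx] <- sel$score
    }
    v
  })
  names(values) <- names(chrom_lengths)
  binned_track(values, bin_size = bin_size, chrom_lengths = chrom_lengths)
}

#' Write a binned track as bedGraph
#'
#' @param track a [binned_track()].
#' @param path output path.
#' @param drop_zero omit zero bins (default TRUE, keeps files small).
#' @export
write_bedgraph <- function(track, path, drop_zero = TRUE) {
  pieces <- lapply(names(track$values), function(chr) {
    v <- track$values[[chr]]
    n <- length(v)
    start <- (seq_len(n) - 1) * track$bin_size
    end <- pmin(start + track$bin_size, track$chrom_lengths[[chr]])
    df <- data.frame(chrom = chr, start = start, end = end, score = v)
    if (drop_zero) df <- df[df$score != 0, , drop = FALSE]
    df
  })
  df <- do.call(rbind, pieces)
  write.table(format(df, scientific = FALSE, trim = TRUE, digits = 10),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write count matrices and sample sheets
#'
#' Count matrices are TSV with feature ids in the first column; sample
#' sheets are TSV with columns `sample`, `genotype`, `replicate`, `batch`.
#'
#' @param path file path.
#' @return integer matrix with feature rownames / sample sheet data.frame.
#' @export
read_count_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_count_matrix
#' @param mat matrix with feature rownames and sample colnames.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_count_matrix
#' @export
read_sample_sheet <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_count_matrix
#' @param sheet sample sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
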