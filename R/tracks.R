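#' Binned coverage track
#'
#' A per-chromosome vector of signal values at a fixed bin width, the common
#' currency of the metaprofile, spreading and region-signal computations.
#' Bin `i` of a chromosome covers BED interval `[(i-1)*bin_size,
#' i*bin_size)`.
#'
#' @param values named list of numeric vectors, one per chromosome.
#' @param bin_size bin width in bp.
#' @param chrom_lengths named vector of chromosome lengths; defaults to
#'   `length(values[[chr]]) * bin_size`.
#' @param norm normalization tag: `"raw"`, `"RPGC"` or `"spike-scaled"`.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(values, bin_size, chrom_lengths = NULL,
                         norm = "raw") {
  stopifnot(is.list(values), length(values) > 0, !is.null(names(values)))
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(values, length, 0) * bin_size
  chrom_lengths <- chrom_lengths[names(values)]
  for (chr in names(values)) {
    expected <- ceiling(chrom_lengths[[chr]] / bin_size)
    if (length(values[[chr]]) != expected)
      stop("track vector for ", chr, " has ", length(values[[chr]]),
           " bins; expected ", expected)
    if (any(values[[chr]] < 0, na.rm = TRUE))
      stop("track values must be non-negative")
  }
  structure(list(values = values, bin_size = bin_size,
                 chrom_lengths = chrom_lengths, norm = norm),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track:", length(x$values), "chromosome(s), bin_size",
      x$bin_size, "bp, norm", x$norm, "\n")
  invisible(x)
}

#' RPGC (1x genomic coverage) normalization
#'
#' Scales raw bin sums by `genome_size / (total_reads * fragment_length)` so
#' that a library whose extended reads tile the genome uniformly gets a
#' genome-wide mean bin value of 1.
#'
#' @param raw a raw [binned_track()] of per-bin read (fragment) counts
#'   scaled to bp (bin sum of extended-read coverage).
#' @param total_reads sequencing depth of the sample.
#' @param fragment_length average extended fragment length (default 150 bp).
#' @param genome_size effective genome size in bp.
#' @return A [binned_track()] tagged `"RPGC"`.
#' @export
rpgc_normalize <- function(raw, total_reads, fragment_length = 150,
                           genome_size) {
  if (total_reads <= 0 || fragment_length <= 0 || genome_size <= 0)
    stop("total_reads, fragment_length and genome_size must be positive")
  scale <- genome_size / (total_reads * fragment_length)
  values <- lapply(raw$values, function(v) v * scale)
  binned_track(values, raw$bin_size, raw$chrom_lengths, norm = "RPGC")
}

#' Spike-in (ChIP-Rx style) scale factors
#'
#' Per-sample factors from exogenous (e.g. fly) read counts:
#' `factor_s = mean(fly_reads) / fly_reads_s`, so the mean factor is 1 and a
#' sample with more spike-in reads (over-sampled) is scaled down.
#'
#' @param fly_reads named numeric vector of spike-in read counts per sample.
#' @return named numeric vector of scale factors.
#' @export
spike_in_factors <- function(fly_reads) {
  if (any(fly_reads <= 0)) stop("spike-in read counts must be positive")
  mean(fly_reads) / fly_reads
}

#' Signal matrix around region centers
#'
#' Each region is expanded to center +/- `flank` and cut into
#' `2 * flank / window` fixed-width windows; each cell holds the mean track
#' signal in that window. The center is the summit when a `summit` column is
#' present, otherwise the midpoint. Rows of minus-strand regions are
#' reversed when `flip = TRUE` so that, e.g., transcription always runs left
#' to right. Windows extending past a chromosome end are `NA` and excluded
#' from downstream averages.
#'
#' @param track a [binned_track()].
#' @param centers a `GRanges` of regions (optionally with `summit`).
#' @param flank half-width in bp (default 5000).
#' @param window window width in bp (default 250); must be a multiple of the
#'   track bin size.
#' @param flip reverse rows of minus-strand regions (default TRUE).
#' @return matrix regions x windows, with attribute `"flipped"` recording
#'   which rows were reversed.
#' @export
signal_matrix <- function(track, centers, flank = 5000, window = 250,
                          flip = TRUE) {
  if (window %% track$bin_size != 0)
    stop("window (", window, ") must be a multiple of the track bin size (",
         track$bin_size, ")")
  if (flank %% window != 0)
    stop("flank must be a multiple of window")
  n_win <- 2 * flank / window
  bs <- track$bin_size
  k <- window / bs
  centers_bp <- region_centers(centers)
  out <- matrix(NA_real_, nrow = length(centers), ncol = n_win,
                dimnames = list(names(centers), NULL))
  chroms <- as.character(GenomicRanges::seqnames(centers))
  strands <- as.character(GenomicRanges::strand(centers))
  for (i in seq_along(centers)) {
    chr <- chroms[i]
    v <- track$values[[chr]]
    if (is.null(v)) next
    left <- centers_bp[i] - flank
    # per-window mean over the k covered bins, bp-weighted for off-grid
    # centers; fully off-chromosome windows stay NA
    for (j in seq_len(n_win)) {
      ws <- left + (j - 1) * window
      we <- ws + window
      if (ws < 0 || we > track$chrom_lengths[[chr]]) next
      b0 <- ws %/% bs
      b1 <- (we - 1) %/% bs
      bins <- (b0:b1) + 1
      lo <- pmax(ws, (bins - 1) * bs)
      hi <- pmin(we, bins * bs)
      w <- hi - lo
      out[i, j] <- sum(v[bins] * w) / sum(w)
    }
    if (flip && strands[i] == "-") out[i, ] <- rev(out[i, ])
  }
  attr(out, "flipped") <- flip & strands == "-"
  attr(out, "window") <- window
  attr(out, "flank") <- flank
  out
}

## internal: center (bp, BED convention) of each region
region_centers <- function(centers) {
  start_bed <- GenomicRanges::start(centers) - 1
  end_bed <- GenomicRanges::end(centers)
  mid <- floor((start_bed + end_bed) / 2)
  if (!is.null(centers$summit)) {
    s <- centers$summit
    mid <- ifelse(is.na(s), mid, start_bed + s)
  }
  mid
}

#' Metaprofile over replicate signal matrices
#'
#' Column means over regions within each replicate matrix, then the mean
#' over replicates; `NA` cells are excluded at both stages.
#'
#' @param matrices list of matrices from [signal_matrix()] with identical
#'   shape and orientation.
#' @return numeric vector, one value per window.
#' @export
metaprofile <- function(matrices) {
  if (!is.list(matrices)) matrices <- list(matrices)
  dims <- vapply(matrices, dim, c(0L, 0L))
  if (length(unique(dims[2, ])) != 1L)
    stop("signal matrices must have identical shapes")
  per_rep <- vapply(matrices, function(m) colMeans(m, na.rm = TRUE),
                    numeric(ncol(matrices[[1]])))
  rowMeans(as.matrix(per_rep), na.rm = TRUE)
}

#' Per-region RPKM from a binned track
#'
#' `RPKM_r = signal_in_r * 1e9 / (length_r * total_signal)`, with the region
#' signal taken as the bp-prorated sum of bin values.
#'
#' @param track a [binned_track()].
#' @param regions a `GRanges`.
#' @param total_signal library total (reads or summed signal).
#' @return named numeric vector of RPKM values.
#' @export
region_rpkm <- function(track, regions, total_signal) {
  if (total_signal <= 0) stop("total_signal must be positive")
  sig <- region_signal(track, regions, how = "sum")
  len <- GenomicRanges::width(regions)
  out <- sig * 1e9 / (len * total_signal)
  names(out) <- names(regions)
  out
}

#' Mean or summed track signal per region
#'
#' @param track a [binned_track()].
#' @param regions a `GRanges`.
#' @param how `"mean"` (bp-weighted mean bin value) or `"sum"` (bp-prorated
#'   sum, i.e. mean * region width / bin size).
#' @return named numeric vector.
#' @export
region_signal <- function(track, regions, how = c("mean", "sum")) {
  how <- match.arg(how)
  bs <- track$bin_size
  n <- length(regions)
  out <- numeric(n)
  chroms <- as.character(GenomicRanges::seqnames(regions))
  starts <- GenomicRanges::start(regions) - 1
  ends <- GenomicRanges::end(regions)
  for (i in seq_len(n)) {
    v <- track$values[[chroms[i]]]
    if (is.null(v)) { out[i] <- NA_real_; next }
    ws <- max(0, starts[i])
    we <- min(ends[i], track$chrom_lengths[[chroms[i]]])
    if (we <= ws) { out[i] <- 0; next }
    b0 <- ws %/% bs
    b1 <- (we - 1) %/% bs
    bins <- (b0:b1) + 1
    lo <- pmax(ws, (bins - 1) * bs)
    hi <- pmin(we, bins * bs)
    w <- hi - lo
    out[i] <- if (how == "mean") sum(v[bins] * w) / sum(w)
              else sum(v[bins] * w) / bs
  }
  names(out) <- names(regions)
  out
}

#' Per-region-per-sample signal matrix from a set of tracks
#'
#' @param tracks named list of [binned_track()] objects (one per sample).
#' @param regions a `GRanges`.
#' @param how passed to [region_signal()].
#' @return matrix regions x samples.
#' @export
region_sample_matrix <- function(tracks, regions, how = "mean") {
  out <- vapply(tracks, function(tr) region_signal(tr, regions, how = how),
                numeric(length(regions)))
  out <- matrix(out, nrow = length(regions),
                dimnames = list(names(regions), names(tracks)))
  out
}
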