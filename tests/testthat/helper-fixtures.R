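# Shared fixtures. The default synthetic genome takes a few seconds to
# build, so it is constructed once per test run and reused.

.fixture_cache <- new.env(parent = emptyenv())

default_genome <- function() {
  if (is.null(.fixture_cache$genome))
    .fixture_cache$genome <- suppressWarnings(build_genome(synth_config()))
  .fixture_cache$genome
}

default_counts <- function() {
  if (is.null(.fixture_cache$counts))
    .fixture_cache$counts <- simulate_counts(default_genome())
  .fixture_cache$counts
}

# quick GRanges constructor for interval tests (BED coordinates)
gr <- function(chrom, start, end, name = NULL, strand = "*") {
  df <- data.frame(chrom = chrom, start = start, end = end,
                   strand = strand, stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- name
  region_set(df)
}

# replicate-averaged signal matrix over one mark/genotype of a genome
averaged_signal <- function(genome, regions, mark, genotype,
                            flank = 5000, window = 250) {
  n_rep <- genome$truth$config$replicates_per_group
  mats <- lapply(seq_len(n_rep), function(r)
    signal_matrix(simulate_tracks(genome, mark, genotype, r),
                  regions, flank = flank, window = window))
  Reduce(`+`, mats) / n_rep
}

# tracks for every sample of one mark, named by sample
sample_track_list <- function(genome, mark, sheet) {
  tracks <- lapply(seq_len(nrow(sheet)), function(i)
    simulate_tracks(genome, mark, sheet$genotype[i], sheet$replicate[i]))
  names(tracks) <- sheet$sample
  tracks
}
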