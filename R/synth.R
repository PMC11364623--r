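#' Configuration for the synthetic study generator
#'
#' Defines a miniature two-genotype-mutant study: a small genome, gene and
#' ERV annotations, three classes of distal H3K9me3 regions (full loss,
#' partial loss, unchanged), bivalent promoters with SUZ12 peaks, binned
#' signal tracks for eight marks, and NB-distributed count matrices. All
#' effect sizes are mutant/control signal multipliers recorded in the ground
#' truth, so recovery tests can compare estimates against what was actually
#' implanted.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp; must be a multiple of
#'   `bin_size`.
#' @param bin_size working bin width in bp (default 250).
#' @param n_genes total number of genes.
#' @param erv_subfamilies data.frame with columns `name`, `family`
#'   (families among ERVK, ERV1, ERVL, MaLR).
#' @param n_erv_instances instances per subfamily.
#' @param erv_large_fraction fraction of ERV instances >= 500 bp.
#' @param n_cluster1_regions,n_cluster2_regions,n_nonda_regions region
#'   counts per class.
#' @param region_width width of each region in bp (bin-aligned).
#' @param erv_overlap_fractions named fractions of regions per class that
#'   contain at least one >= 500 bp ERV instance.
#' @param n_bivalent_promoters number of bivalent (H3K4me3 + H3K27me3 +
#'   SUZ12) promoters.
#' @param replicates_per_group replicates per genotype (default 3).
#' @param groups genotype labels; first is the control.
#' @param effects list of per-mark multipliers/enrichments (see defaults).
#' @param expression list of count-model parameters: `gene_mean_log`,
#'   `gene_mean_sd`, `dispersion` (NB variance = mu + a*mu^2), `linked_lfc`,
#'   `linked_up_fraction`, `te_lfc`, `depth_range`.
#' @param noise_sd lognormal sd of multiplicative track noise (0 = exact
#'   mean surface).
#' @param min_region_spacing minimum bp between placed regions (0 = only
#'   disjointness is enforced).
#' @param link_max_dist maximum region-center-to-TSS distance for an
#'   implanted enhancer-gene link.
#' @param seed root seed; together with the config it fully determines
#'   every output.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_chroms = 2,
                         chrom_length = 1e7,
                         bin_size = 250,
                         n_genes = 1200,
                         erv_subfamilies = default_erv_subfamilies(),
                         n_erv_instances = 50,
                         erv_large_fraction = 0.7,
                         n_cluster1_regions = 200,
                         n_cluster2_regions = 200,
                         n_nonda_regions = 200,
                         region_width = 2000,
                         erv_overlap_fractions = c(Cluster1 = 0.60,
                                                   Cluster2 = 0.40,
                                                   nonDA = 0.22),
                         n_bivalent_promoters = 80,
                         replicates_per_group = 3,
                         groups = c("control", "K9A", "K27A"),
                         effects = list(),
                         expression = list(),
                         noise_sd = 0.3,
                         min_region_spacing = 0,
                         link_max_dist = 250000,
                         seed = 1) {
  eff <- utils::modifyList(list(
    h33_enrichment = c(Cluster1 = 6, Cluster2 = 6, nonDA = 2),
    h33_promoter = 4,
    k9me3_enrichment = 8,
    k9me3_mult = c(Cluster1 = 0.05, Cluster2 = 0.5, nonDA = 1),
    k27ac_gain = c(Cluster1 = 4, Cluster2 = 2.5, nonDA = 1),
    k9ac_gain = c(Cluster1 = 2, Cluster2 = 1.5, nonDA = 1),
    proseq_gain = c(Cluster1 = 3, Cluster2 = 2, nonDA = 1),
    proseq_gene_body = 2,
    k4me3_enrichment = 6,
    k27me3_enrichment = 5,
    suz12_enrichment = 5,
    f_in = 0.7,
    f_flank = 0.4,
    k9a_k27me3_loss = 0.75,
    suz12_k27a_loss = 0.7,
    suz12_flank = 1500,
    active_k27ac = 3
  ), effects)
  expr <- utils::modifyList(list(
    gene_mean_log = log(100),
    gene_mean_sd = 1,
    dispersion = 0.1,
    linked_lfc = 2,
    linked_up_fraction = 0.82,
    te_lfc = 2,
    te_mean_log = log(200),
    te_mean_sd = 0.8,
    depth_range = c(0.8, 1.25)
  ), expression)
  cfg <- list(n_chroms = n_chroms, chrom_length = chrom_length,
              bin_size = bin_size, n_genes = n_genes,
              erv_subfamilies = erv_subfamilies,
              n_erv_instances = n_erv_instances,
              erv_large_fraction = erv_large_fraction,
              n_regions = c(Cluster1 = n_cluster1_regions,
                            Cluster2 = n_cluster2_regions,
                            nonDA = n_nonda_regions),
              region_width = region_width,
              erv_overlap_fractions = erv_overlap_fractions,
              n_bivalent_promoters = n_bivalent_promoters,
              replicates_per_group = replicates_per_group,
              groups = groups, effects = eff, expression = expr,
              noise_sd = noise_sd,
              min_region_spacing = min_region_spacing,
              link_max_dist = link_max_dist, seed = seed)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

default_erv_subfamilies <- function() {
  data.frame(
    name = c("IAPEz-int", "RLTR10-int", "MMERVK10C-int",
             "RLTR4-int", "MURVY-int", "MMERGLN-int",
             "MERVL-int", "MT2-Mm", "ERVL-B4-int",
             "MTA-Mm", "ORR1A0", "MTEa"),
    family = rep(c("ERVK", "ERV1", "ERVL", "MaLR"), each = 3),
    stringsAsFactors = FALSE)
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length > 0, cfg$bin_size > 0,
            cfg$n_genes > 0, cfg$region_width > 0,
            cfg$replicates_per_group >= 1, length(cfg$groups) >= 2)
  if (cfg$chrom_length %% cfg$bin_size != 0)
    stop("bin_size must divide chrom_length")
  if (cfg$region_width %% cfg$bin_size != 0)
    stop("region_width must be a multiple of bin_size")
  if (cfg$expression$dispersion < 0)
    stop("NB dispersion must be non-negative")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(cfg$erv_overlap_fractions < 0 | cfg$erv_overlap_fractions > 1))
    stop("erv_overlap_fractions must lie in [0, 1]")
  if (cfg$seed >= 2^31 || cfg$seed < 1)
    stop("seed must be a positive 31-bit integer")
  invisible(cfg)
}

#' Build the synthetic genome, annotations and ground truth
#'
#' Places genes (TSS snapped to the working bin grid), bivalent promoters
#' with SUZ12 peaks, the three distal region classes (mutually disjoint, at
#' least 2 kb from every TSS and clear of the Polycomb flank zones), ERV
#' instances (the configured per-class fraction of regions receives one
#' instance of at least 500 bp; remaining instances are placed away from the
#' region classes so realized overlaps match the configured targets), and
#' implanted enhancer-gene links (each Cluster1/Cluster2 region is linked to
#' its nearest TSS within `link_max_dist`).
#'
#' @param config a [synth_config()].
#' @return A list of class `synth_genome` with elements `chrom_lengths`,
#'   `genes` (refFlat-like data.frame), `ervs` (`GRanges` with `subfamily`,
#'   `family`), `regions` (`GRanges` with `class`), `suz12` (`GRanges`),
#'   `peak_reps` (replicate peak sets for H3K4me3/H3K27me3 plus a PRC2
#'   set), and `truth` (the ground-truth record).
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  bs <- cfg$bin_size
  chrom_lengths <- setNames(rep(cfg$chrom_length, cfg$n_chroms),
                            paste0("chr", seq_len(cfg$n_chroms)))
  with_seed(substream_seed(cfg$seed, "genome"), {
    genes <- place_genes(cfg, chrom_lengths)
    n_biv <- min(cfg$n_bivalent_promoters, nrow(genes))
    # bivalent genes are picked so their SUZ12 peak + flank zones are
    # mutually disjoint: overlapping Polycomb domains would compound the
    # implanted H3K27me3 multipliers and blur the recorded ground truth
    zone_half <- 1000 + cfg$effects$suz12_flank + cfg$bin_size
    cand <- sample(genes$gene_id)
    bivalent_genes <- character(0)
    taken_tss <- list()
    for (g in cand) {
      if (length(bivalent_genes) >= n_biv) break
      row <- genes[genes$gene_id == g, ]
      prev <- taken_tss[[row$chrom]]
      if (!is.null(prev) && any(abs(prev - row$tss) < 2 * zone_half)) next
      bivalent_genes <- c(bivalent_genes, g)
      taken_tss[[row$chrom]] <- c(prev, row$tss)
    }
    if (length(bivalent_genes) < n_biv)
      stop("could only place ", length(bivalent_genes), " of ", n_biv,
           " bivalent promoters with disjoint Polycomb zones; enlarge the ",
           "genome or reduce n_bivalent_promoters")
    bivalent_genes <- sort(bivalent_genes)
    non_biv <- setdiff(genes$gene_id, bivalent_genes)
    active_genes <- sort(sample(non_biv, floor(length(non_biv) / 2)))
    suz12 <- promoter_windows(genes, bivalent_genes, 1000, chrom_lengths,
                              prefix = "suz12")
    regions <- place_regions(cfg, chrom_lengths, genes, suz12)
    ervs <- place_ervs(cfg, chrom_lengths, regions)
    peak_reps <- simulate_peak_replicates(cfg, genes, bivalent_genes,
                                          active_genes, chrom_lengths)
    links <- implant_links(cfg, regions, genes)
  })
  region_erv <- region_erv_overlaps(regions, ervs)
  linked_genes <- unique(links$gene_id)
  with_seed(substream_seed(cfg$seed, "directions"), {
    n_up <- round(cfg$expression$linked_up_fraction * length(linked_genes))
    up_genes <- if (length(linked_genes))
      sample(linked_genes, n_up) else character(0)
  })
  gene_direction <- setNames(rep("ns", nrow(genes)), genes$gene_id)
  gene_direction[linked_genes] <- "down"
  gene_direction[up_genes] <- "up"
  # subfamilies with an implanted instance under a de-repressed region
  da <- names(regions)[regions$class %in% c("Cluster1", "Cluster2")]
  te_up <- sort(unique(ervs$subfamily[
    IRanges::overlapsAny(ervs, regions[da], ignore.strand = TRUE)]))
  truth <- list(
    region_class = setNames(as.character(regions$class), names(regions)),
    region_erv = region_erv,
    links = links,
    gene_direction = gene_direction,
    bivalent_genes = bivalent_genes,
    active_genes = active_genes,
    te_up = te_up,
    multipliers = cfg$effects,
    config = cfg)
  structure(list(chrom_lengths = chrom_lengths, genes = genes, ervs = ervs,
                 regions = regions, suz12 = suz12, peak_reps = peak_reps,
                 truth = truth),
            class = "synth_genome")
}

## internal ------------------------------------------------------------------

snap <- function(x, bs) round(x / bs) * bs

place_genes <- function(cfg, chrom_lengths) {
  bs <- cfg$bin_size
  n_per <- diff(round(seq(0, cfg$n_genes, length.out =
                            length(chrom_lengths) + 1)))
  rows <- list()
  gi <- 0
  for (ci in seq_along(chrom_lengths)) {
    chr <- names(chrom_lengths)[ci]
    L <- chrom_lengths[[ci]]
    for (j in seq_len(n_per[ci])) {
      gi <- gi + 1
      len <- snap(runif(1, 5000, 30000), bs)
      tx_start <- snap(runif(1, 5000, L - len - 5000), bs)
      tx_end <- tx_start + len
      strand <- sample(c("+", "-"), 1)
      cds_start <- round(tx_start + 0.1 * len)
      cds_end <- round(tx_start + 0.9 * len)
      ex_f <- rbind(c(0, 0.15), c(0.45, 0.6), c(0.85, 1))
      ex_s <- round(tx_start + ex_f[, 1] * len)
      ex_e <- round(tx_start + ex_f[, 2] * len)
      rows[[gi]] <- data.frame(
        gene_id = sprintf("gene_%04d", gi), chrom = chr, strand = strand,
        tx_start = tx_start, tx_end = tx_end,
        cds_start = cds_start, cds_end = cds_end,
        exon_starts = paste(ex_s, collapse = ","),
        exon_ends = paste(ex_e, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  # TSS as the transcription-start boundary coordinate; bin-grid aligned
  genes$tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  genes
}

promoter_windows <- function(genes, gene_ids, flank, chrom_lengths,
                             prefix = "prom") {
  sel <- genes[genes$gene_id %in% gene_ids, , drop = FALSE]
  if (nrow(sel) == 0L) return(GenomicRanges::GRanges())
  start <- pmax(0, sel$tss - flank)
  end <- pmin(sel$tss + flank, chrom_lengths[sel$chrom])
  region_set(data.frame(chrom = sel$chrom, start = start, end = end,
                        name = paste0(prefix, "_", sel$gene_id),
                        stringsAsFactors = FALSE))
}

place_regions <- function(cfg, chrom_lengths, genes, suz12) {
  bs <- cfg$bin_size
  width <- cfg$region_width
  nb <- width %/% bs
  spacing_bins <- ceiling(cfg$min_region_spacing / bs)
  # bin-resolution occupancy masks; all geometry is grid-aligned so the
  # masks are exact, and placement is O(1) per candidate
  keepout_mask <- lapply(chrom_lengths, function(L) logical(L %/% bs))
  block <- function(mask, chrom, start_bp, end_bp) {
    b0 <- max(0, start_bp %/% bs)
    b1 <- min(length(mask[[chrom]]) - 1, (end_bp - 1) %/% bs)
    if (b1 >= b0) mask[[chrom]][(b0:b1) + 1] <- TRUE
    mask
  }
  for (i in seq_len(nrow(genes)))
    keepout_mask <- block(keepout_mask, genes$chrom[i],
                          genes$tss[i] - 2000, genes$tss[i] + 2000)
  if (length(suz12)) {
    pad <- cfg$effects$suz12_flank + bs
    for (i in seq_along(suz12))
      keepout_mask <- block(keepout_mask, as.character(
        GenomicRanges::seqnames(suz12))[i],
        GenomicRanges::start(suz12)[i] - 1 - pad,
        GenomicRanges::end(suz12)[i] + pad)
  }
  placed_mask <- lapply(chrom_lengths, function(L) logical(L %/% bs))
  out <- list()
  total_needed <- sum(cfg$n_regions)
  tries <- 0
  max_tries <- 400 * total_needed
  for (class in names(cfg$n_regions)) {
    n <- cfg$n_regions[[class]]
    got <- 0
    while (got < n) {
      tries <- tries + 1
      if (tries > max_tries)
        stop("could not place ", total_needed, " disjoint regions of ",
             width, " bp at >= 2 kb from every TSS on a ",
             sum(chrom_lengths), " bp genome; enlarge the genome or ",
             "reduce region counts")
      chr <- sample(names(chrom_lengths), 1)
      b0 <- sample.int(length(placed_mask[[chr]]) - nb, 1)
      bins <- b0:(b0 + nb - 1)
      if (any(keepout_mask[[chr]][bins])) next
      buf <- max(1, b0 - spacing_bins):
        min(length(placed_mask[[chr]]), b0 + nb - 1 + spacing_bins)
      if (any(placed_mask[[chr]][buf])) next
      placed_mask[[chr]][bins] <- TRUE
      got <- got + 1
      start <- (b0 - 1) * bs
      out[[length(out) + 1]] <- data.frame(
        chrom = chr, start = start, end = start + width, class = class,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df$name <- sprintf("%s_%03d", df$class,
                     stats::ave(seq_len(nrow(df)), df$class,
                                FUN = seq_along))
  gr <- region_set(df[, c("chrom", "start", "end", "name")])
  gr$class <- df$class[match(names(gr), df$name)]
  gr
}

place_ervs <- function(cfg, chrom_lengths, regions) {
  subfam <- cfg$erv_subfamilies
  if (cfg$n_erv_instances == 0 || nrow(subfam) == 0) {
    warning("no ERV instances configured; all ERV-overlap fractions are 0")
    gr <- GenomicRanges::GRanges()
    gr$subfamily <- character(0)
    gr$family <- character(0)
    return(gr)
  }
  quota <- setNames(rep(cfg$n_erv_instances, nrow(subfam)), subfam$name)
  derep_pool <- subfam$name[subfam$family %in% c("ERVK", "ERV1")]
  rows <- list()
  pick_subfam <- function(pool) {
    avail <- pool[quota[pool] > 0]
    if (!length(avail)) avail <- names(quota)[quota > 0]
    if (!length(avail)) return(NA_character_)
    s <- if (length(avail) == 1) avail else sample(avail, 1)
    quota[s] <<- quota[s] - 1
    s
  }
  # implant one >= 500 bp instance in the designated fraction of each class
  for (class in names(cfg$n_regions)) {
    cls_regions <- regions[regions$class == class]
    n_hit <- round(cfg$erv_overlap_fractions[[class]] * length(cls_regions))
    if (n_hit == 0) next
    hit <- sample(seq_along(cls_regions), n_hit)
    for (i in hit) {
      w <- GenomicRanges::width(cls_regions)[i]
      size <- round(runif(1, 500, min(1500, w)))
      offset <- sample.int(w - size + 1, 1) - 1
      pool <- if (class == "nonDA") subfam$name else derep_pool
      s <- pick_subfam(pool)
      if (is.na(s)) next
      rows[[length(rows) + 1]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(cls_regions))[i],
        start = GenomicRanges::start(cls_regions)[i] - 1 + offset,
        end = GenomicRanges::start(cls_regions)[i] - 1 + offset + size,
        subfamily = s, stringsAsFactors = FALSE)
    }
  }
  # background instances avoid the region classes so fractions stay exact;
  # bin-resolution region mask (regions are grid-aligned, so it is exact)
  bs <- cfg$bin_size
  region_mask <- lapply(chrom_lengths, function(L) logical(L %/% bs))
  reg_chr <- as.character(GenomicRanges::seqnames(regions))
  for (i in seq_along(regions)) {
    b0 <- (GenomicRanges::start(regions)[i] - 1) %/% bs
    b1 <- (GenomicRanges::end(regions)[i] - 1) %/% bs
    region_mask[[reg_chr[i]]][(b0:b1) + 1] <- TRUE
  }
  tries <- 0
  max_tries <- 400 * sum(quota)
  while (sum(quota) > 0 && tries < max_tries) {
    tries <- tries + 1
    chr <- sample(names(chrom_lengths), 1)
    L <- chrom_lengths[[chr]]
    size <- if (runif(1) < cfg$erv_large_fraction)
      round(runif(1, 500, 6000)) else round(runif(1, 100, 499))
    start <- sample.int(L - size, 1) - 1
    bins <- (start %/% bs):((start + size - 1) %/% bs) + 1
    if (any(region_mask[[chr]][bins])) next
    s <- pick_subfam(names(quota))
    if (is.na(s)) break
    rows[[length(rows) + 1]] <- data.frame(
      chrom = chr, start = start, end = start + size, subfamily = s,
      stringsAsFactors = FALSE)
  }
  if (sum(quota) > 0)
    stop("could not place ", sum(quota), " background ERV instances clear ",
         "of the region classes; enlarge the genome")
  df <- do.call(rbind, rows)
  df$name <- sprintf("%s_%04d", gsub("[^A-Za-z0-9]", "", df$subfamily),
                     seq_len(nrow(df)))
  gr <- region_set(df[, c("chrom", "start", "end", "name")])
  gr$subfamily <- df$subfamily[match(names(gr), df$name)]
  gr$family <- subfam$family[match(gr$subfamily, subfam$name)]
  gr
}

simulate_peak_replicates <- function(cfg, genes, bivalent_genes,
                                     active_genes, chrom_lengths,
                                     dropout = 0.05, jitter = 250) {
  n_rep <- cfg$replicates_per_group
  jitter_set <- function(gene_ids, prefix, rep) {
    sel <- genes[genes$gene_id %in% gene_ids, , drop = FALSE]
    keep <- runif(nrow(sel)) > dropout
    sel <- sel[keep, , drop = FALSE]
    if (nrow(sel) == 0L) return(GenomicRanges::GRanges())
    shift <- sample(seq(-jitter, jitter), nrow(sel), replace = TRUE)
    start <- pmax(0, sel$tss - 1000 + shift)
    end <- pmin(sel$tss + 1000 + shift, chrom_lengths[sel$chrom])
    region_set(data.frame(chrom = sel$chrom, start = start, end = end,
                          name = sprintf("%s_r%d_%s", prefix, rep,
                                         sel$gene_id),
                          stringsAsFactors = FALSE))
  }
  k4 <- lapply(seq_len(n_rep), function(r)
    jitter_set(c(bivalent_genes, active_genes), "K4me3", r))
  k27 <- lapply(seq_len(n_rep), function(r)
    jitter_set(bivalent_genes, "K27me3", r))
  prc2 <- promoter_windows(genes, bivalent_genes, 1000, chrom_lengths,
                           prefix = "prc2")
  list(K4me3 = k4, K27me3 = k27, PRC2 = prc2)
}

implant_links <- function(cfg, regions, genes) {
  da <- regions[regions$class %in% c("Cluster1", "Cluster2")]
  if (length(da) == 0L)
    return(data.frame(region_id = character(0), gene_id = character(0)))
  centers <- region_centers(da)
  rows <- lapply(seq_along(da), function(i) {
    chr <- as.character(GenomicRanges::seqnames(da))[i]
    cand <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    d <- abs(cand$tss - centers[i])
    j <- which.min(d)
    if (d[j] > cfg$link_max_dist) return(NULL)
    data.frame(region_id = names(da)[i], gene_id = cand$gene_id[j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region_id = character(0), gene_id = character(0))
  out
}

region_erv_overlaps <- function(regions, ervs) {
  if (length(ervs) == 0L)
    return(setNames(vector("list", length(regions)), names(regions)))
  hits <- GenomicRanges::findOverlaps(regions, ervs, ignore.strand = TRUE)
  split(names(ervs)[S4Vectors::subjectHits(hits)],
        factor(S4Vectors::queryHits(hits), levels = seq_along(regions),
               labels = names(regions)))
}

#' Simulate one binned signal track
#'
#' Multiplicative model: a deterministic mean surface (baseline 1.0, RPGC
#' convention, times the implanted per-class enrichments and mutant
#' multipliers) times mean-one lognormal noise. The K27A genotype reduces
#' H3K27me3 within SUZ12 peaks by `f_in` and in the +/- 1.5 kb flanks by
#' `f_flank < f_in` (flank-specific loss); the K9A genotype applies a
#' uniform H3K27me3 loss over both zones. Every (mark, genotype, replicate)
#' triple draws from its own seed substream.
#'
#' @param truth a `synth_genome` from [build_genome()].
#' @param mark one of H3.3, H3K9me3, H3K27ac, H3K9ac, H3K4me3, H3K27me3,
#'   SUZ12, PROseq.
#' @param genotype a configured genotype label.
#' @param replicate replicate index.
#' @return A [binned_track()] tagged `"RPGC"`.
#' @export
simulate_tracks <- function(truth, mark, genotype, replicate = 1) {
  stopifnot(inherits(truth, "synth_genome"))
  cfg <- truth$truth$config
  marks <- c("H3.3", "H3K9me3", "H3K27ac", "H3K9ac", "H3K4me3", "H3K27me3",
             "SUZ12", "PROseq")
  if (!mark %in% marks)
    stop("unknown mark '", mark, "'; expected one of ",
         paste(marks, collapse = ", "))
  if (!genotype %in% cfg$groups)
    stop("unknown genotype '", genotype, "'; configured groups: ",
         paste(cfg$groups, collapse = ", "))
  surface <- mean_surface(truth, mark, genotype)
  sd <- cfg$noise_sd
  values <- surface
  if (sd > 0) {
    with_seed(substream_seed(cfg$seed, "track", mark, genotype, replicate), {
      values <- lapply(surface, function(v)
        v * rlnorm(length(v), meanlog = -sd^2 / 2, sdlog = sd))
    })
  }
  binned_track(values, cfg$bin_size, truth$chrom_lengths, norm = "RPGC")
}

## internal: noise-free mean surface for one (mark, genotype)
mean_surface <- function(genome, mark, genotype) {
  cfg <- genome$truth$config
  eff <- cfg$effects
  bs <- cfg$bin_size
  values <- lapply(genome$chrom_lengths, function(L)
    rep(1, ceiling(L / bs)))
  mult <- function(values, gr, factor) {
    if (length(gr) == 0L || length(factor) == 0L) return(values)
    factor <- rep_len(factor, length(gr))
    chroms <- as.character(GenomicRanges::seqnames(gr))
    starts <- GenomicRanges::start(gr) - 1
    ends <- GenomicRanges::end(gr)
    for (i in seq_along(gr)) {
      v <- values[[chroms[i]]]
      if (is.null(v)) next
      # bins whose midpoint falls inside the interval
      b0 <- floor((starts[i] + bs / 2) / bs)
      b1 <- ceiling((ends[i] - bs / 2) / bs) - 1
      if (b1 < b0) next
      idx <- pmax(0, b0):pmin(length(v) - 1, b1) + 1
      values[[chroms[i]]][idx] <- v[idx] * factor[i]
    }
    values
  }
  regions <- genome$regions
  cls <- regions$class
  control <- cfg$groups[1]
  is_k9a <- genotype == "K9A"
  is_k27a <- genotype == "K27A"
  biv_prom <- genome$suz12
  active_prom <- promoter_windows(genome$genes, genome$truth$active_genes,
                                  1000, genome$chrom_lengths, "act")
  flanks <- suz12_flanks(genome$suz12, eff$suz12_flank,
                         genome$chrom_lengths)
  gene_bodies <- GenomicRanges::GRanges(
    genome$genes$chrom,
    IRanges::IRanges(genome$genes$tx_start + 1, genome$genes$tx_end))
  if (mark == "H3.3") {
    values <- mult(values, regions, eff$h33_enrichment[cls])
    values <- mult(values, biv_prom, eff$h33_promoter)
  } else if (mark == "H3K9me3") {
    base <- rep(eff$k9me3_enrichment, length(regions))
    if (is_k9a) base <- base * eff$k9me3_mult[cls]
    values <- mult(values, regions, base)
  } else if (mark == "H3K27ac") {
    gain <- if (is_k9a) eff$k27ac_gain[cls] else rep(1, length(regions))
    values <- mult(values, regions, gain)
    values <- mult(values, active_prom, eff$active_k27ac)
  } else if (mark == "H3K9ac") {
    gain <- if (is_k9a) eff$k9ac_gain[cls] else rep(1, length(regions))
    values <- mult(values, regions, gain)
    values <- mult(values, active_prom, eff$active_k27ac)
  } else if (mark == "PROseq") {
    values <- mult(values, gene_bodies, eff$proseq_gene_body)
    gain <- if (is_k9a) eff$proseq_gain[cls] else rep(1, length(regions))
    values <- mult(values, regions, gain)
  } else if (mark == "H3K4me3") {
    values <- mult(values, biv_prom, eff$k4me3_enrichment)
    values <- mult(values, active_prom, eff$k4me3_enrichment)
  } else if (mark == "H3K27me3") {
    values <- mult(values, biv_prom, eff$k27me3_enrichment)
    values <- mult(values, flanks, eff$k27me3_enrichment)
    if (is_k27a) {
      values <- mult(values, biv_prom, eff$f_in)
      values <- mult(values, flanks, eff$f_flank)
    } else if (is_k9a) {
      values <- mult(values, biv_prom, eff$k9a_k27me3_loss)
      values <- mult(values, flanks, eff$k9a_k27me3_loss)
    }
  } else if (mark == "SUZ12") {
    base <- eff$suz12_enrichment
    if (is_k27a) base <- base * eff$suz12_k27a_loss
    values <- mult(values, biv_prom, base)
  }
  values
}

## internal: upstream/downstream flank zones of a peak set
suz12_flanks <- function(peaks, flank, chrom_lengths) {
  if (length(peaks) == 0L) return(GenomicRanges::GRanges())
  up <- GenomicRanges::flank(peaks, flank, start = TRUE,
                             ignore.strand = TRUE)
  down <- GenomicRanges::flank(peaks, flank, start = FALSE,
                               ignore.strand = TRUE)
  out <- c(up, down)
  GenomicRanges::trim(out)
}

#' Simulate count matrices for genes and ERV subfamilies
#'
#' Negative-binomial counts (variance = mu + dispersion * mu^2) with
#' per-sample depth factors. Linked genes get `+linked_lfc` (direction
#' `"up"`) or `-linked_lfc` (direction `"down"`) in the K9A genotype; ERV
#' subfamilies with an implanted instance under a de-repressed region get
#' `te_lfc` in K9A. With `dispersion = 0` counts equal the rounded expected
#' means.
#'
#' @param truth a `synth_genome` from [build_genome()].
#' @return list with `genes` (genes x samples integer matrix), `te`
#'   (subfamilies x samples), `sheet` (sample sheet data.frame) and
#'   `gene_lfc`/`te_lfc` matrices of implanted log2 effects.
#' @export
simulate_counts <- function(truth) {
  stopifnot(inherits(truth, "synth_genome"))
  cfg <- truth$truth$config
  ex <- cfg$expression
  if (ex$dispersion < 0) stop("NB dispersion must be non-negative")
  sheet <- expand.grid(replicate = seq_len(cfg$replicates_per_group),
                       genotype = cfg$groups, stringsAsFactors = FALSE)
  sheet <- data.frame(sample = sprintf("%s_rep%d", sheet$genotype,
                                       sheet$replicate),
                      genotype = sheet$genotype,
                      replicate = sheet$replicate,
                      batch = sprintf("batch%d", sheet$replicate),
                      stringsAsFactors = FALSE)
  gene_ids <- truth$genes$gene_id
  dir <- truth$truth$gene_direction
  gene_lfc <- matrix(0, nrow = length(gene_ids), ncol = nrow(sheet),
                     dimnames = list(gene_ids, sheet$sample))
  gene_lfc[names(dir)[dir == "up"], sheet$genotype == "K9A"] <- ex$linked_lfc
  gene_lfc[names(dir)[dir == "down"],
           sheet$genotype == "K9A"] <- -ex$linked_lfc
  subfams <- cfg$erv_subfamilies$name
  te_lfc <- matrix(0, nrow = length(subfams), ncol = nrow(sheet),
                   dimnames = list(subfams, sheet$sample))
  if (length(truth$truth$te_up))
    te_lfc[truth$truth$te_up, sheet$genotype == "K9A"] <- ex$te_lfc
  draw <- function(base_means, lfc, tag) {
    with_seed(substream_seed(cfg$seed, "counts", tag), {
      depth <- runif(nrow(sheet), ex$depth_range[1], ex$depth_range[2])
      mu <- outer(base_means, depth) * 2^lfc
      counts <- if (ex$dispersion == 0) round(mu)
                else matrix(rnbinom(length(mu), mu = mu,
                                    size = 1 / ex$dispersion),
                            nrow = nrow(mu))
      dimnames(counts) <- dimnames(lfc)
      list(counts = counts, depth = depth)
    })
  }
  with_seed(substream_seed(cfg$seed, "counts", "means"), {
    gene_means <- rlnorm(length(gene_ids), ex$gene_mean_log, ex$gene_mean_sd)
    te_means <- rlnorm(length(subfams), ex$te_mean_log, ex$te_mean_sd)
  })
  g <- draw(gene_means, gene_lfc, "genes")
  t <- draw(te_means, te_lfc, "te")
  list(genes = g$counts, te = t$counts, sheet = sheet,
       gene_lfc = gene_lfc, te_lfc = te_lfc,
       depth = setNames(g$depth, sheet$sample))
}
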