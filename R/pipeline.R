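#' Pipeline run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Unknown
#' keys (top level or in `params`) are rejected so typos fail fast.
#'
#' @param outdir output directory (created if needed).
#' @param seed root seed; every stage derives its streams from it.
#' @param stages character vector of stages to run, in any order; executed
#'   in dependency order. Available: simulate, differential, cluster,
#'   bivalent, spreading, te_enrich, link, report.
#' @param synth list of [synth_config()] overrides.
#' @param params list of stage parameters: `padj_cut`, `lfc_cut`,
#'   `erv_lfc_cut`, `da_lfc_cut`, `fdr_cut`, `max_dist`, `te_iterations`,
#'   `spread_flank`, `write_tracks`.
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1,
                       stages = c("simulate", "differential", "cluster",
                                  "bivalent", "spreading", "te_enrich",
                                  "link", "report"),
                       synth = list(), params = list()) {
  known_stages <- c("simulate", "differential", "cluster", "bivalent",
                    "spreading", "te_enrich", "link", "report")
  bad <- setdiff(stages, known_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  defaults <- list(padj_cut = 0.05, lfc_cut = 1, erv_lfc_cut = 1.5,
                   da_lfc_cut = 0.5, fdr_cut = 0.2, max_dist = 250000,
                   te_iterations = 20, spread_flank = 1500,
                   write_tracks = FALSE)
  bad <- setdiff(names(params), names(defaults))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  params <- utils::modifyList(defaults, params)
  structure(list(outdir = outdir, seed = seed, stages = stages,
                 synth = synth, params = params), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file with the fields of [run_config()].
#' @return list of class `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("outdir", "seed", "stages", "synth", "params")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order on a synthetic study
#' (simulate -> differential -> clustering -> bivalent / spreading /
#' TE enrichment / linkage -> report), writing standard-format artifacts
#' (BED, TSV, bedGraph, JSON) under `outdir`. Rerunning with an identical
#' configuration reproduces identical outputs.
#'
#' @param config a [run_config()] or path to a YAML config file.
#' @return Invisibly, the run report (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  art <- new.env(parent = emptyenv())
  report <- list(seed = config$seed,
                 config_hash = config_hash(config),
                 stages = list())
  files <- character(0)
  note <- function(stage, ...) {
    report$stages[[stage]] <<- c(report$stages[[stage]], list(...))
  }
  out_file <- function(name) {
    f <- file.path(config$outdir, name)
    files <<- c(files, f)
    f
  }
  need <- function(stage, what, from) {
    if (!exists(what, envir = art))
      stop("stage '", stage, "' requires the ", what,
           " artifact from stage '", from, "', which did not run")
    get(what, envir = art)
  }
  stages <- intersect(c("simulate", "differential", "cluster", "bivalent",
                        "spreading", "te_enrich", "link", "report"),
                      config$stages)

  if ("simulate" %in% stages) {
    scfg <- do.call(synth_config, utils::modifyList(
      list(seed = config$seed), config$synth))
    genome <- build_genome(scfg)
    counts <- simulate_counts(genome)
    assign("genome", genome, envir = art)
    assign("counts", counts, envir = art)
    write_gene_table(genome$genes, out_file("genes.tsv"))
    write_bed(genome$regions, out_file("regions.bed"))
    if (length(genome$ervs)) write_bed(genome$ervs, out_file("ervs.bed"))
    write_bed(genome$suz12, out_file("suz12.bed"))
    write_count_matrix(counts$genes, out_file("gene_counts.tsv"))
    write_count_matrix(counts$te, out_file("te_counts.tsv"))
    write_sample_sheet(counts$sheet, out_file("samples.tsv"))
    truth_out <- genome$truth
    truth_out$config <- unclass(truth_out$config)
    jsonlite::write_json(truth_out, out_file("truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (isTRUE(p$write_tracks)) {
      for (mark in c("H3K9me3", "H3K27ac", "H3K27me3")) {
        for (g in scfg$groups) for (r in seq_len(scfg$replicates_per_group))
          write_bedgraph(simulate_tracks(genome, mark, g, r),
                         out_file(sprintf("%s_%s_rep%d.bedGraph",
                                          mark, g, r)))
      }
    }
    note("simulate", n_genes = nrow(genome$genes),
         n_regions = length(genome$regions), n_ervs = length(genome$ervs))
  }

  track_set <- function(genome, mark, genotype) {
    cfg <- genome$truth$config
    lapply(seq_len(cfg$replicates_per_group), function(r)
      simulate_tracks(genome, mark, genotype, r))
  }
  sample_tracks <- function(genome, mark) {
    cfg <- genome$truth$config
    out <- list()
    for (g in cfg$groups) for (r in seq_len(cfg$replicates_per_group))
      out[[sprintf("%s_rep%d", g, r)]] <- simulate_tracks(genome, mark, g, r)
    out
  }

  if ("differential" %in% stages) {
    genome <- need("differential", "genome", "simulate")
    counts <- need("differential", "counts", "simulate")
    contrast <- c("K9A", genome$truth$config$groups[1])
    de <- differential_analysis(counts$genes, counts$sheet, contrast,
                                padj_cut = p$padj_cut, lfc_cut = p$lfc_cut,
                                seed = config$seed)
    # normalize the handful of repeat subfamilies with gene-derived size
    # factors: median-of-ratios on 12 features, half of them de-repressed,
    # would absorb the signal into the normalization
    te <- differential_analysis(counts$te, counts$sheet, contrast,
                                padj_cut = p$padj_cut,
                                lfc_cut = p$erv_lfc_cut, seed = config$seed,
                                factors = size_factors(counts$genes))
    k9_tracks <- sample_tracks(genome, "H3K9me3")
    region_sig <- region_sample_matrix(k9_tracks, genome$regions,
                                       how = "sum")
    da <- differential_analysis(round(region_sig), counts$sheet, contrast,
                                padj_cut = p$padj_cut,
                                lfc_cut = p$da_lfc_cut, seed = config$seed)
    assign("de_genes", de, envir = art)
    assign("de_te", te, envir = art)
    assign("da_regions", da, envir = art)
    write.table(de, out_file("de_genes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(te, out_file("de_te.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(da, out_file("da_regions.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("differential", n_de_genes = sum(de$status != "ns"),
         n_de_te = sum(te$status != "ns"),
         n_da_regions = sum(da$status != "ns"))
  }

  if ("cluster" %in% stages) {
    genome <- need("cluster", "genome", "simulate")
    da <- need("cluster", "da_regions", "differential")
    da_ids <- da$feature[da$status != "ns"]
    da_regions <- genome$regions[names(genome$regions) %in% da_ids]
    ctl <- genome$truth$config$groups[1]
    avg_matrix <- function(genotype) {
      mats <- lapply(track_set(genome, "H3K9me3", genotype),
                     signal_matrix, centers = da_regions)
      Reduce("+", mats) / length(mats)
    }
    cl <- kmeans_cluster_regions(avg_matrix(ctl), avg_matrix("K9A"),
                                 seed = config$seed)
    assign("clusters", cl, envir = art)
    tab <- data.frame(region = names(cl$label), cluster = cl$label,
                      control_mean = cl$control_mean,
                      mutant_mean = cl$mutant_mean, ratio = cl$ratio)
    write.table(tab, out_file("clusters.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("cluster", n_cluster1 = sum(cl$label == "Cluster1"),
         n_cluster2 = sum(cl$label == "Cluster2"),
         degenerate = cl$degenerate)
  }

  if ("bivalent" %in% stages) {
    genome <- need("bivalent", "genome", "simulate")
    biv <- call_bivalent_promoters(genome$peak_reps$K4me3,
                                   genome$peak_reps$K27me3, genome$genes,
                                   genome$peak_reps$PRC2)
    assign("bivalent", biv, envir = art)
    write.table(biv, out_file("bivalent.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("bivalent", n_bivalent = sum(biv$bivalent))
  }

  if ("spreading" %in% stages) {
    genome <- need("spreading", "genome", "simulate")
    ctl <- genome$truth$config$groups[1]
    ctl_tracks <- track_set(genome, "H3K27me3", ctl)
    rows <- list()
    for (g in setdiff(genome$truth$config$groups, ctl)) {
      sp <- spreading_analysis(genome$suz12, ctl_tracks,
                               track_set(genome, "H3K27me3", g),
                               flank = p$spread_flank)
      rows[[g]] <- data.frame(genotype = g, zone = names(sp$ratios),
                              ratio = unname(sp$ratios))
      assign(paste0("spreading_", g), sp, envir = art)
    }
    tab <- do.call(rbind, rows)
    write.table(tab, out_file("spreading.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("spreading", ratios = split(tab$ratio, tab$genotype))
  }

  if ("te_enrich" %in% stages) {
    genome <- need("te_enrich", "genome", "simulate")
    signal <- genome$regions[genome$regions$class %in%
                               c("Cluster1", "Cluster2")]
    if (length(genome$ervs) == 0L) {
      note("te_enrich", skipped = "no ERV instances in the annotation")
    } else {
      te_enr <- te_shuffle_enrichment(signal, genome$ervs,
                                      genome$chrom_lengths,
                                      iterations = p$te_iterations,
                                      seed = config$seed)
      assign("te_enrichment", te_enr, envir = art)
      write.table(te_enr, out_file("te_enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      note("te_enrich", n_enriched = sum(te_enr$enriched))
    }
  }

  if ("link" %in% stages) {
    genome <- need("link", "genome", "simulate")
    counts <- need("link", "counts", "simulate")
    de <- need("link", "de_genes", "differential")
    da <- need("link", "da_regions", "differential")
    da_regions <- genome$regions[names(genome$regions) %in%
                                   da$feature[da$status != "ns"]]
    k27ac <- sample_tracks(genome, "H3K27ac")
    peak_signal <- log2(region_sample_matrix(k27ac, da_regions) + 1)
    expr <- log2(normalize_counts(counts$genes) + 1)
    pairs <- candidate_pairs(da_regions, genome$genes,
                             max_dist = p$max_dist)
    links <- correlate_links(pairs, peak_signal, expr,
                             fdr_cut = p$fdr_cut)
    summ <- link_summary(links, de, genome$truth$region_class)
    assign("links", links, envir = art)
    assign("link_summary", summ, envir = art)
    write.table(links, out_file("links.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(summ, out_file("link_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("link", n_candidates = nrow(links),
         n_retained = sum(links$retained))
  }

  report$artifacts <- lapply(setNames(files, basename(files)), function(f)
    list(md5 = unname(tools::md5sum(f)), bytes = file.size(f)))
  report_path <- file.path(config$outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(report)
}

## internal: stable hash of a configuration
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL  # the same analysis in a different directory is the same
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}
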