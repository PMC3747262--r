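# End-to-end orchestration: simulate (or load) -> normalize -> probe
# statistics -> region calls -> annotation -> report, per cell type, from
# a single config (an R list or a YAML file). Outputs are plain TSV/BED
# with provenance headers (package version + config hash), byte-identical
# for a fixed config and seed.

pkg_version <- function() {
  as.character(utils::packageVersion("tilemeth"))
}

#' Synthetic gene models for simulated loci
#'
#' One gene per locus: the TSS sits `flank` bp after the locus start and
#' the TES `flank` bp before the locus end (so the tiled span covers the
#' gene plus its flanks), alternating strand across loci.
#'
#' @param loci Locus table.
#' @param flank Flank size in bp (default 40000, clipped to fit).
#' @return Gene model `data.frame`.
#' @export
study_gene_models <- function(loci, flank = 40000) {
  fl <- pmin(flank, (loci$length %/% 3))
  plus <- seq_len(nrow(loci)) %% 2 == 1
  tss <- ifelse(plus, loci$start + fl, loci$start + loci$length - fl)
  tes <- ifelse(plus, loci$start + loci$length - fl, loci$start + fl)
  data.frame(gene_id = loci$locus_id, chrom = loci$chrom,
             tss = as.integer(tss),
             strand = ifelse(plus, "+", "-"),
             tes = as.integer(tes), stringsAsFactors = FALSE)
}

write_calls <- function(calls, path_tsv, path_bed, comments) {
  df <- calls
  df$probe_ids <- NULL
  write_tsv_commented(df, path_tsv, comments)
  called <- calls[calls$called, , drop = FALSE]
  bed <- data.frame(chrom = called$chrom, start = called$start,
                    end = called$end, name = called$direction,
                    score = round(-10 * log10(pmax(called$q_region,
                                                   1e-30)), 2),
                    stringsAsFactors = FALSE)
  write_bed(bed, path_bed)
  invisible(NULL)
}

#' Run the whole analysis from a config
#'
#' The config is a list (or path to a YAML file) with entries:
#' \describe{
#'   \item{out_dir}{output directory (created if absent); required.}
#'   \item{simulate}{`TRUE` or a list of [simulation_spec()] arguments —
#'     generate a synthetic study and write its inputs; otherwise}
#'   \item{design, intensities, samples, phenotype, genes}{paths to the
#'     corresponding TSV inputs.}
#'   \item{tracks}{named list of BED paths for annotation tracks.}
#'   \item{thresholds}{list of [calling_thresholds()] arguments.}
#'   \item{cell_types}{cell types to process (default: all in the sample
#'     sheet; each is analyzed independently end-to-end).}
#'   \item{analytes}{analytes for the correlation arm (default: all in
#'     the phenotype table, if any).}
#'   \item{seed}{master seed for simulation.}
#' }
#'
#' @param config List or YAML path.
#' @return A run report: per cell type the contrast calls, correlation
#'   calls, annotation table and summary counts; counts always equal the
#'   lengths of the written call tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop_data("run_pipeline: config needs out_dir")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- object_hash(config[setdiff(names(config), "out_dir")])
  comments <- c(paste0("tilemeth ", pkg_version(), " config=", hash))

  thresholds <- do.call(calling_thresholds,
                        config$thresholds %||% list())

  if (!is.null(config$simulate) && !identical(config$simulate, FALSE)) {
    args <- if (is.list(config$simulate)) config$simulate else list()
    if (!is.null(config$seed)) args$seed <- config$seed
    spec <- do.call(simulation_spec, args)
    sim <- simulate_cohort(spec)
    design <- sim$truth$design
    intensities <- sim$intensities
    samples <- sim$samples
    genes <- study_gene_models(spec$loci)
    tracks <- simulate_tracks(design, seed = derive_seed(spec$seed, "tracks"))
    phenotype <- if (!is.null(spec$phenotype_links))
      simulate_phenotype(sim$truth) else NULL
    write_probe_design(design, file.path(out_dir, "design.tsv"))
    write_intensities(intensities, file.path(out_dir, "intensities.tsv"))
    write_sample_sheet(samples, file.path(out_dir, "samples.tsv"))
    write_gene_models(genes, file.path(out_dir, "genes.tsv"))
    if (!is.null(phenotype)) {
      write_phenotype(phenotype, file.path(out_dir, "phenotype.tsv"))
    }
    if (!is.null(sim$truth$planted)) {
      write_bed(sim$truth$planted, file.path(out_dir, "truth_dmrs.bed"))
    }
    for (tn in names(tracks)) {
      write_bed(tracks[[tn]], file.path(out_dir, paste0("track_", tn, ".bed")))
    }
  } else {
    design <- read_probe_design(config$design)
    intensities <- read_intensities(config$intensities, design)
    samples <- read_sample_sheet(config$samples)
    genes <- if (!is.null(config$genes)) read_gene_models(config$genes)
    phenotype <- if (!is.null(config$phenotype))
      read_phenotype(config$phenotype) else NULL
    tracks <- lapply(config$tracks %||% list(), read_bed)
  }

  cell_types <- config$cell_types %||% unique(samples$cell_type)
  analytes <- config$analytes %||%
    (if (!is.null(phenotype)) unique(phenotype$analyte) else character(0))

  report <- list(version = pkg_version(), config_hash = hash,
                 thresholds = unclass(thresholds), cell_types = list())
  for (ct in cell_types) {
    m <- normalize_arrays(intensities, design, samples, ct)
    contrast <- run_contrast_pipeline(m, design, thresholds = thresholds)
    write_calls(contrast,
                file.path(out_dir, paste0("calls_", ct, ".tsv")),
                file.path(out_dir, paste0("calls_", ct, ".bed")),
                comments)
    corr <- list()
    for (an in analytes) {
      cc <- run_correlation_pipeline(m, design, phenotype, an,
                                     thresholds = thresholds)
      write_calls(cc,
                  file.path(out_dir, sprintf("corr_%s_%s.tsv", ct, an)),
                  file.path(out_dir, sprintf("corr_%s_%s.bed", ct, an)),
                  comments)
      corr[[an]] <- cc
    }
    ann <- NULL
    called <- contrast[contrast$called, , drop = FALSE]
    if (!is.null(genes) && nrow(called) > 0) {
      ann <- annotate_regions(called, genes, tracks)
      ann <- merge(ann,
                   called[c("region_id", "direction", "q_region")],
                   by = "region_id", sort = FALSE)
      write_tsv_commented(ann,
                          file.path(out_dir, paste0("annotated_", ct, ".tsv")),
                          comments)
    }
    per_locus <- table(called$locus_id)
    report$cell_types[[ct]] <- list(
      n_regions_tested = nrow(contrast),
      n_called = nrow(called),
      per_locus = as.list(per_locus),
      n_corr_called = vapply(corr, function(x) sum(x$called), integer(1)),
      contrast = contrast, correlation = corr, annotation = ann)
  }
  report
}
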