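# Seeded synthetic-data generator reproducing the statistical structure of
# a two-group MeDIP tiling-array study: probe designs at fixed spacing over
# multi-kb loci, two-channel intensities whose log2(bound/input) is
# baseline + planted group effect + subject + replicate + probe noise,
# per-subject phenotypes linearly linked to region methylation, and
# BED-style regulatory-element tracks.
#
# Everything is a pure function of (spec, seed): sub-stream seeds are
# derived deterministically per subject / array / purpose, so regenerating
# with the same master seed is bit-identical.

#' Default tiled loci
#'
#' Eight synthetic loci named after the cytokine and transcription-factor
#' genes of the motivating study design (five interleukin loci plus
#' NFKB1, NFAT5, STAT6), each spanning roughly the gene plus ~40 kb of
#' flank on either side (100-180 kb).
#'
#' @return `data.frame` with `locus_id`, `chrom`, `start`, `length`.
#' @export
study_loci <- function() {
  data.frame(
    locus_id = c("IL1A", "IL6", "IL8", "IL4", "IL10",
                 "NFKB1", "NFAT5", "STAT6"),
    chrom = c("chr2", "chr7", "chr4", "chr5", "chr1",
              "chr4", "chr16", "chr12"),
    start = c(113000000L, 22680000L, 74570000L, 132000000L, 206900000L,
              103380000L, 69570000L, 57460000L),
    length = c(100000L, 120000L, 100000L, 140000L, 100000L,
               180000L, 180000L, 100000L),
    stringsAsFactors = FALSE)
}

#' Construct a planted DMR specification
#'
#' Coordinates are relative offsets (bp) within the locus, 0-based
#' half-open. `effect` is the group A minus group B shift of the log2
#' bound/input ratio over probes inside the interval.
#'
#' @param locus_id Locus the DMR lies in.
#' @param start,end Offset interval within the locus (bp).
#' @param effect Log2 shift (non-zero).
#' @param label Identifier used by phenotype links and ground truth.
#' @return One-row `data.frame`.
#' @export
planted_dmr <- function(locus_id, start, end, effect,
                        label = sprintf("%s_%d_%d", locus_id, start, end)) {
  stopifnot(end > start, start >= 0, effect != 0)
  data.frame(locus_id = locus_id, start = as.integer(start),
             end = as.integer(end), effect = effect, label = label,
             stringsAsFactors = FALSE)
}

#' Construct a phenotype link
#'
#' Ties a per-subject analyte level to the subject's true mean methylation
#' over a planted region: `level = intercept + slope * mean + N(0, noise_sd)`.
#'
#' @param label Label of a planted DMR.
#' @param slope Phenotype units per log2 unit.
#' @param intercept Phenotype units (e.g. pg/ml).
#' @param noise_sd Positive Gaussian noise SD.
#' @param analyte Analyte name for the phenotype table.
#' @param cell_type Cell type whose methylation drives the phenotype.
#' @return One-row `data.frame`.
#' @export
phenotype_link <- function(label, slope, intercept = 0, noise_sd = 1,
                           analyte = label, cell_type = "T_cell") {
  stopifnot(noise_sd > 0)
  data.frame(label = label, slope = slope, intercept = intercept,
             noise_sd = noise_sd, analyte = analyte, cell_type = cell_type,
             stringsAsFactors = FALSE)
}

#' Simulation specification
#'
#' Defaults mirror the motivating study design: 8 case (A) vs 12 control
#' (B) subjects, 3 replicate arrays per sample, two cell types, probes at
#' 100-bp spacing, and additive Gaussian noise on the log2 scale at three
#' levels (probe 0.3, subject 0.3, replicate 0.2 log2 units).
#'
#' @param loci Locus table (`locus_id`, `chrom`, `start`, `length`).
#' @param n_group_a,n_group_b Subjects per group.
#' @param n_replicates Arrays per sample.
#' @param cell_types Cell types to simulate.
#' @param probe_spacing Probe spacing in bp.
#' @param probe_noise_sd Per-probe affinity effect SD (log2), drawn once
#'   per cell type and shared across arrays (hybridization/enrichment
#'   efficiency of the probe; cancels in group contrasts).
#' @param subject_sd Per-(subject, probe) biological noise SD (log2).
#' @param replicate_sd Per-(array, probe) technical measurement noise SD
#'   (log2).
#' @param planted_dmrs `data.frame` of [planted_dmr()] rows, or `NULL`.
#' @param phenotype_links `data.frame` of [phenotype_link()] rows, or `NULL`.
#' @param seed Master seed; all randomness derives from it.
#' @return A validated list of class `sim_spec`.
#' @export
simulation_spec <- function(loci = study_loci(), n_group_a = 8,
                            n_group_b = 12, n_replicates = 3,
                            cell_types = c("T_cell", "monocyte"),
                            probe_spacing = 100, probe_noise_sd = 0.3,
                            subject_sd = 0.3, replicate_sd = 0.2,
                            planted_dmrs = NULL, phenotype_links = NULL,
                            seed = 1) {
  stopifnot(n_group_a >= 1, n_group_b >= 1, n_replicates >= 1,
            probe_spacing > 0, probe_noise_sd > 0, subject_sd > 0,
            replicate_sd > 0, length(cell_types) >= 1)
  if (!is.null(planted_dmrs) && nrow(planted_dmrs) > 0) {
    for (i in seq_len(nrow(planted_dmrs))) {
      d <- planted_dmrs[i, ]
      loc <- loci[loci$locus_id == d$locus_id, ]
      if (nrow(loc) != 1) {
        stop_data("simulation_spec: planted DMR references unknown locus ",
                  d$locus_id)
      }
      if (d$start < 0 || d$end > loc$length) {
        stop_data("simulation_spec: planted DMR outside locus ", d$locus_id)
      }
      if (d$effect == 0) stop_data("simulation_spec: planted effect must be non-zero")
    }
  }
  structure(list(loci = loci, n_group_a = n_group_a, n_group_b = n_group_b,
                 n_replicates = n_replicates, cell_types = cell_types,
                 probe_spacing = probe_spacing,
                 probe_noise_sd = probe_noise_sd, subject_sd = subject_sd,
                 replicate_sd = replicate_sd,
                 planted_dmrs = planted_dmrs,
                 phenotype_links = phenotype_links, seed = seed),
            class = "sim_spec")
}

#' Tile loci with probes at fixed spacing
#'
#' Probes of width `spacing` tile `[start, start + length)` of each locus;
#' a trailing remainder shorter than the spacing is left untiled.
#'
#' @param loci Locus table (`locus_id`, `chrom`, `start`, `length`).
#' @param spacing Probe spacing (= probe width) in bp.
#' @return Probe design `data.frame` (`probe_id`, `chrom`, `start`, `end`,
#'   `locus_id`), 0-based half-open.
#' @export
simulate_design <- function(loci, spacing = 100) {
  if (spacing <= 0) stop_data("simulate_design: spacing must be positive")
  if (any(loci$length <= 0)) stop_data("simulate_design: non-positive locus length")
  if (any(loci$length < spacing)) {
    stop_data("simulate_design: locus shorter than probe spacing")
  }
  out <- lapply(seq_len(nrow(loci)), function(i) {
    n <- loci$length[i] %/% spacing
    starts <- loci$start[i] + (seq_len(n) - 1L) * spacing
    data.frame(
      probe_id = sprintf("%s_p%05d", loci$locus_id[i], seq_len(n)),
      chrom = loci$chrom[i], start = as.integer(starts),
      end = as.integer(starts + spacing), locus_id = loci$locus_id[i],
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# Smooth low-frequency baseline methylation profile per locus: mimics the
# slowly varying average methylation track without affecting group
# differences. Deterministic in the locus id.
baseline_profile <- function(design, loci) {
  base <- numeric(nrow(design))
  for (i in seq_len(nrow(loci))) {
    sel <- design$locus_id == loci$locus_id[i]
    pos <- design$start[sel] - loci$start[i]
    phase <- (i * 0.7) %% (2 * pi)
    base[sel] <- 0.4 * sin(2 * pi * pos / 20000 + phase) +
      0.2 * sin(2 * pi * pos / 57000 + 2 * phase)
  }
  base
}

# Per-probe planted effect vector for group A (log2 units).
planted_effect_vector <- function(design, loci, planted_dmrs) {
  eff <- numeric(nrow(design))
  if (is.null(planted_dmrs) || nrow(planted_dmrs) == 0) return(eff)
  for (i in seq_len(nrow(planted_dmrs))) {
    d <- planted_dmrs[i, ]
    loc <- loci[loci$locus_id == d$locus_id, ]
    abs_start <- loc$start + d$start
    abs_end <- loc$start + d$end
    sel <- design$locus_id == d$locus_id & design$start >= abs_start &
      design$start < abs_end
    eff[sel] <- eff[sel] + d$effect
  }
  eff
}

#' Simulate a full cohort of two-channel arrays
#'
#' For every subject, cell type and replicate, per-probe bound and input
#' intensities such that `log2(bound/input)` equals
#' baseline + per-probe affinity + planted group effect (group A only,
#' inside planted DMRs) + subject biological noise + per-array technical
#' noise.
#' The input channel is log-normal around a fixed brightness and
#' `bound = input * 2^(log-ratio)`, so channels are positive by
#' construction and planted log-ratios are exact.
#'
#' @param spec A [simulation_spec()].
#' @param design Probe design; defaults to tiling `spec$loci`.
#' @return List with `intensities` (long table), `samples` (sample
#'   sheet), and `truth` (ground truth: the spec, design, per-cell-type
#'   probes x subjects matrix of true mean log-ratios, and a BED-style
#'   table of planted regions with direction).
#' @export
simulate_cohort <- function(spec,
                            design = simulate_design(spec$loci,
                                                     spec$probe_spacing)) {
  stopifnot(inherits(spec, "sim_spec"))
  loci <- spec$loci
  np <- nrow(design)
  subjects <- c(sprintf("A%02d", seq_len(spec$n_group_a)),
                sprintf("B%02d", seq_len(spec$n_group_b)))
  groups <- rep(c("A", "B"), c(spec$n_group_a, spec$n_group_b))
  base <- baseline_profile(design, loci)
  eff <- planted_effect_vector(design, loci, spec$planted_dmrs)

  probe_means <- list()
  rows <- list()
  sheet <- list()
  for (ct in spec$cell_types) {
    truth_m <- matrix(NA_real_, np, length(subjects),
                      dimnames = list(design$probe_id, subjects))
    set.seed(derive_seed(spec$seed, paste0("affinity/", ct)))
    affinity <- stats::rnorm(np, 0, spec$probe_noise_sd)
    for (si in seq_along(subjects)) {
      s <- subjects[si]
      set.seed(derive_seed(spec$seed, paste0("subj/", ct, "/", s)))
      subj_noise <- stats::rnorm(np, 0, spec$subject_sd)
      mu <- base + affinity + (if (groups[si] == "A") eff else 0) +
        subj_noise
      truth_m[, si] <- mu
      for (r in seq_len(spec$n_replicates)) {
        array_id <- sprintf("%s_%s_r%d", s, ct, r)
        set.seed(derive_seed(spec$seed, paste0("array/", array_id)))
        lr <- mu + stats::rnorm(np, 0, spec$replicate_sd)
        input <- 2^(10 + stats::rnorm(np, 0, 0.5))
        rows[[array_id]] <- data.frame(
          array_id = array_id, probe_id = design$probe_id,
          bound = input * 2^lr, input = input,
          stringsAsFactors = FALSE)
        sheet[[array_id]] <- data.frame(
          array_id = array_id, subject_id = s, group = groups[si],
          cell_type = ct, replicate = r, stringsAsFactors = FALSE)
      }
    }
    probe_means[[ct]] <- truth_m
  }
  intensities <- do.call(rbind, rows)
  samples <- do.call(rbind, sheet)
  rownames(intensities) <- rownames(samples) <- NULL

  dmr_bed <- NULL
  if (!is.null(spec$planted_dmrs) && nrow(spec$planted_dmrs) > 0) {
    d <- spec$planted_dmrs
    loc_start <- loci$start[match(d$locus_id, loci$locus_id)]
    dmr_bed <- data.frame(
      chrom = loci$chrom[match(d$locus_id, loci$locus_id)],
      start = loc_start + d$start, end = loc_start + d$end,
      name = d$label,
      direction = ifelse(d$effect > 0, "higher_in_A", "higher_in_B"),
      effect = d$effect, locus_id = d$locus_id,
      stringsAsFactors = FALSE)
  }
  truth <- list(spec = spec, design = design, subjects = subjects,
                groups = stats::setNames(groups, subjects),
                probe_means = probe_means, planted = dmr_bed)
  list(intensities = intensities, samples = samples, truth = truth)
}

#' Simulate per-subject phenotypes linked to region methylation
#'
#' One value per subject per link:
#' `intercept + slope * (subject mean true methylation over the linked
#' region's probes) + N(0, noise_sd)`, seeded and reproducible.
#'
#' @param truth Ground truth from [simulate_cohort()].
#' @param links `data.frame` of [phenotype_link()] rows (default: the
#'   spec's `phenotype_links`).
#' @param seed Seed for the phenotype noise (default: derived from the
#'   spec's master seed).
#' @return Long-format phenotype `data.frame` (`subject_id`, `analyte`,
#'   `level`).
#' @export
simulate_phenotype <- function(truth, links = truth$spec$phenotype_links,
                               seed = truth$spec$seed) {
  if (is.null(links) || nrow(links) == 0) {
    stop_data("simulate_phenotype: no phenotype links given")
  }
  out <- list()
  for (i in seq_len(nrow(links))) {
    lk <- links[i, ]
    if (is.null(truth$planted) || !(lk$label %in% truth$planted$name)) {
      stop_data("simulate_phenotype: unknown region label ", lk$label)
    }
    pl <- truth$planted[truth$planted$name == lk$label, ]
    ct <- lk$cell_type
    if (!ct %in% names(truth$probe_means)) {
      stop_data("simulate_phenotype: cell type ", ct, " not simulated")
    }
    des <- truth$design
    sel <- des$locus_id == pl$locus_id & des$start >= pl$start &
      des$start < pl$end
    if (!any(sel)) stop_data("simulate_phenotype: linked region covers no probes")
    subj_mean <- colMeans(truth$probe_means[[ct]][sel, , drop = FALSE])
    set.seed(derive_seed(seed, paste0("pheno/", lk$analyte)))
    level <- lk$intercept + lk$slope * subj_mean +
      stats::rnorm(length(subj_mean), 0, lk$noise_sd)
    out[[i]] <- data.frame(subject_id = names(subj_mean),
                           analyte = lk$analyte, level = unname(level),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate regulatory-element annotation tracks
#'
#' BED-style interval tracks (a stand-in for curated regulatory-element
#' catalogues): element counts per tiled locus span are Poisson with the
#' given density, starts uniform within the span, widths exponential
#' around `mean_width` (minimum 1 bp), element names drawn uniformly from
#' `element_names`.
#'
#' @param design Probe design whose tiled spans are populated.
#' @param density Expected elements per 10 kb.
#' @param mean_width Mean element width in bp.
#' @param element_names Non-empty character vector of element names.
#' @param track_names Names of the tracks to generate.
#' @param seed Seed.
#' @return Named list of interval `data.frame`s (`chrom`, `start`, `end`,
#'   `name`), one per track.
#' @export
simulate_tracks <- function(design, density = 1, mean_width = 500,
                            element_names = c("NFkB", "PU.1", "STAT1",
                                              "c-Jun", "GR"),
                            track_names = c("TFBS", "DNase"), seed = 1) {
  if (density <= 0) stop_data("simulate_tracks: density must be positive")
  if (length(element_names) == 0) {
    stop_data("simulate_tracks: element name list is empty")
  }
  spans <- do.call(rbind, lapply(split(design, design$locus_id), function(d) {
    data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  out <- list()
  for (tn in track_names) {
    set.seed(derive_seed(seed, paste0("track/", tn)))
    rows <- list()
    for (i in seq_len(nrow(spans))) {
      span <- spans$end[i] - spans$start[i]
      n <- stats::rpois(1, density * span / 10000)
      if (n == 0) next
      starts <- spans$start[i] + floor(stats::runif(n, 0, span))
      widths <- pmax(1, round(stats::rexp(n, 1 / mean_width)))
      rows[[i]] <- data.frame(
        chrom = spans$chrom[i], start = as.integer(starts),
        end = as.integer(starts + widths),
        name = sample(element_names, n, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    tr <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(0), start = integer(0),
                 end = integer(0), name = character(0))
    tr <- tr[order(tr$chrom, tr$start), , drop = FALSE]
    rownames(tr) <- NULL
    out[[tn]] <- tr
  }
  out
}
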