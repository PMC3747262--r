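# Monte-Carlo evaluation of the full pipeline on synthetic studies:
# false-discovery calibration under the null and sensitivity for planted
# DMRs. These are the quantities a user should check before trusting
# calls on a new design.

#' Compact simulation spec for Monte-Carlo studies
#'
#' Same subjects, replicates, spacing and noise levels as the full
#' default design but restricted to two ~30 kb loci, keeping repeated
#' whole-pipeline simulation fast. Intended for [null_calibration()] and
#' [recovery_sensitivity()].
#'
#' @param seed Master seed.
#' @param planted_dmrs Optional planted DMR table.
#' @param phenotype_links Optional phenotype link table.
#' @param cell_types Cell types to simulate (one by default; the pipeline
#'   treats cell types independently, so calibration per cell type is
#'   representative).
#' @return A [simulation_spec()].
#' @export
mc_spec <- function(seed = 1, planted_dmrs = NULL, phenotype_links = NULL,
                    cell_types = "T_cell") {
  loci <- data.frame(locus_id = c("locusA", "locusB"),
                     chrom = c("chr2", "chr7"),
                     start = c(1000000L, 5000000L),
                     length = c(30000L, 30000L),
                     stringsAsFactors = FALSE)
  simulation_spec(loci = loci, planted_dmrs = planted_dmrs,
                  phenotype_links = phenotype_links,
                  cell_types = cell_types, seed = seed)
}

run_one_sim <- function(spec, thresholds, cell_type) {
  sim <- simulate_cohort(spec)
  m <- normalize_arrays(sim$intensities, sim$truth$design, sim$samples,
                        cell_type)
  calls <- run_contrast_pipeline(m, sim$truth$design,
                                 thresholds = thresholds)
  list(calls = calls, truth = sim$truth)
}

# A called region is a true positive when it overlaps a planted region
# of the same direction.
classify_calls <- function(calls, planted) {
  called <- calls[calls$called, , drop = FALSE]
  if (nrow(called) == 0) {
    return(list(n_called = 0L, n_false = 0L, recovered = character(0)))
  }
  if (is.null(planted) || nrow(planted) == 0) {
    return(list(n_called = nrow(called), n_false = nrow(called),
                recovered = character(0)))
  }
  is_true <- logical(nrow(called))
  recovered <- character(0)
  for (i in seq_len(nrow(planted))) {
    p <- planted[i, ]
    hit <- called$chrom == p$chrom & called$start < p$end &
      called$end > p$start & called$direction == p$direction
    if (any(hit)) recovered <- c(recovered, p$name)
    is_true <- is_true | (called$chrom == p$chrom & called$start < p$end &
                            called$end > p$start)
  }
  list(n_called = nrow(called), n_false = sum(!is_true),
       recovered = recovered)
}

#' Null false-discovery calibration
#'
#' Runs the full contrast pipeline on `n_sims` independent null
#' simulations (no planted DMRs) and reports the per-simulation false
#' discovery proportion (1 if anything is called under the null, 0
#' otherwise, since every null call is false). The mean FDP should be
#' consistent with the nominal region FDR.
#'
#' @param n_sims Number of seeded simulations.
#' @param seed Master seed; simulation i uses a derived sub-seed.
#' @param thresholds A [calling_thresholds()] object.
#' @param spec_fn Function `seed -> sim_spec` (default [mc_spec()]).
#' @param cell_type Cell type analyzed.
#' @return List with `fdp` (per-simulation vector), `mean_fdp`,
#'   `n_called` (per-simulation call counts).
#' @export
null_calibration <- function(n_sims = 50, seed = 1,
                             thresholds = calling_thresholds(),
                             spec_fn = mc_spec, cell_type = "T_cell") {
  fdp <- numeric(n_sims)
  n_called <- integer(n_sims)
  for (i in seq_len(n_sims)) {
    spec <- spec_fn(seed = derive_seed(seed, paste0("null/", i)))
    res <- run_one_sim(spec, thresholds, cell_type)
    cl <- classify_calls(res$calls, res$truth$planted)
    n_called[i] <- cl$n_called
    fdp[i] <- if (cl$n_called == 0) 0 else cl$n_false / cl$n_called
  }
  list(fdp = fdp, mean_fdp = mean(fdp), n_called = n_called)
}

#' Sensitivity for planted DMRs
#'
#' Plants DMRs of the given absolute log2 effect (alternating sign) and
#' reports the fraction recovered — called with the correct direction by
#' a region overlapping the planted interval — over `n_sims` seeded
#' simulations.
#'
#' @inheritParams null_calibration
#' @param effect Absolute planted log2 effect (default 1.0).
#' @param width Planted DMR width in bp (default 1000).
#' @return List with `sensitivity` (overall fraction recovered),
#'   `per_sim` (per-simulation fractions) and `mean_false` (mean false
#'   calls per simulation).
#' @export
recovery_sensitivity <- function(n_sims = 50, seed = 1, effect = 1.0,
                                 width = 1000,
                                 thresholds = calling_thresholds(),
                                 cell_type = "T_cell") {
  planted <- rbind(
    planted_dmr("locusA", 5000, 5000 + width, +effect, "dmr_up"),
    planted_dmr("locusB", 12000, 12000 + width, -effect, "dmr_down"))
  per_sim <- numeric(n_sims)
  false_calls <- integer(n_sims)
  for (i in seq_len(n_sims)) {
    spec <- mc_spec(seed = derive_seed(seed, paste0("power/", i)),
                    planted_dmrs = planted, cell_types = cell_type)
    res <- run_one_sim(spec, thresholds, cell_type)
    cl <- classify_calls(res$calls, res$truth$planted)
    per_sim[i] <- length(cl$recovered) / nrow(planted)
    false_calls[i] <- cl$n_false
  }
  list(sensitivity = mean(per_sim), per_sim = per_sim,
       mean_false = mean(false_calls))
}
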