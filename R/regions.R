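# Region-level DMR calling: fixed-width partition of each tiled locus,
# Wilcoxon rank-sum enrichment of probe statistics per region against the
# remaining probes, Benjamini-Hochberg FDR over all testable regions, and
# directional calls that additionally require a threshold-passing probe of
# concordant sign inside the region.

#' Calling thresholds
#'
#' The dual probe/region calling rule: a region is called differentially
#' methylated (or phenotype-correlated) when its rank-sum FDR is at most
#' `region_fdr_max` *and* it contains at least one probe with p-value at
#' most `probe_p_max` and |log2-fold change| at least `probe_lfc_min`
#' (group contrast) or |Pearson r| at least `probe_r_min` (correlation),
#' with probe sign matching the region's direction.
#'
#' @param probe_p_max Per-probe p-value ceiling (uncorrected).
#' @param probe_lfc_min Minimum absolute per-probe log2-fold change.
#' @param probe_r_min Minimum absolute per-probe Pearson correlation.
#' @param region_fdr_max Region-level BH FDR ceiling.
#' @param region_width Partition width in bp.
#' @param min_probes_per_region Regions with fewer probes are untestable
#'   and excluded from the FDR family.
#' @return A list of class `calling_thresholds`.
#' @export
calling_thresholds <- function(probe_p_max = 0.05, probe_lfc_min = 0.25,
                               probe_r_min = 0.5, region_fdr_max = 0.2,
                               region_width = 1000,
                               min_probes_per_region = 3) {
  stopifnot(probe_p_max > 0, probe_p_max <= 1,
            probe_lfc_min >= 0, probe_r_min >= 0, probe_r_min <= 1,
            region_fdr_max >= 0, region_fdr_max <= 1,
            region_width > 0, min_probes_per_region >= 1)
  structure(list(probe_p_max = probe_p_max, probe_lfc_min = probe_lfc_min,
                 probe_r_min = probe_r_min, region_fdr_max = region_fdr_max,
                 region_width = region_width,
                 min_probes_per_region = min_probes_per_region),
            class = "calling_thresholds")
}

#' Partition tiled loci into fixed-width regions
#'
#' Non-overlapping windows of exactly `width` bp anchored at each locus
#' start; the last window of a locus is truncated at the locus end. Probes
#' are assigned to windows by their start coordinate. Regions with fewer
#' than `min_probes` probes are marked untestable.
#'
#' @param design Probe design `data.frame`.
#' @param width Region width in bp (default 1000).
#' @param min_probes Minimum probes for a region to be testable.
#' @return `data.frame` with columns `region_id`, `chrom`, `start`, `end`,
#'   `locus_id`, `n_probes`, `testable` and a list column `probe_ids`.
#' @export
partition_regions <- function(design, width = 1000, min_probes = 3) {
  if (width <= 0) stop_data("partition_regions: width must be positive")
  design <- design[order(design$locus_id, design$start), , drop = FALSE]
  out <- list()
  for (loc in unique(design$locus_id)) {
    sub <- design[design$locus_id == loc, , drop = FALSE]
    loc_start <- min(sub$start)
    loc_end <- max(sub$end)
    starts <- seq(loc_start, loc_end - 1L, by = width)
    ends <- pmin(starts + width, loc_end)
    bin <- (sub$start - loc_start) %/% width + 1L
    probe_ids <- split(sub$probe_id, factor(bin, levels = seq_along(starts)))
    out[[loc]] <- data.frame(
      region_id = sprintf("%s:%d-%d", loc, starts, ends),
      chrom = sub$chrom[1], start = as.integer(starts),
      end = as.integer(ends), locus_id = loc,
      n_probes = lengths(probe_ids),
      stringsAsFactors = FALSE)
    out[[loc]]$probe_ids <- unname(probe_ids)
  }
  regions <- do.call(rbind, out)
  rownames(regions) <- NULL
  regions$testable <- regions$n_probes >= min_probes
  regions
}

# Exact null distribution of the rank-sum via subset-sum counting.
# ranks2: integer vector of doubled midranks; k: region size.
# Returns counts[s+1] = number of k-subsets with doubled rank sum == s.
rank_sum_counts <- function(ranks2, k) {
  total <- sum(ranks2)
  # f[j+1, s+1] = number of j-subsets summing to s
  f <- matrix(0, nrow = k + 1, ncol = total + 1)
  f[1, 1] <- 1
  for (r in ranks2) {
    jmax <- k
    for (j in jmax:1) {
      nz <- which(f[j, ] > 0)
      if (length(nz)) {
        f[j + 1, nz + r] <- f[j + 1, nz + r] + f[j, nz]
      }
    }
  }
  f[k + 1, ]
}

#' Rank-sum enrichment of a region's probe scores
#'
#' Tests whether the probe scores (moderated t or Pearson r) inside a
#' region are stochastically larger or smaller than a background set,
#' using the Wilcoxon rank-sum statistic with midranks for ties. Two
#' one-sided p-values are computed and combined as
#' `p = min(1, 2 * min(p_up, p_down))`; the direction is the side with
#' the smaller one-sided p. For `<= exact_max` total probes the null is
#' enumerated exactly (subset-sum counting over the midranks); above
#' that, the normal approximation with tie correction and a 0.5
#' continuity correction is used.
#'
#' @param region_scores Numeric scores of the probes in the region.
#' @param background_scores Scores of the background probes (disjoint
#'   from the region's).
#' @param exact_max Size bound for exact enumeration (default 25).
#' @return List with `p` (combined two-sided), `direction` (`"up"`/
#'   `"down"`), `p_up`, `p_down`.
#' @export
region_rank_sum <- function(region_scores, background_scores,
                            exact_max = 25) {
  k <- length(region_scores)
  nb <- length(background_scores)
  if (k == 0 || nb == 0) {
    stop_data("region_rank_sum: empty region or background")
  }
  scores <- c(region_scores, background_scores)
  n <- k + nb
  rk <- rank(scores)           # midranks
  w <- sum(rk[seq_len(k)])     # observed rank sum of the region
  if (n <= exact_max) {
    ranks2 <- as.integer(round(2 * rk))
    counts <- rank_sum_counts(ranks2, k)
    total <- choose(n, k)
    w2 <- as.integer(round(2 * w))
    sums <- seq_along(counts) - 1L
    p_up <- sum(counts[sums >= w2]) / total
    p_down <- sum(counts[sums <= w2]) / total
  } else {
    mu <- k * (n + 1) / 2
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties)
    v <- k * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (v <= 0) {
      p_up <- 1; p_down <- 1
    } else {
      sd <- sqrt(v)
      p_up <- stats::pnorm((w - mu - 0.5) / sd, lower.tail = FALSE)
      p_down <- stats::pnorm((w - mu + 0.5) / sd)
    }
  }
  p <- min(1, 2 * min(p_up, p_down))
  direction <- if (p_up <= p_down) "up" else "down"
  list(p = p, direction = direction, p_up = p_up, p_down = p_down)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_i = min over p_(j) >= p_(i) of m * p_(j) / j`,
#' reported in the input order. Thin wrapper over
#' `stats::p.adjust(method = "BH")` with a domain check.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of adjusted p-values (q-values), same order as input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_data("bh_fdr: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call differentially methylated / correlated regions
#'
#' Scores every testable region by rank-sum enrichment of its probe
#' statistics against a background (all other probes of the same locus by
#' default, or the whole array), adjusts the region p-values by BH over
#' the full testable family, and applies the dual probe/region rule of
#' [calling_thresholds()]. For the group contrast the probe score is the
#' moderated t and directions are reported as `higher_in_A` /
#' `higher_in_B`; for the correlation arm the score is Pearson r and
#' directions are `positive` / `negative`.
#'
#' @param probe_stats Per-probe statistics `data.frame`: `probe_id` plus
#'   `t_mod`, `lfc`, `p_t` (contrast) or `r`, `p_r` (correlation).
#' @param regions Region partition from [partition_regions()].
#' @param thresholds A [calling_thresholds()] object.
#' @param kind `"group_contrast"` or `"phenotype_correlation"`.
#' @param background `"locus"` (default) or `"array"`.
#' @return `data.frame` with one row per testable region: coordinates,
#'   `p_region`, `q_region`, `direction`, `n_sig_probes`, `mean_score`
#'   (mean lfc or mean r over in-region probes), `called`.
#' @export
call_regions <- function(probe_stats, regions, thresholds = calling_thresholds(),
                         kind = c("group_contrast", "phenotype_correlation"),
                         background = c("locus", "array")) {
  kind <- match.arg(kind)
  background <- match.arg(background)
  testable <- regions[regions$testable, , drop = FALSE]
  if (nrow(testable) == 0) stop_data("call_regions: no testable regions")

  if (kind == "group_contrast") {
    score <- stats::setNames(probe_stats$t_mod, probe_stats$probe_id)
    effect <- stats::setNames(probe_stats$lfc, probe_stats$probe_id)
    pval <- stats::setNames(probe_stats$p_t, probe_stats$probe_id)
    eff_min <- thresholds$probe_lfc_min
    dir_labels <- c(up = "higher_in_A", down = "higher_in_B")
  } else {
    score <- stats::setNames(probe_stats$r, probe_stats$probe_id)
    effect <- score
    pval <- stats::setNames(probe_stats$p_r, probe_stats$probe_id)
    eff_min <- thresholds$probe_r_min
    dir_labels <- c(up = "positive", down = "negative")
  }
  all_probes <- unlist(testable$probe_ids, use.names = FALSE)
  if (!all(all_probes %in% names(score))) {
    stop_data("call_regions: probe statistics do not cover all region probes")
  }

  n <- nrow(testable)
  p_region <- numeric(n)
  direction <- character(n)
  n_sig <- integer(n)
  mean_score <- numeric(n)
  for (i in seq_len(n)) {
    ids <- testable$probe_ids[[i]]
    if (background == "locus") {
      loc_probes <- unlist(
        regions$probe_ids[regions$locus_id == testable$locus_id[i]],
        use.names = FALSE)
      bg_ids <- setdiff(loc_probes, ids)
    } else {
      bg_ids <- setdiff(names(score), ids)
    }
    rs <- score[ids]
    bs <- score[bg_ids]
    bs <- bs[!is.na(bs)]
    if (any(is.na(rs)) || length(bs) == 0) {
      p_region[i] <- 1; direction[i] <- "up"
    } else {
      res <- region_rank_sum(rs, bs)
      p_region[i] <- res$p
      direction[i] <- res$direction
    }
    sgn <- if (direction[i] == "up") 1 else -1
    ok <- !is.na(pval[ids]) & pval[ids] <= thresholds$probe_p_max &
      abs(effect[ids]) >= eff_min & sign(effect[ids]) == sgn
    n_sig[i] <- sum(ok)
    mean_score[i] <- mean(effect[ids], na.rm = TRUE)
  }
  q_region <- bh_fdr(p_region)
  called <- q_region <= thresholds$region_fdr_max & n_sig >= 1
  out <- data.frame(
    region_id = testable$region_id, chrom = testable$chrom,
    start = testable$start, end = testable$end,
    locus_id = testable$locus_id, n_probes = testable$n_probes,
    statistic_kind = kind, p_region = p_region, q_region = q_region,
    direction = unname(dir_labels[direction]), n_sig_probes = n_sig,
    mean_score = mean_score, called = called,
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Run the group-contrast pipeline on a methylation matrix
#'
#' Moderated t per probe, region partition, rank-sum region scoring, BH
#' FDR and dual-threshold calls.
#'
#' @param m Probes x subjects methylation matrix (from
#'   [normalize_arrays()]).
#' @param design Probe design.
#' @param groups Group labels per column (default `attr(m, "groups")`).
#' @param thresholds A [calling_thresholds()] object.
#' @param background Background set for the rank-sum test.
#' @return Region call `data.frame` (see [call_regions()]).
#' @export
run_contrast_pipeline <- function(m, design, groups = attr(m, "groups"),
                                  thresholds = calling_thresholds(),
                                  background = "locus") {
  ps <- moderated_t(m, groups)$stats
  regions <- partition_regions(design, thresholds$region_width,
                               thresholds$min_probes_per_region)
  call_regions(ps, regions, thresholds, "group_contrast", background)
}

#' Run the phenotype-correlation pipeline
#'
#' Pearson r per probe against a plasma analyte, then the same region
#' rank-sum / BH / dual-threshold machinery as the group contrast.
#'
#' @inheritParams run_contrast_pipeline
#' @param phenotype Long-format phenotype table.
#' @param analyte Analyte to correlate against.
#' @return Region call `data.frame`.
#' @export
run_correlation_pipeline <- function(m, design, phenotype, analyte,
                                     thresholds = calling_thresholds(),
                                     background = "locus") {
  ps <- probe_phenotype_correlation(m, phenotype, analyte)
  regions <- partition_regions(design, thresholds$region_width,
                               thresholds$min_probes_per_region)
  call_regions(ps, regions, thresholds, "phenotype_correlation", background)
}
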