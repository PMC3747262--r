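# Statistics for targeted bisulfite-pyrosequencing validation: per-CpG
# group means and SEM, two-group Student t-tests, and Pearson correlation
# of the region mean methylation with a plasma analyte.

#' Summarize a pyrosequencing table
#'
#' Technical replicates are averaged within subject first; group mean and
#' SEM (`sd / sqrt(n)`) and a two-sided two-sample Student t-test
#' (equal-variance by default) are then computed per CpG and for the
#' region mean (the mean over all CpG sites per subject). Significance
#' tiers mirror the usual figure convention: `#` for p <= 0.1, `*` for
#' p <= 0.05.
#'
#' @param table Long `data.frame`: `subject_id`, `cpg_id`, `replicate`,
#'   `percent` (percent methylation in \[0, 100\]).
#' @param groups Named character vector of group labels (`"A"`/`"B"`) per
#'   subject.
#' @param var_equal Use the equal-variance Student t (default `TRUE`);
#'   `FALSE` gives Welch.
#' @return List with `per_cpg` (one row per CpG: group means, SEMs, t, p,
#'   marker), `region` (same for the across-CpG mean) and
#'   `subject_region_means` (named vector, input to
#'   [correlate_pyro_phenotype()]).
#' @export
summarize_pyro <- function(table, groups, var_equal = TRUE) {
  if (any(table$percent < 0 | table$percent > 100)) {
    stop_data("summarize_pyro: percent methylation outside [0, 100]")
  }
  # replicate -> subject means per CpG
  subj_cpg <- stats::aggregate(percent ~ subject_id + cpg_id, table, mean)
  g <- groups[subj_cpg$subject_id]
  if (anyNA(g)) stop_data("summarize_pyro: subject missing from groups")
  if (min(table(groups[unique(subj_cpg$subject_id)])) < 2) {
    stop_data("summarize_pyro: each group needs >= 2 subjects")
  }
  one_test <- function(vals, gg) {
    a <- vals[gg == "A"]; b <- vals[gg == "B"]
    tt <- stats::t.test(a, b, var.equal = var_equal)
    c(mean_A = mean(a), sem_A = stats::sd(a) / sqrt(length(a)),
      mean_B = mean(b), sem_B = stats::sd(b) / sqrt(length(b)),
      t = unname(tt$statistic), p = tt$p.value)
  }
  cpgs <- unique(subj_cpg$cpg_id)
  per_cpg <- do.call(rbind, lapply(cpgs, function(cp) {
    sel <- subj_cpg$cpg_id == cp
    as.data.frame(as.list(one_test(subj_cpg$percent[sel],
                                   g[sel])))
  }))
  per_cpg <- cbind(data.frame(cpg_id = cpgs, stringsAsFactors = FALSE),
                   per_cpg)
  per_cpg$marker <- ifelse(per_cpg$p <= 0.05, "*",
                           ifelse(per_cpg$p <= 0.1, "#", ""))
  # region mean per subject = mean over CpGs of subject means
  region_means <- tapply(subj_cpg$percent, subj_cpg$subject_id, mean)
  rg <- groups[names(region_means)]
  region <- as.data.frame(as.list(one_test(as.vector(region_means), rg)))
  region$marker <- ifelse(region$p <= 0.05, "*",
                          ifelse(region$p <= 0.1, "#", ""))
  list(per_cpg = per_cpg, region = region,
       subject_region_means = stats::setNames(as.vector(region_means),
                                              names(region_means)))
}

#' Correlate region methylation with a plasma analyte
#'
#' Pearson correlation between per-subject region mean methylation and a
#' per-subject phenotype, pairwise-complete; two-sided p via the exact t
#' transform (as in [stats::cor.test()]).
#'
#' @param region_means Named numeric vector of region mean methylation
#'   per subject.
#' @param phenotype Named numeric vector of analyte levels per subject
#'   (names matched to `region_means`; `NA`s dropped pairwise).
#' @return List with `r`, `p`, `n`.
#' @export
correlate_pyro_phenotype <- function(region_means, phenotype) {
  common <- intersect(names(region_means), names(phenotype))
  x <- region_means[common]
  y <- phenotype[common]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    stop_data("correlate_pyro_phenotype: need >= 3 paired subjects")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_data("correlate_pyro_phenotype: constant input, correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
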