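# Per-probe inference: empirical-Bayes moderated t-statistics for the
# two-group contrast, and Pearson correlations of probe methylation with a
# continuous phenotype.
#
# The moderated t shrinks each probe's sample variance s^2 (df residual
# degrees of freedom) toward a prior variance s0^2 with prior degrees of
# freedom d0, both estimated from the full set of probes:
#   s_tilde^2 = (d0 * s0^2 + df * s^2) / (d0 + df)
#   t_mod     = lfc / (s_tilde * sqrt(1/nA + 1/nB)),  p ~ t on d0 + df df.

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf); the update is done on 1/x where trigamma is close to linear).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Fit the empirical-Bayes variance prior
#'
#' Method-of-moments fit of the prior degrees of freedom `d0` and prior
#' variance `s0_sq` from per-probe residual variances, matching the mean
#' and the variance of `log(s^2)` to their digamma/trigamma expressions
#' under the scaled-F sampling model. When the observed dispersion of
#' `log(s^2)` does not exceed what the residual degrees of freedom alone
#' explain, there is no finite solution: `d0 = Inf` and `s0_sq` is the
#' geometric mean of the variances (so posterior variances equal `s0_sq`).
#'
#' @param s2 Per-probe residual variances (positive; zeros are excluded
#'   from the fit).
#' @param df Residual degrees of freedom, a scalar or per-probe vector.
#' @return A list with elements `d0` and `s0_sq`.
#' @export
fit_eb_hyperparameters <- function(s2, df) {
  keep <- is.finite(s2) & s2 > 0
  if (sum(keep) < 2) {
    stop_data("fit_eb_hyperparameters: need >= 2 probes with positive variance")
  }
  s2 <- s2[keep]
  df <- rep_len(df, length(keep))[keep]
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(mean(z))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

group_indices <- function(groups) {
  if (!all(groups %in% c("A", "B"))) {
    stop_data("groups must be 'A' or 'B'")
  }
  list(a = which(groups == "A"), b = which(groups == "B"))
}

#' Moderated t-statistics for a two-group contrast
#'
#' Per probe: `lfc = mean(A) - mean(B)` (log2 units), pooled within-group
#' variance on `nA + nB - 2` degrees of freedom, posterior variance from
#' the empirical-Bayes prior (see [fit_eb_hyperparameters()]), moderated t
#' and its two-sided p-value on `d0 + df` degrees of freedom (the normal
#' distribution when `d0 = Inf`).
#'
#' @param m Probes x subjects methylation matrix.
#' @param groups Character vector of group labels (`"A"`/`"B"`), one per
#'   column of `m`; defaults to `attr(m, "groups")`.
#' @param hyper Optional list `(d0, s0_sq)` to use instead of fitting;
#'   `d0 = 0` reproduces the ordinary pooled two-sample t.
#' @return A list with `stats` (a `data.frame`: `probe_id`, `lfc`, `s2`,
#'   `t_mod`, `p_t`) and `hyper` (the prior used).
#' @export
moderated_t <- function(m, groups = attr(m, "groups"), hyper = NULL) {
  idx <- group_indices(groups)
  na <- length(idx$a); nb <- length(idx$b)
  if (na < 2 || nb < 2) {
    stop_data("moderated_t: each group needs >= 2 subjects")
  }
  df <- na + nb - 2
  ma <- rowMeans(m[, idx$a, drop = FALSE])
  mb <- rowMeans(m[, idx$b, drop = FALSE])
  lfc <- ma - mb
  ssa <- rowSums((m[, idx$a, drop = FALSE] - ma)^2)
  ssb <- rowSums((m[, idx$b, drop = FALSE] - mb)^2)
  s2 <- (ssa + ssb) / df
  if (is.null(hyper)) hyper <- fit_eb_hyperparameters(s2, df)
  d0 <- hyper$d0; s0_sq <- hyper$s0_sq
  post_var <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + df * s2) / (d0 + df)
  se <- sqrt(post_var * (1 / na + 1 / nb))
  t_mod <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p_t <- 2 * stats::pt(abs(t_mod), df = d0 + df, lower.tail = FALSE)
  list(stats = data.frame(probe_id = rownames(m), lfc = lfc, s2 = s2,
                          t_mod = t_mod, p_t = p_t,
                          row.names = NULL, stringsAsFactors = FALSE),
       hyper = hyper)
}

#' Per-probe Pearson correlation with a phenotype
#'
#' Correlates each probe's methylation values across subjects with a
#' continuous per-subject phenotype (e.g. a plasma cytokine level).
#' Subjects with a missing phenotype are excluded pairwise. Two-sided
#' p-values come from the exact t transform on `n - 2` degrees of freedom.
#'
#' @param m Probes x subjects methylation matrix (columns named by
#'   subject_id).
#' @param phenotype Long-format phenotype table (`subject_id`, `analyte`,
#'   `level`).
#' @param analyte Which analyte to correlate against.
#' @return `data.frame` with `probe_id`, `r`, `p_r`, `n_used`.
#' @export
probe_phenotype_correlation <- function(m, phenotype, analyte) {
  ph <- phenotype[phenotype$analyte == analyte, , drop = FALSE]
  lev <- ph$level[match(colnames(m), ph$subject_id)]
  keep <- !is.na(lev)
  if (sum(keep) < 3) {
    stop_data("probe_phenotype_correlation: need >= 3 subjects with phenotype")
  }
  y <- lev[keep]
  if (stats::sd(y) == 0) {
    stop_data("probe_phenotype_correlation: phenotype constant across subjects")
  }
  x <- m[, keep, drop = FALSE]
  n <- length(y)
  r <- as.vector(stats::cor(t(x), y))
  # probes constant across subjects have undefined correlation -> NA
  r[!is.finite(r)] <- NA_real_
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p_r <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p_r[abs(r) >= 1] <- 0
  data.frame(probe_id = rownames(m), r = r, p_r = p_r, n_used = n,
             row.names = NULL, stringsAsFactors = FALSE)
}
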