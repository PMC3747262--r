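# From raw two-channel intensities to a replicate-averaged methylation
# matrix: log2(bound/input) per probe per array, quantile normalization
# across the arrays of one cell type, then reduction of technical
# replicates to one column per subject.

#' Compute log2 bound/input ratios
#'
#' The MeDIP enrichment signal per probe per array is
#' `log2(bound / input)`. Channels must be strictly positive; a
#' non-positive intensity is a hard error (it signals an upstream
#' conversion problem and is never silently offset).
#'
#' @param intensities Long-format intensity table
#'   (`array_id`, `probe_id`, `bound`, `input`).
#' @param design Probe design giving the probe order of the result.
#' @return Numeric matrix, probes (rows, in design order) x arrays
#'   (columns), of log2 ratios.
#' @export
compute_log_ratios <- function(intensities, design) {
  if (any(intensities$bound <= 0) || any(intensities$input <= 0)) {
    stop_data("compute_log_ratios: non-positive channel intensity")
  }
  arrays <- unique(intensities$array_id)
  m <- matrix(NA_real_, nrow = nrow(design), ncol = length(arrays),
              dimnames = list(design$probe_id, arrays))
  idx_probe <- match(intensities$probe_id, design$probe_id)
  if (anyNA(idx_probe)) {
    stop_data("compute_log_ratios: probe absent from design")
  }
  idx_array <- match(intensities$array_id, arrays)
  m[cbind(idx_probe, idx_array)] <-
    log2(intensities$bound / intensities$input)
  if (anyNA(m)) stop_data("compute_log_ratios: incomplete (probe, array) grid")
  m
}

#' Quantile-normalize arrays
#'
#' Forces all arrays to a common intensity distribution: every column's
#' sorted value vector becomes the across-array mean of sorted vectors
#' (the standard quantile-normalization procedure). Ties within an array
#' receive the mean of the reference quantiles they span, so the result
#' is independent of tie ordering. Implemented via
#' [limma::normalizeQuantiles()] with `ties = TRUE`.
#'
#' @param m Numeric matrix, probes (rows) x arrays (columns).
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || length(m) == 0) {
    stop_data("quantile_normalize: empty matrix")
  }
  if (ncol(m) == 1) return(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Average technical replicates into one column per subject
#'
#' Reduces the replicate arrays of each sample (one subject in one cell
#' type) to a single per-probe value, by default the arithmetic mean.
#' Only arrays of the requested cell type are used.
#'
#' @param m Probes x arrays log-ratio matrix (columns named by array_id).
#' @param sheet Sample sheet mapping arrays to subjects.
#' @param cell_type Cell type to extract (e.g. `"T_cell"`).
#' @param method `"mean"` (default) or `"median"`.
#' @return Probes x subjects matrix; `attr(, "groups")` holds the named
#'   group label (`"A"`/`"B"`) per subject column.
#' @export
average_replicates <- function(m, sheet, cell_type, method = c("mean", "median")) {
  method <- match.arg(method)
  sub <- sheet[sheet$cell_type == cell_type, , drop = FALSE]
  if (nrow(sub) == 0) stop_data("average_replicates: no arrays for cell type ",
                                cell_type)
  missing <- setdiff(sub$array_id, colnames(m))
  if (length(missing)) {
    stop_data("average_replicates: arrays absent from matrix: ",
              paste(utils::head(missing, 5), collapse = ", "))
  }
  subjects <- unique(sub$subject_id)
  fun <- if (method == "mean") rowMeans else
    function(x) apply(x, 1, stats::median)
  out <- matrix(vapply(subjects, function(s) {
    cols <- sub$array_id[sub$subject_id == s]
    fun(m[, cols, drop = FALSE])
  }, numeric(nrow(m))), nrow = nrow(m), ncol = length(subjects))
  dimnames(out) <- list(rownames(m), subjects)
  groups <- vapply(subjects, function(s)
    unique(sub$group[sub$subject_id == s]), character(1))
  attr(out, "groups") <- groups
  out
}

#' Full normalization for one cell type
#'
#' Composition of [compute_log_ratios()], [quantile_normalize()] (jointly
#' over all arrays of the cell type) and [average_replicates()].
#'
#' @inheritParams compute_log_ratios
#' @inheritParams average_replicates
#' @return Probes x subjects methylation matrix with a `groups` attribute.
#' @export
normalize_arrays <- function(intensities, design, sheet, cell_type,
                             method = "mean") {
  keep <- sheet$array_id[sheet$cell_type == cell_type]
  ints <- intensities[intensities$array_id %in% keep, , drop = FALSE]
  if (nrow(ints) == 0) stop_data("normalize_arrays: no arrays for cell type ",
                                 cell_type)
  lr <- compute_log_ratios(ints, design)
  qn <- quantile_normalize(lr)
  average_replicates(qn, sheet, cell_type, method)
}
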