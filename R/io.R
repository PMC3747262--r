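# Readers and writers for the tabular formats used throughout the pipeline.
# All genomic coordinates are 0-based half-open, here and everywhere else in
# the package; BED output keeps that convention unchanged.

#' Read a probe design table
#'
#' A probe design maps each array probe to a genomic interval and to the
#' tiled locus it belongs to. The file is a tab-separated table with a
#' leading `# probe_id\tchrom\tstart\tend\tlocus_id` header line.
#' Rows are sorted canonically (locus, chrom, start) on read; invalid rows
#' (empty intervals, duplicate probe ids, overlapping probes within a locus)
#' are rejected with the offending line or probe named.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `probe_id`, `chrom`, `start`, `end`,
#'   `locus_id`, sorted by locus then position.
#' @export
read_probe_design <- function(path) {
  df <- read_tsv_commented(path,
    colClasses = c("character", "character", "integer", "integer", "character"))
  need <- c("probe_id", "chrom", "start", "end", "locus_id")
  if (!identical(names(df), need)) {
    stop_data("probe design header must be: ", paste(need, collapse = ", "))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(!(df$end > df$start))
  if (length(bad)) {
    stop_data("probe design: end <= start at data line ", bad[1],
              " (probe ", df$probe_id[bad[1]], ")")
  }
  validate_probe_design(df)
}

validate_probe_design <- function(df) {
  if (anyDuplicated(df$probe_id)) {
    stop_data("probe design: duplicate probe_id ",
              df$probe_id[duplicated(df$probe_id)][1])
  }
  if (any(df$start < 0)) stop_data("probe design: negative start coordinate")
  df <- df[order(df$locus_id, df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  # probes within a locus must not overlap
  for (loc in unique(df$locus_id)) {
    sub <- df[df$locus_id == loc, , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop_data("probe design: overlapping probes within locus ", loc)
    }
  }
  df
}

#' Write a probe design table
#'
#' @param design Probe design `data.frame` (see [read_probe_design()]).
#' @param path Output path.
#' @export
write_probe_design <- function(design, path) {
  design <- validate_probe_design(design)
  write_tsv_commented(design[c("probe_id", "chrom", "start", "end", "locus_id")],
                      path)
}

#' Read and write BED interval tracks
#'
#' BED3+ dialect, 0-based half-open. Columns beyond `chrom`, `start`, `end`
#' (element `name` and `score`) are optional and preserved on round trip.
#' Lines starting with `#` are ignored on read.
#'
#' @param path Path to a BED file.
#' @param name Track name attached to the returned table (e.g. `"TFBS"`).
#' @return `data.frame` with columns `chrom`, `start`, `end` and, when
#'   present, `name` and `score`, sorted by chrom then start, with
#'   `attr(, "track")` set.
#' @export
read_bed <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
    attr(out, "track") <- name
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(parts))
  if (ncol < 3) stop_data("BED: fewer than 3 columns")
  starts <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  ends <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3)))
  if (anyNA(starts) || anyNA(ends)) {
    stop_data("BED: non-integer coordinate at line ",
              which(is.na(starts) | is.na(ends))[1])
  }
  out <- data.frame(chrom = vapply(parts, `[[`, "", 1),
                    start = starts, end = ends,
                    stringsAsFactors = FALSE)
  if (ncol >= 4) out$name <- vapply(parts, `[[`, "", 4)
  if (ncol >= 5) out$score <- as.numeric(vapply(parts, `[[`, "", 5))
  if (any(out$end <= out$start)) {
    stop_data("BED: end <= start at line ", which(out$end <= out$start)[1])
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "track") <- name
  out
}

#' @rdname read_bed
#' @param track Interval `data.frame` to write.
#' @export
write_bed <- function(track, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(track))
  df <- track[cols]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(cols, collapse = "\t")), con)
  if (nrow(df) > 0) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a long-format array intensity table
#'
#' Two-channel intensities per (array, probe): columns `array_id`,
#' `probe_id`, `bound` (Cy5, methyl-enriched fraction) and `input` (Cy3).
#' Every array present must cover every probe in `design`, and both
#' channels must be strictly positive; violations are errors, never
#' silently patched.
#'
#' @param path Path to the TSV file.
#' @param design Probe design the table must be complete against.
#' @return `data.frame` with columns `array_id`, `probe_id`, `bound`, `input`.
#' @export
read_intensities <- function(path, design) {
  df <- read_tsv_commented(path,
    colClasses = c("character", "character", "numeric", "numeric"))
  need <- c("array_id", "probe_id", "bound", "input")
  if (!identical(names(df), need)) {
    stop_data("intensity header must be: ", paste(need, collapse = ", "))
  }
  validate_intensities(df, design)
}

validate_intensities <- function(df, design) {
  bad <- which(!(df$bound > 0) | !(df$input > 0))
  if (length(bad)) {
    stop_data("intensities: non-positive channel at data line ", bad[1],
              " (array ", df$array_id[bad[1]], ", probe ",
              df$probe_id[bad[1]], ")")
  }
  unknown <- setdiff(unique(df$probe_id), design$probe_id)
  if (length(unknown)) {
    stop_data("intensities: probe(s) absent from design: ",
              paste(utils::head(unknown, 5), collapse = ", "))
  }
  for (a in unique(df$array_id)) {
    missing <- setdiff(design$probe_id, df$probe_id[df$array_id == a])
    if (length(missing)) {
      stop_data("intensities: array ", a, " missing probe(s): ",
                paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  df
}

#' @rdname read_intensities
#' @param intensities Intensity `data.frame` to write.
#' @export
write_intensities <- function(intensities, path) {
  write_tsv_commented(
    intensities[c("array_id", "probe_id", "bound", "input")], path)
}

#' Read and write sample sheets
#'
#' One row per hybridized array: `array_id`, `subject_id`, `group`
#' (`A` = case, `B` = control), `cell_type`, `replicate`. The combination
#' (subject, cell type, replicate) must be unique and each subject must
#' belong to a single group.
#'
#' @param path Path to the TSV file.
#' @return Sample sheet `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_commented(path,
    colClasses = c("character", "character", "character", "character",
                   "integer"))
  need <- c("array_id", "subject_id", "group", "cell_type", "replicate")
  if (!identical(names(df), need)) {
    stop_data("sample sheet header must be: ", paste(need, collapse = ", "))
  }
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  if (!all(df$group %in% c("A", "B"))) {
    stop_data("sample sheet: group must be 'A' or 'B'")
  }
  key <- paste(df$subject_id, df$cell_type, df$replicate)
  if (anyDuplicated(key)) {
    stop_data("sample sheet: duplicate (subject, cell_type, replicate): ",
              key[duplicated(key)][1])
  }
  grp <- tapply(df$group, df$subject_id, function(g) length(unique(g)))
  if (any(grp > 1)) {
    stop_data("sample sheet: subject in more than one group: ",
              names(grp)[grp > 1][1])
  }
  if (anyDuplicated(df$array_id)) {
    stop_data("sample sheet: duplicate array_id")
  }
  df
}

#' @rdname read_sample_sheet
#' @param sheet Sample sheet `data.frame` to write.
#' @export
write_sample_sheet <- function(sheet, path) {
  write_tsv_commented(
    sheet[c("array_id", "subject_id", "group", "cell_type", "replicate")],
    path)
}

#' Read and write subject phenotype tables
#'
#' Long format: `subject_id`, `analyte`, `level` (e.g. plasma cytokine
#' concentration in pg/ml). Missing levels are allowed and encoded as `NA`;
#' at most one value per subject per analyte.
#'
#' @param path Path to the TSV file.
#' @return Phenotype `data.frame`.
#' @export
read_phenotype <- function(path) {
  df <- read_tsv_commented(path,
    colClasses = c("character", "character", "numeric"))
  need <- c("subject_id", "analyte", "level")
  if (!identical(names(df), need)) {
    stop_data("phenotype header must be: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(paste(df$subject_id, df$analyte))) {
    stop_data("phenotype: more than one value per subject per analyte")
  }
  if (any(df$level < 0, na.rm = TRUE)) {
    stop_data("phenotype: negative level")
  }
  df
}

#' @rdname read_phenotype
#' @param phenotype Phenotype `data.frame` to write.
#' @export
write_phenotype <- function(phenotype, path) {
  write_tsv_commented(phenotype[c("subject_id", "analyte", "level")], path)
}

#' Read and write gene model tables
#'
#' Columns: `gene_id`, `chrom`, `tss`, `strand` (`+`/`-`), `tes`. The TSS
#' precedes the TES in genomic coordinates on `+` genes and follows it on
#' `-` genes.
#'
#' @param path Path to the TSV file.
#' @return Gene model `data.frame`.
#' @export
read_gene_models <- function(path) {
  df <- read_tsv_commented(path,
    colClasses = c("character", "character", "integer", "character",
                   "integer"))
  need <- c("gene_id", "chrom", "tss", "strand", "tes")
  if (!identical(names(df), need)) {
    stop_data("gene model header must be: ", paste(need, collapse = ", "))
  }
  validate_gene_models(df)
}

validate_gene_models <- function(df) {
  if (anyDuplicated(df$gene_id)) stop_data("gene models: duplicate gene_id")
  if (!all(df$strand %in% c("+", "-"))) {
    stop_data("gene models: strand must be '+' or '-'")
  }
  bad <- (df$strand == "+" & df$tss >= df$tes) |
    (df$strand == "-" & df$tss <= df$tes)
  if (any(bad)) {
    stop_data("gene models: TSS/TES inconsistent with strand for gene ",
              df$gene_id[bad][1])
  }
  df
}

#' @rdname read_gene_models
#' @param genes Gene model `data.frame` to write.
#' @export
write_gene_models <- function(genes, path) {
  write_tsv_commented(genes[c("gene_id", "chrom", "tss", "strand", "tes")],
                      path)
}
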