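# Independent brute-force oracles and tiny fixture builders shared across
# the test files.

# Exhaustive rank-sum null: enumerate every k-subset of the midranks and
# count how often the subset sum is at least / at most the observed sum.
brute_rank_sum <- function(region_scores, background_scores) {
  scores <- c(region_scores, background_scores)
  k <- length(region_scores)
  rk <- rank(scores)
  w <- sum(rk[seq_len(k)])
  subsets <- utils::combn(length(scores), k)
  sums <- colSums(matrix(rk[subsets], nrow = k))
  eps <- 1e-9
  list(p_up = mean(sums >= w - eps), p_down = mean(sums <= w + eps))
}

# Literal step-up BH definition: q_i = min over p_(j) >= p_(i) of m p_(j)/j.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(p[ord] >= p[i] - 1e-15)
    q[i] <- min(1, min(m * p[ord][js] / js))
  }
  q
}

# All-pairs half-open interval intersection.
brute_overlaps <- function(regions, track) {
  out <- list()
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(track))) {
      if (regions$chrom[i] == track$chrom[j] &&
          regions$start[i] < track$end[j] &&
          track$start[j] < regions$end[i]) {
        out[[length(out) + 1]] <- data.frame(
          region_id = regions$region_id[i],
          element = track$name[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(region_id = character(0), element = character(0)))
  }
  unique(do.call(rbind, out))
}

# A 3-probe-per-region toy design on one chromosome.
tiny_design <- function(n_probes = 30, spacing = 100, locus_id = "locusX",
                        chrom = "chr1", origin = 0L) {
  starts <- origin + (seq_len(n_probes) - 1L) * spacing
  data.frame(probe_id = sprintf("%s_p%03d", locus_id, seq_len(n_probes)),
             chrom = chrom, start = as.integer(starts),
             end = as.integer(starts + spacing), locus_id = locus_id,
             stringsAsFactors = FALSE)
}

# Small two-locus simulation spec with optional planted DMRs.
tiny_spec <- function(seed = 1, planted = NULL, links = NULL,
                      cell_types = "T_cell") {
  loci <- data.frame(locus_id = c("locusA", "locusB"),
                     chrom = c("chr2", "chr7"),
                     start = c(100000L, 500000L),
                     length = c(10000L, 10000L), stringsAsFactors = FALSE)
  simulation_spec(loci = loci, planted_dmrs = planted,
                  phenotype_links = links, cell_types = cell_types,
                  seed = seed)
}
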