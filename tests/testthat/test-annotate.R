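test_that("TSS distances are signed, strand-oriented, and gate the promoter flag", {
  genes <- data.frame(gene_id = c("GENE1", "GENE2"),
                      chrom = c("chr1", "chr2"),
                      tss = c(10000L, 10000L),
                      strand = c("+", "-"),
                      tes = c(20000L, 2000L), stringsAsFactors = FALSE)
  regions <- data.frame(
    region_id = c("r_up", "r_out", "r_minus"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(8000L, 7458L, 10000L),
    end = c(9000L, 8458L, 11000L), stringsAsFactors = FALSE)
  ann <- assign_nearest_gene(regions, genes)
  # midpoint 8500, 1500 bp 5' of a + strand TSS: inside the promoter window
  expect_equal(ann$tss_distance[1], -1500)
  expect_true(ann$promoter[1])
  # midpoint 7958 -> -2042: just outside the -2000/+1000 promoter window
  expect_equal(ann$tss_distance[2], -2042)
  expect_false(ann$promoter[2])
  # - strand gene, midpoint 500 bp past the TSS in genomic coordinates:
  # upstream in gene orientation
  expect_equal(ann$tss_distance[3], -500)
  expect_true(ann$promoter[3])
})

test_that("annotation is symmetric under coordinate mirroring and strand flip", {
  set.seed(19)
  M <- 1000000L
  genes <- data.frame(gene_id = "G", chrom = "chr1", tss = 50000L,
                      strand = "+", tes = 70000L, stringsAsFactors = FALSE)
  for (i in 1:20) {
    s <- as.integer(sample(30000:80000, 1))
    region <- data.frame(region_id = "r", chrom = "chr1", start = s,
                         end = s + 1000L, stringsAsFactors = FALSE)
    mirrored_gene <- data.frame(gene_id = "G", chrom = "chr1",
                                tss = M - genes$tss, strand = "-",
                                tes = M - genes$tes,
                                stringsAsFactors = FALSE)
    mirrored_region <- data.frame(region_id = "r", chrom = "chr1",
                                  start = M - region$end,
                                  end = M - region$start,
                                  stringsAsFactors = FALSE)
    a <- assign_nearest_gene(region, genes)
    b <- assign_nearest_gene(mirrored_region, mirrored_gene)
    expect_equal(b$tss_distance, a$tss_distance)
    expect_equal(b$promoter, a$promoter)
  }
})

test_that("nearest gene is chosen by absolute distance with lexicographic ties", {
  genes <- data.frame(gene_id = c("B_GENE", "A_GENE"), chrom = "chr1",
                      tss = c(12000L, 8000L), strand = "+",
                      tes = c(22000L, 18000L), stringsAsFactors = FALSE)
  region <- data.frame(region_id = "r", chrom = "chr1", start = 9500L,
                       end = 10500L, stringsAsFactors = FALSE)  # midpoint 10000
  ann <- assign_nearest_gene(region, genes)
  expect_equal(ann$nearest_gene, "A_GENE")   # both 2000 bp away

  off <- data.frame(region_id = "r2", chrom = "chrX", start = 0L,
                    end = 1000L, stringsAsFactors = FALSE)
  ann2 <- assign_nearest_gene(off, genes)
  expect_true(is.na(ann2$nearest_gene))
})

test_that("interval overlap is half-open with deduplicated elements", {
  regions <- data.frame(region_id = c("r1", "r2"), chrom = "chr1",
                        start = c(100L, 100L), end = c(200L, 200L),
                        stringsAsFactors = FALSE)
  regions$region_id <- c("r1", "r2")
  tracks <- list(TFBS = data.frame(
    chrom = "chr1", start = c(199L, 200L, 120L, 130L),
    end = c(300L, 300L, 140L, 150L),
    name = c("NFkB", "STAT1", "PU.1", "PU.1"), stringsAsFactors = FALSE))
  ov <- overlap_tracks(regions[1, ], tracks)
  expect_true("NFkB" %in% ov$element)      # 1-bp overlap counts
  expect_false("STAT1" %in% ov$element)    # half-open: [200,300) misses [100,200)
  expect_equal(sum(ov$element == "PU.1"), 1)  # deduplicated

  counts <- summarize_overlaps(ov, c("TFBS", "DNase"))
  expect_equal(unname(counts), c(1L, 0L))
})

test_that("overlap agrees with brute-force all-pairs on random tracks", {
  set.seed(55)
  for (i in 1:5) {
    nr <- sample(5:20, 1)
    nt <- sample(10:200, 1)
    regions <- data.frame(
      region_id = sprintf("r%02d", seq_len(nr)),
      chrom = sample(c("chr1", "chr2"), nr, replace = TRUE),
      start = sample(0:50000, nr), stringsAsFactors = FALSE)
    regions$end <- regions$start + sample(500:2000, nr, replace = TRUE)
    track <- data.frame(
      chrom = sample(c("chr1", "chr2"), nt, replace = TRUE),
      start = sample(0:50000, nt), stringsAsFactors = FALSE)
    track$end <- track$start + sample(1:3000, nt, replace = TRUE)
    track$name <- sprintf("e%03d", seq_len(nt))
    got <- overlap_tracks(regions, list(T = track))
    ref <- brute_overlaps(regions, track)
    key <- function(df) sort(paste(df$region_id, df$element))
    expect_equal(key(got), key(ref))

    # interval order in the track must not matter
    shuffled <- overlap_tracks(regions, list(T = track[sample(nt), ]))
    expect_equal(key(shuffled), key(got))
  }
})

test_that("annotate_regions collapses overlaps per track", {
  genes <- data.frame(gene_id = "G", chrom = "chr1", tss = 500L,
                      strand = "+", tes = 5000L, stringsAsFactors = FALSE)
  calls <- data.frame(region_id = "r1", chrom = "chr1", start = 0L,
                      end = 1000L, stringsAsFactors = FALSE)
  tracks <- list(
    TFBS = data.frame(chrom = "chr1", start = c(10L, 600L),
                      end = c(200L, 900L), name = c("NFkB", "PU.1"),
                      stringsAsFactors = FALSE),
    DNase = data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), name = character(0),
                       stringsAsFactors = FALSE))
  ann <- annotate_regions(calls, genes, tracks)
  expect_equal(ann$TFBS, "NFkB,PU.1")
  expect_equal(ann$DNase, "")
  expect_true(ann$promoter)
})
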