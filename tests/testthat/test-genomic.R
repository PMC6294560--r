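test_that("BED files are read, validated and sorted", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100000", path)
  x <- read_bed(path)
  expect_equal(nrow(x), 1L)
  expect_equal(x$end - x$start, 100000L)

  # unsorted input comes back sorted; overlaps preserved, not merged
  writeLines(c("chr1\t5000\t7000", "chr1\t0\t1000", "chr1\t500\t1500"), path)
  y <- read_bed(path)
  expect_equal(y$start, c(0L, 500L, 5000L))
  expect_equal(nrow(y), 3L)
  expect_equal(nrow(merge_intervals(y)), 2L)

  # out-of-bounds against a declared genome
  expect_error(read_bed(path, genome = mini_genome(6000L)),
               "beyond chromosome length")
  writeLines("chrUn\t0\t100", path)
  expect_error(read_bed(path, genome = mini_genome()), "unknown chromosome")
})

test_that("interval complement covers exactly the uncovered bases", {
  genome <- mini_genome(10000L)
  x <- tibble::tibble(chrom = "chr1", start = c(1000L, 4000L),
                      end = c(2000L, 6000L))
  comp <- complement_intervals(x, genome)
  expect_equal(comp$start, c(0L, 2000L, 6000L))
  expect_equal(comp$end, c(1000L, 4000L, 10000L))
  expect_equal(sum(comp$end - comp$start) + sum(x$end - x$start), 10000L)
})

test_that("fragments are assigned to bins by midpoint and totals conserved", {
  genome <- mini_genome(100000L)
  frags <- tibble::tibble(
    chrom = "chr1",
    start = c(5000L, 9950L, 19999L),
    end = c(5100L, 10050L, 20001L)
  )
  track <- bin_fragments(frags, genome, bin_width = 10000)
  expect_equal(nrow(track), 10L)
  expect_equal(track$count[track$start == 0], 1)       # midpoint 5050
  expect_equal(track$count[track$start == 10000], 1)   # midpoint exactly 10000
  expect_equal(track$count[track$start == 20000], 1)   # midpoint 20000
  expect_equal(sum(track$count), 3)

  set.seed(99)
  starts <- sample.int(99000L, 1000) - 1L
  many <- tibble::tibble(chrom = "chr1", start = starts, end = starts + 100L)
  expect_equal(sum(bin_fragments(many, genome)$count), 1000)

  beyond <- tibble::tibble(chrom = "chr1", start = 99950L, end = 100100L)
  expect_error(bin_fragments(beyond, genome), "beyond chromosome length")
})

test_that("terminal partial bins are retained", {
  genome <- mini_genome(25000L)
  bins <- genome_bins(genome, 10000)
  expect_equal(bins$end - bins$start, c(10000L, 10000L, 5000L))
})

test_that("log2 ratio of identical tracks is zero and smoothing-invariant", {
  genome <- mini_genome(200000L)
  set.seed(1)
  starts <- sample.int(199000L, 2000) - 1L
  frags <- tibble::tibble(chrom = "chr1", start = starts, end = starts + 100L)
  track <- bin_fragments(frags, genome)
  lr <- log2_ratio_track(track, track, smooth_bins = 5)
  expect_equal(lr$value, rep(0, nrow(lr)))
})

test_that("planted uniform fold change is recovered as log2(fold)", {
  # IP = 4 x input in every bin at matched depth: after CPM normalization
  # the global scale cancels, so a genome-wide fold gives 0; a planted
  # fold in a sub-region at matched depth gives log2(4) inside.
  genome <- mini_genome(1000000L)
  bins <- genome_bins(genome, 10000)
  input <- dplyr::mutate(bins, count = 100)
  ip_uniform <- dplyr::mutate(bins, count = 400)
  expect_equal(log2_ratio_track(ip_uniform, input)$value, rep(0, 100))

  # planted 4-fold enrichment in a sub-region at matched depth: CPM
  # normalization shifts both levels by the same constant, so the
  # inside-vs-outside contrast is exactly log2(4) away from boundaries
  ip <- dplyr::mutate(
    bins, count = ifelse(start >= 400000 & start < 600000, 400, 100))
  ip$count <- ip$count / sum(ip$count) * sum(input$count)  # matched depth
  lr <- log2_ratio_track(ip, input, smooth_bins = 5)
  interior_in <- lr$start >= 420000 & lr$start < 580000
  interior_out <- lr$start < 380000 | lr$start >= 620000
  contrast <- mean(lr$value[interior_in]) - mean(lr$value[interior_out])
  expect_equal(contrast, log2(4), tolerance = 1e-4)  # pseudocount shifts ~1e-5
  expect_lt(max(lr$value[interior_in]) - min(lr$value[interior_in]), 1e-9)
})

test_that("smoothing with one bin is the identity and constants are fixed points", {
  genome <- mini_genome(100000L)
  track <- dplyr::mutate(genome_bins(genome, 10000), value = rnorm(10))
  expect_equal(smooth_track(track, 1)$value, track$value)
  const <- dplyr::mutate(track, value = 3.25)
  expect_equal(smooth_track(const, 5)$value, rep(3.25, 10))
  expect_error(smooth_track(track, 4), "odd")
  # mismatching geometry is rejected
  a <- dplyr::mutate(genome_bins(genome, 10000), count = 1)
  b <- dplyr::mutate(genome_bins(mini_genome(50000L), 10000), count = 1)
  expect_error(log2_ratio_track(a, b), "mismatching bin geometry")
})

test_that("window means average covered bins and preserve the global mean", {
  genome <- mini_genome(100000L)
  track <- dplyr::mutate(genome_bins(genome, 10000), value = as.numeric(0:9))
  win <- window_means(track, 100000)
  expect_equal(win$value, 4.5)
  expect_equal(win$n_bins, 10L)

  const <- dplyr::mutate(track, value = 2.5)
  expect_equal(window_means(const, 20000)$value, rep(2.5, 5))

  set.seed(3)
  track2 <- dplyr::mutate(genome_bins(mini_genome(500000L), 10000),
                          value = rnorm(50))
  win2 <- window_means(track2, 100000)  # all windows full
  expect_equal(mean(win2$value), mean(track2$value), tolerance = 1e-9)
})

test_that("window masks flag any >= 1 bp overlap", {
  genome <- mini_genome(500000L)
  windows <- window_means(
    dplyr::mutate(genome_bins(genome, 10000), value = 0), 100000)
  exact <- tibble::tibble(chrom = "chr1", start = 100000L, end = 200000L)
  m1 <- region_overlap_mask(windows, exact)
  expect_equal(which(m1$in_region), 2L)

  spanning <- tibble::tibble(chrom = "chr1", start = 195000L, end = 205000L)
  m2 <- region_overlap_mask(windows, spanning)
  expect_equal(which(m2$in_region), c(2L, 3L))

  m0 <- region_overlap_mask(windows, tibble::tibble(chrom = character(),
                                                    start = integer(),
                                                    end = integer()))
  expect_false(any(m0$in_region))
})

test_that("Monte Carlo test is deterministic, floored and validated", {
  set.seed(10)
  windows <- tibble::tibble(
    chrom = "chr1", start = seq(0, 99) * 1000, end = seq(1, 100) * 1000,
    value = rnorm(100, sd = 0.5), in_region = rep(c(TRUE, FALSE), c(20, 80))
  )
  windows$value[windows$in_region] <- windows$value[windows$in_region] + 2

  a <- monte_carlo_enrichment(windows, iterations = 999, seed = 42)
  b <- monte_carlo_enrichment(windows, iterations = 999, seed = 42)
  expect_identical(a$null, b$null)
  expect_equal(a$p_value, 1 / 1000)  # attainable floor by construction
  expect_equal(a$observed, mean(windows$value[windows$in_region]))

  flat <- dplyr::mutate(windows, in_region = TRUE)
  expect_error(monte_carlo_enrichment(flat), "not all")
  none <- dplyr::mutate(windows, in_region = FALSE)
  expect_error(monte_carlo_enrichment(none), "at least one")
  expect_error(monte_carlo_enrichment(dplyr::select(windows, -"in_region")),
               "region_overlap_mask")
})

test_that("Monte Carlo p-values are calibrated under exchangeability", {
  set.seed(20)
  n_runs <- 200
  hits <- vapply(seq_len(n_runs), function(i) {
    w <- tibble::tibble(
      chrom = "chr1", start = 0:149, end = 1:150,
      value = rnorm(150), in_region = rep(c(TRUE, FALSE), c(30, 120))
    )
    monte_carlo_enrichment(w, iterations = 199, seed = 5000 + i)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.02)
  expect_lte(mean(hits), 0.09)
})

test_that("chromosome-matched null preserves per-chromosome composition", {
  windows <- tibble::tibble(
    chrom = rep(c("chr1", "chr2"), each = 50),
    start = rep(0:49, 2) * 1000, end = (rep(0:49, 2) + 1) * 1000,
    value = c(rnorm(50, 1), rnorm(50, -1)),
    in_region = c(rep(TRUE, 10), rep(FALSE, 40), rep(FALSE, 50))
  )
  # all flagged windows on chr1 (mean +1): a genome-wide null spans both
  # chromosome means, the matched null stays near +1
  mc_matched <- monte_carlo_enrichment(windows, iterations = 500, seed = 1,
                                       chromosome_matched = TRUE)
  expect_equal(mean(mc_matched$null), 1, tolerance = 0.2)
})

test_that("fraction positive counts strictly positive region means", {
  genome <- mini_genome(100000L)
  track <- dplyr::mutate(genome_bins(genome, 10000), value = 1)
  regions <- tibble::tibble(chrom = "chr1", start = c(0L, 50000L),
                            end = c(20000L, 70000L))
  expect_equal(fraction_positive(track, regions)$fraction_positive, 1)

  zero <- dplyr::mutate(track, value = 0)
  expect_equal(fraction_positive(zero, regions)$fraction_positive, 0)

  # a region with no overlapping bins is excluded and reported
  track_chr1 <- dplyr::mutate(genome_bins(genome, 10000), value = 1)
  regions2 <- dplyr::bind_rows(
    regions, tibble::tibble(chrom = "chr2", start = 0L, end = 1000L))
  fp <- fraction_positive(track_chr1, regions2)
  expect_equal(fp$n_excluded, 1L)
  expect_equal(fp$n_scored, 2L)
  expect_equal(fp$fraction_positive, 1)
})

test_that("bedGraph round-trips a binned track", {
  genome <- mini_genome(50000L)
  track <- dplyr::mutate(genome_bins(genome, 10000),
                         value = c(-1.5, 0, 0.25, 2, 0.5))
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(track, path)
  back <- read_bedgraph(path)
  expect_equal(back$value, track$value)
  expect_equal(back$start, track$start)
})

test_that("weighted bedGraph-style counts are honoured by binning", {
  genome <- mini_genome(30000L)
  counts <- tibble::tibble(chrom = "chr1", start = c(0L, 10000L),
                           end = c(10000L, 20000L), count = c(7, 3))
  track <- bin_fragments(counts, genome, 10000)
  expect_equal(track$count, c(7, 3, 0))
})
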