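# Grid construction, fragment binning, aggregation, fragment-size filter.

test_that("bin assignment follows floor division on half-open bins", {
  g <- bin_grid(c(chr1 = 100e3, chr2 = 50e3), bin_size = 5000)
  fr <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   midpoint = c(1086, 5000, 0),
                   size = c(173, 200, 150))
  bs <- bin_fragments(fr, g)
  expect_equal(bs$counts[1], 1)          # midpoint 1086 -> bin 0 (global 1)
  expect_equal(bs$counts[2], 1)          # midpoint 5000 -> bin 1 (boundary)
  expect_equal(bs$counts[g$offset["chr2"] + 1], 1)
  expect_equal(sum(bs$counts), 3)
})

test_that("per-bin fragment-size accumulators sum sizes", {
  g <- bin_grid(c(chr1 = 10e3), bin_size = 5000)
  fr <- data.frame(chrom = "chr1", midpoint = c(100, 200, 300),
                   size = c(150, 170, 190))
  bs <- bin_fragments(fr, g)
  expect_equal(bs$counts[1], 3)
  expect_equal(bs$fs_sum[1], 510)
  expect_equal(fs_mean(bs)[1], 170)
  expect_equal(bs$fs_n, bs$counts)       # before fs filtering they coincide
})

test_that("off-grid chromosomes are dropped with a warning; corrupt midpoints error", {
  g <- bin_grid(c(chr1 = 10e3), bin_size = 5000)
  fr <- data.frame(chrom = c("chr1", "chrX"), midpoint = c(100, 100),
                   size = c(150, 150))
  expect_warning(bs <- bin_fragments(fr, g), "outside the grid")
  expect_equal(sum(bs$counts), 1)
  expect_equal(unname(attr(bs, "binning_stats")["off_grid"]), 1L)

  bad <- data.frame(chrom = "chr1", midpoint = 10e3, size = 100)
  expect_error(bin_fragments(bad, g), "corrupt")
})

test_that("binning is permutation-invariant and conserves totals", {
  g <- bin_grid(c(chr1 = 100e3, chr2 = 100e3), bin_size = 5000)
  set.seed(7)
  fr <- data.frame(chrom = sample(c("chr1", "chr2"), 500, TRUE),
                   midpoint = sample.int(100e3, 500, TRUE) - 1,
                   size = sample.int(300, 500, TRUE))
  a <- bin_fragments(fr, g)
  b <- bin_fragments(fr[sample.int(500), ], g)
  expect_equal(a$counts, b$counts)
  expect_equal(a$fs_sum, b$fs_sum)
  expect_equal(sum(a$counts), nrow(fr))
})

test_that("aggregation sums fields, conserves per-chromosome totals, composes", {
  g <- bin_grid(c(chr1 = 500e3, chr2 = 260e3), bin_size = 5000)
  set.seed(11)
  fr <- data.frame(chrom = sample(c("chr1", "chr2"), 2000, TRUE, c(.7, .3)),
                   midpoint = NA, size = sample.int(300, 2000, TRUE))
  fr$midpoint <- ifelse(fr$chrom == "chr1",
                        sample.int(500e3, 2000, TRUE),
                        sample.int(260e3, 2000, TRUE)) - 1
  fine <- bin_fragments(fr, g)

  coarse <- aggregate_bins(fine, 250e3)
  expect_equal(coarse$grid$n_bins, c(chr1 = 2L, chr2 = 2L))
  # 50 consecutive 5 kb bins fold into one 250 kb bin
  expect_equal(coarse$counts[1], sum(fine$counts[1:50]))
  expect_equal(coarse$fs_sum[1], sum(fine$fs_sum[1:50]))
  # conservation per chromosome
  cid_f <- rep(1:2, fine$grid$n_bins)
  cid_c <- rep(1:2, coarse$grid$n_bins)
  for (ch in 1:2) {
    expect_equal(sum(coarse$counts[cid_c == ch]), sum(fine$counts[cid_f == ch]))
  }
  # identity and composition
  expect_equal(aggregate_bins(fine, 5000)$counts, fine$counts)
  via <- aggregate_bins(aggregate_bins(fine, 50e3), 250e3)
  expect_equal(via$counts, coarse$counts)
  expect_equal(via$fs_sum, coarse$fs_sum)
  # non-multiple target errors
  expect_error(aggregate_bins(fine, 7500), "multiple")
})

test_that("fragment-size region filter applies both bounds and leaves counts alone", {
  g <- bin_grid(c(chr1 = 100e3, chr2 = 100e3), bin_size = 5000)
  counts <- rep(50, g$total_bins)
  counts[5] <- 3                           # low fragment count
  counts[12] <- 50 * 20                    # 20x pile-up
  bs <- binned_sample("s", g, counts, fs_sum = counts * 170, fs_n = counts)

  flt <- fs_region_filter(bs, min_frags = 10, max_cov_z = 3)
  expect_false(flt$fs_mask[5])
  # oracle: direct z of the pile-up bin on this fixture
  norm <- counts / sum(counts)
  z12 <- (norm[12] - mean(norm)) / sd(norm)
  expect_gt(z12, 3)
  expect_false(flt$fs_mask[12])
  expect_true(all(flt$fs_mask[-c(5, 12)]))
  expect_equal(flt$counts, bs$counts)      # counts untouched

  # uniform coverage: upper bound masks nothing
  uni <- binned_sample("u", g, rep(50, g$total_bins),
                       fs_sum = rep(50 * 170, g$total_bins),
                       fs_n = rep(50, g$total_bins))
  expect_true(all(fs_region_filter(uni, min_frags = 10, max_cov_z = 3)$fs_mask))
})

test_that("grid constraints and chrom.sizes parsing", {
  expect_error(bin_grid(c(chr1 = 1e6), 750), "multiple of 5000")
  expect_error(bin_grid(c(1e6), 5000), "named")

  f <- tempfile()
  writeLines(c("chr2\t1000000", "chr1\t2000000", "chrX\t500000", "chrM\t16000"), f)
  sizes <- read_chrom_sizes(f)
  expect_equal(names(sizes), c("chr1", "chr2"))    # autosomes, natural order
  expect_equal(unname(sizes), c(2e6, 1e6))

  # .fai style (5 columns) also works
  writeLines(c("chr1\t2000000\t52\t60\t61", "chrY\t500000\t52\t60\t61"), f)
  expect_equal(unname(read_chrom_sizes(f)), 2e6)
})

test_that("binned sample archives round-trip with grid hash", {
  g <- bin_grid(c(chr1 = 50e3), 5000)
  bs <- binned_sample("s1", g, rep(2, g$total_bins),
                      fs_sum = rep(340, g$total_bins), fs_n = rep(2, g$total_bins))
  f <- tempfile(fileext = ".rds")
  save_binned_sample(bs, f)
  back <- load_binned_sample(f)
  expect_equal(back$counts, bs$counts)
  expect_equal(back$grid$hash, g$hash)
  expect_error(load_binned_sample(tempfile()), "not found")
})
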