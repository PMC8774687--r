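# Normalization, masking, PCA bias models, neighbor construction.

mk_panel <- function(count_rows, grid, fs_mean_val = 170) {
  samples <- lapply(seq_len(nrow(count_rows)), function(i) {
    cn <- count_rows[i, ]
    binned_sample(paste0("c", i), grid, cn, fs_sum = cn * fs_mean_val, fs_n = cn)
  })
  control_panel(samples)
}

test_that("count normalization: scale invariance and conservation", {
  x <- c(2, 3, 5)
  expect_equal(normalize_counts(x), c(0.2, 0.3, 0.5))
  expect_equal(normalize_counts(2 * x), normalize_counts(x))
  expect_equal(sum(normalize_counts(x)), 1)

  mask <- c(TRUE, TRUE, FALSE)
  nm <- normalize_counts(x, mask)
  expect_equal(sum(nm[mask]), 1)
  expect_true(is.na(nm[3]))
  expect_error(normalize_counts(c(0, 0, 0)), "zero total")
})

test_that("global mask flags dead and under-covered bins, keeps uniform panels whole", {
  g <- bin_grid(c(chr1 = 50e3, chr2 = 50e3), 5000)
  nb <- g$total_bins
  base <- matrix(100, nrow = 6, ncol = nb)
  # uniform panel: nothing masked
  expect_true(all(build_global_mask(mk_panel(base, g))))

  dead <- base; dead[, 3] <- 0                    # zero in all controls
  low <- dead; low[, 7] <- 1                      # 1% of the median coverage
  mask <- build_global_mask(mk_panel(low, g), mask_min_frac = 0.1)
  expect_false(mask[3])
  expect_false(mask[7])
  expect_true(all(mask[-c(3, 7)]))
  # deterministic given the panel
  expect_identical(mask, build_global_mask(mk_panel(low, g), mask_min_frac = 0.1))
})

test_that("bias model on identical samples reduces to mean subtraction", {
  g <- bin_grid(c(chr1 = 50e3, chr2 = 50e3), 5000)
  base <- matrix(rep(c(80, 120), each = 5, times = 6), nrow = 6, byrow = TRUE,
                 ncol = g$total_bins)
  panel <- mk_panel(base, g)
  m <- fit_bias_model(panel, "read_count", n_comp = 2)
  v <- normalize_counts(panel$samples[[1]]$counts)
  expect_equal(apply_bias_correction(v, m), m$mean %thru% m$mask,
               tolerance = 1e-10)
})

test_that("planted rank-1 multiplicative bias is recovered by the first PC", {
  g <- bin_grid(c(chr1 = 200e3, chr2 = 200e3), 5000)
  nb <- g$total_bins
  set.seed(5)
  profile <- rnorm(nb)
  scalars <- rnorm(12, 0, 0.2)
  counts <- t(sapply(scalars, function(s) rpois(nb, 2000 * exp(profile * s))))
  panel <- mk_panel(counts, g)
  m <- fit_bias_model(panel, "read_count", n_comp = 3)
  cosine <- abs(sum(m$components[, 1] * profile) /
                  sqrt(sum(m$components[, 1]^2) * sum(profile^2)))
  expect_gt(cosine, 0.99)
})

test_that("bias model edge cases: n_comp = 0, too many components, NA input", {
  g <- bin_grid(c(chr1 = 50e3, chr2 = 50e3), 5000)
  base <- matrix(rpois(6 * g$total_bins, 100), nrow = 6)
  panel <- mk_panel(base, g)
  m0 <- fit_bias_model(panel, "read_count", n_comp = 0)
  expect_equal(m0$n_comp, 0L)
  v <- normalize_counts(panel$samples[[1]]$counts)
  expect_equal(apply_bias_correction(v, m0), v, tolerance = 1e-12)
  expect_error(fit_bias_model(panel, "read_count", n_comp = 6), "smaller")

  zeroed <- base; zeroed[2, 4] <- 0
  expect_error(fit_bias_model(mk_panel(zeroed, g), "fragment_size", 2),
               "fs_n = 0")
})

test_that("bias correction removes the component span and leaves orthogonal residual", {
  g <- bin_grid(c(chr1 = 100e3, chr2 = 100e3), 5000)
  set.seed(9)
  base <- matrix(rpois(8 * g$total_bins, 500), nrow = 8)
  panel <- mk_panel(base, g)
  m <- fit_bias_model(panel, "read_count", n_comp = 3)

  mean_full <- m$mean %thru% m$mask
  expect_equal(apply_bias_correction(mean_full, m), mean_full, tolerance = 1e-12)

  spiked <- mean_full
  spiked[m$mask] <- m$mean + 0.01 * m$components[, 1]
  expect_equal(apply_bias_correction(spiked, m), mean_full, tolerance = 1e-10)

  v <- normalize_counts(panel$samples[[3]]$counts)
  resid <- apply_bias_correction(v, m)[m$mask] - m$mean
  expect_true(all(abs(crossprod(m$components, resid)) < 1e-8))

  expect_error(apply_bias_correction(v[-1], m), "does not match")
})

test_that("neighbor lists equal the brute-force exhaustive ranking on a toy panel", {
  # 3 chromosomes, 12 bins, 5 controls
  set.seed(31)
  profiles <- matrix(rnorm(12 * 5), nrow = 12)
  bin_idx <- 1:12
  chrom_id <- rep(1:3, each = 4)
  nb <- build_neighbors(profiles, bin_idx, chrom_id, K = 5)
  oracle <- oracle_neighbors(profiles, bin_idx, chrom_id, K = 5)
  for (q in 1:12) {
    expect_equal(nb$idx[q, 1:5], oracle[[q]]$idx, label = paste("bin", q))
    expect_false(any(chrom_id[nb$idx[q, ]] == chrom_id[q]))
  }
  # weights: sum 1, positive, non-increasing in distance
  expect_equal(rowSums(nb$w), rep(1, 12))
  expect_true(all(nb$w > 0))
  expect_true(all(apply(nb$w, 1, function(w) all(diff(w) <= 1e-12))))
})

test_that("identical candidate ranks first with the largest weight; ties break by index", {
  profiles <- rbind(c(1, 2, 3), c(5, 5, 5), c(1, 2, 3), c(9, 9, 9),
                    c(1, 2, 3), c(0, 0, 0))
  chrom_id <- c(1, 1, 2, 2, 3, 3)
  nb <- build_neighbors(profiles, 1:6, chrom_id, K = 3)
  expect_equal(nb$idx[1, 1], 3L)     # distance 0 at lower index wins over bin 5
  expect_equal(nb$idx[1, 2], 5L)
  expect_gt(nb$w[1, 1], nb$w[1, 3])

  expect_warning(build_neighbors(profiles, 1:6, chrom_id, K = 10),
                 "fewer than K")
})

test_that("reference construction is deterministic and keeps datatypes independent", {
  co <- fx_small_cohort()
  ref <- fx_small_ref()
  ref2 <- build_reference_set(co$panel, K = 100, n_comp = 5)
  expect_identical(ref$neighbors$read_count$idx, ref2$neighbors$read_count$idx)
  expect_identical(ref$global_mask, ref2$global_mask)
  # the two datatype pipelines are parallel: neighbor lists differ
  expect_false(identical(ref$neighbors$read_count$idx,
                         ref$neighbors$fragment_size$idx))
  # archive round trip
  f <- tempfile(fileext = ".rds")
  save_reference(ref, f)
  expect_equal(load_reference(f)$grid$hash, ref$grid$hash)
})
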