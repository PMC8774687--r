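# Z-scoring, track combination, segmentation, event calling.

test_that("within-sample Z matches the direct weighted-moment oracle", {
  # 2 query bins on chrom A, 4 reference bins on chrom B, hand-built lists
  x <- c(10, 14, 9, 11, 13, 10)
  nb <- list(query_idx = c(1L, 2L),
             idx = rbind(c(3L, 4L, 5L), c(4L, 5L, 6L)),
             w = rbind(c(0.5, 0.3, 0.2), c(1, 1, 2) / 4),
             n_nb = c(3L, 3L), K = 3L)
  z <- within_sample_z(x, nb)
  expect_equal(z[1], oracle_weighted_z(x[1], x[c(3, 4, 5)], c(0.5, 0.3, 0.2)))
  expect_equal(z[2], oracle_weighted_z(x[2], x[c(4, 5, 6)], c(1, 1, 2) / 4))
  expect_true(all(is.na(z[3:6])))

  # query equal to the weighted neighbor mean -> Z = 0
  w <- c(0.5, 0.3, 0.2)
  x0 <- x; x0[1] <- sum(w * x[c(3, 4, 5)])
  expect_equal(within_sample_z(x0, nb)[1], 0)

  # x_q = mu + 2 sigma -> Z = 2
  mu <- sum(w * x[c(3, 4, 5)])
  sig <- sqrt(sum(w * (x[c(3, 4, 5)] - mu)^2))
  x2 <- x; x2[1] <- mu + 2 * sig
  expect_equal(within_sample_z(x2, nb)[1], 2)

  # zero neighbor spread invalidates the bin
  xc <- c(10, 14, 7, 7, 7, 10)
  expect_true(is.na(within_sample_z(xc, nb)[1]))

  # NA neighbors drop out with weight renormalization
  xna <- x; xna[3] <- NA
  w2 <- c(0.3, 0.2) / 0.5
  expect_equal(within_sample_z(xna, nb)[1],
               oracle_weighted_z(x[1], x[c(4, 5)], w2))
})

test_that("a 1.5x spiked bin attains the genome-wide maximum |Z|", {
  ref <- fx_small_ref()
  p <- fx_small_params()
  s <- simulate_sample(p, is_case = FALSE, ff = 0.075, seed = 999,
                       profiles = fx_small_cohort()$profiles)
  spike <- which(ref$global_mask)[10]
  s$counts[spike] <- round(s$counts[spike] * 1.5)
  zt <- score_sample(s, ref)
  expect_equal(which.max(abs(zt$z_rc)), spike)
})

test_that("fragment-size orientation flips sign only", {
  expect_equal(orient_fs(-2), 2)
  expect_equal(orient_fs(0), 0)
  expect_equal(orient_fs(c(1.5, -0.3)), c(-1.5, 0.3))
})

test_that("Stouffer combination", {
  expect_equal(combine_z(2, 2, "stouffer"), 2 * sqrt(2), tolerance = 1e-9)
  z <- c(-1.3, 0.4, 3.2)
  expect_equal(combine_z(z, rep(0, 3), "stouffer"), z / sqrt(2))
})

test_that("Fisher combination matches the chi-square tail oracle", {
  # frozen regression value, computed with oracle_fisher (chi-square df 4)
  expect_equal(combine_z(1.5, 1.5, "fisher"), 1.901511, tolerance = 1e-6)
  grid_z <- expand.grid(a = c(-3, -1.2, 0, 0.7, 2, 4.5),
                        b = c(-2.5, -0.4, 0, 1.1, 3))
  got <- combine_z(grid_z$a, grid_z$b, "fisher")
  want <- mapply(oracle_fisher, grid_z$a, grid_z$b)
  expect_equal(got, unname(want), tolerance = 1e-8)
  # antisymmetry under joint sign flip, away from exact gain/loss ties
  # (at a = -b both one-sided combinations coincide and the documented
  # convention resolves to the gain orientation)
  no_tie <- abs(grid_z$a + grid_z$b) > 1e-9
  expect_equal(combine_z(-grid_z$a[no_tie], -grid_z$b[no_tie], "fisher"),
               -got[no_tie], tolerance = 1e-8)
})

test_that("single-valid-datatype bins fall back; double-invalid stay invalid", {
  z_rc <- c(2.0, NA, NA)
  z_fs <- c(NA, -1.2, NA)
  for (m in c("fisher", "stouffer")) {
    out <- combine_z(z_rc, z_fs, m)
    expect_equal(out[1], 2.0)
    expect_equal(out[2], -1.2)
    expect_true(is.na(out[3]))
  }
})

test_that("CBS: constant input yields a single segment", {
  segs <- cbs_segment(rep(1.7, 40), n_perm = 100, seed = 3)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start_idx, 1L)
  expect_equal(segs$end_idx, 40L)
})

test_that("CBS locates a clean step within one bin of the truth", {
  set.seed(17)
  x <- c(rnorm(30, 0, 0.1), rnorm(30, 5, 0.1))
  segs <- cbs_segment(x, n_perm = 300, seed = 17)
  expect_equal(nrow(segs), 2L)
  bk <- segs$end_idx[1]
  expect_lte(abs(bk - 30), 1)
  expect_equal(bk, oracle_single_changepoint(x))
})

test_that("CBS equals the brute-force exhaustive oracle on short arrays", {
  set.seed(23)
  cases <- list(
    rnorm(12),                                   # pure noise
    c(rnorm(8, 0, .3), rnorm(8, 4, .3)),         # one step
    c(rnorm(6, 0, .3), rnorm(6, 5, .3), rnorm(6, 0, .3)),  # inserted arc
    c(rnorm(10, 2, .2), rnorm(4, -3, .2), rnorm(6, 2, .2)),
    rnorm(20, 0, 2)
  )
  for (k in seq_along(cases)) {
    x <- cases[[k]]
    got <- cbs_segment(x, alpha = 0.01, n_perm = 200, min_bins = 2, seed = 7)
    want <- oracle_cbs(x, alpha = 0.01, n_perm = 200, min_bins = 2, seed = 7)
    expect_equal(as.matrix(got[, c("start_idx", "end_idx")]),
                 unname(want), ignore_attr = TRUE,
                 label = paste("case", k))
  }
})

test_that("CBS output partitions the input for arbitrary signals", {
  set.seed(29)
  for (k in 1:5) {
    n <- sample(20:80, 1)
    x <- rnorm(n) + rep(c(0, sample(c(-4, 0, 4), 1)), c(n %/% 2, n - n %/% 2))
    segs <- cbs_segment(x, n_perm = 150, seed = k)
    expect_equal(segs$start_idx[1], 1L)
    expect_equal(segs$end_idx[nrow(segs)], n)
    if (nrow(segs) > 1) {
      expect_equal(segs$start_idx[-1], segs$end_idx[-nrow(segs)] + 1L)
    }
    expect_true(all(segs$n_bins >= 2))
  }
})

test_that("segment scores follow Stouffer aggregation", {
  expect_equal(score_segment(2.5), 2.5)
  expect_equal(score_segment(rep(1.2, 9)), 1.2 * 3)
  expect_equal(score_segment(c(1, NA, 3)), 4 / sqrt(2))
  expect_true(is.na(score_segment(c(NA_real_, NA_real_))))
})

test_that("segment Z grows like sqrt(m) with the event span on simulation", {
  co <- fx_small_cohort()
  ref <- fx_small_ref()
  p <- fx_small_params()
  ratios <- vapply(1:6, function(k) {
    s <- simulate_sample(p, is_case = TRUE, ff = 0.075, seed = 5000 + k,
                         profiles = co$profiles)
    zt <- score_sample(s, ref)
    z <- zt$z_comb[zt$chrom == "chr8" & !is.na(zt$z_comb)]
    half <- z[seq_len(length(z) %/% 2)]
    score_segment(z) / score_segment(half)
  }, numeric(1))
  expect_equal(mean(ratios), sqrt(2), tolerance = 0.15)
})

test_that("event calling applies the published span and Z thresholds", {
  segs <- data.frame(chrom = "chr1",
                     start = c(0, 0, 0),
                     end = c(12e6, 12e6, 5e6),
                     n_bins = c(16, 16, 7),
                     z_segment = c(6, -6, 8))
  callI <- call_events(segs, "I")
  callII <- call_events(segs, "II")
  expect_equal(nrow(callI), 1L)                # only the 12 Mb gain
  expect_equal(callI$direction, "gain")
  expect_equal(nrow(callII), 3L)               # all three qualify in mode II
  expect_setequal(callII$direction, c("gain", "loss"))
  # boundary: span must exceed the threshold strictly, Z inclusive
  edge <- data.frame(chrom = "c", start = 0, end = 10e6, n_bins = 10, z_segment = 5)
  expect_equal(nrow(call_events(edge, "I")), 0L)
  edge$end <- 10e6 + 1
  expect_equal(nrow(call_events(edge, "I")), 1L)
})

test_that("grid mismatch between sample and reference is refused with a hint", {
  ref <- fx_small_ref()
  other <- sim_params(grid = sim_grid(8, 30e6, 1500e3), n_controls = 2,
                      coverage = 100, seed = 1)
  s <- simulate_sample(other, seed = 1)
  expect_error(score_sample(s, ref), "re-bin")
})
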