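#' Miniature pseudo-genome grid for simulations
#'
#' Equal-length pseudo-autosomes, by default 22 chromosomes of 45 Mb at 750 kb
#' bins (60 bins per chromosome, 1320 bins total) — small enough for
#' desk-scale cohorts, large enough that whole-chromosome events exceed the
#' 10 Mb operating threshold and every bin has well over `K = 300` candidate
#' reference bins on other chromosomes.
#'
#' @param n_chrom number of pseudo-chromosomes (default 22).
#' @param chrom_length chromosome length in bp (default 45 Mb).
#' @param bin_size bin width in bp (default 750 kb).
#' @return a [bin_grid()].
#' @export
sim_grid <- function(n_chrom = 22L, chrom_length = 45e6, bin_size = 750e3) {
  lens <- setNames(rep(chrom_length, n_chrom), paste0("chr", seq_len(n_chrom)))
  bin_grid(lens, bin_size)
}

# First two moments of a normal truncated below at `a`.
trunc_norm_moments <- function(mu, sigma, a = 0) {
  mu <- unname(mu); sigma <- unname(sigma)
  al <- (a - mu) / sigma
  lam <- exp(dnorm(al, log = TRUE) - pnorm(al, lower.tail = FALSE, log.p = TRUE))
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + al * lam - lam^2)
  c(mean = m, var = v)
}

# Mean and SD of the maternal/fetal mixture of zero-truncated normals.
mixture_moments <- function(mu_maternal, sigma, ff, delta) {
  mm <- trunc_norm_moments(mu_maternal, sigma)
  mf <- trunc_norm_moments(mu_maternal - delta, sigma)
  m <- (1 - ff) * mm["mean"] + ff * mf["mean"]
  e2 <- (1 - ff) * (mm["var"] + mm["mean"]^2) + ff * (mf["var"] + mf["mean"]^2)
  c(mean = unname(m), sd = sqrt(unname(e2 - m^2)))
}

.calib_cache <- new.env(parent = emptyenv())

#' Calibrate the fragment-size mixture to cohort summary statistics
#'
#' The simulator models fragment sizes as a two-component mixture of
#' zero-truncated normals: maternal `N(mu_maternal, sigma)` and fetal
#' `N(mu_maternal - delta, sigma)`, mixed with weight `ff` (fetal fraction).
#' Rather than asserting unknown component means, the maternal location and
#' the common SD are solved numerically so that the *overall* mixture at the
#' cohort-average fetal fraction reproduces the cohort's observed fragment
#' statistics (mean 173 bp, SD 56 bp by default).
#'
#' @param ff fetal fraction at which to calibrate (default 0.075, the cohort
#'   average).
#' @param delta maternal-fetal component mean gap in bp (default 45.5; see
#'   the methods vignette for the choice).
#' @param mean_target,sd_target mixture targets in bp.
#' @return named vector `c(mu_maternal, sigma)`; the fetal mean is
#'   `mu_maternal - delta`.
#' @export
calibrate_fs_mixture <- function(ff = 0.075, delta = 45.5,
                                 mean_target = 173, sd_target = 56) {
  key <- paste(ff, delta, mean_target, sd_target, sep = "|")
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  obj <- function(p) {
    mom <- mixture_moments(p[1L], p[2L], ff, delta)
    (mom["mean"] - mean_target)^2 + (mom["sd"] - sd_target)^2
  }
  fit <- optim(c(mean_target + ff * delta, sd_target), obj,
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  if (fit$value > 1e-8) fc_stop("fragment-size mixture calibration failed")
  out <- c(mu_maternal = fit$par[1L], sigma = fit$par[2L])
  .calib_cache[[key]] <- out
  out
}

#' Simulation parameters
#'
#' Bundles the stated world of the simulator: the grid, cohort sizes, bin
#' coverage, the fetal-fraction setting, the fragment-size mixture, shared
#' multiplicative bias profiles, and the planted copy-number event.
#'
#' Coverage defaults to the fragment count equivalent of `depth` (0.25x) with
#' 36 bp paired-end reads: `depth * bin_size / (2 * read_len)` fragments per
#' bin. The mixture parameters default to the calibrated values of
#' [calibrate_fs_mixture()].
#'
#' @param grid a [bin_grid()]; default [sim_grid()].
#' @param n_controls,n_cases cohort composition (defaults 50 and 1).
#' @param depth nominal sequencing depth used to derive the default coverage.
#' @param read_len read length in bp (default 36).
#' @param coverage mean fragments per bin; overrides `depth` when given.
#' @param ff fetal fraction: a single value (default 0.075) or a length-2
#'   range `c(lo, hi)` sampled uniformly per sample.
#' @param delta maternal-fetal fragment-size gap in bp (default 45.5).
#' @param mu_maternal,sigma_fs mixture location/scale; default calibrated so
#'   the mixture at `ff = 0.075` has mean `mean_target` and SD `sd_target`.
#' @param mean_target,sd_target calibration targets (173 bp, 56 bp).
#' @param n_bias number of shared multiplicative bias profiles (default 2).
#' @param bias_sd SD of the per-sample bias scalars (default 0.05).
#' @param cnv planted event: list with `chrom`, `start`, `end`, `type`
#'   (`"gain"`/`"loss"`); default a whole-chromosome gain on the grid's last
#'   chromosome (the chromosome-21 analogue).
#' @param seed master seed.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(grid = NULL, n_controls = 50L, n_cases = 1L,
                       depth = 0.25, read_len = 36L, coverage = NULL,
                       ff = 0.075, delta = 45.5,
                       mu_maternal = NULL, sigma_fs = NULL,
                       mean_target = 173, sd_target = 56,
                       n_bias = 2L, bias_sd = 0.05,
                       cnv = NULL, seed = 1L) {
  grid <- grid %||% sim_grid()
  stopifnot(inherits(grid, "bin_grid"))
  coverage <- coverage %||% (depth * grid$bin_size / (2 * read_len))
  if (!is.numeric(coverage) || coverage <= 0) fc_stop("coverage must be positive")
  if (!(length(ff) %in% 1:2) || any(ff <= 0) || any(ff >= 1)) {
    fc_stop("ff must be in (0, 1): a single value or a c(lo, hi) range")
  }
  if (length(ff) == 2L && ff[1L] > ff[2L]) fc_stop("ff range must be increasing")
  ff_cal <- if (length(ff) == 1L) ff else mean(ff)
  if (is.null(mu_maternal) || is.null(sigma_fs)) {
    cal <- calibrate_fs_mixture(ff_cal, delta, mean_target, sd_target)
    mu_maternal <- mu_maternal %||% unname(cal["mu_maternal"])
    sigma_fs <- sigma_fs %||% unname(cal["sigma"])
  }
  if (sigma_fs <= 0) fc_stop("sigma_fs must be positive")
  if (mu_maternal - delta <= 0) fc_stop("fetal mean must be positive")
  cnv <- cnv %||% {
    last <- tail(grid$chroms, 1L)
    list(chrom = last, start = 0, end = unname(grid$lengths[last]), type = "gain")
  }
  if (!all(c("chrom", "start", "end", "type") %in% names(cnv)) ||
      !(cnv$chrom %in% grid$chroms) || !(cnv$type %in% c("gain", "loss")) ||
      cnv$end <= cnv$start) {
    fc_stop("invalid cnv specification")
  }
  structure(list(grid = grid, n_controls = as.integer(n_controls),
                 n_cases = as.integer(n_cases), coverage = coverage,
                 ff = ff, delta = delta, mu_maternal = mu_maternal,
                 sigma_fs = sigma_fs, n_bias = as.integer(n_bias),
                 bias_sd = bias_sd, cnv = cnv, seed = as.integer(seed)),
            class = "sim_params")
}

#' Fetal read share on an altered region
#'
#' On a region where the fetus carries `c` copies (mother diploid), the
#' fraction of reads of fetal origin becomes `ff * c/2 / (1 - ff + ff * c/2)`:
#' `3ff / (2 + ff)` for a trisomy, `ff / (2 - ff)` for a monosomy.
#'
#' @param ff baseline fetal fraction.
#' @param type `"gain"` (3 copies) or `"loss"` (1 copy).
#' @return adjusted fetal read fraction.
#' @export
ff_on_event <- function(ff, type = c("gain", "loss")) {
  type <- match.arg(type)
  if (type == "gain") 3 * ff / (2 + ff) else ff / (2 - ff)
}

#' Draw fragment sizes from the maternal/fetal mixture
#'
#' Each fragment is fetal with probability `ff`, and its size is drawn from
#' the corresponding normal component truncated at zero (negatives redrawn).
#'
#' @param n number of draws.
#' @param ff fetal fraction.
#' @param mu_maternal,delta,sigma_fs mixture parameters; default calibrated
#'   cohort values at `ff = 0.075`.
#' @param seed optional seed (set only when non-NULL).
#' @return numeric vector of `n` fragment sizes in bp.
#' @export
sim_fragment_sizes <- function(n, ff = 0.075, mu_maternal = NULL, delta = 45.5,
                               sigma_fs = NULL, seed = NULL) {
  if (is.null(mu_maternal) || is.null(sigma_fs)) {
    cal <- calibrate_fs_mixture(0.075, delta)
    mu_maternal <- mu_maternal %||% unname(cal["mu_maternal"])
    sigma_fs <- sigma_fs %||% unname(cal["sigma"])
  }
  if (!is.null(seed)) set.seed(seed)
  fetal <- runif(n) < ff
  mu <- ifelse(fetal, mu_maternal - delta, mu_maternal)
  x <- rnorm(n, mu, sigma_fs)
  bad <- which(x < 0)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mu[bad], sigma_fs)
    bad <- bad[x[bad] < 0]
  }
  x
}

#' Shared multiplicative bias profiles
#'
#' Per-bin log-bias directions shared by every sample of a cohort; each sample
#' scales them with its own `N(0, bias_sd)` scalars, mimicking batch-level
#' technical bias (GC and friends) that the reference's PCA step is meant to
#' learn and remove.
#'
#' @param params a [sim_params()].
#' @param seed seed for the profile draw.
#' @return matrix bins x `n_bias` (0 columns when `n_bias = 0`).
#' @export
sim_bias_profiles <- function(params, seed = params$seed) {
  nb <- params$grid$total_bins
  if (params$n_bias == 0L) return(matrix(numeric(0), nrow = nb, ncol = 0L))
  set.seed(fc_subseed(seed, "bias_profiles"))
  matrix(rnorm(nb * params$n_bias), nrow = nb, ncol = params$n_bias)
}

#' Simulate one binned sample
#'
#' Per bin `b` the fragment count is `Poisson(coverage * bias_b * cn_b)`,
#' where `bias_b = exp(sum_k profile_k[b] * s_k)` with per-sample scalars
#' `s_k ~ N(0, bias_sd)`, and `cn_b` is `1 + ff/2` on a gained region,
#' `1 - ff/2` on a lost region, 1 elsewhere. Every fragment's size is drawn
#' from the maternal/fetal mixture; on the event region the fetal probability
#' rises to [ff_on_event()]. Deterministic given the seed.
#'
#' Controls are pregnancies too: they carry the same fetal fraction and size
#' mixture, just no copy-number event (`is_case = FALSE` only disables the
#' planted CNV).
#'
#' @param params a [sim_params()].
#' @param is_case plant the configured CNV.
#' @param ff fetal fraction of this sample (default: drawn from / equal to
#'   `params$ff`).
#' @param seed sample seed (default `params$seed`).
#' @param profiles shared bias profiles from [sim_bias_profiles()];
#'   regenerated from `params` when NULL.
#' @param sample_id sample identifier.
#' @return a [binned_sample()] with attribute `sim_truth`.
#' @export
simulate_sample <- function(params, is_case = FALSE, ff = NULL, seed = NULL,
                            profiles = NULL, sample_id = NULL) {
  stopifnot(inherits(params, "sim_params"))
  profiles <- profiles %||% sim_bias_profiles(params)
  seed <- seed %||% params$seed
  set.seed(seed)
  ff <- ff %||% (if (length(params$ff) == 1L) params$ff
                 else runif(1, params$ff[1L], params$ff[2L]))
  grid <- params$grid
  nb <- grid$total_bins

  cn <- rep(1, nb)
  ff_bin <- rep(ff, nb)
  if (is_case) {
    b <- grid_bins(grid)
    on_ev <- b$chrom == params$cnv$chrom &
      b$start < params$cnv$end & b$end > params$cnv$start
    cn[on_ev] <- if (params$cnv$type == "gain") 1 + ff / 2 else 1 - ff / 2
    ff_bin[on_ev] <- ff_on_event(ff, params$cnv$type)
  }
  s_k <- rnorm(ncol(profiles), 0, params$bias_sd)
  bias <- if (ncol(profiles)) exp(as.vector(profiles %*% s_k)) else rep(1, nb)
  counts <- rpois(nb, params$coverage * bias * cn)

  ids <- rep.int(seq_len(nb), counts)
  n_frag <- length(ids)
  fs_sum <- numeric(nb)
  if (n_frag) {
    fetal <- runif(n_frag) < ff_bin[ids]
    mu <- ifelse(fetal, params$mu_maternal - params$delta, params$mu_maternal)
    x <- rnorm(n_frag, mu, params$sigma_fs)
    bad <- which(x < 0)
    while (length(bad)) {
      x[bad] <- rnorm(length(bad), mu[bad], params$sigma_fs)
      bad <- bad[x[bad] < 0]
    }
    agg <- rowsum(x, ids)
    fs_sum[as.integer(rownames(agg))] <- agg[, 1L]
  }
  sample_id <- sample_id %||% paste0(if (is_case) "case_" else "ctrl_", seed)
  out <- binned_sample(sample_id, grid, counts, fs_sum = fs_sum, fs_n = counts)
  attr(out, "sim_truth") <- list(
    ff = ff, is_case = is_case,
    cnv = if (is_case) params$cnv else NULL,
    expected_count_ratio = if (!is_case) 1 else
      if (params$cnv$type == "gain") 1 + ff / 2 else 1 - ff / 2,
    expected_fs_shift = if (!is_case) 0 else
      -(ff_on_event(ff, params$cnv$type) - ff) * params$delta,
    seed = seed
  )
  out
}

#' Simulate a cohort with known truth
#'
#' Draws `n_controls` event-free samples and `n_cases` CNV-bearing samples,
#' all sharing the same bias profiles, with per-sample fetal fractions from
#' the configured setting and per-sample seeds derived from the master seed.
#' Byte-identical across runs with the same parameters.
#'
#' @param params a [sim_params()].
#' @return list with `panel` (a [control_panel()]), `cases` (list of
#'   [binned_sample()]), `truth` (data.frame: sample_id, ff, is_case, chrom,
#'   start, end, type, expected_count_ratio, expected_fs_shift), `profiles`,
#'   `params`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  profiles <- sim_bias_profiles(params)
  n <- params$n_controls + params$n_cases
  set.seed(fc_subseed(params$seed, "cohort"))
  seeds <- sample.int(2147483646L, n)
  ffs <- if (length(params$ff) == 1L) rep(params$ff, n) else
    runif(n, params$ff[1L], params$ff[2L])
  make <- function(i, case, id) {
    simulate_sample(params, is_case = case, ff = ffs[i], seed = seeds[i],
                    profiles = profiles, sample_id = id)
  }
  controls <- lapply(seq_len(params$n_controls), function(i) {
    make(i, FALSE, sprintf("ctrl_%03d", i))
  })
  cases <- lapply(seq_len(params$n_cases), function(j) {
    make(params$n_controls + j, TRUE, sprintf("case_%03d", j))
  })
  truth <- do.call(rbind, lapply(c(controls, cases), function(s) {
    tr <- attr(s, "sim_truth")
    data.frame(sample_id = s$sample_id, ff = tr$ff, is_case = tr$is_case,
               chrom = if (tr$is_case) tr$cnv$chrom else NA_character_,
               start = if (tr$is_case) tr$cnv$start else NA_real_,
               end = if (tr$is_case) tr$cnv$end else NA_real_,
               type = if (tr$is_case) tr$cnv$type else NA_character_,
               expected_count_ratio = tr$expected_count_ratio,
               expected_fs_shift = tr$expected_fs_shift,
               stringsAsFactors = FALSE)
  }))
  list(panel = control_panel(controls), cases = cases, truth = truth,
       profiles = profiles, params = params)
}

#' Write a toy SAM file of read pairs
#'
#' Read-level emitter for alignment-parsing tests: each row of `pairs` becomes
#' two 36 bp mates with the requested starts, MAPQs and flag tweaks. Only the
#' fields the fragment extractor looks at are meaningful.
#'
#' @param path output SAM path.
#' @param pairs data.frame with columns `qname`, `chrom`, `start1`, `start2`
#'   (0-based) and optionally `mapq1`, `mapq2` (default 30), `proper`
#'   (default TRUE), `secondary` (default FALSE).
#' @param chrom_lengths named vector for the SAM header; defaults to one
#'   chromosome comfortably containing all coordinates.
#' @param read_len read length (default 36).
#' @return `path`, invisibly.
#' @export
write_toy_sam <- function(path, pairs, chrom_lengths = NULL, read_len = 36L) {
  need <- c("qname", "chrom", "start1", "start2")
  if (!all(need %in% names(pairs))) {
    fc_stop("pairs needs columns: ", paste(need, collapse = ", "))
  }
  n <- nrow(pairs)
  mapq1 <- pairs$mapq1 %||% rep(30L, n)
  mapq2 <- pairs$mapq2 %||% rep(30L, n)
  proper <- pairs$proper %||% rep(TRUE, n)
  secondary <- pairs$secondary %||% rep(FALSE, n)
  chrom_lengths <- chrom_lengths %||% {
    mx <- max(pairs$start1, pairs$start2) + read_len + 1000
    lens <- tapply(rep(mx, n), pairs$chrom, max)
    setNames(as.numeric(lens), names(lens))
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  seq1 <- paste(rep("A", read_len), collapse = "")
  qual <- paste(rep("I", read_len), collapse = "")
  recs <- character(0)
  for (r in seq_len(n)) {
    f1 <- 0x1 + 0x40 + 0x20          # paired, first, mate-reverse
    f2 <- 0x1 + 0x80 + 0x10          # paired, second, reverse
    if (proper[r]) { f1 <- f1 + 0x2; f2 <- f2 + 0x2 }
    if (secondary[r]) { f1 <- f1 + 0x100; f2 <- f2 + 0x100 }
    p1 <- pairs$start1[r] + 1L        # SAM is 1-based
    p2 <- pairs$start2[r] + 1L
    tlen <- pairs$start2[r] + read_len - pairs$start1[r]
    recs <- c(recs,
      paste(pairs$qname[r], f1, pairs$chrom[r], p1, mapq1[r],
            paste0(read_len, "M"), "=", p2, tlen, seq1, qual, sep = "\t"),
      paste(pairs$qname[r], f2, pairs$chrom[r], p2, mapq2[r],
            paste0(read_len, "M"), "=", p1, -tlen, seq1, qual, sep = "\t"))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
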