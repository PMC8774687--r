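#' Binned sample container
#'
#' The unit flowing through the pipeline: per-bin read counts plus fragment
#' size accumulators on a fixed [bin_grid()]. `fs_sum` and `fs_n` hold the sum
#' of fragment sizes and the number of size-contributing fragments per bin
#' (before any fragment-size filtering `fs_n` equals `counts`, as both derive
#' from the same fragments); `fs_mask` marks bins whose fragment-size signal is
#' considered usable.
#'
#' @param sample_id sample identifier.
#' @param grid a [bin_grid()].
#' @param counts integer fragment counts per bin.
#' @param fs_sum per-bin sum of fragment sizes (bp).
#' @param fs_n per-bin number of fragments contributing to `fs_sum`.
#' @param fs_mask per-bin logical, TRUE where the size signal is usable.
#' @return object of class `binned_sample`.
#' @export
binned_sample <- function(sample_id, grid, counts, fs_sum = NULL, fs_n = NULL,
                          fs_mask = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  nb <- grid$total_bins
  counts <- as.numeric(counts)
  if (length(counts) != nb) fc_stop("counts length does not match grid")
  fs_sum <- as.numeric(fs_sum %||% numeric(nb))
  fs_n <- as.numeric(fs_n %||% counts)
  fs_mask <- as.logical(fs_mask %||% rep(TRUE, nb))
  if (length(fs_sum) != nb || length(fs_n) != nb || length(fs_mask) != nb) {
    fc_stop("fs_sum / fs_n / fs_mask length does not match grid")
  }
  if (any(fs_sum[fs_n == 0] != 0)) fc_stop("fs_sum must be 0 where fs_n is 0")
  structure(list(sample_id = sample_id, grid = grid, counts = counts,
                 fs_sum = fs_sum, fs_n = fs_n, fs_mask = fs_mask),
            class = "binned_sample")
}

#' @export
print.binned_sample <- function(x, ...) {
  cat(sprintf("binned_sample '%s': %d bins @ %s bp, %s fragments, mean size %.1f bp\n",
              x$sample_id, x$grid$total_bins,
              format(x$grid$bin_size, big.mark = ","),
              format(sum(x$counts), big.mark = ","),
              sum(x$fs_sum) / max(1, sum(x$fs_n))))
  invisible(x)
}

#' Per-bin mean fragment size
#'
#' `fs_sum / fs_n`, defined only where `fs_n > 0` (NA elsewhere). This is the
#' per-region summary statistic used by the fragment-size arm of the pipeline.
#'
#' @param bs a [binned_sample()].
#' @return numeric vector, one value per bin.
#' @export
fs_mean <- function(bs) {
  out <- rep(NA_real_, length(bs$fs_n))
  ok <- bs$fs_n > 0
  out[ok] <- bs$fs_sum[ok] / bs$fs_n[ok]
  out
}

#' Assign fragments to bins
#'
#' Each fragment increments exactly one bin, chosen by its midpoint
#' (floor division by the bin size; bins are half-open, so a midpoint equal to
#' a bin boundary belongs to the right-hand bin). The fragment's size is
#' accumulated into the same bin's `fs_sum`/`fs_n`. Fragments on chromosomes
#' absent from the grid are dropped with a warning count; a midpoint at or
#' beyond the chromosome length indicates corrupt input and is an error.
#'
#' @param fragments fragment table (`chrom`, `midpoint`, `size`).
#' @param grid a [bin_grid()].
#' @param sample_id sample identifier for the result.
#' @return a [binned_sample()]; attribute `binning_stats` counts dropped
#'   off-grid fragments.
#' @export
bin_fragments <- function(fragments, grid, sample_id = "sample") {
  stopifnot(inherits(grid, "bin_grid"))
  ci <- match(fragments$chrom, grid$chroms)
  off <- is.na(ci)
  if (any(off)) {
    warning(sum(off), " fragment(s) on chromosomes outside the grid were dropped")
  }
  mid <- fragments$midpoint[!off]
  size <- fragments$size[!off]
  ci <- ci[!off]
  if (length(mid) && any(mid < 0 | mid >= grid$lengths[ci])) {
    bad <- which(mid < 0 | mid >= grid$lengths[ci])[1L]
    fc_stop(sprintf("fragment midpoint %d outside chromosome %s (length %d): corrupt input",
                    as.integer(mid[bad]), grid$chroms[ci[bad]],
                    as.integer(grid$lengths[ci[bad]])))
  }
  idx <- grid$offset[ci] + mid %/% grid$bin_size + 1L
  nb <- grid$total_bins
  counts <- tabulate(idx, nbins = nb)
  fs_sum <- numeric(nb)
  if (length(idx)) {
    agg <- rowsum(as.numeric(size), idx)
    fs_sum[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out <- binned_sample(sample_id, grid, counts, fs_sum = fs_sum, fs_n = counts)
  attr(out, "binning_stats") <- c(input = nrow(fragments),
                                  off_grid = sum(off),
                                  assigned = length(idx))
  out
}

#' Aggregate a binned sample to a coarser grid
#'
#' Sums `counts`, `fs_sum` and `fs_n` of consecutive fine bins into each target
#' bin, per chromosome. The target bin size must be a multiple of the current
#' one; per-chromosome totals are conserved. The fragment-size mask is reset to
#' TRUE: [fs_region_filter()] is meant to run at the analysis scale.
#'
#' @param bs a [binned_sample()].
#' @param target_bin_size target width in bp.
#' @return a [binned_sample()] on the coarser grid.
#' @export
aggregate_bins <- function(bs, target_bin_size) {
  stopifnot(inherits(bs, "binned_sample"))
  cur <- bs$grid$bin_size
  if (target_bin_size == cur) return(bs)
  if (!is_count(target_bin_size) || target_bin_size %% cur != 0) {
    fc_stop("target bin size (", target_bin_size,
            ") must be a multiple of the current bin size (", cur, ")")
  }
  factor <- target_bin_size / cur
  new_grid <- bin_grid(bs$grid$lengths, target_bin_size)
  local <- unlist(lapply(bs$grid$n_bins, function(n) (seq_len(n) - 1L) %/% factor),
                  use.names = FALSE)
  ci <- grid_chrom_id(bs$grid)
  idx <- new_grid$offset[ci] + local + 1L
  agg <- function(v) {
    out <- numeric(new_grid$total_bins)
    a <- rowsum(v, idx)
    out[as.integer(rownames(a))] <- a[, 1L]
    out
  }
  binned_sample(bs$sample_id, new_grid, agg(bs$counts),
                fs_sum = agg(bs$fs_sum), fs_n = agg(bs$fs_n))
}

#' Per-sample fragment-size reliability filter
#'
#' Marks bins whose fragment-size estimate is unreliable: too few fragments
#' (`fs_n < min_frags`), or anomalously high coverage — the bin's normalized
#' count exceeding the sample's cross-bin mean by more than `max_cov_z`
#' standard deviations (piled-up repetitive bins carry distorted size
#' distributions). Counts are untouched; only `fs_mask` changes. The defaults
#' (`min_frags = 10`, `max_cov_z = 3`) are package choices, exposed in the
#' configuration.
#'
#' @param bs a [binned_sample()] at an analysis scale.
#' @param min_frags minimum fragments per bin for a usable size estimate.
#' @param max_cov_z upper bound, in SD units of normalized coverage.
#' @return the sample with `fs_mask` updated; attribute `fs_filter_stats`.
#' @export
fs_region_filter <- function(bs, min_frags = 10, max_cov_z = 3) {
  stopifnot(inherits(bs, "binned_sample"))
  total <- sum(bs$counts)
  if (total <= 0) fc_stop("sample has zero total count")
  norm <- bs$counts / total
  s <- sd(norm)
  covz <- if (is.finite(s) && s > 0) (norm - mean(norm)) / s else numeric(length(norm))
  mask <- bs$fs_n >= min_frags & covz <= max_cov_z
  out <- bs
  out$fs_mask <- mask
  attr(out, "fs_filter_stats") <- c(
    low_count = sum(bs$fs_n < min_frags),
    high_coverage = sum(covz > max_cov_z),
    usable = sum(mask)
  )
  out
}

#' Save / load a binned sample archive
#'
#' Serialized single-sample archive with a versioned header including the grid
#' hash, so that references and queries can be checked for grid compatibility.
#'
#' @param bs a [binned_sample()].
#' @param path file path (RDS).
#' @export
save_binned_sample <- function(bs, path) {
  stopifnot(inherits(bs, "binned_sample"))
  saveRDS(list(format = "fragcnv.binned_sample", version = 1L,
               grid_hash = bs$grid$hash, sample = bs), path)
  invisible(path)
}

#' @rdname save_binned_sample
#' @export
load_binned_sample <- function(path) {
  if (!file.exists(path)) fc_stop("binned sample archive not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "fragcnv.binned_sample")) {
    fc_stop("not a fragcnv binned sample archive: ", path)
  }
  obj$sample
}
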