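#' Within-sample Z-scores against a neighbor list
#'
#' For each query bin, the observation is judged against the weighted mean and
#' weighted standard deviation of the *same sample's* observations in the
#' bin's reference neighbors (bins on other chromosomes selected during
#' reference construction): `Z_q = (x_q - mu_w) / sigma_w`. Neighbor
#' observations that are NA in this sample drop out and the remaining weights
#' are renormalized; bins whose neighbor spread is (numerically) zero, or
#' whose own observation is NA, are invalidated.
#'
#' @param x full-grid numeric vector of bias-corrected observations.
#' @param neighbors a [build_neighbors()] list.
#' @return full-grid numeric vector of Z-scores (NA where invalid).
#' @export
within_sample_z <- function(x, neighbors) {
  nb <- neighbors
  nq <- length(nb$query_idx)
  X <- matrix(x[nb$idx], nrow = nq)
  W <- nb$w
  W[is.na(X)] <- 0
  X[is.na(X)] <- 0
  wsum <- rowSums(W)
  ok <- wsum > 0
  W[ok, ] <- W[ok, , drop = FALSE] / wsum[ok]
  mu <- rowSums(W * X)
  sig <- sqrt(rowSums(W * (X - mu)^2))
  xq <- x[nb$query_idx]
  z <- (xq - mu) / sig
  z[!ok | !is.finite(z) | sig < 1e-12] <- NA_real_
  out <- rep(NA_real_, length(x))
  out[nb$query_idx] <- z
  out
}

#' Orient fragment-size Z-scores
#'
#' Raw fragment-size Z is positive when fragments are *longer* than expected.
#' Copy-number gains raise the local fetal content, and fetal fragments are
#' shorter, so gains push the raw score negative. Flipping the sign makes the
#' fragment-size track concordant with the read-count track (gains positive).
#'
#' @param z_fs_raw numeric vector of raw fragment-size Z-scores.
#' @return oriented Z-scores (`-z_fs_raw`).
#' @export
orient_fs <- function(z_fs_raw) -z_fs_raw

#' Combine read-count and fragment-size Z-scores
#'
#' Per-bin combination of the two concordantly oriented tracks.
#' `"fisher"` (default) combines the one-sided upper-tail p-values with
#' Fisher's method (`X = -2(ln p_rc + ln p_fs)`, chi-square with 4 df) and
#' maps the combined tail probability back to a standard-normal quantile; the
#' lower tail is combined symmetrically and the combined Z takes the sign of
#' the stronger oriented evidence (exact ties resolve to the gain
#' orientation). `"stouffer"` uses
#' `(z_rc + z_fs) / sqrt(2)`. Bins where only one datatype is valid inherit
#' that datatype's Z; bins with neither stay NA.
#'
#' @param z_rc read-count Z-scores.
#' @param z_fs oriented fragment-size Z-scores (see [orient_fs()]).
#' @param method `"fisher"` or `"stouffer"`.
#' @return combined Z-score vector.
#' @export
combine_z <- function(z_rc, z_fs, method = c("fisher", "stouffer")) {
  method <- match.arg(method)
  if (length(z_rc) != length(z_fs)) fc_stop("track length mismatch")
  out <- rep(NA_real_, length(z_rc))
  both <- !is.na(z_rc) & !is.na(z_fs)
  only_rc <- !is.na(z_rc) & is.na(z_fs)
  only_fs <- is.na(z_rc) & !is.na(z_fs)
  out[only_rc] <- z_rc[only_rc]
  out[only_fs] <- z_fs[only_fs]
  if (any(both)) {
    a <- z_rc[both]
    b <- z_fs[both]
    if (method == "stouffer") {
      out[both] <- (a + b) / sqrt(2)
    } else {
      z_gain <- fisher_tail(a, b, upper = TRUE)
      z_loss <- fisher_tail(a, b, upper = FALSE)
      out[both] <- ifelse(z_gain >= z_loss, z_gain, -z_loss)
    }
  }
  out
}

# One-sided Fisher combination in log space; returns the standard-normal
# quantile of the combined tail probability (large = strong evidence in the
# requested tail).
fisher_tail <- function(za, zb, upper = TRUE) {
  lp_a <- pnorm(za, lower.tail = !upper, log.p = TRUE)
  lp_b <- pnorm(zb, lower.tail = !upper, log.p = TRUE)
  X <- -2 * (lp_a + lp_b)
  lp <- pchisq(X, df = 4, lower.tail = FALSE, log.p = TRUE)
  qnorm(lp, lower.tail = FALSE, log.p = TRUE)
}

#' Score a query sample against a reference set
#'
#' Produces the three per-bin Z-score tracks of a query:
#' \enumerate{
#'   \item read counts are normalized over the reference's global mask,
#'     bias-corrected with the stored read-count model, and scored against the
#'     read-count neighbor lists;
#'   \item per-bin mean fragment sizes are bias-corrected with the
#'     fragment-size model and scored against the fragment-size neighbor
#'     lists; the query-side reliability filter ([fs_region_filter()], with
#'     the thresholds stored in the reference) invalidates unreliable bins,
#'     and the raw Z is sign-flipped via [orient_fs()];
#'   \item the tracks are combined per bin with [combine_z()]; bins valid for
#'     read count only fall back to the read-count Z.
#' }
#'
#' @param sample a [binned_sample()] on the reference grid.
#' @param ref a [build_reference_set()] result.
#' @param combine `"fisher"` (default) or `"stouffer"`.
#' @return object of class `ztrack`: a data.frame with `chrom`, `start`,
#'   `end`, `z_rc`, `z_fs`, `z_comb` and validity flags, plus the grid as an
#'   attribute.
#' @export
score_sample <- function(sample, ref, combine = c("fisher", "stouffer")) {
  combine <- match.arg(combine)
  stopifnot(inherits(sample, "binned_sample"), inherits(ref, "reference_set"))
  if (!identical(sample$grid$hash, ref$grid$hash)) {
    fc_stop("grid mismatch between sample (", sample$grid$hash,
            ") and reference (", ref$grid$hash,
            "); re-bin the sample at the reference's bin size")
  }
  rc_obs <- apply_bias_correction(
    normalize_counts(sample$counts, ref$global_mask),
    ref$models$read_count
  )
  z_rc <- within_sample_z(rc_obs, ref$neighbors$read_count)

  flt <- fs_region_filter(sample, min_frags = ref$params$fs_min_frags,
                          max_cov_z = ref$params$fs_max_cov_z)
  fsv <- fs_mean(flt)
  fs_obs <- apply_bias_correction(fsv, ref$models$fragment_size)
  z_fs_raw <- within_sample_z(fs_obs, ref$neighbors$fragment_size)
  z_fs_raw[!flt$fs_mask] <- NA_real_
  z_fs <- orient_fs(z_fs_raw)

  z_comb <- combine_z(z_rc, z_fs, method = combine)
  bins <- grid_bins(ref$grid)
  out <- data.frame(
    bins,
    z_rc = z_rc, z_fs = z_fs, z_comb = z_comb,
    valid_rc = !is.na(z_rc), valid_fs = !is.na(z_fs),
    valid = !is.na(z_comb),
    stringsAsFactors = FALSE
  )
  attr(out, "grid") <- ref$grid
  attr(out, "combine") <- combine
  class(out) <- c("ztrack", "data.frame")
  out
}

#' Aggregate a segment's bin Z-scores into a segment Z-score
#'
#' Stouffer aggregation over the segment's `m` valid bins:
#' `Z_seg = sum(z_i) / sqrt(m)`. Returns NA for a segment without valid bins
#' (such segments are dropped from event calling).
#'
#' @param z numeric vector of the segment's per-bin Z-scores (NA = invalid).
#' @return single numeric segment Z.
#' @export
score_segment <- function(z) {
  z <- z[!is.na(z)]
  if (!length(z)) return(NA_real_)
  sum(z) / sqrt(length(z))
}

#' Segment a Z-score track
#'
#' Runs [cbs_segment()] chromosome by chromosome on the valid bins of the
#' chosen track and scores every segment with [score_segment()]. Segment
#' genomic bounds span from the start of its first valid bin to the end of
#' its last valid bin.
#'
#' @param ztrack a [score_sample()] result.
#' @param track `"combined"`, `"rc"` or `"fs"`.
#' @param alpha,n_perm,min_bins,seed see [cbs_segment()].
#' @return data.frame of segments: `chrom`, `start`, `end`, `n_bins`,
#'   `z_segment`.
#' @export
segment_ztrack <- function(ztrack, track = c("combined", "rc", "fs"),
                           alpha = 0.01, n_perm = 1000L, min_bins = 2L,
                           seed = 1L) {
  track <- match.arg(track)
  zcol <- switch(track, combined = "z_comb", rc = "z_rc", fs = "z_fs")
  res <- list()
  for (ch in unique(ztrack$chrom)) {
    rows <- which(ztrack$chrom == ch & !is.na(ztrack[[zcol]]))
    if (!length(rows)) next
    z <- ztrack[[zcol]][rows]
    segs <- cbs_segment(z, alpha = alpha, n_perm = n_perm,
                        min_bins = min_bins, seed = seed)
    if (!nrow(segs)) next
    res[[ch]] <- data.frame(
      chrom = ch,
      start = ztrack$start[rows[segs$start_idx]],
      end = ztrack$end[rows[segs$end_idx]],
      n_bins = segs$n_bins,
      z_segment = vapply(seq_len(nrow(segs)), function(r) {
        score_segment(z[segs$start_idx[r]:segs$end_idx[r]])
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_bins = integer(), z_segment = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Call events from scored segments
#'
#' Two published operating points:
#' \describe{
#'   \item{mode I}{segments spanning more than 10 Mb with `Z >= 5`
#'     (gains only).}
#'   \item{mode II}{segments spanning more than 1 Mb with `|Z| >= 5`
#'     (gains and losses).}
#' }
#'
#' @param segments data.frame from [segment_ztrack()].
#' @param mode `"I"` or `"II"`.
#' @param z_min Z-score threshold (default 5).
#' @param span_min_I,span_min_II span thresholds in bp.
#' @return data.frame of events: `chrom`, `start`, `end`, `n_bins`,
#'   `direction` (`"gain"`/`"loss"`), `z_segment`.
#' @export
call_events <- function(segments, mode = c("I", "II"), z_min = 5,
                        span_min_I = 10e6, span_min_II = 1e6) {
  mode <- match.arg(mode)
  segments <- segments[!is.na(segments$z_segment), , drop = FALSE]
  span <- segments$end - segments$start
  keep <- if (mode == "I") {
    span > span_min_I & segments$z_segment >= z_min
  } else {
    span > span_min_II & abs(segments$z_segment) >= z_min
  }
  ev <- segments[keep, , drop = FALSE]
  ev$direction <- ifelse(ev$z_segment >= 0, "gain", "loss")
  rownames(ev) <- NULL
  ev[, c("chrom", "start", "end", "n_bins", "direction", "z_segment")]
}

#' Score, segment and call a query sample
#'
#' Full calling stage: [score_sample()], [segment_ztrack()] on the requested
#' track, [call_events()].
#'
#' @param sample a [binned_sample()] on the reference grid.
#' @param ref a [build_reference_set()] result.
#' @param mode event mode, `"I"` (default) or `"II"`.
#' @param combine per-bin combination method, `"fisher"` or `"stouffer"`.
#' @param track which track drives segmentation and calling (default
#'   `"combined"`; `"rc"`/`"fs"` give the single-signal variants, with the
#'   same thresholds applied to that track).
#' @param alpha,n_perm,min_bins,seed segmentation parameters.
#' @return object of class `cnv_result`: `ztrack`, `segments`, `events`, and
#'   the parameter list (including the seed).
#' @export
predict_sample <- function(sample, ref, mode = c("I", "II"),
                           combine = c("fisher", "stouffer"),
                           track = c("combined", "rc", "fs"),
                           alpha = 0.01, n_perm = 1000L, min_bins = 2L,
                           seed = 1L) {
  mode <- match.arg(mode)
  combine <- match.arg(combine)
  track <- match.arg(track)
  zt <- score_sample(sample, ref, combine = combine)
  segs <- segment_ztrack(zt, track = track, alpha = alpha, n_perm = n_perm,
                         min_bins = min_bins, seed = seed)
  ev <- call_events(segs, mode = mode)
  structure(list(
    sample_id = sample$sample_id,
    ztrack = zt, segments = segs, events = ev,
    params = list(mode = mode, combine = combine, track = track,
                  alpha = alpha, n_perm = as.integer(n_perm),
                  min_bins = as.integer(min_bins), seed = as.integer(seed))
  ), class = "cnv_result")
}

#' @export
print.cnv_result <- function(x, ...) {
  cat(sprintf("cnv_result '%s': %d segments, %d event(s) [mode %s, %s, track %s]\n",
              x$sample_id, nrow(x$segments), nrow(x$events),
              x$params$mode, x$params$combine, x$params$track))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Write a Z-score track as bedGraph
#'
#' @param ztrack a [score_sample()] result.
#' @param column one of `"z_rc"`, `"z_fs"`, `"z_comb"`.
#' @param path output file.
#' @export
write_bedgraph <- function(ztrack, column, path) {
  stopifnot(column %in% c("z_rc", "z_fs", "z_comb"))
  keep <- !is.na(ztrack[[column]])
  df <- data.frame(ztrack$chrom[keep], as.integer(ztrack$start[keep]),
                   as.integer(ztrack$end[keep]),
                   signif(ztrack[[column]][keep], 6))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write called events as BED-compatible TSV
#'
#' Columns: chrom, start, end, direction, z_segment, n_bins.
#'
#' @param events event table from [call_events()].
#' @param path output file.
#' @export
write_events <- function(events, path) {
  df <- events[, c("chrom", "start", "end", "direction", "z_segment", "n_bins")]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$z_segment <- signif(df$z_segment, 6)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
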