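# Circular binary segmentation on a per-chromosome score vector.
#
# Each segment under consideration is treated as a circle: the best arc
# (i, j], 0 <= i < j <= n, maximizes the standardized difference between the
# arc mean and the mean of its complement,
#   T(i, j) = |mean_arc - mean_rest| / (s * sqrt(1/n_arc + 1/n_rest)),
# with s the segment's overall SD (permutation-invariant, so it cancels in the
# permutation test but keeps T on an interpretable scale). A candidate split
# is accepted when its permutation p-value (1 + #exceedances) / (1 + n_perm)
# is below alpha; accepted splits cut the segment at i and j and recursion
# continues on the pieces. Every piece a split creates must have at least
# min_bins bins.
#
# Determinism: the permutations for the segment spanning positions [lo, hi]
# (1-based, within the vector passed to cbs_segment with master seed `seed`)
# are drawn after set.seed(cbs_perm_seed(seed, lo, hi)). Early termination
# (stopping once the p-value can no longer drop below alpha) never changes
# the accept/reject decision.

#' Best circular arc of a segment
#'
#' Exhaustively scans all arcs (i, j] whose induced pieces all have at least
#' `min_bins` bins and returns the maximizer of the standardized
#' mean-difference statistic. Returns NULL when the segment is too short to
#' split or has zero variance. Ties go to the smallest (i, j).
#'
#' @param x numeric segment values.
#' @param min_bins minimum piece size.
#' @return list(i, j, stat) with 0-based cut positions, or NULL.
#' @keywords internal
#' @export
cbs_max_arc <- function(x, min_bins = 2L) {
  n <- length(x)
  if (n < 2L * min_bins) return(NULL)
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12) return(NULL)
  S <- c(0, cumsum(x))
  tot <- S[n + 1L]
  best_stat <- -Inf
  best_i <- best_j <- NA_integer_
  for (i in c(0L, seq.int(min_bins, n - min_bins))) {
    j_hi <- n - min_bins
    js <- if (j_hi >= i + min_bins) seq.int(i + min_bins, j_hi) else integer(0)
    if (i >= min_bins && n - i >= min_bins) js <- c(js, n)
    js <- js[!(i == 0L & js == n)]
    if (!length(js)) next
    a <- js - i
    arc_sum <- S[js + 1L] - S[i + 1L]
    m_arc <- arc_sum / a
    m_rest <- (tot - arc_sum) / (n - a)
    stat <- abs(m_arc - m_rest) / (s * sqrt(1 / a + 1 / (n - a)))
    k <- which.max(stat)
    if (stat[k] > best_stat + 1e-12) {
      best_stat <- stat[k]
      best_i <- i
      best_j <- js[k]
    }
  }
  if (!is.finite(best_stat)) return(NULL)
  list(i = best_i, j = best_j, stat = best_stat)
}

#' Permutation seed for a CBS segment
#'
#' Part of the segmentation contract (so independent re-implementations can
#' reproduce decisions): the RNG for the split test of the segment covering
#' positions `lo..hi` of the input vector is seeded with this value.
#'
#' @param seed master seed of the [cbs_segment()] call.
#' @param lo,hi 1-based segment bounds within the input vector.
#' @keywords internal
#' @export
cbs_perm_seed <- function(seed, lo, hi) {
  as.integer(((as.numeric(seed) %% 1e6) * 1000003 + lo * 1009 + hi) %%
               2147483646 + 1)
}

# Permutation acceptance test; TRUE = split is significant at alpha.
cbs_split_accept <- function(x, obs_stat, alpha, n_perm, perm_seed, min_bins) {
  set.seed(perm_seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    xp <- sample(x)
    arc <- cbs_max_arc(xp, min_bins)
    st <- if (is.null(arc)) 0 else arc$stat
    if (st >= obs_stat - 1e-12) count <- count + 1L
    if ((1 + count) / (1 + n_perm) >= alpha) return(FALSE)
  }
  (1 + count) / (1 + n_perm) < alpha
}

#' Circular binary segmentation
#'
#' Recursively segments a per-bin score vector (one chromosome, valid bins
#' only). At each step the best circular arc is found exhaustively; the split
#' is kept if its permutation p-value is below `alpha`, and recursion
#' continues on the resulting pieces until no split is accepted or pieces
#' would fall below `min_bins`. The result is a contiguous, non-overlapping
#' partition of `1..length(x)`.
#'
#' @param x numeric vector of per-bin scores (finite).
#' @param alpha significance level for a split (default 0.01).
#' @param n_perm permutations per split test (default 1000).
#' @param min_bins minimum bins per segment (default 2).
#' @param seed master seed; per-segment permutation streams are derived via
#'   [cbs_perm_seed()].
#' @return data.frame with 1-based inclusive `start_idx`, `end_idx`, `n_bins`,
#'   `mean`, ordered left to right.
#' @examples
#' z <- c(rnorm(30), rnorm(30, mean = 5))
#' cbs_segment(z, n_perm = 200, seed = 7)
#' @export
cbs_segment <- function(x, alpha = 0.01, n_perm = 1000L, min_bins = 2L, seed = 1L) {
  n <- length(x)
  if (n == 0L) {
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      n_bins = integer(), mean = numeric()))
  }
  if (any(!is.finite(x))) fc_stop("cbs_segment requires finite values")
  done <- list()
  queue <- list(c(1L, n))
  while (length(queue)) {
    seg <- queue[[1L]]
    queue <- queue[-1L]
    lo <- seg[1L]; hi <- seg[2L]
    xs <- x[lo:hi]
    arc <- cbs_max_arc(xs, min_bins)
    split <- FALSE
    if (!is.null(arc) && arc$stat > 0) {
      ps <- cbs_perm_seed(seed, lo, hi)
      if (cbs_split_accept(xs, arc$stat, alpha, n_perm, ps, min_bins)) {
        cuts <- unique(c(0L, arc$i, arc$j, hi - lo + 1L))
        cuts <- sort(cuts)
        pieces <- Map(function(a, b) c(lo + a, lo + b - 1L),
                      cuts[-length(cuts)], cuts[-1L])
        queue <- c(pieces, queue)
        split <- TRUE
      }
    }
    if (!split) done[[length(done) + 1L]] <- seg
  }
  m <- do.call(rbind, done)
  m <- m[order(m[, 1L]), , drop = FALSE]
  data.frame(start_idx = m[, 1L], end_idx = m[, 2L],
             n_bins = m[, 2L] - m[, 1L] + 1L,
             mean = vapply(seq_len(nrow(m)),
                           function(r) mean(x[m[r, 1L]:m[r, 2L]]), numeric(1)))
}
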