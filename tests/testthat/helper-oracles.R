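# Independent oracles used to freeze expected values. These deliberately
# reimplement the contracts with naive code (loops, direct formulas) and must
# stay decoupled from the package internals they check.

# --- Fisher combination oracle: direct chi-square tail computation ----------
oracle_fisher <- function(za, zb) {
  gain <- function(a, b) {
    X <- -2 * (log(pnorm(a, lower.tail = FALSE)) +
                 log(pnorm(b, lower.tail = FALSE)))
    qnorm(pchisq(X, df = 4, lower.tail = FALSE), lower.tail = FALSE)
  }
  zg <- gain(za, zb)
  zl <- gain(-za, -zb)
  if (zg >= zl) zg else -zl
}

# --- weighted mean / SD oracle ----------------------------------------------
oracle_weighted_z <- function(xq, xr, w) {
  w <- w / sum(w)
  mu <- sum(w * xr)
  sig <- sqrt(sum(w * (xr - mu)^2))
  (xq - mu) / sig
}

# --- brute-force neighbor ranking oracle ------------------------------------
# Exhaustive distance sort over all candidate bins on other chromosomes.
oracle_neighbors <- function(profiles, bin_idx, chrom_id, K) {
  n <- nrow(profiles)
  lapply(seq_len(n), function(q) {
    cand <- which(chrom_id != chrom_id[q])
    d <- vapply(cand, function(r) sqrt(sum((profiles[q, ] - profiles[r, ])^2)),
                numeric(1))
    ord <- order(d, bin_idx[cand])
    sel <- head(ord, K)
    list(idx = bin_idx[cand][sel], d = d[sel])
  })
}

# --- brute-force CBS oracle --------------------------------------------------
# Naive double-loop arc scan and recursive segmentation with the same
# acceptance test; the permutation stream per segment follows the documented
# contract (seeded with cbs_perm_seed(seed, lo, hi)).
oracle_max_arc <- function(x, min_bins) {
  n <- length(x)
  if (n < 2L * min_bins) return(NULL)
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12) return(NULL)
  best <- NULL
  for (i in 0:(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- j - i
      r <- n - a
      if (a < min_bins || r < min_bins) next
      if (i > 0L && i < min_bins) next
      if (n - j > 0L && n - j < min_bins) next
      arc <- x[(i + 1L):j]
      rest <- x[-((i + 1L):j)]
      st <- abs(mean(arc) - mean(rest)) / (s * sqrt(1 / a + 1 / r))
      if (is.null(best) || st > best$stat + 1e-12) {
        best <- list(i = i, j = j, stat = st)
      }
    }
  }
  best
}

oracle_cbs <- function(x, alpha, n_perm, min_bins, seed) {
  rec <- function(lo, hi) {
    xs <- x[lo:hi]
    arc <- oracle_max_arc(xs, min_bins)
    if (!is.null(arc) && arc$stat > 0) {
      set.seed(cbs_perm_seed(seed, lo, hi))
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        pa <- oracle_max_arc(sample(xs), min_bins)
        if (!is.null(pa) && pa$stat >= arc$stat - 1e-12) cnt <- cnt + 1L
      }
      if ((1 + cnt) / (1 + n_perm) < alpha) {
        cuts <- sort(unique(c(0L, arc$i, arc$j, hi - lo + 1L)))
        out <- NULL
        for (k in seq_len(length(cuts) - 1L)) {
          out <- rbind(out, rec(lo + cuts[k], lo + cuts[k + 1L] - 1L))
        }
        return(out)
      }
    }
    matrix(c(lo, hi), nrow = 1L)
  }
  m <- rec(1L, length(x))
  m[order(m[, 1L]), , drop = FALSE]
}

# Exhaustive single-changepoint oracle: best split of x into a left and right
# piece by the two-sample statistic.
oracle_single_changepoint <- function(x) {
  n <- length(x)
  stats <- vapply(1:(n - 1L), function(k) {
    a <- x[1:k]; b <- x[(k + 1L):n]
    abs(mean(a) - mean(b)) / (sd(x) * sqrt(1 / k + 1 / (n - k)))
  }, numeric(1))
  which.max(stats)
}
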