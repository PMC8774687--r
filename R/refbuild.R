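#' Control panel of binned samples
#'
#' A set of negative-control samples on one shared grid, used to train the
#' global mask, the per-datatype bias models, and the within-sample reference.
#'
#' @param samples list of [binned_sample()] objects on identical grids.
#' @return object of class `control_panel`.
#' @export
control_panel <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L) {
    fc_stop("a control panel needs at least 2 samples")
  }
  if (!all(vapply(samples, inherits, logical(1), "binned_sample"))) {
    fc_stop("all panel members must be binned_sample objects")
  }
  hashes <- vapply(samples, function(s) s$grid$hash, character(1))
  if (length(unique(hashes)) != 1L) {
    fc_stop("panel samples are on different grids (grid hash mismatch)")
  }
  structure(list(samples = samples, grid = samples[[1L]]$grid,
                 n_controls = length(samples)),
            class = "control_panel")
}

#' @export
print.control_panel <- function(x, ...) {
  cat(sprintf("control_panel: %d samples on %d bins @ %s bp\n",
              x$n_controls, x$grid$total_bins,
              format(x$grid$bin_size, big.mark = ",")))
  invisible(x)
}

#' Normalize read counts within a sample
#'
#' Divides each count by the total count over unmasked bins, so values sum to
#' one over the unmasked genome; masked bins are set to NA. Doubling all counts
#' leaves the result unchanged.
#'
#' @param counts numeric count vector, or a [binned_sample()].
#' @param mask logical keep-mask (TRUE = unmasked); default all bins.
#' @return numeric vector of normalized coverage.
#' @export
normalize_counts <- function(counts, mask = NULL) {
  if (inherits(counts, "binned_sample")) counts <- counts$counts
  mask <- mask %||% rep(TRUE, length(counts))
  if (length(mask) != length(counts)) fc_stop("mask length mismatch")
  total <- sum(counts[mask])
  if (!is.finite(total) || total <= 0) fc_stop("zero total count over unmasked bins")
  out <- counts / total
  out[!mask] <- NA_real_
  out
}

#' Global bin mask from a control panel
#'
#' Uninformative bins (typically centromeric/repetitive, where too few reads
#' align) are identified from the controls' normalized read counts: a bin is
#' masked when its median normalized coverage falls below `mask_min_frac`
#' times the genome-wide median, or when it has zero counts in more than
#' `mask_zero_frac` of the controls. Deterministic given the panel.
#'
#' @param panel a [control_panel()].
#' @param mask_min_frac fraction of the genome-wide median coverage below
#'   which a bin is masked (default 0.1).
#' @param mask_zero_frac maximum tolerated fraction of zero-count controls
#'   (default 0.1).
#' @return logical vector, TRUE = bin kept.
#' @export
build_global_mask <- function(panel, mask_min_frac = 0.1, mask_zero_frac = 0.1) {
  stopifnot(inherits(panel, "control_panel"))
  N <- vapply(panel$samples, function(s) normalize_counts(s$counts),
              numeric(panel$grid$total_bins))
  med <- apply(N, 1L, median)
  genome_med <- median(med)
  zero_frac <- rowMeans(vapply(panel$samples, function(s) s$counts == 0,
                               logical(panel$grid$total_bins)))
  med >= mask_min_frac * genome_med & zero_frac <= mask_zero_frac
}

#' Fit a per-datatype PCA bias model on control samples
#'
#' Technical bias shared across samples (GC content and friends) shows up as a
#' low-rank structure in the controls' bin profiles. The model stores the
#' column means and the top `n_comp` principal components of the
#' samples-by-bins control matrix over the model's bin mask; correction
#' removes the sample's projection onto that subspace.
#'
#' For `datatype = "read_count"` the matrix holds normalized counts
#' (normalized over the mask); for `"fragment_size"` it holds per-bin mean
#' fragment sizes, and bins where any control has `fs_n = 0` must already be
#' excluded from `mask` by the caller.
#'
#' @param panel a [control_panel()].
#' @param datatype `"read_count"` or `"fragment_size"`.
#' @param n_comp number of principal components (default 5); must be smaller
#'   than the number of controls. `n_comp = 0` yields a mean-only model.
#' @param mask logical keep-mask defining the model's bins.
#' @return object of class `bias_model` with fields `datatype`, `mask`,
#'   `mean` (per masked bin), `components` (masked bins x n_comp, orthonormal
#'   columns), `n_comp`, `grid_hash`.
#' @export
fit_bias_model <- function(panel, datatype = c("read_count", "fragment_size"),
                           n_comp = 5L, mask = NULL) {
  stopifnot(inherits(panel, "control_panel"))
  datatype <- match.arg(datatype)
  nb <- panel$grid$total_bins
  mask <- mask %||% rep(TRUE, nb)
  if (!is_count(n_comp)) fc_stop("n_comp must be a non-negative integer")
  if (n_comp >= panel$n_controls) {
    fc_stop("n_comp (", n_comp, ") must be smaller than the number of controls (",
            panel$n_controls, ")")
  }
  X <- panel_matrix(panel, datatype, mask)
  if (anyNA(X)) {
    fc_stop("NA in ", datatype, " control matrix; for fragment_size the mask ",
            "must exclude bins with fs_n = 0 in any control")
  }
  mu <- colMeans(X)
  comps <- matrix(numeric(0), nrow = ncol(X), ncol = 0L)
  if (n_comp > 0L) {
    pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_comp)
    comps <- pc$rotation[, seq_len(min(n_comp, ncol(pc$rotation))), drop = FALSE]
  }
  structure(list(datatype = datatype, mask = mask, mean = mu,
                 components = comps, n_comp = ncol(comps),
                 grid_hash = panel$grid$hash),
            class = "bias_model")
}

# samples x masked-bins matrix of the given datatype.
panel_matrix <- function(panel, datatype, mask) {
  rows <- lapply(panel$samples, function(s) {
    if (datatype == "read_count") {
      normalize_counts(s$counts, mask)[mask]
    } else {
      fs_mean(s)[mask]
    }
  })
  do.call(rbind, rows)
}

#' Apply a bias model to a sample vector
#'
#' Centers the vector with the model mean, removes its projection onto the
#' component subspace, and adds the mean back, preserving signal orthogonal to
#' the learned bias directions. NA entries (e.g. bins without a fragment-size
#' estimate in the query) are mean-imputed for the projection and restored to
#' NA afterwards.
#'
#' @param x full-grid numeric vector for the model's datatype.
#' @param model a [fit_bias_model()] result.
#' @return full-grid numeric vector; bins outside the model mask are NA.
#' @export
apply_bias_correction <- function(x, model) {
  stopifnot(inherits(model, "bias_model"))
  if (length(x) != length(model$mask)) {
    fc_stop("vector length (", length(x), ") does not match the model grid (",
            length(model$mask), " bins)")
  }
  v <- x[model$mask]
  na <- is.na(v)
  cen <- ifelse(na, 0, v - model$mean)
  if (model$n_comp > 0L) {
    proj <- model$components %*% crossprod(model$components, cen)
    cen <- cen - as.vector(proj)
  }
  corr <- model$mean + cen
  corr[na] <- NA_real_
  out <- rep(NA_real_, length(x))
  out[model$mask] <- corr
  out
}

#' Within-sample neighbor lists for one datatype
#'
#' For every query bin, candidate reference bins are all model-mask bins on
#' *other* chromosomes. The distance between a query bin and a candidate is
#' the Euclidean distance between their across-control profiles
#' (bias-corrected), and the `K` nearest candidates become the bin's reference
#' set, weighted by inverse distance (`w ~ 1/(d + eps)`, normalized to sum 1).
#' Ties are broken by lower global bin index; if fewer than `K` candidates
#' exist, all are kept with a warning.
#'
#' @param profiles matrix of bias-corrected control profiles, masked bins in
#'   rows, controls in columns.
#' @param bin_idx global bin index of each row.
#' @param chrom_id chromosome id of each row.
#' @param K neighbors per query bin (default 300).
#' @param eps additive constant in the inverse-distance weights.
#' @return list with `query_idx` (global indices), `idx` (rows x K global
#'   neighbor indices, NA-padded), `w` (weights, rows sum to 1), `n_nb`
#'   (neighbors actually available), `K`.
#' @export
build_neighbors <- function(profiles, bin_idx, chrom_id, K = 300L, eps = 1e-9) {
  stopifnot(is.matrix(profiles), nrow(profiles) == length(bin_idx),
            length(bin_idx) == length(chrom_id))
  if (!is_count(K) || K < 1) fc_stop("K must be a positive integer")
  n <- nrow(profiles)
  G <- tcrossprod(profiles)
  sq <- diag(G)
  idx_m <- matrix(NA_integer_, n, K)
  w_m <- matrix(NA_real_, n, K)
  n_nb <- integer(n)
  short <- FALSE
  for (q in seq_len(n)) {
    cand <- which(chrom_id != chrom_id[q])
    if (!length(cand)) fc_stop("no candidate bins on other chromosomes")
    d2 <- sq[q] + sq[cand] - 2 * G[q, cand]
    d <- sqrt(pmax(d2, 0))
    k <- min(K, length(cand))
    if (k < K) short <- TRUE
    ord <- order(d, bin_idx[cand])[seq_len(k)]
    sel <- cand[ord]
    idx_m[q, seq_len(k)] <- bin_idx[sel]
    wt <- 1 / (d[ord] + eps)
    w_m[q, seq_len(k)] <- wt / sum(wt)
    n_nb[q] <- k
  }
  if (short) warning("fewer than K candidate bins for some query bins; kept all")
  list(query_idx = bin_idx, idx = idx_m, w = w_m, n_nb = n_nb, K = as.integer(K))
}

#' Build the complete two-datatype reference set
#'
#' End-to-end reference construction from a control panel:
#' \enumerate{
#'   \item normalize control counts and derive the global bin mask;
#'   \item fit one PCA bias model per datatype (read counts over the global
#'     mask; mean fragment sizes over the global mask further restricted to
#'     bins where every control has fragments);
#'   \item bias-correct every control and build, independently per datatype,
#'     the top-`K` inverse-distance-weighted neighbor lists on other
#'     chromosomes.
#' }
#' The two datatype pipelines are parallel and their neighbor lists may
#' differ. Construction is deterministic given the panel and parameters.
#'
#' @param panel a [control_panel()].
#' @param K neighbors per query bin (default 300).
#' @param n_comp principal components per datatype (default 5).
#' @param mask_min_frac,mask_zero_frac see [build_global_mask()].
#' @param fs_min_frags,fs_max_cov_z query-side fragment-size filter defaults,
#'   stored for [score_sample()].
#' @param verbose log progress to stderr.
#' @return object of class `reference_set`: grid, `global_mask`, per-datatype
#'   `models` and `neighbors`, `K`, and the parameter block.
#' @export
build_reference_set <- function(panel, K = 300L, n_comp = 5L,
                                mask_min_frac = 0.1, mask_zero_frac = 0.1,
                                fs_min_frags = 10, fs_max_cov_z = 3,
                                verbose = FALSE) {
  stopifnot(inherits(panel, "control_panel"))
  grid <- panel$grid
  fc_msg("building global mask from ", panel$n_controls, " controls",
         verbose = verbose)
  gmask <- build_global_mask(panel, mask_min_frac, mask_zero_frac)
  if (!any(gmask)) fc_stop("global mask removed every bin")
  chrom_id <- grid_chrom_id(grid)

  fc_msg("fitting read-count bias model (", n_comp, " components)",
         verbose = verbose)
  rc_model <- fit_bias_model(panel, "read_count", n_comp, gmask)
  rc_prof <- vapply(panel$samples, function(s) {
    apply_bias_correction(normalize_counts(s$counts, gmask), rc_model)[gmask]
  }, numeric(sum(gmask)))
  fc_msg("read-count neighbor search over ", sum(gmask), " bins",
         verbose = verbose)
  rc_nb <- build_neighbors(rc_prof, which(gmask), chrom_id[gmask], K)

  fs_ok <- gmask & Reduce(`&`, lapply(panel$samples, function(s) s$fs_n > 0))
  if (!any(fs_ok)) fc_stop("no bins with fragment-size data in every control")
  fc_msg("fitting fragment-size bias model over ", sum(fs_ok), " bins",
         verbose = verbose)
  fs_model <- fit_bias_model(panel, "fragment_size", n_comp, fs_ok)
  fs_prof <- vapply(panel$samples, function(s) {
    apply_bias_correction(fs_mean(s), fs_model)[fs_ok]
  }, numeric(sum(fs_ok)))
  fc_msg("fragment-size neighbor search", verbose = verbose)
  fs_nb <- build_neighbors(fs_prof, which(fs_ok), chrom_id[fs_ok], K)

  structure(list(
    grid = grid,
    global_mask = gmask,
    models = list(read_count = rc_model, fragment_size = fs_model),
    neighbors = list(read_count = rc_nb, fragment_size = fs_nb),
    K = as.integer(K),
    n_controls = panel$n_controls,
    params = list(K = as.integer(K), n_comp = as.integer(n_comp),
                  mask_min_frac = mask_min_frac, mask_zero_frac = mask_zero_frac,
                  fs_min_frags = fs_min_frags, fs_max_cov_z = fs_max_cov_z)
  ), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf(paste0("reference_set: %d controls, %d/%d unmasked bins @ %s bp, ",
                     "K = %d, %d PCs/datatype\n"),
              x$n_controls, sum(x$global_mask), x$grid$total_bins,
              format(x$grid$bin_size, big.mark = ","), x$K, x$params$n_comp))
  invisible(x)
}

#' Save / load a reference archive
#'
#' Single serialized file holding the grid, masks, both bias models, both
#' neighbor tables and the parameter block, with a format version and the
#' grid hash in the header.
#'
#' @param ref a [build_reference_set()] result.
#' @param path file path (RDS).
#' @export
save_reference <- function(ref, path) {
  stopifnot(inherits(ref, "reference_set"))
  saveRDS(list(format = "fragcnv.reference", version = 1L,
               grid_hash = ref$grid$hash, reference = ref), path)
  invisible(path)
}

#' @rdname save_reference
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) fc_stop("reference archive not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "fragcnv.reference")) {
    fc_stop("not a fragcnv reference archive: ", path)
  }
  obj$reference
}
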