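#' Genomic bin grid
#'
#' A bin grid discretizes a genome into fixed-width, 0-based half-open bins
#' `[i * bin_size, (i + 1) * bin_size)` per chromosome; the last bin of each
#' chromosome may be short. The base resolution of the pipeline is 5 kb and
#' every analysis grid must be a multiple of it, so that aggregated scales
#' (250 kb up to 10 Mb) nest exactly.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp, in
#'   the desired chromosome order (normally autosomes 1-22).
#' @param bin_size bin width in bp; positive multiple of 5000.
#' @return An object of class `bin_grid`: chromosome order, lengths, bin size,
#'   per-chromosome bin counts and global-index offsets, total bin count, and a
#'   content hash used to detect grid mismatches between samples and references.
#' @examples
#' g <- bin_grid(c(chrA = 1e6, chrB = 5e5), bin_size = 250e3)
#' g$total_bins
#' @export
bin_grid <- function(chrom_lengths, bin_size) {
  if (!is.numeric(chrom_lengths) || length(chrom_lengths) == 0L ||
      is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    fc_stop("chrom_lengths must be a non-empty named numeric vector")
  }
  if (anyDuplicated(names(chrom_lengths))) fc_stop("duplicated chromosome names")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    fc_stop("chromosome lengths must be positive")
  }
  if (!is_count(bin_size) || bin_size <= 0 || bin_size %% 5000 != 0) {
    fc_stop("bin_size must be a positive multiple of 5000 bp")
  }
  n_bins <- as.integer(ceiling(chrom_lengths / bin_size))
  offset <- c(0L, cumsum(n_bins))[seq_along(n_bins)]
  names(offset) <- names(chrom_lengths)
  g <- list(
    chroms = names(chrom_lengths),
    lengths = chrom_lengths,
    bin_size = as.numeric(bin_size),
    n_bins = setNames(n_bins, names(chrom_lengths)),
    offset = offset,
    total_bins = sum(n_bins)
  )
  g$hash <- fc_hash(c(g$chroms, format(g$lengths), format(bin_size)))
  class(g) <- "bin_grid"
  g
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid: %d chromosomes, bin size %s bp, %d bins (hash %s)\n",
              length(x$chroms), format(x$bin_size, big.mark = ","),
              x$total_bins, x$hash))
  invisible(x)
}

#' Per-bin coordinate table of a grid
#'
#' @param grid a [bin_grid()].
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open),
#'   one row per bin in global bin order.
#' @export
grid_bins <- function(grid) {
  stopifnot(inherits(grid, "bin_grid"))
  chrom <- rep(grid$chroms, grid$n_bins)
  local <- unlist(lapply(grid$n_bins, function(n) seq_len(n) - 1L), use.names = FALSE)
  start <- local * grid$bin_size
  end <- pmin(start + grid$bin_size, rep(grid$lengths, grid$n_bins))
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

# Integer chromosome id per global bin (1 .. n_chroms, in grid order).
grid_chrom_id <- function(grid) rep(seq_along(grid$chroms), grid$n_bins)

# TRUE for bins shorter than the nominal bin size (terminal bins).
grid_short_bins <- function(grid) {
  b <- grid_bins(grid)
  (b$end - b$start) < grid$bin_size
}

#' Read chromosome sizes from a chrom.sizes file or FASTA index
#'
#' Accepts a two-column `chrom.sizes` file (name, length) or a `.fai` FASTA
#' index (the first two columns are used). By default only autosomes named
#' `1..22` or `chr1..chr22` are kept, in natural order, since sex chromosomes
#' are excluded from the analysis.
#'
#' @param path file path.
#' @param autosomes_only keep only autosomes 1-22 (default TRUE).
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path, autosomes_only = TRUE) {
  if (!file.exists(path)) fc_stop("chromosome sizes file not found: ", path)
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character", fill = TRUE, header = FALSE)
  if (ncol(tab) < 2L) fc_stop("expected at least two tab-separated columns in ", path)
  sizes <- setNames(as.numeric(tab[[2L]]), tab[[1L]])
  if (any(is.na(sizes))) fc_stop("non-numeric chromosome length in ", path)
  if (autosomes_only) {
    wanted <- sub("^chr", "", names(sizes)) %in% as.character(1:22)
    sizes <- sizes[wanted]
    if (length(sizes) == 0L) fc_stop("no autosomes (1-22 / chr1-chr22) found in ", path)
    ord <- order(as.integer(sub("^chr", "", names(sizes))))
    sizes <- sizes[ord]
  }
  sizes
}
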