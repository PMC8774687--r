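#' Read paired-end alignments into a pair table
#'
#' Parses a SAM or BAM file and assembles one row per read pair. No filtering
#' is applied here beyond discarding unmapped and mate-unmapped records;
#' orientation, primary-alignment, mapping-quality and unique-start rules are
#' applied downstream by [filter_pairs()], so their effect stays observable.
#'
#' Coordinates are converted to 0-based leftmost mapping positions. Mates are
#' joined on read name using the first-of-pair / second-of-pair flags; records
#' whose mate never appears are counted (`orphans`) and skipped, not errors.
#'
#' @param path SAM or BAM file. SAM input is converted on the fly with
#'   [Rsamtools::asBam()].
#' @return data.frame with one row per assembled pair: `qname`, `chrom`,
#'   `chrom2`, `start1`, `start2` (0-based), `mapq1`, `mapq2`, `proper`
#'   (both mates flagged properly paired), `primary` (neither mate secondary or
#'   supplementary), `tlen` (template length of the first-of-pair record).
#'   Attribute `io_stats` holds counters for unmapped records and orphans.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) fc_stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "isize")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1L]]
  if (length(res$qname) == 0L) {
    out <- empty_pair_table()
    attr(out, "io_stats") <- c(records = 0L, unmapped = 0L, orphans = 0L)
    return(out)
  }
  flag <- res$flag
  mapped <- bitwAnd(flag, 0x4L) == 0L & !is.na(res$pos)
  n_unmapped <- sum(!mapped)
  qname <- res$qname[mapped]
  flag <- flag[mapped]
  rname <- as.character(res$rname)[mapped]
  pos0 <- res$pos[mapped] - 1L
  mapq <- res$mapq[mapped]
  isize <- res$isize[mapped]

  is_r1 <- bitwAnd(flag, 0x40L) != 0L
  is_r2 <- bitwAnd(flag, 0x80L) != 0L
  not_primary <- bitwAnd(flag, 0x100L) != 0L | bitwAnd(flag, 0x800L) != 0L
  proper <- bitwAnd(flag, 0x2L) != 0L

  # Join first-of-pair to second-of-pair on read name. When secondary records
  # exist, the first occurrence per (qname, mate) wins and the pair is marked
  # non-primary so filter_pairs() drops it under criterion (2).
  take <- function(side) {
    idx <- which(side)
    idx[!duplicated(qname[idx])]
  }
  i1 <- take(is_r1)
  i2 <- take(is_r2)
  m <- match(qname[i1], qname[i2])
  paired <- !is.na(m)
  j1 <- i1[paired]
  j2 <- i2[m[paired]]
  n_orphans <- sum(!paired) + (length(i2) - sum(paired))
  sec_by_q1 <- tapply(not_primary[is_r1], qname[is_r1], any)
  sec_by_q2 <- tapply(not_primary[is_r2], qname[is_r2], any)
  any_secondary <- as.logical(sec_by_q1[qname[j1]]) | as.logical(sec_by_q2[qname[j1]])

  out <- data.frame(
    qname = qname[j1],
    chrom = rname[j1],
    chrom2 = rname[j2],
    start1 = pos0[j1],
    start2 = pos0[j2],
    mapq1 = mapq[j1],
    mapq2 = mapq[j2],
    proper = proper[j1] & proper[j2],
    primary = !any_secondary,
    tlen = isize[j1],
    stringsAsFactors = FALSE
  )
  attr(out, "io_stats") <- c(records = length(res$qname),
                             unmapped = n_unmapped, orphans = n_orphans)
  out
}

empty_pair_table <- function() {
  data.frame(qname = character(), chrom = character(), chrom2 = character(),
             start1 = integer(), start2 = integer(), mapq1 = integer(),
             mapq2 = integer(), proper = logical(), primary = logical(),
             tlen = integer(), stringsAsFactors = FALSE)
}

#' Filter read pairs
#'
#' Applies the four retention rules for read pairs, in order:
#' \enumerate{
#'   \item correct position/orientation for pairing (properly paired flag on
#'     both mates, and both mates on the same chromosome);
#'   \item primary alignments only;
#'   \item both mates' mapping quality at least `min_mapq` (default 1);
#'   \item unique starting location per read: starts are pooled over both
#'     mates as (chromosome, start) keys, first occurrence in stream order
#'     wins, and a pair is removed if either of its reads repeats an already
#'     seen start. The two mates of one pair may legitimately share a start
#'     (zero-size fragment) and do not evict each other. Pairs removed by
#'     rules 1-3 do not claim start locations.
#' }
#' A pair failing several rules is counted once, under the first failing rule.
#'
#' @param pairs pair table as returned by [read_pairs()] (columns `chrom`,
#'   `chrom2`, `start1`, `start2`, `mapq1`, `mapq2`, `proper`, `primary`).
#' @param min_mapq minimum mapping quality, inclusive; default 1.
#' @return the retained rows, with attribute `filter_stats` counting input,
#'   per-rule removals, and retained pairs.
#' @export
filter_pairs <- function(pairs, min_mapq = 1L) {
  required <- c("chrom", "chrom2", "start1", "start2", "mapq1", "mapq2",
                "proper", "primary")
  missing_cols <- setdiff(required, names(pairs))
  if (length(missing_cols)) {
    fc_stop("malformed pair table, missing columns: ",
            paste(missing_cols, collapse = ", "))
  }
  if (any(is.na(pairs$start1)) || any(is.na(pairs$start2)) ||
      any(pairs$start1 < 0) || any(pairs$start2 < 0)) {
    bad <- which(is.na(pairs$start1) | is.na(pairs$start2) |
                   pairs$start1 < 0 | pairs$start2 < 0)[1L]
    fc_stop("malformed pair record at row ", bad, ": invalid start position")
  }
  n_in <- nrow(pairs)
  ok_orient <- pairs$proper & pairs$chrom == pairs$chrom2
  ok_primary <- pairs$primary
  ok_mapq <- pairs$mapq1 >= min_mapq & pairs$mapq2 >= min_mapq
  fail1 <- !ok_orient
  fail2 <- ok_orient & !ok_primary
  fail3 <- ok_orient & ok_primary & !ok_mapq
  surv <- ok_orient & ok_primary & ok_mapq

  keep <- surv
  n_dup <- 0L
  if (any(surv)) {
    idx <- which(surv)
    k1 <- paste0(pairs$chrom[idx], ":", pairs$start1[idx])
    k2 <- paste0(pairs$chrom[idx], ":", pairs$start2[idx])
    inter <- as.vector(rbind(k1, k2))      # stream order: mate1, mate2, pair by pair
    dup <- duplicated(inter)
    d1 <- dup[seq_along(idx) * 2L - 1L]
    d2 <- dup[seq_along(idx) * 2L]
    # a pair's own mates sharing one start is not a duplicate of itself
    same <- k1 == k2
    d2[same] <- d1[same]
    drop_dup <- d1 | d2
    keep[idx[drop_dup]] <- FALSE
    n_dup <- sum(drop_dup)
  }
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_stats") <- c(
    input = n_in,
    fail_orientation = sum(fail1),
    fail_primary = sum(fail2),
    fail_mapq = sum(fail3),
    fail_unique_start = n_dup,
    retained = nrow(out)
  )
  out
}

#' Reduce read pairs to fragment records
#'
#' A fragment is summarized by the chromosome, the midpoint of the two mates'
#' starting positions (floored for odd sums), and the fragment size. By
#' default the size is the absolute difference of the two starting positions
#' (`"start-start"`); `"tlen"` uses the absolute SAM template length instead
#' (leftmost start to rightmost end).
#'
#' @param pairs filtered pair table (see [filter_pairs()]).
#' @param size_mode `"start-start"` (default) or `"tlen"`.
#' @return data.frame with columns `chrom`, `midpoint`, `size`.
#' @examples
#' p <- data.frame(chrom = "chr1", chrom2 = "chr1", start1 = 1000, start2 = 1173,
#'                 mapq1 = 30, mapq2 = 30, proper = TRUE, primary = TRUE, tlen = 209)
#' pairs_to_fragments(p)  # size 173, midpoint 1086
#' @export
pairs_to_fragments <- function(pairs, size_mode = c("start-start", "tlen")) {
  size_mode <- match.arg(size_mode)
  size <- if (size_mode == "start-start") {
    abs(pairs$start2 - pairs$start1)
  } else {
    if (is.null(pairs$tlen)) fc_stop("tlen column required for size_mode = 'tlen'")
    abs(pairs$tlen)
  }
  data.frame(
    chrom = pairs$chrom,
    midpoint = (pairs$start1 + pairs$start2) %/% 2L,
    size = as.numeric(size),
    stringsAsFactors = FALSE
  )
}

#' Drop oversized fragments
#'
#' Fragments above the size cap (default 300 bp) are uninformative for the
#' maternal/fetal size contrast and are discarded before binning.
#'
#' @param fragments fragment table from [pairs_to_fragments()].
#' @param cap_bp inclusive upper bound on fragment size; default 300.
#' @return retained fragments, with attribute `size_filter_stats`.
#' @export
size_filter <- function(fragments, cap_bp = 300) {
  if (!is.numeric(cap_bp) || length(cap_bp) != 1L || cap_bp <= 0) {
    fc_stop("cap_bp must be a single positive number")
  }
  keep <- fragments$size <= cap_bp
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "size_filter_stats") <- c(input = nrow(fragments),
                                      discarded = sum(!keep),
                                      retained = nrow(out))
  out
}

#' Write / read a fragment table (TSV)
#'
#' Plain three-column TSV (`chrom`, `midpoint`, `size`), the intermediate
#' format between alignment parsing and binning.
#'
#' @param fragments fragment table.
#' @param path output/input file.
#' @export
write_fragments <- function(fragments, path) {
  write.table(fragments[, c("chrom", "midpoint", "size")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) fc_stop("fragment table not found: ", path)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c("character", "numeric", "numeric"))
}

#' Convert an alignment file to a filtered fragment table
#'
#' One-stop wrapper: [read_pairs()] then [filter_pairs()],
#' [pairs_to_fragments()] and [size_filter()], optionally writing the fragment
#' TSV and a JSON with all filter counters.
#'
#' @param path SAM/BAM file.
#' @param out optional output TSV path; stats are written to `<out>.stats.json`.
#' @param min_mapq,cap_bp,size_mode see the individual steps.
#' @return fragment table (invisibly if `out` is given), with `convert_stats`
#'   attribute.
#' @export
convert_alignments <- function(path, out = NULL, min_mapq = 1L, cap_bp = 300,
                               size_mode = c("start-start", "tlen")) {
  size_mode <- match.arg(size_mode)
  pairs <- read_pairs(path)
  flt <- filter_pairs(pairs, min_mapq = min_mapq)
  frags <- size_filter(pairs_to_fragments(flt, size_mode = size_mode), cap_bp = cap_bp)
  stats <- list(io = as.list(attr(pairs, "io_stats")),
                pair_filter = as.list(attr(flt, "filter_stats")),
                size_filter = as.list(attr(frags, "size_filter_stats")),
                params = list(min_mapq = min_mapq, cap_bp = cap_bp,
                              size_mode = size_mode))
  attr(frags, "convert_stats") <- stats
  if (!is.null(out)) {
    write_fragments(frags, out)
    jsonlite::write_json(stats, paste0(out, ".stats.json"), auto_unbox = TRUE)
    return(invisible(frags))
  }
  frags
}
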