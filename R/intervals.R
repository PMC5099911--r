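#' Construct a table of genomic intervals
#'
#' All coordinates in lincChIN are 0-based half-open (BED convention):
#' `start` is the first base of the interval, `end` is one past the last.
#' 1-based formats (GTF, GWAS SNP positions) are converted at their reader
#' boundary, never downstream.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer-like vectors; `start >= 0`, `end > start`.
#' @param strand one of `"+"`, `"-"`, `"."`; recycled. Strand never changes
#'   interval arithmetic here, it only matters for TSS derivation upstream.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
gintervals <- function(chrom = character(), start = integer(), end = integer(),
                       strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_gintervals(df)
  df
}

#' Validate an interval table
#'
#' @param x data.frame with at least `chrom`, `start`, `end` columns.
#' @param what label used in error messages.
#' @return `x` invisibly; errors on the first violated invariant.
#' @export
validate_gintervals <- function(x, what = "interval table") {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop(what, ": chrom must be non-empty")
  bad <- which(x$start < 0 | x$end <= x$start)
  if (length(bad) > 0)
    stop(what, ": invalid coordinates (need start >= 0, end > start) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(x)
}

# interval table -> GRanges (1-based closed), and back; strand dropped to "*"
.gi_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

.granges_to_gi <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = ".",
             stringsAsFactors = FALSE)
}

#' Merge overlapping or nearby intervals
#'
#' Implements the anchor-merging rule used for ChIN node construction:
#' overlapping or "neighboring" intervals collapse into one region. Two
#' inputs end up in the same output interval iff a chain of inputs connects
#' them with pairwise gaps `<= max_gap`. With the default `max_gap = 0`,
#' book-ended intervals (gap exactly 0) still merge, which is the most
#' conservative reading of "overlapping, neighboring" regions.
#'
#' @param intervals interval table (see [gintervals()]).
#' @param max_gap non-negative integer; maximum gap bridged by a merge.
#' @return sorted interval table, pairwise disjoint within each chromosome.
#' @export
merge_intervals <- function(intervals, max_gap = 0) {
  stopifnot(max_gap >= 0)
  validate_gintervals(intervals)
  if (nrow(intervals) == 0)
    return(gintervals())
  gr <- .gi_to_granges(intervals)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1)
  out <- .granges_to_gi(merged)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Do two intervals share at least one base?
#'
#' The >= 1 bp overlap rule used throughout promoter/DRE assignment. Under
#' the half-open convention this is `a.start < b.end && b.start < a.end`
#' on the same chromosome; strand is ignored.
#'
#' @param a,b single-row interval tables (or lists with chrom/start/end).
#' @return logical scalar.
#' @export
overlaps <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

# vectorized hit test: for each row of a, does it overlap any row of b?
# b is pre-merged internally so the answer only depends on b's union.
.overlaps_any <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  bm <- merge_intervals(b)
  hits <- rep(FALSE, nrow(a))
  for (ch in unique(a$chrom)) {
    bi <- bm[bm$chrom == ch, , drop = FALSE]
    ai <- which(a$chrom == ch)
    if (nrow(bi) == 0) next
    # merged b is sorted and disjoint: a row overlaps some b iff the number
    # of b-starts strictly below a$end exceeds the number of b-ends <= a$start
    n_start <- findInterval(a$end[ai] - 1e-9, bi$start) # b.start < a.end
    n_done <- findInterval(a$start[ai] + 1e-9, bi$end)  # b.end <= a.start
    hits[ai] <- n_start > n_done
  }
  hits
}

#' Build a coverage track
#'
#' Piecewise-constant non-negative value function over the genome with
#' bedGraph semantics: positions not covered by any row have value 0.
#'
#' @param cov interval table with an extra numeric `value` column (>= 0);
#'   rows within one chromosome must not overlap.
#' @param library_depth optional total mapped reads, used for per-million
#'   depth normalization in [mean_coverage()].
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(cov = NULL, library_depth = NULL) {
  if (is.null(cov))
    cov <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric())
  validate_gintervals(cov, "coverage track")
  if (!"value" %in% names(cov)) stop("coverage track needs a 'value' column")
  if (any(cov$value < 0)) stop("coverage values must be >= 0")
  if (nrow(cov) > 1) {
    o <- order(cov$chrom, cov$start)
    cov <- cov[o, , drop = FALSE]
    same <- cov$chrom[-1] == cov$chrom[-nrow(cov)]
    if (any(same & cov$start[-1] < cov$end[-nrow(cov)]))
      stop("coverage track rows overlap within a chromosome")
  }
  structure(list(cov = cov, library_depth = library_depth),
            class = "coverage_track")
}

#' Length-weighted mean coverage over an interval
#'
#' Uncovered positions count as 0 (bedGraph semantics). With
#' `normalize = TRUE` and a track `library_depth`, the mean is divided by
#' depth/1e6 (reads-per-million depth normalization).
#'
#' @param track a [coverage_track()].
#' @param interval single-row interval table.
#' @param normalize divide by library depth per million when available.
#' @return non-negative scalar; 0 (with a warning) for chromosomes absent
#'   from the track.
#' @export
mean_coverage <- function(track, interval, normalize = FALSE) {
  stopifnot(inherits(track, "coverage_track"))
  validate_gintervals(as.data.frame(interval), "query interval")
  cov <- track$cov
  width <- interval$end - interval$start
  rows <- cov[cov$chrom == interval$chrom &
                cov$start < interval$end &
                cov$end > interval$start, , drop = FALSE]
  if (nrow(cov) > 0 && !interval$chrom %in% cov$chrom)
    warning("chromosome ", interval$chrom, " absent from coverage track; returning 0")
  total <- if (nrow(rows) == 0) 0 else {
    w <- pmin(rows$end, interval$end) - pmax(rows$start, interval$start)
    sum(w * rows$value)
  }
  m <- total / width
  if (normalize && !is.null(track$library_depth) && track$library_depth > 0)
    m <- m / (track$library_depth / 1e6)
  m
}

#' Mean coverage in equal-width bins across an interval
#'
#' @param track a [coverage_track()].
#' @param interval single-row interval table whose width is divisible into
#'   `n_bins` (last bin absorbs any remainder).
#' @param n_bins number of bins, left-to-right in genome coordinates.
#' @inheritParams mean_coverage
#' @return numeric vector of length `n_bins`.
#' @export
binned_coverage <- function(track, interval, n_bins = 20, normalize = FALSE) {
  width <- interval$end - interval$start
  edges <- interval$start + round(seq(0, width, length.out = n_bins + 1))
  vapply(seq_len(n_bins), function(i) {
    suppressWarnings(mean_coverage(
      track,
      data.frame(chrom = interval$chrom, start = edges[i], end = edges[i + 1]),
      normalize = normalize))
  }, numeric(1))
}

#' Clip intervals to chromosome bounds
#'
#' @param intervals interval table.
#' @param chrom_sizes named numeric vector (or two-column data.frame) of
#'   chromosome lengths.
#' @return interval table with starts floored at 0 and ends capped at the
#'   chromosome length; clipping is reported via `message()`.
#' @export
clip_to_chrom <- function(intervals, chrom_sizes) {
  sizes <- .as_chrom_sizes(chrom_sizes)
  unknown <- setdiff(unique(intervals$chrom), names(sizes))
  if (length(unknown) > 0)
    stop("chromosome(s) absent from chrom_sizes: ", paste(unknown, collapse = ", "))
  s0 <- pmax(intervals$start, 0)
  e0 <- pmin(intervals$end, sizes[intervals$chrom])
  if (any(s0 != intervals$start | e0 != intervals$end))
    message(sum(s0 != intervals$start | e0 != intervals$end),
            " interval(s) clipped at chromosome boundaries")
  intervals$start <- s0
  intervals$end <- unname(e0)
  intervals[intervals$end > intervals$start, , drop = FALSE]
}

.as_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    sizes <- as.numeric(chrom_sizes[[2]])
    names(sizes) <- as.character(chrom_sizes[[1]])
    sizes
  } else {
    stopifnot(!is.null(names(chrom_sizes)))
    chrom_sizes
  }
}

# consistent chromosome dialect check across inputs ("chr1" vs "1")
.check_chrom_dialect <- function(reference_chroms, other_chroms, what) {
  off <- setdiff(unique(other_chroms), reference_chroms)
  if (length(off) > 0)
    stop("chromosome name(s) in ", what,
         " not present in the annotation dialect: ",
         paste(utils::head(off, 10), collapse = ", "))
  invisible(TRUE)
}
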