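#' Construct a table of genomic intervals
#'
#' Intervals are stored in the package-wide convention: 0-based, half-open
#' `[start, end)`, matching BED. Every emitted table states this convention in
#' a `#`-prefixed header comment.
#'
#' @param chrom character vector of chromosome names (compared by exact string
#'   match; no "chr" aliasing).
#' @param start 0-based inclusive start positions (bp).
#' @param end 0-based exclusive end positions (bp); must satisfy `end > start`.
#' @param strand one of `"+"`, `"-"`, `"."` per interval. Strand is carried
#'   but ignored by all overlap tests.
#' @param ... additional per-interval attribute vectors (recycled by
#'   `data.frame`).
#'
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand` plus
#'   any extra attributes.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = as.character(strand),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate interval invariants
#'
#' Checks `end > start`, `start >= 0` and a legal strand code, stopping with a
#' descriptive error otherwise.
#'
#' @param x interval `data.frame` (columns `chrom`, `start`, `end`, and
#'   optionally `strand`).
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$end > x$start))
  if (length(bad) > 0L) {
    stop("invalid interval(s) at row ", paste(utils::head(bad, 5L), collapse = ", "),
         ": end must be > start (0-based half-open convention)")
  }
  if (any(x$start < 0)) {
    stop("invalid interval(s): start must be >= 0")
  }
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  invisible(x)
}

#' Interval widths
#'
#' @param x interval `data.frame`.
#' @return numeric vector `end - start`.
#' @export
interval_width <- function(x) x$end - x$start

#' Pairwise overlap test under the half-open convention
#'
#' Two intervals overlap iff they share a chromosome and
#' `a$start < b$end && b$start < a$end`. Adjacent half-open intervals
#' (`[100,200)` vs `[200,300)`) do not overlap. Strand is ignored.
#'
#' @param a,b interval `data.frame`s of equal length (or one of length 1,
#'   recycled); compared element-wise.
#' @return logical vector.
#' @export
overlaps_any <- function(a, b) {
  validate_intervals(a)
  validate_intervals(b)
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

# Convert the 0-based half-open table to a GRanges (1-based closed) object.
# Internal: only used to drive IRanges overlap machinery.
as_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  } else "*"
  GenomicRanges::GRanges(seqnames = x$chrom,
                         ranges = IRanges::IRanges(start = x$start + 1L,
                                                   end = x$end),
                         strand = strand)
}

#' Map every interval in one set to all overlapping intervals in another
#'
#' Any-overlap (>= 1 bp) under the half-open convention, strand-agnostic.
#' Output rows are ordered deterministically by the A-set member's
#' (chrom, start) and then the B-set member's (chrom, start).
#'
#' @param setA,setB interval `data.frame`s.
#' @return `data.frame` with columns `a` and `b`: row indices into `setA` and
#'   `setB` for each overlapping pair. A-members with no overlap are absent.
#' @export
map_pairs <- function(setA, setB) {
  validate_intervals(setA)
  if (nrow(setB) > 0L) validate_intervals(setB)
  if (nrow(setA) == 0L || nrow(setB) == 0L) {
    return(data.frame(a = integer(0), b = integer(0)))
  }
  hits <- GenomicRanges::findOverlaps(as_granges(setA), as_granges(setB),
                                      ignore.strand = TRUE)
  out <- data.frame(a = S4Vectors::queryHits(hits),
                    b = S4Vectors::subjectHits(hits))
  ord <- order(setA$chrom[out$a], setA$start[out$a], out$a,
               setB$chrom[out$b], setB$start[out$b], out$b)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Sum a per-bin count column over each target interval (any-overlap).
# bins: data.frame chrom/start/end/count; intervals: interval data.frame.
# Returns a numeric vector, one total per interval.
count_in_intervals <- function(bins, intervals) {
  totals <- numeric(nrow(intervals))
  if (nrow(bins) == 0L || nrow(intervals) == 0L) return(totals)
  hits <- map_pairs(intervals, bins)
  if (nrow(hits) > 0L) {
    sums <- tapply(bins$count[hits$b], hits$a, sum)
    totals[as.integer(names(sums))] <- as.numeric(sums)
  }
  totals
}
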