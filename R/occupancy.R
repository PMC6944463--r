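#' Per-bin enrichment test of IP versus input counts
#'
#' For each bin, a one-sided exact binomial test of the IP count against
#' `n = ip + input` trials with success probability
#' `total_ip / (total_ip + total_input)` (the library-size expectation under
#' no enrichment), i.e. `p = P(X >= ip)`. P-values are BH-adjusted across all
#' bins and bins with `q <= fdr` are flagged enriched. This is the package's
#' bin-level enrichment filter; the width of the bins is set upstream when
#' the count tracks are produced (300 bp by default in the simulator).
#'
#' @param ip_bins,input_bins bin-count `data.frame`s (`chrom`, `start`,
#'   `end`, `count`) on an identical bin grid.
#' @param total_ip,total_input library sizes; default the column sums.
#' @param fdr BH false-discovery-rate threshold for the enriched flag.
#' @return `data.frame`: the bin grid plus `ip_count`, `input_count`,
#'   `p_value`, `q_value`, `enriched`.
#' @export
bin_enrichment <- function(ip_bins, input_bins,
                           total_ip = sum(ip_bins$count),
                           total_input = sum(input_bins$count),
                           fdr = 0.05) {
  if (nrow(ip_bins) != nrow(input_bins) ||
      !all(ip_bins$chrom == input_bins$chrom) ||
      !all(ip_bins$start == input_bins$start) ||
      !all(ip_bins$end == input_bins$end)) {
    stop("IP and input bin grids do not match (bin-by-bin)")
  }
  if (total_ip <= 0 || total_input <= 0) stop("library totals must be > 0")
  ip <- ip_bins$count
  inp <- input_bins$count
  n <- ip + inp
  p0 <- total_ip / (total_ip + total_input)
  # one-sided upper tail P(X >= ip); n = 0 gives p = 1
  p <- ifelse(n > 0, stats::pbinom(ip - 1, n, p0, lower.tail = FALSE), 1)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(chrom = ip_bins$chrom, start = ip_bins$start, end = ip_bins$end,
             ip_count = ip, input_count = inp,
             p_value = p, q_value = q, enriched = q <= fdr,
             stringsAsFactors = FALSE)
}

#' Assemble enriched bins into peaks
#'
#' Maximal runs of enriched bins (per chromosome, sorted by coordinate) with
#' inter-bin gaps of at most `max_gap` bp are merged into one peak. The
#' summit is the midpoint of the enriched bin with the highest IP count
#' (leftmost on ties); IP and input counts are summed over the merged span.
#'
#' @param bin_tests output of [bin_enrichment()], sorted by coordinate.
#' @param max_gap largest allowed gap (bp) between consecutive enriched bins
#'   in one peak (default 0: bins must touch).
#' @return peak `data.frame`: `id`, `chrom`, `start`, `end`, `summit`,
#'   `ip_count`, `input_count`, `n_bins`, `min_q`.
#' @export
assemble_peaks <- function(bin_tests, max_gap = 0) {
  empty <- data.frame(id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      summit = numeric(0), ip_count = numeric(0),
                      input_count = numeric(0), n_bins = integer(0),
                      min_q = numeric(0), stringsAsFactors = FALSE)
  enr <- bin_tests[bin_tests$enriched, , drop = FALSE]
  if (nrow(enr) == 0L) return(empty)
  enr <- enr[order(enr$chrom, enr$start), , drop = FALSE]
  new_run <- c(TRUE, enr$chrom[-1L] != enr$chrom[-nrow(enr)] |
                 enr$start[-1L] - enr$end[-nrow(enr)] > max_gap)
  run <- cumsum(new_run)
  peaks <- do.call(rbind, lapply(split(seq_len(nrow(enr)), run), function(ix) {
    b <- enr[ix, , drop = FALSE]
    top <- which(b$ip_count == max(b$ip_count))[1L]  # leftmost tie-break
    data.frame(chrom = b$chrom[1L], start = min(b$start), end = max(b$end),
               summit = floor((b$start[top] + b$end[top]) / 2),
               ip_count = sum(b$ip_count), input_count = sum(b$input_count),
               n_bins = nrow(b), min_q = min(b$q_value),
               stringsAsFactors = FALSE)
  }))
  peaks$id <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  rownames(peaks) <- NULL
  peaks[, c("id", "chrom", "start", "end", "summit", "ip_count",
            "input_count", "n_bins", "min_q")]
}

#' Call peaks from binned IP/input counts
#'
#' Convenience wrapper: [bin_enrichment()] followed by [assemble_peaks()].
#'
#' @inheritParams bin_enrichment
#' @inheritParams assemble_peaks
#' @return list with `bins` (the per-bin test table) and `peaks`.
#' @export
call_peaks <- function(ip_bins, input_bins,
                       total_ip = sum(ip_bins$count),
                       total_input = sum(input_bins$count),
                       fdr = 0.05, max_gap = 0) {
  bins <- bin_enrichment(ip_bins, input_bins, total_ip, total_input, fdr)
  list(bins = bins, peaks = assemble_peaks(bins, max_gap = max_gap))
}

#' Retain externally called peaks that intersect enriched bins
#'
#' Compatibility path for peaks called by an external tool (narrowPeak): a
#' peak is retained iff it overlaps at least one enriched bin (any-overlap,
#' half-open). Non-retained peaks are preserved with `retained = FALSE` for
#' audit.
#'
#' @param peaks peak `data.frame` (e.g. from
#'   `read_intervals(format = "narrowPeak")`).
#' @param bin_tests output of [bin_enrichment()].
#' @return `peaks` with a logical `retained` column appended.
#' @export
retain_external_peaks <- function(peaks, bin_tests) {
  peaks$retained <- FALSE
  enr <- bin_tests[bin_tests$enriched, , drop = FALSE]
  if (nrow(peaks) == 0L || nrow(enr) == 0L) return(peaks)
  hits <- map_pairs(peaks, enr)
  peaks$retained[unique(hits$a)] <- TRUE
  peaks
}
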