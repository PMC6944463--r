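#' Position-weight-matrix model
#'
#' A probability matrix over A/C/G/T with a background distribution. Motif
#' hits are scored as log-odds in bits:
#' `score = sum_j log2(probs[base_j, j] / background[base_j])`.
#'
#' @param probs 4 x width numeric matrix; rows A, C, G, T (rownames set if
#'   absent); every column must sum to 1 within 1e-9.
#' @param background length-4 base probabilities (default uniform).
#' @param pseudocount probability mass already incorporated when the matrix
#'   was built from counts; recorded for provenance.
#' @return object of class `pwm_model` with elements `probs`, `background`,
#'   `width`, `pseudocount`.
#' @export
pwm_model <- function(probs, background = rep(0.25, 4), pseudocount = 0) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  rownames(probs) <- c("A", "C", "G", "T")
  if (ncol(probs) < 1L) stop("PWM width must be >= 1")
  csums <- colSums(probs)
  if (any(abs(csums - 1) > 1e-9)) {
    stop("PWM columns must each sum to 1 (max deviation ",
         format(max(abs(csums - 1))), ")")
  }
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9) {
    stop("background must be 4 probabilities summing to 1")
  }
  structure(list(probs = probs, background = as.numeric(background),
                 width = ncol(probs), pseudocount = pseudocount),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat("PWM model: width", x$width, "bp, max score",
      round(pwm_max_score(x), 3), "bits\n")
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Build a PWM from a stack of aligned sequences
#'
#' @param seqs character vector of equal-length sequences over A/C/G/T.
#' @param pseudocount count added to every cell before normalization.
#' @param background length-4 base probabilities.
#' @return a [pwm_model()].
#' @export
pwm_from_sequences <- function(seqs, pseudocount = 0.5,
                               background = rep(0.25, 4)) {
  if (length(seqs) == 0L) stop("cannot build a PWM from zero sequences")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("sequences must share one length")
  mat <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs), byrow = TRUE)
  counts <- vapply(seq_len(w), function(j) {
    tab <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
    as.numeric(tab)
  }, numeric(4))
  counts <- counts + pseudocount
  pwm_model(sweep(counts, 2L, colSums(counts), "/"), background = background,
            pseudocount = pseudocount)
}

# log2-odds scoring matrix (4 x width)
pwm_logodds <- function(pwm) log2(pwm$probs / pwm$background)

#' Maximum achievable log-odds score of a PWM (bits)
#' @param pwm a [pwm_model()].
#' @return numeric scalar.
#' @export
pwm_max_score <- function(pwm) sum(apply(pwm_logodds(pwm), 2L, max))

#' Consensus string of a PWM (highest-probability base per column)
#' @param pwm a [pwm_model()].
#' @return character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$probs)[apply(pwm$probs, 2L, which.max)], collapse = "")
}

#' Per-position information content of a PWM (bits)
#'
#' For a uniform background, `IC_j = 2 + sum_b p_bj * log2(p_bj)`; bounded in
#' `[0, 2]`.
#'
#' @param pwm a [pwm_model()].
#' @return numeric vector of length `width`.
#' @export
pwm_ic <- function(pwm) {
  p <- pwm$probs
  plogp <- ifelse(p > 0, p * log2(p), 0)
  pmin(2, pmax(0, 2 + colSums(plogp)))
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

# Encode a sequence as integer indices 1..4 (A,C,G,T), NA for anything else.
encode_seq <- function(s) {
  match(strsplit(s, "")[[1L]], c("A", "C", "G", "T"))
}

# Score every window of width w on one strand; returns numeric vector of
# length nchar(s) - w + 1 (NA where the window contains non-ACGT).
score_windows <- function(codes, lo) {
  w <- ncol(lo)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  scores <- numeric(n)
  valid <- !logical(n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1L)]
    ok <- !is.na(cj)
    valid <- valid & ok
    contrib <- numeric(n)
    contrib[ok] <- lo[cbind(cj[ok], j)]
    scores <- scores + contrib
  }
  scores[!valid] <- NA_real_
  scores
}

#' Scan a sequence for PWM hits on both strands
#'
#' Reverse-strand windows are scored against the reverse complement of the
#' window; windows containing non-ACGT characters are skipped. Hits are
#' reported in the forward coordinate system, sorted by start position (and
#' `+` before `-` at equal starts).
#'
#' @param sequence nucleotide string (one chromosome).
#' @param pwm a [pwm_model()].
#' @param min_score minimum log-odds score in bits; default 60% of the PWM's
#'   maximum achievable score.
#' @param chrom chromosome label attached to hits.
#' @return `data.frame` with columns `chrom`, `start` (0-based), `end`,
#'   `strand`, `score` (bits), `sequence` (the matched k-mer, reported on the
#'   motif strand).
#' @export
scan_pwm <- function(sequence, pwm, min_score = 0.6 * pwm_max_score(pwm),
                     chrom = "chr") {
  stopifnot(inherits(pwm, "pwm_model"))
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      score = numeric(0), sequence = character(0))
  w <- pwm$width
  if (nchar(sequence) < w) return(empty)
  codes <- encode_seq(sequence)
  lo <- pwm_logodds(pwm)
  fwd <- score_windows(codes, lo)
  # reverse strand: score the reverse-complemented window = score the forward
  # window against the reverse-complemented scoring matrix
  lo_rc <- lo[4:1, w:1, drop = FALSE]
  rev <- score_windows(codes, lo_rc)
  keep_f <- which(!is.na(fwd) & fwd >= min_score)
  keep_r <- which(!is.na(rev) & rev >= min_score)
  if (length(keep_f) + length(keep_r) == 0L) return(empty)
  starts <- c(keep_f, keep_r) - 1L
  strands <- c(rep("+", length(keep_f)), rep("-", length(keep_r)))
  scores <- c(fwd[keep_f], rev[keep_r])
  kmers <- substring(sequence, starts + 1L, starts + w)
  kmers[strands == "-"] <- revcomp(kmers[strands == "-"])
  out <- data.frame(chrom = chrom, start = starts, end = starts + w,
                    strand = strands, score = scores, sequence = kmers,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a whole genome (named sequence set) for PWM hits
#'
#' @param genome named character vector of chromosome sequences.
#' @inheritParams scan_pwm
#' @return row-bound hit `data.frame` across chromosomes.
#' @export
scan_genome <- function(genome, pwm, min_score = 0.6 * pwm_max_score(pwm)) {
  hits <- lapply(names(genome), function(chr) {
    scan_pwm(genome[[chr]], pwm, min_score = min_score, chrom = chr)
  })
  do.call(rbind, hits)
}

#' Nearest motif hit to each peak summit
#'
#' For every peak, considers hits on the peak's chromosome whose midpoint
#' falls within `[summit - flank, summit + flank]` (both endpoints included)
#' and returns the hit whose midpoint minimizes the distance to the summit;
#' ties break to the lower-coordinate hit. Also reports the total hit count
#' in the window.
#'
#' @param peaks `data.frame` with `chrom` and `summit` columns (plus an `id`
#'   column used as identifier when present).
#' @param hits motif hit `data.frame` from [scan_pwm()].
#' @param flank window half-width in bp around the summit (default 1000).
#' @return `data.frame`, one row per peak: `tam_count`, `tam_start`,
#'   `tam_end`, `tam_strand`, `tam_score`, `tam_sequence`, `tam_distance`
#'   (NA where the window is empty).
#' @export
nearest_tam <- function(peaks, hits, flank = 1000) {
  n <- nrow(peaks)
  out <- data.frame(tam_count = integer(n), tam_start = rep(NA_real_, n),
                    tam_end = rep(NA_real_, n), tam_strand = rep(NA_character_, n),
                    tam_score = rep(NA_real_, n),
                    tam_sequence = rep(NA_character_, n),
                    tam_distance = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L || is.null(hits) || nrow(hits) == 0L) return(out)
  mid <- hits$start + (hits$end - hits$start) / 2
  for (i in seq_len(n)) {
    s <- peaks$summit[i]
    sel <- which(hits$chrom == peaks$chrom[i] & mid >= s - flank &
                   mid <= s + flank)
    out$tam_count[i] <- length(sel)
    if (length(sel) == 0L) next
    d <- abs(mid[sel] - s)
    best <- sel[order(d, hits$start[sel])][1L]
    out$tam_start[i] <- hits$start[best]
    out$tam_end[i] <- hits$end[best]
    out$tam_strand[i] <- hits$strand[best]
    out$tam_score[i] <- hits$score[best]
    out$tam_sequence[i] <- hits$sequence[best]
    out$tam_distance[i] <- mid[best] - s
  }
  out
}

#' Build a per-category motif consensus from peak-proximal hits
#'
#' Takes the single closest hit within `summit_flank` of each qualifying
#' peak's summit, stacks the matched k-mers (minus-strand hits are already
#' reported on the motif strand), and returns the resulting probability
#' matrix with its per-position information content.
#'
#' @param classified classified peak `data.frame` with `chrom`, `summit` and
#'   `category` columns.
#' @param hits motif hit `data.frame` from [scan_pwm()]/[scan_genome()].
#' @param category category label to select.
#' @param summit_flank half-width of the summit window used for consensus
#'   building (default 250 bp).
#' @param pseudocount count added per cell when normalizing the stack.
#' @return list with `pwm` (a [pwm_model()]), `ic` (per-position bits),
#'   `n_sequences`, and `sequences` (the stacked k-mers).
#' @export
build_consensus <- function(classified, hits, category, summit_flank = 250,
                            pseudocount = 0.5) {
  sel <- classified[classified$category == category, , drop = FALSE]
  nt <- nearest_tam(sel, hits, flank = summit_flank)
  seqs <- nt$tam_sequence[!is.na(nt$tam_sequence)]
  if (length(seqs) == 0L) {
    stop("no peaks in category '", category,
         "' carry a motif hit within +/-", summit_flank, " bp of the summit")
  }
  pwm <- pwm_from_sequences(seqs, pseudocount = pseudocount)
  list(pwm = pwm, ic = pwm_ic(pwm), n_sequences = length(seqs),
       sequences = seqs)
}

#' Contrast 5'-half and 3'-half information content of two PWMs
#'
#' Computes the mean per-position IC over positions `[0, split)` (5' half)
#' and `[split, width)` (3' half) for each matrix and the A-minus-B
#' differences. With the default 22-bp motif and `split = 11` the halves are
#' equal.
#'
#' @param pwm_a,pwm_b [pwm_model()] objects of equal width.
#' @param split 0-based position index where the 3' half begins (default 11).
#' @return list with per-matrix half means (`mean_ic_5`, `mean_ic_3`, each a
#'   named vector `c(a=, b=)`) and `delta5`, `delta3` (A minus B).
#' @export
ic_half_contrast <- function(pwm_a, pwm_b, split = 11) {
  if (pwm_a$width != pwm_b$width) {
    stop("PWM widths differ (", pwm_a$width, " vs ", pwm_b$width, ")")
  }
  w <- pwm_a$width
  if (split < 1 || split >= w) stop("split must lie strictly inside the motif")
  ica <- pwm_ic(pwm_a); icb <- pwm_ic(pwm_b)
  i5 <- seq_len(split); i3 <- (split + 1L):w
  m5 <- c(a = mean(ica[i5]), b = mean(icb[i5]))
  m3 <- c(a = mean(ica[i3]), b = mean(icb[i3]))
  list(mean_ic_5 = m5, mean_ic_3 = m3,
       delta5 = unname(m5["a"] - m5["b"]),
       delta3 = unname(m3["a"] - m3["b"]))
}

#' Write motif hits as BED6
#'
#' Score column carries bits x 100, rounded, as documented for downstream
#' browsers.
#'
#' @param hits hit `data.frame` from [scan_pwm()].
#' @param path output path.
#' @export
write_motif_bed <- function(hits, path) {
  x <- hits
  x$name <- x$sequence
  x$score <- round(100 * x$score)
  write_bed(x, path)
}
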