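# Scaled-down study conditions for unit tests: same generative model as the
# 2-Mb reference configuration, smaller genome so per-file suites stay fast.
small_config <- function(seed = 11, ...) {
  args <- list(genome_length = 4e5, n_genes = 80, n_bound_promoters = 40,
               depth_ip = 4e4, depth_input = 4e4, n_direct_down = 12,
               n_indirect = 10, n_silent = 8, seed = seed)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

# Quadratic all-pairs overlap oracle (same chrom, half-open any-overlap).
quadratic_pairs <- function(A, B) {
  out <- list()
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      if (A$chrom[i] == B$chrom[j] && A$start[i] < B$end[j] &&
          B$start[j] < A$end[i]) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0L) return(data.frame(a = integer(0), b = integer(0)))
  m <- do.call(rbind, out)
  data.frame(a = m[, 1L], b = m[, 2L])
}

# Canonical sorted representation of a pair mapping for set comparison.
pair_key <- function(p) sort(paste(p$a, p$b, sep = ":"))

random_intervals <- function(n, chroms = c("c1", "c2"), span = 10000,
                             max_w = 400) {
  start <- sample.int(span, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + w, strand = ".", stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent per-window PWM rescoring (plain loop arithmetic).
brute_scan <- function(sequence, pwm, min_score) {
  lo <- log2(pwm$probs / pwm$background)
  w <- pwm$width
  chars <- strsplit(sequence, "")[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- list()
  for (i in seq_len(nchar(sequence) - w + 1L)) {
    win <- chars[i:(i + w - 1L)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    sc_f <- sum(vapply(seq_len(w), function(j) lo[win[j], j], 0))
    rc <- rev(unname(comp[win]))
    sc_r <- sum(vapply(seq_len(w), function(j) lo[rc[j], j], 0))
    if (sc_f >= min_score) {
      hits[[length(hits) + 1L]] <- data.frame(start = i - 1L, strand = "+",
                                              score = sc_f)
    }
    if (sc_r >= min_score) {
      hits[[length(hits) + 1L]] <- data.frame(start = i - 1L, strand = "-",
                                              score = sc_r)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}
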