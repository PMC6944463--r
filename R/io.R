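## Readers and writers for the plain-text formats the pipeline touches.
## All coordinates are converted to the internal 0-based half-open convention
## on read; GTF (1-based closed) is shifted, BED/narrowPeak are taken as is.

COORD_COMMENT <- "# coordinates: 0-based, half-open [start,end)"

split_fields <- function(lines, n_min, path, what, line_offset = 0L) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < n_min)
  if (length(bad) > 0L) {
    stop("malformed ", what, " line ", bad[1L] + line_offset, " in '", path,
         "': expected >= ", n_min, " tab-separated fields, found ", nf[bad[1L]])
  }
  fields
}

num_field <- function(fields, idx, path, what, line_offset = 0L) {
  v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", idx)))
  bad <- which(is.na(v))
  if (length(bad) > 0L) {
    stop("malformed ", what, " line ", bad[1L] + line_offset, " in '", path,
         "': field ", idx, " is not numeric")
  }
  v
}

chr_field <- function(fields, idx) vapply(fields, `[[`, "", idx)

read_body_lines <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines) &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  list(lines = lines[keep], index = which(keep))
}

#' Read genomic intervals from standard text formats
#'
#' Supported dialects: `"bed"` (BED3/BED6), `"narrowPeak"` (10-column ENCODE
#' narrowPeak; summit offset in column 10 is resolved to an absolute `summit`
#' position), `"gtf"` (gene features only; 1-based closed coordinates are
#' converted to 0-based half-open; attributes `gene_id`, `gene_name`,
#' `gene_type` are extracted when present), and `"tsv"` (header line naming at
#' least `chrom`, `start`, `end`; `#`-prefixed comment lines skipped).
#'
#' @param path file path.
#' @param format one of `"bed"`, `"narrowPeak"`, `"gtf"`, `"tsv"`.
#' @return interval `data.frame` (0-based half-open) with per-record
#'   attribute columns depending on the format.
#' @export
read_intervals <- function(path, format = c("bed", "narrowPeak", "gtf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: '", path, "'")
  out <- switch(format,
                bed = read_bed_like(path, narrow = FALSE),
                narrowPeak = read_bed_like(path, narrow = TRUE),
                gtf = read_gtf_genes(path),
                tsv = read_tsv_table(path))
  validate_intervals(out)
  out
}

read_bed_like <- function(path, narrow = FALSE) {
  body <- read_body_lines(path)
  what <- if (narrow) "narrowPeak" else "BED"
  if (length(body$lines) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0)))
  }
  n_min <- if (narrow) 10L else 3L
  f <- split_fields(body$lines, n_min, path, what)
  df <- data.frame(chrom = chr_field(f, 1L),
                   start = num_field(f, 2L, path, what),
                   end = num_field(f, 3L, path, what),
                   stringsAsFactors = FALSE)
  nf <- min(lengths(f))
  df$name <- if (nf >= 4L) chr_field(f, 4L) else paste0("iv_", seq_len(nrow(df)))
  df$score <- if (nf >= 5L) num_field(f, 5L, path, what) else 0
  df$strand <- if (nf >= 6L) chr_field(f, 6L) else "."
  df$strand[!df$strand %in% c("+", "-")] <- "."
  if (narrow) {
    df$signal <- num_field(f, 7L, path, what)
    df$p_value <- num_field(f, 8L, path, what)
    df$q_value <- num_field(f, 9L, path, what)
    peak_off <- num_field(f, 10L, path, what)
    df$summit <- ifelse(peak_off < 0, NA_real_, df$start + peak_off)
  }
  bad <- which(!(df$end > df$start))
  if (length(bad) > 0L) {
    stop("validation error at ", what, " line ", body$index[bad[1L]], " in '",
         path, "': end <= start")
  }
  df
}

read_gtf_genes <- function(path) {
  body <- read_body_lines(path)
  if (length(body$lines) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      gene_id = character(0), gene_name = character(0),
                      gene_type = character(0)))
  }
  f <- split_fields(body$lines, 9L, path, "GTF")
  feature <- chr_field(f, 3L)
  keep <- feature == "gene"
  f <- f[keep]
  idx <- body$index[keep]
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, "[ =]+\"?([^\";]+)\"?"), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
  }
  attrs <- chr_field(f, 9L)
  start1 <- num_field(f, 4L, path, "GTF")
  end1 <- num_field(f, 5L, path, "GTF")
  bad <- which(end1 < start1)
  if (length(bad) > 0L) {
    stop("validation error at GTF line ", idx[bad[1L]], " in '", path,
         "': end < start")
  }
  data.frame(chrom = chr_field(f, 1L),
             start = start1 - 1,  # 1-based closed -> 0-based half-open
             end = end1,
             strand = chr_field(f, 7L),
             gene_id = attr_get(attrs, "gene_id"),
             gene_name = attr_get(attrs, "gene_name"),
             gene_type = attr_get(attrs, "gene_type"),
             stringsAsFactors = FALSE)
}

read_tsv_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "")
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("TSV interval table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!"strand" %in% names(df)) df$strand <- "."
  df
}

#' Write intervals as BED6
#'
#' @param x interval `data.frame`; optional `name` and `score` columns are
#'   used when present.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  name <- if ("name" %in% names(x)) x$name else paste0("iv_", seq_len(nrow(x)))
  score <- if ("score" %in% names(x)) x$score else 0
  strand <- if ("strand" %in% names(x)) x$strand else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   x$chrom, as.integer(x$start), as.integer(x$end),
                   name, format(score, trim = TRUE, scientific = FALSE),
                   strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write peaks as ENCODE narrowPeak
#'
#' Column 10 carries the summit as an offset from `start` (-1 when unknown).
#'
#' @param x peak `data.frame` with `chrom`, `start`, `end` and optionally
#'   `name`/`id`, `score`, `strand`, `signal`, `p_value`, `q_value`, `summit`.
#' @param path output path.
#' @export
write_narrowpeak <- function(x, path) {
  validate_intervals(x)
  n <- nrow(x)
  name <- if ("name" %in% names(x)) x$name else
    if ("id" %in% names(x)) x$id else paste0("peak_", seq_len(n))
  score <- if ("score" %in% names(x)) round(x$score) else rep(0L, n)
  strand <- if ("strand" %in% names(x)) x$strand else rep(".", n)
  signal <- if ("signal" %in% names(x)) x$signal else rep(0, n)
  p <- if ("p_value" %in% names(x)) x$p_value else rep(-1, n)
  q <- if ("q_value" %in% names(x)) x$q_value else rep(-1, n)
  off <- if ("summit" %in% names(x)) {
    ifelse(is.na(x$summit), -1L, as.integer(x$summit - x$start))
  } else rep(-1L, n)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s\t%d",
                   x$chrom, as.integer(x$start), as.integer(x$end), name,
                   as.integer(score), strand,
                   format(signal, trim = TRUE, scientific = FALSE),
                   format(p, trim = TRUE, scientific = FALSE),
                   format(q, trim = TRUE, scientific = FALSE), off)
  writeLines(lines, path)
  invisible(path)
}

#' Write a data frame as a commented TSV
#'
#' Emits `#`-prefixed comment lines (always including the coordinate
#' convention) followed by a header line and tab-separated rows.
#'
#' @param x data.frame.
#' @param path output path.
#' @param comments extra comment lines (without the leading `#`).
#' @export
write_tsv <- function(x, path, comments = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(COORD_COMMENT, paste0("# ", comments)[seq_along(comments)]), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a commented TSV written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, quote = "")
}

#' Read a TSS annotation table
#'
#' Expected columns: `gene_id`, `gene_name`, `chrom`, `tss` (0-based bp),
#' `strand`, `exonic_length`, `gene_type`.
#'
#' @param path file path.
#' @return data.frame of TSS records.
#' @export
read_tss_table <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "chrom", "tss", "strand", "exonic_length")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("TSS table '", path, "' lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(df$exonic_length <= 0)) stop("TSS table: exonic_length must be > 0")
  df
}

#' Read/write binned count tracks
#'
#' Binned fragment counts are TSVs with columns `chrom`, `start`, `end`,
#' `count` over a regular bin grid.
#'
#' @param path file path.
#' @return data.frame with the four columns.
#' @export
read_bin_counts <- function(path) {
  df <- read_tsv(path)
  names(df)[names(df) == "bin_start"] <- "start"
  names(df)[names(df) == "bin_end"] <- "end"
  need <- c("chrom", "start", "end", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("bin-count table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

#' @rdname read_bin_counts
#' @param x bin-count data.frame.
#' @export
write_bin_counts <- function(x, path) {
  out <- x[, c("chrom", "start", "end", "count")]
  names(out) <- c("chrom", "bin_start", "bin_end", "count")
  write_tsv(out, path)
}

#' Read a gene x sample count matrix
#'
#' TSV with a header of sample names and gene identifiers in the first
#' column.
#'
#' @param path file path.
#' @return integer matrix with gene rownames.
#' @export
read_counts_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", row.names = 1L)
  as.matrix(df)
}

#' Write a gene x sample count matrix
#'
#' @param x matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_counts_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a position probability matrix
#'
#' Tab-delimited, 4 rows (A, C, G, T as the first column) x width, with a
#' header line `base pos1 pos2 ...`.
#'
#' @param path file path.
#' @return a [pwm_model()].
#' @export
read_pwm <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, row.names = 1L)
  m <- as.matrix(df)
  if (!identical(rownames(m), c("A", "C", "G", "T"))) {
    stop("PWM file '", path, "' must have rows A, C, G, T in order")
  }
  dimnames(m) <- list(c("A", "C", "G", "T"), NULL)
  pwm_model(m)
}

#' @rdname read_pwm
#' @param pwm a [pwm_model()].
#' @export
write_pwm <- function(pwm, path) {
  m <- pwm$probs
  df <- data.frame(base = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("base", paste0("pos", seq_len(ncol(m))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write genome FASTA
#'
#' Thin wrappers over Biostrings, returning plain named character vectors so
#' downstream string scanning works on base types.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
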