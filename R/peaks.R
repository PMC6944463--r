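#' Library-size-normalized log2 peak score
#'
#' The score contrasts IP against input fragment counts over a peak after
#' normalizing each sample by its own library size:
#' `score = log2((ip + 1) / (total_ip * width)) -
#'          log2((input + 1) / (total_input * width))`.
#' The width term cancels algebraically between the two halves; it is kept
#' because the per-sample normalized densities (count + 1 per total per bp)
#' are also reported on their own. A +1 pseudocount keeps scores finite for
#' empty peaks.
#'
#' @param ip_count,input_count fragment counts over the peak (vectorized).
#' @param total_ip,total_input library sizes (> 0).
#' @param width peak width in bp (> 0).
#' @return numeric score(s) in log2 units.
#' @export
peak_score <- function(ip_count, input_count, total_ip, total_input, width) {
  if (any(width <= 0)) stop("width must be > 0")
  if (any(total_ip <= 0) || any(total_input <= 0)) {
    stop("library totals must be > 0")
  }
  log2((ip_count + 1) / (total_ip * width)) -
    log2((input_count + 1) / (total_input * width))
}

#' Flag peaks associated with a transcription start site
#'
#' A peak is TSS-associated iff at least one of its nucleotides lies within
#' `flank` bp of a TSS, i.e. iff the peak interval overlaps the inclusive
#' window `[tss - flank, tss + flank]` (rendered half-open as
#' `[tss - flank, tss + flank + 1)`). Strand is ignored; all qualifying
#' genes are linked.
#'
#' @param peaks peak `data.frame` (`chrom`, `start`, `end`).
#' @param tss TSS `data.frame` (`gene_id`, `chrom`, `tss`).
#' @param flank window half-width in bp (default 250).
#' @return `peaks` with `tss_associated` (logical), `linked_genes`
#'   (comma-separated gene ids, `""` when none) and `n_tss_genes` appended.
#' @export
associate_tss <- function(peaks, tss, flank = 250) {
  peaks$tss_associated <- FALSE
  peaks$linked_genes <- ""
  peaks$n_tss_genes <- 0L
  if (nrow(peaks) == 0L || nrow(tss) == 0L) return(peaks)
  windows <- data.frame(chrom = tss$chrom,
                        start = pmax(0, tss$tss - flank),
                        end = tss$tss + flank + 1,
                        stringsAsFactors = FALSE)
  hits <- map_pairs(peaks, windows)
  if (nrow(hits) > 0L) {
    genes <- tapply(tss$gene_id[hits$b], hits$a,
                    function(g) paste(sort(unique(g)), collapse = ","))
    idx <- as.integer(names(genes))
    peaks$tss_associated[idx] <- TRUE
    peaks$linked_genes[idx] <- as.character(genes)
    counts <- tapply(tss$gene_id[hits$b], hits$a,
                     function(g) length(unique(g)))
    peaks$n_tss_genes[idx] <- as.integer(counts)
  }
  peaks
}

#' Categorize peaks across two conditions
#'
#' Cross-condition matching uses any-overlap (configurable minimum overlap in
#' bp). A wild-type peak overlapping at least one mutant peak is `common`
#' (the record keeps the wild-type coordinates); a wild-type peak with no
#' mutant overlap is `F80L_absent`; a mutant peak with no wild-type overlap
#' is `F80L_only`. Mutant peaks overlapping a wild-type peak are consumed by
#' the wild-type record, so
#' `|common| + |F80L_absent| == |WT|` and, for one-to-one overlaps,
#' `|common| + |F80L_only| == |MUT|`.
#'
#' @param wt_peaks,mut_peaks peak `data.frame`s from [assemble_peaks()].
#' @param min_overlap_bp minimum overlap (bp) for two peaks to match
#'   (default 1, i.e. any overlap).
#' @return `data.frame` of classified peaks: wild-type records first (with
#'   `category` `common`/`F80L_absent` and the matched mutant peak id in
#'   `mut_peak_id`), then `F80L_only` mutant records. Condition-specific
#'   count columns are suffixed `_wt` / `_mut` when present in the inputs.
#' @export
categorize <- function(wt_peaks, mut_peaks, min_overlap_bp = 1) {
  ov <- function(a, b) {
    if (nrow(a) == 0L || nrow(b) == 0L) {
      return(data.frame(a = integer(0), b = integer(0)))
    }
    h <- map_pairs(a, b)
    if (nrow(h) > 0L && min_overlap_bp > 1) {
      w <- pmin(a$end[h$a], b$end[h$b]) - pmax(a$start[h$a], b$start[h$b])
      h <- h[w >= min_overlap_bp, , drop = FALSE]
    }
    h
  }
  hits <- ov(wt_peaks, mut_peaks)
  base_cols <- function(p) p[, intersect(c("id", "chrom", "start", "end",
                                           "summit"), names(p)), drop = FALSE]
  wt <- base_cols(wt_peaks)
  if (nrow(wt) > 0L) {
    wt$category <- ifelse(seq_len(nrow(wt)) %in% hits$a, "common", "F80L_absent")
    first_match <- tapply(hits$b, hits$a, min)
    wt$mut_peak_id <- NA_character_
    if (length(first_match) > 0L) {
      wt$mut_peak_id[as.integer(names(first_match))] <-
        mut_peaks$id[as.integer(first_match)]
    }
    wt$ip_count_wt <- wt_peaks$ip_count
    wt$input_count_wt <- wt_peaks$input_count
  }
  only_idx <- setdiff(seq_len(nrow(mut_peaks)), hits$b)
  mo <- base_cols(mut_peaks[only_idx, , drop = FALSE])
  if (nrow(mo) > 0L) {
    mo$category <- "F80L_only"
    mo$mut_peak_id <- mut_peaks$id[only_idx]
    mo$ip_count_wt <- NA_real_
    mo$input_count_wt <- NA_real_
    mo$id <- paste0("mut_", mo$id)
  }
  out <- rbind(if (nrow(wt) > 0L) wt else NULL,
               if (nrow(mo) > 0L) mo else NULL)
  if (is.null(out)) {
    out <- data.frame(id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      summit = numeric(0), category = character(0),
                      mut_peak_id = character(0), ip_count_wt = numeric(0),
                      input_count_wt = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Attach per-condition counts and scores to classified peaks
#'
#' Sums each condition's binned IP and input counts over every classified
#' peak interval and computes the per-condition [peak_score()].
#'
#' @param classified output of [categorize()].
#' @param wt_ip,wt_input,mut_ip,mut_input bin-count `data.frame`s.
#' @return `classified` with `ip_count_wt`, `input_count_wt`,
#'   `ip_count_mut`, `input_count_mut`, `score_wt`, `score_mut` columns.
#' @export
score_classified_peaks <- function(classified, wt_ip, wt_input, mut_ip,
                                   mut_input) {
  if (nrow(classified) == 0L) {
    for (cl in c("ip_count_wt", "input_count_wt", "ip_count_mut",
                 "input_count_mut", "score_wt", "score_mut")) {
      classified[[cl]] <- numeric(0)
    }
    return(classified)
  }
  w <- interval_width(classified)
  classified$ip_count_wt <- count_in_intervals(wt_ip, classified)
  classified$input_count_wt <- count_in_intervals(wt_input, classified)
  classified$ip_count_mut <- count_in_intervals(mut_ip, classified)
  classified$input_count_mut <- count_in_intervals(mut_input, classified)
  classified$score_wt <- peak_score(classified$ip_count_wt,
                                    classified$input_count_wt,
                                    sum(wt_ip$count), sum(wt_input$count), w)
  classified$score_mut <- peak_score(classified$ip_count_mut,
                                     classified$input_count_mut,
                                     sum(mut_ip$count), sum(mut_input$count), w)
  classified
}

#' Long-format per-category score table
#'
#' One row per classified peak and condition, for ECDF/density plotting;
#' per-category-and-condition quantiles are attached as the
#' `"quantiles"` attribute.
#'
#' @param classified classified peaks carrying `score_wt` and `score_mut`.
#' @return long `data.frame` with columns `peak_id`, `category`, `condition`,
#'   `score`.
#' @export
score_distribution <- function(classified) {
  if (nrow(classified) == 0L) {
    long <- data.frame(peak_id = character(0), category = character(0),
                       condition = character(0), score = numeric(0))
    attr(long, "quantiles") <- NULL
    return(long)
  }
  long <- do.call(rbind, lapply(c("WT", "MUT"), function(cond) {
    col <- if (cond == "WT") "score_wt" else "score_mut"
    data.frame(peak_id = classified$id, category = classified$category,
               condition = cond, score = classified[[col]],
               stringsAsFactors = FALSE)
  }))
  long <- long[!is.na(long$score), , drop = FALSE]
  rownames(long) <- NULL
  qs <- if (nrow(long) > 0L) {
    do.call(rbind, lapply(split(long, list(long$category, long$condition),
                                drop = TRUE), function(g) {
      data.frame(category = g$category[1L], condition = g$condition[1L],
                 n = nrow(g), t(stats::quantile(g$score,
                                                c(0.25, 0.5, 0.75))),
                 check.names = FALSE, stringsAsFactors = FALSE)
    }))
  } else NULL
  attr(long, "quantiles") <- qs
  long
}
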