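#' Call direct targets of the factor
#'
#' A direct target is a changing gene (status `up` or `down`) linked by the
#' +/-250 bp TSS rule to a TSS-associated peak of category `F80L_absent`
#' (bound in wild type, lost in the mutant). Records are ranked within each
#' direction by absolute log2 fold change, descending, with deterministic
#' ties broken by gene id. A gene linked to both a common and an
#' `F80L_absent` peak still qualifies unless `require_all_lost = TRUE`.
#'
#' @param classified classified peak table carrying `category`,
#'   `tss_associated` and `linked_genes` columns (see [associate_tss()]).
#' @param expr_results expression result table with `gene_id`, `log2fc`,
#'   `adj_p`, `status`.
#' @param tss optional TSS table; when given, the TSS-to-peak distance is
#'   reported (0 if the TSS falls inside the peak).
#' @param require_all_lost if `TRUE`, genes also linked to a `common` peak
#'   are excluded.
#' @return `data.frame` of direct targets: `gene_id`, `direction`, `log2fc`,
#'   `adj_p`, `peak_id`, `category`, `tss_distance`; `down` block first,
#'   each ranked by |log2fc| descending.
#' @export
call_direct_targets <- function(classified, expr_results, tss = NULL,
                                require_all_lost = FALSE) {
  empty <- data.frame(gene_id = character(0), direction = character(0),
                      log2fc = numeric(0), adj_p = numeric(0),
                      peak_id = character(0), category = character(0),
                      tss_distance = numeric(0), stringsAsFactors = FALSE)
  links <- peak_gene_links(classified)
  absent <- links[links$category == "F80L_absent", , drop = FALSE]
  if (require_all_lost) {
    common_genes <- unique(links$gene_id[links$category == "common"])
    absent <- absent[!absent$gene_id %in% common_genes, , drop = FALSE]
  }
  changing <- expr_results[expr_results$status %in% c("up", "down"), ,
                           drop = FALSE]
  hit <- merge(absent, changing[, c("gene_id", "log2fc", "adj_p", "status")],
               by = "gene_id")
  if (nrow(hit) == 0L) return(empty)
  # one record per gene: keep the closest/first peak deterministically
  hit <- hit[order(hit$gene_id, hit$peak_id), , drop = FALSE]
  hit <- hit[!duplicated(hit$gene_id), , drop = FALSE]
  hit$direction <- hit$status
  hit$tss_distance <- NA_real_
  if (!is.null(tss)) {
    ti <- match(hit$gene_id, tss$gene_id)
    pi <- match(hit$peak_id, classified$id)
    pos <- tss$tss[ti]
    s <- classified$start[pi]; e <- classified$end[pi]
    hit$tss_distance <- ifelse(pos >= s & pos < e, 0,
                               pmin(abs(pos - s), abs(pos - (e - 1))))
  }
  hit <- hit[order(match(hit$direction, c("down", "up")),
                   -abs(hit$log2fc), hit$gene_id), , drop = FALSE]
  rownames(hit) <- NULL
  hit[, c("gene_id", "direction", "log2fc", "adj_p", "peak_id", "category",
          "tss_distance")]
}

# Expand the comma-separated linked_genes column into one row per
# (peak, gene) pair, restricted to TSS-associated peaks.
peak_gene_links <- function(classified) {
  sel <- classified[classified$tss_associated, , drop = FALSE]
  if (nrow(sel) == 0L) {
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  genes <- strsplit(sel$linked_genes, ",", fixed = TRUE)
  data.frame(peak_id = rep(sel$id, lengths(genes)),
             gene_id = unlist(genes),
             category = rep(sel$category, lengths(genes)),
             stringsAsFactors = FALSE)
}

#' Summarize a classified peak table into headline counts
#'
#' Counts the peak universe per condition (wild type = `common` +
#' `F80L_absent`; mutant = `common` + `F80L_only`), the TSS-associated
#' counts per category, and the fraction of TSS-associated `F80L_absent`
#' peaks with no motif hit within the scanning window (when a `tam_count`
#' column is present).
#'
#' @param classified classified peak table.
#' @return named list of counts/fractions.
#' @export
summarize_peaks <- function(classified) {
  cat_tab <- function(x) {
    vapply(c("common", "F80L_absent", "F80L_only"),
           function(k) sum(x$category == k), 0L)
  }
  all_cat <- cat_tab(classified)
  tssd <- classified[isTRUE_vec(classified$tss_associated), , drop = FALSE]
  tss_cat <- cat_tab(tssd)
  out <- list(
    n_peaks_wt = unname(all_cat["common"] + all_cat["F80L_absent"]),
    n_peaks_mut = unname(all_cat["common"] + all_cat["F80L_only"]),
    n_common = unname(all_cat["common"]),
    n_f80l_absent = unname(all_cat["F80L_absent"]),
    n_f80l_only = unname(all_cat["F80L_only"]),
    n_tss_wt = unname(tss_cat["common"] + tss_cat["F80L_absent"]),
    n_tss_common = unname(tss_cat["common"]),
    n_tss_f80l_absent = unname(tss_cat["F80L_absent"]),
    n_tss_f80l_only = unname(tss_cat["F80L_only"]))
  if ("tam_count" %in% names(classified)) {
    ab <- tssd[tssd$category == "F80L_absent", , drop = FALSE]
    out$f80l_absent_no_tam_fraction <-
      if (nrow(ab) > 0L) mean(ab$tam_count == 0) else NA_real_
    co <- tssd[tssd$category == "common", , drop = FALSE]
    out$common_no_tam_fraction <-
      if (nrow(co) > 0L) mean(co$tam_count == 0) else NA_real_
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Export the master peak and expression tables plus a summary
#'
#' Writes the classified-peak master TSV (peak coordinates, category,
#' per-condition counts and scores, motif annotation, linked genes), the
#' expression results TSV, the direct-target TSV and a summary JSON holding
#' every headline number. Columns and row order are stable across runs.
#'
#' @param classified classified peak table (fully annotated).
#' @param expr_results expression result table.
#' @param direct_targets direct-target table from [call_direct_targets()].
#' @param out_dir output directory.
#' @return the summary list, invisibly.
#' @export
export_master_table <- function(classified, expr_results, direct_targets,
                                out_dir) {
  if (is.null(classified) || is.null(expr_results) ||
      is.null(direct_targets)) {
    missing <- c("classified peaks", "expression results",
                 "direct targets")[c(is.null(classified),
                                     is.null(expr_results),
                                     is.null(direct_targets))]
    stop("pipeline stage output missing: ", paste(missing, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(classified, file.path(out_dir, "peaks_master.tsv"))
  write_tsv(expr_results, file.path(out_dir, "expression.tsv"))
  write_tsv(direct_targets, file.path(out_dir, "direct_targets.tsv"))
  summary <- summarize_peaks(classified)
  summary$n_genes_down <- sum(expr_results$status == "down")
  summary$n_genes_up <- sum(expr_results$status == "up")
  summary$n_genes_not_expressed <- sum(expr_results$status == "not_expressed")
  summary$n_direct_targets_down <- sum(direct_targets$direction == "down")
  summary$n_direct_targets_up <- sum(direct_targets$direction == "up")
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Recompute headline counts from supplementary-style tables
#'
#' Takes the master peak table (S1-style) and the expression table
#' (S5-style) as TSVs and recomputes, by direct counting: the per-condition
#' peak universes, the TSS-associated counts per category, the changing-gene
#' counts at the configured cutoffs, the direct-target counts (changing
#' genes linked to TSS-associated `F80L_absent` peaks) and the fraction of
#' `F80L_absent` peaks without a nearby motif.
#'
#' Required peak-table columns: `category`, `n_tss_genes`, `tam_count`,
#' `linked_genes`. Required expression-table columns: `gene_id`, `log2fc`,
#' `adj_p`.
#'
#' @param s1_path path to the peak TSV.
#' @param s5_path path to the expression TSV.
#' @param fc_threshold,alpha changing-gene cutoffs.
#' @return named list of recomputed counts.
#' @export
acceptance_from_supplementary <- function(s1_path, s5_path,
                                          fc_threshold = 0.5, alpha = 0.05) {
  s1 <- read_tsv(s1_path)
  s5 <- read_tsv(s5_path)
  need1 <- c("category", "n_tss_genes", "tam_count", "linked_genes")
  need5 <- c("gene_id", "log2fc", "adj_p")
  miss <- c(paste0("peak table: ", setdiff(need1, names(s1))),
            paste0("expression table: ", setdiff(need5, names(s5))))
  miss <- miss[!endsWith(miss, ": ")]
  if (length(miss) > 0L) {
    stop("schema error; missing column(s): ", paste(miss, collapse = "; "))
  }
  s1$category <- normalize_category(s1$category)
  s1$tss_associated <- s1$n_tss_genes >= 1
  s1$id <- if ("id" %in% names(s1)) s1$id else sprintf("p%05d", seq_len(nrow(s1)))
  counts <- summarize_peaks(s1)

  sig <- !is.na(s5$adj_p) & s5$adj_p <= alpha
  down <- sig & s5$log2fc <= -fc_threshold
  up <- sig & s5$log2fc >= fc_threshold
  counts$n_genes_down <- sum(down)
  counts$n_genes_up <- sum(up)

  expr <- data.frame(gene_id = s5$gene_id, log2fc = s5$log2fc,
                     adj_p = s5$adj_p,
                     status = ifelse(down, "down",
                                     ifelse(up, "up", "unchanged")),
                     stringsAsFactors = FALSE)
  dt <- call_direct_targets(s1, expr)
  counts$n_direct_targets_down <- sum(dt$direction == "down")
  counts$n_direct_targets_up <- sum(dt$direction == "up")
  counts
}

# Accept the category spellings used in exported spreadsheets.
normalize_category <- function(x) {
  y <- tolower(gsub("[ -]", "_", x))
  map <- c(common = "common", f80l_absent = "F80L_absent",
           f80l_only = "F80L_only")
  out <- unname(map[y])
  if (any(is.na(out))) {
    stop("unknown peak category value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Run the full synthetic occupancy pipeline
#'
#' Generates the synthetic experiment, calls peaks in both conditions from
#' the simulated bin counts, classifies peaks across conditions with scores
#' and TSS association, scans the genome with the default motif matrix and
#' annotates nearest hits, builds per-category consensus matrices and their
#' half-IC contrast, runs the expression analysis, and calls direct
#' targets.
#'
#' @param config a [synthetic_config()].
#' @param fdr bin-enrichment FDR threshold (default 0.05).
#' @param max_gap peak-assembly gap tolerance in bp (default 0).
#' @param tam_flank motif search window half-width around summits
#'   (default 1000 bp).
#' @param out_dir optional directory; when given, all inputs and outputs are
#'   written there via [write_synthetic()] and [export_master_table()].
#' @return list with `truth`, `chip` (per condition), `peaks` (per
#'   condition), `classified`, `hits`, `consensus` (per category),
#'   `ic_contrast`, `expression`, `direct_targets`, `summary`.
#' @export
run_synthetic_pipeline <- function(config = synthetic_config(), fdr = 0.05,
                                   max_gap = 0, tam_flank = 1000,
                                   out_dir = NULL) {
  truth <- generate_genome(config)
  chip <- list(WT = simulate_chip_counts(truth, "WT"),
               MUT = simulate_chip_counts(truth, "MUT"))
  calls <- lapply(chip, function(cc) {
    call_peaks(cc$ip, cc$input, fdr = fdr, max_gap = max_gap)
  })
  classified <- categorize(calls$WT$peaks, calls$MUT$peaks)
  classified <- score_classified_peaks(classified, chip$WT$ip, chip$WT$input,
                                       chip$MUT$ip, chip$MUT$input)
  classified <- associate_tss(classified, truth$tss, flank = 250)

  pwm <- tam_default_pwm()
  hits <- scan_genome(truth$genome, pwm)
  nt <- nearest_tam(classified, hits, flank = tam_flank)
  classified <- cbind(classified, nt)

  consensus <- list()
  for (cat in c("common", "F80L_absent")) {
    consensus[[cat]] <- tryCatch(
      build_consensus(classified, hits, cat, summit_flank = 250),
      error = function(e) NULL)
  }
  ic_contrast <- if (!is.null(consensus$common) &&
                     !is.null(consensus$F80L_absent)) {
    ic_half_contrast(consensus$common$pwm, consensus$F80L_absent$pwm,
                     split = TAM_SPLIT)
  } else NULL

  rna <- simulate_rna_counts(truth)
  condition <- rep(c("WT", "MUT"), each = config$n_replicates)
  expr <- expression_pipeline(rna, truth$tss$exonic_length, condition,
                              gene_type = truth$tss$gene_type)
  direct <- call_direct_targets(classified, expr$results, tss = truth$tss)

  summary <- summarize_peaks(classified)
  summary$n_genes_down <- sum(expr$results$status == "down")
  summary$n_genes_up <- sum(expr$results$status == "up")
  summary$n_direct_targets_down <- sum(direct$direction == "down")
  summary$n_direct_targets_up <- sum(direct$direction == "up")

  out <- list(truth = truth, chip = chip, peaks = lapply(calls, `[[`, "peaks"),
              bins = lapply(calls, `[[`, "bins"), classified = classified,
              hits = hits, consensus = consensus, ic_contrast = ic_contrast,
              rna = rna, expression = expr, direct_targets = direct,
              summary = summary)
  if (!is.null(out_dir)) {
    write_synthetic(truth, out_dir)
    export_master_table(classified, expr$results, direct, out_dir)
  }
  out
}
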