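## Synthetic two-condition occupancy experiment with full ground truth.
##
## The generator emulates a wild-type vs. mutant transcription-factor
## ChIP-seq + RNA-seq study: a uniform-background genome carries planted
## 22-bp motif instances near a subset of promoters; site occupancy follows
## a logistic function of the motif's 5'-half and 3'-half match deficits,
## with the mutant both globally depleted (abundance factor `delta`) and
## more sensitive to 3'-half degradation (`a3_mut > a3_wt`); binned IP/input
## fragment counts are Poisson around the occupancy-scaled enrichment; and
## an NB RNA-seq matrix couples expression loss to occupancy loss at
## designated direct-target genes.

TAM_CONSENSUS <- "ACCTGGGAAGTGCTGTAGTTCA"  # 5' CTGGGA anchor, 3' TGTAGT anchor
TAM_WIDTH <- 22L
TAM_SPLIT <- 11L  # first position (0-based) of the 3' half

# Seed offsets per generator stage, so one config seed drives every stage
# deterministically but with independent streams.
SEED_GENOME <- 101L
SEED_CHIP_WT <- 211L
SEED_CHIP_MUT <- 223L
SEED_RNA <- 307L

# Run code under a fixed seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Generator PWM for planted motif instances
#'
#' The 5' half is near-deterministic (consensus probability 0.99); the 3'
#' half carries the consensus base with probability 0.95 (`"strong"` sites)
#' or 0.70 (`"weak"` sites), remaining mass spread evenly. The `"strong"`
#' matrix also serves as the reference for the per-half match deficits
#' recorded in the truth table.
#'
#' @param mode `"strong"` or `"weak"` 3'-half fidelity.
#' @return a [pwm_model()] of width 22.
#' @export
tam_generator_pwm <- function(mode = c("strong", "weak")) {
  mode <- match.arg(mode)
  p3 <- if (mode == "strong") 0.95 else 0.70
  cons <- strsplit(TAM_CONSENSUS, "")[[1L]]
  probs <- vapply(seq_len(TAM_WIDTH), function(j) {
    pm <- if (j <= TAM_SPLIT) 0.99 else p3
    col <- rep((1 - pm) / 3, 4)
    col[match(cons[j], c("A", "C", "G", "T"))] <- pm
    col
  }, numeric(4))
  pwm_model(probs)
}

#' Default scanning PWM shipped for synthetic runs
#'
#' Built from the motif's two consensus anchors: the 5' half is modelled
#' with high confidence (consensus probability 0.9) and the 3' half — known
#' to tolerate degradation — with lower confidence (0.55), so scanning
#' still recovers 3'-degraded instances.
#'
#' @return a [pwm_model()] of width 22.
#' @export
tam_default_pwm <- function() {
  cons <- strsplit(TAM_CONSENSUS, "")[[1L]]
  probs <- vapply(seq_len(TAM_WIDTH), function(j) {
    pm <- if (j <= TAM_SPLIT) 0.9 else 0.55
    col <- rep((1 - pm) / 3, 4)
    col[match(cons[j], c("A", "C", "G", "T"))] <- pm
    col
  }, numeric(4))
  pwm_model(probs)
}

# Per-half log-odds deficits of a 22-mer against the strong generator PWM:
# (score of the half) - (maximum achievable score of the half); <= 0,
# 0 for a perfect consensus half.
half_deficits <- function(seqs) {
  ref <- pwm_logodds(tam_generator_pwm("strong"))
  mx <- apply(ref, 2L, max)
  out <- t(vapply(seqs, function(s) {
    codes <- encode_seq(s)
    per <- ref[cbind(codes, seq_len(TAM_WIDTH))]
    c(sum(per[1:TAM_SPLIT]) - sum(mx[1:TAM_SPLIT]),
      sum(per[(TAM_SPLIT + 1L):TAM_WIDTH]) -
        sum(mx[(TAM_SPLIT + 1L):TAM_WIDTH]))
  }, numeric(2), USE.NAMES = FALSE))
  colnames(out) <- c("s5", "s3")
  out
}

#' Configuration for the synthetic occupancy experiment
#'
#' Defaults define the package's reference study conditions: a 2-Mb genome
#' with 300 genes of which 150 promoters are bound, 300-bp count bins,
#' two replicates per condition, a mutant protein-abundance factor of 0.46,
#' and a strong/weak 3'-half mixture in equal proportions. The logistic
#' occupancy coefficients (`a5`, `a3_wt`, `a3_mut`, `c0`) are calibrated so
#' a consensus-perfect site has wild-type occupancy ~0.95 and a typical
#' 3'-degraded site stays bound in wild type (~0.8) but collapses in the
#' mutant.
#'
#' @param genome_length genome size in bp.
#' @param n_genes number of genes/TSSs.
#' @param n_bound_promoters number of promoters that receive a binding site.
#' @param bin_width ChIP count bin width (bp).
#' @param depth_ip,depth_input expected background fragment totals per
#'   sample.
#' @param background_rate expected background fragments per bp (input).
#' @param a5,a3_wt,a3_mut occupancy sensitivity to the 5'- and 3'-half match
#'   deficits (per bit, deficits are <= 0); `a3_mut > a3_wt` makes the
#'   mutant hypersensitive to 3' degradation.
#' @param c0 logistic intercept.
#' @param delta global mutant abundance factor in (0, 1].
#' @param enrichment_max IP fold enrichment over background at occupancy 1.
#' @param frac_no_motif fraction of bound promoters occupied without a
#'   planted motif (tethered/indirect binding; weak-equivalent affinity).
#' @param mixture_weight_strong probability that a motif-bearing site is
#'   `"strong"` (vs `"weak"` 3' half).
#' @param n_direct_down genes whose expression is coupled to occupancy loss.
#' @param n_indirect genes changing without a bound promoter.
#' @param n_silent genes expressed below the RPKM filter.
#' @param frac_noncoding fraction of genes labelled non-protein-coding.
#' @param effect_log2fc mean expression effect (log2) at full occupancy
#'   loss.
#' @param nb_dispersion RNA-seq NB dispersion.
#' @param n_replicates RNA-seq replicates per condition.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   expression means.
#' @param seed integer seed driving every stage.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(genome_length = 2e6,
                             n_genes = 300,
                             n_bound_promoters = 150,
                             bin_width = 300,
                             depth_ip = 2e5,
                             depth_input = 2e5,
                             background_rate = 0.1,
                             a5 = 0.1,
                             a3_wt = 0.08,
                             a3_mut = 0.30,
                             c0 = 2.94,
                             delta = 0.46,
                             enrichment_max = 8,
                             frac_no_motif = 0.15,
                             mixture_weight_strong = 0.5,
                             n_direct_down = 40,
                             n_indirect = 40,
                             n_silent = 30,
                             frac_noncoding = 0.05,
                             effect_log2fc = 1.5,
                             nb_dispersion = 0.05,
                             n_replicates = 2,
                             baseline_meanlog = log(300),
                             baseline_sdlog = 0.8,
                             seed = 1L) {
  cfg <- list(genome_length = genome_length, n_genes = n_genes,
              n_bound_promoters = n_bound_promoters, bin_width = bin_width,
              motif_width = TAM_WIDTH, depth_ip = depth_ip,
              depth_input = depth_input, background_rate = background_rate,
              a5 = a5, a3_wt = a3_wt, a3_mut = a3_mut, c0 = c0,
              delta = delta, enrichment_max = enrichment_max,
              frac_no_motif = frac_no_motif,
              mixture_weight_strong = mixture_weight_strong,
              n_direct_down = n_direct_down, n_indirect = n_indirect,
              n_silent = n_silent, frac_noncoding = frac_noncoding,
              effect_log2fc = effect_log2fc, nb_dispersion = nb_dispersion,
              n_replicates = n_replicates,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog, seed = as.integer(seed))
  if (cfg$delta <= 0 || cfg$delta > 1) stop("delta must lie in (0, 1]")
  if (cfg$a3_mut < cfg$a3_wt || cfg$a3_wt < 0) {
    stop("need a3_mut >= a3_wt >= 0")
  }
  if (cfg$n_bound_promoters > cfg$n_genes) {
    stop("n_bound_promoters must be <= n_genes")
  }
  if (cfg$n_replicates < 2) stop("n_replicates must be >= 2")
  if (any(unlist(cfg[c("genome_length", "n_genes", "bin_width", "depth_ip",
                       "depth_input")]) <= 0)) {
    stop("sizes, depths and bin_width must be positive")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate the synthetic genome, TSS annotation and planted sites
#'
#' Background sequence is i.i.d. uniform over A/C/G/T. TSSs are placed on a
#' regular grid (spacing >= 2 kb enforced) with +/-200 bp jitter. Each bound
#' promoter receives one 22-bp site centred within +/-100 bp of its TSS:
#' motif-bearing sites are sampled from [tam_generator_pwm()] (strong or
#' weak 3' half per the configured mixture) and written into the genome on a
#' random strand; `no_motif` sites are occupied without a planted sequence
#' (their affinity deficits are drawn from the weak class but no motif is
#' written). Per-site occupancies are
#' `occ_wt  = plogis(a5*s5 + a3_wt*s3 + c0)` and
#' `occ_mut = delta * plogis(a5*s5 + a3_mut*s3 + c0)`
#' where `s5`, `s3` are the (non-positive) per-half match deficits.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_truth`: list with `config`, `genome`
#'   (named character vector), `tss` (TSS table), `sites` (per-site truth
#'   incl. deficits and occupancies) and `genes` (per-gene truth with
#'   baseline means, true log2 effects and direct/indirect/null labels).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  spacing <- floor(cfg$genome_length / cfg$n_genes)
  if (spacing < 2000) {
    stop("genome too short: TSS spacing would be ", spacing,
         " bp (< 2000 bp) for ", cfg$n_genes, " genes")
  }
  with_seed(cfg$seed + SEED_GENOME, {
    bases <- c("A", "C", "G", "T")
    genome_vec <- sample(bases, cfg$genome_length, replace = TRUE)

    gene_id <- sprintf("g%04d", seq_len(cfg$n_genes))
    tss_pos <- round((seq_len(cfg$n_genes) - 0.5) * spacing +
                       stats::runif(cfg$n_genes, -200, 200))
    tss_pos <- pmin(pmax(tss_pos, 300), cfg$genome_length - 300)
    tss <- data.frame(gene_id = gene_id, gene_name = toupper(gene_id),
                      chrom = "chrS", tss = tss_pos,
                      strand = sample(c("+", "-"), cfg$n_genes, TRUE),
                      exonic_length = round(stats::runif(cfg$n_genes, 500, 5000)),
                      gene_type = ifelse(
                        stats::runif(cfg$n_genes) < cfg$frac_noncoding,
                        "lincRNA", "protein_coding"),
                      stringsAsFactors = FALSE)

    bound_idx <- sort(sample.int(cfg$n_genes, cfg$n_bound_promoters))
    n_sites <- length(bound_idx)
    cls <- ifelse(stats::runif(n_sites) < cfg$frac_no_motif, "no_motif",
                  ifelse(stats::runif(n_sites) < cfg$mixture_weight_strong,
                         "strong", "weak"))
    centre <- tss$tss[bound_idx] + round(stats::runif(n_sites, -100, 100))
    start <- centre - TAM_WIDTH %/% 2
    strand <- sample(c("+", "-"), n_sites, TRUE)

    sample_site <- function(mode) {
      pw <- tam_generator_pwm(mode)
      paste(vapply(seq_len(TAM_WIDTH), function(j) {
        sample(bases, 1L, prob = pw$probs[, j])
      }, ""), collapse = "")
    }
    seqs <- vapply(cls, function(cl) {
      sample_site(if (cl == "strong") "strong" else "weak")
    }, "", USE.NAMES = FALSE)

    planted <- cls != "no_motif"
    for (i in which(planted)) {
      s <- if (strand[i] == "+") seqs[i] else revcomp(seqs[i])
      genome_vec[(start[i] + 1L):(start[i] + TAM_WIDTH)] <-
        strsplit(s, "")[[1L]]
    }

    def <- half_deficits(seqs)
    lin_wt <- cfg$a5 * def[, "s5"] + cfg$a3_wt * def[, "s3"] + cfg$c0
    lin_mut <- cfg$a5 * def[, "s5"] + cfg$a3_mut * def[, "s3"] + cfg$c0
    occ_wt <- stats::plogis(lin_wt)
    occ_mut <- cfg$delta * stats::plogis(lin_mut)

    sites <- if (n_sites == 0L) {
      data.frame(site_id = character(0), gene_id = character(0),
                 chrom = character(0), start = numeric(0), end = numeric(0),
                 strand = character(0), class = character(0),
                 sequence = character(0), s5 = numeric(0), s3 = numeric(0),
                 occupancy_wt = numeric(0), occupancy_mut = numeric(0),
                 stringsAsFactors = FALSE)
    } else data.frame(site_id = sprintf("site_%04d", seq_len(n_sites)),
                        gene_id = tss$gene_id[bound_idx],
                        chrom = "chrS", start = start,
                        end = start + TAM_WIDTH, strand = strand,
                        class = cls,
                        sequence = ifelse(planted, seqs, NA_character_),
                        s5 = def[, "s5"], s3 = def[, "s3"],
                        occupancy_wt = occ_wt, occupancy_mut = occ_mut,
                        stringsAsFactors = FALSE)

    genes <- build_gene_truth(cfg, tss, sites)
    genome <- c(chrS = paste(genome_vec, collapse = ""))
    structure(list(config = cfg, genome = genome, tss = tss, sites = sites,
                   genes = genes),
              class = "synthetic_truth")
  })
}

# Per-gene expression truth: baselines, labels and true log2 effects.
# Direct-down genes are drawn from protein-coding bound promoters whose
# occupancy collapses in the mutant (occ_mut < 0.1, occ_wt >= 0.5); their
# effect scales with the occupancy-loss fraction. Indirect genes change
# without a bound promoter. Only protein-coding genes receive effects, since
# the differential analysis is restricted to them.
build_gene_truth <- function(cfg, tss, sites) {
  n <- nrow(tss)
  genes <- data.frame(gene_id = tss$gene_id,
                      baseline_mean = stats::rlnorm(n, cfg$baseline_meanlog,
                                                    cfg$baseline_sdlog),
                      true_log2fc = 0, label = "null", silent = FALSE,
                      stringsAsFactors = FALSE)
  coding <- tss$gene_id[tss$gene_type == "protein_coding"]
  lost <- sites$gene_id[sites$occupancy_mut < 0.1 & sites$occupancy_wt >= 0.5]
  lost <- intersect(lost, coding)
  n_direct <- min(cfg$n_direct_down, length(lost))
  direct <- if (n_direct > 0) sample(lost, n_direct) else character(0)
  loss <- (sites$occupancy_wt - sites$occupancy_mut) / sites$occupancy_wt
  di <- match(direct, genes$gene_id)
  genes$label[di] <- "direct"
  genes$true_log2fc[di] <-
    -cfg$effect_log2fc * loss[match(direct, sites$gene_id)]

  unbound <- intersect(setdiff(genes$gene_id, sites$gene_id), coding)
  n_ind <- min(cfg$n_indirect, length(unbound))
  indirect <- if (n_ind > 0) sample(unbound, n_ind) else character(0)
  ii <- match(indirect, genes$gene_id)
  genes$label[ii] <- "indirect"
  sign_ind <- ifelse(stats::runif(n_ind) < 0.6, -1, 1)
  genes$true_log2fc[ii] <- sign_ind * abs(stats::rnorm(n_ind, 1.2, 0.3))

  still_null <- setdiff(unbound, indirect)
  n_sil <- min(cfg$n_silent, length(still_null))
  silent <- if (n_sil > 0) sample(still_null, n_sil) else character(0)
  si <- match(silent, genes$gene_id)
  genes$silent[si] <- TRUE
  genes$baseline_mean[si] <- 0.05
  genes
}

#' Simulate binned ChIP fragment counts for one condition
#'
#' Input bins are Poisson with mean `depth_input * bin_width /
#' genome_length` (scaled for a partial terminal bin). IP bins overlapping a
#' planted site have mean `background * (1 + (enrichment_max - 1) *
#' occupancy)` (the site's condition-specific occupancy; the maximum over
#' sites when a bin overlaps several), background elsewhere, so occupancy 1
#' yields exactly `enrichment_max`-fold enrichment.
#'
#' @param truth a `synthetic_truth` from [generate_genome()].
#' @param condition `"WT"` or `"MUT"`.
#' @param config configuration; defaults to the truth's own.
#' @return list with `ip` and `input` bin-count `data.frame`s plus
#'   `total_ip`, `total_input` (realized sums).
#' @export
simulate_chip_counts <- function(truth, condition = c("WT", "MUT"),
                                 config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  condition <- match.arg(condition)
  cfg <- config
  starts <- seq(0, cfg$genome_length - 1, by = cfg$bin_width)
  ends <- pmin(starts + cfg$bin_width, cfg$genome_length)
  wfrac <- (ends - starts) / cfg$bin_width
  occ_col <- if (condition == "WT") "occupancy_wt" else "occupancy_mut"
  occ_bin <- numeric(length(starts))
  if (nrow(truth$sites) > 0L) {
    bins_iv <- data.frame(chrom = "chrS", start = starts, end = ends)
    hits <- map_pairs(bins_iv,
                      truth$sites[, c("chrom", "start", "end")])
    if (nrow(hits) > 0L) {
      mx <- tapply(truth$sites[[occ_col]][hits$b], hits$a, max)
      occ_bin[as.integer(names(mx))] <- as.numeric(mx)
    }
  }
  m_in <- cfg$depth_input * cfg$bin_width / cfg$genome_length
  m_ip <- cfg$depth_ip * cfg$bin_width / cfg$genome_length
  lam_in <- m_in * wfrac
  lam_ip <- m_ip * wfrac * (1 + (cfg$enrichment_max - 1) * occ_bin)
  seed <- cfg$seed + if (condition == "WT") SEED_CHIP_WT else SEED_CHIP_MUT
  with_seed(seed, {
    ip <- data.frame(chrom = "chrS", start = starts, end = ends,
                     count = stats::rpois(length(starts), lam_ip),
                     stringsAsFactors = FALSE)
    input <- data.frame(chrom = "chrS", start = starts, end = ends,
                        count = stats::rpois(length(starts), lam_in),
                        stringsAsFactors = FALSE)
    list(ip = ip, input = input, total_ip = sum(ip$count),
         total_input = sum(input$count))
  })
}

#' Simulate the RNA-seq count matrix
#'
#' Counts are negative binomial with the configured dispersion around
#' per-gene means: wild-type means equal the baseline; mutant means are
#' `baseline * 2^true_log2fc` (for direct targets the true effect already
#' scales with the occupancy-loss fraction). A zero dispersion yields
#' Poisson counts.
#'
#' @param truth a `synthetic_truth` from [generate_genome()].
#' @param config configuration; defaults to the truth's own.
#' @return integer matrix, genes x (`n_replicates` WT then `n_replicates`
#'   MUT samples), with gene rownames.
#' @export
simulate_rna_counts <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- config
  genes <- truth$genes
  mu_wt <- genes$baseline_mean
  mu_mut <- genes$baseline_mean * 2^genes$true_log2fc
  nr <- cfg$n_replicates
  draw <- function(mu) {
    if (cfg$nb_dispersion <= 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
  }
  with_seed(cfg$seed + SEED_RNA, {
    cols <- c(lapply(seq_len(nr), function(i) draw(mu_wt)),
              lapply(seq_len(nr), function(i) draw(mu_mut)))
    m <- do.call(cbind, cols)
    dimnames(m) <- list(genes$gene_id,
                        c(paste0("WT_", seq_len(nr)),
                          paste0("MUT_", seq_len(nr))))
    m
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic occupancy experiment (seed ", x$config$seed, ")\n", sep = "")
  cat("  genome: ", x$config$genome_length, " bp; ", nrow(x$tss), " genes; ",
      nrow(x$sites), " bound promoters\n", sep = "")
  cat("  site classes:",
      paste(names(table(x$sites$class)), table(x$sites$class),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write all synthetic outputs to disk
#'
#' Emits the genome FASTA, TSS annotation TSV, per-condition IP/input
#' bin-count TSVs, the RNA count matrix and the per-site/per-gene truth
#' tables under `out_dir`.
#'
#' @param truth a `synthetic_truth`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_synthetic <- function(truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- truth$config
  write_fasta(truth$genome, file.path(out_dir, "genome.fa"))
  write_tsv(truth$tss, file.path(out_dir, "tss.tsv"))
  write_tsv(truth$sites, file.path(out_dir, "truth_sites.tsv"))
  write_tsv(truth$genes, file.path(out_dir, "truth_genes.tsv"))
  for (cond in c("WT", "MUT")) {
    chip <- simulate_chip_counts(truth, cond)
    write_bin_counts(chip$ip, file.path(out_dir, paste0("chip_", cond, "_ip.tsv")))
    write_bin_counts(chip$input,
                     file.path(out_dir, paste0("chip_", cond, "_input.tsv")))
  }
  write_counts_matrix(simulate_rna_counts(truth),
                      file.path(out_dir, "rna_counts.tsv"))
  invisible(out_dir)
}
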