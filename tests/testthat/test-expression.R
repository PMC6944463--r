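test_that("RPKM follows its definition", {
  m <- matrix(c(10, 0), nrow = 2, dimnames = list(c("g1", "g2"), "s1"))
  r <- rpkm(m, lengths = c(500, 1000), totals = 1e6)
  expect_equal(unname(r[, 1]), c(20, 0))
  # scaling a sample's counts and total together leaves RPKM unchanged
  m2 <- matrix(c(10, 40), nrow = 2, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(rpkm(m2, c(500, 800), totals = 2e6),
               rpkm(m2 * 3, c(500, 800), totals = 6e6))
  expect_error(rpkm(m, lengths = c(0, 100)), "lengths")
})

test_that("expressed-gene filter keeps any-sample passes, strictly-below discards", {
  r <- rbind(g1 = c(1.1, 1.0, 0.9, 0.5),
             g2 = c(1.3, 0.2, 0.1, 0.0),
             g3 = c(1.2, 0.1, 0.1, 0.1),   # exact threshold rescues
             g4 = c(0.0, 0.0, 0.0, 0.0))
  expect_setequal(filter_expressed(r, 1.2), c("g2", "g3"))
  # protein-coding filter applies first
  expect_setequal(filter_expressed(r, 1.2,
                                   gene_type = c("protein_coding", "lincRNA",
                                                 "protein_coding",
                                                 "protein_coding")),
                  "g3")
})

test_that("identical condition profiles give zero fold change and p of one", {
  m <- matrix(rep(c(10, 20, 10, 20), each = 6), nrow = 6,
              dimnames = list(paste0("g", 1:6), c("A1", "A2", "B1", "B2")))
  m <- m + matrix(rep(c(0, 5, 0, 5), each = 6), nrow = 6)  # A==B per gene
  de <- nb_differential(m, c("A", "A", "B", "B"))
  expect_equal(de$log2fc, rep(0, 6))
  expect_equal(de$p_value, rep(1, 6))
  expect_error(nb_differential(m[, 1:3], c("A", "A", "B")), "replicates")
})

test_that("NB Wald test attains nominal type-I error on null genes", {
  set.seed(43)
  ng <- 5000
  m <- matrix(rnbinom(ng * 4, mu = 100, size = 20), ncol = 4,
              dimnames = list(sprintf("g%04d", 1:ng),
                              c("A1", "A2", "B1", "B2")))
  de <- nb_differential(m, c("A", "A", "B", "B"))
  frac <- mean(de$p_value <= 0.05)
  ci <- 0.05 + c(-1, 1) * stats::qnorm(0.995) * sqrt(0.05 * 0.95 / ng)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("power sits below the known-dispersion oracle within the shrinkage margin", {
  # oracle: Wald power with the true dispersion known, analytic
  mu_wt <- 100; mu_mut <- 200; d <- 0.05
  se_true <- sqrt(((1 / mu_wt + d) / 2 + (1 / mu_mut + d) / 2) / log(2)^2)
  oracle <- stats::pnorm(1 / se_true - stats::qnorm(0.975))
  set.seed(44)
  ng <- 4000; eff <- 1:400
  muB <- rep(mu_wt, ng); muB[eff] <- mu_mut
  m <- cbind(matrix(rnbinom(ng * 2, mu = mu_wt, size = 1 / d), ncol = 2),
             matrix(rnbinom(ng * 2, mu = muB, size = 1 / d), ncol = 2))
  dimnames(m) <- list(sprintf("g%04d", 1:ng), c("A1", "A2", "B1", "B2"))
  de <- nb_differential(m, c("A", "A", "B", "B"))
  power <- mean(de$p_value[eff] <= 0.05)
  mc <- 3 * sqrt(oracle * (1 - oracle) / length(eff))
  expect_lte(power, oracle + mc)          # never beats the oracle
  expect_gte(power, oracle - 0.15)        # documented cost of trend-floored SEs
})

test_that("BH adjustment is monotone and size factors absorb scaling", {
  set.seed(45)
  m <- matrix(rnbinom(400, mu = 80, size = 10), ncol = 4,
              dimnames = list(sprintf("g%03d", 1:100),
                              c("A1", "A2", "B1", "B2")))
  de <- nb_differential(m, c("A", "A", "B", "B"))
  ord <- order(de$p_value)
  expect_true(all(diff(de$adj_p[ord]) >= -1e-12))
  # multiply one sample by a constant: estimates unchanged
  m2 <- m; m2[, 1] <- m2[, 1] * 3
  de2 <- nb_differential(m2, c("A", "A", "B", "B"))
  expect_equal(de2$log2fc, de$log2fc, tolerance = 1e-9)
  # p-values are only approximately invariant: the NB mean-variance relation
  # is not scale-free, so the moment dispersions shift slightly
  expect_equal(de2$p_value, de$p_value, tolerance = 0.01)
})

test_that("changing-gene calls apply both gates with non-strict cutoffs", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(-0.6, -0.6, 0.4, 0.5),
                    adj_p = c(0.01, 0.2, 0.001, 0.05))
  got <- call_changing(res)$status
  expect_identical(got, c("down", "unchanged", "unchanged", "up"))
})

test_that("pipeline labels filtered genes not_expressed and keeps order", {
  set.seed(46)
  m <- matrix(rnbinom(40, mu = 200, size = 20), ncol = 4,
              dimnames = list(paste0("g", 1:10),
                              c("WT_1", "WT_2", "MUT_1", "MUT_2")))
  m[3, ] <- 0
  out <- expression_pipeline(m, lengths = rep(1000, 10),
                             condition = c("WT", "WT", "MUT", "MUT"))
  expect_identical(out$results$gene_id, paste0("g", 1:10))
  expect_identical(out$results$status[3], "not_expressed")
  expect_false("g3" %in% out$expressed)
})

test_that("fold-change direction and magnitude broadly agree with DESeq2", {
  skip_if_not_installed("DESeq2")
  set.seed(47)
  ng <- 400
  mu <- rep(150, ng); muB <- mu
  muB[1:40] <- mu[1:40] * 2^(rep(c(-1.5, 1.5), 20))
  m <- cbind(matrix(rnbinom(ng * 2, mu = mu, size = 20), ncol = 2),
             matrix(rnbinom(ng * 2, mu = muB, size = 20), ncol = 2))
  dimnames(m) <- list(sprintf("g%04d", 1:ng), c("A1", "A2", "B1", "B2"))
  de <- nb_differential(m, c("A", "A", "B", "B"))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    m, S4Vectors::DataFrame(condition = factor(c("A", "A", "B", "B"))),
    ~condition)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  rr <- DESeq2::results(dds)
  expect_gt(cor(de$log2fc, rr$log2FoldChange), 0.95)
  both_called <- which(de$adj_p <= 0.05 & !is.na(rr$padj) & rr$padj <= 0.05)
  expect_gt(length(both_called), 20)
  expect_true(all(sign(de$log2fc[both_called]) ==
                    sign(rr$log2FoldChange[both_called])))
})
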