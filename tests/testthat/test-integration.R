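toy_classified <- function() {
  data.frame(id = c("p1", "p2", "p3", "p4"),
             chrom = "c", start = c(0, 1000, 2000, 3000),
             end = c(500, 1500, 2500, 3500),
             summit = c(250, 1250, 2250, 3250),
             category = c("common", "F80L_absent", "F80L_absent", "F80L_only"),
             tss_associated = c(TRUE, TRUE, TRUE, FALSE),
             linked_genes = c("gA", "gB", "gC,gD", ""),
             stringsAsFactors = FALSE)
}

toy_expr <- function() {
  data.frame(gene_id = c("gA", "gB", "gC", "gD", "gE"),
             log2fc = c(-2, -1, 0.2, 0.8, -3),
             adj_p = c(0.001, 0.01, 0.001, 0.02, 0.001),
             status = c("down", "down", "unchanged", "up", "down"),
             stringsAsFactors = FALSE)
}

test_that("direct-target calling applies the category and expression gates", {
  dt <- call_direct_targets(toy_classified(), toy_expr())
  # gA changes but is linked only to a common peak -> excluded
  expect_false("gA" %in% dt$gene_id)
  # gC is linked to an absent peak but unchanged -> excluded
  expect_false("gC" %in% dt$gene_id)
  # gE changes but has no peak at all -> excluded
  expect_false("gE" %in% dt$gene_id)
  expect_setequal(dt$gene_id, c("gB", "gD"))
  expect_identical(dt$direction[dt$gene_id == "gB"], "down")
  expect_identical(dt$direction[dt$gene_id == "gD"], "up")
  # down block first, then up
  expect_identical(dt$direction, c("down", "up"))
})

test_that("direct targets rank by |log2fc| within direction with gene-id ties", {
  cl <- toy_classified()
  cl$linked_genes[2] <- "gB,gF,gG"
  ex <- rbind(toy_expr(),
              data.frame(gene_id = c("gF", "gG"), log2fc = c(-1, -1),
                         adj_p = 0.01, status = "down"))
  dt <- call_direct_targets(cl, ex)
  down <- dt[dt$direction == "down", ]
  expect_identical(down$gene_id, c("gB", "gF", "gG"))  # tie broken by id
  # require_all_lost removes genes also linked to a common peak
  cl2 <- cl
  cl2$linked_genes[1] <- "gB"
  dt2 <- call_direct_targets(cl2, ex, require_all_lost = TRUE)
  expect_false("gB" %in% dt2$gene_id)
})

test_that("direct-target set equals independent set algebra on random tables", {
  set.seed(501)
  for (rep in 1:20) {
    n_pk <- 30
    genes <- sprintf("g%03d", 1:60)
    cl <- data.frame(id = sprintf("p%02d", 1:n_pk), chrom = "c",
                     start = (1:n_pk) * 1000, end = (1:n_pk) * 1000 + 400,
                     summit = (1:n_pk) * 1000 + 200,
                     category = sample(c("common", "F80L_absent", "F80L_only"),
                                       n_pk, TRUE),
                     tss_associated = runif(n_pk) < 0.7,
                     linked_genes = vapply(1:n_pk, function(i) {
                       paste(sample(genes, sample(0:2, 1)), collapse = ",")
                     }, ""), stringsAsFactors = FALSE)
    ex <- data.frame(gene_id = genes,
                     log2fc = rnorm(60), adj_p = runif(60),
                     stringsAsFactors = FALSE)
    ex$status <- ifelse(ex$adj_p <= 0.05 & ex$log2fc <= -0.5, "down",
                        ifelse(ex$adj_p <= 0.05 & ex$log2fc >= 0.5, "up",
                               "unchanged"))
    dt <- call_direct_targets(cl, ex)
    # oracle: plain set intersection
    linked <- unlist(strsplit(
      cl$linked_genes[cl$tss_associated & cl$category == "F80L_absent"], ","))
    want <- intersect(ex$gene_id[ex$status %in% c("up", "down")], linked)
    expect_setequal(dt$gene_id, want)
  }
})

test_that("master export is self-consistent, deterministic and handles empty inputs", {
  cl <- toy_classified()
  cl$tam_count <- c(2L, 0L, 1L, 0L)
  ex <- toy_expr()
  dt <- call_direct_targets(cl, ex)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- export_master_table(cl, ex, dt, d1)
  s2 <- export_master_table(cl, ex, dt, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # summary agrees with an independent recount of the written master table
  written <- read_tsv(file.path(d1, "peaks_master.tsv"))
  expect_identical(s1$n_f80l_absent, sum(written$category == "F80L_absent"))
  expect_identical(s1$n_peaks_wt, sum(written$category != "F80L_only"))
  js <- jsonlite::read_json(file.path(d1, "summary.json"))
  expect_identical(js$n_direct_targets_down, sum(dt$direction == "down"))

  # empty peak set: valid zero-row outputs, all counts zero
  d0 <- withr::local_tempdir()
  s0 <- export_master_table(cl[0, ], ex[0, ], dt[0, ], d0)
  expect_identical(s0$n_peaks_wt, 0L)
  expect_identical(nrow(read_tsv(file.path(d0, "peaks_master.tsv"))), 0L)
  expect_error(export_master_table(NULL, ex, dt, d0), "classified")
})

test_that("supplementary-style recounting applies the documented rules", {
  d <- withr::local_tempdir()
  s1 <- data.frame(id = c("p1", "p2", "p3"),
                   category = c("common", "common", "F80L absent"),
                   n_tss_genes = c(1L, 0L, 1L),
                   tam_count = c(1L, 2L, 0L),
                   linked_genes = c("gA", "", "gB"),
                   stringsAsFactors = FALSE)
  s5 <- data.frame(gene_id = c("gA", "gB", "gC"),
                   log2fc = c(-0.6, 0.6, 0.2),
                   adj_p = c(0.01, 0.2, 0.001))
  write_tsv(s1, file.path(d, "s1.tsv"))
  write_tsv(s5, file.path(d, "s5.tsv"))
  got <- acceptance_from_supplementary(file.path(d, "s1.tsv"),
                                       file.path(d, "s5.tsv"))
  expect_identical(got$n_common, 2L)
  expect_identical(got$n_f80l_absent, 1L)
  expect_identical(got$n_genes_down, 1L)   # (-0.6, 0.01) only
  expect_identical(got$n_genes_up, 0L)     # (0.6, 0.2) fails the p gate
  # gA changes but sits under a common peak; gB is under the absent peak but
  # does not change -> no direct targets
  expect_identical(got$n_direct_targets_down, 0L)
  expect_identical(got$n_direct_targets_up, 0L)

  # schema errors list every missing column
  bad <- s1[, c("id", "category")]
  write_tsv(bad, file.path(d, "bad.tsv"))
  expect_error(acceptance_from_supplementary(file.path(d, "bad.tsv"),
                                             file.path(d, "s5.tsv")),
               "n_tss_genes.*tam_count|tam_count.*n_tss_genes")
})
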