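test_that("PWM construction validates probabilities", {
  expect_error(pwm_model(matrix(0.3, 4, 2)), "sum to 1")
  expect_error(pwm_model(matrix(0.25, 3, 2)), "4 rows")
  pw <- pwm_model(matrix(0.25, 4, 3))
  expect_equal(pw$width, 3L)
  expect_equal(pwm_max_score(pw), 0)
})

test_that("scan scores match hand arithmetic on a toy matrix", {
  # two positions, 0.97 on A then C, background 0.25
  probs <- matrix(0.01, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  probs["A", 1] <- 0.97; probs["C", 2] <- 0.97
  pw <- pwm_model(probs)
  hits <- scan_pwm("AC", pw, min_score = 0)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$score, 2 * log2(0.97 / 0.25), tolerance = 1e-12)
  expect_identical(fwd$sequence, "AC")
  # uniform matrix scores every window zero
  u <- pwm_model(matrix(0.25, 4, 2))
  expect_true(all(scan_pwm("ACGTAC", u, min_score = -1)$score == 0))
})

test_that("N-containing windows are skipped and short input is empty", {
  pw <- tam_default_pwm()
  expect_identical(nrow(scan_pwm("ACGT", pw)), 0L)
  s <- paste0(strrep("A", 10), "N", strrep("A", 30))
  expect_silent(h <- scan_pwm(s, pw, min_score = -1e6))
  expect_false(any(h$start <= 10 & h$start + 22 > 10))
})

test_that("scanning agrees with exhaustive per-window rescoring", {
  set.seed(401)
  seq10k <- random_dna(10000)
  # plant a few consensus copies so hits exist above threshold
  cons <- pwm_consensus(tam_default_pwm())
  for (pos in c(1000, 4000, 7777)) {
    substr(seq10k, pos + 1, pos + 22) <- cons
  }
  pw <- tam_default_pwm()
  thr <- 0.6 * pwm_max_score(pw)
  got <- scan_pwm(seq10k, pw, min_score = thr)
  want <- brute_scan(seq10k, pw, thr)
  expect_identical(got$start, want$start)
  expect_identical(got$strand, want$strand)
  expect_equal(got$score, want$score, tolerance = 1e-9)
})

test_that("scanning a sequence and its reverse complement mirrors hits", {
  set.seed(402)
  s <- random_dna(2000)
  substr(s, 501, 522) <- pwm_consensus(tam_default_pwm())
  pw <- tam_default_pwm()
  thr <- 0.5 * pwm_max_score(pw)
  f <- scan_pwm(s, pw, min_score = thr)
  r <- scan_pwm(revcomp(s), pw, min_score = thr)
  mirrored <- sort(2000L - 22L - r$start)
  expect_equal(sort(f$start), mirrored)
  expect_equal(sort(f$score), sort(r$score), tolerance = 1e-9)
})

test_that("nearest hit selection respects window, distance and tie-break", {
  pk <- data.frame(id = "p", chrom = "c", summit = 5000)
  mk <- function(starts) {
    data.frame(chrom = "c", start = starts, end = starts + 22, strand = "+",
               score = 10, sequence = "X", stringsAsFactors = FALSE)
  }
  # -300 vs +150 relative to the summit: the closer downstream hit wins
  nt <- nearest_tam(pk, mk(c(5000 - 300 - 11, 5000 + 150 - 11)), flank = 1000)
  expect_equal(nt$tam_distance, 150)
  expect_identical(nt$tam_count, 2L)
  # nothing within the window
  nt0 <- nearest_tam(pk, mk(8000), flank = 1000)
  expect_identical(nt0$tam_count, 0L)
  expect_true(is.na(nt0$tam_start))
  # exact tie at +/- d: lower coordinate wins
  ntt <- nearest_tam(pk, mk(c(5000 - 200 - 11, 5000 + 200 - 11)), flank = 1000)
  expect_equal(ntt$tam_start, 5000 - 200 - 11)
})

test_that("nearest hit equals an exhaustive scan over random hit sets", {
  set.seed(403)
  for (rep in 1:50) {
    summit <- sample(2000:8000, 1)
    starts <- sample(0:10000, 30)
    hits <- data.frame(chrom = "c", start = starts, end = starts + 22,
                       strand = "+", score = 1, sequence = "X")
    nt <- nearest_tam(data.frame(chrom = "c", summit = summit), hits,
                      flank = 1000)
    mid <- starts + 11
    inside <- which(abs(mid - summit) <= 1000)
    expect_identical(nt$tam_count, length(inside))
    if (length(inside) > 0) {
      d <- abs(mid[inside] - summit)
      best <- inside[order(d, starts[inside])][1]
      expect_equal(nt$tam_start, starts[best])
    }
  }
})

test_that("information content matches hand computations and bounds", {
  # identical stack, no pseudocount: 2 bits everywhere
  pw <- pwm_from_sequences(rep("ACG", 4), pseudocount = 0)
  expect_equal(pwm_ic(pw), rep(2, 3))
  # uniform column: 0 bits
  pu <- pwm_from_sequences(c("A", "C", "G", "T"), pseudocount = 0)
  expect_equal(pwm_ic(pu), 0)
  # three-sequence toy stack, hand computed:
  # pos1 all A -> 2 bits; pos2 {C,C,T} -> 2 + (2/3)log2(2/3) + (1/3)log2(1/3)
  pt <- pwm_from_sequences(c("AC", "AC", "AT"), pseudocount = 0)
  expect_equal(pwm_ic(pt),
               c(2, 2 + (2 / 3) * log2(2 / 3) + (1 / 3) * log2(1 / 3)),
               tolerance = 1e-12)
  # bounds on random stacks
  set.seed(404)
  for (rep in 1:20) {
    ps <- pwm_from_sequences(vapply(1:8, function(i) random_dna(6), ""))
    expect_true(all(pwm_ic(ps) >= 0 & pwm_ic(ps) <= 2))
  }
})

test_that("half-IC contrast reports per-half means and differences", {
  pw <- tam_default_pwm()
  same <- ic_half_contrast(pw, pw)
  expect_equal(same$delta5, 0)
  expect_equal(same$delta3, 0)
  # fully conserved vs uniform: the 3' contrast is exactly 2 bits
  conserved <- pwm_from_sequences(rep(strrep("A", 22), 3), pseudocount = 0)
  uniform <- pwm_model(matrix(0.25, 4, 22))
  con <- ic_half_contrast(conserved, uniform)
  expect_equal(con$delta3, 2)
  expect_equal(con$delta5, 2)
  expect_error(ic_half_contrast(pw, pwm_model(matrix(0.25, 4, 10))), "width")
})

test_that("consensus building uses the closest hit per peak and fails cleanly when empty", {
  cl <- data.frame(id = c("p1", "p2"), chrom = "c", summit = c(1000, 3000),
                   category = "common")
  hits <- data.frame(chrom = "c", start = c(990, 2990), end = c(1012, 3012),
                     strand = "+", score = 10,
                     sequence = c(strrep("A", 22), strrep("A", 22)))
  cons <- build_consensus(cl, hits, "common", summit_flank = 250,
                          pseudocount = 0)
  expect_identical(cons$n_sequences, 2L)
  expect_equal(cons$ic, rep(2, 22))
  expect_error(build_consensus(cl, hits, "F80L_absent"), "F80L_absent")
})

test_that("PWM files round-trip", {
  p <- withr::local_tempfile(fileext = ".tsv")
  pw <- tam_default_pwm()
  write_pwm(pw, p)
  rt <- read_pwm(p)
  expect_equal(rt$probs, pw$probs, tolerance = 1e-12)
})
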