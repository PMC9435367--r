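test_that("build_pfm counts, pseudocounts and error handling", {
  pfm <- build_pfm("ACGT", pseudocount = 0)
  expect_equal(unname(pfm[, 1]), c(1, 0, 0, 0))
  expect_equal(unname(pfm[, 3]), c(0, 0, 1, 0))

  pfm2 <- build_pfm(c("AA", "AC"), pseudocount = 0)
  expect_equal(unname(pfm2[, 2]), c(0.5, 0.5, 0, 0))

  # N contributes a quarter count to each base
  pfmN <- build_pfm(c("A", "N"), pseudocount = 0)
  expect_equal(unname(pfmN[, 1]), c(1.25, 0.25, 0.25, 0.25) / 2)
  expect_true(all(abs(colSums(build_pfm(c("ACG", "TTA"), 0.3)) - 1) < 1e-12))

  expect_error(build_pfm(c("ACGT", "ACG")), "ragged")
})

test_that("PFM from clean consensus samples recovers the printed 13-bp element", {
  tirs <- vapply(1:50, function(i) sample_tir(AAN, 4, 0, seed = i), "")
  e1 <- substr(tirs, 1, 13)
  pfm <- build_pfm(e1, pseudocount = 0.1)
  argmax <- paste(rownames(pfm)[apply(pfm, 2, which.max)], collapse = "")
  expect_identical(argmax, "CACACCCAAACCT")
})

test_that("information content matches closed forms and bounds", {
  uni <- matrix(0.25, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(information_content(uni), 0)
  onehot <- build_pfm("A", 0)
  expect_equal(information_content(onehot), 2)
  half <- matrix(c(0.5, 0.5, 0, 0), 4, 1,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(information_content(half), 1)
  expect_error(information_content(onehot, c(0, 0.5, 0.25, 0.25)),
               "positive")

  # bounds under uniform background for arbitrary columns
  set.seed(1)
  for (i in 1:20) {
    p <- stats::runif(4)
    p <- matrix(p / sum(p), 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
    ic <- information_content(p)
    expect_gte(ic, 0)
    expect_lte(ic, 2 + 1e-12)
  }
})

test_that("log-odds scoring: one-hot, background identity, consensus argmax", {
  onehot <- build_pfm("C", 0)
  s <- log_odds(onehot)
  expect_equal(unname(s["C", 1]), 2)
  expect_equal(unname(s["A", 1]), -Inf)

  bg_pfm <- matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_true(all(log_odds(bg_pfm) == 0))

  # the consensus window scores the per-column argmax sum (matrix maximum)
  tirs <- vapply(1:50, function(i) sample_tir(AAN, 4, 0, seed = i), "")
  pfm <- build_pfm(substr(tirs, 1, 13), 0.1)
  smat <- raglscan:::score_matrix5(pfm, rep(0.25, 4))
  cons <- paste(rownames(pfm)[apply(pfm, 2, which.max)], collapse = "")
  colmax <- sum(apply(log_odds(pfm), 2, max))
  expect_equal(raglscan:::pwm_score_seq(cons, smat), colmax)
})

test_that("scan_bipartite finds a planted consensus TIR and equals brute force", {
  set.seed(5)
  for (case in 1:3) {
    sp <- c(4, 13, 4)[case]
    bg <- random_genome(1200, seed = 100 + case)
    tir <- sample_tir(AAN, sp, 0, seed = case)
    pos <- c(200, 600, 980)[case]
    contig <- paste0(substr(bg, 1, pos), tir, substr(bg, pos + 1, 1200))
    thr <- 0.9 * AAN$max_score
    hits <- scan_bipartite(contig, AAN, thr)
    planted <- hits[hits$strand == "+", ]
    expect_equal(nrow(planted), 1)
    expect_equal(planted$start, pos)
    expect_equal(planted$spacer_len, sp)

    # oracle equivalence over all windows at a permissive threshold
    thr2 <- 5
    got <- scan_bipartite(contig, AAN, thr2)
    want <- brute_scan(contig, AAN, thr2)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$spacer_len, want$spacer_len)
    expect_equal(got$total_score, want$total_score, tolerance = 1e-9)

    # strand symmetry: the reverse-complemented contig mirrors the hit set
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(contig)))
    got_rc <- scan_bipartite(rc, AAN, thr2)
    n <- nchar(contig)
    expect_setequal(paste(n - got$end, ifelse(got$strand == "+", "-", "+"),
                          got$spacer_len, round(got$total_score, 6)),
                    paste(got_rc$start, got_rc$strand, got_rc$spacer_len,
                          round(got_rc$total_score, 6)))
  }
})

test_that("score decomposition and short-contig behaviour", {
  contig <- paste0(random_genome(300, seed = 9),
                   sample_tir(AAN, 13, 0, seed = 2),
                   random_genome(100, seed = 10))
  hits <- scan_bipartite(contig, AAN, 10)
  expect_gte(nrow(hits), 1)
  expect_true(all(abs(hits$total_score - (hits$score1 + hits$score2)) < 1e-9))
  expect_equal(nrow(scan_bipartite("ACGTACGT", AAN, 0)), 0)
})

test_that("threshold calibration is deterministic and hits its quantile", {
  t1 <- calibrate_threshold(AAN, target_fpr = 0.5, n_samples = 2000, seed = 3)
  t2 <- calibrate_threshold(AAN, target_fpr = 0.5, n_samples = 2000, seed = 3)
  expect_identical(t1, t2)

  # FPR 0.5 threshold is the null median
  null <- raglscan:::local_seed(3, raglscan:::null_score_samples(
    AAN, rep(0.25, 4), 2000))
  expect_equal(t1, stats::quantile(null, 0.5, type = 1, names = FALSE))

  # the consensus TIR scores far above a 1e-3 threshold
  t3 <- calibrate_threshold(AAN, target_fpr = 1e-3, n_samples = 2e4,
                            seed = 4)
  expect_gt(AAN$max_score, t3 + 10)
  expect_warning(calibrate_threshold(AAN, target_fpr = 1e-3,
                                     n_samples = 100, seed = 1),
                 "noisy")

  # exact DP null quantile agrees with a large Monte-Carlo sample
  dp <- null_score_quantile(AAN, 0.01)
  mc <- calibrate_threshold(AAN, target_fpr = 0.01, n_samples = 2e5,
                            seed = 8)
  expect_lt(abs(dp - mc), 0.75)
})

test_that("TIR symmetry labels follow the spacer pair", {
  expect_identical(tir_symmetry(4, 13), "asymmetric")
  expect_identical(tir_symmetry(4, 4), "symmetric")
  expect_identical(tir_symmetry(13, 13), "symmetric")
})

test_that("block segmentation recovers the 13/10 conserved-element lengths", {
  tirs <- vapply(1:50, function(i) {
    sample_tir(AAN, AAN$allowed_spacers[(i %% 2) + 1], 0.05, seed = 400 + i)
  }, "")
  seg <- segment_tir_blocks(tirs)
  expect_equal(seg$len1, 13)
  expect_equal(seg$len2, 10)
})

test_that("sample_tir validates spacers and degenerate-free consensus is exact", {
  expect_error(sample_tir(AAN, 7, 0, seed = 1), "allowed set")
  t0 <- sample_tir(AAN, 4, 0, seed = 77)
  expect_identical(substr(t0, 1, 13), "CACACCCAAACCT")
  expect_equal(nchar(t0), 13 + 4 + 10)
  # mouse RSS preset has no degenerate positions: fully deterministic ends
  rss <- mouse_rss_model()
  r <- sample_tir(rss, 12, 0, seed = 5)
  expect_identical(substr(r, 1, 7), "CACAGTG")
  expect_identical(substr(r, 20, 28), "ACAAAAACC")
})

test_that("model and PFM serialization round-trips", {
  dir <- tempfile()
  write_bipartite_model(AAN, dir)
  m2 <- read_bipartite_model(dir)
  expect_equal(m2$pfm1, AAN$pfm1, tolerance = 1e-6)
  expect_equal(m2$allowed_spacers, AAN$allowed_spacers)
  expect_equal(m2$max_score, AAN$max_score, tolerance = 1e-5)

  tab <- ic_table(AAN$pfm1)
  expect_equal(nrow(tab), 13)
  expect_identical(paste(tab$consensus, collapse = ""), "CACACCCAAACCT")
  logo <- ascii_logo(AAN$pfm2)
  expect_length(logo, 10)
  meme <- tempfile()
  write_meme(list(e1 = AAN$pfm1, e2 = AAN$pfm2), meme)
  expect_true(any(grepl("MOTIF e1", readLines(meme))))
})
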