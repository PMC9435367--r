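test_that("pair_tirs enforces inversion, gap window and greedy resolution", {
  hit <- function(start, strand, score, spacer = 4) {
    w <- 13 + spacer + 10
    data.frame(contig = "c", start = start, end = start + w,
               strand = strand, spacer_len = spacer, score1 = score / 2,
               score2 = score / 2, total_score = score,
               stringsAsFactors = FALSE)
  }
  # planted inward-facing pair 8 kb apart
  hits <- rbind(hit(100, "+", 30), hit(8127, "-", 30, 13))
  p <- pair_tirs(hits, 1000, 20000)
  expect_equal(nrow(p), 1)
  expect_equal(p$inner_gap, 8127 - 127)
  expect_identical(p$symmetry, "asymmetric")
  expect_equal(c(p$spacer5, p$spacer3), c(4, 13))

  # direct repeats (two "+" hits) never pair
  expect_equal(nrow(pair_tirs(rbind(hit(100, "+", 30), hit(8000, "+", 30)),
                              1000, 20000)), 0)
  # gap window respected
  expect_equal(nrow(pair_tirs(hits, 1000, 5000)), 0)
  expect_error(pair_tirs(hits, 5000, 1000), "min_gap")

  # middle hit pairable with either end: larger combined score wins and
  # blocks the overlapping alternative
  three <- rbind(hit(0, "+", 10), hit(1000, "+", 30), hit(3000, "-", 30))
  p3 <- pair_tirs(three, 500, 5000)
  expect_equal(nrow(p3), 1)
  expect_equal(p3$tir5_start, 1000)
  # tie on combined score: smaller span wins
  three_tie <- rbind(hit(0, "+", 30), hit(1000, "+", 30), hit(3000, "-", 30))
  pt <- pair_tirs(three_tie, 500, 5000)
  expect_equal(nrow(pt), 1)
  expect_equal(pt$tir5_start, 1000)
})

test_that("detect_tsd returns the largest matching k and handles edges", {
  g <- paste0(random_genome(200, seed = 1), "ACGTT", "EEEE", "ACGTT",
              random_genome(200, seed = 2))
  g <- gsub("E", "G", g)  # element placeholder must be DNA
  # element span [205, 209) flanked by ACGTT on both sides
  got <- detect_tsd(g, 205, 209, 2, 10)
  expect_identical(got$tsd, "ACGTT")
  expect_equal(got$k, 5)

  # homopolymer flanks force a k_max match by definition
  hp <- paste0(strrep("A", 20), "CGCGCG", strrep("A", 20))
  got_hp <- detect_tsd(hp, 20, 26, 2, 10)
  expect_equal(got_hp$k, 10)

  # contig edge: undetectable with a warning
  expect_warning(res <- detect_tsd("ACGTACGT", 0, 4, 2, 10), "edge")
  expect_null(res)

  # random flanks: analytic no-match probability ~ 1 - sum_k 4^-k
  n_match <- 0
  for (i in 1:400) {
    gg <- random_genome(60, seed = 7000 + i)
    if (!is.null(detect_tsd(gg, 25, 35, 4, 10))) n_match <- n_match + 1
  }
  p_hat <- n_match / 400
  p_exp <- sum(4^-(4:10))  # ~= 0.0052
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 400) + 1e-9)
})

test_that("find_orfs matches the naive six-frame oracle", {
  # single forward frame
  set.seed(12)
  body <- paste(sample(setdiff(apply(expand.grid(c("A","C","G","T"),
                                                 c("A","C","G","T"),
                                                 c("A","C","G","T")), 1,
                                     paste, collapse = ""),
                               c("TAA", "TAG", "TGA")), 300, replace = TRUE),
                collapse = "")
  orf <- paste0("ATG", body, "TAA")
  got <- find_orfs(orf, 100)
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 0)
  expect_equal(got$end, nchar(orf))
  expect_identical(got$strand, "+")
  expect_equal(got$n_codons, 302)

  rc <- raglscan:::revcomp(orf)
  got_rc <- find_orfs(rc, 100)
  expect_equal(nrow(got_rc), 1)
  expect_identical(got_rc$strand, "-")
  expect_equal(got_rc$n_codons, 302)

  # oracle equivalence on random sequence
  for (i in 1:3) {
    g <- random_genome(8000, seed = 800 + i)
    for (minlen in c(20, 50)) {
      got <- find_orfs(g, minlen)
      want <- orf_oracle(g, minlen)
      expect_equal(got, want)
    }
  }
})

test_that("architecture decision table", {
  orfs <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r) {
      data.frame(start = r[[1]], end = r[[2]], strand = r[[3]],
                 n_codons = (r[[2]] - r[[1]]) / 3, label = r[[4]],
                 stringsAsFactors = FALSE)
    }))
  }
  # RAG2L "+" upstream, RAG1L "-" downstream, heads converging
  conv <- orfs(list(100, 850, "+", "RAG2L"), list(1000, 2050, "-", "RAG1L"))
  expect_identical(classify_architecture(conv)$architecture,
                   "RAGL_convergent")
  # RAG2L then RAG1L on "+": tandem
  tand <- orfs(list(100, 850, "+", "RAG2L"), list(1000, 2050, "+", "RAG1L"))
  expect_identical(classify_architecture(tand)$architecture, "RAGL_tandem")
  # tandem on "-": RAG2L upstream means larger coordinate
  tand_m <- orfs(list(100, 1150, "-", "RAG1L"), list(1300, 2050, "-", "RAG2L"))
  expect_identical(classify_architecture(tand_m)$architecture, "RAGL_tandem")
  # single RAG1L: Transib-like
  single <- orfs(list(100, 1150, "+", "RAG1L"))
  expect_identical(classify_architecture(single)$architecture, "Transib_like")
  # missing TSD or TIR forces fragmented
  expect_identical(classify_architecture(conv, tsd_present = FALSE)$architecture,
                   "fragmented")
  expect_identical(classify_architecture(single, tir_ok = FALSE)$architecture,
                   "fragmented")
  # divergent orientation and RAG2L-only fall through to fragmented
  div <- orfs(list(100, 1150, "-", "RAG1L"), list(1300, 2050, "+", "RAG2L"))
  expect_identical(classify_architecture(div)$architecture, "fragmented")
  r2 <- orfs(list(100, 850, "+", "RAG2L"))
  expect_identical(classify_architecture(r2)$architecture, "fragmented")
  # duplicated labels: flagged expanded, resolved by the longest
  dup <- orfs(list(100, 850, "+", "RAG2L"), list(1000, 2050, "+", "RAG1L"),
              list(2200, 2800, "+", "RAG1L"))
  cls <- classify_architecture(dup)
  expect_identical(cls$architecture, "RAGL_tandem")
  expect_true("expanded" %in% cls$notes)
})

test_that("annotate_genome recovers planted elements of every kind", {
  for (kind in c("RAGL_tandem", "RAGL_convergent", "Transib_single")) {
    spec <- element_spec(kind)
    g <- random_genome(40000, seed = match(kind, c("RAGL_tandem",
                                                   "RAGL_convergent",
                                                   "Transib_single")))
    res <- plant_insertions(g, spec, positions = 20000L, seed = 77)
    ann <- annotate_genome(res$genome, AAN)
    expect_equal(nrow(ann$calls), 1)
    want_arch <- if (kind == "Transib_single") "Transib_like" else kind
    expect_identical(ann$calls$architecture, want_arch)
    expect_equal(ann$calls$start, res$truth$insertion_start)
    expect_equal(ann$calls$end,
                 res$truth$insertion_start + res$truth$element_length)
    expect_identical(ann$calls$tsd, res$truth$tsd_sequence)
    expect_equal(ann$calls$tsd_len, 5L)
    expect_identical(ann$calls$symmetry, "asymmetric")
  }
})

test_that("symmetric spacer pairs are labelled symmetric", {
  spec <- element_spec(spacer_assignment = c(4L, 4L))
  g <- random_genome(30000, seed = 61)
  res <- plant_insertions(g, spec, positions = 15000L, seed = 5)
  ann <- annotate_genome(res$genome, AAN)
  expect_identical(ann$calls$symmetry, "symmetric")
  expect_equal(c(ann$calls$spacer5, ann$calls$spacer3), c(4L, 4L))
})

test_that("ablating one TIR yields a fragmented call", {
  spec <- element_spec()
  g <- random_genome(30000, seed = 71)
  res <- plant_insertions(g, spec, positions = 12000L, seed = 6)
  # overwrite the 3' TIR with random sequence
  e_end <- res$truth$insertion_start + res$truth$element_length
  g2 <- paste0(substr(res$genome, 1, e_end - 36),
               random_genome(36, seed = 72),
               substr(res$genome, e_end + 1, nchar(res$genome)))
  ann <- annotate_genome(g2, AAN)
  expect_equal(nrow(ann$calls), 1)
  expect_identical(ann$calls$architecture, "fragmented")
  expect_true(grepl("single_tir", ann$calls$notes))
})

test_that("annotation output is deterministic and round-trips as GFF3", {
  spec <- element_spec()
  g <- random_genome(30000, seed = 81)
  res <- plant_insertions(g, spec, positions = 15000L, seed = 7)
  a1 <- annotate_genome(res$genome, AAN)
  a2 <- annotate_genome(res$genome, AAN)
  expect_identical(as_gff3(a1), as_gff3(a2))
  gff <- as_gff3(a1)
  expect_identical(gff[1], "##gff-version 3")
  expect_true(any(grepl("mobile_genetic_element", gff)))
  expect_true(any(grepl("target_site_duplication", gff)))
  expect_true(sum(grepl("\tORF\t", gff)) >= 2)
  # GFF3 is 1-based closed: element start is call start + 1
  mge <- strsplit(gff[grepl("mobile_genetic_element", gff)], "\t")[[1]]
  expect_equal(as.integer(mge[4]), a1$calls$start + 1L)
  expect_equal(as.integer(mge[5]), a1$calls$end)
})
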