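test_that("sample_tir mutation load matches the analytic expectation", {
  # 21 single-base consensus positions mutate at `rate`; the two C/T
  # degenerate positions leave the allowed set with probability 2/3 * rate
  rate <- 0.05
  expected <- rate * (21 + 2 * 2 / 3)
  sets <- aan_consensus_sets()
  n <- 2000
  d <- vapply(seq_len(n), function(i) {
    tir <- sample_tir(AAN, 13, rate, seed = 5000 + i)
    hamming_to_consensus(paste0(substr(tir, 1, 13), substr(tir, 27, 36)),
                         sets)
  }, 0)
  se <- stats::sd(d) / sqrt(n)
  expect_lt(abs(mean(d) - expected), 3 * se + 1e-9)
})

test_that("generators are bit-reproducible for a fixed seed", {
  expect_identical(sample_tir(AAN, 4, 0.2, seed = 9),
                   sample_tir(AAN, 4, 0.2, seed = 9))
  spec <- element_spec()
  expect_identical(build_element(spec, seed = 4)$seq,
                   build_element(spec, seed = 4)$seq)
  g <- random_genome(5000, seed = 1)
  expect_identical(plant_insertions(g, spec, positions = 2500L, seed = 3),
                   plant_insertions(g, spec, positions = 2500L, seed = 3))
  ps <- synthetic_protein_spec("RAG1L", motif_mutation_rate = 0.1)
  expect_identical(synth_protein(ps, seed = 11), synth_protein(ps, seed = 11))
})

test_that("element_spec validates its invariants", {
  expect_error(element_spec(tsd_len = -1), "tsd_len")
  expect_error(element_spec(spacer_assignment = c(4, 7)), "allowed set")
  expect_error(element_spec(gene_lengths = c(RAG1L = 350L)), "exactly 2")
  expect_error(element_spec("Transib_single",
                            gene_lengths = c(A = 300L, B = 300L)),
               "exactly 1")
  expect_error(element_spec(gene_lengths = c(RAG2L = 50L, RAG1L = 350L)),
               "min_orf_codons")
})

test_that("build_element lays out TIRs and gene orientations per kind", {
  conv <- build_element(element_spec("RAGL_convergent"), seed = 2)
  ann <- conv$annotation
  orfs <- ann[ann$part == "ORF", ]
  expect_identical(orfs$label, c("RAG2L", "RAG1L"))
  expect_identical(orfs$strand, c("+", "-"))
  expect_lt(orfs$start[1], orfs$start[2])  # 3' ends adjacent in the middle

  tand <- build_element(element_spec("RAGL_tandem"), seed = 2)
  orfs <- tand$annotation[tand$annotation$part == "ORF", ]
  expect_identical(orfs$label, c("RAG2L", "RAG1L"))
  expect_identical(orfs$strand, c("+", "+"))
  expect_lt(orfs$start[1], orfs$start[2])  # RAG2L upstream

  single <- build_element(element_spec("Transib_single"), seed = 2)
  orfs <- single$annotation[single$annotation$part == "ORF", ]
  expect_equal(nrow(orfs), 1)
  expect_identical(orfs$label, "RAG1L")

  # TIRs are inverted repeats of model samples: both ends match the model
  # in inward-facing orientation
  tirs <- tand$annotation[tand$annotation$part == "terminal_inverted_repeat", ]
  expect_equal(tirs$start[1], 0)
  expect_equal(tirs$end[2], nchar(tand$seq))
  smat <- raglscan:::score_matrix5(AAN$pfm1, AAN$background)
  e1_5p <- substr(tand$seq, 1, 13)
  e1_3p <- raglscan:::revcomp(substring(tand$seq, nchar(tand$seq) - 12))
  expect_gt(raglscan:::pwm_score_seq(e1_5p, smat), 20)
  expect_gt(raglscan:::pwm_score_seq(e1_3p, smat), 20)

  # spans tile the element
  expect_true(all(ann$end[-nrow(ann)] == ann$start[-1]))
})

test_that("plant_insertions duplicates the 5' target site exactly", {
  # single insertion after "ACGTT" in a toy genome
  g <- "AAAAACGTTGGGGG"
  spec <- element_spec()
  res <- raglscan:::insert_elements(g, list("XELEMX"), 9L, 5L, "RAGL_tandem")
  expect_identical(res$genome, "AAAAACGTTXELEMXACGTTGGGGG")
  expect_identical(res$truth$tsd_sequence, "ACGTT")
  expect_equal(res$truth$insertion_start, 9L)

  # empty spec list leaves the genome unchanged with empty truth
  g2 <- random_genome(1000, seed = 2)
  res2 <- plant_insertions(g2, list(), seed = 1)
  expect_identical(res2$genome, g2)
  expect_equal(nrow(res2$truth), 0)

  expect_error(
    raglscan:::insert_elements(g, list("A", "B"), c(9L, 9L), 2L, "x"),
    "overlapping")
})

test_that("insertion arithmetic holds across random configurations", {
  spec <- element_spec()
  for (i in 1:25) {
    g <- random_genome(30000, seed = 3000 + i)
    k <- 1 + (i %% 4)
    res <- plant_insertions(g, spec, n_insertions = k, seed = 40 + i)
    expect_equal(nchar(res$genome),
                 nchar(g) + sum(res$truth$element_length + spec$tsd_len))
    # every element is flanked by identical TSD copies at final coordinates
    for (j in seq_len(k)) {
      s <- res$truth$insertion_start[j]
      e <- s + res$truth$element_length[j]
      left <- substr(res$genome, s - 4, s)
      right <- substr(res$genome, e + 1, e + 5)
      expect_identical(left, right)
      expect_identical(left, res$truth$tsd_sequence[j])
    }
  }
})

test_that("strain pairs: length arithmetic and empty-site excision", {
  spec <- element_spec()
  g <- random_genome(60000, seed = 21)
  sim <- simulate_strain_pair(g, 3, 3, spec, seed = 6)
  expect_equal(nchar(sim$sample) - nchar(sim$reference),
               3 * (sim$truth$element_length[1] + spec$tsd_len))
  expect_setequal(sim$truth$status, c("shared", "sample_only"))

  # excising element + one TSD copy from the sample at a sample_only locus
  # reconstructs the reference around the empty site
  so <- sim$truth[sim$truth$status == "sample_only", ][1, ]
  s <- so$sample_start
  e <- s + so$element_length
  window <- 200
  sample_around <- paste0(
    substr(sim$sample, s - window + 1, s),
    substr(sim$sample, e + spec$tsd_len + 1, e + spec$tsd_len + window))
  p <- so$ref_point
  ref_around <- substr(sim$reference, p - window + 1, p + window)
  expect_identical(sample_around, ref_around)

  # shared = both genomes carry the same element at the same locus
  sh <- sim$truth[sim$truth$status == "shared", ][1, ]
  expect_identical(
    substr(sim$sample, sh$sample_start + 1, sh$sample_start + 50),
    substr(sim$reference, sh$ref_point + 1, sh$ref_point + 50))

  # degenerate counts
  sim0 <- simulate_strain_pair(g, 1, 0, spec, seed = 7)
  expect_equal(sim0$truth$status, "shared")
  expect_equal(nchar(sim0$sample), nchar(sim0$reference))
  sim1 <- simulate_strain_pair(g, 0, 1, spec, seed = 8)
  expect_identical(sim1$reference, g)
})

test_that("flank reads carry stub + TSD and respect contig edges", {
  spec <- element_spec()
  g <- random_genome(20000, seed = 31)
  res <- plant_insertions(g, spec, positions = 10000L, seed = 9)
  reads <- synth_flank_reads(res$genome, res$truth, read_len = 300,
                             tir_stub_len = 30)
  expect_equal(nchar(reads$read5), 300)
  expect_equal(nchar(reads$read3), 300)
  tsd <- res$truth$tsd_sequence
  # on the leaving strand the TSD copy sits right after the 30-bp stub
  expect_identical(substr(reads$read5, 31, 35),
                   raglscan:::revcomp(tsd))
  expect_identical(substr(reads$read3, 31, 35), tsd)
  # and the stub starts with the reverse complement of the outermost
  # element-1 bases
  expect_identical(raglscan:::revcomp(substr(reads$read5, 18, 30)),
                   substr(res$genome, 10001, 10013))

  expect_error(synth_flank_reads(res$genome, res$truth, read_len = 30,
                                 tir_stub_len = 30), "exceed")

  # locus too close to the contig start: 5' read skipped, 3' read emitted
  truth_edge <- res$truth
  truth_edge$insertion_start <- 100L
  truth_edge$sample_start <- NULL
  expect_warning(
    reads_edge <- synth_flank_reads(res$genome, truth_edge, 300, 30),
    "5' read skipped")
  expect_true(is.na(reads_edge$read5))
  expect_false(is.na(reads_edge$read3))
})

test_that("synthetic proteins round-trip through the classifier", {
  lib <- default_profile_library()
  for (cl in c("RAG1L", "Transib_I", "Transib_II")) {
    p <- synth_protein(synthetic_protein_spec(cl), lib, seed = 17)
    expect_identical(classify_protein(p, lib)$clan, cl)
  }
  # Transib_II carries CTT2 but no alpha11-alpha12 match
  p2 <- synth_protein(synthetic_protein_spec("Transib_II"), lib, seed = 18)
  expect_true(match_domain(p2, lib$CTT2)$present)
  expect_false(match_domain(p2, lib$A11_A12)$present)
  # bare scaffold stays unclassified
  p0 <- synth_protein(synthetic_protein_spec("RAG1L",
                                             planted_motifs = character(0)),
                      lib, seed = 19)
  expect_identical(classify_protein(p0, lib)$clan, "unclassified")
  # inconsistent planted set and unknown ids are rejected
  expect_error(synthetic_protein_spec("RAG1L", planted_motifs = c("CTT2")),
               "inconsistent")
  expect_error(synth_protein(
    synthetic_protein_spec("Transib_II", planted_motifs = c("NBD_GRP",
                                                            "CTT2", "NOPE")),
    lib, seed = 1), "not in library")
  expect_error(synth_protein(
    synthetic_protein_spec("Transib_II", scaffold_length = 20L), lib,
    seed = 1), "minimum length")
})

test_that("truth tables and FASTA round-trip on disk", {
  spec <- element_spec()
  g <- random_genome(20000, seed = 51)
  res <- plant_insertions(g, spec, n_insertions = 2, seed = 12)
  tsv <- tempfile(fileext = ".tsv")
  write_truth_tsv(res$truth, tsv)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(back$start, res$truth$insertion_start)
  expect_identical(back$tsd, res$truth$tsd_sequence)

  fa <- tempfile(fileext = ".fasta")
  write_fasta(c(genome = res$genome), fa, "dna")
  expect_identical(unname(read_fasta(fa, "dna")), res$genome)
})
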