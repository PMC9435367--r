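# Seeded generators for synthetic genomes carrying RAGL/Transib insertions
# with the structural statistics the annotator assumes: bipartite TIRs,
# 5-bp target site duplications, single-exon ORF cassettes in tandem or
# convergent orientation, strain pairs differing by polymorphic insertions,
# splinkerette-style flank reads, and proteins with planted domain motifs.
# Every generator takes an explicit seed and is bit-reproducible.

#' Specify a synthetic transposable element
#'
#' Defaults describe an AanRAGL-like element: tandem RAG2L-then-RAG1L genes
#' transcribed in the same direction, asymmetric 4/13-bp TIR spacers and a
#' 5-bp TSD. Which TIR carries the 4-bp and which the 13-bp spacer is not
#' constrained by the biology encoded here, so `spacer_assignment` is an
#' explicit ordered pair (5' TIR, 3' TIR).
#'
#' @param element_kind `"RAGL_tandem"`, `"RAGL_convergent"` or
#'   `"Transib_single"`.
#' @param tir_model A `bipartite_model`.
#' @param spacer_assignment Ordered pair of spacer lengths (bp) for the 5'
#'   and 3' TIR; both must belong to the model's allowed set.
#' @param tsd_len Target-site duplication length (bp, >= 0).
#' @param gene_lengths Named vector of ORF lengths in codons (including
#'   start and stop). Two genes for the RAGL kinds, one for Transib_single.
#' @param per_position_mutation_rate Substitution probability applied to
#'   sampled TIR bases.
#' @param intergenic_len Length (bp) of random sequence between parts.
#' @param min_orf_codons Minimum ORF length the downstream annotator uses;
#'   gene lengths must not fall below it.
#' @return An object of class `element_spec`.
#' @export
element_spec <- function(element_kind = c("RAGL_tandem", "RAGL_convergent",
                                          "Transib_single"),
                         tir_model = aan_ragl_model(),
                         spacer_assignment = c(4L, 13L),
                         tsd_len = 5L,
                         gene_lengths = NULL,
                         per_position_mutation_rate = 0,
                         intergenic_len = 60L,
                         min_orf_codons = 100L) {
  element_kind <- match.arg(element_kind)
  if (is.null(gene_lengths)) {
    gene_lengths <- if (element_kind == "Transib_single") {
      c(RAG1L = 350L)
    } else {
      c(RAG2L = 250L, RAG1L = 350L)
    }
  }
  if (tsd_len < 0) stop("tsd_len must be >= 0")
  if (!all(spacer_assignment %in% tir_model$allowed_spacers)) {
    stop("spacer_assignment must be drawn from the model's allowed set {",
         paste(tir_model$allowed_spacers, collapse = ", "), "}")
  }
  n_genes <- if (element_kind == "Transib_single") 1L else 2L
  if (length(gene_lengths) != n_genes) {
    stop(element_kind, " requires exactly ", n_genes, " gene(s)")
  }
  if (is.null(names(gene_lengths)) || any(names(gene_lengths) == "")) {
    stop("gene_lengths must be named")
  }
  if (any(gene_lengths < min_orf_codons)) {
    stop("gene ORF lengths must be >= min_orf_codons (", min_orf_codons, ")")
  }
  if (per_position_mutation_rate < 0 || per_position_mutation_rate > 1) {
    stop("per_position_mutation_rate must lie in [0, 1]")
  }
  structure(list(element_kind = element_kind,
                 tir_model = tir_model,
                 spacer_assignment = as.integer(spacer_assignment),
                 tsd_len = as.integer(tsd_len),
                 gene_lengths = gene_lengths,
                 per_position_mutation_rate = per_position_mutation_rate,
                 intergenic_len = as.integer(intergenic_len),
                 min_orf_codons = as.integer(min_orf_codons)),
            class = "element_spec")
}

#' Sample a TIR from a bipartite model
#'
#' Returns `element1 + spacer + element2`: element bases drawn from the
#' model's consensus distribution (degenerate positions split between their
#' alternatives) with independent per-position substitution at
#' `mutation_rate`; spacer bases are uniform random.
#'
#' @param model A `bipartite_model`.
#' @param spacer_len Spacer length; must be in the model's allowed set.
#' @param mutation_rate Per-position substitution probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A DNA string of length `L1 + spacer_len + L2`.
#' @export
sample_tir <- function(model, spacer_len, mutation_rate = 0, seed = NULL) {
  stopifnot(inherits(model, "bipartite_model"))
  if (!spacer_len %in% model$allowed_spacers) {
    stop("spacer_len ", spacer_len, " not allowed; allowed set: {",
         paste(model$allowed_spacers, collapse = ", "), "}")
  }
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must lie in [0, 1]")
  }
  local_seed(seed, {
    draw <- function(probs) {
      paste(apply(probs, 2, function(p) sample(DNA_BASES, 1, prob = p)),
            collapse = "")
    }
    e1 <- draw(model$sample_probs1)
    e2 <- draw(model$sample_probs2)
    spacer <- if (spacer_len > 0) {
      paste(sample(DNA_BASES, spacer_len, replace = TRUE), collapse = "")
    } else ""
    paste0(mutate_dna(e1, mutation_rate), spacer,
           mutate_dna(e2, mutation_rate))
  })
}

# Random single-exon ORF: ATG + (n - 2) stop-free codons + stop codon.
make_orf <- function(n_codons, seed = NULL) {
  stopifnot(n_codons >= 2)
  local_seed(seed, {
    all_codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1,
                        paste, collapse = "")
    sense <- setdiff(all_codons, STOP_CODONS)
    paste0("ATG",
           paste(sample(sense, n_codons - 2, replace = TRUE), collapse = ""),
           sample(STOP_CODONS, 1))
  })
}

#' Build a synthetic transposable element
#'
#' Assembles `5'TIR + intergenic + gene cassette(s) + intergenic + 3'TIR`
#' where the 3' TIR is the reverse complement of an independent sample from
#' the same model, so the two TIRs are inverted repeats facing inward. Gene
#' cassettes are random-codon single-exon ORFs oriented according to the
#' element kind: tandem places both genes on the plus strand with the first
#' named gene upstream; convergent places the first gene on "+" and the
#' second on "-" so their 3' ends are adjacent.
#'
#' @param spec An `element_spec`.
#' @param seed Optional integer seed.
#' @return List with `seq` (the element) and `annotation`, a data frame of
#'   0-based half-open part spans (`part`, `label`, `start`, `end`,
#'   `strand`) relative to the element start.
#' @export
build_element <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "element_spec"))
  model <- spec$tir_model
  rate <- spec$per_position_mutation_rate
  tir5 <- sample_tir(model, spec$spacer_assignment[1], rate, subseed(seed, 1))
  tir3_plus <- sample_tir(model, spec$spacer_assignment[2], rate,
                          subseed(seed, 2))
  tir3 <- revcomp(tir3_plus)

  genes <- names(spec$gene_lengths)
  orfs <- lapply(seq_along(genes), function(i) {
    make_orf(spec$gene_lengths[[i]], subseed(seed, 10 + i))
  })
  strands <- switch(spec$element_kind,
                    RAGL_tandem = c("+", "+"),
                    RAGL_convergent = c("+", "-"),
                    Transib_single = "+")
  cassettes <- mapply(function(orf, strand) {
    if (strand == "-") revcomp(orf) else orf
  }, orfs, strands)

  ig <- function(i) {
    random_genome(spec$intergenic_len, seed = subseed(seed, 20 + i))
  }
  parts <- list(list(part = "terminal_inverted_repeat", label = "TIR5",
                     seq = tir5, strand = "+"))
  parts[[length(parts) + 1]] <- list(part = "intergenic", label = "ig",
                                     seq = ig(1), strand = "+")
  for (i in seq_along(genes)) {
    parts[[length(parts) + 1]] <- list(part = "ORF", label = genes[i],
                                       seq = cassettes[[i]],
                                       strand = strands[i])
    parts[[length(parts) + 1]] <- list(part = "intergenic", label = "ig",
                                       seq = ig(1 + i), strand = "+")
  }
  parts[[length(parts) + 1]] <- list(part = "terminal_inverted_repeat",
                                     label = "TIR3", seq = tir3,
                                     strand = "-")
  lens <- vapply(parts, function(p) nchar(p$seq), 0L)
  ends <- cumsum(lens)
  starts <- ends - lens
  annotation <- data.frame(
    part = vapply(parts, `[[`, "", "part"),
    label = vapply(parts, `[[`, "", "label"),
    start = as.integer(starts), end = as.integer(ends),
    strand = vapply(parts, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  list(seq = paste(vapply(parts, `[[`, "", "seq"), collapse = ""),
       annotation = annotation,
       spacer_assignment = spec$spacer_assignment,
       element_kind = spec$element_kind)
}

# Core insertion arithmetic shared by plant_insertions and
# simulate_strain_pair: insert prebuilt element sequences at 0-based points
# of `genome`, duplicating the tsd_len bases immediately 5' of each point.
insert_elements <- function(genome, elements, positions, tsd_len,
                            element_kind, genome_id = "genome") {
  n <- nchar(genome)
  stopifnot(length(elements) == length(positions))
  if (length(positions) == 0) {
    return(list(genome = genome, truth = data.frame(
      locus_id = character(), genome_id = character(),
      insertion_start = integer(), element_length = integer(),
      tsd_sequence = character(), element_kind = character(),
      strand = character(), position_original = integer(),
      stringsAsFactors = FALSE)))
  }
  ord <- order(positions)
  positions <- positions[ord]
  elements <- elements[ord]
  element_kind <- rep(element_kind, length.out = length(elements))[ord]
  if (any(duplicated(positions))) {
    i <- which(duplicated(positions))[1]
    stop("overlapping insertions: loci at positions ", positions[i],
         " and ", positions[i], " conflict")
  }
  if (length(positions) > 1) {
    gaps <- diff(positions)
    if (any(gaps < tsd_len)) {
      i <- which(gaps < tsd_len)[1]
      stop("overlapping insertions: positions ", positions[i], " and ",
           positions[i + 1], " are closer than tsd_len (", tsd_len, ")")
    }
  }
  if (any(positions < tsd_len) || any(positions > n)) {
    stop("insertion points must lie in [tsd_len, genome length]")
  }
  pieces <- character(0)
  prev <- 0
  shift <- 0
  truth <- vector("list", length(positions))
  for (i in seq_along(positions)) {
    p <- positions[i]
    el <- elements[[i]]
    pieces <- c(pieces, subseq0(genome, prev, p), el)
    truth[[i]] <- data.frame(
      locus_id = sprintf("locus_%02d", i),
      genome_id = genome_id,
      insertion_start = as.integer(p + shift),
      element_length = nchar(el),
      tsd_sequence = if (tsd_len > 0) subseq0(genome, p - tsd_len, p) else "",
      element_kind = element_kind[i],
      strand = "+",
      position_original = as.integer(p),
      stringsAsFactors = FALSE)
    shift <- shift + nchar(el) + tsd_len
    prev <- p - tsd_len
  }
  pieces <- c(pieces, subseq0(genome, prev, n))
  list(genome = paste(pieces, collapse = ""),
       truth = do.call(rbind, truth))
}

#' Plant transposable elements into a genome
#'
#' At each insertion point the `tsd_len` bases immediately 5' of the point
#' are duplicated, so each element ends up flanked by identical TSD copies.
#' The output length is the input length plus the sum of element lengths and
#' TSDs; truth records carry final (post-insertion) 0-based coordinates.
#'
#' @param genome DNA string (non-empty).
#' @param specs A single `element_spec` or a list of them (one per site).
#' @param positions Integer vector of distinct 0-based insertion points at
#'   least `tsd_len` apart, or `"random"`.
#' @param n_insertions Number of sites when `positions = "random"` and a
#'   single spec is given.
#' @param seed Optional integer seed.
#' @return List with `genome` (mutated sequence), `truth` (data frame of
#'   truth records) and `elements` (the built elements).
#' @export
plant_insertions <- function(genome, specs, positions = "random",
                             n_insertions = NULL, seed = NULL) {
  if (nchar(genome) == 0) stop("genome must be non-empty")
  if (inherits(specs, "element_spec")) {
    k <- if (!identical(positions, "random")) length(positions)
         else if (!is.null(n_insertions)) n_insertions else 1L
    specs <- rep(list(specs), k)
  }
  if (length(specs) == 0) {
    return(list(genome = genome,
                truth = insert_elements(genome, list(), integer(0), 0,
                                        character(0))$truth,
                elements = list()))
  }
  tsd_len <- unique(vapply(specs, `[[`, 0L, "tsd_len"))
  if (length(tsd_len) != 1) stop("all specs must share one tsd_len")
  if (identical(positions, "random")) {
    positions <- draw_positions(nchar(genome), length(specs), tsd_len,
                                subseed(seed, 999))
  }
  built <- lapply(seq_along(specs), function(i) {
    build_element(specs[[i]], subseed(seed, i))
  })
  res <- insert_elements(genome, lapply(built, `[[`, "seq"), positions,
                         tsd_len,
                         vapply(specs, `[[`, "", "element_kind"))
  res$elements <- built
  res
}

# Distinct random insertion points with generous spacing so element+flank
# windows never collide.
draw_positions <- function(n, k, tsd_len, seed = NULL, min_sep = 8000L) {
  local_seed(seed, {
    lo <- max(tsd_len, 400L)
    hi <- n - 400L
    if (hi <= lo) stop("genome too short for insertions")
    sep <- min(min_sep, max(tsd_len + 1, (hi - lo) %/% max(1, 2 * k)))
    for (try in 1:200) {
      p <- sort(sample(lo:hi, k))
      if (k < 2 || all(diff(p) >= sep)) return(p)
    }
    stop("could not place ", k, " insertions ", sep, " bp apart")
  })
}

#' Simulate a strain pair differing by polymorphic insertions
#'
#' Shared loci carry the element in both genomes; sample-only loci carry it
#' only in the sample genome, the reference retaining the single TSD copy of
#' the empty site. This reproduces the situation where an element has
#' transposed recently in one culture but is absent from the reference
#' assembly.
#'
#' @param reference Pre-insertion host sequence (DNA string).
#' @param shared_loci,sample_only_loci Locus counts (>= 0).
#' @param spec An `element_spec` used at every locus.
#' @param seed Optional integer seed.
#' @return List with `reference`, `sample` (sequences), `truth` (per-locus
#'   data frame with `status`, reference and sample coordinates) and
#'   `elements`.
#' @export
simulate_strain_pair <- function(reference, shared_loci, sample_only_loci,
                                 spec, seed = NULL) {
  stopifnot(shared_loci >= 0, sample_only_loci >= 0)
  k <- shared_loci + sample_only_loci
  if (k == 0) {
    return(list(reference = reference, sample = reference,
                truth = data.frame(), elements = list()))
  }
  positions <- draw_positions(nchar(reference), k, spec$tsd_len,
                              subseed(seed, 999))
  status <- local_seed(subseed(seed, 998), {
    sample(c(rep("shared", shared_loci),
             rep("sample_only", sample_only_loci)))
  })
  built <- lapply(seq_len(k), function(i) build_element(spec, subseed(seed, i)))
  seqs <- lapply(built, `[[`, "seq")

  shared_idx <- which(status == "shared")
  ref_res <- insert_elements(reference, seqs[shared_idx],
                             positions[shared_idx], spec$tsd_len,
                             spec$element_kind, genome_id = "reference")
  smp_res <- insert_elements(reference, seqs, positions, spec$tsd_len,
                             spec$element_kind, genome_id = "sample")

  lens <- vapply(seqs, nchar, 0L)
  ref_shift <- function(p) {
    before <- shared_idx[positions[shared_idx] < p]
    sum(lens[before] + spec$tsd_len)
  }
  # draw_positions returns ascending positions, so truth rows, positions and
  # status share one order
  truth <- smp_res$truth
  truth$status <- status
  truth$sample_start <- truth$insertion_start
  truth$ref_point <- vapply(truth$position_original, function(p) {
    as.integer(p + ref_shift(p))
  }, 0L)
  truth$genome_id <- "sample"
  rownames(truth) <- NULL
  list(reference = ref_res$genome, sample = smp_res$genome,
       truth = truth, elements = built)
}

#' Synthesize splinkerette-style flank read pairs
#'
#' For each truth locus emits a 5' read and a 3' read, each reported on the
#' strand leaving the element: a `tir_stub_len`-bp element stub at the read
#' start followed by genomic flank that begins with the adjacent TSD copy.
#'
#' @param sample_genome Sample-strain sequence the loci live in.
#' @param truth Truth table with `locus_id`, `sample_start` (or
#'   `insertion_start`) and `element_length`.
#' @param read_len Total read length (> `tir_stub_len`).
#' @param tir_stub_len Element stub length (bp).
#' @param substitution_rate Optional per-base read error rate (default 0).
#' @param seed Optional integer seed.
#' @return Data frame of `locus_id, read5, read3, stub5, stub3`; reads that
#'   would run past a contig end are `NA` with a warning.
#' @export
synth_flank_reads <- function(sample_genome, truth, read_len = 300L,
                              tir_stub_len = 30L, substitution_rate = 0,
                              seed = NULL) {
  if (read_len <= tir_stub_len) stop("read_len must exceed tir_stub_len")
  if (nrow(truth) == 0) stop("no loci in truth table")
  starts <- if ("sample_start" %in% names(truth)) truth$sample_start
            else truth$insertion_start
  n <- nchar(sample_genome)
  f <- read_len - tir_stub_len
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    s <- starts[i]
    e <- s + truth$element_length[i]
    read5 <- if (s - f >= 0) {
      revcomp(subseq0(sample_genome, s - f, s + tir_stub_len))
    } else {
      warning("locus ", truth$locus_id[i],
              ": 5' read skipped (too close to contig start)")
      NA_character_
    }
    read3 <- if (e + f <= n) {
      subseq0(sample_genome, e - tir_stub_len, e + f)
    } else {
      warning("locus ", truth$locus_id[i],
              ": 3' read skipped (too close to contig end)")
      NA_character_
    }
    if (substitution_rate > 0) {
      if (!is.na(read5)) read5 <- mutate_dna(read5, substitution_rate,
                                             subseed(seed, 2 * i))
      if (!is.na(read3)) read3 <- mutate_dna(read3, substitution_rate,
                                             subseed(seed, 2 * i + 1))
    }
    data.frame(locus_id = truth$locus_id[i], read5 = read5, read3 = read3,
               stub5 = tir_stub_len, stub3 = tir_stub_len,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a truth table as TSV
#'
#' Columns: `locus_id, genome_id, start, end, element_kind, tsd, strand`.
#'
#' @param truth Truth data frame from the generators.
#' @param path Output path.
#' @export
write_truth_tsv <- function(truth, path) {
  start <- if ("sample_start" %in% names(truth)) truth$sample_start
           else truth$insertion_start
  out <- data.frame(locus_id = truth$locus_id,
                    genome_id = truth$genome_id,
                    start = start,
                    end = start + truth$element_length,
                    element_kind = truth$element_kind,
                    tsd = truth$tsd_sequence,
                    strand = truth$strand,
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Specify a synthetic protein with planted domain motifs
#'
#' @param target_class `"RAG1L"`, `"Transib_I"` or `"Transib_II"`.
#' @param planted_motifs Profile ids to plant, N-to-C order; defaults to the
#'   diagnostic set of the target class. An empty character vector yields a
#'   bare scaffold (classified `unclassified`).
#' @param scaffold_length Scaffold length in residues.
#' @param motif_mutation_rate Substitution probability applied to planted
#'   motif residues.
#' @return An object of class `synthetic_protein_spec`.
#' @export
synthetic_protein_spec <- function(target_class = c("RAG1L", "Transib_I",
                                                    "Transib_II"),
                                   planted_motifs = NULL,
                                   scaffold_length = 900L,
                                   motif_mutation_rate = 0) {
  target_class <- match.arg(target_class)
  if (is.null(planted_motifs)) {
    planted_motifs <- class_motifs(target_class)
  }
  if (length(planted_motifs) > 0) {
    required <- class_motifs(target_class)
    diagnostic <- c("A11_A12", "CTT1", "CTT2", "PRERNH_LOOP")
    if (!setequal(intersect(planted_motifs, diagnostic),
                  intersect(required, diagnostic))) {
      stop("planted motif set is inconsistent with the decision table for ",
           target_class)
    }
  }
  structure(list(target_class = target_class,
                 planted_motifs = planted_motifs,
                 scaffold_length = as.integer(scaffold_length),
                 motif_mutation_rate = motif_mutation_rate),
            class = "synthetic_protein_spec")
}

# Diagnostic + corroborating motif complement of each clan, N-to-C order.
class_motifs <- function(target_class) {
  switch(target_class,
         RAG1L = c("NBD_GRP", "ALPHA1", "PRERNH_LOOP", "A11_A12",
                   "ALPHA17", "CTT1"),
         Transib_I = c("NBD_GRP", "ALPHA1", "A11_A12", "ALPHA17", "CTT1"),
         Transib_II = c("NBD_GRP", "CTT2"))
}

#' Synthesize a protein with planted domain motifs
#'
#' Builds a uniform-random scaffold and overwrites non-overlapping windows
#' with the consensus of each planted profile, in N-to-C order (NBD before
#' core regions before the C-terminal tail), then applies substitutions to
#' motif residues at `motif_mutation_rate`.
#'
#' @param spec A `synthetic_protein_spec`.
#' @param library Profile library (see [default_profile_library()]).
#' @param seed Optional integer seed.
#' @return Amino-acid sequence (character string).
#' @export
synth_protein <- function(spec, library = default_profile_library(),
                          seed = NULL) {
  stopifnot(inherits(spec, "synthetic_protein_spec"))
  missing <- setdiff(spec$planted_motifs, names(library))
  if (length(missing) > 0) {
    stop("planted motif id(s) not in library: ",
         paste(missing, collapse = ", "))
  }
  motifs <- vapply(spec$planted_motifs,
                   function(id) profile_consensus(library[[id]]), "")
  need <- sum(nchar(motifs)) + 2 * (length(motifs) + 1)
  if (spec$scaffold_length < need) {
    stop("scaffold too short to hold all motifs; minimum length ", need)
  }
  local_seed(seed, {
    chars <- sample(AA_ALPHABET, spec$scaffold_length, replace = TRUE)
    if (length(motifs) > 0) {
      slack <- spec$scaffold_length - sum(nchar(motifs))
      cuts <- sort(sample.int(slack - 1, length(motifs)))
      pos <- cuts + c(0, cumsum(nchar(motifs)))[seq_along(motifs)]
      for (i in seq_along(motifs)) {
        m <- strsplit(mutate_protein(motifs[i], spec$motif_mutation_rate),
                      "", fixed = TRUE)[[1]]
        chars[(pos[i] + 1):(pos[i] + length(m))] <- m
      }
    }
    paste(chars, collapse = "")
  })
}
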