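# Insertion-polymorphism calling from paired flanking sequences, the
# downstream logic of a splinkerette-PCR assay: strip the element stub off
# each read, map both genomic portions to the reference, and interpret the
# junction arithmetic. An element present in the sample but absent from the
# reference leaves the two flanks overlapping by exactly one TSD copy in
# the reference ("seamlessly joined"); flanks separated by a TIR-bounded
# interval mean the element is also in the reference; adjacent flanks with
# no duplicated overlap indicate an element lost from the reference.

#' Strip the TIR stub off a flank read
#'
#' Flank reads are reported on the strand leaving the element: a TIR stub at
#' the read start, then genomic flank. The outermost bases of either TIR are
#' the upstream conserved element (on the matching strand), so the stub end
#' is located by sliding the reverse-complemented element-1 PWM along the
#' read and taking the best-scoring end position.
#'
#' @param read Flank read (DNA string).
#' @param model A `bipartite_model`.
#' @param floor_bits Minimum average score (bits/bp over the element-1
#'   window) for the stub to be accepted.
#' @param min_portion Minimum genomic-portion length for the read to be
#'   informative.
#' @return `list(status = "ok", genomic =, stub_len =, score_bits =)` or
#'   `list(status = "rejected", reason =)`.
#' @export
strip_stub <- function(read, model, floor_bits = 0.5, min_portion = 30L) {
  n <- nchar(read)
  L1 <- model$L1
  if (n <= L1) {
    return(list(status = "rejected", reason = "read shorter than stub window"))
  }
  rcread <- revcomp(read)
  s1 <- pwm_score_vector(dna_codes(rcread), model$smat1)
  # position p in rcread corresponds to stub length k = n - p + 1
  # (1-based p); require k <= n - min_portion
  pmin <- max(2L, min_portion + 1L)
  if (pmin > length(s1)) {
    return(list(status = "rejected", reason = "read all stub (uninformative)"))
  }
  cand <- s1[pmin:length(s1)]
  best <- which.max(cand) + pmin - 1L
  score <- s1[best] / L1
  if (score < floor_bits) {
    return(list(status = "rejected",
                reason = sprintf("no TIR stub above floor (%.2f < %.2f bits/bp)",
                                 score, floor_bits)))
  }
  k <- n - best + 1L
  list(status = "ok", genomic = substr(read, k + 1, n),
       stub_len = as.integer(k), score_bits = score)
}

#' Map a genomic flank portion to a reference genome
#'
#' Seed-anchored alignment: exact k-mer seeds locate candidate windows on
#' both strands, each window is aligned with an affine-gap aligner, and the
#' single best hit is returned. Default mode `"glocal"` aligns the whole
#' query against a local stretch of reference, keeping junction coordinates
#' exact under read errors; mode `"local"` is plain Smith-Waterman on the
#' window. Queries whose best and runner-up hits at distinct loci score
#' within 5% are reported unmapped with a multi-hit note.
#'
#' @param query Genomic portion (DNA string, non-empty).
#' @param reference Reference genome (string, named vector or FASTA path).
#' @param seed_len Exact seed length (default 15).
#' @param seed_step Spacing between query seed positions.
#' @param match,mismatch,gap_open,gap_extend Alignment scores (costs given
#'   as positive numbers).
#' @param mode `"glocal"` or `"local"`.
#' @return `list(status = "mapped"/"unmapped", contig =, start =, end =,
#'   strand =, score =, identity =, note =)`; coordinates 0-based half-open
#'   on the reference plus strand.
#' @export
align_flank <- function(query, reference, seed_len = 15L, seed_step = 10L,
                        match = 2, mismatch = 3, gap_open = 5,
                        gap_extend = 2, mode = c("glocal", "local")) {
  mode <- match.arg(mode)
  if (nchar(query) == 0) stop("empty query")
  contigs <- as_contigs(reference)
  nq <- nchar(query)
  if (nq < seed_len) {
    return(unmapped("query shorter than seed length"))
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = -mismatch)
  type <- if (mode == "glocal") "global-local" else "local"

  seed_positions <- unique(c(seq(1, nq - seed_len + 1, by = seed_step),
                             nq - seed_len + 1))
  best <- NULL
  second <- -Inf
  for (cn in names(contigs)) {
    refseq <- contigs[[cn]]
    subj <- Biostrings::DNAString(refseq)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else revcomp(query)
      diags <- integer(0)
      for (sp in seed_positions) {
        kmer <- substr(q, sp, sp + seed_len - 1)
        if (grepl("N", kmer, fixed = TRUE)) next
        hits <- Biostrings::start(Biostrings::matchPattern(kmer, subj))
        if (length(hits) > 0 && length(hits) <= 50) {
          diags <- c(diags, hits - sp)
        }
      }
      if (length(diags) == 0) next
      # cluster diagonals into candidate windows
      diags <- sort(unique(diags))
      grp <- cumsum(c(1, diff(diags) > nq))
      for (g in unique(grp)) {
        d <- diags[grp == g]
        w_start <- max(1, min(d) + 1 - 50)
        w_end <- min(nchar(refseq), max(d) + nq + 50)
        window <- Biostrings::subseq(subj, w_start, w_end)
        aln <- Biostrings::pairwiseAlignment(
          pattern = q, subject = window, type = type,
          substitutionMatrix = submat, gapOpening = gap_open,
          gapExtension = gap_extend)
        sc <- Biostrings::score(aln)
        s0 <- w_start - 1 + Biostrings::start(Biostrings::subject(aln)) - 1
        e0 <- w_start - 1 + Biostrings::end(Biostrings::subject(aln))
        pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
        sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
        ident <- 100 * sum(pa == sa & pa != "-") / length(pa)
        hit <- list(status = "mapped", contig = cn, start = as.integer(s0),
                    end = as.integer(e0), strand = strand, score = sc,
                    identity = ident, note = "")
        if (is.null(best) || sc > best$score) {
          if (!is.null(best) &&
              (best$contig != cn || abs(best$start - s0) > nq)) {
            second <- max(second, best$score)
          }
          best <- hit
        } else if (best$contig != cn || abs(best$start - s0) > nq) {
          second <- max(second, sc)
        }
      }
    }
  }
  if (is.null(best)) return(unmapped("no seed match"))
  if (second > 0 && second >= 0.95 * best$score) {
    return(unmapped("multi_hit"))
  }
  best
}

unmapped <- function(note) {
  list(status = "unmapped", contig = NA_character_, start = NA_integer_,
       end = NA_integer_, strand = NA_character_, score = NA_real_,
       identity = NA_real_, note = note)
}

#' Call the insertion status of one locus
#'
#' Strips the stubs off both reads, maps the genomic portions, and reads the
#' junction: overlapping by exactly `tsd_k` identical reference bases means
#' the element is in the sample but the reference carries the empty site
#' (`sample_only_empty_ref`); adjacency with no duplicated overlap is
#' `footprint_free_ref` (consistent with loss of a copy from the
#' reference); separation by an interval whose ends match the TIR model is
#' `shared_present_in_ref`; anything else is `unmapped` with a diagnostic.
#'
#' @param pair List or one-row data frame with `locus_id`, `read5`,
#'   `read3`.
#' @param reference Reference genome (string, named vector or FASTA path).
#' @param model A `bipartite_model`.
#' @param tsd_k Expected TSD length (bp).
#' @param junction_tol Tolerance (bp) on the junction offset, default 0.
#' @param min_identity,min_coverage Mapping acceptance cutoffs (percent
#'   identity, fraction of the portion aligned).
#' @param floor_bits Stub acceptance floor passed to [strip_stub()].
#' @param ... Further arguments to [align_flank()].
#' @return One-row data frame: `locus_id, status, contig, flank5_start,
#'   flank5_end, flank3_start, flank3_end, junction_offset,
#'   tsd_at_junction, note`.
#' @export
call_locus <- function(pair, reference, model, tsd_k = 5L,
                       junction_tol = 0L, min_identity = 90,
                       min_coverage = 0.8, floor_bits = 0.5, ...) {
  locus_id <- if (is.list(pair)) pair$locus_id else pair["locus_id"]
  res <- function(status, note = "", contig = NA_character_,
                  f5 = c(NA_integer_, NA_integer_),
                  f3 = c(NA_integer_, NA_integer_),
                  offset = NA_integer_, tsd = NA_character_) {
    data.frame(locus_id = locus_id, status = status, contig = contig,
               flank5_start = f5[1], flank5_end = f5[2],
               flank3_start = f3[1], flank3_end = f3[2],
               junction_offset = offset, tsd_at_junction = tsd,
               note = note, stringsAsFactors = FALSE)
  }
  if (is.na(pair$read5) || is.na(pair$read3)) {
    return(res("unmapped", "missing read"))
  }
  s5 <- strip_stub(pair$read5, model, floor_bits = floor_bits)
  s3 <- strip_stub(pair$read3, model, floor_bits = floor_bits)
  if (s5$status != "ok") return(res("unmapped", paste0("read5: ", s5$reason)))
  if (s3$status != "ok") return(res("unmapped", paste0("read3: ", s3$reason)))
  contigs <- as_contigs(reference)
  a5 <- align_flank(s5$genomic, contigs, ...)
  a3 <- align_flank(s3$genomic, contigs, ...)
  if (a5$status != "mapped") return(res("unmapped",
                                        paste0("flank5: ", a5$note)))
  if (a3$status != "mapped") return(res("unmapped",
                                        paste0("flank3: ", a3$note)))
  cov5 <- (a5$end - a5$start) / nchar(s5$genomic)
  cov3 <- (a3$end - a3$start) / nchar(s3$genomic)
  if (a5$identity < min_identity || a3$identity < min_identity ||
      cov5 < min_coverage || cov3 < min_coverage) {
    return(res("unmapped", "low identity/coverage",
               contig = a5$contig,
               f5 = c(a5$start, a5$end), f3 = c(a3$start, a3$end)))
  }
  if (a5$contig != a3$contig) {
    return(res("unmapped", "flanks map to different contigs",
               f5 = c(a5$start, a5$end), f3 = c(a3$start, a3$end)))
  }
  if (a5$strand == a3$strand) {
    return(res("unmapped", "strand_inconsistent", contig = a5$contig,
               f5 = c(a5$start, a5$end), f3 = c(a3$start, a3$end)))
  }
  # the junction is where query base 1 (the base next to the stub) maps
  junction <- function(a) if (a$strand == "+") a$start else a$end
  j5 <- junction(a5)
  j3 <- junction(a3)
  offset <- if (a5$strand == "-") j3 - j5 else j5 - j3
  refseq <- contigs[[a5$contig]]
  if (abs(offset + tsd_k) <= junction_tol) {
    lo <- min(j5, j3); hi <- max(j5, j3)
    return(res("sample_only_empty_ref", contig = a5$contig,
               f5 = c(a5$start, a5$end), f3 = c(a3$start, a3$end),
               offset = as.integer(offset),
               tsd = subseq0(refseq, lo, hi)))
  }
  if (abs(offset) <= junction_tol) {
    return(res("footprint_free_ref", contig = a5$contig,
               f5 = c(a5$start, a5$end), f3 = c(a3$start, a3$end),
               offset = as.integer(offset)))
  }
  min_window <- model$L1 + min(model$allowed_spacers) + model$L2
  if (offset >= min_window) {
    lo <- min(j5, j3); hi <- max(j5, j3)
    interval <- subseq0(refseq, lo, hi)
    L1 <- model$L1
    left_ok <- pwm_score_seq(substr(interval, 1, L1), model$smat1) / L1 >=
      floor_bits
    right_ok <- pwm_score_seq(
      revcomp(substr(interval, nchar(interval) - L1 + 1, nchar(interval))),
      model$smat1) / L1 >= floor_bits
    if (isTRUE(left_ok) && isTRUE(right_ok)) {
      return(res("shared_present_in_ref", contig = a5$contig,
                 f5 = c(a5$start, a5$end), f3 = c(a3$start, a3$end),
                 offset = as.integer(offset)))
    }
    return(res("unmapped", "intervening interval lacks TIR ends",
               contig = a5$contig, f5 = c(a5$start, a5$end),
               f3 = c(a3$start, a3$end), offset = as.integer(offset)))
  }
  res("unmapped", "junction_inconsistent", contig = a5$contig,
      f5 = c(a5$start, a5$end), f3 = c(a3$start, a3$end),
      offset = as.integer(offset))
}

#' Call all loci of a flank-pair table
#'
#' Per-pair failures are reported as status `unmapped`; the batch never
#' aborts. Deterministic for identical inputs.
#'
#' @param pairs Data frame from [synth_flank_reads()] (or columns
#'   `locus_id`, `read5`, `read3`), or a FASTA path with the
#'   `locusID/5`-`locusID/3` naming convention.
#' @param reference Reference genome.
#' @param model A `bipartite_model`.
#' @param ... Arguments passed on to [call_locus()].
#' @return List with `calls` (one row per pair) and `summary` (status
#'   counts).
#' @export
call_all <- function(pairs, reference, model, ...) {
  if (is.character(pairs) && length(pairs) == 1 && file.exists(pairs)) {
    pairs <- read_flank_fasta(pairs)
  }
  contigs <- as_contigs(reference)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    call_locus(pairs[i, ], contigs, model, ...)
  })
  calls <- if (length(rows) == 0) {
    data.frame(locus_id = character(), status = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  statuses <- c("sample_only_empty_ref", "shared_present_in_ref",
                "footprint_free_ref", "unmapped")
  list(calls = calls,
       summary = table(factor(calls$status, levels = statuses)))
}

#' Read flank pairs from FASTA (`locusID/5`, `locusID/3` naming)
#'
#' @param path FASTA path.
#' @return Data frame `locus_id, read5, read3`.
#' @export
read_flank_fasta <- function(path) {
  seqs <- read_fasta(path, "dna")
  loci <- unique(sub("/[35]$", "", names(seqs)))
  do.call(rbind, lapply(loci, function(l) {
    data.frame(
      locus_id = l,
      read5 = if (paste0(l, "/5") %in% names(seqs))
        unname(seqs[paste0(l, "/5")]) else NA_character_,
      read3 = if (paste0(l, "/3") %in% names(seqs))
        unname(seqs[paste0(l, "/3")]) else NA_character_,
      stringsAsFactors = FALSE)
  }))
}

#' Write inferred insertion sites as BED
#'
#' One BED record per `sample_only_empty_ref` call: the TSD interval of the
#' empty site in the reference (0-based half-open, as BED expects), named by
#' locus.
#'
#' @param calls Call data frame from [call_all()].
#' @param path Output path.
#' @export
write_insertion_bed <- function(calls, path) {
  so <- calls[calls$status == "sample_only_empty_ref", , drop = FALSE]
  lines <- vapply(seq_len(nrow(so)), function(i) {
    # the junction overlap interval is the empty-site TSD copy
    start <- min(so$flank3_start[i], so$flank5_end[i])
    sprintf("%s\t%d\t%d\t%s", so$contig[i], start,
            start + abs(so$junction_offset[i]), so$locus_id[i])
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write flank pairs to FASTA
#'
#' @param pairs Data frame with `locus_id`, `read5`, `read3`.
#' @param path Output path.
#' @export
write_flank_fasta <- function(pairs, path) {
  seqs <- character(0)
  for (i in seq_len(nrow(pairs))) {
    if (!is.na(pairs$read5[i])) {
      seqs[paste0(pairs$locus_id[i], "/5")] <- pairs$read5[i]
    }
    if (!is.na(pairs$read3[i])) {
      seqs[paste0(pairs$locus_id[i], "/3")] <- pairs$read3[i]
    }
  }
  write_fasta(seqs, path, "dna")
}
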