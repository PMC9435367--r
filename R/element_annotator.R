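# Assembly of TIR hits into transposon calls: inverted-repeat pairing with
# greedy non-overlap resolution, exact-match TSD validation, six-frame ORF
# discovery and architecture classification (tandem / convergent RAGL,
# Transib-like single gene, or fragmented).

#' Pair inverted TIR hits into element candidates
#'
#' Candidates are (h1 on "+", h2 on "-" downstream) — inverted repeats
#' facing inward — whose inner distance lies in `[min_gap, max_gap]`.
#' Overlapping candidates are resolved greedily by descending combined
#' score, ties broken by smaller span then leftmost start. When the contig
#' sequence is supplied, candidates with a validated TSD outrank TSD-less
#' ones before the greedy sweep (the TSD is insertion evidence and prevents
#' chimeric cross-element pairs); omit `contig` for pure score-greedy
#' pairing.
#'
#' @param hits Hit data frame from [scan_bipartite()] (one contig, one
#'   model).
#' @param min_gap,max_gap Inner distance bounds in bp (`min_gap <= max_gap`).
#' @param contig Optional contig sequence for TSD-aware ranking.
#' @param tsd_range Length-2 TSD search range used when `contig` is given.
#' @return Data frame of selected pairs: TIR coordinates and scores, element
#'   span, `spacer5`, `spacer3`, `symmetry`, `inner_gap`, `combined_score`,
#'   and `tsd`/`tsd_len` (NA unless `contig` was given and a TSD was found).
#' @export
pair_tirs <- function(hits, min_gap, max_gap, contig = NULL,
                      tsd_range = c(2L, 10L)) {
  if (min_gap > max_gap) stop("min_gap must be <= max_gap")
  empty <- data.frame(contig = character(), span_start = integer(),
                      span_end = integer(), tir5_start = integer(),
                      tir5_end = integer(), tir3_start = integer(),
                      tir3_end = integer(), spacer5 = integer(),
                      spacer3 = integer(), symmetry = character(),
                      inner_gap = integer(), score5 = numeric(),
                      score3 = numeric(), combined_score = numeric(),
                      tsd = character(), tsd_len = integer(),
                      stringsAsFactors = FALSE)
  plus <- hits[hits$strand == "+", , drop = FALSE]
  minus <- hits[hits$strand == "-", , drop = FALSE]
  if (nrow(plus) == 0 || nrow(minus) == 0) return(empty)
  cand <- list()
  for (i in seq_len(nrow(plus))) {
    gap <- minus$start - plus$end[i]
    ok <- which(gap >= min_gap & gap <= max_gap)
    for (j in ok) {
      cand[[length(cand) + 1]] <- data.frame(
        contig = plus$contig[i],
        span_start = plus$start[i], span_end = minus$end[j],
        tir5_start = plus$start[i], tir5_end = plus$end[i],
        tir3_start = minus$start[j], tir3_end = minus$end[j],
        spacer5 = plus$spacer_len[i], spacer3 = minus$spacer_len[j],
        symmetry = tir_symmetry(plus$spacer_len[i], minus$spacer_len[j]),
        inner_gap = gap[j],
        score5 = plus$total_score[i], score3 = minus$total_score[j],
        combined_score = plus$total_score[i] + minus$total_score[j],
        tsd = NA_character_, tsd_len = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  if (!is.null(contig)) {
    for (i in seq_len(nrow(cand))) {
      tsd <- detect_tsd(contig, cand$span_start[i], cand$span_end[i],
                        tsd_range[1], tsd_range[2])
      if (!is.null(tsd)) {
        cand$tsd[i] <- tsd$tsd
        cand$tsd_len[i] <- tsd$k
      }
    }
  }
  span <- cand$span_end - cand$span_start
  ord <- order(-as.integer(!is.na(cand$tsd)), -cand$combined_score, span,
               cand$span_start)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  occ_start <- integer(0); occ_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$span_start[i]; e <- cand$span_end[i]
    if (!any(s < occ_end & e > occ_start)) {
      keep[i] <- TRUE
      occ_start <- c(occ_start, s); occ_end <- c(occ_end, e)
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$span_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect a target-site duplication flanking an element span
#'
#' Returns the largest `k` in `[k_min, k_max]` for which the `k` bases
#' immediately 5' of the element exactly equal the `k` bases immediately 3'
#' of it. Homopolymeric flanks force a match at `k_max` by definition. An
#' element too close to a contig edge yields `NULL` with a warning.
#'
#' @param contig Contig sequence.
#' @param start,end 0-based half-open element span.
#' @param k_min,k_max TSD length search range (`1 <= k_min <= k_max`).
#' @return `list(tsd =, k =)` or `NULL`.
#' @export
detect_tsd <- function(contig, start, end, k_min = 2L, k_max = 10L) {
  stopifnot(k_min >= 1, k_min <= k_max)
  n <- nchar(contig)
  edge <- TRUE
  for (k in seq(k_max, k_min)) {
    if (start - k < 0 || end + k > n) next
    edge <- FALSE
    left <- subseq0(contig, start - k, start)
    right <- subseq0(contig, end, end + k)
    if (left == right && !grepl("N", left, fixed = TRUE)) {
      return(list(tsd = left, k = as.integer(k)))
    }
  }
  if (edge) warning("element at contig edge; TSD undetectable")
  NULL
}

#' Find open reading frames in both strands
#'
#' Reports every maximal ATG-to-stop frame (standard genetic code, stop
#' codon included in the span and the codon count) of at least
#' `min_len_codons` codons, on both strands and all three frames.
#'
#' @param seq DNA sequence (e.g. an element).
#' @param min_len_codons Minimum ORF length in codons (>= 1).
#' @return Data frame `start, end, strand, n_codons` with 0-based half-open
#'   nucleotide spans relative to the start of `seq`.
#' @export
find_orfs <- function(seq, min_len_codons = 100L) {
  stopifnot(min_len_codons >= 1)
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "-") revcomp(seq) else seq
    for (frame in 0:2) {
      if (n - frame < 3) next
      cs <- seq(frame + 1, n - 2, by = 3)
      codons <- substring(s, cs, cs + 2)
      stop_idx <- which(codons %in% STOP_CODONS)
      atg_idx <- which(codons == "ATG")
      if (length(stop_idx) == 0 || length(atg_idx) == 0) next
      seg_of_atg <- findInterval(atg_idx, stop_idx) + 1L
      usable <- seg_of_atg <= length(stop_idx)
      if (!any(usable)) next
      first_atg <- tapply(atg_idx[usable], seg_of_atg[usable], min)
      segs <- as.integer(names(first_atg))
      for (si in seq_along(segs)) {
        a <- first_atg[[si]]
        st <- stop_idx[segs[si]]
        n_codons <- st - a + 1L
        if (n_codons < min_len_codons) next
        s0 <- cs[a] - 1L
        e0 <- cs[st] + 2L
        if (strand == "-") {
          tmp <- s0
          s0 <- n - e0
          e0 <- n - tmp
        }
        out[[length(out) + 1]] <- data.frame(
          start = s0, end = e0, strand = strand,
          n_codons = as.integer(n_codons), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), n_codons = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Label ORFs by size rank
#'
#' Homology search is out of scope here, so the default labeller is a
#' length-threshold heuristic: the longest ORF of at least
#' `min_rag1_codons` codons is labelled `RAG1L`, the next-longest of at
#' least `min_rag2_codons` is labelled `RAG2L`, everything else `unknown`.
#' Random open frames essentially never reach these thresholds, so the
#' labels are effectively reserved for planted (or real, large) transposase
#' genes.
#'
#' @param orfs ORF data frame from [find_orfs()].
#' @param min_rag1_codons,min_rag2_codons Label length floors in codons.
#' @return `orfs` with a `label` column.
#' @export
default_orf_labeler <- function(orfs, min_rag1_codons = 300L,
                                min_rag2_codons = 200L) {
  orfs$label <- rep("unknown", nrow(orfs))
  if (nrow(orfs) == 0) return(orfs)
  ord <- order(-orfs$n_codons)
  if (orfs$n_codons[ord[1]] >= min_rag1_codons) {
    orfs$label[ord[1]] <- "RAG1L"
    if (length(ord) > 1 && orfs$n_codons[ord[2]] >= min_rag2_codons) {
      orfs$label[ord[2]] <- "RAG2L"
    }
  }
  orfs
}

#' Classify element architecture from labelled ORFs
#'
#' Decision table: RAG1L and RAG2L on opposite strands with 3' ends facing
#' is `RAGL_convergent`; same strand with RAG2L upstream is `RAGL_tandem`;
#' a lone RAG1L is `Transib_like`; labelled ORFs with a failed TIR pairing
#' or missing TSD (or an orientation outside the table) are `fragmented`.
#' Duplicated labels are flagged `expanded` and resolved by the longest ORF
#' per label.
#'
#' @param orfs ORF data frame with a `label` column (`RAG1L`, `RAG2L`,
#'   `unknown`).
#' @param tir_ok Whether a valid inward-facing TIR pair brackets the ORFs.
#' @param tsd_present Whether a TSD was detected.
#' @return `list(architecture =, notes =)`.
#' @export
classify_architecture <- function(orfs, tir_ok = TRUE, tsd_present = TRUE) {
  notes <- character(0)
  lab <- orfs[orfs$label %in% c("RAG1L", "RAG2L"), , drop = FALSE]
  if (nrow(lab) == 0) {
    return(list(architecture = "fragmented", notes = "no_labelled_orf"))
  }
  for (l in c("RAG1L", "RAG2L")) {
    if (sum(lab$label == l) > 1) {
      notes <- c(notes, "expanded")
      rows <- which(lab$label == l)
      keep <- rows[which.max(lab$n_codons[rows])]
      lab <- lab[-setdiff(rows, keep), , drop = FALSE]
    }
  }
  if (!tir_ok || !tsd_present) {
    return(list(architecture = "fragmented",
                notes = c(notes, if (!tir_ok) "tir_incomplete",
                          if (!tsd_present) "tsd_missing")))
  }
  r1 <- lab[lab$label == "RAG1L", , drop = FALSE]
  r2 <- lab[lab$label == "RAG2L", , drop = FALSE]
  if (nrow(r1) == 1 && nrow(r2) == 1) {
    if (r1$strand != r2$strand) {
      plus <- if (r1$strand == "+") r1 else r2
      minus <- if (r1$strand == "-") r1 else r2
      if (plus$start < minus$start) {
        return(list(architecture = "RAGL_convergent", notes = notes))
      }
      return(list(architecture = "fragmented",
                  notes = c(notes, "divergent_orientation")))
    }
    upstream <- if (r1$strand == "+") {
      if (r2$start < r1$start) "RAG2L" else "RAG1L"
    } else {
      if (r2$start > r1$start) "RAG2L" else "RAG1L"
    }
    if (upstream == "RAG2L") {
      return(list(architecture = "RAGL_tandem", notes = notes))
    }
    return(list(architecture = "fragmented",
                notes = c(notes, "rag1l_upstream_tandem")))
  }
  if (nrow(r1) == 1) {
    return(list(architecture = "Transib_like", notes = notes))
  }
  list(architecture = "fragmented", notes = c(notes, "rag2l_only"))
}

#' Annotate a genome for RAGL/Transib elements
#'
#' Composes the full structural pipeline: bipartite TIR scan, TSD-aware
#' inverted-repeat pairing, TSD detection, ORF discovery, labelling and
#' architecture classification. TIR hits left unpaired are examined for a
#' nearby labelled ORF and reported as `fragmented` elements. Pairs with
#' neither a TSD nor a labelled ORF are dropped as scan noise. Elements
#' overlapping contig edges are reported fragmented, never extended.
#'
#' @param genome DNA string, named character vector of contigs, or FASTA
#'   path.
#' @param model A `bipartite_model`.
#' @param threshold Scan threshold in bits; when `NULL`, computed by
#'   [null_score_quantile()] at `target_fpr`.
#' @param target_fpr Per-window false positive rate for the default
#'   threshold.
#' @param k_range Length-2 TSD search range (bp).
#' @param gap_window Length-2 inner-distance window `[min_gap, max_gap]`
#'   between paired TIRs (bp).
#' @param min_orf_codons Minimum ORF length (codons).
#' @param orf_labeler Function mapping an ORF data frame to one with a
#'   `label` column; defaults to [default_orf_labeler()].
#' @param spacers Optional spacer-set override for the scan.
#' @return Object of class `ragl_annotation`: list with `calls` (one row
#'   per TransposonCall), `orfs` (per-call ORF tables, element-relative
#'   coordinates), `threshold` and `model_id`.
#' @export
annotate_genome <- function(genome, model, threshold = NULL,
                            target_fpr = 1e-6, k_range = c(2L, 10L),
                            gap_window = c(500L, 30000L),
                            min_orf_codons = 100L,
                            orf_labeler = default_orf_labeler,
                            spacers = NULL) {
  contigs <- as_contigs(genome)
  if (is.null(threshold)) {
    threshold <- null_score_quantile(model, target_fpr)
  }
  calls <- list()
  orf_tables <- list()
  for (cn in names(contigs)) {
    seq <- contigs[[cn]]
    hits <- scan_bipartite(seq, model, threshold, spacers = spacers,
                           contig_name = cn)
    pairs <- pair_tirs(hits, gap_window[1], gap_window[2], contig = seq,
                       tsd_range = k_range)
    used_spans <- cbind(pairs$span_start, pairs$span_end)
    for (i in seq_len(nrow(pairs))) {
      p <- pairs[i, ]
      inner <- subseq0(seq, p$span_start, p$span_end)
      orfs <- orf_labeler(find_orfs(inner, min_orf_codons))
      tsd_present <- !is.na(p$tsd)
      cls <- classify_architecture(orfs, tir_ok = TRUE,
                                   tsd_present = tsd_present)
      has_label <- any(orfs$label %in% c("RAG1L", "RAG2L"))
      if (!tsd_present && !has_label) next  # scan noise
      calls[[length(calls) + 1]] <- data.frame(
        contig = cn, start = p$span_start, end = p$span_end,
        architecture = cls$architecture, symmetry = p$symmetry,
        spacer5 = p$spacer5, spacer3 = p$spacer3,
        tsd = p$tsd, tsd_len = p$tsd_len,
        total_score = p$combined_score,
        n_orfs = nrow(orfs),
        notes = paste(cls$notes, collapse = ";"),
        stringsAsFactors = FALSE)
      orf_tables[[length(orf_tables) + 1]] <- orfs
    }
    # unpaired hits: fragmented elements (single TIR plus a labelled ORF)
    paired <- logical(nrow(hits))
    if (nrow(pairs) > 0 && nrow(hits) > 0) {
      for (i in seq_len(nrow(hits))) {
        paired[i] <- any(hits$start[i] < pairs$span_end &
                           hits$end[i] > pairs$span_start)
      }
    }
    frag_spans <- cbind(integer(0), integer(0))
    unpaired <- which(!paired)
    unpaired <- unpaired[order(-hits$total_score[unpaired])]
    for (i in unpaired) {
      h <- hits[i, ]
      # one fragment per locus: skip hits overlapping a fragment already
      # called (the same TIR usually scores at several spacer offsets)
      if (nrow(frag_spans) > 0 &&
          any(h$start < frag_spans[, 2] & h$end > frag_spans[, 1])) next
      if (h$strand == "+") {
        w_start <- h$end
        w_end <- min(nchar(seq), h$end + gap_window[2])
        # do not search into elements already called
        nxt <- pairs$span_start[pairs$span_start >= h$end]
        if (length(nxt) > 0) w_end <- min(w_end, min(nxt))
      } else {
        w_start <- max(0, h$start - gap_window[2])
        w_end <- h$start
        prv <- pairs$span_end[pairs$span_end <= h$start]
        if (length(prv) > 0) w_start <- max(w_start, max(prv))
      }
      if (w_end - w_start < 3 * min_orf_codons) next
      orfs <- orf_labeler(find_orfs(subseq0(seq, w_start, w_end),
                                    min_orf_codons))
      lab <- orfs[orfs$label %in% c("RAG1L", "RAG2L"), , drop = FALSE]
      if (nrow(lab) == 0) next
      span <- if (h$strand == "+") {
        c(h$start, w_start + max(lab$end))
      } else {
        c(w_start + min(lab$start), h$end)
      }
      calls[[length(calls) + 1]] <- data.frame(
        contig = cn, start = span[1], end = span[2],
        architecture = "fragmented", symmetry = NA_character_,
        spacer5 = if (h$strand == "+") h$spacer_len else NA_integer_,
        spacer3 = if (h$strand == "-") h$spacer_len else NA_integer_,
        tsd = NA_character_, tsd_len = NA_integer_,
        total_score = h$total_score, n_orfs = nrow(orfs),
        notes = "single_tir", stringsAsFactors = FALSE)
      orf_tables[[length(orf_tables) + 1]] <- orfs
      frag_spans <- rbind(frag_spans, span)
    }
  }
  calls <- if (length(calls) == 0) {
    data.frame(contig = character(), start = integer(), end = integer(),
               architecture = character(), symmetry = character(),
               spacer5 = integer(), spacer3 = integer(),
               tsd = character(), tsd_len = integer(),
               total_score = numeric(), n_orfs = integer(),
               notes = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, calls)
  }
  ord <- order(calls$contig, calls$start)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(calls = calls, orfs = orf_tables[ord],
                 threshold = threshold, model_id = model$id),
            class = "ragl_annotation")
}

#' @export
print.ragl_annotation <- function(x, ...) {
  cat("RAGL/Transib annotation (model ", x$model_id, ", threshold ",
      sprintf("%.2f", x$threshold), " bits)\n", sep = "")
  cat(nrow(x$calls), "call(s)\n")
  if (nrow(x$calls) > 0) {
    print(x$calls[, c("contig", "start", "end", "architecture", "symmetry",
                      "tsd_len", "total_score")])
  }
  invisible(x)
}

#' Render an annotation as GFF3
#'
#' Emits one `mobile_genetic_element` per call with
#' `terminal_inverted_repeat`, `target_site_duplication` and `ORF`
#' children. Coordinates are converted to GFF3's 1-based closed convention.
#'
#' @param annotation A `ragl_annotation`.
#' @return Character vector of GFF3 lines.
#' @export
as_gff3 <- function(annotation) {
  calls <- annotation$calls
  lines <- "##gff-version 3"
  fmt <- function(seqid, type, s0, e0, score, strand, attrs) {
    sprintf("%s\traglscan\t%s\t%d\t%d\t%s\t%s\t.\t%s", seqid, type,
            s0 + 1L, e0, score, strand, attrs)
  }
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    id <- sprintf("element_%03d", i)
    lines <- c(lines, fmt(cl$contig, "mobile_genetic_element", cl$start,
                          cl$end, sprintf("%.3f", cl$total_score), "+",
                          sprintf("ID=%s;architecture=%s;symmetry=%s", id,
                                  cl$architecture,
                                  ifelse(is.na(cl$symmetry), "NA",
                                         cl$symmetry))))
    if (!is.na(cl$tsd)) {
      lines <- c(lines,
                 fmt(cl$contig, "target_site_duplication",
                     cl$start - cl$tsd_len, cl$start, ".", "+",
                     sprintf("Parent=%s;seq=%s", id, cl$tsd)),
                 fmt(cl$contig, "target_site_duplication", cl$end,
                     cl$end + cl$tsd_len, ".", "+",
                     sprintf("Parent=%s;seq=%s", id, cl$tsd)))
    }
    orfs <- annotation$orfs[[i]]
    for (j in seq_len(nrow(orfs))) {
      lines <- c(lines, fmt(cl$contig, "ORF", cl$start + orfs$start[j],
                            cl$start + orfs$end[j], ".", orfs$strand[j],
                            sprintf("Parent=%s;label=%s", id,
                                    orfs$label[j])))
    }
  }
  lines
}

#' Write an annotation to GFF3 and a TSV call table
#'
#' @param annotation A `ragl_annotation`.
#' @param prefix Output path prefix (`<prefix>.gff3`, `<prefix>.calls.tsv`).
#' @export
write_annotation <- function(annotation, prefix) {
  writeLines(as_gff3(annotation), paste0(prefix, ".gff3"))
  write_tsv(annotation$calls, paste0(prefix, ".calls.tsv"))
  invisible(prefix)
}
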