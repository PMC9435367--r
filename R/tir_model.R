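# Bipartite TIR motif model: two conserved elements (position frequency
# matrices) separated by a short variable spacer drawn from a small set of
# allowed lengths. The same representation covers RAGL/Transib TIRs
# (13-bp + 4/13-bp spacer + 10-bp) and the mouse RSS (heptamer + 12/23-bp
# spacer + nonamer). Scores are log-odds in bits throughout.

#' Build a position frequency matrix from aligned sequences
#'
#' Column `j` frequency of base `b` is `(count + pseudocount) /
#' (n + 4 * pseudocount)`. An `N` contributes 1/4 of a count to each base.
#'
#' @param seqs Character vector of equal-length sequences over `A,C,G,T,N`.
#' @param pseudocount Nonnegative pseudocount added per base per column.
#' @return 4 x L matrix with rows `A,C,G,T`; every column sums to 1.
#' @export
build_pfm <- function(seqs, pseudocount = 0.1) {
  stopifnot(length(seqs) >= 1, pseudocount >= 0)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    bad <- which(lens != lens[1])[1]
    stop("ragged input: record ", bad, " has length ", lens[bad],
         ", expected ", lens[1])
  }
  chars <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  bad <- !(chars %in% c(DNA_BASES, "N"))
  if (any(bad)) stop("unexpected character(s): ",
                     paste(unique(chars[bad]), collapse = ", "))
  n <- length(seqs)
  counts <- sapply(seq_len(ncol(chars)), function(j) {
    col <- chars[, j]
    nN <- sum(col == "N")
    vapply(DNA_BASES, function(b) sum(col == b) + nN / 4, 0)
  })
  counts <- matrix(counts, nrow = 4,
                   dimnames = list(DNA_BASES, NULL))
  pfm <- (counts + pseudocount) / (n + 4 * pseudocount)
  pfm
}

#' Per-position information content of a PFM (bits)
#'
#' Relative entropy against the background, the sequence-logo convention:
#' `IC_j = sum_b p_jb * log2(p_jb / q_b)` with `0 * log 0 := 0`. Under a
#' uniform background each position lies in `[0, 2]` bits.
#'
#' @param pfm 4 x L position frequency matrix.
#' @param background Length-4 base frequency vector, strictly positive.
#' @return Numeric vector of length L.
#' @export
information_content <- function(pfm, background = rep(0.25, 4)) {
  check_background(background)
  apply(pfm, 2, function(p) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / background[nz]))
  })
}

check_background <- function(background) {
  stopifnot(length(background) == 4)
  if (any(background <= 0)) stop("background must be strictly positive")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  invisible(background)
}

#' Log-odds scoring matrix of a PFM (bits)
#'
#' `S_jb = log2(p_jb / q_b)`. With zero pseudocount a zero frequency yields
#' `-Inf`, which is allowed and propagates through window scores.
#'
#' @inheritParams information_content
#' @return 4 x L matrix of log-odds scores.
#' @export
log_odds <- function(pfm, background = rep(0.25, 4)) {
  check_background(background)
  log2(pfm / background)
}

# 5 x L scoring matrix: rows 1..4 are ACGT log-odds, row 5 is the expected
# score under the background (used for N-containing windows).
score_matrix5 <- function(pfm, background) {
  s <- log_odds(pfm, background)
  expected <- colSums(background * s)
  rbind(s, expected)
}

# Score of the PFM at every start position of a coded sequence.
pwm_score_vector <- function(codes, smat5) {
  L <- ncol(smat5)
  n <- length(codes)
  if (n < L) return(numeric(0))
  m <- n - L + 1
  s <- numeric(m)
  for (j in seq_len(L)) {
    s <- s + smat5[cbind(codes[j:(m + j - 1)], j)]
  }
  s
}

pwm_score_seq <- function(seq, smat5) {
  v <- pwm_score_vector(dna_codes(seq), smat5)
  if (length(v) == 0) NA_real_ else v[1]
}

consensus_string <- function(pfm) {
  # ties broken alphabetically (A<C<G<T), the rownames order
  paste(rownames(pfm)[apply(pfm, 2, which.max)], collapse = "")
}

#' Construct a bipartite TIR motif model
#'
#' @param pfm1,pfm2 PFMs of the upstream and downstream conserved element.
#' @param allowed_spacers Non-empty integer set of permitted spacer lengths
#'   (bp) between the two elements.
#' @param background Base frequency vector (sums to 1, strictly positive).
#' @param pseudocount Pseudocount recorded for provenance.
#' @param sample_probs1,sample_probs2 Optional pre-pseudocount frequency
#'   matrices used by [sample_tir()]; default to the PFMs.
#' @param id Model identifier.
#' @return An object of class `bipartite_model`.
#' @export
bipartite_model <- function(pfm1, pfm2, allowed_spacers,
                            background = rep(0.25, 4), pseudocount = 0.1,
                            sample_probs1 = NULL, sample_probs2 = NULL,
                            id = "bipartite_model") {
  stopifnot(nrow(pfm1) == 4, nrow(pfm2) == 4)
  if (length(allowed_spacers) == 0) stop("allowed_spacers must be non-empty")
  check_background(background)
  if (any(abs(colSums(pfm1) - 1) > 1e-6) || any(abs(colSums(pfm2) - 1) > 1e-6)) {
    stop("PFM columns must sum to 1")
  }
  m <- structure(list(
    id = id,
    pfm1 = pfm1, pfm2 = pfm2,
    L1 = ncol(pfm1), L2 = ncol(pfm2),
    allowed_spacers = sort(unique(as.integer(allowed_spacers))),
    background = background,
    pseudocount = pseudocount,
    sample_probs1 = if (is.null(sample_probs1)) pfm1 else sample_probs1,
    sample_probs2 = if (is.null(sample_probs2)) pfm2 else sample_probs2
  ), class = "bipartite_model")
  m$smat1 <- score_matrix5(pfm1, background)
  m$smat2 <- score_matrix5(pfm2, background)
  m$max_score <- sum(apply(m$smat1[1:4, , drop = FALSE], 2, max)) +
    sum(apply(m$smat2[1:4, , drop = FALSE], 2, max))
  m
}

#' @export
print.bipartite_model <- function(x, ...) {
  cat("Bipartite TIR model:", x$id, "\n")
  cat("  element 1:", x$L1, "bp, consensus", consensus_string(x$pfm1), "\n")
  cat("  element 2:", x$L2, "bp, consensus", consensus_string(x$pfm2), "\n")
  cat("  allowed spacers:", paste(x$allowed_spacers, collapse = ", "),
      "bp; max score", sprintf("%.2f", x$max_score), "bits\n")
  invisible(x)
}

# Expand a degenerate consensus written with [XY] classes into the set of
# sequences obtained by taking each alternative at every degenerate position
# jointly (marginal per-column frequencies are what matters downstream).
expand_degenerate <- function(consensus) {
  parts <- regmatches(consensus,
                      gregexpr("\\[[ACGT/]+\\]|[ACGT]", consensus))[[1]]
  alts <- lapply(parts, function(p) {
    if (startsWith(p, "[")) strsplit(gsub("[\\[\\]/]", "", p, perl = TRUE),
                                     "", fixed = TRUE)[[1]] else p
  })
  k <- max(lengths(alts))
  vapply(seq_len(k), function(i) {
    paste(vapply(alts, function(a) a[((i - 1) %% length(a)) + 1], ""),
          collapse = "")
  }, "")
}

#' The AanRAGL bipartite TIR model
#'
#' Encodes the published TIR consensus of the pelagophyte RAGL element: a
#' 13-bp element `CACACCCAAACCT` and a 10-bp element `CCTCAA[C/T]A[C/T]G`,
#' separated by a 4- or 13-bp spacer. Degenerate positions are split evenly
#' between their alternatives (the per-position proportions of the original
#' logo are graphical only, so the consensus string is the model).
#'
#' @param pseudocount Pseudocount used when turning the consensus into PFMs.
#' @param background Base frequency vector.
#' @return A `bipartite_model`.
#' @export
aan_ragl_model <- function(pseudocount = 0.1, background = rep(0.25, 4)) {
  e1 <- expand_degenerate("CACACCCAAACCT")
  e2 <- expand_degenerate("CCTCAA[C/T]A[C/T]G")
  bipartite_model(
    pfm1 = build_pfm(rep(e1, length.out = 2), pseudocount),
    pfm2 = build_pfm(e2, pseudocount),
    allowed_spacers = c(4L, 13L),
    background = background, pseudocount = pseudocount,
    sample_probs1 = build_pfm(rep(e1, length.out = 2), 0),
    sample_probs2 = build_pfm(e2, 0),
    id = "AanRAGL_TIR"
  )
}

#' Mouse RSS preset (heptamer/nonamer with 12/23-bp spacers)
#'
#' Shipped for convenience; encodes the canonical consensus strings only and
#' has not been validated against curated RSS collections.
#'
#' @inheritParams aan_ragl_model
#' @return A `bipartite_model`.
#' @export
mouse_rss_model <- function(pseudocount = 0.1, background = rep(0.25, 4)) {
  bipartite_model(
    pfm1 = build_pfm(rep("CACAGTG", 2), pseudocount),
    pfm2 = build_pfm(rep("ACAAAAACC", 2), pseudocount),
    allowed_spacers = c(12L, 23L),
    background = background, pseudocount = pseudocount,
    sample_probs1 = build_pfm("CACAGTG", 0),
    sample_probs2 = build_pfm("ACAAAAACC", 0),
    id = "mouse_RSS"
  )
}

#' Scan a contig with a bipartite TIR model
#'
#' Slides both conserved-element PWMs over the contig and, for every allowed
#' spacer length, reports each window (on either strand) whose combined
#' log-odds score `score1 + score2` meets the threshold. Spacer bases are not
#' scored (the model treats them as background). `N` bases score at their
#' background expectation.
#'
#' @param contig A DNA sequence (single character string).
#' @param model A `bipartite_model`.
#' @param threshold Minimum total score in bits (finite).
#' @param spacers Optional spacer-length override (defaults to the model's
#'   allowed set).
#' @param contig_name Name used in the output.
#' @return A data frame of hits: `contig, start, end, strand, spacer_len,
#'   score1, score2, total_score`, 0-based half-open coordinates, sorted by
#'   start then strand. A contig shorter than the minimal window yields zero
#'   rows.
#' @export
scan_bipartite <- function(contig, model, threshold, spacers = NULL,
                           contig_name = "contig") {
  stopifnot(inherits(model, "bipartite_model"), is.finite(threshold))
  if (is.null(spacers)) spacers <- model$allowed_spacers
  spacers <- sort(unique(as.integer(spacers)))
  n <- nchar(contig)
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      spacer_len = integer(), score1 = numeric(),
                      score2 = numeric(), total_score = numeric(),
                      stringsAsFactors = FALSE)
  if (n < model$L1 + min(spacers) + model$L2) return(empty)

  scan_strand <- function(seq, strand) {
    codes <- dna_codes(seq)
    s1 <- pwm_score_vector(codes, model$smat1)
    s2 <- pwm_score_vector(codes, model$smat2)
    out <- list()
    for (sp in spacers) {
      w <- model$L1 + sp + model$L2
      m <- n - w + 1
      if (m < 1) next
      off <- model$L1 + sp
      tot <- s1[seq_len(m)] + s2[seq_len(m) + off]
      idx <- which(tot >= threshold - 1e-12)
      if (length(idx) == 0) next
      start0 <- if (strand == "+") idx - 1L else n - (idx - 1L) - w
      out[[length(out) + 1]] <- data.frame(
        contig = contig_name, start = as.integer(start0),
        end = as.integer(start0 + w), strand = strand,
        spacer_len = sp, score1 = s1[idx], score2 = s2[idx + off],
        total_score = tot[idx], stringsAsFactors = FALSE)
    }
    if (length(out) == 0) empty else do.call(rbind, out)
  }

  hits <- rbind(scan_strand(contig, "+"),
                scan_strand(revcomp(contig), "-"))
  hits <- hits[order(hits$start, hits$strand, hits$spacer_len), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Calibrate a scan threshold to a target per-window false-positive rate
#'
#' Draws `n_samples` random windows from the background distribution, scores
#' them with both element PWMs (spacer unscored, as in scanning) and returns
#' the empirical `1 - target_fpr` quantile of the total score.
#'
#' @param model A `bipartite_model`.
#' @param background Base frequencies of the null (defaults to the model's).
#' @param target_fpr Per-window false positive rate in `(0, 1)`.
#' @param n_samples Number of null windows; a warning is issued below
#'   `10 / target_fpr`.
#' @param seed Integer seed; identical seeds give identical thresholds.
#' @return Threshold in bits.
#' @export
calibrate_threshold <- function(model, background = model$background,
                                target_fpr, n_samples = 1e5, seed = NULL) {
  stopifnot(target_fpr > 0, target_fpr < 1, n_samples >= 1)
  if (n_samples < 10 / target_fpr) {
    warning("n_samples < 10 / target_fpr; the quantile estimate will be noisy")
  }
  check_background(background)
  local_seed(seed, {
    tot <- null_score_samples(model, background, n_samples)
    stats::quantile(tot, 1 - target_fpr, type = 1, names = FALSE)
  })
}

null_score_samples <- function(model, background, n) {
  smats <- cbind(model$smat1[1:4, , drop = FALSE],
                 model$smat2[1:4, , drop = FALSE])
  L <- ncol(smats)
  codes <- matrix(sample.int(4, n * L, replace = TRUE, prob = background),
                  nrow = n)
  tot <- numeric(n)
  for (j in seq_len(L)) tot <- tot + smats[codes[, j], j]
  tot
}

#' Exact null quantile of the bipartite score by convolution
#'
#' Computes the distribution of the total window score under the background
#' by dynamic-programming convolution over the scored columns (scores
#' discretized to `binwidth` bits) and returns the smallest threshold whose
#' null exceedance probability is at most `target_fpr`. Deterministic, so it
#' is the default threshold source for annotation.
#'
#' @inheritParams calibrate_threshold
#' @param binwidth Score discretization in bits.
#' @return Threshold in bits.
#' @export
null_score_quantile <- function(model, target_fpr,
                                background = model$background,
                                binwidth = 0.005) {
  stopifnot(target_fpr > 0, target_fpr < 1)
  smats <- cbind(model$smat1[1:4, , drop = FALSE],
                 model$smat2[1:4, , drop = FALSE])
  bins <- round(smats / binwidth)
  # running distribution over bin offsets; origin tracks the score of the
  # first vector element as columns accrue
  p <- 1
  origin <- 0
  for (j in seq_len(ncol(bins))) {
    cmin <- min(bins[, j]); cmax <- max(bins[, j])
    newlen <- length(p) + (cmax - cmin)
    q <- numeric(newlen)
    for (b in 1:4) {
      sh <- bins[b, j] - cmin
      q[(1 + sh):(length(p) + sh)] <-
        q[(1 + sh):(length(p) + sh)] + background[b] * p
    }
    p <- q
    origin <- origin + cmin
  }
  tail_p <- rev(cumsum(rev(p)))
  ok <- which(tail_p <= target_fpr)
  if (length(ok) == 0) return(Inf)
  (origin + ok[1] - 1) * binwidth
}

#' Classify a TIR pair as symmetric or asymmetric
#'
#' A transposon's two TIRs are asymmetric when their spacer lengths differ
#' (the 4/13 situation of the RAGL elements) and symmetric otherwise.
#'
#' @param spacer5,spacer3 Spacer lengths (bp) of the two TIRs, or two
#'   one-row hit data frames from [scan_bipartite()].
#' @return `"asymmetric"` or `"symmetric"`.
#' @export
tir_symmetry <- function(spacer5, spacer3) {
  s5 <- if (is.data.frame(spacer5)) spacer5$spacer_len else spacer5
  s3 <- if (is.data.frame(spacer3)) spacer3$spacer_len else spacer3
  if (s5 != s3) "asymmetric" else "symmetric"
}

#' Segment aligned TIR sequences into two conserved blocks
#'
#' Given TIR sequences of possibly different total lengths (conserved block,
#' variable spacer, conserved block), finds the block lengths `(a, b)` that
#' maximize the summed per-position information content of the length-`a`
#' prefix alignment plus the length-`b` suffix alignment, each column
#' penalized by `penalty_bits`. The penalty is what makes the objective
#' peak at the true block extents: spacer columns carry only small-sample
#' noise IC, well below the penalty, while genuinely conserved columns carry
#' 1-2 bits.
#'
#' @param seqs Character vector of TIR sequences (>= 2).
#' @param pseudocount Pseudocount for the per-block PFMs.
#' @param background Base frequencies.
#' @param penalty_bits Per-column penalty in bits.
#' @return List with `len1`, `len2`, the two block PFMs and their IC vectors.
#' @export
segment_tir_blocks <- function(seqs, pseudocount = 0.1,
                               background = rep(0.25, 4),
                               penalty_bits = 0.5) {
  stopifnot(length(seqs) >= 2)
  minlen <- min(nchar(seqs))
  prefix <- substr(seqs, 1, minlen)
  suffix <- substr(seqs, nchar(seqs) - minlen + 1, nchar(seqs))
  ic_left <- information_content(build_pfm(prefix, pseudocount), background)
  ic_right <- rev(information_content(build_pfm(suffix, pseudocount),
                                      background))
  f <- cumsum(ic_left - penalty_bits)   # f[a]: prefix block of length a
  g <- cumsum(ic_right - penalty_bits)  # g[b]: suffix block of length b
  best <- c(1L, 1L); best_obj <- -Inf
  for (a in seq_len(minlen - 1)) {
    bmax <- minlen - a
    b <- which.max(g[seq_len(bmax)])
    obj <- f[a] + g[b]
    if (obj > best_obj) {
      best_obj <- obj
      best <- c(a, b)
    }
  }
  a <- best[1]; b <- best[2]
  pfm1 <- build_pfm(substr(seqs, 1, a), pseudocount)
  pfm2 <- build_pfm(substr(seqs, nchar(seqs) - b + 1, nchar(seqs)),
                    pseudocount)
  list(len1 = a, len2 = b, pfm1 = pfm1, pfm2 = pfm2,
       ic1 = information_content(pfm1, background),
       ic2 = information_content(pfm2, background),
       objective = best_obj)
}
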