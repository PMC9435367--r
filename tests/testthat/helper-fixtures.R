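# Shared fixtures and independent oracles. Oracles are deliberately naive
# implementations, separate from the package code paths they check.

AAN <- aan_ragl_model()

# Brute-force bipartite scanner: enumerate every (position, spacer, strand)
# window and score it column by column from the raw PFMs.
brute_scan <- function(contig, model, threshold, spacers = NULL) {
  if (is.null(spacers)) spacers <- model$allowed_spacers
  lo1 <- log2(model$pfm1 / model$background)
  lo2 <- log2(model$pfm2 / model$background)
  score_el <- function(seq, lo) {
    chars <- strsplit(seq, "")[[1]]
    sum(vapply(seq_along(chars), function(j) lo[chars[j], j], 0))
  }
  n <- nchar(contig)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(contig)))
    } else contig
    for (sp in spacers) {
      w <- model$L1 + sp + model$L2
      if (n < w) next
      for (i in 0:(n - w)) {
        e1 <- substr(s, i + 1, i + model$L1)
        e2 <- substr(s, i + model$L1 + sp + 1, i + w)
        sc <- score_el(e1, lo1) + score_el(e2, lo2)
        if (sc >= threshold - 1e-12) {
          start <- if (strand == "+") i else n - i - w
          out[[length(out) + 1]] <- data.frame(
            start = start, end = start + w, strand = strand,
            spacer_len = sp, total_score = sc)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), spacer_len = integer(),
                      total_score = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand, res$spacer_len), , drop = FALSE]
}

# Naive six-frame ORF scanner: walk codons one by one.
orf_oracle <- function(seq, min_len_codons) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "-") rc else seq
    for (frame in 0:2) {
      i <- frame + 1
      open_at <- NA
      while (i + 2 <= n) {
        codon <- substr(s, i, i + 2)
        if (is.na(open_at) && codon == "ATG") open_at <- i
        if (codon %in% c("TAA", "TAG", "TGA")) {
          if (!is.na(open_at)) {
            ncod <- (i + 3 - open_at) / 3
            if (ncod >= min_len_codons) {
              s0 <- open_at - 1
              e0 <- i + 2
              if (strand == "-") {
                tmp <- s0
                s0 <- n - e0
                e0 <- n - tmp
              }
              out[[length(out) + 1]] <- data.frame(
                start = s0, end = e0, strand = strand,
                n_codons = as.integer(ncod))
            }
          }
          open_at <- NA
        }
        i <- i + 3
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), n_codons = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Hamming distance to a degenerate consensus (a position matches when the
# base lies in the allowed set).
hamming_to_consensus <- function(seq, sets) {
  chars <- strsplit(seq, "")[[1]]
  sum(vapply(seq_along(sets), function(j) !(chars[j] %in% sets[[j]]), TRUE))
}

aan_consensus_sets <- function() {
  c(as.list(strsplit("CACACCCAAACCT", "")[[1]]),
    list("C", "C", "T", "C", "A", "A", c("C", "T"), "A", c("C", "T"), "G"))
}

# Unrooted-topology equality via ape's topological distance.
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
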