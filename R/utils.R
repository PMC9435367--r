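# Shared low-level helpers. Coordinates are 0-based half-open everywhere in
# the package API; only the GFF3/BED writers convert to 1-based.

DNA_BASES <- c("A", "C", "G", "T")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic fan-out of per-locus sub-seeds from one run seed.
# Stays below 2^31 - 1 so the result is a valid R integer seed.
subseed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer(((as.numeric(seed) %% 1000003) * 2017 +
                as.numeric(i) * 7919) %% 2147483629 + 1)
}

# 0-based half-open substring.
subseq0 <- function(x, start, end) substr(x, start + 1, end)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a uniform-random DNA sequence
#'
#' Background genomes are i.i.d. with configurable GC fraction (the model
#' organisms' composition is not modelled; a uniform background keeps
#' threshold calibration analytic-friendly).
#'
#' @param n Length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A single character string of length `n`.
#' @export
random_genome <- function(n, gc = 0.5, seed = NULL) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  local_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
  })
}

# Integer codes 1..4 for ACGT, 5 for N/other.
dna_codes <- function(x) {
  codes <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_BASES)
  codes[is.na(codes)] <- 5L
  codes
}

# Substitute each base independently with probability `rate`; substitutions
# always change the base.
mutate_dna <- function(x, rate, seed = NULL) {
  if (rate <= 0) return(x)
  local_seed(seed, {
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    hit <- stats::runif(length(chars)) < rate
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(b) {
        sample(setdiff(DNA_BASES, b), 1)
      }, "")
    }
    paste(chars, collapse = "")
  })
}

mutate_protein <- function(x, rate, seed = NULL) {
  if (rate <= 0) return(x)
  local_seed(seed, {
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    hit <- stats::runif(length(chars)) < rate
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(a) {
        sample(setdiff(AA_ALPHABET, a), 1)
      }, "")
    }
    paste(chars, collapse = "")
  })
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @param type `"dna"` or `"protein"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param type `"dna"` or `"protein"`.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") {
    Biostrings::DNAStringSet(seqs)
  } else {
    Biostrings::AAStringSet(seqs)
  }
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

# Coerce a genome argument (string, named vector, or FASTA path) to a named
# character vector of contigs.
as_contigs <- function(genome, default_name = "contig") {
  if (length(genome) == 1 && !grepl("[^ACGTNacgtn]", genome)) {
    if (is.null(names(genome))) names(genome) <- default_name
    return(genome)
  }
  if (length(genome) == 1 && file.exists(genome)) {
    return(read_fasta(genome, "dna"))
  }
  if (is.null(names(genome))) {
    names(genome) <- paste0(default_name, seq_along(genome))
  }
  genome
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
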