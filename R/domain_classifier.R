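# Domain-diagnostic protein classification. RAG1L transposases and the two
# Transib subgroups differ by a small set of regions: the RAG2-binding
# alpha11-alpha12 region of the zinc-binding domain and the type-1
# C-terminal tail (CTT1) are shared by RAG1Ls and Subgroup I Transibs but
# lost/replaced (CTT2) in Subgroup II; the beta1-beta3 loop of the
# pre-RNase-H domain is a RAG1L gain; the GRP positions of the
# nonamer-binding domain are common to all three clans, as are partial
# alpha1/alpha17 except in Subgroup II.

#' Construct a domain profile
#'
#' A profile is a degenerate amino-acid motif: an ordered list of allowed
#' residue sets, one per position, with a match-fraction threshold. A window
#' scores the fraction of positions whose residue lies in the allowed set;
#' `X` scores at its background expectation (`|set| / 20`).
#'
#' @param profile_id Unique identifier.
#' @param motif Motif string; degenerate positions in brackets, e.g.
#'   `"GR[PA]LV"`.
#' @param min_score Match-fraction threshold in `[0, 1]`.
#' @return An object of class `domain_profile`.
#' @export
domain_profile <- function(profile_id, motif, min_score = 0.75) {
  stopifnot(is.finite(min_score))
  parts <- regmatches(motif, gregexpr("\\[[A-Z]+\\]|[A-Z]", motif))[[1]]
  sets <- lapply(parts, function(p) {
    strsplit(gsub("[\\[\\]]", "", p, perl = TRUE), "", fixed = TRUE)[[1]]
  })
  structure(list(profile_id = profile_id, sets = sets,
                 length = length(sets), min_score = min_score,
                 motif = motif),
            class = "domain_profile")
}

profile_consensus <- function(profile) {
  paste(vapply(profile$sets, `[`, "", 1), collapse = "")
}

#' Default (synthetic) domain profile library
#'
#' The seven diagnostic/corroborating profiles: `NBD_GRP`, `ALPHA1`,
#' `PRERNH_LOOP`, `A11_A12`, `ALPHA17`, `CTT1`, `CTT2`. The published
#' evidence for these regions is a full protein alignment that is not
#' machine-readable, so the motifs shipped here are synthetic placeholders
#' that exercise the classifier end to end; real use requires profiles
#' built from the user's own alignments (see [read_profiles()]).
#'
#' @param min_score Shared match-fraction threshold.
#' @return Named list of `domain_profile` objects.
#' @export
default_profile_library <- function(min_score = 0.75) {
  defs <- c(
    NBD_GRP     = "SWKT[VI]HGRP[DE]LKQW[ML]R",
    ALPHA1      = "DQ[EK]LFWRAVNTME",
    PRERNH_LOOP = "YH[TS]GPWNDKRFECL",
    A11_A12     = "EL[RK]HWAQDMK[LI]SPEKIT",
    ALPHA17     = "NV[FY]RDTQCLHWSE",
    CTT1        = "WP[KR]DFEYHLNQGT[VA]SM",
    CTT2        = "KC[QN]GYVMTRWA[DE]PHLF"
  )
  lib <- lapply(names(defs), function(id) {
    domain_profile(id, defs[[id]], min_score)
  })
  names(lib) <- names(defs)
  lib
}

#' Read a profile library from a structured text file
#'
#' Tab-separated, three columns: `profile_id`, `motif` (bracket notation),
#' `min_score`. Lines starting with `#` are skipped.
#'
#' @param path Input file.
#' @return Named list of `domain_profile` objects.
#' @export
read_profiles <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (any(duplicated(df$profile_id))) stop("duplicate profile ids")
  lib <- lapply(seq_len(nrow(df)), function(i) {
    domain_profile(df$profile_id[i], df$motif[i], df$min_score[i])
  })
  names(lib) <- df$profile_id
  lib
}

#' Write a profile library
#'
#' @param library Named list of `domain_profile` objects.
#' @param path Output file.
#' @export
write_profiles <- function(library, path) {
  df <- data.frame(
    profile_id = vapply(library, `[[`, "", "profile_id"),
    motif = vapply(library, `[[`, "", "motif"),
    min_score = vapply(library, `[[`, 0, "min_score"),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Match a domain profile against a protein
#'
#' Slides the profile over the sequence and reports the highest-scoring
#' window. Present iff the best score reaches the profile's `min_score`.
#' Raising `min_score` can therefore never flip an absent call to present.
#'
#' @param protein Amino-acid sequence (20-letter alphabet plus `X`).
#' @param profile A `domain_profile`.
#' @return `list(present =, position = 0-based best offset, score =)`.
#' @export
match_domain <- function(protein, profile) {
  if (nchar(protein) == 0) stop("empty sequence")
  chars <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  L <- profile$length
  nw <- length(chars) - L + 1
  if (nw < 1) {
    return(list(present = FALSE, position = NA_integer_, score = 0))
  }
  score <- numeric(nw)
  for (j in seq_len(L)) {
    set <- profile$sets[[j]]
    v <- chars[j:(nw + j - 1)]
    sc <- as.numeric(v %in% set)
    sc[v == "X"] <- length(set) / 20
    score <- score + sc
  }
  score <- score / L
  best <- which.max(score)
  list(present = score[best] >= profile$min_score,
       position = as.integer(best - 1L), score = score[best])
}

#' Classify a transposase protein into RAG1L / Transib subgroup I / II
#'
#' Decision table over the diagnostic regions: alpha11-alpha12 present with
#' CTT1 and the PreRNH beta1-beta3 loop is `RAG1L`; alpha11-alpha12 with
#' CTT1 but no loop is `Transib_I`; no alpha11-alpha12 but CTT2 is
#' `Transib_II`; anything else is `unclassified`. `NBD_GRP`, `ALPHA1` and
#' `ALPHA17` are recorded as corroborating flags only. CTT typing matches
#' CTT1 and CTT2 independently; if both exceed threshold the higher score
#' wins, a tie gives `none` with a note. An optional genomic-context flag
#' (a linked RAG2L gene) can override a `Transib_I` verdict to `RAG1L`.
#'
#' @param protein Amino-acid sequence.
#' @param library Profile library containing all seven profiles.
#' @param rag2l_linked Genomic-context override flag.
#' @return `list(flags =, positions =, scores =, ctt_type =, clan =,
#'   notes =)`.
#' @export
classify_protein <- function(protein, library = default_profile_library(),
                             rag2l_linked = FALSE) {
  required <- c("NBD_GRP", "ALPHA1", "PRERNH_LOOP", "A11_A12", "ALPHA17",
                "CTT1", "CTT2")
  missing <- setdiff(required, names(library))
  if (length(missing) > 0) {
    stop("library is missing profile(s): ", paste(missing, collapse = ", "))
  }
  m <- lapply(library[required], function(p) match_domain(protein, p))
  flags <- vapply(m, `[[`, TRUE, "present")
  positions <- vapply(m, `[[`, 0L, "position")
  scores <- vapply(m, `[[`, 0, "score")
  notes <- character(0)
  ctt_type <- if (flags[["CTT1"]] && flags[["CTT2"]]) {
    if (scores[["CTT1"]] > scores[["CTT2"]]) "CTT1"
    else if (scores[["CTT2"]] > scores[["CTT1"]]) "CTT2"
    else {
      notes <- c(notes, "ctt_tie")
      "none"
    }
  } else if (flags[["CTT1"]]) "CTT1"
  else if (flags[["CTT2"]]) "CTT2"
  else "none"
  clan <- clan_from_flags(flags[["A11_A12"]], ctt_type,
                          flags[["PRERNH_LOOP"]])
  if (clan == "unclassified" && flags[["A11_A12"]] && ctt_type == "CTT2") {
    notes <- c(notes, "contradictory_evidence")
  }
  if (clan == "Transib_I" && rag2l_linked) {
    clan <- "RAG1L"
    notes <- c(notes, "rag2l_context_override")
  }
  list(flags = flags, positions = positions, scores = scores,
       ctt_type = ctt_type, clan = clan, notes = notes)
}

# The decision table proper: total over every flag/CTT combination.
clan_from_flags <- function(a11, ctt_type, prernh_loop) {
  if (a11 && ctt_type == "CTT1" && prernh_loop) return("RAG1L")
  if (a11 && ctt_type == "CTT1" && !prernh_loop) return("Transib_I")
  if (!a11 && ctt_type == "CTT2") return("Transib_II")
  "unclassified"
}

#' Classify a batch of proteins
#'
#' @param proteins Named character vector of sequences or a FASTA path.
#' @param library Profile library.
#' @return Data frame with one row per record (id, per-profile flags,
#'   `ctt_type`, `clan`, `notes`) plus a `summary` attribute of clan counts.
#' @export
classify_batch <- function(proteins, library = default_profile_library()) {
  if (length(proteins) == 1 && file.exists(proteins) &&
      !grepl("^[A-Z]+$", proteins)) {
    proteins <- read_fasta(proteins, "protein")
  }
  if (length(proteins) == 0) {
    out <- data.frame(id = character(), clan = character(),
                      ctt_type = character(), stringsAsFactors = FALSE)
    attr(out, "summary") <- table(factor(character(),
                                         levels = clan_levels()))
    return(out)
  }
  if (is.null(names(proteins))) {
    names(proteins) <- paste0("seq", seq_along(proteins))
  }
  dup <- names(proteins)[duplicated(names(proteins))]
  if (length(dup) > 0) {
    stop("duplicate ids: ", paste(unique(dup), collapse = ", "))
  }
  rows <- lapply(names(proteins), function(id) {
    r <- classify_protein(proteins[[id]], library)
    cbind(data.frame(id = id, stringsAsFactors = FALSE),
          as.data.frame(as.list(r$flags)),
          data.frame(ctt_type = r$ctt_type, clan = r$clan,
                     notes = paste(r$notes, collapse = ";"),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- table(factor(out$clan, levels = clan_levels()))
  out
}

clan_levels <- function() c("RAG1L", "Transib_I", "Transib_II",
                            "unclassified")
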