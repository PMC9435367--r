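# Pairwise/grouped protein identities and a neighbor-joining clan-partition
# check. Published full-scale phylogenies of these proteins are
# maximum-likelihood trees; here NJ serves as the in-package sanity check
# that two labelled protein clans fall on opposite sides of a single tree
# edge.

#' Global percent identity between two proteins
#'
#' Needleman-Wunsch global alignment with affine gaps (BLOSUM62 by
#' default); identity is identical columns over alignment columns times
#' 100. By default the denominator includes gap columns; set
#' `count_gap_columns = FALSE` to restrict it to aligned (ungapped)
#' columns.
#'
#' @param a,b Amino-acid sequences (non-empty).
#' @param substitution_matrix Matrix name or matrix for
#'   `Biostrings::pairwiseAlignment()`.
#' @param gap_open,gap_extend Affine gap costs (positive numbers).
#' @param count_gap_columns Include gap columns in the denominator.
#' @return Percent identity in `[0, 100]`.
#' @export
global_identity <- function(a, b, substitution_matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.5,
                            count_gap_columns = TRUE) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(a), subject = Biostrings::AAString(b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ident <- sum(pa == sa & pa != "-")
  denom <- if (count_gap_columns) length(pa) else sum(pa != "-" & sa != "-")
  100 * ident / denom
}

#' Within- and between-group average identities
#'
#' Within averages are over unordered distinct pairs inside a group (a
#' single-sequence group has no within average and is reported `NA`);
#' between averages are over all cross pairs; `combined` is the mean over
#' every cross-group pair, the statistic used to compare two clans as a
#' whole.
#'
#' @param seqs Named character vector of protein sequences.
#' @param groups Character vector of group labels, parallel to `seqs`.
#' @param ... Passed to [global_identity()].
#' @return Object of class `group_identity_summary`: `within` (named
#'   vector), `between` (symmetric matrix), `combined`, `n_pairs` tables
#'   and the full pairwise identity matrix.
#' @export
group_identity_matrix <- function(seqs, groups, ...) {
  stopifnot(length(seqs) == length(groups))
  gl <- unique(groups)
  if (length(gl) < 2) stop("need >= 2 groups")
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  idm <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      idm[i, j] <- idm[j, i] <- global_identity(seqs[[i]], seqs[[j]], ...)
    }
  }
  within <- vapply(gl, function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2) return(NA_real_)
    sub <- idm[idx, idx]
    mean(sub[upper.tri(sub)])
  }, 0)
  between <- matrix(NA_real_, length(gl), length(gl),
                    dimnames = list(gl, gl))
  cross_vals <- c()
  for (i in seq_along(gl)) {
    for (j in seq_along(gl)) {
      if (i < j) {
        v <- idm[groups == gl[i], groups == gl[j], drop = FALSE]
        between[i, j] <- between[j, i] <- mean(v)
        cross_vals <- c(cross_vals, as.numeric(v))
      }
    }
  }
  structure(list(groups = gl, within = within, between = between,
                 combined = mean(cross_vals),
                 identity_matrix = idm,
                 group_of = stats::setNames(groups, names(seqs))),
            class = "group_identity_summary")
}

#' @export
print.group_identity_summary <- function(x, ...) {
  cat("Group identity summary\n  within-group averages (%):\n")
  for (g in x$groups) cat(sprintf("    %-12s %6.2f\n", g, x$within[[g]]))
  cat(sprintf("  combined cross-group average: %.2f%%\n", x$combined))
  invisible(x)
}

#' Convert percent identities to evolutionary distances
#'
#' p-distance `d = 1 - identity/100` by default, or the Poisson correction
#' `-ln(identity/100)`; the latter rejects identity 0 (infinite distance).
#'
#' @param identities Numeric matrix (or `group_identity_summary`) of
#'   percent identities in `[0, 100]`.
#' @param method `"p"` or `"poisson"`.
#' @return Object of class `dist_matrix`: symmetric matrix, zero diagonal.
#' @export
identity_to_distance <- function(identities, method = c("p", "poisson")) {
  method <- match.arg(method)
  if (inherits(identities, "group_identity_summary")) {
    identities <- identities$identity_matrix
  }
  if (any(identities < 0 | identities > 100)) {
    stop("identities must lie in [0, 100]")
  }
  d <- if (method == "p") {
    1 - identities / 100
  } else {
    if (any(identities == 0)) {
      stop("identity 0 gives infinite Poisson distance")
    }
    -log(identities / 100)
  }
  diag(d) <- 0
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via `ape::nj()`); the input must
#' be a symmetric nonnegative matrix with zero diagonal and taxon names.
#'
#' @param d Distance matrix with dimnames.
#' @return An unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(d) {
  d <- unclass(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  if (nrow(d) < 3) stop("need >= 3 taxa")
  if (is.null(rownames(d))) stop("distance matrix must have taxon names")
  ape::nj(stats::as.dist(d))
}

#' Write / read Newick
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

# Tip sets below every internal edge of an unrooted phylo object.
edge_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  # edges in postorder so children are resolved before parents
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1]; ch <- eo[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(k) {
    sort(desc[[tree$edge[k, 2]]])
  })
}

#' Check whether a tree separates two clans across one edge
#'
#' TRUE iff some edge of the (unrooted) tree bipartitions the taxa exactly
#' into the two clan label sets — the monophyly criterion for "the two
#' groups form two separate clans".
#'
#' @param tree A `phylo` object.
#' @param labels Named character vector mapping every tip label to one of
#'   exactly two clan labels.
#' @return `list(separated = logical, edge = splitting edge index or NA,
#'   clans =)`.
#' @export
clan_partition_check <- function(tree, labels) {
  tips <- tree$tip.label
  if (!all(tips %in% names(labels))) stop("every taxon must be labelled")
  lab <- labels[tips]
  clans <- unique(lab)
  if (length(clans) != 2) stop("exactly two clans required")
  target <- sort(unname(which(lab == clans[1])))
  sets <- edge_tip_sets(tree)
  all_tips <- seq_along(tips)
  for (k in seq_along(sets)) {
    below <- intersect(sets[[k]], all_tips)
    if (identical(below, target) ||
        identical(sort(setdiff(all_tips, below)), target)) {
      return(list(separated = TRUE, edge = k, clans = clans))
    }
  }
  list(separated = FALSE, edge = NA_integer_, clans = clans)
}

#' Simulate a protein family from a common ancestor
#'
#' Each member substitutes every site of the ancestor independently with
#' probability `divergence` (substitutions always change the residue). Used
#' to emulate two clans whose within-clan identity exceeds the between-clan
#' identity.
#'
#' @param n Number of members.
#' @param length Protein length (ignored when `ancestor` is given).
#' @param divergence Per-site substitution probability.
#' @param ancestor Optional ancestor sequence.
#' @param seed Optional integer seed.
#' @param prefix Name prefix for the members.
#' @return Named character vector of `n` sequences; the ancestor is kept as
#'   the `"ancestor"` attribute.
#' @export
sim_protein_family <- function(n, length = 300L, divergence = 0.1,
                               ancestor = NULL, seed = NULL,
                               prefix = "seq") {
  local_seed(seed, {
    if (is.null(ancestor)) {
      ancestor <- paste(sample(AA_ALPHABET, length, replace = TRUE),
                        collapse = "")
    }
    out <- vapply(seq_len(n), function(i) {
      mutate_protein(ancestor, divergence)
    }, "")
    names(out) <- paste0(prefix, seq_len(n))
    attr(out, "ancestor") <- ancestor
    out
  })
}

#' Write a group identity summary as TSV
#'
#' @param summary A `group_identity_summary`.
#' @param prefix Output prefix (`<prefix>.within.tsv`,
#'   `<prefix>.between.tsv`, `<prefix>.identities.tsv`).
#' @export
write_identity_summary <- function(summary, prefix) {
  write_tsv(data.frame(group = summary$groups,
                       within_avg_identity = summary$within[summary$groups],
                       stringsAsFactors = FALSE),
            paste0(prefix, ".within.tsv"))
  bt <- as.data.frame(summary$between)
  bt <- cbind(group = rownames(summary$between), bt)
  write_tsv(bt, paste0(prefix, ".between.tsv"))
  idm <- as.data.frame(summary$identity_matrix)
  idm <- cbind(id = rownames(summary$identity_matrix), idm)
  write_tsv(idm, paste0(prefix, ".identities.tsv"))
  invisible(prefix)
}
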