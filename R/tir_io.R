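# Matrix and model serialization: JASPAR-style tab-separated PFMs, a minimal
# MEME-format writer, per-position IC tables and a plain-text logo.

#' Write a PFM as a JASPAR-style tab-separated matrix
#'
#' One header line `>id` followed by four rows `A|C|G|T<TAB>f1<TAB>f2...`.
#'
#' @param pfm 4 x L matrix.
#' @param path Output file.
#' @param id Matrix identifier.
#' @export
write_pfm <- function(pfm, path, id = "pfm") {
  lines <- c(paste0(">", id),
             vapply(DNA_BASES, function(b) {
               paste(c(b, format(pfm[b, ], digits = 6)), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PFM written by [write_pfm()]
#'
#' @param path Input file.
#' @return 4 x L matrix with columns renormalized to sum to 1.
#' @export
read_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, ">")]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bases <- vapply(rows, `[[`, "", 1)
  vals <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  rownames(vals) <- bases
  vals <- vals[DNA_BASES, , drop = FALSE]
  sweep(vals, 2, colSums(vals), "/")
}

#' Write motifs in minimal MEME format
#'
#' @param pfms Named list of 4 x L PFMs.
#' @param path Output file.
#' @param background Base frequencies recorded in the header.
#' @export
write_meme <- function(pfms, path, background = rep(0.25, 4)) {
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "Background letter frequencies",
           paste(sprintf("%s %.5f", DNA_BASES, background), collapse = " "),
           "")
  for (nm in names(pfms)) {
    pfm <- pfms[[nm]]
    out <- c(out,
             paste("MOTIF", nm),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     ncol(pfm)),
             apply(pfm, 2, function(col) paste(sprintf("%.6f", col),
                                               collapse = " ")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Per-position information content table
#'
#' @param pfm 4 x L matrix.
#' @param background Base frequencies.
#' @return Data frame with `position` (1-based column index), per-base
#'   frequencies, `consensus` and `ic_bits`.
#' @export
ic_table <- function(pfm, background = rep(0.25, 4)) {
  data.frame(position = seq_len(ncol(pfm)),
             A = pfm["A", ], C = pfm["C", ], G = pfm["G", ], T = pfm["T", ],
             consensus = rownames(pfm)[apply(pfm, 2, which.max)],
             ic_bits = information_content(pfm, background),
             stringsAsFactors = FALSE)
}

#' Plain-text sequence logo
#'
#' One line per position: consensus base and a bar proportional to its
#' information content (full scale 2 bits).
#'
#' @inheritParams ic_table
#' @return Character vector of lines.
#' @export
ascii_logo <- function(pfm, background = rep(0.25, 4)) {
  tab <- ic_table(pfm, background)
  vapply(seq_len(nrow(tab)), function(i) {
    sprintf("%2d %s %5.2f %s", tab$position[i], tab$consensus[i],
            tab$ic_bits[i],
            strrep("#", round(tab$ic_bits[i] / 2 * 20)))
  }, "")
}

#' Write a bipartite model to a directory
#'
#' Emits `element1.pfm`, `element2.pfm` and `model.yaml` (spacers,
#' background, pseudocount, id).
#'
#' @param model A `bipartite_model`.
#' @param dir Output directory (created if needed).
#' @export
write_bipartite_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pfm(model$pfm1, file.path(dir, "element1.pfm"),
            paste0(model$id, "_e1"))
  write_pfm(model$pfm2, file.path(dir, "element2.pfm"),
            paste0(model$id, "_e2"))
  yaml::write_yaml(list(id = model$id,
                        allowed_spacers = model$allowed_spacers,
                        background = model$background,
                        pseudocount = model$pseudocount),
                   file.path(dir, "model.yaml"))
  invisible(dir)
}

#' Read a bipartite model written by [write_bipartite_model()]
#'
#' @param dir Model directory.
#' @return A `bipartite_model`.
#' @export
read_bipartite_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  bipartite_model(read_pfm(file.path(dir, "element1.pfm")),
                  read_pfm(file.path(dir, "element2.pfm")),
                  allowed_spacers = meta$allowed_spacers,
                  background = as.numeric(meta$background),
                  pseudocount = meta$pseudocount,
                  id = meta$id)
}
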