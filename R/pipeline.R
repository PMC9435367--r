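# End-to-end simulation study: generate a strain pair with planted
# elements, annotate the sample genome and score recovery against truth,
# classify synthetic proteins, call insertion polymorphisms from flank
# reads, and summarize two-clan identity statistics with an NJ
# clan-partition verdict. Fully deterministic for a fixed seed; every
# metric is traceable to a truth table.

#' Default study configuration
#'
#' @param seed Run seed; all stage sub-seeds derive from it.
#' @return Nested configuration list (see [validate_config()] for the
#'   schema).
#' @export
default_run_config <- function(seed = 42L) {
  list(
    seed = as.integer(seed),
    genome = list(length = 200000L, gc = 0.5),
    elements = list(
      n_shared = 3L, n_sample_only = 3L,
      element_kind = "RAGL_tandem",
      spacer_assignment = c(4L, 13L),
      tsd_len = 5L,
      mutation_rate = 0.0
    ),
    scan = list(target_fpr = 1e-6, k_range = c(2L, 10L),
                gap_window = c(500L, 30000L), min_orf_codons = 100L),
    flanks = list(read_len = 300L, stub_len = 30L, substitution_rate = 0),
    proteins = list(per_class = 5L, scaffold_length = 900L,
                    mutation_rate = 0),
    stats = list(n_per_clan = 5L, seq_length = 250L,
                 within_divergence = 0.1, between_divergence = 0.6),
    outdir = NULL
  )
}

config_schema <- function() {
  list(seed = NA, genome = c("length", "gc"),
       elements = c("n_shared", "n_sample_only", "element_kind",
                    "spacer_assignment", "tsd_len", "mutation_rate"),
       scan = c("target_fpr", "k_range", "gap_window", "min_orf_codons"),
       flanks = c("read_len", "stub_len", "substitution_rate"),
       proteins = c("per_class", "scaffold_length", "mutation_rate"),
       stats = c("n_per_clan", "seq_length", "within_divergence",
                 "between_divergence"),
       outdir = NA)
}

#' Validate a study configuration
#'
#' Accepts a YAML path or a configuration list; missing fields are filled
#' from the defaults, unknown keys are rejected, and every violation is
#' collected (not just the first).
#'
#' @param config YAML file path or list.
#' @return The completed configuration (class `run_config`), or an error
#'   whose message lists all violations.
#' @export
validate_config <- function(config = default_run_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("cannot read config file: ", config)
    config <- yaml::read_yaml(config)
  }
  schema <- config_schema()
  defaults <- default_run_config()
  errs <- character(0)
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown) > 0) {
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  for (sec in names(schema)) {
    if (is.null(config[[sec]])) {
      config[[sec]] <- defaults[[sec]]
    } else if (!anyNA(schema[[sec]])) {
      bad <- setdiff(names(config[[sec]]), schema[[sec]])
      if (length(bad) > 0) {
        errs <- c(errs, paste0("unknown key(s) in ", sec, ": ",
                               paste(bad, collapse = ", ")))
      }
      for (k in setdiff(schema[[sec]], names(config[[sec]]))) {
        config[[sec]][[k]] <- defaults[[sec]][[k]]
      }
    }
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single number")
  chk(config$genome$length >= 10000, "genome length must be >= 10000")
  chk(config$genome$gc >= 0 && config$genome$gc <= 1,
      "genome gc must lie in [0, 1]")
  chk(config$elements$n_shared >= 0, "n_shared must be >= 0")
  chk(config$elements$n_sample_only >= 0, "n_sample_only must be >= 0")
  chk(config$elements$tsd_len >= 0, "tsd_len must be >= 0")
  chk(config$elements$mutation_rate >= 0 && config$elements$mutation_rate <= 1,
      "element mutation_rate must lie in [0, 1]")
  chk(config$elements$element_kind %in%
        c("RAGL_tandem", "RAGL_convergent", "Transib_single"),
      "element_kind must be RAGL_tandem, RAGL_convergent or Transib_single")
  chk(config$scan$target_fpr > 0 && config$scan$target_fpr < 1,
      "target_fpr must lie in (0, 1)")
  chk(length(config$scan$k_range) == 2 &&
        config$scan$k_range[1] >= 1 &&
        config$scan$k_range[1] <= config$scan$k_range[2],
      "k_range must satisfy 1 <= k_min <= k_max")
  chk(length(config$scan$gap_window) == 2 &&
        config$scan$gap_window[1] <= config$scan$gap_window[2],
      "gap_window must satisfy min_gap <= max_gap")
  chk(config$flanks$read_len > config$flanks$stub_len,
      "read_len must exceed stub_len")
  chk(config$proteins$per_class >= 0, "per_class must be >= 0")
  chk(config$stats$n_per_clan >= 2, "n_per_clan must be >= 2")
  if (length(errs) > 0) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  structure(config, class = "run_config")
}

#' Score annotation calls against a truth table
#'
#' A call matches a truth record when their spans overlap reciprocally by
#' at least `min_reciprocal`. Precision counts matched calls over all
#' calls; recall counts recovered truth records.
#'
#' @param calls Call data frame from [annotate_genome()].
#' @param truth Truth table with `sample_start`/`insertion_start` and
#'   `element_length`.
#' @param min_reciprocal Reciprocal-overlap fraction.
#' @return List with `recall`, `precision`, `n_calls`, `n_truth`,
#'   `matches` (call index per truth row, NA if missed) and
#'   `tsd_correct` (per matched locus, reported TSD equals truth).
#' @export
evaluate_calls <- function(calls, truth, min_reciprocal = 0.9) {
  starts <- if ("sample_start" %in% names(truth)) truth$sample_start
            else truth$insertion_start
  n_truth <- nrow(truth)
  matches <- rep(NA_integer_, n_truth)
  tsd_correct <- rep(NA, n_truth)
  for (i in seq_len(n_truth)) {
    ts <- starts[i]; te <- ts + truth$element_length[i]
    for (j in seq_len(nrow(calls))) {
      ov <- min(te, calls$end[j]) - max(ts, calls$start[j])
      if (ov > 0 && ov >= min_reciprocal * (te - ts) &&
          ov >= min_reciprocal * (calls$end[j] - calls$start[j])) {
        matches[i] <- j
        tsd_correct[i] <- identical(calls$tsd[j], truth$tsd_sequence[i])
        break
      }
    }
  }
  recall <- if (n_truth == 0) NA_real_ else mean(!is.na(matches))
  precision <- if (nrow(calls) == 0) NA_real_ else
    length(unique(stats::na.omit(matches))) / nrow(calls)
  list(recall = recall, precision = precision, n_calls = nrow(calls),
       n_truth = n_truth, matches = matches, tsd_correct = tsd_correct)
}

#' Run the full simulation study
#'
#' Executes generation, annotation, protein classification, polymorphism
#' calling and clan statistics in order; writes intermediate files when
#' `config$outdir` is set; returns a `study_report`. Byte-identical
#' reports for identical configurations.
#'
#' @param config A configuration from [validate_config()] /
#'   [default_run_config()], or a YAML path.
#' @return Object of class `study_report`.
#' @export
run_study <- function(config = default_run_config()) {
  config <- validate_config(config)
  seed <- config$seed
  model <- aan_ragl_model()
  spec <- element_spec(
    element_kind = config$elements$element_kind,
    tir_model = model,
    spacer_assignment = config$elements$spacer_assignment,
    tsd_len = config$elements$tsd_len,
    per_position_mutation_rate = config$elements$mutation_rate,
    min_orf_codons = config$scan$min_orf_codons)

  # stage 1: genomes
  base <- random_genome(config$genome$length, config$genome$gc,
                        subseed(seed, 1))
  n_loci <- config$elements$n_shared + config$elements$n_sample_only
  sim <- simulate_strain_pair(base, config$elements$n_shared,
                              config$elements$n_sample_only, spec,
                              subseed(seed, 2))

  # stage 2: annotation of the sample genome
  threshold <- null_score_quantile(model, config$scan$target_fpr)
  ann <- annotate_genome(c(sample = sim$sample), model,
                         threshold = threshold,
                         k_range = config$scan$k_range,
                         gap_window = config$scan$gap_window,
                         min_orf_codons = config$scan$min_orf_codons)
  recovery <- if (n_loci > 0) {
    evaluate_calls(ann$calls, sim$truth)
  } else {
    list(recall = NA_real_, precision = NA_real_,
         n_calls = nrow(ann$calls), n_truth = 0L,
         matches = integer(0), tsd_correct = logical(0))
  }

  # stage 3: polymorphism calls from flank reads
  poly <- NULL
  poly_accuracy <- NA_real_
  if (n_loci > 0) {
    flanks <- synth_flank_reads(sim$sample, sim$truth,
                                read_len = config$flanks$read_len,
                                tir_stub_len = config$flanks$stub_len,
                                substitution_rate =
                                  config$flanks$substitution_rate,
                                seed = subseed(seed, 3))
    poly <- call_all(flanks, c(reference = sim$reference), model)
    expected <- ifelse(sim$truth$status == "shared",
                       "shared_present_in_ref", "sample_only_empty_ref")
    poly_accuracy <- mean(poly$calls$status == expected)
  }

  # stage 4: protein classification round trip
  confusion <- NULL
  class_accuracy <- NA_real_
  if (config$proteins$per_class > 0) {
    lib <- default_profile_library()
    classes <- c("RAG1L", "Transib_I", "Transib_II")
    prots <- character(0)
    want <- character(0)
    for (ci in seq_along(classes)) {
      for (i in seq_len(config$proteins$per_class)) {
        sp <- synthetic_protein_spec(
          classes[ci], scaffold_length = config$proteins$scaffold_length,
          motif_mutation_rate = config$proteins$mutation_rate)
        prots[sprintf("%s_%02d", classes[ci], i)] <-
          synth_protein(sp, lib, subseed(seed, 100 + 10 * ci + i))
        want <- c(want, classes[ci])
      }
    }
    cls <- classify_batch(prots, lib)
    confusion <- table(truth = factor(want, levels = clan_levels()),
                       called = factor(cls$clan, levels = clan_levels()))
    class_accuracy <- mean(cls$clan == want)
  }

  # stage 5: clan identity statistics and NJ partition
  ancA <- sim_protein_family(1, config$stats$seq_length, 0,
                             seed = subseed(seed, 200))
  ancB <- mutate_protein(attr(ancA, "ancestor"),
                         config$stats$between_divergence,
                         subseed(seed, 201))
  famA <- sim_protein_family(config$stats$n_per_clan,
                             divergence = config$stats$within_divergence,
                             ancestor = attr(ancA, "ancestor"),
                             seed = subseed(seed, 202), prefix = "RAG1L_")
  famB <- sim_protein_family(config$stats$n_per_clan,
                             divergence = config$stats$within_divergence,
                             ancestor = ancB,
                             seed = subseed(seed, 203), prefix = "Transib_")
  seqs <- c(famA, famB)
  groups <- c(rep("RAG1L", length(famA)), rep("Transib", length(famB)))
  idsum <- group_identity_matrix(seqs, groups)
  tree <- nj_tree(identity_to_distance(idsum$identity_matrix))
  partition <- clan_partition_check(tree,
                                    stats::setNames(groups, names(seqs)))

  report <- structure(list(
    config = config,
    provenance = list(seed = seed,
                      config_hash = config_hash(config),
                      version = as.character(utils::packageVersion("raglscan"))),
    threshold_bits = threshold,
    element_recovery = recovery[c("recall", "precision", "n_calls",
                                  "n_truth")],
    tsd_correct = recovery$tsd_correct,
    polymorphism = list(summary = if (is.null(poly)) NULL else poly$summary,
                        accuracy = poly_accuracy),
    classification = list(confusion = confusion,
                          accuracy = class_accuracy),
    identity = list(within = idsum$within, combined = idsum$combined),
    clan_partition = partition$separated,
    annotation = ann,
    calls = if (is.null(poly)) NULL else poly$calls,
    truth = sim$truth,
    tree = tree
  ), class = "study_report")

  if (!is.null(config$outdir)) {
    write_study_outputs(report, sim, config$outdir)
  }
  report
}

config_hash <- function(config) {
  # hash a canonical text rendering (serialization headers carry R version
  # metadata and would break cross-session stability)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$outdir <- NULL  # output location is not a study condition
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

write_study_outputs <- function(report, sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(c(reference = sim$reference, sample = sim$sample),
              file.path(outdir, "genomes.fasta"), "dna")
  write_truth_tsv(sim$truth, file.path(outdir, "truth.tsv"))
  write_annotation(report$annotation, file.path(outdir, "annotation"))
  if (!is.null(report$calls)) {
    write_tsv(report$calls, file.path(outdir, "polymorphism_calls.tsv"))
  }
  write_newick(report$tree, file.path(outdir, "clans.nwk"))
  writeLines(utils::capture.output(print(report)),
             file.path(outdir, "report.txt"))
  invisible(outdir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("raglscan simulation study\n")
  cat(sprintf("  seed %d | config %s | raglscan %s\n",
              x$provenance$seed, x$provenance$config_hash,
              x$provenance$version))
  cat(sprintf("  scan threshold: %.2f bits\n", x$threshold_bits))
  cat(sprintf("  element recovery: recall %.3f, precision %.3f (%d calls / %d truth)\n",
              x$element_recovery$recall, x$element_recovery$precision,
              x$element_recovery$n_calls, x$element_recovery$n_truth))
  cat(sprintf("  polymorphism call accuracy: %.3f\n", x$polymorphism$accuracy))
  if (!is.null(x$polymorphism$summary)) {
    s <- x$polymorphism$summary
    cat("    ", paste(sprintf("%s=%d", names(s), as.integer(s)),
                      collapse = " "), "\n")
  }
  cat(sprintf("  protein classification accuracy: %.3f\n",
              x$classification$accuracy))
  cat(sprintf("  within-clan identities: %s; cross-clan combined: %.2f%%\n",
              paste(sprintf("%s %.2f%%", names(x$identity$within),
                            x$identity$within), collapse = ", "),
              x$identity$combined))
  cat(sprintf("  clan partition on NJ tree: %s\n",
              ifelse(x$clan_partition, "separated", "NOT separated")))
  invisible(x)
}
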