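---
title: "Methods: models, parameters and design choices in raglscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in raglscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raglscan)
```

## What the package computes

`raglscan` implements the structural side of RAG-like (RAGL) and Transib
transposon analysis. A RAGL element is recognized by independent layers of
evidence, and the package keeps them as separate, composable operations:

1. **Bipartite TIR detection** (`scan_bipartite`): the terminal inverted
   repeats of these elements are RSS-like — two conserved blocks separated
   by a short variable spacer. The default model (`aan_ragl_model()`)
   encodes a 13-bp element (`CACACCCAAACCT`) and a 10-bp element
   (`CCTCAA[C/T]A[C/T]G`) with allowed spacers of 4 and 13 bp. The mouse
   RSS (heptamer/nonamer with 12/23-bp spacers) fits the same
   representation and ships as an unvalidated preset.
2. **Element assembly** (`pair_tirs`, `detect_tsd`, `find_orfs`,
   `classify_architecture`, composed by `annotate_genome`): inverted hit
   pairs, exact-duplication TSD search, six-frame ORF discovery and an
   architecture decision table.
3. **Domain classification** (`classify_protein`): RAG1L vs Transib
   subgroup I vs subgroup II from diagnostic protein regions.
4. **Polymorphism calling** (`call_locus`): insertion status of a locus
   from a pair of flanking sequences against a reference genome.
5. **Clan statistics** (`group_identity_matrix`, `nj_tree`,
   `clan_partition_check`): average within/between-group identities and a
   neighbor-joining check that two labelled clans are separated by a
   single tree edge.
6. **Synthetic data** (`element_spec`, `plant_insertions`,
   `simulate_strain_pair`, `synth_flank_reads`, `synth_protein`): seeded
   generators with machine-readable truth, so every stage above is
   benchmarked against known ground truth.

Coordinates are 0-based half-open throughout the API; the GFF3/BED writers
convert to the 1-based conventions of those formats.

## The TIR model and its scoring

Each conserved block is a position frequency matrix; windows are scored in
bits as log-odds against a background distribution, and the two block
scores are added. Spacer bases are unscored: the biology specifies spacer
*length*, not composition, so the spacer contributes only through the set
of allowed lengths. `N` bases score at their background expectation.
Consensus ties in reported consensus strings break alphabetically
(A<C<G<T).

Tunable parameters, defaults, and rationale:

| parameter | default | meaning |
|---|---|---|
| `pseudocount` | 0.1 per base per column | avoids infinite log-odds from small training sets |
| `allowed_spacers` | {4, 13} bp | the two spacer lengths of the modelled TIRs |
| `target_fpr` | 1e-6 per window | per-window false-positive rate of the scan threshold |
| `gap_window` | [500, 30000] bp | inner distance between paired TIRs; elements of the size range studied fit comfortably, and no hard size bound is biologically established |
| `k_range` | 2–10 bp | TSD search range; 5 bp is the expected value but is never presupposed |
| `min_orf_codons` | 100 | floor for reported ORFs |

**Thresholds.** Two routes are provided. `calibrate_threshold` draws null
windows from the background and returns an empirical quantile — the
operation to use when the null must be estimated. `null_score_quantile`
computes the same quantile exactly by convolving the per-column score
distributions (discretized to 0.005 bits) and is the default inside
`annotate_genome`, because it is deterministic and exact at rates (1e-6)
where Monte-Carlo sampling would be expensive. A numerical caveat: a model
built from one or two consensus strings has only a handful of distinct
column scores, so its null distribution is atomic and the attainable
false-positive rates form a coarse grid; quantile calibration behaves as
expected once the PFMs are trained from real (or simulated, mutated) TIR
collections, which give near-continuous nulls. The calibration test in the
package therefore exercises a trained model.

**Segmentation** (`segment_tir_blocks`, used to recover the 13/10-bp block
lengths from unsegmented TIRs): block lengths maximize the summed
per-column information content of the prefix and suffix alignments, with a
0.5-bit penalty per column. The penalty is necessary — every column has
positive IC from sampling noise alone, so the unpenalized objective grows
monotonically with block length. With 50 sequences the noise floor is
roughly 0.04 bits/column and genuinely conserved columns carry 0.8–2 bits,
so the result is insensitive to the penalty over a wide range (roughly
0.1–0.7 bits).

## Assembling and classifying elements

`pair_tirs` keeps inward-facing (+, −) hit pairs within the gap window and
resolves overlaps greedily by descending combined score (ties: smaller
span, then leftmost). When the contig sequence is available —
`annotate_genome` always passes it — candidate pairs with a validated TSD
rank above TSD-less candidates before the greedy sweep. This matters when
two elements lie within the gap window of each other: a chimeric pair
(5' TIR of one element with the 3' TIR of the next) can outscore a true
pair by chance, but it essentially never has an exact flanking duplication,
while true pairs essentially always do.

`detect_tsd` is an exact-match, largest-k-wins search. Homopolymeric flanks
force a match at `k_max` by definition; this caveat is inherent to any
exact-duplication criterion. For a planted k-bp TSD, a spurious call at
k + 1 requires a (2k + 2)-homopolymer-like shift pattern and occurs with
probability about 4^-(k+1).

ORF labels come from a pluggable labeller. The default
(`default_orf_labeler`) is a length heuristic — the longest ORF of at least
300 codons is RAG1L, the next of at least 200 is RAG2L — because homology
search is out of scope for this package; in random sequence, open frames of
300 codons arise at a rate of roughly `0.95^300` per start codon, so the
labels are effectively reserved for real transposase-scale genes. Users
with homology evidence can supply their own labeller.

The architecture table maps labelled ORFs to `RAGL_convergent` (RAG1L and
RAG2L on opposite strands, 3' ends facing), `RAGL_tandem` (same strand,
RAG2L upstream — the arrangement of the pelagophyte element),
`Transib_like` (a lone RAG1L) or `fragmented` (labelled ORFs with a failed
TIR pairing, missing TSD, or an orientation outside the table). `fragmented`
is thus a *structural completeness* class, not a homology judgment.
Unpaired TIR hits with a labelled ORF nearby are also reported fragmented;
hit pairs with neither a TSD nor a labelled ORF are dropped as scan noise.

## Domain classification

The clan decision table is: α11–α12 present ∧ CTT1 ∧ PreRNH β1–β3 loop →
RAG1L; α11–α12 ∧ CTT1 ∧ no loop → Transib subgroup I; no α11–α12 ∧ CTT2 →
Transib subgroup II; anything else → unclassified (α11–α12 together with
CTT2 additionally gets a contradictory-evidence note). NBD-GRP, α1 and α17
are corroborating flags only. CTT1/CTT2 are matched independently; when
both pass, the higher score wins and a tie yields `none`.

Profiles are degenerate amino-acid motifs with a match-fraction threshold
(default 0.75); `X` scores at its background expectation, and raising a
threshold can only flip calls from present to absent (monotonicity). The
published evidence for these regions is a figure-format alignment, not a
machine-readable profile set, so the shipped library
(`default_profile_library()`) is **synthetic**: motifs that exercise the
decision logic end to end and give the synthetic-protein generator exact
targets. Real analyses must supply profiles derived from their own
alignments (`read_profiles`). An optional genomic-context flag (a linked
RAG2L gene) upgrades Transib-I verdicts to RAG1L, mirroring how RAGL
elements are recognized in genomes.

## Polymorphism calling

Flank reads are modelled on splinkerette-PCR products: on the strand
leaving the element, a TIR stub followed by genomic flank that begins with
the adjacent TSD copy. Because the outermost 13 bp of either TIR are the
upstream conserved element, `strip_stub` finds the stub end by sliding the
reverse-complemented element-1 PWM along the read (acceptance floor 0.5
bits/bp).

`align_flank` maps the genomic portion by exact 15-mer seeding, diagonal
clustering, and affine-gap extension of the candidate window (match +2,
mismatch −3, gap open −5, gap extend −2). The default mode aligns the whole
query against a local stretch of reference ("glocal"), which pins the
junction coordinate even when a read error falls on the junction base; pure
Smith–Waterman is available as `mode = "local"`. One best hit is returned;
runner-up hits within 5% at a distinct locus yield `unmapped` with a
multi-hit note. Default acceptance: identity ≥ 90%, query coverage ≥ 80% —
the source assay reports no cutoffs, so these are documented knobs.

The junction arithmetic: with both flanks mapped on opposite strands, the
signed offset between the two junction coordinates is −k when the reference
carries the empty site with one k-bp TSD copy (`sample_only_empty_ref`,
requiring k equal to the expected TSD length, tolerance 0 by default), 0
when the flanks join with no duplication (`footprint_free_ref`, consistent
with loss of the copy from the reference), and +L for an occupied site,
accepted as `shared_present_in_ref` only when the L-bp interval has
TIR-matching ends.

## Clan statistics

`global_identity` is Needleman–Wunsch with affine gaps over BLOSUM62
(configurable); identity counts identical columns over all alignment
columns, including gap columns, with the ungapped-denominator variant as a
switch — published identity figures for these proteins do not state their
convention, so both are provided and neither is asserted as "the" value.
For the same reason the package treats published average-identity values as
data-dependent and instead tests the *ordering* property on emulated
two-clan data: both within-clan averages exceed the cross-clan average.
Core-region boundaries are user-supplied spans, since no coordinates are
published.

`nj_tree` is standard neighbor joining (via ape) on p-distances
(`1 − identity/100`; Poisson correction optional). NJ is used as a sanity
check, not a substitute for model-based phylogenetics: for the two-clan
question only the existence of a separating edge matters
(`clan_partition_check`), and NJ is consistent on additive distances — the
test suite verifies exact topology recovery on additive matrices up to
eight taxa against exhaustive topology search.

## The synthetic-data generator

The generator produces the study conditions the rest of the package
assumes: uniform-background genomes (GC configurable; real genomes are not
i.i.d., see limitations), elements with TIRs sampled from the consensus
distribution (degenerate positions split 50/50, as the published logo
proportions are graphical only), uniform-random spacers, 5-bp TSDs created
by duplicating the five bases 5' of the insertion point, random-codon
single-exon ORFs (350 codons RAG1L, 250 codons RAG2L) oriented per element
kind, strain pairs with shared and sample-only loci, error-free flank reads
(substitution rate is a knob, default 0), and proteins with planted domain
motifs. Which TIR carries the 4-bp and which the 13-bp spacer is not
established, so `spacer_assignment` is an explicit ordered pair, default
(4, 13). Seeds are explicit everywhere; a run seed fans out deterministic
per-locus sub-seeds, and every generator is bit-reproducible.

`sample_tir` draws element bases from the consensus distribution and then
applies independent per-position substitution (always to a different base).
Drawing from the pseudocounted scoring PFM instead would make even
zero-mutation samples differ from the consensus, which would conflate model
uncertainty with sequence divergence.

Problem sizes used by the shipped tests and default study: 100–200-kb
genomes with 1–6 planted elements, 20-seed repetitions for recovery and
polymorphism properties, 50-TIR collections for segmentation, 30–90
proteins for classification, and 10–16-taxon trees. These sizes give the
binomial checks comfortable margins while keeping the full suite fast.

## What passing tests do and do not show

The generator reproduces the *structural statistics* of the elements, not
their sequence ecology. Real genomes have repeats, compositional skew and
nested or decayed elements; the annotator's precision there depends on the
false-positive behaviour of the PWM threshold under non-uniform background,
which the package exposes (`background` is a model parameter) but the tests
do not explore. Gene content is random-codon, so the domain classifier is
exercised on proteins with planted synthetic motifs, not on real
transposase sequences. Flank reads carry no indels. The NJ check is a
topology sanity check, not a phylogeny. Known limitations, by design: no
homology search, no nested/decayed element reconstruction, no profile-HMM
training, no read-quality model, no maximum-likelihood tree inference.
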