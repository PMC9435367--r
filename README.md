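# raglscan

Structural annotation of RAG-like (RAGL) and Transib DNA transposons.

RAG recombinase — the enzyme behind V(D)J recombination in jawed
vertebrates — descends from a transposon family whose elements carry
recombination-signal-sequence-like terminal inverted repeats (TIRs) around
RAG1-like (and sometimes RAG2-like) transposase genes. The structural
evidence for such elements is stereotyped: a bipartite TIR (two conserved
elements, here 13 bp and 10 bp, separated by a 4- or 13-bp spacer), a 5-bp
target-site duplication (TSD) flanking the element, single-exon RAG1L/RAG2L
open reading frames in tandem or convergent orientation, diagnostic
transposase domains (the α11–α12 RAG2-binding region, CTT1/CTT2 C-terminal
tails, the PreRNH β1–β3 loop, the GRP positions of the nonamer-binding
domain), and — for recently mobile copies — insertion polymorphisms between
strains. `raglscan` implements each of those inferences as tested,
composable functions for people studying transposon-derived recombinases or
benchmarking TIR/TSD annotation methods.

## The model at the core

A TIR is scored with a bipartite position-weight-matrix model. For a window
starting at position *i* with spacer length *s* drawn from the allowed set
*S* (default *S* = {4, 13}):

```
score(i, s) = Σ_j log2( p1[ b(i+j), j ] / q[b] )              (element 1, 13 bp)
            + Σ_j log2( p2[ b(i+13+s+j), j ] / q[b] )         (element 2, 10 bp)
```

in bits against background *q*; spacer bases are unscored. Both strands are
scanned and every window with `score ≥ threshold` is reported; thresholds
come from the exact null distribution of the score (dynamic-programming
convolution) at a per-window false-positive rate, or from an empirical null
quantile. Downstream, inverted hit pairs are assembled greedily (TSD
evidence first, then combined score), the TSD is the largest exact flank
duplication with k in 2–10 bp, ORFs are labelled and the architecture is
classified (`RAGL_tandem`, `RAGL_convergent`, `Transib_like`,
`fragmented`). Protein clans follow a decision table over domain flags:
α11–α12 + CTT1 + PreRNH loop → RAG1L; α11–α12 + CTT1 without the loop →
Transib subgroup I; CTT2 without α11–α12 → Transib subgroup II.

## Worked example

```r
library(raglscan)

model  <- aan_ragl_model()                      # 13-bp + 4/13-bp spacer + 10-bp TIR model
spec   <- element_spec()                        # tandem RAG2L->RAG1L, 5-bp TSD
genome <- random_genome(1e5, seed = 42)
sim    <- plant_insertions(genome, spec, n_insertions = 1, seed = 42)

ann <- annotate_genome(sim$genome, model)
ann$calls[, c("start", "end", "architecture", "symmetry",
              "spacer5", "spacer3", "tsd", "tsd_len")]
#>   start   end architecture   symmetry spacer5 spacer3   tsd tsd_len
#> 1 39820 41863  RAGL_tandem asymmetric       4      13 CCGAT       5
```

The annotator was told nothing about the element: it recovered the planted
span, called the architecture tandem (RAG2L upstream of RAG1L, same
strand), labelled the 4/13-bp spacer pair asymmetric, and found the 5-bp
TSD `CCGAT` duplicated on both flanks. A full simulation study — strain
pair, polymorphism calls from splinkerette-style flank reads, protein
classification, clan statistics — runs with:

```r
report <- run_study(default_run_config(seed = 42))
report
#> raglscan simulation study
#>   seed 42 | config 551af65ba34a24537e0cc9b30b6270c7 | raglscan 0.1.0
#>   scan threshold: 13.32 bits
#>   element recovery: recall 1.000, precision 1.000 (6 calls / 6 truth)
#>   polymorphism call accuracy: 1.000
#>      sample_only_empty_ref=3 shared_present_in_ref=3 footprint_free_ref=0 unmapped=0
#>   protein classification accuracy: 1.000
#>   within-clan identities: RAG1L 82.72%, Transib 82.28%; cross-clan combined: 35.00%
#>   clan partition on NJ tree: separated
```

`recall`/`precision` score calls against the generator's truth table;
`sample_only_empty_ref` means a locus whose two flanks join seamlessly in
the reference, overlapping by exactly one 5-bp TSD copy — the signature of
an insertion present in the sample strain but absent from the reference.
The clan statistics build two protein families from diverged ancestors,
confirm within-clan identity exceeds the cross-clan average, and check that
one edge of the neighbor-joining tree separates the clans.

A command-line front end over the same functions ships in
`inst/cli/raglscan.R` (`simulate`, `scan`, `annotate`, `classify-proteins`,
`call-polymorphisms`, `stats`, `run-study`).

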