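---
title: "Mechanism-aware annotation of fusion transcripts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanism-aware annotation of fusion transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionscope)
```

# The problem

Chimeric mRNAs whose 5′ and 3′ portions come from two different parental
genes occur in plant transcriptomes at low but reproducible rates (roughly
1–3% of genes participate, across species). Unlike the oncogenic fusions of
cancer genomics, most plant fusion transcripts have no underlying genomic
rearrangement: they are made at the RNA level, chiefly by spliceosomal
*trans*-splicing (two pre-mRNAs spliced together, leaving the canonical
GT–AG intron dinucleotides at the chimeric junction), by polymerase
template switching guided by short homologous sequences (SHSs) present on
both sides of the junction, or by transcriptional read-through into an
adjacent gene. This package takes the breakpoint calls of read-level fusion
callers and classifies each junction by those mechanistic signatures,
then carries the downstream analyses such a study performs: consensus
merging, expression association, qPCR quantification, cross-genotype
conservation, long-read validation, and caller benchmarking.

# Coordinate model

All coordinates are 1-based and inclusive (GFF3 convention). A fusion call
carries `bp5`, the genomic position of the **last** transcribed base
contributed by the 5′ gene, and `bp3`, the **first** transcribed base of
the 3′ gene. Every sequence window is taken in the transcription direction
of its gene: on the minus strand "after the breakpoint" means decreasing
genomic coordinate and the sequence is reverse-complemented. This single
convention makes all motif arithmetic unambiguous; callers that report the
first-base-after instead of last-base-before convention must be shifted by
one when converted into the unified TSV (the package fixes one convention
rather than guessing each tool's).

Unknown bases are kept as `N`; `N` matches nothing in motif and homology
comparisons, so runs of `N` can only reduce reported signals, never create
them.

# Junction operators

**Splice motifs.** The donor is the 2-mer immediately after `bp5`, the
acceptor the 2-mer immediately before `bp3` (both transcription-oriented).
Only the exact pair GT–AG is "canonical"; every other pair (GT–AT, AT–AC,
CT–GC, GA–AG, …) is reported verbatim but classed non-canonical. A window
that would run off the contig is an error rather than a silent truncation,
since a 1-base motif is meaningless.

**Exon-boundary class.** A breakpoint "is at a boundary" when any annotated
isoform of its gene has an exon whose transcription-direction 3′ end equals
`bp5` (5′ side) or whose 5′ start equals `bp3` (3′ side) — on the minus
strand the transcriptional end of an exon is its genomic start. Accepting
any isoform is deliberate: documented fusion cases use exon boundaries of
two different alternatively spliced transcripts of the same gene.

**SHS detection.** Microhomology is measured as `f + b`: `f` = longest
common prefix of the `K` bases after `bp5` and the 3′ segment's first `K`
bases; `b` = longest common suffix of the 5′ segment's last `K` bases and
the `K` bases before `bp3`. The literature never fixes an operational SHS
definition, so the package exposes both knobs: `K = 20` keeps the window
comfortably above observed SHS lengths (mostly under 10 bp), and
`L_min = 4` excludes the 1–2 bp matches expected by chance at any random
junction (each flank match is geometric with success probability 1/4, so
E[f + b] ≈ 2/3 and P(f + b ≥ 4) ≈ 2%). Windows are clipped at contig ends.
The operator is verified against an exhaustive oracle that tries every
(b, f) split.

**Reading frame.** Applicable only when both genes have a CDS and both
breakpoints fall inside it; then with `L5` = coding bases from the start
codon through `bp5` and `O3` = coding bases strictly before `bp3`, the
fusion is in frame iff `L5 mod 3 == O3 mod 3`. When a gene has several
CDS-bearing isoforms the transcript whose exon boundary matches the
breakpoint is used, else the longest CDS — a tie-break the source material
is silent on, chosen to prefer the isoform most consistent with the
observed junction.

**Mechanism call.** `both` when canonical and SHS ≥ `L_min` co-occur;
`canonical_splice` or `shs` when only one signal is present; `other`
otherwise. `other` is a genuine residual class — junctions with neither
signature, attributed in the field to unknown mechanisms.

**Junction query.** The validation query is the last `flank` (default 100)
transcribed bases of the 5′ segment plus the first `flank` of the 3′
segment. The flanks are *contiguous genomic* sequence in transcription
orientation, not spliced transcript sequence; for breakpoints within ~100
bp of an intron the spliced alternative would differ. We chose genomic
flanks because breakpoint-local validation should not presuppose the exon
structure of an unobserved chimeric molecule; the choice only affects
queries near intron boundaries, and the long-read filter's 150-bp length
threshold tolerates a partially matching flank.

# Consensus, expression, conservation, benchmarking

**Deduplication** merges calls sharing the ordered gene pair, chromosomes,
strands, and breakpoints within `bp_tolerance` (default 0 = exact; the
criterion behind published "unique fusion" counts is typically unstated).
With a positive tolerance, merging is the transitive closure of the
pairwise relation, so every call belongs to exactly one unique fusion. The
representative keeps the breakpoints of the most-supported call
(junction-read count, ties by smallest `(bp5, bp3)`). Gene pairs are
ordered — a 5′→3′ arrangement is biologically directional.

**F/P vs F/A fold change.** For each fusion, samples with the fusion
(F/P) are compared to samples without it (F/A) per parental gene as
`(mean_FP + 1) / (mean_FA + 1)`; the pseudocount stabilizes zero-TPM
genes, and ≥2-fold in either direction is called up/down. The comparison
is mean-vs-mean; a stricter per-sample-pair rule (every F/P sample ≥2-fold
over every F/A sample) is a noted alternative that we did not implement,
as it conflates group effect with within-group variance.

**Co-expression** is the Pearson correlation over per-pair points
`(log2(mean TPM5 + 1), log2(mean TPM3 + 1))`; the log base cancels in
Pearson R (tested). A zero-variance axis is an explicit "degenerate
correlation" error.

**2^-ddCt.** Per replicate ΔCt = Ct(target) − Ct(reference); ΔΔCt is the
treated-minus-control difference of group means and RQ = 2^−ΔΔCt.
Mean ± SD comes from per-replicate RQs normalized to the control mean.
The group test is a Welch *t*-test on ΔCt values — testing on the cycle
scale (where noise is approximately Gaussian) rather than on the
exponentiated RQs, which standard qPCR practice recommends even where
reports just say "Student's t-test".

**Conservation.** Presence/absence of each reference gene pair per
genotype (detection in a single sample counts), clustered with Jaccard
distance and average linkage — the standard pairing for sparse binary
profiles; both are arguments. "Conserved across multiple genotypes" is
operationalized as ≥2 genotypes, exposed as a flag, and clustering runs on
the reference pair rows. Cross-species conservation maps each native pair
through a many-to-many ortholog table with direction preserved.

**Long-read validation** filters BLAST outfmt-6 hits at identity > 80 and
length > 150, strictly — the published wording ("greater than",
"exceeding") is strict, and `strict = FALSE` covers the ≥ reading.
Transcript length is estimated as the subject (read) length of the
best-bitscore supporting hit, the simplest defensible rule where none is
published. **Benchmarking** computes S = 100·TP/TF, P = 100·TP/(TP+FP) and
F = 2SP/(S+P) (the printed source formula "2∗(S∗P)/(S/P)" is an evident
typo for the harmonic mean); zero predictions give P = 0, not NaN, to keep
rankings total.

# The synthetic world

The generator emulates the data a chickpea-scale fusion study feeds this
pipeline, with truth labels:

- **Genome/annotation**: by default 2 chromosomes × 100 kb of uniform
  A/C/G/T, 40 genes of 2–6 exons (90–240 bp) and introns (60–180 bp) on
  both strands, half with CDS spanning all exons; GT..AG written at every
  intron edge in transcription orientation. Sizes are scaled for test
  speed, two orders below a real genome, but preserve everything the
  operators touch: multi-exon structure, both strands, realistic
  exon/intron lengths.
- **Planted fusions** per mechanism: exon-boundary junctions (canonical by
  construction), novel-site junctions with GT/AG edited in, engineered
  4–9 bp homologies for SHS events (with and without canonical motifs),
  rejection-sampled junctions with neither signal, and read-through events
  between genomically adjacent genes. Events never share genes, so edits
  cannot interfere; candidate junctions whose random context violates the
  intended label (e.g. chance microhomology at a canonical junction) are
  re-drawn. Each event emits 1–3 duplicate calls from pseudo-tools for
  deduplication tests. Construction validity is checked with the package's
  own motif/SHS operators — legitimate because those operators are pinned
  independently by hand-built fixtures and an exhaustive oracle.
- **Expression**: log-normal TPM (log2-scale mean 4, SD 2, sample noise
  SD 0.3, 26 samples as in the study's library count); each pair shares a
  latent factor giving pair-level correlation ρ (default 0.5, near the
  published R = 0.53); fusion-present samples are a random 20–50% subset,
  optionally scaled by a fusion effect. The `+1` pseudocount and sample
  averaging attenuate recovered R by a few percent — within the ±0.1
  acceptance band at 300 pairs.
- **Long reads**: true hits drawn inside the passing region (identity
  (81, 100], length (152, 200]); decoys straddle exactly one threshold
  each, so filter regressions are caught on both sides.
- **qPCR**: stable reference (Ct ≈ 20), target shifted by
  −log2(fold change) in the treated group, Gaussian cycle noise, 3
  replicates — mirroring a 3×3 replicate design.

What a green test does *not* establish: real genomes are not uniform
random (GC structure, repeats, paralogy can inflate SHS and boundary
coincidences), real callers have correlated error modes that the
independent pseudo-tools do not model, and real expression has
heavier-than-log-normal tails. The planted-truth suite validates the
*operators*, not the biological prevalence of any mechanism.

# Numerical choices and degenerate inputs

- `gene_fraction` rounds half-up (R's `round` is round-half-even) to match
  how published percentages are printed.
- Proportion vectors sum to 1 within 1e-9; empty summary input is an error.
- Jaccard distance between two all-zero genotype profiles is defined as 0
  (identical emptiness), keeping `hclust` heights in [0, 1].
- Breakpoints too close to a contig edge error out of motif extraction but
  only clip SHS windows and junction queries, which remain meaningful when
  shortened.
- All generators call `set.seed` internally and are pure functions of
  their seed; the CLI's outputs are byte-identical across reruns (tested).

# Known limitations

- Single-caller dialect adapter (STAR-Fusion-style `chrom:pos:strand`);
  other tools enter through the unified TSV, shifting convention
  reconciliation to the user.
- The frame model assumes the fusion preserves both parents' exon
  structure up to the breakpoints; aberrant splicing around the junction
  is not modeled.
- Junction queries use genomic flanks (see above); a spliced-flank mode
  would need the chimera's transcript model.
- The acceptance criteria that recompute published percentages (76/24
  locality, 69% GT-AG, 57% boundary-none) need the study's supplementary
  fusion table and the reference genome/annotation; the tests run the real
  pipeline when those files are placed under `inst/extdata/sm3/` and fail
  with an explicit message otherwise.
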