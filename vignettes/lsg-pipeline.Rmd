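---
title: "Identifying lineage-specific genes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying lineage-specific genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Every sequenced genome contains genes with no detectable homolog outside a
narrow taxonomic lineage. In *Caenorhabditis elegans* these lineage-specific
genes (LSGs) split into species-specific genes (SSGs, no homolog outside
*C. elegans*) and genus-specific genes (GSGs, homologs only within
*Caenorhabditis*; sometimes called CTSGs — this package treats the two
terms as synonyms, since both denote genes restricted to the genus). The
remainder are evolutionarily conserved (EC). Beyond
detection, the interesting questions are structural (are LSGs shorter,
exon-poorer, compositionally different?), mechanistic (did they arise by
exaptation from transposable elements, by gene duplication, or by
retroposition?), and functional (are they expressed, and when?).

`lsgscan` implements that whole chain as a desk-scale, fully testable
pipeline. Because the genome-scale inputs (multi-species proteome panels,
TE and paralog tracks, EST mappings, stage-resolved RNA-seq) are large,
versioned, and external, the package pairs every classifier with a
synthetic-world generator that plants each label and lets the tests check
the classifiers against known truth. All analysis code paths are identical
whether the inputs come from the generator or from real files in the same
formats.

## The homology screen

A protein is screened against ordered clade panels: congeners (other
*Caenorhabditis* species), other nematodes, invertebrates, vertebrates, and
an outgroup protein set standing in for a general protein knowledgebase. A
"hit" is any local alignment with Karlin–Altschul E-value
$E = K m n e^{-\lambda S} \le 10^{-5}$, where $m$ is the query length and
$n$ the concatenated residue count of the panel (database-style
composition, matching how a BLAST database defines its search space). The
label is decided by which panels contain hits:

* hit in any non-genus panel → **EC**;
* hits only among congeners → **GSG**;
* no hit anywhere → **SSG**.

Because short proteins carry less signal, the scoring matrix is selected by
query length: PAM30 below 30 aa, PAM70 from 30 to 70 aa, BLOSUM62 above 70
aa. The class boundaries are assigned inclusively to the middle class
([30, 70] → PAM70); the boundary convention is configurable
(`select_matrix(bounds = )`) since either reading of "between 30 and 70" is
defensible. Gap penalties are the community defaults per matrix (BLOSUM62
11/1, PAM70 10/1, PAM30 9/1 — a gap of length $k$ costs open + $k$·extend),
and $\lambda$, $K$ ship as fixed per-matrix constants (the NCBI gapped
values) rather than being fitted, which keeps E-values deterministic. No
low-complexity masking is applied.

The aligner behind `smith_waterman()` is full local dynamic programming
with affine gaps (`Biostrings::pairwiseAlignment`, no heuristic seeding —
exact and fast at these scales). The test suite cross-checks it against an
independent exhaustive enumeration of local alignments on small
reduced-alphabet pairs, so the DP route and the oracle route never share
code. Two residue conventions matter downstream: `X` scores 0 against
everything, and `*` (stop codons, which only appear in translated genomic
frames) scores −30 so that no local alignment ever crosses a stop.

When a gene has several isoforms, the gene is EC if *any* isoform has a
non-genus hit and SSG only if *all* isoforms are hit-free — the most
conservative collapse for claiming specificity. Entries in the outgroup
set carrying the focal species' own tag are excluded at panel-loading time;
the generator deliberately plants one such record to keep that exclusion
honest.

## Characterization and statistics

Per gene: gene length (genomic span in nt, introns included), protein
length (aa), exon count, and GC content. GC is computed over the gene's
full genomic span by default (`gc_on = "spliced"` switches to exonic
sequence); the span convention is also used as the RPKM length, so the two
modules agree. Group comparisons use classic one-way ANOVA
(equal-variance pooling, via `stats::oneway.test`); the degenerate
all-identical case is defined as F = 0, p = 1 rather than NaN. Standard
errors are sample SD (n−1) over √n. The published group table contains an
ambiguous unlabeled numeric column; it is not reproduced as a named metric
here — the four metrics above are.

## Origin analysis

"Complete overlap" is read literally: a gene is TE-derived
(duplication-derived) iff its genomic span is fully contained in the union
of TE (paralog) track intervals. Containment is exposed as a fraction
(`containment_threshold`, default 1.0) because the literal reading is
strict; lowering it can only add flags (a tested monotonicity). Overlap is
strand-ignorant — exaptation from an antisense TE is still exaptation. The
direction of the containment test (gene-inside-annotation rather than
annotation-inside-gene) is a deliberate choice: exaptation and duplication
copy the *gene* out of pre-existing sequence, so the gene should lie inside
the annotated feature.

The category table reports TE, DUP, BOTH and the union
Total = TE + DUP − BOTH, with percentages of the group total rounded
half-up to two decimals (base R's banker's rounding would disagree with the
published formatting in half cases). The inclusion–exclusion identity,
BOTH ≤ min(TE, DUP), and Total ≤ group size are asserted on every output.

## The retrogene and chimera screen

Retroposition leaves a diagnostic signature: an intronless genomic copy of
a spliced, multi-exon parent. The screen proceeds in the order

1. **Translated matching** — every protein is aligned against all six
   translated frames of the genome (E ≤ 10⁻³; within a frame, hits are
   recovered iteratively by masking and realigning).
2. **Merging** — adjacent matches on one protein/chromosome/strand merge
   when the genomic gap is strictly under 40 bp, transitively; merged
   identity is the alignment-length-weighted mean.
3. **Filtering** — merged matches survive with identity > 30% and length
   > 50 aa (both strict).
4. **Parental assignment** — the translated merged locus is compared
   against all multi-exon (≥ 3 exons, i.e. ≥ 2 introns) proteins; the
   closest passing parent wins, with deterministic tie-breaks (similarity,
   then parent length, then id).
5. **Intron-aware verification** — the parent's per-exon peptide blocks are
   aligned within the locus ± 10,000 bp. The score is the sum of block
   scores minus a penalty (default 10) per genomic gap over 30 nt between
   consecutive blocks: an intronless copy keeps its blocks contiguous and
   pays nothing, a spliced locus pays per intron. This scorer is an
   internal spliced-alignment proxy — its score of 35 is retained as the
   acceptance threshold on this scale, configurable, and not comparable to
   external protein-to-genome aligners' bit scores.
6. **Acceptance** — score > 35, at least 2 parental introns inside the
   matched part of the parent, parent coverage > 40% (strict; coverage is
   of the *parent protein*, the less gameable of the two possible
   denominators).

Two guards matter in practice and are easy to miss. First, every protein
trivially matches its own genomic locus; candidate loci overlapping the
query's own gene, or the assigned parent's own annotation, are self-matches
and are excluded. Second, the ±10 kb verification window can contain the
parent gene itself when parent and copy are near neighbours, so the
parent's annotated span is masked (with `N`) inside the window before block
alignment — otherwise the source verifies instead of the copy.

An annotated gene whose CDS overlaps an accepted retro locus by more than
50 bp is called chimeric (overlap measured on CDS intervals only, UTRs
excluded); overlaps above 90 bp set a `possible_false_positive` flag. The
two thresholds plainly overlap — anything above 90 bp is both chimeric and
flagged — so the flag is exactly that, a flag, never a removal: both
readings stay available downstream. The parent gene itself is never called
chimeric.

## Expression profiling

Transcript mappings pass four inclusive filters (mapping length ≥ 150 bp,
identity ≥ 98%, coverage within mapping ≥ 97%, coverage of the whole
transcript ≥ 75%), then multi-locus transcripts are discarded as ambiguous
when the runner-up score is within 2% of the best — relative to the best
score, since an absolute score difference is meaningless across transcript
lengths. A gene overlapping retained mappings by strictly more than 100 bp
counts as EST-supported.

Per stage, a read counts for a gene when it overlaps the gene span by at
least 1 bp (a read across two genes counts for both; `multi = "unique"`
switches to unique-only). RPKM = count · 10⁹ / (span · library size).
"Expressed" means RPKM strictly above a threshold whose default is 0 — any
nonzero signal — because no published cutoff exists for these data;
the threshold is a visible parameter precisely because the choice is
unconstrained. Stage proportions are expressed-gene fractions per group;
group contrasts use Welch's t-test.

## What the synthetic world emulates — and what it does not

The generator plants, per seed, deterministically:

* genes in three classes whose protein-length and exon-count ranges bracket
  the published group contrasts (SSG ≈ 100–180 aa / 1–3 exons,
  GSG ≈ 220–340 / 2–5, EC ≈ 400–600 / 5–9), as codon-aligned exons with
  random introns on a single contig (default 500 kb; the analysis scripts
  and tests run 40–60 kb worlds with 9–16 genes so the whole suite stays in
  minutes on one CPU);
* homolog copies mutated per clade (defaults 0.05 / 0.15 / 0.30 / 0.45,
  non-decreasing with distance so detectability decays outward; congeners
  carry GSG+EC homologs, deeper clades EC only), plus unrelated decoy
  proteins per species;
* TE/paralog tracks that fully contain a random subset of LSGs (origin
  flags), plus intergenic TE intervals at the configured density —
  placed intergenically so a random TE can never accidentally contain a
  gene and contradict the planted flag;
* intronless retrocopies (default 2% amino-acid divergence) of distinct
  multi-exon EC parents, free-standing or overlapping a planted single-exon
  host gene's CDS by a configured amount (default 70 bp) for the chimera
  case;
* clean transcript mappings for expressed genes plus decoys that fail each
  mapping filter and one planted ambiguous pair; expressed-gene prevalence
  per class defaults to 32.04% / 58.69% / 80.97%;
* per-stage reads (Poisson, mean 20 per expressed gene per stage) across
  fourteen named developmental stages, with intergenic background reads
  padding the library size; unexpressed genes receive zero reads, so
  RPKM > 0 is an exact oracle for the planted flag.

Amino-acid substitution is uniform random replacement, not
matrix-weighted: downstream only hit/no-hit detectability matters, and the
uniform model makes detectability a clean function of the rate. There are
no indels, no codon-usage realism, no sequencing-error model, and all genes
sit on the plus strand of one contig. Consequently, passing tests
demonstrate that the *decision logic* is correct — labels, thresholds,
boundaries, bookkeeping — under planted truth; they do not demonstrate
robustness to alignment ambiguity, repetitive DNA, fragmented assemblies,
or isoform complexity in real data.

## Numerical and degenerate-input choices

* Boundary conventions follow the stated inequalities exactly: mapping
  filters inclusive (≥), merged-match filters strict (>), merge gap strict
  (< 40), chimera overlap strict (> 50 / > 90), EST overlap strict
  (> 100), retro coverage strict (> 0.40), ambiguity strict (< 2%).
* Zero-score local alignments are "no hit"; empty panels never hit.
* Same seed ⇒ byte-identical world files and pipeline outputs (checked by
  checksum in the tests); the run manifest records the seed and an MD5 of
  the canonical config serialization, which changes iff a threshold does.
* The configuration validator requires clade mutation rates to be
  non-decreasing rather than strictly increasing so that the exact-homology
  limit (all rates zero), which anchors the recovery tests, is a valid
  configuration.
* Retro parents require ≥ 3 exons; a configuration asking for more
  retrocopies than available multi-exon parents is rejected up front.

## Known limitations

The E-value calibration uses fixed ungapped-adjusted constants, so absolute
E-values differ from tools that fit composition-corrected parameters —
cutoff behaviour, not calibration, is what the package tests. The spliced
verification score is proxy-scaled (see above). The screen assumes
annotated gene models with coding exons; UTR-aware chimera calling would
need richer annotations than the pipeline consumes. Retrogene age, poly-A
tails and target-site duplications are out of scope, as is any external
annotation service.
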