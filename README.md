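# lsgscan

Genome-wide identification and characterization of **lineage-specific genes
(LSGs)** in *Caenorhabditis elegans*, as a tested, reusable R pipeline.

Most genes in a genome have recognizable homologs across distant taxa; a
sizable minority do not. `lsgscan` classifies every protein of a focal
species into

* **SSG** — species-specific gene: no homolog outside *C. elegans*,
* **GSG** — genus-specific gene: homologs only within *Caenorhabditis*,
* **EC** — evolutionarily conserved gene: homologs beyond the genus,

by hierarchical homology screening against clade-stratified proteome
panels, then asks how the LSGs arose and whether they are expressed:

1. **Homology screen** — full Smith–Waterman local alignment with
   length-dependent scoring matrices (PAM30 < 30 aa, PAM70 for 30–70 aa,
   BLOSUM62 > 70 aa) and Karlin–Altschul statistics,
   E = K·m·n·e^(−λS), hit cutoff E ≤ 10⁻⁵.
2. **Characterization** — gene size, exon number, protein size, GC content
   per group, with one-way ANOVA across SSG/GSG/EC.
3. **Origin analysis** — a gene completely contained in the union of TE
   (paralog) annotations is called TE-derived (duplication-derived);
   categories are tabulated by inclusion–exclusion,
   Total = TE + DUP − BOTH.
4. **Retrogene / chimera screen** — six-frame translated matching
   (E ≤ 10⁻³), merging of adjacent matches (< 40 bp), identity/length
   filters (> 30%, > 50 aa), parental assignment among multi-exon
   proteins, intron-aware spliced verification (±10 kb flanks; accepted at
   score > 35, ≥ 2 parental introns in the match, parent coverage > 40%),
   then chimera calls for annotated genes whose CDS overlaps a retro locus
   by > 50 bp (flagged as possible false positives above 90 bp).
5. **Expression profiling** — transcript-mapping quality filters
   (≥ 150 bp, ≥ 98% identity, ≥ 97% / ≥ 75% coverage), 2% ambiguity rule,
   EST-overlap calls (> 100 bp), per-stage read counting with
   RPKM = count·10⁹/(length·library), expressed-gene proportions across
   fourteen developmental stages, and Welch t-tests between groups.

A **synthetic-world generator** (`generate_world()`) plants genes of known
class, origin, retro/chimera status and expression on a miniature genome —
with clade-stratified mutated homolog panels, annotation tracks, transcript
mappings and stage-resolved reads — so every classifier is validated
against ground truth without any external download. The same code paths
consume real FASTA/GFF3/BED/TSV inputs.

## Worked example

The `analysis/` directory holds the numbered workflow; each script is a
thin driver over the package and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate_world.R     # plant the synthetic study world
Rscript analysis/02_classify_lsg.R       # SSG / GSG / EC labels
Rscript analysis/03_characterize_genes.R # group features + ANOVA
Rscript analysis/04_origin_overlap.R     # TE / duplication origin table
Rscript analysis/05_retrogene_chimera.R  # retrogene + chimera screen
Rscript analysis/06_expression_profiles.R# stage expression + proportions
```

`02_classify_lsg.R` prints, for the default seed (11):

```
classifying 16 proteins against panels: congeners, other_nematodes, invertebrates, vertebrates, outgroup_proteins
counts: SSG 6, GSG 5, EC 5
agreement with planted truth: 100.0% (16/16)
```

every planted label is recovered (the sixth SSG is the planted chimeric
host gene, which has no homologs by construction). `03_characterize_genes.R`
shows the planted size ordering EC > GSG > SSG and its significance:

```
group means (gene size in nt):
  SSG     533.0 +/-   78.6 (n=6)
  GSG    1284.0 +/-   57.6 (n=5)
  EC     2526.6 +/-  163.8 (n=5)
ANOVA across groups:
  gene_length_nt     F =    90.08, p = 2.41e-08
```

`04_origin_overlap.R` runs the inclusion–exclusion bookkeeping both on the
synthetic calls (100% agreement with planted flags) and on the published
genome-scale per-mechanism counts shipped with the package:

```
 mechanism count   pct group
        TE   374 26.28   SSG
       DUP   355 24.95   SSG
      BOTH   107  7.52   SSG
     Total   622 43.71   SSG
        TE  1588 34.99   GSG
       DUP  2527 55.67   GSG
      BOTH   887 19.54   GSG
     Total  3228 71.12   GSG
```

and `05_retrogene_chimera.R` recovers all three planted retro loci at their
exact coordinates with zero false calls, including the chimera:

```
accepted retrogene calls: 3
      gene_id      retro_id cds_overlap_bp possible_false_positive
 gene_CHIM_01 retro_call_01             70                   FALSE
planted retro loci recovered: 3/3; false calls: 0
```

Alternatively, `run_pipeline(out_dir, synthetic_seed = 11)` performs all
stages in one call (or `run_pipeline(out_dir, input_dir = ...)` on your own
files), writing `labels.tsv`, `table1.tsv`, `table2.tsv`,
`retrogenes.tsv`, `chimeras.tsv`, `expression.tsv`, `proportions.tsv` and a
`manifest.yaml` with the seed and config hash.

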