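---
title: "Detecting stop-codon reassignment in phage genomes: models and methods"
author: "PhageRecode authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stop-codon reassignment in phage genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhageRecode)
```

## The problem

Some tailed phages (Caudoviricetes) translate one of the canonical stop
codons as an amino acid. The best-documented case is amber (TAG)
reassignment to glutamine, NCBI translation table 15; opal (TGA) to
tryptophan (table 4) also occurs. When such a genome is annotated under the
bacterial standard table 11, every gene carrying an internal reassigned
codon is fragmented into short spurious ORFs, and downstream comparative
analysis (orthology, proteomic similarity, taxonomy) silently degrades.
`PhageRecode` detects the reassignment from the genome sequence alone,
re-annotates under the recommended table, and provides the comparative
statistics (nucleotide identity, normalized translated similarity,
VIRIDIC-style intergenomic similarity with 95%/70% species/genus
thresholds, reciprocal-best-hit orthology, synteny) needed to place such
genomes taxonomically.

## Evidence model for reassignment

For each candidate stop codon $c \in \{TAG, TGA, TAA\}$ the genome is
annotated twice: under table 11 and under the table that reads $c$ as
sense. Three kinds of evidence are collected.

**Interrupted-ORF candidates.** In the table-11 six-frame segmentation, an
interruption candidate is a pair of adjacent stop-to-stop coding fragments
separated only by in-frame stops of type $c$. The upstream-most fragment of
a chain must contain a start codon at least `minFragmentAa` (default 15)
codons before the interrupting stop; continuation fragments need no start,
because a genuine interrupted gene resumes mid-sequence. Consecutive $c$
stops chain, so a gene with $k$ internal reassigned codons contributes $k$
candidate rows in one chain.

**Coding-fraction gain.** Six-frame ORF sets contain heavy shadow
redundancy: antisense and off-frame "junk" ORFs cover most of a gene-dense
genome under any table, so a naive coverage difference between tables is
dominated by noise. Two design choices make the statistic specific:

1. Coverage is computed on the *optimal non-overlapping tiling* of the ORF
   set, found by weighted interval scheduling with quadratic length
   weights ($\sum_i w_i^2$). Quadratic weighting means a single long gene
   always beats any mosaic of short shadow ORFs over the same span, so
   real genes own their territory in the tiling and junk enters only
   where nothing competes.
2. Only ORFs of at least `minRescueLengthAa` (default 90 aa) enter the
   rescue statistics. Intergenic gaps in gene-dense phage genomes are far
   shorter than 270 nt, so chance ORFs that merge across a random
   stop cannot reach this length anywhere a real gene does not already
   dominate. The final annotation still uses the ordinary caller minimum
   (30 aa).

The gain for codon $c$ is the tiling coverage under the reassigned table
minus the coverage under table 11. On genomes that do not reassign $c$ the
two annotations are nearly identical and the gain is ~0; on recoded
genomes the table-11 tiling loses the stretches between a gene's start and
the next in-frame start after each reassigned codon, plus every fragment
shorter than the caller minimum.

**Suppressor tRNAs.** tRNAs whose anticodon base-pairs with a stop codon
(CTA to TAG, TCA to TGA, TTA to TAA) corroborate reassignment. Support is
recorded but *not required*: recoded phage genomes without suppressor tRNA
genes are documented, so the decision rule never conditions on it.

**Decision rule.** Codon $c$ is called reassigned when
`coding_fraction_gain(c) >= gMin` (default 0.02) **and**
`n_interruption_candidates(c) >= kMin` (default 5). Ties between codons go
to the larger gain (no standard table reassigns two stops). TAA is
evaluated for completeness but never recommended: no supported NCBI table
reassigns TAA alone. On the synthetic study conditions below, the default
thresholds give zero false verdicts over 100 standard-code genomes and
call table 15 on 100/100 recoded genomes, with over 90% of the designed
reassigned codons recovered in the final annotations (the validation
suite recomputes all three figures).

## The synthetic study conditions

The generator emulates the genome architecture this method targets:
gene-dense dsDNA phage genomes. Defaults: 20 genes of 100-400 aa
(uniform), intergenic spacers of 20-120 nt, GC 44.5%, 28% of genes
carrying 1-4 internal TAG codons (at least 20 codons from the gene ends
and from each other), three suppressor tRNA genes with anticodon CTA, 30%
of genes on the minus strand. Genes are drawn codon-wise from a
GC-consistent distribution over the 61 sense codons, so no stop can occur
by accident and the designed ambers are the *only* in-frame TAGs. Each
gene sits in stop-bounded context (an in-frame stop immediately 5' of the
ATG), which real intergenic DNA provides statistically; without it, the
longest-ORF start rule would run upstream through the spacer under the
readthrough table and collect spurious "reassigned" positions.

Features of real data the generator does **not** emulate: realistic gene
content and codon usage, regulatory signals (RBS), overlapping genes,
modified bases, and assembly artifacts. Passing tests therefore show that
the inference machinery is correct under the declared model, not that the
thresholds are optimal for every natural genome; both thresholds are
config-exposed.

The mutator applies per-site substitutions (uniform over the three
alternatives) and 1-6 nt indels, logging every event, so alignment
statistics can be checked against exact ground truth. The
`preserveOrfs` mode emulates purifying selection: substitutions that would
create an in-frame stop inside a gene (or touch a start/stop/amber codon)
are rejected. Uniform mutation at 5% per site would otherwise place a
premature stop in roughly every other gene, which no pair of naturally
related phage genomes shows; ortholog and synteny truths use this mode,
alignment-identity truths use the unconstrained mode.

## Sequence comparison

**Nucleotide identity (NI).** Small genome pairs (up to 2.5e7 DP cells,
roughly 5 kb x 5 kb) are aligned by a full affine Needleman-Wunsch dynamic
program (match 10, mismatch -9, gap open 25, extend 6; co-optimal terminal
gaps resolve to the alignment boundary). Larger pairs are aligned at genome
scale by chaining k-mer anchors (k = 15, unique in both genomes, longest
collinear chain by LIS) and closing the inter-anchor gaps with the same
kernel; anchor-free large pairs are reported as NI 0 with a `no_homology`
flag. NI = matches / aligned columns; terminal overhangs are excluded and
internal gap columns count as mismatches (a config switch drops them from
the denominator instead, since reference implementations of genome
identity differ on this point). On 200 mutant pairs up to 2 kb the kernel
reproduces the identity computed by an independent dynamic-programming
implementation exactly, and on substitution-only mutants at genome scale
NI equals 1 minus the realized substitution fraction from the mutation
log.

**SG score.** The translated similarity of a genome pair is the sum of
non-overlapping local amino-acid alignment scores between all six-frame
translations: exact 4-aa seeds, ungapped X-drop extension (X = 20) under
BLOSUM62, HSPs kept above a raw-score cutoff, greedy non-overlap selection
on the first genome's nucleotide coordinates, symmetrized by averaging the
two directions. Normalization by the smaller self-score maps the result to
$0 \le SG \le 1$ with $SG(a,a) = 1$ exactly. The HSP cutoff (default 70)
is calibrated on the empirical null: with the textbook cutoff of 50, the
expected number of chance HSPs between unrelated 20-kb genomes is in the
dozens (Karlin-Altschul statistics put E(score >= 50) near 30 for this
search space), which would leak a few percent of SG; at 70 the expectation
drops below 0.05 and unrelated pairs score SG < 0.01.

**Intergenomic similarity.** Following the VIRIDIC definition, the
identities of the reciprocal local alignments are summed and divided by
the sum of the genome lengths, so partial homology dilutes the score
through the length denominator; a genome versus its own half scores 2/3.
Species and genera are delimited at 95% and 70% with single-linkage
clustering (complete linkage available); species are clustered within each
genus, so the species partition refines the genus partition by
construction.

**Orthology and synteny.** Reciprocal best hits under global affine
BLOSUM62 alignment (identity >= 30% of aligned residues, coverage >= 50%
of the longer protein), computed on the *recoded* proteomes — under table
11 recoded genes fragment and their orthologs are lost, which is the
practical cost of mis-annotation this package exists to avoid. The shared
core of a genome set is the number of RBH-graph components containing
exactly one ORF per genome. Gene-order conservation is Kendall's tau over
the ortholog order indices, with the second genome's order reversed when
most ortholog pairs lie on opposite strands (inversion flag), plus the
fraction of ortholog pairs adjacent in both genomes.

## tRNA detection

The builtin detector scans both strands for the canonical cloverleaf
layout on standard tRNA numbering: a 7-bp acceptor stem (>= 6 pairs, G-U
wobble allowed), 4-bp D stem (>= 3 pairs), 5-bp anticodon stem (all 5
pairs) enclosing a 7-nt loop with the anticodon at loop positions 3-5, a
5-bp T stem (>= 4 pairs) opened by the TTC motif, and a variable loop of
3-15 nt. Score is the paired-base count plus motif bonuses; overlapping
candidates resolve to the best score. The measured null over seeded
random genomes stays below one false detection per 100 kb. The detector recovers canonical
76-nt tRNAs (it finds the yeast phenylalanine tRNA in random context) and,
by construction, every simulated suppressor gene — the generator emits the
same structural template the detector scans for, a deliberate coupling
that makes the detector's role in the pipeline testable but says nothing
about sensitivity on non-canonical natural tRNAs. For production use the
pipeline ingests tRNAscan-SE calls from GFF3 (`ingestExternalTrnas`),
after which suppressor classification — the step this package actually
depends on — is exact arithmetic on the anticodon.

## Numerical and interface choices

* Coordinates are 1-based inclusive `GRanges` throughout, the Bioconductor
  convention; GFF3 and GenBank writers inherit it directly. Features of
  circular genomes may cross the origin; they are scanned on a virtually
  doubled sequence and reported with end > genome length plus a `wraps`
  flag.
* Ambiguity characters other than N are rejected at read time; codons
  containing N translate to X and never seed alignments.
* The alignment scoring constants (10/-9/25/6) are deliberately
  incommensurate so that co-optimal alignments with different match counts
  are essentially impossible, which is what makes exact oracle equivalence
  a meaningful test.
* Determinism: every stochastic routine takes an explicit seed and
  restores the caller's RNG state; identical spec + seed gives
  byte-identical FASTA.
* Problem sizes in the validation suite (20-gene / ~17-kb synthetic
  genomes, 100 seeds per condition, 200 oracle pairs up to 2 kb, 20-kb
  null pairs for SG) were chosen so the full suite characterizes every
  statistical property while staying comfortably runnable on a laptop.

## Known limitations

* The ORF caller uses the longest-ORF-per-stop start rule without RBS
  scoring; reported gene starts on natural genomes are approximate, and
  absolute ORF counts are caller-dependent (the pipeline reports its own
  counts rather than promising agreement with any external annotator).
* The structural tRNA detector trades sensitivity for near-zero false
  positives; natural tRNAs with non-canonical arm lengths are missed
  (use external calls).
* TAA reassignment is measured but cannot be recommended as an annotation
  table.
* `shared_core` counts all single-copy ortholog groups; published core
  counts restricted to ORFs with assigned functions are a lower-bounded
  comparison, since functional annotation is out of scope here.
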