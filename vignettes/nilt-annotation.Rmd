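---
title: "Annotating clustered immunoglobulin-like receptor (NILT) gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating clustered immunoglobulin-like receptor (NILT) gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niltr)
```

## The biological problem

Novel immunoglobulin-like transcripts (NILTs) are innate-immune receptors
of teleost fish. Each receptor carries one or two extracellular V-type Ig
domains, a serine/threonine-rich connecting peptide (CP), a transmembrane
helix (TM) and a cytoplasmic tail whose immunoreceptor tyrosine-based
inhibitory motifs (ITIMs) determine signalling. In Atlantic salmon the
genes form a tight cluster: six intact genes plus pseudogenes on a single
BAC, with genes on both strands, a conserved six-exon architecture
(leader peptide, Ig, CP, TM and two cytoplasmic exons) and highly
conserved intron phases — phase 1 for the introns upstream of the
ITIM-bearing exon and phase 0 immediately before it, which is what keeps
the inhibitory module in frame.

`niltr` re-implements the characterisation of such a cluster as a tested,
reusable pipeline: gene-structure tables and intron phases, pseudogene
detection, receptor feature annotation, alignment-based
identity/similarity and Shannon-entropy variability, neighbour-joining
phylogeny with bootstrap, and the single-individual clone-repertoire
survey. A ground-truthed simulator generates loci and clone libraries
with every one of these features planted, so the entire pipeline is
testable without any sequence download.

## Gene models and structure arithmetic

Exon-level annotations (GFF3, roles `LP`, `Ig1`, `Ig2`, `CP`, `TM`,
`Cyt1`, `Cyt2`) are assembled into gene models. Internally all
coordinates are 0-based half-open, which makes length and phase
arithmetic exact; GFF3 on disk stays 1-based inclusive and the
conversion is a bijection. Exons of minus-strand genes are ranked in
transcription order and reverse-complemented at extraction time.

Two conventions make the structure table sum exactly to the published
open reading frames: exon 1 length is its *coding* length (the 5'UTR is
not part of the feature), and the terminal stop codon is counted inside
the last cytoplasmic exon. With those, the six salmon genes give ORFs of
1032, 993, 1278, 1062, 933 and 945 bp:

```{r}
st <- structure_table(ssa_nilt_gene_models())
st[, c("gene_id", "orf_length")]
```

The phase of intron *i* is the number of coding nucleotides upstream
modulo 3 (phase 0 between codons). Recomputed from the exon lengths
alone, all one-Ig genes give `1,1,1,1,0` and the two-Ig gene gains one
extra phase-1 intron.

Pseudogene detection is a set of independent flags, not a hard error:
in-frame stop codons before the final codon (reported with their locus
coordinate), a missing essential exon (CP, TM or Cyt2 while leader and
Ig are present), a summed coding length not divisible by three, and
non-GT-AG splice sites. Non-canonical splice sites *flag* a model rather
than reject it, since the check is a heuristic; any raised flag
classifies the model as a putative pseudogene and excludes it from
protein-level annotation.

## Protein regions and receptor features

Translation uses the standard code, refuses degenerate bases inside a
CDS (ambiguity codes are fine in primers and raw input, not in an
assembled coding sequence) and strips the terminal stop, so the protein
always has orf/3 − 1 residues. Region boundaries follow the cumulative
exon amino-acid boundaries with a split codon assigned to the
*downstream* region; this reproduces, for example, a 56-residue CP from
a 168-nt CP exon flanked by phase-1 introns. The TM exon encodes the
membrane helix followed by the start of the tail, so the cytoplasmic
region is the TM-exon remainder plus both cytoplasmic exons. The helix
length is a parameter (`tm_aa_len`, default 23 aa — a typical
single-pass helix); the annotation cannot infer it from exon structure,
and the simulator plants the same value it reports.

* **Cysteine spacing.** A V-type Ig domain has its fold cysteines near
  alignment positions 17 and 89; the profile anchors each within a ±5
  window (outside it the domain is flagged, never force-fit) and then
  takes the unique cysteine pair strictly between them. The class is
  CX*n*C with *n* the gap between that pair minus one; *n* ∈ {3, 6, 7}
  are the classes seen in this family.
* **ITIMs.** Consensus (S/I/V/L)xYxx(I/V/L), short form Yxx(I/V/L);
  `x` means any residue. Overlapping matches are found, each distinct
  tyrosine yields at most one hit, and the long form wins; this is the
  natural reading of "four or five inhibitory motifs" without
  double-counting a tyrosine.
* **CP composition** is a literal Ser+Thr count with the region length,
  reported as `st_count / cp_length`.
* **TM charge.** An Arg or Lys in the helix is the classic hallmark of
  an activating receptor that pairs with an ITAM-bearing adaptor; the
  check is a boolean, not a prediction.
* **Group classification.** CX3C Ig domains split into two groups by
  three diagnostics read in a reference coordinate frame: His20 +
  SLYY(32–35) + Leu66 (Group 1) versus Gln20 + (P/R)V(F/L)N(32–35) +
  Ile66 (Group 2). Positions are transferred onto the query by global
  alignment to a configurable reference Ig domain; the package ships a
  synthetic 116-residue scaffold (`nilt_reference_ig()`) carrying the
  canonical cysteines and the Group-1 diagnostic set, and any family Ig
  domain can be substituted. A group needs 2 of 3 diagnostics — full
  agreement is not required because the motif column itself is
  degenerate. Non-CX3C domains are refused with reason
  `"spacing_class"`.

## Alignment, identity and variability

Pairwise global alignment is Needleman–Wunsch with affine gaps
(BLOSUM62, open 10, extend 0.5 for proteins). Percent identity divides
by the aligned residue–residue columns (gaps excluded) — the convention
stated explicitly so matrix values are interpretable; similarity
additionally counts pairs with a positive substitution score. The
identity/similarity matrix is laid out the way such tables are
published: identity in the upper triangle, similarity in the lower,
100 on the diagonal, rows in display order. Permuting the input permutes
the display; every pair's values stay attached to its labels.

The multiple aligner is progressive: pairwise identity distances, a
UPGMA guide tree (average-linkage `hclust`), and profile–profile
Needleman–Wunsch with mean substitution scores. It makes no claim of
reproducing any particular aligner's output bit-for-bit; its contracts
are that rows stay equal-length and that ungapping any row returns the
input.

Per-column variability is Shannon entropy, H = −Σ f·log₂ f with
frequencies over non-gap residues only; an all-gap column has no
defined H and is never called variable. The variability threshold is
1.3 bits, adopted as the family's published convention; it is a
parameter everywhere it appears.

## Phylogeny

Distances are p-distances with pairwise deletion (the common default of
the MEGA-era toolchain; a Poisson correction −ln(1−p) is available).
Neighbour joining is the Saitou–Nei algorithm with two deterministic
details worth stating: exact Q-ties are broken by the lexicographically
smallest pair of cluster labels, and negative branch-length estimates
are clamped to zero with the deficit moved to the sister branch, so edge
lengths are non-negative and results are order-independent. Bootstrap
resamples columns with replacement; replicate *r* draws its RNG state
from a substream derived from (seed, *r*), so supports are exactly
reproducible and independent of evaluation order. Supports are the
percentage of replicates containing each internal bipartition of the
reference tree; 1000 replicates is the desk-scale default and the count
is a parameter for users who want the published 10,000. Outgroup rooting
places the root on the outgroup's pendant edge and moves node labels
with their edges, which matters because a divergent second Ig domain is
the natural outgroup for this family.

The tests check neighbour joining against two independent oracles:
recovery of the generating topology on additive matrices (exhaustively
over all unrooted topologies with 4–6 taxa) and a brute-force
least-squares search over all topologies, plus agreement with `ape`'s
implementation.

## The repertoire survey

The survey procedure from a single individual: clones from 10
independent PCRs × 10 sequenced clones are screened for family
membership, deduplicated exactly at the nucleotide level, and only
sequences observed more than once are retained; sequences seen once are
translated and deduplicated at the amino-acid level to give the
singleton count (mirroring the mixed nucleotide/amino-acid phrasing of
the original rule — both tallies are reported since the source is
ambiguous about which level "different sequences" refers to). Retained
sequences are assigned to known genes by exact nucleotide identity over
the amplified interval, anything else is novel, and novels are
group-classified from their translation. The positivity screen — best
translated identity to any known Ig domain — uses a 70% threshold; the
original criterion is unstated, and 70% sits comfortably between
within-family identities (77–96%) and what unrelated sequence attains.
Degenerate primer-derived bases at amplicon ends are trimmed before
matching.

## The synthetic generator

`simulate_locus()` builds each gene protein-first: leader peptide
(initiator Met + background), Ig domain(s) derived from the reference
scaffold with the requested CXnC spacing and diagnostic group planted
and unconstrained positions substituted at `ig_divergence` (default
0.15, matching the 77–96% within-family identity range), a CP with the
requested Ser+Thr fraction (default 29/56, the family's exemplar), a
charge-free hydrophobic TM helix (an Arg is planted instead when an
activating receptor is requested), and a cytoplasmic tail with exactly
`n_itims` long-form ITIMs planted in the Cyt2-encoded segment. The
backgrounds exclude Cys (no spurious spacing pairs) and Tyr (no
spurious ITIMs), and the generator nevertheless re-scans every planted
region with the same annotation functions it is meant to fool,
regenerating locally (up to 100 attempts) before accepting — the
recorded truth is therefore exact by construction *and* by
verification. Proteins are back-translated with uniformly random
synonymous codons, split at the template's exon boundaries (defaults:
the published exon/intron lengths of the one-Ig exemplar gene, 46, 348,
168, 96, 50, 324 nt coding with introns 275, 2056, 1074, 218, 753 nt,
and of the two-Ig gene for the seven-exon template), joined by GT-AG
introns of uniform random composition and embedded between random
spacers, reverse-complemented on the minus strand.

Lesions reproduce the observed pseudogene patterns: an in-frame TAA
rewritten into the Ig1 exon just downstream of the second canonical
cysteine; removal of the CP exon from the annotation; or a single-base
deletion in the CP exon. A frameshift usually also creates downstream
in-frame stops, so its validation report may carry `internal_stop`
alongside `frameshift`; the truth records the planted mode and the
tests require the mode's flag to be present (and exact flag sets for
the other two modes).

`simulate_clone_library()` draws template-weighted clones for the
10 × 10 survey design and applies independent per-base substitutions.
The default error rate is 5 × 10⁻⁴ per base — a realistic figure for
high-fidelity PCR plus Sanger reads, chosen once; indels are excluded
because the survey compares equal-length amplicon intervals. The truth
records each clone's template and planted error count, giving exact
oracles: at rate 0 the retained set equals the templates drawn at least
twice and the singleton count is the number drawn exactly once.

What the simulator does *not* emulate: transposable-element content
(spacers are uniform random DNA), realistic codon usage or
isochore-like base composition, 5'/3' UTRs, allelic variation within a
gene, or chimeric/indel PCR artefacts. Passing the round-trip tests
therefore shows the annotation logic is exact on clean inputs, not that
it is robust to assembly error or mispredicted exon boundaries — those
enter this pipeline as given annotation.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated
data: loci of 2–6 genes with full-size or shortened introns, 50 seeded
random configurations for the round-trip property, all unrooted
topologies on 4–6 taxa for the neighbour-joining oracle (with the
least-squares search exhaustive at 4–5 taxa and sampled at 6),
bootstrap runs of 40–100 replicates in tests and 1000 in the analysis
scripts, and 100-clone libraries. Entropy closed forms are asserted to
1e-12. These sizes were chosen to exercise every code path at desk
scale; all of them are parameters, and the analysis scripts show the
full-scale settings.

Known limitations: the accession-backed quantities (the 96% Ig identity
between the first two genes, the 29/56 CP composition, the five ITIMs)
are properties of the deposited BAC sequence and can only be recomputed
when that sequence and its exon annotation are supplied under
`inst/extdata/GU552297.*`; the package does not download. Region
boundaries are taken from exon roles, not predicted; Clustal-exact MSA
output and maximum-likelihood trees are out of scope.
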