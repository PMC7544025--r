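---
title: "Methods: diagnostic markers, phylogeny and expression for MeSA candidate genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic markers, phylogeny and expression for MeSA candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and procedures behind `mesamarker`,
the assumptions they rest on, the tunable parameters and their defaults,
the design of the synthetic-data generators, and the numerical choices
that make the pipeline deterministic. It is written for a reader who
wants to judge whether the methods apply to their own data.

## The biological setting

Birch species fall into two chemotypes: constitutive high producers of
methyl salicylate (MeSA) — *B. lenta*, *B. alleghaniensis*, *B. grossa*,
*B. medwediewii* — and low producers that synthesize MeSA only as a
defense signal. Two enzymes bracket the MeSA pool: SAMT methylates
salicylic acid to MeSA; SABP2 hydrolyses MeSA back. The analyses here
compare the candidate genes *SAMT* and *SABP2* between the chemotype
groups at four levels: nucleotide (diagnostic SNPs, heterozygosity),
phylogenetic (group monophyly), regulatory (promoter cis-element
frequencies) and transcriptional (ΔCt relative expression).

## Diagnostic markers from IUPAC consensus calls

### Data model

The unit of observation is a *consensus call*: one IUPAC character per
individual per position, as produced by Sanger sequencing of a possibly
polyploid template. A heterozygous site appears as an ambiguity code
(`S` = C/G, `R` = A/G, …). The `allele_matrix` is a long tibble
(position × individual) of such calls; `"."` denotes a missing call and
is excluded from every denominator, whereas `N` expands to all four
bases and is flagged uninformative — it can never defeat
contrast-absence, so it inflates nothing.

### Marker definition

A base $a$ is *diagnostic* for the target group at a position when

1. **contrast absence** — no non-missing contrast-group call carries
   $a$ (carriage = membership in the IUPAC expansion of the call);
2. **penetrance** — the fraction of non-missing target-group calls
   carrying $a$ is at least $\theta$; and
3. optionally, **contrast fixation** — all non-missing contrast calls
   are one identical homozygous base.

`theta = 0.9` is the default. The motivation: a 20-individual target
group with one or two non-carriers should still yield a marker (real
validation panels contain genotypically intermediate individuals), while
positions where a third or more of the group lacks the allele should
not. $\theta$ formalizes "prominent group specificity" without
per-position exceptions. At most one marker is reported per position —
the highest-penetrance allele, ties broken alphabetically (two
qualifying alleles at one position is only possible at $\theta \le
0.5$).

The carrier semantics are what make the method work on consensus data:
a high-group `S` call *carries* C, so a position printed as `S`/`C` in
the high group against `G`-fixed low producers is fully diagnostic even
though no high individual is homozygous-different at every position.

### Classification

`classify_individual()` votes across the panel positions covered by an
individual's calls; the verdict is `target` above half the votes,
`contrast` below, and `ambiguous` at an exact tie or when fewer than
three positions are covered (a two-position panel cannot outvote a
single discordant call). On the packaged 38-individual genotype table
the panel classifies 37/38 individuals with their chemotype group; the
exception is an intermediate *B. medwediewii* individual carrying the
diagnostic allele at only two positions — consistent with the proposed
hybrid origin of that decaploid species.

### A note on the published heterozygosity count

The source table's prose states that four of the six marker positions
show heterozygous calls in the high group once *B. medwediewii* is
excluded. Recomputing from the genotype table itself gives three
positions (160, 189, 304). The pipeline does not hard-code either
number: it reports the recomputed profile and writes a discrepancy note
into the run manifest's warnings.

## Distance phylogeny and the two-clade property

The tree stage substitutes p-distance + neighbor joining + bootstrap
for likelihood tree building: the property of interest — a single edge
separating the high from the low producers — is topological, a
distance method recovers it under planted group signal, and the whole
computation stays inside the package with no external binaries. The
substitution is recorded in every run manifest.

`p_distance()` offers three treatments of ambiguity codes, chosen via
`ambiguity`:

* `"overlap"` (default for general use): codes match when their
  expansions share an allele. Appropriate when ambiguity mostly encodes
  uncertainty.
* `"strict"` (default for tree building): codes must be identical. In
  this data heterozygosity itself is group-structured — the high
  producers are heterozygous at specific marker positions, the low
  producers never are — so an `S` vs `G` difference is genuine signal.
  Under overlap semantics a heterozygous carrier is indistinguishable
  from the contrast group at that site and the group signal vanishes.
* `"missing"`: pairwise deletion of ambiguous calls, as classical
  distance software does. This discards the heterozygosity signal and
  lets fully heterozygous individuals drift toward the contrast group;
  it is provided for comparability, not recommended here.

`neighbor_joining()` is the Saitou–Nei algorithm with the standard Q
criterion. Negative branch-length estimates are clamped to zero. Ties
in Q are resolved deterministically (first minimum in row-major order
over the active clusters), so a fixed input yields a bit-identical
tree; on additive matrices the generating topology and branch lengths
are recovered exactly, which the tests verify against random trees and
against the reference implementation in `ape`.

`bootstrap_support()` resamples alignment columns with replacement,
rebuilds the tree per replicate, and annotates each internal
bipartition of the full-data tree with the percentage of replicates
containing it. Bipartitions whose internal edge is (near-)zero are
treated as unresolved polytomies and not counted — identical sequences
therefore support nothing. Monophyly (`is_group_monophyletic()`) is an
unrooted bipartition question and is tested as such; outgroup rooting
is display-only.

## Protein-level comparison

`translate_cds()` uses the standard genetic code; a trailing stop is
dropped and an internal stop is an error unless explicitly allowed (then
emitted as `X`). `global_align()` is Needleman–Wunsch/Gotoh with affine
gap penalties (default BLOSUM62, gap open −10, extend −0.5 — standard
protein defaults; the published identity/coverage percentages came from
heuristic database searches and are not reproduction targets). Identity
is computed over columns excluding terminal gap runs; coverage is
query-relative, matching the BLAST reporting convention. Traceback ties
prefer diagonal, then a gap in the second sequence, so alignments are
deterministic. `check_residues()` maps annotated positions on an
ungapped reference (e.g. the tobacco SABP2 catalytic triad S81, D210,
H238) through the reference row's gaps and checks conservation in every
other sequence; the mapping is invariant to all-gap column insertion.

## Promoter scanning

`scan_motifs()` matches IUPAC consensus patterns under superset
semantics (a pattern symbol matches a base contained in its expansion),
on both strands, reporting minus-strand hits at their forward-strand
start coordinate in the compact `"74+"` / `"191-"` notation. All
overlapping hits are reported. The shipped dictionary
(`motifs.yaml`) contains published consensus strings — TATA-box
`TATAWAW`, CAAT-box `CCAAT`, ABRE `ACGTG`, G-box `CACGTG`, and others —
and is deliberately editable: commercial promoter databases do not
document their internal element definitions, so the package reproduces
the *shape* of the analysis (per-species frequency tables and group
contrasts) and makes no claim of database equivalence. Position-weight
matrices and de-novo motif discovery are out of scope.

## ΔCt relative expression

Technical replicates are averaged per biological sample
(`aggregate_replicates()`; technical SD above 0.5 cycles flags an
outlier). The reference Ct is the arithmetic mean of the housekeeping
genes' mean Cts — equivalent to geometric-mean normalization on the
expression scale; whether the two reference genes should be averaged or
used separately is not documented in the study design this emulates, so
the choice is recorded in the result's `normalization` attribute.
$\Delta C_t = C_t^{target} - C_t^{ref}$ and relative expression is
$E^{-\Delta C_t}$ with amplification efficiency $E = 2$ (the value the
classical ΔCt method implies; exposed as a parameter). Relative
expression is invariant to per-sample plate shifts, and condition ratios
equal $2^{\Delta\Delta C_t}$ by construction — both tested.

## Synthetic data: what it emulates, and what it does not

The generators exist so every stage can be exercised against known
ground truth without downloads.

`gen_gene_family()` defaults encode the study design: 20 high / 18 low
individuals across the eight birch species (6/6/4/4 + 6/4/4/4), a
792 bp SABP2-like CDS, six planted diagnostic positions at the published
coordinates with penetrance (1, 0.95, 0.95, 0.9, 0.95, 1), heterozygous
carrier rate 0.5 in the high group and zero heterozygosity in the low
group. Which individuals carry is **deterministic**: non-carriers rotate
one position at a time from the end of the high group (so penetrance
leakage never accumulates in one individual), and heterozygosity is
**position-structured** — `round(het_rate_high × n_positions)`
designated positions carry the {high, low} ambiguity code in every
carrier. That mirrors the real genotype table, where specific marker
positions are heterozygous in nearly all high-group individuals while
others are homozygous throughout, and it keeps threshold and recovery
tests exact rather than flaky; only background substitutions are
stochastic. The background substitution rate defaults to
5 × 10⁻⁴ per site — the scale of Sanger consensus error and
intraspecific silent variation — which keeps the planted group signal
the dominant polymorphism, as a planted-truth simulation requires.

What the generator does **not** emulate: species-level shared
substitutions (each individual's background is independent), indels,
alignment error, and recombination. Passing round-trip tests therefore
demonstrates correctness of the discovery/phylogeny machinery under
clean planted signal, not robustness to misalignment or to
population structure beyond the two-group design.

`gen_promoters()` plants non-overlapping motif instances at recorded
positions and strands into random backgrounds scrubbed of chance
dictionary matches, redrawing until the scanner finds exactly the
planted instances; promoter length defaults to 650 bp, within the
603–770 bp range of the study's amplicons. `gen_ct_table()` generates
$C_t = 20 - \log_2(\text{level}) + \mathcal{N}(0, 0.3)$ per technical
replicate (3 biological × 3 technical), reference genes at level 1; the
default scenario plants SAMT bark expression 8-fold over leaf in
*B. lenta*, high bark expression in both high producers, and flat SABP2
— the qualitative pattern reported for the real tissues.

## Determinism and problem sizes

Every stochastic component takes an explicit seed, and generators
restore the caller's RNG state, so a run is a pure function of
(config, seed); the pipeline writes stage outputs as TSV and a JSON
manifest (config snapshot, input/output checksums, warnings incl. the
documented deviations), and two runs with the same seed are
byte-identical. The test suite sizes are chosen to finish in minutes on
one core: NJ exactness over 50 random trees of up to 8 taxa; alignment
enumeration up to length 8 (the brute-force alignment count grows
Delannoy-fast, so most random pairs are shorter); bootstrap properties
at 100 replicates (study-scale practice is 1000; 100 resolves a
clear-cut split); strand symmetry over 1000 random sequences.

## Known limitations

* Marker discovery assumes the two groups are correctly assigned a
  priori; it quantifies penetrance but performs no significance testing
  or correction for relatedness between individuals.
* The distance phylogeny is a topology-level stand-in; branch lengths
  and supports are not comparable to likelihood analyses, and printed
  topologies involving outside reference sequences are out of scope.
* Promoter element counts depend entirely on the user's consensus
  dictionary.
* ΔCt assumes equal amplification efficiency across genes; efficiency
  estimation from standard curves is not implemented.
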