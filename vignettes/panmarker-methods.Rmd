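---
title: "panmarker: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panmarker: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Closely related bacterial species and subspecies — the *Bifidobacterium*
panel used in probiotic and dairy products is the motivating case — are
often indistinguishable by 16S rRNA or housekeeping-gene assays because
those sequences are nearly identical across the group. Whole-genome
collections make a different strategy possible: compare all annotated
genes across many genomes per taxon, find genes that every genome of one
taxon carries in near-identical form while no genome of any other taxon
carries anything similar, and build a real-time PCR assay on each such
*taxon-specific genetic marker*. panmarker implements that workflow end
to end, from gene FASTA/GFF3 input through pan-genome construction,
marker selection, primer design and in-silico specificity screening, to
qPCR standard-curve quantification and label-claim verdicts for
commercial products.

## Identity, alignment, and why the gap penalties matter

Every comparison in the pipeline uses one statistic: global
(Needleman–Wunsch/Gotoh) alignment identity, defined as

> identity = matches / alignment columns (gap columns included)

so that length mismatch is penalized — a short gene aligned into a long
one cannot score high. Scoring defaults are match +1, mismatch −1, and
affine gaps costing 10 for the first column of a run plus 1 per further
column. The gap penalties are load-bearing: with near-free gaps the
optimal global alignment of two *unrelated* random genes contains about
52% matched columns, which would sit *above* the 0.50 threshold that
separates "marker absent" from "gene family shared". Under the
needle-class defaults used here, unrelated genes of length 300–1500 nt
measure ≈0.36 (empirical max ≈0.42 over hundreds of trials), while
within-taxon copies at a 1% substitution rate measure ≥0.96 — the
statistic cleanly separates the regimes the thresholds refer to.

Among equal-score alignments the implementation reports the one with the
most matches, then the fewest columns, so identity is a deterministic
function of its inputs; the test suite verifies the compiled kernel
against an independently coded quadratic dynamic program and against
brute-force enumeration of all alignments for tiny strings.

### Seed screen

Before any alignment, candidate pairs must share at least one exact
k-mer (default k = 12). At typical gene lengths two random sequences
share an 8-mer almost surely (expected ≈12 shared 8-mers at 900 nt), so
a shorter seed would prune nothing; at k = 12 random pairs seed with
probability ≈0.05 while every pair above the 0.5 identity threshold in
realistic conditions seeds with near certainty. The screen is part of
the method's hit definition: a non-target gene that shares no seed with
a marker candidate is "no hit" and contributes a cross identity of 0.
For very low rejection thresholds (`id_cross` < 0.3) that certificate is
no longer meaningful, so the cross screen then falls back to exhaustive
alignment; this is why a degenerate `id_cross = 0` run rejects
everything rather than accepting unseeded candidates. Tests run the
clustering and selection with the screen disabled to confirm on fixtures
that it only prunes.

## Pan-genome clustering and partition

Genes are clustered by greedy incremental centroid clustering: processed
in deterministic order (length descending, gene id as tie-break), each
gene joins the first existing centroid with identity ≥ the clustering
threshold (default 0.50, the conventional pan-genome setting), otherwise
it founds a new cluster. This mirrors the widely used centroid
clusterers while staying simple enough to verify exactly against a
naive re-implementation, which the tests do for desk-scale inputs. The
clusters-by-genomes copy-count matrix then yields the classic partition:
*core* clusters present in every genome, *unique* clusters present in
exactly one, *accessory* the rest; and per-taxon cores (clusters present
in at least `presence_fraction` of a taxon's genomes, default 1.0).

The strict `presence_fraction = 1` default is deliberate. When a marker
is missing from part of its labeled taxon the usual cause is a
mislabeled genome, and the remedy this package recommends is the
phylogenetic audit (below) followed by relabeling — not loosening the
presence requirement, which silently degrades assay sensitivity.

## Phylogenetic label audit

Two trees are built by neighbor joining (exact on additive matrices;
negative branch estimates are clamped to zero and logged): a *pan
tree* from Jaccard distances on binary cluster presence ("1 − shared /
union", the frequency view of the pan-genome), and a *core tree* from
1 − mean pairwise identity over core clusters in which both genomes are
single-copy (paralogs are excluded per pair). A multiple sequence
alignment stage was considered and rejected: only the tree's grouping
behavior is consumed downstream (does each labeled taxon form a clade?),
and mean pairwise identity preserves exactly that at a fraction of the
cost. `monophyly_report()` checks each taxon for an edge bipartition
isolating its genomes and names the foreign genomes inside the smallest
spanning clade otherwise — the tool for spotting mislabeled genomes
before they poison the strict taxon core.

## Marker selection

For each target taxon, every taxon-core cluster is screened:

* `within_min_identity` — the representative aligned against the best
  gene of each target genome, minimized over genomes; must be ≥
  `id_within` (default 0.90);
* `cross_max_identity` — against every gene of every non-target genome;
  must be ≤ `id_cross` (default 0.50);
* replicon — any target copy on a plasmid-flagged contig rejects the
  candidate, and an operator-supplied mobile-element FASTA rejects
  candidates aligning at ≥ 0.80 to any entry (plasmid and prophage
  screening against external databases is the operator's
  responsibility; the package consumes the resulting sequence set).

The 0.90/0.50 values are exposed as thresholds with overrides. The
screen is gene-level, not cluster-level, so a non-target gene that
failed to co-cluster still rejects a candidate. For rejected candidates
the scan stops at the first disqualifying hit (the recorded cross value
is a witness of rejection); for accepted candidates the maximum is
exhaustive, and the tests re-verify accepted markers by brute-force
alignment against all non-target genes.

## Primer design and the conservation mask

Primer pairs are designed per marker by exhaustive window scanning:
oligo lengths 18–24 nt, nearest-neighbor Tm within 58–62 °C, GC fraction
0.40–0.60, homopolymer runs ≤ 4, hairpin stem ≤ 6, pair dimer score ≤ 8
(complementarity scores are maximal antiparallel complementary run
lengths, with runs anchored at a 3′ end weighted double), and product
size 80–200 bp. The 200 bp cap keeps amplification efficient from
processed-food DNA; the 80 bp floor keeps products separable from primer
artifacts in SYBR-type assays. Pairs are ranked by Tm balance, then by
distance of the mean Tm from the 60 °C annealing step, then by product
size, with coordinates as the final deterministic tie-break.

Melting temperatures use SantaLucia (1998) unified nearest-neighbor
parameters with terminal initiation terms, the entropic salt correction
ΔS + 0.368 (N−1) ln[Na⁺], and Tm = 1000·ΔH / (ΔS + R ln(C/4)) − 273.15
at the assay conditions (0.5 µM of each primer, 50 mM monovalent salt);
a Wallace-rule method is included for quick estimates.

The pipeline computes a *conservation mask* per marker — the positions
at which every target-genome copy agrees with the representative — and
requires oligo windows to sit entirely on conserved positions. This is
standard strain-tolerant assay practice, and it is what makes perfect
in-silico sensitivity a designed property rather than luck: without the
mask, a 1% within-taxon substitution rate gives each 3′-anchored binding
site about a 2% per-genome failure probability, and some strain of some
taxon would eventually escape its own assay.

## In-silico PCR

The binding model is deliberately conservative and standard: no indels,
at most 2 substitutions per oligo, and zero mismatches in the
3′-terminal 2 bases (mismatches there abort extension in practice). All
convergent, non-overlapping forward/reverse site pairs within 1500 bp
are reported on both strands. The site search is verified against a
naive all-position scan, and the hit set is invariant (with coordinates
remapped) under reverse-complementing every contig.
`specificity_matrix()` summarizes, per primer pair, sensitivity
(fraction of target genomes amplified) and specificity (fraction of
non-target genomes not amplified).

## qPCR quantification and label-claim verdicts

Standard curves are ordinary least squares of Ct against log10
concentration (log10 CFU/mL); R² is the squared Pearson correlation,
with a warning below the conventional 0.98 reliability floor;
amplification efficiency is (10^(−1/slope) − 1)·100, 100% meaning
perfect doubling (slope −1/log10(2) ≈ −3.32). Quantification inverts the
curve and flags values outside the 8×10⁵–8×10⁹ CFU/mL dynamic range as
extrapolated rather than suppressing them. The detection cutoff defaults
to Ct 35 — the assay's cycle count.

Label-claim comparison is a total, deterministic four-verdict rule:
all-non-specific labels ("Lactic acid bacteria", "Bifidus") are
`unverifiable_label` with detections attached; each labeled subspecies
must be detected exactly while a labeled species is satisfied by itself
or any of its subspecies; an unsatisfied label or an uncovered detection
is a `mismatch`; otherwise `consistent`, or
`consistent_with_refinement` when a species-level label was resolved at
subspecies level. Two points were genuinely open and are decided here:
mixed non-specific + specific labels let the non-specific token cover
otherwise-uncovered detections (with a note) rather than forcing a
mismatch, since such a token claims unspecified additional organisms;
and the package reports counts per verdict rather than a single
"consistent" tally, because any one-number summary hides exactly the
species-to-subspecies refinements that make the assay interesting.

## The synthetic-data generator

`simulate_pangenome()` generates the study conditions the tests run
under: labeled genomes built from a genus-wide core (per-taxon variants
at a cross-taxon branch substitution rate, default 0.45), planted
taxon-specific markers (independent sequences per taxon, present in
every genome of the taxon and nowhere else), randomly distributed
accessory families (each genome carries a given family with probability
0.3), and decoy families present in *all* genomes whose cross-taxon
pairwise identity is driven into a 0.65–0.85 band — squarely between the
0.50 rejection and 0.90 acceptance thresholds, so a correct screen must
reject them on identity, not on presence. Genes are concatenated into
1–3 contigs with random 50–200 nt spacers, placed on either strand with
probability 0.5, and a configurable fraction of genomes receives a
plasmid contig carrying accessory genes to exercise the mobile-element
filter. Default sizes (3 taxa × 3 genomes, 12 core + 3 markers/taxon +
12 accessory + 6 decoy families, genes 300–1500 nt) are desk-scale:
large enough that seed screens, length pruning and tie-breaks all
exercise, small enough that the whole suite runs in minutes on one CPU.

Substitutions only, by default: every identity band above is then
analytically controllable (copies stay equal length, alignments stay
essentially ungapped), which is what lets the generator *prove* its
planted-marker contract — within-taxon identity ≥ 0.90, cross-taxon
≤ 0.50 under the pipeline's own identity definition — empirically on
every emitted set, redrawing a violating family from the same RNG
stream and counting regenerations. One seeded generator drives all
draws in a documented order, so identical specs give byte-identical
files.

What the generator does *not* emulate: genome rearrangement, horizontal
transfer networks, annotation error, sequencing error, and indel
variation (the indel channel exists but defaults to off). Passing tests
therefore demonstrate that the method implements its stated
discrimination contract, not that 90/50 are the right thresholds for
any particular real genus — on real data the decisive step remains the
phylogenetic label audit plus the operator's exclusion FASTA.

## Numerical and scale choices

Alignment statistics are computed in a packed-integer dynamic program
(Rcpp) with exact lexicographic tie-breaks; there is no banding or
heuristic truncation, so oracle-equivalence tests can demand exact
equality. Test and acceptance workloads use 5 taxa × 4 genomes with 3
planted markers per taxon and 20 decoy families (≈770 genes per
replicate) — chosen so the full recovery check over 10 seeds, the
end-to-end assay run, and the unit suite complete in roughly a quarter
hour on a single core. Nothing in the code is fixture-specific, so
collections of hundreds of genomes are supported in principle; they are
simply not test targets at desk scale.

## Known limitations

* Protein-space clustering is out of scope; all comparisons are
  nucleotide-level and coding-strand oriented (inputs are annotated
  CDS, so orientation is canonical).
* Dimer/hairpin scoring is a complementarity-run heuristic, not a
  thermodynamic secondary-structure model; borderline oligos deserve a
  dedicated folding check.
* The in-silico binding model ignores indels and degenerate bases
  (degenerate codes are legal in genomes but mismatch everything except
  themselves, and are illegal in primers).
* Efficiencies recomputed from published slopes printed at 3 decimals
  inherit that rounding (≈±0.017% in the efficiency); agreement beyond
  it is not attainable from the printed values.
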