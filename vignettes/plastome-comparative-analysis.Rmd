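---
title: "Comparative plastome analysis with plastomics: models, parameters and design"
author: "plastomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis with plastomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
```

## Scope

`plastomics` implements the quantitative core of a comparative plastome
study: quadripartite structure and IR-junction analysis, microsatellite and
dispersed/tandem repeat detection, alignment-based SNV/InDel
characterization with per-region mutation rates, sliding-window nucleotide
diversity with hotspot calling, a complete codon-usage-bias suite, and
pairwise Nei–Gojobori Ka/Ks with functional-category comparisons. A
synthetic plastome evolver generates annotated quadripartite genomes along
a phylogeny with a ground-truth event log, so every statistic in the
package can be validated end to end without downloading any sequence data.

This vignette documents the models, the parameters that matter (with their
defaults and why), the numerical choices, and what the synthetic data do
and do not establish about real plastomes.

## Genome model and coordinates

Internally all intervals are 0-based half-open and may wrap the origin of
the circular molecule; every user-facing report is 1-based inclusive, the
GenBank convention. GenBank `join(...)`/`complement(...)` locations are
parsed into ordered interval lists; a `join(n..L, 1..m)` pair on a circular
record is collapsed into a single origin-wrapping interval. Translation
uses the plastid/bacterial genetic code (table 11), whose
codon-to-amino-acid map coincides with the standard code, so the classic
synonymous-family structure (59 synonymous codons; Met, Trp and stops
excluded) applies throughout.

Coding sequences enter the codon-usage suite only if they are longer than
300 bp, start with ATG, are not pseudogenes, and have length divisible by
three; IR-duplicated genes are deduplicated by (symbol, sequence) identity.
Alternative starts (GTG/TTG) are excluded rather than translated, matching
the screening rule the package is built around. Ambiguity codes are kept in
sequences but excluded position-wise from GC, codon and variant
computations.

`feature_context()` classifies a position as exon, intron, RNA gene or
intergenic with that precedence; introns are either annotated explicitly or
inferred as the gaps between a spliced feature's intervals.

## Quadripartite structure

`detect_partition()` searches for the longest pair of inverted repeats with
at most `max_mismatch` mismatches (default 0) and at least `min_ir` bases
(default 1000), using exact k-mer seeding (k = 25) between the sequence
and its reverse complement. Seed matches are grouped by diagonal; a
diagonal is examined only if it carries at least
`min_ir − max_mismatch − (k−1)(max_mismatch+1)` seeds, a pigeonhole bound
that any qualifying IR pair must satisfy, which keeps the scan fast on
low-complexity genomes. On each candidate diagonal, maximal windows with at
most `max_mismatch` mismatches are enumerated from the sorted mismatch
positions. The longer single-copy segment is labelled LSC and the IR copy
that follows it in circular order IRb, giving the canonical order
LSC→IRb→SSC→IRa; a genome without a qualifying pair yields a
"no structure" result rather than an error. Neither a minimum IR length nor
a mismatch tolerance is a published constant of the analyses the package
reproduces; the defaults are the package's own and are exposed as
parameters.

Junction reports name the four junctions JLB, JSB, JSA and JLA. A gene
ending exactly at a junction belongs to the upstream region; a spanning
gene is reported with its per-region split lengths (which always sum to
its span), otherwise the nearest gene on each side is reported with its
distance. Pseudogene fragments (e.g. an IR copy of ycf1) participate, and
an overlap flag marks features that overlap each other across a junction.

## Repeats

**SSRs** follow MISA semantics: maximal perfect tracts of primitive 1–6 nt
motifs with per-class minimum copies (10, 5, 4, 3, 3, 3). Copies count
complete units only; a partial trailing unit neither adds a copy nor
extends the reported locus. Primitivity prevents an (AT)n tract from also
being reported as (ATAT)m. Compound loci are *not* merged — the merging
conventions of MISA versions differ, and reporting individual loci makes
counts reproducible; this is the main source of any small discrepancy
against compound-merging tools. Scanning is linear, mirroring the cited
tools' treatment of the linearized molecule.

**Dispersed repeats** are maximal pairs of the four REPuter kinds
(forward, reverse, complement, palindromic) with length ≥ 30 and Hamming
distance ≤ 3 (90% identity at the minimum length). The scanner
seed-and-extends: exact seed k-mers shared between the sequence and its
transform are collapsed into runs, extended in 256-base blocks under the
mismatch budget, and expanded into all maximal windows; containment-
redundant pairs are removed and identical-coordinate self pairs dropped.
With seed length ≤ ⌈(min_len − e)/(e + 1)⌉ (the default up to 10 kb) the
scan is provably complete; for longer sequences a sparser seed (12) is
used, complete for any pair containing an exact 12-base stretch — the
standard seeded-search trade-off. Note that *maximal* k-mismatch windows
around a planted exact repeat legitimately extend into flanking sequence
until the budget is exhausted, and several distinct maximal windows can
cover one biological repeat; counts are therefore of maximal windows, as
in REPuter.

**Tandem repeats** are exact arrays of primitive 7–100 nt units with ≥ 2
(possibly fractional) copies; overlapping calls resolve to the longest
span, then the smallest unit. This is an exact-array simplification —
TRF's probabilistic alignment model is out of scope, so imperfect arrays
are split at their mismatches.

## Variation

Variant calling consumes a multiple alignment (the package never aligns;
aligner choice is the dominant source of irreproducibility in published
comparisons, so it is left explicit). Against a chosen reference row, each
maximal run of gap columns in the sample is one deletion, each maximal run
in the reference one insertion, and substitution columns are individual
SNVs — adjacent SNV columns are never merged. Columns gapped in both rows
or containing ambiguity codes are skipped and counted. InDels are
left-aligned within homopolymer/repeat context, the usual normalization;
an insertion is anchored to the reference base it follows (0 = before the
first base). Per-kb rates divide region counts by region length in kb,
with the two IR copies pooled; when several samples are pooled the
orchestrator also reports the per-sample mean, which is the quantity most
comparative studies print.

Sliding-window nucleotide diversity uses 600 bp windows with 200 bp steps.
Within a window, columns containing any gap or ambiguity are excluded for
all pairs (complete deletion), and π is the mean over all sequence pairs
of differences per usable site. Windows are placed on alignment columns by
default, with a reference-coordinate mode (the published parameter pair is
stated for the windows; whether they were alignment- or
reference-anchored is not, so both modes exist). A final partial window is
kept when at least half the window length remains — a rule of this
package. Consecutive windows with π strictly above 0.010 merge into
hotspots annotated with overlapping (or nearest) features. One invariant
sometimes claimed for π — that duplicating every sequence leaves it
unchanged — does not hold under the distinct-pairs estimator used here
(duplicate pairs contribute zero differences), so the suite tests
permutation invariance instead.

## Codon usage

RSCU is observed count over the family-uniform expectation; observed
families therefore always have mean RSCU 1. The third-position
compositions T3s/C3s/A3s/G3s follow classic usage-index semantics: each
base's frequency is taken over the synonymous codons whose family permits
that base at the third position. ENC is Wright's statistic from
per-family homozygosities averaged within degeneracy classes
(2-fold ×9, Ile alone as the 3-fold class, 4-fold ×5, 6-fold ×3), with
Wright's substitution of (F̄2 + F̄4)/2 for a missing 3-fold class; any
other missing class leaves ENC undefined, and values are capped at 61.
The expected-ENC curve is the standard
`2 + GC3s + 29/[GC3s² + (1 − GC3s)²]`, and the ENC deviation is
(ENCexp − ENCobs)/ENCexp. PR2 coordinates default to Sueoka's
construction over the eight fourfold-degenerate codon boxes, with an
all-synonymous-codons mode since published descriptions are often
ambiguous on this point.

Optimal codons use the ΔRSCU procedure: genes are ranked by ENC, the
lowest-ENC 5% tail is taken as the high-expression set (strongest bias —
the standard codon-bias reading of "high expression"; a switch inverts
it), the highest-ENC tail as the low-expression set, ties at the cut
included; a codon is optimal when its RSCU in the high set exceeds 1 and
the high-minus-low difference exceeds 0.08. The "RSCU > 1" clause is
evaluated in the high-expression set by default, with an overall-RSCU mode
provided. CAI uses relative adaptiveness w = RSCU_ref/max-in-family over
the high-expression reference, with w = 0.01 for codons unobserved in the
reference (families wholly unobserved are excluded); Fop is the fraction
of synonymous codons that are optimal; CBI is (Nopt − Nrand)/(Ntot −
Nrand) restricted to families containing an optimal codon. Correlations
among indices are Pearson by default (Spearman available).

## Selection

Ka/Ks is pairwise Nei–Gojobori (1986): fractional synonymous site counts
per codon position (changes to stops count as nonsynonymous), averaged
over both sequences; multi-hit codons are resolved by averaging over
shortest mutational pathways, excluding pathways through stop codons
whenever a stop-free pathway exists; Jukes–Cantor correction
d = −(3/4)ln(1 − 4p/3) with p ≥ 3/4 flagged undefined. Ks = 0 yields an
undefined ratio (never ∞), and genes with undefined ratios are excluded
from group tests but counted. NG86 mirrors the default pairwise method of
the software most such studies cite; model-based estimators are out of
scope. Note that a synonymous codon *exchange* spanning two positions
(e.g. the two serine boxes) legitimately produces a nonzero Ka under
pathway averaging; only single-step synonymous changes leave Ka at exactly
zero.

Functional categories follow the conventional plastid split:
photosynthesis (psa*, psb*, pet*, ndh*, atp*, rbcL), self-replication
(rpl*, rps*, rpo*, infA), and other (matK, ccsA, cemA, accD, clpP, ycf*,
…). Group comparisons are two-sided rank-sum tests, exact by full
enumeration of the rank-sum distribution (midranks for ties) when the
combined sample size is ≤ 20, else the normal approximation, with the
usual star codes.

## The synthetic evolver: what it emulates

`build_root_genome()` assembles a quadripartite genome whose defaults are
the study conditions of a typical Engelhardia-like plastome: LSC 90 kb,
SSC 19 kb, IR 26 kb (161 kb total), a ~95-gene model with real plastid
gene names and typical lengths, introns in the usual genes, a
junction-spanning rps19 (LSC/IRb) and ycf1 (SSC/IRa) with their IR
pseudogene fragments, planted SSR tracts (defaults: 40 tracts,
A/T-dominated, allocated ~72/20/8% to LSC/SSC/IR), one planted forward
and one palindromic dispersed repeat, and six fast-evolving intergenic
spacers emulating mutation hotspots. IRa is the exact reverse complement
of IRb, and the inner junction flanks are adjusted so the planted IR pair
is not extendable — without this, boundary-recovery would fail for the
uninteresting reason that a chance flanking match makes a longer IR the
true maximum.

Coding sequences are synthetic ORFs (start, no internal stops, stop):
codons are sampled with AT-biased first/second positions and a per-gene
third-position bias whose strength is gamma-distributed and whose
direction is jittered per gene. The strength drives a realistic ENC
spread while the jitter keeps family preferences from being perfectly
concordant across genes; both are needed for the codon suite to face
data of realistic difficulty.

`evolve_along_tree()` applies, per branch: HKY-like substitutions
(rate 0.008/site/unit branch, ts/tv = 2), insertions and deletions
(rate 0.0014/site, geometric lengths of mean 4 — real plastome InDels are
dominated by 1–2 bp slippage events, with a long tail), and SSR slippage
(0.3/tract/unit, ±1 unit). Region multipliers make the IR evolve at 0.1×
the single-copy rate and suppress InDels in coding sequence (×0.05);
hotspot spacers run at 4×. Purifying selection is emulated by rejection:
a substitution that would change the amino acid is accepted with
probability 0.12 (photosynthesis genes), 0.35 (self-replication) or 0.5
(other), and changes creating stop codons are always rejected. These
acceptance probabilities were chosen once to place Ka/Ks in the band
comparative plastome studies report (almost all genes < 1, photosynthesis
most constrained) and are not tuned thereafter. Copy correction mirrors
every IR event into the partner copy (complemented, coordinate-mirrored),
reproducing the concerted evolution that keeps real IR copies identical;
it can be switched off. Deletions never straddle region junctions, which
keeps planted boundaries meaningful; substitutions are applied to root
coordinates only (inserted material does not mutate further), an accepted
simplification at these divergences. The default tree has 13 shallow
ingroup accessions in nested clades plus one distant outgroup
(root-to-outgroup ≈ 1.1 expected substitutions per site ×0.008), sized so
that outgroup-referenced SNV densities and ingroup π land in the range
genus-level plastome comparisons report.

Every event is logged in root coordinates with a global id;
`replay_events()` rebuilds any tip from the log alone, and the suite
asserts byte-identity against the emitted tips. The emitted "true"
alignment allocates one column per root position and one block per
insertion event, so the variation module's calling conventions recover
the log exactly when events are non-adjacent.

**What passing tests do not show:** the synthetic genomes have uniform
base composition within each region class, no rearrangements or gene
loss, no sequencing or assembly error, no annotation error, and true
alignments. Results on real data inherit none of these guarantees — in
particular, aligner choice and annotation quality will dominate variant
and junction calls long before any limitation of these implementations.

## Problem sizes and numerical choices

The test suite exercises the full 161 kb study scale once through the
orchestrator and otherwise uses a reduced "mini" gene model (~21 kb
genome, same architecture including both junction genes) so that
100-replicate property checks (boundary recovery, variant
recall/precision, IR-conservation recovery) run in minutes. Oracle
comparisons use 5 kb sequences for the SSR scanner and 2 kb for the
dispersed-repeat scanner at a reduced (min_len 12, 2-mismatch) setting —
smaller windows make the exhaustive oracles affordable while exercising
every code path. Exact rank-sum enumeration switches to the normal
approximation above a combined n of 20 (choose(20,10) ≈ 1.8×10⁵
enumerated subsets). Floating-point comparisons in tests use 1e-9 or
tighter where hand-derived values exist.

## Known limitations

- The tandem detector is exact-array only; imperfect arrays are split.
- Compound SSRs are reported as separate loci by design.
- GenBank support covers the feature subset plastome annotations use;
  trans-spliced locations (`order(...)`, multi-record joins) are treated
  as plain interval lists.
- The evolver does not model rearrangement, IR expansion/contraction, or
  substitution on inserted material.
- `detect_partition()` reports the single best IR pair; genomes with
  multiple near-equal inverted repeats keep only the longest.
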