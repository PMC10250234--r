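---
title: "Models and methods behind rrnflank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rrnflank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rrnflank` analyses the RNA regions that flank bacterial 16S rRNA genes in
the primary *rrn* transcript: the leader (carrying *boxB*, *boxA*, *boxC*
and the local helices hA, hB, h0) and the trailer, which together form the
long leader–trailer helix (hLT) processed by RNase III. This vignette
explains each model, the parameters that matter, and what the synthetic
benchmark does and does not establish.

## Anchored flank extraction

Extraction is pure window arithmetic on the gene's sense strand
(minus-strand genes are reverse-complemented first; all internal
coordinates are 0-based half-open, converted to and from GFF3's 1-based
inclusive convention only at I/O):

* the trailer anchor `AAGUCGUAACAAGGUA` is searched from 100 nt upstream
  to 200 nt downstream of the annotated 3' end (exact match by default;
  the hit nearest the annotated 3' end wins, ties broken upstream-first);
  the trailer is the sequence at 1-based positions 51–107 downstream of
  the match start (57 nt). Counting from the match start places the
  default trailer at 16S-numbered positions 1543–1599 in E. coli, the
  trailer interval mutagenesis experiments target; counting from the
  match end is available via `trailer_from = "end"`.
* *boxC* (`UCUGUGUGGG`, Hamming distance ≤ 2, no indels) is searched where
  its match start lies 90–257 nt upstream of the annotated 5' end (bounds
  inclusive); the 3'-most match wins. The leader runs from 23 nt upstream
  of the match to the 18th gene nucleotide.
* pairs with leader + trailer < 350 nt are discarded (`too_short`);
  kept pairs are joined as `leader + NNNNNN + trailer`.

These defaults are internally tense: a 57-nt trailer plus the 350-nt
filter keeps only pairs whose *boxC* lies ≥ 252 nt upstream, although
*boxC* sits much closer in E. coli. The package deliberately keeps the
published geometry verbatim, surfaces the discard tally in the extraction
report (`glance()` on the result), and makes every window a configuration
knob (`extraction_config()`), so any consistent geometry runs correctly.
Genes whose required windows come within 5 nt of a contig edge are
reported `Truncated`, never silently clipped; a motif that is not found
inside a window clipped by a contig edge is likewise reported `Truncated`
rather than `NoAnchor`/`NoBoxC`.

## Structure primitives

Folding uses a declared per-basepair pseudo-energy model (GC/CG −3, AU/UA
−2, GU/UG −1 arbitrary units, kT = 1) rather than nearest-neighbour
thermodynamics: the package's claims are about covariation and geometry,
not folding free energies, and a transparent model keeps every number
reproducible by enumeration. Structures are nested sets of canonical
pairs (wobble included) with a minimum hairpin loop of 3 nt — the standard
steric minimum — and N never pairs.

* `nussinov_fold()` maximises pair count with a deterministic traceback
  (smallest 5' index first, then smallest partner).
* `enumerate_structures()` (guarded to 16 nt) is the exhaustive oracle the
  tests compare everything against.
* `basepair_probs()` runs a McCaskill-style inside–outside recursion over
  exactly the same structure space, with per-length scaling against
  overflow (scales 1–16 are tried; failure is an error, not a wrong
  number). The tests require agreement with enumeration Boltzmann
  frequencies to 1e−9.
* `duplex_align()` performs a local alignment of leader (5'→3') against
  trailer (3'→5') scoring GC/AU +2, GU +1, mismatch −2, gap −3. On
  genome-scale flanks a maximal local duplex legitimately extends a
  planted helix through cheap mismatches, so duplex length comparisons
  against a fixed threshold are made either on genome-scale plants well
  above/below the threshold or on minimal constructs whose background
  cannot pair (A-runs against A-runs).

## Structure-aware clustering

The distance between two NNNNNN-joined flank pairs is
`D = 1 − (w_seq·S_seq + w_str·S_str)` with equal default weights.
`S_seq` is affine-gap global-alignment identity in which columns touching
N carry no credit and do not enter the denominator — the 16S placeholder
cannot drive clustering. `S_str` compares per-position pairing
probabilities (row sums of the basepair probability matrix) along the same
alignment. The two sequences are put in a canonical order before aligning
so the distance is exactly symmetric. This profile-based distance replaces
Sankoff-class simultaneous alignment-and-folding (RNAclust/LocARNA),
which is quartic-time and far beyond desk scale at ~350 nt × hundreds of
sequences; the substitution is validated only on synthetic data and is
never claimed to reproduce any published tree.

Trees are built by hand-rolled agglomerative linkage (WPGMA by default,
matching the weighted-average family; single/complete/average available)
with a documented deterministic tie-break — at equal distance the cluster
pair whose lexicographically smallest member labels sort first merges
next. The result is a valid `hclust` object (heights = merge distances);
ultrametric node heights (half the distances) are what `write_newick()`
serialises. `cut_tree(tree, k)` removes the k−1 highest merges; k is a
user choice, mirroring the fact that published clade counts for such trees
come from manual inspection.

## Consensus structure and covariation

Per clade, sequences are progressively aligned along the guide tree
(match +2, mismatch −1, gap open −4, extend −1, N neutral,
"once a gap, always a gap"); with two sequences this is an optimal global
alignment, and on the indel-free synthetic data it is gap-free, making
alignment columns identical to template coordinates.

Consensus folding maximises, over nested column-pair sets, the sum of
`s(i,j) = f_can + β·(n_types−1)/5 − γ·f_mm` for admitted pairs
(`f_can ≥ τ`; defaults τ = 0.5, β = γ = 1), plus a helix-continuity bonus
δ = 0.5 for each directly stacked pair. The continuity term is this
package's design choice: without it the optimum is massively degenerate —
a conserved alignment offers thousands of isolated chance-complementary
column pairs with the same per-pair score as true helix pairs — and the
maximiser has no reason to prefer a long supported helix over scattered
complementarity. δ plays exactly the role stacking energies play in
thermodynamic alignment folding; δ = 0 recovers the bare per-pair
objective.

For every consensus pair, `covariation_stats()` counts `n_types`, the
distinct **ordered** canonical pair types across rows (GC ≠ CG, GU ≠ UG —
ordering is what makes six classes attainable), and `n_mismatch`, rows
non-canonical **or gapped** at either column. Colour encodes `n_types`
(red 1, yellow 2, green 3, cyan 4, blue 5, magenta 6) and tint encodes
mismatches (full 0, medium 1, light 2, white ≥ 3); tint is categorical
because the exact shading of published figures is presentation, not data.
Helices are contiguous stacked runs with a one-residue bulge tolerance;
the largest helix whose arms straddle the all-N spacer columns is labelled
hLT.

## hLT features

`profile_flank_pairs()` reports the duplex basepair count with the
functional threshold applied as a strict inequality (`hlt_bp > 17`),
*boxA* detection (default motif `UGCUCUUUAACA`, the E. coli *rrn* boxA
consensus from the antitermination literature, ≤ 2 mismatches, best =
fewest mismatches then 3'-most, restricted upstream of the *boxC* match),
and the *boxA*–*boxC* spacing counted as nucleotides strictly between the
elements ("18 or 19 nt" phrasing; a start-to-start measure is a config
option). Note that under the default 23-nt leader pad a 12-nt *boxA* at
18–19 nt spacing cannot lie inside the extracted leader; spacing analyses
therefore use a wider pad (the examples use 60 nt), which the
configuration supports directly.

## The synthetic benchmark

`flank_template()` lays out an ancestor locus mirroring the E. coli
architecture: boxB hairpin (6 bp), *boxA*, 18-nt spacing, an hLT 5' arm of
25 bp containing *boxC*, hA (6 bp), hB (9 bp), h0 (9 bp pairing the last
leader nucleotides with gene nt 9–17), a random 1542-nt gene body whose
only non-random element is the 3'-terminal anchor (placed so the default
trailer slice starts exactly at the gene end, as in E. coli), and a
trailer arm complementary to the 5' arm. The default *boxC* distance of
255 nt keeps planted pairs above the verbatim 350-nt filter. An exact
decoy *boxC* is planted at distance 300 — outside the legal window — to
exercise the window logic.

`simulate_phylogeny()` draws rescaled random-coalescent clade subtrees of
height 0.1 attached by long stems near total depth 1 — the
long-stem/short-intra-branch shape that makes clades separable.
`evolve_flanks()` substitutes sites independently at 0.2 substitutions per
site per unit branch length; substitutions at planted paired sites are
mirrored at the partner with compensatory probability 0.8, else the
mismatch stands; motif sites only accept substitutions within their caps
(anchor 0, *boxA*/*boxC* 2), and a compensation blocked by a cap rejects
the whole substitution. The rate was set to give ~18% root-to-leaf
divergence, in the range of within-family variable-region divergence, and
to keep permanently broken planted pairs rare — the generator's purpose
is to emulate covariation-*supported* helices. There are no indels, so
alignment truth is exact and covariation tests are sharp; an indel mode
would be an extension. The generator also rewrites accidental in-window
*boxC* look-alikes in evolved filler (repairing any planted pair it
touches), because the recovery contract — 100% recovery with exact
coordinates — is only meaningful when the planted element is the unique
in-window match.

What passing the synthetic benchmark shows: the extraction geometry,
window logic, strand handling and reporting are correct; the distance,
tree and cut recover planted population structure; consensus folding with
the covariation score finds planted helices and scores their pair-type
diversity correctly. What it does not show: performance on real genomes —
real flanks have indels, annotation-boundary noise, horizontal transfer
and thermodynamics the simple energy model ignores; clade assignments on
real data would likely differ from Sankoff-class tools. Sizes used in the
tests (50 genomes for recovery, 4 clades × 10 leaves × 10 seeds for clade
recovery, ~360-nt combined sequences) are desk-scale choices that keep
the whole suite in a few minutes while leaving every statistic
well-resolved.

## Numerical and degenerate-input choices

* Hamming-only motif matching; an N in the haystack mismatches everything;
  IUPAC codes other than N are rejected (strict default) or mapped to N
  (lenient).
* Partition-function scaling retries 1–16 before erroring; probabilities
  are exact inside–outside values, not samples.
* All DP tracebacks have documented deterministic tie-breaks; permuting
  input order changes no distances and no memberships.
* Empty consensus structures, single-leaf trees (`"label;"` Newick
  dialect), header-only TSVs and empty duplexes are all representable and
  tested.
* `k` outside 1..n leaves, unknown contigs, features past contig ends,
  unbalanced consensus brackets and unknown configuration keys are errors
  by contract; per-gene extraction failures are recorded, never fatal.
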