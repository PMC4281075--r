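---
title: "Mate-pair aware reconciliation of taxonomic read assignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mate-pair aware reconciliation of taxonomic read assignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(binpairs)
```

## The problem

Paired-end sequencing yields two reads per DNA fragment, and both mates
therefore come from the same organism. Most taxonomic binners nonetheless
classify each mate independently, so the two assignments of one pair often
disagree: one mate lands at species level while the other stops at order, or
one mate is left unassigned entirely. `binpairs` exploits the pairing
constraint *after* binning: it reconciles the two assignments of every pair
using only the taxonomy, so it can be layered on top of any binner
(alignment-based, composition-based or hybrid) without touching the binner
itself.

## Rank algebra

All operations live on the seven-level canonical ladder

> superkingdom > phylum > class > order > family > genus > species

with "lower" meaning more specific. The package assigns each rank an ordinal
(species = 1 ... superkingdom = 7) and places the root at 8. Real taxonomies
contain nodes outside this ladder (`no rank`, strains, clades); those are kept
in the tree but are transparent to the algebra: `canonical_rank()` projects
every node onto its nearest canonically-ranked ancestor-or-self, and
`step_up()` climbs to the next canonical rank actually present on the lineage,
skipping gaps. The root doubles as the representation of "unassigned", which
gives one uniform rule set below.

## The reconciliation rules

Let the two mates X and Y be assigned taxa Tx and Ty, with Tx the more
specific of the two after canonical projection.

* **Divergent lineages** (neither assignment is an ancestor of the other):
  both mates are moved to the lowest common ancestor of Tx and Ty, whatever
  the strategy. If that ancestor is the root, both come back unassigned.
* **Same taxon or both unassigned**: the pair is returned unchanged.
* **Same lineage** (one assignment a strict ancestor of the other, which
  includes the case of one unassigned mate, whose assignment is the root):
  the four strategies are
  * `SI` - both mates take Tx (most specific; rescues an unassigned mate to
    its partner's taxon);
  * `SII` - the specific mate keeps Tx, the other moves to the intermediate
    level Tx+1;
  * `SIII` - both mates move to Tx+1;
  * `SIV` - both mates take Ty (most conservative; a pair with an unassigned
    mate comes back entirely unassigned, which is why this strategy leaves
    the largest unassigned fraction).

Tx+1 is `step_up(Tx)` clamped at Ty: when Tx and Ty are on adjacent canonical
ranks, a single step would overshoot Ty, so SII and SIII degenerate to SIV
there. The strategy is a run-level parameter: one strategy per invocation.

Two structural guarantees follow from these rules and are enforced by the
test suite: every output taxon is an ancestor-or-self of at least one input
taxon (reconciliation never invents specificity), and if both inputs lie on
the truth lineage then so do all outputs (two correct assignments cannot be
turned into a wrong one). Per-mate specificity is monotone along
SI, SII, SIII, SIV.

One design choice was genuinely open: what SI-SIV should do when exactly one
mate is unassigned. We model the unassigned mate as an assignment to the
root, which makes the case an instance of the same-lineage rule with
Ty = root. This choice makes SI recover the unassigned mate and makes SIV
discard the assigned one - the asymmetry between the most and least
aggressive strategies that motivates having four of them.

```{r}
tax <- toy_taxonomy()
reconcile_pair(tax, 561, 91347, "SII")   # genus keeps, order -> family
reconcile_pair(tax, 562, 1313, "SI")     # divergent: both -> Bacteria (2)
reconcile_pair(tax, 561, NA, "SIV")      # unassigned mate wins under SIV
```

## The simulator

`sim_config()` captures the validation conditions as defaults: 20,000
fragments of exactly 400 bp sampled in equal proportions from the reference
genomes (counts differ by at most one; the remainder goes to the first
genomes in input order), 2x150 bp short clones cut from either end of each
fragment, and 2x150 bp long clones whose outer insert span is uniform on
2000-5000 bp. Sequencing error is substitution-only at 0.01 per bp: each base
independently mutates to one of the three *other* bases, so the configured
rate equals the expected observed mismatch rate exactly; `N` positions are
untouched and indels are not modelled. Fragment lengths are fixed rather than
drawn from a distribution (a uniform +/-10% jitter option exists but is off
by default). Mates are mutated independently rather than inheriting the
parent fragment's errors, since each sequencing read carries its own errors;
pass unmutated fragments from `sample_fragments()` to the clone builders.

Coordinates are 0-based half-open on the forward strand; mate 2 is
reverse-complemented (FR orientation, the Illumina paired-end convention).
The long-clone insert span is measured outer edge to outer edge, which makes
the 2-5 kbp bound directly checkable on the truth table. A distal mate that
would overrun the genome is re-drawn on the other side of mate 1; pairs that
fit neither way are skipped with a warning. All datasets are byte-identical
under a fixed `seed`; the clone builders derive their streams from
`seed + 1` and `seed + 2` so the three datasets are mutually independent.

`synth_genomes()` supplies reference genomes so no downloads are needed. With
`ancestral_sharing = 0` the genomes are independent uniform-random sequences -
"well separated", in that a k-mer classifier recovers the source organism
perfectly in the absence of noise. A positive sharing fraction assembles that
proportion of each genome from pools attached to the organism's canonical
ancestors (shared verbatim by all organisms under that ancestor), emulating
conserved sequence: reads from shared blocks are genuinely ambiguous and get
classified to inner nodes of the taxonomy. Random genomes do not reproduce
real genome composition (GC structure, repeats, mobile elements), so passing
tests demonstrate the correctness of the machinery under the stated model,
not classifier performance on real data.

## The fixture binner

`kmer_index()`/`assign_reads()` form a deliberately simple shared-k-mer
classifier (canonical k-mers, k = 12 by default) used to exercise the
pipeline end to end; it is test scaffolding, not a method of interest, and
not competitive with real binners. A read goes to the top-scoring genome's
organism when the runner-up scores below `(1 - margin)` of the top (margin
0.2 by default), to the LCA of all near-top organisms otherwise, and comes
back unassigned with no shared k-mers at all. The optional
`rank_degrade_prob` moves each final assignment up one canonical rank with
the given probability, emulating the rank-varying, partially unassigned
outputs of real binners - exactly the disagreement pattern the strategies
repair.

## Evaluation

`judge()` scores an assignment as correct when it lies on the truth lineage
(ancestor-or-self of the source organism's taxon). Correct assignments are
bucketed by the canonical rank of the assigned node - genus-and-below,
family/order, class/phylum - wrong assignments and unassigned reads get their
own buckets, and correct superkingdom-level assignments are kept in a
separate `superkingdom` bucket rather than folded into a neighbouring one
(the bucketing convention of this package; percentage tables print to one
decimal place). `summarize_assignments()` tallies a whole run over the truth
table, counting reads missing from the assignment table as unassigned, and
`compare_summaries()` reports per-bucket deltas and ratios (a ratio over a
zero before-count is reported as missing rather than infinite).

## Problem sizes and numerical choices

The test suite validates the strategy rules exhaustively (all 289 ordered
assignment pairs over the 16-taxon fixture taxonomy, times four strategies,
against an independent brute-force transcription of the rules) and the LCA
operator on 100 random trees of up to 200 nodes against lineage
materialization. The simulator fidelity check runs the full 20-genome,
20,000-read/pair configuration (8 Mbp of fragment sequence); mutation-rate
recovery is accepted within three binomial standard deviations. The
end-to-end directional check uses a three-organism community of 100 kbp
genomes with 50% ancestral sharing, 2,000 short-clone pairs, and a binner
degradation probability of 0.4; it asserts directions only (SI strictly
increases the number of correct assignments; SIV leaves the most reads
unassigned), never magnitudes, because the magnitudes depend on the
degradation model.

Ties in the binner's margin rule resolve toward the LCA (ambiguity is made
explicit rather than broken arbitrarily); equal-rank same-lineage pairs are
by construction the same taxon after projection and are returned unchanged;
`lca()` is implemented by depth equalization and joint ascent, which is exact
on any rooted tree.

## Limitations

The package reconciles *existing* assignments; it contains no alignment or
composition machinery and does not implement score-combining approaches that
merge the mates' alignment scores before assignment. Confidence weighting of
the two mates, per-pair strategy auto-selection, abundance-skewed
communities, platform-specific error profiles and indel errors are out of
scope. Taxonomy handling rejects unknown ids rather than consulting
merged/deleted-node histories.
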