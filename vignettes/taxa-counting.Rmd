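---
title: "Counting taxa with specific-peptide markers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting taxa with specific-peptide markers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spcount)
```

## The model

A *specific peptide* (SP) is a short deterministic amino-acid word whose
exact occurrence in a protein marks membership in a particular enzyme
family (an EC number). `spcount` works with SPs of the S61 set: markers
of the aminoacyl-tRNA synthetases EC 6.1.1.x, enzymes that occur as
single-copy genes on essentially all bacterial genomes. Single-copy is
the load-bearing assumption: if two sequences carry the same SP but
cannot come from the same protein, they must come from *different
genomes*, i.e. different taxa.

Metagenomic reads or contigs are translated in all six frames
(`six_frame_translate()`), the SP table is searched on every putative
peptide (`find_sp_hits()`), and all sequences sharing one SP are aligned
by that SP — the anchor. Two anchored sequences are **consistent** when
they agree at every position of their overlap; consistent sequences may
be **fused** into a longer string that could be part of one protein.
Inconsistent sequences demand distinct source proteins. The minimal
number of mutually inconsistent fused strings is therefore a *lower
bound* on the number of taxa in the sample.

Formally, with vertices the sequences and edges the inconsistent pairs,
the bound is the chromatic number of the inconsistency graph: each
colour class is a mutually consistent set, fusable into one string.
Graph colouring is NP-hard in general, but the anchored-string structure
makes realistic instances easy; the package ships both an exact
backtracking solver for small instances (`chromatic_number_exact()`,
capped at 18 vertices) and the fast heuristic used in practice
(`count_taxa_heuristic()`).

Only SPs of length \(\ge 9\) residues are used on reads (the package
default `min_length = 9`): a 9-mer has random-occurrence probability
\(20^{-9}\) per position, so chance hits are negligible, and such an SP
occurs at most once per gene — which is what lets each hit anchor the
coordinate frame. For whole-protein analyses a length-7 table may be
loaded instead; `evaluate_specificity()` quantifies what that costs.

## The counting heuristic

`count_taxa_heuristic()` proceeds in four steps:

1. **First pass.** Sequences inconsistent with *all* others are counted
   and removed; each is certainly its own taxon.
2. **Blocks.** The remainder splits into connected components of the
   consistency graph. Sequences in different blocks can never fuse, so
   blocks are processed independently.
3. **Fusion.** Within a block, sequences are placed one at a time into
   compatible fused strings; substrings are absorbed; a sequence
   compatible with several strings extends the one yielding the longest
   fusion (ties toward the string holding the earliest input).
4. **Reiteration.** Any two resulting strings that are still consistent
   are merged; this repeats to a fixpoint. The final strings are
   asserted pairwise inconsistent.

One design choice was genuinely open: the *order* in which step 3 takes
the sequences. Processing purely by decreasing length — with the
extension choice otherwise arbitrary — provably wastes colours on
path-like conflict structures: with reads `r1 ~ r2`, `r1 ~ r4`,
`r2 ~ r3` but `r1 × r3`, `r2 × r4`, `r3 × r4`, taking `r1` then `r2`
first welds the two path endpoints together and forces three strings
where two suffice. `spcount` therefore orders sequences within a block
by *conflict saturation* — the number of existing strings a sequence is
inconsistent with — breaking ties by length and then input order (the
DSATUR rule from graph colouring, which is optimal on bipartite conflict
structures). The block/fusion/reiteration frame is unchanged. With this
order the heuristic matched the exact chromatic number on 200 random
simulated-read instances and on 200 adversarial near-duplicate
instances (see `test-acceptance.R` and `test-taxa_count.R`); without it,
about 3% of instances came out one or two colours too high. The
heuristic remains a heuristic: its count is always a valid partition
size (hence still a correct *upper* bound on the optimum and a valid
taxa lower bound — coarsening a partition never invalidates
inconsistency), but no optimality guarantee exists beyond the empirical
agreement.

Exactly identical duplicate reads are collapsed before the graph is
built and re-attached to the absorbing string's member list.

## Distance-resolved counting

Fused strings from one SP group are compared by **anchored Hamming
distance** (`anchored_hamming()`): the number of differing residues on
the anchored overlap, with the wildcard `X` excluded. Counting at
*minimal distance d* collapses strings that are fewer than `d`
substitutions apart, trading strain resolution for robustness:

* `count_at_min_distance(m, d)` implements the index-pair removal: list
  all pairs at distance `<= d` as (shorter-index, longer-index) rows,
  take the unique indices of each column, remove the smaller set (ties
  toward the left), and iterate on the residual pairs until none
  remain. Survivors are certified against the matrix to be pairwise
  `> d` apart.
* `count_curve(strings, d_max)` reports, for each `d`, the number of
  strings pairwise `>= d` apart — i.e. removal at threshold `d - 1` —
  so the `d = 1` point is the plain count of mutually inconsistent
  strings (which are at distance `>= 1` by definition). Removal is
  applied cumulatively in `d`, making the curve non-increasing by
  construction.

Two numerical caveats are worth knowing. First, the removal rule keeps
a *large* set of pairwise-distant strings (it approximates a maximum
independent set; `count_at_min_distance_exact()` quantifies the gap on
up to 25 strings). Keeping many strings can be counter-intuitive: for a
"star" of one long hub string with several satellites each at distance
1 from the hub but 2 from each other, removal at `d = 1` removes the
*hub* and keeps the satellites. Second, pairs whose anchored overlap is
only the SP span itself have distance 0 and no discriminative signal;
they are flagged in `distance_matrix()$sp_only`.

The strain/species thresholds themselves (e.g. distance \(\le 2\)
separating strains for glutaminyl-tRNA synthetase data, none existing
for the valyl enzyme) are empirical properties of reference data, not
constants of the algorithm; they enter only as the `d` argument the user
chooses.

`subsample_counts()` repeats the whole pipeline on random subsamples of
size `S` (20 trials by default) and reports mean and standard error per
`d`, which is how depth-dependence is examined.

## Error model and calibration

Sequencing and translation errors are modelled as independent
per-residue substitutions at rate `p` (`inject_errors()`); indels are
excluded deliberately, since an indel breaks the anchor coordinate
system and the whole method with it. A substitution inside the SP span
destroys recruitment: by default such sequences are dropped (expected
fraction \(1-(1-p)^L\)). For calibration experiments that inject errors
into an *already recruited* set — where the SP search is not re-run —
`drop = FALSE` keeps them, and `error_shift_check()` uses that mode.
This distinction matters: dropping reads thins the sample and biases
subsampled counts low by roughly the drop fraction, which is a
recruitment effect, not a counting effect.

The calibration claim exercised in the acceptance suite is: counting at
`d >= 2` on data with 1% injected errors approximates the error-free
count at `d >= 1`, because an erroneous read typically sits exactly one
substitution away from its taxon's string and is absorbed by the
distance-1 removal. The property is statistical, not exact; its known
systematic residues at read length 24 are (i) reads drawing two or more
errors (probability \(\approx \binom{15}{2}p^2 \approx 1\%\) at
\(p=0.01\)) survive a `d >= 2` filter, and (ii) at high per-taxon
coverage several single-error reads of one taxon form mutually
distance-2 satellites that the star-removal behaviour keeps. Both are
small at the sample sizes and coverages the short-read setting
produces, and the acceptance test verifies the claim within two
standard errors over 20 trials on a 120-taxon world.

`inequality_probability()` addresses a different calibration question:
what read length can distinguish which taxonomic ranks. For a pair of
proteins it slides every window of `W` residues along the shorter one
and counts windows absent from the longer; the aggregate fraction
`P_ine = N_dif / Sigma` is the probability that a read of length `W`
separates the pair. For a fixed window start the no-match indicator is
monotone in `W`; the aggregated `P_ine` is monotone in practice because
window counts shrink only by one per unit `W`.

`evaluate_specificity()` estimates SP false-positive rates on an
annotated genome: hits are mapped back to nucleotide coordinates, genic
hits split into TP/FP by EC agreement, and intergenic hits — a natural
negative set — are scaled by the genic/intergenic length ratio into the
expected number of random genic false positives (EFP, rounded). On the
published *E. coli* benchmark this formula reproduces the printed EFP at
L = 8 and L = 10 but gives 432 where 413 is printed at L = 7; the
formula is implemented as stated and the discrepancy left alone.

`match_to_reference()` profiles novelty: for each query read the best
reference match is found (anchored at shared SP occurrences by default,
all embeddings with `free_offset = TRUE`; query positions hanging off
the reference count as mismatches) and the fraction of queries matched
within `k` mismatches is tabulated for `k = 0..k_max`.

## The synthetic world

`simulate_taxa_proteins()` generates `K` proteins with one shared SP at
a common offset and independently drawn random flanks, rejection-sampled
until every pair differs at `min_pair_distance` positions or more
(default 10, the scale separating genuinely different species in
reference data) with at least `near_sp_fraction` of that minimum inside
one read length of the SP — the property that makes the taxa
distinguishable from SP-recruited short reads. Defaults: 120-residue
proteins, 24-residue reads (the short-read length of the motivating
data), uniform read starts constrained to cover the SP, and uniform
synonymous codons for nucleotide output (codon bias is irrelevant to
every downstream computation).

What the generator deliberately does **not** emulate: realistic
abundance distributions (coverage is uniform per taxon), indels and
chimeras, quality-score structure, strain mixtures at small distances,
or homology between taxa (flanks are independent, so inter-taxon
distances are near-maximal). A green recovery test therefore
establishes that the pipeline counts what the model plants — `K`
mutually distinguishable single-copy genes — not that real communities
are this easy. Conversely the lower-bound property (`count <= K`) is
model-free: colouring reads by their true source is always a proper
colouring.

`simulate_annotated_genome()` concatenates reverse-translated genes
(each closed with a `TAA` stop) with random spacers and emits the
matching genic/intergenic annotation, giving `evaluate_specificity()` a
ground-truthed fixture.

## Degenerate inputs and numerical choices

* Empty inputs: empty read files warn and return empty collections; an
  empty anchored set counts zero taxa.
* Ambiguity: `N`-containing codons translate to `X`; `X` never matches
  an SP, matches anything in consistency, is overwritten in fusion and
  excluded from distances — ambiguity can merge taxa but never create
  one, preserving lower-bound semantics.
* Stops: `*` is an ordinary mismatching symbol; a stop inside an SP span
  is rejected as a contradiction.
* Rare letters: `U`/`O` become `X` on input; `B`/`Z`/`J` are kept as
  distinct symbols that match only themselves.
* Ties are broken deterministically everywhere (lexicographic SP choice,
  earliest-input string preference, left column in pair removal) so that
  fixed seeds give bit-identical output.
* The exact colouring solver refuses more than 18 vertices; the exact
  independent-set check refuses more than 25 strings. Both caps are
  arguments.

## Known limitations

* The bound is only as single-copy as the marker set; paralogues or
  horizontal transfer of a synthetase would inflate counts.
* Fusion is anchored and single-SP; it is not a general assembler, and
  sequences recruited by different SPs of one EC are reconciled only
  through the length-cutoff aggregation (`aggregate_lower_bound()`,
  default cutoffs 700/500/450 residues for EC 6.1.1.9/6.1.1.18/6.1.1.3).
* Short reads cannot separate strains; large-`d` counts on short reads
  approximate family-level counts rather than species.
* The heuristic count equals the exact chromatic number on every tested
  instance class but carries no worst-case guarantee.
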