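---
title: "Exome matching: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exome matching: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomatch)
```

## The problem and the model

Dietary protein quality is a 20-dimensional balancing problem: an animal
needs amino acids (AA) roughly in the proportions in which it
incorporates them into protein, and the essential amino acids (EAA) it
cannot synthesise set a hard stoichiometric ceiling on how much biomass —
eggs, somatic growth — a given food can support. *Exome matching* takes
the organism's own genome as the estimate of that requirement: translate
every protein-coding gene in silico, compute each protein's proportional
AA usage, and average over proteins. The resulting 20-vector `p` is the
reference requirement profile; a diet is summarised the same way as a
molar proportion vector `d`.

The package's central quantity is the limiting score

$$ r = \min_i \; d_i / p_i $$

taken over the EAAs, with the convention that the conditionally essential
amino acids tyrosine (made from phenylalanine) and cysteine (made from
methionine) draw on their precursor mole-for-mole when the diet
undersupplies them: for a precursor--dependent pair $(P, D)$ the
constraint is $d_P/p_P$ while the dependent is in surplus
($d_D/p_D \ge d_P/p_P$) and pools to $(d_P + d_D)/(p_P + p_D)$ otherwise.
`r` predicts the output attainable on the diet relative to a perfectly
matched one, and its argmin is the limiting amino acid. This is Liebig's
law of the minimum applied to amino-acid stoichiometry, and it is
deliberately linear: doubling the limiting amino acid's supply (with
everything else fixed) doubles predicted output, until the next
constraint binds.

Two conventions are worth stating explicitly. When a pooled pair
constraint binds, the *precursor* is reported as the limiting amino acid,
because supplementation must come through the precursor. And a diet with
zero supply of an essential amino acid yields `r = 0` rather than an
error — "no output" is the model's genuine prediction for a deficient
diet.

## Building the exome profile

`exome_profile()` reads a protein FASTA, strips trailing stop symbols,
and removes extreme-length translations before averaging: proteins
shorter than `min_len` (default 100 residues) or longer than `max_len`
(default 2000) are dropped, with boundary lengths retained (only strictly
shorter/longer sequences are removed). Extremes are trimmed because very
short and very long translations would otherwise distort the average
usage. Non-canonical symbols (B, J, O, U, X, Z) occur in real proteome
files; they are excluded from both numerator and denominator of every
proportion rather than raising an error, and a tally is carried in the
profile's provenance.

The averaging step is genuinely ambiguous and the package supports both
readings:

* `mean_of_proportions` (default): the unweighted arithmetic mean of
  per-protein proportion vectors — every gene counts equally;
* `pooled_counts`: total residue counts across proteins, normalised —
  genes weighted by length.

The two coincide exactly when all proteins have equal length (a property
the test suite checks), and differ little on realistic length
distributions. The default is `mean_of_proportions` because the
per-gene reading matches the idea that each gene contributes one protein
requirement; the mode used is always recorded in the output provenance,
so downstream results are attributable to one or the other.

Multiple isoforms per gene are kept as separate records by default; the
package does not attempt to guess an isoform-collapsing rule from
identifiers, and callers who want one-protein-per-gene should filter the
FASTA beforehand.

## Diet recipes and units

Recipes arrive either as g/L of free amino acid or as molar proportions
(`diet_recipe()`, `read_diet_tsv()`). Mass amounts are converted with
built-in free (unhydrated, non-salt) L-amino-acid molecular weights;
chemically defined media often supply some amino acids as salts or
hydrates, so `recipe_to_profile()` accepts a user override table where
exactness matters. All scoring is done on the molar scale. Whether a
published breakpoint was computed on the mass or the molar scale cannot
be decided in the abstract; the package computes on molar proportions
and the conversion layer lets users feed in either representation of the
same recipe to compare.

## Supplementation: breakpoints and response curves

`breakpoint()` answers: by what fold `x` can the limiting amino acid be
added before something else becomes limiting? Supplementation is modelled
as multiplying only that amino acid's dietary amount by `x`, holding all
other amounts fixed — the total mass rises slightly. The alternative
(renormalising to constant total) was rejected because it would change
every `d_i`, which is not what single-amino-acid supplementation
experiments do. Scores are therefore recomputed un-renormalised: every
other constraint is constant in `x`, the supplemented one rises, and

$$ x^\* = \frac{r_{\text{next}}}{d_{aa} / p_{aa}} $$

where `r_next` is the minimum over the constraints not involving the
supplemented amino acid. One subtlety: if the limiting amino acid is a
conditional-pair precursor whose *pooled* constraint binds, the rising
constraint is affine rather than linear in `x`
($(x\,d_P + d_D)/(p_P + p_D)$), and the package inverts the exact
piecewise-linear function instead of using the closed form; the two
agree whenever the limiting amino acid is unpaired. `response_curve()`
evaluates the same algebra on a grid — output rises with the supplemented
constraint and plateaus at `r_next` — and accepts an optional empirical
ceiling (for example, a maximum output level observed on rich food)
which caps the curve at `ceiling / r` on the relative scale.

`fold_change(diet1, diet2, exome)` returns
`output(diet2)/output(diet1) = r2/r1`. The direction is fixed and
documented here because a ratio of limiting scores is otherwise easy to
read both ways.

## Designing a maximally mismatched control

A fair "mismatched" control diet should be exactly as far from the
requirement profile as an existing mismatched diet, while sharing as
little as possible with it. `design_mismatch()` formalises this: given
reference A and source B on the 20-simplex, find C with
$\lVert C-A\rVert = \lVert B-A\rVert$ (Euclidean, one dimension per amino
acid), $C \ge 0$, $\sum C = 1$, maximising $\lVert C-B\rVert$.

The reflection $C = 2A - B$ preserves the sum constraint automatically
and is the unconstrained global optimum, giving
$\lVert C-B\rVert = 2\lVert B-A\rVert$ exactly; it is returned verbatim
whenever it is non-negative, and the `feasible_reflection` flag records
which branch ran. When some coordinate of the reflection is negative the
problem becomes maximisation of a linear function over a sphere cut by a
polytope — non-convex, with optima on faces of the non-negativity
boundary. The solver combines, deterministically:

* exhaustive active-set enumeration (both branches of the sphere slice on
  every face) for alphabets of up to six letters, which makes the
  low-dimensional case exact;
* for the full alphabet, greedy active-set paths, a penalised multistart
  (16 deterministic starts ordered by how badly the reflection violates
  each bound), and projected-gradient ascent with an
  alternating-projection repair, anchored at the always-feasible point
  C = B.

The equidistance constraint is verified to `tol` (default `1e-8`) and a
violation is an error, never silently accepted. There is no randomness
anywhere in the solver, so identical inputs give identical designs. On
three-letter instances the solution matches a dense grid-search oracle to
better than `1e-3`; on the full alphabet, optimality is not certified
(the test suite checks equidistance, simplex feasibility and
no-shrinkage, i.e. the design is at least as far from B as A is).

## Ranking genes and the mean-rank null

`rank_by_similarity()` scores every gene by the Euclidean distance
between its AA proportion vector and the exome average (rank 1 = most
similar). The metric is recorded in the output; Euclidean distance on
proportion vectors is the default because it matches the geometry used
for the mismatch design, but nothing in the test depends on that choice.
Ties get average ranks for statistics and stable ordinal ranks (by
distance, then gene identifier) for display.

`set_mean_rank_test()` asks whether a gene set's mean rank is smaller
(more exome-like) than expected under uniform sampling without
replacement of same-size sets. The null moments of the sampled mean rank
are exact — mean $(N+1)/2$, variance $(N-n)(N+1)/(12n)$ — and the normal
approximation applies a continuity correction of one half on the
rank-sum scale before standardisation. The permutation route draws
seeded random sets and reports the add-one estimate
$(1 + \#\{\text{perm} \le \text{obs}\})/(1 + B)$, which is never exactly
zero. The test is one-sided by construction. Calibration is checked
empirically: over ten thousand random sets the null p-values are uniform
within Kolmogorov–Smirnov tolerance, and on a ten-gene universe the
permutation estimate agrees with exhaustive enumeration of all
$\binom{10}{3}$ subsets. All permutation draws restore the caller's RNG
state afterwards.

## The synthetic proteome generator

`make_synthetic_proteome()` stands in for a real proteome download in
tests, examples and the acceptance script. It emulates the features of a
proteome that this package actually consumes: a length distribution with
exact counts in the short (< core minimum), core, and long (> core
maximum) strata; per-protein AA compositions drawn from a Dirichlet
distribution centred on a global composition; residues placed by
multinomial draw and shuffled. Defaults were chosen once, on biological
plausibility: the global composition is a typical eukaryotic proteome
usage (Swiss-Prot-style frequencies, `typical_proteome_composition()`),
the Dirichlet concentration is 50 (per-protein usage dispersion of a few
percentage points around the mean, comparable to real between-protein
variation), short-stratum lengths are 30–99 and long-stratum lengths
2001–4000 residues. The generator is seeded explicitly, byte-identical
across runs for a fixed seed, and leaves the caller's RNG state
untouched.

What it does *not* emulate matters for interpreting green tests: real
proteomes have domain structure, low-complexity regions, codon- and
GC-content-driven compositional covariance between amino acids, and
isoform redundancy. A passing test on synthetic data validates the
arithmetic and the bookkeeping of the pipeline, not the biological
accuracy of any particular organism's requirement profile.

The validation suite exercises the documented proteome scale — 21,070
proteins of which 821 fall below 100 residues and 513 above 2,000,
leaving 19,736 — as the package's reference problem size for the
length-filter bookkeeping; the rank-test calibration uses universes of
1,000–2,000 genes with sets of 50.

## Packaged recipes

`packaged_recipes()` is a registry for diet formulations transcribed from
published tables. Transcription is deliberate: recipes are only ever
entered from a concrete published table with a provenance note, never
fabricated, and this installation ships with the registry empty —
requesting a recipe raises an explicit "not packaged" error. Users with
access to a published formulation can supply it as a TSV via
`read_diet_tsv()` and obtain every downstream analysis unchanged;
the pipeline and all scoring functions are indifferent to whether a
profile came from the registry or a file.

## Degenerate inputs and numerical choices

* Profiles must sum to one within `1e-9` after construction; all
  constructors renormalise.
* A zero exome proportion for an essential amino acid is an error (the
  model cannot demand zero of an essential input); a zero dietary supply
  gives `r = 0` with that amino acid limiting.
* Ties at the minimum are resolved to the full tie set, reported in
  canonical alphabet order (`ACDEFGHIKLMNPQRSTVWY`), with the first
  element as the nominal limiting amino acid; the tie tolerance is
  `1e-12` relative.
* `design_mismatch(A, A)` returns A with all distances zero, flagged
  degenerate.
* `breakpoint()` for a limiting amino acid with zero dietary supply is an
  error, since fold-multiplication of zero cannot relieve the
  limitation; with no other essential constraint the breakpoint is
  infinite.

## Known limitations

* The requirement profile is unweighted by expression: transcript or
  protein abundance weighting is intentionally out of scope.
* The model is stoichiometric only — no absorption kinetics, no
  microbial contribution, no toxicity terms, and no prediction for
  traits (such as lifespan) that do not respond to AA ratio.
* Optimality of the constrained mismatch design is certified only in low
  dimension; in 20 dimensions the deterministic multistart is a strong
  heuristic with verified feasibility.
* No published diet formulations ship with the package (see above), so
  analyses of specific published diets require the user to transcribe
  the corresponding tables.
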