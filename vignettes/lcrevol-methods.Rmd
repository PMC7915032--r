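---
title: "Methods: detecting and comparing low complexity regions across orthologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and comparing low complexity regions across orthologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcrevol)
```

## Scope and assumptions

`lcrevol` analyses low complexity regions (LCRs) in families of aligned
orthologous proteins. It deliberately consumes, rather than computes,
the upstream artifacts that have mature dedicated tools: ortholog
inference, multiple sequence alignment, coiled-coil prediction and
energy-based disorder prediction all enter as files. Everything
downstream — feature detection on individual sequences, projection onto
the alignment, conservation profiles, enrichment, co-occurrence and
co-evolution — is implemented and tested here.

Two structural assumptions run through the package:

* a fixed, ordered ten-species panel (`species_panel()`, human first).
  Conservation profiles are strings with one symbol per panel species,
  so their order must be identical everywhere; the panel is therefore a
  package constant rather than a parameter.
* 1-based inclusive coordinates throughout, in two frames: sequence
  positions (gap-free) and alignment columns. `build_coordinate_map()`
  converts between them; conversion to 0-based indexing never leaks out
  of internal array arithmetic.

## Feature detectors and their parameters

### Homorepeats (polyX)

A residue type X forms a homorepeat wherever a window of
`polyx_window = 10` consecutive residues contains at least
`polyx_min_count = 8` copies of X. Qualifying windows for the same X
that overlap or abut are merged, and the merged span is trimmed so it
starts and ends on X. The 8-in-10 rule tolerates short interruptions
(e.g. `PPPPPPAPQP` is one polyP) while excluding diffuse composition
bias; the trimming rule guarantees that reported intervals begin and end
on the repeated residue, which is how such regions are conventionally
quoted. Sequences shorter than the window are scanned as a single
truncated window when at least 8 residues long, so degenerate inputs
are total rather than errors. Homorepeats of different residues may
overlap; they are never merged across residue types.

### Compositionally biased regions (CBR)

Bias detection follows the CAST idea: score every residue of the
sequence against a homopolymer of residue X with BLOSUM62 and take the
maximal-scoring contiguous segment (running sum reset at zero — the
classic maximal-segment recurrence). The scan iterates globally: among
all 20 residue types, the best-scoring segment is found; if its score
reaches `cast_threshold = 40` it is emitted as `CBR:X`, occurrences of X
inside the emitted interval are masked to score zero against every
target, and the search repeats until the best remaining score falls
below the threshold.

Two design points deserve justification:

* *Global ordering.* Emitting the globally best residue type first, and
  only then rescanning, attributes a region to the residue that
  dominates it. A per-residue-type-independent scan would mis-fire: a
  pure-alanine region scores +1 per residue against serine, so a long
  polyA tract would be called S-rich as well — and since the region
  contains no serine to mask, such a scan cannot even terminate. The
  global iteration masks at least one residue per emission, so
  termination is guaranteed.
* *Neutral masking.* Masked positions score 0 against every target
  rather than a penalty. This keeps already-attributed composition from
  being counted twice while not artificially splitting the remaining
  signal. A side effect is that segments of a second residue type may
  bridge across a masked region; this is intended — a region can
  genuinely be rich in two residues.

Ties in the maximal-segment recurrence are resolved to the segment with
the smallest end position (the update is strict), so results are
deterministic and endpoints always score strictly positively.

### Intrinsically disordered regions (IDR)

IDRs are maximal runs of at least `idr_min_length = 30` residues whose
per-residue disorder score is at least `idr_score_threshold = 0.5`.
Scores are expected from an external per-residue predictor through
`read_disorder_profile()` (3-column `position residue score` files; the
residue column is cross-checked against the sequence, and mismatches are
errors rather than warnings because a silently shifted profile corrupts
every downstream coordinate). The 0.5 cutoff is the conventional
midpoint of normalized disorder scores; the 30-residue floor suppresses
the very short runs that most predictors emit as noise.

For corpora without predictor output, `fallback_disorder_scores()`
provides a smoothed residue-propensity scale (centered moving average,
width 21, truncated at the ends, clamped to [0, 1]). It is an
order-of-magnitude stand-in for testing the machinery — it preserves the
ranking of strongly ordered versus strongly disordered composition but
is *not* an energy-based predictor, and analyses that depend on
predictor fidelity must use the adapter.

### Coiled coils (CC)

CC intervals are ingested annotations (`read_feature_annotations()`),
never predicted; heptad-repeat prediction is a solved problem elsewhere
and re-implementing it would add nothing but version skew.

## Consolidation and conservation profiles

For one ortholog group and one feature kind, every per-sequence interval
is translated to alignment columns (interior gap columns are spanned, so
an interval stays one contiguous run of columns) and the union of
covered columns is taken. Each maximal contiguous run of covered
columns is one consolidated feature. Its conservation profile assigns,
per panel species: `1` if that species contributes a feature overlapping
the run by at least one column, `0` if the species is present in the
group without such a feature, `-` if the species is absent from the
group. One shared column suffices for a `1` — the simplest reading of
"the interval contains a feature for this species" — and kinds are
consolidated independently (an A-rich CBR and a polyA are different
kinds even though they often overlap). Union intervals separated by a
single uncovered column are *not* merged; the union is taken literally.

Consolidation is idempotent and independent of sequence input order, and
every covered column lies in exactly one consolidated interval; these
invariants are enforced by property tests.

## Enrichment

`hypergeom_upper_tail(k, n, K, N)` is the exact upper tail
`P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, evaluated through the
log-space distribution function so that tails around 1e-100 are exact to
double precision (values below the double denormal range necessarily
underflow to zero).

`enrichment_pvalue()` fixes the tabulation convention for comparing a
foreground set against a background proteome whose counts *include* the
foreground: the foreground's feature-positive proteins are subtracted
from the background feature count while the background total stays the
proteome size, i.e. the one-sided Fisher table is
`[k, n-k; K-k, N-K]`, equivalently `P(X >= k)` for
`X ~ Hypergeometric(N + n - k, K, n)`. This is the convention under
which the package's reference statistics were validated; the pure
hypergeometric primitive remains available for other designs. Raw
p-values are the primary output (a Benjamini–Hochberg column is appended
for convenience only).

## Co-occurrence and the conserved A-rich cascade

Presence vectors are built from raw per-sequence features — one 0/1
entry per feature kind per individual sequence, orthologs included —
because co-occurrence is a statement about individual proteins, not
about consolidated family-level features. The co-occurrence matrix is
all-pairs Jaccard over the 42 kind rows, with the empty-union score
defined as 0.

The cascade that searches for interactors resembling a diffusely
alanine-rich, proline-punctuated binding mode proceeds in four
monotone stages on the consolidated tables: (s1) groups with an A-rich
CBR; (s2) those where some A-rich CBR is conserved in at least four
species (counting `1`s in the profile, human included); (s3) those where
such a region overlaps no consolidated polyA by even one column, however
conserved the polyA — this separates diffuse bias from plain
homorepeats; (s4) those additionally containing any consolidated polyP,
however conserved. Group-level polyP presence (rather than adjacency to
the A-rich region) is the filter; observed bordering is a finding to
report, not a criterion.

## IDR co-evolution

Each present species contributes a binary profile over alignment
columns: 1 where the column holds a residue inside an IDR, 0 at other
residues and at gaps. Every unordered species pair (45 for the
ten-species panel, fixed order) is scored by the Jaccard overlap of the
two profiles. A pair is non-informative (`NA`) when a species is absent
or when *both* profiles are empty — two proteins with no predicted
disorder are not evidence of similarity; one empty against one non-empty
scores 0.

Long proteins can be split into fragment groups (`split_fragments()`)
along intervals of the human sequence translated through the human
coordinate map; all species are retained in each column slice, including
fully gapped ones (they then yield non-informative pairs). The default
`htt_fragments()` table encodes the five large huntingtin regions
delimited by its long disordered insertions (1–402, 403–970, 971–1330,
1331–2080, 2081–3142).

Profiles are clustered with complete linkage on a pairwise-deletion
Euclidean distance: coordinates informative in both profiles enter the
sum of squares, which is rescaled by `sqrt(45 / n_shared)`. Rescaling
keeps fully informative pairs at their plain Euclidean distance while
preventing profiles that share only a few informative cells from looking
spuriously close; zero-filling the missing cells was rejected because it
would make missingness itself look like dissimilarity. A pair with no
shared informative coordinate receives the maximal attainable distance
`sqrt(45)` with a warning. Rows are sorted by identifier before
clustering so the dendrogram does not depend on input order; the number
of flat clusters is a user parameter (`k`), as no principled cut height
exists for these profiles.

## The synthetic-data generator

`group_plan()`/`gen_group()` build ortholog groups directly in a shared
column frame: planted features are specified in alignment columns,
species-specific indels are realized as gap blocks, and the alignment is
therefore exact by construction. No aligner runs, which removes aligner
nondeterminism from every test. Defaults: 10-species panel, uniform
background composition (a rough human-proteome composition is
available), 600 columns.

Plant realization is designed so that a noiseless plan has an exhaustive
truth table:

* polyX plants at purity 1 are contiguous runs of the residue; at purity
  p < 1 each column keeps the residue with probability p.
* CBR plants are *diffuse*: every second or third column (purity ≤ 0.5
  or above) is replaced by a residue drawn from the set scoring strictly
  negatively against the plant residue, which caps the local density
  below the homorepeat rule — a diffusely biased region should not also
  be a homorepeat. W and C are excluded from that set because their
  large self-scores could otherwise accumulate into their own segment
  once neighbouring emissions are masked.
* every polyX/CBR plant gets a 3-column flank of such residues: a
  10-window reaching past a 3-column flank can hold at most 7 plant
  residues, so the homorepeat rule cannot recruit flanking background,
  and the negative scores stop maximal-segment creep.
* a pure homorepeat long enough to clear the CBR threshold is, by
  definition, also a compositionally biased region; the truth table
  expects this co-detection (unless a wider CBR plant of the same
  residue already covers it).
* the background is scrubbed: columns where the realized sequence would
  still yield a polyX or CBR call outside planted-plus-flank columns are
  deterministically resampled (bounded rejection under the plan's seed),
  so planted truth is exhaustive and "no plants" really means "no
  features".
* planted IDRs are expressed through emitted per-residue score files
  (0.9 inside, 0.1 outside); CC plants are emitted as annotation rows.

Generation is byte-deterministic under the plan seed, including all
emitted files. `evaluate_recovery()` scores pipeline output against the
truth table with interval matching at reciprocal overlap ≥ 0.9, exact
profile comparison, presence-matrix agreement, cascade stage agreement
and a Rand index for cluster labels.

What the generator does *not* emulate: phylogenetic substitution
processes (background columns are independent across species), sequence
fragments and mistranslations, alignment errors, and the correlation
structure of real disorder scores. Tests passing on synthetic corpora
therefore demonstrate the correctness of the machinery under its stated
rules, not robustness to noisy real-world alignments.

The test corpora use groups of 200–400 columns and 4–10 species, and the
property batches use a few hundred randomized cases per invariant —
sizes chosen so the full suite exercises every code path in well under a
minute while still making boundary mistakes (off-by-one in windows,
trimming, profile bits) essentially certain to surface.

## Numerical and degenerate-input choices

* All-gap sequences have no coordinate map and raise an error; fragment
  slices in which a species is fully gapped are retained as
  empty-profile members instead (the two cases differ: the former is a
  malformed input, the latter a legitimate analysis state).
* Jaccard of two empty supports is 0; the non-informative `NA` is
  reserved for the co-evolution profiles, where "nothing to compare"
  and "no overlap" must be distinguished.
* `p.adjust` ties, `hclust` tie-breaking and RNG all run under fixed
  seeds in tests; the pipeline stages write sorted, rounded TSVs so
  reruns are byte-identical.
* The hypergeometric tail at `k = 0` is exactly 1; impossible count
  combinations are errors, not NaN.

## Known limitations

* CBR boundaries from the maximal-segment rule depend on the
  substitution matrix; they are comparable within a corpus analysed with
  one matrix but not across matrices.
* The fallback disorder scale is for plumbing tests only; conclusions
  about real IDRs require external predictor scores through the adapter.
* The enrichment convention bakes in a specific treatment of
  foreground/background overlap (see above); designs with a disjoint
  background should call `hypergeom_upper_tail()` directly.
* Conservation profiles are presence/absence at the feature level; they
  do not quantify partial conservation of feature length or composition.
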