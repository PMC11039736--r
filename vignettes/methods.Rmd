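---
title: "Footprint-based de novo motif discovery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Footprint-based de novo motif discovery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Digital genomic footprinting turns ATAC-seq (or DNase-seq) cut-site
profiles into a per-base *binding score*: DNA-bound proteins shield their
binding site from transposase insertion, leaving short stretches of locally
elevated score — footprints — inside open chromatin. Scanning footprints
against a motif database explains many of them, but a substantial fraction
remains unexplained. `denovofp` takes a per-base score track (BigWig or
bedGraph) plus a genome, removes the portions of footprints that known
motifs explain, and derives new motifs from what is left, iteratively, so
that factors with few binding sites are not drowned out by abundant ones.
A differential mode (`max(0, score_A - score_B)` per base) restricts the
whole analysis to binding events unique to one of two conditions.

This vignette documents the models, the tunable parameters, and the design
decisions taken where the problem statement left the design open. Every
number shown in the package documentation is produced by the test suite or
the acceptance script; nothing here reports an empirical claim the code
does not recompute.

# Footprint calling

A position is part of a candidate footprint when its score exceeds both
zero and a *local height limit*, defined as `height_factor` (default 1.5)
times the mean score in a centered `local_window` (default 200 bp,
truncated at chromosome ends). Because the limit is relative, calls are
invariant under positive rescaling of the track — a property the tests
assert, and the reason the caller works for any upstream scorer's units.

Maximal qualifying runs are then filtered:

* width within `[min_width, max_width]` (defaults 6–60 bp, the typical
  range of transcription-factor footprints);
* a *flat top*: the plateau of positions scoring at least
  `(1 - flat_top_tolerance) x run maximum` (tolerance default 0.15) must be
  contiguous and at least 2 bp wide. Runs narrower than 4 bp are exempt —
  a plateau rule is meaningless at that width. The flat-top concept is
  qualitative in the literature; this plateau formulation is our
  quantitative stand-in, and it is evaluated before merging (merged
  footprints are not re-tested).

Nearby footprints merge when the gap is shorter than `merge_gap_max`
(default 6 bp) *and* the minimum score inside the gap is at least
`merge_depth_frac` (default 0.5) of the smaller of the two footprint
maxima; merging is applied left-to-right and transitively, with scores
recomputed from the track. Footprints shorter than `min_fp_size` (default
8 bp) are removed last. The caller is verified against a brute-force
re-implementation of the same rules on random tracks.

# Masking by known motifs

Footprint sequences are scanned on both strands with log2-odds PWMs
(pseudocount 1, background = strand-symmetrized pool composition). The
match threshold is the score whose exact tail probability under the
background model is at most `threshold_quantile` (default 1e-4, the
conventional motif-match level), computed by dynamic programming over
per-column score distributions discretized to 0.01 bins. Two numerical
choices matter:

* the distribution is taken under the *background* model — that is the
  only convention under which "expected hits = 2 (L - W + 1) q on random
  sequence" holds, which the tests verify;
* for short motifs the requested quantile can be unreachable (a 6-mer's
  best word already has probability about 2.4e-4 under a uniform
  background); the threshold then falls back to the best attainable score
  bin, and the achieved tail probability is reported alongside. The
  scanner uses the same binned PWM as the threshold computation so that
  the achieved probability is exact for it too.

Masking then either drops any footprint overlapping a hit by one base
(`whole_fp`) or — the default, and the more informative mode — subtracts
only the hit locations and keeps flanking fragments of at least
`min_fp_size` bp (`motif_location`), so that the binding sites of closely
bound partner factors survive for discovery. With an empty database the
masking step is the identity, which is what enables the database-free mode.

# The ZOOPS-EM motif finder

The built-in finder replaces an external motif-discovery binary behind a
pluggable interface (any function honoring the `em_zoops()` contract can be
substituted). It implements the zero-or-one-occurrence-per-sequence
mixture: with prior `gamma` a sequence carries exactly one site at a
uniformly chosen offset and strand, emitting bases from the PFM columns;
all other bases come from a 0-order background. EM alternates the exact
posterior over (no site, offset x strand) with re-estimation of the PFM
(pseudocount 0.1, background-distributed) and `gamma`, until the
log-likelihood gain falls below `tol` (default 1e-3, at most 100
iterations). The fit is deterministic; the `rng_seed` argument exists only
so stochastic replacement finders share the interface.

Two guards proved necessary beyond the textbook model:

* **Site-significance gate.** Hard assignment by "best site posterior beats
  no-site" alone collapses in mixtures: the fitted `gamma` approaches 1 and
  nearly every sequence — including pure background — gets a site, whose
  subtraction then destroys the discovery pool in one iteration (we observed
  247 of 250 sequences absorbed in a two-motif mixture). A site must
  therefore also pass the fitted PWM's exact background score distribution
  at a per-sequence false-assignment rate `alpha` (default 0.05, Bonferroni
  over the `2 (L - w + 1)` windows).
* **Edge trimming.** Flank columns fitted on random context carry little
  information but blur motif comparisons; edge columns with information
  content below 0.25 bits are trimmed (never below 4 columns), with site
  coordinates narrowed accordingly.

# Seeding, significance and iteration

Seeds are the `seeds_per_iteration` (default 2) most over-represented
k-mers per width in `[w_min, w_max]` (default 6–15), ranked by the z-score
of their both-strand count (a k-mer and its reverse complement form one
class) against the mononucleotide-background expectation. Classes observed
fewer than `min_count = 5` times are discarded first: for long k-mers the
expectation is so small that any singleton would top the z-ranking and
seed chimeric motifs.

Each candidate motif receives a binomial E-value: with
`p0 = min(1, 2 (L - w + 1) 2^(-IC))` the chance that a background sequence
of mean length `L` contains a site as informative as the motif,
`E = P[X >= nsites | Binomial(pool, p0)] x tests`. Two calibration terms
keep EM-optimized noise from looking significant — without them a
pure-background pool yields confidently "significant" motifs:

* `p0` is floored at the finder's site-gate false-assignment rate (the
  null probability of an assignment cannot be below the gate's own false
  rate);
* `tests` is the number of k-mer classes that entered the seed ranking at
  the iteration's widths, not merely the handful of fitted candidates —
  the seed search *is* a motif search.

The dynamic significance filter maps E-values to `-log10`, sorts them
decreasingly, min–max normalizes, and places the knee at the point of
maximum perpendicular distance to the chord between the first and last
point; candidates strictly before the knee that also satisfy the absolute
cap `evalue_cap` (default 0.05) are significant. With fewer than three
candidates, or a flat curve (which has no knee), the cap alone decides.
The knee is applied across *all* candidates of an iteration and the best
`motifs_per_iteration` (default 3) distinct significant motifs are then
kept — a knee on exactly three points would be degenerate, only ever
admitting the first.

The sites of the kept motifs are cut out of the pool; flanking fragments of
at least `min_fragment_size` (default 8 bp) re-enter with updated genomic
coordinates. The loop stops when the pool is empty, after `max_iterations`
(default 30), or after `stagnation_limit` (default 3 — "several")
consecutive iterations without a significant motif. Total pool length in bp
strictly decreases whenever sites were subtracted, which guarantees
termination; the per-iteration pool sizes and candidate significance flags
are recorded for reporting.

Finally all significant motifs are clustered (single linkage) and merged at
the similarity-distance threshold 0.4 — the threshold used for *every*
merging and rediscovery decision in the package — by aligning each cluster
member to its highest-`nsites` member and summing counts over the
overlapping span.

# The motif similarity distance

The distance between two motifs is `1 - max` over all ungapped offsets
(both orientations, at least 4 overlapping columns) of the mean per-column
Pearson correlation between probability columns, *weighted by
`overlap / min(W1, W2)`*. The weight is 1 whenever the narrower motif is
fully covered, so identical motifs and reverse-complement pairs have
distance 0; without it, chance agreement over a minimal 4-column ledge
regularly places unrelated motifs below the 0.4 threshold (two crisp
8-mers sharing a 3-of-4-column edge land at distance 1/3), which makes
clustering merge distinct motifs and voids the rediscovered/novel
labeling. This weighting is the one place where we deliberately hardened
the stated column-correlation metric; equality with any external tool's
clustering is not claimed.

# Downstream characterization

* **Region enrichment** uses a binomial tail with
  `p0 = region_bp / genome_bp` rather than Fisher's test: the genome side
  is a fixed length, not a sampled count.
* **Annotation** assigns each hit the nearest strand-aware feature anchor
  (start for `+`, end for `-` features) within 10 kb, ties broken by
  distance then name.
* **Gene-set enrichment** is a flat hypergeometric over-representation test
  with Benjamini–Hochberg correction; all hypergeometric and binomial
  tails are verified against exhaustive enumeration.
* **Database comparison** labels a motif *rediscovered* when its minimum
  distance to the database is strictly below 0.4, else *novel*.
* **TF-class assignment** computes the binding-site overlap coefficient
  (shared hits on the smaller set / size of the smaller set) of the target
  motif against every database motif, takes the motifs above the 95th
  percentile of that per-target distribution as the top set N, and tests
  each class via `fold = (n/N)/(dn/DN)` with a hypergeometric p-value.
  Motifs lacking a class annotation are excluded from all counts. The
  percentile is computed per target motif, a choice the problem statement
  left open.
* **Aggregate profiles** average the track in 120 bp windows (flank 60 bp)
  centered on hit midpoints, reversing minus-strand windows and skipping
  windows that leave the chromosome.

# The synthetic world

The generator exists so that every pipeline stage is testable without
external data, and its defaults state that world once:

* genomes are i.i.d. with GC 0.41 (mammalian-like; the benchmark source
  material gives no composition);
* the benchmark mixture implants four truth motifs at 40/30/20/10% of
  2,000 sites. The built-in truth PFMs have 0.85 dominant-base columns at
  widths 8–10 and consensi (`TGGAGTCT`, `AAGGCACA`, `GACGGATGC`,
  `TCATCATATC`) selected once, by randomized search over the package's own
  distance, so that all pairwise distances exceed 0.5 — an earlier draft
  with textbook-looking consensi collided below 0.4 through 4-column edge
  overlaps, making the implant truth ambiguous. The selection used only
  the truth PFMs themselves, never a test outcome;
* implants are placed uniformly, non-overlapping with a 30 bp minimum gap
  (overlap injection is deliberately not modelled), on random strands;
* the score track is a flat-topped bump of height 10 spanning each site
  ±5 bp over truncated-at-zero Gaussian noise (sd 0.1 by default; scores
  are non-negative by definition). Two-condition tracks put shared bumps in
  both conditions and exclusive bumps in the first only.

What the generator does *not* emulate: transposase sequence bias, read
sampling noise, overlapping/cooperative sites, non-flat footprint shapes,
and chromatin-accessibility structure. A green recovery test therefore
establishes that the algorithmic chain is correct on well-posed input, not
that real-data footprints of a given scorer will be equally clean.

# Acceptance properties and their interpretation

The quantitative results of the original study depend on external datasets
and database versions, so acceptance is property-based
(`tests/testthat/test-acceptance.R`): exact oracle equivalence for the
footprint caller, differential arithmetic, masking soundness, statistics
versus enumeration, knee selection, merging conservation, profile shape,
byte-level determinism — plus three simulation properties: the scaled
40/30/20/10 mixture must be fully recovered while a single non-iterative
finder call (implemented as a one-iteration run) recovers strictly fewer
truth motifs; a two-condition run must recover the exclusive and not the
shared motif; and recovery distance must not increase with implant count
over {50, 200, 800} sites. For the last property the three seeds are
replicates: at 200 versus 800 sites the recovered PFMs are both essentially
exact and differ only by estimation noise of order 1e-3, so monotonicity is
asserted on the seed-averaged distances (and per seed on the unsaturated
50 to 200 step).

# Known limitations

* The E-value is a calibrated stand-in, not a reimplementation of any
  external tool's statistic; absolute values are comparable within a run,
  not across tools.
* Minus-strand handling assumes strand-symmetrized backgrounds; strongly
  skewed single-stranded inputs would need an explicit background.
* `cluster_and_merge` trims merged motifs to the reference member's span;
  information unique to a longer member's overhang is discarded.
* The footprint caller assumes dense per-base scores; sparse tracks are
  densified with zeros on read, which is correct for scorers that emit
  zero outside open chromatin but inflates the denominator of the local
  mean elsewhere.
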