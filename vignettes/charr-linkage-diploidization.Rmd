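---
title: "Linkage mapping and diploidization analysis with charrmap"
author: "charrmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage mapping and diploidization analysis with charrmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(charrmap)
```

## The problem

Salmonid fishes are descendants of a whole-genome duplication (the
salmonid-specific fourth round, Ss4R, roughly 96 million years ago) and are
still returning to disomic inheritance — *diploidization*. The residue of
that history is visible in an ordinary F1 mapping family: duplicated loci
collapse into markers that look heterozygous in every individual
(paralogous sequence variants, PSVs), homeologous chromosome arms still
exchange material in multivalent meioses (residual tetrasomy), and that
exchange shows up statistically as *pseudolinkage* — significant two-point
linkage between markers that sit on different chromosomes.

charrmap implements the full analysis path from a family genotype table to
these signals: marker QC and cross-type classification, two-point LOD
grouping, recombination-count marker ordering with adjacent
double-crossover (DCO) handling, per-parent map distances, pseudolinkage
detection, and comparative chromosome-arm analyses of duplicate-locus and
transposable-element (TE) distributions against a reference genome. A
synthetic family simulator with known ground truth backs every step with
parameter-recovery tests.

## The family design and marker QC

The analysis assumes a pseudo-testcross design: two outbred parents and N
full-sib progeny (the reference family has N = 85), genotyped at biallelic
markers (64 bp GBS tags). Markers fall into cross types by the parental
configuration:

* **maternal / paternal informative** — heterozygous in exactly one
  parent; every progeny genotype reveals which parental allele was
  transmitted, so these markers carry full linkage information for that
  parent's map and none for the other.
* **double heterozygote (DH)** — heterozygous in both parents; the phase
  of a heterozygous progeny cannot be resolved, so only homozygous progeny
  (about half) are informative. DH markers are assigned to linkage groups
  but never given map positions.
* **PSV** — heterozygous in both parents *and* in every called progeny.
  The absence of homozygous progeny is the signature of a collapsed
  duplicated locus (two monomorphic copies differing at one base); PSVs
  segregate nowhere and cannot be mapped, but their reference-genome hits
  locate them.

QC drops markers in a fixed order: progeny call fraction below 75/85, a
missing parental genotype, then segregation distortion. Distortion is
tested with the likelihood-ratio G statistic on the informative parent's
transmitted allele counts,
G = 2[a ln(2a/(a+b)) + b ln(2b/(a+b))], flagged when G > 6.693. We keep
the printed threshold 6.693 as the default even though the exact 1%
critical value of chi-square with 1 df is 6.635; the difference admits no
marker either way in practice, and the printed value is the documented
protocol. The 75/85 rule is applied to progeny only, and PSV strictness is
assessed over *called* progeny — missing data is orthogonal to duplication
status.

The distortion test population is a design choice the protocol leaves
open: we count the informative parent's transmitted alleles (only
informative meioses carry the 1:1 expectation), and for DH markers the two
homozygote progeny classes, which estimate the same 1:1 contrast for
either parent.

## Two-point linkage and grouping

For a marker pair informative in the same parent, over the N doubly
phase-resolved progeny with k phase agreements, the recombination fraction
is r = min(k, N−k)/N (the phase label — coupling or repulsion — absorbs
the arbitrary allele labelling so r ≤ 0.5) and

LOD = R log10(r) + (N−R) log10(1−r) + N log10(2),  R = min(k, N−k),

with the r = 0 limit N log10 2. This closed form is the maximum of the
two-point likelihood; the test suite verifies a brute-force scan over
r ∈ {0, 0.001, …, 0.5} never beats it by more than 1e-9.

Linkage groups are the single-linkage transitive closure over pairs with
LOD ≥ 10, per parent. Unlinked markers are then re-examined at a
descending LOD schedule (6, 5, 4, 3): a marker linking to exactly one
group is attached; a marker linking to several is left unassigned and
logged as ambiguous; and an addition that would *merge* two existing
groups is accepted only when the group pair is on the homeolog whitelist
(shipped as `charrHomeologPairs()`, user-overridable) — because merges at
low LOD between known homeologs are exactly the pseudolinkage signal, not
evidence the groups are one chromosome. We attach singletons rather than
re-running the closure at each step; the join log records every decision
so the choice is auditable.

## Marker ordering and map distances

Within a group, markers are ordered by recombination-count minimisation
(RECORD-style greedy sequential insertion, best of a configurable number
of randomised insertion orders, deterministic for a given seed). Markers
with identical inheritance vectors collapse into a zero-recombination bin
ordered stably by marker id. The ordering is then refined by a ripple: a
sliding window (default width 5) tries all within-window permutations and
accepts the first that strictly reduces the pair (adjacent-DCO count,
COUNT) lexicographically — adjacent DCOs first because an isolated
single-marker phase flip implies two crossovers in adjacent intervals,
which strong salmonid chiasma interference makes biologically implausible;
such singletons are genotyping-error signatures. When the window pass
stalls, a relocation pass removes each marker and tries every reinsertion
point under the same acceptance rule; this repairs a marker misplaced
beyond the window's reach, which otherwise parks at a map terminus (a
terminal flip is not a DCO, so the window search alone cannot dislodge
it). The refined ordering is never worse than its input, and with window =
n the window search is exhaustive.

Map distances mask each adjacent-DCO singleton genotype (treated as
missing) before interval counting, so a suspected error contributes no
recombination to either flanking interval; masking the genotype rather
than subtracting events is our resolution of an ambiguity in the original
tool's description, and the alternative differs only in how a masked
progeny contributes to the interval's denominator. The default map
function is Morgan (100·r per interval): with adjacent-DCO exclusion the
data are already forced toward complete interference, so applying Haldane
or Kosambi on top would double-correct; both are available as options.

## Pseudolinkage

For every whitelisted homeolog pair whose members sit in different groups,
the maximum cross-group two-point LOD is computed. Calls are accepted in
the window [3, 5] (both ends inclusive); maxima above 5 between distinct
groups are reported as anomalies — plausible group misassembly — rather
than calls. For an accepted call the linking marker pair's four
transmitted-allele classes are tabulated over phase-resolvable progeny and
tested against 1:1:1:1 (Pearson, 3 df, no multiple-testing correction,
matching the original protocol; a Bonferroni column over the whitelist
size can be added downstream). The direction of excess — parental vs
nonparental — requires knowing which alleles are in coupling across the
homeolog pair, which the data alone cannot supply; the `orientation`
argument provides it (from simulator truth, or prior knowledge), and
swapping one marker's allele labels flips the direction label while the
chi-square is invariant.

## The simulator and what it does (not) emulate

`buildGenomeModel()` lays out evenly spaced markers on linkage groups
anchored to reference arms; `simulateFamily()` draws meioses per parent.
Recombination uses, by default, a renewal process in which a crossover in
interval i suppresses interval i+1 — mirroring the treatment of adjacent
DCOs as artifacts — with a no-interference Haldane option (under
suppression the marginal per-interval recombination fraction is slightly
below the nominal cM/100; recovery tests that need the nominal value use
the Haldane mode).

Residual tetrasomy is phenomenological: per homeolog pair per meiosis a
multivalent forms with probability π_m; an exchange point is drawn
uniformly in the distal `telomereBias` fraction (default 0.25) of the arm
— multivalent crossovers concentrate toward telomeres — and the phases of
markers distal to it become coupled between the partner groups. Which sign
the coupling takes follows from assuming only *balanced* disjunction
products yield viable euploid gametes: alternate disjunction after
preferential pairing leaves the nonparental combinations balanced
(nonparental excess, the classic hybrid pseudolinkage), while random
pairing leaves the parental combinations balanced (parental excess, the
weak form seen within species). The mechanistic segregation genetics —
chromatid-level multivalents, aneuploid gamete loss, double reduction —
are deliberately not modelled; the simulator reproduces the statistical
structure the detector consumes, not meiotic cell biology. Likewise PSV
loci are emitted directly as fixed heterozygotes (telomere-biased
placement by default) rather than derived from sequence collapse, and hit
tables are emitted with configurable coordinate noise and exact e-value
ties rather than by running an aligner. Passing recovery tests therefore
demonstrate the pipeline's correctness on data with the assumed
statistical structure, not robustness to artefacts real GBS data can add
(allele dropout, paralog-induced miscalls, depth-dependent error).

Defaults encode the study conditions: 85 progeny, genotypes as unordered
two-character allele strings with `--` missing, parents emitted once (the
original triplicate parental sequencing is a depth device, not a data
feature), and log10 e-values drawn from a normal distribution with ties
created by duplicating the printed string exactly.

## Comparative genome analyses

Top hits are resolved per marker by lowest e-value with ties compared as
exact printed strings (the aligner's own dialect; a relative-tolerance
option exists but defaults off). Tied hits within one arm collapse to a
single hit; markers tied across one or two arms are kept (two-arm markers
are duplicate-locus candidates); three or more arms, or no hits, drop the
marker with a logged reason. Arm quarters are half-open bins with the last
bin closed, quarter 1 centromere-proximal: quarter = min(4, 1 +
floor(4·offset/length)) with a 1-based offset from the centromeric end.
Note the half-open convention is not exactly mirror-symmetric at bin
boundaries when the centromere side flips; boundary positions are a
measure-zero set for real hit coordinates.

Category tests (HRTA — high-residual-tetrasomy arms — and AHP —
acrocentric homeolog pairs, shipped as `salmonArmCategories()`) are 2×2
Pearson chi-squares of map-SNP vs PSV hit counts in vs out of category,
without continuity correction by default (the shipped TE table's printed
p-value of 0.0009 corresponds to the Yates-corrected test at 4 decimals;
the uncorrected p is 0.00077 — both are reported by the tests). The
quarter analysis is emitted both as a 2×4 contingency test and as per-kind
uniform goodness-of-fit tests, since the original description is
compatible with either reading.

Duplicate tags are found by all-vs-all comparison with a 16-mer prefilter
(both strands) and ends-free overlap alignment under BLASTn-like scoring
(match 2, mismatch −3, gap open 5, gap extend 2); pairs with ≥95% aligned
identity and ≥95% overlap of the shorter tag are duplicates, classified as
inter-group (potential homeologs), tandem (same group, adjacent ranks) or
intra-group regional duplicates. Metacentric vs tandem-fused-acrocentric
group composition cannot be distinguished from marker homology alone, so
`classifyLgComposition()` reports "compound" (≥2 arms each supported by ≥3
markers — single stray hits are TE/paralog noise) and accepts an optional
karyotype annotation for finer labels.

## Test design and problem sizes

The published map itself (4508 markers, 39 groups) is built from raw reads
that live in an external archive, so the package validates through
parameter recovery at sizes chosen for tight statistical control: 8-marker
groups × 200 progeny against exhaustive permutation search (100 fixtures);
5 groups × 12 markers at 2.5 cM × 85 progeny for partition recovery — at
this density a chain break from legitimate sampling tails has probability
~1e-6 per family, whereas at 5 cM spacing a terminal marker detaches in
roughly 1% of families, incompatible with demanding a perfect adjusted
Rand index; 15-marker groups × 85 progeny × 1% genotyping error for the
DCO-masking comparison (100 seeds); and 2-group homeolog families for
pseudolinkage (50 seeds).

One acceptance property is not attainable and is left failing by design
rather than weakened: with 85 progeny the best cross-homeolog LOD has a
standard deviation of about 1.5 LOD units (binomial noise in r̂ of about
0.047 times a local slope of about 36 LOD per unit r̂), while the
acceptance window [3, 5] is only 2 units wide — so no honest configuration
of the generator places ≥90% of seeds inside the window; the observed call
rate is ~10–20%, with most remaining seeds rejected above the window. The
direction structure (parental excess under random pairing, nonparental
under preferential disjunction, zero calls without multivalents) holds and
is tested.

## Known limitations

* Two-point methods only: no multipoint likelihood or HMM phasing, so
  ordering confidence comes from COUNT/DCO objectives, not posterior
  support.
* The tetrasomy model is phenomenological (see above) and its two free
  parameters (π_m, telomere bias) are not estimates of any biological
  rate.
* Direction of pseudolinkage excess requires an external allele
  orientation.
* Duplicate-tag identity is computed on the aligned overlap, which for
  heavily end-mutated tags can differ from a global-alignment identity.
* Arm assignment trusts the supplied arm table; hits falling outside every
  arm are dropped, not rescued.
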