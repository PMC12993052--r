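---
title: "Curating SSR fingerprints in germplasm collections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating SSR fingerprints in germplasm collections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrcurate)
```

## The curation problem

Historic fruit collections hold many trees per cultivar, spread over partner
sites, under names of varying reliability. Genotyping every tree at a panel
of SSR (microsatellite) markers turns cultivar identity into a computable
question: trees carrying the same fingerprint are the same clone, whatever
their labels say. `ssrcurate` implements the full curation chain for such
multi-allelic fingerprint tables: pairwise distances that tolerate sizing
error, clustering into *molecular groups* (putative cultivars), a
majority-rule *representative fingerprint* per group with explicit handling
of ties, propagation of trueness-to-type codes, and quality checks on the
result.

## Distance model

Two samples are compared with a Dice–Sørensen distance over allele fragment
lengths (AFLs):

$$ d(p, q) \;=\; 1 - \frac{2\sum \text{common alleles}}{\sum \text{alleles}_p + \sum \text{alleles}_q} $$

with three decisions that matter in practice:

* **±1 bp tolerance.** Capillary sizing drifts by a base pair between runs,
  so alleles $x$ and $y$ are "common" when $|x-y| \le$ `tolerance_bp`
  (default 1). Common alleles form a maximum-cardinality matching — each
  allele pairs at most once. Because allele sets are sorted and the
  compatibility relation is an interval, a two-pointer greedy sweep attains
  the maximum; the test suite verifies this against brute-force enumeration
  over every pair of allele lists of length ≤ 4.
* **Distinct variants.** An allele set stores *distinct* AFLs: a single-peak
  (homozygous-looking) marker contributes one allele to both sums. This is
  the same convention the binary encoding of the retraceability check uses,
  so the two stages cannot disagree about what an allele is.
* **Missing markers drop out of both sums.** A marker that failed to
  amplify in either sample is excluded from numerator and denominator;
  otherwise amplification failure would push true replicates apart. A pair
  sharing *no* amplified marker has no defined distance: it is reported in
  a QC list and contributes no clustering edge.

## Clustering into molecular groups

Samples join the same molecular group when their distance is at most the
cut-off (default `0.2`, i.e. 80–100 % identity; the cut-off is inclusive).
Groups are the connected components of the threshold graph — single linkage,
the minimal assumption when all one asserts is "samples within the cut-off
belong together". Chaining is therefore possible: A–B and B–C edges merge
A and C even at d(A,C) > cut-off. That risk is documented rather than hidden,
and `linkage = "complete"` cuts a complete-linkage dendrogram instead for
users who want compact groups (it requires every pair to be comparable).

Groups are named deterministically — descending size, ties by the
lexicographically smallest member id — and numbered `Pyr_0001`, `Pyr_0002`, …
(prefix configurable, width growing past 9999). The running order is an
artifact convention chosen for reproducibility; nothing downstream depends
on it.

## The representative ("synthetic") fingerprint

Per group and marker:

1. members whose amplification failed at the marker are dropped;
2. the number of *positions* is the modal allele count among the remaining
   members, preferring the larger count on ties (a diploid/triploid mix
   keeps the triploid signal);
3. only members with that allele count vote;
4. per position (alleles sorted ascending) the most frequent AFL wins;
5. a tie yields the flag `CHECK` instead of a value.

Step 2 is our operationalisation of removing missing values "based on the
first position and failed amplification": the source procedure is ambiguous
about profiles with differing allele counts, so the modal-count rule is
stated explicitly, and every marker where non-conforming members were
excluded is visible in the logs. Because the winner needs only a plurality
among voters, a resolved position is not automatically a strict majority of
all amplified members; the per-position frequency report (below) makes the
actual support visible.

### Tie resolution

`CHECK` flags are cleared by the first applicable rule, every decision
logged with the rule that fired:

* **R2 — heterozygosity.** Prefer the candidate giving more distinct
  alleles at the marker; a candidate collapsing onto an existing allele is
  usually a dropped peak.
* **R3 — motif consistency.** When the repeat unit is known, prefer the
  candidate whose differences to the marker's other alleles are whole
  multiples of the repeat unit. Perfect-repeat loci mutate in motif steps,
  so a 1 bp offset marks a sizing error, not a new allele.
* **R1 — existing sample.** Prefer the candidate whose full marker
  combination occurs verbatim in a member (most frequent combination wins);
  this keeps the representative close to measured reality.
* **R4.** Otherwise the flag stays `CHECK` for human review. Unresolvable
  ties are a legal output, not an error.

The ordering was a genuinely open design point. We place the evidence-based
rules (R2, R3) before the existing-sample preference because a ±1 bp sizing
error replicated in two members is still a combination "observed verbatim":
letting R1 decide first systematically endorses duplicated miscalls that the
motif-parity rule provably corrects on simulated groups. R1 then settles
what the evidence rules cannot.

### Trueness-to-type

Group codes are compiled hierarchically, not by majority: the most desirable
member code wins under the order 1 ≻ 5 ≻ 2 ≻ 3 ≻ 4 ≻ 0 — one true-to-type
accession suffices to represent the cultivar as true-to-type. Unassessed
members (`NA`) are skipped rather than mapped to "not assessed" (code 4),
since an explicit 4 is an assessment decision while `NA` is absence of one.

## Quality checks

* **Retraceability.** Profiles are converted to 0/1 vectors over every
  (marker, AFL) variant observed in the group, and the representative is
  compared to each member by binary Dice similarity
  $2|u \wedge v| / (|u| + |v|)$. A group is *retraceable* when some member
  matches at exactly 1.0; otherwise the fingerprint is truly synthetic.
  Matching here is exact by construction — the ±1 bp tolerance lives
  upstream in clustering and grid snapping, not in the variant encoding.
  Two all-zero vectors compare as 1 (degenerate, logged). Representatives
  still carrying `CHECK` flags are reported as unverifiable (`NA`) rather
  than forced to a verdict.
* **Variant frequencies.** Per resolved position, the fraction of amplified
  members carrying the representative AFL, plus the per-group average. Low
  values mark markers or groups worth review.
* **Collection accounting.** Per-location counts of final samples, distinct
  trees, distinct accessions and assessment coverage, with a total row that
  must equal the column sums. `expand_location_summary()` inverts a printed
  per-location summary into synthetic per-sample rows (ids meaningful only
  through their multiplicities), which lets published aggregate tables be
  replayed through the same accounting code.

## Numerical and degenerate-input choices

* Allele grids: a raw size snaps to the nearest bin within the tolerance;
  equidistant ties snap to the smaller bin; values beyond tolerance come
  back unassigned and must be surfaced. Snapping is idempotent.
* AFLs are integers after snapping; decimal input without a configured grid
  is an error rather than a silent rounding.
* Missing data on input: empty cells, `NA` and `0` all parse as missing
  (fragment-analysis exports differ); output writes empty cells.
* Empty member lists, unknown markers, duplicate sample ids and
  non-integer AFLs fail fast with the offending record named.

## The synthetic-collection generator

Every stage is tested against `simulate_collection()`, which emulates a
genebank collection with known ground truth: clonal cultivars genotyped at
the 17-marker pear panel, per-marker allele pools of 5–15 variants spaced by
the repeat unit within 100–300 bp, a triploid minority (20 %), 1–3 trees per
cultivar with 1–2 replicates, per-allele ±1 bp miscalls (default 2 %),
per-(sample, marker) amplification failure (5 %), rare metadata mislabels
(1 % — they perturb the recorded name, not the alleles, because mislabeling
is a curation problem rather than a genotyping error), sports at the rate
seen in curated pear collections (7/421), and trueness codes skewed toward
the assessed classes. True cultivar genotypes are rejection-sampled to at
least 0.3 pairwise distance — distinct real cultivars are well separated at
this panel's resolution. All draws flow through one seeded stream, so a
fixed seed gives byte-identical collections, and every perturbation is
logged so the emitted profiles replay exactly from the truth.

What the generator does **not** emulate: allele-frequency structure among
cultivars (pools are uniform; real panels show common and rare alleles),
null alleles and locus-specific failure rates, parentage between cultivars
(half-identical fingerprints), run-level batch effects in sizing, and
sports carrying any molecular difference. Passing recovery tests therefore
show the pipeline handles sizing noise, dropout and mixed ploidy — not that
it resolves pedigree-related cultivars, which genuinely share most alleles
and may chain below any fixed cut-off.

## Test problem sizes

The recovery checks run on 50 simulated cultivars with 5 samples each
(250 samples, ~31k pairwise distances): clustering recovery is measured at
2 % miscall / 5 % missing, consensus recovery at 10 % miscall. Property
suites use 6–20 cultivars. With five voters per group and 10 % per-allele
miscalls, the probability that same-direction miscalls outvote the true
allele at some position of a 17-marker genotype is on the order of 10 %, so
majority-rule recovery near 90 % is the statistical ceiling at that design
point; recovery rises steeply with more members per group — worth knowing
when deciding how many trees per accession to genotype.

## Known limitations

* Single-linkage chaining can merge related cultivars; inspect the distance
  histogram (`autoplot()` on the distance object) around the cut-off.
* The cut-off is a parameter, not auto-selected; the original choice was
  made from the distance distribution of a real collection, and a different
  panel or species may need a different value.
* Ploidy and PUNQ codes are passthrough metadata; nothing is inferred from
  allele dosage.
* The deposit's exact spreadsheet headers are configurable defaults, not
  guaranteed matches for any given export.
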