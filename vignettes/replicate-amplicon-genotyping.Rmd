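---
title: "Replicate-aware genotyping of multilocus amplicons: methods and design"
author: "ampliTyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-aware genotyping of multilocus amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliTyper)
```

## The problem

Multigene families such as the MHC class II DRB loci resist locus-specific
primer design, so genotyping proceeds by co-amplifying all loci with one
primer pair and deep-sequencing the pooled amplicon. Two PCR-borne failure
modes then dominate the analysis. First, artefacts — chimeras formed by
template switching, polymerase substitution errors amplified across cycles,
and platform errors — can outnumber the true allele variants by an order of
magnitude. Second, primers amplify different alleles at different rates;
when an allele's amplification efficiency is low, finite read depth makes it
drop out of a genotype entirely, inflating apparent homozygosity.

ampliTyper implements a genotyping workflow built around two independent PCR
replicates per individual. Replication, rather than any fixed frequency
threshold, is what separates alleles from artefacts: an artefact arises
independently in each PCR, so its profile across the two replicates betrays
it. The package also quantifies the dropout risk directly, by estimating
per-allele amplification efficiencies under a multinomial read-count model
and translating them into minimum read-depth requirements (the T1 family).

## Read filtering

`filterAmplicons()` applies, in order:

1. **Length**: raw reads shorter than `minReadLength` (default 250 bp,
   against a ~290 bp expected read) are removed; they cannot contain a
   complete barcode-primer-target-primer-barcode construct.
2. **Demultiplexing**: a read is assigned to an amplicon only if its first
   10 bases equal the forward barcode (MID) and its last 10 the reverse
   complement of the reverse MID, with zero mismatches. Barcodes in a set
   differ at three or more positions, so exact matching is the conservative
   reading; anything else is discarded as unassignable. Both read
   orientations are searched and reverse-orientation reads are flipped.
3. **Primers**: both primer regions must match exactly under IUPAC
   semantics — a degenerate primer letter accepts any base of its set, and
   an uncalled `N` in the read matches nothing. Matching reads are trimmed
   to the bare target.
4. **Quality**: a read is kept iff at least 95% of its bases have a Phred
   score strictly greater than 20 (the predicate is strictly `> 20`, so a
   read of uniform Q20 fails).
5. **Length and frame**: the target length must differ from the expected
   length by a multiple of 3 bp (at most `maxIndelUnits` = 2 codons), and
   the fixed-frame translation must contain no internal stop codon. The
   stop-codon rule automates what is otherwise a visual reading-frame
   inspection of a coding exon; it is a deliberate proxy, and reads whose
   frameshift happens to preserve an open frame at a codon-multiple length
   are beyond its reach. An `N` inside the target does not by itself reject
   a read — such reads end up as singletons downstream.

Every read is accounted for exactly once across the kept set and the five
rejection counters (`filterReport()`), and the kept set is invariant to the
input order.

## Clustering and intra-amplicon typology

Within an amplicon, identical reads form clusters (`clusterReads()`),
ranked by count with lexicographic tie-breaks so that the ranking is
deterministic. Sequences seen once — singletons — are set aside as putative
artefacts immediately: a polymerase or sequencing error is overwhelmingly
unlikely to recur identically. Cluster frequencies are therefore computed
over non-singleton reads.

Every cluster below rank 1 receives one intra-amplicon category
(`classifyIntra()`), applied in this order:

- **chimera** — the cluster is a template-switch product of two distinct
  clusters with strictly higher counts: `query = parent1[1..b] +
  parent2[b+1..end]` for some breakpoint `b`, with the query differing from
  both parents. The product inherits parent 2's coordinates (hence its
  length), which keeps in-frame indel variants out of the chimera class.
  Testing runs in rank order and reports the certificate with the lowest
  (parent-1 rank, parent-2 rank, breakpoint). Mosaics of more than two
  fragments are not searched; they land in the distance classes below.
- **1-2 bp diff** / **>2 bp diff** — the Levenshtein distance (mismatches
  plus gap columns of a global alignment, so a 3 bp indel counts 3) to the
  most similar strictly-more-frequent cluster, ties resolved to the lowest
  rank.

"More frequent" is read as *strictly greater count* throughout: the model
assumption that artefacts are rarer than their sources degenerates under
ties, so equal-count clusters can never be each other's parents. A cluster
that is both 1 bp from a parent and a valid chimera is labelled chimera —
the chimera test runs first.

## Replicate reconciliation and allele calling

`callAlleles()` reconciles the two replicates of each individual, then all
individuals, iterating to a fixed point.

**Step II** (clear artefacts): a 1-2 bp variant or a chimera absent (as a
non-singleton cluster) from the other replicate; a chimera in *both*
replicates (two independent PCRs producing the same chimera is expected —
the same parent pair offers few distinct splice products — whereas a true
allele would not be chimera-decomposable in only one replicate); and a
>2 bp variant absent from the other replicate *and* from every other
individual.

**Step III** (alleles, iterated): the putative artefacts of an amplicon set
a frequency bar — the maximum artefact frequency. A variant present in both
replicates and strictly above the bar in both is a **putative allele**;
present in both but not above the bar, an **unclassified variant** (it
appears twice in independent PCRs in at least two copies each, so it cannot
be dismissed, but it is not frequent enough to call). A >2 bp variant in
one replicate only is unclassified when the same sequence is an allele or
unclassified variant in another individual, otherwise an artefact. A
chimera-labelled variant whose replicate partner carries a different
category is accepted as a *natural recombinant* when the sequence occurs in
other individuals. Rank-1 clusters carry no artefact typology, so a top
cluster missing from its replicate partner is unclassified, not an
artefact — there is no evidence either way. Step III re-runs, synchronously
over all amplicons (making the result independent of processing order),
until no label changes: a newly annotated artefact can raise an amplicon's
bar and demote an earlier allele call in the next pass.

**Census**: a sequence called allele in at least one individual but
unclassified in strictly more individuals than it is an allele is re-flagged
**low-efficiency allele** everywhere it occurs — a candidate true allele
whose weak, inconsistent amplification makes it dropout-prone and whose
read counts should not feed the efficiency model. The strict majority is
our own choice of threshold; the concept has no canonical cutoff.

Individuals are excluded, with a report entry, when they lack exactly two
replicates, when an amplicon has fewer than `floorReads` (default 100)
post-filter reads, or when the two replicates share no allele candidate at
all (the signature of cross-contamination or a barcode swap).

`classifyByFrequencyThreshold()` implements the fixed intra-amplicon
frequency threshold (T2) of earlier pipelines purely as a comparison
baseline; the main workflow deliberately avoids any such threshold.

## Amplification efficiencies

Each allele is assumed to amplify at one relative efficiency \(e_a\),
independent of genotype and PCR. An amplicon with genotype \(G\) and read
counts \(c\) contributes a multinomial term with cell probabilities
\(p_a = e_a / \sum_{b \in G} e_b\); the data log-likelihood is the sum over
amplicons, and `estimateEfficiencies()` maximises it. Details that matter:

- The likelihood only identifies efficiency *ratios* within a connected
  component of the genotype-sharing graph. Estimation runs per component
  with one allele pinned to 1 (log-scale parameterisation enforces
  positivity and removes the scale degeneracy); the component structure is
  reported, and cross-component comparisons are meaningless.
- BFGS with the analytic gradient, five starts (equal efficiencies, then
  seeded random perturbations) guarding against multimodality; objective
  tolerance 1e-12, convergence flagged on a gradient norm below 1e-6.
- `standardise()` divides by a chosen reference allele afterwards; this is
  equivalent to pinning the reference during optimisation, up to scale.
  Standardised efficiencies of 2 or more mark candidate duplicated (or
  homozygous) alleles.
- Reads of low-efficiency-flagged alleles are excluded by default
  (`genotypeObservations()`), since their counts are unreliable by
  definition; a flag re-admits them.
- For a single amplicon the MLE reduces to the observed read frequencies —
  the closed form the tests pin.

## Minimum read depths: the T1 family

T1 is the smallest read count \(n\) such that every allele of a genotype is
represented by at least \(m\) reads (default 2) with confidence \(\gamma\)
(default 99.9%) — the classical definition of the dropout-safe depth. The
default \(m = 2\) reproduces the established equal-efficiency thresholds
(15 reads for two alleles, 100 for nine); \(m\) is configurable, and
\(m = 3\) grids are one call away.

- `probAllAtLeast()` computes \(P(\min_a X_a \ge m)\) under
  \(\mathrm{Multinomial}(n, p)\) *exactly*, by inclusion-exclusion over the
  subsets of alleles that fail to reach \(m\) reads. Each subset's joint
  probability is assembled from the coefficients of
  \(\prod_{i \in S}\sum_{c<m}(p_i x)^c/c!\), in log space, keeping the cost
  at \(O(2^k)\) and the result stable out to \(k = 15\); beyond that bound
  the simulation path takes over. This exact kernel replaces the
  negative-multinomial machinery of earlier work; agreement with the
  published thresholds is part of the acceptance suite.
- `t1Analytic()` searches \(n\) by doubling plus binary search —
  \(P\) is monotone in \(n\).
- `t1Simulated()` estimates the success fraction from `nSims` = 10,000
  multinomial draws per candidate \(n\) and takes the median over `nReps` =
  100 replications; a pilot search brackets the candidate range once so
  every replication searches the same interval. It serves both the
  equal-efficiency case and probabilities proportional to estimated
  efficiencies. Because each replication accepts the first candidate whose
  *estimated* success fraction clears \(\gamma\), its median sits a read or
  three below the analytic value — the known small-sample bias of the
  simulated variant.
- `t1Resampled()` resamples an amplicon's observed allele-labelled reads
  with replacement — identically, multinomial draws at the observed
  frequencies (resampling depth 1,000) — thereby letting each allele's
  effective efficiency vary between amplicons. The genotype-level value is
  the maximum over the two replicates; an allele with zero reads in a
  replicate leaves that replicate's T1 undefined and is itself the dropout
  evidence. Only allele-labelled reads enter the resampling pool, matching
  the definition of the observed allele frequencies.
- `t1MinEfficiencyGrid()` tabulates T1 over (number of alleles, minimum
  efficiency) with all but one allele at efficiency 1 — the a-priori
  planning grid. T1 grows linearly in the allele number at fixed minimum
  efficiency, so the grid extrapolates graphically to larger genotypes.

`runPipeline()` chains all stages and marks a genotype `reliable` when both
replicates carry at least T1-resampled allele reads — the a-posteriori
confidence verdict.

## The simulator

`simulateDataset()` generates dual-barcoded runs with complete truth tables
so that every stage is testable without external data. Its defaults *are*
the emulated study conditions: 36 individuals in duplicate from a pool of
20 alleles (2-11 per individual, 228 bp codon-clean targets, pairwise
divergence 4-30 bp), standardised efficiencies log-uniform on [0.2, 2.4]
(a 12-fold span), read depths normal with mean 768 and sd 314 (clamped to
the observed 142-2400 range). Of the reads that survive filtering, about
47% are allele copies, 34% unique singleton errors, and 19% multi-read
artefact clusters with chimeras carrying half of those reads — proportions
chosen to match the artefact census of a real 454 DRB run, where artefact
clusters outnumber allele clusters by roughly nine to one. Corrupted reads
(1 bp frameshifts standing in for homopolymer errors, low-quality reads
with 8% of bases at Q10, truncated reads, corrupted barcodes) are planted
on top for the filter cascade to remove, each carrying its provenance
label.

Two structural assumptions of the calling workflow hold by construction at
the defaults: every artefact cluster is strictly rarer than its source(s),
and (via `respectAlleleFloor`) rarer than the rarest allele cluster of its
amplicon. The knob exists precisely so robustness studies can violate
assumption 2. Chimeras are single-breakpoint splices of two genotype
alleles; quality strings are flat Q38 plateaus for clean reads — no
position-dependent quality model, no flow-space signal emulation, and no
read-length distribution beyond the indel classes above. Passing tests on
this generator therefore validate the classification logic and the coverage
arithmetic, not platform-specific error profiles.

## Numerical choices and degenerate inputs

- Tie-breaks are deterministic everywhere: cluster ranks break ties
  lexicographically, nearest-parent ties resolve to the lowest rank, and
  chimera certificates to the lowest (rank, rank, breakpoint).
- A rank-2 cluster tied in count with rank 1 has no strictly-more-frequent
  comparator; it is treated like a top cluster (no artefact typology), the
  coherent limit of the strict-count reading.
- Empty amplicons, empty read sets, and single-allele components are all
  legal and return empty or conventional (efficiency 1) results.
- All stochastic paths (`t1Simulated`, `t1Resampled`, efficiency restarts,
  the simulator) consume seeds through a self-contained RNG stream that
  never perturbs the caller's RNG state; identical seeds give identical
  bytes.
- Test and example problem sizes (20-seed batteries at 36 individuals and
  ~700+ reads per amplicon; resampling at 1,000 draws) were chosen to keep
  the full validation suite in the minutes range on one core while staying
  at the emulated study's scale.

## Known limitations

- MID and primer matching is exact; runs with degraded barcode regions will
  lose reads that a fuzzy matcher could rescue. The loss is counted, never
  silent.
- The chimera detector models single template switches. Multi-breakpoint
  mosaics are classified by distance instead (>2 bp diff), which matches
  how they present, but they are not certified as recombination products.
- The efficiency model assumes one efficiency per allele across genotypes
  and PCRs; the resampled T1 exists precisely because that assumption is
  only an approximation, and disagreement between `simulated_var_eff` and
  `resampled` thresholds is the diagnostic.
- The low-efficiency census needs the allele to be *called* somewhere; an
  allele that never clears the artefact bar in any individual is invisible
  to the census and will surface only as a depressed allele count or a
  failed T1 verdict.
- Locus assignment, allele nomenclature beyond stable registry names, and
  amino-acid reporting beyond the stop-codon check are out of scope.
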