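---
title: "Crossover regions and recombination landscapes in hypervariable haploid crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossover regions and recombination landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressWarnings(suppressPackageStartupMessages(library(meioscan)))
```

## The problem

Meiotic crossing-over is usually studied between genotypes that are more
than 98% identical.  In hypervariable species — fungi whose within-population
nucleotide diversity reaches 5–6% and whose inter-population crosses can
involve parents differing at ~14% of sites — the marker density is so high
(one interparental difference every ~7 nt) that a crossover can be localized
to a tract of a few tens of nucleotides.  `meioscan` implements the full
analysis for such a cross between two haploid parents:

1. call every aligned site where the parents carry different unambiguous
   bases (`callMarkers`),
2. assign a parental origin to every marker along each haploid offspring
   (`assignOrigin`),
3. emit a **crossover region (COR)** wherever at least *k* consecutive
   markers match one parent followed by at least *k* matching the other
   (`detectCrossovers`), and
4. test the landscape of those CORs against carefully matched nulls:
   a length-biased exponential null for COR lengths, identity-tract-matched
   permutation controls for exon/intron enrichment, diversity / GC / MAF
   windows, Tajima's D, and linkage disequilibrium across COR midpoints.

A synthetic-cross generator (`simulateParents`, `simulateOffspring`,
`simulatePopulation`) reproduces the statistical structure this analysis
assumes, with every true breakpoint recorded, and is what the test suite and
the acceptance script run on.

## Coordinates and data model

Marker and COR coordinates are 0-based internally; GFF3 I/O is 1-based
inclusive and BED output 0-based half-open.  True breakpoints are inter-base:
breakpoint *b* falls between positions *b − 1* and *b*, so a COR
`[left, right]` contains *b* iff `left < b <= right`.  This makes containment
tests unambiguous.  COR length is defined as `right − left`, the positional
difference between the two flanking markers.  With mean marker spacing *g*
this convention makes the null expectation exactly *2g* (below); the
alternative "bases strictly between" convention would subtract one and is not
used.

## The detection rule and the double-crossover exclusion

`detectCrossovers` drops undetermined (`U`) calls — gaps, Ns, third alleles —
*before* run-length analysis, so missing offspring data weakens support
counts but never splits a run.  This mirrors analyses of independently
assembled (gappy) genomes, where a gap is evidence of nothing.  A boundary
between maximal same-origin runs is reported only when both flanking runs
hold at least *k* markers (default `k = 10`; 50 and 100 are the
conventional stricter settings).  A double crossover that transfers fewer
than *k* markers creates an interior run shorter than *k*, so neither of its
boundaries is emitted: the run-length rule *is* the double-CO exclusion, and
no separate pass is needed.  On clean data detection at `k = 100` is a
subset of `k = 50` which is a subset of `k = 10` (threshold monotonicity;
the test suite asserts it).

Two auxiliary filters follow the same conservatism: `boundaryFilter` removes
CORs within 500 nt of scaffold ends (assembly artifacts concentrate there),
and `classifyComplex` re-scans switches at a relaxed threshold and flags any
three switches within a window (default 1 kb) as a candidate complex
conversion tract (an A-B-A-B patchwork), since a single reciprocal exchange
cannot produce them.

## The length-biased exponential null

If interparental differences fall independently at per-site rate *p*,
inter-marker gaps are approximately exponential with mean *g = 1/p*.  A
crossover placed uniformly at random falls into a gap with probability
proportional to its length (the inspection paradox), and for exponential
lengths the containing gap has expectation **2g**.  At 14% divergence,
*g ≈ 7* nt and the null expected COR length is ≈ 14 nt.
`expectedCORLength` computes the analytic value; `containingGapMean` verifies
it by direct Monte-Carlo (draw gaps, drop uniform points, average the
containing gaps).  The discrete geometric analogue would give
*2/p − 1 ≈ 13.3*; we use the continuous form as the default and note the
discrete value here for completeness.

`fitExponentialKS` tests observed COR lengths against an exponential with
rate estimated as 1/mean.  Because the rate comes from the same sample, the
plain one-sample Kolmogorov–Smirnov p-value is conservative; a
Lilliefors-style parametric bootstrap (`bootstrap = TRUE`) is available when
a calibrated p-value matters.  The plain test is the default because it is
the form conventionally reported.

## Identity-tract-matched controls

Any enrichment statement about CORs must control for the one thing CORs are
guaranteed to be: long identity tracts.  `sampleMatchedRegions` draws, for
each COR, a random inter-marker gap of *exactly* the same length elsewhere in
the genome, excluding gaps overlapping any observed COR.  When no exact
match exists the nearest length within ±10% is accepted with a warning, and
an orphan COR raises an error naming it — silent mismatches would bias the
null.  `permutationEnrichment` builds the null feature-count distribution
from 1,000 such control sets by default and reports the add-one estimator
`(1 + #{null ≥ obs})/(n + 1)` for enrichment (and its ≤ twin for depletion),
which cannot return p = 0.  "Residing within" a feature means full
containment of `[left, right]`; a midpoint-containment variant is exposed as
a flag because the choice is not forced by anything in the data.

For the diversity contrast (`piContrast`) the control sets can additionally
match each COR's exon-containment status (`matchExon = TRUE`), isolating the
within-exon diversity reduction from the mere fact that CORs sit in exons.

## Population statistics

Two panels of aligned haploid genomes enter through a joint site filter
(`sampleSites`): a site is kept only when at least 10 individuals are
callable in *both* panels, and exactly 10 callable individuals are drawn at
random *per site* and frozen.  Subsampling per site rather than per region is
a deliberate simplification: every statistic used downstream (π, MAF,
Tajima's D) is a per-site statistic, for which the two schemes are
equivalent in distribution, and the per-site rule needs no region bookkeeping.

* π is the average pairwise dissimilarity among the 10 sampled haplotypes,
  averaged over callable sites (pairwise deletion).  `piContrast` reports
  both the mean of per-window values and the site-pooled value, since curves
  in the literature are ambiguous between the two; they agree at large
  windows.
* MAF is minor-allele count / 10 at biallelic sampled sites (multiallelic
  sites are excluded, extending the biallelic rule used for LD).
  `mafProfile` compares sites inside CORs with sites in 10-kb windows
  centered at COR midpoints (COR-internal sites excluded from the control)
  using a two-sided Mann–Whitney test, and attaches 95% confidence intervals
  from 1,000 bootstrap resamples of the observed frequency classes — i.e.
  sites are resampled i.i.d. with the empirical class probabilities, which
  is our reading of frequency-stratified resampling; by construction the CI
  covers the observed mean.
* `classifySites` calls a biallelic exonic site synonymous or nonsynonymous
  by substituting the two alleles into the codon reconstructed from the
  panel's majority bases at the other two codon positions; codons containing
  gaps or a second segregating site are excluded rather than guessed.
* `tajimasD` is the standard 1989 statistic computed from the fixed sample
  of 10; it is undefined (NA, flagged) with no segregating sites.

## Linkage disequilibrium

`ldR2` implements
r² = (x₁₁ − p₁q₁)² / (p₁p₂q₁q₂)
on the sampled haplotypes, identical to the squared Pearson correlation of
0/1-coded alleles (a property the tests exploit as an independent check).
`ldAroundCORs` compares pairs of biallelic SNPs that straddle a COR midpoint
against pairs lying wholly in a window centered 10 kb away.  The control
side alternates per COR so neither flank is systematically favoured, and
both control SNPs must sit on the same side of the COR.  Pair distance is
capped (default 5 kb) and pairs per COR are subsampled to a cap, which
bounds compute without biasing the distance mix within a class.  Each pair
re-draws 10 individuals among those callable at both sites, as sample-size
equality across pairs matters more than reusing a fixed panel.

## What the generator emulates — and what it does not

`SimConfig` defaults encode the study conditions: genome-wide parental
divergence 0.14; exon fraction 0.5 with divergence suppressed in exons
(factor 0.7, reproducing ~7 nt genome-wide vs ~9 nt exonic marker spacing);
exon GC 0.60 vs background 0.58; 17 offspring; two panels of 13 and 19
haplotypes targeting π = 0.06 and 0.05; LD decay scale 1,000 nt.  Because
`divergence` is a *genome-wide realized* target, the non-exon rate is
inflated so the exon-suppressed mixture still lands on 0.14.  Mutations are
independent per site with no indels, so the parental alignment is exact by
construction — producing alignments is outside this package's scope, and
downstream code consumes aligned coordinates only.

Crossover placement models: `uniform`; `exon_biased` (exonic positions
weighted); `hotspot` (restricted to hotspot intervals); and `mmr_biased`,
where uniform proposals are accepted with probability 1 − exp(−g/s) for
containing inter-marker gap g and scale s (`mmrScale`, default 20 nt).  No
quantitative form of mismatch-repair rejection is established for this
system; the exponential-in-gap acceptance is this package's modeling choice,
chosen because it is monotone in local identity-tract length, has a single
interpretable scale, and degenerates to uniform placement as s → 0.  It is
exposed in the configuration rather than hidden.

Population panels are mosaics of two founders with exponential ancestry
segments of mean `ldDecayScale`, extra breakpoints concentrated in hotspots
(`hotspotIntensity`), and per-site private mutations contributing
`popSingletonShare` (default 15%) of diversity.  This is the stationary
endpoint of a forward founder-recombination process; only the properties the
analysis consumes — π level, exon suppression, LD decay scale, a rare-variant
excess where selection is emulated — are calibrated, and founder divergence
is re-calibrated up to three times (error if the target stays >25% away).
The generator does **not** emulate coalescent genealogies, indels,
inversions, assembly or read error, or gene conversion without crossover, so
green tests certify the statistical machinery, not robustness to those
artifacts; on real data the conservative filters (ACGT-only sites, U-calls,
boundary margins, double-CO exclusion) carry that weight.

## Numerical choices and problem sizes

All randomized operations take an explicit seed and derive per-stage
sub-seeds; identical configurations reproduce outputs byte for byte.
Majority-vote windows (`smoothGenotype`, 100 kb / 25 kb defaults) return `U`
on ties or empty windows.  The 2×2 GC test uses no continuity correction —
counts are nucleotides and large.  The test suite and the acceptance script
run on genomes of 30 kb–1 Mb with up to 400 replicate crosses for the
permutation-uniformity property and 10 replicate panels for diversity
calibration; these sizes were chosen as the smallest at which the asserted
tolerances (3 binomial SEs; 20% relative on π; binomial confidence band on
type-I error) are comfortably informative.

## Known limitations

* Misalignment screening (BLAST, read-pair confirmation) is out of scope;
  on real assemblies the detected set should be treated as candidates until
  screened.
* The exon model is compact single-CDS genes; UTRs and alternative splicing
  are not represented, so synonymous/nonsynonymous calls on real annotation
  should use the annotation's own CDS records.
* The permutation null conditions on identity-tract length only (optionally
  exon status); other covariates of crossover placement (GC, chromatin) are
  reported as window statistics but not matched.
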