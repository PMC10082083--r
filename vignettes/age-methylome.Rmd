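---
title: "Age-resolved methylome analysis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-resolved methylome analysis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`methage` analyses age-structured whole-genome bisulfite sequencing (WGBS)
designs: several chronological ages, two biological replicates per age,
per-cytosine methylated/unmethylated read counts as input. This vignette
explains the statistical models behind each stage, why the defaults are
what they are, what the bundled synthetic data generator does and does not
emulate, and the numerical conventions used throughout.

## Site-level model

A cytosine's methylation ratio is the number of methylated reads divided
by total reads at that site. Sites below `coverage_min = 4` reads are
excluded from all level calculations — at lower depth the ratio is too
granular to be informative. All *regional* levels are count-weighted:
`sum(mC) / sum(mC + uC)` over the covered sites of the region, never a
mean of per-site ratios, so deeply covered sites carry proportionally more
information and the statistic is invariant to splitting a site's reads
into pseudo-sites. A configuration flag (`level_weighting` semantics via
`merge_cg_strands`/pooling choices below) is deliberately not offered for
the ratio itself; the count-weighted form is the only one used.

Symmetric CG sites on the two strands are **not** merged into dyads by
default. Keeping strands separate preserves the ability to check
plus/minus profile consistency, which the package tests as an invariant;
`merge_cg_strands = TRUE` pools the pair by summing counts.

Bisulfite conversion is estimated from an unmethylated lambda spike-in as
one minus the pooled lambda methylation level (counts summed over all
lambda cytosines, not site-averaged, so deep sites dominate as they
should). The conversion rate is reported as QC only; observed ratios are
not corrected for non-conversion. For the companion "fraction of
methylated cytosines" statistic, a site is called methylated when a
one-sided binomial test of its methylated count against the non-conversion
rate survives BH control at `mc_call_fdr = 0.05` — the conventional WGBS
call, needed because the underlying studies never define "methylated site"
operationally.

## Contexts and sub-contexts

Both strands are scanned: a plus-strand cytosine is read with its two
downstream bases, a minus-strand cytosine (a G on the reference) on the
reverse complement. CG/CHG/CHH follow the plant convention (H = A, C or
T), refining into 4 + 3 + 9 trinucleotide sub-contexts. Cytosines whose
downstream trinucleotide runs off the chromosome end cannot be classified
and are dropped, as are trinucleotides containing N (tallied in a QC
attribute).

## Metaprofiles

Gene and TE profiles divide the body proportionally into 20 bins and the
2-kb flanks into 20 fixed 100-bp bins, oriented 5′→3′. Proportional bodies
with fixed flanks is standard metaplot practice: body bins compare
positions across features of different length, while flank decay is a
distance effect best shown on an absolute scale. Features with a body
shorter than 20 bp cannot host 20 proportional bins and are skipped with a
tally. Pooling across features is read-count-weighted; the profile of a
union of disjoint feature sets therefore equals the count-weighted
combination of the parts (a tested invariant).

Exon-only profiles concatenate each gene's exons in transcript order into
a virtual body before binning, and report a 3′-skew statistic — mean of
the last five bins minus mean of the first five — per intron-count group
(defaults 0, 1–2, 3–5, ≥6). Intron-length panels profile the upstream
exon (5 bins), intron (10 bins) and downstream exon (5 bins) per intron
ordinal and length group. The length groups default to ≤1 kb, 1–5 kb,
5–20 kb and >20 kb: 5 kb and 20 kb are the biologically salient
thresholds for long conifer introns, and the remaining break splits the
short-intron mass sensibly; all breaks are configurable.

## DMR detection

The genome is tiled into fixed 1000-bp bins. A bin enters testing for a
context when it contains at least one cytosine of that context and has
total read coverage of at least 4 in at least one sample; per-site
coverage filters are *not* applied at this stage, since binning already
aggregates counts. For a two-group comparison, replicate counts are summed
within each group and the 2×2 table of methylated/unmethylated counts is
tested with a two-sided Fisher exact test — the p-value sums all
hypergeometric outcomes no more probable than the observed one, with the
customary `1e-7` relative tie tolerance. The pooled-replicate Fisher
exact test is the standard choice for count-based windowed DMR calling
and matches the pooled-level effect definition exactly. The effect is the
difference of pooled weighted levels, and a DMR call requires a BH-adjusted
*p* strictly below 0.01 *and* an absolute difference of at least 0.2 (CG),
0.15 (CHG) or 0.1 (CHH). BH families are per context × comparison, because
the effect thresholds are context-specific. "Hyper" always means more
methylated in the older group of an age comparison. Adjacent significant
bins are not merged into larger regions; all downstream set logic
("overlap" between DMR sets) is bin identity on the shared grid.

Degenerate inputs: a group with zero total count yields NA difference and
p; an all-methylated or all-unmethylated margin gives p = 1.

## Age-trend analysis

Age DMRs are called for the three big-gap comparisons (oldest vs youngest
and the two flanking gaps). To remove age-independent epigenetic drift,
DMRs are also called between the two replicates within every age, at the
same thresholds; any age-DMR bin that is also a replicate-DMR bin *of the
same context in any age* is excluded, and the surviving "reserved" DMRs
feed the trend analyses. A bin becomes part of the consensus set when
called in the same direction in at least `min_consensus_comparisons = 2`
comparisons; bins called hyper in one comparison and hypo in another are
contradictory and dropped (tallied).

Reserved bins yield 4-point trajectories (replicates pooled per age, bins
uncovered in any age dropped). Trajectories are clustered against model
profiles in the spirit of short time-series expression mining: with only
four ordinal time points and a maximum unit change `c = 1`, all 27
integer step profiles are enumerated and the profile-selection step of the
original algorithm is unnecessary. Each trajectory is standardized
(subtract the first value, scale by the range unless degenerate) and
assigned to the profile with the highest Pearson correlation, ties going
to the lower profile index in the fixed lexicographic profile order; flat
trajectories go to the flat reference profile, which never enters
significance ranking. Ages are treated as ordered categories, not calendar
years — the planted "linear" trends are linear in age index, matching the
unit-step profile geometry. Profile significance compares the observed
assignment count with the expectation estimated from `n_permutations`
(default 1000) full passes in which every trajectory's time order is
permuted independently; the one-sided binomial tail p is computed (also in
log space, which breaks ties between astronomically small p-values when
ranking), then BH-adjusted across the 26 non-flat profiles. On pure-noise
trajectories this procedure is conservative — the discrete binomial tail
plus an expectation estimated under the same assignment rule keeps the
family-wise rate of any significant profile well below the nominal level
(a tested property).

Element assignment of DMR bins is an exhaustive, exclusive priority
partition — TE > gene body > promoter (2 kb upstream of the TSS) >
downstream (2 kb past the TES) > intergenic — with one base pair of
overlap sufficing. Gene linkage uses the gene body ± 2 kb; a gene may be
both hyper- and hypo-linked and one DMR may link several overlapping
genes.

## Expression linkage

Genes are grouped by TPM with the canonical half-open breaks (0, ≤1, ≤10,
≤50, >50). For the gene-level groupings the expression value is the mean
TPM across samples; the two-group flank profiles are explicitly
per-sample, using each sample's own TPM. Pairwise group comparisons use
the two-sided Mann–Whitney test as implemented in `stats::wilcox.test` —
exact for small tie-free samples, normal approximation with continuity and
tie correction otherwise — on *raw* p-values at the 0.01 threshold: the
letter display deliberately encodes plain pairwise significance rather
than multiplicity-adjusted p, so a letter difference reads directly as
"this pair differs at p < 0.01". The
compact letter display uses insert-and-absorb, so two groups share a
letter exactly when their pairwise p is at or above the threshold (a
tested invariant). Groups with fewer than two members are excluded and
reported.

Marker segments are user-supplied intervals (a real genome is out of
scope); the synthetic markers carry their own coordinates in the ground
truth. Per segment, replicate counts are pooled per age and the Pearson
correlations of the level series with the per-age mean TPM and with age
rank are reported; constant series yield NA.

## The synthetic methylome generator

The generator emulates the statistical structure the analyses assume:

* a compact random genome (default 2 × 1 Mb) with conifer-flavoured gene
  architecture — log-normal exons, an intron mixture in which 15% of
  introns fall in 5–20 kb and 5% exceed 20 kb, and TEs filling 45% of the
  genome with a strong preference for long introns and intergenic space,
  never exons;
* class-based background methylation per context (exon, intron, TE,
  intergenic), with high CG/CHG and low CHH levels, a per-gene multiplier
  on exons and flanks creating between-gene variation, and Gaussian
  site-level jitter (SD 0.05) shared by all samples;
* negative-binomial coverage (mean 20×, size 8) — the sources are silent
  on coverage dispersion, and the negative binomial mimics real WGBS
  coverage heterogeneity; methylated counts are binomial with
  `p + (1 - p) * conversion_failure_rate`, so non-conversion (default
  0.005) inflates observed methylation additively on the unmethylated
  fraction only, and no other error mode is modelled;
* planted signal on the 1000-bp grid: age-trend bins moving linearly over
  the age index from 0.4 by ±0.3 (defaults: 120/40 CG and 200/60 CHG
  hyper/hypo bins), 100 age-independent bins in which the two replicates
  differ by 0.25 in every age, and 10 marker genes with a forced long
  first intron carrying a segment (2.5 kb upstream through the 5′ 8 kb of
  that intron) whose CHG level falls 0.70 → 0.25 across ages while TPM
  rises 10 → 100 linearly in age index;
* expression coupled linearly in log space to each gene's true
  exon+downstream methylation (slope −8, gene noise SD 0.8, sample noise
  SD 0.1), with a quarter of genes silenced to TPM = 0 by a noisy
  threshold on methylation itself, so silenced genes occupy the
  methylated extreme — real silencing is of course not a deterministic
  function of methylation, but this is the cleanest way to make the
  TPM = 0 group behave like its real counterpart;
* an unmethylated lambda spike-in (60 000 cytosines per sample) and sRNA
  density tracks per length class, independent of methylation by default.

What it does **not** emulate: read-level artefacts (mapping bias, M-bias,
PCR duplicates, SNPs misread as conversion events), chromosome-scale
methylation gradients, correlated site-to-site methylation along reads,
biological age variance beyond the planted trends, and the sheer scale of
a conifer genome. Passing tests therefore demonstrate that the statistical
machinery is correct and calibrated on data satisfying its assumptions —
not that those assumptions hold on any particular real library.

Every stochastic stage derives its own stream from the master seed, so an
identical configuration reproduces byte-identical outputs regardless of
which subset of stages is run.

## Validation study sizes

The packaged validation suite (tests and `scripts/acceptance.R`) runs, as
the package's chosen desk-scale designs: the default study above (~0.8 M
cytosines × 8 samples); a type-I calibration design with no planted signal
on 1 Mb; a gene-dense expression design (260 compact genes on 2 × 1.2 Mb)
sized so all five TPM groups are populated; and noise-free uniform-level
designs (no jitter, unit gene factors, zero non-conversion, 30× coverage)
for metaprofile fidelity, where every deeply covered bin (≥ 10⁴ pooled
reads) must sit within 0.02 of its planted level and the binomial error
model must hold across bins. Exact-arithmetic checks (Fisher p against
full hypergeometric enumeration for all tables with margins ≤ 60, BH
against the brute-force min-over-tail rule, rank-sum p against exact
enumeration) are independent of the simulations. Model-profile ranking
stability uses 20 reruns at 300 permutation passes each.

## Known limitations

* The Fisher test treats reads as independent Bernoulli draws; biological
  replicate overdispersion is absorbed only through the effect-size
  threshold, not the p-value. A dispersion-aware test (e.g. logistic
  regression per bin) would be the natural extension.
* Bin-identity overlap means a real DMR straddling a grid boundary counts
  as two bins; no merging of adjacent significant bins is performed.
* With four time points the model-profile space is tiny; profiles are
  ranked by log-tail p, and ties beyond that resolve by fixed profile
  order.
* The per-bin "methylation level" used in replicate correlation is
  count-weighted; a site-mean variant would weight shallow sites more and
  give slightly different r.
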