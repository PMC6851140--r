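---
title: "Methods: sex-linked marker discovery, genotypic sexing and Y-lineage profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-linked marker discovery, genotypic sexing and Y-lineage profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexlinkr)
```

## The problem

Many amphibians carry homomorphic sex chromosomes: the X and Y (or Z and W)
are cytologically indistinguishable, so the sex-determining system cannot be
read off a karyotype. Reduced-representation genotyping-by-sequencing
platforms such as DArTseq produce two marker types that make the system
visible statistically: codominant SNP calls, and dominant presence/absence
(PA) calls recording whether a restriction fragment appears in a sample's
genomic representation at all. A locus inside the non-recombining
sex-determining region shows a diagnostic pattern: under male heterogamety
(XX‑XY) every male is heterozygous (reference allele on the X, alternate on
the Y) and every female homozygous for the reference allele, while a
Y-specific fragment is present in every male and absent from every female.
Under female heterogamety (ZZ‑ZW) the same patterns attach to females.

`sexlinkr` turns that observation into a tested pipeline: score every locus
under both hypotheses, call the system only on unanimous evidence, bound the
number of markers that would pass by chance, sex unknown individuals from
the discovered markers, and profile partial sex linkage, which carries
information about the recombination history of the Y.

## Concordance scoring

For one SNP locus and the XY hypothesis the statistic is

$$S = \underbrace{\tfrac{\#\{\text{males scored HET}\}}{\#\text{males}}}_{p_{het}}
    + \underbrace{\tfrac{\#\{\text{females scored HOM\_REF}\}}{\#\text{females}}}_{p_{hom}},$$

with denominators over *all* confidently sexed individuals of the sex, so a
null allele or any discordant call counts against the score
(`denominator = "all"`, switchable to `"called"` for unfiltered data — with
the call-rate-1 SNP filter the two coincide). A locus is *perfectly
sex-linked* iff both proportions equal 1 exactly; the test is on integer
counts, never a floating-point tolerance on $S$. Unknown-sex (`U`)
individuals are excluded from discovery scans. The ZW score is the mirror
image, and swapping every M/F label provably exchanges the XY and ZW outputs
at every level (a property the test-suite asserts).

PA loci use the analogous proportions with a relaxed threshold: dominant
markers score at lower call rates, and a heterozygous fragment dose often
surfaces as a null rather than a clean "present". A PA locus is sex-linked
when presence in the heterogametic sex and absence in the homogametic sex
both reach `min_prop` (default 0.9) *and* no contradictory call exists
(no absent male, no present female under XY; `require_contradiction_free`).

The system is inferred conservatively (`infer_system()`): XY only if at
least one XY-linked marker exists and zero ZW-linked ones, ZW symmetric,
otherwise `UNDETERMINED`. No majority voting: one genuine counter-marker is
evidence of a problem, not noise to be outvoted.

## Spurious linkage

Screening tens of thousands of loci in a modest sample will produce some
sex-concordant loci by chance. The screening model treats each individual as
matching a sex-specific genotype independently with probability one half, so
a locus passes the perfect screen with probability $P_i = 0.5^n$ for $n$
sexed individuals, and the expected spurious count among $m$ loci is
$m \cdot 0.5^n$ (`spurious_probability()`, `expected_spurious()`). At
$n = 44$ and $m \approx 2 \times 10^4$ this is $\sim 10^{-9}$: discovery is
effectively noise-free at this sample size. `min_sample_size()` inverts the
bound, returning the smallest $n$ with $m \cdot 0.5^n < 1$ under strict
inequality (15 for $m = 20{,}111$).

The one-half is a heterozygosity-0.5 approximation, not an exact null: the
true per-locus pass probability depends on allele frequency
($(2pq)^{n_m}(p^2)^{n_f}$ under Hardy–Weinberg) and is typically smaller.
The suite therefore checks the implementation against an *exact permutation
oracle* rather than the closed form: with 4 males and 4 females there are
$\binom{8}{4} = 70$ sex labelings, and a locus is XY-perfect under exactly
one of them iff it carries exactly four HET and four HOM_REF calls, giving
an exact null expectation of (number of such loci)/70 per dataset. The
observed spurious count on simulated unlinked data matches that expectation
and sits below the $0.5^n$-scale prediction, as an upper bound should.

## Moderately sex-linked loci and false-positive control

A recombining (pseudoautosomal) region of the Y produces loci where every
female is still homozygous reference but only a subset of males is
heterozygous. `find_moderate_loci()` implements: every homogametic-sex call
exactly `HOM_REF` (nulls forbidden by default, `allow_null_homogametic` to
tolerate), heterogametic-sex HET proportion in `[min_het_prop, 1)`, no
heterogametic `HOM_ALT` call (impossible when the alternate allele is
confined to the Y; `allow_homalt_heterogametic` to tolerate), and not
already in the perfect class.

`min_het_prop` defaults to **0.5**, and the choice is deliberate. The
female-side rule alone is weak protection when the reference allele is
common: with 18 females, an autosomal locus at reference frequency $p$ has
all females homozygous reference with probability $p^{36}$, and its male
heterozygosity is around $2pq$. Integrating over a uniform allele-frequency
spectrum on $[0.05, 0.95]$, a floor of 0.25 admits an autosomal locus with
probability $3.1 \times 10^{-4}$ — about six expected false positives among
20,000 autosomal loci, which would silently contaminate the moderate set and
corrupt every downstream per-male profile. A floor of 0.5 plus the
`HOM_ALT` exclusion drives the expectation below 0.01 per study-scale run,
while a genuine pseudoautosomal locus — one male lineage fully heterozygous
and a second mostly so — sits near 0.6–0.75 male heterozygosity and passes
with near certainty. Users scanning smaller panels, or populations where
the fully heterozygous lineage is small, can lower the floor explicitly.

The moderate scan runs on the *genotype-augmented* registry: unknown-sex
individuals first receive their genotypic sex from the perfect markers
(`augment_registry()`), then contribute to the per-sex proportions. This
ordering matters — discovery never uses genotypic sexes (that would be
circular), but the moderate-locus proportions are sharpened by them.

## Genotypic sexing

`assign_sex()` pools SNP and PA markers with equal weight. Under XY a HET
call or PRESENT fragment votes male, HOM_REF or ABSENT votes female, a null
is uninformative, and a HOM_ALT call at a perfectly sex-linked locus —
impossible under the clean model — votes for *neither* sex, lowering
concordance rather than being silently dropped. The call is the winning sex
when its vote share reaches `unanimity` (default 1.0, i.e. perfect
conformity; lower for noisy data), else `AMBIGUOUS`.
`flag_discordance()` marks calls whose confident phenotype contradicts a
confident genotype — candidate sex reversal or field mis-sexing; unknown
phenotypes are never discordant. Note that an individual that is genuinely
sex-reversed *and* confidently phenotyped will weaken the discovery scan
itself (its calls contradict its recorded sex at every truly linked locus);
detecting reversal therefore presupposes markers discovered in individuals
whose phenotype is trusted, which is why tentatively sexed animals belong in
the `U` class.

## Male heterozygosity groups and the Welch test

`male_het_profiles()` computes each male's heterozygous fraction over the
moderate loci, with non-null calls as the denominator — grouping is
per-individual and a null call carries no genotype (switchable to the
all-loci denominator). `assign_groups()` applies fixed thresholds: fraction
exactly 1 → `MALES1` (unrecombined Y haplotype), `[high, 1)` → `MALES2`
(occasional X–Y recombination; `high` = 0.85), `≤ low` → `MALES3`
(feminised Y, carrying X-like reference alleles at most pseudoautosomal
loci; `low` = 0.20), otherwise `UNASSIGNED`. The groups partition the
defined profiles by construction.

`welch_t_from_values()` / `welch_t_from_summary()` implement the
unequal-variance two-sample $t$-test:
$t = (\bar a - \bar b)/\sqrt{s_a^2/n_a + s_b^2/n_b}$ with
Welch–Satterthwaite degrees of freedom and a two-tailed $p$ from the
$t$ distribution. The summary route exists because published comparisons
often survive only as $(n, \bar x, s)$ triples, which `stats::t.test()`
cannot consume; the value route reduces to the same formulas and the suite
pins both to `stats::t.test()` at $10^{-12}$. Degrees of freedom are
reported both real and floored (the floored value is what test write-ups
print); $p$-values are never clamped.

## Population-structure support

*F_ST.* `pairwise_fst()` is a Nei-style $G_{ST}$ on expected
heterozygosities: per locus, $H_S$ is the unweighted mean within-site
$2p(1-p)$ and $H_T$ the expected heterozygosity of the mean site frequency;
the estimate is the ratio of sums across loci (ratio-of-averages, which is
stable where averaging per-locus ratios is not). Loci monomorphic across
the compared sites are skipped. No small-sample correction is applied — the
implementation is documented and swappable, and its outputs are
descriptive, not estimator-grade.

*Nei distance.* For individuals, per-locus allele frequencies are 1, 0.5
or 0, and $D = -\ln\!\big(J_{xy}/\sqrt{J_x J_y}\big)$ with the identity
sums $J$ accumulated **across loci before the ratio** — aggregating first
keeps $D$ finite when single loci carry opposite homozygotes, which is
exactly what a feminised-Y male versus an unrecombined male produces. Null
calls are dropped pairwise. A pair with zero total identity (or no shared
called locus) receives a configurable sentinel distance (default 50) with a
warning rather than an infinity that would poison downstream embedding.

*PCoA.* Classical metric scaling: double-centre $-D^2/2$, eigendecompose,
scale eigenvectors by the square roots of the positive eigenvalues.
Negative eigenvalues (non-Euclidean distances) are dropped and excluded
from the variance proportions. Axis signs follow a fixed convention — the
largest-magnitude coordinate on each axis is positive — so coordinate files
are reproducible across platforms and BLAS implementations.

## The synthetic-data generator

`simulate_dartseq()` emulates the structure the pipeline is designed to
detect, at the scale of a 52-sample wild population
(`study_preset()`: 34 true males in lineages of 13/12/9, 18 true females,
8 masked phenotypes, 11 perfect SNP loci, 47 moderate loci, 6 Y-specific PA
fragments, and autosomal SNP/PA loci bringing the filtered totals to
20,111 and 19,121):

- **Perfect loci / PA fragments**: deterministic given true sex — males
  HET/PRESENT, females HOM_REF/ABSENT.
- **Moderate loci**: each male of lineage $i$ is heterozygous at $k$ of the
  $L$ moderate loci, with positions uniform. $k$ is drawn
  $\mathrm{Binomial}(L, p_i)$ at the lineage level ($p = 1,\ 0.92,\ 0.16$
  by default) and constrained to the lineage's band
  ($[\lceil 0.85L \rceil, L-1]$ for lineage 2, $[0, \lfloor 0.20L \rfloor]$
  for lineage 3). A per-locus independent Bernoulli model was considered
  and rejected: at $p_2 = 0.92$ and $L = 47$ an unconstrained draw lands a
  lineage-2 male at fraction 1.0 (or below 0.85) often enough that the
  planted group structure would be violated in a large share of datasets,
  making "generate then recover" tests meaningless. The band constraint
  binds rarely (≈ 4 % of draws at $L = 47$), preserves between-male
  variance, and is applied only when $p_i$ itself lies in the band — so the
  degenerate setting $p = (1,1,1)$ collapses every moderate locus into the
  perfect class, as it should.
- **Autosomal loci**: Hardy–Weinberg at reference-allele frequencies drawn
  uniformly from `af_range` (default $[0.05, 0.95]$); autosomal PA
  fragments present with a drawn per-locus frequency.
- **Unknowns**: `n_unknown` samples, chosen uniformly without replacement
  (equivalently, with probability proportional to class sizes), have their
  phenotype masked to `U`; genotypes follow true sex. **Sex-reversed**
  individuals (`n_sex_reversed`) instead have their recorded phenotype
  flipped.
- **Noise**: `null_rate` replaces cells by nulls uniformly; under the
  all-individuals denominator a planted perfect locus then scores
  $2(1-\text{null\_rate})$ in expectation (asserted by Monte-Carlo in the
  suite). `callrate_noise` assigns a fraction of loci a call-rate metadata
  value in $[0.5, 1)$, feeding the quality filter.
- **Reproducibility**: one global stream from `seed`; identical parameters
  give byte-identical files.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: linkage disequilibrium among autosomal loci,
a realistic (U-shaped) allele-frequency spectrum, genotyping error beyond
uniform nulls, read-depth structure, haplotypic (shared-breakpoint)
recombination in the pseudoautosomal region, or any correlation between
site and genotype (simulated sites are exchangeable labels, so simulated
F_ST hovers near its small-sample bias floor rather than reflecting real
substructure).

## Numerical and design choices

- Perfection is integer-count equality; no tolerance on $S$.
- Call categories are exact strings; `"0"/"1"/"2"` are categories, not
  counts, and parsing rejects any other token with locus/sample named.
- Metadata call rate is *given*, never recomputed: upstream reproducibility
  and call-rate metrics are computed on technical context (replicate
  assays, pre-filter samples) the delivered matrix no longer carries. The
  PA call-rate boundary is inclusive (≥ 0.90) by default with a strict
  option (`pa_call_rate_strict`).
- `min_sample_size()` uses strict inequality ($m \cdot 0.5^n < $ threshold)
  and is verified by direct evaluation on both sides of the boundary.
- Welch with zero variance in both groups: equal means is an error
  (statistic undefined); unequal means returns $t = \pm\infty$, $p = 0$.
- The per-locus scan is vectorised but pinned against the scalar
  single-locus implementation in the tests, and is deterministic and
  invariant to locus/sample permutation up to input order.

## Problem sizes used by the test-suite

Unit and property tests run on matrices of tens to hundreds of loci; the
null-scan oracle uses 1,000 loci × 44 samples × 20 replicates and the
permutation oracle 10,000 loci × 8 samples × 20 replicates; the end-to-end
acceptance checks run the full pipeline at study scale (52 samples,
20,111 + 19,121 loci). The whole suite completes in well under a minute on
one CPU; `scripts/acceptance.R` in a few seconds.

## Known limitations

- The spurious-linkage bound is a screening approximation; for exact
  inference on small samples use the permutation construction directly.
- F_ST is uncorrected for sample size and the published values it is
  compared against come from unspecified estimators on withheld site
  labels; treat it as descriptive.
- Moderate-locus discovery is per-locus; it does not exploit the block
  (haplotype) structure across males that a dedicated biclustering approach
  could, and its false-positive control is calibrated for study-scale
  panels (~20k loci, ~18 homogametic individuals) — re-examine
  `min_het_prop` for very different shapes.
- Genotypic sexing assumes the discovered markers are truly linked;
  in populations with ongoing sex reversal the discovery panel must come
  from individuals of trusted phenotype.
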