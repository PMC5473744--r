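---
title: "Haplotype-based genotype imputation for multiparental inbred strains: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based genotype imputation: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccimpute)
```

## The problem

Collaborative Cross (CC) strains are recombinant inbred mice descended from
eight inbred founder strains (AJ, B6, 129, NOD, NZO, CAST, PWK, WSB). Each CC
genome is a mosaic of founder haplotypes, so the genotype of a CC strain at
any founder variant can be inferred without sequencing the strain itself:
sparse array genotyping places founder-haplotype probabilities at markers,
and founder sequencing supplies the alleles each haplotype carries. Three
sources of uncertainty must be carried through rather than collapsed:
founder sequencing calls can be ambiguous (and occasionally heterozygous),
marker haplotype assignments are probabilistic, and nominally inbred strains
still segregate at some loci (residual heterozygosity). `ccimpute`
implements the full probabilistic chain and keeps every output a
distribution.

## The model

All quantities are specific to one variant and one strain. Let $H$ be the
founder haplotype set, $\{h,h'\}$ an unphased founder pair (diplotype; 36
states for 8 founders), and $\{a,a'\}$ an unphased allele pair.

1. **Marker interpolation.** The diplotype distribution at a variant is the
   linear mix of the distributions at the nearest flanking markers. In the
   default *proximal* convention each marker's distribution is weighted by
   the distance to the opposite marker,
   $p = (w_r p_{\mathrm{left}} + w_l p_{\mathrm{right}})/(w_l + w_r)$,
   where $w_l$ ($w_r$) is the distance from the variant to the left (right)
   marker. This makes a variant that coincides with a marker inherit that
   marker's distribution exactly. The alternative `as_printed` convention
   multiplies the left marker by $w_l$ instead; it assigns weight zero to a
   coincident marker, which we consider a transcription slip in the source
   derivation, but it is provided verbatim for auditability and can be
   selected everywhere via `mode = "as_printed"`. Outside the marker span
   the nearest marker is used with weight 1 (the zero-distance limit).

2. **Phasing.** Both phasings of a heterozygous diplotype are taken as
   equally likely, so each ordered pair receives half of the unphased mass.
   A homozygous diplotype has one phasing and keeps full mass; applying the
   factor 1/2 there would destroy probability, so the halving is restricted
   to heterozygous states.

3. **Transmission.** Given a phased diplotype $(h, h')$, the maternal and
   paternal alleles are transmitted independently; each copy of a founder's
   (possibly uncertain, possibly heterozygous) genotype is transmitted with
   probability 1/2:
   $p(T_h = a) = \sum_g \tfrac{\#a\,\text{in}\,g}{2}\, p(UG_h = g)$.

4. **Unphasing.** Ordered allele pairs are folded into unordered pairs by
   summing the two phasings; the homozygous diagonal is counted once.

F1 crosses reuse step 3 at the strain level: each parent transmits one
allele (or one haplotype) drawn from its own unphased distribution, the two
transmissions are independent, and the offspring distribution follows the
same unphasing rule. Functional consequences ride along with the
transmitted haplotype: the probability of a genotype state is applied
unchanged to its per-transcript consequences, and an allele equal to the
reference carries the literal term `"reference"`. Within-gene recombination
is ignored (mid-gene recombinations are rare in this population), exactly
as in the founder-consequence predictions the package consumes.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `prune_threshold` | 0.001 | probability | stored states below this are dropped and the remaining mass is *not* renormalized, so stored distributions may honestly sum to < 1 |
| `mode` | `"proximal"` | — | interpolation weight convention (see above) |
| het threshold in `residual_het_summary` | 0.25 | probability | a locus counts as residually heterozygous when it has at least a 25% chance of continuing to segregate (inclusive) |
| exon window | 100 | bp | variants are buildable when within 100 bp of an exon, closed arithmetic on 1-based coordinates; an indel intersects if any reference-spanned base does |
| `strict` | `FALSE` | — | founders absent from a VCF record are homozygous reference (the VCF convention); strict mode errors instead |

Equality comparisons on probabilities use a 1e-9 tolerance throughout;
`is_max` ties within 1e-9 are all flagged, so a max-only restriction can
return more than one row per group — deliberately, since picking one of two
equally likely states would misrepresent the distribution.

## What the synthetic generator emulates — and what it does not

`simulate_founder_panel()` and `simulate_cc_mosaics()` produce the complete
input set (founder VCF, consequence TSV, exon BED, marker diplotype CSV) in
exactly the dialects the readers consume, with a single integer seed
recorded in every file header. The stated world is: 8 founders, 20 strains,
2 chromosomes, 50 markers and 500 variants per chromosome; occasional
founder heterozygosity (`het_rate`, default 0.02); short indels
(`indel_rate`, default 0.1); mosaic breakpoints Poisson with mean 9 per
chromosome (within the realistic range for CC chromosomes); residual
heterozygosity drawn once per mosaic segment (default 0.03, matching the
few-percent genome-wide figure reported for the real population); marker
blurring that leaves most markers near-certain and spreads `uncertainty_level`
mass over states sharing a haplotype with the truth.

It does **not** emulate: real mouse recombination maps or array marker
spacing, funnel-breeding pedigrees, linkage between variants (each variant
is imputed independently, as in the source method), sex-chromosome or
mitochondrial transmission asymmetries (autosomal rules are applied to
every contig), or structural variants over 100 bp. A green test on this
world therefore establishes the correctness of the probabilistic machinery,
not genome-scale accuracy figures, which depend on the real marker density
and founder call quality.

Two statistical notes on the recovery tests, decided before the tests were
frozen:

* With point-mass markers, a variant whose flanking markers straddle a
  mosaic breakpoint is *necessarily* imputed as a two-state mixture — no
  correct implementation can return the truth point mass there. Exact
  recovery is therefore asserted on "clean" (strain, variant) pairs (both
  flanking markers in one truth segment; the large majority), and
  flanking-mixture consistency is asserted on the rest.
* The residual-heterozygosity summary is a variant-weighted mean of
  per-segment Bernoulli draws, so its sampling SE is
  $\sqrt{p(1-p)\sum_k w_k^2}$ with $w_k$ the share of (strain, variant)
  pairs in segment $k$ — not $\sqrt{p(1-p)/n_{\text{variants}}}$, which
  would ignore the perfect correlation of variants within a segment.
  Similarly, the sampler-oracle check makes roughly a thousand simultaneous
  per-state comparisons; an exact implementation is expected to exceed 3 SE
  on ~0.3% of them, so the exceedance count is judged against its own
  binomial envelope while per-instance agreement is held to a total
  variation distance below 0.01.

## Numerical and design choices

* Unphased pairs are stored under canonical string keys (`"C/T"`), sorted
  byte-wise so equal-prefix indel alleles order shorter-first and dumps are
  reproducible across locales.
* The store is a directory of per-chromosome CSV shards plus JSON metadata,
  mirroring the per-chromosome sharding of the original database while
  keeping the artifact dependency-light and diffable; rebuilds from
  identical inputs are byte-identical. Variant ids are assigned in
  ascending (chromosome, position, reference, alternate) order.
* The builder works in a dense 36-state diplotype basis with a precomputed
  phasing operator and per-variant transmission matrices, so the per-variant
  genotype is two small matrix products; tests verify it against a
  completely independent nested-loop enumeration at 1e-12.
* Founder genotype uncertainty defaults to point masses on the VCF GT call
  (consensus calls); `mode = "likelihood"` converts PL/GL fields instead.
  The construction of founder call distributions is not specified by the
  source method, so the point-mass default was chosen to match released
  consensus calls and the likelihood path is opt-in.
* Pruning never renormalizes, in any code path; mass lost to pruning is
  visible in query output and in cross results (offspring mass is the
  product of parent masses).
* Reference identity uses the maximum-likelihood genotype (ties involving
  the reference count as identical); a probability-weighted alternative is
  exposed via `method = "weighted"` since the original definition is
  ambiguous.
* Consequence restrictions match if *either* allele's consequence is
  requested; `consequence_match = "both"` switches to the stricter reading.

## Known limitations

* Each variant is imputed independently; no linkage-aware joint imputation.
* F2, backcross and multi-generation pedigrees are out of scope; only F1.
* The consequence model inherits the founder predictions per haplotype and
  cannot re-predict effects for multi-variant haplotypes.
* Queries materialize annotated rows in memory; the store is desk-scale by
  design, not a server database.
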