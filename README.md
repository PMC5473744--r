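# ccimpute

Probabilistic genotype and diplotype imputation for multiparental
recombinant inbred strains — the Collaborative Cross (CC) in particular —
from founder sequencing calls and sparse marker haplotype probabilities.

## Who this is for

Geneticists working with CC (or CC-like) panels who need, at any exonic
founder variant: the probability distribution of a strain's unphased
genotype, its founder diplotype, the predicted state of an F1 cross between
any two strains, and per-transcript functional consequences — all *as
distributions*, because founder calls are imperfect, marker haplotyping is
probabilistic, and nominally inbred strains still segregate at some loci.

## The model in brief

For a strain $c$ at one variant, with founder haplotype set $H$:

$$p(UG_c = \{a,a'\}) = \sum_{(h,h') \in H \times H}
  p(T_h = a)\,p(T_{h'} = a')\; p(D_c = (h,h'))$$

(both orderings summed for $a \ne a'$), where the phased diplotype
probability $p(D_c)$ comes from linear interpolation of the unphased marker
diplotype distributions flanking the variant (each phasing of a
heterozygous pair equally likely), and the transmission probability
$p(T_h = a) = \sum_g \frac{\#a \text{ in } g}{2}\, p(UG_h = g)$
marginalizes the founder's own (possibly heterozygous, possibly uncertain)
genotype. F1 crosses apply the same transmission logic at the strain level;
consequences inherit the transmitted haplotype's annotation with unchanged
probability. Stored distributions are pruned at 0.001 and *never*
renormalized, so reported masses may honestly be < 1. See the vignette
(`vignettes/imputation-model.Rmd`) for conventions, edge cases and design
rationale.

## Worked example

Everything below is generated — no downloads. The synthetic generator
emits a founder VCF, exon BED, consequence TSV and marker diplotype CSV in
the exact dialects the readers consume:

```r
library(ccimpute)
panel <- simulate_founder_panel(dir = "demo", n_variants = 120, n_chrom = 1, seed = 7)
mos   <- simulate_cc_mosaics(panel, dir = "demo", n_strains = 6,
                             markers_per_chrom = 20, seed = 8)
store <- build_store(panel$vcf, mos$csv, panel$exons,
                     out_dir = "demo/store", consequence_tsv = panel$csq)

rows <- query_genotype(store, strains = "CC003", region = "chr1:1-400000")
head(rows[, c("variant_id", "pos", "strain", "allele_1", "allele_2",
              "prob", "is_max", "consequence_1", "consequence_2")], 3)
#>   variant_id    pos strain allele_1 allele_2 prob is_max      consequence_1      consequence_2
#> 1          1 160546  CC003        C        C 0.25  FALSE          reference          reference
#> 2          1 160546  CC003        C        T 0.50   TRUE          reference synonymous_variant
#> 3          1 160546  CC003        T        T 0.25  FALSE synonymous_variant synonymous_variant
```

Variant 1 sits in a residually heterozygous region of CC003: the strain has
a 25% chance of C/C, 50% of C/T and 25% of T/T, and each genotype row
carries its own per-transcript consequence with the genotype's probability.
Only the C/T row is flagged `is_max`. Summaries:

```r
head(residual_het_summary(store), 3)
#>   strain chrom   prop_het
#> 1  CC001  chr1 0.04166667
#> 2  CC002  chr1 0.00000000
#> 3  CC003  chr1 0.41666667
reference_identity_summary(store)
#> [1] 0.65625
```

`prop_het` is the fraction of buildable variants with at least a 25% chance
of continuing to segregate; `reference_identity_summary` is the fraction of
(strain, variant) pairs whose maximum-likelihood genotype is homozygous
reference. An uncertain parent's consequence transmission to an F1
offspring (the 40:30:30 diplotype with one synonymous and two stop-gain
haplotypes):

```r
v   <- cc_variant("chr1", 100L, "C", c("A", "G"), variant_id = 1L)
dip <- diplotype_dist(c(`AJ/AJ` = 0.40, `129/129` = 0.30, `NOD/NOD` = 0.30))
fg  <- list(AJ = c(`A/A` = 1), `129` = c(`G/G` = 1), NOD = c(`G/G` = 1))
ann <- data.frame(allele = c("A", "G"),
                  term = c("synonymous_variant", "stop_gained"))
f1_consequence_prob(dip, ann, fg, v)
#>        stop_gained synonymous_variant
#>                0.6                0.4
```

Picking only the most likely diplotype (AJ/AJ) would call this variant
synonymous; the full distribution shows a 60% stop-gain probability.

A command-line interface covers the same ground:

```sh
Rscript -e 'ccimpute::cc_cli()' simulate --out demo --seed 7
Rscript -e 'ccimpute::cc_cli()' build --vcf demo/founders.vcf \
    --markers demo/marker_diplotypes.csv --exons demo/exons.bed \
    --csq demo/consequences.tsv --out demo/store
Rscript -e 'ccimpute::cc_cli()' query genotype --store demo/store \
    --strains CC001,CC002 --region chr1:1-2000000 --max-only --out rows.csv
Rscript -e 'ccimpute::cc_cli()' stats het --store demo/store
```

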