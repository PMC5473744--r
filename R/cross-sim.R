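## F1 cross simulation: offspring genotype and diplotype distributions from
## two parental distributions, and marginal functional-consequence
## probabilities for the allele transmitted by one uncertain parent.

#' Transmission distribution of a parent strain
#'
#' The probability that a parent transmits each allele to an offspring:
#' each allele copy of the parent's (possibly uncertain) unphased genotype
#' is transmitted with probability 1/2. Works identically over haplotypes
#' when given a diplotype distribution. The output's total mass equals the
#' input's, so pruned parents yield sub-unit transmission mass.
#'
#' @param parent_dist a [genotype_dist()] or [diplotype_dist()].
#' @return a [transmission_dist()] over alleles (or haplotypes).
#' @export
strain_transmission <- function(parent_dist) {
  if (!length(parent_dist)) stop("empty parent distribution")
  transmission_dist(founder_transmission(parent_dist),
                    source = attr(parent_dist, "strain"))
}

## combine two transmission distributions into an unphased pair distribution
combine_transmissions <- function(t1, t2) {
  out <- outer(as.numeric(t1), as.numeric(t2))
  keys <- canonical_unphased(rep(names(t1), times = length(t2)),
                             rep(names(t2), each = length(t1)))
  tab <- rowsum(as.vector(out), keys)
  p <- stats::setNames(tab[, 1L], rownames(tab))
  p[p > 0]
}

#' F1 offspring genotype distribution
#'
#' Alleles are transmitted independently from the two parents, so the
#' offspring's unphased genotype {a, a'} has probability
#' `p(T1=a) p(T2=a') + p(T1=a') p(T2=a)` for `a != a'` and
#' `p(T1=a) p(T2=a)` for the homozygous states. Exactly symmetric in its
#' arguments; total mass is the product of the parents' masses (1 for
#' unpruned parents).
#'
#' @param parent1_gt,parent2_gt [genotype_dist()] objects at the same
#'   variant (an imputed distribution or a founder point mass).
#' @return a [genotype_dist()] for the offspring; its `strain` attribute
#'   holds both parent names in caller order.
#' @export
f1_genotype <- function(parent1_gt, parent2_gt) {
  v1 <- attr(parent1_gt, "variant_id"); v2 <- attr(parent2_gt, "variant_id")
  if (!is.null(v1) && !is.null(v2) && !is.na(v1) && !is.na(v2) && v1 != v2)
    stop("parents refer to different variants (", v1, " vs ", v2, ")")
  p <- combine_transmissions(strain_transmission(parent1_gt),
                             strain_transmission(parent2_gt))
  genotype_dist(p, strain = c(attr(parent1_gt, "strain"),
                              attr(parent2_gt, "strain")))
}

#' F1 offspring diplotype distribution
#'
#' Identical in form to [f1_genotype()], but transmission is of founder
#' haplotypes counted from each parent's diplotype distribution.
#'
#' @param parent1_dip,parent2_dip [diplotype_dist()] objects at the same
#'   locus.
#' @return a [diplotype_dist()] (source `"interpolated"`) for the offspring.
#' @export
f1_diplotype <- function(parent1_dip, parent2_dip) {
  l1 <- c(attr(parent1_dip, "chrom"), attr(parent1_dip, "pos"))
  l2 <- c(attr(parent2_dip, "chrom"), attr(parent2_dip, "pos"))
  if (!anyNA(c(l1, l2)) && !identical(l1, l2))
    stop("parents refer to different loci")
  p <- combine_transmissions(strain_transmission(parent1_dip),
                             strain_transmission(parent2_dip))
  diplotype_dist(p,
                 strain = paste(c(attr(parent1_dip, "strain"),
                                  attr(parent2_dip, "strain")), collapse = "x"),
                 chrom = attr(parent1_dip, "chrom"),
                 pos = attr(parent1_dip, "pos"), source = "interpolated")
}

#' Consequence probabilities for the allele transmitted by one parent
#'
#' Marginal probability that the allele one (possibly uncertain) parent
#' transmits to an F1 offspring carries each functional-consequence term,
#' marginalizing over the parent's diplotype, haplotype transmission, and
#' founder genotype uncertainty. An allele equal to the variant's reference
#' carries the term `"reference"`.
#'
#' @param parent_dip the parent's [diplotype_dist()] at the variant.
#' @param annotations data.frame with columns `allele`, `term` (optionally
#'   `gene_id`, `transcript_id`) for one transcript at this variant.
#' @param founder_gts named list of [founder_genotype_dist()] objects.
#' @param variant a [cc_variant()].
#' @param strict error on missing founder distributions (default fills
#'   homozygous reference).
#' @return named numeric: probability per consequence term, summing to the
#'   diplotype's total mass.
#' @export
f1_consequence_prob <- function(parent_dip, annotations, founder_gts, variant,
                                strict = FALSE) {
  haps <- unique(as.vector(split_pair(names(parent_dip))))
  founder_gts <- complete_founder_gts(founder_gts, haps, variant, strict)
  ## p(transmitted haplotype) then p(transmitted allele | haplotype)
  th <- founder_transmission(parent_dip)
  allele_p <- numeric(0)
  for (h in names(th)) {
    tr <- founder_transmission(founder_gts[[h]]) * th[[h]]
    allele_p <- c(allele_p, tr)
  }
  tab <- rowsum(allele_p, names(allele_p))
  allele_p <- stats::setNames(tab[, 1L], rownames(tab))
  terms <- consequence_for_alleles(names(allele_p), annotations, variant)
  tab <- rowsum(as.numeric(allele_p), terms)
  stats::setNames(tab[, 1L], rownames(tab))
}

## look up the consequence term of each allele; reference allele is always
## "reference", unannotated non-reference alleles error (they indicate a
## malformed annotation set for the requested transcript)
consequence_for_alleles <- function(alleles, annotations, variant) {
  terms <- ifelse(alleles == variant$ref_allele, "reference", NA_character_)
  need <- which(is.na(terms))
  for (i in need) {
    hit <- annotations$term[annotations$allele == alleles[i]]
    if (!length(hit))
      stop("no consequence annotation for allele '", alleles[i], "' at ",
           variant$chrom, ":", variant$pos,
           if (!is.null(annotations$transcript_id))
             paste0(" (transcript ",
                    paste(unique(annotations$transcript_id), collapse = ","), ")")
           else "")
    terms[i] <- hit[1L]
  }
  terms
}
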