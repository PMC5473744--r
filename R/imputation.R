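## Core derivation: from marker diplotype probabilities and founder genotype
## distributions to a strain's genotype distribution at any variant position.
## The chain is: linear interpolation between flanking markers -> equal-odds
## phasing -> independent maternal/paternal transmission (each founder copy
## transmitted with probability 1/2) -> unphasing.

#' Interpolate a diplotype distribution between two flanking markers
#'
#' Linearly mixes the diplotype distributions observed at the nearest marker
#' on each side of a variant. Two weight conventions are provided:
#'
#' * `proximal` (default): each marker is weighted by the distance to the
#'   *opposite* marker, so a marker the variant coincides with receives all
#'   the weight. This is the endpoint-consistent reading of linear
#'   interpolation.
#' * `as_printed`: each marker is weighted by the distance to *itself*
#'   (left marker times `wl`), reproducing the published formula verbatim.
#'   Under this convention a coincident marker receives weight 0; it is kept
#'   for auditability against released dumps.
#'
#' If only one flanking marker exists (variant before the first or after the
#' last marker of a chromosome), that marker's distribution is returned
#' unchanged: the zero-distance limit of interpolation.
#'
#' @param left,right marker-source [diplotype_dist()] objects for the same
#'   strain and chromosome; either (not both) may be `NULL`.
#' @param wl,wr distances in bp from the variant to the left and right
#'   marker respectively; non-negative.
#' @param mode `"proximal"` or `"as_printed"`.
#' @return a [diplotype_dist()] with `source = "interpolated"`, over the
#'   union of the two key sets.
#' @export
interpolate_diplotype <- function(left, right, wl, wr,
                                  mode = c("proximal", "as_printed")) {
  mode <- match.arg(mode)
  if (is.null(left) && is.null(right)) stop("no flanking markers supplied")
  if (is.null(left)) return(right)
  if (is.null(right)) return(left)
  if (wl < 0 || wr < 0) stop("marker distances must be non-negative")
  keys <- union(names(left), names(right))
  pl <- stats::setNames(unclass(left)[keys], keys); pl[is.na(pl)] <- 0
  pr <- stats::setNames(unclass(right)[keys], keys); pr[is.na(pr)] <- 0
  if (wl + wr == 0) {
    if (max(abs(pl - pr)) > PROB_TOL)
      stop("co-located markers with differing distributions must be merged upstream")
    return(rewrap(pl, left, source = "interpolated"))
  }
  p <- switch(mode,
              proximal   = (wr * pl + wl * pr) / (wl + wr),
              as_printed = (wl * pl + wr * pr) / (wl + wr))
  rewrap(p[p > 0], left, source = "interpolated")
}

#' Phase an unphased diplotype distribution
#'
#' Both phasings of a heterozygous founder pair are taken as equally likely,
#' so each ordered pair receives half the unphased mass; a homozygous pair
#' has a single phasing which keeps its full mass. Total mass is preserved
#' exactly.
#'
#' @param unphased a [diplotype_dist()] (or named numeric over `"h/h'"` keys).
#' @return named numeric vector over ordered keys `"h|h'"`.
#' @export
phase_diplotype <- function(unphased) {
  pair <- split_pair(names(unphased))
  het <- pair[, 1L] != pair[, 2L]
  p <- as.numeric(unphased)
  keys <- c(ordered_key(pair[, 1L], pair[, 2L]),
            ordered_key(pair[het, 2L], pair[het, 1L]))
  vals <- c(ifelse(het, p / 2, p), p[het] / 2)
  stats::setNames(vals, keys)[order(keys, method = "radix")]
}

#' Allele transmission probability from one founder haplotype
#'
#' The probability that a chromosome copy inherited from founder haplotype
#' `h` carries allele `a`: each of the founder's two copies is transmitted
#' with probability 1/2, summed over the founder's (possibly uncertain,
#' possibly heterozygous) genotype distribution.
#'
#' @param founder_gt a [founder_genotype_dist()].
#' @param allele allele sequence to score.
#' @return probability in `[0, 1]`.
#' @export
transmission_prob <- function(founder_gt, allele) {
  alleles <- as.vector(split_pair(names(founder_gt)))
  if (!allele %in% alleles)
    stop("allele '", allele, "' not present in the genotype distribution's allele set")
  unname(founder_transmission(founder_gt)[allele])
}

## transmission distribution over all alleles of a founder genotype dist
founder_transmission <- function(founder_gt) {
  pair <- split_pair(names(founder_gt))
  p <- as.numeric(founder_gt)
  tab <- rowsum(c(p, p) / 2, c(pair[, 1L], pair[, 2L]))
  stats::setNames(tab[, 1L], rownames(tab))
}

## founders x alleles transmission-probability matrix at one variant
transmission_matrix <- function(founder_gts, alleles) {
  Tm <- matrix(0, nrow = length(founder_gts), ncol = length(alleles),
               dimnames = list(names(founder_gts), alleles))
  for (f in names(founder_gts)) {
    tr <- founder_transmission(founder_gts[[f]])
    Tm[f, names(tr)] <- tr
  }
  Tm
}

#' Phased genotype distribution given a phased diplotype
#'
#' Maternal and paternal alleles are transmitted independently, so the
#' probability of ordered allele pair `(a, a')` given phased diplotype
#' `(h, h')` is the product of the two haplotypes' transmission
#' probabilities.
#'
#' @param h1,h2 founder haplotype names (maternal, paternal).
#' @param founder_gts named list of [founder_genotype_dist()] objects.
#' @return named numeric over ordered keys `"a|a'"`.
#' @export
genotype_given_phased_diplotype <- function(h1, h2, founder_gts) {
  for (h in c(h1, h2))
    if (is.null(founder_gts[[h]]))
      stop("no founder genotype distribution for '", h, "'")
  t1 <- founder_transmission(founder_gts[[h1]])
  t2 <- founder_transmission(founder_gts[[h2]])
  out <- stats::setNames(as.vector(outer(t1, t2)),
                         ordered_key(rep(names(t1), times = length(t2)),
                                     rep(names(t2), each = length(t1))))
  out[order(names(out), method = "radix")]
}

## fold an ordered-pair distribution into canonical unphased keys;
## the diagonal (a = a') term is counted once
fold_unphased <- function(phased) {
  pair <- split_ordered(names(phased))
  key <- canonical_unphased(pair[, 1L], pair[, 2L])
  tab <- rowsum(as.numeric(phased), key)
  stats::setNames(tab[, 1L], rownames(tab))
}

## fill missing founders with a homozygous-reference point mass (VCF
## convention for non-variant samples); strict mode errors instead
complete_founder_gts <- function(founder_gts, haplotypes, variant,
                                 strict = FALSE) {
  missing <- setdiff(haplotypes, names(founder_gts))
  if (length(missing)) {
    if (strict || is.null(variant))
      stop("missing founder genotype distribution at ",
           if (!is.null(variant)) paste0(variant$chrom, ":", variant$pos) else "variant",
           " for: ", paste(missing, collapse = ", "))
    ref <- stats::setNames(1, canonical_unphased(variant$ref_allele,
                                                 variant$ref_allele))
    for (f in missing)
      founder_gts[[f]] <- founder_genotype_dist(ref, founder = f)
  }
  founder_gts
}

#' Impute a strain's diplotype distribution at a variant position
#'
#' Interpolation only — no transmission step. At a marker position
#' (`wl = 0`, proximal mode) this returns the marker's own distribution.
#'
#' @inheritParams interpolate_diplotype
#' @return a [diplotype_dist()] with `source = "interpolated"`.
#' @export
impute_diplotype <- function(left, right, wl, wr,
                             mode = c("proximal", "as_printed")) {
  interpolate_diplotype(left, right, wl, wr, mode = mode)
}

#' Impute a strain's unphased genotype distribution at a variant
#'
#' Composes the full derivation: interpolate the flanking marker diplotype
#' distributions to the variant position, phase with equal odds, transmit
#' one allele independently from each haplotype of the phased diplotype
#' (marginalizing over each founder's genotype distribution), and fold the
#' resulting phased genotype distribution into unphased allele pairs. With
#' unpruned inputs the result sums to 1 within 1e-9.
#'
#' @param variant a [cc_variant()].
#' @param founder_gts named list of [founder_genotype_dist()] objects;
#'   founders absent from the list are treated as homozygous reference
#'   (strict mode errors instead).
#' @inheritParams interpolate_diplotype
#' @param strain strain name recorded on the result.
#' @param strict error on missing founder distributions instead of
#'   substituting homozygous reference.
#' @return a [genotype_dist()].
#' @export
impute_genotype <- function(variant, founder_gts, left, right, wl, wr,
                            strain = NA_character_,
                            mode = c("proximal", "as_printed"),
                            strict = FALSE) {
  dip <- interpolate_diplotype(left, right, wl, wr, mode = mode)
  genotype_from_diplotype(dip, variant, founder_gts, strain = strain,
                          strict = strict)
}

#' Genotype distribution implied by a diplotype distribution
#'
#' The transmission step of the derivation, reusable for distributions that
#' are already interpolated (or observed at a marker).
#'
#' @param dip a [diplotype_dist()].
#' @inheritParams impute_genotype
#' @return a [genotype_dist()].
#' @export
genotype_from_diplotype <- function(dip, variant, founder_gts,
                                    strain = NA_character_, strict = FALSE) {
  haps <- unique(as.vector(split_pair(names(dip))))
  founder_gts <- complete_founder_gts(founder_gts, haps, variant, strict)
  alleles <- sort(unique(unlist(lapply(founder_gts[haps], function(g)
    as.vector(split_pair(names(g)))))), method = "radix")
  Tm <- transmission_matrix(founder_gts[haps], alleles)
  ## phased diplotype as a haplotype x haplotype matrix
  ph <- phase_diplotype(dip)
  pair <- split_ordered(names(ph))
  D <- matrix(0, length(haps), length(haps), dimnames = list(haps, haps))
  D[pair] <- as.numeric(ph)
  ## p(a, a') = sum_{h, h'} D[h, h'] T[h, a] T[h', a']
  P <- crossprod(Tm, D %*% Tm)
  phased <- stats::setNames(as.vector(P),
                            ordered_key(rep(alleles, times = length(alleles)),
                                        rep(alleles, each = length(alleles))))
  p <- fold_unphased(phased)
  genotype_dist(p[p > 0], strain = strain, variant = variant)
}

## ---------------------------------------------------------------------------
## marker lookup

## Given sorted marker positions for one strain/chromosome, return the
## flanking-marker indices and distances for a variant position.
flanking_markers <- function(positions, pos) {
  if (!length(positions)) stop("no markers on chromosome")
  li <- findInterval(pos, positions)            # last marker <= pos
  ri <- findInterval(pos, positions, left.open = TRUE) + 1L  # first > pos... see below
  ## findInterval with left.open counts markers < pos; +1 gives first >= pos
  left <- if (li >= 1L) li else NA_integer_
  right <- if (ri <= length(positions)) ri else NA_integer_
  list(left = left, right = right,
       wl = if (is.na(left)) NA_real_ else pos - positions[left],
       wr = if (is.na(right)) NA_real_ else positions[right] - pos)
}
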