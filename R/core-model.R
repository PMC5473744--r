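#' ccimpute: probabilistic imputation for multiparental recombinant inbreds
#'
#' Distributions throughout the package are named numeric vectors: names are
#' canonical unphased-pair keys (`"a/b"` with `a <= b` in C-locale order) or,
#' for internal phased intermediates, ordered keys `"a|b"`. Probability mass
#' may be < 1 after pruning; it is never silently renormalized.
#'
#' @keywords internal
#' @import data.table
"_PACKAGE"

PROB_TOL <- 1e-9

## ---------------------------------------------------------------------------
## canonical keys

#' Canonical key for an unphased pair
#'
#' Folds an ordered pair of alleles (or founder haplotypes) into the single
#' unordered key used throughout the package: the two elements sorted in
#' C-locale (radix) order and joined with `/`. Sorting is byte-wise, so for
#' equal-prefix indel alleles the shorter allele sorts first, and the same key
#' is produced on every platform.
#'
#' @param a,b character vectors of equal length (or length 1, recycled);
#'   allele sequences or haplotype names. Empty strings are an error.
#' @return character vector of keys, e.g. `"C/T"` for `("T","C")`.
#' @examples
#' canonical_unphased("T", "C")   # "C/T"
#' canonical_unphased("A", "A")   # "A/A"
#' canonical_unphased("A", "AC")  # "A/AC"
#' @export
canonical_unphased <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (any(!nzchar(a)) || any(!nzchar(b)) || anyNA(a) || anyNA(b))
    stop("alleles must be non-empty strings")
  ## byte-wise (radix) ranks make the ordering locale-independent
  lev <- sort(unique(c(a, b)), method = "radix")
  swap <- match(a, lev) > match(b, lev)
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "/")
}

#' Split unphased keys back into their two elements
#'
#' @param key character vector of `"a/b"` keys.
#' @return a 2-column character matrix (columns `first`, `second`).
#' @export
split_pair <- function(key) {
  parts <- strsplit(key, "/", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed pair key: ", key[bad][1L])
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("first", "second")
  m
}

ordered_key <- function(a, b) paste(a, b, sep = "|")

split_ordered <- function(key) {
  m <- matrix(unlist(strsplit(key, "|", fixed = TRUE)), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("first", "second")
  m
}

## ---------------------------------------------------------------------------
## probability-distribution primitives

new_dist <- function(probs, class, ...) {
  stopifnot(is.numeric(probs))
  if (is.null(names(probs)) || any(!nzchar(names(probs))))
    stop("distribution must be a named numeric vector")
  if (anyNA(probs) || any(probs < 0))
    stop("probabilities must be non-negative and non-missing")
  if (any(probs > 1 + PROB_TOL))
    stop("probabilities must not exceed 1")
  if (sum(probs) > 1 + PROB_TOL)
    stop("distribution mass exceeds 1: ", format(sum(probs)))
  if (anyDuplicated(names(probs)))
    stop("duplicate keys in distribution")
  ## deterministic key order
  probs <- probs[order(names(probs), method = "radix")]
  structure(probs, class = c(class, "cc_dist"), ...)
}

#' @export
print.cc_dist <- function(x, ...) {
  cat("<", class(x)[1L], "> mass=", format(sum(x)), "\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

dist_attrs <- function(x) attributes(x)[setdiff(names(attributes(x)),
                                                c("names", "class"))]

## rebuild a distribution of the same class with new probs, keeping metadata
rewrap <- function(probs, template, ...) {
  at <- dist_attrs(template)
  at[names(list(...))] <- list(...)
  do.call(new_dist, c(list(probs = probs, class = setdiff(class(template), "cc_dist")),
                      at))
}

#' Founder genotype distribution
#'
#' Per (variant, founder) probability distribution over unphased genotypes.
#' Keys are canonical allele-pair keys; every allele must be the variant's
#' reference allele or one of its alternates when a variant is supplied.
#'
#' @param probs named numeric vector, names are `"a/b"` keys.
#' @param founder founder-strain name.
#' @param variant optional [cc_variant()] used to validate alleles.
#' @return an object of class `founder_genotype_dist`.
#' @export
founder_genotype_dist <- function(probs, founder = NA_character_, variant = NULL) {
  d <- new_dist(probs, "founder_genotype_dist", founder = founder)
  if (!is.null(variant)) {
    ok <- c(variant$ref_allele, variant$alt_alleles)
    alle <- unique(as.vector(split_pair(names(d))))
    if (!all(alle %in% ok))
      stop("genotype alleles not in variant allele set: ",
           paste(setdiff(alle, ok), collapse = ", "))
    attr(d, "variant_id") <- variant$variant_id
  }
  d
}

#' Diplotype distribution
#'
#' Per (strain, locus) distribution over unphased founder-haplotype pairs
#' (36 states for 8 founders).
#'
#' @param probs named numeric vector over `"h/h'"` keys.
#' @param strain strain name.
#' @param chrom,pos locus (1-based bp).
#' @param source `"marker"` (observed at a genotyping marker) or
#'   `"interpolated"` (derived at a variant position).
#' @param founders optional haplotype-set names to validate keys against.
#' @return an object of class `diplotype_dist`.
#' @export
diplotype_dist <- function(probs, strain = NA_character_, chrom = NA_character_,
                           pos = NA_real_, source = c("marker", "interpolated"),
                           founders = NULL) {
  source <- match.arg(source)
  d <- new_dist(probs, "diplotype_dist", strain = strain, chrom = chrom,
                pos = as.numeric(pos), source = source)
  if (!is.null(founders)) {
    haps <- unique(as.vector(split_pair(names(d))))
    if (!all(haps %in% founders))
      stop("unknown founder haplotype(s): ",
           paste(setdiff(haps, founders), collapse = ", "))
  }
  d
}

#' Genotype distribution for a strain (or strain pair) at a variant
#'
#' @param probs named numeric vector over canonical allele-pair keys.
#' @param strain one strain name, or two for an F1 offspring.
#' @param variant optional [cc_variant()] for allele validation.
#' @return an object of class `genotype_dist`.
#' @export
genotype_dist <- function(probs, strain = NA_character_, variant = NULL) {
  d <- new_dist(probs, "genotype_dist", strain = strain)
  if (!is.null(variant)) {
    ok <- c(variant$ref_allele, variant$alt_alleles)
    alle <- unique(as.vector(split_pair(names(d))))
    if (!all(alle %in% ok))
      stop("alleles not in variant allele set: ",
           paste(setdiff(alle, ok), collapse = ", "))
    attr(d, "variant_id") <- variant$variant_id
  }
  d
}

#' Transmission distribution
#'
#' Probability that a parental haplotype (or parent strain) transmits each
#' allele (or haplotype) to an offspring. Built from a genotype or diplotype
#' distribution by counting copies: each of the two copies is transmitted
#' with probability 1/2.
#'
#' @param probs named numeric over single alleles or haplotype names.
#' @param source name of the transmitting haplotype or strain.
#' @return an object of class `transmission_dist`.
#' @export
transmission_dist <- function(probs, source = NA_character_) {
  new_dist(probs, "transmission_dist", source = source)
}

#' Check that a probability map is normalized
#'
#' Distributions read straight from the model sum to 1; stored distributions
#' may have lost mass to pruning (entries < 0.001 dropped, never
#' renormalized). This check distinguishes the two states and never mutates
#' its input.
#'
#' @param dist named numeric vector of probabilities.
#' @param tol positive tolerance on `|sum - 1|`.
#' @return `TRUE` iff the total mass is within `tol` of 1.
#' @export
normalize_check <- function(dist, tol = PROB_TOL) {
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0) stop("tol must be > 0")
  if (anyNA(dist) || any(dist < 0)) stop("negative or missing probability")
  abs(sum(dist) - 1) <= tol
}

#' Drop low-probability states without renormalizing
#'
#' Entries with probability strictly below `threshold` are removed; the
#' remaining probabilities are left untouched, so the stored distribution may
#' sum to less than 1. This mirrors how desk-scale stores keep table sizes
#' down while reporting honest (non-unit) mass.
#'
#' @param dist a distribution (any `cc_dist` subclass, or plain named numeric).
#' @param threshold probability floor in `[0, 1)`; default 0.001.
#' @return the same type of object with sub-threshold entries removed.
#' @export
prune_distribution <- function(dist, threshold = 0.001) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1)
    stop("threshold must be in [0, 1)")
  keep <- dist >= threshold
  if (all(keep)) return(dist)
  if (inherits(dist, "cc_dist")) rewrap(unclass(dist)[keep], dist)
  else dist[keep]
}

## ---------------------------------------------------------------------------
## variants and haplotype sets

#' Construct a variant record
#'
#' @param chrom chromosome name.
#' @param pos 1-based start position (bp), matching VCF POS.
#' @param ref_allele reference allele sequence.
#' @param alt_alleles character vector of alternate alleles (each 1-100 bp,
#'   distinct from the reference).
#' @param variant_id optional integer surrogate key (assigned by the store
#'   builder in ascending chrom, pos, alt order).
#' @return a list of class `cc_variant` with a derived `variant_class`
#'   (`"SNP"` when all alleles are single bases, else `"indel"`).
#' @export
cc_variant <- function(chrom, pos, ref_allele, alt_alleles,
                       variant_id = NA_integer_) {
  pos <- as.numeric(pos)
  if (is.na(pos) || pos < 1) stop("pos must be >= 1")
  alleles <- c(ref_allele, alt_alleles)
  if (length(alt_alleles) < 1L) stop("alt_alleles must be non-empty")
  if (any(!nzchar(alleles)) || anyNA(alleles)) stop("empty allele string")
  if (any(nchar(alleles) > 100L)) stop("allele longer than 100 bp")
  if (any(alt_alleles == ref_allele)) stop("alt allele equals reference")
  if (anyDuplicated(alt_alleles)) stop("duplicate alt alleles")
  structure(list(variant_id = as.integer(variant_id),
                 chrom = as.character(chrom), pos = pos,
                 ref_allele = ref_allele,
                 alt_alleles = as.character(alt_alleles),
                 variant_class = if (all(nchar(alleles) == 1L)) "SNP" else "indel"),
            class = "cc_variant")
}

#' @export
print.cc_variant <- function(x, ...) {
  cat(sprintf("<cc_variant %s %s:%d %s>%s\n",
              ifelse(is.na(x$variant_id), "", paste0("#", x$variant_id)),
              x$chrom, x$pos, paste(c(x$ref_allele, x$alt_alleles), collapse = ">"),
              paste0(" [", x$variant_class, "]")))
  invisible(x)
}

#' Founder haplotype set
#'
#' @param founders character vector of unique founder-strain names (default:
#'   the eight Collaborative Cross founders).
#' @return character vector of class `haplotype_set`.
#' @export
haplotype_set <- function(founders = cc_founders()) {
  founders <- as.character(founders)
  if (anyDuplicated(founders) || any(!nzchar(founders)))
    stop("founder names must be unique and non-empty")
  structure(founders, class = "haplotype_set")
}

#' Default Collaborative Cross founder strain names
#'
#' A/J, C57BL/6J (the reference strain), 129S1/SvImJ, NOD/ShiLtJ, NZO/HlLtJ,
#' CAST/EiJ, PWK/PhJ and WSB/EiJ, under their conventional short labels.
#'
#' @return character vector of length 8.
#' @export
cc_founders <- function() c("AJ", "B6", "129", "NOD", "NZO", "CAST", "PWK", "WSB")

#' All unphased diplotype keys over a haplotype set
#'
#' @param founders character vector of haplotype names.
#' @return character vector of `choose(n,2) + n` keys (36 for 8 founders).
#' @export
diplotype_states <- function(founders = cc_founders()) {
  n <- length(founders)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  sort(canonical_unphased(founders[idx[, 1L]], founders[idx[, 2L]]),
       method = "radix")
}
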