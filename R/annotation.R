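## Attach per-transcript functional consequences to genotype distributions,
## producing the 12-column query-row schema. Annotation replicates rows per
## (gene, transcript) and never re-weights: the probability of a genotype
## state is applied unchanged to its consequences.

query_row_columns <- function(cross = FALSE) {
  c("variant_id", "chrom", "pos",
    if (cross) c("strain_1", "strain_2") else "strain",
    "allele_1", "allele_2", "prob", "is_max",
    "gene_id", "transcript_id", "consequence_1", "consequence_2")
}

#' Expand a genotype distribution into annotated query rows
#'
#' One row per (genotype state x overlapping gene x transcript). Consequences
#' are looked up per allele in the annotation set; an allele equal to the
#' variant's reference gets the literal term `"reference"`. A gene
#' overlapping the variant with no annotated transcript is emitted with an
#' empty `transcript_id` and consequence `"unannotated"` for non-reference
#' alleles (strict mode errors instead). Per-group probability sums are
#' exactly those of the genotype distribution.
#'
#' @param gt a [genotype_dist()].
#' @param annotations data.frame with columns `allele`, `gene_id`,
#'   `transcript_id`, `term` for this variant (zero rows allowed).
#' @param variant a [cc_variant()].
#' @param strain strain name (length 2 for a cross row).
#' @param genes character vector of gene ids overlapping the variant;
#'   defaults to the genes present in `annotations`.
#' @param strict error on unannotated non-reference alleles.
#' @return data.frame of query rows with `is_max` set (see [flag_is_max()]).
#' @export
annotate_genotype_rows <- function(gt, annotations, variant,
                                   strain = attr(gt, "strain"),
                                   genes = NULL, strict = FALSE) {
  if (is.null(genes)) genes <- unique(annotations$gene_id)
  if (!length(genes)) genes <- NA_character_
  pair <- split_pair(names(gt))
  cross <- length(strain) == 2L
  out <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    ann_g <- annotations[!is.na(g) & annotations$gene_id == g, , drop = FALSE]
    txs <- unique(ann_g$transcript_id)
    if (!length(txs)) txs <- ""   # gene overlap without annotated transcript
    blocks <- lapply(txs, function(tx) {
      ann_tx <- ann_g[ann_g$transcript_id == tx, , drop = FALSE]
      c1 <- lookup_terms(pair[, 1L], ann_tx, variant, strict)
      c2 <- lookup_terms(pair[, 2L], ann_tx, variant, strict)
      df <- data.frame(variant_id = variant$variant_id, chrom = variant$chrom,
                       pos = variant$pos, stringsAsFactors = FALSE)
      if (cross) { df$strain_1 <- strain[1L]; df$strain_2 <- strain[2L] }
      else df$strain <- strain
      cbind(df, data.frame(allele_1 = pair[, 1L], allele_2 = pair[, 2L],
                           prob = as.numeric(gt), is_max = NA,
                           gene_id = if (is.na(g)) "" else g,
                           transcript_id = tx,
                           consequence_1 = c1, consequence_2 = c2,
                           stringsAsFactors = FALSE))
    })
    out[[gi]] <- do.call(rbind, blocks)
  }
  flag_is_max(do.call(rbind, out))
}

lookup_terms <- function(alleles, ann_tx, variant, strict) {
  terms <- ifelse(alleles == variant$ref_allele, "reference", NA_character_)
  for (i in which(is.na(terms))) {
    hit <- ann_tx$term[ann_tx$allele == alleles[i]]
    if (length(hit)) terms[i] <- hit[1L]
    else if (strict)
      stop("unannotated non-reference allele '", alleles[i], "' at ",
           variant$chrom, ":", variant$pos)
    else terms[i] <- "unannotated"
  }
  terms
}

#' Flag maximum-likelihood rows within each query group
#'
#' Within each (variant, strain(s), gene, transcript) group, `is_max` is set
#' for every row whose probability is within 1e-9 of the group maximum.
#' Ties therefore mark multiple rows: a max-only restriction may honestly
#' return more than one row per group.
#'
#' @param rows data.frame of query rows (any subset of groups).
#' @return the same data.frame with `is_max` filled in.
#' @export
flag_is_max <- function(rows) {
  if (!nrow(rows)) { rows$is_max <- logical(0); return(rows) }
  strain_cols <- intersect(c("strain", "strain_1", "strain_2"), names(rows))
  key_cols <- c("variant_id", strain_cols,
                intersect(c("gene_id", "transcript_id"), names(rows)))
  key <- do.call(paste, c(rows[key_cols], sep = "\r"))
  gmax <- stats::ave(rows$prob, key, FUN = max)
  rows$is_max <- rows$prob >= gmax - PROB_TOL
  rows
}
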