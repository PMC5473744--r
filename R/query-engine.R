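## Per-chromosome embedded store and the four query types. The store is a
## directory: one sub-directory per chromosome with genotype.csv and
## diplotype.csv (indexed by variant_id and strain), plus shared variants,
## consequence and metadata files. Distributions are pruned at build time
## (entries < prune_threshold dropped, never renormalized).

#' Build a per-chromosome store of imputed distributions
#'
#' Reads the founder VCF, marker diplotype CSV and exon annotations, applies
#' the build filter (exonic +/- 100 bp, polymorphic among founders, alleles
#' 1-100 bp), assigns deterministic variant ids (ascending chromosome,
#' position, reference, alternate order), imputes the genotype and diplotype
#' distribution of every strain at every buildable variant, prunes, and
#' writes one CSV shard per chromosome. Founder strains are stored alongside
#' the CC strains: a founder's genotype is its own VCF distribution and its
#' diplotype a point mass on its homozygous founder pair.
#'
#' @param founder_vcf path to the founder VCF.
#' @param marker_csv path to the marker diplotype CSV.
#' @param exons path to exon BED/GFF3.
#' @param out_dir store directory (created; overwritten if present).
#' @param founders founder names; default the VCF's sample columns.
#' @param consequence_tsv optional 5-column consequence TSV (merged with any
#'   CSQ annotations found in the VCF).
#' @param prune_threshold probability floor for stored entries (0.001; 0
#'   disables pruning).
#' @param mode interpolation weight convention, `"proximal"` or
#'   `"as_printed"` (see [interpolate_diplotype()]).
#' @param likelihood read founder genotypes from PL/GL instead of GT.
#' @param strict error on missing founder genotypes instead of substituting
#'   homozygous reference.
#' @param verbose print per-stage record counts.
#' @return a `cc_store` handle (see [load_store()]).
#' @export
build_store <- function(founder_vcf, marker_csv, exons, out_dir,
                        founders = NULL, consequence_tsv = NULL,
                        prune_threshold = 0.001,
                        mode = c("proximal", "as_printed"),
                        likelihood = FALSE, strict = FALSE, verbose = FALSE) {
  mode <- match.arg(mode)
  say <- function(...) if (verbose) message(sprintf(...))
  vcfdat <- read_founder_vcf(founder_vcf, founders,
                             mode = if (likelihood) "likelihood" else "gt")
  founders <- vcfdat$founders
  say("VCF: %d records, %d founders", nrow(vcfdat$variants), length(founders))
  exon_df <- read_exons(exons)
  markers <- read_marker_diplotypes(marker_csv, founders = founders)
  strains <- sort(unique(markers$strain), method = "radix")
  say("markers: %d strains, %d marker states", length(strains), nrow(markers))

  keep <- filter_buildable_variants(vcfdat$variants, vcfdat$genotypes,
                                    exon_df, founders)
  variants <- vcfdat$variants[keep, , drop = FALSE]
  genotypes <- vcfdat$genotypes[keep]
  say("build filter: %d of %d variants kept", nrow(variants), length(keep))
  if (!nrow(variants)) stop("no buildable variants")
  ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt,
               method = "radix")
  variants <- variants[ord, , drop = FALSE]
  genotypes <- genotypes[ord]
  variants$variant_id <- seq_len(nrow(variants))
  variants$genes <- genes_for_variants(variants, exon_df)

  ## annotations -> variant ids
  ann <- vcfdat$annotations
  if (!is.null(consequence_tsv))
    ann <- rbind(ann, read_consequence_tsv(consequence_tsv))
  key <- paste(ann$chrom, ann$pos)
  vid <- variants$variant_id[match(key, paste(variants$chrom, variants$pos))]
  ann <- cbind(variant_id = vid, ann)[!is.na(vid), , drop = FALSE]
  ann <- ann[order(ann$variant_id, ann$gene_id, ann$transcript_id, ann$allele,
                   ann$term, method = "radix"), , drop = FALSE]

  ## precompute per-variant transmission machinery
  nf <- length(founders)
  states <- diplotype_states(founders)
  spair <- split_pair(states)
  i1 <- match(spair[, 1L], founders); i2 <- match(spair[, 2L], founders)
  Mphase <- matrix(0, nf * nf, length(states))
  for (s in seq_along(states)) {
    if (i1[s] == i2[s]) Mphase[(i1[s] - 1L) * nf + i1[s], s] <- 1
    else {
      Mphase[(i2[s] - 1L) * nf + i1[s], s] <- 0.5
      Mphase[(i1[s] - 1L) * nf + i2[s], s] <- 0.5
    }
  }
  prep <- prepare_variants(variants, genotypes, founders, strict)

  ## dense marker matrices per (strain, chrom)
  mk <- split(markers, list(markers$strain, markers$chrom), drop = TRUE)
  mk_index <- lapply(mk, function(m) {
    pos <- sort(unique(m$pos))
    P <- matrix(0, length(states), length(pos),
                dimnames = list(states, NULL))
    P[cbind(match(m$key, states), match(m$pos, pos))] <- m$prob
    list(pos = pos, P = P)
  })

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chroms <- sort(unique(variants$chrom), method = "radix")
  for (ch in chroms) {
    vi <- which(variants$chrom == ch)
    gt_acc <- dip_acc <- list()
    ## founder strains: their own genotype, certain homozygous diplotype
    for (fi in seq_along(founders)) {
      f <- founders[fi]
      fg <- lapply(vi, function(i) {
        d <- prep$fgd[[i]][[f]]
        d[d >= prune_threshold & d > 0]
      })
      nstate <- lengths(fg)
      pr <- split_pair(unlist(lapply(fg, names), use.names = FALSE))
      gt_acc[[f]] <- data.table::data.table(
        variant_id = rep(variants$variant_id[vi], nstate), strain = f,
        allele_1 = pr[, 1L], allele_2 = pr[, 2L],
        prob = unlist(fg, use.names = FALSE))
      dip_acc[[f]] <- data.table::data.table(
        variant_id = variants$variant_id[vi], strain = f,
        haplotype_1 = f, haplotype_2 = f, prob = 1)
    }
    for (s in strains) {
      idx <- mk_index[[paste(s, ch, sep = ".")]]
      if (is.null(idx))
        stop("strain ", s, " has no markers on chromosome ", ch)
      res <- impute_chromosome(variants[vi, ], prep, vi, idx, Mphase, nf,
                               states, spair, mode, prune_threshold)
      res$genotype$strain <- s
      res$diplotype$strain <- s
      gt_acc[[s]] <- res$genotype
      dip_acc[[s]] <- res$diplotype
    }
    gt <- data.table::rbindlist(gt_acc, use.names = TRUE)[
      , c("variant_id", "strain", "allele_1", "allele_2", "prob"),
      with = FALSE]
    dip <- data.table::rbindlist(dip_acc, use.names = TRUE)[
      , c("variant_id", "strain", "haplotype_1", "haplotype_2", "prob"),
      with = FALSE]
    data.table::setorder(gt, variant_id, strain, allele_1, allele_2)
    data.table::setorder(dip, variant_id, strain, haplotype_1, haplotype_2)
    dir.create(file.path(out_dir, ch), showWarnings = FALSE)
    data.table::fwrite(gt, file.path(out_dir, ch, "genotype.csv"),
                       quote = FALSE)
    data.table::fwrite(dip, file.path(out_dir, ch, "diplotype.csv"),
                       quote = FALSE)
    say("%s: %d genotype rows, %d diplotype rows", ch, nrow(gt), nrow(dip))
  }
  ## alt and genes are comma-joined lists: quoting is required
  data.table::fwrite(variants[, c("variant_id", "chrom", "pos", "ref", "alt",
                                  "class", "genes")],
                     file.path(out_dir, "variants.csv"), quote = TRUE)
  data.table::fwrite(ann, file.path(out_dir, "consequences.csv"),
                     quote = FALSE)
  meta <- list(founders = founders, cc_strains = strains, chroms = chroms,
               prune_threshold = prune_threshold, interpolation = mode,
               n_variants = nrow(variants))
  jsonlite::write_json(meta, file.path(out_dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  load_store(out_dir)
}

## per-variant founder genotype maps (missing founders -> hom ref),
## transmission matrices and unphased fold groups
prepare_variants <- function(variants, genotypes, founders, strict) {
  n <- nrow(variants)
  fgd <- Tm <- fold <- vector("list", n)
  for (i in seq_len(n)) {
    v <- cc_variant(variants$chrom[i], variants$pos[i], variants$ref[i],
                    strsplit(variants$alt[i], ",", fixed = TRUE)[[1]],
                    variant_id = variants$variant_id[i])
    gmap <- complete_founder_gts(genotypes[[i]], founders, v, strict)
    alleles <- sort(unique(as.vector(split_pair(unlist(lapply(gmap, names),
                                                       use.names = FALSE)))),
                    method = "radix")
    fgd[[i]] <- gmap[founders]
    Tm[[i]] <- transmission_matrix(gmap[founders], alleles)
    k <- length(alleles)
    keys <- canonical_unphased(rep(alleles, times = k), rep(alleles, each = k))
    lev <- sort(unique(keys), method = "radix")
    kp <- split_pair(lev)
    fold[[i]] <- list(grp = match(keys, lev), keys = lev,
                      a1 = kp[, 1L], a2 = kp[, 2L])
  }
  list(fgd = fgd, Tm = Tm, fold = fold)
}

## impute all variants of one chromosome for one strain (dense fast path)
impute_chromosome <- function(vtab, prep, vi, idx, Mphase, nf, states, spair,
                              mode, prune_threshold) {
  mpos <- idx$pos
  nm <- length(mpos)
  li <- findInterval(vtab$pos, mpos)
  ri <- findInterval(vtab$pos, mpos, left.open = TRUE) + 1L
  g_vid <- g_a1 <- g_a2 <- g_p <- vector("list", nrow(vtab))
  d_vid <- d_key <- d_p <- vector("list", nrow(vtab))
  for (j in seq_len(nrow(vtab))) {
    l <- li[j]; r <- ri[j]
    p36 <- if (l < 1L) idx$P[, r]
      else if (r > nm) idx$P[, l]
      else if (l == r) idx$P[, l]
      else {
        wl <- vtab$pos[j] - mpos[l]; wr <- mpos[r] - vtab$pos[j]
        if (mode == "proximal") (wr * idx$P[, l] + wl * idx$P[, r]) / (wl + wr)
        else                    (wl * idx$P[, l] + wr * idx$P[, r]) / (wl + wr)
      }
    i <- vi[j]
    D <- matrix(Mphase %*% p36, nf, nf)
    Tm <- prep$Tm[[i]]
    P <- crossprod(Tm, D %*% Tm)
    fold <- prep$fold[[i]]
    p <- rowsum(as.vector(P), fold$grp)[, 1L]
    keep <- which(p >= prune_threshold & p > 0)
    g_vid[[j]] <- rep(vtab$variant_id[j], length(keep))
    g_a1[[j]] <- fold$a1[keep]; g_a2[[j]] <- fold$a2[keep]
    g_p[[j]] <- p[keep]
    dkeep <- which(p36 >= prune_threshold & p36 > 0)
    d_vid[[j]] <- rep(vtab$variant_id[j], length(dkeep))
    d_key[[j]] <- states[dkeep]
    d_p[[j]] <- unname(p36[dkeep])
  }
  dk <- split_pair(unlist(d_key, use.names = FALSE))
  list(genotype = data.table::data.table(
         variant_id = unlist(g_vid), allele_1 = unlist(g_a1),
         allele_2 = unlist(g_a2), prob = unlist(g_p, use.names = FALSE)),
       diplotype = data.table::data.table(
         variant_id = unlist(d_vid), haplotype_1 = dk[, 1L],
         haplotype_2 = dk[, 2L], prob = unlist(d_p, use.names = FALSE)))
}

#' Open an existing store
#'
#' @param path store directory written by [build_store()].
#' @return a `cc_store` handle: metadata, the variant and consequence tables,
#'   and a lazy per-chromosome cache of the genotype/diplotype shards.
#' @export
load_store <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  variants <- data.table::fread(file.path(path, "variants.csv"),
                                colClasses = list(character = c("chrom", "ref",
                                                                "alt")))
  variants$genes[is.na(variants$genes)] <- ""
  cons_path <- file.path(path, "consequences.csv")
  consequences <- if (file.size(cons_path) > 1L)
    data.table::fread(cons_path, colClasses = list(character = "chrom"))
  else data.table::data.table(variant_id = integer(), chrom = character(),
                              pos = numeric(), allele = character(),
                              gene_id = character(),
                              transcript_id = character(), term = character())
  structure(list(path = path, meta = meta, variants = variants,
                 consequences = consequences, cache = new.env(parent = emptyenv())),
            class = "cc_store")
}

#' @export
print.cc_store <- function(x, ...) {
  cat(sprintf("<cc_store %s: %d variants, %d CC strains + %d founders, %s>\n",
              x$path, x$meta$n_variants, length(x$meta$cc_strains),
              length(x$meta$founders),
              paste(x$meta$chroms, collapse = ",")))
  invisible(x)
}

store_table <- function(store, chrom, type = c("genotype", "diplotype")) {
  type <- match.arg(type)
  key <- paste(chrom, type, sep = ".")
  if (!is.null(store$cache[[key]])) return(store$cache[[key]])
  f <- file.path(store$path, chrom, paste0(type, ".csv"))
  if (!file.exists(f)) stop("no shard for chromosome ", chrom)
  dt <- data.table::fread(f, colClasses = list(character = "strain"))
  store$cache[[key]] <- dt
  dt
}

all_strains <- function(store) c(store$meta$founders, store$meta$cc_strains)

check_strains <- function(store, strains) {
  valid <- all_strains(store)
  bad <- setdiff(strains, valid)
  if (length(bad))
    stop("unknown strain(s): ", paste(bad, collapse = ", "),
         ". Valid strains: ", paste(valid, collapse = ", "))
  strains
}

#' Parse a 1-based closed genomic region string
#'
#' @param region `"chrom:start-end"`.
#' @return list(chrom, start, end).
#' @export
parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop("region must be chrom:start-end, got '", region, "'")
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

## resolve a region / gene list / variant-id list to variant ids
resolve_variants <- function(store, region = NULL, genes = NULL,
                             variant_ids = NULL) {
  v <- store$variants
  if (!is.null(variant_ids)) {
    bad <- setdiff(variant_ids, v$variant_id)
    if (length(bad)) stop("unknown variant id(s): ", paste(bad, collapse = ", "))
    return(sort(unique(as.integer(variant_ids))))
  }
  if (!is.null(genes)) {
    gl <- strsplit(v$genes, ",", fixed = TRUE)
    known <- unique(unlist(gl))
    bad <- setdiff(genes, known)
    if (length(bad))
      stop("unknown gene(s): ", paste(bad, collapse = ", "),
           ". Valid genes: ", paste(sort(known[nzchar(known)]), collapse = ", "))
    hit <- vapply(gl, function(g) any(g %in% genes), NA)
    return(v$variant_id[hit])
  }
  if (!is.null(region)) {
    r <- if (is.character(region)) parse_region(region) else region
    return(v$variant_id[v$chrom == r$chrom & v$pos >= r$start &
                          v$pos <= r$end])
  }
  v$variant_id
}

## shared restriction semantics (applied after is_max is computed)
apply_restrictions <- function(rows, max_only = FALSE, prob_threshold = NULL,
                               zygosity = NULL, consequence = NULL,
                               consequence_match = c("either", "both")) {
  consequence_match <- match.arg(consequence_match)
  if (max_only) rows <- rows[rows$is_max, , drop = FALSE]
  if (!is.null(prob_threshold))
    rows <- rows[rows$prob >= prob_threshold, , drop = FALSE]
  if (!is.null(zygosity)) {
    zygosity <- match.arg(zygosity, c("hom", "het"))
    a1 <- if ("allele_1" %in% names(rows)) rows$allele_1 else rows$haplotype_1
    a2 <- if ("allele_2" %in% names(rows)) rows$allele_2 else rows$haplotype_2
    hom <- a1 == a2
    rows <- rows[if (zygosity == "hom") hom else !hom, , drop = FALSE]
  }
  if (!is.null(consequence)) {
    if (!"consequence_1" %in% names(rows))
      stop("consequence restriction applies only to genotype queries")
    m1 <- rows$consequence_1 %in% consequence
    m2 <- rows$consequence_2 %in% consequence
    rows <- rows[if (consequence_match == "either") m1 | m2 else m1 & m2, ,
                 drop = FALSE]
  }
  rows
}

#' Genotype query
#'
#' Returns annotated 12-column query rows for the requested strains and
#' region / genes / variant ids, with the secondary restrictions applied
#' conjunctively. `is_max` is computed per (variant, strain, gene,
#' transcript) group before restrictions, so a max-only query keeps every
#' row tied for the group maximum.
#'
#' @param store a `cc_store`.
#' @param strains character vector of CC or founder strain names.
#' @param region `"chrom:start-end"` (1-based closed), or `NULL`.
#' @param genes gene id list, or `NULL`.
#' @param variant_ids variant id list, or `NULL` (all variants when no
#'   selector is given).
#' @param max_only keep only maximum-likelihood rows.
#' @param prob_threshold keep rows with `prob >=` this value.
#' @param zygosity `"hom"` or `"het"`.
#' @param consequence character vector of consequence terms to keep.
#' @param consequence_match `"either"` (default: a row matches if either
#'   allele's consequence is requested) or `"both"`.
#' @param strict error on unannotated non-reference alleles.
#' @return data.frame of query rows.
#' @export
query_genotype <- function(store, strains, region = NULL, genes = NULL,
                           variant_ids = NULL, max_only = FALSE,
                           prob_threshold = NULL, zygosity = NULL,
                           consequence = NULL,
                           consequence_match = c("either", "both"),
                           strict = FALSE) {
  strains <- check_strains(store, strains)
  vids <- resolve_variants(store, region, genes, variant_ids)
  v <- store$variants[match(vids, store$variants$variant_id), ]
  out <- list()
  for (ch in unique(v$chrom)) {
    dt <- store_table(store, ch, "genotype")
    dt <- dt[dt$variant_id %in% vids & dt$strain %in% strains, ]
    if (!nrow(dt)) next
    grp <- split(dt, list(dt$variant_id, dt$strain), drop = TRUE)
    for (g in grp) {
      i <- match(g$variant_id[1L], store$variants$variant_id)
      out[[length(out) + 1L]] <- annotate_store_group(
        store, i, g$strain[1L],
        stats::setNames(g$prob, canonical_unphased(g$allele_1, g$allele_2)),
        strict = strict)
    }
  }
  finalize_rows(out, cross = FALSE, max_only = max_only,
                prob_threshold = prob_threshold, zygosity = zygosity,
                consequence = consequence,
                consequence_match = consequence_match)
}

annotate_store_group <- function(store, i, strain, probs, strict = FALSE) {
  v <- store$variants
  var <- cc_variant(v$chrom[i], v$pos[i], v$ref[i],
                    strsplit(v$alt[i], ",", fixed = TRUE)[[1]],
                    variant_id = v$variant_id[i])
  ann <- as.data.frame(store$consequences[
    store$consequences$variant_id == v$variant_id[i], ])
  gene_list <- strsplit(v$genes[i], ",", fixed = TRUE)[[1]]
  gt <- genotype_dist(probs, strain = strain)
  annotate_genotype_rows(gt, ann, var, strain = strain,
                         genes = gene_list, strict = strict)
}

finalize_rows <- function(out, cross, ...) {
  cols <- query_row_columns(cross)
  rows <- if (length(out)) do.call(rbind, out) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  rows <- flag_is_max(rows)
  rows <- apply_restrictions(rows, ...)
  strain_cols <- intersect(c("strain", "strain_1", "strain_2"), names(rows))
  ord <- do.call(order, c(rows[c("variant_id", strain_cols, "gene_id",
                                 "transcript_id", "allele_1", "allele_2")],
                          method = "radix"))
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Diplotype query
#'
#' Like [query_genotype()] but over stored founder-pair diplotypes; rows
#' carry `haplotype_1`/`haplotype_2` and no transcript or consequence
#' columns (a diplotype has no functional consequence). The consequence
#' restriction is therefore not accepted.
#'
#' @inheritParams query_genotype
#' @return data.frame with columns variant_id, chrom, pos, strain,
#'   haplotype_1, haplotype_2, prob, is_max.
#' @export
query_diplotype <- function(store, strains, region = NULL, genes = NULL,
                            variant_ids = NULL, max_only = FALSE,
                            prob_threshold = NULL, zygosity = NULL) {
  strains <- check_strains(store, strains)
  vids <- resolve_variants(store, region, genes, variant_ids)
  v <- store$variants[match(vids, store$variants$variant_id), ]
  out <- list()
  for (ch in unique(v$chrom)) {
    dt <- store_table(store, ch, "diplotype")
    dt <- dt[dt$variant_id %in% vids & dt$strain %in% strains, ]
    if (nrow(dt)) out[[length(out) + 1L]] <- as.data.frame(dt)
  }
  rows <- if (length(out)) do.call(rbind, out) else
    data.frame(variant_id = integer(), strain = character(),
               haplotype_1 = character(), haplotype_2 = character(),
               prob = numeric())
  vmatch <- match(rows$variant_id, store$variants$variant_id)
  rows$chrom <- store$variants$chrom[vmatch]
  rows$pos <- store$variants$pos[vmatch]
  rows$is_max <- NA
  rows <- rows[, c("variant_id", "chrom", "pos", "strain", "haplotype_1",
                   "haplotype_2", "prob", "is_max")]
  rows <- flag_is_max(rows)
  rows <- apply_restrictions(rows, max_only = max_only,
                             prob_threshold = prob_threshold,
                             zygosity = zygosity)
  rows <- rows[order(rows$variant_id, rows$strain, rows$haplotype_1,
                     rows$haplotype_2, method = "radix"), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

## fetch one strain's stored distribution at one variant as a named vector
stored_dist <- function(store, chrom, type, vid, strain) {
  dt <- store_table(store, chrom, type)
  sel <- dt$variant_id == vid & dt$strain == strain
  g <- dt[which(sel), ]
  if (!nrow(g)) return(NULL)
  if (type == "genotype")
    stats::setNames(g$prob, canonical_unphased(g$allele_1, g$allele_2))
  else
    stats::setNames(g$prob, canonical_unphased(g$haplotype_1, g$haplotype_2))
}

#' F1 cross genotype query
#'
#' Takes exactly two parent strains (CC or founder), simulates their F1
#' offspring's genotype distribution at each selected variant from the
#' stored parent distributions, and returns annotated rows with
#' `strain_1`/`strain_2` columns. Pruned parents give sub-unit offspring
#' mass (never renormalized).
#'
#' @inheritParams query_genotype
#' @param strains exactly two strain names (parent order is preserved in the
#'   output columns; probabilities are order-invariant).
#' @return data.frame of 13-column cross query rows.
#' @export
query_genotype_cross <- function(store, strains, region = NULL, genes = NULL,
                                 variant_ids = NULL, max_only = FALSE,
                                 prob_threshold = NULL, zygosity = NULL,
                                 consequence = NULL,
                                 consequence_match = c("either", "both"),
                                 strict = FALSE) {
  if (length(strains) != 2L)
    stop("a cross query takes exactly two strains")
  strains <- check_strains(store, strains)
  vids <- resolve_variants(store, region, genes, variant_ids)
  v <- store$variants[match(vids, store$variants$variant_id), ]
  out <- list()
  for (j in seq_along(vids)) {
    ch <- v$chrom[j]
    g1 <- stored_dist(store, ch, "genotype", vids[j], strains[1L])
    g2 <- stored_dist(store, ch, "genotype", vids[j], strains[2L])
    if (is.null(g1) || is.null(g2)) next
    f1 <- f1_genotype(genotype_dist(g1, strain = strains[1L]),
                      genotype_dist(g2, strain = strains[2L]))
    out[[length(out) + 1L]] <- annotate_store_group(
      store, match(vids[j], store$variants$variant_id), strains, f1,
      strict = strict)
  }
  finalize_rows(out, cross = TRUE, max_only = max_only,
                prob_threshold = prob_threshold, zygosity = zygosity,
                consequence = consequence,
                consequence_match = consequence_match)
}

#' F1 cross diplotype query
#'
#' @inheritParams query_genotype_cross
#' @return data.frame with strain_1/strain_2 and haplotype pair columns.
#' @export
query_diplotype_cross <- function(store, strains, region = NULL, genes = NULL,
                                  variant_ids = NULL, max_only = FALSE,
                                  prob_threshold = NULL, zygosity = NULL) {
  if (length(strains) != 2L)
    stop("a cross query takes exactly two strains")
  strains <- check_strains(store, strains)
  vids <- resolve_variants(store, region, genes, variant_ids)
  v <- store$variants[match(vids, store$variants$variant_id), ]
  out <- list()
  for (j in seq_along(vids)) {
    ch <- v$chrom[j]
    d1 <- stored_dist(store, ch, "diplotype", vids[j], strains[1L])
    d2 <- stored_dist(store, ch, "diplotype", vids[j], strains[2L])
    if (is.null(d1) || is.null(d2)) next
    t1 <- founder_transmission(d1); t2 <- founder_transmission(d2)
    p <- combine_transmissions(transmission_dist(t1), transmission_dist(t2))
    pr <- split_pair(names(p))
    out[[length(out) + 1L]] <-
      data.frame(variant_id = vids[j], chrom = ch, pos = v$pos[j],
                 strain_1 = strains[1L], strain_2 = strains[2L],
                 haplotype_1 = pr[, 1L], haplotype_2 = pr[, 2L],
                 prob = as.numeric(p), is_max = NA, stringsAsFactors = FALSE)
  }
  rows <- if (length(out)) do.call(rbind, out) else
    data.frame(variant_id = integer(), chrom = character(), pos = numeric(),
               strain_1 = character(), strain_2 = character(),
               haplotype_1 = character(), haplotype_2 = character(),
               prob = numeric(), is_max = logical())
  rows <- flag_is_max(rows)
  rows <- apply_restrictions(rows, max_only = max_only,
                             prob_threshold = prob_threshold,
                             zygosity = zygosity)
  rows <- rows[order(rows$variant_id, rows$haplotype_1, rows$haplotype_2,
                     method = "radix"), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Residual heterozygosity summary
#'
#' Per strain and chromosome, the fraction of buildable variants whose total
#' heterozygous-genotype probability is at least 0.25 — i.e. loci with at
#' least a 25% chance of continuing to segregate.
#'
#' @param store a `cc_store`.
#' @param strains strains to summarize (default: the CC strains).
#' @param threshold segregation-probability cutoff (default 0.25, inclusive).
#' @return data.frame with columns strain, chrom, prop_het.
#' @export
residual_het_summary <- function(store, strains = store$meta$cc_strains,
                                 threshold = 0.25) {
  strains_req <- check_strains(store, strains)
  variant_id <- strain <- prob <- phet <- allele_1 <- allele_2 <- NULL
  out <- list()
  for (ch in store$meta$chroms) {
    nvar <- sum(store$variants$chrom == ch)
    dt <- store_table(store, ch, "genotype")
    dt <- dt[dt$strain %in% strains_req, ]
    het <- dt[, list(phet = sum(prob[allele_1 != allele_2])),
              by = list(strain, variant_id)]
    agg <- het[, list(n_het = sum(phet >= threshold)), by = strain]
    agg <- agg[match(strains_req, agg$strain), ]
    out[[ch]] <- data.frame(strain = strains_req, chrom = ch,
                            prop_het = ifelse(is.na(agg$n_het), 0,
                                              agg$n_het) / nvar,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reference identity summary
#'
#' The fraction of (strain, variant) pairs whose maximum-probability
#' genotype is homozygous for the reference allele (ties involving the
#' reference count as identical). `method = "weighted"` instead averages the
#' probability of the homozygous-reference state.
#'
#' @param store a `cc_store`.
#' @param strains non-empty strain set (default: the CC strains).
#' @param method `"ml"` (default) or `"weighted"`.
#' @return proportion in `[0, 1]`.
#' @export
reference_identity_summary <- function(store,
                                       strains = store$meta$cc_strains,
                                       method = c("ml", "weighted")) {
  method <- match.arg(method)
  if (!length(strains)) stop("empty strain set")
  strains <- check_strains(store, strains)
  variant_id <- strain <- prob <- NULL
  num <- 0; den <- 0
  for (ch in store$meta$chroms) {
    dt <- store_table(store, ch, "genotype")
    dt <- dt[dt$strain %in% strains, ]
    ref <- store$variants$ref[match(dt$variant_id, store$variants$variant_id)]
    dt$isref <- dt$allele_1 == ref & dt$allele_2 == ref
    isref <- NULL
    per <- dt[, list(refid = if (method == "ml")
                       any(isref & prob >= max(prob) - 1e-9)
                     else sum(prob[isref])),
              by = list(strain, variant_id)]
    ## (strain, variant) pairs whose states were all pruned count as absent
    nvar <- sum(store$variants$chrom == ch)
    num <- num + sum(per$refid)
    den <- den + nvar * length(strains)
  }
  num / den
}

#' Probability-weighted consequence spectrum
#'
#' For every annotated (variant, allele, gene, transcript) combination, sums
#' the stored genotype probability mass carried on that allele (each allele
#' slot of each genotype state counts once), then normalizes across
#' consequence terms. Reference alleles do not contribute.
#'
#' @param store a `cc_store`.
#' @param strains strains to include (default: the CC strains).
#' @return data.frame with columns term, share (shares sum to 1), ordered by
#'   decreasing share.
#' @export
consequence_spectrum <- function(store, strains = store$meta$cc_strains) {
  strains <- check_strains(store, strains)
  ann <- store$consequences
  acc <- NULL
  variant_id <- allele <- prob <- term <- allele_1 <- allele_2 <- NULL
  for (ch in store$meta$chroms) {
    dt <- store_table(store, ch, "genotype")
    dt <- dt[dt$strain %in% strains, ]
    if (!nrow(dt)) next
    long <- data.table::rbindlist(list(
      dt[, list(variant_id, allele = allele_1, prob)],
      dt[, list(variant_id, allele = allele_2, prob)]))
    hit <- merge(long, ann[, list(variant_id, allele, term)],
                 by = c("variant_id", "allele"), allow.cartesian = TRUE)
    if (nrow(hit))
      acc <- data.table::rbindlist(list(acc, hit[, list(variant_id, term, prob)]))
  }
  if (is.null(acc) || !nrow(acc))
    return(data.frame(term = character(), share = numeric()))
  tot <- acc[, list(mass = sum(prob)), by = term]
  tot$share <- tot$mass / sum(tot$mass)
  tot <- tot[order(-tot$share, tot$term), ]
  data.frame(term = tot$term, share = tot$share, stringsAsFactors = FALSE)
}
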