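## Readers and writers for the external formats: founder VCF (via
## VariantAnnotation), exon BED/GFF3 (via rtracklayer, normalized to 1-based
## closed coordinates), the long-format marker diplotype CSV, the 5-column
## consequence TSV, and the query-row CSV dumps.

#' Read a founder panel VCF
#'
#' Parses a VCF v4.x with one sample column per founder strain into variant
#' records and per-founder genotype distributions. By default each GT call
#' becomes a point mass (heterozygous calls such as `0/1` are preserved as
#' residual founder heterozygosity); `mode = "likelihood"` converts PL (or
#' GL) fields into a normalized distribution over genotypes. Missing calls
#' (`./.`) leave the founder absent from the variant's map, which downstream
#' code treats as homozygous reference. Records whose GT is malformed are
#' skipped with a warning. A VEP-style CSQ INFO field, if declared, is
#' parsed into consequence annotations.
#'
#' @param path VCF file (plain text or gzipped).
#' @param founders founder sample names to extract; default all samples.
#' @param mode `"gt"` (point mass, default) or `"likelihood"` (PL/GL).
#' @return list with elements `variants` (data.frame: chrom, pos, ref, alt
#'   comma-joined, class), `genotypes` (per-variant named list of named
#'   probability vectors), `annotations` (data.frame: chrom, pos, allele,
#'   gene_id, transcript_id, term), `founders`.
#' @export
read_founder_vcf <- function(path, founders = NULL, mode = c("gt", "likelihood")) {
  mode <- match.arg(mode)
  vcf <- VariantAnnotation::readVcf(path, genome = "unspecified")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- lapply(as.list(VariantAnnotation::alt(vcf)), as.character)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  samples <- colnames(gt)
  if (is.null(founders)) founders <- samples
  missing <- setdiff(founders, samples)
  if (length(missing))
    stop("founder sample(s) not in VCF: ", paste(missing, collapse = ", "),
         "; available: ", paste(samples, collapse = ", "))
  pl <- if (mode == "likelihood") {
    g <- VariantAnnotation::geno(vcf)
    if ("PL" %in% names(g)) g$PL else if ("GL" %in% names(g)) g$GL else
      stop("likelihood mode requires a PL or GL FORMAT field")
  }
  n <- length(pos)
  genotypes <- vector("list", n)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    alleles <- c(ref[i], alt_list[[i]])
    gmap <- list()
    ok <- TRUE
    for (f in founders) {
      d <- if (mode == "likelihood")
        genotype_probs_from_pl(extract_pl(pl, i, f), alleles)
      else
        genotype_probs_from_gt(gt[i, f], alleles)
      if (identical(d, "malformed")) { ok <- FALSE; break }
      if (!is.null(d)) gmap[[f]] <- d
    }
    if (!ok) {
      warning("skipping record ", chrom[i], ":", pos[i], " (malformed GT)")
      keep[i] <- FALSE
    } else genotypes[[i]] <- gmap
  }
  variants <- data.frame(chrom = chrom, pos = pos, ref = ref,
                         alt = vapply(alt_list, paste, "", collapse = ","),
                         stringsAsFactors = FALSE)[keep, , drop = FALSE]
  variants$class <- ifelse(nchar(variants$ref) == 1L &
                             !grepl("[^,]{2,}", variants$alt), "SNP", "indel")
  rownames(variants) <- NULL
  list(variants = variants, genotypes = genotypes[keep],
       annotations = parse_csq(vcf, chrom[keep], pos[keep]),
       founders = founders)
}

## point-mass distribution from one GT string; NULL for missing, the string
## "malformed" for unparseable calls
genotype_probs_from_gt <- function(gt, alleles) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NULL)
  idx <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
  if (length(idx) != 2L || anyNA(idx) || any(idx < 0) ||
      any(idx >= length(alleles)))
    return("malformed")
  stats::setNames(1, canonical_unphased(alleles[idx[1L] + 1L],
                                        alleles[idx[2L] + 1L]))
}

extract_pl <- function(pl, i, f) {
  v <- if (length(dim(pl)) == 3L) pl[i, f, ] else pl[[i, f]]
  as.numeric(unlist(v))
}

## VCF genotype ordering: index k(k+1)/2 + j for allele pair (j, k), j <= k
genotype_probs_from_pl <- function(pl, alleles) {
  if (!length(pl) || all(is.na(pl))) return(NULL)
  n <- length(alleles)
  if (length(pl) != n * (n + 1) / 2) return("malformed")
  lik <- 10^(-pl / 10)
  lik <- lik / sum(lik)
  keys <- character(length(pl))
  for (k in 0:(n - 1)) for (j in 0:k)
    keys[k * (k + 1) / 2 + j + 1] <- canonical_unphased(alleles[j + 1],
                                                        alleles[k + 1])
  tab <- rowsum(lik, keys)
  p <- stats::setNames(tab[, 1L], rownames(tab))
  p[p > 0]
}

## parse a VEP-style CSQ INFO field (subfields Allele|Consequence|Gene|Feature,
## order taken from the header Description); returns zero rows when absent
parse_csq <- function(vcf, chrom, pos) {
  empty <- data.frame(chrom = character(), pos = numeric(),
                      allele = character(), gene_id = character(),
                      transcript_id = character(), term = character(),
                      stringsAsFactors = FALSE)
  hdr <- VariantAnnotation::info(VariantAnnotation::header(vcf))
  if (!"CSQ" %in% rownames(hdr)) return(empty)
  desc <- hdr["CSQ", "Description"]
  fields <- strsplit(sub(".*Format: *", "", desc), "|", fixed = TRUE)[[1]]
  fields <- trimws(gsub('"', "", fields))
  csq <- VariantAnnotation::info(vcf)$CSQ
  rows <- list()
  for (i in seq_along(csq)) {
    for (entry in csq[[i]]) {
      parts <- strsplit(entry, "|", fixed = TRUE)[[1]]
      names(parts) <- fields[seq_along(parts)]
      terms <- strsplit(parts[["Consequence"]], "&", fixed = TRUE)[[1]]
      tx <- if ("Feature" %in% names(parts)) parts[["Feature"]] else
        parts[["Transcript"]]
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = chrom[i], pos = pos[i], allele = parts[["Allele"]],
                   gene_id = parts[["Gene"]], transcript_id = tx,
                   term = terms, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Read a 5-column consequence TSV
#'
#' Columns: chrom, pos, allele, `gene_id:transcript_id`, term. A header line
#' is optional; `#`-prefixed comment lines are skipped.
#'
#' @param path TSV file.
#' @return data.frame with chrom, pos, allele, gene_id, transcript_id, term.
#' @export
read_consequence_tsv <- function(path) {
  dt <- fread_skip_comments(path, sep = "\t", header = "auto")
  if (ncol(dt) != 5L) stop("consequence TSV must have 5 columns")
  data.table::setnames(dt, c("chrom", "pos", "allele", "gene_tx", "term"))
  gtx <- data.table::tstrsplit(dt$gene_tx, ":", fixed = TRUE)
  out <- data.frame(chrom = as.character(dt$chrom), pos = as.numeric(dt$pos),
                    allele = dt$allele, gene_id = gtx[[1]],
                    transcript_id = if (length(gtx) > 1L) gtx[[2]] else "",
                    term = dt$term, stringsAsFactors = FALSE)
  out
}

fread_skip_comments <- function(path, ...) {
  first <- readLines(path, n = 50L)
  nskip <- match(FALSE, startsWith(first, "#"), nomatch = 1L) - 1L
  data.table::fread(path, skip = nskip, ...)
}

#' Read marker diplotype probabilities
#'
#' Long-format CSV with header `strain,chrom,pos,marker,hap1,hap2,prob`: one
#' row per (strain, marker, unphased founder pair). Rows are grouped per
#' (strain, marker); `hap1`/`hap2` order is irrelevant (duplicate phasings of
#' one unordered pair are merged by summing). Per-marker total mass within
#' [0.98, 1.02] is accepted silently (haplotype-reconstruction output is not
#' exactly normalized); anything else draws a warning. Marker positions must
#' be non-decreasing within each (strain, chrom) block.
#'
#' @param path CSV file (leading `#` comment lines allowed).
#' @param founders optional haplotype-set names; unknown names error.
#' @return a `data.table` with columns strain, chrom, pos, marker, key, prob
#'   (one row per state, canonical keys, merged).
#' @export
read_marker_diplotypes <- function(path, founders = NULL) {
  dt <- fread_skip_comments(path, sep = ",", header = TRUE)
  need <- c("strain", "chrom", "pos", "marker", "hap1", "hap2", "prob")
  if (!all(need %in% names(dt)))
    stop("marker CSV must have columns: ", paste(need, collapse = ","))
  if (anyNA(dt$prob) || any(dt$prob < 0) || any(dt$prob > 1 + PROB_TOL))
    stop("marker probabilities must lie in [0, 1]")
  if (!is.null(founders)) {
    bad <- setdiff(unique(c(dt$hap1, dt$hap2)), founders)
    if (length(bad))
      stop("unknown founder name(s) in marker file: ",
           paste(bad, collapse = ", "))
  }
  dt$chrom <- as.character(dt$chrom)
  ## positions must already be sorted within each strain/chrom block
  pos <- chrom <- strain <- prob <- key <- marker <- hap1 <- hap2 <- NULL
  unsorted <- dt[, any(diff(pos) < 0), by = list(strain, chrom)]$V1
  if (any(unsorted))
    stop("marker positions are not sorted within a strain/chromosome block")
  dt[, key := canonical_unphased(hap1, hap2)]
  out <- dt[, list(prob = sum(prob)),
            by = list(strain, chrom, pos, marker, key)]
  sums <- out[, list(s = sum(prob)), by = list(strain, chrom, pos, marker)]
  off <- sums$s < 0.98 | sums$s > 1.02
  if (any(off))
    warning(sum(off), " marker(s) with total probability outside [0.98, 1.02]")
  out[]
}

#' Read exon intervals from BED or GFF3
#'
#' BED input (0-based half-open) and GFF3 input (1-based closed) are both
#' normalized to 1-based fully closed intervals. The gene identifier is taken
#' from the BED name column, or from the `gene_id` (falling back to `Parent`
#' then `ID`) attribute of GFF3 `exon` features.
#'
#' @param path `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @return data.frame with columns chrom, start, end, gene_id.
#' @export
read_exons <- function(path) {
  fmt <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "BED" else "GFF"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "GFF" && "type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) == "exon"]
  mc <- S4Vectors::mcols(gr)
  gene <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id)
    else if ("name" %in% names(mc)) as.character(mc$name)
    else if ("Parent" %in% names(mc)) vapply(as.list(mc$Parent), function(x)
      if (length(x)) x[[1]] else NA_character_, "")
    else if ("ID" %in% names(mc)) as.character(mc$ID)
    else rep(NA_character_, length(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             gene_id = gene, stringsAsFactors = FALSE)
}

#' Build-time variant filter
#'
#' Keeps variants that (i) intersect an exon interval expanded by `window`
#' bp on both sides (closed arithmetic; an indel intersects if any base of
#' its reference span falls in a window), (ii) are polymorphic among the
#' founders (the per-founder genotype distributions are not all identical,
#' with founders missing from a record counted as homozygous reference), and
#' (iii) have only alleles of 1-100 bp (SNPs and short indels).
#'
#' @param variants data.frame as from [read_founder_vcf()].
#' @param genotypes per-variant genotype maps as from [read_founder_vcf()].
#' @param exons data.frame as from [read_exons()].
#' @param founders full founder panel (needed to treat missing founders as
#'   homozygous reference in the polymorphism check).
#' @param window bp added to each side of every exon (default 100).
#' @return logical vector: keep the variant?
#' @export
filter_buildable_variants <- function(variants, genotypes, exons,
                                      founders, window = 100L) {
  span_end <- variants$pos + nchar(variants$ref) - 1L
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, span_end))
  er <- GenomicRanges::GRanges(exons$chrom,
                               IRanges::IRanges(pmax(1L, exons$start - window),
                                                exons$end + window))
  in_window <- IRanges::overlapsAny(vr, er)
  alt_split <- strsplit(variants$alt, ",", fixed = TRUE)
  len_ok <- nchar(variants$ref) <= 100L &
    vapply(alt_split, function(a) all(nchar(a) >= 1L & nchar(a) <= 100L), NA)
  poly <- vapply(seq_len(nrow(variants)), function(i) {
    ref_key <- canonical_unphased(variants$ref[i], variants$ref[i])
    sigs <- vapply(founders, function(f) {
      d <- genotypes[[i]][[f]]
      if (is.null(d)) d <- stats::setNames(1, ref_key)
      paste(names(d), format(as.numeric(d), digits = 12), collapse = ";")
    }, "")
    length(unique(sigs)) > 1L
  }, NA)
  in_window & len_ok & poly
}

#' Map each variant to the genes whose windows it overlaps
#'
#' @inheritParams filter_buildable_variants
#' @return character vector: comma-joined gene ids per variant ("" if none).
#' @export
genes_for_variants <- function(variants, exons, window = 100L) {
  span_end <- variants$pos + nchar(variants$ref) - 1L
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, span_end))
  er <- GenomicRanges::GRanges(exons$chrom,
                               IRanges::IRanges(pmax(1L, exons$start - window),
                                                exons$end + window))
  hits <- GenomicRanges::findOverlaps(vr, er)
  out <- rep("", nrow(variants))
  if (length(hits)) {
    dt <- data.table::data.table(v = S4Vectors::queryHits(hits),
                                 g = exons$gene_id[S4Vectors::subjectHits(hits)])
    v <- g <- NULL
    agg <- dt[, list(genes = paste(sort(unique(g), method = "radix"),
                                   collapse = ",")), by = v]
    out[agg$v] <- agg$genes
  }
  out
}

#' Write query rows to CSV
#'
#' Emits exactly the documented column set in documented order: the
#' 12-column genotype schema (with `strain` split into `strain_1`/`strain_2`
#' for cross queries), or the diplotype schema (`haplotype_1`/`haplotype_2`,
#' no transcript or consequence columns).
#'
#' @param rows data.frame of query rows.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_query_csv <- function(rows, path) {
  if ("haplotype_1" %in% names(rows) || !"gene_id" %in% names(rows)) {
    cols <- c("variant_id", "chrom", "pos",
              intersect(c("strain", "strain_1", "strain_2"), names(rows)),
              "haplotype_1", "haplotype_2", "prob", "is_max")
  } else {
    cols <- query_row_columns(cross = "strain_1" %in% names(rows))
  }
  miss <- setdiff(cols, names(rows))
  if (length(miss)) stop("rows missing columns: ", paste(miss, collapse = ", "))
  data.table::fwrite(data.table::as.data.table(rows)[, cols, with = FALSE],
                     path, quote = FALSE)
  invisible(path)
}

#' Read back a query-row CSV
#'
#' @param path file written by [write_query_csv()].
#' @return data.frame of query rows.
#' @export
read_query_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE,
                          colClasses = list(character = "chrom"))
  df <- as.data.frame(dt)
  for (col in intersect(c("gene_id", "transcript_id"), names(df)))
    df[[col]][is.na(df[[col]])] <- ""
  df$is_max <- as.logical(df$is_max)
  df
}
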