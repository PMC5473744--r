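## Ground-truthed synthetic inputs: an 8-founder variant panel (VCF +
## consequence TSV + exon BED) and per-strain founder-haplotype mosaics
## emitted as marker diplotype probabilities (CSV), in exactly the dialects
## the readers consume. A single integer seed governs all randomness and is
## recorded in a header comment of every output file.

CONSEQUENCE_VOCAB <- c(missense_variant = 0.35, synonymous_variant = 0.40,
                       stop_gained = 0.03, splice_region_variant = 0.07,
                       `5_prime_UTR_variant` = 0.07,
                       `3_prime_UTR_variant` = 0.08)

#' Simulate a founder variant panel
#'
#' Generates exon annotations, a founder VCF and a consequence TSV for a
#' synthetic genome. Variants are placed inside exon windows (exon +/- 100
#' bp) except for a configurable fraction placed outside, to exercise the
#' build filter. Every variant is polymorphic among the founders; a fraction
#' `het_rate` of founder genotype calls is heterozygous (residual founder
#' heterozygosity); a fraction `indel_rate` of variants are short indels.
#'
#' Two allele-sharing structures are available: `"shared"` (default; one
#' biallelic alternate carried by a random subset of non-reference founders,
#' the realistic case) and `"private"` (each non-reference founder carries
#' its own distinguishing alternate allele, so any two distinct founders
#' differ at every variant — useful for exact parameter-recovery tests).
#'
#' @param dir output directory (created if needed).
#' @param n_variants variants per chromosome.
#' @param n_chrom number of chromosomes.
#' @param founders founder names; the first entry in `reference_founder`
#'   position is treated as the reference-like strain.
#' @param het_rate per-(founder, variant) probability of a heterozygous call.
#' @param indel_rate fraction of variants that are indels.
#' @param frac_outside fraction of variants placed outside every exon window.
#' @param allele_structure `"shared"` or `"private"`.
#' @param n_genes_per_chrom genes per chromosome.
#' @param chrom_length chromosome length in bp.
#' @param reference_founder founder treated as matching the reference
#'   assembly (never carries an alternate in the generator).
#' @param seed integer seed; recorded in every output header.
#' @return list with file paths (`vcf`, `exons`, `csq`), the founder names,
#'   chromosome geometry, and a `truth` list (variant table with placement
#'   flags, founder-by-variant genotype codes where 0 = hom ref, 1 = het,
#'   2 = hom alt, and the gene/exon tables).
#' @export
simulate_founder_panel <- function(dir = tempfile("panel"),
                                   n_variants = 500L, n_chrom = 2L,
                                   founders = cc_founders(),
                                   het_rate = 0.02, indel_rate = 0.1,
                                   frac_outside = 0,
                                   allele_structure = c("shared", "private"),
                                   n_genes_per_chrom = 10L,
                                   chrom_length = 2e6,
                                   reference_founder = "B6",
                                   seed = 1L) {
  allele_structure <- match.arg(allele_structure)
  for (r in c(het_rate, indel_rate, frac_outside))
    if (!is.numeric(r) || r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (!reference_founder %in% founders) stop("reference_founder not a founder")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chrom))

  ## genes: evenly spaced loci, 2-4 exons each, 1-2 transcripts
  genes <- exons <- list()
  for (ci in seq_len(n_chrom)) {
    centers <- seq(chrom_length * 0.08, chrom_length * 0.92,
                   length.out = n_genes_per_chrom)
    for (gi in seq_len(n_genes_per_chrom)) {
      gid <- sprintf("GENE%s_%02d", ci, gi)
      n_ex <- sample(2:4, 1L)
      ex_start <- sort(round(centers[gi] + seq(0, by = 4000, length.out = n_ex) +
                               sample(-500:500, n_ex, replace = TRUE)))
      ex_len <- sample(800:2500, n_ex, replace = TRUE)
      exons[[length(exons) + 1L]] <-
        data.frame(chrom = chroms[ci], start = ex_start,
                   end = ex_start + ex_len - 1L, gene_id = gid,
                   stringsAsFactors = FALSE)
      genes[[length(genes) + 1L]] <-
        data.frame(gene_id = gid, chrom = chroms[ci],
                   n_tx = sample(1:2, 1L), stringsAsFactors = FALSE)
    }
  }
  exons <- do.call(rbind, exons)
  genes <- do.call(rbind, genes)

  ## variant placement
  variants <- list()
  for (ci in seq_len(n_chrom)) {
    ex_c <- exons[exons$chrom == chroms[ci], , drop = FALSE]
    win <- IRanges::reduce(IRanges::IRanges(pmax(1L, ex_c$start - 100L),
                                            ex_c$end + 100L))
    n_out <- round(n_variants * frac_outside)
    n_in <- n_variants - n_out
    ## inside: sample windows by width, uniform position within
    wi <- sample(length(win), n_in, replace = TRUE,
                 prob = IRanges::width(win))
    pos_in <- IRanges::start(win)[wi] +
      floor(stats::runif(n_in) * IRanges::width(win)[wi])
    ## outside: rejection-sample positions not in any window
    pos_out <- integer(0)
    while (length(pos_out) < n_out) {
      cand <- sample.int(chrom_length, n_out * 2L, replace = TRUE)
      hit <- IRanges::overlapsAny(IRanges::IRanges(cand, cand), win)
      pos_out <- c(pos_out, cand[!hit])
    }
    pos_out <- pos_out[seq_len(n_out)]
    pos <- sort(unique(c(pos_in, pos_out)))
    variants[[ci]] <- data.frame(chrom = chroms[ci], pos = pos,
                                 inside = pos %in% pos_in,
                                 stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, variants)
  nv <- nrow(variants)

  ## alleles
  bases <- c("A", "C", "G", "T")
  variants$ref <- sample(bases, nv, replace = TRUE)
  is_indel <- stats::runif(nv) < indel_rate
  nf <- length(founders)
  if (allele_structure == "private") {
    ## (nf - 1) distinct alternates: the 3 other bases plus suffix-extended
    ## alleles; all distinct from the single-base reference
    alts <- lapply(seq_len(nv), function(i)
      c(setdiff(bases, variants$ref[i]),
        paste0(variants$ref[i], bases))[seq_len(nf - 1L)])
  } else {
    alts <- lapply(seq_len(nv), function(i) {
      if (is_indel[i]) {
        if (stats::runif(1) < 0.5)
          paste0(variants$ref[i],
                 paste(sample(bases, sample(1:4, 1L), replace = TRUE),
                       collapse = ""))
        else {  # deletion: extend the ref, alt is the single base
          variants$ref[i] <<- paste0(variants$ref[i],
                                     paste(sample(bases, sample(1:4, 1L),
                                                  replace = TRUE),
                                           collapse = ""))
          substr(variants$ref[i], 1L, 1L)
        }
      } else sample(setdiff(bases, variants$ref[i]), 1L)
    })
  }
  variants$alt <- vapply(alts, paste, "", collapse = ",")

  ## founder genotype codes: 0 hom ref, k hom alt_k, negative -k = het ref/alt_k
  ref_idx <- match(reference_founder, founders)
  gcodes <- matrix(0L, nrow = nf, ncol = nv, dimnames = list(founders, NULL))
  for (i in seq_len(nv)) {
    if (allele_structure == "private") {
      others <- setdiff(seq_len(nf), ref_idx)
      gcodes[others, i] <- seq_len(nf - 1L)
    } else {
      carriers <- sample(setdiff(seq_len(nf), ref_idx),
                         sample(1:4, 1L), replace = FALSE)
      gcodes[carriers, i] <- 1L
    }
    het <- stats::runif(nf) < het_rate
    ## a het call keeps one ref copy and one copy of the founder's alt
    ## (carriers) or of alt 1 (non-carriers, creating low-level polymorphism)
    for (f in which(het))
      gcodes[f, i] <- -max(1L, gcodes[f, i])
  }

  ## consequence annotations: per (inside-variant, alt, gene transcript)
  gene_of <- genes_for_variants(variants, exons)
  csq <- list()
  for (i in which(nzchar(gene_of))) {
    for (g in strsplit(gene_of[i], ",", fixed = TRUE)[[1]]) {
      n_tx <- genes$n_tx[genes$gene_id == g]
      for (t in seq_len(n_tx)) {
        tx <- sprintf("%s_T%d", g, t)
        for (a in strsplit(variants$alt[i], ",", fixed = TRUE)[[1]]) {
          csq[[length(csq) + 1L]] <- data.frame(
            chrom = variants$chrom[i], pos = variants$pos[i], allele = a,
            gene_tx = paste0(g, ":", tx),
            term = sample(names(CONSEQUENCE_VOCAB), 1L,
                          prob = CONSEQUENCE_VOCAB),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  csq <- if (length(csq)) do.call(rbind, csq) else
    data.frame(chrom = character(), pos = numeric(), allele = character(),
               gene_tx = character(), term = character())

  paths <- list(vcf = file.path(dir, "founders.vcf"),
                exons = file.path(dir, "exons.bed"),
                csq = file.path(dir, "consequences.tsv"))
  write_panel_vcf(paths$vcf, variants, gcodes, founders, chroms,
                  chrom_length, seed)
  write_panel_bed(paths$exons, exons, seed)
  writeLines(c(sprintf("# seed=%d", seed),
               paste("chrom", "pos", "allele", "gene_tx", "term", sep = "\t"),
               do.call(paste, c(csq, sep = "\t"))),
             paths$csq)

  list(vcf = paths$vcf, exons = paths$exons, csq = paths$csq,
       founders = founders, chroms = chroms, chrom_length = chrom_length,
       reference_founder = reference_founder, seed = seed,
       truth = list(variants = variants, gcodes = gcodes, exons = exons,
                    genes = genes, csq = csq))
}

write_panel_vcf <- function(path, variants, gcodes, founders, chroms,
                            chrom_length, seed) {
  gt_string <- function(code) {
    if (code >= 0L) sprintf("%d/%d", code, code) else sprintf("0/%d", -code)
  }
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
            variants$alt[i], ".", "PASS", ".", "GT",
            vapply(gcodes[, i], gt_string, "")), collapse = "\t")
  }, "")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##seed=%d", seed),
               sprintf("##contig=<ID=%s,length=%d>", chroms,
                       as.integer(chrom_length)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", founders), collapse = "\t"),
               body), path)
}

write_panel_bed <- function(path, exons, seed) {
  writeLines(c(sprintf('track name="exons" description="seed=%d"', seed),
               paste(exons$chrom, exons$start - 1L, exons$end, exons$gene_id,
                     0L, "+", sep = "\t")), path)
}

#' Simulate CC strain mosaics and their marker diplotype probabilities
#'
#' Each strain's genome is a piecewise-constant mosaic of founder-haplotype
#' pairs: breakpoints are Poisson (`recomb_rate` expected per chromosome),
#' each segment is homozygous for one founder except that a fraction
#' `residual_het_rate` of segments still segregates and carries two distinct
#' founder haplotypes. A shared marker grid (evenly spaced, as on a
#' genotyping array) observes the mosaic; with `uncertainty_level` u > 0 a
#' fraction `mixed_fraction` of marker calls shares mass u with two states
#' confusable with the truth (sharing one haplotype), while the rest remain
#' near-certain point masses.
#'
#' @param panel result of [simulate_founder_panel()] (supplies geometry and
#'   founder names).
#' @param dir output directory.
#' @param n_strains number of CC strains.
#' @param markers_per_chrom markers per chromosome (shared grid).
#' @param recomb_rate expected breakpoints per chromosome.
#' @param residual_het_rate per-segment probability of residual
#'   heterozygosity.
#' @param uncertainty_level probability mass moved off the true state at a
#'   blurred marker (0 = all point masses).
#' @param mixed_fraction fraction of markers blurred when
#'   `uncertainty_level > 0`.
#' @param seed integer seed (independent of the panel's).
#' @return list with `csv` (marker diplotype file), `strains`, `markers`
#'   (the grid), and `truth`: the segment table (strain, chrom, start, end,
#'   hap1, hap2, het) and the per-marker true states.
#' @export
simulate_cc_mosaics <- function(panel, dir = dirname(panel$vcf),
                                n_strains = 20L, markers_per_chrom = 50L,
                                recomb_rate = 9, residual_het_rate = 0.03,
                                uncertainty_level = 0.05,
                                mixed_fraction = 0.3, seed = 2L) {
  stopifnot(n_strains >= 1L, markers_per_chrom >= 2L, recomb_rate >= 0,
            residual_het_rate >= 0, residual_het_rate <= 1,
            uncertainty_level >= 0, uncertainty_level < 1)
  set.seed(seed)
  founders <- panel$founders
  L <- panel$chrom_length
  strains <- sprintf("CC%03d", seq_len(n_strains))
  grid <- round(seq(L / (markers_per_chrom + 1), L * markers_per_chrom /
                      (markers_per_chrom + 1), length.out = markers_per_chrom))

  segs <- rows <- mk_truth <- list()
  for (s in strains) for (ch in panel$chroms) {
    nb <- stats::rpois(1L, recomb_rate)
    bp <- sort(sample.int(L - 1L, nb))
    bounds <- c(1L, bp + 1L)
    ends <- c(bp, L)
    het <- stats::runif(length(bounds)) < residual_het_rate
    hap1 <- sample(founders, length(bounds), replace = TRUE)
    hap2 <- hap1
    for (k in which(het))
      hap2[k] <- sample(setdiff(founders, hap1[k]), 1L)
    segs[[length(segs) + 1L]] <-
      data.frame(strain = s, chrom = ch, start = bounds, end = ends,
                 hap1 = hap1, hap2 = hap2, het = het,
                 stringsAsFactors = FALSE)
    seg_at <- findInterval(grid, bounds)
    truth_key <- canonical_unphased(hap1[seg_at], hap2[seg_at])
    mk_truth[[length(mk_truth) + 1L]] <-
      data.frame(strain = s, chrom = ch, pos = grid,
                 marker = sprintf("%s_m%03d", ch, seq_along(grid)),
                 key = truth_key, stringsAsFactors = FALSE)
    for (mi in seq_along(grid)) {
      key <- truth_key[mi]
      probs <- stats::setNames(1, key)
      if (uncertainty_level > 0 && stats::runif(1) < mixed_fraction) {
        tk <- split_pair(key)
        others <- setdiff(founders, tk)
        confus <- c(canonical_unphased(tk[1L], sample(others, 1L)),
                    canonical_unphased(tk[2L], sample(others, 1L)))
        confus <- setdiff(unique(confus), key)
        probs <- stats::setNames(
          c(1 - uncertainty_level,
            rep(uncertainty_level / length(confus), length(confus))),
          c(key, confus))
      }
      pp <- split_pair(names(probs))
      rows[[length(rows) + 1L]] <-
        data.frame(strain = s, chrom = ch, pos = grid[mi],
                   marker = sprintf("%s_m%03d", ch, mi),
                   hap1 = pp[, 1L], hap2 = pp[, 2L],
                   prob = as.numeric(probs), stringsAsFactors = FALSE)
    }
  }
  segs <- do.call(rbind, segs)
  rows <- do.call(rbind, rows)
  mk_truth <- do.call(rbind, mk_truth)

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "marker_diplotypes.csv")
  writeLines(sprintf("# seed=%d", seed), csv)
  suppressWarnings(data.table::fwrite(rows, csv, append = TRUE,
                                      col.names = TRUE, quote = FALSE))
  list(csv = csv, strains = strains, markers = grid,
       truth = list(segments = segs, marker_states = mk_truth),
       seed = seed)
}

#' True diplotype of a simulated strain at a position
#'
#' @param truth the `truth` element of [simulate_cc_mosaics()]'s result.
#' @param strain,chrom,pos locus to look up.
#' @return list with `key` (canonical founder-pair key) and `het`.
#' @export
truth_diplotype_at <- function(truth, strain, chrom, pos) {
  seg <- truth$segments
  hit <- seg$strain == strain & seg$chrom == chrom &
    seg$start <= pos & seg$end >= pos
  i <- which(hit)[1L]
  if (is.na(i)) stop("position outside simulated genome")
  list(key = canonical_unphased(seg$hap1[i], seg$hap2[i]), het = seg$het[i])
}

#' Classify variant positions by flanking-marker cleanliness
#'
#' A (strain, variant) pair is "clean" when its flanking markers (or its
#' single flanking marker, outside the grid span) lie in the same truth
#' segment as the variant: interpolation of point-mass markers then recovers
#' the true diplotype exactly. Pairs straddling a mosaic breakpoint are
#' necessarily imputed as two-state mixtures and cannot be point masses.
#'
#' @param truth `truth` element of [simulate_cc_mosaics()]'s result.
#' @param strain,chrom strain and chromosome.
#' @param positions variant positions.
#' @param markers the marker grid.
#' @return logical vector parallel to `positions`.
#' @export
clean_gap <- function(truth, strain, chrom, positions, markers) {
  seg <- truth$segments
  seg <- seg[seg$strain == strain & seg$chrom == chrom, , drop = FALSE]
  seg_of <- function(p) findInterval(p, seg$start)
  vapply(positions, function(p) {
    fl <- flanking_markers(markers, p)
    ms <- c(if (!is.na(fl$left)) markers[fl$left],
            if (!is.na(fl$right)) markers[fl$right])
    all(seg_of(ms) == seg_of(p))
  }, NA)
}
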