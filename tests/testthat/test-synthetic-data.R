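test_that("generators are deterministic under a fixed seed", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  p1 <- simulate_founder_panel(dir = d1, n_variants = 40, n_chrom = 1,
                               seed = 9L)
  p2 <- simulate_founder_panel(dir = d2, n_variants = 40, n_chrom = 1,
                               seed = 9L)
  expect_identical(readLines(p1$vcf), readLines(p2$vcf))
  expect_identical(readLines(p1$exons), readLines(p2$exons))
  expect_identical(readLines(p1$csq), readLines(p2$csq))
  m1 <- simulate_cc_mosaics(p1, dir = d1, n_strains = 3,
                            markers_per_chrom = 10, seed = 10L)
  m2 <- simulate_cc_mosaics(p2, dir = d2, n_strains = 3,
                            markers_per_chrom = 10, seed = 10L)
  expect_identical(readLines(m1$csv), readLines(m2$csv))
  # the seed is recorded in every output header
  expect_true(any(grepl("seed=9", readLines(p1$vcf, n = 3))))
  expect_true(any(grepl("seed=10", readLines(m1$csv, n = 1))))
})

test_that("rate knobs hit their limits", {
  d <- file.path(tempdir(), "limits")
  # het_rate = 0: no 0/x heterozygous GT anywhere
  p <- simulate_founder_panel(dir = d, n_variants = 60, n_chrom = 1,
                              het_rate = 0, seed = 11L)
  body <- grep("^#", readLines(p$vcf), value = TRUE, invert = TRUE)
  gts <- unlist(lapply(strsplit(body, "\t"), function(x) x[-(1:9)]))
  pair <- do.call(rbind, strsplit(gts, "/"))
  expect_true(all(pair[, 1] == pair[, 2] | pair[, 1] == "0"))
  expect_false(any(pair[, 1] == "0" & pair[, 2] != "0"))
  expect_error(simulate_founder_panel(het_rate = 1.5), "rates")

  # frac_outside: the build filter retains about the inside fraction
  p2 <- simulate_founder_panel(dir = file.path(d, "o"), n_variants = 500,
                               n_chrom = 2, frac_outside = 0.2, seed = 12L)
  dat <- read_founder_vcf(p2$vcf)
  keep <- filter_buildable_variants(dat$variants, dat$genotypes,
                                    read_exons(p2$exons), dat$founders)
  expect_equal(mean(keep), 0.8, tolerance = 0.05)
  # generator bookkeeping agrees with the filter
  expect_identical(keep, p2$truth$variants$inside)

  # uncertainty_level = 0 and residual_het_rate = 0: point masses only
  m0 <- simulate_cc_mosaics(p, dir = d, n_strains = 4, markers_per_chrom = 8,
                            residual_het_rate = 0, uncertainty_level = 0,
                            seed = 13L)
  mk <- read_marker_diplotypes(m0$csv)
  expect_true(all(mk$prob == 1))
  hp <- split_pair(mk$key)
  expect_true(all(hp[, 1] == hp[, 2]))

  # recomb_rate -> 0: single founder pair genome-wide per strain
  mR <- simulate_cc_mosaics(p, dir = d, n_strains = 4, markers_per_chrom = 8,
                            recomb_rate = 0, residual_het_rate = 0,
                            uncertainty_level = 0, seed = 14L)
  per_strain <- tapply(mR$truth$segments$hap1, mR$truth$segments$strain,
                       function(x) length(unique(x)))
  expect_true(all(per_strain == 1))
})

test_that("all emitted marker distributions are normalized", {
  w <- small_world()
  mk <- read_marker_diplotypes(w$mos$csv)
  sums <- mk[, list(s = sum(prob)), by = c("strain", "chrom", "marker")]
  expect_lt(max(abs(sums$s - 1)), 1e-6)
})

test_that("truth lookups and clean-gap classification are consistent", {
  w <- small_world()
  truth <- w$mos$truth
  seg <- truth$segments
  # truth at a marker equals the recorded marker state
  ms <- truth$marker_states
  set.seed(31)
  for (i in sample(nrow(ms), 20)) {
    td <- truth_diplotype_at(truth, ms$strain[i], ms$chrom[i], ms$pos[i])
    expect_identical(td$key, ms$key[i])
  }
  # a position in a clean gap shares its segment with both flanking markers
  v <- w$store$variants
  pos1 <- v$pos[v$chrom == "chr1"]
  cg <- clean_gap(truth, "CC001", "chr1", pos1, w$mos$markers)
  expect_type(cg, "logical")
  expect_gt(mean(cg), 0.5)  # most gaps contain no breakpoint
})

test_that("end-to-end: uncertainty-free builds recover the truth mosaic", {
  dir <- file.path(tempdir(), "e2e")
  panel <- simulate_founder_panel(dir = dir, n_variants = 120, n_chrom = 1,
                                  het_rate = 0, indel_rate = 0.1, seed = 15L)
  mos <- simulate_cc_mosaics(panel, dir = dir, n_strains = 4,
                             markers_per_chrom = 12, recomb_rate = 3,
                             residual_het_rate = 0, uncertainty_level = 0,
                             seed = 16L)
  st <- build_store(panel$vcf, mos$csv, panel$exons,
                    file.path(dir, "store"), consequence_tsv = panel$csq,
                    prune_threshold = 0)
  dat <- read_founder_vcf(panel$vcf)
  vkey <- paste(dat$variants$chrom, dat$variants$pos)
  for (s in mos$strains) {
    dip <- query_diplotype(st, s)
    gt <- ccimpute:::store_table(st, "chr1", "genotype")
    gt <- gt[gt$strain == s, ]
    v <- st$variants
    cg <- clean_gap(mos$truth, s, "chr1", v$pos, mos$markers)
    for (j in which(cg)) {
      td <- truth_diplotype_at(mos$truth, s, "chr1", v$pos[j])
      drows <- dip[dip$variant_id == v$variant_id[j], ]
      # diplotype: exact point mass on the truth state
      expect_equal(nrow(drows), 1L)
      expect_identical(canonical_unphased(drows$haplotype_1,
                                          drows$haplotype_2), td$key)
      expect_equal(drows$prob, 1)
      # genotype: the point mass implied by the founder alleles
      i <- match(paste(v$chrom[j], v$pos[j]), vkey)
      hp <- as.vector(split_pair(td$key))
      a1 <- as.vector(split_pair(names(
        dat$genotypes[[i]][[hp[1]]] %||%
          stats::setNames(1, canonical_unphased(v$ref[j], v$ref[j])))))[1]
      a2 <- as.vector(split_pair(names(
        dat$genotypes[[i]][[hp[2]]] %||%
          stats::setNames(1, canonical_unphased(v$ref[j], v$ref[j])))))[1]
      grows <- gt[gt$variant_id == v$variant_id[j], ]
      expect_equal(nrow(grows), 1L)
      expect_identical(canonical_unphased(grows$allele_1, grows$allele_2),
                       canonical_unphased(a1, a2))
      expect_equal(grows$prob, 1)
    }
    # breakpoint gaps: supported only on the two flanking marker states
    for (j in which(!cg)) {
      fl <- ccimpute:::flanking_markers(mos$markers, v$pos[j])
      allow <- unique(c(
        if (!is.na(fl$left))
          truth_diplotype_at(mos$truth, s, "chr1",
                             mos$markers[fl$left])$key,
        if (!is.na(fl$right))
          truth_diplotype_at(mos$truth, s, "chr1",
                             mos$markers[fl$right])$key))
      drows <- dip[dip$variant_id == v$variant_id[j], ]
      expect_true(all(canonical_unphased(drows$haplotype_1,
                                         drows$haplotype_2) %in% allow))
      expect_equal(sum(drows$prob), 1, tolerance = 1e-9)
    }
  }
})
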