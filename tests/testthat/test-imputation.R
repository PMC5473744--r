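test_that("interpolation follows both weight conventions", {
  l <- marker_at(c(`AJ/AJ` = 1), 1000)
  r <- marker_at(c(`B6/B6` = 1), 5000)
  same <- marker_at(c(`AJ/AJ` = 1), 5000)

  # identical endpoints: invariant under weights and mode
  for (m in c("proximal", "as_printed"))
    expect_equal(as.numeric(interpolate_diplotype(l, same, 100, 3900,
                                                  mode = m)["AJ/AJ"]), 1)
  # midpoint symmetry
  mid <- interpolate_diplotype(l, r, 2000, 2000)
  expect_equal(unclass(mid)[c("AJ/AJ", "B6/B6")], c(`AJ/AJ` = 0.5, `B6/B6` = 0.5))
  # wl = 1000, wr = 3000: proximal favours the nearer (left) marker
  prox <- interpolate_diplotype(l, r, 1000, 3000, mode = "proximal")
  expect_equal(unclass(prox)[c("AJ/AJ", "B6/B6")],
               c(`AJ/AJ` = 0.75, `B6/B6` = 0.25))
  asp <- interpolate_diplotype(l, r, 1000, 3000, mode = "as_printed")
  expect_equal(unclass(asp)[c("AJ/AJ", "B6/B6")],
               c(`AJ/AJ` = 0.25, `B6/B6` = 0.75))
  expect_identical(attr(prox, "source"), "interpolated")
  # single flanking marker: returned unchanged
  expect_identical(unclass(interpolate_diplotype(NULL, r, NA, 10)), unclass(r))
  # co-located conflicting markers must be merged upstream
  expect_error(interpolate_diplotype(l, r, 0, 0), "merged upstream")
  # monotonicity: each state lies between its endpoint probabilities
  set.seed(7)
  for (i in 1:20) {
    inst <- random_instance()
    wl <- inst$wl; wr <- inst$wr
    if (wl + wr == 0) next
    out <- interpolate_diplotype(inst$left, inst$right, wl, wr)
    for (k in names(out)) {
      lv <- unclass(inst$left)[k];  lv <- if (is.na(lv)) 0 else lv
      rv <- unclass(inst$right)[k]; rv <- if (is.na(rv)) 0 else rv
      expect_gte(out[[k]] + 1e-12, min(lv, rv))
      expect_lte(out[[k]] - 1e-12, max(lv, rv))
    }
  }
})

test_that("phasing halves heterozygous states and preserves mass", {
  expect_equal(phase_diplotype(c(`AJ/B6` = 1.0)),
               c(`AJ|B6` = 0.5, `B6|AJ` = 0.5))
  expect_equal(phase_diplotype(c(`AJ/AJ` = 1.0)), c(`AJ|AJ` = 1.0))
  expect_equal(phase_diplotype(c(`AJ/B6` = 0.4, `AJ/AJ` = 0.6)),
               c(`AJ|AJ` = 0.6, `AJ|B6` = 0.2, `B6|AJ` = 0.2))
  set.seed(8)
  for (i in 1:20) {
    inst <- random_instance()
    expect_equal(sum(phase_diplotype(inst$left)), sum(inst$left))
  }
})

test_that("transmission probabilities count allele copies", {
  fixed <- founder_genotype_dist(c(`C/C` = 1), "AJ")
  expect_equal(transmission_prob(fixed, "C"), 1.0)
  mixed <- founder_genotype_dist(c(`C/C` = 0.9, `C/T` = 0.1), "AJ")
  expect_equal(transmission_prob(mixed, "C"), 0.95)
  expect_equal(transmission_prob(mixed, "T"), 0.05)
  expect_error(transmission_prob(mixed, "G"), "allele")
})

test_that("genotype given phased diplotype multiplies independent transmissions", {
  fg <- list(AJ = c(`C/C` = 1), B6 = c(`T/T` = 1))
  expect_equal(genotype_given_phased_diplotype("AJ", "B6", fg), c(`C|T` = 1))
  # residually heterozygous founder selfed: 2x2 transmission enumeration
  fg2 <- list(AJ = c(`C/T` = 1))
  expect_equal(genotype_given_phased_diplotype("AJ", "AJ", fg2),
               c(`C|C` = 0.25, `C|T` = 0.25, `T|C` = 0.25, `T|T` = 0.25))
  fg3 <- list(AJ = c(`C/C` = 0.5, `T/T` = 0.5), B6 = c(`T/T` = 1))
  expect_equal(genotype_given_phased_diplotype("AJ", "B6", fg3),
               c(`C|T` = 0.5, `T|T` = 0.5))
  expect_error(genotype_given_phased_diplotype("AJ", "NOD", fg),
               "NOD")
})

test_that("impute_genotype composes the full chain", {
  v <- cc_variant("chr1", 3000, "C", "T", variant_id = 1L)
  fg <- list(AJ = c(`C/C` = 1))
  l <- marker_at(c(`AJ/AJ` = 1), 1000); r <- marker_at(c(`AJ/AJ` = 1), 5000)
  out <- impute_genotype(v, fg, l, r, 2000, 2000)
  expect_equal(unclass(out), c(`C/C` = 1), ignore_attr = TRUE)

  # mixed diplotype with two fixed founders: 25/25/50
  fx <- uncertain_locus_example()
  gt <- genotype_from_diplotype(fx$dip, fx$variant, fx$founder_gts,
                                strain = "CC012")
  expect_equal(unclass(gt)[c("C/C", "T/T", "C/T")],
               c(`C/C` = 0.25, `T/T` = 0.25, `C/T` = 0.5))
  expect_true(normalize_check(gt))
})

test_that("missing founder genotypes default to homozygous reference", {
  v <- cc_variant("chr1", 3000, "C", "T", variant_id = 1L)
  l <- marker_at(c(`NOD/NOD` = 1), 1000)
  r <- marker_at(c(`NOD/NOD` = 1), 5000)
  out <- impute_genotype(v, list(), l, r, 2000, 2000)
  expect_equal(unclass(out), c(`C/C` = 1), ignore_attr = TRUE)
  expect_error(impute_genotype(v, list(), l, r, 2000, 2000, strict = TRUE),
               "NOD")
})

test_that("imputed distributions match the exhaustive enumeration oracle", {
  set.seed(11)
  for (i in 1:60) {
    inst <- random_instance()
    got <- impute_genotype(inst$variant, inst$founder_gts, inst$left,
                           inst$right, inst$wl, inst$wr)
    want <- oracle_impute_genotype(inst$variant, inst$founder_gts, inst$left,
                                   inst$right, inst$wl, inst$wr)
    expect_lt(max_abs_diff(unclass(got), want), 1e-12)
    expect_true(normalize_check(got))
  }
})

test_that("imputed distributions agree with the Monte-Carlo sampler", {
  set.seed(12)
  for (i in 1:5) {
    inst <- random_instance()
    got <- impute_genotype(inst$variant, inst$founder_gts, inst$left,
                           inst$right, inst$wl, inst$wr)
    mc <- sample_impute_genotype(inst$variant, inst$founder_gts, inst$left,
                                 inst$right, inst$wl, inst$wr, n = 1e5)
    # total-variation distance well under sampling noise
    keys <- union(names(got), names(mc))
    g <- stats::setNames(rep(0, length(keys)), keys); g[names(got)] <- got
    m <- stats::setNames(rep(0, length(keys)), keys); m[names(mc)] <- mc
    expect_lt(sum(abs(g - m)) / 2, 0.01)
  }
})

test_that("impute_diplotype is interpolation with endpoint consistency", {
  l <- marker_at(c(`AJ/AJ` = 1), 1000)
  r <- marker_at(c(`AJ/B6` = 1), 5000)
  # at the left marker position (wl = 0): the marker's own distribution
  at_marker <- impute_diplotype(l, r, 0, 4000)
  expect_equal(unclass(at_marker), c(`AJ/AJ` = 1), ignore_attr = TRUE)
  mid <- impute_diplotype(l, r, 2000, 2000)
  expect_equal(unclass(mid)[c("AJ/AJ", "AJ/B6")],
               c(`AJ/AJ` = 0.5, `AJ/B6` = 0.5))
  near <- impute_diplotype(marker_at(c(`AJ/AJ` = 1), 0),
                           marker_at(c(`B6/B6` = 1), 10), 1, 9)
  expect_equal(unclass(near)[c("AJ/AJ", "B6/B6")],
               c(`AJ/AJ` = 0.9, `B6/B6` = 0.1))
})
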