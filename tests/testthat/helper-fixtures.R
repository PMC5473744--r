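# Shared fixtures, built once per test run. All synthetic, generated in
# code; nothing is read from outside the temporary directory.

fixture_env <- new.env(parent = emptyenv())

# small panel + mosaics + built store reused by io/query/cli tests
small_world <- function() {
  if (!is.null(fixture_env$world)) return(fixture_env$world)
  dir <- file.path(tempdir(), "ccimpute-small")
  panel <- simulate_founder_panel(dir = dir, n_variants = 80L, n_chrom = 2L,
                                  het_rate = 0.03, indel_rate = 0.15,
                                  frac_outside = 0.2, seed = 42L)
  mos <- simulate_cc_mosaics(panel, dir = dir, n_strains = 5L,
                             markers_per_chrom = 15L, recomb_rate = 4,
                             residual_het_rate = 0.1,
                             uncertainty_level = 0.1, seed = 43L)
  store <- build_store(panel$vcf, mos$csv, panel$exons,
                       out_dir = file.path(dir, "store"),
                       consequence_tsv = panel$csq)
  fixture_env$world <- list(dir = dir, panel = panel, mos = mos, store = store)
  fixture_env$world
}

# deterministic hand-built marker distributions
marker_at <- function(probs, pos, strain = "CC900", chrom = "chr1") {
  diplotype_dist(probs, strain = strain, chrom = chrom, pos = pos,
                 source = "marker")
}

# the example used throughout: 25% C/C, 25% T/T, 50% C/T at one variant
uncertain_locus_example <- function() {
  variant <- cc_variant("chr19", 6054740L, "C", "T", variant_id = 7L)
  founder_gts <- list(AJ = stats::setNames(1, "C/C"),
                      B6 = stats::setNames(1, "C/C"),
                      CAST = stats::setNames(1, "T/T"))
  dip <- diplotype_dist(c(`AJ/AJ` = 0.25, `CAST/CAST` = 0.25,
                          `AJ/CAST` = 0.5),
                        strain = "CC012", chrom = "chr19", pos = 6054740,
                        source = "interpolated")
  ann <- data.frame(allele = "T", gene_id = "G1", transcript_id = "G1_T1",
                    term = "missense_variant", stringsAsFactors = FALSE)
  list(variant = variant, founder_gts = founder_gts, dip = dip, ann = ann)
}
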