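# Independent oracles for the imputation chain. Both deliberately avoid the
# package's matrix formulation: the exhaustive oracle enumerates every
# (marker choice, diplotype state, phasing, founder genotype pair,
# transmitted copy) combination with nested loops; the sampler draws the
# same chain stochastically.

`%||%` <- function(a, b) if (is.null(a)) b else a

hom_ref_dist <- function(variant) {
  stats::setNames(1, canonical_unphased(variant$ref_allele, variant$ref_allele))
}

oracle_impute_genotype <- function(variant, founder_gts, left, right, wl, wr,
                                   mode = "proximal") {
  mix <- if (is.null(left)) list(list(d = right, w = 1))
  else if (is.null(right)) list(list(d = left, w = 1))
  else {
    wL <- if (mode == "proximal") wr / (wl + wr) else wl / (wl + wr)
    list(list(d = left, w = wL), list(d = right, w = 1 - wL))
  }
  res <- numeric(0)
  add <- function(key, p) {
    cur <- res[key]
    if (is.na(cur)) cur <- 0
    res[key] <<- cur + p
  }
  for (m in mix) {
    if (m$w == 0) next
    for (sk in names(m$d)) {
      hp <- as.vector(split_pair(sk))
      phasings <- if (hp[1] == hp[2]) list(list(h = hp, w = 1))
      else list(list(h = hp, w = 0.5), list(h = rev(hp), w = 0.5))
      for (ph in phasings) {
        g1 <- founder_gts[[ph$h[1]]] %||% hom_ref_dist(variant)
        g2 <- founder_gts[[ph$h[2]]] %||% hom_ref_dist(variant)
        for (k1 in names(g1)) for (k2 in names(g2)) {
          a1 <- as.vector(split_pair(k1)); a2 <- as.vector(split_pair(k2))
          for (c1 in 1:2) for (c2 in 1:2) {
            add(canonical_unphased(a1[c1], a2[c2]),
                m$w * as.numeric(m$d[sk]) * ph$w *
                  as.numeric(g1[k1]) * as.numeric(g2[k2]) / 4)
          }
        }
      }
    }
  }
  res[res > 0][order(names(res[res > 0]), method = "radix")]
}

sample_impute_genotype <- function(variant, founder_gts, left, right, wl, wr,
                                   n = 1e5, mode = "proximal") {
  wL <- if (is.null(left)) 0 else if (is.null(right)) 1
  else if (mode == "proximal") wr / (wl + wr) else wl / (wl + wr)
  use_left <- stats::runif(n) < wL
  key <- character(n)
  for (side in c(TRUE, FALSE)) {
    idx <- which(use_left == side)
    if (!length(idx)) next
    d <- if (side) left else right
    key[idx] <- sample(names(d), length(idx), replace = TRUE,
                       prob = as.numeric(d))
  }
  hp <- split_pair(key)
  swap <- stats::runif(n) < 0.5
  h1 <- ifelse(swap, hp[, 2], hp[, 1])
  h2 <- ifelse(swap, hp[, 1], hp[, 2])
  draw_allele <- function(hvec) {
    out <- character(n)
    for (f in unique(hvec)) {
      idx <- which(hvec == f)
      g <- founder_gts[[f]]
      if (is.null(g)) g <- hom_ref_dist(variant)
      gk <- sample(names(g), length(idx), replace = TRUE, prob = as.numeric(g))
      pr <- split_pair(gk)
      out[idx] <- ifelse(stats::runif(length(idx)) < 0.5, pr[, 1], pr[, 2])
    }
    out
  }
  tab <- table(canonical_unphased(draw_allele(h1), draw_allele(h2)))
  stats::setNames(as.numeric(tab) / n, names(tab))
}

# gamete-sampling oracle for F1 genotype
sample_f1_genotype <- function(gt1, gt2, n = 1e5) {
  draw <- function(gt) {
    gk <- sample(names(gt), n, replace = TRUE, prob = as.numeric(gt))
    pr <- split_pair(gk)
    ifelse(stats::runif(n) < 0.5, pr[, 1], pr[, 2])
  }
  tab <- table(canonical_unphased(draw(gt1), draw(gt2)))
  stats::setNames(as.numeric(tab) / n, names(tab))
}

# random small imputation instance (<= 8 founders, <= 4 alleles)
random_instance <- function(n_founders = sample(2:8, 1),
                            n_alleles = sample(2:4, 1),
                            het_chance = 0.3, missing_chance = 0.15) {
  founders <- cc_founders()[seq_len(n_founders)]
  alleles <- c("A", "C", "G", "T")[seq_len(n_alleles)]
  variant <- cc_variant("chr1", sample(1000:9999, 1), alleles[1],
                        alleles[-1], variant_id = 1L)
  founder_gts <- list()
  for (f in founders) {
    if (stats::runif(1) < missing_chance) next
    a1 <- sample(alleles, 1)
    a2 <- if (stats::runif(1) < het_chance) sample(alleles, 1) else a1
    k1 <- canonical_unphased(a1, a2)
    if (stats::runif(1) < 0.4) {            # two-state uncertain call
      b <- sample(alleles, 2, replace = TRUE)
      k2 <- canonical_unphased(b[1], b[2])
      p <- stats::runif(1, 0.1, 0.9)
      d <- stats::setNames(c(p, 1 - p), c(k1, k2))
      d <- tapply(d, names(d), sum)
      founder_gts[[f]] <- stats::setNames(as.numeric(d), names(d))
    } else founder_gts[[f]] <- stats::setNames(1, k1)
  }
  rand_marker <- function(pos) {
    states <- diplotype_states(founders)
    k <- sample(seq_len(min(4L, length(states))), 1)
    sk <- sample(states, k)
    p <- stats::runif(k); p <- p / sum(p)
    diplotype_dist(stats::setNames(p, sk), strain = "CCX", chrom = "chr1",
                   pos = pos, source = "marker")
  }
  wl <- sample(0:5000, 1); wr <- sample(1:5000, 1)
  list(variant = variant, founder_gts = founder_gts,
       left = rand_marker(variant$pos - wl), right = rand_marker(variant$pos + wr),
       wl = wl, wr = wr)
}

max_abs_diff <- function(a, b) {
  keys <- union(names(a), names(b))
  av <- stats::setNames(rep(0, length(keys)), keys); av[names(a)] <- a
  bv <- stats::setNames(rep(0, length(keys)), keys); bv[names(b)] <- b
  max(abs(av - bv))
}
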