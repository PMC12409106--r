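test_that("Weir-Cockerham theta handles fixation and panmixia", {
  df <- data.frame(
    sample_id = paste0("i", 1:20), species = "s",
    population = rep(c("p1", "p2"), each = 10),
    L1.1 = rep(c(1, 2), each = 10), L1.2 = rep(c(1, 2), each = 10),
    L2.1 = rep(c(3, 4), each = 10), L2.2 = rep(c(3, 4), each = 10),
    check.names = FALSE)
  expect_equal(wc_theta(genotype_table(df)), 1)

  # two labels drawn from one panmictic pool: theta centred on 0
  th <- vapply(seq_len(50), function(i) {
    set.seed(i)
    a <- matrix(sample(1:4, 4 * 60, replace = TRUE), 60)
    d <- data.frame(sample_id = paste0("i", 1:60), species = "s",
                    population = rep(c("p1", "p2"), each = 30),
                    L1.1 = a[, 1], L1.2 = a[, 2], L2.1 = a[, 3],
                    L2.2 = a[, 4], check.names = FALSE)
    wc_theta(genotype_table(d))
  }, numeric(1))
  expect_lt(abs(mean(th)), 0.01)
})

test_that("theta matches hand-computed variance components on a toy table", {
  g <- toy_genotypes()
  # oracle: Weir & Cockerham (1984) a, b, c computed from first principles
  wc_oracle <- function(counts1, counts2) {
    # counts per population: list of 2-col allele matrices (one row per ind)
    r <- 2; ni <- c(nrow(counts1), nrow(counts2))
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    alleles <- sort(unique(c(counts1, counts2)))
    tot <- c(a = 0, b = 0, c = 0)
    for (u in alleles) {
      cnt <- list(rowSums(counts1 == u), rowSums(counts2 == u))
      p_i <- vapply(cnt, function(v) mean(v) / 2, numeric(1))
      h_i <- vapply(cnt, function(v) mean(v == 1), numeric(1))
      pbar <- sum(ni * p_i) / (r * nbar)
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h_i) / (r * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                    (2 * nbar - 1) / (4 * nbar) * hbar)
      tot <- tot + c(a = a, b = b, c = hbar / 2)
    }
    tot
  }
  l1p1 <- cbind(c(1, 1), c(1, 2)); l1p2 <- cbind(c(2, 2), c(2, 2))
  l2p1 <- cbind(c(1, 1), c(1, 1)); l2p2 <- cbind(c(1, 2), c(2, 2))
  o <- wc_oracle(l1p1, l1p2) + wc_oracle(l2p1, l2p2)
  expect_equal(wc_theta(g), o[["a"]] / sum(o), tolerance = 1e-12)
})

test_that("theta is invariant to allele relabeling and locus order", {
  cfg <- sim_config(n_species = 3, inds_per_pop = 12, n_loci = 5,
                    fst_target = 0.2, seed = 7)
  g <- gen_genotypes(cfg)
  base <- wc_theta(g)
  relab <- g
  for (l in g$loci) {
    for (cc in paste0(l, c(".1", ".2"))) {
      relab$data[[cc]] <- 9 - relab$data[[cc]]    # bijective relabeling
    }
  }
  expect_equal(wc_theta(relab), base, tolerance = 1e-12)
  shuf <- g
  perm <- c("sample_id", "species", "population",
            unlist(lapply(rev(g$loci), paste0, c(".1", ".2"))))
  shuf <- genotype_table(g$data[perm])
  expect_equal(wc_theta(shuf), base, tolerance = 1e-12)
})

test_that("pairwise F_ST bootstrap CIs behave", {
  cfg <- sim_config(n_species = 3, inds_per_pop = 15, n_loci = 8,
                    fst_target = 0.15, seed = 3)
  g <- gen_genotypes(cfg)
  res <- pairwise_fst(g, level = "population", n_boot = 200, seed = 1)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$ci_low <= res$theta + 1e-9))
  expect_true(all(res$ci_high >= res$theta - 1e-9))
  expect_identical(res, pairwise_fst(g, level = "population",
                                     n_boot = 200, seed = 1))

  # loci carrying identical information give a zero-width CI
  d <- data.frame(sample_id = paste0("i", 1:8), species = "s",
                  population = rep(c("p1", "p2"), each = 4),
                  L1.1 = rep(c(1, 2), each = 4), L1.2 = rep(c(1, 2), each = 4),
                  L2.1 = rep(c(1, 2), each = 4), L2.2 = rep(c(1, 2), each = 4),
                  check.names = FALSE)
  ci <- fst_bootstrap_ci(genotype_table(d), c("p1", "p2"),
                         level = "population", n_boot = 100, seed = 1)
  expect_equal(unname(ci[1]), unname(ci[2]))
  one <- genotype_table(d[c("sample_id", "species", "population",
                            "L1.1", "L1.2")])
  expect_error(fst_bootstrap_ci(one, c("p1", "p2"), level = "population"),
               "single locus")
})

test_that("AMOVA percentages close to 100 and detect fixed structure", {
  cfg <- sim_config(n_species = 2, pops_per_species = 2, inds_per_pop = 10,
                    n_loci = 6, fst_target = 0.1, seed = 5)
  g <- gen_genotypes(cfg)
  a <- amova(g, n_perm = 0)
  expect_equal(sum(a$percent), 100, tolerance = 0.1)

  # species fixed for private alleles at every locus
  d <- data.frame(sample_id = paste0("i", 1:24),
                  species = rep(c("s1", "s2"), each = 12),
                  population = rep(c("a", "b", "c", "d"), each = 6),
                  L1.1 = rep(c(1, 2), each = 12), L1.2 = rep(c(1, 2), each = 12),
                  L2.1 = rep(c(5, 6), each = 12), L2.2 = rep(c(5, 6), each = 12),
                  check.names = FALSE)
  af <- amova(genotype_table(d), n_perm = 0)
  expect_equal(af$percent[af$level == "among_species"], 100, tolerance = 1e-9)

  # permutation p-values at strong structure are small
  ap <- amova(g, n_perm = 49, seed = 1)
  expect_true(all(is.na(ap$p_value) | ap$p_value <= 1))
})

test_that("AMOVA component ratios survive duplicating every individual", {
  cfg <- sim_config(n_species = 2, pops_per_species = 2, inds_per_pop = 8,
                    n_loci = 4, fst_target = 0.2, seed = 11)
  g <- gen_genotypes(cfg)
  a1 <- amova(g, n_perm = 0)
  dup <- g$data[rep(seq_len(nrow(g$data)), 2), ]
  dup$sample_id <- paste0(dup$sample_id, "_", rep(1:2, each = nrow(g$data)))
  a2 <- amova(genotype_table(dup), n_perm = 0)
  # duplication leaves the allele-frequency structure untouched; the
  # df-corrected mean squares shift only at O(1/n), so the percentage
  # decomposition must agree closely (exact invariance would require
  # uncorrected mean squares)
  expect_equal(a2$percent, a1$percent, tolerance = 0.08)
  expect_equal(sum(a2$percent), 100, tolerance = 0.1)
})

test_that("Evanno delta-K finds the elbow", {
  ev <- evanno_delta_k(list(`1` = c(-100, -100.2), `2` = c(-82, -78),
                            `3` = c(-75, -75.4)))
  mu2 <- mean(c(-82, -78)); sd2 <- stats::sd(c(-82, -78))
  expect_equal(ev$delta_k$delta_k[1],
               abs(mean(c(-75, -75.4)) - 2 * mu2 + (-100.1)) / sd2)
  expect_equal(ev$best_k, 2)

  # perfectly linear mean likelihood: delta-K identically zero
  lin <- evanno_delta_k(list(`1` = c(-99, -101), `2` = c(-91, -89),
                             `3` = c(-80.5, -79.5), `4` = c(-70, -70)))
  expect_warning(ev0 <- evanno_delta_k(list(`1` = c(-10, -10), `2` = c(-9, -9),
                                            `3` = c(-8, -8))), "zero")
  expect_equal(lin$delta_k$delta_k, c(0, 0), tolerance = 1e-9)
  expect_error(evanno_delta_k(list(`1` = c(-1, -2), `2` = c(-1, -2))),
               "consecutive")
})

test_that("membership assignment applies its thresholds", {
  q <- rbind(c(0.7, 0.3), c(0.5, 0.5), c(0.65, 0.35))
  m6 <- assign_membership(q, threshold = 0.6)
  expect_equal(m6$cluster, c(1L, NA, 1L))
  expect_equal(m6$admixed, c(FALSE, TRUE, FALSE))
  m7 <- assign_membership(q, threshold = 0.7)
  expect_equal(m7$cluster, c(1L, NA, NA))
  expect_error(assign_membership(rbind(c(0.5, 0.4))), "sum to 1")
})

test_that("genotype tables round-trip through delimited and STRUCTURE formats", {
  g <- toy_genotypes()
  p <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(g$data, p, sep = "\t", quote = FALSE, row.names = FALSE)
  g2 <- read_genotypes(p)
  expect_equal(g2$data$L1.1, g$data$L1.1)

  # STRUCTURE layout: two rows per individual
  ps <- withr::local_tempfile(fileext = ".str")
  lines <- c("i1 p1 1 1", "i1 p1 1 1",
             "i2 p1 1 2", "i2 p1 2 1",
             "i3 p2 2 -9", "i3 p2 2 -9")
  writeLines(lines, ps)
  gs <- read_structure(ps)
  expect_equal(nrow(gs$data), 3L)
  expect_equal(gs$data$L1.1, c(1, 1, 2))
  expect_true(is.na(gs$data$L2.1[3]))
})
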