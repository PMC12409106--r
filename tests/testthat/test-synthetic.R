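test_that("Yule phylogenies have the right shape and are deterministic", {
  tr <- gen_phylogeny(3, seed = 5)
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(tr$Nnode, 2L)
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-10)

  t17 <- gen_phylogeny(17, seed = 2)
  expect_equal(length(t17$tip.label), 17L)
  expect_equal(t17$Nnode, 16L)
  expect_true(ape::is.ultrametric(t17))
  expect_true(all(t17$edge.length > 0))

  a <- ape::write.tree(gen_phylogeny(10, seed = 42))
  b <- ape::write.tree(gen_phylogeny(10, seed = 42))
  expect_identical(a, b)
  expect_error(gen_phylogeny(2), "n_tips")
})

test_that("BM trait simulation matches its Gaussian process", {
  tr <- gen_phylogeny(6, seed = 1)
  expect_equal(unname(gen_bm_traits(tr, sigma2 = 0, root_value = 3, seed = 1)),
               rep(3, 6))

  # star tree: tips iid Normal(root, sigma2 * depth)
  st <- star_tree(5, depth = 2)
  sims <- vapply(seq_len(1000), function(i)
    gen_bm_traits(st, sigma2 = 1.5, root_value = 0, seed = i), numeric(5))
  expect_equal(stats::var(as.numeric(sims)), 1.5 * 2, tolerance = 0.05 * 3)
  expect_equal(mean(sims), 0, tolerance = 0.1)

  # balanced 4-tip tree: sister tips share one unit branch of covariance
  b4 <- balanced4()
  sims <- vapply(seq_len(2000), function(i)
    gen_bm_traits(b4, sigma2 = 1, root_value = 0, seed = 10000 + i),
    numeric(4))
  cc <- stats::cov(t(sims))
  expect_equal(cc["t1", "t2"], 1, tolerance = 0.12)   # shared path length 1
  expect_equal(cc["t1", "t3"], 0, tolerance = 0.12)   # no shared branch
  expect_equal(cc["t1", "t1"], 2, tolerance = 0.2)    # root-to-tip depth 2
  expect_error(gen_bm_traits(tr, sigma2 = -1), "sigma2")
})

test_that("genotype generator hits its differentiation target", {
  # panmixia: theta centred on zero
  th0 <- vapply(seq_len(50), function(i)
    wc_theta(gen_genotypes(sim_config(n_species = 4, inds_per_pop = 15,
                                      n_loci = 10, fst_target = 0,
                                      seed = 100 + i))), numeric(1))
  expect_lt(abs(mean(th0)), 0.01)

  th <- vapply(seq_len(50), function(i)
    wc_theta(gen_genotypes(sim_config(n_species = 4, inds_per_pop = 30,
                                      n_loci = 20, fst_target = 0.15,
                                      seed = 200 + i))), numeric(1))
  expect_gte(mean(th), 0.12)
  expect_lte(mean(th), 0.18)

  # single population still yields a valid table
  g1 <- gen_genotypes(sim_config(n_species = 1, inds_per_pop = 5,
                                 n_loci = 3, seed = 1))
  expect_s3_class(g1, "genotype_table")
  expect_equal(nrow(g1$data), 5L)
  alleles <- unlist(g1$data[grep("^L", names(g1$data))])
  expect_true(all(alleles >= 1 & alleles <= 8))
  expect_error(gen_genotypes(sim_config(alleles_per_locus = 1)),
               "alleles_per_locus")
})

test_that("spectra generator is baseline-plus-features with monotone depth", {
  lib <- data.frame(trait = "x", center = 1450, width = 50, loading = 0.1)
  cfg0 <- sim_config(trait_archetypes = list(x = list(mean = 0, sd = 1)),
                     band_library = lib, noise_sd = 0, seed = 1)
  tdf <- data.frame(sample_id = c("a", "b", "c"), x = c(0, 0, 0))
  s0 <- gen_spectra(tdf, cfg0)
  expect_equal(s0$reflectance[1, ], s0$reflectance[2, ])
  expect_equal(s0$reflectance[2, ], s0$reflectance[3, ])

  tdf2 <- data.frame(sample_id = c("a", "b", "c"), x = c(0.5, 1, 2))
  s2 <- gen_spectra(tdf2, cfg0)
  at <- which.min(abs(s2$wavelengths - 1450))
  expect_true(all(diff(s2$reflectance[, at]) < 0))
  expect_true(all(s2$reflectance > 0 & s2$reflectance < 1))
  expect_lte(max(diff(s2$wavelengths)), 3)
  expect_error(gen_spectra(data.frame(sample_id = "a", y = 1), cfg0),
               "band_library")
})

test_that("environment generator honours its IBE/IBD composition", {
  cfg <- sim_config(n_species = 4, inds_per_pop = 20, ibe_fraction = 1,
                    ibd_fraction = 0, seed = 3)
  eg <- gen_env_geo(cfg, rep(paste0("p", 1:4), each = 20))
  within_sd <- tapply(eg$env$env1, rep(paste0("p", 1:4), each = 20), stats::sd)
  expect_true(all(within_sd < 1e-12))

  cfg2 <- sim_config(ibe_fraction = 0, ibd_fraction = 1, seed = 4)
  eg2 <- gen_env_geo(cfg2, rep(paste0("p", 1:6), each = 20))
  expect_gt(stats::cor(eg2$env$env1, eg2$geo$lat), 0.99)
  expect_error(gen_env_geo(cfg2, character(0)), "non-empty")
})

test_that("a full synthetic dataset is seed-deterministic with ground truth", {
  cfg <- sim_config(n_species = 3, inds_per_pop = 6, n_loci = 4, seed = 9)
  d1 <- gen_dataset(cfg)
  d2 <- gen_dataset(cfg)
  expect_identical(d1$genotypes$data, d2$genotypes$data)
  expect_identical(d1$spectra$reflectance, d2$spectra$reflectance)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_identical(d1$env$env1, d2$env$env1)
  expect_named(d1$truth, c("group_means", "fst_target", "ibe_share",
                           "ibd_share", "bm_sigma2"))
  # changing the seed changes the draws
  d3 <- gen_dataset(sim_config(n_species = 3, inds_per_pop = 6, n_loci = 4,
                               seed = 10))
  expect_false(identical(d1$genotypes$data, d3$genotypes$data))
})
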