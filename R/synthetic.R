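#' Simulation configuration with known ground truth
#'
#' Bundles every knob of the synthetic-data generators: group structure,
#' microsatellite simulation targets, spectral feature library, and the
#' isolation-by-environment / isolation-by-distance variance shares. A single
#' `seed` fully determines all generator outputs; each generator draws from
#' its own substream (see [seed_streams()]) so that generators can be added
#' without perturbing existing streams.
#'
#' @param n_species Number of species (groups at the top level).
#' @param pops_per_species Populations nested within each species.
#' @param inds_per_pop Diploid individuals per population.
#' @param n_loci Number of microsatellite-like loci.
#' @param alleles_per_locus Alleles segregating per locus (>= 2).
#' @param fst_target Expected Weir-Cockerham differentiation among
#'   populations, in `[0, 1)`.
#' @param trait_archetypes Named list, one entry per trait:
#'   `list(mean = <per-group means>, sd = <within-group sd>)`. Group means are
#'   recycled across the `n_species * pops_per_species` populations.
#' @param band_library Data frame with columns `trait`, `center`, `width`,
#'   `loading` describing Gaussian absorption features (centers in 400-2500 nm).
#' @param noise_sd Reflectance noise SD.
#' @param ibe_fraction,ibd_fraction Target variance shares of the group
#'   (environmental) effect and of the smooth spatial gradient in the
#'   generated environmental variable; their sum must be <= 1.
#' @param bm_sigma2 Brownian-motion rate for trait evolution on the phylogeny.
#' @param seed Master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 4, pops_per_species = 1, inds_per_pop = 30,
                       n_loci = 20, alleles_per_locus = 8, fst_target = 0.15,
                       trait_archetypes = NULL,
                       band_library = default_band_library(),
                       noise_sd = 0.003,
                       ibe_fraction = 0.4, ibd_fraction = 0.1,
                       bm_sigma2 = 1, seed = 1) {
  .assert(fst_target >= 0 && fst_target < 1, "fst_target must be in [0, 1)")
  .assert(alleles_per_locus >= 2, "alleles_per_locus must be >= 2")
  .assert(ibe_fraction >= 0 && ibd_fraction >= 0 &&
            ibe_fraction + ibd_fraction <= 1,
          "ibe_fraction and ibd_fraction must be fractions summing to <= 1")
  if (!is.null(band_library)) {
    .assert(all(band_library$center >= 400 & band_library$center <= 2500),
            "band centers must lie within 400-2500 nm")
  }
  if (is.null(trait_archetypes)) {
    k <- n_species * pops_per_species
    trait_archetypes <- list(
      LMA = list(mean = seq(0.8, 1.6, length.out = k), sd = 0.08),
      lignin = list(mean = seq(10, 20, length.out = k), sd = 1.2)
    )
  }
  structure(list(n_species = n_species, pops_per_species = pops_per_species,
                 inds_per_pop = inds_per_pop, n_loci = n_loci,
                 alleles_per_locus = alleles_per_locus,
                 fst_target = fst_target,
                 trait_archetypes = trait_archetypes,
                 band_library = band_library, noise_sd = noise_sd,
                 ibe_fraction = ibe_fraction, ibd_fraction = ibd_fraction,
                 bm_sigma2 = bm_sigma2, seed = seed),
            class = "sim_config")
}

#' Default Gaussian absorption-feature library
#'
#' Two features per default trait, placed at wavelengths where structural and
#' chemical leaf constituents absorb: a visible/red-edge feature and a SWIR
#' feature.
#' @return Data frame with columns trait, center, width, loading.
#' @export
default_band_library <- function() {
  data.frame(
    trait = c("LMA", "LMA", "lignin", "lignin"),
    center = c(670, 1450, 550, 2100),
    width = c(30, 60, 25, 50),
    loading = c(0.15, 0.10, 0.01, 0.012)
  )
}

#' Simulate a Yule phylogeny
#'
#' Generates a rooted, ultrametric pure-birth tree with unit speciation rate,
#' positive branch lengths and unique tip labels `t1..tn`.
#'
#' @param n_tips Number of tips (>= 3).
#' @param seed Integer seed; the same seed yields a byte-identical tree.
#' @return An `ape::phylo` tree.
#' @export
gen_phylogeny <- function(n_tips, seed = 1) {
  .assert(is.numeric(n_tips) && n_tips >= 3, "n_tips must be >= 3")
  set.seed(seed)
  tree <- ape::rphylo(n = n_tips, birth = 1, death = 0)
  tree$tip.label <- paste0("t", seq_len(n_tips))
  tree
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Traits evolve by accumulating independent Gaussian increments along each
#' branch, variance `sigma2 * branch length`, starting from `root_value`.
#' Tip values are therefore jointly Gaussian with covariance
#' `sigma2 *` shared-branch-length matrix.
#'
#' @param tree A rooted `phylo` tree with positive branch lengths.
#' @param sigma2 BM rate (trait^2 per unit branch length); `sigma2 = 0` is
#'   allowed and returns the root value at every tip.
#' @param root_value Trait value at the root.
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
gen_bm_traits <- function(tree, sigma2 = 1, root_value = 0, seed = 1) {
  .assert(inherits(tree, "phylo"), "tree must be a phylo object")
  .assert(is.numeric(sigma2) && sigma2 >= 0, "sigma2 must be non-negative")
  .assert(all(tree$edge.length > 0), "tree must have positive branch lengths")
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  vals <- numeric(n_tip + n_node)
  root <- n_tip + 1L
  vals[root] <- root_value
  # preorder traversal so each parent's value exists before its children
  ord <- ape::reorder.phylo(tree, "postorder")
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  lens <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  incr <- stats::rnorm(nrow(edges), 0, sqrt(sigma2 * lens))
  for (i in seq_len(nrow(edges))) {
    vals[edges[i, 2L]] <- vals[edges[i, 1L]] + incr[i]
  }
  out <- vals[seq_len(n_tip)]
  names(out) <- tree$tip.label
  out
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Simulate diploid microsatellite genotypes (Balding-Nichols model)
#'
#' Per locus, ancestral allele frequencies are drawn from a symmetric
#' Dirichlet(1); each population's frequencies are then drawn from
#' `Dirichlet(p_anc * (1 - F) / F)` with `F = fst_target`, which makes the
#' expected Weir-Cockerham differentiation among populations approximately
#' `fst_target`. Diploid genotypes are independent draws from the population
#' frequencies. `fst_target = 0` collapses all populations onto the ancestral
#' frequencies.
#'
#' @param cfg A [sim_config()].
#' @return A `genotype_table` (see [genotype_table()]) with species and
#'   population labels `sp1..`, `sp<i>_p<j>`.
#' @export
gen_genotypes <- function(cfg) {
  .assert(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  seed <- seed_streams(cfg$seed, .sim_streams)[["genotypes"]]
  set.seed(seed)
  n_pop <- cfg$n_species * cfg$pops_per_species
  n_per <- cfg$inds_per_pop
  n_tot <- n_pop * n_per
  species <- rep(paste0("sp", rep(seq_len(cfg$n_species),
                                  each = cfg$pops_per_species)), each = n_per)
  pops <- rep(paste0("sp", rep(seq_len(cfg$n_species), each = cfg$pops_per_species),
                     "_p", rep(seq_len(cfg$pops_per_species), cfg$n_species)),
              each = n_per)
  geno <- matrix(NA_integer_, n_tot, 2L * cfg$n_loci)
  for (l in seq_len(cfg$n_loci)) {
    p_anc <- .rdirichlet(rep(1, cfg$alleles_per_locus))
    for (k in seq_len(n_pop)) {
      p_pop <- if (cfg$fst_target == 0) p_anc else {
        .rdirichlet(p_anc * (1 - cfg$fst_target) / cfg$fst_target)
      }
      rows <- ((k - 1L) * n_per + 1L):(k * n_per)
      draws <- sample.int(cfg$alleles_per_locus, 2L * n_per,
                          replace = TRUE, prob = p_pop)
      geno[rows, 2L * l - 1L] <- draws[seq_len(n_per)]
      geno[rows, 2L * l] <- draws[n_per + seq_len(n_per)]
    }
  }
  colnames(geno) <- paste0("L", rep(seq_len(cfg$n_loci), each = 2L),
                           ".", rep(1:2, cfg$n_loci))
  genotype_table(data.frame(sample_id = paste0("ind", seq_len(n_tot)),
                            species = species, population = pops,
                            geno, check.names = FALSE))
}

.sim_streams <- c("phylogeny", "bm_traits", "genotypes", "traits",
                  "spectra", "env_geo")

#' Simulate per-sample trait values from population archetypes
#'
#' Each population has an archetype mean per trait (recycled from
#' `cfg$trait_archetypes`); individual values are Gaussian around it with the
#' archetype's within-group SD.
#'
#' @param cfg A [sim_config()].
#' @return List with `traits` (data.frame, sample_id/species/population +
#'   one column per trait) and `group_means` (population x trait matrix, the
#'   ground truth).
#' @export
gen_traits <- function(cfg) {
  .assert(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  seed <- seed_streams(cfg$seed, .sim_streams)[["traits"]]
  set.seed(seed)
  n_pop <- cfg$n_species * cfg$pops_per_species
  n_per <- cfg$inds_per_pop
  species <- rep(paste0("sp", rep(seq_len(cfg$n_species),
                                  each = cfg$pops_per_species)), each = n_per)
  pops <- rep(paste0("sp", rep(seq_len(cfg$n_species), each = cfg$pops_per_species),
                     "_p", rep(seq_len(cfg$pops_per_species), cfg$n_species)),
              each = n_per)
  df <- data.frame(sample_id = paste0("ind", seq_len(n_pop * n_per)),
                   species = species, population = pops)
  gm <- matrix(NA_real_, n_pop, length(cfg$trait_archetypes),
               dimnames = list(unique(pops), names(cfg$trait_archetypes)))
  for (tr in names(cfg$trait_archetypes)) {
    a <- cfg$trait_archetypes[[tr]]
    mu <- rep_len(a$mean, n_pop)
    gm[, tr] <- mu
    df[[tr]] <- rep(mu, each = n_per) +
      stats::rnorm(n_pop * n_per, 0, a$sd)
  }
  list(traits = df, group_means = gm)
}

#' Simulate reflectance spectra from trait values
#'
#' Reflectance is a smooth sigmoidal baseline minus one Gaussian absorption
#' feature per entry of `cfg$band_library`, with depth `loading * trait`,
#' plus Gaussian noise, clipped to (0.001, 0.999). The grid covers
#' 400-2500 nm at 3 nm. Because features are strictly subtractive, the
#' reflectance at a feature center is strictly decreasing in the generating
#' trait value.
#'
#' @param traits Data frame with a `sample_id` column and one column per
#'   trait named in `cfg$band_library`.
#' @param cfg A [sim_config()].
#' @return A `spectra_set` in `resampled` state (already on the 3 nm grid).
#' @export
gen_spectra <- function(traits, cfg) {
  .assert(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  lib <- cfg$band_library
  .assert(all(lib$trait %in% names(traits)),
          "every trait in cfg$band_library must be a column of traits")
  seed <- seed_streams(cfg$seed, .sim_streams)[["spectra"]]
  set.seed(seed)
  wl <- seq(400, 2500, by = 3)
  n <- nrow(traits)
  # smooth baseline: low in the VIS, high plateau in the NIR, gentle SWIR decay
  base <- 0.25 + 0.35 / (1 + exp(-(wl - 720) / 40)) - 0.00008 * pmax(wl - 1300, 0)
  refl <- matrix(rep(base, each = n), n, length(wl))
  for (f in seq_len(nrow(lib))) {
    shape <- exp(-((wl - lib$center[f])^2) / (2 * lib$width[f]^2))
    depth <- lib$loading[f] * traits[[lib$trait[f]]]
    refl <- refl - outer(depth, shape)
  }
  if (cfg$noise_sd > 0) {
    refl <- refl + matrix(stats::rnorm(n * length(wl), 0, cfg$noise_sd),
                          n, length(wl))
  }
  refl[refl < 0.001] <- 0.001
  refl[refl > 0.999] <- 0.999
  spectra_set(refl, wl, as.character(traits$sample_id), state = "resampled")
}

#' Simulate clustered coordinates and an environmental variable
#'
#' Populations get cluster centres on a latitudinal gradient; individuals
#' scatter around their centre. The environmental variable is a weighted sum
#' of a group (population) effect, a smooth spatial gradient (latitude), and
#' noise, with weights chosen so that the population effect contributes
#' `ibe_fraction` and the spatial gradient `ibd_fraction` of the total
#' variance in expectation. The realised ground-truth shares are recorded.
#'
#' @param cfg A [sim_config()].
#' @param groups Character vector of population labels, one per individual.
#' @return List with `env` (data.frame sample_id, env1), `geo` (data.frame
#'   sample_id, lon, lat) and `truth` (list ibe_share, ibd_share).
#' @export
gen_env_geo <- function(cfg, groups) {
  .assert(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  .assert(length(groups) >= 1, "groups must be non-empty")
  seed <- seed_streams(cfg$seed, .sim_streams)[["env_geo"]]
  set.seed(seed)
  n <- length(groups)
  gl <- unique(groups)
  k <- length(gl)
  # cluster centres: spread in longitude, jittered; latitude carries the
  # smooth spatial gradient, independent of group identity
  centre_lon <- seq(-100, -80, length.out = max(k, 2))[seq_len(k)]
  centre_lat <- stats::runif(k, 5, 35)
  gi <- match(groups, gl)
  lon <- centre_lon[gi] + stats::rnorm(n, 0, 0.5)
  lat <- centre_lat[gi] + stats::rnorm(n, 0, 0.5)
  # group (niche) effect, decorrelated from the latitudinal gradient at the
  # group level so the IBE and IBD shares are separately identifiable
  grp_eff <- stats::rnorm(k)
  if (k > 3) {
    grp_eff <- stats::residuals(stats::lm(grp_eff ~ centre_lat + centre_lon))
  }
  safe_scale <- function(v) {
    if (stats::sd(v) == 0) rep(0, length(v)) else as.numeric(scale(v))
  }
  comp_e <- safe_scale(grp_eff[gi])
  comp_d <- safe_scale(lat)
  noise <- stats::rnorm(n)
  noise <- as.numeric(scale(stats::residuals(
    stats::lm(noise ~ comp_e + comp_d))))
  w_e <- sqrt(cfg$ibe_fraction)
  w_d <- sqrt(cfg$ibd_fraction)
  w_n <- sqrt(max(0, 1 - cfg$ibe_fraction - cfg$ibd_fraction))
  env <- w_e * comp_e + w_d * comp_d + w_n * noise
  v_tot <- stats::var(env)
  truth <- list(ibe_share = stats::var(w_e * comp_e) / v_tot,
                ibd_share = stats::var(w_d * comp_d) / v_tot,
                components = data.frame(group = comp_e, spatial = comp_d,
                                        noise = noise))
  ids <- paste0("ind", seq_len(n))
  list(env = data.frame(sample_id = ids, env1 = env),
       geo = data.frame(sample_id = ids, lon = lon, lat = lat),
       truth = truth)
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Runs every generator under its own substream of `cfg$seed`: phylogeny
#' (one tip per population), BM tip traits, genotypes, archetype traits,
#' spectra and environment/coordinates. The `truth` element records
#' everything needed to score downstream recovery: group trait means, the
#' F_ST target, the IBE/IBD shares and the BM rate.
#'
#' @param cfg A [sim_config()].
#' @return List: `tree`, `bm_traits`, `genotypes`, `traits`, `spectra`,
#'   `env`, `geo`, `truth`.
#' @export
gen_dataset <- function(cfg) {
  .assert(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  seeds <- seed_streams(cfg$seed, .sim_streams)
  n_pop <- cfg$n_species * cfg$pops_per_species
  tree <- gen_phylogeny(max(n_pop, 3), seed = seeds[["phylogeny"]])
  bm <- gen_bm_traits(tree, sigma2 = cfg$bm_sigma2, root_value = 0,
                      seed = seeds[["bm_traits"]])
  geno <- gen_genotypes(cfg)
  tr <- gen_traits(cfg)
  spec <- gen_spectra(tr$traits, cfg)
  eg <- gen_env_geo(cfg, tr$traits$population)
  list(tree = tree, bm_traits = bm, genotypes = geno,
       traits = tr$traits, spectra = spec, env = eg$env, geo = eg$geo,
       truth = list(group_means = tr$group_means,
                    fst_target = cfg$fst_target,
                    ibe_share = eg$truth$ibe_share,
                    ibd_share = eg$truth$ibd_share,
                    bm_sigma2 = cfg$bm_sigma2))
}
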