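#' Pipeline configuration
#'
#' One flat configuration object for the whole analysis chain. Either point
#' the input paths at delimited files (spectra, genotypes, metadata,
#' environment, tree, measured traits) or supply a [sim_config()] to run on
#' synthetic data. Thresholds default to the package conventions: VIP 0.8
#' with a 0.4 floor, membership 0.6, c/h2 anchors 0.25/0.5/0.75, VIF 5, and
#' |r| <= 0.60 for correlation screening. The configuration round-trips
#' losslessly through JSON.
#'
#' @param inputs Named list of file paths (`spectra`, `genotypes`,
#'   `metadata`, `environment`, `tree`, `traits`) or NULL when simulating.
#' @param sim A [sim_config()] or NULL.
#' @param stages Character vector of stages to run, a subset of
#'   `c("preprocess", "plsr", "plsda", "popgen", "pstfst", "varpart", "physig")`.
#' @param vip_primary,vip_secondary VIP thresholds.
#' @param membership_threshold Cluster-membership threshold.
#' @param ratio_anchors c/h2 reporting anchors.
#' @param vif_threshold,r_max Predictor screening thresholds.
#' @param n_boot,n_perm Bootstrap and permutation counts.
#' @param common_garden Logical; a common-garden run restricts the
#'   divergence scan to predicted traits (no VIP band scan).
#' @param seed Global seed.
#' @param outdir Output directory (NULL disables file output).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(inputs = NULL, sim = NULL,
                            stages = c("preprocess", "plsr", "plsda",
                                       "popgen", "pstfst", "varpart",
                                       "physig"),
                            vip_primary = 0.8, vip_secondary = 0.4,
                            membership_threshold = 0.6,
                            ratio_anchors = c(0.25, 0.5, 0.75),
                            vif_threshold = 5, r_max = 0.60,
                            n_boot = 200, n_perm = 199,
                            common_garden = FALSE,
                            seed = 1, outdir = NULL) {
  .assert(!is.null(inputs) || !is.null(sim),
          "provide input paths or a sim_config")
  if (!is.null(inputs)) {
    .assert(all(file.exists(unlist(inputs))), "all input paths must exist")
  }
  .assert(vip_primary >= vip_secondary, "vip_primary must be >= vip_secondary")
  .assert(membership_threshold > 0 && membership_threshold <= 1,
          "membership threshold must be in (0, 1]")
  structure(list(inputs = inputs, sim = sim, stages = stages,
                 vip_primary = vip_primary, vip_secondary = vip_secondary,
                 membership_threshold = membership_threshold,
                 ratio_anchors = ratio_anchors,
                 vif_threshold = vif_threshold, r_max = r_max,
                 n_boot = n_boot, n_perm = n_perm,
                 common_garden = common_garden,
                 seed = seed, outdir = outdir),
            class = "pipeline_config")
}

# stable content hash of the configuration (md5 of its canonical JSON)
.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  x <- unclass(cfg)
  if (!is.null(x$sim)) x$sim <- unclass(x$sim)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Validate sample-identifier joins across input tables
#'
#' Reports which sample ids are present or absent across the spectra,
#' genotype, metadata and environment tables, erroring on duplicates and on
#' an empty intersection.
#'
#' @param tables Named list of vectors of sample ids (e.g.
#'   `list(spectra = ..., genotypes = ...)`).
#' @return List `shared` (ids present everywhere) and `orphans` (named list
#'   of ids missing from at least one table).
#' @export
validate_inputs <- function(tables) {
  .assert(length(tables) >= 2, "need at least two tables to join")
  for (nm in names(tables)) {
    dup <- unique(tables[[nm]][duplicated(tables[[nm]])])
    if (length(dup)) {
      stop("duplicate sample ids in ", nm, ": ",
           paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
    }
  }
  shared <- Reduce(intersect, tables)
  if (length(shared) == 0) stop("empty sample-id intersection across inputs",
                                call. = FALSE)
  all_ids <- unique(unlist(tables))
  orphans <- lapply(tables, function(v) setdiff(all_ids, v))
  list(shared = shared, orphans = orphans)
}

#' Run the full spectra-to-evolution pipeline
#'
#' Sequences preprocessing, PLSR trait prediction, PLS-DA classification,
#' neutral-marker statistics, the P_ST-F_ST divergence scan, IBE/IBD
#' variance partitioning, and spectrum-wide phylogenetic signal, on either
#' synthetic or file inputs. Per-stage tables, a JSON summary and a run
#' manifest (seed, config hash) are written when `cfg$outdir` is set.
#' Identical configuration and seed yield identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Named list of stage results plus `manifest`.
#' @export
run_pipeline <- function(cfg) {
  .assert(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  seeds <- seed_streams(cfg$seed, c("split", "plsda", "popgen", "pstfst",
                                    "varpart", "physig"))
  res <- list()
  if (!is.null(cfg$sim)) {
    ds <- gen_dataset(cfg$sim)
  } else {
    md <- utils::read.table(cfg$inputs$metadata, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    ds <- list(
      spectra = read_spectra(cfg$inputs$spectra),
      genotypes = if (!is.null(cfg$inputs$genotypes))
        read_genotypes(cfg$inputs$genotypes),
      traits = if (!is.null(cfg$inputs$traits))
        utils::read.table(cfg$inputs$traits, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE),
      env = if (!is.null(cfg$inputs$environment))
        utils::read.table(cfg$inputs$environment, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE),
      geo = md[, intersect(c("sample_id", "lon", "lat"), names(md))],
      tree = if (!is.null(cfg$inputs$tree)) ape::read.tree(cfg$inputs$tree))
    ds$traits <- merge(md[c("sample_id", "species", "population")],
                       ds$traits, by = "sample_id")
  }
  meta <- ds$traits[c("sample_id", "species", "population")]
  trait_names <- setdiff(names(ds$traits),
                         c("sample_id", "species", "population"))

  # --- preprocess -----------------------------------------------------------
  spec <- ds$spectra
  if ("preprocess" %in% cfg$stages) {
    if (spec$state == "raw") {
      spec <- resample_spectra(splice_correct(spec), step = 3)
    }
    wavelet <- cwt_transform(spec)
    res$preprocess <- list(resampled = spec, cwt = wavelet,
                           indices = vegetation_indices(spec))
  } else {
    wavelet <- cwt_transform(spec)
  }

  # --- PLSR trait models ----------------------------------------------------
  if ("plsr" %in% cfg$stages) {
    sp <- split_data(nrow(wavelet$reflectance), meta$species,
                     seed = seeds[["split"]])
    res$plsr <- lapply(stats::setNames(trait_names, trait_names), function(tr) {
      y <- ds$traits[[tr]]
      fit <- fit_plsr(wavelet$reflectance[sp$train, ], y[sp$train],
                      n_components = min(8, length(sp$train) - 2))
      pred <- predict(fit, wavelet$reflectance[sp$test, ])
      list(model = fit, vip = vip_scores(fit),
           test_r2 = 1 - sum((y[sp$test] - pred)^2) /
             sum((y[sp$test] - mean(y[sp$test]))^2),
           test_rmsep = sqrt(mean((y[sp$test] - pred)^2)))
    })
  }

  # --- PLS-DA species classification ---------------------------------------
  if ("plsda" %in% cfg$stages && length(unique(meta$species)) >= 2) {
    sp <- split_data(nrow(wavelet$reflectance), meta$species,
                     seed = seeds[["split"]])
    res$plsda <- suppressWarnings(fit_plsda(
      wavelet$reflectance[sp$train, ], meta$species[sp$train],
      n_components = min(6, length(sp$train) - 2),
      X_test = wavelet$reflectance[sp$test, ],
      labels_test = meta$species[sp$test],
      seed = seeds[["plsda"]]))
  }

  # --- neutral markers ------------------------------------------------------
  if ("popgen" %in% cfg$stages && !is.null(ds$genotypes)) {
    res$popgen <- list(
      fst = pairwise_fst(ds$genotypes, level = "population",
                         n_boot = cfg$n_boot, seed = seeds[["popgen"]]),
      amova = amova(ds$genotypes, n_perm = min(cfg$n_perm, 99),
                    seed = seeds[["popgen"]]))
  }

  # --- P_ST-F_ST ------------------------------------------------------------
  if ("pstfst" %in% cfg$stages && !is.null(res$popgen)) {
    scan_traits <- ds$traits[trait_names]
    res$pstfst <- pst_fst_scan(scan_traits, meta$population,
                               res$popgen$fst, n_boot = cfg$n_boot,
                               seed = seeds[["pstfst"]])
    if (!cfg$common_garden && !is.null(res$plsda)) {
      vip <- vip_scores(res$plsda$model)
      keep <- vip_select(vip, cfg$vip_primary, cfg$vip_secondary)
      if (any(keep)) {
        bands <- as.data.frame(wavelet$reflectance[, keep, drop = FALSE])
        names(bands) <- paste0("band_", wavelet$wavelengths[keep])
        res$pstfst_bands <- pst_fst_scan(
          bands[seq_len(min(ncol(bands), 12))], meta$population,
          res$popgen$fst, n_boot = cfg$n_boot, seed = seeds[["pstfst"]])
      }
    }
  }

  # --- IBE/IBD --------------------------------------------------------------
  if ("varpart" %in% cfg$stages && !is.null(ds$env)) {
    env <- ds$env[setdiff(names(ds$env), "sample_id")]
    if (ncol(env) >= 2) env <- vif_filter(env, cfg$vif_threshold)
    res$varpart <- variance_partition(
      scale(ds$traits[trait_names]), env, geo_predictors(ds$geo),
      n_perm = cfg$n_perm, seed = seeds[["varpart"]])
  }

  # --- phylogenetic signal --------------------------------------------------
  if ("physig" %in% cfg$stages && !is.null(ds$tree)) {
    tip_map <- ds$tree$tip.label[
      match(meta$population, sort(unique(meta$population)))]
    prof_spec <- wavelet
    res$physig <- list(
      traits = lapply(stats::setNames(trait_names, trait_names), function(tr) {
        pm <- population_means(ds$traits[[tr]], tip_map, ds$tree$tip.label)
        k_significance(ds$tree, stats::setNames(pm$mean, pm$tip),
                       n_perm = min(cfg$n_perm, 199), n_sim = 199,
                       seed = seeds[["physig"]])
      }),
      profile = spectral_k_profile(
        ds$tree,
        spectra_set(prof_spec$reflectance[, seq(1, ncol(prof_spec$reflectance),
                                                by = 20), drop = FALSE],
                    prof_spec$wavelengths[seq(1, length(prof_spec$wavelengths),
                                              by = 20)],
                    prof_spec$sample_ids, state = "cwt"),
        tip_map, n_perm = 99, seed = seeds[["physig"]]))
  }

  manifest <- list(seed = cfg$seed, stage_seeds = as.list(seeds),
                   config_hash = .config_hash(cfg),
                   stages = cfg$stages,
                   package_version = as.character(utils::packageVersion("spectevol")))
  res$manifest <- manifest

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$popgen)) {
      utils::write.table(res$popgen$fst, file.path(cfg$outdir, "fst.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(as.data.frame(res$popgen$amova),
                         file.path(cfg$outdir, "amova.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$pstfst)) {
      utils::write.table(res$pstfst, file.path(cfg$outdir, "pst_fst.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$varpart)) {
      utils::write.table(as.data.frame(res$varpart),
                         file.path(cfg$outdir, "varpart.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$physig)) {
      utils::write.table(res$physig$profile,
                         file.path(cfg$outdir, "k_profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summary <- pipeline_summary(res)
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                                null = "null"),
               file.path(cfg$outdir, "summary.json"))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, null = "null"),
               file.path(cfg$outdir, "manifest.json"))
  }
  res
}

#' Condense pipeline results into a flat summary
#'
#' @param res Result list from [run_pipeline()].
#' @return Named list of scalar summaries suitable for JSON.
#' @export
pipeline_summary <- function(res) {
  out <- list(config_hash = res$manifest$config_hash)
  if (!is.null(res$plsr)) {
    out$plsr_test_r2 <- lapply(res$plsr, function(m) m$test_r2)
  }
  if (!is.null(res$plsda)) {
    out$plsda_accuracy <- res$plsda$accuracy
    out$plsda_kappa <- res$plsda$kappa
  }
  if (!is.null(res$popgen)) {
    out$mean_pairwise_fst <- mean(res$popgen$fst$theta)
    out$amova_percent <- stats::setNames(as.list(res$popgen$amova$percent),
                                         res$popgen$amova$level)
  }
  if (!is.null(res$pstfst)) {
    out$n_flagged_025 <- sum(res$pstfst$flag_0.25, na.rm = TRUE)
    out$n_scanned <- nrow(res$pstfst)
  }
  if (!is.null(res$varpart)) {
    v <- as.data.frame(res$varpart)
    out$ibe_adj_r2 <- v$adj_r2[v$fraction == "env_given_geo"]
    out$ibd_adj_r2 <- v$adj_r2[v$fraction == "geo_given_env"]
  }
  if (!is.null(res$physig)) {
    out$median_k_by_region <- as.list(tapply(res$physig$profile$k,
                                             res$physig$profile$region,
                                             stats::median, na.rm = TRUE))
  }
  out
}
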