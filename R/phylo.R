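#' Population (tip) means of per-sample traits
#'
#' Averages sample-level trait values onto the tips of a phylogeny via a
#' sample-to-tip mapping, retaining per-tip counts and standard errors.
#'
#' @param values Numeric per-sample values.
#' @param mapping Character vector, the tip label of each sample.
#' @param tips Character vector of required tip labels (each must receive at
#'   least one sample).
#' @return Data frame: tip, mean, n, se (SE is `NA` for single-sample tips).
#' @export
population_means <- function(values, mapping, tips = unique(mapping)) {
  .assert(length(values) == length(mapping),
          "values and mapping must have equal length")
  missing_tips <- setdiff(tips, mapping)
  .assert(length(missing_tips) == 0,
          paste("tips with no mapped sample:", paste(missing_tips, collapse = ", ")))
  out <- do.call(rbind, lapply(tips, function(tp) {
    v <- values[mapping == tp]
    data.frame(tip = tp, mean = mean(v), n = length(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

# BM covariance (shared branch length) matrix ordered like x's names
.bm_vcv <- function(tree, labels) {
  V <- ape::vcv.phylo(tree)
  .assert(all(labels %in% rownames(V)), "tip values must match tree tip labels")
  V[labels, labels]
}

#' Blomberg's K phylogenetic-signal statistic
#'
#' Ratio of the observed mean squared error of tip values around the
#' phylogenetically weighted mean (ordinary deviations) to the mean squared
#' error under the Brownian-motion covariance inverse, scaled by its
#' Brownian expectation `(tr(V) - n / sum(V^-1)) / (n - 1)`. K near 1
#' indicates Brownian-like signal, near 0 a phylogenetically random trait.
#' K is invariant to affine transformations of the trait.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param x Named numeric vector of tip values (names = tip labels).
#' @return Scalar K >= 0.
#' @export
blomberg_k <- function(tree, x) {
  .assert(!is.null(names(x)), "x must be named by tip label")
  .assert(stats::sd(x) > 0, "undefined signal: trait is constant")
  n <- length(x)
  V <- .bm_vcv(tree, names(x))
  Vi <- solve(V)
  one <- rep(1, n)
  denom1 <- as.numeric(t(one) %*% Vi %*% one)
  ahat <- as.numeric(t(one) %*% Vi %*% x) / denom1
  d <- x - ahat
  mse0 <- sum(d^2) / (n - 1)
  mse <- as.numeric(t(d) %*% Vi %*% d) / (n - 1)
  expected <- (sum(diag(V)) - n / denom1) / (n - 1)
  (mse0 / mse) / expected
}

#' Significance of Blomberg's K against white-noise and Brownian nulls
#'
#' The white-noise P-value permutes tip values across the tree
#' (`P = (1 + #{K_perm >= K_obs}) / (n_perm + 1)`). The Brownian envelope is
#' the 2.5-97.5 percentile band of K from BM simulations rescaled to the
#' observed tip variance. Flags: `signal_present` when the permutation P is
#' at most `alpha`; `less_than_bm` when the observed K falls below the 2.5th
#' BM percentile.
#'
#' @param tree A `phylo` tree.
#' @param x Named tip values.
#' @param n_perm Tip-swap permutations (default 999).
#' @param n_sim BM simulations (default 1000).
#' @param alpha Significance level for the permutation test.
#' @param seed Integer seed.
#' @return A `phylo_signal_result` list: `k`, `p_wn`, `bm_low`, `bm_high`,
#'   `signal_present`, `less_than_bm`.
#' @export
k_significance <- function(tree, x, n_perm = 999, n_sim = 1000,
                           alpha = 0.05, seed = 1) {
  k_obs <- blomberg_k(tree, x)
  seeds <- seed_streams(seed, c("perm", "bm"))
  set.seed(seeds[["perm"]])
  labs <- names(x)
  k_perm <- vapply(seq_len(n_perm), function(i) {
    xi <- stats::setNames(sample(unname(x)), labs)
    blomberg_k(tree, xi)
  }, numeric(1))
  p_wn <- (1 + sum(k_perm >= k_obs)) / (n_perm + 1)
  set.seed(seeds[["bm"]])
  sdx <- stats::sd(x)
  k_bm <- vapply(seq_len(n_sim), function(i) {
    sim <- gen_bm_traits(tree, sigma2 = 1, root_value = 0,
                         seed = sample.int(.Machine$integer.max, 1))
    sim <- sim / stats::sd(sim) * sdx          # scale-free envelope
    blomberg_k(tree, sim[labs])
  }, numeric(1))
  env <- stats::quantile(k_bm, c(0.025, 0.975), names = FALSE)
  structure(list(k = k_obs, p_wn = p_wn, bm_low = env[1], bm_high = env[2],
                 signal_present = p_wn <= alpha,
                 less_than_bm = k_obs < env[1]),
            class = "phylo_signal_result")
}

#' @export
print.phylo_signal_result <- function(x, ...) {
  cat(sprintf("<phylo_signal_result> K = %.3f, P_WN = %.4f, BM envelope [%.3f, %.3f]\n",
              x$k, x$p_wn, x$bm_low, x$bm_high))
  invisible(x)
}

#' Spectrum-wide phylogenetic-signal profile
#'
#' Computes the population-mean spectrum per tip, then Blomberg's K with its
#' white-noise significance at every band, annotated with the spectral
#' region. Constant bands are skipped with a flag.
#'
#' @param tree A `phylo` tree.
#' @param spectra A `spectra_set` in `cwt` or `resampled` state.
#' @param mapping Tip label per sample.
#' @param n_perm Tip-swap permutations per band.
#' @param n_sim BM simulations per band (0 skips the envelope).
#' @param seed Integer seed.
#' @return Data frame: wavelength, region, k, p_wn, bm_low, bm_high,
#'   signal_present, skipped.
#' @export
spectral_k_profile <- function(tree, spectra, mapping, n_perm = 199,
                               n_sim = 0, seed = 1) {
  .require_state(spectra, c("cwt", "resampled"), "spectral_k_profile")
  tips <- tree$tip.label
  seeds <- seed_streams(seed, paste0("band", seq_along(spectra$wavelengths)))
  rows <- lapply(seq_along(spectra$wavelengths), function(j) {
    pm <- population_means(spectra$reflectance[, j], mapping, tips)
    x <- stats::setNames(pm$mean, pm$tip)
    if (stats::sd(x) == 0) {
      return(data.frame(wavelength = spectra$wavelengths[j],
                        region = region_of(spectra$wavelengths[j]),
                        k = NA_real_, p_wn = NA_real_, bm_low = NA_real_,
                        bm_high = NA_real_, signal_present = NA,
                        skipped = TRUE))
    }
    if (n_sim > 0) {
      r <- k_significance(tree, x, n_perm = n_perm, n_sim = n_sim,
                          seed = seeds[j])
      data.frame(wavelength = spectra$wavelengths[j],
                 region = region_of(spectra$wavelengths[j]),
                 k = r$k, p_wn = r$p_wn, bm_low = r$bm_low,
                 bm_high = r$bm_high, signal_present = r$signal_present,
                 skipped = FALSE)
    } else {
      set.seed(seeds[j])
      k_obs <- blomberg_k(tree, x)
      k_perm <- vapply(seq_len(n_perm), function(i)
        blomberg_k(tree, stats::setNames(sample(unname(x)), names(x))),
        numeric(1))
      p_wn <- (1 + sum(k_perm >= k_obs)) / (n_perm + 1)
      data.frame(wavelength = spectra$wavelengths[j],
                 region = region_of(spectra$wavelengths[j]),
                 k = k_obs, p_wn = p_wn, bm_low = NA_real_,
                 bm_high = NA_real_, signal_present = p_wn <= 0.05,
                 skipped = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phylogenetic generalized least squares regression
#'
#' GLS of a tip trait on a tip-level predictor with error covariance
#' proportional to the Brownian shared-branch-length matrix. On a star
#' phylogeny this reduces exactly to ordinary least squares.
#'
#' @param tree A `phylo` tree.
#' @param y Named tip response values.
#' @param x Named tip predictor values.
#' @param predictor Name to report for the predictor.
#' @return A `pgls_result` list: slope, intercept, se, t, p_value, n,
#'   sigma2 (residual BM rate).
#' @export
pgls_fit <- function(tree, y, x, predictor = deparse(substitute(x))) {
  .assert(!is.null(names(y)) && !is.null(names(x)),
          "y and x must be named by tip label")
  labs <- names(y)
  .assert(setequal(labs, names(x)), "y and x must cover the same tips")
  x <- x[labs]
  n <- length(y)
  .assert(n >= 4, "need at least 4 tips")
  V <- .bm_vcv(tree, labs)
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular phylogenetic covariance; check for duplicated zero-length tips",
         call. = FALSE))
  X <- cbind(intercept = 1, slope = x)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  resid <- y - X %*% beta
  sigma2 <- as.numeric(t(resid) %*% Vi %*% resid) / (n - 2)
  covb <- sigma2 * solve(XtVi %*% X)
  se <- sqrt(diag(covb))[["slope"]]
  tstat <- beta[["slope", 1]] / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(predictor = predictor, slope = beta[["slope", 1]],
                 intercept = beta[["intercept", 1]], se = se, t = tstat,
                 p_value = p, n = n, sigma2 = sigma2),
            class = "pgls_result")
}

#' @export
print.pgls_result <- function(x, ...) {
  cat(sprintf("<pgls_result> %s: slope = %.4g (SE %.3g), t = %.3f, P = %.4g, n = %d\n",
              x$predictor, x$slope, x$se, x$t, x$p_value, x$n))
  invisible(x)
}

#' Pearson trait-environment correlations
#'
#' Standard Pearson correlation with a two-sided t-test for every
#' (trait, environment variable) combination, on per-sample data.
#'
#' @param traits Data frame of per-sample traits.
#' @param env Data frame of per-sample environmental variables.
#' @return Data frame: trait, variable, r, p_value, n.
#' @export
pearson_trait_env <- function(traits, env) {
  traits <- as.data.frame(traits); env <- as.data.frame(env)
  .assert(nrow(traits) == nrow(env), "traits and env must align by row")
  .assert(nrow(traits) >= 3, "need n >= 3")
  out <- expand.grid(trait = names(traits), variable = names(env),
                     stringsAsFactors = FALSE)
  res <- t(mapply(function(tr, vb) {
    ok <- stats::complete.cases(traits[[tr]], env[[vb]])
    xv <- traits[[tr]][ok]; yv <- env[[vb]][ok]
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
      return(c(NA_real_, NA_real_, sum(ok)))
    }
    ct <- stats::cor.test(xv, yv)
    c(unname(ct$estimate), ct$p.value, sum(ok))
  }, out$trait, out$variable))
  out$r <- res[, 1]; out$p_value <- res[, 2]; out$n <- res[, 3]
  out
}
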