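#' Iterative variance-inflation-factor filtering
#'
#' Repeatedly drops the predictor with the largest VIF until every remaining
#' VIF is below the threshold. With an exactly collinear pair the first of
#' the two (in column order) has the numerically larger or equal VIF and ties
#' are broken towards the earlier column, so the survivor set is
#' deterministic.
#'
#' @param env Data frame of numeric predictors (n rows > number of columns).
#' @param threshold VIF threshold (default 5).
#' @return The filtered data frame (attribute `dropped` lists removals).
#' @export
vif_filter <- function(env, threshold = 5) {
  env <- as.data.frame(env)
  .assert(ncol(env) >= 2, "need >= 2 variables")
  .assert(nrow(env) > ncol(env), "need more observations than variables")
  dropped <- character(0)
  repeat {
    if (ncol(env) == 1) break
    v <- vapply(seq_along(env), function(j) {
      # perfect fits are expected here (exact collinearity); silence lm's note
      r2 <- suppressWarnings(
        summary(stats::lm(env[[j]] ~ ., data = env[-j]))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    if (all(v < threshold)) break
    worst <- which.max(v)          # ties -> earliest column
    dropped <- c(dropped, names(env)[worst])
    env <- env[-worst]
  }
  attr(env, "dropped") <- dropped
  env
}

#' Greedy Pearson-correlation filtering
#'
#' Retains variables in the given column order, dropping any variable whose
#' absolute Pearson correlation with an already-retained variable exceeds
#' `r_max`. The result is order-dependent by construction.
#'
#' @param env Data frame of numeric predictors.
#' @param r_max Maximum tolerated |r| (default 0.60).
#' @return Filtered data frame (attribute `dropped`).
#' @export
corr_filter <- function(env, r_max = 0.60) {
  env <- as.data.frame(env)
  .assert(ncol(env) >= 1, "need >= 1 variable")
  keep <- 1L
  for (j in seq_along(env)[-1]) {
    r <- vapply(keep, function(i) abs(stats::cor(env[[i]], env[[j]])),
                numeric(1))
    if (all(r <= r_max)) keep <- c(keep, j)
  }
  out <- env[keep]
  attr(out, "dropped") <- names(env)[-keep]
  out
}

#' Build spatial predictors from coordinates
#'
#' Centered longitude and latitude plus their squares and interaction
#' (five columns), the default spatial block for distance-based partitioning.
#'
#' @param geo Data frame with `lon` and `lat` columns.
#' @return Data frame with columns lon, lat, lon2, lat2, lonlat.
#' @export
geo_predictors <- function(geo) {
  lon <- geo$lon - mean(geo$lon)
  lat <- geo$lat - mean(geo$lat)
  data.frame(lon = lon, lat = lat, lon2 = lon^2, lat2 = lat^2,
             lonlat = lon * lat)
}

#' Redundancy analysis of a multivariate response on predictors
#'
#' Constrained ordination: multivariate least squares of the (internally
#' centered) response on the predictor block; the reported R2 is the share of
#' total response variance captured by the fitted values and the adjusted R2
#' uses the Ezekiel correction. Backed by `vegan::rda`.
#'
#' @param Y Numeric response matrix (samples x variables).
#' @param X Data frame of predictors.
#' @return List `r2`, `adj_r2`, `axis_scores` (site scores on constrained
#'   axes), `fit` (the underlying vegan model).
#' @export
rda_fit <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- as.data.frame(X)
  .assert(nrow(Y) == nrow(X), "Y and X must have the same number of rows")
  .assert(nrow(Y) > ncol(X), "need more samples than predictors")
  fit <- vegan::rda(Y ~ ., data = X)
  rs <- vegan::RsquareAdj(fit)
  scores <- tryCatch(
    vegan::scores(fit, display = "sites", choices = seq_len(fit$CCA$rank)),
    error = function(e) NULL)
  list(r2 = rs$r.squared, adj_r2 = rs$adj.r.squared,
       axis_scores = scores, fit = fit)
}

#' Partial redundancy analysis
#'
#' Effect of `X` on `Y` after removing the conditioning block `Z`: the
#' semipartial adjusted R2 is `adjR2(X + Z) - adjR2(Z)`; the pseudo-F and its
#' permutation P-value come from residual permutation under the reduced
#' model.
#'
#' @param Y Response matrix.
#' @param X Data frame of focal predictors.
#' @param Z Data frame of conditioning predictors (NULL reduces to [rda_fit()]).
#' @param n_perm Permutations for the significance test (0 skips it).
#' @param seed Integer seed.
#' @return List `semipartial_adj_r2`, `pseudo_f`, `p_value`, `fit`.
#' @export
partial_rda <- function(Y, X, Z = NULL, n_perm = 999, seed = 1) {
  Y <- as.matrix(Y)
  X <- as.data.frame(X)
  if (is.null(Z) || ncol(as.data.frame(Z)) == 0) {
    r <- rda_fit(Y, X)
    pf <- NA_real_; pv <- NA_real_
    if (n_perm > 0) {
      set.seed(seed)
      an <- vegan::anova.cca(r$fit, permutations = n_perm)
      pf <- an$F[1]; pv <- an$`Pr(>F)`[1]
    }
    return(list(semipartial_adj_r2 = r$adj_r2, pseudo_f = pf, p_value = pv,
                fit = r$fit))
  }
  Z <- as.data.frame(Z)
  .assert(length(intersect(names(X), names(Z))) == 0,
          "X and Z must not share columns")
  dat <- cbind(X, Z)
  fml <- stats::as.formula(paste(
    "Y ~", paste(names(X), collapse = " + "),
    "+ Condition(", paste(names(Z), collapse = " + "), ")"))
  fit <- vegan::rda(fml, data = dat)
  full <- rda_fit(Y, dat)
  red <- rda_fit(Y, Z)
  semi <- full$adj_r2 - red$adj_r2
  pf <- NA_real_; pv <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    an <- vegan::anova.cca(fit, permutations = n_perm)
    pf <- an$F[1]; pv <- an$`Pr(>F)`[1]
  }
  list(semipartial_adj_r2 = semi, pseudo_f = pf, p_value = pv, fit = fit)
}

#' Partition response variance into environment, space and joint fractions
#'
#' The isolation-by-environment fraction `a = adjR2(E+G) - adjR2(G)` is the
#' environmental effect conditioned on space; the isolation-by-distance
#' fraction `c = adjR2(E+G) - adjR2(E)` is the spatial effect conditioned on
#' environment; the joint fraction `b` is the remainder of the total
#' `adjR2(E+G)`; `unexplained = 1 - adjR2(E+G)`. The two conditional
#' fractions are permutation-tested by residual permutation under the
#' reduced model. Negative adjusted fractions are reported as-is and flagged.
#' Genetic predictor blocks can be passed through the same interface (the
#' partitioning is block-label agnostic).
#'
#' @param Y Response matrix (traits or wavelet bands).
#' @param ENV Environmental predictor data frame.
#' @param GEO Spatial predictor data frame (e.g. [geo_predictors()]).
#' @param n_perm Permutations (default 999).
#' @param seed Integer seed.
#' @return A `varpart_result`: data frame with fraction, adj_r2, pve_percent,
#'   p_value, negative flag; attribute `total_adj_r2`.
#' @export
variance_partition <- function(Y, ENV, GEO, n_perm = 999, seed = 1) {
  Y <- as.matrix(Y)
  ENV <- as.data.frame(ENV); GEO <- as.data.frame(GEO)
  seeds <- seed_streams(seed, c("env_given_geo", "geo_given_env"))
  both <- rda_fit(Y, cbind(ENV, GEO))
  env_only <- rda_fit(Y, ENV)
  geo_only <- rda_fit(Y, GEO)
  total <- both$adj_r2
  a <- total - geo_only$adj_r2
  c_ <- total - env_only$adj_r2
  b <- total - a - c_
  pa <- partial_rda(Y, ENV, GEO, n_perm = n_perm, seed = seeds[[1]])
  pc <- partial_rda(Y, GEO, ENV, n_perm = n_perm, seed = seeds[[2]])
  fr <- data.frame(
    fraction = c("env_given_geo", "geo_given_env", "joint", "unexplained"),
    adj_r2 = c(a, c_, b, 1 - total),
    pve_percent = c(a, c_, b, NA) / total * 100,
    p_value = c(pa$p_value, pc$p_value, NA, NA))
  fr$negative <- fr$adj_r2 < 0
  attr(fr, "total_adj_r2") <- total
  class(fr) <- c("varpart_result", "data.frame")
  fr
}
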