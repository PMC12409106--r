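#' One-way random-effects variance components for a trait
#'
#' Method-of-moments decomposition used by the phenotypic-divergence
#' statistic: `sigma2_within = MS_within` and
#' `sigma2_between = max(0, (MS_between - MS_within) / n0)` with `n0` the
#' standard unbalanced-design coefficient
#' `n0 = (N - sum(n_i^2)/N) / (k - 1)`.
#'
#' @param values Numeric trait values, one per sample.
#' @param groups Group label per sample; >= 2 groups with >= 2 samples each.
#' @return List `sigma2_between`, `sigma2_within`, `sigma2_between_raw`
#'   (before truncation at zero), `n0`.
#' @export
trait_variance_components <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  ni <- as.numeric(table(groups))
  .assert(length(ni) >= 2, "need >= 2 groups")
  .assert(all(ni >= 2), "insufficient data: every group needs >= 2 samples")
  k <- length(ni); N <- sum(ni)
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ss_b <- sum(ni * (gm - grand)^2)
  ss_w <- sum((values - gm[groups])^2)
  ms_b <- ss_b / (k - 1)
  ms_w <- ss_w / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  s2b_raw <- (ms_b - ms_w) / n0
  list(sigma2_between = max(0, s2b_raw), sigma2_within = ms_w,
       sigma2_between_raw = s2b_raw, n0 = n0)
}

#' Phenotypic divergence statistic P_ST
#'
#' `P_ST = (ratio * s2b) / (ratio * s2b + 2 * s2w)` where `ratio = c/h2` is
#' the assumed proportion of between-group phenotypic variance that is
#' additive-genetic, scaled by heritability. The two never appear separately.
#'
#' @param ratio Positive c/h2 value(s).
#' @param s2b Between-group variance component.
#' @param s2w Within-group variance component.
#' @return P_ST in `[0, 1]`, vectorized over `ratio`.
#' @export
pst <- function(ratio, s2b, s2w) {
  .assert(all(ratio > 0), "ratio must be positive")
  .assert(s2b >= 0 && s2w >= 0, "variance components must be non-negative")
  .assert(!(s2b == 0 && s2w == 0), "P_ST undefined when both components are 0")
  (ratio * s2b) / (ratio * s2b + 2 * s2w)
}

#' Default c/h2 sensitivity grid
#'
#' 40 log-spaced ratios on `[0.05, 2]`, always containing the reporting
#' anchors 0.25, 0.5 and 0.75.
#' @export
default_ratio_grid <- function() {
  g <- exp(seq(log(0.05), log(2), length.out = 40))
  sort(unique(c(g, 0.25, 0.5, 0.75)))
}

#' Bootstrap P_ST over a c/h2 grid
#'
#' Resamples individuals within groups with replacement, recomputes the
#' variance components, and forms percentile CIs of P_ST at every grid ratio.
#'
#' @param values Numeric trait values.
#' @param groups Group labels.
#' @param ratio_grid c/h2 grid (default [default_ratio_grid()]).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param alpha CI tail mass (default 0.05).
#' @param seed Integer seed.
#' @return A `pst_result` list: `ratio`, `pst`, `ci_low`, `ci_high`,
#'   `sigma2_between`, `sigma2_within`, `anchors` (P_ST at 0.25/0.5/0.75).
#' @export
pst_bootstrap <- function(values, groups, ratio_grid = default_ratio_grid(),
                          n_boot = 1000, alpha = 0.05, seed = 1) {
  comp <- trait_variance_components(values, groups)
  p_obs <- pst(ratio_grid, comp$sigma2_between, comp$sigma2_within)
  groups <- factor(groups)
  idx_by_group <- split(seq_along(values), groups)
  boot_labels <- rep(names(idx_by_group), lengths(idx_by_group))
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(ratio_grid))
  for (b in seq_len(n_boot)) {
    ix <- unlist(lapply(idx_by_group, function(ii)
      ii[sample.int(length(ii), replace = TRUE)]), use.names = FALSE)
    cb <- trait_variance_components(values[ix], boot_labels)
    if (cb$sigma2_between == 0 && cb$sigma2_within == 0) {
      boot[b, ] <- NA_real_
    } else {
      boot[b, ] <- pst(ratio_grid, cb$sigma2_between, cb$sigma2_within)
    }
  }
  ci <- apply(boot, 2, .percentile_ci, alpha = alpha)
  anchors <- c(0.25, 0.5, 0.75)
  structure(list(ratio = ratio_grid, pst = p_obs,
                 ci_low = ci[1, ], ci_high = ci[2, ],
                 sigma2_between = comp$sigma2_between,
                 sigma2_within = comp$sigma2_within,
                 sigma2_between_raw = comp$sigma2_between_raw,
                 anchors = stats::setNames(
                   pst(anchors, comp$sigma2_between, comp$sigma2_within),
                   anchors)),
            class = "pst_result")
}

#' @export
print.pst_result <- function(x, ...) {
  cat(sprintf("<pst_result> s2b = %.4g, s2w = %.4g; P_ST at c/h2 {0.25, 0.5, 0.75} = %s\n",
              x$sigma2_between, x$sigma2_within,
              paste(sprintf("%.3f", x$anchors), collapse = ", ")))
  invisible(x)
}

#' Smallest c/h2 at which P_ST exceeds F_ST with confidence
#'
#' Returns the smallest grid ratio whose lower P_ST confidence limit exceeds
#' the upper F_ST confidence limit, or `NA` if no ratio qualifies.
#'
#' @param p A `pst_result`.
#' @param fst_ci_high Upper confidence limit of F_ST for the same pair.
#' @return Scalar ratio or `NA_real_`.
#' @export
critical_ratio <- function(p, fst_ci_high) {
  .assert(inherits(p, "pst_result"), "p must be a pst_result")
  .assert(is.finite(fst_ci_high), "fst_ci_high must be finite")
  hit <- which(p$ci_low > fst_ci_high)
  if (length(hit) == 0) NA_real_ else p$ratio[min(hit)]
}

#' P_ST-F_ST scan over traits or spectral bands for all group pairs
#'
#' For each pair of groups present in the F_ST table and each trait (or
#' wavelet-coefficient band), bootstraps P_ST over the c/h2 grid, finds the
#' critical ratio against the pair's F_ST upper CI, and emits a long-format
#' table with decision flags at the 0.25/0.5/0.75 anchors.
#'
#' @param traits Data frame of per-sample trait values (or a band matrix with
#'   named columns).
#' @param groups Group label per sample.
#' @param fst Data frame as returned by [pairwise_fst()].
#' @param ratio_grid c/h2 grid.
#' @param n_boot Bootstrap replicates per trait/pair.
#' @param alpha CI tail mass.
#' @param seed Integer seed.
#' @return Long data frame: pair, trait, s2b, s2w, pst at anchors, ci_low at
#'   anchors, critical_ratio, fst, fst_ci_high, flags at anchors.
#' @export
pst_fst_scan <- function(traits, groups, fst,
                         ratio_grid = default_ratio_grid(),
                         n_boot = 1000, alpha = 0.05, seed = 1) {
  traits <- as.data.frame(traits)
  groups <- as.character(groups)
  seeds <- seed_streams(seed, paste0("pair", seq_len(nrow(fst))))
  rows <- list()
  for (k in seq_len(nrow(fst))) {
    pair <- c(fst$group1[k], fst$group2[k])
    sel <- groups %in% pair
    .assert(any(sel), paste("no samples for pair", paste(pair, collapse = "-")))
    tseeds <- seed_streams(seeds[k], names(traits))
    for (tr in names(traits)) {
      pr <- pst_bootstrap(traits[[tr]][sel], groups[sel],
                          ratio_grid = ratio_grid, n_boot = n_boot,
                          alpha = alpha, seed = tseeds[[tr]])
      crit <- critical_ratio(pr, fst$ci_high[k])
      a <- function(r) which.min(abs(ratio_grid - r))
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = pair[1], group2 = pair[2], trait = tr,
        s2b = pr$sigma2_between, s2w = pr$sigma2_within,
        pst_0.25 = pr$anchors[["0.25"]], pst_0.5 = pr$anchors[["0.5"]],
        pst_0.75 = pr$anchors[["0.75"]],
        ci_low_0.25 = pr$ci_low[a(0.25)], ci_low_0.5 = pr$ci_low[a(0.5)],
        ci_low_0.75 = pr$ci_low[a(0.75)],
        critical_ratio = crit,
        fst = fst$theta[k], fst_ci_high = fst$ci_high[k],
        flag_0.25 = !is.na(crit) && crit <= 0.25,
        flag_0.5 = !is.na(crit) && crit <= 0.5,
        flag_0.75 = !is.na(crit) && crit <= 0.75)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
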