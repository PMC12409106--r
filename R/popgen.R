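#' Diploid genotype table
#'
#' Wraps a data.frame with columns `sample_id`, `species`, `population`, and
#' two integer allele columns per locus named `<locus>.1` and `<locus>.2`.
#' Missing genotypes are `NA`. Ploidy is exactly 2.
#'
#' @param df Data frame in the layout above.
#' @return A `genotype_table`.
#' @export
genotype_table <- function(df) {
  .assert(all(c("sample_id", "species", "population") %in% names(df)),
          "df must have sample_id, species and population columns")
  allele_cols <- setdiff(names(df), c("sample_id", "species", "population"))
  .assert(length(allele_cols) >= 2 && length(allele_cols) %% 2 == 0,
          "need two allele columns per locus (>= 1 locus)")
  loci <- unique(sub("\\.[12]$", "", allele_cols))
  .assert(all(paste0(rep(loci, each = 2), c(".1", ".2")) %in% allele_cols),
          "allele columns must be named <locus>.1 and <locus>.2")
  structure(list(data = df, loci = loci), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals, %d loci, %d species, %d populations\n",
              nrow(x$data), length(x$loci),
              length(unique(x$data$species)),
              length(unique(x$data$population))))
  invisible(x)
}

#' Read a delimited genotype table
#'
#' Layout: columns `sample_id`, `species`, `population`, then two columns per
#' locus (`<locus>.1`, `<locus>.2`). A configurable missing code is converted
#' to `NA`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @param missing_code Value encoding missing alleles (default `-9`).
#' @return A `genotype_table`.
#' @export
read_genotypes <- function(path, sep = "\t", missing_code = -9) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  allele_cols <- setdiff(names(df), c("sample_id", "species", "population"))
  for (cc in allele_cols) df[[cc]][df[[cc]] == missing_code] <- NA
  genotype_table(df)
}

#' Read STRUCTURE-format genotypes (two rows per individual)
#'
#' Columns: individual id, population label, then one allele per locus; two
#' consecutive rows per individual. Species labels are taken equal to the
#' population label unless a `species_map` is supplied.
#'
#' @param path File path.
#' @param sep Field separator (whitespace by default).
#' @param missing_code Missing allele code (default `-9`).
#' @param species_map Optional named vector population -> species.
#' @return A `genotype_table`.
#' @export
read_structure <- function(path, sep = "", missing_code = -9,
                           species_map = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          stringsAsFactors = FALSE)
  .assert(nrow(df) %% 2 == 0, "STRUCTURE file must have two rows per individual")
  odd <- df[seq(1, nrow(df), by = 2), , drop = FALSE]
  even <- df[seq(2, nrow(df), by = 2), , drop = FALSE]
  .assert(all(odd[[1]] == even[[1]]), "row pairs must share the individual id")
  n_loci <- ncol(df) - 2L
  out <- data.frame(sample_id = as.character(odd[[1]]),
                    population = as.character(odd[[2]]))
  out$species <- if (is.null(species_map)) out$population else
    unname(species_map[out$population])
  for (l in seq_len(n_loci)) {
    a1 <- odd[[l + 2L]]; a2 <- even[[l + 2L]]
    a1[a1 == missing_code] <- NA; a2[a2 == missing_code] <- NA
    out[[paste0("L", l, ".1")]] <- a1
    out[[paste0("L", l, ".2")]] <- a2
  }
  genotype_table(out[, c("sample_id", "species", "population",
                         setdiff(names(out), c("sample_id", "species", "population")))])
}

# Weir & Cockerham (1984) variance components a, b, c for every allele at one
# locus, given the two allele columns and a grouping factor. Complete-case
# within the locus. Returns c(a=, b=, c=) summed over alleles.
.wc_locus <- function(a1, a2, groups) {
  ok <- !is.na(a1) & !is.na(a2) & !is.na(groups)
  a1 <- a1[ok]; a2 <- a2[ok]; groups <- factor(groups[ok])
  ni <- as.numeric(table(groups))
  r <- length(ni)
  if (r < 2 || any(ni < 1) || length(a1) == 0) return(c(a = 0, b = 0, c = 0))
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2) return(c(a = 0, b = 0, c = 0))
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  A <- B <- C <- 0
  for (u in alleles) {
    cnt <- (a1 == u) + (a2 == u)
    p_i <- tapply(cnt, groups, mean) / 2
    h_i <- tapply(cnt == 1L, groups, mean)
    pbar <- sum(ni * p_i) / (r * nbar)
    s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h_i) / (r * nbar)
    if (nbar > 1) {
      a_u <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b_u <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
    } else {
      a_u <- 0; b_u <- 0
    }
    c_u <- hbar / 2
    A <- A + a_u; B <- B + b_u; C <- C + c_u
  }
  c(a = A, b = B, c = C)
}

# per-locus WC components for a genotype table restricted to `groups`
.wc_components <- function(g, groups) {
  comp <- t(vapply(g$loci, function(l) {
    .wc_locus(g$data[[paste0(l, ".1")]], g$data[[paste0(l, ".2")]], groups)
  }, numeric(3)))
  rownames(comp) <- g$loci
  comp
}

#' Multi-locus Weir-Cockerham theta
#'
#' The multiallelic, multilocus estimator of F_ST: the ratio of the summed
#' among-group variance components to the summed total components across all
#' alleles and loci. Negative estimates are reported as computed.
#'
#' @param g A `genotype_table`.
#' @param groups Grouping vector (one label per individual); defaults to the
#'   population column.
#' @return Scalar theta.
#' @export
wc_theta <- function(g, groups = g$data$population) {
  comp <- .wc_components(g, groups)
  denom <- sum(comp)
  if (denom == 0) return(NA_real_)
  sum(comp[, "a"]) / denom
}

#' Pairwise Weir-Cockerham F_ST with bootstrap confidence intervals
#'
#' For every pair of groups at the chosen level, computes the multiallelic
#' multilocus theta and a percentile bootstrap CI from resampling loci with
#' replacement.
#'
#' @param g A `genotype_table`.
#' @param level `"species"` or `"population"`.
#' @param n_boot Bootstrap replicates over loci (default 1000); set to 0 to
#'   skip CIs.
#' @param alpha CI tail mass (default 0.05 for a 95% interval).
#' @param seed Integer seed.
#' @return Data frame with one row per pair: `group1`, `group2`, `theta`,
#'   `ci_low`, `ci_high`, `n_loci`.
#' @export
pairwise_fst <- function(g, level = c("population", "species"),
                         n_boot = 1000, alpha = 0.05, seed = 1) {
  level <- match.arg(level)
  labs <- g$data[[level]]
  gl <- sort(unique(labs))
  .assert(length(gl) >= 2, "need >= 2 groups at the chosen level")
  pairs <- utils::combn(gl, 2)
  set.seed(seed)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    sel <- labs %in% pairs[, k]
    sub <- genotype_table(g$data[sel, , drop = FALSE])
    grp <- labs[sel]
    tab <- table(grp)
    if (any(tab < 2)) {
      stop("insufficient data: group with < 2 individuals in pair ",
           paste(pairs[, k], collapse = "-"), call. = FALSE)
    }
    comp <- .wc_components(sub, grp)
    theta <- if (sum(comp) == 0) NA_real_ else sum(comp[, "a"]) / sum(comp)
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0 && nrow(comp) >= 2) {
      bt <- vapply(seq_len(n_boot), function(b) {
        ix <- sample.int(nrow(comp), replace = TRUE)
        cc <- comp[ix, , drop = FALSE]
        if (sum(cc) == 0) NA_real_ else sum(cc[, "a"]) / sum(cc)
      }, numeric(1))
      ci <- .percentile_ci(bt, alpha)
    }
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k], theta = theta,
               ci_low = unname(ci[1]), ci_high = unname(ci[2]),
               n_loci = nrow(comp))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bootstrap CI over loci for one pair of groups
#'
#' @param g A `genotype_table`.
#' @param pair Character vector of two group labels.
#' @param level `"population"` or `"species"`.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param alpha CI tail mass.
#' @param seed Integer seed.
#' @return Numeric vector `c(low, high)`.
#' @export
fst_bootstrap_ci <- function(g, pair, level = c("population", "species"),
                             n_boot = 1000, alpha = 0.05, seed = 1) {
  level <- match.arg(level)
  .assert(length(g$loci) >= 2, "cannot bootstrap with a single locus")
  res <- pairwise_fst(genotype_table(
    g$data[g$data[[level]] %in% pair, , drop = FALSE]),
    level = level, n_boot = n_boot, alpha = alpha, seed = seed)
  c(low = res$ci_low[1], high = res$ci_high[1])
}

# Variance components of the 4-level nested gene-copy ANOVA at one locus.
# y: copies x alleles indicator matrix; sp/pop/ind: factor per copy.
.amova_locus <- function(a1, a2, species, pop, ind) {
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  species <- species[ok]; pop <- pop[ok]; ind <- ind[ok]
  alleles <- sort(unique(c(a1, a2)))
  copies_allele <- c(a1, a2)
  sp2 <- factor(rep(species, 2)); pp2 <- factor(rep(pop, 2))
  id2 <- factor(rep(ind, 2))
  Y <- vapply(alleles, function(u) as.numeric(copies_allele == u),
              numeric(length(copies_allele)))
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = length(alleles))
  Ncop <- nrow(Y)
  M <- length(unique(id2)); P <- length(unique(pp2)); S <- length(unique(sp2))
  # sums of squares per hierarchy level, summed across allele indicators
  gmean <- colMeans(Y)
  im <- rowsum(Y, id2) / as.numeric(table(id2))
  pm <- rowsum(Y, pp2) / as.numeric(table(pp2))
  sm <- rowsum(Y, sp2) / as.numeric(table(sp2))
  ind_of <- id2[!duplicated(id2)]
  # map: individual -> pop, pop -> species (constant within unit)
  pop_of_ind <- pp2[match(levels(id2), id2)]
  sp_of_pop <- sp2[match(levels(pp2), pp2)]
  n_ind <- as.numeric(table(id2))               # copies per individual (=2)
  n_pop <- as.numeric(table(pp2))               # copies per pop
  n_sp <- as.numeric(table(sp2))                # copies per species
  ss_wi <- sum((Y - im[id2, , drop = FALSE])^2)
  ss_ai <- sum(n_ind * rowSums((im - pm[pop_of_ind, , drop = FALSE])^2))
  ss_ap <- sum(n_pop * rowSums((pm - sm[sp_of_pop, , drop = FALSE])^2))
  ss_as <- sum(n_sp * rowSums(sweep(sm, 2, gmean)^2))
  df_wi <- M
  df_ai <- M - P
  df_ap <- P - S
  df_as <- S - 1
  ms_wi <- ss_wi / df_wi
  ms_ai <- if (df_ai > 0) ss_ai / df_ai else NA_real_
  ms_ap <- if (df_ap > 0) ss_ap / df_ap else NA_real_
  ms_as <- if (df_as > 0) ss_as / df_as else NA_real_
  # unbalanced-design coefficients (copies per individual is exactly 2)
  npop_sq_by_sp <- tapply(n_pop, sp_of_pop, function(v) sum(v^2))
  n_i_tot <- tapply(n_pop, sp_of_pop, sum)
  cf_n <- (Ncop - sum(npop_sq_by_sp / n_i_tot)) / max(df_ap, 1)
  cf_np <- (sum(npop_sq_by_sp / n_i_tot) - sum(n_pop^2) / Ncop) / max(df_as, 1)
  cf_npp <- (Ncop - sum(n_sp^2) / Ncop) / max(df_as, 1)
  v_wi <- ms_wi
  v_ai <- if (is.na(ms_ai)) 0 else (ms_ai - ms_wi) / 2
  v_ap <- if (is.na(ms_ap) || cf_n == 0) 0 else (ms_ap - ms_ai) / cf_n
  v_as <- if (is.na(ms_as) || cf_npp == 0) 0 else
    (ms_as - ms_ai - cf_np * v_ap) / cf_npp
  c(among_species = v_as, among_pops_within_species = v_ap,
    among_inds_within_pops = v_ai, within_individuals = v_wi)
}

.amova_components_all <- function(g, species, pop, ind) {
  comps <- vapply(g$loci, function(l) {
    .amova_locus(g$data[[paste0(l, ".1")]], g$data[[paste0(l, ".2")]],
                 species, pop, ind)
  }, numeric(4))
  rowSums(comps)
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Nested ANOVA on allele indicator variables under the infinite-alleles
#' distance: each allele at each locus contributes an indicator, individuals
#' contribute two gene copies, and variance is decomposed into four levels:
#' among species, among populations within species, among individuals within
#' populations, and within individuals. P-values come from permuting units at
#' the appropriate level (populations among species; individuals among
#' populations within species; gene copies among individuals within
#' populations).
#'
#' @param g A `genotype_table` with nested species/population labels.
#' @param n_perm Permutations per testable level (default 999; 0 skips tests).
#' @param seed Integer seed.
#' @return An `amova_result`: data frame with `level`, `variance`, `percent`,
#'   `p_value`.
#' @export
amova <- function(g, n_perm = 999, seed = 1) {
  d <- g$data
  sp_of_pop <- tapply(d$species, d$population, function(v) v[1])
  if (any(table(sp_of_pop) < 2)) {
    warning("some species contain a single population; the among-populations",
            "-within-species component has reduced degrees of freedom there")
  }
  obs <- .amova_components_all(g, d$species, d$population, d$sample_id)
  total <- sum(pmax(obs, 0))
  pct <- pmax(obs, 0) / total * 100
  pvals <- rep(NA_real_, 4)
  if (n_perm > 0) {
    set.seed(seed)
    pops <- unique(d$population)
    count <- c(0L, 0L, 0L)
    for (b in seq_len(n_perm)) {
      # level 1: shuffle whole populations among species
      perm_sp_of_pop <- sample(unname(sp_of_pop))
      names(perm_sp_of_pop) <- names(sp_of_pop)
      sp1 <- unname(perm_sp_of_pop[d$population])
      c1 <- .amova_components_all(g, sp1, d$population, d$sample_id)
      if (c1[1] >= obs[1]) count[1] <- count[1] + 1L
      # level 2: shuffle individuals among populations within species
      pop2 <- d$population
      for (s in unique(d$species)) {
        ix <- which(d$species == s)
        pop2[ix] <- sample(pop2[ix])
      }
      c2 <- .amova_components_all(g, d$species, pop2, d$sample_id)
      if (c2[2] >= obs[2]) count[2] <- count[2] + 1L
      # level 3: shuffle gene copies among individuals within populations
      g3 <- g
      for (l in g$loci) {
        cc <- c(paste0(l, ".1"), paste0(l, ".2"))
        for (p in pops) {
          ix <- which(d$population == p)
          copies <- c(g$data[[cc[1]]][ix], g$data[[cc[2]]][ix])
          copies <- sample(copies)
          g3$data[[cc[1]]][ix] <- copies[seq_along(ix)]
          g3$data[[cc[2]]][ix] <- copies[length(ix) + seq_along(ix)]
        }
      }
      c3 <- .amova_components_all(g3, d$species, d$population, d$sample_id)
      if (c3[3] >= obs[3]) count[3] <- count[3] + 1L
    }
    pvals[1:3] <- (1 + count) / (n_perm + 1)
  }
  structure(data.frame(
    level = c("among_species", "among_pops_within_species",
              "among_inds_within_pops", "within_individuals"),
    variance = unname(obs), percent = unname(pct), p_value = pvals),
    class = c("amova_result", "data.frame"))
}

#' Evanno delta-K from clustering log-probabilities
#'
#' Given replicate log-probabilities of the data for consecutive K, computes
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))` and the
#' maximizing K. K values with zero replicate SD are excluded with a warning.
#'
#' @param loglik_table Data frame or matrix: column `K` plus replicate columns,
#'   or a named list `K -> numeric vector of replicate log-probabilities`.
#' @return List with `best_k` and `delta_k` (data frame K, delta_k).
#' @export
evanno_delta_k <- function(loglik_table) {
  if (is.list(loglik_table) && !is.data.frame(loglik_table)) {
    ks <- as.numeric(names(loglik_table))
    reps <- loglik_table
  } else {
    df <- as.data.frame(loglik_table)
    ks <- df$K
    reps <- lapply(seq_len(nrow(df)), function(i)
      as.numeric(df[i, setdiff(names(df), "K")]))
  }
  ord <- order(ks); ks <- ks[ord]; reps <- reps[ord]
  .assert(length(ks) >= 3 && all(diff(ks) == 1),
          "need >= 3 consecutive K values")
  .assert(all(vapply(reps, length, 1L) >= 2),
          "need >= 2 replicates per K to estimate the sd")
  mu <- vapply(reps, mean, numeric(1))
  sdev <- vapply(reps, stats::sd, numeric(1))
  inner <- 2:(length(ks) - 1)
  dk <- abs(mu[inner + 1] - 2 * mu[inner] + mu[inner - 1]) / sdev[inner]
  bad <- sdev[inner] == 0
  if (any(bad)) {
    warning("zero replicate sd at K = ", paste(ks[inner][bad], collapse = ", "),
            "; delta-K undefined there and excluded")
    dk[bad] <- NA_real_
  }
  out <- data.frame(K = ks[inner], delta_k = dk)
  list(best_k = out$K[which.max(out$delta_k)], delta_k = out)
}

#' Assign cluster membership from a Q matrix
#'
#' Each individual is assigned to its maximum-membership cluster when that
#' membership reaches the threshold, otherwise flagged admixed. A threshold
#' of 0.6 reflects a majority-membership rule for highly admixing systems; a
#' stricter 0.7 is conventional for spatially explicit clustering output.
#'
#' @param q_matrix Numeric matrix or data frame, rows = individuals, columns =
#'   clusters; rows must sum to 1 (tolerance 1e-6).
#' @param threshold Membership threshold (default 0.6).
#' @return Data frame: `cluster` (integer, NA when admixed), `max_q`,
#'   `admixed` (logical).
#' @export
assign_membership <- function(q_matrix, threshold = 0.6) {
  q <- as.matrix(q_matrix)
  .assert(all(abs(rowSums(q) - 1) <= 1e-6),
          "each row of the Q matrix must sum to 1")
  best <- max.col(q, ties.method = "first")
  maxq <- q[cbind(seq_len(nrow(q)), best)]
  admixed <- maxq < threshold
  data.frame(cluster = ifelse(admixed, NA_integer_, best),
             max_q = maxq, admixed = admixed)
}

#' Read a CLUMPP/STRUCTURE-style Q matrix
#'
#' Reads a delimited table whose last `k` columns are cluster membership
#' fractions.
#'
#' @param path File path.
#' @param k Number of clusters (defaults to all numeric columns).
#' @param sep Field separator (whitespace by default).
#' @return Numeric matrix of membership fractions.
#' @export
read_qmatrix <- function(path, k = NULL, sep = "") {
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  q <- as.matrix(df[, num, drop = FALSE])
  if (!is.null(k)) q <- q[, (ncol(q) - k + 1L):ncol(q), drop = FALSE]
  unname(q)
}
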