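test_that("VIF filtering drops collinear predictors deterministically", {
  set.seed(1)
  ortho <- as.data.frame(qr.Q(qr(matrix(rnorm(50 * 3), 50))))
  names(ortho) <- c("a", "b", "c")
  out <- vif_filter(ortho, threshold = 5)
  expect_equal(names(out), c("a", "b", "c"))
  expect_length(attr(out, "dropped"), 0)

  dup <- data.frame(x = rnorm(40))
  dup$y <- dup$x
  dup$z <- rnorm(40)
  out2 <- vif_filter(dup, threshold = 5)
  expect_length(attr(out2, "dropped"), 1)
  expect_true("z" %in% names(out2))

  # known structure: x1 and x2 correlated ~0.95, x3 independent; brute-force
  # all-subsets check of which sets satisfy the threshold
  set.seed(7)
  x1 <- rnorm(200)
  x2 <- 0.95 * x1 + sqrt(1 - 0.95^2) * rnorm(200)
  x3 <- rnorm(200)
  env <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  surv <- names(vif_filter(env, threshold = 5))
  max_vif <- function(d) {
    if (ncol(d) < 2) return(1)
    max(vapply(seq_along(d), function(j)
      1 / (1 - summary(stats::lm(d[[j]] ~ ., data = d[-j]))$r.squared),
      numeric(1)))
  }
  expect_lt(max_vif(env[surv]), 5)
  # the survivor set keeps x3 and exactly one of the correlated pair
  expect_true("x3" %in% surv)
  expect_equal(sum(c("x1", "x2") %in% surv), 1L)
})

test_that("correlation filtering is greedy in column order", {
  set.seed(2)
  a <- rnorm(100); b <- a + rnorm(100, 0, 0.1); c_ <- rnorm(100)
  env <- data.frame(a = a, b = b, c = c_)
  out <- corr_filter(env, r_max = 0.6)
  expect_equal(names(out), c("a", "c"))
  rev_out <- corr_filter(env[c("b", "a", "c")], r_max = 0.6)
  expect_equal(names(rev_out), c("b", "c"))   # order decides the survivor
  low <- data.frame(x = rnorm(50), y = rnorm(50))
  expect_equal(names(corr_filter(low, 0.99)), c("x", "y"))
})

test_that("RDA recovers exact fits and the correlation identity", {
  set.seed(3)
  X <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  B <- matrix(c(1, -1, 0.5, 2), 2)
  Y <- as.matrix(X) %*% B
  r <- rda_fit(Y, X)
  expect_equal(r$r2, 1, tolerance = 1e-9)

  y1 <- rnorm(40); x1 <- rnorm(40)
  r2 <- rda_fit(matrix(y1), data.frame(x = x1))
  expect_equal(r2$r2, stats::cor(y1, x1)^2, tolerance = 1e-9)

  # orthogonal predictors: null adjusted R2 centred on zero
  adj <- vapply(seq_len(40), function(i) {
    set.seed(300 + i)
    rda_fit(matrix(rnorm(50)), data.frame(x = rnorm(50)))$adj_r2
  }, numeric(1))
  expect_lt(abs(mean(adj)), 0.02)
})

test_that("partial RDA reduces to RDA without conditioning and respects orthogonality", {
  set.seed(4)
  Y <- matrix(rnorm(60 * 2), 60)
  X <- data.frame(x = rnorm(60))
  pr <- partial_rda(Y, X, Z = NULL, n_perm = 0)
  expect_equal(pr$semipartial_adj_r2, rda_fit(Y, X)$adj_r2, tolerance = 1e-12)

  # X orthogonal to Z: semipartial fraction equals marginal fraction
  Q <- qr.Q(qr(matrix(rnorm(100 * 2), 100)))
  X2 <- data.frame(x = Q[, 1]); Z2 <- data.frame(z = Q[, 2])
  Y2 <- matrix(2 * Q[, 1] + Q[, 2] + rnorm(100, 0, 0.5))
  semi <- partial_rda(Y2, X2, Z2, n_perm = 0)$semipartial_adj_r2
  marg <- rda_fit(Y2, X2)$adj_r2
  expect_equal(semi, marg, tolerance = 0.02)
  expect_error(partial_rda(Y2, X2, data.frame(x = Q[, 2])), "share")
})

test_that("variance partitioning closes and recovers generative shares", {
  # duplicated blocks: everything lands in the joint fraction
  set.seed(5)
  E <- data.frame(e = rnorm(80))
  Y <- matrix(E$e + rnorm(80, 0, 0.3))
  # vegan flags the duplicated block as aliased, which is the point here
  vp0 <- suppressMessages(suppressWarnings(
    variance_partition(Y, E, data.frame(g = E$e), n_perm = 0)))
  fr <- as.data.frame(vp0)
  expect_lt(abs(fr$adj_r2[fr$fraction == "env_given_geo"]), 0.02)
  expect_lt(abs(fr$adj_r2[fr$fraction == "geo_given_env"]), 0.02)
  expect_equal(sum(fr$adj_r2), 1, tolerance = 1e-6)

  # generative oracle: Y = 1.0 E + 0.5 G + noise with E orthogonal to G
  set.seed(6)
  Q <- qr.Q(qr(matrix(rnorm(300 * 2), 300))) * sqrt(300)
  e <- Q[, 1]; g <- Q[, 2]
  noise <- stats::residuals(stats::lm(rnorm(300) ~ e + g))
  noise <- noise / stats::sd(noise)
  y <- 1.0 * e + 0.5 * g + 0.8 * noise
  share_e <- 1 / (1 + 0.25 + 0.64); share_g <- 0.25 / (1 + 0.25 + 0.64)
  vp <- variance_partition(matrix(y), data.frame(e = e), data.frame(g = g),
                           n_perm = 99, seed = 1)
  fr2 <- as.data.frame(vp)
  expect_equal(fr2$adj_r2[fr2$fraction == "env_given_geo"], share_e,
               tolerance = 0.05)
  expect_equal(fr2$adj_r2[fr2$fraction == "geo_given_env"], share_g,
               tolerance = 0.05)
  expect_equal(sum(fr2$adj_r2), 1, tolerance = 1e-6)
  expect_lt(fr2$p_value[1], 0.05)
})

test_that("IBE-dominant synthetic data yields a larger IBE than IBD fraction", {
  hits <- vapply(seq_len(20), function(i) {
    cfg <- sim_config(n_species = 10, inds_per_pop = 30, ibe_fraction = 0.4,
                      ibd_fraction = 0.1, seed = 500 + i)
    grp <- rep(paste0("p", 1:10), each = 30)
    eg <- gen_env_geo(cfg, grp)
    vp <- variance_partition(matrix(eg$env$env1),
                             data.frame(niche = eg$truth$components$group),
                             eg$geo[c("lon", "lat")], n_perm = 0)
    fr <- as.data.frame(vp)
    fr$adj_r2[fr$fraction == "env_given_geo"] >
      fr$adj_r2[fr$fraction == "geo_given_env"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
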