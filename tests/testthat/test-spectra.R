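test_that("splice correction inverts an injected multiplicative step", {
  wl <- seq(400, 2500, by = 3)
  base <- 0.2 + 0.0001 * (wl - 400)          # locally linear spectrum
  stepped <- base
  stepped[wl > 990] <- stepped[wl > 990] * 1.1
  stepped[wl > 1900] <- stepped[wl > 1900] * 0.95
  s <- spectra_set(rbind(stepped, stepped), wl)
  corr <- splice_correct(s)
  expect_lt(max(abs(corr$reflectance[1, ] - base)), 1e-9)
  expect_equal(corr$state, "spliced")

  # an already-continuous spectrum passes through unchanged
  cont <- spectra_set(rbind(base, base), wl)
  out <- splice_correct(cont)
  expect_lt(max(abs(out$reflectance - cont$reflectance)), 1e-9)
  expect_error(splice_correct(cont, joints = 100), "joint")
})

test_that("resampling is exact on linear spectra and matches an interpolation oracle", {
  wl <- seq(400, 700, by = 3)
  ramp <- 0.1 + 0.001 * (wl - 400)
  s <- spectra_set(matrix(ramp, 1), wl)
  expect_equal(resample_spectra(s, 3)$reflectance[1, ], ramp,
               tolerance = 1e-12, ignore_attr = TRUE)

  wl1 <- seq(400, 700, by = 1)
  sine <- 0.5 + 0.2 * sin(wl1 / 30)
  s1 <- spectra_set(matrix(sine, 1), wl1)
  r <- resample_spectra(s1, 3)
  # oracle: manual two-point interpolation at each target wavelength
  oracle <- vapply(r$wavelengths, function(x) {
    i <- findInterval(x, wl1)
    if (wl1[i] == x) return(sine[i])
    sine[i] + (sine[i + 1] - sine[i]) * (x - wl1[i]) / (wl1[i + 1] - wl1[i])
  }, numeric(1))
  expect_lt(max(abs(r$reflectance[1, ] - oracle)), 1e-9)
  expect_error(resample_spectra(s1, -1), "step")
})

test_that("the summed CWT is zero-mean, linear, and localizes absorption dips", {
  s <- resample_spectra(flat_spectra(0.5, n = 1), 3)
  w <- cwt_transform(s)
  expect_lt(max(abs(w$reflectance)), 1e-9)
  expect_equal(w$state, "cwt")
  expect_gte(min(w$wavelengths), 400)
  expect_lte(max(w$wavelengths), 2450)

  wl <- seq(400, 2500, by = 3)
  s1 <- 0.4 + 0.1 * sin(wl / 200)
  s2 <- 0.5 - 0.1 * exp(-((wl - 1450)^2) / (2 * 60^2))
  mk <- function(v) spectra_set(matrix(v, 1), wl, state = "resampled")
  lhs <- cwt_transform(mk(0.3 * s1 + 0.6 * s2))$reflectance
  rhs <- 0.3 * cwt_transform(mk(s1))$reflectance +
    0.6 * cwt_transform(mk(s2))$reflectance
  expect_lt(max(abs(lhs - rhs)), 1e-9)

  # dip localization against a dense convolution oracle coded independently
  dip <- 0.5 - 0.2 * exp(-((wl - 1450)^2) / (2 * 40^2))
  w2 <- cwt_transform(mk(dip))
  ext <- w2$wavelengths[which.max(abs(w2$reflectance[1, ]))]
  expect_lte(abs(ext - 1450), 3)
  oracle <- rep(0, length(wl))
  for (a in c(4, 16, 64)) {
    hw <- ceiling(6 * a)
    t <- (-hw):hw
    k <- (1 - (t / a)^2) * exp(-(t / a)^2 / 2)
    k <- k - mean(k); k <- k / sqrt(sum(k^2))
    padded <- c(dip[(hw + 1):2], dip, dip[(length(wl) - 1):(length(wl) - hw)])
    oracle <- oracle + vapply(seq_along(wl), function(b)
      sum(padded[b:(b + 2 * hw)] * k), numeric(1))
  }
  keep <- wl >= 400 & wl <= 2450
  expect_lt(max(abs(w2$reflectance[1, ] - oracle[keep])), 1e-9)
  short <- spectra_set(matrix(0.5, 1, 50), seq(400, 547, by = 3),
                       state = "resampled")
  expect_error(cwt_transform(short), "too few bands")
})

test_that("region slicing partitions the trimmed grid", {
  wl <- seq(400, 2450, by = 3)
  s <- spectra_set(matrix(0.5, 1, length(wl)), wl)
  vis <- region_slice(s, "VIS")
  expect_equal(length(vis$wavelengths), 100L)            # 400, 403, ..., 697
  expect_equal(range(vis$wavelengths), c(400, 697))
  nir <- region_slice(s, "NIR")
  swir <- region_slice(s, "SWIR")
  all_wl <- c(vis$wavelengths, nir$wavelengths, swir$wavelengths)
  expect_equal(sort(all_wl), wl)
  expect_equal(anyDuplicated(all_wl), 0L)
  tiny <- spectra_set(matrix(0.5, 1, 3), c(1300, 1400, 1500))
  expect_error(region_slice(tiny, "VIS"), "empty selection")
})

test_that("vegetation indices follow their band-ratio formulas", {
  flat <- flat_spectra(0.5, n = 1)
  idx <- vegetation_indices(flat)
  expect_equal(idx$CI, 1)
  expect_equal(idx$NDWI, 0)
  expect_equal(idx$ARI, 0)

  wl <- seq(400, 2500, by = 5)
  r <- rep(0.5, length(wl))
  r[which.min(abs(wl - 550))] <- 0.04
  r[which.min(abs(wl - 700))] <- 0.08
  r[which.min(abs(wl - 835))] <- 0.6
  r[which.min(abs(wl - 1610))] <- 0.2
  s <- spectra_set(matrix(r, 1), wl)
  idx2 <- vegetation_indices(s)
  expect_equal(idx2$ARI, 1 / 0.04 - 1 / 0.08)   # 12.5
  expect_equal(idx2$NDWI, (0.6 - 0.2) / (0.6 + 0.2))

  zero <- flat_spectra(0.5, n = 1)
  zero$reflectance[1, which.min(abs(zero$wavelengths - 550))] <- 0
  expect_warning(vegetation_indices(zero), "undefined index")
})

test_that("bandwise group summaries equal brute-force statistics", {
  set.seed(1)
  wl <- seq(400, 430, by = 3)
  m <- matrix(runif(6 * length(wl), 0.2, 0.8), 6)
  s <- spectra_set(m, wl)
  grp <- rep(c("a", "b"), each = 3)
  sm <- spectra_summary(s, grp)
  expect_equal(sm$mean[sm$group == "a" & sm$wavelength == 403],
               mean(m[1:3, 2]))
  expect_equal(sm$sd[sm$group == "b" & sm$wavelength == 400],
               stats::sd(m[4:6, 1]))
})

test_that("spectra round-trip through delimited text", {
  s <- flat_spectra(0.42, n = 3, wl = seq(400, 460, by = 3))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_spectra(s, p)
  s2 <- read_spectra(p)
  expect_equal(s2$reflectance, s$reflectance, tolerance = 1e-12)
  expect_equal(s2$wavelengths, s$wavelengths)
  expect_equal(s2$sample_ids, s$sample_ids)
})

test_that("state transitions are enforced", {
  s <- flat_spectra()
  expect_error(cwt_transform(s), "state")
  r <- resample_spectra(s)
  expect_error(splice_correct(r), "state")
  w <- cwt_transform(r)
  expect_error(vegetation_indices(w), "state")
})
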