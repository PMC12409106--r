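#' Spectral data container
#'
#' A `spectra_set` holds a samples-by-bands reflectance matrix together with
#' its wavelength grid (nm) and a preprocessing state. Raw reflectance values
#' are unitless fractions in \[0, 1\]; after the continuous wavelet transform
#' the values are signed coefficients. The state advances only along
#' `raw -> spliced -> resampled -> cwt`.
#'
#' @param reflectance Numeric matrix, one row per sample, one column per band.
#' @param wavelengths Strictly ascending numeric vector of band centres in nm.
#' @param sample_ids Character vector of sample identifiers (defaults to
#'   rownames of `reflectance` or `s1..sn`).
#' @param state Preprocessing state, one of `"raw"`, `"spliced"`,
#'   `"resampled"`, `"cwt"`.
#' @return An object of class `spectra_set`.
#' @examples
#' s <- spectra_set(matrix(0.5, 2, 3), c(400, 500, 600))
#' s
#' @export
spectra_set <- function(reflectance, wavelengths,
                        sample_ids = NULL,
                        state = c("raw", "spliced", "resampled", "cwt")) {
  state <- match.arg(state)
  reflectance <- as.matrix(reflectance)
  wavelengths <- as.numeric(wavelengths)
  .assert(ncol(reflectance) == length(wavelengths),
          "number of reflectance columns must equal number of wavelengths")
  .assert(all(diff(wavelengths) > 0), "wavelengths must be strictly ascending")
  if (state %in% c("raw", "spliced", "resampled")) {
    .assert(all(is.finite(reflectance)) &&
              min(reflectance) >= 0 && max(reflectance) <= 1,
            "raw reflectance must lie in [0, 1]")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(reflectance)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(reflectance)))
  }
  .assert(length(sample_ids) == nrow(reflectance),
          "one sample id per spectrum required")
  rownames(reflectance) <- sample_ids
  colnames(reflectance) <- format(wavelengths, trim = TRUE)
  structure(list(reflectance = reflectance,
                 wavelengths = wavelengths,
                 sample_ids = as.character(sample_ids),
                 state = state),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d bands (%.0f-%.0f nm), state: %s\n",
              nrow(x$reflectance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths), x$state))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$reflectance)

.state_rank <- c(raw = 1L, spliced = 2L, resampled = 3L, cwt = 4L)

.require_state <- function(s, allowed, op) {
  .assert(inherits(s, "spectra_set"), "input must be a spectra_set")
  .assert(s$state %in% allowed,
          sprintf("%s requires state in {%s}, got '%s'",
                  op, paste(allowed, collapse = ", "), s$state))
}

#' Correct detector-splice discontinuities
#'
#' Field spectroradiometers stitch several detectors; the stitch points leave
#' small step artifacts near the joint wavelengths. Each segment downstream of
#' a joint is multiplicatively rescaled so that its first band matches the
#' linear extrapolation of the two last upstream bands, which removes a
#' multiplicative step exactly when the spectrum is locally linear at the
#' joint.
#'
#' @param s A `spectra_set` in `raw` state.
#' @param joints Joint wavelengths in nm; defaults to the common 990 and
#'   1900 nm detector boundaries.
#' @return A `spectra_set` in `spliced` state.
#' @export
splice_correct <- function(s, joints = c(990, 1900)) {
  .require_state(s, "raw", "splice_correct")
  wl <- s$wavelengths
  .assert(all(joints > wl[2] & joints < wl[length(wl) - 1]),
          "each joint must lie strictly inside the wavelength grid")
  refl <- s$reflectance
  for (j in sort(joints)) {
    i <- max(which(wl <= j))
    .assert(i >= 2 && i < length(wl), "joint too close to the grid edge")
    # extrapolate upstream segment linearly to the first downstream band
    slope <- (refl[, i] - refl[, i - 1L]) / (wl[i] - wl[i - 1L])
    predicted <- refl[, i] + slope * (wl[i + 1L] - wl[i])
    observed <- refl[, i + 1L]
    fac <- ifelse(observed == 0, 1, predicted / observed)
    down <- (i + 1L):length(wl)
    refl[, down] <- refl[, down] * fac
  }
  refl[refl < 0] <- 0
  refl[refl > 1] <- 1
  spectra_set(refl, wl, s$sample_ids, state = "spliced")
}

#' Resample spectra onto a regular wavelength grid
#'
#' Linear interpolation onto an arithmetic grid with the requested spacing,
#' covering the input range.
#'
#' @param s A `spectra_set` in `raw` or `spliced` state.
#' @param step Grid spacing in nm (default 3).
#' @return A `spectra_set` in `resampled` state.
#' @export
resample_spectra <- function(s, step = 3) {
  .require_state(s, c("raw", "spliced"), "resample_spectra")
  .assert(is.numeric(step) && step > 0, "step must be positive")
  wl <- s$wavelengths
  grid <- seq(wl[1], wl[length(wl)], by = step)
  out <- t(apply(s$reflectance, 1L, function(r) {
    stats::approx(wl, r, xout = grid, method = "linear", rule = 2)$y
  }))
  spectra_set(out, grid, s$sample_ids, state = "resampled")
}

# L2-normalised second-derivative-of-Gaussian (Mexican hat) kernel at a
# given scale, sampled at integer band offsets.
.mexhat_kernel <- function(scale, half_width = ceiling(6 * scale)) {
  t <- (-half_width):half_width
  u <- t / scale
  k <- (1 - u^2) * exp(-u^2 / 2)
  k <- k - mean(k)             # enforce exact zero mean on the discrete grid
  k / sqrt(sum(k^2))
}

.reflect_pad <- function(x, m) {
  n <- length(x)
  .assert(m < n, "spectrum too short for the requested wavelet scale")
  c(x[(m + 1L):2L], x, x[(n - 1L):(n - m)])
}

#' Summed continuous wavelet transform of spectra
#'
#' Convolves each spectrum with a Mexican-hat (second derivative of Gaussian)
#' mother wavelet at dyadic scales `2^e` for each exponent in
#' `scale_exponents`, L2-normalising the kernel per scale, and sums the scale
#' layers bandwise. Edge effects are controlled by reflect padding. Bands
#' below 400 nm and above 2450 nm are trimmed from the output because
#' spectrometer edges are noise-dominated and transform artifacts accumulate
#' there.
#'
#' @param s A `spectra_set` in `resampled` state.
#' @param scale_exponents Integer exponents of the dyadic scales (default
#'   `c(2, 4, 6)`, i.e. scales 4, 16 and 64 bands).
#' @param trim Numeric length-2 vector, wavelength window retained after the
#'   transform (nm).
#' @return A `spectra_set` in `cwt` state holding summed wavelet coefficients.
#' @export
cwt_transform <- function(s, scale_exponents = c(2, 4, 6),
                          trim = c(400, 2450)) {
  .require_state(s, "resampled", "cwt_transform")
  .assert(length(scale_exponents) >= 1, "need at least one scale")
  scales <- 2^scale_exponents
  n <- length(s$wavelengths)
  max_half <- ceiling(6 * max(scales))
  .assert(n > max_half,
          "too few bands to support the largest wavelet scale")
  coef <- matrix(0, nrow(s$reflectance), n)
  for (a in scales) {
    k <- .mexhat_kernel(a)
    m <- (length(k) - 1L) / 2L
    for (i in seq_len(nrow(s$reflectance))) {
      padded <- .reflect_pad(s$reflectance[i, ], m)
      conv <- stats::filter(padded, rev(k), method = "convolution", sides = 2)
      coef[i, ] <- coef[i, ] + as.numeric(conv[(m + 1L):(m + n)])
    }
  }
  keep <- s$wavelengths >= trim[1] & s$wavelengths <= trim[2]
  .assert(any(keep), "trim window excludes every band")
  out <- spectra_set(matrix(0, nrow(coef), sum(keep)), s$wavelengths[keep],
                     s$sample_ids, state = "cwt")
  out$reflectance[] <- coef[, keep, drop = FALSE]
  rownames(out$reflectance) <- s$sample_ids
  out
}

#' Spectral region definitions
#'
#' Visible (VIS) 400-700 nm, near-infrared (NIR) 700-1200 nm, and short-wave
#' infrared (SWIR) 1200-2500 nm. Intervals are closed below and open above,
#' except SWIR which is closed at 2500 nm, so the three regions partition the
#' grid.
#' @export
spectral_regions <- function() {
  list(VIS = c(400, 700), NIR = c(700, 1200), SWIR = c(1200, 2500))
}

#' Restrict spectra to one spectral region
#'
#' @param s A `spectra_set` in any state.
#' @param region One of `"VIS"`, `"NIR"`, `"SWIR"`.
#' @return A `spectra_set` with the same state, restricted to the region.
#' @export
region_slice <- function(s, region = c("VIS", "NIR", "SWIR")) {
  region <- match.arg(region)
  .assert(inherits(s, "spectra_set"), "input must be a spectra_set")
  b <- spectral_regions()[[region]]
  keep <- if (region == "SWIR") {
    s$wavelengths >= b[1] & s$wavelengths <= b[2]
  } else {
    s$wavelengths >= b[1] & s$wavelengths < b[2]
  }
  if (!any(keep)) stop("empty selection: no bands fall in region ", region,
                       call. = FALSE)
  out <- s
  out$reflectance <- s$reflectance[, keep, drop = FALSE]
  out$wavelengths <- s$wavelengths[keep]
  out
}

#' Annotate wavelengths with their spectral region
#' @param wavelengths Numeric vector (nm).
#' @return Character vector of region labels.
#' @export
region_of <- function(wavelengths) {
  ifelse(wavelengths < 700, "VIS",
         ifelse(wavelengths < 1200, "NIR", "SWIR"))
}

.nearest_band <- function(s, target) {
  i <- which.min(abs(s$wavelengths - target))
  step <- stats::median(diff(s$wavelengths))
  .assert(abs(s$wavelengths[i] - target) <= step / 2 + 1e-9,
          sprintf("no band within half a grid step of %g nm", target))
  s$reflectance[, i]
}

#' Band-ratio vegetation indices
#'
#' Computes, per sample, the Chlorophyll Index Red Edge
#' `CI = R(750)/R(710)`, the Normalized Difference Water Index
#' `NDWI = (R(835) - R(1610)) / (R(835) + R(1610))`, and the Anthocyanin
#' Reflectance Index `ARI = 1/R(550) - 1/R(700)`. Index wavelengths are
#' resolved by nearest-band lookup within half a grid step.
#'
#' @param s A `spectra_set` in `raw`, `spliced` or `resampled` state.
#' @return A data.frame with columns `sample_id`, `CI`, `NDWI`, `ARI`.
#' @export
vegetation_indices <- function(s) {
  .require_state(s, c("raw", "spliced", "resampled"), "vegetation_indices")
  r550 <- .nearest_band(s, 550); r700 <- .nearest_band(s, 700)
  r710 <- .nearest_band(s, 710); r750 <- .nearest_band(s, 750)
  r835 <- .nearest_band(s, 835); r1610 <- .nearest_band(s, 1610)
  bad <- r550 == 0 | r700 == 0 | r710 == 0 | (r835 + r1610) == 0
  if (any(bad)) {
    warning("undefined index (zero reflectance at a required band) for: ",
            paste(s$sample_ids[bad], collapse = ", "))
  }
  data.frame(sample_id = s$sample_ids,
             CI = ifelse(r710 == 0, NA_real_, r750 / r710),
             NDWI = ifelse((r835 + r1610) == 0, NA_real_,
                           (r835 - r1610) / (r835 + r1610)),
             ARI = ifelse(r550 == 0 | r700 == 0, NA_real_,
                          1 / r550 - 1 / r700),
             row.names = NULL)
}

#' Read a delimited spectra matrix
#'
#' Expects a header row whose first field names the sample-id column and
#' whose remaining fields are wavelengths in nm; one row per sample.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @param state Preprocessing state of the stored spectra.
#' @return A `spectra_set`.
#' @export
read_spectra <- function(path, sep = "\t", state = "raw") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  wl <- as.numeric(colnames(df)[-1])
  spectra_set(m, wl, ids, state = state)
}

#' Write a spectra matrix as delimited text
#' @param s A `spectra_set`.
#' @param path File path.
#' @param sep Field separator (default tab).
#' @export
write_spectra <- function(s, path, sep = "\t") {
  df <- data.frame(sample_id = s$sample_ids, s$reflectance,
                   check.names = FALSE)
  colnames(df) <- c("sample_id", format(s$wavelengths, trim = TRUE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bandwise mean and standard deviation by group
#'
#' Summary used for spectra-by-species figures: per group, the mean and SD of
#' every band.
#'
#' @param s A `spectra_set`.
#' @param groups Group label per sample.
#' @return A long data.frame: group, wavelength, mean, sd.
#' @export
spectra_summary <- function(s, groups) {
  .assert(length(groups) == nrow(s$reflectance),
          "one group label per sample required")
  out <- do.call(rbind, lapply(split(seq_along(groups), groups), function(ix) {
    m <- s$reflectance[ix, , drop = FALSE]
    data.frame(group = groups[ix[1]], wavelength = s$wavelengths,
               mean = colMeans(m), sd = apply(m, 2, stats::sd))
  }))
  rownames(out) <- NULL
  out
}
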