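#' @keywords internal
"_PACKAGE"

# Fan a single user seed out into named per-stage substreams.  The order of
# `streams` is part of the contract: adding a stream at the end never
# perturbs the seeds of earlier streams.
#' Derive per-stage random seeds from one master seed
#'
#' A single pipeline seed is expanded into one reproducible integer seed per
#' named stage, so that every stochastic stage draws from its own substream
#' and adding a new stage never changes the draws of existing ones.
#'
#' @param seed Integer master seed.
#' @param streams Character vector of stage names, in canonical order.
#' @return Named integer vector of seeds, one per stream.
#' @examples
#' seed_streams(1, c("phylogeny", "genotypes"))
#' @export
seed_streams <- function(seed, streams) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(streams) >= 1L)
  # deterministic arithmetic stream derivation (no RNG state consumed), kept
  # strictly below 2^31 so the result is always a valid integer seed
  base <- as.double(seed) %% 2147483647
  idx <- seq_along(streams)
  out <- as.integer((base * 48271 + idx * 1664525) %% 2147483647)
  names(out) <- streams
  out
}

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# percentile bootstrap interval helper
.percentile_ci <- function(x, alpha = 0.05) {
  qs <- stats::quantile(x, probs = c(alpha / 2, 1 - alpha / 2),
                        na.rm = TRUE, names = FALSE, type = 7)
  c(low = qs[1], high = qs[2])
}
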