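#' Noise-corrupted oracle prediction tracks
#'
#' Turns reference labels into synthetic probability tracks, standing in for
#' a trained predictor so the decoder and metrics can be exercised at
#' controlled corruption levels.  Each row is the mixture
#' `(1 - noise) * one_hot + noise * uniform`; with `jitter > 0`, each base is
#' additionally replaced, independently with probability `jitter`, by a draw
#' from a symmetric Dirichlet distribution (concentration
#' `jitter_concentration`), which is what actually flips argmax calls and
#' degrades decoding.  At `noise = 0, jitter = 0` the output is exactly the
#' one-hot truth.
#'
#' @param truth A [labeled_tracks()] object.
#' @param noise Mixture weight of the uniform distribution, in `[0, 1]`.
#' @param seed Optional integer seed (required when `jitter > 0` for
#'   reproducibility).
#' @param jitter Per-base probability of replacing the row with a random
#'   distribution, in `[0, 1]`.
#' @param jitter_concentration Dirichlet concentration parameter for the
#'   replacement rows (values < 1 give spiky, confident-looking errors).
#' @return A [prediction_tracks()] object.
#' @export
oracle_predictor <- function(truth, noise = 0, seed = NULL, jitter = 0,
                             jitter_concentration = 0.5) {
  if (noise < 0 || noise > 1) stop("noise must lie in [0, 1]")
  if (jitter < 0 || jitter > 1) stop("jitter must lie in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  mix <- function(one_hot) (1 - noise) * one_hot + noise / 4
  cls <- mix(truth$class)
  phs <- mix(truth$phase)
  n <- nrow(cls)
  if (jitter > 0) {
    hit <- which(runif(n) < jitter)
    if (length(hit) > 0L) {
      cls[hit, ] <- .rdirichlet(length(hit), jitter_concentration)
      phs[hit, ] <- .rdirichlet(length(hit), jitter_concentration)
    }
  }
  prediction_tracks(cls, phs, contig = attr(truth, "contig"),
                    strand = attr(truth, "strand"), validate = FALSE)
}

## Symmetric Dirichlet(alpha, ..., alpha) draws via normalised gammas.
.rdirichlet <- function(n, alpha, k = 4L) {
  g <- matrix(rgamma(n * k, shape = alpha), nrow = n)
  ## guard against all-zero rows from tiny shape values
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- 1
  g / rowSums(g)
}
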