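#' Sliding-window prediction with mean-ensemble overlap combination
#'
#' Predicts on a sliding window of subsequences and combines overlapping
#' windows by averaging: each base's output distribution is the arithmetic
#' mean over all windows covering it.  The final window is anchored at the
#' sequence end so every base is covered; sequences shorter than the window
#' are zero-padded for prediction and trimmed afterwards.  Averages of
#' probability rows remain probability rows (renormalised only against
#' floating point drift).
#'
#' @param predictor A `toy_predictor` or any function mapping an encoding
#'   matrix to a list with `class` and `phase` probability matrices.
#' @param encoding Base-encoding matrix of the full sequence.
#' @param window Window length in bases.
#' @param stride Step between window starts; must not exceed `window`.
#'   Defaults to half the window.
#' @return A [prediction_tracks()] object covering the full sequence.
#' @export
predict_sliding <- function(predictor, encoding, window,
                            stride = window %/% 2L) {
  n <- nrow(encoding)
  window <- as.integer(window)
  stride <- as.integer(stride)
  if (stride > window) stop("stride must not exceed window")
  if (stride < 1L) stop("stride must be positive")
  run_one <- function(block) {
    if (inherits(predictor, "toy_predictor")) {
      out <- predict(predictor, block)
    } else {
      out <- predictor(block)
    }
    out
  }
  if (n <= window) {
    pad <- window - n
    block <- rbind(encoding, matrix(0, nrow = pad, ncol = ncol(encoding)))
    out <- run_one(block)
    return(prediction_tracks(.renorm(out$class[seq_len(n), , drop = FALSE]),
                             .renorm(out$phase[seq_len(n), , drop = FALSE]),
                             validate = FALSE))
  }
  starts <- seq(0L, n - window, by = stride)
  if (tail(starts, 1L) != n - window) starts <- c(starts, n - window)
  cls_sum <- matrix(0, n, 4L)
  phs_sum <- matrix(0, n, 4L)
  cover <- numeric(n)
  for (s in starts) {
    idx <- (s + 1L):(s + window)
    out <- run_one(encoding[idx, , drop = FALSE])
    cls_sum[idx, ] <- cls_sum[idx, ] + out$class
    phs_sum[idx, ] <- phs_sum[idx, ] + out$phase
    cover[idx] <- cover[idx] + 1
  }
  prediction_tracks(.renorm(cls_sum / cover), .renorm(phs_sum / cover),
                    validate = FALSE)
}

.renorm <- function(m) {
  s <- rowSums(m)
  s[s == 0] <- 1
  m / s
}
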