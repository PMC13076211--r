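#' Subsequence window length configuration
#'
#' Fixed window lengths used when slicing contigs into model-sized
#' subsequences: 21,384 bases for training, and the longer inference windows
#' of 106,920 bases for the plant profile and 213,840 bases for the animal
#' (vertebrate/invertebrate) profile.  Inference lengths must be integer
#' multiples of the training length.
#'
#' @param train_length,inference_length_plant,inference_length_animal Window
#'   lengths in bases.
#' @return Object of class `chunk_config`.
#' @export
chunk_config <- function(train_length = 21384L,
                         inference_length_plant = 106920L,
                         inference_length_animal = 213840L) {
  cfg <- list(train_length = as.integer(train_length),
              inference_length_plant = as.integer(inference_length_plant),
              inference_length_animal = as.integer(inference_length_animal))
  if (cfg$inference_length_plant %% cfg$train_length != 0L ||
      cfg$inference_length_animal %% cfg$train_length != 0L) {
    stop("inference lengths must be integer multiples of train_length")
  }
  structure(cfg, class = "chunk_config")
}

#' Window length for a chunking mode
#' @param cfg A [chunk_config()].
#' @param mode One of `"train"`, `"inference_plant"`, `"inference_animal"`.
#' @export
window_length_for <- function(cfg, mode = c("train", "inference_plant",
                                            "inference_animal")) {
  mode <- match.arg(mode)
  switch(mode,
         train = cfg$train_length,
         inference_plant = cfg$inference_length_plant,
         inference_animal = cfg$inference_length_animal)
}

#' Slice per-base tracks into fixed-length windows
#'
#' Tiles a contig's tracks into consecutive windows of exactly the configured
#' length, zero-padding the final window where the contig is shorter; padded
#' positions are recorded in `pad_mask` and, for labeled tracks, also added
#' to the loss/metric mask.  Concatenating the unpadded positions of the
#' windows in order reconstructs the input (see [unchunk()]).
#'
#' @param x A [labeled_tracks()], [prediction_tracks()] or a plain numeric
#'   matrix (e.g. a base encoding) with one row per base.
#' @param cfg A [chunk_config()].
#' @param mode Window-length profile; see [window_length_for()].
#' @param contig,strand Provenance for window origins (defaults taken from
#'   `x` attributes when present).
#' @return Object of class `subsequence_batch`: a list with `windows` (each a
#'   slice of `x`, padded), `pad_mask` (logical per window), `origin`
#'   (data.frame of contig, start, strand) and `window_length`.
#' @export
chunk <- function(x, cfg = chunk_config(), mode = "train",
                  contig = NULL, strand = NULL) {
  w <- window_length_for(cfg, mode)
  if (is.null(contig)) contig <- attr(x, "contig") %||% NA_character_
  if (is.null(strand)) strand <- attr(x, "strand") %||% "+"
  n <- if (is.matrix(x)) nrow(x) else nrow(x$class)
  if (n == 0L) {
    return(structure(list(windows = list(), pad_mask = list(),
                          origin = data.frame(contig = character(0),
                                              start = integer(0),
                                              strand = character(0)),
                          window_length = w),
                     class = "subsequence_batch"))
  }
  n_windows <- ceiling(n / w)
  windows <- vector("list", n_windows)
  pads <- vector("list", n_windows)
  starts <- (seq_len(n_windows) - 1L) * w
  for (k in seq_len(n_windows)) {
    lo <- starts[k] + 1L
    hi <- min(starts[k] + w, n)
    n_real <- hi - lo + 1L
    pad <- c(rep(FALSE, n_real), rep(TRUE, w - n_real))
    windows[[k]] <- .slice_padded(x, lo, hi, w)
    pads[[k]] <- pad
  }
  structure(list(windows = windows, pad_mask = pads,
                 origin = data.frame(contig = contig, start = starts,
                                     strand = strand,
                                     stringsAsFactors = FALSE),
                 window_length = w),
            class = "subsequence_batch")
}

.slice_padded <- function(x, lo, hi, w) {
  n_real <- hi - lo + 1L
  pad_rows <- w - n_real
  pad_block <- function(m) {
    out <- m[lo:hi, , drop = FALSE]
    if (pad_rows > 0L) {
      out <- rbind(out, matrix(0, nrow = pad_rows, ncol = ncol(m)))
    }
    out
  }
  if (is.matrix(x)) return(pad_block(x))
  if (inherits(x, "labeled_tracks")) {
    mask <- c(x$mask[lo:hi], rep(TRUE, pad_rows))
    return(labeled_tracks(pad_block(x$class), pad_block(x$phase), mask,
                          contig = attr(x, "contig"),
                          strand = attr(x, "strand")))
  }
  if (inherits(x, "prediction_tracks")) {
    return(structure(list(class = pad_block(x$class),
                          phase = pad_block(x$phase)),
                     contig = attr(x, "contig"), strand = attr(x, "strand"),
                     class = "prediction_tracks"))
  }
  stop("unsupported input to chunk()")
}

#' Reassemble chunked tracks
#'
#' Drops padded positions and concatenates windows in order; the inverse of
#' [chunk()] for a single contig.
#'
#' @param batch A `subsequence_batch`.
#' @return An object of the same type that was chunked.
#' @export
unchunk <- function(batch) {
  stopifnot(inherits(batch, "subsequence_batch"))
  if (length(batch$windows) == 0L) stop("empty batch")
  pieces <- Map(function(win, pad) {
    keep <- which(!pad)
    if (is.matrix(win)) return(win[keep, , drop = FALSE])
    if (inherits(win, "labeled_tracks")) {
      return(labeled_tracks(win$class[keep, , drop = FALSE],
                            win$phase[keep, , drop = FALSE],
                            win$mask[keep],
                            contig = attr(win, "contig"),
                            strand = attr(win, "strand")))
    }
    structure(list(class = win$class[keep, , drop = FALSE],
                   phase = win$phase[keep, , drop = FALSE]),
              contig = attr(win, "contig"), strand = attr(win, "strand"),
              class = "prediction_tracks")
  }, batch$windows, batch$pad_mask)
  first <- pieces[[1L]]
  if (is.matrix(first)) return(do.call(rbind, pieces))
  cls <- do.call(rbind, lapply(pieces, `[[`, "class"))
  phs <- do.call(rbind, lapply(pieces, `[[`, "phase"))
  if (inherits(first, "labeled_tracks")) {
    mask <- do.call(c, lapply(pieces, `[[`, "mask"))
    return(labeled_tracks(cls, phs, mask, contig = attr(first, "contig"),
                          strand = attr(first, "strand")))
  }
  structure(list(class = cls, phase = phs),
            contig = attr(first, "contig"), strand = attr(first, "strand"),
            class = "prediction_tracks")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of padded bases in a batch
#' @param batch A `subsequence_batch`.
#' @export
n_padded <- function(batch) {
  sum(vapply(batch$pad_mask, sum, numeric(1)))
}
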