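#' Find candidate genic regions
#'
#' Slides a window of `intergenic_window` bases over the intergenic
#' probability track and returns the maximal intervals where the windowed
#' moving average stays below `intergenic_threshold`.  Near contig edges the
#' window shrinks to the available bases.  Intervals separated by fewer than
#' `intergenic_window` bases are merged.
#'
#' @param tracks A [prediction_tracks()] object for one contig strand.
#' @param params A [penalty_params()].
#' @return Two-column integer matrix of `[start, end)` intervals (0-based
#'   half-open, strand-local coordinates), disjoint and sorted.
#' @export
find_candidate_regions <- function(tracks, params = penalty_params()) {
  p_ig <- tracks$class[, 1L]
  n <- length(p_ig)
  w <- min(params$intergenic_window, n)
  h1 <- (w - 1L) %/% 2L
  h2 <- w - 1L - h1
  cs <- c(0, cumsum(p_ig))
  lo <- pmax(seq_len(n) - h1, 1L)
  hi <- pmin(seq_len(n) + h2, n)
  avg <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  low <- avg < params$intergenic_threshold
  if (!any(low)) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values] - 1L, ends[r$values])  # 0-based half-open
  merged <- .merge_intervals(iv, gap = params$intergenic_window)
  dimnames(merged) <- list(NULL, c("start", "end"))
  merged
}

## merge sorted intervals whose separation is smaller than `gap`
.merge_intervals <- function(iv, gap = 0L) {
  if (nrow(iv) <= 1L) return(iv)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (i in 2L:nrow(iv)) {
    if (iv[i, 1L] - out[nrow(out), 2L] < gap) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], iv[i, 2L])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Decode one candidate region into gene models
#'
#' Runs the minimum-penalty dynamic program over the region's bases and
#' parses the optimal state path into zero or more gene models.  The path is
#' constrained to start and end in the intergenic state; a region with no
#' finite-penalty path (or whose best path never leaves intergenic) yields
#' zero genes.  Decoded genes with a total CDS shorter than
#' `params$min_cds_length` are discarded.  Ties are broken deterministically
#' (intergenic-first state order).
#'
#' @param region Integer vector `c(start, end)`, 0-based half-open, in the
#'   same strand-local coordinates as `tracks` and `seq`.
#' @param tracks A [prediction_tracks()] object for the whole contig strand.
#' @param seq The contig sequence (strand-local, i.e. reverse-complemented
#'   for the minus strand) as a character string.
#' @param params A [penalty_params()].
#' @param space Optional pre-built [build_state_space()].
#' @param contig,strand Recorded on the returned models.
#' @return List of [gene_model()] objects in strand-local coordinates.
#' @export
decode_region <- function(region, tracks, seq, params = penalty_params(),
                          space = build_state_space(params),
                          contig = NA_character_, strand = "+") {
  start0 <- as.integer(region[[1L]])
  end0 <- as.integer(region[[2L]])
  stopifnot(end0 > start0, start0 >= 0L, end0 <= nrow(tracks$class))
  idx <- (start0 + 1L):end0
  eps <- params$emission_floor
  clpen <- -log(pmax(tracks$class[idx, , drop = FALSE], eps))
  phpen <- -log(pmax(tracks$phase[idx, , drop = FALSE], eps))
  chars <- .as_base_chars(substr(seq, start0 + 1L, end0))
  kindpen <- kind_penalty_matrix(chars, params)
  st <- space$states
  ig <- st$id[st$name == "IG"] - 1L
  res <- viterbi_min_path(
    tr_from = space$transitions$from - 1L,
    tr_to = space$transitions$to - 1L,
    tr_kind = space$transitions$kind_idx - 1L,
    clpen = clpen, phpen = phpen, kindpen = kindpen,
    state_class = st$class_idx - 1L,
    state_phase = ifelse(is.na(st$phase_idx), -1L, st$phase_idx - 1L),
    init_state = ig, final_state = ig
  )
  if (!is.finite(res$cost)) return(list())
  .parse_state_path(res$path + 1L, space, offset = start0,
                    contig = contig, min_cds = params$min_cds_length)
}

## Turn a decoded state path (1-based state ids, local positions) into gene
## models with 0-based half-open intervals offset into contig coordinates.
.parse_state_path <- function(path, space, offset, contig, min_cds) {
  types <- space$states$type[path]
  genic <- types != "ig"
  if (!any(genic)) return(list())
  r <- rle(genic)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  models <- list()
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    seg <- types[a:b]
    exonic <- seg != "intron"
    er <- rle(exonic)
    e_ends <- cumsum(er$lengths)
    e_starts <- e_ends - er$lengths + 1L
    exons <- cbind(a + e_starts[er$values] - 1L,
                   a + e_ends[er$values]) - 1L + offset
    cds_mask <- seg == "cds"
    cr <- rle(cds_mask)
    c_ends <- cumsum(cr$lengths)
    c_starts <- c_ends - cr$lengths + 1L
    if (!any(cr$values)) next
    cds <- cbind(a + c_starts[cr$values] - 1L,
                 a + c_ends[cr$values]) - 1L + offset
    ## models are built in strand-local (plus) orientation; decode_genome
    ## mirrors minus-strand results back to forward coordinates
    gm <- gene_model("pending", contig, "+", exons, cds)
    if (total_cds_length(gm) < min_cds) next
    models[[length(models) + 1L]] <- gm
  }
  models
}

#' Decode a whole genome from per-strand probability tracks
#'
#' For every contig, finds candidate genic regions on each strand and
#' decodes them independently: the minus strand is processed on the reverse
#' complement (with tracks already in reverse-complement orientation) and
#' the resulting models are mapped back to forward genomic coordinates.
#' Gene ids are assigned stably by genomic order.
#'
#' @param tracks Named list, one entry per contig, each a list with `plus`
#'   and `minus` [prediction_tracks()] in strand-local orientation (as
#'   produced by [reference_tracks()] plus [corrupt_tracks()]).
#' @param sequences Named character vector of contig sequences (forward
#'   orientation).
#' @param params A [penalty_params()].
#' @param space Optional pre-built [build_state_space()].
#' @return An [annotation_set()].
#' @export
decode_genome <- function(tracks, sequences, params = penalty_params(),
                          space = build_state_space(params)) {
  if (!setequal(names(tracks), names(sequences))) {
    stop("contig names of tracks and sequences do not match")
  }
  models <- list()
  for (contig in names(sequences)) {
    seq_fwd <- toupper(sequences[[contig]])
    L <- nchar(seq_fwd)
    for (strand in c("+", "-")) {
      tr <- tracks[[contig]][[if (strand == "+") "plus" else "minus"]]
      if (is.null(tr)) next
      if (nrow(tr$class) != L) {
        stop(sprintf("track length (%d) does not match contig %s (%d)",
                     nrow(tr$class), contig, L))
      }
      seq_local <- if (strand == "-") revcomp(seq_fwd) else seq_fwd
      regions <- find_candidate_regions(tr, params)
      if (nrow(regions) == 0L) next
      ## pad regions so the path can open and close in intergenic state
      pad <- params$intergenic_window %/% 2L
      regions[, 1L] <- pmax(regions[, 1L] - pad, 0L)
      regions[, 2L] <- pmin(regions[, 2L] + pad, L)
      regions <- .merge_intervals(regions, gap = 1L)
      for (ri in seq_len(nrow(regions))) {
        found <- decode_region(regions[ri, ], tr, seq_local, params, space,
                               contig = contig, strand = strand)
        if (strand == "-") {
          found <- lapply(found, flip_gene_model, contig_length = L)
        }
        models <- c(models, found)
      }
    }
  }
  ann <- annotation_set(models, stats::setNames(nchar(sequences),
                                                names(sequences)))
  for (i in seq_along(ann$models)) {
    ann$models[[i]]$gene_id <- sprintf("gene_%04d", i)
  }
  ann
}
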