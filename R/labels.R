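#' Construct labeled per-base tracks
#'
#' Container for the reference labels of one contig strand: a one-hot genic
#' class track over \{intergenic, UTR, CDS, intron\}, a one-hot coding-phase
#' track over \{none, 0, 1, 2\} and a logical mask (`TRUE` = excluded from
#' loss and metrics).
#'
#' @param class_mat,phase_mat Numeric `n x 4` matrices.
#' @param mask Logical vector of length `n`.
#' @param contig,strand Provenance attributes.
#' @return Object of class `labeled_tracks`.
#' @export
labeled_tracks <- function(class_mat, phase_mat, mask = NULL,
                           contig = NA_character_, strand = "+") {
  n <- nrow(class_mat)
  stopifnot(ncol(class_mat) == 4L, ncol(phase_mat) == 4L,
            nrow(phase_mat) == n)
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(length(mask) == n)
  colnames(class_mat) <- GENIC_CLASSES
  colnames(phase_mat) <- PHASE_CLASSES
  structure(list(class = class_mat, phase = phase_mat, mask = as.logical(mask)),
            contig = contig, strand = strand, class = "labeled_tracks")
}

#' Construct per-base prediction tracks
#'
#' Container for predicted per-base probability distributions: one row per
#' base for the genic class head and the coding phase head.  Every row must
#' be a probability distribution.
#'
#' @param class_probs,phase_probs Numeric `n x 4` matrices of row-wise
#'   probability distributions.
#' @param contig,strand Provenance attributes.
#' @param validate Check the row-distribution invariant (default `TRUE`).
#' @return Object of class `prediction_tracks`.
#' @export
prediction_tracks <- function(class_probs, phase_probs,
                              contig = NA_character_, strand = "+",
                              validate = TRUE) {
  stopifnot(ncol(class_probs) == 4L, ncol(phase_probs) == 4L,
            nrow(class_probs) == nrow(phase_probs))
  if (validate) {
    .check_distribution_rows(class_probs, "class_probs")
    .check_distribution_rows(phase_probs, "phase_probs")
  }
  colnames(class_probs) <- GENIC_CLASSES
  colnames(phase_probs) <- PHASE_CLASSES
  structure(list(class = class_probs, phase = phase_probs),
            contig = contig, strand = strand, class = "prediction_tracks")
}

.check_distribution_rows <- function(m, what, tol = 1e-6) {
  if (any(m < -tol)) stop(what, ": negative probabilities")
  bad <- abs(rowSums(m) - 1) > tol
  if (any(bad)) {
    stop(sprintf("%s: row %d does not sum to 1", what, which(bad)[1L]))
  }
  invisible(TRUE)
}

#' @export
print.labeled_tracks <- function(x, ...) {
  cat(sprintf("<labeled_tracks> %s (%s), %d bases, %d masked\n",
              attr(x, "contig"), attr(x, "strand"), nrow(x$class),
              sum(x$mask)))
  invisible(x)
}

#' @export
print.prediction_tracks <- function(x, ...) {
  cat(sprintf("<prediction_tracks> %s (%s), %d bases\n",
              attr(x, "contig"), attr(x, "strand"), nrow(x$class)))
  invisible(x)
}

#' Label every base of a contig strand from gene models
#'
#' Produces one-hot genic class and coding phase tracks for one strand of a
#' contig.  Bases covered by no transcript are intergenic; exonic bases
#' outside the CDS are UTR; CDS bases carry their coding phase (the number of
#' bases until the start of the next codon, giving the cycle 0, 2, 1 across a
#' codon); intronic bases are intron with phase "none".
#'
#' Each strand is processed as an independent sequence: only models on
#' `strand` contribute, and for the minus strand both models and coordinates
#' are mirrored into reverse-complement space, so the returned tracks read 5'
#' to 3' along that strand.  Same-strand overlapping models are not resolved
#' here (later models overwrite earlier ones base-wise); they are flagged by
#' [flag_errors()].
#'
#' @param models List of [gene_model()] objects (any strand; filtered).
#' @param seq Contig sequence as a character string (defines the length).
#' @param strand Which strand to label, `"+"` or `"-"`.
#' @param contig Contig name recorded in the result.
#' @return A [labeled_tracks()] object with an all-`FALSE` mask.
#' @export
label_bases <- function(models, seq, strand = c("+", "-"),
                        contig = NA_character_) {
  strand <- match.arg(strand)
  L <- nchar(seq)
  local <- .models_in_local_coords(models, strand, L)
  for (gm in local) {
    if (gene_span(gm)[1L] < 0L || gene_span(gm)[2L] > L) {
      stop(sprintf("gene model %s lies outside contig bounds", gm$gene_id))
    }
  }
  cls <- rep(1L, L)   # intergenic
  phs <- rep(1L, L)   # none
  for (gm in local) {
    span <- gene_span(gm)
    cls[(span[1L] + 1L):span[2L]] <- 4L            # intron fills the span
    for (i in seq_len(nrow(gm$exons))) {
      cls[(gm$exons[i, 1L] + 1L):gm$exons[i, 2L]] <- 2L  # utr
    }
    cds_pos <- integer(0)
    for (i in seq_len(nrow(gm$cds))) {
      cds_pos <- c(cds_pos, (gm$cds[i, 1L] + 1L):gm$cds[i, 2L])
    }
    if (length(cds_pos) > 0L) {
      cls[cds_pos] <- 3L
      codon_pos <- (seq_along(cds_pos) - 1L) %% 3L
      phs[cds_pos] <- PHASE_OF_CODON_POS[codon_pos + 1L] + 2L
    }
  }
  class_mat <- matrix(0, nrow = L, ncol = 4L)
  class_mat[cbind(seq_len(L), cls)] <- 1
  phase_mat <- matrix(0, nrow = L, ncol = 4L)
  phase_mat[cbind(seq_len(L), phs)] <- 1
  labeled_tracks(class_mat, phase_mat, contig = contig, strand = strand)
}

## Filter models to one strand and, for "-", mirror them into
## reverse-complement coordinates where they read as plus-strand models.
.models_in_local_coords <- function(models, strand, L) {
  sel <- Filter(function(gm) gm$strand == strand, models)
  if (strand == "-") sel <- lapply(sel, flip_gene_model, contig_length = L)
  sel
}

#' Mask bases of erroneous or conflicting gene models
#'
#' Identifies partial and conflicting gene models and returns a per-base
#' logical mask (in the same strand-local coordinates as [label_bases()])
#' marking every base that must be excluded from loss and metric
#' calculations.  A model is partial when its CDS is missing the start codon
#' and/or stop codon, its CDS length is not divisible by 3, or the model is
#' truncated by a contig edge; all bases of its span are masked.  For
#' same-strand models whose spans overlap, the overlapping region is masked.
#'
#' @inheritParams label_bases
#' @return Logical vector of length `nchar(seq)`; `TRUE` = masked.
#' @export
flag_errors <- function(models, seq, strand = c("+", "-")) {
  strand <- match.arg(strand)
  L <- nchar(seq)
  seq_local <- if (strand == "-") revcomp(seq) else toupper(seq)
  local <- .models_in_local_coords(models, strand, L)
  mask <- rep(FALSE, L)
  spans <- matrix(integer(0), ncol = 2L)
  for (gm in local) {
    span <- gene_span(gm)
    truncated <- span[1L] < 0L || span[2L] > L
    bad <- truncated
    if (!truncated) {
      cds_len <- total_cds_length(gm)
      if (cds_len == 0L || cds_len %% 3L != 0L) {
        bad <- TRUE
      } else {
        cds_seq <- spliced_cds(gm, seq_local)
        last <- substr(cds_seq, nchar(cds_seq) - 2L, nchar(cds_seq))
        if (substr(cds_seq, 1L, 3L) != "ATG" || !last %in% STOP_CODONS) {
          bad <- TRUE
        }
      }
    }
    if (bad) {
      lo <- max(span[1L], 0L); hi <- min(span[2L], L)
      if (hi > lo) mask[(lo + 1L):hi] <- TRUE
    }
    spans <- rbind(spans, pmin(pmax(span, 0L), L))
  }
  if (nrow(spans) > 1L) {
    for (i in seq_len(nrow(spans) - 1L)) {
      for (j in (i + 1L):nrow(spans)) {
        lo <- max(spans[i, 1L], spans[j, 1L])
        hi <- min(spans[i, 2L], spans[j, 2L])
        if (hi > lo) mask[(lo + 1L):hi] <- TRUE
      }
    }
  }
  mask
}
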