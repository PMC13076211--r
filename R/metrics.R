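#' Base-wise confusion matrix
#'
#' Counts true class against predicted class over the bases that are neither
#' masked nor padding (the mask carries both).  Classes are taken from the
#' requested track: the four genic classes or the four phase classes.
#'
#' @param pred Predicted classes: a [prediction_tracks()] object, a
#'   probability matrix (argmax is taken), or an integer vector of class
#'   indices.
#' @param truth A [labeled_tracks()] object.
#' @param track `"class"` or `"phase"`.
#' @return Integer `4 x 4` matrix, true classes as rows.
#' @export
confusion <- function(pred, truth, track = c("class", "phase")) {
  track <- match.arg(track)
  labels <- if (track == "class") GENIC_CLASSES else PHASE_CLASSES
  truth_idx <- max.col(truth[[track]], ties.method = "first")
  pred_idx <- .as_class_indices(pred, track)
  if (length(pred_idx) != length(truth_idx)) {
    stop("prediction and truth lengths differ")
  }
  keep <- !truth$mask
  cm <- table(factor(truth_idx[keep], levels = 1:4),
              factor(pred_idx[keep], levels = 1:4))
  cm <- matrix(as.integer(cm), 4L, 4L, dimnames = list(labels, labels))
  cm
}

.as_class_indices <- function(pred, track) {
  if (inherits(pred, "prediction_tracks")) pred <- pred[[track]]
  if (is.matrix(pred)) return(max.col(pred, ties.method = "first"))
  as.integer(pred)
}

#' Precision, recall and F1 from a confusion matrix
#'
#' Computes per-class precision `TP / (TP + FP)`, recall `TP / (TP + FN)`
#' and `F1 = 2 * precision * recall / (precision + recall)`, plus the
#' support-weighted aggregates used for gene prediction: genic F1 (weighted
#' over UTR, CDS and intron), subgenic F1 (CDS and intron) and phase F1
#' (phases 0, 1 and 2), whichever apply to the matrix's class names.
#' Classes with empty support (or an undefined ratio) score 0 and are
#' flagged.
#'
#' @param cm Square confusion matrix with named dimensions (true classes as
#'   rows).
#' @return Object of class `f1_report`: a list with `per_class` (data frame)
#'   and, when applicable, `genic_f1`, `subgenic_f1`, `phase_f1`.
#' @export
f1_scores <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  classes <- rownames(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  support <- rowSums(cm)
  per_class <- data.frame(class = classes, precision = precision,
                          recall = recall, f1 = f1,
                          support = as.integer(support),
                          empty_support = support == 0,
                          row.names = NULL, stringsAsFactors = FALSE)
  weighted <- function(sel) {
    sel <- intersect(sel, classes)
    if (length(sel) == 0L) return(NULL)
    i <- match(sel, classes)
    if (sum(support[i]) == 0) return(0)
    sum(f1[i] * support[i]) / sum(support[i])
  }
  out <- list(per_class = per_class,
              genic_f1 = weighted(c("utr", "cds", "intron")),
              subgenic_f1 = weighted(c("cds", "intron")),
              phase_f1 = weighted(c("phase0", "phase1", "phase2")))
  structure(out[!vapply(out, is.null, logical(1L))], class = "f1_report")
}

#' @export
print.f1_report <- function(x, ...) {
  print(x$per_class, digits = 4)
  for (nm in c("genic_f1", "subgenic_f1", "phase_f1")) {
    if (!is.null(x[[nm]])) cat(sprintf("%s: %.4f\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Full base-wise F1 summary for a prediction
#'
#' Convenience wrapper computing the class and phase confusion matrices and
#' the genic, subgenic and phase F1 aggregates in one call.
#'
#' @param pred A [prediction_tracks()] object.
#' @param truth A [labeled_tracks()] object.
#' @return List with `genic_f1`, `subgenic_f1`, `phase_f1`, `class_report`
#'   and `phase_report`.
#' @export
f1_summary <- function(pred, truth) {
  cls <- f1_scores(confusion(pred, truth, "class"))
  phs <- f1_scores(confusion(pred, truth, "phase"))
  list(genic_f1 = cls$genic_f1, subgenic_f1 = cls$subgenic_f1,
       phase_f1 = phs$phase_f1, class_report = cls, phase_report = phs)
}

#' Draw a random evaluation subset of subsequences
#'
#' Samples `n` windows without replacement (all windows when fewer are
#' available); used to evaluate training and validation genomes on a random
#' sample of 800 subsequences.
#'
#' @param batch A `subsequence_batch` (see [chunk()]).
#' @param n Number of windows to draw.
#' @param seed Integer seed.
#' @return Integer vector of window indices.
#' @export
sample_subsequences <- function(batch, n = 800L, seed = 1L) {
  n_avail <- length(batch$windows)
  if (n_avail < 1L) stop("batch contains no windows")
  set.seed(as.integer(seed))
  sort(sample.int(n_avail, min(as.integer(n), n_avail)))
}

#' F1 restricted to bases adjacent to class transitions
#'
#' Evaluates only the unmasked bases lying within `radius` bases of a true
#' genic-class change (that many bases on each side of each boundary), the
#' regions where prediction sharpness matters most.
#'
#' @param pred A [prediction_tracks()] object (or class indices/probability
#'   matrix).
#' @param truth A [labeled_tracks()] object.
#' @param radius Number of bases on each side of a boundary.
#' @return An `f1_report` with attribute `n_evaluated`; when the truth has
#'   no transitions the report carries attribute `empty = TRUE`.
#' @export
transition_adjacent_f1 <- function(pred, truth, radius = 3L) {
  stopifnot(radius >= 1L)
  cls <- max.col(truth$class, ties.method = "first")
  n <- length(cls)
  boundary <- which(cls[-1L] != cls[-n]) + 1L  # first base of new segment
  adj <- rep(FALSE, n)
  for (i in boundary) {
    adj[max(1L, i - radius):min(n, i + radius - 1L)] <- TRUE
  }
  eval_mask <- adj & !truth$mask
  if (!any(eval_mask)) {
    rep0 <- f1_scores(matrix(0L, 4L, 4L,
                             dimnames = list(GENIC_CLASSES, GENIC_CLASSES)))
    attr(rep0, "empty") <- TRUE
    attr(rep0, "n_evaluated") <- 0L
    return(rep0)
  }
  sub_truth <- labeled_tracks(truth$class[eval_mask, , drop = FALSE],
                              truth$phase[eval_mask, , drop = FALSE])
  pred_idx <- .as_class_indices(pred, "class")[eval_mask]
  rep <- f1_scores(confusion(pred_idx, sub_truth, "class"))
  attr(rep, "empty") <- FALSE
  attr(rep, "n_evaluated") <- sum(eval_mask)
  rep
}

## CDS-bounded exon intervals (UTRs stripped) per model, transcript order
.cds_exons <- function(gm) {
  gm$cds
}

.feature_keys <- function(models, level) {
  keys <- character(0)
  for (gm in models) {
    cds <- .cds_exons(gm)
    if (nrow(cds) == 0L) next
    pre <- paste0(gm$contig, ":", gm$strand, ":")
    if (level == "exon") {
      keys <- c(keys, paste0(pre, cds[, 1L], "-", cds[, 2L]))
    } else if (level == "intron") {
      if (nrow(cds) > 1L) {
        keys <- c(keys, paste0(pre, cds[-nrow(cds), 2L], "-", cds[-1L, 1L]))
      }
    } else if (level == "intron_chain") {
      if (nrow(cds) > 1L) {
        chain <- paste(cds[-nrow(cds), 2L], cds[-1L, 1L], sep = "-",
                       collapse = ",")
        keys <- c(keys, paste0(pre, chain))
      }
    } else if (level == "transcript") {
      chain <- if (nrow(cds) > 1L) {
        paste(cds[-nrow(cds), 2L], cds[-1L, 1L], sep = "-", collapse = ",")
      } else ""
      keys <- c(keys, paste0(pre, min(cds[, 1L]), "..", max(cds[, 2L]),
                             "|", chain))
    }
  }
  unique(keys)
}

#' Feature-level exact-match evaluation
#'
#' Compares predicted against reference annotations by precise coordinate
#' match at the exon, intron, intron chain or transcript level, on primary
#' transcripts with all UTRs removed (features are the CDS-bounded exons).
#' A feature counts as a true positive only when its coordinates (and
#' strand) match exactly; an intron chain matches only when the whole
#' ordered intron list is identical; a transcript matches when its intron
#' chain and its CDS start and end all match.
#'
#' @param pred,ref [annotation_set()] objects (or lists of gene models).
#' @param level One of `"exon"`, `"intron"`, `"intron_chain"`,
#'   `"transcript"`, or `"all"` for every level at once.
#' @return Data frame with columns `level`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
feature_match <- function(pred, ref,
                          level = c("all", "exon", "intron", "intron_chain",
                                    "transcript")) {
  level <- match.arg(level)
  levels <- if (level == "all") {
    c("exon", "intron", "intron_chain", "transcript")
  } else level
  pred_models <- if (inherits(pred, "annotation_set")) pred$models else pred
  ref_models <- if (inherits(ref, "annotation_set")) ref$models else ref
  rows <- lapply(levels, function(lv) {
    pk <- .feature_keys(pred_models, lv)
    rk <- .feature_keys(ref_models, lv)
    tp <- length(intersect(pk, rk))
    fp <- length(pk) - tp
    fn <- length(rk) - tp
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    data.frame(level = lv, tp = tp, fp = fp, fn = fn,
               precision = precision, recall = recall, f1 = f1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fraction of reference genes recovered exactly
#'
#' A reference gene counts as recovered when some predicted model matches it
#' exactly: same contig, strand, exon intervals and CDS intervals
#' (coordinates, introns and phases all implied).
#'
#' @param pred,ref [annotation_set()] objects (or lists of gene models).
#' @return Fraction in `[0, 1]` (1 when the reference is empty).
#' @export
gene_recovery_rate <- function(pred, ref) {
  pred_models <- if (inherits(pred, "annotation_set")) pred$models else pred
  ref_models <- if (inherits(ref, "annotation_set")) ref$models else ref
  if (length(ref_models) == 0L) return(1)
  key <- function(gm) {
    paste0(gm$contig, ":", gm$strand, ":",
           paste(gm$exons[, 1L], gm$exons[, 2L], sep = "-", collapse = ","),
           "|",
           paste(gm$cds[, 1L], gm$cds[, 2L], sep = "-", collapse = ","))
  }
  pk <- vapply(pred_models, key, character(1L))
  rk <- vapply(ref_models, key, character(1L))
  mean(rk %in% pk)
}
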