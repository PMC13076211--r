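#' Loss configuration for the dual-head sequence labeler
#'
#' The overall training loss is a weighted sum of the class-head loss (head
#' weight 0.8) and the phase-head categorical cross-entropy (head weight
#' 0.2).  The class head uses per-class weights to de-emphasise the abundant
#' intergenic class, and bases directly before or after one of the four class
#' transition sites (start codon, stop codon, donor splice site, acceptor
#' splice site) get their weight multiplied to sharpen boundaries.
#'
#' @param class_weights Numeric length-4 vector of per-class weights in
#'   channel order (intergenic, UTR, CDS, intron).
#' @param transition_multiplier Multiplier (>= 1) applied to class weights
#'   within `transition_radius` of a transition site.
#' @param transition_radius Number of bases on each side of a transition
#'   boundary that receive the multiplier.
#' @param genic_head_weight,phase_head_weight Head weights; must sum to 1.
#' @return Object of class `loss_config`.
#' @export
loss_config <- function(class_weights = c(intergenic = 0.7, utr = 1.6,
                                          cds = 1.2, intron = 1.2),
                        transition_multiplier = 10,
                        transition_radius = 3L,
                        genic_head_weight = 0.8,
                        phase_head_weight = 0.2) {
  stopifnot(length(class_weights) == 4L, all(class_weights > 0))
  if (transition_multiplier < 1) stop("transition_multiplier must be >= 1")
  if (transition_radius < 0L) stop("transition_radius must be >= 0")
  if (abs(genic_head_weight + phase_head_weight - 1) > 1e-12) {
    stop("head weights must sum to 1")
  }
  names(class_weights) <- GENIC_CLASSES
  structure(list(class_weights = class_weights,
                 transition_multiplier = transition_multiplier,
                 transition_radius = as.integer(transition_radius),
                 genic_head_weight = genic_head_weight,
                 phase_head_weight = phase_head_weight),
            class = "loss_config")
}

#' Locate the four class-transition site categories
#'
#' Derives, from the reference genic class track alone, per-base flags for
#' the four transition site categories: start codon (UTR or intergenic to
#' CDS), stop codon (CDS to UTR or intergenic), donor splice site (exon to
#' intron) and acceptor splice site (intron to exon).  A site is flagged at
#' the first base of the new segment.  Transitions not in these four
#' categories (e.g. intergenic to UTR at a transcription start) are not
#' flagged.
#'
#' @param truth A [labeled_tracks()] object.
#' @return Logical `n x 4` matrix with columns `start_codon`, `stop_codon`,
#'   `donor`, `acceptor`.
#' @export
transition_sites <- function(truth) {
  cls <- max.col(truth$class, ties.method = "first")
  n <- length(cls)
  sites <- matrix(FALSE, nrow = n, ncol = 4L,
                  dimnames = list(NULL, c("start_codon", "stop_codon",
                                          "donor", "acceptor")))
  if (n < 2L) return(sites)
  prev <- cls[-n]
  nxt <- cls[-1L]
  at <- seq_len(n - 1L) + 1L  # position of the first base of the new segment
  ig <- 1L; utr <- 2L; cds <- 3L; intron <- 4L
  sites[at[prev %in% c(ig, utr) & nxt == cds], "start_codon"] <- TRUE
  sites[at[prev == cds & nxt %in% c(ig, utr)], "stop_codon"] <- TRUE
  sites[at[prev %in% c(utr, cds) & nxt == intron], "donor"] <- TRUE
  sites[at[prev == intron & nxt %in% c(utr, cds)], "acceptor"] <- TRUE
  sites
}

#' Per-base loss weight map with transition boosting
#'
#' Every base starts at the weight of its true genic class; bases within
#' `transition_radius` of a flagged transition site (that many bases on each
#' side of the boundary) have their weight multiplied once by
#' `transition_multiplier`; masked bases get weight 0.
#'
#' @param truth A [labeled_tracks()] object.
#' @param cfg A [loss_config()].
#' @return Numeric weight vector, one entry per base.
#' @export
transition_weight_map <- function(truth, cfg = loss_config()) {
  cls <- max.col(truth$class, ties.method = "first")
  w <- unname(cfg$class_weights[cls])
  r <- cfg$transition_radius
  if (r > 0L && cfg$transition_multiplier > 1) {
    sites <- which(rowSums(transition_sites(truth)) > 0)
    if (length(sites) > 0L) {
      boosted <- rep(FALSE, length(cls))
      for (i in sites) {
        lo <- max(1L, i - r)
        hi <- min(length(cls), i + r - 1L)
        boosted[lo:hi] <- TRUE
      }
      w[boosted] <- w[boosted] * cfg$transition_multiplier
    }
  }
  w[truth$mask] <- 0
  w
}

#' Composite dual-head loss
#'
#' `genic_head_weight` times the class-weighted categorical cross-entropy of
#' the genic class head plus `phase_head_weight` times the categorical
#' cross-entropy of the phase head, each averaged over unmasked bases.  The
#' class-head average is weighted by [transition_weight_map()] (normalised by
#' the total weight), so with `transition_multiplier = 1` it reduces to the
#' plain class-weighted loss.
#'
#' @param pred A [prediction_tracks()] object.
#' @param truth A [labeled_tracks()] object of the same length.
#' @param cfg A [loss_config()].
#' @return Scalar loss value.
#' @export
composite_loss <- function(pred, truth, cfg = loss_config()) {
  n <- nrow(truth$class)
  if (nrow(pred$class) != n) stop("prediction/truth length mismatch")
  .check_distribution_rows(pred$class, "class probabilities")
  .check_distribution_rows(pred$phase, "phase probabilities")
  keep <- which(!truth$mask)
  if (length(keep) == 0L) stop("no unmasked bases to compute the loss on")
  true_cls <- max.col(truth$class, ties.method = "first")
  true_phs <- max.col(truth$phase, ties.method = "first")
  p_cls <- pred$class[cbind(seq_len(n), true_cls)]
  p_phs <- pred$phase[cbind(seq_len(n), true_phs)]
  ce_cls <- -log(p_cls)
  ce_phs <- -log(p_phs)
  w <- transition_weight_map(truth, cfg)
  class_term <- sum(w[keep] * ce_cls[keep]) / sum(w[keep])
  phase_term <- mean(ce_phs[keep])
  cfg$genic_head_weight * class_term + cfg$phase_head_weight * phase_term
}
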