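test_that("head weighting reproduces the 0.8 / 0.2 split on analytic batches", {
  truth <- tracks_from_classes(1L, 1L)
  # class cross-entropy exactly 1 (p = e^-1), phase head perfect
  pred1 <- prediction_tracks(matrix(c(exp(-1), 1 - exp(-1), 0, 0), 1),
                             onehot_rows(1L))
  expect_equal(composite_loss(pred1, truth), 0.8)
  # phase cross-entropy exactly 1, class head perfect
  pred2 <- prediction_tracks(onehot_rows(1L),
                             matrix(c(exp(-1), 1 - exp(-1), 0, 0), 1))
  expect_equal(composite_loss(pred2, truth), 0.2)
})

test_that("perfect one-hot predictions give zero loss", {
  genome <- small_genome(seed = 4L, n_genes = 3L, contig_length = 20000L)
  truth <- label_bases(genome$models, genome$sequences[[1]], "+")
  pred <- oracle_predictor(truth, noise = 0)
  expect_equal(composite_loss(pred, truth), 0)
})

test_that("rows that are not distributions are rejected", {
  truth <- tracks_from_classes(c(1L, 1L))
  bad <- structure(list(class = matrix(c(0.5, 0.1, 0.1, 0.1,
                                         0.25, 0.25, 0.25, 0.25),
                                       2, 4, byrow = TRUE),
                        phase = onehot_rows(c(1L, 1L))),
                   class = "prediction_tracks")
  expect_error(composite_loss(bad, truth), "sum to 1")
})

test_that("exactly four transition site categories exist", {
  # intergenic / 5'UTR / CDS / intron / CDS / 3'UTR / intergenic
  cls <- c(rep(1L, 10), rep(2L, 5), rep(3L, 6), rep(4L, 6), rep(3L, 6),
           rep(2L, 5), rep(1L, 10))
  tr <- tracks_from_classes(cls)
  sites <- transition_sites(tr)
  expect_equal(colnames(sites),
               c("start_codon", "stop_codon", "donor", "acceptor"))
  expect_equal(ncol(sites), 4L)
  expect_equal(which(sites[, "start_codon"]), 16L)  # UTR -> CDS
  expect_equal(which(sites[, "donor"]), 22L)        # CDS -> intron
  expect_equal(which(sites[, "acceptor"]), 28L)     # intron -> CDS
  expect_equal(which(sites[, "stop_codon"]), 34L)   # CDS -> UTR
  # the intergenic/UTR boundaries at 11 and 39 are in no category
  expect_equal(sum(sites), 4L)
})

test_that("an all-intergenic track gets uniform intergenic class weights", {
  tr <- tracks_from_classes(rep(1L, 50))
  w <- transition_weight_map(tr)
  expect_equal(w, rep(0.7, 50))
})

test_that("a single donor site doubles exactly 2 x radius bases", {
  cls <- c(rep(3L, 20), rep(4L, 20))
  tr <- tracks_from_classes(cls)
  cfg <- loss_config(transition_multiplier = 2, transition_radius = 3L)
  w <- transition_weight_map(tr, cfg)
  boosted <- which(w == 1.2 * 2)
  expect_equal(boosted, 18:23)   # 3 bases each side of the boundary
  expect_length(boosted, 6)
})

test_that("masked bases get weight zero and do not affect the loss", {
  cls <- c(rep(1L, 10), rep(3L, 9), rep(1L, 10))
  phs <- c(rep(1L, 10), rep(c(2L, 4L, 3L), 3), rep(1L, 10))
  mask <- rep(FALSE, 29)
  mask[12:14] <- TRUE
  tr <- tracks_from_classes(cls, phs, mask)
  expect_equal(transition_weight_map(tr)[12:14], c(0, 0, 0))
  pred_a <- oracle_predictor(tr, noise = 0.3)
  pred_b <- pred_a
  pred_b$class[12:14, ] <- matrix(rep(c(0.1, 0.2, 0.3, 0.4), 3), 3,
                                  byrow = TRUE)
  pred_b$phase[12:14, ] <- matrix(rep(c(0.4, 0.3, 0.2, 0.1), 3), 3,
                                  byrow = TRUE)
  expect_equal(composite_loss(pred_a, tr), composite_loss(pred_b, tr))
})

test_that("multiplier 1 reduces to the plain class-weighted loss", {
  genome <- small_genome(seed = 6L, n_genes = 3L, contig_length = 20000L)
  truth <- label_bases(genome$models, genome$sequences[[1]], "+")
  pred <- oracle_predictor(truth, noise = 0.4, seed = 1L, jitter = 0.2)
  cfg1 <- loss_config(transition_multiplier = 1)
  # independent plain weighted loss
  cls <- max.col(truth$class)
  phs <- max.col(truth$phase)
  n <- length(cls)
  w <- c(0.7, 1.6, 1.2, 1.2)[cls]
  ce_c <- -log(pred$class[cbind(1:n, cls)])
  ce_p <- -log(pred$phase[cbind(1:n, phs)])
  expected <- 0.8 * sum(w * ce_c) / sum(w) + 0.2 * mean(ce_p)
  expect_equal(composite_loss(pred, truth, cfg1), expected)
})
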