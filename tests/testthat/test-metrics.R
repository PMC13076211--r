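test_that("perfect predictions give a diagonal confusion matrix", {
  cls <- sample(1:4, 200, replace = TRUE)
  tr <- tracks_from_classes(cls)
  cm <- confusion(cls, tr, "class")
  expect_equal(sum(diag(cm)), 200L)
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
})

test_that("masked bases are excluded and cannot change the matrix", {
  cls <- rep(c(1L, 3L), 50)
  mask <- rep(c(TRUE, FALSE), 50)
  tr <- tracks_from_classes(cls, mask = mask)
  pred <- cls
  cm1 <- confusion(pred, tr, "class")
  pred_flipped <- pred
  pred_flipped[mask] <- 5L - pred_flipped[mask]
  cm2 <- confusion(pred_flipped, tr, "class")
  expect_identical(cm1, cm2)
  expect_equal(sum(cm1), 50L)
  # all bases masked: all-zero matrix
  tr_all <- tracks_from_classes(cls, mask = rep(TRUE, 100))
  expect_equal(sum(confusion(pred, tr_all, "class")), 0L)
})

test_that("precision, recall and F1 follow their defining ratios", {
  # one class with TP = 2, FP = 1, FN = 1
  cm <- matrix(0L, 4, 4, dimnames = list(GC <- c("intergenic", "utr", "cds",
                                                 "intron"), GC))
  cm["cds", "cds"] <- 2L
  cm["utr", "cds"] <- 1L     # FP for cds
  cm["cds", "utr"] <- 1L     # FN for cds
  r <- f1_scores(cm)
  cds <- r$per_class[r$per_class$class == "cds", ]
  expect_equal(cds$precision, 2 / 3)
  expect_equal(cds$recall, 2 / 3)
  expect_equal(cds$f1, 2 / 3)
  # precision = recall = 1 gives F1 = 1
  cm2 <- diag(c(5L, 5L, 5L, 5L))
  dimnames(cm2) <- dimnames(cm)
  expect_true(all(f1_scores(cm2)$per_class$f1 == 1))
})

test_that("empty-support classes score 0 and are flagged", {
  cm <- matrix(0L, 4, 4, dimnames = list(GENIC <- c("intergenic", "utr",
                                                    "cds", "intron"), GENIC))
  cm["intergenic", "intergenic"] <- 10L
  r <- f1_scores(cm)
  expect_true(all(r$per_class$empty_support[2:4]))
  expect_equal(r$per_class$f1[2:4], c(0, 0, 0))
  expect_equal(r$genic_f1, 0)
})

test_that("f1_scores agrees with a brute-force recomputation from labels", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- 200L
    truth_cls <- sample(1:4, n, replace = TRUE)
    pred_cls <- ifelse(runif(n) < 0.7, truth_cls, sample(1:4, n, TRUE))
    mask <- runif(n) < 0.1
    tr <- tracks_from_classes(truth_cls, mask = mask)
    r <- f1_scores(confusion(pred_cls, tr, "class"))
    # independent oracle: count per class directly from the label vectors
    t <- truth_cls[!mask]; p <- pred_cls[!mask]
    for (k in 1:4) {
      tp <- sum(t == k & p == k)
      fp <- sum(t != k & p == k)
      fn <- sum(t == k & p != k)
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      expect_equal(r$per_class$precision[k], prec)
      expect_equal(r$per_class$recall[k], rec)
      expect_equal(r$per_class$f1[k], f1)
    }
    sup <- vapply(2:4, function(k) sum(t == k), numeric(1))
    f1s <- r$per_class$f1[2:4]
    expected_genic <- if (sum(sup) > 0) sum(f1s * sup) / sum(sup) else 0
    expect_equal(r$genic_f1, expected_genic)
  }
})

test_that("genic F1 is 1 exactly when unmasked genic bases all match", {
  cls <- c(rep(1L, 20), rep(2L, 5), rep(3L, 12), rep(4L, 6), rep(3L, 9),
           rep(2L, 4), rep(1L, 20))
  tr <- tracks_from_classes(cls)
  expect_equal(f1_scores(confusion(cls, tr, "class"))$genic_f1, 1)
  wrong <- cls
  wrong[30] <- 4L   # one CDS base called intron
  expect_lt(f1_scores(confusion(wrong, tr, "class"))$genic_f1, 1)
})

test_that("the evaluator draws exactly 800 windows when more are available", {
  batch <- chunk(matrix(0.25, 2000 * 50, 4),
                 chunk_config(train_length = 50L,
                              inference_length_plant = 100L,
                              inference_length_animal = 200L))
  expect_length(batch$windows, 2000)
  idx <- sample_subsequences(batch, n = 800, seed = 4L)
  expect_length(idx, 800)
  expect_false(anyDuplicated(idx) > 0)
  expect_identical(idx, sample_subsequences(batch, n = 800, seed = 4L))
  # clamped when fewer are available
  small <- chunk(matrix(0.25, 100 * 50, 4),
                 chunk_config(train_length = 50L,
                              inference_length_plant = 100L,
                              inference_length_animal = 200L))
  expect_length(sample_subsequences(small, n = 800, seed = 1L), 100)
})

test_that("transition-adjacent F1 restricts to boundary neighbourhoods", {
  # uniform truth: no transitions, flagged empty
  tr0 <- tracks_from_classes(rep(1L, 50))
  r0 <- transition_adjacent_f1(rep(1L, 50), tr0)
  expect_true(attr(r0, "empty"))
  # perfect predictions score 1 on the restricted set
  cls <- c(rep(1L, 30), rep(3L, 30), rep(1L, 30))
  tr <- tracks_from_classes(cls)
  r1 <- transition_adjacent_f1(cls, tr, radius = 3)
  expect_equal(attr(r1, "n_evaluated"), 12L)
  expect_equal(r1$per_class$f1[r1$per_class$support > 0],
               rep(1, sum(r1$per_class$support > 0)))
  # when every base is within radius of a transition the restriction is void
  short <- c(1L, 1L, 3L, 3L)
  trs <- tracks_from_classes(short)
  pred <- c(1L, 3L, 3L, 1L)
  full <- f1_scores(confusion(pred, trs, "class"))
  restricted <- transition_adjacent_f1(pred, trs, radius = 2)
  expect_equal(restricted$per_class$f1, full$per_class$f1)
})

test_that("feature matching is exact per level", {
  g1 <- gene_model("a", "c1", "+", rbind(c(0, 100), c(200, 300)),
                   rbind(c(10, 100), c(200, 250)))
  g2 <- gene_model("b", "c1", "+", rbind(c(400, 500)), rbind(c(410, 470)))
  ref <- list(g1, g2)
  # identical annotations: everything 1
  fm <- feature_match(ref, ref)
  expect_true(all(fm$precision == 1 & fm$recall == 1 & fm$f1 == 1))
  # one CDS exon shifted by 1 bp stops matching; the other two still do
  g1_shift <- gene_model("a", "c1", "+", rbind(c(0, 100), c(200, 300)),
                         rbind(c(11, 100), c(200, 250)))
  fm2 <- feature_match(list(g1_shift, g2), ref, level = "exon")
  expect_equal(fm2$tp, 2L)
  expect_equal(fm2$recall, 2 / 3)
  # intron chain is all-or-nothing
  fm3 <- feature_match(list(g1_shift), list(g1), level = "intron_chain")
  expect_equal(fm3$tp, 1L)   # chain defined by CDS gap, unchanged here
  g1_badintron <- gene_model("a", "c1", "+", rbind(c(0, 100), c(201, 300)),
                             rbind(c(10, 100), c(201, 251)))
  fm4 <- feature_match(list(g1_badintron), list(g1), level = "intron_chain")
  expect_equal(fm4$tp, 0L)
  expect_equal(fm4$f1, 0)
})

test_that("feature matching is symmetric with precision and recall swapped", {
  pred <- annotation_set(small_genome(seed = 33L, n_genes = 5L)$models,
                         c(contig_1 = 30000L))
  ref <- annotation_set(small_genome(seed = 34L, n_genes = 5L)$models,
                        c(contig_1 = 30000L))
  a <- feature_match(pred, ref)
  b <- feature_match(ref, pred)
  expect_equal(a$precision, b$recall)
  expect_equal(a$recall, b$precision)
  expect_equal(a$f1, b$f1)
})

test_that("evaluation is invariant to GFF3 row order", {
  genome <- small_genome(seed = 35L, n_genes = 4L)
  ann <- annotation_set(genome$models, nchar(genome$sequences))
  f <- tempfile(fileext = ".gff3")
  write_gff3(ann, f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  shuffled <- c(lines[startsWith(lines, "#")], rev(body))
  f2 <- tempfile(fileext = ".gff3")
  writeLines(shuffled, f2)
  a1 <- suppressWarnings(read_gff3(f))
  a2 <- suppressWarnings(read_gff3(f2))
  expect_equal(feature_match(a1, a2),
               feature_match(a1, a1))
  expect_true(all(feature_match(a1, a2)$f1 == 1))
})
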