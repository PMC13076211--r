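test_that("a contig with no models is all intergenic, all phase none", {
  seq <- strrep("ACGT", 25)
  tr <- label_bases(list(), seq, "+")
  expect_equal(unname(colSums(tr$class)), c(100, 0, 0, 0))
  expect_equal(unname(colSums(tr$phase)), c(100, 0, 0, 0))
  expect_false(any(tr$mask))
})

test_that("phases across a codon follow the bases-to-next-codon convention", {
  # single-exon gene: 5 bp UTR, ATG AAA TAA, 4 bp UTR
  seq <- paste0("CCCCC", "ATGAAATAA", "CCCC")
  gm <- gene_model("g1", "c1", "+", rbind(c(0, 18)), rbind(c(5, 14)))
  tr <- label_bases(list(gm), seq, "+")
  phase_idx <- max.col(tr$phase)
  # oracle: (start of next codon - position) mod 3, applied per CDS position
  expected <- vapply(0:8, function(q) (3 - q %% 3) %% 3, numeric(1))
  got <- phase_idx[6:14] - 2L
  expect_equal(got, expected)
  expect_equal(expected[1:3], c(0, 2, 1))
  # off-CDS bases have phase none
  expect_true(all(phase_idx[c(1:5, 15:18)] == 1L))
})

test_that("intron bases inside the CDS span are intron with phase none", {
  seq <- paste0("CC", "ATGA", "GTTTAG", "AATAA", "CC")
  gm <- gene_model("g1", "c1", "+", rbind(c(2, 6), c(12, 17)),
                   rbind(c(2, 6), c(12, 17)))
  tr <- label_bases(list(gm), seq, "+")
  cls <- max.col(tr$class)
  expect_equal(cls[7:12], rep(4L, 6))       # intron
  expect_equal(max.col(tr$phase)[7:12], rep(1L, 6))
})

test_that("labels round-trip: class intervals reproduce the gene structure", {
  genome <- small_genome(seed = 5L, n_genes = 5L, strand_prob = 0)
  seq <- genome$sequences[[1]]
  tr <- label_bases(genome$models, seq, "+")
  cls <- max.col(tr$class)
  for (gm in genome$models) {
    span <- gene_span(gm)
    for (i in seq_len(nrow(gm$cds))) {
      expect_true(all(cls[(gm$cds[i, 1] + 1):gm$cds[i, 2]] == 3L))
    }
    for (i in seq_len(nrow(introns_of(gm)))) {
      iv <- introns_of(gm)[i, ]
      expect_true(all(cls[(iv[1] + 1):iv[2]] == 4L))
    }
    u <- utrs_of(gm)
    for (m in list(u$five, u$three)) {
      for (i in seq_len(nrow(m))) {
        expect_true(all(cls[(m[i, 1] + 1):m[i, 2]] == 2L))
      }
    }
  }
  # outside gene spans everything is intergenic
  genic <- rep(FALSE, nchar(seq))
  for (gm in genome$models) {
    span <- gene_span(gm)
    genic[(span[1] + 1):span[2]] <- TRUE
  }
  expect_true(all(cls[!genic] == 1L))
})

test_that("phase labels cycle with period 3 within unmasked CDS runs", {
  genome <- small_genome(seed = 13L, n_genes = 8L)
  for (strand in c("+", "-")) {
    tr <- label_bases(genome$models, genome$sequences[[1]], strand)
    cls <- max.col(tr$class)
    phs <- max.col(tr$phase) - 2L
    cds_pos <- which(cls == 3L)
    runs <- split(cds_pos, cumsum(c(1L, diff(cds_pos) != 1L)))
    for (run in runs) {
      vals <- phs[run]
      expected <- rep(c(0L, 2L, 1L), length.out = length(vals))
      offset <- match(vals[1], c(0L, 2L, 1L)) - 1L
      expect_equal(vals,
                   c(0L, 2L, 1L)[((seq_along(vals) - 1L + offset) %% 3L) + 1L])
    }
  }
})

test_that("unmasked rows of both tracks sum to exactly 1", {
  genome <- small_genome(seed = 3L, n_genes = 4L)
  tr <- label_bases(genome$models, genome$sequences[[1]], "+")
  expect_true(all(rowSums(tr$class) == 1))
  expect_true(all(rowSums(tr$phase) == 1))
})

test_that("complete canonical genes leave no base masked", {
  genome <- small_genome(seed = 21L, n_genes = 5L)
  for (strand in c("+", "-")) {
    mask <- flag_errors(genome$models, genome$sequences[[1]], strand)
    expect_equal(sum(mask), 0)
  }
})

test_that("a CDS running off the contig end masks the whole gene", {
  seq <- strrep("C", 30)
  gm <- gene_model("g1", "c1", "+", rbind(c(20, 40)), rbind(c(20, 40)))
  mask <- flag_errors(list(gm), seq, "+")
  expect_true(all(mask[21:30]))
  expect_false(any(mask[1:20]))
})

test_that("a CDS without start or stop codon masks its gene span", {
  seq <- paste0("CC", "CCCAAATAA", "CC")   # no ATG at CDS start
  gm <- gene_model("g1", "c1", "+", rbind(c(2, 11)), rbind(c(2, 11)))
  mask <- flag_errors(list(gm), seq, "+")
  expect_true(all(mask[3:11]))
})

test_that("same-strand genes overlapping in CDS mask the overlap region", {
  seq <- strrep("A", 60)
  g1 <- gene_model("g1", "c1", "+", rbind(c(0, 30)), rbind(c(0, 30)))
  g2 <- gene_model("g2", "c1", "+", rbind(c(20, 50)), rbind(c(20, 50)))
  mask <- flag_errors(list(g1, g2), seq, "+")
  expect_true(all(mask[21:30]))   # overlap [20, 30)
  expect_false(any(mask[51:60]))
})
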