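params_default <- penalty_params()
space_default <- build_state_space(params_default)

test_that("emission penalties follow the floored negative log rule", {
  # CDS phase-0 state with perfect class and phase probabilities
  expect_equal(emission_penalty("R0", c(0, 0, 1, 0), c(0, 1, 0, 0),
                                params_default, space_default), 0)
  # half class, half phase: 2 ln 2
  expect_equal(emission_penalty("R0", c(0, 0, 0.5, 0.5), c(0, 0.5, 0.5, 0),
                                params_default, space_default), 2 * log(2))
  # zero probability is floored at epsilon
  expect_equal(emission_penalty("IG", c(0, 1, 0, 0), c(1, 0, 0, 0),
                                params_default, space_default),
               -log(1e-8))
  # non-CDS states carry no phase term
  expect_equal(emission_penalty("U5", c(0, 0.5, 0.5, 0), c(1, 0, 0, 0),
                                params_default, space_default), log(2))
})

test_that("transition penalties enforce canonical motifs", {
  seq <- "CCATGCC"
  # UTR -> start codon over the A of ATG
  expect_equal(transition_penalty("U5", "S0", seq, 3, params_default,
                                  space_default), 0)
  # start codon not at A: infinite under canonical-only parameters
  expect_equal(transition_penalty("U5", "S0", seq, 1, params_default,
                                  space_default), Inf)
  # CDS -> intron over GT is free, over GC infinite by default
  seq2 <- "AAGTAAGCAA"
  expect_equal(transition_penalty("R0", "I_start_gtag_R1", seq2, 3,
                                  params_default, space_default), 0)
  expect_equal(transition_penalty("R0", "I_start_gcag_R1", seq2, 7,
                                  params_default, space_default), Inf)
  # a configured finite GC-AG class pays its penalty
  p2 <- penalty_params(motif_penalties = list(donor_gcag = 4))
  s2 <- build_state_space(p2)
  expect_equal(transition_penalty("R0", "I_start_gcag_R1", seq2, 7, p2, s2),
               4)
  # transitions not in the table are infinite
  expect_equal(transition_penalty("IG", "R1", seq, 2, params_default,
                                  space_default), Inf)
})

test_that("uniformly intergenic tracks give no candidate regions", {
  tr <- prediction_tracks(onehot_rows(rep(1L, 2000)),
                          onehot_rows(rep(1L, 2000)), validate = FALSE)
  expect_equal(nrow(find_candidate_regions(tr, params_default)), 0L)
})

test_that("candidate regions match the moving-average oracle", {
  p_ig <- c(rep(1, 500), rep(0, 1000), rep(1, 500))
  tr <- prediction_tracks(cbind(p_ig, 1 - p_ig, 0, 0),
                          onehot_rows(rep(1L, 2000)), validate = FALSE)
  got <- find_candidate_regions(tr, params_default)
  # oracle: evaluate the shrinking-edge moving average definition directly
  w <- 100L; h1 <- 49L; h2 <- 50L
  avg <- vapply(seq_along(p_ig), function(i) {
    mean(p_ig[max(1, i - h1):min(length(p_ig), i + h2)])
  }, numeric(1))
  low <- which(avg < 0.5)
  expect_equal(nrow(got), 1L)
  expect_equal(unname(got[1, "start"]), min(low) - 1L)
  expect_equal(unname(got[1, "end"]), max(low))
  # the region covers the low block up to the threshold-boundary base
  expect_lte(got[1, "start"], 500L)
  expect_gte(got[1, "end"], 1499L)
})

test_that("low blocks separated by at least a window stay separate regions", {
  p_ig <- c(rep(1, 300), rep(0, 400), rep(1, 150), rep(0, 400), rep(1, 300))
  tr <- prediction_tracks(cbind(p_ig, 1 - p_ig, 0, 0),
                          onehot_rows(rep(1L, length(p_ig))),
                          validate = FALSE)
  expect_equal(nrow(find_candidate_regions(tr, params_default)), 2L)
  # merged when the separation is well below the window
  p_ig2 <- c(rep(1, 300), rep(0, 400), rep(1, 30), rep(0, 400), rep(1, 300))
  tr2 <- prediction_tracks(cbind(p_ig2, 1 - p_ig2, 0, 0),
                           onehot_rows(rep(1L, length(p_ig2))),
                           validate = FALSE)
  expect_equal(nrow(find_candidate_regions(tr2, params_default)), 1L)
})

test_that("noiseless tracks of a single-exon gene decode to the exact model", {
  seq <- paste0(strrep("C", 150), "TTTTT",
                "ATG", "GCTGCAGCC", "TAA", strrep("C", 5), strrep("A", 150))
  gm <- gene_model("g1", "c1", "+", rbind(c(150, 175)), rbind(c(155, 170)))
  truth <- label_bases(list(gm), seq, "+")
  tr <- oracle_predictor(truth, noise = 0)
  p <- penalty_params(min_cds_length = 15L)
  found <- decode_region(c(100L, nchar(seq)), tr, seq, p,
                         build_state_space(p), contig = "c1")
  expect_length(found, 1)
  expect_true(same_gene_model(found[[1]],
                              gene_model("x", "c1", "+", gm$exons, gm$cds)))
})

test_that("all-UTR tracks with no ATG in the sequence decode to zero genes", {
  n <- 80L
  seq <- strrep("C", n)
  cls <- cbind(rep(0, n), rep(1, n), 0, 0)
  tr <- prediction_tracks(cls, onehot_rows(rep(1L, n)), validate = FALSE)
  found <- decode_region(c(0L, n), tr, seq, params_default, space_default)
  expect_length(found, 0)
})

test_that("the dynamic program equals brute-force path enumeration", {
  for (seed in 1:15) {
    inst <- random_decoder_instance(n = 10L + (seed %% 5L), seed = seed)
    expect_equal(dp_min_penalty(inst),
                 brute_force_min_penalty(inst$class, inst$phase, inst$seq),
                 tolerance = 1e-10)
  }
})

test_that("a plus-strand-only genome decodes no minus-strand genes", {
  genome <- small_genome(seed = 25L, n_genes = 5L, strand_prob = 0)
  tracks <- corrupt_tracks(reference_tracks(genome), 0, 1L)
  ann <- decode_genome(tracks, genome$sequences)
  expect_length(ann$models, 5)
  expect_true(all(vapply(ann$models, function(m) m$strand,
                         character(1)) == "+"))
})

test_that("strand-swapped input decodes to mirror-image coordinates", {
  genome <- small_genome(seed = 26L, n_genes = 4L)
  tracks <- corrupt_tracks(reference_tracks(genome), 0, 1L)
  ann <- decode_genome(tracks, genome$sequences)
  L <- nchar(genome$sequences[[1]])
  mirrored_seq <- c(contig_1 = revcomp(genome$sequences[[1]]))
  mirrored_tracks <- list(contig_1 = list(plus = tracks$contig_1$minus,
                                          minus = tracks$contig_1$plus))
  ann2 <- decode_genome(mirrored_tracks, mirrored_seq)
  expect_length(ann2$models, length(ann$models))
  flipped <- lapply(ann$models, flip_gene_model, contig_length = L)
  for (gm in ann2$models) {
    expect_true(any(vapply(flipped, same_gene_model, logical(1), gm)))
  }
})

test_that("a genome without genes decodes to an empty annotation", {
  genome <- simulate_genome(synthetic_genome_spec(contig_length = 5000L,
                                                  n_genes = 0L, seed = 2L))
  tracks <- corrupt_tracks(reference_tracks(genome), 0, 1L)
  ann <- decode_genome(tracks, genome$sequences)
  expect_length(ann$models, 0)
  lines <- write_gff3(ann, "")
  expect_equal(lines, c("##gff-version 3",
                        "##sequence-region contig_1 1 5000"))
})

test_that("decoded models always satisfy the canonical grammar", {
  genome <- small_genome(seed = 27L, n_genes = 6L)
  truth <- reference_tracks(genome)
  for (noise in c(0, 0.25)) {
    tracks <- corrupt_tracks(truth, noise, 11L)
    ann <- decode_genome(tracks, genome$sequences)
    expect_valid_models(ann, genome$sequences)
  }
})
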