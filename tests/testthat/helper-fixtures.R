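# Shared fixtures, built in code.  The default fixture (the generator's
# default spec) is cached per test run since several files decode it.

.fixture_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

default_genome <- function() {
  if (is.null(.fixture_cache$genome)) {
    .fixture_cache$genome <- simulate_genome(synthetic_genome_spec())
  }
  .fixture_cache$genome
}

default_truth <- function() {
  if (is.null(.fixture_cache$truth)) {
    .fixture_cache$truth <- reference_tracks(default_genome())
  }
  .fixture_cache$truth
}

small_genome <- function(seed = 42L, n_genes = 6L, contig_length = 30000L,
                         ...) {
  simulate_genome(synthetic_genome_spec(contig_length = contig_length,
                                        n_genes = n_genes, seed = seed, ...))
}

# one-hot track helpers for hand-built cases -------------------------------

onehot_rows <- function(idx, k = 4L) {
  m <- matrix(0, length(idx), k)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

tracks_from_classes <- function(cls, phs = rep(1L, length(cls)),
                                mask = rep(FALSE, length(cls))) {
  labeled_tracks(onehot_rows(cls), onehot_rows(phs), mask)
}

expect_valid_models <- function(ann, sequences) {
  for (gm in ann$models) {
    # the grammar invariants: ATG start, canonical stop, GT..AG introns,
    # CDS length divisible by 3 (codons interrupted by introns may not be
    # checkable for in-frame stops by a Markov decoder, so that check is a
    # generator guarantee, not a decoder invariant)
    issues <- validate_gene_model(gm, sequences[[gm$contig]],
                                  check_internal_stops = FALSE)
    expect_length(issues, 0)
  }
  invisible(ann)
}
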