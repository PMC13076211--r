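#' Specification for a synthetic test genome
#'
#' Describes the toy genomes used to exercise the pipeline end to end:
#' random intergenic background at a target GC fraction, with multi-exon
#' protein-coding genes whose structure is canonical by construction (ATG
#' start, TAA/TAG/TGA stop, GT-AG introns, CDS length divisible by 3, no
#' in-frame premature stops).  The default is sized so the full pipeline runs
#' in seconds: one 100 kb contig carrying 20 genes of 1-4 exons.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bases.
#' @param n_genes Total number of genes, distributed evenly over contigs.
#' @param exon_count_range Inclusive range of exon counts per gene.
#' @param cds_codon_range Inclusive range of CDS codon counts (excluding the
#'   stop codon).
#' @param intron_length_range Inclusive range of intron lengths (>= 4 bases
#'   for the GT..AG motifs).
#' @param utr_length_range Inclusive range of UTR lengths on each side.
#' @param gc GC fraction of intergenic, intron and UTR sequence.
#' @param strand_prob Probability that a gene lies on the minus strand.
#' @param min_intergenic Minimum intergenic gap between genes and to contig
#'   edges.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return Object of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(n_contigs = 1L, contig_length = 100000L,
                                  n_genes = 20L,
                                  exon_count_range = c(1L, 4L),
                                  cds_codon_range = c(60L, 180L),
                                  intron_length_range = c(60L, 200L),
                                  utr_length_range = c(30L, 150L),
                                  gc = 0.42, strand_prob = 0.5,
                                  min_intergenic = 200L, seed = 1L) {
  stopifnot(n_contigs >= 1L, contig_length > 0L, n_genes >= 0L,
            exon_count_range[1L] >= 1L,
            intron_length_range[1L] >= 4L,
            utr_length_range[1L] >= 1L,
            gc > 0, gc < 1, strand_prob >= 0, strand_prob <= 1,
            min_intergenic >= 1L)
  structure(list(n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 n_genes = as.integer(n_genes),
                 exon_count_range = as.integer(exon_count_range),
                 cds_codon_range = as.integer(cds_codon_range),
                 intron_length_range = as.integer(intron_length_range),
                 utr_length_range = as.integer(utr_length_range),
                 gc = gc, strand_prob = strand_prob,
                 min_intergenic = as.integer(min_intergenic),
                 seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

SENSE_CODONS <- local({
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all_codons, STOP_CODONS)
})

.random_seq <- function(n, gc) {
  if (n <= 0L) return("")
  paste0(sample(c("G", "C", "A", "T"), n, replace = TRUE,
                prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
         collapse = "")
}

.sample_range <- function(range) {
  if (range[1L] == range[2L]) range[1L] else sample(range[1L]:range[2L], 1L)
}

## Build one gene in block-local plus orientation.  Returns the block
## sequence plus exon/CDS intervals (0-based half-open, block-local).
.simulate_gene_block <- function(spec) {
  n_codons <- .sample_range(spec$cds_codon_range)
  stop_codon <- sample(STOP_CODONS, 1L)
  cds_seq <- paste0("ATG",
                    paste0(sample(SENSE_CODONS, n_codons, replace = TRUE),
                           collapse = ""),
                    stop_codon)
  cds_len <- nchar(cds_seq)
  n_exons <- .sample_range(spec$exon_count_range)
  ## Split points fall anywhere inside the CDS (exercising every interrupted
  ## phase, including start- and stop-codon splits), except immediately
  ## before the third base of a TGA stop, whose split variant the decoder
  ## grammar does not represent.
  allowed <- 1L:(cds_len - 1L)
  if (stop_codon == "TGA") allowed <- setdiff(allowed, cds_len - 1L)
  n_splits <- min(n_exons - 1L, length(allowed))
  splits <- sort(sample(allowed, n_splits))
  u5 <- .random_seq(.sample_range(spec$utr_length_range), spec$gc)
  u3 <- .random_seq(.sample_range(spec$utr_length_range), spec$gc)
  piece_bounds <- c(0L, splits, cds_len)
  seq_parts <- list(u5)
  exons <- list()
  cds <- list()
  pos <- nchar(u5)
  exon_start <- 0L
  for (i in seq_len(length(piece_bounds) - 1L)) {
    piece <- substr(cds_seq, piece_bounds[i] + 1L, piece_bounds[i + 1L])
    seq_parts[[length(seq_parts) + 1L]] <- piece
    cds[[length(cds) + 1L]] <- c(pos, pos + nchar(piece))
    pos <- pos + nchar(piece)
    if (i < length(piece_bounds) - 1L) {
      exons[[length(exons) + 1L]] <- c(exon_start, pos)
      ilen <- .sample_range(spec$intron_length_range)
      intron <- paste0("GT", .random_seq(ilen - 4L, spec$gc), "AG")
      seq_parts[[length(seq_parts) + 1L]] <- intron
      pos <- pos + ilen
      exon_start <- pos
    }
  }
  seq_parts[[length(seq_parts) + 1L]] <- u3
  pos <- pos + nchar(u3)
  exons[[length(exons) + 1L]] <- c(exon_start, pos)
  list(seq = paste0(seq_parts, collapse = ""),
       exons = do.call(rbind, exons),
       cds = do.call(rbind, cds))
}

#' Simulate a synthetic genome with gene models
#'
#' Generates contig sequences and the gene models placed on them, strictly
#' following the spec: genes are laid out with at least `min_intergenic`
#' bases between them (and to contig edges), slack is distributed randomly,
#' and each gene is canonical by construction.  Deterministic given the
#' spec's seed.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return Object of class `synthetic_genome`: a list with `sequences`
#'   (named character vector) and `models` (list of [gene_model()]).
#' @export
simulate_genome <- function(spec = synthetic_genome_spec()) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  set.seed(spec$seed)
  per_contig <- rep(spec$n_genes %/% spec$n_contigs, spec$n_contigs)
  extra <- spec$n_genes %% spec$n_contigs
  if (extra > 0L) per_contig[seq_len(extra)] <- per_contig[seq_len(extra)] + 1L
  sequences <- character(spec$n_contigs)
  names(sequences) <- sprintf("contig_%d", seq_len(spec$n_contigs))
  models <- list()
  for (ci in seq_len(spec$n_contigs)) {
    contig <- names(sequences)[ci]
    n_here <- per_contig[ci]
    blocks <- lapply(seq_len(n_here), function(i) .simulate_gene_block(spec))
    block_lens <- vapply(blocks, function(b) nchar(b$seq), integer(1L))
    needed <- sum(block_lens) + (n_here + 1L) * spec$min_intergenic
    if (needed > spec$contig_length) {
      stop(sprintf(paste0("infeasible spec: %d genes need at least %d bases ",
                          "but contig_length is %d"),
                   n_here, needed, spec$contig_length))
    }
    slack <- spec$contig_length - needed
    ## split the slack over the n_here + 1 gaps at random
    cuts <- sort(c(0L, sample.int(slack + 1L, n_here, replace = TRUE) - 1L,
                   slack))
    gap_extra <- diff(cuts)
    background <- .random_seq(spec$contig_length, spec$gc)
    pos <- 0L
    for (gi in seq_len(n_here)) {
      pos <- pos + spec$min_intergenic + gap_extra[gi]
      b <- blocks[[gi]]
      strand <- if (runif(1L) < spec$strand_prob) "-" else "+"
      block_seq <- b$seq
      exons <- b$exons
      cds <- b$cds
      if (strand == "-") {
        Lb <- nchar(block_seq)
        block_seq <- revcomp(block_seq)
        flipm <- function(m) cbind(Lb - m[, 2L], Lb - m[, 1L])
        exons <- flipm(exons)
        cds <- flipm(cds)
      }
      substr(background, pos + 1L, pos + nchar(block_seq)) <- block_seq
      models[[length(models) + 1L]] <-
        gene_model(gene_id = "tmp", contig = contig, strand = strand,
                   exons = exons + pos, cds = cds + pos)
      pos <- pos + nchar(block_seq)
    }
    sequences[ci] <- background
  }
  ## stable ids by genomic order
  ord <- order(vapply(models, function(m) m$contig, character(1L)),
               vapply(models, function(m) gene_span(m)[1L], integer(1L)))
  models <- models[ord]
  for (i in seq_along(models)) {
    models[[i]]$gene_id <- sprintf("gene_%04d", i)
  }
  structure(list(sequences = sequences, models = models, spec = spec),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d contig(s), %d bases, %d gene(s)\n",
              length(x$sequences), sum(nchar(x$sequences)),
              length(x$models)))
  invisible(x)
}

#' Reference tracks for every contig strand of a genome
#'
#' Runs [label_bases()] and [flag_errors()] on both strands of every contig.
#'
#' @param genome A `synthetic_genome` (or a list with `sequences` and
#'   `models` in the same layout).
#' @return Named list (one element per contig) of lists with `plus` and
#'   `minus` [labeled_tracks()].
#' @export
reference_tracks <- function(genome) {
  out <- list()
  for (contig in names(genome$sequences)) {
    seq <- genome$sequences[[contig]]
    models <- Filter(function(m) m$contig == contig, genome$models)
    tr <- list()
    for (strand in c("+", "-")) {
      t <- label_bases(models, seq, strand, contig = contig)
      t$mask <- flag_errors(models, seq, strand)
      tr[[if (strand == "+") "plus" else "minus"]] <- t
    }
    out[[contig]] <- tr
  }
  out
}

#' Corrupt reference tracks into oracle prediction tracks
#'
#' Applies [oracle_predictor()] to every strand of every contig, deriving a
#' distinct sub-seed per strand.  `noise` drives both the uniform mixture
#' and the per-base jitter probability, so 0 gives exact one-hot tracks and
#' increasing values progressively corrupt argmax calls.
#'
#' @param truth Output of [reference_tracks()].
#' @param noise Corruption level in `[0, 1]`.
#' @param seed Integer seed.
#' @return Named list matching the input layout, with
#'   [prediction_tracks()] values.
#' @export
corrupt_tracks <- function(truth, noise = 0, seed = 1L) {
  out <- list()
  k <- 0L
  for (contig in names(truth)) {
    tr <- list()
    for (strand in c("plus", "minus")) {
      k <- k + 1L
      tr[[strand]] <- oracle_predictor(truth[[contig]][[strand]],
                                       noise = noise,
                                       seed = as.integer(seed) + 7919L * k,
                                       jitter = noise)
    }
    out[[contig]] <- tr
  }
  out
}

#' Generate an on-disk end-to-end test fixture
#'
#' Bundles [simulate_genome()], [reference_tracks()] and [corrupt_tracks()]
#' into one directory: FASTA, GFF3, clean (noise-0) tracks and corrupted
#' tracks, plus the in-memory objects.  Byte-identical for identical spec,
#' noise and seed.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param noise Corruption level for the corrupted tracks.
#' @param seed Seed for the corruption (the genome itself uses `spec$seed`).
#' @param dir Output directory (created if missing).
#' @return List with file paths (`fasta`, `gff3`, `tracks`,
#'   `corrupted_tracks`) and objects (`genome`, `truth`, `clean`,
#'   `corrupted`).
#' @export
make_fixture <- function(spec = synthetic_genome_spec(), noise = 0,
                         seed = 1L, dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(spec)
  fasta <- file.path(dir, "genome.fa")
  gff3 <- file.path(dir, "annotation.gff3")
  write_fasta(genome$sequences, fasta)
  write_gff3(annotation_set(genome$models, nchar(genome$sequences)), gff3)
  truth <- reference_tracks(genome)
  clean <- corrupt_tracks(truth, noise = 0, seed = seed)
  corrupted <- corrupt_tracks(truth, noise = noise, seed = seed)
  tracks_path <- file.path(dir, "tracks.rds")
  corrupted_path <- file.path(dir, "corrupted_tracks.rds")
  saveRDS(clean, tracks_path)
  saveRDS(corrupted, corrupted_path)
  list(fasta = fasta, gff3 = gff3, tracks = tracks_path,
       corrupted_tracks = corrupted_path, genome = genome, truth = truth,
       clean = clean, corrupted = corrupted)
}

#' Write sequences to a FASTA file
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  ## keep only the first word of each header, as annotation files do
  names(out) <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1L), 1L)
  out
}
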