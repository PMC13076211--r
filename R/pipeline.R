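#' Run the full pipeline: FASTA in, GFF3 out
#'
#' Single-call orchestration of encode, predict and decode: reads the genome
#' sequence, obtains per-strand probability tracks (either supplied directly,
#' e.g. from a fixture, or produced by sliding-window inference with a
#' predictor on both strands), decodes them into primary gene models and
#' writes GFF3.  Per-stage counts are logged via `message()`.
#'
#' @param fasta Path to the genome FASTA file.
#' @param out_gff3 Output GFF3 path.
#' @param tracks Per-contig per-strand [prediction_tracks()] (the layout of
#'   [corrupt_tracks()]), or the path of an RDS file holding them.  Mutually
#'   exclusive with `predictor`.
#' @param predictor A `toy_predictor` (or prediction function) used with
#'   [predict_sliding()] when `tracks` is not given.
#' @param profile Lineage profile selecting the inference window length:
#'   `"plant"` (106,920 bp) or `"animal"` (213,840 bp).
#' @param params A [penalty_params()].
#' @param cfg A [chunk_config()].
#' @return Invisibly, the decoded [annotation_set()].
#' @export
run_end_to_end <- function(fasta, out_gff3, tracks = NULL, predictor = NULL,
                           profile = c("plant", "animal"),
                           params = penalty_params(), cfg = chunk_config()) {
  profile <- match.arg(profile)
  if (!file.exists(fasta)) stop("FASTA file not found: ", fasta)
  sequences <- read_fasta(fasta)
  message(sprintf("loaded %d contig(s), %d bases", length(sequences),
                  sum(nchar(sequences))))
  if (is.null(tracks)) {
    if (is.null(predictor)) {
      stop("either tracks or a predictor must be supplied")
    }
    window <- window_length_for(cfg, paste0("inference_", profile))
    tracks <- list()
    for (contig in names(sequences)) {
      fwd <- sequences[[contig]]
      tracks[[contig]] <- list(
        plus = predict_sliding(predictor, encode_sequence(fwd), window),
        minus = predict_sliding(predictor, encode_sequence(revcomp(fwd)),
                                window)
      )
    }
    message(sprintf("predicted tracks with %d bp windows", window))
  } else if (is.character(tracks)) {
    tracks <- readRDS(tracks)
  }
  ann <- decode_genome(tracks, sequences, params)
  message(sprintf("decoded %d gene model(s)", length(ann$models)))
  write_gff3(ann, out_gff3)
  message(sprintf("wrote %s", out_gff3))
  invisible(ann)
}
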