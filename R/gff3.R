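#' Annotation set container
#'
#' A collection of primary gene models together with the contig lengths they
#' live on; the unit serialized to and from GFF3.
#'
#' @param models List of [gene_model()] objects.
#' @param seqlengths Named integer vector of contig lengths.
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(models, seqlengths) {
  stopifnot(is.list(models))
  seqlengths <- stats::setNames(as.integer(seqlengths), names(seqlengths))
  ord <- order(vapply(models, function(m) m$contig, character(1L)),
               vapply(models, function(m) gene_span(m)[1L], integer(1L)),
               vapply(models, function(m) m$strand, character(1L)))
  structure(list(models = models[ord], seqlengths = seqlengths),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d gene model(s) on %d contig(s)\n",
              length(x$models), length(x$seqlengths)))
  invisible(x)
}

## GFF3 phase of each CDS part: number of bases of the part that belong to
## the previous codon's completion, given the CDS length preceding it in
## transcript order.
.cds_phases <- function(gm) {
  cds <- gm$cds
  n <- nrow(cds)
  if (n == 0L) return(integer(0))
  ord <- if (gm$strand == "+") seq_len(n) else rev(seq_len(n))
  lens <- cds[ord, 2L] - cds[ord, 1L]
  before <- c(0L, cumsum(lens)[-n])
  phase_tx <- (3L - before %% 3L) %% 3L
  out <- integer(n)
  out[ord] <- phase_tx
  out
}

#' Write an annotation set to GFF3
#'
#' Emits gene, mRNA, exon, CDS, five_prime_UTR and three_prime_UTR rows with
#' 1-based inclusive coordinates, deterministic ordering (contig, then start)
#' and CDS phase columns consistent with the models' reading frames.  Models
#' violating their structural invariants are refused with a diagnosis.
#'
#' @param ann An [annotation_set()].
#' @param path Output file path (or `""` to return the text invisibly only).
#' @return Invisibly, the GFF3 text as a character vector of lines.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  for (gm in ann$models) {
    issues <- validate_gene_model(gm)
    if (length(issues) > 0L) {
      stop(sprintf("refusing to write invalid gene model %s: %s",
                   gm$gene_id, paste(issues, collapse = "; ")))
    }
  }
  lines <- c("##gff-version 3")
  for (contig in names(ann$seqlengths)) {
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", contig,
                              ann$seqlengths[[contig]]))
  }
  row <- function(contig, type, start0, end0, strand, phase, attrs) {
    sprintf("%s\tgenedecoder\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            contig, type, start0 + 1L, end0, strand, phase, attrs)
  }
  for (gm in ann$models) {
    span <- gene_span(gm)
    gid <- gm$gene_id
    tid <- paste0(gid, ".t1")
    lines <- c(lines,
               row(gm$contig, "gene", span[1L], span[2L], gm$strand, ".",
                   sprintf("ID=%s", gid)),
               row(gm$contig, "mRNA", span[1L], span[2L], gm$strand, ".",
                   sprintf("ID=%s;Parent=%s", tid, gid)))
    for (i in seq_len(nrow(gm$exons))) {
      lines <- c(lines, row(gm$contig, "exon", gm$exons[i, 1L],
                            gm$exons[i, 2L], gm$strand, ".",
                            sprintf("Parent=%s", tid)))
    }
    phases <- .cds_phases(gm)
    for (i in seq_len(nrow(gm$cds))) {
      lines <- c(lines, row(gm$contig, "CDS", gm$cds[i, 1L], gm$cds[i, 2L],
                            gm$strand, as.character(phases[i]),
                            sprintf("Parent=%s", tid)))
    }
    u <- utrs_of(gm)
    for (i in seq_len(nrow(u$five))) {
      lines <- c(lines, row(gm$contig, "five_prime_UTR", u$five[i, 1L],
                            u$five[i, 2L], gm$strand, ".",
                            sprintf("Parent=%s", tid)))
    }
    for (i in seq_len(nrow(u$three))) {
      lines <- c(lines, row(gm$contig, "three_prime_UTR", u$three[i, 1L],
                            u$three[i, 2L], gm$strand, ".",
                            sprintf("Parent=%s", tid)))
    }
  }
  if (nzchar(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read gene models from a GFF3 file
#'
#' Parses a GFF3 file (via `rtracklayer`) tolerating the usual
#' gene/mRNA/exon/CDS/UTR hierarchy and converts to the internal 0-based
#' half-open representation.  When a gene carries several transcripts, the
#' one with the longest total CDS (longest protein) is kept as the primary
#' transcript.  Transcripts without exon rows fall back to their CDS
#' intervals as exons.
#'
#' @param path GFF3 file path.
#' @param seqlengths Optional named contig lengths; defaults to the
#'   `##sequence-region` pragmas when present.
#' @return An [annotation_set()].
#' @export
read_gff3 <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (is.null(seqlengths)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (all(is.na(sl))) {
      sl <- vapply(split(BiocGenerics::end(gr),
                         as.character(GenomeInfoDb::seqnames(gr))),
                   max, numeric(1L))
    }
    seqlengths <- sl
  }
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA, length(gr))
  parents <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p[1L]) else NA_character_,
           character(1L))
  } else rep(NA_character_, length(gr))
  is_tx <- type %in% c("mRNA", "transcript")
  tx_ids <- ids[is_tx]
  tx_parent <- parents[is_tx]
  models <- list()
  for (k in seq_along(tx_ids)) {
    tid <- tx_ids[k]
    child <- which(parents == tid)
    exon_rows <- child[type[child] == "exon"]
    cds_rows <- child[type[child] == "CDS"]
    if (length(cds_rows) == 0L && length(exon_rows) == 0L) next
    to_mat <- function(rows) {
      if (length(rows) == 0L) return(NULL)
      cbind(BiocGenerics::start(gr)[rows] - 1L, BiocGenerics::end(gr)[rows])
    }
    exons <- to_mat(exon_rows)
    cds <- to_mat(cds_rows)
    if (is.null(exons)) exons <- cds
    contig <- as.character(GenomeInfoDb::seqnames(gr))[is_tx][k]
    strand <- as.character(BiocGenerics::strand(gr))[is_tx][k]
    if (!strand %in% c("+", "-")) strand <- "+"
    gid <- if (is.na(tx_parent[k])) tid else tx_parent[k]
    models[[length(models) + 1L]] <-
      list(model = gene_model(gid, contig, strand, exons, cds), gene = gid)
  }
  ## keep the longest-protein transcript per gene
  genes <- vapply(models, `[[`, character(1L), "gene")
  keep <- tapply(seq_along(models), genes, function(idx) {
    lens <- vapply(idx, function(i) total_cds_length(models[[i]]$model),
                   integer(1L))
    idx[which.max(lens)]
  })
  models <- lapply(models[sort(unname(keep))], `[[`, "model")
  annotation_set(models, seqlengths)
}
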