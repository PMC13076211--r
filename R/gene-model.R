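#' Construct a primary gene model
#'
#' A gene model holds one primary transcript: its exon and CDS intervals on a
#' contig.  Intervals are 0-based half-open `[start, end)` in forward genomic
#' coordinates regardless of strand; GFF3 input/output converts to and from
#' 1-based inclusive coordinates.  UTR intervals are derived (exonic sequence
#' outside the CDS) rather than stored.
#'
#' @param gene_id Character scalar identifier.
#' @param contig Contig (sequence) name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column integer matrix of `[start, end)` exon intervals.
#' @param cds Two-column integer matrix of `[start, end)` CDS intervals.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, exons, cds) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- .as_interval_matrix(exons, "exons")
  cds <- .as_interval_matrix(cds, "cds")
  structure(
    list(gene_id = as.character(gene_id), contig = as.character(contig),
         strand = strand, exons = exons, cds = cds),
    class = "gene_model"
  )
}

.as_interval_matrix <- function(x, what) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0L) || length(x) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  if (!is.matrix(x)) x <- matrix(as.integer(x), ncol = 2L, byrow = FALSE)
  storage.mode(x) <- "integer"
  if (ncol(x) != 2L) stop(what, " must be a two-column matrix")
  x <- x[order(x[, 1L]), , drop = FALSE]
  if (any(x[, 2L] <= x[, 1L])) stop(what, " intervals must satisfy end > start")
  dimnames(x) <- list(NULL, c("start", "end"))
  x
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s> %s:%d-%d (%s), %d exon(s), CDS %d bp\n",
              x$gene_id, x$contig, gene_span(x)[1L], gene_span(x)[2L],
              x$strand, nrow(x$exons), total_cds_length(x)))
  invisible(x)
}

#' Genomic span of a gene model
#' @param gm A `gene_model`.
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
gene_span <- function(gm) {
  c(min(gm$exons[, 1L]), max(gm$exons[, 2L]))
}

#' Total CDS length of a gene model in bases
#' @param gm A `gene_model`.
#' @export
total_cds_length <- function(gm) {
  if (nrow(gm$cds) == 0L) return(0L)
  sum(gm$cds[, 2L] - gm$cds[, 1L])
}

#' Intron intervals of a gene model
#'
#' Gaps between consecutive exons, 0-based half-open, in forward genomic
#' coordinates.
#' @param gm A `gene_model`.
#' @export
introns_of <- function(gm) {
  ex <- gm$exons
  if (nrow(ex) < 2L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  m <- cbind(start = ex[-nrow(ex), 2L], end = ex[-1L, 1L])
  storage.mode(m) <- "integer"
  m
}

#' UTR intervals of a gene model
#'
#' Exonic bases outside the CDS, split into five-prime and three-prime sides
#' according to strand.
#' @param gm A `gene_model`.
#' @return List with interval matrices `five` and `three`.
#' @export
utrs_of <- function(gm) {
  if (nrow(gm$cds) == 0L) {
    side <- gm$exons
    empty <- matrix(integer(0), ncol = 2L)
    return(if (gm$strand == "+") list(five = side, three = empty)
           else list(five = side, three = empty))
  }
  cds_lo <- min(gm$cds[, 1L])
  cds_hi <- max(gm$cds[, 2L])
  left <- list(); right <- list()
  for (i in seq_len(nrow(gm$exons))) {
    s <- gm$exons[i, 1L]; e <- gm$exons[i, 2L]
    if (s < cds_lo) left[[length(left) + 1L]] <- c(s, min(e, cds_lo))
    if (e > cds_hi) right[[length(right) + 1L]] <- c(max(s, cds_hi), e)
  }
  left <- .as_interval_matrix(do.call(rbind, left), "utr")
  right <- .as_interval_matrix(do.call(rbind, right), "utr")
  if (gm$strand == "+") list(five = left, three = right)
  else list(five = right, three = left)
}

#' Mirror a gene model into reverse-complement coordinates
#'
#' Maps every interval `[s, e)` on a contig of length `L` to `[L - e, L - s)`
#' and flips the strand.  Applying the map twice is the identity.  This is the
#' coordinate transform used to process minus-strand features on the reverse
#' complement as if they were plus-strand.
#'
#' @param gm A `gene_model`.
#' @param contig_length Length of the contig in bases.
#' @export
flip_gene_model <- function(gm, contig_length) {
  L <- as.integer(contig_length)
  flip <- function(m) {
    if (nrow(m) == 0L) return(m)
    .as_interval_matrix(cbind(L - m[, 2L], L - m[, 1L]), "interval")
  }
  gene_model(gm$gene_id, gm$contig, if (gm$strand == "+") "-" else "+",
             flip(gm$exons), flip(gm$cds))
}

#' Spliced CDS sequence of a gene model
#'
#' Concatenates the CDS intervals and, for minus-strand models, reverse
#' complements the result so the returned string reads 5' to 3' in transcript
#' orientation (starting at the start codon).
#'
#' @param gm A `gene_model`.
#' @param seq Contig sequence as a character string.
#' @export
spliced_cds <- function(gm, seq) {
  if (nrow(gm$cds) == 0L) return("")
  parts <- vapply(seq_len(nrow(gm$cds)), function(i) {
    substr(seq, gm$cds[i, 1L] + 1L, gm$cds[i, 2L])
  }, character(1L))
  s <- toupper(paste0(parts, collapse = ""))
  if (gm$strand == "-") revcomp(s) else s
}

#' Validate a gene model against its structural invariants
#'
#' Checks interval sanity (sorted, non-overlapping exons; CDS contained in
#' exons), that the total CDS length is a multiple of 3 and, when the contig
#' sequence is supplied, the canonical grammar: the coding sequence begins
#' with ATG, ends with TAA/TAG/TGA, contains no internal in-frame stop codon,
#' and every intron starts with GT and ends with AG.
#'
#' @param gm A `gene_model`.
#' @param seq Optional contig sequence (character) for motif checks.
#' @param check_internal_stops Also scan for premature in-frame stops.
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_gene_model <- function(gm, seq = NULL, check_internal_stops = TRUE) {
  issues <- character(0)
  ex <- gm$exons
  if (nrow(ex) == 0L) return("gene model has no exons")
  if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L])) {
    issues <- c(issues, "exons overlap or are unsorted")
  }
  if (nrow(gm$cds) == 0L) {
    issues <- c(issues, "gene model has no CDS")
  } else {
    for (i in seq_len(nrow(gm$cds))) {
      inside <- any(gm$cds[i, 1L] >= ex[, 1L] & gm$cds[i, 2L] <= ex[, 2L])
      if (!inside) {
        issues <- c(issues,
                    sprintf("CDS interval [%d,%d) not contained in an exon",
                            gm$cds[i, 1L], gm$cds[i, 2L]))
      }
    }
    if (total_cds_length(gm) %% 3L != 0L) {
      issues <- c(issues, "total CDS length is not a multiple of 3")
    }
  }
  if (!is.null(seq)) {
    seq <- toupper(seq)
    L <- nchar(seq)
    if (gene_span(gm)[1L] < 0L || gene_span(gm)[2L] > L) {
      issues <- c(issues, "gene model extends beyond contig bounds")
      return(issues)
    }
    if (nrow(gm$cds) > 0L && total_cds_length(gm) %% 3L == 0L) {
      cds_seq <- spliced_cds(gm, seq)
      if (substr(cds_seq, 1L, 3L) != "ATG") {
        issues <- c(issues, "coding sequence does not begin with ATG")
      }
      last <- substr(cds_seq, nchar(cds_seq) - 2L, nchar(cds_seq))
      if (!last %in% STOP_CODONS) {
        issues <- c(issues, "coding sequence does not end with a stop codon")
      }
      if (check_internal_stops && nchar(cds_seq) >= 6L) {
        n_codons <- nchar(cds_seq) / 3L
        starts <- 3L * (seq_len(n_codons - 1L) - 1L) + 1L
        codons <- substring(cds_seq, starts, starts + 2L)
        if (any(codons[-1L] %in% STOP_CODONS)) {
          issues <- c(issues, "internal in-frame stop codon in CDS")
        }
      }
    }
    ints <- introns_of(gm)
    for (i in seq_len(nrow(ints))) {
      intron_seq <- substr(seq, ints[i, 1L] + 1L, ints[i, 2L])
      if (gm$strand == "-") intron_seq <- revcomp(intron_seq)
      if (nchar(intron_seq) < 4L) {
        issues <- c(issues, sprintf("intron %d shorter than 4 bases", i))
        next
      }
      if (substr(intron_seq, 1L, 2L) != "GT") {
        issues <- c(issues, sprintf("intron %d does not start with GT", i))
      }
      if (substr(intron_seq, nchar(intron_seq) - 1L, nchar(intron_seq)) != "AG") {
        issues <- c(issues, sprintf("intron %d does not end with AG", i))
      }
    }
  }
  issues
}

#' Test two gene models for exact structural identity
#'
#' Identical contig, strand, exon intervals and CDS intervals.
#' @param a,b `gene_model` objects.
#' @export
same_gene_model <- function(a, b) {
  identical(a$contig, b$contig) && identical(a$strand, b$strand) &&
    identical(unname(a$exons), unname(b$exons)) &&
    identical(unname(a$cds), unname(b$cds))
}
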