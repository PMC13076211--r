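#' IUPAC nucleotide encoding table
#'
#' Row per IUPAC code, columns in channel order C, A, T, G.  Unambiguous bases
#' are one-hot; ambiguity codes spread probability uniformly over the
#' compatible bases, so every row sums to 1.
#' @keywords internal
iupac_encoding_table <- local({
  compat <- list(
    C = "C", A = "A", T = "T", G = "G", U = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
  enc <- matrix(0, nrow = length(compat), ncol = 4,
                dimnames = list(names(compat), c("C", "A", "T", "G")))
  for (code in names(compat)) {
    enc[code, compat[[code]]] <- 1 / length(compat[[code]])
  }
  enc
})

#' One-hot / ambiguity encoding of a nucleotide sequence
#'
#' Encodes an IUPAC nucleotide string as a `length x 4` matrix in channel
#' order C, A, T, G.  Unambiguous bases give one-hot rows; ambiguity codes
#' give a uniform distribution over the compatible bases (e.g. `R` becomes
#' 0.5 A + 0.5 G, `N` becomes 0.25 everywhere), so every row sums to 1.
#'
#' @param seq A single character string (case-insensitive), a
#'   [Biostrings::DNAString], or a character vector of single bases.
#' @return A numeric matrix with one row per base and columns `C, A, T, G`.
#' @examples
#' encode_sequence("CATG")
#' encode_sequence("NRY")
#' @export
encode_sequence <- function(seq) {
  chars <- .as_base_chars(seq)
  if (length(chars) == 0L) {
    stop("sequence is empty")
  }
  idx <- match(chars, rownames(iupac_encoding_table))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("non-IUPAC character '%s' at position %d", chars[bad], bad))
  }
  m <- iupac_encoding_table[idx, , drop = FALSE]
  dimnames(m) <- list(NULL, BASE_CHANNELS)
  m
}

## Split any accepted sequence representation into an uppercase character
## vector of single bases.
.as_base_chars <- function(seq) {
  if (inherits(seq, "DNAString") || inherits(seq, "DNAStringSet")) {
    seq <- as.character(seq)
  }
  if (!is.character(seq)) {
    stop("sequence must be a character string or DNAString")
  }
  if (length(seq) == 1L) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  } else {
    chars <- seq
  }
  toupper(chars)
}

## Reverse complement for plain character strings (IUPAC-aware).
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
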