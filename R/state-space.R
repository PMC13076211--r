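#' Penalty and decoding parameters
#'
#' All decoder penalties are configuration constants encoding well-established
#' gene grammar, not fitted likelihoods.  Candidate genic regions are
#' intervals whose sliding-window mean intergenic probability stays below
#' `intergenic_threshold`; emissions are floored at `emission_floor` before
#' taking logs; transitions at sequences conflicting with the grammar cost
#' the configured motif penalties (infinite = canonical-only, the default;
#' `donor_gcag` may be set finite to admit GC-AG introns at a price).
#'
#' @param intergenic_window Sliding-window width in bases for candidate
#'   region detection.
#' @param intergenic_threshold Windowed mean intergenic probability below
#'   which a base is candidate-genic.
#' @param emission_floor Small probability floor used inside
#'   `-log(max(floor, p))`.
#' @param min_cds_length Decoded genes with a shorter total CDS are dropped.
#' @param motif_penalties Named list of non-negative penalties (or `Inf`):
#'   `codon` for start/stop codon bases that do not match the canonical
#'   motifs, `donor_gcag` and `donor_other` for the non-canonical donor
#'   classes, `acceptor` for intron ends not reading AG.
#' @param intron_motif_classes The donor motif classes; must have length 3
#'   so the intron state count comes out at 60.
#' @return Object of class `penalty_params`.
#' @export
penalty_params <- function(intergenic_window = 100L,
                           intergenic_threshold = 0.5,
                           emission_floor = 1e-8,
                           min_cds_length = 60L,
                           motif_penalties = list(codon = Inf,
                                                  donor_gcag = Inf,
                                                  donor_other = Inf,
                                                  acceptor = Inf),
                           intron_motif_classes = c("gtag", "gcag", "other")) {
  stopifnot(intergenic_window >= 1L,
            intergenic_threshold > 0, intergenic_threshold < 1,
            emission_floor > 0, emission_floor <= 1,
            min_cds_length >= 0L)
  defaults <- list(codon = Inf, donor_gcag = Inf, donor_other = Inf,
                   acceptor = Inf)
  for (nm in names(motif_penalties)) defaults[[nm]] <- motif_penalties[[nm]]
  if (any(unlist(defaults) < 0)) stop("motif penalties must be non-negative")
  structure(list(intergenic_window = as.integer(intergenic_window),
                 intergenic_threshold = intergenic_threshold,
                 emission_floor = emission_floor,
                 min_cds_length = as.integer(min_cds_length),
                 motif_penalties = defaults,
                 intron_motif_classes = intron_motif_classes),
            class = "penalty_params")
}

## Sequence-condition kinds attached to transitions.  Base conditions apply
## to the destination base, donor conditions to the first two intron bases,
## acceptor ("acc*") conditions to the two bases preceding the destination
## (the intron's final AG) plus optionally the destination base itself.
TRANSITION_KINDS <- c("none", "base_A", "base_T", "base_G", "base_AG",
                      "donor_gtag", "donor_gcag", "donor_other",
                      "acc", "acc_A", "acc_T", "acc_G", "acc_AG",
                      "not_stop")

#' Build the decoder state space
#'
#' Enumerates the states of the gene-structure grammar and their legal
#' transitions.  Super-states are intergenic, UTR, CDS and intron.  The CDS
#' super-state has exactly 10 substates: three start-codon positions, three
#' regular codon positions (by phase) and a four-state stop-codon automaton
#' (T, TA, TG and the final base).  The intron super-state has exactly 60
#' substates: entry-or-continuation (2) times donor motif class (3: GT-AG,
#' GC-AG, other) times outer state (10: the state the path resumes after the
#' intron -- one of nine CDS substates or the 5' UTR).  Every transition
#' either requires no motif or names a canonical motif condition (ATG bases,
#' stop-codon bases, GT/GC donors, AG acceptor); non-canonical alternatives
#' carry the configured penalties.
#'
#' @param params A [penalty_params()].
#' @return Object of class `hmm_state_space` with `states` and `transitions`
#'   data frames.
#' @export
build_state_space <- function(params = penalty_params()) {
  motifs <- params$intron_motif_classes
  if (length(motifs) != 3L || anyDuplicated(motifs)) {
    stop("intron_motif_classes must be 3 distinct classes ",
         "(the intron substate count must come out at 60)")
  }
  cds_def <- data.frame(
    name = c("S0", "S1", "S2", "R0", "R1", "R2", "T", "TA", "TG", "F"),
    codon_pos = c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 1L, 2L),
    stringsAsFactors = FALSE
  )
  states <- data.frame(
    name = c("IG", "U5", "U3", cds_def$name),
    type = c("ig", "utr5", "utr3", rep("cds", 10L)),
    super = c("intergenic", "utr", "utr", rep("cds", 10L)),
    codon_pos = c(NA, NA, NA, cds_def$codon_pos),
    stringsAsFactors = FALSE
  )
  ## outer state: where the path resumes after the intron
  outers <- c("U5", "S1", "S2", "R0", "R1", "R2", "T", "TA", "TG", "F")
  for (o in outers) {
    for (m in motifs) {
      states <- rbind(states, data.frame(
        name = c(sprintf("I_start_%s_%s", m, o),
                 sprintf("I_cont_%s_%s", m, o)),
        type = "intron", super = "intron", codon_pos = NA,
        stringsAsFactors = FALSE))
    }
  }
  states$id <- seq_len(nrow(states))
  states$class_idx <- match(states$super, GENIC_CLASSES)
  states$phase_idx <- ifelse(is.na(states$codon_pos), NA_integer_,
                             PHASE_OF_CODON_POS[states$codon_pos + 1L] + 2L)
  sid <- stats::setNames(states$id, states$name)

  tr <- list()
  add <- function(from, to, kind) {
    tr[[length(tr) + 1L]] <<- data.frame(from = sid[[from]], to = sid[[to]],
                                         kind = kind,
                                         stringsAsFactors = FALSE)
  }
  ## entry base condition of each resumable state (also used on intron exit)
  entry_base <- c(S0 = "base_A", S1 = "base_T", S2 = "base_G",
                  R0 = "none", R1 = "none", R2 = "none",
                  T = "base_T", TA = "base_A", TG = "base_G", F = "base_AG",
                  U5 = "none", U3 = "none", IG = "none")
  add("IG", "IG", "none"); add("IG", "U5", "none"); add("IG", "S0", "base_A")
  add("U5", "U5", "none"); add("U5", "S0", "base_A")
  add("S0", "S1", "base_T"); add("S1", "S2", "base_G")
  add("S2", "R0", "none"); add("S2", "T", "base_T")
  ## completing a regular codon read contiguously must not spell a stop;
  ## codons interrupted by an intron cannot be checked (their first bases
  ## are not part of the Markov state) and are left unconstrained
  add("R0", "R1", "none"); add("R1", "R2", "not_stop")
  add("R2", "R0", "none"); add("R2", "T", "base_T")
  add("T", "TA", "base_A"); add("T", "TG", "base_G")
  add("TA", "F", "base_AG"); add("TG", "F", "base_A")
  add("F", "U3", "none"); add("F", "IG", "none")
  add("U3", "U3", "none"); add("U3", "IG", "none")
  ## which exon states an intron with a given outer state can follow;
  ## the outer is the successor the donor-side state would have had
  intron_prev <- list(U5 = "U5", S1 = "S0", S2 = "S1",
                      R0 = c("S2", "R2"), R1 = "R0", R2 = "R1",
                      T = c("S2", "R2"), TA = "T", TG = "T", F = "TA")
  donor_kind <- stats::setNames(paste0("donor_", motifs), motifs)
  for (o in outers) {
    for (m in motifs) {
      i_start <- sprintf("I_start_%s_%s", m, o)
      i_cont <- sprintf("I_cont_%s_%s", m, o)
      for (p in intron_prev[[o]]) add(p, i_start, donor_kind[[m]])
      add(i_start, i_cont, "none")
      add(i_cont, i_cont, "none")
      exit_kind <- if (entry_base[[o]] == "none") "acc" else {
        sub("^base_", "acc_", entry_base[[o]])
      }
      add(i_cont, o, exit_kind)
    }
  }
  transitions <- do.call(rbind, tr)
  ## deterministic tie-break order: by destination, then by source id
  ## (intergenic first), so equal-cost paths prefer staying intergenic longer
  transitions <- transitions[order(transitions$to, transitions$from), ]
  rownames(transitions) <- NULL
  transitions$kind_idx <- match(transitions$kind, TRANSITION_KINDS)
  stopifnot(!anyNA(transitions$kind_idx))
  structure(list(states = states, transitions = transitions,
                 params = params),
            class = "hmm_state_space")
}

#' @export
print.hmm_state_space <- function(x, ...) {
  cat(sprintf("<hmm_state_space> %d states (%d CDS, %d intron), %d transitions\n",
              nrow(x$states), sum(x$states$type == "cds"),
              sum(x$states$type == "intron"), nrow(x$transitions)))
  invisible(x)
}

#' Emission penalty of a state at one base
#'
#' `-log(max(eps, P[state's genic class]))` plus, for CDS substates,
#' `-log(max(eps, P[state's coding phase]))`.
#'
#' @param state State name or id.
#' @param class_row,phase_row Length-4 probability vectors for this base.
#' @param params A [penalty_params()].
#' @param space A [build_state_space()] result.
#' @return Non-negative penalty.
#' @export
emission_penalty <- function(state, class_row, phase_row,
                             params = penalty_params(),
                             space = build_state_space(params)) {
  st <- .lookup_state(space, state)
  eps <- params$emission_floor
  pen <- -log(max(eps, class_row[[st$class_idx]]))
  if (!is.na(st$phase_idx)) {
    pen <- pen - log(max(eps, phase_row[[st$phase_idx]]))
  }
  pen
}

.lookup_state <- function(space, state) {
  states <- space$states
  if (is.character(state)) {
    i <- match(state, states$name)
  } else {
    i <- match(as.integer(state), states$id)
  }
  if (is.na(i)) stop("unknown state: ", state)
  states[i, ]
}

#' Per-position penalties of every transition condition
#'
#' Evaluates, for every base of a sequence, the penalty of each condition in
#' `TRANSITION_KINDS`: 0 when the local sequence matches the canonical
#' motif, the configured motif penalty (default infinity) otherwise.
#' Ambiguous bases never match a motif condition.
#'
#' @param seq_chars Uppercase character vector of single bases.
#' @param params A [penalty_params()].
#' @return Numeric `n x 13` matrix, columns in `TRANSITION_KINDS` order.
#' @keywords internal
kind_penalty_matrix <- function(seq_chars, params) {
  n <- length(seq_chars)
  mp <- params$motif_penalties
  m <- matrix(Inf, nrow = n, ncol = length(TRANSITION_KINDS),
              dimnames = list(NULL, TRANSITION_KINDS))
  m[, "none"] <- 0
  base_pen <- function(ok) ifelse(ok, 0, mp$codon)
  m[, "base_A"] <- base_pen(seq_chars == "A")
  m[, "base_T"] <- base_pen(seq_chars == "T")
  m[, "base_G"] <- base_pen(seq_chars == "G")
  m[, "base_AG"] <- base_pen(seq_chars %in% c("A", "G"))
  nxt <- c(seq_chars[-1L], "")
  m[, "donor_gtag"] <- ifelse(seq_chars == "G" & nxt == "T", 0, Inf)
  m[, "donor_gcag"] <- ifelse(seq_chars == "G" & nxt == "C",
                              mp$donor_gcag, Inf)
  m[, "donor_other"] <- mp$donor_other
  prev2 <- c(rep("", min(2L, n)), seq_chars[seq_len(max(0L, n - 2L))])
  prev1 <- c(rep("", min(1L, n)), seq_chars[seq_len(max(0L, n - 1L))])
  acc_ok <- prev2 == "A" & prev1 == "G"
  acc_base <- ifelse(acc_ok, 0, mp$acceptor)
  m[, "acc"] <- acc_base
  m[, "acc_A"] <- acc_base + base_pen(seq_chars == "A")
  m[, "acc_T"] <- acc_base + base_pen(seq_chars == "T")
  m[, "acc_G"] <- acc_base + base_pen(seq_chars == "G")
  m[, "acc_AG"] <- acc_base + base_pen(seq_chars %in% c("A", "G"))
  codon_end_here <- paste0(prev2, prev1, seq_chars)
  m[, "not_stop"] <- ifelse(codon_end_here %in% STOP_CODONS, mp$codon, 0)
  m
}

#' Transition penalty between two states at a position
#'
#' Penalty of taking the transition whose destination base is at `pos`
#' (1-based) of `seq`: 0 at the required motif, the configured penalty for a
#' recognised non-canonical class, infinity for transitions not in the
#' table.
#'
#' @param from,to State names or ids.
#' @param seq Contig or region sequence (character string or vector).
#' @param pos 1-based position of the destination base.
#' @inheritParams emission_penalty
#' @export
transition_penalty <- function(from, to, seq, pos,
                               params = penalty_params(),
                               space = build_state_space(params)) {
  f <- .lookup_state(space, from)$id
  t <- .lookup_state(space, to)$id
  row <- space$transitions[space$transitions$from == f &
                             space$transitions$to == t, ]
  if (nrow(row) == 0L) return(Inf)
  chars <- .as_base_chars(seq)
  kp <- kind_penalty_matrix(chars, params)
  unname(kp[pos, row$kind_idx[1L]])
}
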