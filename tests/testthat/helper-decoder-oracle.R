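# Independent oracle for the decoder: exhaustive depth-first enumeration of
# every legal state path (with cost-bound pruning), sharing only the penalty
# definitions with the implementation, not the dynamic program.

brute_force_min_penalty <- function(class_probs, phase_probs, seq_chars,
                                    params = penalty_params(),
                                    space = build_state_space(params)) {
  n <- length(seq_chars)
  st <- space$states
  eps <- params$emission_floor
  clpen <- -log(pmax(class_probs, eps))
  phpen <- -log(pmax(phase_probs, eps))
  kp <- genedecoder:::kind_penalty_matrix(seq_chars, params)
  emis <- function(i, s) {
    e <- clpen[i, st$class_idx[s]]
    if (!is.na(st$phase_idx[s])) e <- e + phpen[i, st$phase_idx[s]]
    e
  }
  adj <- split(space$transitions[, c("to", "kind_idx")],
               space$transitions$from)
  ig <- st$id[st$name == "IG"]
  best <- Inf
  rec <- function(pos, s, cost) {
    if (cost >= best) return(invisible())
    if (pos == n) {
      if (s == ig && cost < best) best <<- cost
      return(invisible())
    }
    out <- adj[[as.character(s)]]
    if (is.null(out)) return(invisible())
    for (j in seq_len(nrow(out))) {
      p <- unname(kp[pos + 1L, out$kind_idx[j]])
      if (!is.finite(p)) next
      to <- out$to[j]
      rec(pos + 1L, to, cost + p + emis(pos + 1L, to))
    }
    invisible()
  }
  rec(1L, ig, emis(1L, ig))
  best
}

# random instance: spiky probability rows plus random sequence
random_decoder_instance <- function(n, seed) {
  set.seed(seed)
  cls <- genedecoder:::.rdirichlet(n, 0.4)
  phs <- genedecoder:::.rdirichlet(n, 0.4)
  seq_chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  list(class = cls, phase = phs, seq = seq_chars)
}

dp_min_penalty <- function(inst, params = penalty_params(),
                           space = build_state_space(params)) {
  tr <- prediction_tracks(inst$class, inst$phase, validate = FALSE)
  n <- nrow(inst$class)
  eps <- params$emission_floor
  st <- space$states
  ig <- st$id[st$name == "IG"] - 1L
  res <- genedecoder:::viterbi_min_path(
    tr_from = space$transitions$from - 1L,
    tr_to = space$transitions$to - 1L,
    tr_kind = space$transitions$kind_idx - 1L,
    clpen = -log(pmax(inst$class, eps)),
    phpen = -log(pmax(inst$phase, eps)),
    kindpen = genedecoder:::kind_penalty_matrix(inst$seq, params),
    state_class = st$class_idx - 1L,
    state_phase = ifelse(is.na(st$phase_idx), -1L, st$phase_idx - 1L),
    init_state = ig, final_state = ig)
  res$cost
}
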