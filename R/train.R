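## Feature construction for the toy per-base classifier.  Three blocks:
## (1) a convolution-style window of one-hot base channels around each
## position; (2) reading-frame features (length of the stop-free codon run
## containing the position, per genomic frame) and local motif flags, giving
## the model access to open-reading-frame structure; (3) a fixed-decay
## bidirectional recurrent layer: exponential moving averages of the motif
## and frame indicators, run forward and backward at two decay scales, which
## summarise gene-body context far beyond the local window.
.toy_features <- function(encoding, k = 10L, decays = c(0.95, 0.99)) {
  n <- nrow(encoding)
  ctx <- matrix(0, nrow = n, ncol = 4L * (2L * k + 1L))
  col <- 0L
  for (d in (-k):k) {
    src <- seq_len(n) + d
    ok <- src >= 1L & src <= n
    block <- matrix(0, nrow = n, ncol = 4L)
    block[ok, ] <- encoding[src[ok], , drop = FALSE]
    ctx[, col + 1:4] <- block
    col <- col + 4L
  }
  chars <- BASE_CHANNELS[max.col(encoding, ties.method = "first")]
  run_len_by_frame <- matrix(0, nrow = n, ncol = 3L)
  for (f in 0:2) {
    starts <- seq(f + 1L, n - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    is_stop <- codons %in% STOP_CODONS
    ## run id increments after each stop codon
    run_id <- cumsum(c(0L, head(is_stop, -1L)))
    run_len <- as.numeric(table(factor(run_id, levels = unique(run_id))))
    codon_run <- run_len[run_id + 1L]
    base_codon <- ((seq_len(n) - 1L - f) %/% 3L) + 1L
    ok <- seq_len(n) > f & base_codon <= length(codons)
    vals <- numeric(n)
    vals[ok] <- codon_run[base_codon[ok]]
    run_len_by_frame[, f + 1L] <- vals
  }
  frame_feats <- cbind(log1p(run_len_by_frame) / log1p(1000),
                       run_len_by_frame >= 30)
  nxt1 <- c(chars[-1L], "")
  nxt2 <- c(chars[-(1:2)], "", "")
  prv1 <- c("", chars[-n])
  max_run <- apply(run_len_by_frame, 1L, max)
  ind <- cbind(atg = as.numeric(chars == "A" & nxt1 == "T" & nxt2 == "G"),
               donor = as.numeric(chars == "G" & nxt1 == "T"),
               acceptor = as.numeric(prv1 == "A" & chars == "G"),
               long_orf = as.numeric(max_run >= 25),
               max_run = log1p(max_run) / log1p(300))
  ema <- vector("list", 2L * length(decays))
  j <- 0L
  for (a in decays) {
    fwd <- apply(ind, 2L, function(x) {
      as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
    })
    bwd <- apply(ind[n:1, , drop = FALSE], 2L, function(x) {
      as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
    })[n:1, , drop = FALSE]
    ema[[j <- j + 1L]] <- fwd
    ema[[j <- j + 1L]] <- bwd
  }
  cbind(ctx, frame_feats, ind, do.call(cbind, ema))
}

.softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## forward pass of the one-hidden-layer dual-head network
.toy_forward <- function(params, X) {
  H <- tanh(sweep(X %*% params$W1, 2L, params$b1, "+"))
  list(H = H,
       class = .softmax_rows(sweep(H %*% params$W2c, 2L, params$b2c, "+")),
       phase = .softmax_rows(sweep(H %*% params$W2p, 2L, params$b2p, "+")))
}

#' Train the toy dual-head per-base predictor
#'
#' A deliberately small sequence labeler honouring the dual-head training
#' contract: one shared hidden layer over windowed sequence features with
#' simultaneous genic-class and coding-phase softmax outputs, trained by
#' full-batch Adam on the composite loss (class head weighted by
#' [transition_weight_map()], head weights from the loss config).  After
#' every epoch the validation genic F1 is logged and the returned model is
#' the checkpoint that maximised it.  Training and validation data must come
#' from different contigs.  Deterministic given `seed`.
#'
#' @param train,validation Lists of per-contig examples, each a list with
#'   `encoding` (a base-encoding matrix) and `truth` (a [labeled_tracks()]).
#' @param cfg A [loss_config()].
#' @param hidden Hidden layer width.
#' @param epochs Number of training epochs.
#' @param batch_size Minibatch size (one Adam step per minibatch).
#' @param lr Adam learning rate.
#' @param context_radius Bases of one-hot context on each side.
#' @param seed Integer seed for initialisation and shuffling.
#' @return Object of class `toy_predictor` with the best checkpoint and an
#'   epoch history (`history$genic_f1`).
#' @export
train_toy <- function(train, validation, cfg = loss_config(), hidden = 32L,
                      epochs = 30L, batch_size = 2048L, lr = 0.01,
                      context_radius = 10L, seed = 1L) {
  prep <- function(examples) {
    X <- do.call(rbind, lapply(examples, function(e) {
      .toy_features(e$encoding, k = context_radius)
    }))
    cls <- do.call(c, lapply(examples, function(e) {
      max.col(e$truth$class, ties.method = "first")
    }))
    phs <- do.call(c, lapply(examples, function(e) {
      max.col(e$truth$phase, ties.method = "first")
    }))
    mask <- do.call(c, lapply(examples, function(e) e$truth$mask))
    w <- do.call(c, lapply(examples, function(e) {
      transition_weight_map(e$truth, cfg)
    }))
    list(X = X, cls = cls, phs = phs, mask = mask, w = w)
  }
  tr <- prep(train)
  va <- prep(validation)
  keep <- which(!tr$mask)
  if (length(keep) == 0L) stop("no unmasked bases in the training data")
  X <- tr$X[keep, , drop = FALSE]
  cls <- tr$cls[keep]
  phs <- tr$phs[keep]
  w <- tr$w[keep]
  w <- w / mean(w)
  n <- nrow(X); d <- ncol(X); h <- as.integer(hidden)
  set.seed(as.integer(seed))
  params <- list(W1 = matrix(stats::rnorm(d * h, sd = sqrt(1 / d)), d, h),
                 b1 = numeric(h),
                 W2c = matrix(stats::rnorm(h * 4L, sd = sqrt(1 / h)), h, 4L),
                 b2c = numeric(4L),
                 W2p = matrix(stats::rnorm(h * 4L, sd = sqrt(1 / h)), h, 4L),
                 b2p = numeric(4L))
  m_acc <- lapply(params, function(p) p * 0)
  v_acc <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  onehot <- function(idx) {
    m <- matrix(0, length(idx), 4L)
    m[cbind(seq_along(idx), idx)] <- 1
    m
  }
  Yc <- onehot(cls); Yp <- onehot(phs)
  hw_c <- cfg$genic_head_weight; hw_p <- cfg$phase_head_weight
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        genic_f1 = numeric(0))
  best <- list(f1 = -Inf, params = params)
  step <- 0L
  batch_size <- as.integer(batch_size)
  for (epoch in seq_len(as.integer(epochs))) {
    perm <- sample.int(n)
    epoch_loss <- 0
    n_batches <- ceiling(n / batch_size)
    for (bi in seq_len(n_batches)) {
      sel <- perm[((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)]
      nb <- length(sel)
      Xb <- X[sel, , drop = FALSE]
      wb <- w[sel]
      fw <- .toy_forward(params, Xb)
      ce_c <- -log(pmax(fw$class[cbind(seq_len(nb), cls[sel])], 1e-12))
      ce_p <- -log(pmax(fw$phase[cbind(seq_len(nb), phs[sel])], 1e-12))
      loss <- hw_c * sum(wb * ce_c) / sum(wb) + hw_p * mean(ce_p)
      epoch_loss <- epoch_loss + loss * nb / n
      dZc <- (fw$class - Yc[sel, , drop = FALSE]) * (hw_c * wb / sum(wb))
      dZp <- (fw$phase - Yp[sel, , drop = FALSE]) * (hw_p / nb)
      dH <- dZc %*% t(params$W2c) + dZp %*% t(params$W2p)
      dA <- dH * (1 - fw$H^2)
      grads <- list(W1 = crossprod(Xb, dA), b1 = colSums(dA),
                    W2c = crossprod(fw$H, dZc), b2c = colSums(dZc),
                    W2p = crossprod(fw$H, dZp), b2p = colSums(dZp))
      step <- step + 1L
      for (nm in names(params)) {
        m_acc[[nm]] <- beta1 * m_acc[[nm]] + (1 - beta1) * grads[[nm]]
        v_acc[[nm]] <- beta2 * v_acc[[nm]] + (1 - beta2) * grads[[nm]]^2
        m_hat <- m_acc[[nm]] / (1 - beta1^step)
        v_hat <- v_acc[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] - lr * m_hat / (sqrt(v_hat) + eps)
      }
    }
    loss <- epoch_loss
    ## validation genic F1 for checkpoint selection
    fw_val <- .toy_forward(params, va$X)
    val_truth <- labeled_tracks(onehot(va$cls), onehot(va$phs), va$mask)
    rep <- f1_scores(confusion(max.col(fw_val$class, ties.method = "first"),
                               val_truth, "class"))
    history <- rbind(history, data.frame(epoch = epoch, loss = loss,
                                         genic_f1 = rep$genic_f1))
    if (rep$genic_f1 > best$f1) {
      best <- list(f1 = rep$genic_f1, params = params, epoch = epoch)
    }
  }
  structure(list(params = best$params, best_epoch = best$epoch,
                 best_genic_f1 = best$f1, history = history,
                 context_radius = as.integer(context_radius),
                 loss_config = cfg),
            class = "toy_predictor")
}

#' @export
print.toy_predictor <- function(x, ...) {
  cat(sprintf("<toy_predictor> best epoch %d, validation genic F1 %.4f\n",
              x$best_epoch, x$best_genic_f1))
  invisible(x)
}

#' Predict probability tracks with the toy predictor
#'
#' @param object A [train_toy()] model.
#' @param encoding A base-encoding matrix (see [encode_sequence()]).
#' @param ... Unused.
#' @return A [prediction_tracks()] object.
#' @export
predict.toy_predictor <- function(object, encoding, ...) {
  X <- .toy_features(encoding, k = object$context_radius)
  fw <- .toy_forward(object$params, X)
  prediction_tracks(fw$class, fw$phase, validate = FALSE)
}
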