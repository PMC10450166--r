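# Single-layer attention classifier over token sentences:
#   embedding (word + learned position) -> h-head self-attention with
#   QK^T/d_k scaling -> concatenation -> flatten -> dense(64) -> dense(1)
#   -> sigmoid, trained with class-weighted binary cross-entropy and Adam.
# There are deliberately no residual connections, layer norms or
# feed-forward sublayers: the architecture is exactly embedding, one
# multi-head attention block and the fully connected block.

#' Transformer configuration
#'
#' @param sentence_len Sentence length L (350 for nt-BPE, 1000 for AA, 400
#'   for aa-BPE and PC).
#' @param vocab_size Number of token ids (reserved ids included).
#' @param d_model Embedding width (published setting: 512; reduce, e.g. to
#'   64, for CPU-scale runs).
#' @param heads Number of attention heads h (8).
#' @param fc_hidden Width of the first fully connected layer (64).
#' @param dropout Dropout rate (0.1), applied after the embedding block and
#'   before the final dense layer.
#' @param lr Adam learning rate (0.001).
#' @param batch_size Mini-batch size (256).
#' @param epochs Training epochs (2).
#' @param attention_scale \code{"d_k"} divides attention logits by d_k (as
#'   the method prints); \code{"sqrt_d_k"} is the canonical alternative.
#' @param mask_padding If \code{TRUE}, padding positions (token id 0) are
#'   excluded as attention keys. Off by default: the mask token participates
#'   in attention like any other token.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return Named list of class \code{"transformer_config"}.
#' @export
transformer_config <- function(sentence_len, vocab_size, d_model = 512L,
                               heads = 8L, fc_hidden = 64L, dropout = 0.1,
                               lr = 0.001, batch_size = 256L, epochs = 2L,
                               attention_scale = c("d_k", "sqrt_d_k"),
                               mask_padding = FALSE, seed = 1L) {
  attention_scale <- match.arg(attention_scale)
  stopifnot(d_model %% heads == 0L)
  structure(list(
    sentence_len = as.integer(sentence_len), vocab_size = as.integer(vocab_size),
    d_model = as.integer(d_model), heads = as.integer(heads),
    d_k = as.integer(d_model / heads), fc_hidden = as.integer(fc_hidden),
    dropout = dropout, lr = lr, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), attention_scale = attention_scale,
    mask_padding = mask_padding, seed = as.integer(seed),
    flat_len = as.integer(sentence_len) * as.integer(d_model)),
    class = "transformer_config")
}

xavier <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize a transformer model
#'
#' Uniform Xavier initialization of all weight tensors, biases at zero.
#'
#' @param config A \code{\link{transformer_config}}.
#' @return A \code{plasmeld_transformer}: list with \code{config} and
#'   \code{params} (word, pos, Wq, Wk, Wv, W1, b1, w2, b2).
#' @export
init_transformer <- function(config) {
  set.seed(config$seed)
  L <- config$sentence_len; d <- config$d_model
  h <- config$heads; dk <- config$d_k
  params <- list(
    word = xavier(config$vocab_size, d),
    pos = xavier(L, d),
    Wq = array(xavier(d, dk * h), c(d, dk, h)),
    Wk = array(xavier(d, dk * h), c(d, dk, h)),
    Wv = array(xavier(d, dk * h), c(d, dk, h)),
    W1 = xavier(config$flat_len, config$fc_hidden),
    b1 = numeric(config$fc_hidden),
    w2 = as.numeric(xavier(config$fc_hidden, 1L)),
    b2 = 0)
  structure(list(config = config, params = params),
            class = "plasmeld_transformer")
}

#' @export
print.plasmeld_transformer <- function(x, ...) {
  cfg <- x$config
  cat("attention classifier: L =", cfg$sentence_len, ", d_model =",
      cfg$d_model, ", heads =", cfg$heads, ", flattened length =",
      cfg$flat_len, "\n")
  invisible(x)
}

attn_scale <- function(config) {
  if (config$attention_scale == "d_k") config$d_k else sqrt(config$d_k)
}

row_softmax <- function(S) {
  # column-major recycling subtracts/divides row statistics in place
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

# 0-based masked key columns for a sentence, or integer(0) when masking is
# off or degenerate (all-pad / no-pad sentences are never masked)
masked_cols <- function(config, ids) {
  if (!config$mask_padding || is.null(ids)) return(integer(0))
  ids <- as.integer(ids)
  if (!any(ids == 0L) || !any(ids != 0L)) return(integer(0))
  which(ids == 0L) - 1L
}

#' Embed a token sentence
#'
#' Row i of the output is the word embedding of token i plus the position-i
#' embedding (word + position lookup tables, both learned).
#'
#' @param ids Integer vector of 0-based token ids (a
#'   \code{\link{token_sentence}} works directly).
#' @param model A \code{plasmeld_transformer} (its tables are used).
#' @return Matrix \code{L x d_model}.
#' @export
embed_sentence <- function(ids, model) {
  ids <- as.integer(ids)
  V <- nrow(model$params$word)
  if (any(ids < 0L | ids >= V)) {
    stop("token id out of range at position ", which(ids < 0L | ids >= V)[1L])
  }
  stopifnot(length(ids) == model$config$sentence_len)
  model$params$word[ids + 1L, , drop = FALSE] + model$params$pos
}

# Forward pass through the attention block for one embedded sentence.
# Returns Z (L x d_model) and, optionally, per-head caches.
attention_forward <- function(X, params, config, keep = FALSE, ids = NULL) {
  mc <- masked_cols(config, ids)
  res <- .cpp_attn_forward(X, params$Wq, params$Wk, params$Wv,
                           attn_scale(config), mc, keep)
  cache <- NULL
  if (keep) {
    L <- config$sentence_len
    cache <- lapply(seq_len(config$heads),
                    function(k) list(A = matrix(res$A[, , k], L, L)))
  }
  list(Z = res$Z, cache = cache)
}

#' Multi-head self-attention over an embedded sentence
#'
#' Per head: Q, K, V are linear projections of the input; the attention
#' matrix is the row-softmax of \code{Q K^T / scale} (scale = d_k by
#' default); the head output is \code{alpha V}; head outputs are
#' concatenated column-wise.
#'
#' @param X_embed Matrix \code{L x d_model} from \code{\link{embed_sentence}}.
#' @param model A \code{plasmeld_transformer}.
#' @param return_attention Also return the per-head attention matrices.
#' @return \code{Z} (L x d_model), or a list \code{(Z, attention)} when
#'   \code{return_attention} is \code{TRUE}.
#' @export
multi_head_attention <- function(X_embed, model, return_attention = FALSE) {
  res <- attention_forward(X_embed, model$params, model$config,
                           keep = return_attention)
  if (!return_attention) return(res$Z)
  list(Z = res$Z, attention = lapply(res$cache, `[[`, "A"))
}

#' Fully connected classification head
#'
#' Flattens Z (length L * d_model), applies dense(fc_hidden) with ReLU,
#' dense(1), and a sigmoid.
#'
#' @param Z Attention output matrix \code{L x d_model}.
#' @param model A \code{plasmeld_transformer}.
#' @return Probability in (0, 1).
#' @export
classify_head <- function(Z, model) {
  p <- model$params
  f <- as.vector(Z)
  stopifnot(length(f) == model$config$flat_len)
  a1 <- pmax(drop(crossprod(p$W1, f)) + p$b1, 0)
  stats::plogis(sum(p$w2 * a1) + p$b2)
}

#' Class weights for imbalanced training
#'
#' \code{w_i = max(N_plasmid, N_chromosome) / N_i}: the majority class gets
#' weight 1, the minority class a proportionally larger weight.
#'
#' @param n_plasmid,n_chromosome Positive class counts.
#' @return Named numeric vector \code{c(plasmid=, chromosome=)}.
#' @export
class_weights <- function(n_plasmid, n_chromosome) {
  if (n_plasmid <= 0L || n_chromosome <= 0L) {
    stop("both classes must be present (non-zero counts)")
  }
  m <- max(n_plasmid, n_chromosome)
  c(plasmid = m / n_plasmid, chromosome = m / n_chromosome)
}

# Full forward + backward for a batch. sentences: B x L integer matrix of
# 0-based ids; y in {0,1}; w per-example loss weights. Returns mean weighted
# BCE loss and gradients for every parameter tensor. Dropout masks are drawn
# from the current RNG state when training = TRUE.
transformer_batch_grads <- function(model, sentences, y, w,
                                    training = FALSE) {
  cfg <- model$config; par <- model$params
  B <- nrow(sentences); L <- cfg$sentence_len; d <- cfg$d_model
  keep1 <- 1 - if (training) cfg$dropout else 0
  # cache the attention matrices for the backward pass when they fit
  # comfortably in memory (L^2 * heads doubles per example)
  cache_A <- (as.numeric(L)^2 * cfg$heads * 8 * B) <= 6e8
  Xs <- vector("list", B); M1s <- vector("list", B)
  Acaches <- vector("list", B)
  scale <- attn_scale(cfg)
  Fmat <- matrix(0, cfg$flat_len, B)
  for (b in seq_len(B)) {
    X <- embed_sentence(sentences[b, ], model)
    if (training && cfg$dropout > 0) {
      M1 <- matrix((stats::runif(L * d) < keep1) / keep1, L, d)
      X <- X * M1
      M1s[[b]] <- M1
    }
    Xs[[b]] <- X
    fw <- .cpp_attn_forward(X, par$Wq, par$Wk, par$Wv, scale,
                            masked_cols(cfg, sentences[b, ]), cache_A)
    if (cache_A) Acaches[[b]] <- fw$A
    Fmat[, b] <- as.vector(fw$Z)
  }
  Z1 <- sweep(crossprod(par$W1, Fmat), 1L, par$b1, "+")  # fc_hidden x B
  A1 <- pmax(Z1, 0)
  if (training && cfg$dropout > 0) {
    M2 <- matrix((stats::runif(length(A1)) < keep1) / keep1,
                 nrow(A1), ncol(A1))
    A1d <- A1 * M2
  } else {
    M2 <- NULL; A1d <- A1
  }
  o <- drop(crossprod(A1d, par$w2)) + par$b2
  p <- stats::plogis(o)
  eps <- 1e-12
  loss <- mean(w * -(y * log(p + eps) + (1 - y) * log(1 - p + eps)))
  # ---- backward ----
  do <- w * (p - y) / B                       # d loss / d o, per example
  g <- list()
  g$w2 <- drop(A1d %*% do)
  g$b2 <- sum(do)
  dA1d <- outer(par$w2, do)                   # fc_hidden x B
  dA1 <- if (is.null(M2)) dA1d else dA1d * M2
  dZ1 <- dA1 * (Z1 > 0)
  g$W1 <- Fmat %*% t(dZ1)
  g$b1 <- rowSums(dZ1)
  dF <- par$W1 %*% dZ1                        # flat_len x B
  g$word <- matrix(0, nrow(par$word), d)
  g$pos <- matrix(0, L, d)
  g$Wq <- array(0, dim(par$Wq)); g$Wk <- array(0, dim(par$Wk))
  g$Wv <- array(0, dim(par$Wv))
  no_cache <- array(0, c(0L, 0L, 0L))
  for (b in seq_len(B)) {
    X <- Xs[[b]]
    dZ <- matrix(dF[, b], L, d)
    bk <- .cpp_attn_backward(X, dZ, par$Wq, par$Wk, par$Wv, scale,
                             masked_cols(cfg, sentences[b, ]),
                             if (cache_A) Acaches[[b]] else no_cache)
    g$Wq <- g$Wq + bk$dWq
    g$Wk <- g$Wk + bk$dWk
    g$Wv <- g$Wv + bk$dWv
    dX <- bk$dX
    if (!is.null(M1s[[b]])) dX <- dX * M1s[[b]]
    g$pos <- g$pos + dX
    agg <- rowsum(dX, group = sentences[b, ] + 1L)
    ridx <- as.integer(rownames(agg))
    g$word[ridx, ] <- g$word[ridx, ] + agg
  }
  list(loss = loss, grads = g)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the attention classifier
#'
#' Class-weighted binary cross-entropy (per-example weight
#' \code{max(N_p, N_c) / N_class}) minimized with Adam. Dropout is applied
#' after the embedding block and before the final dense layer. With a fixed
#' config seed the loss trace is reproducible bit-for-bit.
#'
#' @param model A freshly initialized \code{plasmeld_transformer} (or one to
#'   continue training).
#' @param sentences Integer matrix \code{n x L} of 0-based token ids (build
#'   rows with \code{\link{token_sentence}}).
#' @param labels Numeric/integer vector in \{0, 1\} (1 = plasmid) or a
#'   factor/character with levels \code{plasmid}/\code{chromosome}.
#' @param epochs,batch_size,lr Override the config values.
#' @param verbose Print per-epoch mean loss.
#' @return The trained model, with a \code{loss_trace} data.frame
#'   (epoch, batch, loss) attached as \code{model$loss_trace}.
#' @export
train_transformer <- function(model, sentences, labels,
                              epochs = model$config$epochs,
                              batch_size = model$config$batch_size,
                              lr = model$config$lr, verbose = FALSE) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.integer(as.character(labels) == "plasmid")
  }
  y <- as.numeric(labels)
  stopifnot(nrow(sentences) == length(y), all(y %in% c(0, 1)))
  n_p <- sum(y == 1); n_c <- sum(y == 0)
  if (n_p == 0L || n_c == 0L) {
    stop("training set must contain both classes (plasmid and chromosome)")
  }
  cw <- class_weights(n_p, n_c)
  w_all <- ifelse(y == 1, cw[["plasmid"]], cw[["chromosome"]])
  set.seed(model$config$seed)
  state <- adam_init(model$params)
  trace <- list()
  n <- length(y)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + batch_size - 1L, n)]
      res <- transformer_batch_grads(model, sentences[idx, , drop = FALSE],
                                     y[idx], w_all[idx], training = TRUE)
      upd <- adam_step(model$params, res$grads, state, lr)
      model$params <- upd$params; state <- upd$state
      trace[[length(trace) + 1L]] <- data.frame(epoch = ep, batch = bi,
                                                loss = res$loss)
    }
    if (verbose) {
      ep_loss <- mean(vapply(trace[vapply(trace, function(t) t$epoch == ep,
                                          TRUE)], `[[`, 0, "loss"))
      message(sprintf("epoch %d: mean weighted BCE %.4f", ep, ep_loss))
    }
  }
  model$loss_trace <- do.call(rbind, trace)
  model
}

#' Predict plasmid probabilities for token sentences
#'
#' @param model A trained \code{plasmeld_transformer}.
#' @param sentences Integer matrix \code{n x L} (or a single sentence).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, sentences) {
  if (is.null(dim(sentences))) sentences <- matrix(as.integer(sentences), 1L)
  vapply(seq_len(nrow(sentences)), function(b) {
    X <- embed_sentence(sentences[b, ], model)
    Z <- attention_forward(X, model$params, model$config,
                           ids = sentences[b, ])$Z
    classify_head(Z, model)
  }, 0)
}

#' Per-head attention matrices for one sentence
#'
#' @param model A \code{plasmeld_transformer}.
#' @param ids One token sentence (0-based ids, length L).
#' @return List of \code{heads} row-stochastic \code{L x L} matrices.
#' @export
attention_maps <- function(model, ids) {
  X <- embed_sentence(ids, model)
  res <- attention_forward(X, model$params, model$config, keep = TRUE,
                           ids = as.integer(ids))
  lapply(res$cache, `[[`, "A")
}

#' Window-sampling training-set augmentation
#'
#' Each sequence contributes itself plus every non-overlapping window sample
#' at each window size (200-4000 bp by default); windows larger than the
#' sequence are skipped so the full sequence is not duplicated. Labels are
#' inherited by every sample.
#'
#' @param seqs Named character vector (or \code{DNAStringSet}) of sequences.
#' @param labels Vector of labels, parallel to \code{seqs}.
#' @param windows Window sizes in bp.
#' @return data.frame with columns \code{seq}, \code{label},
#'   \code{source_id}, \code{window} (NA for originals).
#' @export
augment_training_set <- function(seqs, labels,
                                 windows = c(200L, 400L, 600L, 800L, 1000L,
                                             2000L, 4000L)) {
  seqs <- as_seq_set(seqs)
  stopifnot(length(labels) == length(seqs))
  out <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    out[[length(out) + 1L]] <- data.frame(
      seq = s, label = labels[i], source_id = names(seqs)[i],
      window = NA_integer_, stringsAsFactors = FALSE)
    for (w in windows) {
      if (w > nchar(s)) next
      segs <- segment_sequence(s, w, step = w)
      out[[length(out) + 1L]] <- data.frame(
        seq = segs, label = labels[i], source_id = names(seqs)[i],
        window = w, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Save / load a trained model
#'
#' The checkpoint is a binary RDS bundle with a JSON sidecar carrying the
#' config for quick inspection.
#'
#' @param model A \code{plasmeld_transformer}.
#' @param path Checkpoint path (\code{.rds}).
#' @return \code{path} (\code{save_transformer}) or the model
#'   (\code{load_transformer}).
#' @export
save_transformer <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(model$config[names(model$config)],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_transformer
#' @export
load_transformer <- function(path) readRDS(path)
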