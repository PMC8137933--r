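# Autoregressive GRU sequence generator, trained on penetrating peptides
# only and sampled by random-prefix elongation to a fixed target length.

#' Generator configuration
#'
#' Defaults are desk-scale: hidden size 64 and a few hundred epochs with
#' early stopping. The reference architecture (two stacked GRUs of 256
#' hidden units, up to 1e5 epochs) is reachable through these fields.
#'
#' @param n_layers number of stacked GRU layers (default 2).
#' @param hidden hidden state width per layer (default 64).
#' @param max_length maximum generated sequence length (default 20).
#' @param epochs training epoch cap (default 200).
#' @param lr Adam learning rate (default 0.01).
#' @param patience early-stopping patience in epochs (default 25).
#' @param min_delta minimum loss improvement counted as progress.
#' @param seed integer seed for initialization and training.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_layers = 2L, hidden = 64L, max_length = 20L,
                             epochs = 200L, lr = 0.01, patience = 25L,
                             min_delta = 1e-4, seed = 1L) {
  if (hidden < 1L || max_length < 1L) {
    stop_validation("hidden and max_length must be >= 1")
  }
  structure(list(n_layers = as.integer(n_layers), hidden = as.integer(hidden),
                 max_length = as.integer(max_length),
                 epochs = as.integer(epochs), lr = lr,
                 patience = as.integer(patience), min_delta = min_delta,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# token encoding shared by generator training and sampling:
# inputs  1..20 = residues, 21 = begin-of-sequence
# outputs 1..20 = residues, 21 = end-of-sequence
GEN_BOS <- 21L
GEN_EOS <- 21L

encode_lm_batch <- function(x) {
  idx <- lapply(unclass(x), function(s) {
    match(strsplit(s, "", fixed = TRUE)[[1]], AA_STANDARD)
  })
  lens <- lengths(idx)
  Tn <- max(lens) + 1L
  B <- length(idx)
  tokens_in <- matrix(GEN_BOS, B, Tn)
  targets <- matrix(NA_integer_, B, Tn)
  for (b in seq_len(B)) {
    L <- lens[b]
    if (L > 0L) tokens_in[b, 2L:(L + 1L)] <- idx[[b]][seq_len(L)]
    if (Tn > L + 1L) tokens_in[b, (L + 2L):Tn] <- GEN_BOS  # padding, masked
    targets[b, seq_len(L)] <- idx[[b]]
    targets[b, L + 1L] <- GEN_EOS
  }
  # inputs beyond position L+1 are padding; their targets stay NA (masked)
  tokens_in <- tokens_in[, seq_len(Tn), drop = FALSE]
  list(tokens_in = tokens_in, targets = targets)
}

#' Train the autoregressive peptide generator
#'
#' A stacked-GRU next-residue language model trained on the positive
#' (penetrating) sequences only, with full-batch Adam and early stopping on
#' a plateaued training loss. The returned model carries the weights of the
#' best epoch, so the checkpointed loss sequence is non-increasing.
#'
#' @param positives a [peptides] object of training sequences.
#' @param config a [generator_config()].
#' @return An object of class `cpp_generator`.
#' @export
train_generator <- function(positives, config = generator_config()) {
  if (length(positives) == 0L) stop_validation("empty training set")
  enc <- encode_lm_batch(positives)
  params <- gru_init(input_dim = 21L, hidden = config$hidden,
                     n_layers = config$n_layers, output_dim = 21L,
                     seed = derive_seed(config$seed, "gen-init"))
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- numeric(0)
  stall <- 0L
  for (ep in seq_len(config$epochs)) {
    lg <- lm_loss_and_grads(params, enc$tokens_in, enc$targets)
    history[ep] <- lg$loss
    if (lg$loss < best$loss - config$min_delta) {
      best <- list(loss = lg$loss, params = params, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
    st <- adam_step(params, lg$grads, state, lr = config$lr)
    params <- st$params
    state <- st$state
  }
  structure(list(params = best$params, config = config,
                 loss_history = history, best_loss = best$loss,
                 best_epoch = best$epoch, n_training = length(positives)),
            class = "cpp_generator")
}

#' @export
print.cpp_generator <- function(x, ...) {
  cat(sprintf(paste0("GRU peptide generator: %d layer(s) x %d hidden, ",
                     "%d parameters\n"),
              x$config$n_layers, x$config$hidden, n_params(x$params)))
  cat(sprintf("  trained on %d sequences, best loss %.4f at epoch %d/%d\n",
              x$n_training, x$best_loss, x$best_epoch, length(x$loss_history)))
  invisible(x)
}

# advance the GRU stack by one input token; h is a list of [1 x H] states
gru_step <- function(params, h, token) {
  x <- one_hot(token, params$input_dim)
  for (l in seq_len(params$n_layers)) {
    p <- params$layers[[l]]
    hp <- h[[l]]
    z <- sigmoid(add_bias(x %*% p$Wz + hp %*% p$Uz, p$bz))
    r <- sigmoid(add_bias(x %*% p$Wr + hp %*% p$Ur, p$br))
    hh <- tanh(add_bias(x %*% p$Wh + (r * hp) %*% p$Uh, p$bh))
    h[[l]] <- (1 - z) * hp + z * hh
    x <- h[[l]]
  }
  h
}

#' Sample peptide sequences from a trained generator
#'
#' Each sequence starts from a random prefix (letters drawn uniformly from
#' `prefix_alphabet`, prefix length uniform on 1..`target_length`) and is
#' elongated autoregressively to exactly `target_length` residues.
#' End-of-sequence probability is masked during elongation so every output
#' has the requested length. Sampling is multinomial at the given
#' temperature; `greedy = TRUE` takes the modal residue instead.
#'
#' @param model a `cpp_generator`.
#' @param count number of sequences (>= 1).
#' @param target_length output length (default 20).
#' @param seed integer seed; identical seeds give identical output.
#' @param temperature softmax temperature for sampling (default 1).
#' @param greedy use argmax decoding for the elongation (default FALSE).
#' @param prefix_alphabet residues eligible for the random prefix (default
#'   all 20 standard residues).
#' @return A [peptides] object of `count` sequences (ids `gen0001`, ...)
#'   with a `prefix_lengths` attribute recording the random prefix length
#'   of each sequence.
#' @export
generate_sequences <- function(model, count, target_length = 20L, seed = 1L,
                               temperature = 1, greedy = FALSE,
                               prefix_alphabet = AA_STANDARD) {
  if (!inherits(model, "cpp_generator")) stop_validation("not a cpp_generator")
  if (count < 1L) stop_validation("count must be >= 1")
  if (target_length < 1L) stop_validation("target_length must be >= 1")
  pa_idx <- match(prefix_alphabet, AA_STANDARD)
  if (anyNA(pa_idx)) stop_validation("prefix_alphabet contains non-standard letters")
  params <- model$params
  out <- character(count)
  prefix_lens <- integer(count)
  with_seed(seed, {
    for (i in seq_len(count)) {
      u <- sample.int(target_length, 1L)
      prefix_lens[i] <- u
      toks <- pa_idx[sample.int(length(pa_idx), u, replace = TRUE)]
      h <- lapply(seq_len(params$n_layers),
                  function(l) matrix(0, 1L, params$hidden))
      for (tok in c(GEN_BOS, toks)) h <- gru_step(params, h, tok)
      while (length(toks) < target_length) {
        logits <- drop(h[[params$n_layers]] %*% params$Wo + params$bo)
        logits <- logits[seq_len(20L)]  # mask end-of-sequence
        logits <- logits / temperature
        p <- exp(logits - max(logits))
        p <- p / sum(p)
        nxt <- if (greedy) which.max(p) else
          sample.int(20L, 1L, prob = p)
        toks <- c(toks, nxt)
        h <- gru_step(params, h, nxt)
      }
      out[i] <- paste(AA_STANDARD[toks], collapse = "")
    }
  })
  res <- peptides(out, ids = sprintf("gen%04d", seq_len(count)))
  attr(res, "prefix_lengths") <- prefix_lens
  res
}

#' Per-position next-residue distribution of the generator
#'
#' Utility for inspecting what the model has learned: returns the softmax
#' distribution over the 21 output classes after consuming the given
#' residue prefix (begin token included automatically).
#'
#' @param model a `cpp_generator`.
#' @param prefix residue string (may be empty).
#' @return Named numeric vector of probabilities (20 residues + `EOS`).
#' @export
next_residue_probs <- function(model, prefix = "") {
  params <- model$params
  toks <- GEN_BOS
  if (nzchar(prefix)) {
    idx <- match(strsplit(toupper(prefix), "", fixed = TRUE)[[1]], AA_STANDARD)
    if (anyNA(idx)) stop_validation("prefix contains non-standard letters")
    toks <- c(toks, idx)
  }
  h <- lapply(seq_len(params$n_layers),
              function(l) matrix(0, 1L, params$hidden))
  for (tok in toks) h <- gru_step(params, h, tok)
  logits <- drop(h[[params$n_layers]] %*% params$Wo + params$bo)
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  names(p) <- c(AA_STANDARD, "EOS")
  p
}
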