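# Permeability predictor: a GRU computes a hidden vector at every position,
# a one-layer dense readout yields a per-position partial score, the scores
# are max-pooled over positions and squashed by the logistic to a
# likelihood in [0, 1].

#' Predictor configuration
#'
#' @param hidden GRU hidden width (default 64).
#' @param epochs training epoch cap (default 150).
#' @param lr Adam learning rate (default 0.02).
#' @param patience early-stopping patience in epochs (default 25).
#' @param min_delta minimum loss improvement counted as progress.
#' @param seed integer seed.
#' @return A list of class `predictor_config`.
#' @export
predictor_config <- function(hidden = 64L, epochs = 150L, lr = 0.02,
                             patience = 25L, min_delta = 1e-4, seed = 1L) {
  if (hidden < 1L) stop_validation("hidden must be >= 1")
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 lr = lr, patience = as.integer(patience),
                 min_delta = min_delta, seed = as.integer(seed)),
            class = "predictor_config")
}

#' Assemble a training set of positive and negative peptides
#'
#' @param positives,negatives [peptides] objects; the two classes must be
#'   disjoint by residue string and both non-empty for training.
#' @param max_source_length sequences longer than this are dropped
#'   (default 52).
#' @param redundancy_cutoff pairwise-identity cutoff used by
#'   [deduplicate_training()] (default 0.35).
#' @return A list of class `training_set`.
#' @export
training_set <- function(positives, negatives, max_source_length = 52L,
                         redundancy_cutoff = 0.35) {
  positives <- positives[nchar(positives) <= max_source_length]
  negatives <- negatives[nchar(negatives) <= max_source_length]
  overlap <- intersect(unclass(positives), unclass(negatives))
  if (length(overlap) > 0L) {
    negatives <- negatives[!(unclass(negatives) %in% overlap)]
  }
  structure(list(positives = positives, negatives = negatives,
                 max_source_length = as.integer(max_source_length),
                 redundancy_cutoff = redundancy_cutoff),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("training set: %d positive, %d negative sequences\n",
              length(x$positives), length(x$negatives)))
  invisible(x)
}

encode_classifier_batch <- function(x) {
  idx <- lapply(unclass(x), function(s) {
    match(strsplit(s, "", fixed = TRUE)[[1]], AA_STANDARD)
  })
  lens <- lengths(idx)
  Tn <- max(lens)
  B <- length(idx)
  tokens <- matrix(NA_integer_, B, Tn)
  mask <- matrix(FALSE, B, Tn)
  for (b in seq_len(B)) {
    tokens[b, seq_len(lens[b])] <- idx[[b]]
    mask[b, seq_len(lens[b])] <- TRUE
  }
  list(tokens = tokens, mask = mask)
}

#' Train the max-pooling permeability predictor
#'
#' Binary cross-entropy training of the GRU/max-pool classifier on the
#' positive and negative sequences of a [training_set()]. Errors when
#' either class is empty.
#'
#' @param training a [training_set()].
#' @param config a [predictor_config()].
#' @return An object of class `cpp_predictor`.
#' @export
train_predictor <- function(training, config = predictor_config()) {
  if (!inherits(training, "training_set")) {
    stop_validation("`training` must be a training_set")
  }
  if (length(training$positives) == 0L || length(training$negatives) == 0L) {
    stop_validation("both classes must be non-empty")
  }
  all_seqs <- peptides(c(unclass(training$positives),
                         unclass(training$negatives)),
                       ids = c(names(training$positives),
                               names(training$negatives)))
  labels <- c(rep(1, length(training$positives)),
              rep(0, length(training$negatives)))
  enc <- encode_classifier_batch(all_seqs)
  params <- gru_init(input_dim = 20L, hidden = config$hidden, n_layers = 1L,
                     output_dim = 1L,
                     seed = derive_seed(config$seed, "pred-init"))
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- numeric(0)
  stall <- 0L
  for (ep in seq_len(config$epochs)) {
    lg <- predictor_loss_and_grads(params, enc$tokens, labels, enc$mask)
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
                 best_epoch = best$epoch),
            class = "cpp_predictor")
}

#' @export
print.cpp_predictor <- function(x, ...) {
  cat(sprintf(paste0("GRU max-pooling permeability predictor: %d hidden, ",
                     "%d parameters\n"), x$config$hidden, n_params(x$params)))
  cat(sprintf("  best loss %.4f at epoch %d/%d\n",
              x$best_loss, x$best_epoch, length(x$loss_history)))
  invisible(x)
}

#' Likelihood scores for peptides under a trained predictor
#'
#' Each sequence is scored alone (batch composition and padding cannot
#' change its score): the per-position partial scores are squashed by the
#' logistic and the final likelihood is their maximum, so it always lies in
#' `[0, 1]` and equals the squashed max-pooled raw score (the logistic is
#' monotone).
#'
#' @param model a `cpp_predictor`.
#' @param x a [peptides] object.
#' @return A data frame of class `likelihood_scores` with columns `id`,
#'   `sequence`, `likelihood`, and an attribute `partials`: a named list of
#'   per-position squashed partial scores.
#' @export
score_likelihood <- function(model, x) {
  if (!inherits(model, "cpp_predictor")) stop_validation("not a cpp_predictor")
  params <- model$params
  partials <- vector("list", length(x))
  names(partials) <- names(x)
  lik <- numeric(length(x))
  for (i in seq_along(x)) {
    enc <- encode_classifier_batch(x[i])
    fwd <- gru_forward(params, enc$tokens)
    s <- vapply(fwd$top, function(h) drop(h %*% params$Wo + params$bo), 0)
    partials[[i]] <- sigmoid(s)
    lik[i] <- max(partials[[i]])
  }
  out <- data.frame(id = names(x), sequence = unclass(x), likelihood = lik,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "partials") <- partials
  class(out) <- c("likelihood_scores", "data.frame")
  out
}

#' @export
#' @rdname score_likelihood
#' @param object a `cpp_predictor`.
#' @param newdata a [peptides] object.
#' @param ... unused.
predict.cpp_predictor <- function(object, newdata, ...) {
  score_likelihood(object, newdata)
}

#' Select the top-k peptides by likelihood score
#'
#' Descending by likelihood; ties broken lexicographically by residue
#' string, then id. Requesting more than available returns everything with
#' a warning.
#'
#' @param scores a `likelihood_scores` data frame.
#' @param k number of peptides to keep (>= 1).
#' @return Character vector of peptide ids, best first.
#' @export
select_top <- function(scores, k) {
  if (k < 1L) stop_validation("k must be >= 1")
  if (k > nrow(scores)) {
    warning("k exceeds number of candidates; returning all")
    k <- nrow(scores)
  }
  ord <- order(-scores$likelihood, scores$sequence, scores$id)
  scores$id[ord][seq_len(k)]
}

#' Held-out classification accuracy of a predictor
#'
#' Fraction of peptides classified correctly at the 0.5 likelihood
#' threshold.
#'
#' @param model a `cpp_predictor`.
#' @param positives,negatives [peptides] objects of held-out sequences.
#' @return Accuracy in `[0, 1]`.
#' @export
predictor_accuracy <- function(model, positives, negatives) {
  sp <- score_likelihood(model, positives)$likelihood
  sn <- score_likelihood(model, negatives)$likelihood
  (sum(sp > 0.5) + sum(sn <= 0.5)) / (length(sp) + length(sn))
}
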