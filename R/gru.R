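# Minimal batched GRU machinery: forward pass, backpropagation through time
# and an Adam optimizer, in plain matrix algebra. Both the autoregressive
# sequence generator and the max-pooling permeability predictor are built on
# these primitives; gradients are verified against finite differences in the
# test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(m, b) m + rep(b, each = nrow(m))

# One-hot encode a column of token indices (NA rows stay all-zero).
one_hot <- function(idx, n_classes) {
  m <- matrix(0, length(idx), n_classes)
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

# Glorot-uniform initialization of a single GRU stack plus a linear readout.
# layer_input_dims[l] is the input width of layer l; hidden is shared.
gru_init <- function(input_dim, hidden, n_layers, output_dim, seed) {
  with_seed(seed, {
    glorot <- function(nin, nout) {
      lim <- sqrt(6 / (nin + nout))
      matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
    }
    layers <- vector("list", n_layers)
    d <- input_dim
    for (l in seq_len(n_layers)) {
      layers[[l]] <- list(
        Wz = glorot(d, hidden), Uz = glorot(hidden, hidden), bz = numeric(hidden),
        Wr = glorot(d, hidden), Ur = glorot(hidden, hidden), br = numeric(hidden),
        Wh = glorot(d, hidden), Uh = glorot(hidden, hidden), bh = numeric(hidden)
      )
      d <- hidden
    }
    list(layers = layers, Wo = glorot(hidden, output_dim),
         bo = numeric(output_dim),
         input_dim = input_dim, hidden = hidden, n_layers = n_layers,
         output_dim = output_dim)
  })
}

n_params <- function(params) {
  tot <- length(params$Wo) + length(params$bo)
  for (l in params$layers) tot <- tot + sum(vapply(l, length, 0))
  tot
}

# Forward pass over a [B x T] matrix of input token indices. Returns hidden
# states of the top layer per step plus the full cache needed for BPTT.
gru_forward <- function(params, tokens) {
  B <- nrow(tokens); Tn <- ncol(tokens)
  H <- params$hidden; L <- params$n_layers
  h <- lapply(seq_len(L), function(l) matrix(0, B, H))
  cache <- vector("list", Tn)
  top <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- one_hot(tokens[, t], params$input_dim)
    step <- vector("list", L)
    for (l in seq_len(L)) {
      p <- params$layers[[l]]
      hp <- h[[l]]
      z <- sigmoid(add_bias(x %*% p$Wz + hp %*% p$Uz, p$bz))
      r <- sigmoid(add_bias(x %*% p$Wr + hp %*% p$Ur, p$br))
      hh <- tanh(add_bias(x %*% p$Wh + (r * hp) %*% p$Uh, p$bh))
      hn <- (1 - z) * hp + z * hh
      step[[l]] <- list(x = x, h_prev = hp, z = z, r = r, hh = hh)
      h[[l]] <- hn
      x <- hn
    }
    cache[[t]] <- step
    top[[t]] <- h[[L]]
  }
  list(top = top, cache = cache, final = h)
}

zero_like_params <- function(params) {
  g <- params
  for (l in seq_along(g$layers)) {
    g$layers[[l]] <- lapply(g$layers[[l]], function(m) m * 0)
  }
  g$Wo <- g$Wo * 0
  g$bo <- g$bo * 0
  g
}

# Backpropagation through time. `d_top` is a list over t of [B x H]
# gradients w.r.t. the top-layer hidden state at each step (contributions
# from the readout); returns gradients for all GRU parameters.
gru_backward <- function(params, fwd, d_top) {
  L <- params$n_layers
  Tn <- length(fwd$cache)
  B <- nrow(d_top[[1]])
  H <- params$hidden
  g <- zero_like_params(params)
  dh_next <- lapply(seq_len(L), function(l) matrix(0, B, H))
  for (t in rev(seq_len(Tn))) {
    dx_up <- d_top[[t]]  # gradient arriving at the output of the top layer
    for (l in rev(seq_len(L))) {
      st <- fwd$cache[[t]][[l]]
      p <- params$layers[[l]]
      dh <- dh_next[[l]] + dx_up
      dz <- dh * (st$hh - st$h_prev)
      dhh <- dh * st$z
      dh_prev <- dh * (1 - st$z)
      dahh <- dhh * (1 - st$hh^2)
      g$layers[[l]]$Wh <- g$layers[[l]]$Wh + crossprod(st$x, dahh)
      g$layers[[l]]$Uh <- g$layers[[l]]$Uh + crossprod(st$r * st$h_prev, dahh)
      g$layers[[l]]$bh <- g$layers[[l]]$bh + colSums(dahh)
      drh <- dahh %*% t(p$Uh)
      dr <- drh * st$h_prev
      dh_prev <- dh_prev + drh * st$r
      daz <- dz * st$z * (1 - st$z)
      dar <- dr * st$r * (1 - st$r)
      g$layers[[l]]$Wz <- g$layers[[l]]$Wz + crossprod(st$x, daz)
      g$layers[[l]]$Uz <- g$layers[[l]]$Uz + crossprod(st$h_prev, daz)
      g$layers[[l]]$bz <- g$layers[[l]]$bz + colSums(daz)
      g$layers[[l]]$Wr <- g$layers[[l]]$Wr + crossprod(st$x, dar)
      g$layers[[l]]$Ur <- g$layers[[l]]$Ur + crossprod(st$h_prev, dar)
      g$layers[[l]]$br <- g$layers[[l]]$br + colSums(dar)
      dh_prev <- dh_prev + daz %*% t(p$Uz) + dar %*% t(p$Ur)
      dx <- daz %*% t(p$Wz) + dar %*% t(p$Wr) + dahh %*% t(p$Wh)
      dh_next[[l]] <- dh_prev
      dx_up <- dx  # becomes gradient w.r.t. the output of layer l-1
    }
  }
  g
}

# Masked softmax cross-entropy language-model loss over top-layer states.
# targets: [B x T] of output-class indices (NA = masked). Returns loss and
# the per-step gradients w.r.t. the top hidden states plus readout grads.
lm_loss <- function(params, fwd, targets) {
  Tn <- length(fwd$top)
  B <- nrow(targets)
  total <- sum(!is.na(targets))
  loss <- 0
  d_top <- vector("list", Tn)
  gWo <- params$Wo * 0
  gbo <- params$bo * 0
  for (t in seq_len(Tn)) {
    h <- fwd$top[[t]]
    logits <- add_bias(h %*% params$Wo, params$bo)
    logits <- logits - apply(logits, 1, max)
    p <- exp(logits)
    p <- p / rowSums(p)
    tgt <- targets[, t]
    ok <- !is.na(tgt)
    if (any(ok)) {
      loss <- loss - sum(log(pmax(p[cbind(which(ok), tgt[ok])], 1e-12)))
      dlog <- p
      dlog[cbind(which(ok), tgt[ok])] <- dlog[cbind(which(ok), tgt[ok])] - 1
      dlog[!ok, ] <- 0
      dlog <- dlog / total
      gWo <- gWo + crossprod(h, dlog)
      gbo <- gbo + colSums(dlog)
      d_top[[t]] <- dlog %*% t(params$Wo)
    } else {
      d_top[[t]] <- matrix(0, B, params$hidden)
    }
  }
  list(loss = loss / total, d_top = d_top, gWo = gWo, gbo = gbo)
}

# Full loss + gradient for the autoregressive generator on one batch.
lm_loss_and_grads <- function(params, tokens_in, targets) {
  fwd <- gru_forward(params, tokens_in)
  ll <- lm_loss(params, fwd, targets)
  g <- gru_backward(params, fwd, ll$d_top)
  g$Wo <- ll$gWo
  g$bo <- ll$gbo
  list(loss = ll$loss, grads = g)
}

# Max-pooled binary classification loss for the permeability predictor.
# The readout Wo is [H x 1]; the per-position partial score is h_t Wo + bo,
# pooled by max over unmasked positions and squashed by the logistic.
predictor_loss_and_grads <- function(params, tokens_in, labels, mask) {
  fwd <- gru_forward(params, tokens_in)
  Tn <- length(fwd$top)
  B <- nrow(tokens_in)
  s <- matrix(-Inf, B, Tn)
  for (t in seq_len(Tn)) {
    s[, t] <- fwd$top[[t]] %*% params$Wo + params$bo
  }
  s[!mask] <- -Inf
  pool_t <- max.col(s, ties.method = "first")
  pooled <- s[cbind(seq_len(B), pool_t)]
  prob <- sigmoid(pooled)
  loss <- -mean(labels * log(pmax(prob, 1e-12)) +
                  (1 - labels) * log(pmax(1 - prob, 1e-12)))
  dpool <- (prob - labels) / B
  d_top <- vector("list", Tn)
  gWo <- params$Wo * 0
  gbo <- 0
  for (t in seq_len(Tn)) {
    ds <- ifelse(pool_t == t, dpool, 0)
    d_top[[t]] <- ds %*% t(params$Wo)
    gWo <- gWo + crossprod(fwd$top[[t]], matrix(ds, B, 1))
    gbo <- gbo + sum(ds)
  }
  g <- gru_backward(params, fwd, d_top)
  g$Wo <- gWo
  g$bo <- gbo
  list(loss = loss, grads = g, prob = prob)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_like_params(params), v = zero_like_params(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.01,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (l in seq_along(params$layers)) {
    for (nm in names(params$layers[[l]])) {
      u <- upd(params$layers[[l]][[nm]], grads$layers[[l]][[nm]],
               state$m$layers[[l]][[nm]], state$v$layers[[l]][[nm]])
      params$layers[[l]][[nm]] <- u$p
      state$m$layers[[l]][[nm]] <- u$m
      state$v$layers[[l]][[nm]] <- u$v
    }
  }
  for (nm in c("Wo", "bo")) {
    u <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    params[[nm]] <- u$p
    state$m[[nm]] <- u$m
    state$v[[nm]] <- u$v
  }
  list(params = params, state = state)
}
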