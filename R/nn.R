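# Minimal transformer engine with hand-written backpropagation.
#
# All heavy lifting is dense matrix algebra through BLAS. Token sequences for
# a batch of B trials are stored as a single (B*L) x d matrix with trial-major
# row blocks; attention runs per trial (sequences are short, so the per-trial
# loop is cheap relative to the projections).

.addrow <- function(X, b) X + rep(b, rep.int(nrow(X), length(b)))

.ln_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = .addrow(xhat * rep(g, rep.int(nrow(X), length(g))), b),
       xhat = xhat, inv = inv)
}

.ln_backward <- function(dY, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dxhat <- dY * rep(g, rep.int(nrow(dY), length(g)))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- inv * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Transformer architecture configuration
#'
#' An NDT1-style encoder: each time bin is one token; per-session linear
#' projections (stitching) map the neuron dimension in and out of the shared
#' `d_model` space; attention is bidirectional for every masking scheme
#' (causality is enforced by the input mask, not by attention masking).
#'
#' @param d_model token dimensionality; divisible by `n_heads`.
#' @param n_layers number of encoder layers (pre-LayerNorm blocks).
#' @param n_heads attention heads.
#' @param ffn_dim hidden width of the feed-forward block (default
#'   `2 * d_model`).
#' @param max_bins maximum trial length in bins (sizes the learned positional
#'   embedding table).
#' @param dropout inverted-dropout rate applied during training to the token
#'   embeddings and to each attention and feed-forward output before its
#'   residual add. Neural-data transformers of this family need unusually
#'   aggressive dropout to generalize from a few hundred trials; 0.4 is the
#'   default, 0 disables. Inference never drops.
#' @param mask_channel if `TRUE`, the binary context-mask row is concatenated
#'   with the zero-filled counts before the input projection (`2N -> d`), so
#'   the model can tell a hidden entry from an observed zero. The default is
#'   `FALSE` (plain projection of the masked counts, the NDT convention):
#'   feeding the mask makes the masking scheme directly observable, which
#'   both lets a temporal-masking baseline renormalize gracefully under
#'   region masking and makes the prompt token redundant — exactly the two
#'   contrasts (scheme-specific failure of the baseline, prompt-based mode
#'   switching) this framework is designed to expose.
#' @param rate_link `"softplus"` (default; floored at `rate_floor`) or
#'   `"exp"`. Softplus avoids the early-training overflow of the exponential
#'   GLM link while keeping rates strictly positive.
#' @param rate_floor additive floor on rates keeping the Poisson likelihood
#'   finite.
#' @param prompt_enabled whether a learnable per-scheme prompt token is
#'   prepended to the token sequence.
#' @return An object of class `model_config`.
#' @export
model_config <- function(d_model = 128L, n_layers = 4L, n_heads = 4L,
                         ffn_dim = NULL, max_bins = 200L, dropout = 0.4,
                         mask_channel = FALSE,
                         rate_link = c("softplus", "exp"),
                         rate_floor = 1e-6, prompt_enabled = TRUE) {
  rate_link <- match.arg(rate_link)
  if (d_model %% n_heads != 0L) stop("`d_model` must be divisible by `n_heads`")
  if (dropout < 0 || dropout >= 1) stop("`dropout` must lie in [0, 1)")
  if (is.null(ffn_dim)) ffn_dim <- 2L * d_model
  structure(list(d_model = as.integer(d_model), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), ffn_dim = as.integer(ffn_dim),
                 max_bins = as.integer(max_bins), dropout = dropout,
                 mask_channel = isTRUE(mask_channel), rate_link = rate_link,
                 rate_floor = rate_floor, prompt_enabled = isTRUE(prompt_enabled)),
            class = "model_config")
}

# Xavier/Glorot scaling: at small d_model a fixed small sd leaves attention
# logits indistinguishable from zero and the softmax stuck uniform.
.init_mat <- function(nr, nc, sd = sqrt(2 / (nr + nc))) {
  matrix(rnorm(nr * nc, sd = sd), nr, nc)
}

# sinusoidal position table (learnable after init); gives queries and keys a
# usable position comparison from step one, which random init does not.
.init_pos <- function(max_bins, d, scale = 0.1) {
  pos <- matrix(0, max_bins, d)
  half <- ceiling(d / 2)
  freq <- 1 / 10000^((seq_len(half) - 1) / half)
  ang <- outer(seq_len(max_bins), freq)
  pos[, seq_len(half)] <- sin(ang)
  pos[, half + seq_len(d - half)] <- cos(ang[, seq_len(d - half)])
  pos * scale
}

.init_params <- function(cfg) {
  d <- cfg$d_model; f <- cfg$ffn_dim
  layers <- lapply(seq_len(cfg$n_layers), function(l) list(
    ln1_g = rep(1, d), ln1_b = rep(0, d),
    Wq = .init_mat(d, d), bq = rep(0, d),
    Wk = .init_mat(d, d), bk = rep(0, d),
    Wv = .init_mat(d, d), bv = rep(0, d),
    Wo = .init_mat(d, d), bo = rep(0, d),
    ln2_g = rep(1, d), ln2_b = rep(0, d),
    W1 = .init_mat(d, f), b1 = rep(0, f),
    W2 = .init_mat(f, d), b2 = rep(0, d)))
  prompt <- .init_mat(4L, d)
  rownames(prompt) <- mask_schemes()
  list(pos = .init_pos(cfg$max_bins, d), prompt = prompt, layers = layers,
       lnf_g = rep(1, d), lnf_b = rep(0, d), sessions = list())
}

#' Create an untrained MtM model
#'
#' @param cfg a [model_config()].
#' @param mask_params a [mask_params()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `mtm_model` with an empty session registry;
#'   register sessions with [register_session()].
#' @export
mtm_model <- function(cfg = model_config(), mask_params = NULL, seed = 1L) {
  if (is.null(mask_params)) mask_params <- mask_params()
  params <- withr::with_seed(seed, .init_params(cfg))
  structure(list(cfg = cfg, params = params, mask_params = mask_params,
                 sessions = list(), history = NULL),
            class = "mtm_model")
}

#' @export
print.mtm_model <- function(x, ...) {
  cat(sprintf("<mtm_model> d=%d, %d layers, %d heads, prompt=%s; sessions: %s\n",
              x$cfg$d_model, x$cfg$n_layers, x$cfg$n_heads,
              x$cfg$prompt_enabled,
              if (length(x$sessions)) paste(names(x$sessions), collapse = ", ")
              else "(none)"))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs, best val score %.4f (epoch %d)\n",
                nrow(x$history), max(x$history$val_score, na.rm = TRUE),
                x$history$epoch[which.max(x$history$val_score)]))
  invisible(x)
}

#' Register a session with the stitcher
#'
#' Adds a fresh per-session input projection (`N -> d`, or `2N -> d` when the
#' config enables the mask channel), output projection
#' (`d -> N`), and session context embedding. The output bias is initialized
#' so that the initial rates match the session's per-neuron mean counts (the
#' null model), which removes the early epochs a randomly initialized head
#' would spend learning marginal firing rates. Existing sessions are
#' untouched.
#'
#' @param model an `mtm_model`.
#' @param bundle the [session_bundle()] to register (neuron count, region
#'   labels and mean counts are recorded).
#' @param seed seed for the new projections.
#' @return The updated model.
#' @export
register_session <- function(model, bundle, seed = 1L) {
  stopifnot(inherits(model, "mtm_model"), inherits(bundle, "session_bundle"))
  sid <- bundle$session_id
  if (sid %in% names(model$params$sessions))
    stop(sprintf("session '%s' already registered", sid))
  N <- dim(bundle$spikes$counts)[3L]
  d <- model$cfg$d_model
  mean_rates <- pmax(apply(bundle$spikes$counts, 3L, mean), 1e-3)
  b_out0 <- if (model$cfg$rate_link == "softplus") {
    # inverse softplus: log(exp(m) - 1), stable for small m
    log(expm1(mean_rates))
  } else log(mean_rates)
  n_in <- if (model$cfg$mask_channel) 2L * N else N
  model$params$sessions[[sid]] <- withr::with_seed(seed, list(
    W_in = .init_mat(n_in, d), b_in = rep(0, d), emb = .init_mat(1L, d)[1L, ],
    W_out = .init_mat(d, N), b_out = b_out0))
  model$sessions[[sid]] <- list(n_neurons = N, regions = bundle$regions)
  model
}

# --- internal forward/backward ------------------------------------------------

# Xm: B x T x N masked counts; ctx: T x N logical. Returns the (B*T) x N
# input matrix with trial-major rows, or (B*T) x 2N (counts then mask
# channel) when the config requests the mask channel.
.input_mat <- function(Xm, ctx, mask_channel = FALSE) {
  B <- dim(Xm)[1L]; Tt <- dim(Xm)[2L]; N <- dim(Xm)[3L]
  Xmat <- matrix(aperm(Xm, c(2L, 1L, 3L)), B * Tt, N)
  if (!mask_channel) return(Xmat)
  Cmat <- matrix(as.numeric(ctx), Tt, N)[rep.int(seq_len(Tt), B), , drop = FALSE]
  cbind(Xmat, Cmat)
}

.drop_mask <- function(nr, nc, p) {
  if (p <= 0) return(1)
  (matrix(stats::runif(nr * nc), nr, nc) >= p) / (1 - p)
}

# Core forward pass. scheme = NULL disables the prompt token; train_mode
# activates dropout (inference is deterministic).
.nn_forward <- function(params, cfg, Xm, ctx, session_id, scheme = NULL,
                        want_cache = FALSE, train_mode = FALSE) {
  sess <- params$sessions[[session_id]]
  if (is.null(sess)) stop(sprintf("session '%s' not registered", session_id))
  B <- dim(Xm)[1L]; Tt <- dim(Xm)[2L]; N <- dim(Xm)[3L]
  if (N != length(sess$b_out))
    stop("neuron count mismatch with the session's stitcher entry")
  if (Tt > cfg$max_bins) stop("trial longer than `max_bins`")
  d <- cfg$d_model
  use_prompt <- cfg$prompt_enabled && !is.null(scheme)
  if (use_prompt && !scheme %in% rownames(params$prompt))
    stop(sprintf("no prompt token for scheme '%s' (the temporal baseline has none)",
                 scheme))
  Min <- .input_mat(Xm, ctx, cfg$mask_channel)
  tidx <- rep.int(seq_len(Tt), B)
  Ht <- .addrow(Min %*% sess$W_in, sess$b_in + sess$emb) +
    params$pos[tidx, , drop = FALSE]
  if (use_prompt) {
    L <- Tt + 1L
    prow <- (seq_len(B) - 1L) * L + 1L
    trow <- rep((seq_len(B) - 1L) * L, each = Tt) + 1L + seq_len(Tt)
    H <- matrix(0, B * L, d)
    H[prow, ] <- rep(params$prompt[scheme, ], rep.int(B, d))
    H[trow, ] <- Ht
  } else {
    L <- Tt
    prow <- integer(0)
    trow <- seq_len(B * L)
    H <- Ht
  }
  nh <- cfg$n_heads; dk <- d %/% nh
  scale <- 1 / sqrt(dk)
  p_drop <- if (train_mode) cfg$dropout else 0
  D0 <- .drop_mask(nrow(H), d, p_drop)
  # the prompt token is never dropped: it is the only carrier of the scheme
  # identity, and stochastically deleting it teaches the model to ignore it
  if (length(prow) && is.matrix(D0)) D0[prow, ] <- 1
  H <- H * D0
  blocks <- lapply(seq_len(B), function(b) (b - 1L) * L + seq_len(L))
  hcols <- lapply(seq_len(nh), function(j) (j - 1L) * dk + seq_len(dk))
  cache <- if (want_cache) list(Min = Min, tidx = tidx, trow = trow, prow = prow,
                                B = B, L = L, Tt = Tt, scheme = scheme,
                                session_id = session_id, D0 = D0,
                                layers = vector("list", cfg$n_layers))
  for (l in seq_len(cfg$n_layers)) {
    ly <- params$layers[[l]]
    ln1 <- .ln_forward(H, ly$ln1_g, ly$ln1_b)
    A1 <- ln1$y
    Q <- .addrow(A1 %*% ly$Wq, ly$bq)
    K <- .addrow(A1 %*% ly$Wk, ly$bk)
    V <- .addrow(A1 %*% ly$Wv, ly$bv)
    O <- matrix(0, nrow(H), d)
    Ps <- if (want_cache) vector("list", B * nh)
    for (b in seq_len(B)) {
      idx <- blocks[[b]]
      for (j in seq_len(nh)) {
        cj <- hcols[[j]]
        S <- tcrossprod(Q[idx, cj, drop = FALSE], K[idx, cj, drop = FALSE]) * scale
        P <- exp(S - max(S))  # global shift: row-valid, keeps exp() in range
        P <- P / rowSums(P)
        O[idx, cj] <- P %*% V[idx, cj, drop = FALSE]
        if (want_cache) Ps[[(b - 1L) * nh + j]] <- P
      }
    }
    D1 <- .drop_mask(nrow(H), d, p_drop)
    H2 <- H + D1 * .addrow(O %*% ly$Wo, ly$bo)
    ln2 <- .ln_forward(H2, ly$ln2_g, ly$ln2_b)
    A2 <- ln2$y
    F1 <- .addrow(A2 %*% ly$W1, ly$b1)
    Rl <- F1 * (F1 > 0)
    D2 <- .drop_mask(nrow(H), d, p_drop)
    H3 <- H2 + D2 * .addrow(Rl %*% ly$W2, ly$b2)
    if (want_cache)
      cache$layers[[l]] <- list(ln1 = ln1, A1 = A1, Q = Q, K = K, V = V, O = O,
                                Ps = Ps, H2 = H2, ln2 = ln2, A2 = A2, F1 = F1,
                                Rl = Rl, D1 = D1, D2 = D2)
    H <- H3
  }
  lnf <- .ln_forward(H, params$lnf_g, params$lnf_b)
  Hf <- lnf$y[trow, , drop = FALSE]
  Out <- .addrow(Hf %*% sess$W_out, sess$b_out)
  rates_mat <- if (cfg$rate_link == "softplus") .softplus(Out) + cfg$rate_floor
               else exp(pmin(Out, 30)) + cfg$rate_floor
  if (any(!is.finite(rates_mat))) stop("non-finite rates in forward pass")
  rates <- aperm(array(rates_mat, dim = c(Tt, B, N)), c(2L, 1L, 3L))
  if (want_cache) {
    cache$lnf <- lnf; cache$Hf <- Hf; cache$Out <- Out
    cache$rates_mat <- rates_mat
    list(rates = rates, cache = cache)
  } else rates
}

# Backward pass: d_rates_mat is the (B*Tt) x N gradient wrt rates (time rows).
# Returns a grads tree mirroring params (NULL where untouched).
.nn_backward <- function(params, cfg, cache, d_rates_mat) {
  sess <- params$sessions[[cache$session_id]]
  d <- cfg$d_model; nh <- cfg$n_heads; dk <- d %/% nh; scale <- 1 / sqrt(dk)
  B <- cache$B; L <- cache$L
  dOut <- if (cfg$rate_link == "softplus") {
    d_rates_mat * stats::plogis(cache$Out)
  } else {
    d_rates_mat * exp(pmin(cache$Out, 30))
  }
  gsess <- list(W_in = NULL, b_in = NULL, emb = NULL,
                W_out = crossprod(cache$Hf, dOut), b_out = colSums(dOut))
  dHf <- dOut %*% t(sess$W_out)
  dHfull <- matrix(0, B * L, d)
  dHfull[cache$trow, ] <- dHf
  lnb <- .ln_backward(dHfull, cache$lnf, params$lnf_g)
  g <- list(pos = NULL, prompt = NULL, layers = vector("list", cfg$n_layers),
            lnf_g = lnb$dg, lnf_b = lnb$db, sessions = list())
  dH <- lnb$dX
  blocks <- lapply(seq_len(B), function(b) (b - 1L) * L + seq_len(L))
  hcols <- lapply(seq_len(nh), function(j) (j - 1L) * dk + seq_len(dk))
  for (l in rev(seq_len(cfg$n_layers))) {
    ly <- params$layers[[l]]
    cl <- cache$layers[[l]]
    # FFN block: H3 = H2 + D2 * (relu(LN2(H2) W1 + b1) W2 + b2)
    dF2 <- dH * cl$D2
    dW2 <- crossprod(cl$Rl, dF2); db2 <- colSums(dF2)
    dR <- dF2 %*% t(ly$W2)
    dF1 <- dR * (cl$F1 > 0)
    dW1 <- crossprod(cl$A2, dF1); db1 <- colSums(dF1)
    dA2 <- dF1 %*% t(ly$W1)
    ln2b <- .ln_backward(dA2, cl$ln2, ly$ln2_g)
    dH2 <- dH + ln2b$dX
    # attention block: H2 = H + D1 * ((per-head softmax attention) Wo + bo)
    dAttn <- dH2 * cl$D1
    dWo <- crossprod(cl$O, dAttn); dbo <- colSums(dAttn)
    dO <- dAttn %*% t(ly$Wo)
    dQ <- matrix(0, B * L, d); dK <- matrix(0, B * L, d); dV <- matrix(0, B * L, d)
    for (b in seq_len(B)) {
      idx <- blocks[[b]]
      for (j in seq_len(nh)) {
        cj <- hcols[[j]]
        P <- cl$Ps[[(b - 1L) * nh + j]]
        dOb <- dO[idx, cj, drop = FALSE]
        Vb <- cl$V[idx, cj, drop = FALSE]
        dP <- dOb %*% t(Vb)
        dV[idx, cj] <- crossprod(P, dOb)
        dS <- P * (dP - rowSums(dP * P))
        dQ[idx, cj] <- dS %*% cl$K[idx, cj, drop = FALSE] * scale
        dK[idx, cj] <- crossprod(dS, cl$Q[idx, cj, drop = FALSE]) * scale
      }
    }
    dA1 <- dQ %*% t(ly$Wq) + dK %*% t(ly$Wk) + dV %*% t(ly$Wv)
    ln1b <- .ln_backward(dA1, cl$ln1, ly$ln1_g)
    g$layers[[l]] <- list(
      ln1_g = ln1b$dg, ln1_b = ln1b$db,
      Wq = crossprod(cl$A1, dQ), bq = colSums(dQ),
      Wk = crossprod(cl$A1, dK), bk = colSums(dK),
      Wv = crossprod(cl$A1, dV), bv = colSums(dV),
      Wo = dWo, bo = dbo,
      ln2_g = ln2b$dg, ln2_b = ln2b$db,
      W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
    dH <- dH2 + ln1b$dX
  }
  dH <- dH * cache$D0   # embedding dropout
  if (length(cache$prow)) {
    dprompt <- matrix(0, 4L, d, dimnames = list(mask_schemes(), NULL))
    dprompt[cache$scheme, ] <- colSums(dH[cache$prow, , drop = FALSE])
    g$prompt <- dprompt
  }
  dHt <- dH[cache$trow, , drop = FALSE]
  gsess$W_in <- crossprod(cache$Min, dHt)
  gsess$b_in <- colSums(dHt)
  gsess$emb <- colSums(dHt)
  dpos <- matrix(0, cfg$max_bins, d)
  agg <- rowsum(dHt, cache$tidx)
  dpos[as.integer(rownames(agg)), ] <- agg
  g$pos <- dpos
  g$sessions[[cache$session_id]] <- gsess
  g
}

# --- AdamW --------------------------------------------------------------------

.zeros_like <- function(x) {
  if (is.list(x)) lapply(x, .zeros_like) else x * 0
}

.adamw_walk <- function(p, grad, m, v, lr, b1, b2, eps, wd, bc1, bc2) {
  if (is.null(grad)) return(list(p = p, m = m, v = v))
  if (is.list(p)) {
    for (nm in names(p)) {
      if (is.null(grad[[nm]])) next
      res <- .adamw_walk(p[[nm]], grad[[nm]], m[[nm]], v[[nm]],
                         lr, b1, b2, eps, wd, bc1, bc2)
      p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * grad
  v <- b2 * v + (1 - b2) * grad * grad
  p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + wd * p)
  list(p = p, m = m, v = v)
}

.adamw_init <- function(params) list(t = 0L, m = .zeros_like(params),
                                     v = .zeros_like(params))

# Session entries created after optimizer init (fine-tuning) need fresh slots.
.adamw_sync <- function(state, params) {
  for (sid in names(params$sessions)) {
    if (is.null(state$m$sessions[[sid]])) {
      state$m$sessions[[sid]] <- .zeros_like(params$sessions[[sid]])
      state$v$sessions[[sid]] <- .zeros_like(params$sessions[[sid]])
    }
  }
  state
}

.adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  res <- .adamw_walk(params, grads, state$m, state$v, lr, beta1, beta2, eps,
                     weight_decay, bc1, bc2)
  state$m <- res$m; state$v <- res$v
  list(params = res$p, state = state)
}

# --- exported model operations ------------------------------------------------

#' Tokenize masked spike counts
#'
#' Each time bin becomes one token: the zero-filled masked counts (optionally
#' concatenated with the binary context-mask row, see
#' [model_config()]'s `mask_channel`) are linearly projected to `d_model`
#' through the session's stitcher, then the session embedding and a learned
#' positional embedding are added.
#'
#' @param model an `mtm_model` with the session registered.
#' @param counts numeric array `trial x time_bin x neuron` of masked counts
#'   (see [mask_input()]).
#' @param ctx logical `time_bin x neuron` context mask (`TRUE` = visible).
#' @param session_id registered session id.
#' @return Numeric array `trial x time_bin x d_model`.
#' @export
tokenize <- function(model, counts, ctx, session_id) {
  stopifnot(inherits(model, "mtm_model"))
  sess <- model$params$sessions[[session_id]]
  if (is.null(sess)) stop(sprintf("session '%s' not registered", session_id))
  B <- dim(counts)[1L]; Tt <- dim(counts)[2L]
  if (dim(counts)[3L] != length(sess$b_out))
    stop("neuron count mismatch with the session's stitcher entry")
  Min <- .input_mat(counts, ctx, model$cfg$mask_channel)
  tidx <- rep.int(seq_len(Tt), B)
  Ht <- .addrow(Min %*% sess$W_in, sess$b_in + sess$emb) +
    model$params$pos[tidx, , drop = FALSE]
  aperm(array(Ht, dim = c(Tt, B, model$cfg$d_model)), c(2L, 1L, 3L))
}

#' Prepend the masking-scheme prompt token
#'
#' @param model an `mtm_model`.
#' @param tokens array `trial x time_bin x d_model` from [tokenize()].
#' @param scheme one of [mask_schemes()]; the temporal baseline has no prompt
#'   and is rejected.
#' @return Array `trial x (time_bin + 1) x d_model` with the prompt first, or
#'   `tokens` unchanged when prompting is disabled in the model config.
#' @export
prepend_prompt <- function(model, tokens, scheme) {
  stopifnot(inherits(model, "mtm_model"))
  if (!model$cfg$prompt_enabled) return(tokens)
  if (!scheme %in% rownames(model$params$prompt))
    stop(sprintf("no prompt token for scheme '%s' (the temporal baseline has none)",
                 scheme))
  d <- dim(tokens)
  out <- array(0, dim = c(d[1L], d[2L] + 1L, d[3L]))
  out[, 1L, ] <- rep(model$params$prompt[scheme, ], each = d[1L])
  out[, -1L, ] <- tokens
  out
}

#' Infer firing rates for masked input
#'
#' Runs the full model: tokenize, prepend the scheme's prompt token (when
#' prompting is enabled and a scheme is given), encode with the bidirectional
#' transformer, discard the prompt position, and map each time token through
#' the session's output projection and the rate link to strictly positive
#' Poisson intensities. Deterministic (the model has no stochastic layers at
#' inference).
#'
#' @param model an `mtm_model`.
#' @param counts array `trial x time_bin x neuron` of (masked) counts.
#' @param ctx logical `time_bin x neuron` context mask.
#' @param session_id registered session id.
#' @param scheme masking scheme naming the prompt token; `NULL` for no prompt.
#' @return `rate_tensor`: numeric array `trial x time_bin x neuron`, strictly
#'   positive.
#' @export
forward_rates <- function(model, counts, ctx, session_id, scheme = NULL) {
  stopifnot(inherits(model, "mtm_model"))
  .nn_forward(model$params, model$cfg, counts, ctx, session_id, scheme)
}

#' Masked Poisson negative log-likelihood
#'
#' `loss = mean over scored entries of (lambda - x * log(lambda) + log(x!))`,
#' where the mean runs over all `(trial, bin, neuron)` entries whose
#' `target_mask` is `TRUE`; unscored entries contribute exactly zero.
#'
#' @param rates positive array `trial x time_bin x neuron`.
#' @param counts non-negative integer array of the same shape (the unmasked
#'   observed counts).
#' @param target_mask logical `time_bin x neuron`, `TRUE` = scored.
#' @return Scalar loss (nats per scored entry).
#' @export
poisson_nll <- function(rates, counts, target_mask) {
  d <- dim(rates)
  if (!all(d == dim(counts))) stop("shape mismatch between rates and counts")
  if (d[2L] != nrow(target_mask) || d[3L] != ncol(target_mask))
    stop("target mask shape mismatch")
  sel <- aperm(array(target_mask, dim = c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  lam <- rates[sel]; x <- counts[sel]
  if (length(lam) == 0L) stop("empty target mask")
  if (any(lam <= 0)) stop("non-positive rate at a scored entry")
  mean(lam - x * log(lam) + lgamma(x + 1))
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores weights, architecture config, the stitcher registry
#' and the prompt table; [load_checkpoint()] restores an identical model.
#'
#' @param model an `mtm_model`.
#' @param path file path (RDS).
#' @return `path` invisibly / the restored model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mtm_model"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mtm_model")) stop("not an mtm_model checkpoint")
  model
}
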