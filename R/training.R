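#' Training configuration
#'
#' @param epochs number of passes over the training trials.
#' @param batch_size trials per gradient step.
#' @param learning_rate AdamW learning rate (constant schedule).
#' @param weight_decay AdamW decoupled weight decay.
#' @param mask_params a [mask_params()].
#' @param schemes masking schemes sampled uniformly per batch; default the
#'   four MtM schemes. Use `"temporal"` alone for the baseline.
#' @param seed integer seed governing batching, scheme sampling and masks.
#' @param k_active neurons entering the checkpoint-selection score: the
#'   validation score of an epoch is the mean single-neuron reconstruction
#'   R^2 (predicted rate vs observed count, under neuron masking of the
#'   scored neuron) across the `k_active` most active neurons.
#' @param eval_every score the validation set every this many epochs (the
#'   final epoch is always scored).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L, learning_rate = 1e-3,
                         weight_decay = 0.01, mask_params = NULL,
                         schemes = mask_schemes(), seed = 1L, k_active = 50L,
                         eval_every = 1L) {
  if (epochs < 1L) stop("`epochs` must be >= 1")
  if (is.null(mask_params)) mask_params <- mask_params()
  if (!all(schemes %in% .all_schemes())) stop("unknown scheme in `schemes`")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 mask_params = mask_params, schemes = schemes,
                 seed = as.integer(seed), k_active = as.integer(k_active),
                 eval_every = as.integer(eval_every)),
            class = "train_config")
}

# gradient of the normalized Poisson NLL wrt the rate matrix ((B*T) x N)
.nll_rate_grad <- function(rates_mat, counts, tgt) {
  B <- dim(counts)[1L]; Tt <- dim(counts)[2L]; N <- dim(counts)[3L]
  xmat <- matrix(aperm(counts, c(2L, 1L, 3L)), B * Tt, N)
  sel <- tgt[rep.int(seq_len(Tt), B), , drop = FALSE]
  n_tgt <- sum(sel)
  dr <- matrix(0, B * Tt, N)
  dr[sel] <- (1 - xmat[sel] / rates_mat[sel]) / n_tgt
  list(grad = dr,
       loss = mean(rates_mat[sel] - xmat[sel] * log(rates_mat[sel]) +
                     lgamma(xmat[sel] + 1)))
}

#' One masked training step
#'
#' Draws the scheme's mask, zero-fills hidden entries, runs the forward pass
#' with the scheme's prompt token (when prompting is enabled), computes the
#' Poisson NLL on the scored entries, backpropagates, and applies one AdamW
#' update. Region schemes on sessions without eligible regions fall back to
#' neuron masking with a warning.
#'
#' @param model an `mtm_model`.
#' @param opt optimizer state from a previous step, or `NULL` to start.
#' @param counts batch array `trial x time_bin x neuron` of raw counts.
#' @param session the [session_bundle()] the batch comes from.
#' @param scheme masking scheme for this batch.
#' @param tc a [train_config()].
#' @return List `(model, opt, loss)`.
#' @export
train_step <- function(model, opt, counts, session, scheme, tc,
                       stitcher_only = FALSE) {
  Tt <- dim(counts)[2L]
  mask <- make_mask(scheme, Tt, session$regions, tc$mask_params, fallback = TRUE)
  Xm <- mask_input(counts, mask)
  prompt_scheme <- if (model$cfg$prompt_enabled && mask$scheme != "temporal")
    mask$scheme else NULL
  fw <- .nn_forward(model$params, model$cfg, Xm, mask$context_mask,
                    session$session_id, prompt_scheme, want_cache = TRUE,
                    train_mode = TRUE)
  gr <- .nll_rate_grad(fw$cache$rates_mat, counts, mask$target_mask)
  grads <- .nn_backward(model$params, model$cfg, fw$cache, gr$grad)
  if (stitcher_only) {
    # update only the session's read-in/read-out projections and embedding
    grads <- list(sessions = grads$sessions)
  }
  if (is.null(opt)) opt <- .adamw_init(model$params)
  opt <- .adamw_sync(opt, model$params)
  upd <- .adamw_step(model$params, grads, opt, lr = tc$learning_rate,
                     weight_decay = tc$weight_decay)
  model$params <- upd$params
  list(model = model, opt = upd$state, loss = gr$loss)
}

# mean single-neuron reconstruction R^2 across the k most active neurons,
# each scored under neuron masking of that neuron on validation trials.
.checkpoint_score <- function(model, session, val_trials, k_active) {
  counts <- session$spikes$counts[val_trials, , , drop = FALSE]
  Tt <- dim(counts)[2L]; N <- dim(counts)[3L]
  k <- min(k_active, N)
  top <- most_active_neurons(session$spikes, k)
  prompt <- if (model$cfg$prompt_enabled) "neuron" else NULL
  scores <- vapply(top, function(n) {
    ctx <- matrix(TRUE, Tt, N); ctx[, n] <- FALSE
    Xm <- counts; Xm[, , n] <- 0
    r <- .nn_forward(model$params, model$cfg, Xm, ctx, session$session_id, prompt)
    x <- as.vector(counts[, , n]); p <- as.vector(r[, , n])
    sst <- sum((x - mean(x))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((x - p)^2) / sst
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

.fit_masked <- function(model, sessions, tc, splits, opt = NULL,
                        history0 = NULL, verbose = FALSE,
                        stitcher_only = FALSE) {
  if (inherits(sessions, "session_bundle")) sessions <- list(sessions)
  names(sessions) <- vapply(sessions, `[[`, "", "session_id")
  for (sb in sessions)
    if (!sb$session_id %in% names(model$params$sessions))
      model <- register_session(model, sb, seed = tc$seed + length(model$sessions))
  if (is.null(splits)) {
    splits <- lapply(sessions, function(sb)
      split_trials(dim(sb$spikes$counts)[1L], seed = tc$seed))
  }
  history <- list()
  best <- list(score = -Inf, epoch = NA_integer_, params = NULL)
  scheme_counts <- stats::setNames(integer(length(tc$schemes)), tc$schemes)
  withr::with_seed(tc$seed, {
    for (epoch in seq_len(tc$epochs)) {
      epoch_loss <- 0; n_batches <- 0L
      batches <- list()
      for (sid in names(sessions)) {
        tr <- sample(splits[[sid]]$train)
        starts <- seq(1L, length(tr), by = tc$batch_size)
        for (s in starts)
          batches[[length(batches) + 1L]] <-
            list(sid = sid, trials = tr[s:min(s + tc$batch_size - 1L, length(tr))])
      }
      batches <- batches[sample.int(length(batches))]
      for (bt in batches) {
        scheme <- sample_scheme(tc$schemes)
        scheme_counts[scheme] <- scheme_counts[scheme] + 1L
        sb <- sessions[[bt$sid]]
        counts <- sb$spikes$counts[bt$trials, , , drop = FALSE]
        st <- train_step(model, opt, counts, sb, scheme, tc,
                         stitcher_only = stitcher_only)
        model <- st$model; opt <- st$opt
        epoch_loss <- epoch_loss + st$loss; n_batches <- n_batches + 1L
      }
      score <- NA_real_
      if (epoch %% tc$eval_every == 0L || epoch == tc$epochs) {
        score <- mean(vapply(names(sessions), function(sid)
          .checkpoint_score(model, sessions[[sid]], splits[[sid]]$val,
                            tc$k_active), numeric(1)))
        if (is.finite(score) && score > best$score) {
          best <- list(score = score, epoch = epoch, params = model$params)
        }
      }
      history[[epoch]] <- data.frame(epoch = epoch,
                                     train_loss = epoch_loss / n_batches,
                                     val_score = score)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val R2 %s", epoch,
                        epoch_loss / n_batches,
                        ifelse(is.na(score), "-", sprintf("%.4f", score))))
    }
  })
  if (is.null(best$params)) stop("no finite validation score in any epoch")
  model$params <- best$params
  hist <- do.call(rbind, history)
  hist$scheme_counts <- NULL
  if (!is.null(history0)) hist <- rbind(history0, hist)
  model$history <- hist
  attr(model$history, "scheme_counts") <- scheme_counts
  attr(model$history, "best_epoch") <- best$epoch
  model$opt <- opt
  model
}

#' Train a model with multi-task masking
#'
#' Per batch, a masking scheme is sampled uniformly from `tc$schemes`
#' (default: causal, neuron, intra-region, inter-region) and one masked
#' reconstruction step is taken. Validation is scored every
#' `tc$eval_every` epochs and the weights of the best-scoring epoch are
#' restored at the end (ties keep the earliest epoch). Deterministic given
#' `tc$seed`.
#'
#' @param sessions a [session_bundle()] or list of them (multi-session
#'   training stitches them into one model).
#' @param tc a [train_config()].
#' @param cfg a [model_config()]; prompting is enabled by default.
#' @param splits optional named list of [split_trials()] per session id;
#'   defaults to 80/10/10 splits drawn from `tc$seed`.
#' @param model optionally continue training an existing model.
#' @param verbose print per-epoch progress.
#' @return A trained `mtm_model` with a `history` data frame (epoch,
#'   train_loss, val_score; best epoch in `attr(history, "best_epoch")`).
#' @export
fit_mtm <- function(sessions, tc = train_config(), cfg = model_config(),
                    splits = NULL, model = NULL, verbose = FALSE) {
  if (is.null(model))
    model <- mtm_model(cfg, mask_params = tc$mask_params, seed = tc$seed)
  .fit_masked(model, sessions, tc, splits, verbose = verbose)
}

#' Train the temporal-masking baseline
#'
#' Identical loop to [fit_mtm()] with the scheme fixed to temporal masking
#' and no prompt token (NDT-style baseline).
#'
#' @inheritParams fit_mtm
#' @return A trained `mtm_model`.
#' @export
fit_temporal_baseline <- function(sessions, tc = train_config(),
                                  cfg = model_config(), splits = NULL,
                                  verbose = FALSE) {
  tc$schemes <- "temporal"
  cfg$prompt_enabled <- FALSE
  model <- mtm_model(cfg, mask_params = tc$mask_params, seed = tc$seed)
  .fit_masked(model, sessions, tc, splits, verbose = verbose)
}

#' Select the best checkpoint from a training history
#'
#' The checkpoint score of an epoch is the mean single-neuron reconstruction
#' R^2 across the session's most active neurons (see [train_config()]);
#' the earliest epoch wins ties.
#'
#' @param history data frame with columns `epoch` and `val_score`.
#' @return Row of `history` for the selected epoch.
#' @export
select_checkpoint <- function(history) {
  ok <- which(is.finite(history$val_score))
  if (!length(ok)) stop("all checkpoint scores are NaN")
  best <- ok[which.max(history$val_score[ok])]  # which.max keeps the earliest tie
  history[best, , drop = FALSE]
}

#' Fine-tune a pretrained model on a new session
#'
#' Registers fresh stitcher entries (input/output projections and session
#' embedding) for the unseen session, then continues the model's own
#' self-supervised objective on that session's training trials. Fine-tuning
#' is two-phase: first `warmup_epochs` with only the new session's stitcher
#' trainable (a randomly initialized read-in would otherwise feed noise
#' through — and degrade — the pretrained trunk), then the full model with
#' all weights trainable. The prompt table is reused throughout.
#'
#' @param model a pretrained `mtm_model`.
#' @param session an unregistered [session_bundle()].
#' @param tc a [train_config()] for the all-weights phase (its `schemes`
#'   should match the pretraining objective).
#' @param split optional [split_trials()] for the new session.
#' @param warmup_epochs stitcher-only epochs before full training; 0
#'   disables the warmup.
#' @return The fine-tuned model.
#' @export
finetune_session <- function(model, session, tc = train_config(), split = NULL,
                             warmup_epochs = 10L) {
  stopifnot(inherits(model, "mtm_model"), inherits(session, "session_bundle"))
  if (session$session_id %in% names(model$params$sessions))
    stop(sprintf("session '%s' is already registered", session$session_id))
  model <- register_session(model, session, seed = tc$seed + 101L)
  splits <- if (is.null(split)) NULL else
    stats::setNames(list(split), session$session_id)
  if (warmup_epochs > 0L) {
    tcw <- tc
    tcw$epochs <- as.integer(warmup_epochs)
    tcw$seed <- tc$seed + 211L
    model <- .fit_masked(model, list(session), tcw, splits, opt = NULL,
                         history0 = model$history, stitcher_only = TRUE)
  }
  .fit_masked(model, list(session), tc, splits, opt = NULL,
              history0 = model$history)
}
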