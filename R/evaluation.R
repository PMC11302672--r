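#' Per-neuron mean-rate null model
#'
#' The bits-per-spike reference: each neuron is assigned its mean count per
#' bin over the training trials, constant across time. Rates are floored at
#' 1e-9 inside log-likelihoods to avoid silent `-Inf`.
#'
#' @param session a [session_bundle()].
#' @param train_trials trial indices the means are computed on.
#' @return An object of class `null_model` (numeric vector of per-neuron
#'   rates).
#' @export
null_model <- function(session, train_trials) {
  stopifnot(inherits(session, "session_bundle"))
  cc <- session$spikes$counts[train_trials, , , drop = FALSE]
  rates <- apply(cc, 3L, mean)
  structure(list(rates = rates), class = "null_model")
}

.flag_undefined <- function() {
  structure(NA_real_, undefined = TRUE)
}

#' Bits per spike relative to the mean-rate null
#'
#' `bps = (LL(model) - LL(null)) / (S * ln 2)` where `LL` is the Poisson
#' log-likelihood summed over scored entries and `S` the total spike count in
#' those entries. 0 means no better than the per-neuron constant-rate null; a
#' zero spike count makes the metric undefined and returns a flagged `NA`.
#'
#' @param rates model rates, array `trial x time_bin x neuron`.
#' @param counts observed counts, same shape.
#' @param target_mask logical `time_bin x neuron`; `TRUE` entries are scored.
#' @param null a [null_model()] (or numeric per-neuron rate vector).
#' @return Scalar bps; `NA` with attribute `undefined = TRUE` when no spikes
#'   fall in the scored entries.
#' @export
bits_per_spike <- function(rates, counts, target_mask, null) {
  null_rates <- if (inherits(null, "null_model")) null$rates else null
  d <- dim(counts)
  sel <- aperm(array(target_mask, dim = c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  x <- counts[sel]
  S <- sum(x)
  if (S == 0) return(.flag_undefined())
  lam <- pmax(rates[sel], 1e-9)
  nmat <- aperm(array(rep(null_rates, each = d[2L]), dim = c(d[2L], d[3L], d[1L])),
                c(3L, 1L, 2L))
  lam0 <- pmax(nmat[sel], 1e-9)
  ll_model <- sum(x * log(lam) - lam - lgamma(x + 1))
  ll_null <- sum(x * log(lam0) - lam0 - lgamma(x + 1))
  (ll_model - ll_null) / (S * log(2))
}

# Generic rate prediction under a mask; oracle and null models plug in here.
#' Predict rates for test trials under a mask
#'
#' S3 generic used by all evaluation routines. `mtm_model` runs the masked
#' forward pass with the given prompt; `oracle_model` returns the simulator's
#' ground-truth rates (mask-independent); `null_model` returns its constant
#' per-neuron rates.
#'
#' @param object a model.
#' @param session a [session_bundle()].
#' @param trials trial indices to predict.
#' @param mask a `mask_result` (context defines what the model may see).
#' @param prompt_scheme prompt token to use (`NULL` = none).
#' @return Rates array `length(trials) x time_bin x neuron`.
#' @export
predict_rates <- function(object, session, trials, mask, prompt_scheme = NULL) {
  UseMethod("predict_rates")
}

#' @export
predict_rates.mtm_model <- function(object, session, trials, mask,
                                    prompt_scheme = NULL) {
  counts <- session$spikes$counts[trials, , , drop = FALSE]
  Xm <- mask_input(counts, mask)
  if (!object$cfg$prompt_enabled) prompt_scheme <- NULL
  .nn_forward(object$params, object$cfg, Xm, mask$context_mask,
              session$session_id, prompt_scheme)
}

#' Oracle model carrying the simulator's true rates
#'
#' @param session a synthetic [session_bundle()] with `truth$rates`.
#' @return An object of class `oracle_model`.
#' @export
oracle_model <- function(session) {
  if (is.null(session$truth$rates))
    stop("session carries no ground-truth rates")
  structure(list(session_id = session$session_id), class = "oracle_model")
}

#' @export
predict_rates.oracle_model <- function(object, session, trials, mask,
                                       prompt_scheme = NULL) {
  session$truth$rates[trials, , , drop = FALSE]
}

#' @export
predict_rates.null_model <- function(object, session, trials, mask,
                                     prompt_scheme = NULL) {
  d <- dim(session$spikes$counts)
  aperm(array(rep(object$rates, each = d[2L]),
              dim = c(d[2L], d[3L], length(trials))), c(3L, 1L, 2L))
}

.full_ctx <- function(Tt, N) matrix(TRUE, Tt, N)

#' Co-smoothing bits per spike
#'
#' For every neuron in turn: hide that neuron on the test trials (all bins),
#' present all other neurons, predict with the neuron-masking prompt, and
#' accumulate the scored log-likelihoods; a single pooled bps is returned
#' over all neurons' entries (micro-average).
#'
#' @param model any model with a [predict_rates()] method.
#' @param session a [session_bundle()].
#' @param split a [split_trials()].
#' @param prompt_scheme prompt used at test time (default `"neuron"`).
#' @param batch_k hide this many neurons jointly per forward pass (speed
#'   mode); 1 reproduces the exact one-neuron-at-a-time reference.
#' @return Pooled bps over all neurons.
#' @export
eval_co_smoothing <- function(model, session, split, prompt_scheme = "neuron",
                              batch_k = 1L) {
  counts <- session$spikes$counts[split$test, , , drop = FALSE]
  Tt <- dim(counts)[2L]; N <- dim(counts)[3L]
  null <- null_model(session, split$train)
  pred <- array(NA_real_, dim = dim(counts))
  groups <- split(seq_len(N), ceiling(seq_len(N) / batch_k))
  for (gr in groups) {
    ctx <- .full_ctx(Tt, N); ctx[, gr] <- FALSE
    tgt <- !ctx
    mask <- .mask_result(ctx, tgt, "neuron")
    r <- predict_rates(model, session, split$test, mask, prompt_scheme)
    pred[, , gr] <- r[, , gr]
  }
  bits_per_spike(pred, counts, matrix(TRUE, Tt, N), null)
}

#' Forward-prediction bits per spike
#'
#' Hides the final `horizon_fraction` of bins (default 10%) on test trials,
#' predicts them from the preceding bins with the causal prompt, and scores
#' the hidden tail.
#'
#' @inheritParams eval_co_smoothing
#' @param horizon_fraction fraction of final bins to predict.
#' @return Pooled bps over the masked tail.
#' @export
eval_forward_prediction <- function(model, session, split,
                                    prompt_scheme = "causal",
                                    horizon_fraction = 0.10) {
  counts <- session$spikes$counts[split$test, , , drop = FALSE]
  Tt <- dim(counts)[2L]; N <- dim(counts)[3L]
  mp <- mask_params(causal_horizon_fraction = horizon_fraction)
  mask <- apply_causal_mask(Tt, N, mp)
  r <- predict_rates(model, session, split$test, mask, prompt_scheme)
  bits_per_spike(r, counts, mask$target_mask, null_model(session, split$train))
}

#' Intra-region co-smoothing bits per spike
#'
#' For each eligible region and each of its neurons: hide the neuron and all
#' out-of-region neurons (the latter unscored), leaving only same-region
#' neurons as context, predict with the intra-region prompt, and score the
#' hidden neuron. Returns pooled bps per region plus their unweighted mean.
#'
#' @inheritParams eval_co_smoothing
#' @param min_region_size regions below this size are skipped.
#' @param batch_k hide this many same-region neurons jointly per forward
#'   pass; 1 is the exact one-at-a-time reference.
#' @return List with `per_region` (named bps vector) and `mean`.
#' @export
eval_intra_region <- function(model, session, split,
                              prompt_scheme = "intra_region",
                              min_region_size = 5L, batch_k = 1L) {
  counts <- session$spikes$counts[split$test, , , drop = FALSE]
  Tt <- dim(counts)[2L]; N <- dim(counts)[3L]
  null <- null_model(session, split$train)
  regions <- session$regions
  elig <- names(regions$index)[lengths(regions$index) >= min_region_size]
  if (!length(elig)) return(list(per_region = numeric(0), mean = .flag_undefined()))
  per_region <- stats::setNames(numeric(length(elig)), elig)
  for (reg in elig) {
    members <- regions$index[[reg]]
    pred <- array(NA_real_, dim = c(dim(counts)[1L], Tt, length(members)))
    groups <- split(seq_along(members), ceiling(seq_along(members) / batch_k))
    for (gr in groups) {
      ns <- members[gr]
      ctx <- matrix(FALSE, Tt, N)
      ctx[, setdiff(members, ns)] <- TRUE
      tgt <- matrix(FALSE, Tt, N); tgt[, ns] <- TRUE
      mask <- .mask_result(ctx, tgt, "intra_region", reg)
      r <- predict_rates(model, session, split$test, mask, prompt_scheme)
      pred[, , gr] <- r[, , ns]
    }
    tgt_all <- matrix(TRUE, Tt, length(members))
    per_region[reg] <- bits_per_spike(pred, counts[, , members, drop = FALSE],
                                      tgt_all, null$rates[members])
  }
  list(per_region = per_region, mean = mean(per_region))
}

#' Inter-region co-smoothing bits per spike
#'
#' For each region: hide the entire region, present all other regions,
#' predict with the inter-region prompt, and score every neuron of the hidden
#' region. Returns pooled bps per region plus their unweighted mean.
#'
#' @inheritParams eval_co_smoothing
#' @return List with `per_region` (named bps vector) and `mean`; flagged
#'   undefined for single-region sessions.
#' @export
eval_inter_region <- function(model, session, split,
                              prompt_scheme = "inter_region") {
  counts <- session$spikes$counts[split$test, , , drop = FALSE]
  Tt <- dim(counts)[2L]; N <- dim(counts)[3L]
  regions <- session$regions
  if (length(regions$index) < 2L)
    return(list(per_region = numeric(0), mean = .flag_undefined()))
  null <- null_model(session, split$train)
  regs <- names(regions$index)
  per_region <- stats::setNames(numeric(length(regs)), regs)
  for (reg in regs) {
    members <- regions$index[[reg]]
    ctx <- .full_ctx(Tt, N); ctx[, members] <- FALSE
    tgt <- matrix(FALSE, Tt, N); tgt[, members] <- TRUE
    mask <- .mask_result(ctx, tgt, "inter_region", reg)
    r <- predict_rates(model, session, split$test, mask, prompt_scheme)
    per_region[reg] <- bits_per_spike(r, counts, tgt, null)
  }
  list(per_region = per_region, mean = mean(per_region))
}

# rates on fully visible input, as used for behavior decoding
.decoding_rates <- function(model, session, trials, prompt_scheme) {
  d <- dim(session$spikes$counts)
  ctx <- .full_ctx(d[2L], d[3L])
  mask <- .mask_result(ctx, matrix(TRUE, d[2L], d[3L]), "neuron")
  predict_rates(model, session, trials, mask, prompt_scheme)
}

#' Decode the trial's binary choice from inferred rates
#'
#' Rates are inferred on unmasked input (neuron-masking prompt by default),
#' flattened per trial to a `time x neuron` feature vector, and fed to an
#' L2-regularized logistic classifier (ridge penalty, fixed `lambda`) fit on
#' the training trials. Reports test-trial accuracy.
#'
#' @inheritParams eval_co_smoothing
#' @param lambda ridge penalty of the linear classifier.
#' @param rates optional precomputed rates (`trial x bin x neuron`, full
#'   session) to decode from, bypassing the model forward pass.
#' @return Test accuracy in `[0, 1]`.
#' @export
decode_choice <- function(model, session, split, prompt_scheme = "neuron",
                          lambda = 1.0, rates = NULL) {
  y <- session$behavior$choice
  if (length(unique(y[split$train])) < 2L)
    stop("training split contains a single choice class")
  if (is.null(rates)) {
    r_train <- .decoding_rates(model, session, split$train, prompt_scheme)
    r_test <- .decoding_rates(model, session, split$test, prompt_scheme)
  } else {
    r_train <- rates[split$train, , , drop = FALSE]
    r_test <- rates[split$test, , , drop = FALSE]
  }
  flat <- function(r) matrix(r, nrow = dim(r)[1L])
  fit <- glmnet::glmnet(flat(r_train), y[split$train], family = "binomial",
                        alpha = 0, lambda = lambda)
  pred <- as.integer(stats::predict(fit, flat(r_test), type = "class"))
  mean(pred == y[split$test])
}

#' Decode whisker motion energy from inferred rates
#'
#' Rates are inferred on unmasked input (causal prompt by default); a ridge
#' regression maps the per-bin rate vector to motion energy at the same bin,
#' fit on training-trial bins. Reports R^2 pooled over test-trial bins
#' (`1 - SSE/SST`, SST from the test-split target variance).
#'
#' @inheritParams decode_choice
#' @return Test R^2; flagged `NA` if the test target has zero variance.
#' @export
decode_motion_energy <- function(model, session, split, prompt_scheme = "causal",
                                 lambda = 1.0, rates = NULL) {
  me <- session$behavior$motion_energy
  if (is.null(rates)) {
    r_train <- .decoding_rates(model, session, split$train, prompt_scheme)
    r_test <- .decoding_rates(model, session, split$test, prompt_scheme)
  } else {
    r_train <- rates[split$train, , , drop = FALSE]
    r_test <- rates[split$test, , , drop = FALSE]
  }
  stack <- function(r) matrix(aperm(r, c(2L, 1L, 3L)), dim(r)[1L] * dim(r)[2L])
  yvec <- function(tr) as.vector(t(me[tr, , drop = FALSE]))
  ytr <- yvec(split$train); yte <- yvec(split$test)
  if (stats::var(yte) == 0) return(.flag_undefined())
  fit <- glmnet::glmnet(stack(r_train), ytr, family = "gaussian",
                        alpha = 0, lambda = lambda)
  pred <- as.vector(stats::predict(fit, stack(r_test)))
  1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
}

#' Behavior decoding restricted to one brain region
#'
#' Hides every out-of-region neuron, predicts the region's rates with the
#' intra-region prompt, and runs both behavior decoders on those rates only.
#'
#' @inheritParams eval_co_smoothing
#' @param region region label present in the session.
#' @param lambda ridge penalty for both decoders.
#' @return List `(choice_accuracy, motion_energy_r2)`.
#' @export
region_restricted_decoding <- function(model, session, region, split,
                                       lambda = 1.0) {
  regions <- session$regions
  if (!region %in% names(regions$index))
    stop(sprintf("unknown region '%s'", region))
  d <- dim(session$spikes$counts)
  members <- regions$index[[region]]
  ctx <- matrix(FALSE, d[2L], d[3L]); ctx[, members] <- TRUE
  tgt <- matrix(FALSE, d[2L], d[3L]); tgt[, members] <- TRUE
  mask <- .mask_result(ctx, tgt, "intra_region", region)
  all_trials <- seq_len(d[1L])
  r <- predict_rates(model, session, all_trials, mask, "intra_region")
  r <- r[, , members, drop = FALSE]
  list(choice_accuracy = decode_choice(model, session, split, rates = r,
                                       lambda = lambda),
       motion_energy_r2 = decode_motion_energy(model, session, split,
                                               rates = r, lambda = lambda))
}

#' Run the full evaluation benchmark on one session
#'
#' Computes every activity metric with its associated prompt token (neuron
#' masking for co-smoothing, causal for forward prediction, intra-/inter-
#' region for the region metrics) plus both behavior decoders, and assembles
#' an `eval_report`.
#'
#' @inheritParams eval_co_smoothing
#' @param model_id label recorded in the report.
#' @param batch_k passed to [eval_co_smoothing()].
#' @return An object of class `eval_report` (a list of metric values plus
#'   metadata).
#' @export
evaluate_all <- function(model, session, split, model_id = "model",
                         batch_k = 1L) {
  intra <- eval_intra_region(model, session, split, batch_k = batch_k)
  inter <- eval_inter_region(model, session, split)
  structure(list(
    model_id = model_id,
    session_id = session$session_id,
    prompts = c(co_smoothing = "neuron", forward = "causal",
                intra_region = "intra_region", inter_region = "inter_region",
                choice = "neuron", motion_energy = "causal"),
    co_smoothing_bps = eval_co_smoothing(model, session, split, batch_k = batch_k),
    forward_bps = eval_forward_prediction(model, session, split),
    intra_region_bps = intra$mean,
    intra_region_per_region = intra$per_region,
    inter_region_bps = inter$mean,
    inter_region_per_region = inter$per_region,
    choice_accuracy = decode_choice(model, session, split),
    motion_energy_r2 = decode_motion_energy(model, session, split)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> model '%s' on session '%s'\n", x$model_id, x$session_id))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("% .4f", v)
  cat("  co-smoothing bps:   ", fmt(x$co_smoothing_bps), "\n")
  cat("  forward bps:        ", fmt(x$forward_bps), "\n")
  cat("  intra-region bps:   ", fmt(x$intra_region_bps), "\n")
  cat("  inter-region bps:   ", fmt(x$inter_region_bps), "\n")
  cat("  choice accuracy:    ", fmt(x$choice_accuracy), "\n")
  cat("  motion-energy R^2:  ", fmt(x$motion_energy_r2), "\n")
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `report.json` (full report) and `report.csv` (flat
#' session/metric/value table, one row per metric including per-region
#' entries).
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  scalars <- c(co_smoothing_bps = report$co_smoothing_bps,
               forward_bps = report$forward_bps,
               intra_region_bps = report$intra_region_bps,
               inter_region_bps = report$inter_region_bps,
               choice_accuracy = report$choice_accuracy,
               motion_energy_r2 = report$motion_energy_r2)
  rows <- data.table::data.table(
    session_id = report$session_id, region = "all",
    metric = names(scalars), value = as.numeric(scalars))
  pr <- function(v, metric) if (length(v)) data.table::data.table(
    session_id = report$session_id, region = names(v), metric = metric,
    value = as.numeric(v))
  rows <- data.table::rbindlist(list(
    rows, pr(report$intra_region_per_region, "intra_region_bps"),
    pr(report$inter_region_per_region, "inter_region_bps")))
  data.table::fwrite(rows, file.path(dir, "report.csv"))
  invisible(dir)
}
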