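#' The four multi-task masking schemes
#'
#' Training alternates uniformly among these; the `temporal` baseline scheme
#' (see [apply_temporal_mask()]) is deliberately not part of the set.
#'
#' @return Character vector `c("causal", "neuron", "intra_region",
#'   "inter_region")`.
#' @export
mask_schemes <- function() c("causal", "neuron", "intra_region", "inter_region")

.all_schemes <- function() c(mask_schemes(), "temporal")

#' Masking hyper-parameters
#'
#' @param neuron_mask_ratio fraction of neurons hidden by neuron masking.
#' @param temporal_mask_ratio fraction of time bins hidden by the temporal
#'   baseline.
#' @param causal_horizon_fraction fraction of final bins hidden by causal
#'   masking; 0.10 matches the forward-prediction evaluation.
#' @param causal_random_start if `TRUE` (default), causal masks drawn during
#'   training place the cut point uniformly at random (hiding everything
#'   after it) instead of always hiding the same final fraction. Training
#'   only at one fixed tail lets a model memorize position-keyed trial tails
#'   that do not transfer to held-out trials; a random cut forces genuine
#'   past-to-future prediction at every position, as in GPT-style next-step
#'   training. Evaluation always uses the fixed final fraction.
#' @param region_mask_ratio fraction of the chosen region's neurons hidden by
#'   intra-region masking (context must remain inside the region).
#' @param inter_region_mask_ratio fraction of the chosen region's neurons
#'   scored by inter-region masking; default 1 (the whole region may be
#'   hidden since context comes from the other regions).
#' @param min_region_size regions with fewer neurons are never chosen for
#'   region masking.
#' @return An object of class `mask_params`.
#' @export
mask_params <- function(neuron_mask_ratio = 0.3,
                        temporal_mask_ratio = 0.3,
                        causal_horizon_fraction = 0.10,
                        causal_random_start = TRUE,
                        region_mask_ratio = 0.3,
                        inter_region_mask_ratio = 1.0,
                        min_region_size = 5L) {
  fr <- c(neuron_mask_ratio, temporal_mask_ratio, causal_horizon_fraction,
          region_mask_ratio)
  if (any(fr <= 0) || any(fr >= 1))
    stop("mask ratios must lie strictly in (0, 1)")
  if (inter_region_mask_ratio <= 0 || inter_region_mask_ratio > 1)
    stop("`inter_region_mask_ratio` must lie in (0, 1]")
  if (min_region_size < 2L) stop("`min_region_size` must be >= 2")
  structure(list(neuron_mask_ratio = neuron_mask_ratio,
                 temporal_mask_ratio = temporal_mask_ratio,
                 causal_horizon_fraction = causal_horizon_fraction,
                 causal_random_start = isTRUE(causal_random_start),
                 region_mask_ratio = region_mask_ratio,
                 inter_region_mask_ratio = inter_region_mask_ratio,
                 min_region_size = as.integer(min_region_size)),
            class = "mask_params")
}

.mask_result <- function(context, target, scheme, chosen_region = NULL) {
  structure(list(context_mask = context, target_mask = target,
                 scheme = scheme, chosen_region = chosen_region),
            class = "mask_result")
}

#' @export
print.mask_result <- function(x, ...) {
  cat(sprintf("<mask_result> scheme=%s%s: %d/%d entries scored, %d visible\n",
              x$scheme,
              if (is.null(x$chosen_region)) "" else paste0(" region=", x$chosen_region),
              sum(x$target_mask), length(x$target_mask), sum(x$context_mask)))
  invisible(x)
}

#' Sample a masking scheme uniformly
#'
#' One draw from the uniform distribution over the four MtM schemes; uses the
#' current RNG state.
#'
#' @param schemes scheme set to draw from (default [mask_schemes()]).
#' @return A single scheme name.
#' @export
sample_scheme <- function(schemes = mask_schemes()) {
  stopifnot(all(schemes %in% .all_schemes()))
  schemes[sample.int(length(schemes), 1L)]
}

#' Neuron masking
#'
#' Hides a random subset of whole neurons (all time bins) and scores exactly
#' those entries; the remaining neurons are fully visible and never scored.
#'
#' @param n_bins,n_neurons mask dimensions.
#' @param params a [mask_params()].
#' @return A `mask_result` with logical `context_mask` and `target_mask`
#'   matrices of dimension `n_bins x n_neurons` (`TRUE` in `context_mask` =
#'   visible to the model; `TRUE` in `target_mask` = scored in the loss).
#' @export
apply_neuron_mask <- function(n_bins, n_neurons, params = mask_params()) {
  if (n_neurons < 2L) stop("neuron masking needs at least 2 neurons")
  k <- ceiling(params$neuron_mask_ratio * n_neurons)
  if (k >= n_neurons)
    stop("`neuron_mask_ratio` leaves no visible neurons as context")
  hidden <- sample.int(n_neurons, k)
  ctx <- matrix(TRUE, n_bins, n_neurons); ctx[, hidden] <- FALSE
  tgt <- matrix(FALSE, n_bins, n_neurons); tgt[, hidden] <- TRUE
  .mask_result(ctx, tgt, "neuron")
}

#' Causal masking
#'
#' Hides the final `ceiling(fraction * n_bins)` bins for every neuron and
#' scores them; earlier bins are fully visible. Deterministic.
#'
#' @inheritParams apply_neuron_mask
#' @return A `mask_result`.
#' @export
apply_causal_mask <- function(n_bins, n_neurons, params = mask_params()) {
  h <- ceiling(params$causal_horizon_fraction * n_bins)
  if (h < 1L || h >= n_bins)
    stop("`causal_horizon_fraction` must leave >= 1 visible and >= 1 masked bin")
  tail_bins <- (n_bins - h + 1L):n_bins
  ctx <- matrix(TRUE, n_bins, n_neurons); ctx[tail_bins, ] <- FALSE
  tgt <- matrix(FALSE, n_bins, n_neurons); tgt[tail_bins, ] <- TRUE
  .mask_result(ctx, tgt, "causal")
}

.eligible_regions <- function(regions, params) {
  names(regions$index)[lengths(regions$index) >= params$min_region_size]
}

#' Intra-region masking
#'
#' Chooses one eligible region uniformly at random, hides and scores a random
#' subset of its neurons, keeps the remaining same-region neurons as the only
#' visible context, and hides — without scoring — every out-of-region neuron.
#'
#' @param n_bins number of time bins.
#' @param regions a [region_assignment()].
#' @param params a [mask_params()].
#' @return A `mask_result` with `chosen_region` set.
#' @export
apply_intra_region_mask <- function(n_bins, regions, params = mask_params()) {
  elig <- .eligible_regions(regions, params)
  if (length(elig) < 1L)
    stop("no region with >= min_region_size neurons is eligible")
  reg <- elig[sample.int(length(elig), 1L)]
  members <- regions$index[[reg]]
  k <- ceiling(params$region_mask_ratio * length(members))
  k <- min(k, length(members) - 1L)  # context must remain inside the region
  hidden <- members[sample.int(length(members), k)]
  n_neurons <- length(regions$labels)
  ctx <- matrix(FALSE, n_bins, n_neurons)     # out-of-region: hidden, unscored
  ctx[, setdiff(members, hidden)] <- TRUE
  tgt <- matrix(FALSE, n_bins, n_neurons)
  tgt[, hidden] <- TRUE
  .mask_result(ctx, tgt, "intra_region", reg)
}

#' Inter-region masking
#'
#' Chooses one eligible region uniformly at random, hides the whole region,
#' scores a subset of its neurons (default all of them), and keeps every
#' other region's neurons visible as context.
#'
#' @inheritParams apply_intra_region_mask
#' @return A `mask_result` with `chosen_region` set.
#' @export
apply_inter_region_mask <- function(n_bins, regions, params = mask_params()) {
  if (length(regions$index) < 2L)
    stop("inter-region masking needs at least 2 regions")
  elig <- .eligible_regions(regions, params)
  if (length(elig) < 1L)
    stop("no region with >= min_region_size neurons is eligible")
  reg <- elig[sample.int(length(elig), 1L)]
  members <- regions$index[[reg]]
  k <- max(1L, ceiling(params$inter_region_mask_ratio * length(members)))
  scored <- members[sample.int(length(members), k)]
  n_neurons <- length(regions$labels)
  ctx <- matrix(TRUE, n_bins, n_neurons); ctx[, members] <- FALSE
  tgt <- matrix(FALSE, n_bins, n_neurons); tgt[, scored] <- TRUE
  .mask_result(ctx, tgt, "inter_region", reg)
}

#' Temporal masking (baseline)
#'
#' NDT-style baseline: hides a random subset of whole time bins across all
#' neurons and scores exactly those bins.
#'
#' @inheritParams apply_neuron_mask
#' @return A `mask_result`.
#' @export
apply_temporal_mask <- function(n_bins, n_neurons, params = mask_params()) {
  k <- ceiling(params$temporal_mask_ratio * n_bins)
  if (k >= n_bins) stop("`temporal_mask_ratio` leaves no visible bins")
  hidden <- sample.int(n_bins, k)
  ctx <- matrix(TRUE, n_bins, n_neurons); ctx[hidden, ] <- FALSE
  tgt <- matrix(FALSE, n_bins, n_neurons); tgt[hidden, ] <- TRUE
  .mask_result(ctx, tgt, "temporal")
}

#' Draw a mask for a given scheme
#'
#' Dispatcher used by the training loop; region schemes on sessions lacking
#' eligible regions fall back to neuron masking with a warning.
#'
#' @param scheme one of [mask_schemes()] or `"temporal"`.
#' @param n_bins number of time bins.
#' @param regions a [region_assignment()] (required for region schemes).
#' @param params a [mask_params()].
#' @param fallback if `TRUE`, ineligible region schemes degrade to neuron
#'   masking instead of erroring.
#' @return A `mask_result`.
#' @export
make_mask <- function(scheme, n_bins, regions, params = mask_params(),
                      fallback = FALSE) {
  n_neurons <- length(regions$labels)
  res <- switch(scheme,
    neuron = apply_neuron_mask(n_bins, n_neurons, params),
    causal = if (params$causal_random_start) {
      # visible prefix of random length, everything after it hidden + scored
      u <- sample.int(n_bins - 1L, 1L)
      ctx <- matrix(TRUE, n_bins, n_neurons); ctx[(u + 1L):n_bins, ] <- FALSE
      .mask_result(ctx, !ctx, "causal")
    } else apply_causal_mask(n_bins, n_neurons, params),
    temporal = apply_temporal_mask(n_bins, n_neurons, params),
    intra_region = , inter_region = {
      ok <- length(.eligible_regions(regions, params)) >=
        if (scheme == "inter_region") 1L else 1L &&
        (scheme != "inter_region" || length(regions$index) >= 2L)
      if (!ok && fallback) {
        warning(sprintf("scheme '%s' ineligible for this session; falling back to neuron masking",
                        scheme), call. = FALSE)
        apply_neuron_mask(n_bins, n_neurons, params)
      } else if (scheme == "intra_region") {
        apply_intra_region_mask(n_bins, regions, params)
      } else {
        apply_inter_region_mask(n_bins, regions, params)
      }
    },
    stop(sprintf("unknown masking scheme '%s'", scheme)))
  res
}

#' Apply a mask to spike counts
#'
#' Entries hidden from the model (`context_mask` `FALSE`) are zero-filled; the
#' binary context mask must be passed onward alongside the counts so that the
#' tokenizer can distinguish "hidden" from "observed zero". The input array is
#' never modified in place.
#'
#' @param counts numeric array `trial x time_bin x neuron` (or a matrix
#'   `time_bin x neuron` for a single trial).
#' @param mask a `mask_result` whose masks match the trailing two dimensions.
#' @return Array of the same shape with hidden entries set to 0.
#' @export
mask_input <- function(counts, mask) {
  stopifnot(inherits(mask, "mask_result"))
  ctx <- mask$context_mask
  if (is.matrix(counts)) {
    if (!all(dim(counts) == dim(ctx))) stop("shape mismatch between counts and mask")
    out <- counts
    out[!ctx] <- 0
    return(out)
  }
  d <- dim(counts)
  if (length(d) != 3L || d[2L] != nrow(ctx) || d[3L] != ncol(ctx))
    stop("shape mismatch between counts and mask")
  out <- counts
  for (n in which(colSums(ctx) < nrow(ctx))) out[, !ctx[, n], n] <- 0
  out
}
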