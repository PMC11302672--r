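# Shared fixtures: all data is generated in code, nothing is read from disk.

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small hand-buildable session: 2 regions, deterministic counts
tiny_session <- function(n_trials = 6L, n_bins = 8L, seed = 7L) {
  withr::with_seed(seed, {
    labels <- c(rep("A", 3L), rep("B", 5L))
    counts <- array(rpois(n_trials * n_bins * length(labels), 0.5),
                    dim = c(n_trials, n_bins, length(labels)))
    session_bundle(
      "tiny", binned_spikes(counts, 0.02, n_bins * 0.02),
      region_assignment(labels),
      behavior_table(rep_len(c(0L, 1L), n_trials),
                     matrix(rnorm(n_trials * n_bins), n_trials, n_bins)))
  })
}

# small simulator config for fast training tests
small_sim <- function(seed = 1L, ...) {
  sim_config(n_trials = 60L, n_bins = 30L,
             regions = c(CA1 = 8L, LP = 8L, PO = 8L), seed = seed, ...)
}

tiny_model_config <- function(d_model = 16L, max_bins = 64L, ...) {
  model_config(d_model = d_model, n_layers = 1L, n_heads = 2L,
               ffn_dim = 2L * d_model, max_bins = max_bins, ...)
}

# independent Poisson log-likelihood oracle via dpois (used to cross-check
# the vectorized bits-per-spike and NLL implementations)
ll_pois_oracle <- function(x, lam) sum(dpois(x, lam, log = TRUE))

expect_mask_valid <- function(mask, regions = NULL) {
  expect_false(any(mask$context_mask & mask$target_mask))
  expect_gt(sum(mask$target_mask), 0)
  expect_gt(sum(mask$context_mask), 0)
  if (!is.null(regions) && !is.null(mask$chosen_region)) {
    members <- regions$index[[mask$chosen_region]]
    outside <- setdiff(seq_along(regions$labels), members)
    # targets always inside the chosen region
    expect_true(all(which(colSums(mask$target_mask) > 0) %in% members))
    if (mask$scheme == "intra_region") {
      expect_true(all(which(colSums(mask$context_mask) > 0) %in% members))
    } else if (mask$scheme == "inter_region") {
      expect_true(all(which(colSums(mask$context_mask) > 0) %in% outside))
    }
  }
  invisible(TRUE)
}
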