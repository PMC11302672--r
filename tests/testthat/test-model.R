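make_registered_model <- function(sb = tiny_session(), cfg = tiny_model_config(),
                                  seed = 3L) {
  m <- mtm_model(cfg, seed = seed)
  register_session(m, sb, seed = seed + 1L)
}

test_that("tokenizer is insensitive to hidden counts and length-preserving", {
  sb <- tiny_session()
  m <- make_registered_model(sb)
  counts <- sb$spikes$counts
  ctx <- matrix(TRUE, 8, 8); ctx[, 3] <- FALSE
  mk <- mtmspike:::.mask_result(ctx, !ctx, "neuron")
  tok <- tokenize(m, mask_input(counts, mk), ctx, "tiny")
  expect_equal(dim(tok), c(6, 8, 16))
  # changing a hidden entry's value leaves the tokens unchanged
  counts2 <- counts; counts2[, , 3] <- counts2[, , 3] + 50L
  tok2 <- tokenize(m, mask_input(counts2, mk), ctx, "tiny")
  expect_identical(tok, tok2)
  # identical input bins yield identical tokens only before position is added
  cc <- counts; cc[1, , ] <- rep(cc[1, 1, ], each = 8)  # all bins equal
  tokc <- tokenize(m, cc, matrix(TRUE, 8, 8), "tiny")
  base <- m$params$pos[1:8, ]
  depos <- tokc[1, , ] - base
  for (t in 2:8) expect_equal(depos[t, ], depos[1, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(tokc[1, 1, ], tokc[1, 2, ])))
  expect_error(tokenize(m, counts, ctx, "nope"), "not registered")
})

test_that("prompt token prepends per scheme and respects the baseline exclusion", {
  sb <- tiny_session()
  m <- make_registered_model(sb)
  tok <- tokenize(m, sb$spikes$counts, matrix(TRUE, 8, 8), "tiny")
  pn <- prepend_prompt(m, tok, "neuron")
  pc <- prepend_prompt(m, tok, "causal")
  expect_equal(dim(pn), c(6, 9, 16))
  expect_equal(pn[1, 1, ], unname(m$params$prompt["neuron", ]))
  expect_identical(pn[, -1, ], pc[, -1, ])
  expect_false(isTRUE(all.equal(pn[1, 1, ], pc[1, 1, ])))
  expect_error(prepend_prompt(m, tok, "temporal"), "no prompt token")
  m2 <- make_registered_model(sb, tiny_model_config(prompt_enabled = FALSE))
  expect_identical(prepend_prompt(m2, tok, "neuron"), tok)
})

test_that("forward_rates is positive, deterministic, and mask-insensitive", {
  sb <- tiny_session()
  m <- make_registered_model(sb)
  counts <- sb$spikes$counts
  ctx <- matrix(TRUE, 8, 8); ctx[5:8, 2] <- FALSE
  mk <- mtmspike:::.mask_result(ctx, !ctx, "neuron")
  r1 <- forward_rates(m, mask_input(counts, mk), ctx, "tiny", "neuron")
  r2 <- forward_rates(m, mask_input(counts, mk), ctx, "tiny", "neuron")
  expect_identical(r1, r2)
  expect_true(all(r1 > 0) && all(is.finite(r1)))
  expect_equal(dim(r1), dim(counts))
  # rates invariant to values at context-hidden entries (exact)
  counts2 <- counts; counts2[, 5:8, 2] <- counts2[, 5:8, 2] + 9L
  r3 <- forward_rates(m, mask_input(counts2, mk), ctx, "tiny", "neuron")
  expect_identical(r1, r3)
  # prompt changes the output when enabled
  r4 <- forward_rates(m, mask_input(counts, mk), ctx, "tiny", "causal")
  expect_false(identical(r1, r4))
})

test_that("neuron permutation equivariance holds through the stitcher", {
  sb <- tiny_session()
  m <- make_registered_model(sb)
  counts <- sb$spikes$counts
  ctx <- matrix(TRUE, 8, 8)
  r <- forward_rates(m, counts, ctx, "tiny")
  perm <- c(3L, 1L, 2L, 5L, 4L, 8L, 7L, 6L)
  m2 <- m
  m2$params$sessions$tiny$W_in <- m$params$sessions$tiny$W_in[perm, ]
  m2$params$sessions$tiny$W_out <- m$params$sessions$tiny$W_out[, perm]
  m2$params$sessions$tiny$b_out <- m$params$sessions$tiny$b_out[perm]
  rp <- forward_rates(m2, counts[, , perm], ctx[, perm], "tiny")
  expect_equal(rp, r[, , perm], tolerance = 1e-12)
})

test_that("poisson_nll matches closed-form spot values and is additive", {
  # x = 0, lambda = 1 -> contribution exactly 1
  r <- array(1, dim = c(1, 1, 1)); x <- array(0L, dim = c(1, 1, 1))
  expect_equal(poisson_nll(r, x, matrix(TRUE, 1, 1)), 1.0)
  # x = 2, lambda = 3 -> 3 - 2 ln 3 + ln 2
  r <- array(3, dim = c(1, 1, 1)); x <- array(2L, dim = c(1, 1, 1))
  expect_equal(poisson_nll(r, x, matrix(TRUE, 1, 1)), 3 - 2 * log(3) + log(2),
               tolerance = 1e-12)
  expect_equal(poisson_nll(r, x, matrix(TRUE, 1, 1)), 1.4959226,
               tolerance = 1e-6)
  # additivity over disjoint target masks (sum-weighted by entry counts)
  withr::with_seed(5, {
    rr <- array(runif(2 * 6 * 4, 0.2, 3), dim = c(2, 6, 4))
    xx <- array(rpois(2 * 6 * 4, 1), dim = c(2, 6, 4))
    m1 <- matrix(FALSE, 6, 4); m1[, 1:2] <- TRUE
    m2 <- matrix(FALSE, 6, 4); m2[, 3] <- TRUE
    mu <- m1 | m2
    n1 <- 2 * sum(m1); n2 <- 2 * sum(m2)
    expect_equal(poisson_nll(rr, xx, mu),
                 (n1 * poisson_nll(rr, xx, m1) + n2 * poisson_nll(rr, xx, m2)) /
                   (n1 + n2), tolerance = 1e-10)
    # cross-check against the independent dpois oracle
    sel <- aperm(array(mu, dim = c(6, 4, 2)), c(3, 1, 2))
    expect_equal(poisson_nll(rr, xx, mu),
                 -ll_pois_oracle(xx[sel], rr[sel]) / sum(sel),
                 tolerance = 1e-10)
  })
  expect_error(poisson_nll(array(0, dim = c(1, 1, 1)), x[, , 1, drop = FALSE],
                           matrix(TRUE, 1, 1)), "non-positive")
})

test_that("analytic gradients match finite differences on a tiny model", {
  sb <- tiny_session(n_trials = 2L, n_bins = 5L)
  cfg <- model_config(d_model = 8L, n_layers = 2L, n_heads = 2L, ffn_dim = 12L,
                      max_bins = 8L)
  m <- mtm_model(cfg, seed = 3L)
  m <- register_session(m, sb, seed = 4L)
  counts <- sb$spikes$counts[1:2, , , drop = FALSE]
  ctx <- matrix(TRUE, 5, 8); ctx[, 2] <- FALSE
  tgt <- !ctx
  Xm <- counts; Xm[, , 2] <- 0

  loss_fn <- function(params) {
    r <- mtmspike:::.nn_forward(params, cfg, Xm, ctx, "tiny", scheme = "neuron")
    poisson_nll(r, counts, tgt)
  }
  fw <- mtmspike:::.nn_forward(m$params, cfg, Xm, ctx, "tiny", scheme = "neuron",
                               want_cache = TRUE)
  gr <- mtmspike:::.nll_rate_grad(fw$cache$rates_mat, counts, tgt)
  g <- mtmspike:::.nn_backward(m$params, cfg, fw$cache, gr$grad)

  get_leaf <- function(p, path) Reduce(function(a, b) a[[b]], path, p)
  set_leaf <- function(p, path, idx, val) {
    rec <- function(pp, pa) {
      if (length(pa) == 1) { pp[[pa[[1]]]][idx] <- val; return(pp) }
      pp[[pa[[1]]]] <- rec(pp[[pa[[1]]]], pa[-1]); pp
    }
    rec(p, path)
  }
  check <- function(path, idx, eps = 1e-6, tol = 1e-4) {
    l0 <- get_leaf(m$params, path)[idx]
    num <- (loss_fn(set_leaf(m$params, path, idx, l0 + eps)) -
              loss_fn(set_leaf(m$params, path, idx, l0 - eps))) / (2 * eps)
    ana <- get_leaf(g, path)[idx]
    expect_equal(ana, num, tolerance = tol,
                 label = paste(c(path, idx), collapse = "/"))
  }
  check(list("sessions", "tiny", "W_in"), 5)
  check(list("sessions", "tiny", "W_in"), 60)
  check(list("sessions", "tiny", "b_out"), 2)
  check(list("sessions", "tiny", "emb"), 2)
  check(list("pos"), 3)
  check(list("prompt"), 6)                      # row for the active scheme
  check(list("layers", 1, "Wq"), 10)
  check(list("layers", 1, "Wv"), 12)
  check(list("layers", 2, "Wo"), 13)
  check(list("layers", 2, "W1"), 14)
  check(list("layers", 1, "W2"), 15)
  check(list("layers", 2, "ln1_g"), 3)
  check(list("lnf_b"), 7)
  # gradient flows into the active scheme's prompt row only
  expect_gt(sum(abs(g$prompt["neuron", ])), 0)
  expect_equal(sum(abs(g$prompt[c("causal", "intra_region", "inter_region"), ])), 0)
})

test_that("checkpoints round-trip through disk", {
  sb <- tiny_session()
  m <- make_registered_model(sb)
  path <- file.path(withr::local_tempdir(), "ckpt.rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$cfg, m$cfg)
})
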