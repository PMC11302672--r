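test_that("bits_per_spike matches an independent dpois oracle and unit anchors", {
  # null rates as model -> exactly 0
  sb <- tiny_session()
  split <- split_trials(6, c(0.5, 0.25, 0.25), seed = 1)
  nm <- null_model(sb, split$train)
  d <- dim(sb$spikes$counts)
  null_rates <- aperm(array(rep(nm$rates, each = d[2]), dim = c(d[2], d[3], d[1])),
                      c(3, 1, 2))
  tgt <- matrix(TRUE, d[2], d[3])
  expect_equal(bits_per_spike(null_rates, sb$spikes$counts, tgt, nm), 0)

  # random tensors vs brute-force likelihood sums
  withr::with_seed(21, {
    for (i in 1:5) {
      x <- array(rpois(125, 1), dim = c(5, 5, 5))
      r <- array(runif(125, 0.1, 2), dim = c(5, 5, 5))
      n0 <- runif(5, 0.2, 1.5)
      tg <- matrix(sample(c(TRUE, FALSE), 25, replace = TRUE), 5, 5)
      if (!any(tg)) tg[1, 1] <- TRUE
      sel <- aperm(array(tg, dim = c(5, 5, 5)), c(3, 1, 2))
      S <- sum(x[sel])
      nfull <- aperm(array(rep(n0, each = 5), dim = c(5, 5, 5)), c(3, 1, 2))
      expected <- (ll_pois_oracle(x[sel], r[sel]) -
                     ll_pois_oracle(x[sel], nfull[sel])) / (S * log(2))
      expect_equal(bits_per_spike(r, x, tg, n0), expected, tolerance = 1e-10)
    }
  })

  # constructed log-likelihood gap of S*ln2 nats -> exactly 1 bps
  a <- 0.1
  b <- uniroot(function(b) log(b / a) - (b - a) - log(2), c(1, 8),
               tol = 1e-14)$root
  x1 <- array(1L, dim = c(1, 4, 2))
  expect_equal(bits_per_spike(array(b, dim = dim(x1)), x1, matrix(TRUE, 4, 2),
                              rep(a, 2)), 1.0, tolerance = 1e-10)

  # zero spikes in the scored entries -> flagged undefined
  x0 <- array(0L, dim = c(1, 2, 2))
  out <- bits_per_spike(array(1, dim = dim(x0)), x0, matrix(TRUE, 2, 2),
                        rep(1, 2))
  expect_true(is.na(out))
  expect_true(attr(out, "undefined"))
})

test_that("bps ignores unscored entries exactly", {
  withr::with_seed(4, {
    x <- array(rpois(60, 1), dim = c(3, 4, 5))
    r <- array(runif(60, 0.2, 2), dim = c(3, 4, 5))
    n0 <- runif(5, 0.3, 1)
    tg <- matrix(FALSE, 4, 5); tg[, 2] <- TRUE
    base <- bits_per_spike(r, x, tg, n0)
    r2 <- r; r2[, , c(1, 3:5)] <- 1e6  # garbage outside the target
    expect_equal(bits_per_spike(r2, x, tg, n0), base)
  })
})

test_that("oracle rates score positive bps on coupled synthetic data, null scores zero", {
  cfg <- small_sim(seed = 10)
  sb <- generate_session(cfg, 1)
  split <- split_trials(60, seed = 1)
  orc <- oracle_model(sb)
  expect_gt(eval_co_smoothing(orc, sb, split), 0)
  expect_gt(eval_forward_prediction(orc, sb, split), 0)
  intra <- eval_intra_region(orc, sb, split)
  expect_gt(intra$mean, 0)
  expect_setequal(names(intra$per_region), names(cfg$regions))
  inter <- eval_inter_region(orc, sb, split)
  expect_gt(inter$mean, 0)
  # the null model scores exactly 0 on every metric
  nm <- null_model(sb, split$train)
  expect_equal(eval_co_smoothing(nm, sb, split), 0)
  expect_equal(eval_forward_prediction(nm, sb, split), 0)
  expect_equal(eval_inter_region(nm, sb, split)$mean, 0)
})

test_that("batched co-smoothing approximates the exact reference", {
  cfg <- small_sim(seed = 12)
  sb <- generate_session(cfg, 1)
  split <- split_trials(60, seed = 1)
  orc <- oracle_model(sb)
  exact <- eval_co_smoothing(orc, sb, split, batch_k = 1L)
  batched <- eval_co_smoothing(orc, sb, split, batch_k = 6L)
  # oracle rates are mask-independent, so the two must agree exactly
  expect_equal(batched, exact, tolerance = 1e-12)
})

test_that("intra-region evaluation never leaks out-of-region activity", {
  cfg <- small_sim(seed = 13)
  sb <- generate_session(cfg, 1)
  split <- split_trials(60, seed = 1)
  m <- mtm_model(tiny_model_config(), seed = 2L)
  m <- register_session(m, sb, seed = 3L)
  base <- eval_intra_region(m, sb, split)
  sb2 <- sb
  out_of_CA1 <- setdiff(seq_len(24), sb$regions$index$CA1)
  sb2$spikes$counts[split$test, , out_of_CA1] <-
    sb2$spikes$counts[split$test, , out_of_CA1] + 7L
  pert <- eval_intra_region(m, sb2, split)
  expect_identical(base$per_region[["CA1"]], pert$per_region[["CA1"]])
})

test_that("behavior decoding finds the simulated choice signal and not permuted labels", {
  cfg <- sim_config(n_trials = 150L, n_bins = 40L,
                    regions = c(A = 15L, B = 15L), seed = 17)
  sb <- generate_session(cfg, 1)
  split <- split_trials(150, seed = 2)
  orc <- oracle_model(sb)
  expect_gt(decode_choice(orc, sb, split), 0.75)
  # permuting training labels destroys the decodable signal
  sbp <- sb
  sbp$behavior$choice <- withr::with_seed(8, sample(sb$behavior$choice))
  accp <- decode_choice(orc, sbp, split)
  expect_lt(abs(accp - 0.5), 0.35)
  # motion energy: oracle latent-driven rates explain variance
  r2 <- decode_motion_energy(orc, sb, split)
  expect_gt(r2, 0.2)
  expect_lte(r2, 1)
  # single-class training split errors cleanly
  sb1 <- sb; sb1$behavior$choice <- rep(0L, 150)
  expect_error(decode_choice(orc, sb1, split), "single choice class")
})

test_that("region-restricted decoding uses only the region's rates", {
  cfg <- small_sim(seed = 19)
  sb <- generate_session(cfg, 1)
  split <- split_trials(60, seed = 3)
  orc <- oracle_model(sb)
  res <- region_restricted_decoding(orc, sb, "CA1", split)
  expect_true(res$choice_accuracy >= 0 && res$choice_accuracy <= 1)
  expect_true(res$motion_energy_r2 <= 1)
  expect_error(region_restricted_decoding(orc, sb, "V1", split), "unknown region")
})

test_that("evaluate_all assembles a complete, reproducible report", {
  cfg <- small_sim(seed = 20)
  sb <- generate_session(cfg, 1)
  split <- split_trials(60, seed = 1)
  m <- mtm_model(tiny_model_config(), seed = 5L)
  m <- register_session(m, sb, seed = 6L)
  rep1 <- evaluate_all(m, sb, split, model_id = "untrained", batch_k = 4L)
  expect_s3_class(rep1, "eval_report")
  for (f in c("co_smoothing_bps", "forward_bps", "intra_region_bps",
              "inter_region_bps", "choice_accuracy", "motion_energy_r2"))
    expect_true(is.finite(rep1[[f]]) || isTRUE(attr(rep1[[f]], "undefined")))
  expect_identical(unname(rep1$prompts["co_smoothing"]), "neuron")
  expect_identical(unname(rep1$prompts["motion_energy"]), "causal")
  rep2 <- evaluate_all(m, sb, split, model_id = "untrained", batch_k = 4L)
  rep2$model_id <- rep1$model_id
  expect_equal(rep1[-1], rep2[-1])
  dir <- withr::local_tempdir()
  write_eval_report(rep1, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  tab <- data.table::fread(file.path(dir, "report.csv"))
  expect_true(all(c("co_smoothing_bps", "forward_bps") %in% tab$metric))
})
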