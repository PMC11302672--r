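test_that("scheme sampling is uniform over the four MtM schemes", {
  draws <- withr::with_seed(1, replicate(4000, sample_scheme()))
  tab <- table(factor(draws, levels = mask_schemes()))
  expect_true(all(tab >= 900 & tab <= 1100))
  expect_gt(chisq.test(tab)$p.value, 0.01)
  expect_false("temporal" %in% draws)
  # seeded reproducibility
  expect_identical(withr::with_seed(2, replicate(10, sample_scheme())),
                   withr::with_seed(2, replicate(10, sample_scheme())))
})

test_that("neuron masking hides whole neurons at the configured ratio", {
  mk <- withr::with_seed(1, apply_neuron_mask(5, 4, mask_params(neuron_mask_ratio = 0.25)))
  hidden <- which(colSums(mk$context_mask) == 0)
  expect_length(hidden, 1L)
  expect_true(all(mk$target_mask[, hidden]))
  expect_true(all(!mk$context_mask[, hidden]))
  expect_true(all(mk$context_mask[, -hidden]))
  expect_true(all(!mk$target_mask[, -hidden]))
  # inclusion frequency ~ k/N over many draws
  withr::with_seed(2, {
    freq <- rowSums(replicate(4000, colSums(apply_neuron_mask(
      2, 10, mask_params(neuron_mask_ratio = 0.3))$target_mask) > 0))
  })
  expect_true(all(abs(freq - 1200) < 3 * sqrt(4000 * 0.3 * 0.7) + 50))
  expect_error(apply_neuron_mask(5, 2, mask_params(neuron_mask_ratio = 0.9)),
               "no visible")
})

test_that("causal masking hides exactly the final fraction of bins", {
  mk <- apply_causal_mask(200, 3, mask_params(causal_horizon_fraction = 0.10))
  expect_equal(sum(rowSums(mk$target_mask) > 0), 20)        # last 10% of 200
  expect_true(all(mk$target_mask[181:200, ]))
  expect_true(all(mk$context_mask[1:180, ]))
  mk <- apply_causal_mask(10, 3, mask_params(causal_horizon_fraction = 0.10))
  expect_true(all(mk$target_mask[10, ]) && sum(mk$target_mask) == 3)
  # purely temporal structure: no neuron dependence
  expect_true(all(apply(mk$context_mask, 1, function(r) all(r) || !any(r))))
})

test_that("region masks respect containment and uniform region choice", {
  reg <- region_assignment(c(rep("A", 3), rep("B", 5)))
  mp <- mask_params(min_region_size = 4L, region_mask_ratio = 0.4)
  mk <- withr::with_seed(1, apply_intra_region_mask(6, reg, mp))
  expect_identical(mk$chosen_region, "B")      # A ineligible
  expect_equal(sum(colSums(mk$target_mask) > 0), 2)  # ceil(0.4*5)
  expect_true(all(colSums(mk$context_mask)[1:3] == 0))  # A hidden, unscored
  expect_true(all(colSums(mk$target_mask)[1:3] == 0))
  expect_mask_valid(mk, reg)

  reg2 <- region_assignment(c(rep("A", 6), rep("B", 6)))
  picks <- withr::with_seed(3, replicate(2000, apply_intra_region_mask(
    2, reg2, mask_params())$chosen_region))
  expect_gt(chisq.test(table(picks))$p.value, 0.01)
  picks_inter <- withr::with_seed(4, replicate(2000, apply_inter_region_mask(
    2, reg2, mask_params())$chosen_region))
  expect_gt(chisq.test(table(picks_inter))$p.value, 0.01)

  mk <- withr::with_seed(5, apply_inter_region_mask(
    4, region_assignment(c(rep("A", 4), rep("B", 4))),
    mask_params(min_region_size = 4L)))
  members <- reg$index[[mk$chosen_region]]
  expect_equal(sum(colSums(mk$target_mask) > 0), 4)  # whole region scored
  expect_true(all(!mk$context_mask[, colSums(mk$target_mask) > 0]))
  expect_error(apply_inter_region_mask(4, region_assignment(rep("A", 8)),
                                       mask_params()), "at least 2 regions")
})

test_that("every scheme satisfies its structural invariants over random draws", {
  withr::with_seed(42, {
    for (i in 1:250) {
      n_bins <- sample(5:40, 1)
      sizes <- sample(5:12, sample(2:4, 1), replace = TRUE)
      reg <- region_assignment(rep(LETTERS[seq_along(sizes)], sizes))
      for (scheme in c(mask_schemes(), "temporal")) {
        mk <- make_mask(scheme, n_bins, reg, mask_params())
        expect_mask_valid(mk, reg)
        if (scheme == "temporal") {
          # whole-bin structure only
          expect_true(all(apply(mk$context_mask, 1,
                                function(r) all(r) || !any(r))))
        }
      }
    }
  })
})

test_that("mask_input zero-fills hidden entries without aliasing or leakage", {
  sb <- tiny_session()
  counts <- sb$spikes$counts
  full <- mtmspike:::.mask_result(matrix(TRUE, 8, 8), matrix(TRUE, 8, 8), "neuron")
  expect_identical(mask_input(counts, full), counts)

  mk <- withr::with_seed(1, apply_intra_region_mask(8, sb$regions,
                                                    mask_params(min_region_size = 3L)))
  masked <- mask_input(counts, mk)
  hidden_cols <- which(colSums(mk$context_mask) == 0)
  expect_true(all(masked[, , hidden_cols] == 0))
  # no aliasing: mutating the copy leaves the original intact
  masked[1, 1, 1] <- 99
  expect_false(counts[1, 1, 1] == 99)
  # intra-region leakage: perturbing out-of-region counts changes nothing
  members <- sb$regions$index[[mk$chosen_region]]
  outside <- setdiff(1:8, members)
  perturbed <- counts
  perturbed[, , outside] <- perturbed[, , outside] + 100L
  expect_identical(mask_input(perturbed, mk)[, , members],
                   mask_input(counts, mk)[, , members])
  expect_error(mask_input(counts[, 1:4, ], mk), "shape mismatch")
})
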