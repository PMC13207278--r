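test_that("comparison-matrix invariants are enforced", {
  good <- gen_consistent_comparison_matrix(c(2, 1, 1), spread = 0.1, seed = 5)
  expect_s3_class(good, "fuzzy_comparison_matrix")

  bad <- good$entries
  bad[1, 2, ] <- c(1, 2, 3)   # break reciprocity with (2,1,)
  expect_error(fuzzy_comparison_matrix(bad), "reciprocal")

  bad2 <- good$entries
  bad2[2, 2, ] <- c(1, 2, 2)
  expect_error(fuzzy_comparison_matrix(bad2), "diagonal")
})

test_that("panel aggregation is the entry-wise geometric mean with exact reciprocity", {
  m <- gen_consistent_comparison_matrix(c(3, 2, 1), spread = 0.2, seed = 9)
  # idempotence on identical judgements; single expert unchanged
  agg3 <- aggregate_panel(list(m, m, m))
  expect_equal(agg3$entries, m$entries, tolerance = 1e-12)
  expect_equal(aggregate_panel(list(m))$entries, m$entries, tolerance = 1e-12)

  # two experts disagreeing on one entry -> hand geometric mean
  e1 <- fuzzy_comparison_matrix(list(list(c(1, 1, 1), c(1, 3, 5)), list(NULL, c(1, 1, 1))))
  e2 <- fuzzy_comparison_matrix(list(list(c(1, 1, 1), c(3, 5, 7)), list(NULL, c(1, 1, 1))))
  agg <- aggregate_panel(list(e1, e2))
  expect_equal(agg$entries[1, 2, ], c(sqrt(3), sqrt(15), sqrt(35)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # lower triangle is the exact reciprocal
  expect_identical(agg$entries[2, 1, ], rev(1 / agg$entries[1, 2, ]))

  expect_error(aggregate_panel(list()), "empty")
  expect_error(aggregate_panel(list(m, e1)), "mismatched")
})

test_that("extent analysis: indifference, pairwise dominance, permutation equivariance", {
  ones <- fuzzy_comparison_matrix(array(1, dim = c(3, 3, 3)))
  w <- chang_extent_weights(ones)
  expect_equal(w$global, rep(1 / 3, 3))

  two <- fuzzy_comparison_matrix(list(list(c(1, 1, 1), c(3, 3, 3)),
                                      list(NULL, c(1, 1, 1))))
  expect_warning(w2 <- chang_extent_weights(two), "zero weight")
  expect_gt(w2$global[1], w2$global[2])
  expect_equal(sum(w2$global), 1)

  # permuting criteria permutes the weights identically
  fcm <- gen_consistent_comparison_matrix(c(0.4, 0.3, 0.2, 0.1),
                                          perturbation = 0.1, spread = 0.8,
                                          seed = 21)
  perm <- c(3, 1, 4, 2)
  permuted <- fuzzy_comparison_matrix(fcm$entries[perm, perm, , drop = FALSE])
  w_orig <- chang_extent_weights(fcm)$global
  w_perm <- chang_extent_weights(permuted)$global
  expect_equal(w_perm, w_orig[perm], tolerance = 1e-12)
})

test_that("extent analysis recovers the generating weight order on consistent matrices", {
  for (n in 3:6) {
    truth <- seq(2, 1, length.out = n) / sum(seq(2, 1, length.out = n))
    fcm <- gen_consistent_comparison_matrix(truth, perturbation = 0,
                                            spread = 0.3, seed = 100 + n)
    w <- chang_extent_weights(fcm)
    expect_equal(order(w$global, decreasing = TRUE), seq_len(n),
                 info = paste("n =", n))
    expect_equal(sum(w$global), 1, tolerance = 1e-12)
    # fuzzy local weights are the synthetic extents: valid non-negative TFNs
    expect_true(all(w$l >= 0 & w$l <= w$m & w$m <= w$u))
  }
})

test_that("consistency ratio is zero on consistent matrices and grows with noise", {
  fcm <- gen_consistent_comparison_matrix(c(0.35, 0.3, 0.2, 0.15),
                                          perturbation = 0, spread = 0, seed = 2)
  rep0 <- consistency_ratio(fcm)
  expect_equal(rep0$CR, 0, tolerance = 1e-9)
  expect_equal(rep0$lambda_max, 4, tolerance = 1e-9)
  expect_true(rep0$pass)

  # identity-ratio 6x6 matrix: lambda_max = n, CI = 0
  rep6 <- consistency_ratio(fuzzy_comparison_matrix(array(1, dim = c(6, 6, 3))))
  expect_equal(rep6$lambda_max, 6, tolerance = 1e-9)
  expect_equal(rep6$CI, 0, tolerance = 1e-9)

  # mean CR increases with multiplicative perturbation
  mean_cr <- vapply(c(0.05, 0.2, 0.5), function(p) {
    mean(vapply(1:20, function(s) {
      consistency_ratio(gen_consistent_comparison_matrix(
        c(0.4, 0.25, 0.2, 0.15), perturbation = p, spread = 0,
        seed = 1000 * s))$CR
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cr) > 0))

  expect_error(consistency_ratio(two <- fuzzy_comparison_matrix(
    array(1, dim = c(2, 2, 3)))), "3 <= n <= 10")
})

test_that("weights-given mode derives crisp globals by defuzzification", {
  local <- rbind(c(0.2, 0.25, 0.3), c(0.1, 0.15, 0.2))
  w <- weight_vector(c("C1", "C2"), local)
  crisp <- c(mean(local[1, ]), mean(local[2, ]))
  expect_equal(w$global, crisp / sum(crisp))
  expect_equal(sum(w$global), 1, tolerance = 1e-12)
})
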