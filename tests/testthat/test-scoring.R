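# The interaction score: reversed PAE, observed/expected contacts,
# classification.

test_that("reverse_pae maps ceiling to zero and matches an elementwise loop", {
  pm <- pae_matrix(matrix(30, 3, 3), max_pae = 30)
  expect_equal(reverse_pae(pm), matrix(0, 3, 3))
  pm2 <- pae_matrix(matrix(10, 2, 2), max_pae = 30)
  expect_equal(reverse_pae(pm2)[1, 1], 20)
  set.seed(42)
  vals <- matrix(runif(36, 0, 31.75), 6, 6)
  pm3 <- pae_matrix(vals, max_pae = 31.75)
  got <- reverse_pae(pm3)
  want <- matrix(NA_real_, 6, 6)
  for (i in 1:6) for (j in 1:6) want[i, j] <- 31.75 - vals[i, j]
  expect_identical(got, want)
})

test_that("observed_contacts sums exactly the two inter-chain blocks", {
  part <- chain_partition(tibble::tibble(chain = c("A", "B"), length = c(2, 3)),
                          bait = "A", prey = "B")
  # no interface signal: all inter-chain PAE at the ceiling
  m <- matrix(0, 5, 5); m[1:2, 3:5] <- 30; m[3:5, 1:2] <- 30
  expect_equal(observed_contacts(reverse_pae(pae_matrix(m, 30)), part), 0)
  # uniform inter-chain PAE 10, max 30: 2 * (2*3) * 20 = 240
  m2 <- matrix(0, 5, 5); m2[1:2, 3:5] <- 10; m2[3:5, 1:2] <- 10
  expect_equal(observed_contacts(reverse_pae(pae_matrix(m2, 30)), part), 240)
  # intra-chain values never contribute
  m3 <- m2; m3[1, 2] <- 29; m3[4, 5] <- 29
  expect_equal(observed_contacts(reverse_pae(pae_matrix(m3, 30)), part), 240)
  expect_error(
    observed_contacts(matrix(0, 4, 4), part),
    class = "spryscreen_dimension_error")
})

test_that("observed_contacts equals the double-loop oracle on 100 random fixtures", {
  set.seed(20240901)
  for (i in 1:100) {
    la <- sample(2:50, 1); lb <- sample(2:50, 1)
    pred <- random_pae_prediction(la, lb)
    rev <- reverse_pae(pred$pae)
    expect_identical(observed_contacts(rev, pred$partition),
                     oc_oracle(rev, la, lb))
  }
})

test_that("oc is block-additive, chain-order invariant and monotone", {
  set.seed(7)
  pred <- random_pae_prediction(6, 9)
  rev <- reverse_pae(pred$pae)
  part <- pred$partition
  ai <- 1:6; bi <- 7:15
  oc <- observed_contacts(rev, part)
  expect_equal(oc, sum(rev[ai, bi]) + sum(rev[bi, ai]))
  # relabeling bait <-> prey leaves oc unchanged
  flipped <- chain_partition(part$chains, bait = "B", prey = "A")
  expect_equal(observed_contacts(rev, flipped), oc)
  # lowering a single inter-chain PAE strictly increases oc
  m <- pred$pae$values
  m[2, 10] <- m[2, 10] / 2
  oc_low <- observed_contacts(reverse_pae(pae_matrix(m, pred$pae$max_pae)), part)
  expect_gt(oc_low, oc)
  # changing an intra-chain value does nothing
  m2 <- pred$pae$values
  m2[1, 2] <- 0
  expect_equal(
    observed_contacts(reverse_pae(pae_matrix(m2, pred$pae$max_pae)), part), oc)
  # doubling every reversed inter-chain entry doubles oc (built so the
  # doubled values stay within [0, max_pae])
  mp <- pred$pae$max_pae
  m4 <- matrix(runif(15 * 15, mp / 2, mp), 15, 15)
  oc4 <- observed_contacts(reverse_pae(pae_matrix(m4, mp)), part)
  m5 <- m4
  m5[ai, bi] <- mp - 2 * (mp - m5[ai, bi])
  m5[bi, ai] <- mp - 2 * (mp - m5[bi, ai])
  expect_equal(observed_contacts(reverse_pae(pae_matrix(m5, mp)), part),
               2 * oc4, tolerance = 1e-9)
})

test_that("calibration fits recover noiseless lines exactly", {
  pts <- make_calibration_fixture(2, 5, seq(100, 500, 100))
  m <- fit_calibration(pts)
  expect_equal(m$slope, 2, tolerance = 1e-10)
  expect_equal(m$intercept, 5, tolerance = 1e-8)
  # the published screen-wide calibration line
  pts2 <- make_calibration_fixture(243.9, 279484, seq(100, 2000, 100))
  m2 <- fit_calibration(pts2)
  expect_equal(m2$slope, 243.9, tolerance = 1e-9)
  expect_equal(m2$intercept, 279484, tolerance = 1e-6)
  expect_equal(m2$r_squared, 1, tolerance = 1e-12)
  expect_identical(tidy(m2)$term, c("intercept", "slope"))
  expect_equal(glance(m2)$n_points, 20L)
  expect_error(
    fit_calibration(tibble::tibble(length = c(100, 100), oc = c(1, 2))),
    class = "spryscreen_degenerate_fit_error")
})

test_that("noisy calibration fits agree with an independent OLS and the planted slope", {
  planted_slope <- 243.9; planted_intercept <- 279484
  for (n in c(20, 200)) {
    set.seed(1000 + n)
    lengths <- sample(100:2000, n, replace = TRUE)
    pts <- make_calibration_fixture(planted_slope, planted_intercept, lengths,
                                    noise_sd = 0.05 * planted_intercept,
                                    seed = n)
    m <- fit_calibration(pts)
    ref <- ols_oracle(pts$length, pts$oc)
    expect_equal(m$slope, unname(ref["slope"]), tolerance = 1e-9)
    expect_equal(m$intercept, unname(ref["intercept"]), tolerance = 1e-9)
    if (n == 200)
      expect_lt(abs(m$slope - planted_slope) / planted_slope, 0.02)
  }
})

test_that("expected_contacts evaluates the line and guards its domain", {
  expect_equal(expected_contacts(500, default_calibration()),
               243.9 * 500 + 279484)
  expect_equal(expected_contacts(500, default_calibration()), 401434)
  expect_equal(expected_contacts(123, calibration_model(0, 7)), 7)
  expect_error(expected_contacts(20, calibration_model(-1, 10)),
               class = "spryscreen_calibration_domain_error")
})

test_that("interaction_score and classify follow the strict >2.5 semantics", {
  expect_equal(interaction_score(0, 100), 0)
  expect_equal(interaction_score(96, 96), 1)  # background level
  expect_equal(interaction_score(240, 96), 2.5)
  expect_error(interaction_score(10, 0),
               class = "spryscreen_calibration_domain_error")
  expect_false(classify(2.5))       # exactly at the cutoff is NOT a hit
  expect_true(classify(2.5 + 1e-12))
  expect_true(classify(2.51))
  expect_false(classify(0.9))
  # inverted orientation for the EC/OC convention
  expect_equal(interaction_score(240, 96, orientation = "ec_over_oc"), 0.4)
})

test_that("score_complex matches generator closed forms to 1e-9 relative", {
  fx <- make_pae_fixture(40, 60, interface_fraction = 0.25, pae_interface = 2,
                         pae_background = 28, seed = 3)
  rec <- score_complex(fx$prediction)
  expect_equal(rec$oc, fx$oc_star, tolerance = 1e-9)
  expect_equal(rec$ec, fx$ec_star, tolerance = 1e-9)
  expect_equal(rec$score, fx$score_star, tolerance = 1e-9)
  expect_identical(rec$high_confidence, fx$high_confidence_star)
  # swapping bait/prey labels leaves oc and score unchanged (combined length)
  pred <- fx$prediction
  swapped <- complex_prediction(
    pred$pair_id, pred$prey_name, pred$bait_name, pred$pae,
    chain_partition(pred$partition$chains, bait = "B", prey = "A"))
  rec2 <- score_complex(swapped)
  expect_equal(rec2$oc, rec$oc)
  expect_equal(rec2$score, rec$score)
  # an all-ceiling PAE scores 0 and is never high-confidence
  flat <- make_pae_fixture(10, 10, interface_fraction = 0,
                           pae_background = 31.75, pae_interface = 0)
  rec3 <- score_complex(flat$prediction)
  expect_equal(rec3$score, 0)
  expect_false(rec3$high_confidence)
})
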