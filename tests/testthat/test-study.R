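test_that("roster generation enforces the recruitment counts", {
  roster <- make_roster(153, 3, rng_seed = 2)
  expect_identical(nrow(roster), 153L)
  expect_identical(sum(roster$completed), 150L)
  expect_identical(make_roster(0, 0), make_roster(0, 0))
  expect_identical(nrow(make_roster(0, 0)), 0L)
  expect_identical(make_roster(20, 2, rng_seed = 5),
                   make_roster(20, 2, rng_seed = 5))
  expect_error(make_roster(5, 6), "n_incomplete")
  expect_true(all(roster$age >= 18))
  expect_true(all(roster$attitude %in% c("Positive", "Neutral", "Negative")))
})

test_that("layer groups are equal, disjoint, covering, and slots complete", {
  inv <- inception_layer_inventory()
  roster <- make_roster(30, 0, rng_seed = 3)
  asn <- assign_groups(inv, roster, n_groups = 3, rng_seed = 3)
  expect_identical(unname(lengths(asn$layer_groups)), rep(48L, 3))
  expect_identical(sort(unname(unlist(asn$layer_groups))), sort(inv))
  expect_false(anyDuplicated(unlist(asn$layer_groups)) > 0)
  counts <- table(asn$slots$participant_id)
  expect_true(all(counts == 48L))
  expect_true(all(asn$slots$seed_index %in% 0:4))
  # per-participant presentation order is a permutation
  ord <- asn$slots$presentation_order[asn$slots$participant_id == roster$id[1]]
  expect_identical(sort(ord), 1:48)
  expect_error(assign_groups(inv[1:10], roster, n_groups = 3),
               "not divisible")
})

test_that("R-squared calibration has the closed form and recovers empirically", {
  ft <- data.frame(f = c(0, 2, 4))              # Var(X beta) = 4 with beta 1
  expect_equal(rsq_to_noise_sd(c(f = 1), ft, 0.5), 2)
  expect_lt(rsq_to_noise_sd(c(f = 1), ft, 0.9999), 0.03)
  expect_error(rsq_to_noise_sd(c(f = 1), ft, 0), "residual_sd")
  # Monte-Carlo: empirical R-squared of the generating model hits the target
  withr::with_seed(21, {
    ft2 <- data.frame(x1 = rnorm(50000), x2 = rnorm(50000))
    beta <- c(x1 = 1.5, x2 = -1)
    sigma <- rsq_to_noise_sd(beta, ft2, 0.4)
    eta <- drop(as.matrix(ft2) %*% beta)
    y <- eta + rnorm(50000, 0, sigma)
  })
  expect_equal(stats::var(eta) / stats::var(y), 0.4, tolerance = 0.01)
})

test_that("rating simulation honors the effect structure and slider bounds", {
  inv <- paste0("layer", 1:6)
  roster <- make_roster(9, 0, rng_seed = 4)
  asn <- assign_groups(inv, roster, n_groups = 3, n_images = 2, rng_seed = 4)
  ft <- expand.grid(seed = 0:1, layer = inv, stringsAsFactors = FALSE)
  withr::with_seed(4, {
    for (f in c("hue", "saturation", "brightness", "jpeg_pct", "cfc", "cse"))
      ft[[f]] <- rnorm(nrow(ft))
  })
  zero <- stats::setNames(rep(0, 6), names(ft)[3:8])
  eff0 <- effect_spec(zero, zero, intercept = c(60, 40), participant_sd = 0,
                      residual_sd = 0)
  r0 <- simulate_ratings(asn, ft, eff0, rng_seed = 1)
  expect_true(all(r0$arousal == 60) && all(r0$valence == 40))
  beta <- stats::setNames(c(2, 0, -1, 0, 1, -2), names(zero))
  eff <- effect_spec(beta, beta, participant_sd = 2, residual_sd = 5)
  r1 <- simulate_ratings(asn, ft, eff, rng_seed = 2)
  expect_identical(r1, simulate_ratings(asn, ft, eff, rng_seed = 2))
  expect_false(identical(r1$arousal,
                         simulate_ratings(asn, ft, eff, rng_seed = 3)$arousal))
  expect_true(all(r1$arousal >= 0 & r1$arousal <= 100))
  expect_lt(attr(r1, "clipped_fraction"), 0.01)
  # missing features are reported by pair
  direct <- list(slots = data.frame(participant_id = "X", group = 1,
                                    layer_name = "layer1", seed_index = 9,
                                    presentation_order = 1))
  expect_error(simulate_ratings(direct, ft, eff, 1), "layer1 9")
  # exactly one noise specification is allowed
  expect_error(effect_spec(beta, beta, residual_sd = 1, target_r2 = 0.5),
               "exactly one")
})

test_that("bimodal layer overrides create two response clusters", {
  inv <- c("uni", "bi")
  roster <- make_roster(200, 0, rng_seed = 6)
  asn <- assign_groups(inv, roster, n_groups = 1, n_images = 1, rng_seed = 6)
  ft <- data.frame(layer = inv, seed = 0, f = 0)
  eff <- effect_spec(c(f = 0), c(f = 0), intercept = 50, residual_sd = 2,
                     bimodal_layers = list(
                       bi = list(mode1 = c(20, 80), mode2 = c(80, 20),
                                 weight = 0.5, sd = 3)))
  r <- simulate_ratings(asn, ft, eff, rng_seed = 7)
  bi <- r[r$layer_name == "bi", ]
  expect_gt(mean(bi$arousal < 40 | bi$arousal > 60), 0.95)
  expect_gt(sum(bi$arousal < 40), 50)
  expect_gt(sum(bi$arousal > 60), 50)
  uni <- r[r$layer_name == "uni", ]
  expect_lt(mean(uni$arousal < 40 | uni$arousal > 60), 0.05)
})

test_that("the completeness filter keeps exactly the full-data participants", {
  roster <- make_roster(153, 3, rng_seed = 8)
  inv <- inception_layer_inventory()
  asn <- assign_groups(inv, roster, rng_seed = 8)
  ft <- expand.grid(seed = 0:4, layer = inv, stringsAsFactors = FALSE)
  ft$f <- 0
  eff <- effect_spec(c(f = 0), c(f = 0), residual_sd = 10)
  ratings <- simulate_ratings(asn, ft, eff, rng_seed = 9, roster = roster)
  kept <- suppressMessages(filter_complete(roster, ratings))
  expect_identical(nrow(kept), 150L)
  expect_true(all(kept$completed))
  # all-complete ratings pass through untouched
  r2 <- simulate_ratings(asn, ft, eff, rng_seed = 9)
  all_kept <- filter_complete(roster[roster$completed, ], r2)
  expect_identical(nrow(all_kept), 150L)
  # a participant with 47 of 48 ratings is dropped even if flagged complete
  r3 <- r2[!(r2$participant_id == roster$id[1] &
               r2$presentation_order == 1L), ]
  expect_message(k3 <- filter_complete(roster[roster$completed, ], r3),
                 "incomplete")
  expect_false(roster$id[1] %in% k3$id)
})
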