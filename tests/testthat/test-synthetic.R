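small_spec <- function(seed = 5, n_p = 3L, n_c = 4L) {
  spec <- default_study_spec(seed = seed)
  spec$n_patients <- n_p
  spec$n_controls <- n_c
  spec
}

test_that("choice probabilities follow the logistic-with-lapse model", {
  p_delayed <- ddcurve:::p_delayed
  # indifference: logistic(0) = 0.5, shifted by the lapse mixture
  expect_equal(p_delayed(1000, 1000, 2000, beta = 10, lapse = 0), 0.5)
  expect_equal(p_delayed(1000, 1000, 2000, beta = Inf, lapse = 0), 0.5)
  expect_equal(p_delayed(1500, 1000, 2000, beta = Inf, lapse = 0), 1)
  expect_equal(p_delayed(500, 1000, 2000, beta = Inf, lapse = 0), 0)
  # lapse mixes toward 0.5
  expect_equal(p_delayed(1500, 1000, 2000, beta = Inf, lapse = 0.2),
               0.1 + 0.8 * 1)
  # scale invariance of the normalized value difference
  expect_equal(p_delayed(15, 10, 20, beta = 3, lapse = 0),
               p_delayed(1500, 1000, 2000, beta = 3, lapse = 0))
})

test_that("effective discount rate applies the magnitude and EFT multipliers", {
  ag <- agent_params(k_small = 0.01, magnitude_multiplier = 0.5,
                     eft_multiplier = 0.5)
  expect_equal(effective_k(ag, "small", "Standard"), 0.01)
  expect_equal(effective_k(ag, "small", "EFT"), 0.005)
  expect_equal(effective_k(ag, "large", "Standard"), 0.005)
  expect_equal(effective_k(ag, "large", "EFT"), 0.0025)
  expect_error(agent_params(k_small = -1), "k_small")
})

test_that("a deterministic value-maximizing agent always picks the better side", {
  ag <- agent_params(k_small = 0.01, beta = Inf, lapse = 0)
  # V = 2000 / (1 + 0.01 * 365) = 430.1; offer below -> delayed
  expect_equal(simulate_choice(ag, 100, 2000, 365), "delayed")
  expect_equal(simulate_choice(ag, 1500, 2000, 365), "immediate")
})

test_that("a simulated study has the full factorial design and is seed-deterministic", {
  spec <- small_spec(seed = 5)
  ch <- simulate_study(spec)
  # participants x conditions x (2 amounts x 7 delays x 6 choices)
  expect_equal(nrow(ch), (3 + 4) * 2 * 84)
  expect_true(all(table(ch$participant_id, ch$condition) == 84))
  counts <- table(ch$participant_id, ch$condition, ch$delayed_amount,
                  ch$delay_months)
  expect_true(all(counts == 6))

  expect_identical(ch, simulate_study(small_spec(seed = 5)))
  ch2 <- simulate_study(small_spec(seed = 6))
  expect_false(identical(ch, ch2))
})

test_that("full-size cohorts produce the documented 8904 choice rows", {
  spec <- default_study_spec(seed = 1)
  spec$n_controls <- 41L
  spec$n_patients <- 12L
  ch <- simulate_study(spec)
  expect_equal(nrow(ch), 53 * 2 * 84)
})

test_that("block order is randomized per participant-condition and recorded", {
  ch <- simulate_study(small_spec(seed = 9))
  first_blocks <- unique(ch[ch$block_order == 1,
                            c("participant_id", "condition",
                              "delayed_amount", "delay_months")])
  expect_gt(nrow(unique(first_blocks[c("delayed_amount", "delay_months")])), 1)
  per_block <- unique(ch[c("participant_id", "condition", "block_order")])
  expect_equal(nrow(per_block), 7 * 2 * 14)
})

test_that("noiseless agents recover their exact indifference points through the pipeline", {
  d <- c(0.25, 1, 3, 6, 12, 36, 120)
  days <- months_to_days(d)
  for (k in c(0.0005, 0.005, 0.05)) {
    ag <- agent_params(k_small = k, beta = Inf, lapse = 0)
    for (amount in c(100, 2000)) {
      exact <- 1 / (1 + k * days)
      stair <- vapply(seq_along(d), function(j) {
        v <- amount * exact[j]
        st <- run_block(amount, d[j], function(offer) {
          if (offer > v) "immediate" else "delayed"
        })
        subjective_value(st)
      }, numeric(1))
      slack <- (amount / 64 + 5) / amount
      expect_true(all(abs(stair - exact) <= slack))
      # the trapezoid sum propagates at most the same normalized slack
      a_stair <- auc(discounting_curve(d, stair))
      a_exact <- auc(discounting_curve(d, exact))
      expect_lte(abs(a_stair - a_exact), slack)
    }
  }
})

test_that("steeper discounting lowers every indifference point and the AuC", {
  d <- c(0.25, 1, 3, 6, 12, 36, 120)
  days <- months_to_days(d)
  ks <- 10^seq(-4, -1, length.out = 10)
  svs <- lapply(ks, function(k) 1 / (1 + k * days))
  aucs <- vapply(svs, function(s) auc(discounting_curve(d, s)), numeric(1))
  for (j in 2:length(ks)) expect_true(all(svs[[j]] < svs[[j - 1]]))
  expect_true(all(diff(aucs) < 0))
})

test_that("group multipliers propagate to the simulated magnitude effect", {
  # controls (m < 1) should show a positive AuC(large) - AuC(small);
  # patients (m = 1) should not, on average
  effs <- t(vapply(1:8, function(i) {
    spec <- default_study_spec(seed = 300 + i)
    spec$n_patients <- 8L
    spec$n_controls <- 12L
    ac <- analyze_curves(replay_choices(simulate_study(spec)), fit = FALSE)
    e <- ddcurve:::effect_summaries(ac)
    c(e$magnitude$control$mean, e$magnitude$patient$mean)
  }, numeric(2)))
  expect_gt(mean(effs[, 1]), 0.05)
  expect_lt(abs(mean(effs[, 2])), 0.05)
})

test_that("switching off the EFT multiplier removes the condition effect", {
  spec <- default_study_spec(seed = 77)
  spec$patients$eft_multiplier <- 1
  spec$controls$eft_multiplier <- 1
  spec$n_patients <- 10L
  spec$n_controls <- 10L
  effs <- vapply(1:6, function(i) {
    spec$seed <- 400L + i
    ac <- analyze_curves(replay_choices(simulate_study(spec)), fit = FALSE)
    e <- ddcurve:::effect_summaries(ac)
    (e$eft$control$mean + e$eft$patient$mean) / 2
  }, numeric(1))
  expect_lt(abs(mean(effs)), 0.03)
})
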