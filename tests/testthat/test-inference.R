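test_that("pooled t-tests reproduce the demographic matching statistics", {
  age <- pooled_t(group_summary(12, 57.41, 8.20),
                  group_summary(41, 61.09, 6.58))
  expect_equal(age$df, 51)
  expect_equal(abs(age$t), 1.61, tolerance = 0.01)
  expect_gt(age$p, 0.05)

  # printed as -0.22 with the groups in the opposite order
  edu <- pooled_t(group_summary(12, 13.41, 3.67),
                  group_summary(41, 13.19, 2.82))
  expect_equal(abs(edu$t), 0.22, tolerance = 0.01)

  same <- pooled_t(group_summary(10, 5, 1), group_summary(10, 5, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("uncorrected chi-square matches hand computation on 2x2 tables", {
  # one expected count is below 5; the approximation warning is passed
  # through deliberately and silenced here
  gender <- suppressWarnings(chi_square_2x2(matrix(c(8, 35, 4, 6), nrow = 2)))
  expect_equal(gender$chi2, 2.12, tolerance = 0.01)
  expect_equal(gender$df, 1)

  expect_equal(chi_square_2x2(matrix(c(10, 20, 5, 10), nrow = 2))$chi2, 0)
  # all expected counts 5, every |O - E| = 5 -> sum 4 * 25/5 = 20
  # (small-sample approximation warning is irrelevant to the identity)
  expect_equal(
    suppressWarnings(chi_square_2x2(matrix(c(10, 0, 0, 10), nrow = 2))$chi2),
    20)
  expect_error(chi_square_2x2(matrix(c(1, 2, 3), nrow = 1)), "2 x 2")
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 5), nrow = 2)), "marginal")
})

test_that("mixed ANOVA matches the cell-means oracle on balanced designs", {
  for (seed in 1:5) {
    d <- make_balanced_toy(n_per_group = 4, seed = seed,
                           effects = list(group = 0.4, condition = 0.6,
                                          magnitude = 0.2, gxm = 0.5))
    a <- mixed_anova(d, dv = "y")
    o <- cellmeans_anova_oracle(d)
    for (eff in a$effect) {
      expect_equal(a$ss_effect[a$effect == eff], unname(o$ss[eff]),
                   tolerance = 1e-8, label = paste("SS", eff, "seed", seed))
      expect_equal(a$F[a$effect == eff], unname(o$f[eff]),
                   tolerance = 1e-8, label = paste("F", eff, "seed", seed))
    }
    # complete decomposition: all strata add up to the total SS
    expect_equal(sum(o$ss), o$total, tolerance = 1e-8 * o$total)
    expect_equal(sum(a$ss_effect) + a$ss_error[a$effect == "group"] +
                   a$ss_error[a$effect == "condition"] +
                   a$ss_error[a$effect == "magnitude"] +
                   a$ss_error[a$effect == "condition:magnitude"],
                 o$total, tolerance = 1e-8 * o$total)
  }
})

test_that("partial eta squared is consistent with its F/df identity", {
  d <- make_balanced_toy(n_per_group = 5, seed = 3,
                         effects = list(group = 0.3, condition = 0.5,
                                        magnitude = 0.1, gxm = 0.4))
  a <- mixed_anova(d, dv = "y")
  expect_equal(a$partial_eta_sq,
               a$F * a$df_effect / (a$F * a$df_effect + a$df_error),
               tolerance = 1e-10)
  expect_true(all(a$partial_eta_sq >= 0 & a$partial_eta_sq <= 1))
})

test_that("participants constant across within cells give zero within effects", {
  d <- expand.grid(participant_id = sprintf("s%d", 1:8),
                   condition = c("Standard", "EFT"),
                   magnitude = c("small", "large"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("s", "", d$participant_id)) <= 4,
                    "patient", "control")
  base <- stats::rnorm(8)
  names(base) <- sprintf("s%d", 1:8)
  d$auc <- base[d$participant_id]
  a <- mixed_anova(d)
  within_rows <- a$effect != "group"
  expect_true(all(a$ss_effect[within_rows] < 1e-20))
  expect_true(all(a$F[within_rows] == 0))
  expect_true(all(a$p[within_rows] == 1))
})

test_that("unequal group sizes reproduce the expected error degrees of freedom", {
  set.seed(8)
  d <- expand.grid(participant_id = sprintf("s%02d", 1:53),
                   condition = c("Standard", "EFT"),
                   magnitude = c("small", "large"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("s", "", d$participant_id)) <= 12,
                    "patient", "control")
  d$auc <- stats::runif(nrow(d))
  a <- mixed_anova(d)
  expect_true(all(a$df_effect == 1))
  expect_true(all(a$df_error == 51))
})

test_that("incomplete designs raise informative errors", {
  d <- make_balanced_toy(n_per_group = 3, seed = 1)
  expect_error(mixed_anova(d[-1, ], dv = "y"), "design error")
  expect_error(mixed_anova(d, dv = "nope"), "missing columns")
})

test_that("Fisher LSD agrees with a hand-computed contrast and degenerates to p = 1", {
  d <- make_balanced_toy(n_per_group = 6, seed = 4,
                         effects = list(group = 0, condition = 0,
                                        magnitude = 0.8, gxm = 0))
  a <- mixed_anova(d, dv = "y")
  res <- fisher_lsd(d, a,
                    list(group = "control", magnitude = "large"),
                    list(group = "control", magnitude = "small"))
  # hand computation from the magnitude-stratum pooled MSE
  mse <- a$ss_error[a$effect == "magnitude"] / a$df_error[a$effect == "magnitude"]
  y1 <- d$y[d$group == "control" & d$magnitude == "large"]
  y2 <- d$y[d$group == "control" & d$magnitude == "small"]
  t_hand <- (mean(y1) - mean(y2)) /
    sqrt(mse * (1 / length(y1) + 1 / length(y2)))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, a$df_error[a$effect == "magnitude"])
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), res$df), tolerance = 1e-12)

  same <- fisher_lsd(d, a,
                     list(group = "control", magnitude = "large"),
                     list(group = "control", magnitude = "large"))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})
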