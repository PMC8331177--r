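# Independent oracles used to cross-check the package's implementations.
# These deliberately use different algorithms from the code under test.

standard_delays <- c(0.25, 1, 3, 6, 12, 36, 120)

# --- staircase: deterministic threshold agent ------------------------------
# Prefers whichever side of its indifference point the offer falls on
# (ties go to the delayed reward).
threshold_chooser <- function(threshold) {
  function(offer) if (offer > threshold) "immediate" else "delayed"
}

# --- hyperbolic fit: brute-force grid search -------------------------------
# 1000 log-spaced candidate rates, refined once around the best candidate.
grid_fit_oracle <- function(delay_months, sv, k_max = 10) {
  days <- months_to_days(delay_months)
  ssr <- function(k) sum((sv - 1 / (1 + k * days))^2)
  grid <- c(0, 10^seq(-6, log10(k_max), length.out = 1000))
  s <- vapply(grid, ssr, numeric(1))
  i <- which.min(s)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  fine <- seq(lo, hi, length.out = 1000)
  s2 <- vapply(fine, ssr, numeric(1))
  fine[which.min(s2)]
}

# --- inconsistency count: explicit pair loop -------------------------------
brute_inconsistency <- function(sv, threshold = 0.1) {
  n <- 0L
  for (j in 2:length(sv)) if (sv[j] > sv[j - 1] + threshold) n <- n + 1L
  n
}

# --- mixed ANOVA: cell-means decomposition on balanced designs -------------
# Explicit marginal-mean inclusion-exclusion estimates of every effect and
# error stratum of the 1-between (g) x 2-within (c, m) split-plot layout;
# sums of squares accumulated over observations. Valid for equal group
# sizes and a complete within design.
cellmeans_anova_oracle <- function(data, dv = "y", id = "participant_id",
                                   between = "group",
                                   within = c("condition", "magnitude")) {
  y <- data[[dv]]
  g <- data[[between]]
  s <- data[[id]]
  cc <- data[[within[1]]]
  m <- data[[within[2]]]

  grand <- mean(y)
  mg <- stats::ave(y, g)
  mc <- stats::ave(y, cc)
  mm <- stats::ave(y, m)
  mgc <- stats::ave(y, g, cc)
  mgm <- stats::ave(y, g, m)
  mcm <- stats::ave(y, cc, m)
  mgcm <- stats::ave(y, g, cc, m)
  ms <- stats::ave(y, s)
  msc <- stats::ave(y, s, cc)
  msm <- stats::ave(y, s, m)

  n_per_group <- length(unique(s)) / length(unique(g))
  a <- length(unique(g))

  ss <- c(
    group = sum((mg - grand)^2),
    subjects = sum((ms - mg)^2),
    condition = sum((mc - grand)^2),
    `group:condition` = sum((mgc - mg - mc + grand)^2),
    `subjects:condition` = sum((msc - ms - mgc + mg)^2),
    magnitude = sum((mm - grand)^2),
    `group:magnitude` = sum((mgm - mg - mm + grand)^2),
    `subjects:magnitude` = sum((msm - ms - mgm + mg)^2),
    `condition:magnitude` = sum((mcm - mc - mm + grand)^2),
    `group:condition:magnitude` =
      sum((mgcm - mgc - mgm - mcm + mg + mc + mm - grand)^2),
    `subjects:condition:magnitude` =
      sum((y - msc - msm - mgcm + ms + mgc + mgm - mg)^2)
  )
  df_subj <- a * (n_per_group - 1)
  f <- c(
    group = (ss["group"] / (a - 1)) / (ss["subjects"] / df_subj),
    condition = ss["condition"] / (ss["subjects:condition"] / df_subj),
    `group:condition` =
      (ss["group:condition"] / (a - 1)) / (ss["subjects:condition"] / df_subj),
    magnitude = ss["magnitude"] / (ss["subjects:magnitude"] / df_subj),
    `group:magnitude` =
      (ss["group:magnitude"] / (a - 1)) / (ss["subjects:magnitude"] / df_subj),
    `condition:magnitude` =
      ss["condition:magnitude"] / (ss["subjects:condition:magnitude"] / df_subj),
    `group:condition:magnitude` =
      (ss["group:condition:magnitude"] / (a - 1)) /
        (ss["subjects:condition:magnitude"] / df_subj)
  )
  names(f) <- sub("\\..*$", "", names(f))
  list(ss = ss, f = f, total = sum((y - grand)^2))
}

# balanced 2 (group) x 2 (condition) x 2 (magnitude) toy data set
make_balanced_toy <- function(n_per_group = 4, seed = 1,
                              effects = list(group = 0, condition = 0,
                                             magnitude = 0, gxm = 0)) {
  set.seed(seed)
  d <- expand.grid(
    participant_id = sprintf("s%02d", seq_len(2 * n_per_group)),
    condition = c("Standard", "EFT"),
    magnitude = c("small", "large"),
    stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("s", "", d$participant_id)) <= n_per_group,
                    "patient", "control")
  subj_int <- stats::rnorm(2 * n_per_group, 0, 0.5)
  names(subj_int) <- sprintf("s%02d", seq_len(2 * n_per_group))
  d$y <- subj_int[d$participant_id] +
    effects$group * (d$group == "control") +
    effects$condition * (d$condition == "EFT") +
    effects$magnitude * (d$magnitude == "large") +
    effects$gxm * (d$group == "control") * (d$magnitude == "large") +
    stats::rnorm(nrow(d), 0, 0.3)
  d
}

# --- JZS Bayes factor: quadrature over the Cauchy effect-size prior --------
# Marginalizes the noncentral-t likelihood over delta ~ Cauchy(0, r)
# directly, instead of the inverse-gamma g-representation used by the
# implementation.
jzs_oracle <- function(t, n1, n2, r = sqrt(2) / 2) {
  nu <- n1 + n2 - 2
  n_eff <- n1 * n2 / (n1 + n2)
  # dt() warns about reduced precision far in the noncentral tail; the
  # integral is still accurate to far better than the tolerances used here
  num <- suppressWarnings(stats::integrate(
    function(d) stats::dt(t, nu, ncp = d * sqrt(n_eff)) *
      stats::dcauchy(d, 0, r),
    -Inf, Inf, rel.tol = 1e-10)$value)
  num / stats::dt(t, nu)
}
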