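#' Group summary statistics
#'
#' Small container for the (n, mean, sd) triplets that papers print for
#' each group, sufficient for pooled-variance t-tests and default-prior
#' Bayes factors.
#'
#' @param n Sample size (>= 2).
#' @param mean Group mean.
#' @param sd Group standard deviation (>= 0).
#' @return A `dd_group_summary` list.
#' @export
group_summary <- function(n, mean, sd) {
  if (n < 2) stop("group summary needs n >= 2", call. = FALSE)
  if (sd < 0) stop("sd must be nonnegative", call. = FALSE)
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "dd_group_summary")
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Student's independent-samples t with the classical pooled variance,
#' computed from printed group summaries rather than raw data, as used to
#' check demographic matching (age, education) between a patient and a
#' control group.
#'
#' @param a,b `dd_group_summary` objects (see [group_summary()]).
#' @return A list with `t`, `df` (`n_a + n_b - 2`) and the two-tailed `p`.
#' @examples
#' pooled_t(group_summary(12, 57.41, 8.20), group_summary(41, 61.09, 6.58))
#' @export
pooled_t <- function(a, b) {
  stopifnot(inherits(a, "dd_group_summary"), inherits(b, "dd_group_summary"))
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  t <- if (se == 0) 0 else (a$mean - b$mean) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test on a 2 x 2 contingency table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with
#' one degree of freedom, as used for gender-balance checks between
#' groups.
#'
#' @param counts 2 x 2 matrix of nonnegative integer counts with positive
#'   marginals.
#' @return A list with `chi2`, `df` (1) and `p`.
#' @examples
#' chi_square_2x2(matrix(c(8, 35, 4, 6), nrow = 2)) # patients/controls by sex
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) {
    stop("counts must be a 2 x 2 table", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("all marginals must be positive", call. = FALSE)
  }
  res <- stats::chisq.test(counts, correct = FALSE)
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' JZS default-prior Bayes factor for an independent-samples t-test
#'
#' Two-sided Bayes factor BF10 for the two-sample comparison under the
#' Jeffreys-Zellner-Siow default prior: a Cauchy prior with scale `r` on
#' the standardized effect size and the Jeffreys prior on the variance.
#' Computed from the pooled t statistic and group sizes by numerical
#' integration over the g-prior representation (the Cauchy arises as a
#' scale mixture of normals with an inverse-gamma(1/2, r^2/2) mixing
#' distribution on g):
#'
#' BF10 = \[ integral over g of (1+Ng)^(-1/2) (1 + t^2 / ((1+Ng) v))^(-(v+1)/2)
#' pi(g) dg \] / (1 + t^2/v)^(-(v+1)/2),
#'
#' with effective sample size N = n1 n2 / (n1 + n2) and v = n1 + n2 - 2
#' degrees of freedom. BF10 > 1 favors a group difference, BF10 < 1 the
#' null.
#'
#' @param a,b `dd_group_summary` objects, or `NULL` when `t`, `n1`, `n2`
#'   are supplied directly.
#' @param prior_scale Cauchy prior scale on the standardized effect;
#'   default `sqrt(2)/2 = 0.707`, the conventional default for two-sample
#'   tests.
#' @param t,n1,n2 Alternative parameterization: the t statistic and the
#'   two group sizes.
#' @return A list of class `dd_bayes_result` with `bf10`, `t`, `df` and
#'   `prior_scale`.
#' @examples
#' # evidence about a group difference from printed summaries
#' jzs_bf_ttest(group_summary(12, 0.17, 0.21), group_summary(41, 0.26, 0.17))
#' @export
jzs_bf_ttest <- function(a = NULL, b = NULL, prior_scale = sqrt(2) / 2,
                         t = NULL, n1 = NULL, n2 = NULL) {
  if (prior_scale <= 0) stop("prior_scale must be positive", call. = FALSE)
  if (is.null(t)) {
    stopifnot(inherits(a, "dd_group_summary"), inherits(b, "dd_group_summary"))
    t <- pooled_t(a, b)$t
    n1 <- a$n
    n2 <- b$n
  }
  nu <- n1 + n2 - 2
  n_eff <- n1 * n2 / (n1 + n2)
  r2 <- prior_scale^2

  # marginal likelihood under H1: integrate over g with the
  # inverse-gamma(1/2, r^2/2) density induced by the Cauchy prior
  integrand <- function(g) {
    (1 + n_eff * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n_eff * g) * nu))^(-(nu + 1) / 2) *
      (r2 / 2)^(1 / 2) / gamma(1 / 2) * g^(-3 / 2) * exp(-r2 / (2 * g))
  }
  m1 <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10,
                         stop.on.error = FALSE)
  if (m1$message != "OK" || !is.finite(m1$value) || m1$value <= 0) {
    stop("numerical error: JZS integral did not converge (",
         m1$message, ")", call. = FALSE)
  }
  m0 <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  structure(list(bf10 = m1$value / m0, t = t, df = nu,
                 prior_scale = prior_scale),
            class = "dd_bayes_result")
}
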