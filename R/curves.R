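#' Construct a discounting curve from indifference points
#'
#' Bundles one participant-by-condition-by-magnitude set of normalized
#' indifference points (subjective value as a fraction of the delayed
#' amount) at the task's delays.
#'
#' @param delays_months Delays in months, strictly increasing.
#' @param sv Normalized subjective values in `[0, 1]`, same length.
#' @return A `dd_curve` object (a data frame with columns `delay_months`,
#'   `sv`).
#' @export
discounting_curve <- function(delays_months, sv) {
  if (length(delays_months) != length(sv)) {
    stop("delays and subjective values must have equal length", call. = FALSE)
  }
  if (is.unsorted(delays_months, strictly = TRUE)) {
    stop("delays must be strictly increasing", call. = FALSE)
  }
  if (any(sv < -1e-9 | sv > 1 + 1e-9)) {
    stop("normalized subjective values must lie in [0, 1]", call. = FALSE)
  }
  structure(
    data.frame(delay_months = as.numeric(delays_months),
               sv = pmin(pmax(as.numeric(sv), 0), 1)),
    class = c("dd_curve", "data.frame")
  )
}

as_dd_curve <- function(x) {
  if (inherits(x, "dd_curve")) x else discounting_curve(x$delay_months, x$sv)
}

hyperbolic_sv <- function(k, days) 1 / (1 + k * days)

hyperbolic_ssr <- function(k, days, sv) sum((sv - hyperbolic_sv(k, days))^2)

#' Fit the hyperbolic discounting function SV = 1/(1 + kD)
#'
#' Least-squares fit of the one-parameter hyperbola to normalized
#' indifference points, with the delay D expressed in days (1 week = 7,
#' 1 month = 30, 1 year = 365). The discount rate k is found by bounded
#' minimization of the residual sum of squares over k in `[0, k_max]`,
#' seeded from a coarse logarithmic scan so that very shallow and very
#' steep discounters are both recovered.
#'
#' @param curve A `dd_curve`, or any data frame with `delay_months` and `sv`.
#' @param k_max Upper bound for the per-day discount rate (default 10).
#' @return A list of class `dd_hyperbolic_fit` with elements `k` (per-day
#'   discount rate), `r_squared` (1 - SSres/SStot; can be negative for
#'   nonmonotone data), and `degenerate` (`TRUE` when the observed values
#'   have no variance, in which case `r_squared` is 1 for a perfect fit).
#' @examples
#' d <- c(0.25, 1, 3, 6, 12, 36, 120)
#' fit_hyperbolic(discounting_curve(d, 1 / (1 + 0.005 * months_to_days(d))))
#' @export
fit_hyperbolic <- function(curve, k_max = 10) {
  curve <- as_dd_curve(curve)
  days <- months_to_days(curve$delay_months)
  sv <- curve$sv

  # coarse log-spaced scan, then local refinement around the best bracket
  grid <- c(0, 10^seq(log10(1e-7), log10(k_max), length.out = 60))
  ssr <- vapply(grid, hyperbolic_ssr, numeric(1), days = days, sv = sv)
  i <- which.min(ssr)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  k <- if (lo == hi) lo else {
    stats::optimize(hyperbolic_ssr, c(lo, hi), days = days, sv = sv,
                    tol = .Machine$double.eps^0.5)$minimum
  }
  # snap to the boundary when the interior optimum is not better
  if (hyperbolic_ssr(0, days, sv) <= hyperbolic_ssr(k, days, sv)) k <- 0

  ss_res <- hyperbolic_ssr(k, days, sv)
  ss_tot <- sum((sv - mean(sv))^2)
  degenerate <- ss_tot < .Machine$double.eps
  r_squared <- if (degenerate) {
    if (ss_res < 1e-12) 1 else NA_real_
  } else {
    1 - ss_res / ss_tot
  }
  structure(list(k = k, r_squared = r_squared, degenerate = degenerate),
            class = "dd_hyperbolic_fit")
}

#' Area under the empirical discounting curve
#'
#' Model-free discounting measure: delays are expressed as proportions of
#' the maximum delay (120 months by default), normalized subjective values
#' are plotted against them, and the area is the sum of the trapezoids
#' `(x2 - x1) * (y1 + y2) / 2` over successive delays. A zero-delay anchor
#' at (0, 1) is prepended so that a participant who never discounts attains
#' the theoretical maximum of 1; an AuC of 0 corresponds to maximally steep
#' discounting.
#'
#' @param curve A `dd_curve`, or any data frame with `delay_months` and `sv`.
#' @param max_delay_months Normalization constant for the x axis.
#' @param anchor Prepend the (0, 1) zero-delay anchor point (default `TRUE`).
#' @return The AuC, a unitless number in `[0, 1]`.
#' @examples
#' d <- c(0.25, 1, 3, 6, 12, 36, 120)
#' auc(discounting_curve(d, rep(1, 7))) # 1: no discounting
#' @export
auc <- function(curve, max_delay_months = 120, anchor = TRUE) {
  curve <- as_dd_curve(curve)
  x <- curve$delay_months / max_delay_months
  y <- curve$sv
  if (max(x) > 1 + 1e-9) {
    stop("delays exceed the normalization constant", call. = FALSE)
  }
  if (anchor) {
    x <- c(0, x)
    y <- c(1, y)
  }
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Count inconsistent preferences along a discounting curve
#'
#' An indifference point is inconsistent when it exceeds the one at the
#' preceding delay by more than 10% of the delayed amount: with values
#' normalized by the amount, the pair (sv1, sv2) at consecutive delays
#' counts when sv2 > sv1 + 0.1 (strictly). With seven delays the count
#' ranges over 0..6.
#'
#' @param curve A `dd_curve`, or any data frame with `delay_months` and `sv`.
#' @param threshold Fraction of the delayed amount a rise must exceed
#'   (default 0.1).
#' @return Integer count of inconsistent consecutive-delay pairs.
#' @examples
#' d <- c(0.25, 1, 3, 6, 12, 36, 120)
#' count_inconsistencies(
#'   discounting_curve(d, c(0.90, 0.95, 0.80, 0.92, 0.50, 0.40, 0.30))) # 1
#' @export
count_inconsistencies <- function(curve, threshold = 0.1) {
  curve <- as_dd_curve(curve)
  as.integer(sum(diff(curve$sv) > threshold))
}
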