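#' Task design for an adjusting-amount delay-discounting experiment
#'
#' Describes the factorial layout of the titration task: the delayed reward
#' amounts, the set of delays (in months), the number of titration choices
#' per block, and the cueing conditions. The default reproduces the common
#' two-magnitude, seven-delay design with six choices per block, run once
#' under a Standard condition and once under an episodic future thinking
#' (EFT) condition.
#'
#' @param delayed_amounts Integer currency amounts of the delayed rewards,
#'   e.g. `c(100, 2000)` for a small and a large magnitude.
#' @param delays_months Delays until receipt, in months, strictly increasing.
#'   The default is 1 week (0.25), 1, 3, 6 months, 1, 3 and 10 years.
#' @param trials_per_block Number of titration choices per delay block.
#' @param conditions Character vector of condition labels.
#' @return An object of class `dd_task_design`.
#' @examples
#' design <- task_design()
#' design$delays_months
#' @export
task_design <- function(delayed_amounts = c(100L, 2000L),
                        delays_months = c(0.25, 1, 3, 6, 12, 36, 120),
                        trials_per_block = 6L,
                        conditions = c("Standard", "EFT")) {
  if (any(delayed_amounts <= 0)) {
    stop("invalid design: delayed amounts must be positive", call. = FALSE)
  }
  if (is.unsorted(delays_months, strictly = TRUE)) {
    stop("invalid design: delays must be strictly increasing", call. = FALSE)
  }
  if (trials_per_block < 1) {
    stop("invalid design: trials_per_block must be >= 1", call. = FALSE)
  }
  structure(
    list(
      delayed_amounts = as.integer(delayed_amounts),
      delays_months = as.numeric(delays_months),
      trials_per_block = as.integer(trials_per_block),
      conditions = as.character(conditions)
    ),
    class = "dd_task_design"
  )
}

#' Convert delays in months to days
#'
#' Day-count convention used for hyperbolic fitting: 1 week = 7 days,
#' 1 month = 30 days, 1 year = 365 days. The seven standard delays map to
#' 7, 30, 90, 180, 365, 1095 and 3650 days.
#'
#' @param months Numeric vector of delays in months (0.25 denotes 1 week).
#' @return Numeric vector of delays in days.
#' @export
months_to_days <- function(months) {
  vapply(months, function(m) {
    if (isTRUE(all.equal(m, 0.25))) {
      7
    } else if (m < 12) {
      m * 30
    } else {
      (m / 12) * 365
    }
  }, numeric(1))
}

# round-half-away-from-zero to the nearest currency unit; base round() goes
# to even and would break the printed staircase traces
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Start an adjusting-amount staircase block
#'
#' The first choice offers half the delayed amount immediately; the first
#' adjustment is half the difference between the delayed amount and that
#' first offer (i.e. a quarter of the delayed amount). For a $2000 reward at
#' 3 years the opening choice is $1000 now versus $2000 in 3 years.
#'
#' @param delayed_amount Positive delayed reward, in whole currency units.
#' @param delay_months Delay until the delayed reward, in months.
#' @return A `dd_staircase` state with fields `delayed_amount`,
#'   `delay_months`, `trial_index`, `immediate_offer`, `adjustment` and
#'   `history` (a data frame of past offers and choices).
#' @seealso [staircase_step()], [subjective_value()]
#' @examples
#' st <- init_block(2000, 36)
#' st$immediate_offer # 1000
#' @export
init_block <- function(delayed_amount, delay_months) {
  if (!is.numeric(delayed_amount) || length(delayed_amount) != 1 ||
      !is.finite(delayed_amount) || delayed_amount <= 0) {
    stop("invalid design: delayed_amount must be a positive number",
         call. = FALSE)
  }
  delayed_amount <- round_half_away(delayed_amount)
  structure(
    list(
      delayed_amount = delayed_amount,
      delay_months = delay_months,
      trial_index = 1L,
      immediate_offer = round_half_away(delayed_amount / 2),
      adjustment = round_half_away(delayed_amount / 4),
      history = data.frame(
        trial = integer(0),
        immediate_offer = numeric(0),
        choice = character(0),
        stringsAsFactors = FALSE
      )
    ),
    class = "dd_staircase"
  )
}

#' Advance a staircase block by one recorded choice
#'
#' A choice of the delayed reward raises the next immediate offer by the
#' current adjustment; a choice of the immediate reward lowers it. Each
#' subsequent adjustment is half the preceding one, rounded to the nearest
#' currency unit (ties away from zero), so offers titrate toward the
#' indifference point with geometrically shrinking steps. Because rounding
#' can overshoot the reward itself for small amounts, presented offers are
#' clamped to stay strictly between 0 and the delayed amount.
#'
#' @param state A `dd_staircase` from [init_block()] or a previous step.
#' @param choice `"immediate"` or `"delayed"`.
#' @return The updated `dd_staircase` state.
#' @examples
#' st <- init_block(2000, 36)
#' st <- staircase_step(st, "delayed")   # next offer 1500
#' st <- staircase_step(st, "immediate") # next offer 1250
#' st$immediate_offer
#' @export
staircase_step <- function(state, choice) {
  stopifnot(inherits(state, "dd_staircase"))
  choice <- match.arg(choice, c("immediate", "delayed"))
  if (state$trial_index > 6L) {
    stop("state error: block already complete (6 choices recorded)",
         call. = FALSE)
  }
  offset <- if (choice == "delayed") state$adjustment else -state$adjustment
  state$history <- rbind(
    state$history,
    data.frame(
      trial = state$trial_index,
      immediate_offer = state$immediate_offer,
      choice = choice,
      stringsAsFactors = FALSE
    )
  )
  offer <- state$immediate_offer + offset
  # rounding can push the offer past the reward for small amounts (e.g.
  # 50+25+13+7+4+2 = 101 for A = 100); presented offers are clamped inside
  # (0, A), the hypothetical trial-7 value into [0, A]
  state$immediate_offer <- if (state$trial_index < 6L) {
    clamp_offer(offer, state$delayed_amount, presented = TRUE)
  } else {
    clamp_offer(offer, state$delayed_amount, presented = FALSE)
  }
  state$adjustment <- round_half_away(state$adjustment / 2)
  state$trial_index <- state$trial_index + 1L
  state
}

clamp_offer <- function(offer, amount, presented = TRUE) {
  if (presented) pmin(pmax(offer, 1), amount - 1) else
    pmin(pmax(offer, 0), amount)
}

#' Subjective value (indifference point) of a completed block
#'
#' After the six titration choices, the subjective value of the delayed
#' reward is the immediate amount that would have been offered on a seventh
#' trial.
#'
#' @param state A `dd_staircase` holding exactly six recorded choices.
#' @param normalized If `TRUE` (default) return the subjective value as a
#'   fraction of the delayed amount; otherwise in currency units.
#' @return A single number: the estimated indifference point.
#' @examples
#' st <- init_block(2000, 36)
#' for (i in 1:6) st <- staircase_step(st, "delayed")
#' subjective_value(st, normalized = FALSE) # 1986
#' @export
subjective_value <- function(state, normalized = TRUE) {
  stopifnot(inherits(state, "dd_staircase"))
  if (nrow(state$history) != 6L) {
    stop(sprintf("incomplete block: %d of 6 choices recorded",
                 nrow(state$history)), call. = FALSE)
  }
  sv <- state$immediate_offer
  if (normalized) sv / state$delayed_amount else sv
}

#' Run one staircase block against a deterministic choice rule
#'
#' Convenience driver used by the simulator and in tests: plays the six
#' trials, asking `chooser(immediate_offer)` for `"immediate"` or
#' `"delayed"` at each trial.
#'
#' @param delayed_amount,delay_months Block parameters, as in [init_block()].
#' @param chooser Function of the current immediate offer returning the
#'   choice label.
#' @return The completed `dd_staircase` state.
#' @export
run_block <- function(delayed_amount, delay_months, chooser) {
  st <- init_block(delayed_amount, delay_months)
  for (i in 1:6) {
    st <- staircase_step(st, chooser(st$immediate_offer))
  }
  st
}

#' Replay a stored block of choice records and validate its offers
#'
#' Re-runs the deterministic staircase from the recorded choices and checks
#' that every stored immediate offer matches the replay, guarding against
#' corrupted or mis-sorted trial data; returns the block's normalized
#' subjective value.
#'
#' @param records Data frame with one row per trial (six rows) and columns
#'   `trial`, `immediate_offer`, `choice`, plus `delayed_amount` and
#'   `delay_months` (constant within the block).
#' @return Normalized subjective value in `[0, 1]`.
#' @examples
#' recs <- data.frame(
#'   trial = 1:6, delayed_amount = 2000, delay_months = 36,
#'   immediate_offer = c(1000, 1500, 1250, 1375, 1438, 1470),
#'   choice = c("delayed", "immediate", rep("delayed", 4))
#' )
#' replay_block(recs)
#' @export
replay_block <- function(records) {
  required <- c("trial", "immediate_offer", "choice",
                "delayed_amount", "delay_months")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("corrupt data: missing columns ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- records[order(records$trial), , drop = FALSE]
  if (nrow(records) != 6L || !identical(as.integer(records$trial), 1:6)) {
    stop("corrupt data: block must hold trials 1..6 exactly", call. = FALSE)
  }
  amount <- unique(records$delayed_amount)
  delay <- unique(records$delay_months)
  if (length(amount) != 1L || length(delay) != 1L) {
    stop("corrupt data: delayed_amount/delay_months not constant in block",
         call. = FALSE)
  }
  st <- init_block(amount, delay)
  for (i in 1:6) {
    if (st$immediate_offer != records$immediate_offer[i]) {
      stop(sprintf(
        "corrupt data: trial %d stored offer %s but replay gives %s",
        i, format(records$immediate_offer[i]), format(st$immediate_offer)),
        call. = FALSE)
    }
    st <- staircase_step(st, records$choice[i])
  }
  subjective_value(st)
}
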