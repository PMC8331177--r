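#' Generative parameters of a simulated intertemporal chooser
#'
#' A simulated participant discounts hyperbolically with baseline per-day
#' rate `k_small` for the small reward magnitude. The large magnitude
#' multiplies the rate by `magnitude_multiplier` (values < 1 produce the
#' magnitude effect: shallower discounting of larger rewards), and the
#' episodic future thinking (EFT) condition multiplies it by
#' `eft_multiplier` (values < 1 produce the EFT effect). Choices are
#' noisy: a logistic function of the value difference normalized by the
#' delayed amount (inverse temperature `beta`, so the noise is invariant
#' to reward scale), plus a `lapse` probability of a uniformly random
#' choice.
#'
#' @param k_small Baseline per-day discount rate (> 0).
#' @param magnitude_multiplier,eft_multiplier Rate multipliers in (0, 2].
#' @param beta Inverse temperature (> 0); `Inf` gives a deterministic
#'   value-maximizing chooser.
#' @param lapse Probability of a random choice, in [0, 0.5).
#' @return A `dd_agent` list.
#' @export
agent_params <- function(k_small, magnitude_multiplier = 1,
                         eft_multiplier = 1, beta = 10, lapse = 0.02) {
  stopifnot(k_small > 0,
            magnitude_multiplier > 0, magnitude_multiplier <= 2,
            eft_multiplier > 0, eft_multiplier <= 2,
            beta > 0, lapse >= 0, lapse < 0.5)
  structure(list(k_small = k_small,
                 magnitude_multiplier = magnitude_multiplier,
                 eft_multiplier = eft_multiplier,
                 beta = beta, lapse = lapse),
            class = "dd_agent")
}

#' Effective discount rate of an agent in a given design cell
#'
#' @param agent A `dd_agent`.
#' @param magnitude `"small"` or `"large"`.
#' @param condition `"Standard"` or `"EFT"`.
#' @return The per-day discount rate the agent applies in that cell.
#' @export
effective_k <- function(agent, magnitude = "small", condition = "Standard") {
  k <- agent$k_small
  if (magnitude == "large") k <- k * agent$magnitude_multiplier
  if (condition == "EFT") k <- k * agent$eft_multiplier
  k
}

# P(choose delayed); vectorized over offers/values
p_delayed <- function(value, immediate, delayed, beta, lapse) {
  d <- (value - immediate) / delayed
  base <- ifelse(is.infinite(beta),
                 (d > 0) + 0.5 * (d == 0),
                 stats::plogis(beta * d))
  lapse / 2 + (1 - lapse) * base
}

#' Simulate one choice of an agent
#'
#' The delayed reward's subjective value is `delayed / (1 + k_eff * D)`
#' with D in days; the probability of choosing it is
#' `lapse/2 + (1 - lapse) * logistic(beta * (V - immediate) / delayed)`.
#' Draws from R's global RNG.
#'
#' @param agent A `dd_agent`.
#' @param immediate,delayed Offered amounts (currency units).
#' @param delay_days Delay of the delayed reward, in days.
#' @param magnitude,condition Design-cell labels (set the effective rate).
#' @return `"immediate"` or `"delayed"`.
#' @export
simulate_choice <- function(agent, immediate, delayed, delay_days,
                            magnitude = "small", condition = "Standard") {
  k <- effective_k(agent, magnitude, condition)
  v <- delayed / (1 + k * delay_days)
  p <- p_delayed(v, immediate, delayed, agent$beta, agent$lapse)
  if (stats::runif(1) < p) "delayed" else "immediate"
}

#' Specification of a simulated two-group discounting study
#'
#' Describes a cohort of hyperbolic agents split into a patient and a
#' control group, each group with its own distribution of generative
#' parameters: log-normal baseline rates (discount rates are positive and
#' right-skewed) and log-normal jitter around group-level magnitude and
#' EFT multipliers, truncated to (0, 2].
#'
#' @param n_patients,n_controls Group sizes.
#' @param patients,controls Per-group parameter distributions: lists with
#'   `log_k_mean`, `log_k_sd` (log of the per-day small-magnitude rate),
#'   `magnitude_multiplier`, `eft_multiplier` (group geometric means),
#'   `magnitude_log_sd`, `eft_log_sd` (log-normal jitter of the two
#'   multipliers), `beta`, `lapse`.
#' @param design A `dd_task_design`.
#' @param seed Integer seed recorded in the spec and used by
#'   [simulate_study()].
#' @return A `dd_study_spec` list.
#' @seealso [default_study_spec()] for the calibrated defaults.
#' @export
study_spec <- function(n_patients = 12L, n_controls = 41L,
                       patients, controls,
                       design = task_design(), seed = 1L) {
  stopifnot(n_patients >= 1, n_controls >= 1)
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 patients = patients, controls = controls,
                 design = design, seed = as.integer(seed)),
            class = "dd_study_spec")
}

#' Calibrated default study specification
#'
#' The shipped default parameterization of the synthetic cohort. It
#' emulates a 12-patient / 41-control design and was calibrated once, by
#' Monte-Carlo simulation of the full staircase-to-AuC pipeline, so that
#' the simulated group means of the two standard effect scores
#' approximate a vmPFC-lesion study of intertemporal choice:
#' the EFT effect (AuC in the EFT condition minus Standard, collapsed over
#' magnitude) averages about 0.26 in controls and 0.17 in patients, and
#' the magnitude effect (AuC for the large minus the small reward,
#' collapsed over condition) averages about 0.14 in controls and about
#' 0.01 in patients. Patients discount more steeply at baseline and show
#' essentially no magnitude modulation; both groups respond to EFT cues.
#'
#' @param seed Seed stored in the spec.
#' @return A `dd_study_spec` with the frozen calibrated parameters.
#' @export
default_study_spec <- function(seed = 1L) {
  study_spec(
    n_patients = 12L, n_controls = 41L,
    patients = list(
      log_k_mean = log(0.0065), log_k_sd = 1.1,
      magnitude_multiplier = 1.0, eft_multiplier = 0.19,
      magnitude_log_sd = 0.6, eft_log_sd = 1.0, beta = 6, lapse = 0.05
    ),
    controls = list(
      log_k_mean = log(0.0023), log_k_sd = 1.1,
      magnitude_multiplier = 0.36, eft_multiplier = 0.15,
      magnitude_log_sd = 0.6, eft_log_sd = 1.0, beta = 10, lapse = 0.02
    ),
    seed = seed
  )
}

# draw n agents from a group distribution (uses the current RNG stream)
sample_agents <- function(n, dist) {
  trunc02 <- function(x) pmin(pmax(x, 1e-6), 2)
  data.frame(
    k_small = stats::rlnorm(n, dist$log_k_mean, dist$log_k_sd),
    magnitude_multiplier = trunc02(stats::rlnorm(
      n, log(dist$magnitude_multiplier), dist$magnitude_log_sd)),
    eft_multiplier = trunc02(stats::rlnorm(
      n, log(dist$eft_multiplier), dist$eft_log_sd)),
    beta = rep(dist$beta, n),
    lapse = rep(dist$lapse, n)
  )
}

#' Simulate a full two-group adjusting-amount discounting study
#'
#' Draws agents for both groups, then runs every participant through the
#' titration task in both conditions: for each condition, the 14 blocks
#' (2 delayed amounts x 7 delays) are administered in seeded-random order,
#' each block titrating over 6 choices, i.e. 84 choices per participant
#' per condition. The whole simulation is deterministic given the spec's
#' seed.
#'
#' @param spec A `dd_study_spec`.
#' @param return_agents If `TRUE`, also return the sampled agent
#'   parameters (as attribute `"agents"`).
#' @return A long-format data frame of choice records with columns
#'   `participant_id`, `group`, `condition`, `magnitude`, `delayed_amount`,
#'   `delay_months`, `block_order`, `trial`, `immediate_offer`, `choice`.
#' @examples
#' spec <- default_study_spec(seed = 7)
#' spec$n_patients <- 2L; spec$n_controls <- 3L
#' nrow(simulate_study(spec)) # 5 participants x 2 conditions x 84 choices
#' @export
simulate_study <- function(spec, return_agents = FALSE) {
  stopifnot(inherits(spec, "dd_study_spec"))
  set.seed(spec$seed)
  design <- spec$design
  n_total <- spec$n_patients + spec$n_controls

  agents <- rbind(
    cbind(sample_agents(spec$n_patients, spec$patients),
          group = "patient"),
    cbind(sample_agents(spec$n_controls, spec$controls),
          group = "control")
  )
  agents$participant_id <- sprintf(
    "%s%02d", ifelse(agents$group == "patient", "P", "C"),
    c(seq_len(spec$n_patients), seq_len(spec$n_controls)))

  # one row per staircase block, in administration order
  amounts <- design$delayed_amounts
  blocks_tpl <- expand.grid(
    delayed_amount = amounts, delay_months = design$delays_months,
    KEEP.OUT.ATTRS = FALSE)
  blocks_tpl$magnitude <- ifelse(
    blocks_tpl$delayed_amount == min(amounts), "small", "large")
  n_blk <- nrow(blocks_tpl)

  all_blocks <- vector("list", n_total * length(design$conditions))
  bi <- 1L
  for (i in seq_len(n_total)) {
    for (cond in design$conditions) {
      b <- blocks_tpl[sample.int(n_blk), , drop = FALSE]
      b$block_order <- seq_len(n_blk)
      b$participant <- i
      b$condition <- cond
      all_blocks[[bi]] <- b
      bi <- bi + 1L
    }
  }
  blocks <- do.call(rbind, all_blocks)
  nb <- nrow(blocks)

  ag <- agents[blocks$participant, ]
  k_eff <- ag$k_small *
    ifelse(blocks$magnitude == "large", ag$magnitude_multiplier, 1) *
    ifelse(blocks$condition == "EFT", ag$eft_multiplier, 1)
  d_days <- months_to_days(blocks$delay_months)
  value <- blocks$delayed_amount / (1 + k_eff * d_days)

  # lock-step vectorized staircase across all blocks
  a <- blocks$delayed_amount
  offer <- round_half_away(a / 2)
  adj <- round_half_away(a / 4)
  offers <- choices <- vector("list", design$trials_per_block)
  for (tr in seq_len(design$trials_per_block)) {
    p <- p_delayed(value, offer, a, ag$beta, ag$lapse)
    delayed_chosen <- stats::runif(nb) < p
    offers[[tr]] <- offer
    choices[[tr]] <- ifelse(delayed_chosen, "delayed", "immediate")
    offer <- clamp_offer(offer + ifelse(delayed_chosen, adj, -adj), a,
                         presented = tr < design$trials_per_block)
    adj <- round_half_away(adj / 2)
  }

  ntr <- design$trials_per_block
  out <- data.frame(
    participant_id = rep(ag$participant_id, each = ntr),
    group = rep(ag$group, each = ntr),
    condition = rep(blocks$condition, each = ntr),
    magnitude = rep(blocks$magnitude, each = ntr),
    delayed_amount = rep(a, each = ntr),
    delay_months = rep(blocks$delay_months, each = ntr),
    block_order = rep(blocks$block_order, each = ntr),
    trial = rep(seq_len(ntr), times = nb),
    immediate_offer = as.vector(t(do.call(cbind, offers))),
    choice = as.vector(t(do.call(cbind, choices))),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (return_agents) attr(out, "agents") <- agents
  out
}
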