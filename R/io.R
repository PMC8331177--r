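choice_columns <- c("participant_id", "group", "condition", "magnitude",
                    "delayed_amount", "delay_months", "trial",
                    "immediate_offer", "choice")

#' Read a long-format choice table
#'
#' Reads and validates a CSV of trial-level staircase choices (one row per
#' titration trial). Required columns: `participant_id`, `group`,
#' `condition`, `magnitude`, `delayed_amount`, `delay_months`, `trial`,
#' `immediate_offer`, `choice`; extra columns are preserved.
#'
#' @param path Path to the CSV file (header required, UTF-8).
#' @return A validated data frame of choice records.
#' @seealso [write_choices()], [replay_choices()]
#' @export
read_choices <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8", comment.char = "#")
  validate_choices(records)
}

validate_choices <- function(records) {
  missing_cols <- setdiff(choice_columns, names(records))
  if (length(missing_cols)) {
    stop("parse error: missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!records$choice %in% c("immediate", "delayed"))
  if (length(bad)) {
    stop(sprintf("parse error: row %d has unknown choice '%s'",
                 bad[1], records$choice[bad[1]]), call. = FALSE)
  }
  if (!is.numeric(records$immediate_offer) ||
      any(records$immediate_offer != round(records$immediate_offer))) {
    bad <- which(records$immediate_offer != round(records$immediate_offer))[1]
    stop(sprintf("parse error: row %s has non-integer immediate_offer",
                 format(bad)), call. = FALSE)
  }
  off_bad <- which(records$immediate_offer <= 0 |
                     records$immediate_offer >= records$delayed_amount)
  if (length(off_bad)) {
    stop(sprintf(
      "parse error: row %d offer %s outside (0, delayed_amount)",
      off_bad[1], format(records$immediate_offer[off_bad[1]])),
      call. = FALSE)
  }
  records
}

#' Write a choice table to CSV
#'
#' @param records Choice records as from [simulate_study()].
#' @param path Output CSV path.
#' @param comment Optional character vector written as `#`-prefixed header
#'   lines (e.g. the simulation seed and spec, for provenance).
#' @return `path`, invisibly.
#' @export
write_choices <- function(records, path, comment = NULL) {
  validate_choices(records)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comment)) writeLines(paste("#", comment), con)
  utils::write.csv(records, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Replay all staircase blocks of a choice table
#'
#' Validates every block against the deterministic titration rule (see
#' [replay_block()]) and extracts its indifference point.
#'
#' @param records Choice records (see [read_choices()]).
#' @return A data frame with one row per participant x condition x
#'   magnitude x delay and columns `participant_id`, `group`, `condition`,
#'   `magnitude`, `delayed_amount`, `delay_months`, `sv` (normalized
#'   subjective value).
#' @export
replay_choices <- function(records) {
  records <- validate_choices(records)
  keys <- c("participant_id", "group", "condition", "magnitude",
            "delayed_amount", "delay_months")
  block_id <- interaction(records[keys], drop = TRUE, lex.order = TRUE)
  ord <- order(block_id, records$trial)
  records <- records[ord, , drop = FALSE]
  block_id <- block_id[ord]

  nb <- nlevels(block_id)
  if (nrow(records) != nb * 6L ||
      !all(records$trial == rep(1:6, nb))) {
    stop("corrupt data: every block must hold trials 1..6 exactly",
         call. = FALSE)
  }
  first <- seq(1L, nrow(records), by = 6L)
  meta <- records[first, keys, drop = FALSE]

  # lock-step vectorized replay of all blocks, mirroring staircase_step()
  a <- meta$delayed_amount
  offer <- round_half_away(a / 2)
  adj <- round_half_away(a / 4)
  stored_offer <- matrix(records$immediate_offer, ncol = 6L, byrow = TRUE)
  delayed_chosen <- matrix(records$choice == "delayed", ncol = 6L,
                           byrow = TRUE)
  for (tr in 1:6) {
    bad <- which(offer != stored_offer[, tr])
    if (length(bad)) {
      stop(sprintf(
        "corrupt data: trial %d of block %s stored offer %s but replay gives %s",
        tr, as.character(block_id[first])[bad[1]],
        format(stored_offer[bad[1], tr]), format(offer[bad[1]])),
        call. = FALSE)
    }
    offer <- clamp_offer(offer + ifelse(delayed_chosen[, tr], adj, -adj),
                         a, presented = tr < 6L)
    adj <- round_half_away(adj / 2)
  }

  out <- cbind(meta, sv = offer / a)
  rownames(out) <- NULL
  out[order(out$participant_id, out$condition, out$magnitude,
            out$delay_months), , drop = FALSE]
}

#' Per-curve discounting analytics
#'
#' For each participant x condition x magnitude discounting curve,
#' computes the area under the empirical discounting curve, the
#' hyperbolic-fit discount rate and R-squared, and the
#' inconsistent-preference count.
#'
#' @param svs Subjective-value table from [replay_choices()] (or the same
#'   schema read from disk).
#' @param fit Also fit the hyperbolic function per curve (default `TRUE`);
#'   set `FALSE` to compute only AuC and inconsistency counts, e.g. in
#'   large simulation sweeps.
#' @return A data frame with columns `participant_id`, `group`,
#'   `condition`, `magnitude`, `auc`, `k`, `r_squared`, `n_inconsistent`
#'   (`k` and `r_squared` are `NA` when `fit = FALSE`).
#' @export
analyze_curves <- function(svs, fit = TRUE) {
  keys <- c("participant_id", "group", "condition", "magnitude")
  missing_cols <- setdiff(c(keys, "delay_months", "sv"), names(svs))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(
    split(svs, interaction(svs[keys], drop = TRUE, lex.order = TRUE)),
    function(d) {
      d <- d[order(d$delay_months), , drop = FALSE]
      curve <- discounting_curve(d$delay_months, d$sv)
      hf <- if (fit) fit_hyperbolic(curve) else
        list(k = NA_real_, r_squared = NA_real_)
      cbind(d[1, keys, drop = FALSE],
            auc = auc(curve),
            k = hf$k,
            r_squared = hf$r_squared,
            n_inconsistent = count_inconsistencies(curve),
            stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out[order(out$participant_id, out$condition, out$magnitude), ,
      drop = FALSE]
}

#' Read a deposited per-participant AuC table with column mapping
#'
#' Reads an externally deposited wide- or long-format AuC table into the
#' long format expected by [mixed_anova()]. Because deposited layouts
#' vary, columns are mapped by name through `mapping` rather than
#' hard-coded.
#'
#' @param path CSV path.
#' @param mapping Named list mapping the required names (`participant_id`,
#'   `group`, `condition`, `magnitude`, `auc`) to the file's column names.
#' @return Long-format data frame with the five required columns.
#' @export
read_auc_source <- function(path,
                            mapping = list(participant_id = "participant_id",
                                           group = "group",
                                           condition = "condition",
                                           magnitude = "magnitude",
                                           auc = "auc")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", comment.char = "#")
  need <- c("participant_id", "group", "condition", "magnitude", "auc")
  unmapped <- setdiff(need, names(mapping))
  if (length(unmapped)) {
    stop("config error: no mapping for ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(unlist(mapping[need]), names(raw))
  if (length(absent)) {
    stop("config error: file lacks columns ",
         paste(absent, collapse = ", "),
         "; available: ", paste(names(raw), collapse = ", "),
         call. = FALSE)
  }
  out <- raw[unlist(mapping[need])]
  names(out) <- need
  out
}

#' Run the full group-level inference stack on an AuC table
#'
#' Reproduces the standard results pipeline of a two-group discounting
#' study: the three-way mixed ANOVA on AuC (Group x Condition x Reward
#' magnitude) with partial eta squared, Fisher LSD post hocs for the
#' magnitude effect within each group, JZS Bayes factors for the group
#' comparison of the EFT effect and of the magnitude effect (computed from
#' the derived per-participant difference scores), and — when trial-level
#' analytics are supplied — the parallel ANOVA on inconsistent-preference
#' counts.
#'
#' @param auc_table Long-format AuC table with columns `participant_id`,
#'   `group`, `condition`, `magnitude`, `auc` (see [analyze_curves()] or
#'   [read_auc_source()]).
#' @param inconsistency_table Optional table with the same keys and a
#'   `n_inconsistent` column (as produced by [analyze_curves()]).
#' @param exclude_ids Participant ids dropped before analysis (e.g. a
#'   lesion-extent sensitivity analysis).
#' @param seed Optional integer recorded in the provenance block.
#' @return A `dd_results` list: `anova_auc`, `posthoc`, `bayes`
#'   (EFT and magnitude effect group comparisons), `effects` (the
#'   per-group summaries of the two difference scores),
#'   optionally `anova_inconsistency`, and `provenance`.
#' @export
reproduce <- function(auc_table, inconsistency_table = NULL,
                      exclude_ids = NULL, seed = NULL) {
  if (length(exclude_ids)) {
    auc_table <- auc_table[!auc_table$participant_id %in% exclude_ids, ,
                           drop = FALSE]
    if (!is.null(inconsistency_table)) {
      inconsistency_table <- inconsistency_table[
        !inconsistency_table$participant_id %in% exclude_ids, , drop = FALSE]
    }
  }
  anova_auc <- mixed_anova(auc_table, dv = "auc")

  posthoc <- list(
    control_magnitude = fisher_lsd(
      auc_table, anova_auc,
      list(group = "control", magnitude = "large"),
      list(group = "control", magnitude = "small")),
    patient_magnitude = fisher_lsd(
      auc_table, anova_auc,
      list(group = "patient", magnitude = "large"),
      list(group = "patient", magnitude = "small")),
    large_group = fisher_lsd(
      auc_table, anova_auc,
      list(group = "patient", magnitude = "large"),
      list(group = "control", magnitude = "large"))
  )

  effects <- effect_summaries(auc_table)
  bayes <- list(
    eft_effect = jzs_bf_ttest(effects$eft$patient, effects$eft$control),
    magnitude_effect = jzs_bf_ttest(effects$magnitude$patient,
                                    effects$magnitude$control)
  )

  res <- list(anova_auc = anova_auc, posthoc = posthoc,
              effects = effects, bayes = bayes)
  if (!is.null(inconsistency_table)) {
    res$anova_inconsistency <- mixed_anova(inconsistency_table,
                                           dv = "n_inconsistent")
  }
  res$provenance <- list(
    seed = seed,
    n_participants = length(unique(auc_table$participant_id)),
    n_rows = nrow(auc_table),
    excluded = exclude_ids,
    timestamp = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("ddcurve"))
  )
  class(res) <- "dd_results"
  res
}

# per-participant EFT and magnitude difference scores, summarized by group
effect_summaries <- function(auc_table) {
  wide <- stats::aggregate(auc ~ participant_id + group + condition,
                           data = auc_table, FUN = mean)
  eft <- merge(wide[wide$condition == "EFT", ],
               wide[wide$condition == "Standard", ],
               by = c("participant_id", "group"),
               suffixes = c("_eft", "_std"))
  eft$score <- eft$auc_eft - eft$auc_std

  widem <- stats::aggregate(auc ~ participant_id + group + magnitude,
                            data = auc_table, FUN = mean)
  mag <- merge(widem[widem$magnitude == "large", ],
               widem[widem$magnitude == "small", ],
               by = c("participant_id", "group"),
               suffixes = c("_large", "_small"))
  mag$score <- mag$auc_large - mag$auc_small

  summarize <- function(d) {
    lapply(split(d$score, d$group), function(x) {
      group_summary(length(x), mean(x), stats::sd(x))
    })
  }
  list(eft = summarize(eft), magnitude = summarize(mag))
}

#' Serialize a results bundle to JSON
#'
#' @param results A `dd_results` from [reproduce()].
#' @param path Output path for the JSON document.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path) {
  stopifnot(inherits(results, "dd_results"))
  jsonlite::write_json(unclass(results), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
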