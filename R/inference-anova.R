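#' Three-way mixed (split-plot) ANOVA with partial eta squared
#'
#' Classical univariate repeated-measures ANOVA with one between-subjects
#' factor (e.g. patient vs control group) and one or two within-subjects
#' factors (e.g. cueing condition and reward magnitude). The between effect
#' is tested against subjects-within-groups; each within effect and its
#' interactions with the group are tested against the corresponding
#' subject-by-effect error stratum. No sphericity correction is applied by
#' default (with two-level within factors sphericity holds trivially).
#'
#' Sums of squares are Type III (unweighted means), the convention of the
#' mainstream point-and-click packages, so unequal group sizes reproduce
#' the usual reported degrees of freedom (e.g. F(1, 51) for 12 patients vs
#' 41 controls).
#'
#' @param data Long-format data frame, one row per participant x within
#'   cell.
#' @param dv Name of the dependent-variable column (e.g. `"auc"`).
#' @param id Name of the participant identifier column.
#' @param between Name of the between-subjects factor column.
#' @param within Character vector (length 1 or 2) of within-subjects factor
#'   columns.
#' @return A `dd_anova` object: a data frame with one row per effect and
#'   columns `effect`, `df_effect`, `df_error`, `ss_effect`, `ss_error`,
#'   `F`, `p`, `partial_eta_sq`.
#' @examples
#' set.seed(1)
#' d <- expand.grid(participant_id = 1:6, condition = c("Standard", "EFT"),
#'                  magnitude = c("small", "large"))
#' d$group <- ifelse(d$participant_id <= 3, "patient", "control")
#' d$auc <- runif(nrow(d))
#' mixed_anova(d, dv = "auc")
#' @export
mixed_anova <- function(data, dv = "auc", id = "participant_id",
                        between = "group",
                        within = c("condition", "magnitude")) {
  data <- as.data.frame(data)
  needed <- c(dv, id, between, within)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("design error: missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(within) < 1 || length(within) > 2) {
    stop("one or two within-subject factors are supported", call. = FALSE)
  }
  for (f in c(id, between, within)) data[[f]] <- factor(data[[f]])

  # complete crossed design: one observation per participant x within cell
  cell <- interaction(data[, within, drop = FALSE], drop = FALSE)
  tab <- table(data[[id]], cell)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "design error: participant %s has %d observations in cell %s",
      rownames(tab)[bad[1]], tab[bad[1], bad[2]], colnames(tab)[bad[2]]),
      call. = FALSE)
  }
  groups <- unique(data[, c(id, between)])
  if (min(table(groups[[between]])) < 2) {
    stop("design error: need >= 2 participants per group", call. = FALSE)
  }

  # wide matrix of within cells, one row per participant
  idata <- rev(expand.grid(rev(lapply(data[within], levels))))
  names(idata) <- within
  cols <- do.call(paste, c(idata, sep = "."))
  wide <- matrix(NA_real_, nrow = nrow(groups), ncol = length(cols),
                 dimnames = list(as.character(groups[[id]]), cols))
  key <- do.call(paste, c(data[within], sep = "."))
  wide[cbind(as.character(data[[id]]), key)] <- data[[dv]]

  grp <- groups[[between]]
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  mod <- stats::lm(wide ~ grp)
  av <- car::Anova(mod, idata = idata,
                   idesign = stats::as.formula(
                     paste("~", paste(within, collapse = "*"))),
                   type = 3)
  # sphericity diagnostics are not part of the output (two-level within
  # factors satisfy sphericity trivially); silence their warnings for
  # degenerate error matrices
  ut <- withCallingHandlers(
    summary(av, multivariate = FALSE)$univariate.tests,
    warning = function(w) {
      if (grepl("sphericity", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })

  keep <- setdiff(rownames(ut), "(Intercept)")
  eff <- gsub("\\bgrp\\b", between, keep)
  ss_e <- ut[keep, "Sum Sq"]
  ss_err <- ut[keep, "Error SS"]
  f_val <- ut[keep, "F value"]
  p_val <- ut[keep, "Pr(>F)"]
  # a degenerate stratum (no within-participant variance) yields 0/0
  zero <- ss_e < 1e-12 & !is.finite(f_val)
  f_val[zero] <- 0
  p_val[zero] <- 1
  peta <- ifelse(ss_e + ss_err > 0, ss_e / (ss_e + ss_err), 0)

  structure(
    data.frame(
      effect = eff,
      df_effect = ut[keep, "num Df"],
      df_error = ut[keep, "den Df"],
      ss_effect = ss_e,
      ss_error = ss_err,
      F = f_val,
      p = p_val,
      partial_eta_sq = peta,
      row.names = NULL,
      stringsAsFactors = FALSE
    ),
    class = c("dd_anova", "data.frame"),
    dv = dv, id = id, between = between, within = within
  )
}

#' Fisher LSD post hoc comparison of two design cells
#'
#' Unprotected (no multiplicity correction) two-tailed t-test of a pair of
#' cell means using a pooled error term from the mixed ANOVA. Each cell is
#' named by fixing levels of one or more design factors (factors left
#' unspecified are averaged over); the error term defaults to the ANOVA
#' effect formed by the factors that differ between the two cells, i.e. the
#' stratum against which that contrast is tested.
#'
#' t = (m1 - m2) / sqrt(MSE * (1/n1 + 1/n2)), with MSE and degrees of
#' freedom taken from the chosen error stratum and n the number of
#' observations entering each cell mean.
#'
#' @param data The long-format data frame passed to [mixed_anova()].
#' @param anova The fitted `dd_anova` table.
#' @param cell1,cell2 Named lists selecting the two cells, e.g.
#'   `list(group = "control", magnitude = "large")`.
#' @param error_term Optional name of the ANOVA effect whose error stratum
#'   supplies MSE and df; defaults to the interaction of the factors named
#'   in the cells.
#' @return A list with the two cell `means`, `t`, `df` and the two-tailed
#'   `p`.
#' @export
fisher_lsd <- function(data, anova, cell1, cell2, error_term = NULL) {
  stopifnot(inherits(anova, "dd_anova"))
  data <- as.data.frame(data)
  dv <- attr(anova, "dv")

  pick <- function(cells) {
    sel <- rep(TRUE, nrow(data))
    for (f in names(cells)) sel <- sel & data[[f]] == cells[[f]]
    data[[dv]][sel]
  }
  y1 <- pick(cell1)
  y2 <- pick(cell2)
  if (!length(y1) || !length(y2)) {
    stop("empty cell in post hoc comparison", call. = FALSE)
  }

  if (is.null(error_term)) {
    facs <- union(names(cell1), names(cell2))
    # the between factor alone -> between stratum; otherwise the stratum of
    # the within factors involved (interactions with group share it)
    wi <- intersect(attr(anova, "within"), facs)
    error_term <- if (length(wi)) {
      paste(c(attr(anova, "between"), wi), collapse = ":")
    } else {
      attr(anova, "between")
    }
  }
  row <- match(error_term, anova$effect)
  if (is.na(row)) {
    stop("error_term not found in ANOVA table: ", error_term, call. = FALSE)
  }
  mse <- anova$ss_error[row] / anova$df_error[row]
  df <- anova$df_error[row]

  m1 <- mean(y1)
  m2 <- mean(y2)
  se <- sqrt(mse * (1 / length(y1) + 1 / length(y2)))
  t <- if (se == 0) 0 else (m1 - m2) / se
  list(means = c(m1, m2), t = t, df = df,
       p = if (se == 0 && m1 == m2) 1 else 2 * stats::pt(-abs(t), df))
}
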