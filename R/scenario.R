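#' Paradigm presets
#'
#' Known paradigms and the conventions attached to each: which decision the
#' observed unknown-condition probability refers to (the focal decision), and
#' the fixed phase-combination rule used to predict the unknown-condition
#' phase.
#'
#' The cell labels follow the convention that reproduces the published
#' tables: `theta1` = (reference, positive), `theta2` = (alternative,
#' positive), `theta3` = (reference, negative), `theta4` = (alternative,
#' negative), where the reference decision is withdraw (categorization),
#' play-again (gambling) or defect (prisoner's dilemma).
#'
#' @format NULL
#' @name paradigms
NULL

PARADIGMS <- c("categorization_wide", "categorization_narrow",
               "gambling", "prisoners_dilemma", "custom")

paradigm_focal <- function(paradigm) {
  switch(paradigm,
    categorization_wide = ,
    categorization_narrow = "alternative",
    gambling = ,
    prisoners_dilemma = "reference",
    "reference")
}

#' Construct a phase-combination rule
#'
#' Two functional forms cover all published paradigms:
#' `sum_complement` gives \eqn{\theta_{fit} = 360° - (\theta_a + \theta_b)}
#' (categorization; the two cells are the safest and riskiest choices) and
#' `half_complement` gives \eqn{\theta_{fit} = (360° - \theta_a)/2}
#' (disjunction-effect paradigms; the cell is the riskiest choice).
#'
#' @param form `"sum_complement"` or `"half_complement"`.
#' @param cells character vector of cell labels (`"theta1"` ... `"theta4"`)
#'   feeding the rule: two cells for `sum_complement`, one for
#'   `half_complement`.
#' @return A `phase_fit_rule` object.
#' @export
phase_fit_rule <- function(form = c("sum_complement", "half_complement"),
                           cells) {
  form <- match.arg(form)
  need <- if (form == "sum_complement") 2L else 1L
  if (length(cells) != need || !all(cells %in% paste0("theta", 1:4)))
    stop(sprintf("`cells` must name %d of theta1..theta4 for form '%s'",
                 need, form), call. = FALSE)
  structure(list(form = form, cells = cells), class = "phase_fit_rule")
}

#' Preset phase-combination rule for a paradigm
#'
#' Fixed-cell presets: wide-face categorization uses
#' \eqn{360 - (\theta_1 + \theta_2)}, narrow-face categorization
#' \eqn{360 - (\theta_1 + \theta_4)}, and both disjunction paradigms
#' (gambling, prisoner's dilemma) \eqn{(360 - \theta_2)/2}.
#'
#' `strategy = "min_conditional"` is an optional alternative for the
#' disjunction paradigms that selects the cell with the smallest conditional
#' probability (the riskiest choice) instead of the fixed `theta2` cell. The
#' fixed-cell reading is the default because at least one published
#' prisoner's-dilemma experiment has its minimum-probability cell elsewhere
#' while the printed fit still uses `theta2`.
#'
#' @param paradigm one of the presets; `"custom"` has no preset rule.
#' @param scenario optionally, the scenario (required for
#'   `"min_conditional"`).
#' @param strategy `"fixed"` (default) or `"min_conditional"`.
#' @return A [phase_fit_rule()].
#' @export
paradigm_rule <- function(paradigm, scenario = NULL,
                          strategy = c("fixed", "min_conditional")) {
  strategy <- match.arg(strategy)
  paradigm <- match.arg(paradigm, PARADIGMS)
  if (paradigm == "custom")
    stop("paradigm 'custom' has no preset rule; supply a phase_fit_rule",
         call. = FALSE)
  if (strategy == "fixed") {
    return(switch(paradigm,
      categorization_wide   = phase_fit_rule("sum_complement", c("theta1", "theta2")),
      categorization_narrow = phase_fit_rule("sum_complement", c("theta1", "theta4")),
      gambling              = ,
      prisoners_dilemma     = phase_fit_rule("half_complement", "theta2")))
  }
  if (!startsWith(paradigm, "categorization")) {
    if (is.null(scenario))
      stop("`strategy = 'min_conditional'` needs the scenario", call. = FALSE)
    cond <- c(theta1 = scenario$p_ref_given_pos,
              theta2 = 1 - scenario$p_ref_given_pos,
              theta3 = scenario$p_ref_given_neg,
              theta4 = 1 - scenario$p_ref_given_neg)
    return(phase_fit_rule("half_complement", names(which.min(cond))))
  }
  stop("min_conditional strategy applies to disjunction paradigms only",
       call. = FALSE)
}

#' One two-condition, two-decision experiment
#'
#' Holds the complete probability structure of a binary decision made under
#' two possible conditions: the positive-condition marginal, the two
#' conditional probabilities of the reference decision, and optionally the
#' observed probability of the focal decision when the condition is unknown.
#'
#' The reference decision is the one mapped to the `theta1` cell (withdraw,
#' play-again, defect in the bundled paradigms); the focal decision is the
#' one the unknown-condition probability refers to (attack, play-again,
#' defect).
#'
#' @param study_id free-text identifier.
#' @param paradigm one of `"categorization_wide"`, `"categorization_narrow"`,
#'   `"gambling"`, `"prisoners_dilemma"`, `"custom"`.
#' @param p_cond_pos probability of the positive condition.
#' @param p_ref_given_pos,p_ref_given_neg conditional probabilities of the
#'   reference decision under each known condition.
#' @param p_focal_unknown observed unknown-condition probability of the focal
#'   decision, or `NA` when the experiment has no unknown condition.
#' @param focal_decision `"reference"` or `"alternative"`; defaults to the
#'   paradigm's convention.
#' @param n_subjects optional sample size per condition group.
#' @param condition_labels,decision_labels optional display labels,
#'   `c(positive, negative)` and `c(reference, alternative)`.
#' @return A `binary_scenario` object.
#' @examples
#' s <- binary_scenario("gambling_exp_1", "gambling",
#'   p_cond_pos = 0.5, p_ref_given_pos = 0.69, p_ref_given_neg = 0.57,
#'   p_focal_unknown = 0.38)
#' analyze_scenario(s)
#' @export
binary_scenario <- function(study_id, paradigm, p_cond_pos,
                            p_ref_given_pos, p_ref_given_neg,
                            p_focal_unknown = NA_real_,
                            focal_decision = NULL,
                            n_subjects = NA_integer_,
                            condition_labels = c("positive", "negative"),
                            decision_labels = c("reference", "alternative")) {
  paradigm <- match.arg(paradigm, PARADIGMS)
  check_prob(p_cond_pos, "p_cond_pos")
  check_prob(p_ref_given_pos, "p_ref_given_pos")
  check_prob(p_ref_given_neg, "p_ref_given_neg")
  check_prob(p_focal_unknown, "p_focal_unknown", allow_na = TRUE)
  if (is.null(focal_decision)) focal_decision <- paradigm_focal(paradigm)
  focal_decision <- match.arg(focal_decision, c("reference", "alternative"))
  if (!is.na(n_subjects) && (n_subjects < 1 || n_subjects != round(n_subjects)))
    stop("`n_subjects` must be a positive integer", call. = FALSE)
  structure(
    list(study_id = as.character(study_id), paradigm = paradigm,
         p_cond_pos = p_cond_pos,
         p_ref_given_pos = p_ref_given_pos,
         p_ref_given_neg = p_ref_given_neg,
         p_focal_unknown = p_focal_unknown,
         focal_decision = focal_decision,
         n_subjects = as.integer(n_subjects),
         condition_labels = condition_labels,
         decision_labels = decision_labels),
    class = "binary_scenario")
}

#' @export
print.binary_scenario <- function(x, ...) {
  cat(sprintf("<binary_scenario '%s' [%s]>\n", x$study_id, x$paradigm))
  cat(sprintf("  p(%s) = %.4g;  p(%s|%s) = %.4g, p(%s|%s) = %.4g\n",
              x$condition_labels[1], x$p_cond_pos,
              x$decision_labels[1], x$condition_labels[1], x$p_ref_given_pos,
              x$decision_labels[1], x$condition_labels[2], x$p_ref_given_neg))
  if (!is.na(x$p_focal_unknown))
    cat(sprintf("  observed p(%s|unknown) = %.4g\n",
                x$decision_labels[if (x$focal_decision == "reference") 1 else 2],
                x$p_focal_unknown))
  invisible(x)
}

#' Joint probabilities and decision marginals of a scenario
#'
#' Law-of-total-probability bookkeeping: `joint(d, c) = p(c) p(d|c)` for the
#' four decision-by-condition cells, plus the two decision marginals.
#'
#' @param scenario a [binary_scenario()].
#' @return A list with `joint` (2x2 matrix, decisions in rows, conditions in
#'   columns), `p_decision` (named length-2 vector) and `p_condition`.
#' @export
cell_joints <- function(scenario) {
  stopifnot(inherits(scenario, "binary_scenario"))
  pc <- c(positive = scenario$p_cond_pos,
          negative = 1 - scenario$p_cond_pos)
  joint <- rbind(
    reference   = c(pc[1] * scenario$p_ref_given_pos,
                    pc[2] * scenario$p_ref_given_neg),
    alternative = c(pc[1] * (1 - scenario$p_ref_given_pos),
                    pc[2] * (1 - scenario$p_ref_given_neg)))
  colnames(joint) <- names(pc)
  list(joint = joint,
       p_decision = c(reference = sum(joint["reference", ]),
                      alternative = sum(joint["alternative", ])),
       p_condition = pc)
}

# theta1..theta4 cell map: (decision, condition) per cell label
CELL_MAP <- data.frame(
  cell = paste0("theta", 1:4),
  decision = c("reference", "alternative", "reference", "alternative"),
  condition = c("positive", "positive", "negative", "negative"),
  stringsAsFactors = FALSE)

#' Known-condition interference phases of a scenario
#'
#' Inverts the two-wave law for each of the four decision-by-condition cells:
#' for cell \eqn{(d, c)}, \eqn{\cos\theta = (p(d,c) - p(d) - p(c)) /
#' (2\sqrt{p(d)p(c)})}. Cell labels: `theta1` = (reference, positive),
#' `theta2` = (alternative, positive), `theta3` = (reference, negative),
#' `theta4` = (alternative, negative).
#'
#' @param scenario a [binary_scenario()].
#' @return A `cell_phase_table` data frame with one row per cell: the joint,
#'   both marginals, `theta_deg`, `raw_cosine` and `clamped`.
#' @export
known_condition_phases <- function(scenario) {
  cj <- cell_joints(scenario)
  out <- CELL_MAP
  out$joint <- mapply(function(d, co) cj$joint[d, co],
                      out$decision, out$condition)
  out$p_decision <- cj$p_decision[out$decision]
  out$p_condition <- cj$p_condition[out$condition]
  bad <- out$p_decision == 0 | out$p_condition == 0
  if (any(bad))
    stop(sprintf("zero marginal: phase undefined for cell(s) %s",
                 paste(out$cell[bad], collapse = ", ")), call. = FALSE)
  ph <- invert_phase(out$joint, out$p_decision, out$p_condition)
  out$theta_deg <- ph$theta_deg
  out$raw_cosine <- ph$raw_cosine
  out$clamped <- ph$clamped
  rownames(out) <- out$cell
  class(out) <- c("cell_phase_table", "data.frame")
  out
}

#' @export
print.cell_phase_table <- function(x, ...) {
  cat("<known-condition interference phases>\n")
  df <- data.frame(cell = x$cell,
                   decision = x$decision, condition = x$condition,
                   joint = round(x$joint, 4),
                   theta_deg = round(x$theta_deg, 2),
                   clamped = x$clamped)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

focal_joints <- function(scenario, cj = cell_joints(scenario)) {
  cj$joint[scenario$focal_decision, ]
}

#' Experimental unknown-condition phase
#'
#' Inverts the two-wave law over the two focal-decision joints at the
#' observed unknown-condition probability, giving the phase the experiment
#' actually realized. Equals 90 degrees exactly when the observation obeys
#' the classical law of total probability.
#'
#' @param scenario a [binary_scenario()] with `p_focal_unknown` present.
#' @return A single-row `phase_result`.
#' @export
experimental_phase <- function(scenario) {
  stopifnot(inherits(scenario, "binary_scenario"))
  if (is.na(scenario$p_focal_unknown))
    stop("scenario has no observed unknown-condition probability",
         call. = FALSE)
  jf <- focal_joints(scenario)
  invert_phase(scenario$p_focal_unknown, jf[[1]], jf[[2]])
}

#' Predicted phase from known-condition cells
#'
#' Applies a phase-combination rule to a table of known-condition phases.
#'
#' @param table a `cell_phase_table` from [known_condition_phases()].
#' @param rule a [phase_fit_rule()].
#' @return Predicted phase in degrees, in `[0, 360)`.
#' @export
fitted_phase <- function(table, rule) {
  stopifnot(inherits(table, "cell_phase_table"),
            inherits(rule, "phase_fit_rule"))
  th <- table$theta_deg[match(rule$cells, table$cell)]
  out <- switch(rule$form,
    sum_complement = 360 - sum(th),
    half_complement = (360 - th) / 2)
  out %% 360
}

#' Predicted unknown-condition probability
#'
#' Plugs a phase into the two-wave law over the focal-decision joints.
#'
#' @param scenario a [binary_scenario()].
#' @param theta_deg phase in degrees (typically from [fitted_phase()]).
#' @return A list with `p_fit` (raw value, not truncated) and
#'   `out_of_range` (`TRUE` when `p_fit` falls outside `[0, 1]`).
#' @export
predict_unknown <- function(scenario, theta_deg) {
  jf <- focal_joints(scenario)
  p <- two_wave_probability(jf[[1]], jf[[2]], theta_deg)
  list(p_fit = p, out_of_range = !in_unit_interval(p))
}

#' Full scenario analysis
#'
#' Chains the pipeline: cell joints, known-condition phases, experimental
#' phase (when an unknown-condition observation exists), fitted phase under
#' the paradigm's rule, and the predicted unknown-condition probability.
#'
#' @param scenario a [binary_scenario()].
#' @param rule a [phase_fit_rule()]; defaults to the paradigm preset.
#' @param strategy passed to [paradigm_rule()] when `rule` is `NULL`.
#' @return A `scenario_analysis` list: `phases` (cell table), `theta_expt_deg`
#'   (`NA` when no observation), `theta_fit_deg`, `p_fit`, `residual_deg`
#'   (= theta_expt - theta_fit), and flags `expt_clamped`, `any_cell_clamped`,
#'   `p_fit_out_of_range`.
#' @export
analyze_scenario <- function(scenario, rule = NULL,
                             strategy = c("fixed", "min_conditional")) {
  stopifnot(inherits(scenario, "binary_scenario"))
  strategy <- match.arg(strategy)
  if (is.null(rule))
    rule <- paradigm_rule(scenario$paradigm, scenario, strategy)
  phases <- known_condition_phases(scenario)
  theta_fit <- fitted_phase(phases, rule)
  pred <- predict_unknown(scenario, theta_fit)
  if (!is.na(scenario$p_focal_unknown)) {
    expt <- experimental_phase(scenario)
    theta_expt <- expt$theta_deg
    expt_clamped <- expt$clamped
  } else {
    theta_expt <- NA_real_
    expt_clamped <- NA
  }
  structure(
    list(study_id = scenario$study_id, paradigm = scenario$paradigm,
         rule = rule, phases = phases,
         theta_expt_deg = theta_expt, theta_fit_deg = theta_fit,
         p_fit = pred$p_fit,
         p_observed_unknown = scenario$p_focal_unknown,
         residual_deg = theta_expt - theta_fit,
         expt_clamped = expt_clamped,
         any_cell_clamped = any(phases$clamped),
         p_fit_out_of_range = pred$out_of_range),
    class = "scenario_analysis")
}

#' @export
print.scenario_analysis <- function(x, ...) {
  cat(sprintf("<scenario_analysis '%s' [%s]>\n", x$study_id, x$paradigm))
  th <- round(x$phases$theta_deg, 2)
  cl <- ifelse(x$phases$clamped, "*", "")
  cat("  cell phases: ",
      paste(sprintf("%s=%.2f%s", x$phases$cell, th, cl), collapse = "  "),
      "\n", sep = "")
  if (!is.na(x$theta_expt_deg))
    cat(sprintf("  theta_expt = %.2f deg   residual = %+.2f deg\n",
                x$theta_expt_deg, x$residual_deg))
  cat(sprintf("  theta_fit  = %.2f deg   p_fit = %.4f%s\n",
              x$theta_fit_deg, x$p_fit,
              if (x$p_fit_out_of_range) " (outside [0,1])" else ""))
  if (any(x$phases$clamped))
    cat("  * cosine clamped to [-1, 1]\n")
  invisible(x)
}

#' Analyze many scenarios into a flat table
#'
#' @param scenarios a list of [binary_scenario()] objects.
#' @param ... passed to [analyze_scenario()].
#' @return A data frame, one row per scenario: the four cell phases,
#'   `theta_expt_deg`, `theta_fit_deg`, `p_fit`, `residual_deg` and flags.
#' @export
analyze_scenarios <- function(scenarios, ...) {
  rows <- lapply(scenarios, function(s) {
    a <- analyze_scenario(s, ...)
    th <- stats::setNames(a$phases$theta_deg, a$phases$cell)
    data.frame(study_id = a$study_id, paradigm = a$paradigm,
               theta1 = th[["theta1"]], theta2 = th[["theta2"]],
               theta3 = th[["theta3"]], theta4 = th[["theta4"]],
               theta_expt_deg = a$theta_expt_deg,
               theta_fit_deg = a$theta_fit_deg,
               p_observed_unknown = a$p_observed_unknown,
               p_fit = a$p_fit,
               residual_deg = a$residual_deg,
               any_cell_clamped = a$any_cell_clamped,
               p_fit_out_of_range = a$p_fit_out_of_range,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read and write scenario tables
#'
#' Flat comma-separated format, one row per experiment, with a mandatory
#' header: `study_id, paradigm, p_cond_pos, p_ref_given_pos, p_ref_given_neg,
#' p_focal_unknown, focal_decision, n_subjects`. `p_focal_unknown`,
#' `focal_decision` and `n_subjects` may be empty.
#'
#' @param path file path.
#' @return `read_scenarios()`: a list of [binary_scenario()] objects.
#'   Rows that violate the schema raise an error naming the row and column.
#' @export
read_scenarios <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("study_id", "paradigm", "p_cond_pos", "p_ref_given_pos",
                "p_ref_given_neg")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("scenario file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    tryCatch(
      binary_scenario(
        row$study_id, row$paradigm, row$p_cond_pos,
        row$p_ref_given_pos, row$p_ref_given_neg,
        p_focal_unknown = if ("p_focal_unknown" %in% names(df) &&
                              !is.na(row$p_focal_unknown))
          row$p_focal_unknown else NA_real_,
        focal_decision = if ("focal_decision" %in% names(df) &&
                             !is.na(row$focal_decision) &&
                             nzchar(row$focal_decision))
          row$focal_decision else NULL,
        n_subjects = if ("n_subjects" %in% names(df) &&
                         !is.na(row$n_subjects))
          row$n_subjects else NA_integer_),
      error = function(e)
        stop(sprintf("row %d ('%s'): %s", i, row$study_id,
                     conditionMessage(e)), call. = FALSE))
  })
}

#' @rdname read_scenarios
#' @param scenarios list of [binary_scenario()] objects.
#' @export
write_scenarios <- function(scenarios, path) {
  df <- do.call(rbind, lapply(scenarios, function(s)
    data.frame(study_id = s$study_id, paradigm = s$paradigm,
               p_cond_pos = s$p_cond_pos,
               p_ref_given_pos = s$p_ref_given_pos,
               p_ref_given_neg = s$p_ref_given_neg,
               p_focal_unknown = s$p_focal_unknown,
               focal_decision = s$focal_decision,
               n_subjects = s$n_subjects, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
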