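#' Bundled reference tables
#'
#' Six published tables ship with the package as plain CSV fixtures: three
#' ERP electrode tables (`erp_n270`, `erp_p300_distance`,
#' `erp_p300_intention`) and three behavioral tables (`categorization`,
#' `gambling`, `prisoners_dilemma`). Input columns are stored exactly as
#' printed (2-decimal probabilities, amplitudes in microvolts); the printed
#' derived columns (`printed_theta*`, `printed_p_fit`) are retained for
#' comparison only and are never fed back into any computation.
#'
#' @param table_id one of `"erp_n270"`, `"erp_p300_distance"`,
#'   `"erp_p300_intention"`, `"categorization"`, `"gambling"`,
#'   `"prisoners_dilemma"`.
#' @return A data frame with attributes `table_id` and `kind` (`"erp"` or
#'   `"scenario"`).
#' @examples
#' nrow(load_fixture("gambling"))  # 9 experiments
#' @export
load_fixture <- function(table_id) {
  table_id <- match.arg(table_id, FIXTURE_IDS)
  path <- system.file("extdata", paste0(table_id, ".csv"),
                      package = "phasefit", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  kind <- if (startsWith(table_id, "erp")) "erp" else "scenario"
  if (kind == "scenario") {
    probs <- grep("^(p_|printed_p)", names(df), value = TRUE)
    for (cn in probs) check_prob(df[[cn]], cn)
  } else {
    for (cn in grep("^amplitude", names(df), value = TRUE))
      check_nonneg(df[[cn]], cn)
  }
  attr(df, "table_id") <- table_id
  attr(df, "kind") <- kind
  df
}

FIXTURE_IDS <- c("erp_n270", "erp_p300_distance", "erp_p300_intention",
                 "categorization", "gambling", "prisoners_dilemma")

#' @rdname load_fixture
#' @format NULL
#' @export
fixture_ids <- function() FIXTURE_IDS

#' Convert a behavioral fixture to scenarios
#'
#' Maps each printed row onto a [binary_scenario()]. Conventions per table:
#' categorization rows have reference = withdraw (so `p_ref_given_pos` =
#' 1 - p(attack|good)), positive condition = good face, focal decision =
#' attack; gambling rows have reference = focal = play-again, positive =
#' win; prisoner's-dilemma rows have reference = focal = defect, positive =
#' the known-defect condition.
#'
#' For the prisoner's-dilemma table, `inputs = "fractions"` replaces each
#' probability (both conditionals and the unknown-condition observation) by
#' the nearest fraction with denominator 30, the granularity the printed
#' values were evidently rounded from. This input set explains the printed
#' phase cells that the 2-decimal inputs cannot reproduce.
#'
#' @param fixture a behavioral fixture from [load_fixture()], or its id.
#' @param inputs `"printed"` (default) or `"fractions"` (prisoner's dilemma
#'   only).
#' @param fraction_denominator denominator used by `inputs = "fractions"`.
#' @return A list of [binary_scenario()] objects.
#' @export
fixture_scenarios <- function(fixture, inputs = c("printed", "fractions"),
                              fraction_denominator = 30) {
  inputs <- match.arg(inputs)
  if (is.character(fixture)) fixture <- load_fixture(fixture)
  id <- attr(fixture, "table_id")
  if (!identical(attr(fixture, "kind"), "scenario"))
    stop("not a behavioral fixture: ", id, call. = FALSE)
  if (inputs == "fractions" && id != "prisoners_dilemma")
    stop("fraction-reconstructed inputs are defined for the prisoner's ",
         "dilemma table only", call. = FALSE)
  snap <- function(x) round(x * fraction_denominator) / fraction_denominator
  lapply(seq_len(nrow(fixture)), function(i) {
    r <- fixture[i, ]
    switch(id,
      categorization = binary_scenario(
        paste0(r$study_id, "_", r$face_type),
        if (r$face_type == "W") "categorization_wide"
        else "categorization_narrow",
        p_cond_pos = r$p_good,
        p_ref_given_pos = 1 - r$p_attack_good,
        p_ref_given_neg = 1 - r$p_attack_bad,
        p_focal_unknown = r$p_attack_alone,
        condition_labels = c("good", "bad"),
        decision_labels = c("withdraw", "attack")),
      gambling = binary_scenario(
        r$study_id, "gambling",
        p_cond_pos = r$p_win,
        p_ref_given_pos = r$p_again_win,
        p_ref_given_neg = r$p_again_lose,
        p_focal_unknown = r$p_again_unknown,
        condition_labels = c("win", "lose"),
        decision_labels = c("again", "not-again")),
      prisoners_dilemma = {
        f <- if (inputs == "fractions") snap else identity
        binary_scenario(
          r$study_id, "prisoners_dilemma",
          p_cond_pos = r$p_kd,
          p_ref_given_pos = f(r$p_defect_kd),
          p_ref_given_neg = f(r$p_defect_kc),
          p_focal_unknown = f(r$p_defect_unknown),
          condition_labels = c("known-defect", "known-cooperate"),
          decision_labels = c("defect", "cooperate"))
      })
  })
}

#' Known reproduction exceptions
#'
#' Cells of the bundled tables whose printed derived value cannot be
#' recomputed from the printed inputs, with the reason. The
#' prisoner's-dilemma phase cells deviate by more than 0.5 degrees because
#' the source probabilities were rounded from fractions with denominator 30
#' (they reproduce within 0.1 degrees under `inputs = "fractions"`); the
#' gambling table carries one `p_fit` cell that is inconsistent with the
#' table's own printed fitted phase under every input treatment.
#'
#' @param table_id a behavioral fixture id.
#' @return A data frame with columns `study_id`, `column`, `reason` (possibly
#'   zero rows).
#' @export
known_exceptions <- function(table_id) {
  table_id <- match.arg(table_id,
                        c("categorization", "gambling", "prisoners_dilemma"))
  switch(table_id,
    categorization = data.frame(study_id = character(), column = character(),
                                reason = character(),
                                stringsAsFactors = FALSE),
    gambling = data.frame(
      study_id = "gam_2", column = "p_fit",
      reason = "printed 0.40 inconsistent with the row's own printed fitted phase; recomputes to 0.45",
      stringsAsFactors = FALSE),
    prisoners_dilemma = data.frame(
      study_id = c("pd_4", "pd_4", "pd_5", "pd_5", "pd_6"),
      column = c("theta2", "theta_fit", "theta2", "theta4", "theta4"),
      reason = "inputs rounded from fractions with denominator 30",
      stringsAsFactors = FALSE))
}

# Comparison columns: fixture printed name -> recomputed name
DERIVED_COLS <- c(theta1 = "printed_theta1", theta2 = "printed_theta2",
                  theta3 = "printed_theta3", theta4 = "printed_theta4",
                  theta_expt = "printed_theta_expt",
                  theta_fit = "printed_theta_fit",
                  p_fit = "printed_p_fit")

#' Recompute a bundled table from its printed inputs
#'
#' Re-derives every derived column of a bundled table from the printed input
#' probabilities (or amplitudes) via the scenario or ERP pipeline and
#' compares cell by cell against print. Phases are compared as printed, at 2
#' decimals; probabilities likewise. Cells listed by [known_exceptions()]
#' are reported but not counted as mismatches.
#'
#' Summary statistics accompany behavioral tables: per-column phase
#' mean +/- sample SD, RMSD between experimental and fitted phase (on
#' 2-decimal phases, the printed precision), and MAPE between observed and
#' fitted unknown-condition probabilities (unrounded recomputed fits,
#' fitted-value denominator by default). ERP tables get the phase CV and the
#' amplitude-column CVs.
#'
#' @param table_id fixture id.
#' @param inputs passed to [fixture_scenarios()] (behavioral tables only).
#' @param mape_denominator passed to [mape()].
#' @return A `reproduction_report` list: `table_id`, `comparison` (long data
#'   frame: study/electrode, column, printed, recomputed, diff, `match_2dp`,
#'   `known_exception`), `summary` (named list of statistics),
#'   `n_unexplained` (mismatches at 2 decimals outside the exception list,
#'   phases judged at 0.5 degrees), and `warnings`.
#' @export
reproduce_table <- function(table_id, inputs = c("printed", "fractions"),
                            mape_denominator = c("fitted", "observed")) {
  table_id <- match.arg(table_id, FIXTURE_IDS)
  inputs <- match.arg(inputs)
  mape_denominator <- match.arg(mape_denominator)
  fx <- load_fixture(table_id)
  if (attr(fx, "kind") == "erp")
    return(reproduce_erp_table(fx))

  scen <- fixture_scenarios(fx, inputs = inputs)
  res <- analyze_scenarios(scen)
  res$theta_expt <- res$theta_expt_deg
  res$theta_fit <- res$theta_fit_deg
  exc <- known_exceptions(table_id)
  long <- do.call(rbind, lapply(names(DERIVED_COLS), function(col) {
    printed <- fx[[DERIVED_COLS[[col]]]]
    recomputed <- res[[col]]
    sid <- if (table_id == "categorization")
      paste0(fx$study_id, "_", fx$face_type) else fx$study_id
    data.frame(study_id = sid, column = col, printed = printed,
               recomputed = recomputed,
               diff = recomputed - printed, stringsAsFactors = FALSE)
  }))
  long$match_2dp <- round(long$recomputed, 2) == round(long$printed, 2)
  long$known_exception <- mapply(function(s, co)
    any(exc$study_id == s & exc$column == co), long$study_id, long$column)
  # printed inputs are themselves rounded to 2 decimals, which can move a
  # recomputed phase by up to ~0.5 degrees and a predicted probability by up
  # to ~0.02; larger deviations outside the known-exception list are
  # unexplained
  is_phase <- long$column != "p_fit"
  unexplained <- !long$known_exception &
    ifelse(is_phase, abs(long$diff) > 0.5, abs(long$diff) > 0.02)

  warnings <- character()
  clamped <- res$any_cell_clamped
  if (any(clamped))
    warnings <- c(warnings, sprintf(
      "clamped cosine in row(s): %s", paste(res$study_id[clamped],
                                            collapse = ", ")))
  if (any(res$p_fit_out_of_range))
    warnings <- c(warnings, sprintf(
      "p_fit outside [0, 1] in row(s): %s",
      paste(res$study_id[res$p_fit_out_of_range], collapse = ", ")))
  exc_hit <- long$known_exception & !long$match_2dp
  if (any(exc_hit))
    warnings <- c(warnings, sprintf(
      "known exception cell(s): %s",
      paste(unique(paste0(long$study_id[exc_hit], ":", long$column[exc_hit])),
            collapse = ", ")))

  r2 <- function(x) round(x, 2)
  summary <- list(
    n_rows = nrow(res),
    phase_mean_sd = vapply(
      c("theta1", "theta2", "theta3", "theta4", "theta_expt", "theta_fit"),
      function(col) {
        s <- summarize_phases(r2(res[[col]]))
        c(mean = s$mean, sample_sd = s$sample_sd)
      }, numeric(2)),
    rmsd_expt_fit = rmsd(r2(res$theta_expt), r2(res$theta_fit)),
    mape_p = mape(res$p_observed_unknown, res$p_fit,
                  denominator = mape_denominator))
  if (table_id == "categorization") {
    for (ft in c("W", "N")) {
      sel <- fx$face_type == ft
      summary[[paste0("rmsd_", tolower(ft))]] <-
        rmsd(r2(res$theta_expt[sel]), r2(res$theta_fit[sel]))
      summary[[paste0("mape_", tolower(ft))]] <-
        mape(res$p_observed_unknown[sel], res$p_fit[sel],
             denominator = mape_denominator)
    }
  }
  structure(
    list(table_id = table_id, inputs = inputs, comparison = long,
         results = res, summary = summary,
         n_unexplained = sum(unexplained), warnings = warnings),
    class = "reproduction_report")
}

reproduce_erp_table <- function(fx) {
  withph <- erp_phases(fx)
  rep <- erp_stability_report(fx)
  long <- data.frame(
    study_id = fx$electrode, column = "theta",
    printed = fx$printed_theta_deg,
    recomputed = withph$theta_deg,
    diff = withph$theta_deg - fx$printed_theta_deg,
    stringsAsFactors = FALSE)
  long$match_2dp <- round(long$recomputed, 2) == round(long$printed, 2)
  long$known_exception <- FALSE
  # printed ERP phases derive from unrounded source amplitudes; agreement
  # is judged at 0.6 degrees rather than printed precision
  unexplained <- abs(long$diff) > 0.6
  structure(
    list(table_id = attr(fx, "table_id"), inputs = "printed",
         comparison = long, results = withph,
         summary = list(n_rows = nrow(fx), phase_cv = rep$phase_cv,
                        amplitude_cv = rep$amplitude_cv,
                        phase_mean = rep$phases$mean,
                        phase_sample_sd = rep$phases$sample_sd,
                        phase_most_stable = rep$phase_most_stable),
         n_unexplained = sum(unexplained),
         warnings = character()),
    class = "reproduction_report")
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat(sprintf("<reproduction report: %s (%s inputs)>\n", x$table_id,
              x$inputs))
  n_cells <- nrow(x$comparison)
  cat(sprintf("  %d cells compared; %d match at printed precision; %d unexplained\n",
              n_cells, sum(x$comparison$match_2dp), x$n_unexplained))
  if (any(x$comparison$known_exception))
    cat(sprintf("  known exceptions: %d cell(s)\n",
                sum(x$comparison$known_exception)))
  if (!is.null(x$summary$rmsd_expt_fit))
    cat(sprintf("  RMSD(theta_expt, theta_fit) = %.2f deg;  MAPE = %.3f\n",
                x$summary$rmsd_expt_fit, x$summary$mape_p))
  if (!is.null(x$summary$phase_cv))
    cat(sprintf("  phase CV = %.2f;  amplitude CV = %s\n",
                x$summary$phase_cv,
                paste(sprintf("%.2f", x$summary$amplitude_cv),
                      collapse = " / ")))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
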