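#' Interference phase from an ERP amplitude triplet
#'
#' Treats the mean ERP amplitude evoked by a neutral-valence stimulus class
#' as the superposition of the waves evoked by a positive and a negative
#' class. With intensity proportional to amplitude squared (the
#' proportionality constant cancels), the phase difference between the two
#' interfering waves is
#' \deqn{\cos\theta = \frac{A_{neutral}^2 - A_{pos}^2 - A_{neg}^2}
#'       {2 A_{pos} A_{neg}}}
#' The extracted phase is invariant to any common rescaling of the three
#' amplitudes, so attenuation between source and electrode does not affect
#' it. Amplitudes are magnitudes; component polarity (N270 vs P300) is not
#' interpreted.
#'
#' @param amplitude_pos,amplitude_neg,amplitude_neutral mean amplitudes in
#'   microvolts (non-negative; `amplitude_pos` and `amplitude_neg` strictly
#'   positive). Vectorized.
#' @return A `phase_result` data frame (see [invert_phase()]).
#' @examples
#' erp_phase(7.93, 4.6, 5.19)  # about 141.5 degrees
#' @export
erp_phase <- function(amplitude_pos, amplitude_neg, amplitude_neutral) {
  check_nonneg(amplitude_pos, "amplitude_pos")
  check_nonneg(amplitude_neg, "amplitude_neg")
  check_nonneg(amplitude_neutral, "amplitude_neutral")
  if (any(amplitude_pos == 0) || any(amplitude_neg == 0))
    stop("phase is undefined when a component amplitude is zero",
         call. = FALSE)
  invert_phase(amplitude_neutral^2, amplitude_pos^2, amplitude_neg^2)
}

#' Phases for a table of electrodes
#'
#' @param triplets data frame with columns `electrode`, `amplitude_pos`,
#'   `amplitude_neg`, `amplitude_neutral` (extra columns are kept).
#' @return The input with `theta_deg`, `raw_cosine`, `clamped` appended.
#' @export
erp_phases <- function(triplets) {
  needed <- c("amplitude_pos", "amplitude_neg", "amplitude_neutral")
  if (!all(needed %in% names(triplets)))
    stop("electrode table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  ph <- erp_phase(triplets$amplitude_pos, triplets$amplitude_neg,
                  triplets$amplitude_neutral)
  cbind(triplets, ph)
}

#' Phase-versus-amplitude stability across electrodes
#'
#' The model predicts that, while ERP amplitudes vary substantially across
#' scalp locations, the interference phase extracted from each electrode's
#' triplet is nearly constant. This report compares the coefficient of
#' variation (sample SD / mean) of the derived phases against the CV of each
#' amplitude column.
#'
#' @param triplets electrode data frame as in [erp_phases()], at least 2 rows.
#' @return A list: `n`, `phases` (a [summarize_phases()] summary),
#'   `phase_cv`, `amplitude_cv` (named length-3 vector), and
#'   `phase_most_stable` (`TRUE` when the phase CV is below every amplitude
#'   CV).
#' @export
erp_stability_report <- function(triplets) {
  if (nrow(triplets) < 2L)
    stop("at least 2 electrodes are required", call. = FALSE)
  withph <- erp_phases(triplets)
  phase_sum <- summarize_phases(withph$theta_deg)
  amp_cv <- vapply(
    withph[c("amplitude_pos", "amplitude_neg", "amplitude_neutral")],
    function(x) stats::sd(x) / mean(x), numeric(1))
  structure(
    list(n = nrow(triplets), phases = phase_sum, phase_cv = phase_sum$cv,
         amplitude_cv = amp_cv,
         phase_most_stable = phase_sum$cv < min(amp_cv)),
    class = "erp_stability_report")
}

#' @export
print.erp_stability_report <- function(x, ...) {
  cat(sprintf("<ERP stability report, %d electrodes>\n", x$n))
  cat(sprintf("  phase: %.2f +/- %.2f deg  (CV = %.2f)\n",
              x$phases$mean, x$phases$sample_sd, x$phase_cv))
  cat(sprintf("  amplitude CV: %s\n",
              paste(sprintf("%s %.2f", sub("amplitude_", "", names(x$amplitude_cv)),
                            x$amplitude_cv), collapse = ", ")))
  cat(if (x$phase_most_stable)
    "  phase is more stable than every amplitude column\n"
    else "  phase CV is NOT below every amplitude CV\n")
  invisible(x)
}

#' Read an electrode amplitude table
#'
#' Comma-separated, header mandatory; columns `electrode`, `amplitude_pos`,
#' `amplitude_neg`, `amplitude_neutral` plus free-text metadata columns.
#'
#' @param path file path.
#' @return A data frame.
#' @export
read_erp_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("electrode", "amplitude_pos", "amplitude_neg",
              "amplitude_neutral")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("electrode file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}
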