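#' Intensity of superposed waves
#'
#' Combines any number of equal-frequency wave components, each given by an
#' intensity (squared amplitude, or a probability standing in for one) and a
#' phase, into the intensity of their superposition:
#' \deqn{I = \sum_i I_i + 2 \sum_{j>i} \sqrt{I_j I_i}\,\cos(\theta_j - \theta_i)}
#' which equals the squared modulus of the complex phasor sum
#' \eqn{\sum_i \sqrt{I_i}\, e^{i\theta_i}}.
#'
#' @param intensity numeric vector of non-negative intensities, one per
#'   component.
#' @param phase_deg numeric vector of phases in degrees, same length as
#'   `intensity`.
#' @return A single non-negative number, the resultant intensity.
#' @examples
#' resultant_intensity(c(0.5, 0.5), c(0, 0))    # fully constructive: 2
#' resultant_intensity(c(0.3, 0.3), c(0, 180))  # fully destructive: 0
#' @export
resultant_intensity <- function(intensity, phase_deg) {
  if (length(intensity) < 1L || length(intensity) != length(phase_deg))
    stop("`intensity` and `phase_deg` must be non-empty vectors of equal length",
         call. = FALSE)
  if (!is.numeric(intensity) || !is.numeric(phase_deg) || anyNA(intensity) ||
      anyNA(phase_deg))
    stop("`intensity` and `phase_deg` must be numeric and free of NA",
         call. = FALSE)
  if (any(intensity < 0))
    stop("intensities must be non-negative", call. = FALSE)
  a <- sqrt(intensity)
  rad <- phase_deg * pi / 180
  total <- sum(intensity)
  n <- length(a)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      total <- total + sum(2 * a[j] * a[i] * cos(rad[j] - rad[i]))
    }
  }
  # superposition of non-negative intensities; clip tiny negative round-off
  max(total, 0)
}

#' Two-wave interference probability
#'
#' The two-component interference law
#' \eqn{p = p_1 + p_2 + 2\sqrt{p_1 p_2}\cos\theta}. At \eqn{\theta = 90°} the
#' interference term vanishes and the classical law of total probability is
#' recovered. The raw value is returned even when it falls outside
#' \eqn{[0, 1]}; use [in_unit_interval()] to flag such values. The law is not
#' a normalized probability rule and no renormalization is applied.
#'
#' @param p1,p2 non-negative numerics (probabilities or joint probabilities).
#' @param theta_deg phase difference in degrees.
#' @return Numeric, the (possibly out-of-range) combined value. Vectorized.
#' @seealso [invert_phase()] for the inverse operation.
#' @examples
#' two_wave_probability(0.345, 0.285, 106.89)  # 0.4478
#' two_wave_probability(0.3, 0.4, 90)          # exactly 0.7
#' @export
two_wave_probability <- function(p1, p2, theta_deg) {
  check_nonneg(p1, "p1")
  check_nonneg(p2, "p2")
  p1 + p2 + 2 * sqrt(p1 * p2) * cos(theta_deg * pi / 180)
}

#' Is a combined value a valid probability?
#'
#' @param p numeric vector.
#' @param tol numerical slack at the boundaries.
#' @return Logical vector, `TRUE` where `p` lies in `[0, 1]`.
#' @export
in_unit_interval <- function(p, tol = 1e-12) {
  p >= -tol & p <= 1 + tol
}

#' Invert the two-wave interference law for the phase
#'
#' Given a combined probability and its two components, recovers the
#' interference-phase difference:
#' \deqn{\cos\theta = \frac{p_{combined} - p_1 - p_2}{2\sqrt{p_1 p_2}}}
#' Cosines outside \eqn{[-1, 1]} — which occur in published tables whenever
#' the printed inputs are rounded — are clamped rather than rejected, and the
#' clamp is flagged so reports can mark those cells. The returned phase lies
#' on the principal arccos branch \eqn{[0°, 180°]}.
#'
#' @param p_combined numeric, the combined (unknown-condition or joint)
#'   probability.
#' @param p1,p2 strictly positive component probabilities.
#' @return A `phase_result` data frame with columns `theta_deg`, `raw_cosine`
#'   and `clamped`, one row per input. Vectorized over all three arguments.
#' @examples
#' invert_phase(0.38, 0.345, 0.285)      # 113.49 degrees
#' invert_phase(0.0768, 0.6228, 0.16)    # clamped, 180 degrees
#' @export
invert_phase <- function(p_combined, p1, p2) {
  check_nonneg(p1, "p1")
  check_nonneg(p2, "p2")
  if (any(p1 == 0) || any(p2 == 0))
    stop("phase is undefined when a component probability is zero",
         call. = FALSE)
  if (!is.numeric(p_combined) || anyNA(p_combined))
    stop("`p_combined` must be numeric and free of NA", call. = FALSE)
  raw <- (p_combined - p1 - p2) / (2 * sqrt(p1 * p2))
  clamped <- abs(raw) > 1
  theta <- acos(pmax(-1, pmin(1, raw))) * 180 / pi
  phase_result(theta, raw, clamped)
}

phase_result <- function(theta_deg, raw_cosine, clamped) {
  structure(
    data.frame(theta_deg = theta_deg, raw_cosine = raw_cosine,
               clamped = clamped),
    class = c("phase_result", "data.frame")
  )
}

#' @export
print.phase_result <- function(x, ...) {
  cat("<interference phase>\n")
  df <- data.frame(theta_deg = round(x$theta_deg, 2),
                   raw_cosine = signif(x$raw_cosine, 6),
                   clamped = x$clamped)
  print.data.frame(df, row.names = nrow(df) > 1L)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || anyNA(x))
    stop(sprintf("`%s` must be numeric and free of NA", name), call. = FALSE)
  if (any(x < 0))
    stop(sprintf("`%s` must be non-negative", name), call. = FALSE)
  invisible(x)
}

check_prob <- function(x, name, allow_na = FALSE) {
  if (allow_na && length(x) == 1L && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || anyNA(x))
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  if (any(x < 0 | x > 1))
    stop(sprintf("`%s` must lie in [0, 1] (got %s)", name,
                 paste(format(x[x < 0 | x > 1]), collapse = ", ")),
         call. = FALSE)
  invisible(x)
}
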