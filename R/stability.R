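#' Mean, sample SD and coefficient of variation
#'
#' The dispersion summary used for phase-stability claims: mean, sample
#' standard deviation (n - 1 denominator) and their ratio (CV). The sample
#' SD is the convention that reproduces the published per-column
#' "mean +/- SD" values and phase CVs.
#'
#' @param values numeric vector, length >= 2 (degrees, probabilities, or any
#'   common unit).
#' @param exclusions optional character vector of ids recorded in the
#'   summary for reporting (the values passed in must already reflect them).
#' @return A `stability_summary` list: `n`, `mean`, `sample_sd`, `cv`,
#'   `exclusions`.
#' @examples
#' summarize_phases(c(134.37, 134.64, 133.80))
#' @export
summarize_phases <- function(values, exclusions = character()) {
  if (!is.numeric(values) || anyNA(values))
    stop("`values` must be numeric and free of NA", call. = FALSE)
  if (length(values) < 2L)
    stop("at least 2 values are required", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  structure(
    list(n = length(values), mean = m, sample_sd = s,
         cv = if (m != 0) s / m else NA_real_,
         exclusions = exclusions),
    class = "stability_summary")
}

#' @export
print.stability_summary <- function(x, ...) {
  cat(sprintf("<stability summary, n = %d>  %.2f +/- %.2f  (CV = %.3f)\n",
              x$n, x$mean, x$sample_sd, x$cv))
  if (length(x$exclusions))
    cat("  excluded:", paste(x$exclusions, collapse = ", "), "\n")
  invisible(x)
}

#' Root-mean-square deviation
#'
#' \eqn{\sqrt{\frac{1}{N}\sum_i (a_i - b_i)^2}} with the population
#' denominator N — the convention that reproduces the published
#' phase-deviation values.
#'
#' @param a,b numeric vectors of equal length (typically experimental and
#'   fitted phases in degrees).
#' @return A single non-negative number.
#' @export
rmsd <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1L)
    stop("`a` and `b` must be non-empty vectors of equal length",
         call. = FALSE)
  sqrt(mean((a - b)^2))
}

#' Mean absolute percentage error
#'
#' \eqn{\frac{1}{N}\sum_i |o_i - f_i| / d_i} where the denominator `d` is by
#' default the fitted value. The fitted-denominator convention is the one
#' that reproduces the published probability-fit errors; the
#' observed-denominator variant is provided because MAPE is conventionally
#' defined against the observation. The statistic is not symmetric in its
#' arguments.
#'
#' @param observed,fitted numeric vectors of equal length.
#' @param denominator `"fitted"` (default) or `"observed"`.
#' @return A single non-negative fraction.
#' @export
mape <- function(observed, fitted, denominator = c("fitted", "observed")) {
  denominator <- match.arg(denominator)
  if (length(observed) != length(fitted) || length(observed) < 1L)
    stop("`observed` and `fitted` must be non-empty vectors of equal length",
         call. = FALSE)
  den <- if (denominator == "fitted") fitted else observed
  if (any(den == 0))
    stop("zero denominator in MAPE", call. = FALSE)
  mean(abs(observed - fitted) / abs(den))
}

#' Probability that n uniform draws cluster in a narrow window
#'
#' How likely is it that n independent draws from a uniform distribution on
#' `[0, domain]` all fall within some window of width `w`? Two readings are
#' provided. `range_exact` is the exact probability that the sample range is
#' at most `w`:
#' \deqn{P(R \le w) = n (w/L)^{n-1} - (n-1)(w/L)^n}
#' `naive_power` is \eqn{(w/L)^n}, the probability that all n draws fall in
#' one prespecified window — an underestimate of the clustering probability,
#' but the reading under which published order-of-magnitude claims were
#' made.
#'
#' @param n number of draws, >= 2.
#' @param width window width, in the same units as `domain`.
#' @param domain length of the uniform support (default 180, for phases on
#'   the arccos branch).
#' @param method `"range_exact"` (default) or `"naive_power"`.
#' @return A probability.
#' @examples
#' uniform_window_probability(5, 36, method = "naive_power")  # 1/3125
#' uniform_window_probability(5, 36)                          # exact, larger
#' @export
uniform_window_probability <- function(n, width, domain = 180,
                                       method = c("range_exact",
                                                  "naive_power")) {
  method <- match.arg(method)
  if (n < 2 || n != round(n))
    stop("`n` must be an integer >= 2", call. = FALSE)
  if (width <= 0 || width > domain)
    stop("`width` must satisfy 0 < width <= domain", call. = FALSE)
  r <- width / domain
  switch(method,
    range_exact = n * r^(n - 1) - (n - 1) * r^n,
    naive_power = r^n)
}
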