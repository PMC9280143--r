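#' Configuration for synthetic experiments
#'
#' Describes a ground-truth scenario for simulation: the paradigm (which
#' fixes the phase-combination rule and focal decision), the true
#' conditional probabilities, the condition marginal, and optionally a
#' per-group sample size for binomial response noise.
#'
#' The generative assumption mirrors the model itself: the true
#' unknown-condition probability is the two-wave prediction at the rule's
#' fitted phase, so in the noise-free limit the experimental phase recovered
#' from a generated scenario equals the fitted phase exactly.
#'
#' @param paradigm paradigm preset (see [binary_scenario()]).
#' @param p_ref_given_pos,p_ref_given_neg true conditional probabilities of
#'   the reference decision.
#' @param p_cond_pos condition marginal (a design constant; it is not
#'   resampled).
#' @param n_subjects subjects per condition group, or `NULL` for noise-free
#'   generation.
#' @param n_replicates number of replicate experiments for
#'   [recovery_experiment()].
#' @param seed integer master seed; replicate r uses an independent
#'   deterministic substream so any replicate is reproducible in isolation.
#' @param rule optional [phase_fit_rule()] overriding the paradigm preset.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(paradigm, p_ref_given_pos, p_ref_given_neg,
                             p_cond_pos = 0.5, n_subjects = NULL,
                             n_replicates = 100L, seed = 1L, rule = NULL) {
  paradigm <- match.arg(paradigm, PARADIGMS)
  check_prob(p_ref_given_pos, "p_ref_given_pos")
  check_prob(p_ref_given_neg, "p_ref_given_neg")
  check_prob(p_cond_pos, "p_cond_pos")
  if (!is.null(n_subjects) &&
      (n_subjects < 1 || n_subjects != round(n_subjects)))
    stop("`n_subjects` must be a positive integer or NULL", call. = FALSE)
  if (n_replicates < 1 || n_replicates != round(n_replicates))
    stop("`n_replicates` must be a positive integer", call. = FALSE)
  if (paradigm == "custom" && is.null(rule))
    stop("paradigm 'custom' requires an explicit `rule`", call. = FALSE)
  if (!is.null(rule) && !inherits(rule, "phase_fit_rule"))
    stop("`rule` must be a phase_fit_rule", call. = FALSE)
  structure(
    list(paradigm = paradigm, p_ref_given_pos = p_ref_given_pos,
         p_ref_given_neg = p_ref_given_neg, p_cond_pos = p_cond_pos,
         n_subjects = if (is.null(n_subjects)) NULL else as.integer(n_subjects),
         n_replicates = as.integer(n_replicates), seed = as.integer(seed),
         rule = rule),
    class = "synthetic_config")
}

config_rule <- function(config, scenario = NULL) {
  if (!is.null(config$rule)) config$rule
  else paradigm_rule(config$paradigm, scenario)
}

#' Ground-truth quantities of a synthetic configuration
#'
#' @param config a [synthetic_config()].
#' @return A list: the noise-free scenario, its cell phases, the rule's
#'   fitted phase (which is also the true experimental phase under the
#'   generative assumption) and the true unknown-condition probability.
#' @export
synthetic_truth <- function(config) {
  s <- binary_scenario("truth", config$paradigm, config$p_cond_pos,
                       config$p_ref_given_pos, config$p_ref_given_neg)
  phases <- known_condition_phases(s)
  theta_fit <- fitted_phase(phases, config_rule(config, s))
  pred <- predict_unknown(s, theta_fit)
  list(scenario = s, phases = phases, theta_fit_deg = theta_fit,
       p_unknown = pred$p_fit, p_unknown_out_of_range = pred$out_of_range)
}

# deterministic per-replicate substream below 2^31
replicate_seed <- function(seed, replicate) {
  (as.double(seed) + 1000003 * as.double(replicate)) %% 2147483647
}

#' Generate one synthetic scenario
#'
#' Noise-free mode (`n_subjects = NULL`): the unknown-condition probability
#' is set to the model's own prediction at the rule's fitted phase, so the
#' round trip through [analyze_scenario()] recovers that phase exactly.
#'
#' Noisy mode: each probability estimated from a subject group — the two
#' conditionals and the unknown-condition probability — is replaced by a
#' binomial sample frequency at `n_subjects` (independent groups, as in the
#' between-subjects source designs). The condition marginal is a design
#' constant and is not resampled.
#'
#' @param config a [synthetic_config()].
#' @param replicate replicate index (selects the random substream).
#' @return A [binary_scenario()].
#' @export
generate_scenario <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- synthetic_truth(config)
  id <- sprintf("synth_%s_r%d", config$paradigm, replicate)
  if (is.null(config$n_subjects)) {
    s <- binary_scenario(id, config$paradigm, config$p_cond_pos,
                         config$p_ref_given_pos, config$p_ref_given_neg,
                         p_focal_unknown = truth$p_unknown)
    return(s)
  }
  n <- config$n_subjects
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(replicate_seed(config$seed, replicate))
  p_unknown_true <- min(max(truth$p_unknown, 0), 1)
  binary_scenario(
    id, config$paradigm, config$p_cond_pos,
    p_ref_given_pos = stats::rbinom(1, n, config$p_ref_given_pos) / n,
    p_ref_given_neg = stats::rbinom(1, n, config$p_ref_given_neg) / n,
    p_focal_unknown = stats::rbinom(1, n, p_unknown_true) / n,
    n_subjects = n)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Phase-recovery experiment under binomial sampling noise
#'
#' Generates `n_replicates` noisy scenarios from the configured truth,
#' recovers the experimental phase and the four cell phases from each, and
#' summarizes recovery: mean, SD, bias against the ground truth, and the
#' fraction of replicates in which any inversion clamped (phases near the
#' 180-degree boundary produce biased recoveries; the clamped fraction is
#' reported, not corrected).
#'
#' A focal conditional of exactly 0 or 1 can make a sampled scenario
#' degenerate (zero focal joint); such replicates are dropped and counted.
#'
#' @param config a [synthetic_config()] with `n_subjects` set.
#' @return A `recovery_summary` list.
#' @export
recovery_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$n_subjects))
    stop("recovery needs noisy mode: set `n_subjects`", call. = FALSE)
  truth <- synthetic_truth(config)
  true_cells <- stats::setNames(truth$phases$theta_deg, truth$phases$cell)
  rows <- vector("list", config$n_replicates)
  dropped <- 0L
  for (r in seq_len(config$n_replicates)) {
    s <- generate_scenario(config, r)
    ok <- tryCatch({
      ph <- known_condition_phases(s)
      ex <- experimental_phase(s)
      rows[[r]] <- c(stats::setNames(ph$theta_deg, ph$cell),
                     theta_expt = ex$theta_deg,
                     clamped = as.numeric(any(ph$clamped) || ex$clamped))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) dropped <- dropped + 1L
  }
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  est <- colMeans(rows[, c(paste0("theta", 1:4), "theta_expt"), drop = FALSE])
  sds <- apply(rows[, c(paste0("theta", 1:4), "theta_expt"), drop = FALSE],
               2, stats::sd)
  true_all <- c(true_cells, theta_expt = truth$theta_fit_deg)
  structure(
    list(config = config, truth = true_all,
         n_used = nrow(rows), n_dropped = dropped,
         mean = est, sd = sds, bias = est - true_all,
         clamped_fraction = mean(rows[, "clamped"])),
    class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("<recovery summary: %s, n_subjects = %d, %d replicates used>\n",
              x$config$paradigm, x$config$n_subjects, x$n_used))
  df <- data.frame(truth = round(x$truth, 2), mean = round(x$mean, 2),
                   bias = round(x$bias, 2), sd = round(x$sd, 2))
  print(df)
  cat(sprintf("  clamped fraction: %.3f;  dropped replicates: %d\n",
              x$clamped_fraction, x$n_dropped))
  invisible(x)
}

#' Read a synthetic configuration from a YAML file
#'
#' Keys mirror the arguments of [synthetic_config()]; a `rule` section with
#' `form` and `cells` builds a [phase_fit_rule()]. A `grid` section may
#' supply vectors for `p_ref_given_pos` / `p_ref_given_neg`; the result is
#' then a list of configs over the grid's cross product.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's.
#' @return A `synthetic_config`, or a list of them for grid files.
#' @export
read_synthetic_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  base <- function(pp, pn) synthetic_config(
    paradigm = y$paradigm,
    p_ref_given_pos = pp, p_ref_given_neg = pn,
    p_cond_pos = if (is.null(y$p_cond_pos)) 0.5 else y$p_cond_pos,
    n_subjects = y$n_subjects,
    n_replicates = if (is.null(y$n_replicates)) 100L else y$n_replicates,
    seed = if (!is.null(seed)) seed else
      if (is.null(y$seed)) 1L else y$seed,
    rule = if (!is.null(y$rule))
      phase_fit_rule(y$rule$form, unlist(y$rule$cells)) else NULL)
  if (!is.null(y$grid)) {
    g <- expand.grid(pp = unlist(y$grid$p_ref_given_pos),
                     pn = unlist(y$grid$p_ref_given_neg))
    return(mapply(base, g$pp, g$pn, SIMPLIFY = FALSE))
  }
  base(y$p_ref_given_pos, y$p_ref_given_neg)
}
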