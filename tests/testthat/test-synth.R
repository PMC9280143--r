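test_that("noise-free generation round-trips the fitted phase exactly", {
  grids <- expand.grid(pp = c(0.35, 0.55, 0.7, 0.85),
                       pn = c(0.3, 0.5, 0.65, 0.8))
  for (paradigm in c("categorization_wide", "categorization_narrow",
                     "gambling", "prisoners_dilemma")) {
    for (i in seq_len(nrow(grids))) {
      cf <- synthetic_config(paradigm, grids$pp[i], grids$pn[i],
                             p_cond_pos = if (startsWith(paradigm, "cat"))
                               0.7 else 0.5)
      truth <- synthetic_truth(cf)
      if (truth$p_unknown_out_of_range) next
      s <- generate_scenario(cf)
      a <- analyze_scenario(s)
      expect_equal(a$theta_expt_deg, a$theta_fit_deg, tolerance = 1e-9)
      expect_equal(a$theta_expt_deg, truth$theta_fit_deg, tolerance = 1e-9)
    }
  }
})

test_that("noise-free example reproduces the first gambling experiment's fit", {
  cf <- synthetic_config("gambling", 0.69, 0.57)
  truth <- synthetic_truth(cf)
  expect_equal(round(truth$theta_fit_deg, 2), 106.89)
  s <- generate_scenario(cf)
  expect_equal(round(s$p_focal_unknown, 4), 0.4478)
})

test_that("generation is deterministic given the seed and leaves the RNG alone", {
  cf <- synthetic_config("gambling", 0.69, 0.57, n_subjects = 100, seed = 7)
  s1 <- generate_scenario(cf, replicate = 3)
  set.seed(999); before <- stats::runif(1)
  set.seed(999)
  s2 <- generate_scenario(cf, replicate = 3)
  expect_identical(s1[c("p_ref_given_pos", "p_ref_given_neg",
                        "p_focal_unknown")],
                   s2[c("p_ref_given_pos", "p_ref_given_neg",
                        "p_focal_unknown")])
  expect_identical(stats::runif(1), before)
  # different replicates draw different samples
  s3 <- generate_scenario(cf, replicate = 4)
  expect_false(identical(s1$p_ref_given_pos, s3$p_ref_given_pos) &&
                 identical(s1$p_focal_unknown, s3$p_focal_unknown))
})

test_that("sampled frequencies converge to the configured probabilities", {
  cf <- synthetic_config("gambling", 0.69, 0.57, n_subjects = 1e6, seed = 2)
  s <- generate_scenario(cf)
  se <- sqrt(0.69 * 0.31 / 1e6)
  expect_lt(abs(s$p_ref_given_pos - 0.69), 3 * se)
  se2 <- sqrt(0.57 * 0.43 / 1e6)
  expect_lt(abs(s$p_ref_given_neg - 0.57), 3 * se2)
})

test_that("phase recovery is unbiased near the truth at moderate samples", {
  cf <- synthetic_config("gambling", 0.69, 0.57, n_subjects = 200,
                         n_replicates = 500, seed = 42)
  rec <- recovery_experiment(cf)
  expect_equal(rec$n_used + rec$n_dropped, 500)
  expect_lt(abs(rec$bias[["theta_expt"]]), 2)
})

test_that("recovery noise shrinks with sample size", {
  small <- recovery_experiment(
    synthetic_config("gambling", 0.69, 0.57, n_subjects = 50,
                     n_replicates = 200, seed = 11))
  big <- recovery_experiment(
    synthetic_config("gambling", 0.69, 0.57, n_subjects = 5000,
                     n_replicates = 200, seed = 11))
  expect_lt(big$sd[["theta_expt"]], small$sd[["theta_expt"]])
})

test_that("recovery bias at n = 10^4 is below bias at n = 10^2 across a conditional grid", {
  grid <- expand.grid(pp = c(0.4, 0.6, 0.8), pn = c(0.35, 0.5, 0.7))
  bias_at <- function(n) {
    mean(vapply(seq_len(nrow(grid)), function(i) {
      rec <- recovery_experiment(
        synthetic_config("gambling", grid$pp[i], grid$pn[i], n_subjects = n,
                         n_replicates = 60, seed = 100 + i))
      abs(rec$bias[["theta_expt"]])
    }, numeric(1)))
  }
  expect_lt(bias_at(1e4), bias_at(1e2))
})

test_that("truths near the clamp boundary report a positive clamped fraction", {
  # prisoner's-dilemma-like conditionals with theta2 at the 180-degree clamp
  cf <- synthetic_config("prisoners_dilemma", 0.90, 0.87, n_subjects = 150,
                         n_replicates = 100, seed = 3)
  truth <- synthetic_truth(cf)
  expect_true(any(truth$phases$clamped))
  rec <- recovery_experiment(cf)
  expect_gt(rec$clamped_fraction, 0)
})

test_that("configs validate and read from YAML", {
  expect_error(synthetic_config("gambling", 1.2, 0.5), "p_ref_given_pos")
  expect_error(synthetic_config("gambling", 0.5, 0.5, n_replicates = 0),
               "positive integer")
  expect_error(synthetic_config("custom", 0.5, 0.5), "rule")
  expect_error(recovery_experiment(synthetic_config("gambling", 0.6, 0.5)),
               "noisy mode")

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("paradigm: gambling", "p_ref_given_pos: 0.69",
               "p_ref_given_neg: 0.57", "n_subjects: 100",
               "n_replicates: 10", "seed: 5"), path)
  cf <- read_synthetic_config(path)
  expect_s3_class(cf, "synthetic_config")
  expect_equal(cf$seed, 5L)
  expect_equal(read_synthetic_config(path, seed = 9)$seed, 9L)

  gridfile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("paradigm: gambling", "n_subjects: 50", "n_replicates: 5",
               "grid:", "  p_ref_given_pos: [0.6, 0.7]",
               "  p_ref_given_neg: [0.4, 0.5]"), gridfile)
  cfs <- read_synthetic_config(gridfile)
  expect_length(cfs, 4)
})
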