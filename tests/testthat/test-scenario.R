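test_that("cell joints follow the law of total probability", {
  s <- wide_face_row()
  cj <- cell_joints(s)
  expect_equal(cj$joint["alternative", "positive"], 0.84 * 0.35)
  expect_equal(unname(cj$p_decision["alternative"]), 0.3772)
  expect_equal(sum(cj$joint), 1)

  g <- gambling_row1()
  cjg <- cell_joints(g)
  expect_equal(cjg$joint["reference", "positive"], 0.345)
  expect_equal(cjg$joint["reference", "negative"], 0.285)

  sure <- binary_scenario("sure", "custom", p_cond_pos = 1,
                          p_ref_given_pos = 0.6, p_ref_given_neg = 0.3)
  expect_equal(unname(cell_joints(sure)$joint[, "negative"]), c(0, 0))
})

test_that("known-condition phases reproduce published cells", {
  ph <- known_condition_phases(gambling_row1())
  expect_equal(round(ph$theta_deg, 2), c(134.37, 146.22, 138.83, 139.59))
  expect_false(any(ph$clamped))

  phw <- known_condition_phases(wide_face_row())
  expect_equal(round(phw$theta_deg[phw$cell == "theta1"], 2), 129.33)
  expect_true(phw$clamped[phw$cell == "theta3"])
  expect_equal(phw$theta_deg[phw$cell == "theta3"], 180)
})

test_that("symmetric scenarios give pairwise-equal phases", {
  s <- binary_scenario("sym", "custom", p_cond_pos = 0.5,
                       p_ref_given_pos = 0.62, p_ref_given_neg = 0.62)
  ph <- known_condition_phases(s)
  th <- stats::setNames(ph$theta_deg, ph$cell)
  expect_identical(th[["theta1"]], th[["theta3"]])
  expect_identical(th[["theta2"]], th[["theta4"]])
})

test_that("swapping conditionals at even condition odds swaps the cell pairs", {
  set.seed(3)
  for (i in 1:20) {
    a <- stats::runif(1, 0.05, 0.95); b <- stats::runif(1, 0.05, 0.95)
    s1 <- binary_scenario("x", "custom", 0.5, a, b)
    s2 <- binary_scenario("x", "custom", 0.5, b, a)
    t1 <- known_condition_phases(s1)$theta_deg
    t2 <- known_condition_phases(s2)$theta_deg
    expect_identical(t1[1], t2[3])
    expect_identical(t1[2], t2[4])
  }
})

test_that("experimental phase matches published values and the classical limit", {
  expect_equal(round(experimental_phase(gambling_row1())$theta_deg, 2), 113.49)
  expect_equal(round(experimental_phase(wide_face_row())$theta_deg, 2), 87.65)
  # observing exactly the decision marginal means zero interference
  g <- gambling_row1()
  g$p_focal_unknown <- 0.5 * 0.69 + 0.5 * 0.57
  expect_equal(experimental_phase(g)$theta_deg, 90)
  g$p_focal_unknown <- NA_real_
  expect_error(experimental_phase(g), "no observed")
})

test_that("fitted phase follows the paradigm presets", {
  phw <- known_condition_phases(wide_face_row())
  tf <- fitted_phase(phw, paradigm_rule("categorization_wide"))
  expect_equal(round(tf, 2), 85.58)

  phg <- known_condition_phases(gambling_row1())
  expect_equal(round(fitted_phase(phg, paradigm_rule("gambling")), 2), 106.89)

  # prisoner's dilemma with a clamped theta2 collapses to 90 degrees
  pd3 <- binary_scenario("pd_3", "prisoners_dilemma", 0.5, 0.90, 0.87, 0.87)
  a <- analyze_scenario(pd3)
  expect_true(a$phases$clamped[a$phases$cell == "theta2"])
  expect_equal(a$theta_fit_deg, 90)
  expect_equal(round(a$p_fit, 2), 0.88)

  expect_error(paradigm_rule("custom"), "no preset")
  expect_error(phase_fit_rule("sum_complement", "theta1"), "must name 2")
  custom <- phase_fit_rule("half_complement", "theta4")
  expect_equal(fitted_phase(phg, custom),
               (360 - phg$theta_deg[phg$cell == "theta4"]) / 2)
})

test_that("min-conditional strategy picks the riskiest cell", {
  # here the riskiest (lowest-probability) choice is the theta2 cell: same fit
  g <- gambling_row1()
  expect_identical(paradigm_rule("gambling", g, "min_conditional")$cells,
                   "theta2")
  # reference conditionals below 0.5 move the riskiest choice to theta1
  g2 <- binary_scenario("g2", "gambling", 0.5, 0.30, 0.45)
  expect_identical(paradigm_rule("gambling", g2, "min_conditional")$cells,
                   "theta1")
  expect_error(paradigm_rule("categorization_wide", g, "min_conditional"),
               "disjunction")
})

test_that("predicted probability matches published fits and the classical limit", {
  g <- gambling_row1()
  expect_equal(round(predict_unknown(g, 106.89)$p_fit, 2), 0.45)
  w <- wide_face_row()
  expect_equal(round(predict_unknown(w, 85.58)$p_fit, 2), 0.40)
  cj <- cell_joints(w)
  expect_equal(predict_unknown(w, 90)$p_fit,
               unname(cj$p_decision["alternative"]))
})

test_that("full analysis chains the pipeline and reports residuals", {
  # conditionals as the source fractions (22/30, 20/30) behind the printed
  # 0.73 / 0.67 row
  pd1 <- binary_scenario("pd_1", "prisoners_dilemma", 0.5,
                         22 / 30, 20 / 30, 18 / 30)
  a <- analyze_scenario(pd1)
  expect_equal(round(a$theta_fit_deg, 2), 105.30)
  expect_equal(a$residual_deg, -7.07, tolerance = 0.01)
  expect_lt(a$residual_deg, 0)

  lowrate <- binary_scenario("gam_9", "gambling", 0.5, 0.30, 0.24, 0.17)
  ak <- analyze_scenario(lowrate)
  expect_equal(round(ak$p_fit, 2), 0.17)

  # prediction-only mode
  noobs <- binary_scenario("pred", "gambling", 0.5, 0.69, 0.57)
  ap <- analyze_scenario(noobs)
  expect_true(is.na(ap$theta_expt_deg))
  expect_false(is.na(ap$theta_fit_deg))
  expect_false(is.na(ap$p_fit))
})

test_that("prediction and inversion are self-consistent over the focal joints", {
  set.seed(21)
  for (i in 1:50) {
    s <- binary_scenario("rt", "gambling", 0.5,
                         stats::runif(1, 0.2, 0.9), stats::runif(1, 0.2, 0.9))
    th <- stats::runif(1, 60, 150)
    p <- predict_unknown(s, th)$p_fit
    jf <- cell_joints(s)$joint["reference", ]
    expect_equal(invert_phase(p, jf[[1]], jf[[2]])$theta_deg, th,
                 tolerance = 1e-9)
  }
})

test_that("scenario tables round-trip through CSV and reject bad rows", {
  scens <- list(gambling_row1(),
                binary_scenario("pred_only", "prisoners_dilemma", 0.5,
                                0.8, 0.7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_scenarios(scens, path)
  back <- read_scenarios(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$p_ref_given_pos, 0.69)
  expect_true(is.na(back[[2]]$p_focal_unknown))
  expect_identical(analyze_scenario(back[[1]])$theta_fit_deg,
                   analyze_scenario(scens[[1]])$theta_fit_deg)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study_id,paradigm,p_cond_pos,p_ref_given_pos,p_ref_given_neg",
               "b1,gambling,0.5,1.2,0.4"), bad)
  expect_error(read_scenarios(bad), "row 1.*p_ref_given_pos")
  incomplete <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study_id,p_cond_pos", "x,0.5"), incomplete)
  expect_error(read_scenarios(incomplete), "lacks column")
})

test_that("scenario constructor validates inputs", {
  expect_error(binary_scenario("x", "gambling", 0.5, 1.01, 0.5),
               "p_ref_given_pos")
  expect_error(binary_scenario("x", "nonsense", 0.5, 0.5, 0.5))
  expect_error(binary_scenario("x", "gambling", 0.5, 0.5, 0.5,
                               n_subjects = 2.5), "positive integer")
})
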