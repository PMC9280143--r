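# shared fixtures built in code

# first wide-face categorization row: p(attack|good)=0.35, p(attack|bad)=0.52,
# p(good)=0.84, observed p(attack|D-alone)=0.39
wide_face_row <- function() {
  binary_scenario("wide_1", "categorization_wide",
                  p_cond_pos = 0.84,
                  p_ref_given_pos = 1 - 0.35,
                  p_ref_given_neg = 1 - 0.52,
                  p_focal_unknown = 0.39)
}

# first two-stage gambling experiment: p(again|win)=0.69, p(again|lose)=0.57,
# even first-stage odds, observed p(again|unknown)=0.38
gambling_row1 <- function() {
  binary_scenario("gam_1", "gambling",
                  p_cond_pos = 0.5,
                  p_ref_given_pos = 0.69,
                  p_ref_given_neg = 0.57,
                  p_focal_unknown = 0.38)
}

# independent complex-phasor oracle for the superposition intensity
phasor_intensity <- function(intensity, phase_deg) {
  Mod(sum(sqrt(intensity) * exp(1i * phase_deg * pi / 180)))^2
}

cell_theta <- function(scenario, cell) {
  ph <- known_condition_phases(scenario)
  ph$theta_deg[ph$cell == cell]
}
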