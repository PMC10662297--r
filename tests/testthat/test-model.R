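test_that("the base-case bundle validates and enumerates the published topology", {
  bc <- base_case()
  for (arm in bc$arms) {
    expect_length(validate_model(arm, bc$costs, bc$profiles), 0)
  }
  paths <- enumerate_paths(bc$arms[["X-ray/IMA"]])
  expect_equal(nrow(paths), 6) # loose{surgery,other}, not-loose, uncertain x3
  expect_equal(sum(paths$probability), 1, tolerance = 1e-9)
  # uncertain -> IMA loose -> surgery: 0.15 x 0.3 x 0.75
  p_ima_surgery <- paths$probability[grepl("uncertain.*loose > surgery",
                                           paths$path)]
  expect_equal(p_ima_surgery, 0.03375, tolerance = 1e-12)
})

test_that("validation reports, rather than raises, broken inputs", {
  bc <- base_case()
  bad_node <- chance_node("initial_xray", list(
    branch("a", 0.7, terminal_state("a", "X-ray", "other_treatment")),
    branch("b", 0.7, terminal_state("b", "X-ray", "other_treatment"))
  ))
  v <- validate_model(pathway_model("bad", bad_node), bc$costs, bc$profiles)
  expect_match(v, "sum to 1.4", all = FALSE)

  dangling <- pathway_model("dangling", chance_node("n", list(
    branch("a", 1, terminal_state("a", c("Gold plating"), "no_such_profile"))
  )))
  v <- validate_model(dangling, bc$costs, bc$profiles)
  expect_match(v, "unknown cost component", all = FALSE)
  expect_match(v, "unknown HRQoL profile", all = FALSE)

  v <- validate_model(pathway_model("h", dangling$root, horizon_years = 1),
                      bc$costs, bc$profiles)
  expect_false(any(grepl("horizon", v)))
  expect_error(pathway_model("h", dangling$root, horizon_years = 0))
})

test_that("a single-branch tree yields one path with probability 1", {
  leaf <- terminal_state("only", c("X-ray", "Surgery"), "immediate_surgery")
  m <- pathway_model("trivial", chance_node("root", list(branch("go", 1, leaf))))
  paths <- enumerate_paths(m)
  expect_equal(nrow(paths), 1)
  expect_equal(paths$probability, 1)
  ev <- evaluate_arm(m, fixture_costs, fixture_profiles)
  expect_equal(ev$expected_cost,
               unname(fixture_costs["X-ray"] + fixture_costs["Surgery"]))
  expect_equal(ev$expected_qaly,
               trapezoid_qaly(fixture_profiles$immediate_surgery))
})

test_that("evaluation agrees with the backward-induction oracle on random trees", {
  set.seed(2024)
  for (i in 1:40) {
    m <- pathway_model(paste0("rand", i), random_tree())
    expect_length(validate_model(m, fixture_costs, fixture_profiles), 0)
    paths <- enumerate_paths(m)
    expect_equal(sum(paths$probability), 1, tolerance = 1e-9)
    ev <- evaluate_arm(m, fixture_costs, fixture_profiles)
    orc <- oracle_expectation(m$root, fixture_costs, fixture_profiles)
    expect_equal(ev$expected_cost, unname(orc["cost"]), tolerance = 1e-9)
    expect_equal(ev$expected_qaly, unname(orc["qaly"]), tolerance = 1e-9)
    expect_true(ev$expected_qaly >= 0 && ev$expected_qaly <= m$horizon)
  }
})

test_that("expected cost scales linearly with the cost table; QALYs do not move", {
  set.seed(7)
  m <- pathway_model("scale", random_tree())
  base <- evaluate_arm(m, fixture_costs, fixture_profiles)
  for (k in c(0, 0.5, 3)) {
    scaled_costs <- fixture_costs * k
    class(scaled_costs) <- class(fixture_costs)
    ev <- evaluate_arm(m, scaled_costs, fixture_profiles)
    expect_equal(ev$expected_cost, k * base$expected_cost, tolerance = 1e-9)
    expect_identical(ev$expected_qaly, base$expected_qaly)
  }
})

test_that("with identical terminal profiles both arms return identical QALYs", {
  bc <- base_case()
  flat <- lapply(bc$profiles, function(...) bc$profiles$other_treatment)
  q <- vapply(bc$arms, function(arm) {
    evaluate_arm(arm, bc$costs, flat)$expected_qaly
  }, numeric(1))
  expect_equal(unname(q[1]), unname(q[2]), tolerance = 1e-12)
  expect_equal(unname(q[1]), trapezoid_qaly(bc$profiles$other_treatment),
               tolerance = 1e-12)
})

test_that("unresolvable components or profiles are configuration errors", {
  m <- pathway_model("bad", chance_node("n", list(
    branch("a", 1, terminal_state("a", "Gold plating", "other_treatment"))
  )))
  expect_error(evaluate_arm(m, fixture_costs, fixture_profiles),
               "unknown cost component")
  m2 <- pathway_model("bad2", chance_node("n", list(
    branch("a", 1, terminal_state("a", "X-ray", "no_such"))
  )))
  expect_error(evaluate_arm(m2, fixture_costs, fixture_profiles),
               "unknown HRQoL profile")
})
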