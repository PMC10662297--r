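test_that("the four base-case trajectories integrate to their published QALYs", {
  # generating assumptions -> knot utilities -> trapezoid integral
  cases <- list(
    list(traj = make_linear_plateau(0.62, 0.8, 18),
         knots = c(0.68, 0.74, 0.80, 0.80), qaly = 1.465),
    list(traj = make_linear_decline(0.62, 0.0528),
         knots = c(0.5672, 0.5144, 0.4616, 0.4088), qaly = 1.0288),
    list(traj = make_delayed_surgery(0.62, 0.0528, 12, 0.8),
         knots = c(0.5672, 0.5144, 0.6308, 0.7472), qaly = 1.198),
    list(traj = make_constant_level(0.62, 0.65),
         knots = c(0.65, 0.65, 0.65, 0.65), qaly = 1.2925)
  )
  for (case in cases) {
    expect_equal(case$traj$utilities, c(0.62, case$knots), tolerance = 1e-12)
    expect_equal(trapezoid_qaly(case$traj), case$qaly, tolerance = 1e-12)
  }
})

test_that("trapezoid integration handles constants and extremes exactly", {
  perfect <- hrqol_trajectory(c(0, 6, 12, 18, 24), rep(1, 5))
  expect_identical(trapezoid_qaly(perfect), 2)
  for (u in c(0, 0.37, 0.62, 1)) {
    const <- hrqol_trajectory(c(0, 6, 12, 18, 24), rep(u, 5))
    expect_equal(trapezoid_qaly(const), u * 2, tolerance = 1e-15)
  }
})

test_that("constructors cover early plateau, zero slope, floor and delay variants", {
  # plateau already reached at the first knot
  expect_equal(make_linear_plateau(0.62, 0.8, 6)$utilities,
               c(0.62, 0.8, 0.8, 0.8, 0.8))
  # zero slope collapses to the baseline
  expect_equal(make_linear_plateau(0.62, 0.62, 18)$utilities, rep(0.62, 5))
  expect_equal(make_linear_decline(0.62, 0)$utilities, rep(0.62, 5))
  # decline floors at zero
  expect_equal(make_linear_decline(0.10, 0.0528)$utilities,
               c(0.10, 0.0472, 0, 0, 0), tolerance = 1e-12)
  # no pre-surgery decline: linear rise to the unadjusted ceiling
  expect_equal(make_delayed_surgery(0.62, 0, 12, 0.8)$utilities,
               c(0.62, 0.62, 0.62, 0.71, 0.80), tolerance = 1e-12)
  # surgery at the horizon degenerates to the pure decline
  expect_warning(
    deg <- make_delayed_surgery(0.62, 0.0528, 24, 0.8),
    "pure decline"
  )
  expect_equal(deg$utilities, make_linear_decline(0.62, 0.0528)$utilities)
})

test_that("invalid trajectories and parameters are rejected", {
  expect_error(hrqol_trajectory(c(0, 6), c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(hrqol_trajectory(c(6, 12), c(0.5, 0.5)), "month 0")
  expect_error(hrqol_trajectory(c(0, 12, 6), c(0.5, 0.5, 0.5)), "increasing")
  expect_error(make_linear_plateau(0.62, 0.8, 0), "plateau_month")
  expect_error(make_linear_decline(0.62, -0.01), ">= 0")
  expect_error(make_delayed_surgery(0.62, 0.0528, 7, 0.8), "knot grid")
  expect_error(make_delayed_surgery(0.62, 0.3, 12, 0.1), "ceiling")
})

test_that("trapezoid rule matches fine-grid integration and is monotone", {
  set.seed(101)
  for (i in 1:25) {
    u <- runif(5)
    traj <- hrqol_trajectory(c(0, 6, 12, 18, 24), u)
    # fine grid including the knots: exact for a piecewise-linear profile
    grid <- sort(unique(c(traj$times, seq(0, 24, length.out = 721))))
    ug <- approx(traj$times, traj$utilities, xout = grid)$y
    fine <- sum(diff(grid) / 12 * (head(ug, -1) + tail(ug, -1)) / 2)
    expect_equal(trapezoid_qaly(traj), fine, tolerance = 1e-9)
    # pointwise-higher trajectory never integrates lower
    lift <- pmin(1, u + runif(5, 0, 0.3))
    expect_gte(trapezoid_qaly(hrqol_trajectory(traj$times, lift)),
               trapezoid_qaly(traj))
  }
})

test_that("profiles rebuild from their stored generating spec", {
  for (traj in hrqol_profiles()) {
    spec <- attr(traj, "spec")
    expect_false(is.null(spec))
    rebuilt <- build_profile(spec)
    expect_equal(rebuilt$utilities, traj$utilities, tolerance = 1e-15)
  }
  expect_error(build_profile(list(type = "nope")), "unknown profile type")
})
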