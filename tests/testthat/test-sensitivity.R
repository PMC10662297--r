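bc <- base_case()

test_that("override targets edit probabilities, costs and utilities in place", {
  b <- apply_overrides(bc, list(
    "prob:initial_xray" = c(8, 1, 1), # renormalised to sum to 1
    "cost:Surgery" = 200000,
    "utility:immediate_surgery:plateau" = 0.9
  ))
  p <- vapply(b$arms[[1]]$root$branches, `[[`, numeric(1), "p")
  expect_equal(p, c(0.8, 0.1, 0.1), tolerance = 1e-12)
  # shared label: the comparator arm moved too
  p2 <- vapply(b$arms[[2]]$root$branches, `[[`, numeric(1), "p")
  expect_equal(p2, p)
  expect_equal(unname(b$costs["Surgery"]), 200000)
  expect_equal(max(b$profiles$immediate_surgery$utilities), 0.9)

  expect_error(apply_overrides(bc, list("prob:no_such_node" = c(1, 1))),
               "resolves to no chance node")
  expect_error(apply_overrides(bc, list("cost:Gold plating" = 1)),
               "resolves to no cost component")
  expect_error(apply_overrides(bc, list("utility:nope:baseline" = 0.5)),
               "resolves to no rebuildable")
  expect_error(apply_overrides(bc, list("banana" = 1)), "malformed target")
})

test_that("PSA with point distributions reproduces the base case bit-for-bit", {
  ev <- evaluate_bundle(bc)
  dists <- list(
    param_distribution("cost:Surgery", "point",
                       value = unname(bc$costs["Surgery"])),
    param_distribution("prob:initial_xray", "point",
                       value = c(0.7, 0.15, 0.15))
  )
  psa <- run_psa(bc, dists, n = 10, seed = 99)
  base_dc <- ev$comparison$delta_cost
  base_de <- ev$comparison$delta_effect
  expect_identical(unique(psa$draws$delta_cost), base_dc)
  expect_identical(unique(psa$draws$delta_effect), base_de)
  expect_equal(unname(psa$summary$quadrant_shares["NE"]), 1)
})

test_that("PSA is reproducible under a fixed seed and stable across seeds", {
  a <- run_psa(bc, n = 200, seed = 5)
  b <- run_psa(bc, n = 200, seed = 5)
  expect_identical(a$draws, b$draws)
  c_ <- run_psa(bc, n = 200, seed = 6)
  expect_false(identical(a$draws, c_$draws))
  # summaries agree within 3 Monte-Carlo standard errors of a share
  se3 <- 3 * sqrt(0.25 / 200)
  expect_lt(abs(a$summary$share_effect_positive -
                c_$summary$share_effect_positive), se3 + 1e-12)
})

test_that("Dirichlet draws recover their base probabilities in the mean", {
  d <- param_distribution("prob:initial_xray", "dirichlet",
                          alpha = 11 * c(0.7, 0.15, 0.15))
  draws <- withr::with_seed(31, t(replicate(10000,
                                            imacea:::draw_distribution(d))))
  expect_equal(colMeans(draws), c(0.7, 0.15, 0.15), tolerance = 0.01)
  expect_equal(rowSums(draws), rep(1, 10000), tolerance = 1e-12)
})

test_that("gamma cost draws keep the base mean through the model", {
  dists <- list(param_distribution("cost:Surgery", "gamma",
                                   mean = unname(bc$costs["Surgery"]),
                                   cv = 0.3))
  psa <- run_psa(bc, dists, n = 1500, seed = 17)
  base_cost <- evaluate_bundle(bc)$arms$expected_cost[1]
  # surgery enters the intervention arm with path weight 0.55875
  se3 <- 3 * sd(psa$draws$cost_intervention) / sqrt(psa$n)
  expect_lt(abs(mean(psa$draws$cost_intervention) - base_cost), se3)
})

test_that("BC bootstrap matches an independently coded oracle on a fixed stream", {
  x <- c(1, 2, 3, 4, 5)
  for (seed in c(1, 42, 2024)) {
    ci <- bc_bootstrap_ci(x, mean, n_boot = 1000, level = 0.95, seed = seed)
    expect_equal(as.numeric(ci), oracle_bc_bootstrap(x, 1000, 0.95, seed),
                 tolerance = 1e-12)
  }
  skewed <- withr::with_seed(99, rexp(40)^2)
  ci <- bc_bootstrap_ci(skewed, mean, n_boot = 500, seed = 7)
  expect_equal(as.numeric(ci), oracle_bc_bootstrap(skewed, 500, 0.95, 7),
               tolerance = 1e-12)
})

test_that("BC bootstrap degenerate and near-symmetric cases behave", {
  expect_identical(as.numeric(bc_bootstrap_ci(rep(3.3, 10), seed = 1)),
                   c(3.3, 3.3))
  expect_error(bc_bootstrap_ci(numeric(0)), "empty sample")
  # large symmetric sample: bias term ~0, interval ~plain percentile
  x <- withr::with_seed(8, rnorm(500))
  ci <- bc_bootstrap_ci(x, mean, n_boot = 2000, seed = 12)
  expect_lt(abs(attr(ci, "z0")), 0.1)
  set.seed(12)
  idx <- matrix(sample.int(500, 500 * 2000, replace = TRUE), nrow = 2000)
  stats_b <- apply(idx, 1, function(i) mean(x[i]))
  pct <- quantile(stats_b, c(0.025, 0.975), names = FALSE)
  expect_equal(as.numeric(ci), pct, tolerance = 0.02)
  expect_gte(ci["lower"], min(stats_b))
  expect_lte(ci["upper"], max(stats_b))
})

test_that("BCa acceleration reduces to BC when switched off and stays ordered", {
  x <- withr::with_seed(3, rgamma(30, 2, 0.5))
  bca <- bc_bootstrap_ci(x, mean, n_boot = 1000, seed = 4,
                         accelerated = TRUE)
  bc_ <- bc_bootstrap_ci(x, mean, n_boot = 1000, seed = 4)
  expect_false(identical(as.numeric(bca), as.numeric(bc_)))
  expect_identical(attr(bc_, "acceleration"), 0)
  expect_lte(bca["lower"], bca["upper"])
})

test_that("scenario engine: identity, empty list, skipping, and monotone effect", {
  expect_equal(nrow(one_way_scenarios(bc, list())), 0)

  base <- evaluate_bundle(bc)$comparison
  tbl <- one_way_scenarios(bc, list(list(id = "base", overrides = list())))
  expect_equal(tbl$delta_cost, base$delta_cost, tolerance = 1e-12)
  expect_equal(tbl$delta_effect, base$delta_effect, tolerance = 1e-12)
  expect_equal(tbl$icer, base$icer, tolerance = 1e-12)

  # raising the loosening rate found at follow-up raises the incremental
  # effect monotonically (more delayed-vs-immediate surgery contrast)
  shares <- c(0.1, 0.3, 0.5, 0.8)
  scens <- lapply(shares, function(s) {
    list(id = paste0("s", s),
         overrides = list("prob:ima_followup" = c(s, 1 - s),
                          "prob:xray_followup" = c(s, 1 - s)))
  })
  tbl <- one_way_scenarios(bc, scens)
  expect_equal(nrow(tbl), 4)
  expect_true(all(diff(tbl$delta_effect) > 0))

  # an invalid override is skipped with a report, not fatal
  tbl <- one_way_scenarios(bc, list(
    list(id = "ok", overrides = list()),
    list(id = "broken", overrides = list("prob:initial_xray" = c(-1, 1, 1)))
  ))
  expect_equal(tbl$id, "ok")
  expect_match(attr(tbl, "skipped"), "broken", all = FALSE)
})

test_that("the shipped scenario catalogue runs end to end", {
  scens <- load_scenarios(system.file("extdata", "scenarios_default.yaml",
                                      package = "imacea"))
  expect_equal(vapply(scens, `[[`, character(1), "id"),
               paste0(1:8, "P"))
  tbl <- one_way_scenarios(bc, scens)
  expect_equal(nrow(tbl), 8)
  expect_length(attr(tbl, "skipped"), 0)
  expect_true(all(is.finite(tbl$icer)))
})

test_that("tornado bars are exactly linear in cost components and sorted", {
  # analytic path weight of a component = sum over paths of
  # probability x number of occurrences
  arm <- bc$arms[[1]]
  paths <- enumerate_paths(arm)
  weight <- function(cmp) {
    sum(paths$probability *
          vapply(paths$components, function(x) sum(x == cmp), numeric(1)))
  }
  ranges <- list(
    "cost:Surgery" = list(100000, 200000),
    "cost:IMA" = list(4500, 18000),
    "cost:X-ray" = list(1029, 1029) # zero width, must sort last
  )
  tt <- tornado(bc, ranges, output = "cost", arm = arm$label)
  expect_equal(tt$parameter[1], "cost:Surgery")
  expect_equal(tt$parameter[3], "cost:X-ray")
  expect_equal(tt$width[tt$parameter == "cost:Surgery"],
               weight("Surgery") * 100000, tolerance = 1e-9)
  expect_equal(tt$width[tt$parameter == "cost:IMA"],
               weight("IMA") * 13500, tolerance = 1e-9)
  expect_equal(tt$width[tt$parameter == "cost:X-ray"], 0)
  expect_true(all(diff(tt$width) <= 0))

  expect_error(tornado(bc, list("cost:Surgery" = list(2, 1))), "low > high")
})

test_that("tornado on QALYs ranks the immediate-surgery utility as influential", {
  tt <- tornado(bc, default_tornado_ranges(bc, "qaly"), output = "qaly")
  expect_true(grepl("immediate_surgery|other_treatment", tt$parameter[1]))
  expect_equal(attr(tt, "output"), "qaly")
  expect_true(all(tt$width >= 0))
})
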