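test_that("single-species FBA reproduces the closed-form growth rates", {
  fx <- toy3_fixture()
  expect_equal(fba_single(fx$models$A, fx$diet)$growth, 0.4,
               tolerance = 1e-9)
  expect_equal(fba_single(fx$models$B, fx$diet)$growth, 0,
               tolerance = 1e-9)
  expect_equal(fba_single(fx$models$C, fx$diet)$growth, 0.3,
               tolerance = 1e-9)
})

test_that("feasible_at_mu separates feasible from infeasible growth", {
  cm <- toy3_cm()
  expect_gte(feasible_at_mu(cm, 0.2)$total, 1)
  expect_lt(feasible_at_mu(cm, 0.5)$total, 1)
  # mu = 0 without maintenance: any simplex abundance works (degenerate)
  expect_gte(feasible_at_mu(cm, 0)$total, 1)
})

test_that("bisection finds the toy3 optima and abundance structure", {
  sol <- toy3_opt()
  expect_lt(abs(sol$mu - 0.4), 1e-6 + 1e-9)
  expect_equal(unname(sol$abundances["A"]), 1, tolerance = 1e-6)
  expect_equal(sol$sum_p, 1, tolerance = 1e-9)

  cm <- toy3_cm()
  ab <- cm$abundance_bounds
  ab["A", 2] <- 0.5
  sol2 <- maximize_community_growth(cm, ab)
  expect_lt(abs(sol2$mu - 0.3), 1e-6 + 1e-9)
  expect_lte(sol2$abundances[["A"]], 0.5 + 1e-9)
})

test_that("a community that cannot meet maintenance fails at mu = 0", {
  fx <- toy3_fixture()
  models <- lapply(fx$models, set_atpm, 10)
  empty <- diet_spec("none", c(G = 0))
  cm <- build_community(models, empty, fx$policy)
  expect_error(maximize_community_growth(cm), "mu = 0")
})

test_that("feasibility is monotone decreasing in growth rate", {
  cm <- toy8_cm()
  mus <- seq(0.05, 0.6, by = 0.05)
  feas <- vapply(mus, function(mu)
    feasible_at_mu(cm, mu)$total >= 1 - 1e-9, logical(1))
  # once infeasible, stays infeasible
  expect_lte(sum(rle(feas)$values), 1)
})

test_that("tightening abundance bounds never increases maximal growth", {
  cm <- toy8_cm()
  mu0 <- toy8_opt()$mu
  set.seed(3)
  for (rep in 1:4) {
    ab <- cm$abundance_bounds
    ab[, 2] <- runif(nrow(ab), 0.3, 1)
    mu1 <- maximize_community_growth(cm, ab)$mu
    expect_lte(mu1, mu0 + 1e-6)
    ab2 <- ab
    ab2[, 2] <- ab[, 2] * runif(nrow(ab), 0.5, 1)
    if (sum(ab2[, 2]) < 1.05) next  # keep the community feasible
    mu2 <- maximize_community_growth(cm, ab2)$mu
    expect_lte(mu2, mu1 + 1e-6)
  }
})

test_that("accepted solutions satisfy all conservation invariants", {
  cm <- toy3_cm()
  expect_silent(check_solution(cm, toy3_opt()))
  ab <- cm$abundance_bounds
  ab["A", 2] <- 0.5
  expect_silent(check_solution(cm, maximize_community_growth(cm, ab)))
  cm8 <- toy8_cm()
  expect_silent(check_solution(cm8, toy8_opt()))
})

test_that("single-species profile reports obligate crossfeeders and SCFAs", {
  cm <- toy3_cm()
  prof <- single_species_profile(cm)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$growth[prof$species == "B"], 0, tolerance = 1e-9)
  # blocked SCFA-analog P can only be secreted
  expect_true(all(prof$P >= -1e-9, na.rm = TRUE))
  # 1-species community: byproduct secretion equals community exchange
  only_a <- restrict_species(cm, "A")
  sol <- maximize_community_growth(only_a)
  expect_equal(sol$exchange[["M"]],
               sol$fluxes[["A:EX_M"]], tolerance = 1e-9)
})

test_that("ATPM tuning hits the target growth rate as a fixed point", {
  fx <- toy3_fixture()
  r <- tune_atpm(fx$models$A, fx$diet, target_mu = 0.2)
  expect_true(r$attained)
  expect_equal(fba_single(set_atpm(fx$models$A, r$atpm), fx$diet)$growth,
               0.2, tolerance = 1e-6)

  # unattainable target: species C maxes out at 0.3
  r2 <- tune_atpm(fx$models$C, fx$diet, target_mu = 0.5)
  expect_false(r2$attained)
  expect_equal(r2$atpm, 0)

  # target 0: the largest maintenance flux the diet can support
  r3 <- tune_atpm(fx$models$A, fx$diet, target_mu = 0)
  expect_equal(r3$growth, 0, tolerance = 1e-6)
  expect_equal(r3$atpm, 10, tolerance = 1e-4)  # full energy supply
})
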