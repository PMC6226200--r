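test_that("closed-form toy growth rates match FBA to solver precision", {
  for (fx in list(toy3_fixture(), toy8_fixture())) {
    for (def in fx$defs) {
      m <- fx$models[[def$id]]
      cf <- toy_growth_closed_form(def, fx$diet)
      r <- fba_single(m, fx$diet, on_infeasible = "na")
      if (is.na(cf)) expect_true(is.na(r$growth)) else
        expect_equal(r$growth, cf, tolerance = 1e-9,
                     label = paste("fba growth for", def$id))
    }
  }
})

test_that("every generated model passes species-model validation", {
  for (fx in list(toy3_fixture(), toy8_fixture())) {
    for (m in fx$models) {
      expect_s3_class(m, "species_model")
      expect_true(m$biomass_id %in% m$rxns$id)
      expect_true(m$atpm_id %in% m$rxns$id)
      expect_gt(length(m$exchange_ids), 0)
    }
  }
})

test_that("the documented toy3 facts hold computationally", {
  facts <- toy3_facts()
  expect_lt(abs(toy3_opt()$mu - facts$mu_max), 1e-6 + 1e-9)
  expect_equal(unname(toy3_opt()$abundances),
               unname(facts$abundances_at_max), tolerance = 1e-6)
  fx <- toy3_fixture()
  expect_equal(fba_single(fx$models$B, fx$diet)$growth,
               facts$b_single_growth, tolerance = 1e-9)
})

test_that("toy8 exhibits the required structural features", {
  fx <- toy8_fixture()
  solo <- vapply(fx$models, function(m)
    fba_single(m, fx$diet, on_infeasible = "na")$growth, numeric(1))
  # two obligate crossfeeders with zero single-species growth
  expect_equal(unname(solo[c("S5", "S6")]), c(0, 0), tolerance = 1e-9)
  # one species whose ATP maintenance exactly consumes its energy supply
  expect_equal(atpm_value(fx$models$S8), 10)
  expect_equal(unname(solo["S8"]), 0, tolerance = 1e-9)
  # heterogeneous growth rates with a clear fastest specialist
  expect_equal(unname(solo["S1"]), 0.5, tolerance = 1e-9)
  expect_gt(length(unique(round(solo, 6))), 4)
  # three tagged SCFA analogs with distinct producer sets
  scfa <- fx$policy$scfa_ids
  producers <- lapply(scfa, function(met)
    names(Filter(function(m) met %in% exchange_mets(m), fx$models)))
  expect_length(unique(producers), 3)
  expect_true(all(scfa[c("butyrate", "propionate")] %in%
                  fx$policy$blocked_uptake_ids))
})

test_that("maximal toy8 growth concentrates on few species", {
  expect_lt(richness(toy8_opt()$abundances), 8)
})

test_that("cyclic crossfeeding topologies are rejected unless flagged", {
  defs <- list(
    toy_species_def("X", c(G = 10, M2 = 5), yield = 0.04,
                    byproducts = c(M1 = 1)),
    toy_species_def("Y", c(M1 = 5), yield = 0.04,
                    byproducts = c(M2 = 1)))
  diet <- diet_spec("d", c(G = 10))
  expect_error(
    toy_community_spec(defs, diet, crossfed_ids = c("M1", "M2")),
    "cyclic")
  spec <- toy_community_spec(defs, diet, crossfed_ids = c("M1", "M2"),
                             cyclic_ok = TRUE)
  expect_s3_class(spec, "toy_community_spec")
})

test_that("a spec without a primary-substrate importer is invalid", {
  defs <- list(toy_species_def("X", c(M = 10), yield = 0.04))
  expect_error(
    toy_community_spec(defs, diet_spec("d", c(G = 10)), crossfed_ids = "M"),
    "primary substrate")
})

test_that("equal yields without crossfeeding give a degenerate optimum", {
  defs <- lapply(c("U", "V", "W"), function(id)
    toy_species_def(id, c(G = 10), yield = 0.04))
  spec <- toy_community_spec(defs, diet_spec("d", c(G = 10)),
                             crossfed_ids = character(0))
  fx <- make_toy_community(spec)
  cm <- build_community(fx$models, fx$diet, fx$policy)
  sol <- maximize_community_growth(cm)
  expect_lt(abs(sol$mu - 0.4), 1e-6 + 1e-9)  # common solo rate
  res <- abundance_fva(cm, 1.0, sol$mu)
  expect_equal(res$table$p_min, c(0, 0, 0), tolerance = 1e-4)
  expect_equal(res$table$p_max, c(1, 1, 1), tolerance = 1e-4)
})

test_that("fixture sets are written once per format and reload cleanly", {
  d <- withr::local_tempdir()
  write_fixture_set(d)
  xmls <- list.files(d, pattern = "\\.xml$")
  jsons <- list.files(d, pattern = "\\.json$")
  expect_length(xmls, 11)  # 3 + 8 species
  expect_length(jsons, 11)
  for (p in file.path(d, xmls))
    expect_s3_class(load_species_model(p), "species_model")
  expect_s3_class(load_diet(file.path(d, "toy_western.tsv")), "diet_spec")
  sched <- utils::read.delim(file.path(d, "schedule_reduced.tsv"))
  expect_equal(sum(sched$n_cases), 90)

  # deterministic: writing again yields identical files
  d2 <- withr::local_tempdir()
  write_fixture_set(d2)
  for (fn in xmls)
    expect_identical(readLines(file.path(d, fn)),
                     readLines(file.path(d2, fn)))
})
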