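test_that("species_model validates its invariants with named errors", {
  mets <- data.frame(id = c("E", "G"), compartment = c("c", "e"))
  rx <- function(...) list(...)
  base <- list(
    rx(id = "EX_G", stoich = c(G = -1), lb = -10, ub = 1000),
    rx(id = "CAT", stoich = c(G = -1, E = 1), lb = 0, ub = 1000),
    rx(id = "BIOMASS_X", stoich = c(E = -20), lb = 0, ub = 1000),
    rx(id = "ATPM_X", stoich = c(E = -1), lb = 0, ub = 1000))
  expect_s3_class(species_model("X", mets, base), "species_model")

  bad <- base
  bad[[2]]$stoich <- c(G = -1, Q = 1)
  expect_error(species_model("X", mets, bad), "undeclared metabolite 'Q'")

  bad <- base
  bad[[1]]$lb <- 5
  bad[[1]]$ub <- -5
  expect_error(species_model("X", mets, bad), "inverted bounds")

  expect_error(species_model("X", mets, base[-3]), "biomass")
  expect_error(species_model("X", mets, base[-4]), "ATPM")

  bad <- base
  bad[[1]]$stoich <- c(G = -2)
  expect_error(species_model("X", mets, bad), "must be -1")
})

test_that("diet tables load, reject invalid rows, and round-trip", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("metabolite_id\tmax_uptake", "glc\t10", "o2\t0"), p)
  d <- load_diet(p)
  expect_length(d$max_uptake, 2)
  expect_equal(d$max_uptake[["glc"]], 10)

  writeLines(c("metabolite_id\tmax_uptake", "glc\t-1"), p)
  expect_error(load_diet(p), ">= 0")

  writeLines(c("metabolite_id\tmax_uptake", "glc\t10", "glc\t5"), p)
  expect_error(load_diet(p), "duplicate")

  writeLines(c("metabolite_id\tmax_uptake", "glc\tten"), p)
  expect_error(load_diet(p), "malformed")

  d <- diet_spec("x", c(a = 1.23456789012345, b = 0))
  write_diet(d, p)
  d2 <- load_diet(p)
  expect_identical(d2$max_uptake, d$max_uptake)
})

test_that("an empty diet plus maintenance forbids growth", {
  fx <- toy3_fixture()
  m <- set_atpm(fx$models$A, 10)
  empty <- diet_spec("none", stats::setNames(numeric(0), character(0)))
  r <- fba_single(m, empty, on_infeasible = "na")
  expect_identical(r$status, "infeasible")
  expect_error(fba_single(m, empty), "maintenance")
  # without maintenance the model is feasible at zero growth instead
  expect_equal(fba_single(fx$models$A, empty)$growth, 0, tolerance = 1e-9)
})

test_that("SBML and JSON serializations reload field-identically", {
  d <- withr::local_tempdir()
  for (fx in list(toy3_fixture(), toy8_fixture())) {
    for (m in fx$models) {
      px <- file.path(d, paste0(m$species_id, ".xml"))
      pj <- file.path(d, paste0(m$species_id, ".json"))
      write_species_sbml(m, px)
      write_species_json(m, pj)
      a1 <- load_species_model(px)
      a2 <- load_species_model(pj, format = "json")
      for (a in list(a1, a2)) {
        expect_identical(a$species_id, m$species_id)
        expect_identical(a$S, m$S)
        expect_identical(a$rxns, m$rxns)
        expect_identical(a$biomass_id, m$biomass_id)
        expect_identical(a$atpm_id, m$atpm_id)
        expect_setequal(a$exchange_ids, m$exchange_ids)
      }
      # both formats agree with each other field by field
      expect_identical(a1$S, a2$S)
      expect_identical(a1$rxns, a2$rxns)
    }
  }
})

test_that("unparseable model files raise parse errors", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines("<not-sbml>", p)
  expect_error(load_species_model(p), "parse")
  expect_error(load_species_model("no/such/file.xml"), "not found")
})

test_that("crossfeed_policy rejects overlapping blocked and crossfed sets", {
  expect_error(crossfeed_policy(c("a", "b"), blocked_uptake_ids = "a"),
               "overlap")
  expect_error(crossfeed_policy("a", crossfeed_uptake_bound = -1))
  p <- crossfeed_policy("a", scfa_ids = c(acetate = "x", butyrate = "y",
                                          propionate = "z"))
  expect_identical(p$scfa_ids[["butyrate"]], "y")
})

test_that("case tables round-trip at 12 significant digits", {
  camp <- toy8_campaign()
  df <- as.data.frame(camp)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_case_table(camp, p)
  back <- read_case_table(p)
  expect_equal(nrow(back), nrow(df))
  acc <- df$accepted
  expect_equal(signif(back$equitability[acc], 12),
               signif(df$equitability[acc], 12))
  # serialization identity: rereading what was written is lossless
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_case_table(back, p2)
  expect_identical(readLines(p), readLines(p2))
  expect_error(write_case_table(df[0, ], p), "empty")
})

test_that("a single-species campaign row parses with richness 1", {
  cm <- toy3_cm()
  sol <- maximize_community_growth(cm)  # A-monoculture optimum
  expect_equal(richness(sol$abundances), 1L)
  p <- withr::local_tempfile(fileext = ".json")
  write_solution_json(sol, p)
  back <- read_solution_json(p)
  expect_equal(back$abundances, sol$abundances, tolerance = 1e-12)
  expect_equal(back$mu, sol$mu, tolerance = 0)
})
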