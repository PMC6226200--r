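test_that("community construction counts species blocks and exchanges", {
  cm <- toy3_cm()
  expect_identical(cm$species, c("A", "B", "C"))
  # shared extracellular metabolites G, M, P -> one community exchange each
  expect_setequal(cm$lumen_mets, c("G", "M", "P"))
  expect_length(cm$lp$ie, 3)
  # community uptake bound: diet rate for G, 0 otherwise; secretion capped
  expect_equal(unname(cm$lp$lower[cm$lp$ie["G"]]), -10)
  expect_equal(unname(cm$lp$lower[cm$lp$ie["M"]]), 0)
  expect_equal(unname(cm$lp$upper[cm$lp$ie]), rep(1000, 3))
})

test_that("blocked metabolites cannot be consumed but secretion is free", {
  cm <- toy3_cm()
  for (tpl in cm$templates) {
    exm <- exchange_mets(tpl)
    for (r in names(exm)) {
      if (exm[[r]] == "P") {
        i <- match(r, tpl$rxns$id)
        expect_gte(tpl$rxns$lb[i], 0)
        expect_gt(tpl$rxns$ub[i], 0)
      }
    }
  }
})

test_that("crossfed uptake allowances are raised, never lowered", {
  cm <- toy3_cm()
  b <- cm$templates$B
  i <- match("EX_M", b$rxns$id)
  expect_equal(b$rxns$lb[i], -10)  # crossfeed bound
})

test_that("intracellular rows touch exactly one species block", {
  cm <- toy8_cm()
  A <- cm$lp$A
  iV <- cm$lp$iV
  sp_of_col <- sub(":.*$", "", names(iV))
  for (rn in grep(":", rownames(A), value = TRUE)) {
    if (startsWith(rn, "lumen:")) next
    nz <- which(A[rn, seq_along(iV)] != 0)
    if (!length(nz)) next
    expect_length(unique(sp_of_col[nz]), 1)
  }
})

test_that("a diet metabolite unknown to every species is rejected", {
  fx <- toy3_fixture()
  bad <- diet_spec("bad", c(G = 10, unobtainium = 5))
  expect_error(build_community(fx$models, bad, fx$policy), "unobtainium")
})

test_that("duplicate species ids are rejected", {
  fx <- toy3_fixture()
  expect_error(build_community(list(fx$models$A, fx$models$A), fx$diet,
                               fx$policy), "duplicate species")
})

test_that("single-species community growth equals standalone FBA", {
  for (fx in list(toy3_fixture(), toy8_fixture())) {
    cm <- build_community(fx$models, fx$diet, fx$policy)
    for (sp in cm$species) {
      solo <- fba_single(fx$models[[sp]], fx$diet, on_infeasible = "na")
      sub <- restrict_species(cm, sp)
      com <- tryCatch(maximize_community_growth(sub), error = function(e) e)
      if (is.na(solo$growth)) {
        # maintenance unmeetable alone in either formulation
        expect_true(inherits(com, "error") || com$mu < 1e-6)
      } else {
        expect_false(inherits(com, "error"))
        expect_lt(abs(com$mu - solo$growth), 2e-6,
                  label = paste("community mu for", sp))
      }
    }
  }
})

test_that("keep-all restriction is the identity and modes agree", {
  cm <- toy3_cm()
  same <- restrict_species(cm, cm$species)
  expect_identical(same$abundance_bounds, cm$abundance_bounds)

  soft <- restrict_species(cm, c("A", "B"), mode = "soft")
  hard <- restrict_species(cm, c("A", "B"), mode = "hard")
  mu_soft <- maximize_community_growth(soft)$mu
  mu_hard <- maximize_community_growth(hard)$mu
  expect_equal(mu_soft, mu_hard, tolerance = 1e-6)

  expect_error(restrict_species(cm, "Z"), "unknown species")
})

test_that("keeping only one toy3 species recovers its solo growth", {
  cm <- toy3_cm()
  only_a <- restrict_species(cm, "A")
  expect_lt(abs(maximize_community_growth(only_a)$mu - 0.4), 2e-6)
})

test_that("raising crossfeed uptake bounds never decreases growth", {
  fx <- toy3_fixture()
  mus <- vapply(c(0.5, 2, 10), function(bnd) {
    pol <- crossfeed_policy("M", crossfeed_uptake_bound = bnd,
                            blocked_uptake_ids = "P")
    cm <- build_community(fx$models, fx$diet, pol)
    ab <- cm$abundance_bounds
    ab["A", 2] <- 0.4  # force reliance on crossfeeding
    maximize_community_growth(cm, ab)$mu
  }, numeric(1))
  expect_true(all(diff(mus) >= -1e-6))
})
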