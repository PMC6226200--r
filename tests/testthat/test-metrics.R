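test_that("equitability spans monoculture to even community", {
  p <- c(1, rep(0, 27))
  expect_equal(equitability(p), 1 / 28, tolerance = 1e-12)
  expect_equal(equitability(rep(1 / 28, 28)), 1, tolerance = 1e-12)
  expect_equal(equitability(c(0.5, 0.3, 0.2)), (1 / 3) / 0.38,
               tolerance = 1e-12)
  expect_error(equitability(c(0, 0, 0)), "all-zero")
  expect_error(equitability(c(0.5, 0.2)), "sum to 1")
})

test_that("SCFA fractions normalize net secretion and flag degeneracy", {
  mk <- function(net) structure(list(exchange = net),
                                class = "community_solution")
  ids <- c(acetate = "ace", butyrate = "but", propionate = "ppa")
  fr <- scfa_fractions(mk(c(ace = 9.1, but = 0, ppa = 0.9)), ids)
  expect_equal(as.vector(fr), c(0.91, 0, 0.09), tolerance = 1e-12)
  expect_true(attr(fr, "defined"))

  fr0 <- scfa_fractions(mk(c(ace = 0, but = 0, ppa = 0)), ids)
  expect_false(attr(fr0, "defined"))
  expect_true(all(is.na(fr0)))

  fre <- scfa_fractions(mk(c(ace = 2, but = 2, ppa = 2)), ids)
  expect_equal(as.vector(fre), rep(1 / 3, 3), tolerance = 1e-12)

  expect_error(scfa_fractions(mk(c(ace = 1, but = -0.5, ppa = 0)), ids),
               "negative net")
})

test_that("crossfeed reports conserve mass against community exchange", {
  cm <- toy3_cm()
  # single-species community: the only exchanger carries the whole flux
  only_a <- restrict_species(cm, "A")
  sol_a <- maximize_community_growth(only_a)
  rep1 <- crossfeed_report(cm, sol_a, crossfed_ids = "M")
  expect_equal(dim(rep1$matrix), c(3, 1))
  expect_equal(rep1$matrix["A", "M"], sol_a$exchange[["M"]],
               tolerance = 1e-9)
  expect_equal(unname(rep1$net["M"]), sol_a$exchange[["M"]],
               tolerance = 1e-9)

  # secretion by A and uptake by B net out to the community exchange
  ab <- cm$abundance_bounds
  ab["A", 2] <- 0.5
  sol <- maximize_community_growth(cm, ab)
  rep2 <- crossfeed_report(cm, sol, crossfed_ids = "M")
  expect_equal(unname(rep2$net["M"]), sol$exchange[["M"]],
               tolerance = 1e-8)
})

test_that("crossfed metabolite ranking is deterministic under ties", {
  fake <- structure(list(matrix = matrix(c(2, 3, 1, 1, 1, 1),
                                         nrow = 2, byrow = TRUE,
                                         dimnames = list(c("s1", "s2"),
                                                         c("zz", "aa",
                                                           "mm")))),
                    class = "crossfeed_report")
  # totals: zz = 3, aa = 4, mm = 2 -> aa, zz, mm
  expect_identical(rank_crossfed(fake, 3), c("aa", "zz", "mm"))
  fake$matrix[, "zz"] <- c(1, 1)  # tie zz with mm -> lexical order
  expect_identical(rank_crossfed(fake, 3), c("aa", "mm", "zz"))
  expect_identical(rank_crossfed(fake, 0), character(0))
})

test_that("toy3 ranks its only crossfed metabolite first", {
  cm <- toy3_cm()
  ab <- cm$abundance_bounds
  ab["A", 2] <- 0.5
  sol <- maximize_community_growth(cm, ab)
  rp <- crossfeed_report(cm, sol)
  expect_identical(rank_crossfed(rp, 1), "M")
})

test_that("binning assigns half-open bins and flags out-of-range cases", {
  df <- data.frame(accepted = TRUE,
                   growth_fraction = c(0.79, 0.70, 0.799999, 0.80, 1.0),
                   richness = c(5, 3, 6, 7, 1),
                   equitability = c(0.5, 0.4, 0.55, 0.6, 0.125),
                   scfa_acetate = 1, scfa_butyrate = 0,
                   scfa_propionate = 0)
  bs <- bin_cases(df)
  at <- function(center) which.min(abs(bs$center - center))
  expect_equal(bs$n[at(0.79)], 2)  # 0.79 and 0.799999
  expect_equal(bs$n[at(0.81)], 1)  # 0.80 starts the next bin
  expect_equal(bs$n[at(0.71)], 1)  # 0.70 sits on the first bin edge
  expect_equal(attr(bs, "out_of_range"), 1)  # 1.0 beyond the last bin
  expect_equal(bs$richness_mean[at(0.79)], 5.5)
})

test_that("binned summaries are invariant to case order", {
  camp <- toy8_campaign()
  df <- as.data.frame(camp)
  b1 <- bin_cases(df)
  b2 <- bin_cases(df[rev(seq_len(nrow(df))), ])
  expect_equal(as.data.frame(b1), as.data.frame(b2))
})

test_that("tradeoff line fit recovers exact and degenerate patterns", {
  df <- data.frame(accepted = TRUE,
                   growth_fraction = seq(0.6, 0.95, by = 0.05),
                   equitability = 1 - seq(0.6, 0.95, by = 0.05))
  fit <- fit_tradeoff_line(df)
  expect_equal(fit$slope, -1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  df$equitability <- 0.5
  fit2 <- fit_tradeoff_line(df)
  expect_equal(fit2$slope, 0, tolerance = 1e-9)

  expect_error(fit_tradeoff_line(df[1:2, ]), "at least 3")
  df3 <- df
  df3$growth_fraction <- 0.8
  expect_error(fit_tradeoff_line(df3), "variance")
})

test_that("presence fractions count threshold exceedance per species", {
  df <- data.frame(accepted = c(TRUE, TRUE, TRUE, FALSE),
                   p_A = c(0.5, 0.9, 0.2, 0.0),
                   p_B = c(0.005, 0.0, 0.02, 1.0),
                   p_C = c(0, 0, 0, 0))
  pf <- presence_fraction(df)
  expect_equal(unname(pf), c(1, 1 / 3, 0))
  expect_named(pf, c("A", "B", "C"))
  expect_error(presence_fraction(df[df$p_C > 1, ]), "no accepted")
})

test_that("toy8 campaign keeps the capped specialist present throughout", {
  pf <- presence_fraction(toy8_campaign())
  # S1 is the fastest primary-substrate consumer: every accepted case
  # includes it above threshold
  expect_equal(unname(pf["S1"]), 1)
})

test_that("rank correlation recovers monotone and null relationships", {
  x <- 1:10
  r1 <- abundance_growth_correlation(x, x * 2 + 1, n_perm = 200,
                                     seed = 1)
  expect_equal(r1$rho, 1)
  expect_lt(r1$p_value, 0.05)
  r2 <- abundance_growth_correlation(x, -x, n_perm = 200, seed = 1)
  expect_equal(r2$rho, -1)
  expect_error(abundance_growth_correlation(rep(1, 10), x), "constant")

  # null calibration: independent draws rarely reach significance
  set.seed(2024)
  hits <- 0L
  for (i in 1:60) {
    a <- runif(28)
    g <- runif(28)
    r <- abundance_growth_correlation(a, g, n_perm = 300)
    if (r$p_value > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 54)  # >= 90% of replicates stay null
})
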