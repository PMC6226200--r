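# Fixture communities and derived results are expensive enough to share
# across test files; everything is deterministic, so caching is safe.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache))
    assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

toy3_cm <- function() cached("toy3_cm", {
  fx <- toy3_fixture()
  build_community(fx$models, fx$diet, fx$policy)
})

toy8_cm <- function() cached("toy8_cm", {
  fx <- toy8_fixture()
  build_community(fx$models, fx$diet, fx$policy)
})

toy3_opt <- function() cached("toy3_opt",
  maximize_community_growth(toy3_cm()))

toy8_opt <- function() cached("toy8_opt",
  maximize_community_growth(toy8_cm()))

toy8_fva <- function() cached("toy8_fva", {
  mu <- toy8_opt()$mu
  lv <- campaign_schedule()$f
  out <- lapply(lv, function(f) abundance_fva(toy8_cm(), f, mu))
  names(out) <- as.character(lv)
  out
})

toy8_campaign <- function() cached("toy8_campaign",
  run_campaign(toy8_cm(), toy8_opt()$mu, toy8_fva(),
               reduced_schedule(10L), master_seed = 1L))
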