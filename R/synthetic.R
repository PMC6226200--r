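#' Define one toy species
#'
#' Toy species use a deliberately simple metabolic architecture chosen so
#' that single-species growth rates have a closed form: one internal energy
#' currency metabolite `E`, one catabolic reaction per substrate
#' (substrate -> energy + byproducts), a lumped biomass reaction consuming
#' energy, an ATPM energy drain, and exchange reactions for every
#' extracellular metabolite touched.  With substrate uptakes `u_s`
#' (mmol/gDW/h), energy yields `q_s` (E per substrate), biomass energy cost
#' `q_primary / yield` and maintenance `a`, the maximal growth rate is
#' `mu = (sum_s q_s u_s - a) * yield / q_primary`, or infeasible when the
#' energy supply cannot cover maintenance.
#'
#' @param id species label.
#' @param substrates named numeric vector of uptake capacities
#'   (extracellular metabolite -> mmol/gDW/h); the first entry is the
#'   primary substrate defining the biomass yield scale.
#' @param yield biomass yield on the primary substrate (gDW/mmol).
#' @param byproducts named numeric vector of secretion stoichiometries per
#'   unit substrate catabolized (same for every substrate).
#' @param atpm non-growth ATP maintenance (mmol/gDW/h of energy drain).
#' @param e_yield energy per unit substrate; scalar or named per substrate.
#' @return A `toy_species_def` list.
#' @export
toy_species_def <- function(id, substrates, yield, byproducts = NULL,
                            atpm = 0, e_yield = 1) {
  stopifnot(length(substrates) >= 1L, !is.null(names(substrates)),
            yield > 0, atpm >= 0, all(substrates > 0))
  if (length(e_yield) == 1L && is.null(names(e_yield)))
    e_yield <- stats::setNames(rep(e_yield, length(substrates)),
                               names(substrates))
  stopifnot(all(names(substrates) %in% names(e_yield)),
            all(e_yield > 0))
  structure(list(id = id, substrates = substrates, yield = yield,
                 byproducts = byproducts, atpm = atpm,
                 e_yield = e_yield[names(substrates)]),
            class = "toy_species_def")
}

#' Closed-form single-species growth rate of a toy species
#'
#' @param def a [toy_species_def()].
#' @param diet a [diet_spec()].
#' @return Growth rate in 1/h, or `NA` when maintenance cannot be met.
#' @export
toy_growth_closed_form <- function(def, diet) {
  up <- vapply(names(def$substrates), function(m) {
    rate <- if (m %in% names(diet$max_uptake)) diet$max_uptake[[m]] else 0
    min(def$substrates[[m]], rate)
  }, numeric(1))
  supply <- sum(def$e_yield * up)
  if (supply < def$atpm - 1e-12) return(NA_real_)
  cost <- def$e_yield[[1L]] / def$yield
  (supply - def$atpm) / cost
}

# materialize a toy_species_def as a species_model
.toy_model <- function(def) {
  E <- paste0("E_", def$id)
  ex_mets <- unique(c(names(def$substrates), names(def$byproducts)))
  mets <- data.frame(id = c(E, ex_mets),
                     compartment = c("c", rep("e", length(ex_mets))))
  rxns <- list()
  for (m in ex_mets) {
    cap <- if (m %in% names(def$substrates)) def$substrates[[m]] else 0
    rxns[[length(rxns) + 1L]] <-
      list(id = paste0("EX_", m), stoich = stats::setNames(-1, m),
           lb = -cap, ub = 1000)
  }
  for (m in names(def$substrates)) {
    st <- c(stats::setNames(-1, m), stats::setNames(def$e_yield[[m]], E))
    if (length(def$byproducts))
      st <- c(st, def$byproducts)
    rxns[[length(rxns) + 1L]] <-
      list(id = paste0("CAT_", m, "_", def$id), stoich = st,
           lb = 0, ub = 1000)
  }
  cost <- def$e_yield[[1L]] / def$yield
  rxns[[length(rxns) + 1L]] <-
    list(id = paste0("BIOMASS_", def$id),
         stoich = stats::setNames(-cost, E), lb = 0, ub = 1000)
  rxns[[length(rxns) + 1L]] <-
    list(id = paste0("ATPM_", def$id),
         stoich = stats::setNames(-1, E), lb = def$atpm, ub = 1000)
  species_model(def$id, mets, rxns)
}

#' Toy community specification
#'
#' Bundles species definitions with a diet and crossfeeding policy and
#' validates the structural assumptions the analyses rely on: positive
#' yields, at least one species importing the primary substrate, and an
#' acyclic crossfeeding topology (metabolite-level consumption/production
#' graph) unless cycles are explicitly allowed.
#'
#' @param species list of [toy_species_def()] objects.
#' @param diet a [diet_spec()].
#' @param crossfed_ids,blocked_uptake_ids,scfa_ids passed to
#'   [crossfeed_policy()].
#' @param crossfeed_uptake_bound per-species crossfed uptake bound.
#' @param primary_substrate id of the diet-supplied primary substrate.
#' @param cyclic_ok allow cyclic crossfeeding topologies.
#' @param seed integer seed recorded for generators that randomize fields.
#' @return A `toy_community_spec`.
#' @export
toy_community_spec <- function(species, diet, crossfed_ids,
                               blocked_uptake_ids = character(0),
                               scfa_ids = NULL,
                               crossfeed_uptake_bound = 10,
                               primary_substrate = "G",
                               cyclic_ok = FALSE, seed = 1L) {
  stopifnot(length(species) >= 1L,
            all(vapply(species, inherits, logical(1), "toy_species_def")))
  ids <- vapply(species, function(s) s$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate toy species id: ", ids[duplicated(ids)][1L],
         call. = FALSE)
  importers <- vapply(species, function(s)
    primary_substrate %in% names(s$substrates), logical(1))
  if (!any(importers))
    stop("no species imports the primary substrate '", primary_substrate,
         "'", call. = FALSE)
  # metabolite-level topology: edge consumed -> produced
  edges <- do.call(rbind, lapply(species, function(s) {
    if (!length(s$byproducts)) return(NULL)
    expand.grid(from = names(s$substrates), to = names(s$byproducts),
                stringsAsFactors = FALSE)
  }))
  if (!cyclic_ok && !is.null(edges) && .has_cycle(edges))
    stop("crossfeeding topology is cyclic; pass cyclic_ok = TRUE to allow",
         call. = FALSE)
  structure(list(species = species, diet = diet,
                 policy = crossfeed_policy(
                   crossfed_ids, crossfeed_uptake_bound,
                   blocked_uptake_ids, scfa_ids),
                 primary_substrate = primary_substrate,
                 seed = as.integer(seed)),
            class = "toy_community_spec")
}

.has_cycle <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new 1 open 2 done
  visit <- function(v) {
    if (state[[v]] == 1L) return(TRUE)
    if (state[[v]] == 2L) return(FALSE)
    state[[v]] <<- 1L
    for (w in edges$to[edges$from == v]) if (visit(w)) return(TRUE)
    state[[v]] <<- 2L
    FALSE
  }
  any(vapply(nodes, visit, logical(1)))
}

#' Materialize a toy community
#'
#' @param spec a [toy_community_spec()].
#' @return list with `models` (list of [species_model()]), `diet`,
#'   `policy`, and `defs` (the input definitions, for closed-form checks).
#' @export
make_toy_community <- function(spec) {
  stopifnot(inherits(spec, "toy_community_spec"))
  models <- lapply(spec$species, .toy_model)
  names(models) <- vapply(spec$species, function(s) s$id, character(1))
  list(models = models, diet = spec$diet, policy = spec$policy,
       defs = spec$species)
}

#' The three-species teaching fixture
#'
#' A deliberately small community with closed-form optima, used as the
#' test oracle throughout the package:
#' * species `A`: glucose-analog `G` uptake <= 10, `1 G -> 1 M + 0.04`
#'   biomass (secretes the crossfed byproduct `M`);
#' * species `B`: no `G` route, `M` uptake <= 10, `1 M -> 0.03` biomass
#'   (obligate crossfeeder, zero growth alone);
#' * species `C`: `G` uptake <= 5, `1 G -> 1 P + 0.06` biomass, where `P`
#'   is an SCFA-analog whose uptake is blocked community-wide.
#'
#' Diet: community `G` uptake <= 10.  Closed-form facts (see
#' [toy3_facts()]): unconstrained maximal community growth 0.4 1/h at
#' abundances (1, 0, 0); capping `A` at 0.5 gives 0.3 1/h with a
#' non-unique abundance split; `B` alone grows at 0.
#'
#' @return list with `models`, `diet`, `policy`, `defs`.
#' @export
toy3_fixture <- function() {
  spec <- toy_community_spec(
    species = list(
      toy_species_def("A", c(G = 10), yield = 0.04, byproducts = c(M = 1)),
      toy_species_def("B", c(M = 10), yield = 0.03),
      toy_species_def("C", c(G = 5), yield = 0.06, byproducts = c(P = 1))),
    diet = diet_spec("toy_western", c(G = 10)),
    crossfed_ids = "M",
    blocked_uptake_ids = "P",
    primary_substrate = "G")
  make_toy_community(spec)
}

#' Documented closed-form facts about the toy3 fixture
#'
#' @return list of constants: `mu_max`, `abundances_at_max`,
#'   `mu_max_capA_half` (A's abundance capped at 0.5) and
#'   `b_single_growth`.
#' @export
toy3_facts <- function() {
  list(mu_max = 0.4,
       abundances_at_max = c(A = 1, B = 0, C = 0),
       mu_max_capA_half = 0.3,
       b_single_growth = 0)
}

#' The eight-species campaign fixture
#'
#' A toy community built to reproduce, qualitatively, the structural
#' features real gut communities show in this modeling framework: a fast
#' glucose specialist that dominates the maximal-growth community, slower
#' fermenters that coexist only via crossfed byproducts (amino-acid analog
#' `AA`, lactate analog `LAC`), two obligate crossfeeders with zero
#' single-species growth, one species whose maintenance exactly consumes
#' its energy supply (zero growth at ATPM 10), and three tagged SCFA
#' analogs (`ACE`, `BUT`, `PRO`) with distinct producer sets.  `BUT` and
#' `PRO` cannot be consumed by any species.
#'
#' @return list with `models`, `diet`, `policy`, `defs`.
#' @export
toy8_fixture <- function() {
  spec <- toy_community_spec(
    species = list(
      toy_species_def("S1", c(G = 10), yield = 0.050,
                      byproducts = c(ACE = 0.5)),
      toy_species_def("S2", c(G = 10), yield = 0.048,
                      byproducts = c(AA = 0.6, ACE = 0.4)),
      toy_species_def("S3", c(G = 6, LAC = 5), yield = 0.040,
                      byproducts = c(PRO = 0.5, ACE = 0.3)),
      toy_species_def("S4", c(G = 6, AA = 6), yield = 0.038,
                      byproducts = c(BUT = 0.5, ACE = 0.2)),
      toy_species_def("S5", c(AA = 10), yield = 0.042,
                      byproducts = c(LAC = 0.5)),
      toy_species_def("S6", c(LAC = 10), yield = 0.040,
                      byproducts = c(BUT = 0.4)),
      toy_species_def("S7", c(G = 5, AA = 5), yield = 0.042,
                      byproducts = c(LAC = 0.3, ACE = 0.2)),
      toy_species_def("S8", c(G = 5, AA = 10), yield = 0.020,
                      byproducts = c(PRO = 0.6), atpm = 10, e_yield = 2)),
    diet = diet_spec("toy_western", c(G = 10)),
    crossfed_ids = c("AA", "LAC", "ACE"),
    blocked_uptake_ids = c("BUT", "PRO"),
    scfa_ids = c(acetate = "ACE", butyrate = "BUT", propionate = "PRO"),
    primary_substrate = "G")
  make_toy_community(spec)
}

#' Write the fixture set to a directory
#'
#' Emits the toy3 and toy8 communities in both SBML and JSON, their diet
#' tables as TSV, and a reduced campaign schedule (10 cases per level)
#' suitable for continuous-integration runs.
#'
#' @param directory output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_fixture_set <- function(directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (fx in list(toy3 = toy3_fixture(), toy8 = toy8_fixture())) {
    for (m in fx$models) {
      p1 <- file.path(directory, paste0(m$species_id, ".xml"))
      p2 <- file.path(directory, paste0(m$species_id, ".json"))
      write_species_sbml(m, p1)
      write_species_json(m, p2)
      paths <- c(paths, p1, p2)
    }
  }
  pd <- file.path(directory, "toy_western.tsv")
  write_diet(toy3_fixture()$diet, pd)
  ps <- file.path(directory, "schedule_reduced.tsv")
  sched <- reduced_schedule()
  utils::write.table(sched, ps, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, pd, ps))
}
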