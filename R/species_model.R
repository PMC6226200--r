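#' Construct a single-species metabolic model
#'
#' A species model is the stoichiometric description of one organism: a set
#' of metabolites (intracellular, compartment `"c"`, or extracellular,
#' compartment `"e"`), a set of bounded reactions, a biomass reaction whose
#' flux is the specific growth rate (1/h), and a non-growth ATP maintenance
#' (ATPM) reaction whose lower bound represents mandatory cellular upkeep.
#'
#' Exchange reactions follow the standard constraint-based convention: a
#' reaction touching exactly one extracellular metabolite with coefficient
#' -1, so that positive flux is secretion and negative flux is uptake.
#' Uptake capacity is encoded in the (negative) lower bound, in mmol/gDW/h.
#'
#' @param species_id short label, unique within a community.
#' @param metabolites data.frame with columns `id` and `compartment`
#'   (`"c"` or `"e"`).
#' @param reactions list of reactions, each a list with elements `id`,
#'   `stoich` (named numeric, metabolite -> coefficient), `lb`, `ub`
#'   (mmol/gDW/h).
#' @param biomass_id,atpm_id reaction identifiers; if `NULL` they are
#'   auto-detected by the id patterns `"biomass"` and `"atpm"`
#'   (case-insensitive).
#'
#' @return An object of class `species_model` with fields `species_id`,
#'   `mets`, `rxns` (data.frame `id`, `lb`, `ub`), stoichiometric matrix `S`
#'   (metabolites x reactions), `biomass_id`, `atpm_id` and
#'   `exchange_ids`.
#' @export
species_model <- function(species_id, metabolites, reactions,
                          biomass_id = NULL, atpm_id = NULL) {
  stopifnot(is.character(species_id), length(species_id) == 1L,
            nzchar(species_id))
  mets <- data.frame(id = as.character(metabolites$id),
                     compartment = as.character(metabolites$compartment),
                     stringsAsFactors = FALSE)
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite id: ",
         mets$id[duplicated(mets$id)][1L], call. = FALSE)
  if (!all(mets$compartment %in% c("c", "e")))
    stop("metabolite compartment must be 'c' or 'e'", call. = FALSE)

  rids <- vapply(reactions, function(r) as.character(r$id), character(1))
  if (anyDuplicated(rids))
    stop("duplicate reaction id: ", rids[duplicated(rids)][1L], call. = FALSE)
  lb <- vapply(reactions, function(r) as.numeric(r$lb), numeric(1))
  ub <- vapply(reactions, function(r) as.numeric(r$ub), numeric(1))
  for (i in seq_along(reactions)) {
    st <- reactions[[i]]$stoich
    bad <- setdiff(names(st), mets$id)
    if (length(bad))
      stop("reaction '", rids[i], "' references undeclared metabolite '",
           bad[1L], "'", call. = FALSE)
    if (lb[i] > ub[i])
      stop("reaction '", rids[i], "' has inverted bounds (lb ", lb[i],
           " > ub ", ub[i], ")", call. = FALSE)
    if (!all(is.finite(c(lb[i], ub[i]))))
      stop("reaction '", rids[i], "' has non-finite bounds; use a large ",
           "finite cap instead", call. = FALSE)
  }
  S <- matrix(0, nrow(mets), length(reactions),
              dimnames = list(mets$id, rids))
  for (i in seq_along(reactions)) {
    st <- reactions[[i]]$stoich
    S[names(st), i] <- as.numeric(st)
  }

  detect <- function(pattern, what, given) {
    if (!is.null(given)) {
      if (!given %in% rids)
        stop(what, " reaction '", given, "' not found", call. = FALSE)
      return(given)
    }
    hit <- grep(pattern, rids, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0L)
      stop("no ", what, " reaction found: no reaction id matches the ",
           "pattern '", pattern, "' (case-insensitive) and none was given ",
           "explicitly", call. = FALSE)
    hit[1L]
  }
  biomass_id <- detect("biomass", "biomass", biomass_id)
  atpm_id <- detect("atpm", "ATPM", atpm_id)
  if (identical(biomass_id, atpm_id))
    stop("biomass and ATPM reactions must be distinct ('", biomass_id, "')",
         call. = FALSE)

  # exchange reactions: single extracellular metabolite with coefficient -1
  e_mets <- mets$id[mets$compartment == "e"]
  exchange_ids <- character(0)
  for (i in seq_along(rids)) {
    nz <- which(S[, i] != 0)
    if (length(nz) == 1L && rownames(S)[nz] %in% e_mets) {
      if (abs(S[nz, i] + 1) > 1e-12)
        stop("reaction '", rids[i], "' looks like an exchange reaction but ",
             "its extracellular coefficient is ", S[nz, i],
             " (must be -1, export convention)", call. = FALSE)
      exchange_ids <- c(exchange_ids, rids[i])
    }
  }

  structure(list(species_id = species_id,
                 mets = mets,
                 rxns = data.frame(id = rids, lb = lb, ub = ub,
                                   stringsAsFactors = FALSE),
                 S = S,
                 biomass_id = biomass_id,
                 atpm_id = atpm_id,
                 exchange_ids = exchange_ids),
            class = "species_model")
}

#' @export
print.species_model <- function(x, ...) {
  cat("<species_model> ", x$species_id, ": ",
      nrow(x$mets), " metabolites, ", nrow(x$rxns), " reactions (",
      length(x$exchange_ids), " exchange)\n", sep = "")
  cat("  biomass: ", x$biomass_id, "   ATPM: ", x$atpm_id,
      " (lb ", x$rxns$lb[x$rxns$id == x$atpm_id], ")\n", sep = "")
  invisible(x)
}

#' Metabolite moved by each exchange reaction
#'
#' @param model a [species_model()].
#' @return named character vector: exchange reaction id -> extracellular
#'   metabolite id.
#' @export
exchange_mets <- function(model) {
  vapply(model$exchange_ids, function(r) {
    rownames(model$S)[which(model$S[, r] != 0)]
  }, character(1))
}

#' Apply a diet to a species model
#'
#' Uptake of each exchanged metabolite is limited to the diet rate (0 when
#' absent from the diet); the model's own transporter capacity is never
#' relaxed.  Metabolites in the diet that this species does not exchange
#' are ignored unless `strict`.
#'
#' @param model a [species_model()].
#' @param diet a [diet_spec()].
#' @param strict error on diet metabolites the species does not exchange.
#' @return the model with updated exchange bounds.
#' @export
apply_diet <- function(model, diet, strict = FALSE) {
  stopifnot(inherits(model, "species_model"), inherits(diet, "diet_spec"))
  exm <- exchange_mets(model)
  if (strict) {
    bad <- setdiff(names(diet$max_uptake), exm)
    if (length(bad))
      stop("diet metabolite '", bad[1L], "' is not exchanged by species '",
           model$species_id, "'", call. = FALSE)
  }
  for (r in model$exchange_ids) {
    m <- exm[[r]]
    rate <- if (m %in% names(diet$max_uptake)) diet$max_uptake[[m]] else 0
    i <- match(r, model$rxns$id)
    model$rxns$lb[i] <- max(model$rxns$lb[i], -rate)
  }
  model
}

#' ATP maintenance value of a model
#'
#' @param model a [species_model()].
#' @return lower bound of the maintenance reaction (mmol/gDW/h).
#' @export
atpm_value <- function(model) {
  model$rxns$lb[model$rxns$id == model$atpm_id]
}

#' Replace the ATP maintenance value
#'
#' @param model a [species_model()].
#' @param value new ATPM lower bound (mmol/gDW/h).
#' @return the updated model.
#' @export
set_atpm <- function(model, value) {
  stopifnot(value >= 0)
  i <- match(model$atpm_id, model$rxns$id)
  model$rxns$lb[i] <- value
  if (model$rxns$ub[i] < value) model$rxns$ub[i] <- max(value, 1000)
  model
}
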