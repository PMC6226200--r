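#' Diet specification
#'
#' A diet is a table of maximum uptake rates for extracellular metabolites.
#' Applied to a single species the rates are in mmol/gDW/h; applied to the
#' shared extracellular space of a community they are in mmol/h per unit
#' total community biomass, so the same numbers serve both uses.
#' Metabolites absent from the diet cannot be taken up from outside the
#' system (crossfed metabolites can still circulate inside a community).
#'
#' @param name diet label, e.g. `"western"` or `"highfiber"`.
#' @param max_uptake named non-negative numeric vector,
#'   metabolite id -> maximum uptake rate.
#' @return An object of class `diet_spec`.
#' @export
diet_spec <- function(name, max_uptake) {
  max_uptake <- unlist(max_uptake)
  if (length(max_uptake) && is.null(names(max_uptake)))
    stop("max_uptake must be named by metabolite id", call. = FALSE)
  if (anyDuplicated(names(max_uptake)))
    stop("duplicate diet metabolite: ",
         names(max_uptake)[duplicated(names(max_uptake))][1L], call. = FALSE)
  if (any(!is.finite(max_uptake)) || any(max_uptake < 0))
    stop("diet rates must be finite and >= 0 (offending metabolite: ",
         names(max_uptake)[which(!is.finite(max_uptake) | max_uptake < 0)[1L]],
         ")", call. = FALSE)
  structure(list(name = name, max_uptake = max_uptake), class = "diet_spec")
}

#' @export
print.diet_spec <- function(x, ...) {
  cat("<diet_spec> ", x$name, ": ", length(x$max_uptake),
      " metabolites with non-default uptake\n", sep = "")
  invisible(x)
}

#' Read a diet table
#'
#' Expects a TSV file with header columns `metabolite_id` and `max_uptake`.
#'
#' @param path file path.
#' @param name diet label; defaults to the file name without extension.
#' @return A [diet_spec()].
#' @export
load_diet <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("metabolite_id", "max_uptake") %in% names(tab)))
    stop("diet table must have columns 'metabolite_id' and 'max_uptake'",
         call. = FALSE)
  rates <- suppressWarnings(as.numeric(tab$max_uptake))
  if (anyNA(rates))
    stop("malformed max_uptake value in row ", which(is.na(rates))[1L],
         call. = FALSE)
  diet_spec(name, stats::setNames(rates, tab$metabolite_id))
}

#' Write a diet table
#' @param diet a [diet_spec()].
#' @param path output TSV path.
#' @export
write_diet <- function(diet, path) {
  stopifnot(inherits(diet, "diet_spec"))
  tab <- data.frame(metabolite_id = names(diet$max_uptake),
                    max_uptake = sprintf("%.17g", diet$max_uptake))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Crossfeeding policy
#'
#' Defines which extracellular metabolites species may exchange with each
#' other inside a community.  Uptake bounds of crossfed metabolites are
#' raised to `crossfeed_uptake_bound` for every species (a single value, as
#' metabolite- and species-resolved uptake kinetics are rarely available),
#' while metabolites in `blocked_uptake_ids` cannot be consumed by any
#' species -- the convention used for butyrate- and propionate-like
#' short-chain fatty acids, which are assumed to be absorbed by the host
#' rather than recycled by the community.
#'
#' @param crossfed_ids extracellular metabolite ids open to crossfeeding.
#' @param crossfeed_uptake_bound per-species uptake bound for crossfed
#'   metabolites, mmol/gDW/h (default 10).
#' @param blocked_uptake_ids metabolites no species may take up; must be
#'   disjoint from `crossfed_ids`.
#' @param scfa_ids named character vector of length 3 with names
#'   `acetate`, `butyrate`, `propionate` tagging the SCFA(-analog)
#'   metabolites whose synthesis balance is reported.
#' @return An object of class `crossfeed_policy`.
#' @export
crossfeed_policy <- function(crossfed_ids, crossfeed_uptake_bound = 10,
                             blocked_uptake_ids = character(0),
                             scfa_ids = NULL) {
  if (length(intersect(blocked_uptake_ids, crossfed_ids)))
    stop("blocked_uptake_ids and crossfed_ids overlap: ",
         intersect(blocked_uptake_ids, crossfed_ids)[1L], call. = FALSE)
  stopifnot(crossfeed_uptake_bound >= 0)
  if (!is.null(scfa_ids)) {
    stopifnot(length(scfa_ids) == 3L)
    if (is.null(names(scfa_ids)))
      names(scfa_ids) <- c("acetate", "butyrate", "propionate")
    stopifnot(setequal(names(scfa_ids),
                       c("acetate", "butyrate", "propionate")))
  }
  structure(list(crossfed_ids = as.character(crossfed_ids),
                 crossfeed_uptake_bound = crossfeed_uptake_bound,
                 blocked_uptake_ids = as.character(blocked_uptake_ids),
                 scfa_ids = scfa_ids),
            class = "crossfeed_policy")
}

#' Default crossfed metabolite list
#'
#' The conventional crossfeeding set for gut community models: the 20
#' proteinogenic amino acids, optionally one additional amino acid (the
#' 21st member is study-specific and therefore configurable), and eight
#' common metabolic byproducts (acetate, CO2, ethanol, formate, H2,
#' D-lactate, L-lactate, succinate).  Identifiers are generic lowercase
#' stems; map them onto the metabolite namespace of the models in use
#' before building a policy.
#'
#' @param extra_aa id of an additional amino acid (e.g. an ornithine or
#'   citrulline analog), or `NULL` for the 20 proteinogenic ones only.
#' @return character vector of metabolite ids.
#' @export
default_crossfed_ids <- function(extra_aa = NULL) {
  aa <- c("ala", "arg", "asn", "asp", "cys", "gln", "glu", "gly", "his",
          "ile", "leu", "lys", "met", "phe", "pro", "ser", "thr", "trp",
          "tyr", "val")
  byproducts <- c("ac", "co2", "etoh", "for", "h2", "lac_D", "lac_L",
                  "succ")
  unique(c(aa, extra_aa, byproducts))
}

#' @export
print.crossfeed_policy <- function(x, ...) {
  cat("<crossfeed_policy> ", length(x$crossfed_ids), " crossfed metabolites",
      " (uptake bound ", x$crossfeed_uptake_bound, " mmol/gDW/h), ",
      length(x$blocked_uptake_ids), " uptake-blocked\n", sep = "")
  invisible(x)
}

# ---- flat JSON model format ------------------------------------------------

#' Write a species model to flat JSON
#'
#' The JSON layout mirrors the common constraint-based JSON dialect:
#' top-level `id`, `metabolites` (objects with `id`, `compartment`),
#' `reactions` (objects with `id`, `metabolites` map, `lower_bound`,
#' `upper_bound`), plus explicit `biomass_reaction` and `atpm_reaction`.
#'
#' @param model a [species_model()].
#' @param path output path.
#' @export
write_species_json <- function(model, path) {
  stopifnot(inherits(model, "species_model"))
  rx <- lapply(seq_len(nrow(model$rxns)), function(i) {
    nz <- which(model$S[, i] != 0)
    list(id = model$rxns$id[i],
         metabolites = as.list(stats::setNames(model$S[nz, i],
                                               rownames(model$S)[nz])),
         lower_bound = model$rxns$lb[i],
         upper_bound = model$rxns$ub[i])
  })
  obj <- list(id = model$species_id,
              metabolites = lapply(seq_len(nrow(model$mets)), function(i)
                list(id = model$mets$id[i],
                     compartment = model$mets$compartment[i])),
              reactions = rx,
              biomass_reaction = model$biomass_id,
              atpm_reaction = model$atpm_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

read_species_json <- function(path) {
  obj <- jsonlite::read_json(path)
  mets <- data.frame(
    id = vapply(obj$metabolites, function(m) m$id, character(1)),
    compartment = vapply(obj$metabolites, function(m) m$compartment,
                         character(1)),
    stringsAsFactors = FALSE)
  rxns <- lapply(obj$reactions, function(r)
    list(id = r$id,
         stoich = unlist(r$metabolites),
         lb = r$lower_bound, ub = r$upper_bound))
  species_model(obj$id, mets, rxns,
                biomass_id = obj$biomass_reaction,
                atpm_id = obj$atpm_reaction)
}

# ---- SBML Level 3 + FBC ----------------------------------------------------

sbml_ns_core <- "http://www.sbml.org/sbml/level3/version1/core"
sbml_ns_fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Write a species model as SBML Level 3 with the FBC package
#'
#' Emits the minimal SBML subset used for fixtures: compartments `c` and
#' `e`, species, flux-bound parameters, reactions with
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound`, and an FBC maximization
#' objective naming the biomass reaction.
#'
#' @param model a [species_model()].
#' @param path output path.
#' @export
write_species_sbml <- function(model, path) {
  stopifnot(inherits(model, "species_model"))
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" level="3" version="1" xmlns:fbc="%s"',
                   ' fbc:required="false">'), sbml_ns_core, sbml_ns_fbc),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$species_id)),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '      <compartment id="e" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    sprintf(paste0('      <species id="%s" compartment="%s"',
                   ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
                   ' constant="false"/>'),
            esc(model$mets$id), esc(model$mets$compartment)),
    '    </listOfSpecies>',
    '    <listOfParameters>')
  bnd_ids <- character(0)
  bnd_vals <- numeric(0)
  for (v in sort(unique(c(model$rxns$lb, model$rxns$ub)))) {
    id <- sprintf("bnd_%d", length(bnd_ids) + 1L)
    bnd_ids <- c(bnd_ids, id)
    bnd_vals <- c(bnd_vals, v)
  }
  bnd_for <- function(v) bnd_ids[match(v, bnd_vals)]
  lines <- c(lines,
    sprintf(paste0('      <parameter id="%s" value="%s" constant="true"',
                   '/>'), bnd_ids, num(bnd_vals)),
    '    </listOfParameters>',
    '    <listOfReactions>')
  for (i in seq_len(nrow(model$rxns))) {
    rid <- model$rxns$id[i]
    st <- model$S[, i]
    nzr <- which(st < 0)
    nzp <- which(st > 0)
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false"',
             ' fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(rid), tolower(model$rxns$lb[i] < 0),
      bnd_for(model$rxns$lb[i]), bnd_for(model$rxns$ub[i])))
    if (length(nzr)) {
      lines <- c(lines, '        <listOfReactants>',
        sprintf(paste0('          <speciesReference species="%s"',
                       ' stoichiometry="%s" constant="true"/>'),
                esc(rownames(model$S)[nzr]), num(-st[nzr])),
        '        </listOfReactants>')
    }
    if (length(nzp)) {
      lines <- c(lines, '        <listOfProducts>',
        sprintf(paste0('          <speciesReference species="%s"',
                       ' stoichiometry="%s" constant="true"/>'),
                esc(rownames(model$S)[nzp]), num(st[nzp])),
        '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines,
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s"',
                   ' fbc:coefficient="1"/>'), esc(model$biomass_id)),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

read_species_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  ns <- c(s = sbml_ns_core, fbc = sbml_ns_fbc)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing"))
    stop("SBML parse failure: no <model> element in '", path, "'",
         call. = FALSE)
  sid <- xml2::xml_attr(mdl, "id")

  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(id = xml2::xml_attr(sp, "id"),
                     compartment = xml2::xml_attr(sp, "compartment"),
                     stringsAsFactors = FALSE)

  pars <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  rnodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rnodes, function(nd) {
    rid <- xml2::xml_attr(nd, "id")
    lbref <- xml2::xml_attr(nd, "fbc:lowerFluxBound", ns = ns)
    ubref <- xml2::xml_attr(nd, "fbc:upperFluxBound", ns = ns)
    reac <- xml2::xml_find_all(nd, "./s:listOfReactants/s:speciesReference",
                               ns)
    prod <- xml2::xml_find_all(nd, "./s:listOfProducts/s:speciesReference",
                               ns)
    st <- c(stats::setNames(
              -as.numeric(xml2::xml_attr(reac, "stoichiometry")),
              xml2::xml_attr(reac, "species")),
            stats::setNames(
              as.numeric(xml2::xml_attr(prod, "stoichiometry")),
              xml2::xml_attr(prod, "species")))
    list(id = rid, stoich = st,
         lb = unname(parval[lbref]), ub = unname(parval[ubref]))
  })

  fo <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  biomass <- if (!inherits(fo, "xml_missing"))
    xml2::xml_attr(fo, "fbc:reaction", ns = ns) else NULL
  species_model(sid, mets, rxns, biomass_id = biomass)
}

#' Load a species model from SBML or JSON
#'
#' @param path model file.
#' @param format `"sbml"`, `"json"`, or `"auto"` (by file extension).
#' @return A validated [species_model()].
#' @export
load_species_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "sbml"
  switch(format,
         sbml = read_species_sbml(path),
         json = read_species_json(path))
}
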