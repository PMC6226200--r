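#' Build a community model from single-species models
#'
#' Merges species models into one stoichiometric system with a shared
#' extracellular compartment (the "lumen").  Intracellular and
#' species-boundary metabolite rows are namespaced per species; every
#' extracellular metabolite exchanged by at least one species gains a lumen
#' row and one community exchange reaction.  Community uptake of metabolite
#' `m` is limited to the diet rate (0 when absent, the union-of-diets
#' convention); community secretion is capped at `secretion_cap`, an
#' effectively unbounded value that avoids unbounded LPs.
#'
#' Constraint layout (the SteadyCom formulation): for species `k` with
#' abundance \eqn{p_k} and aggregate fluxes \eqn{V^k} (mmol/h per unit
#' community biomass), \eqn{S^k V^k = 0}, flux bounds scale with abundance
#' (\eqn{l_j p_k \le V^k_j \le u_j p_k}), the biomass flux is tied to the
#' shared community growth rate (\eqn{V^k_{bio} = \mu p_k}), and each lumen
#' metabolite balances species exchange against the community exchange flux
#' (\eqn{\sum_k V^k_{ex(m)} - e_m = 0}).
#'
#' The crossfeeding policy is applied at the species level: uptake
#' allowances for crossfed metabolites are raised (never lowered) to the
#' policy bound, and uptake of blocked metabolites is forbidden for every
#' species while their secretion (and thus net community synthesis) remains
#' free.
#'
#' @param models list of [species_model()] objects with unique ids.
#' @param diet a [diet_spec()].
#' @param policy a [crossfeed_policy()].
#' @param secretion_cap upper bound on community exchange fluxes
#'   (mmol/h per unit community biomass).
#' @return An object of class `community_model`.
#' @export
build_community <- function(models, diet, policy, secretion_cap = 1000) {
  stopifnot(length(models) >= 1L, inherits(diet, "diet_spec"),
            inherits(policy, "crossfeed_policy"))
  ids <- unname(vapply(models, function(m) m$species_id, character(1)))
  if (anyDuplicated(ids))
    stop("duplicate species id: ", ids[duplicated(ids)][1L], call. = FALSE)
  names(models) <- ids

  # species-level bounds: diet first, then crossfeed relaxation / blocking
  templates <- lapply(models, function(m) {
    m <- apply_diet(m, diet)
    exm <- exchange_mets(m)
    for (r in m$exchange_ids) {
      met <- exm[[r]]
      i <- match(r, m$rxns$id)
      if (met %in% policy$crossfed_ids)
        m$rxns$lb[i] <- min(m$rxns$lb[i], -policy$crossfeed_uptake_bound)
      if (met %in% policy$blocked_uptake_ids)
        m$rxns$lb[i] <- max(m$rxns$lb[i], 0)
    }
    m
  })

  all_ex_mets <- sort(unique(unlist(lapply(templates, exchange_mets))))
  unknown <- setdiff(names(diet$max_uptake), all_ex_mets)
  if (length(unknown))
    stop("diet names metabolite '", unknown[1L],
         "' which no species exchanges", call. = FALSE)
  lumen <- all_ex_mets

  cm <- structure(list(species = ids,
                       models = models,
                       templates = templates,
                       lumen_mets = lumen,
                       diet = diet,
                       policy = policy,
                       secretion_cap = secretion_cap,
                       abundance_bounds = matrix(
                         rep(c(0, 1), each = length(ids)),
                         ncol = 2,
                         dimnames = list(ids, c("lower", "upper")))),
                  class = "community_model")
  cm$lp <- .community_lp_parts(cm)
  cm
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", length(x$species), " species (",
      paste(x$species, collapse = ", "), ")\n", sep = "")
  cat("  ", length(x$lumen_mets), " shared extracellular metabolites; diet '",
      x$diet$name, "'\n", sep = "")
  invisible(x)
}

# Static LP skeleton shared by all community solves.  The biomass-coupling
# rows carry a -mu coefficient on the abundance column that is filled in per
# solve; everything else is fixed at build time.
.community_lp_parts <- function(cm) {
  ids <- cm$species
  tpl <- cm$templates
  lumen <- cm$lumen_mets
  nV <- sum(vapply(tpl, function(m) nrow(m$rxns), integer(1)))
  np <- length(ids)
  ne <- length(lumen)
  nvar <- nV + np + ne

  v_names <- unlist(lapply(tpl, function(m)
    paste(m$species_id, m$rxns$id, sep = ":")))
  iV <- stats::setNames(seq_len(nV), v_names)
  ip <- stats::setNames(nV + seq_len(np), ids)
  ie <- stats::setNames(nV + np + seq_len(ne), lumen)

  # variable bounds; abundance-scaled flux bounds are rows, so V variables
  # are only sign-restricted where the template bound pins the sign
  lower <- numeric(nvar)
  upper <- numeric(nvar)
  lower[seq_len(nV)] <- unlist(lapply(tpl, function(m)
    ifelse(m$rxns$lb >= 0, 0, -Inf)))
  upper[seq_len(nV)] <- unlist(lapply(tpl, function(m)
    ifelse(m$rxns$ub <= 0, 0, Inf)))
  lower[ip] <- NA  # filled per solve from abundance bounds
  upper[ip] <- NA
  lower[ie] <- -vapply(lumen, function(m)
    if (m %in% names(cm$diet$max_uptake)) cm$diet$max_uptake[[m]] else 0,
    numeric(1))
  upper[ie] <- cm$secretion_cap

  rows <- list()
  dirs <- character(0)
  rhs <- numeric(0)
  rnames <- character(0)
  add_row <- function(idx, coef, dir, b, name) {
    r <- numeric(nvar)
    r[idx] <- coef
    rows[[length(rows) + 1L]] <<- r
    dirs <<- c(dirs, dir)
    rhs <<- c(rhs, b)
    rnames <<- c(rnames, name)
  }

  off <- 0L
  biom_rows <- integer(np)
  for (k in seq_along(ids)) {
    m <- tpl[[k]]
    nr <- nrow(m$rxns)
    cols <- off + seq_len(nr)
    # metabolite balances (intracellular and species-boundary rows)
    for (i in seq_len(nrow(m$mets))) {
      nz <- which(m$S[i, ] != 0)
      add_row(cols[nz], m$S[i, nz], "=", 0,
              paste0(ids[k], ":", m$mets$id[i]))
    }
    # abundance-scaled flux bounds (skip zero bounds: plain variable bounds)
    for (j in seq_len(nr)) {
      rid <- m$rxns$id[j]
      if (rid == m$biomass_id) next  # tied to mu p below
      if (m$rxns$lb[j] != 0)
        add_row(c(cols[j], ip[k]), c(1, -m$rxns$lb[j]), ">=", 0,
                paste0(ids[k], ":", rid, ":lb"))
      if (m$rxns$ub[j] != 0)
        add_row(c(cols[j], ip[k]), c(1, -m$rxns$ub[j]), "<=", 0,
                paste0(ids[k], ":", rid, ":ub"))
    }
    # biomass coupling V_bio = mu p (mu written per solve)
    add_row(c(cols[match(m$biomass_id, m$rxns$id)], ip[k]), c(1, 0), "=", 0,
            paste0(ids[k], ":growth"))
    biom_rows[k] <- length(rows)
    off <- off + nr
  }
  # lumen balances: sum of species exchange fluxes minus community exchange
  ex_cols <- lapply(lumen, function(met) {
    unlist(lapply(seq_along(ids), function(k) {
      m <- tpl[[k]]
      exm <- exchange_mets(m)
      r <- names(exm)[exm == met]
      if (length(r)) iV[paste(ids[k], r, sep = ":")] else integer(0)
    }))
  })
  for (l in seq_along(lumen))
    add_row(c(ex_cols[[l]], ie[l]), c(rep(1, length(ex_cols[[l]])), -1),
            "=", 0, paste0("lumen:", lumen[l]))

  A <- do.call(rbind, rows)
  rownames(A) <- rnames
  list(A = A, dir = dirs, rhs = rhs, lower = lower, upper = upper,
       iV = iV, ip = ip, ie = ie, biom_rows = biom_rows,
       ex_cols = stats::setNames(ex_cols, lumen))
}

# Solve the community LP at a fixed growth rate.
#  obj: named one of "total_abundance" / "none", or a numeric objective
#  over all variables; ab: abundance bound matrix; fix_sum: add sum(p) = 1.
.community_solve <- function(cm, mu, ab = cm$abundance_bounds,
                             obj = "total_abundance", maximize = TRUE,
                             fix_sum = FALSE) {
  lp <- cm$lp
  A <- lp$A
  A[cbind(lp$biom_rows, lp$ip)] <- -mu
  lower <- lp$lower
  upper <- lp$upper
  lower[lp$ip] <- ab[, 1L]
  upper[lp$ip] <- ab[, 2L]
  dir <- lp$dir
  rhs <- lp$rhs
  if (fix_sum) {
    r <- numeric(ncol(A))
    r[lp$ip] <- 1
    A <- rbind(A, r)
    dir <- c(dir, "=")
    rhs <- c(rhs, 1)
  }
  if (is.character(obj)) {
    ov <- numeric(ncol(A))
    if (obj == "total_abundance") ov[lp$ip] <- 1
  } else ov <- obj
  res <- solve_lp(ov, A, dir, rhs, lower, upper, maximize = maximize)
  if (res$status != "optimal") return(list(status = res$status))
  x <- res$x
  list(status = "optimal",
       objval = res$objval,
       x = x,
       p = stats::setNames(x[lp$ip], cm$species),
       V = stats::setNames(x[lp$iV], names(lp$iV)),
       e = stats::setNames(x[lp$ie], cm$lumen_mets))
}

#' Restrict a community to a subset of species
#'
#' Soft restriction clamps the abundance upper bound of excluded species to
#' zero (the model keeps its size); hard restriction rebuilds the community
#' from the kept species models only.  Both modes have identical optima
#' because a species with zero abundance carries zero flux.
#'
#' @param community a [build_community()] result.
#' @param keep character vector of species ids to retain.
#' @param mode `"soft"` (default) or `"hard"`.
#' @return A `community_model`.
#' @export
restrict_species <- function(community, keep, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  stopifnot(inherits(community, "community_model"))
  unknown <- setdiff(keep, community$species)
  if (length(unknown))
    stop("unknown species id: ", unknown[1L], call. = FALSE)
  if (mode == "hard")
    return(build_community(community$models[keep], community$diet,
                           community$policy, community$secretion_cap))
  drop <- setdiff(community$species, keep)
  community$abundance_bounds[drop, ] <- 0
  community
}
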