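#' Single-species flux balance analysis
#'
#' Maximizes the biomass flux of one species subject to steady-state mass
#' balance, the model's flux bounds and the diet's uptake limits.  A growth
#' rate of zero (the LP is feasible but no biomass can be formed) is
#' distinguished from an infeasible LP (the mandatory ATP maintenance flux
#' cannot be met), which signals an inconsistent model/diet pairing.
#'
#' @param model a [species_model()].
#' @param diet a [diet_spec()].
#' @param on_infeasible `"error"` (default) or `"na"` to return a growth
#'   rate of `NA` with status `"infeasible"`.
#' @return A list with `growth` (1/h), `fluxes` (named vector,
#'   mmol/gDW/h) and `status`.
#' @export
fba_single <- function(model, diet, on_infeasible = c("error", "na")) {
  on_infeasible <- match.arg(on_infeasible)
  m <- apply_diet(model, diet)
  res <- .fba_template(m)
  if (res$status != "optimal") {
    if (on_infeasible == "error")
      stop("FBA for species '", model$species_id, "' is ", res$status,
           ": the ATP maintenance requirement cannot be met on diet '",
           diet$name, "'", call. = FALSE)
    return(list(growth = NA_real_, fluxes = NULL, status = res$status))
  }
  res
}

# FBA on a model whose bounds are already final (no diet application)
.fba_template <- function(m) {
  obj <- as.numeric(m$rxns$id == m$biomass_id)
  res <- solve_lp(obj, m$S, rep("=", nrow(m$S)), numeric(nrow(m$S)),
                  m$rxns$lb, m$rxns$ub, maximize = TRUE)
  if (res$status != "optimal") return(list(status = res$status))
  list(growth = res$objval,
       fluxes = stats::setNames(res$x, m$rxns$id),
       status = "optimal")
}

#' Feasibility of a community growth rate
#'
#' Solves the SteadyCom feasibility LP at fixed growth rate `mu`: maximize
#' the total abundance subject to species mass balance, abundance-scaled
#' flux bounds, biomass coupling and lumen balance.  A growth rate is
#' feasible for a unit-biomass community iff the optimum is >= 1.
#'
#' @param community a [build_community()] result.
#' @param mu community growth rate (1/h).
#' @param abundance_bounds optional N x 2 matrix overriding the community's
#'   per-species abundance bounds.
#' @return A list with `total` (maximal total abundance), `status` and the
#'   raw solution components `p`, `V`, `e`.
#' @export
feasible_at_mu <- function(community, mu,
                           abundance_bounds = community$abundance_bounds) {
  stopifnot(mu >= 0)
  r <- .community_solve(community, mu, ab = abundance_bounds,
                        obj = "total_abundance")
  if (r$status == "unbounded")
    stop("community LP unbounded at mu = ", mu,
         " (missing secretion cap?)", call. = FALSE)
  if (r$status != "optimal")
    return(list(total = 0, status = r$status))
  list(total = r$objval, status = "optimal", p = r$p, V = r$V, e = r$e)
}

#' Maximal community growth rate
#'
#' Bisection over [feasible_at_mu()]: the largest growth rate (within
#' `mu_tol`) whose feasibility LP attains total abundance >= 1.  The upper
#' bracket starts from the largest relaxed single-species growth rate
#' (every species' community-aggregate flux scaled by its abundance is a
#' feasible single-species flux vector, so no community can outgrow its
#' fastest member) and is doubled until infeasible as a safeguard.  The
#' returned solution is re-extracted at the feasible endpoint with the
#' total abundance fixed to 1.
#'
#' @param community a [build_community()] result.
#' @param abundance_bounds optional N x 2 matrix of abundance bounds.
#' @param mu_tol bisection tolerance on the growth rate (1/h).
#' @param max_iter bisection iteration cap.
#' @return A `community_solution`: list with `mu`, `abundances`, `fluxes`
#'   (named `species:reaction`), `exchange` (community exchange fluxes by
#'   lumen metabolite), `sum_p` and `status`.
#' @export
maximize_community_growth <- function(community,
                                      abundance_bounds = NULL,
                                      mu_tol = 1e-6, max_iter = 60L) {
  stopifnot(inherits(community, "community_model"))
  ab <- if (is.null(abundance_bounds)) community$abundance_bounds else
    abundance_bounds
  f0 <- feasible_at_mu(community, 0, ab)
  if (f0$status != "optimal" || f0$total < 1 - 1e-9)
    stop("community infeasible at mu = 0: no abundance assignment meets ",
         "the maintenance requirements (model/diet inconsistency)",
         call. = FALSE)

  mu_hi <- max(vapply(community$templates, function(m) {
    r <- .fba_template(m)
    if (r$status == "optimal") r$growth else 0
  }, numeric(1)))
  mu_hi <- max(mu_hi, mu_tol) * (1 + 1e-9) + mu_tol
  feas <- function(mu) {
    # unit community feasible, with slack for LP noise; NA marks a solver
    # failure (possible exactly at degenerate critical growth rates)
    r <- feasible_at_mu(community, mu, ab)
    if (r$status != "optimal" && r$status != "infeasible") return(NA)
    isTRUE(r$total >= 1 - 1e-9)
  }
  n_dbl <- 0L
  while (isTRUE(feas(mu_hi)) && n_dbl < 40L) {
    mu_hi <- mu_hi * 2
    n_dbl <- n_dbl + 1L
  }
  lo <- 0
  hi <- mu_hi
  it <- 0L
  while (hi - lo > mu_tol && it < max_iter) {
    # if the probe fails numerically, split the bracket elsewhere: any
    # interior point keeps the bisection invariant
    fmid <- NA
    for (w in c(0.5, 0.38, 0.62, 0.45)) {
      mid <- lo + w * (hi - lo)
      fmid <- feas(mid)
      if (!is.na(fmid)) break
    }
    if (is.na(fmid)) {
      hi <- mid  # conservative: shrink from above
    } else if (fmid) lo <- mid else hi <- mid
    it <- it + 1L
  }
  r <- .community_solve(community, lo, ab = ab, obj = "none",
                        fix_sum = TRUE)
  for (shrink in c(1e-9, 1e-7)) {  # boundary numerics: step just inside
    if (r$status == "optimal") break
    r <- .community_solve(community, lo * (1 - shrink), ab = ab,
                          obj = "none", fix_sum = TRUE)
  }
  if (r$status != "optimal")
    stop("solution extraction failed at mu = ", lo, " (", r$status, ")",
         call. = FALSE)
  new_community_solution(community, mu = lo, r)
}

new_community_solution <- function(cm, mu, r) {
  structure(list(mu = mu,
                 abundances = r$p,
                 fluxes = r$V,
                 exchange = r$e,
                 sum_p = sum(r$p),
                 status = "optimal"),
            class = "community_solution")
}

#' @export
print.community_solution <- function(x, ...) {
  cat("<community_solution> mu = ", format(x$mu, digits = 6),
      " 1/h; sum(p) = ", format(x$sum_p, digits = 6), "\n", sep = "")
  nz <- x$abundances[x$abundances > 1e-6]
  cat("  abundances > 1e-6: ",
      paste(sprintf("%s=%.4f", names(nz), nz), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Verify the conservation invariants of a community solution
#'
#' Checks, against the community the solution came from: intracellular and
#' species-boundary mass balance, lumen balance against community exchange
#' fluxes, the biomass coupling \eqn{V_{bio} = \mu p}, abundance-scaled
#' flux bounds, and the unit total abundance.
#'
#' @param community the `community_model` the solution was computed on.
#' @param solution a `community_solution`.
#' @param tol_balance tolerance on mass-balance residuals.
#' @param tol_abundance tolerance on `|sum(p) - 1|`.
#' @return Invisibly, a named list of maximal absolute violations; throws
#'   if any check fails.
#' @export
check_solution <- function(community, solution, tol_balance = 1e-6,
                           tol_abundance = 1e-4) {
  stopifnot(inherits(solution, "community_solution"))
  lp <- community$lp
  viol <- list()
  V <- solution$fluxes
  p <- solution$abundances
  e <- solution$exchange
  bal <- numeric(0)
  bound_viol <- 0
  for (k in seq_along(community$species)) {
    m <- community$templates[[k]]
    vk <- V[paste(community$species[k], m$rxns$id, sep = ":")]
    bal <- c(bal, max(abs(m$S %*% vk)))
    bound_viol <- max(bound_viol,
                      max(m$rxns$lb * p[k] - vk, vk - m$rxns$ub * p[k]))
  }
  viol$species_balance <- max(bal)
  viol$lumen_balance <- max(abs(vapply(community$lumen_mets, function(met) {
    sum(V[names(lp$ex_cols[[met]])]) - e[[met]]
  }, numeric(1))))
  bio <- vapply(seq_along(community$species), function(k)
    V[paste(community$species[k], community$templates[[k]]$biomass_id,
            sep = ":")], numeric(1))
  viol$biomass_coupling <- max(abs(bio - solution$mu * p))
  viol$flux_bounds <- bound_viol
  viol$abundance_sum <- abs(sum(p) - 1)
  viol$abundance_sign <- max(0, -min(p))
  if (viol$species_balance > tol_balance)
    stop("species mass balance violated: ", viol$species_balance)
  if (viol$lumen_balance > tol_balance)
    stop("lumen balance violated: ", viol$lumen_balance)
  if (viol$biomass_coupling > tol_balance)
    stop("biomass-growth coupling violated: ", viol$biomass_coupling)
  if (viol$flux_bounds > tol_balance)
    stop("abundance-scaled flux bounds violated: ", viol$flux_bounds)
  if (viol$abundance_sum > tol_abundance)
    stop("total abundance deviates from 1 by ", viol$abundance_sum)
  if (viol$abundance_sign > 1e-9)
    stop("negative abundance: ", viol$abundance_sign)
  invisible(viol)
}

#' Growth and byproduct secretion of every species alone
#'
#' Runs each species as a single-member community (all other abundances
#' clamped to zero) on the community's diet and reports its maximal growth
#' rate and the community exchange (net secretion) of the requested
#' byproducts.  Species that cannot meet maintenance alone are reported
#' with `NA` growth rather than aborting the sweep.
#'
#' @param community a `community_model`.
#' @param byproduct_ids extracellular metabolite ids to report; defaults to
#'   the policy's crossfed + blocked metabolites present in the lumen.
#' @return data.frame with one row per species: `species`, `growth`,
#'   `status`, and one secretion column per byproduct.
#' @export
single_species_profile <- function(community, byproduct_ids = NULL) {
  if (is.null(byproduct_ids))
    byproduct_ids <- intersect(
      unique(c(community$policy$crossfed_ids,
               community$policy$blocked_uptake_ids,
               community$policy$scfa_ids)),
      community$lumen_mets)
  rows <- lapply(community$species, function(sp) {
    sub <- restrict_species(community, sp, mode = "soft")
    sol <- tryCatch(maximize_community_growth(sub),
                    error = function(e) e)
    if (inherits(sol, "error")) {
      sec <- stats::setNames(rep(NA_real_, length(byproduct_ids)),
                             byproduct_ids)
      return(data.frame(species = sp, growth = NA_real_,
                        status = "infeasible", t(sec),
                        check.names = FALSE))
    }
    sec <- vapply(byproduct_ids, function(m)
      if (m %in% names(sol$exchange)) sol$exchange[[m]] else 0, numeric(1))
    data.frame(species = sp, growth = sol$mu, status = "optimal", t(sec),
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tune the ATP maintenance value to hit a target growth rate
#'
#' Single-species growth decreases monotonically in the ATPM lower bound,
#' so the ATPM value reproducing a target growth rate is found by
#' bisection.  If the species cannot reach the target even without
#' maintenance, the value 0 is returned with `attained = FALSE` ("to the
#' extent possible").  A target of 0 returns the largest maintenance flux
#' the diet can support.
#'
#' @param model a [species_model()].
#' @param diet a [diet_spec()].
#' @param target_mu target growth rate (1/h).
#' @param tol tolerance on the achieved growth rate.
#' @return list with `atpm`, `growth` (achieved rate) and `attained`.
#' @export
tune_atpm <- function(model, diet, target_mu = 0.2, tol = 1e-6) {
  stopifnot(target_mu >= 0)
  g <- function(a) {
    r <- fba_single(set_atpm(model, a), diet, on_infeasible = "na")
    if (is.na(r$growth)) -Inf else r$growth
  }
  if (g(0) < target_mu - tol)
    return(list(atpm = 0, growth = g(0), attained = FALSE))
  lo <- 0
  hi <- 1
  n <- 0L
  while (g(hi) >= target_mu && n < 60L) {
    lo <- hi
    hi <- hi * 2
    n <- n + 1L
  }
  for (i in seq_len(80L)) {
    mid <- (lo + hi) / 2
    if (g(mid) >= target_mu) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  gr <- g(lo)
  list(atpm = lo, growth = gr, attained = abs(gr - target_mu) <= tol)
}
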