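#' Community flux variability analysis over species abundances
#'
#' At a fixed fraction `f` of the maximal community growth rate, each
#' species' abundance is minimized and maximized subject to the full
#' community constraint set with the total abundance fixed to 1.  Growth is
#' imposed as an equality at `f * mu_max`, so the possibility of a species
#' need not be monotone in `f`.  If the LP is infeasible at exactly
#' `f * mu_max` (which can happen when `f = 1` and `mu_max` carries the
#' bisection tolerance), the analysis is retried once at
#' `f * mu_max * (1 - 1e-6)`.
#'
#' @param community a [build_community()] result.
#' @param f fraction of maximal growth, in (0, 1].
#' @param mu_max maximal community growth rate from
#'   [maximize_community_growth()].
#' @param abundance_bounds optional N x 2 abundance bound matrix.
#' @return An `fva_result`: list with `f`, `mu`, `table` (data.frame
#'   `species`, `p_min`, `p_max`) and `solutions` (the 2N optimizing
#'   abundance vectors as `community_solution` objects, `$min` and `$max`
#'   per species).
#' @export
abundance_fva <- function(community, f, mu_max, abundance_bounds = NULL) {
  stopifnot(f > 0, f <= 1, mu_max >= 0)
  ab <- if (is.null(abundance_bounds)) community$abundance_bounds else
    abundance_bounds
  ids <- community$species
  np <- length(ids)
  lp_ip <- community$lp$ip

  solve_dir <- function(mu, k, maximize) {
    ov <- numeric(length(community$lp$lower))
    ov[lp_ip[k]] <- 1
    .community_solve(community, mu, ab = ab, obj = ov,
                     maximize = maximize, fix_sum = TRUE)
  }
  mu <- f * mu_max
  probe <- solve_dir(mu, 1L, TRUE)
  if (probe$status != "optimal") {
    mu <- f * mu_max * (1 - 1e-6)
    probe <- solve_dir(mu, 1L, TRUE)
    if (probe$status != "optimal")
      stop("community FVA infeasible at f = ", f,
           " (mu = ", f * mu_max, ")", call. = FALSE)
  }
  p_min <- numeric(np)
  p_max <- numeric(np)
  sols <- list(min = vector("list", np), max = vector("list", np))
  for (k in seq_len(np)) {
    rmin <- solve_dir(mu, k, FALSE)
    rmax <- if (k == 1L) probe else solve_dir(mu, k, TRUE)
    if (rmin$status != "optimal" || rmax$status != "optimal")
      stop("abundance FVA subproblem failed for species '", ids[k], "'",
           call. = FALSE)
    p_min[k] <- rmin$objval
    p_max[k] <- rmax$objval
    sols$min[[k]] <- new_community_solution(community, mu, rmin)
    sols$max[[k]] <- new_community_solution(community, mu, rmax)
  }
  names(sols$min) <- ids
  names(sols$max) <- ids
  structure(list(f = f, mu = mu,
                 table = data.frame(species = ids,
                                    p_min = pmax(p_min, 0),
                                    p_max = pmin(pmax(p_max, 0), 1)),
                 solutions = sols),
            class = "fva_result")
}

#' @export
print.fva_result <- function(x, ...) {
  cat("<fva_result> f = ", x$f, " (mu = ", format(x$mu, digits = 6),
      ")\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' Classify possible and essential species
#'
#' A species is *possible* at a growth fraction when its abundance can be
#' maximized to exceed the threshold (default 1%), and *essential* when it
#' cannot be minimized below it.  Essential species are always possible.
#'
#' @param result an [abundance_fva()] result.
#' @param threshold abundance threshold in (0, 1); the comparison is
#'   strict (`> threshold`).
#' @return list with `possible` (count), `essential` (count) and `flags`
#'   (data.frame `species`, `possible`, `essential`).
#' @export
classify_possible_essential <- function(result, threshold = 0.01) {
  stopifnot(inherits(result, "fva_result"),
            threshold > 0, threshold < 1)
  possible <- result$table$p_max > threshold
  essential <- result$table$p_min > threshold
  list(possible = sum(possible),
       essential = sum(essential),
       flags = data.frame(species = result$table$species,
                          possible = possible, essential = essential))
}

#' Per-species coexistence cutoff over a growth-fraction grid
#'
#' For each species, the largest grid fraction at which its maximized
#' abundance still exceeds 1%.  Because growth is fixed as an equality,
#' possibility need not be nested in `f`; species whose possibility
#' pattern is non-monotone over the grid are flagged.
#'
#' @param community a `community_model`.
#' @param mu_max maximal community growth rate.
#' @param f_grid ascending fractions in (0, 1].
#' @param threshold possibility threshold (strict).
#' @param fva_by_level optional precomputed list of [abundance_fva()]
#'   results named by `f` value (as formatted by `as.character`).
#' @return data.frame `species`, `cutoff`, `monotone`; the FVA results are
#'   attached as attribute `"fva"`.
#' @export
coexistence_cutoff <- function(community, mu_max,
                               f_grid = default_f_grid(),
                               threshold = 0.01, fva_by_level = NULL) {
  stopifnot(all(diff(f_grid) > 0), all(f_grid > 0), all(f_grid <= 1))
  if (is.null(fva_by_level)) {
    fva_by_level <- lapply(f_grid, function(f)
      abundance_fva(community, f, mu_max))
    names(fva_by_level) <- as.character(f_grid)
  }
  pm <- vapply(as.character(f_grid), function(fk)
    fva_by_level[[fk]]$table$p_max, numeric(length(community$species)))
  pm <- matrix(pm, nrow = length(community$species))
  poss <- pm > threshold
  cutoff <- apply(poss, 1L, function(z)
    if (any(z)) max(f_grid[z]) else 0)
  monotone <- apply(poss, 1L, function(z) {
    # monotone here: the possible fractions form one contiguous run, i.e.
    # once possibility is lost with increasing f it never returns
    sum(rle(z)$values) <= 1L
  })
  out <- data.frame(species = community$species, cutoff = cutoff,
                    monotone = monotone)
  attr(out, "fva") <- fva_by_level
  out
}

#' Default growth-fraction grid for coexistence analysis
#'
#' Spans 10% to 99.99% of the maximal growth rate.
#' @return numeric vector of fractions.
#' @export
default_f_grid <- function() {
  c(seq(0.1, 0.9, by = 0.1), 0.95, 0.99, 0.9999)
}

#' Reduce a community by coexistence cutoffs
#'
#' Retains species that can coexist above the cutoff fraction on at least
#' one diet; species possible only at `f_cut` or below on every diet are
#' eliminated.
#'
#' @param cutoffs a single [coexistence_cutoff()] data.frame or a list of
#'   them (one per diet, sharing the species column).
#' @param f_cut elimination threshold on the growth fraction (strict:
#'   retained when `cutoff > f_cut` somewhere).
#' @return character vector of retained species ids.
#' @export
reduce_community <- function(cutoffs, f_cut = 0.70) {
  if (is.data.frame(cutoffs)) cutoffs <- list(cutoffs)
  species <- cutoffs[[1L]]$species
  for (ct in cutoffs)
    stopifnot(identical(ct$species, species))
  best <- do.call(pmax, lapply(cutoffs, function(ct) ct$cutoff))
  retained <- species[best > f_cut]
  if (!length(retained))
    stop("no species survives the coexistence cutoff f_cut = ", f_cut,
         call. = FALSE)
  retained
}
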