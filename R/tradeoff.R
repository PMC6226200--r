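#' Sample randomized abundance upper bounds from FVA maxima
#'
#' Draws i.i.d. uniform multipliers `r_j ~ U[0, 1]` and sets
#' `p_U_j = min(1, 2 r_j p_max_j / sum_i p_max_i)`.  The factor 2
#' compensates for the expectation 0.5 of the uniform draw, so on average
#' the upper bound equals the normalized FVA maximum; species with zero
#' FVA maximum are excluded outright.  The whole vector is redrawn until
#' `sum(p_U) >= 1`, which avoids structurally infeasible abundance caps
#' (total abundance must reach 1); redrawing, rather than rescaling,
#' preserves the sampling distribution conditional on feasibility.
#'
#' @param p_max per-species FVA abundance maxima; `sum(p_max) > 0`.
#' @param max_attempts redraw budget; exhausting it signals that
#'   `sum(p_max)` is barely above the feasibility threshold.
#' @param constrain redraw until `sum(p_U) >= 1` (default); `FALSE`
#'   returns the first draw unconditionally, exposing the raw sampling
#'   distribution.
#' @return list with `r` (the accepted uniform draws), `p_U` (clamped
#'   upper bounds), `p_U_raw` (before clamping to 1) and `attempts`.
#' @export
sample_bounds <- function(p_max, max_attempts = 1000L, constrain = TRUE) {
  stopifnot(sum(p_max) > 0, all(p_max >= 0))
  n <- length(p_max)
  denom <- sum(p_max)
  for (att in seq_len(max_attempts)) {
    r <- stats::runif(n)
    raw <- 2 * r * p_max / denom
    p_u <- pmin(1, raw)
    if (!constrain || sum(p_u) >= 1)
      return(list(r = r, p_U = p_u, p_U_raw = raw, attempts = att))
  }
  stop("sample_bounds: no draw with sum(p_U) >= 1 in ", max_attempts,
       " attempts (sum(p_max) = ", format(denom), ")", call. = FALSE)
}

#' Campaign schedules
#'
#' The full campaign runs 900 cases across growth-fraction levels 0.60 to
#' 0.99, with more cases at lower fractions where high-diversity
#' communities live: 150 at 0.60 and 0.65, 125 at 0.70 and 0.75, 100 at
#' 0.80, 0.85 and 0.90, 25 at 0.95 and 0.99.  `reduced_schedule()` keeps
#' the nine levels but runs `n_per_level` cases each, sized for test runs.
#'
#' @return data.frame with columns `f` and `n_cases`.
#' @export
campaign_schedule <- function() {
  data.frame(f = c(0.60, 0.65, 0.70, 0.75, 0.80, 0.85, 0.90, 0.95, 0.99),
             n_cases = c(150L, 150L, 125L, 125L, 100L, 100L, 100L, 25L,
                         25L))
}

#' @rdname campaign_schedule
#' @param n_per_level cases per growth-fraction level.
#' @export
reduced_schedule <- function(n_per_level = 10L) {
  s <- campaign_schedule()
  s$n_cases <- as.integer(n_per_level)
  s
}

#' Run a growth-diversity tradeoff campaign
#'
#' For every scheduled case: sample abundance upper bounds from the FVA
#' maxima of the case's growth-fraction level, maximize community growth
#' under those bounds, discard solutions whose total abundance deviates
#' from 1 by more than `sum_tol` (keeping all retained solutions at the
#' same accuracy), and compute diversity/SCFA metrics.  Per-case RNG seeds
#' are derived from the master seed and the case counter, so results are
#' reproducible independent of execution order.  Failed and discarded
#' cases are logged, not dropped silently.
#'
#' @param community a `community_model`.
#' @param mu_max maximal community growth rate of the unconstrained
#'   community.
#' @param fva_by_level named list of [abundance_fva()] results, one per
#'   `f` in the schedule (names: `as.character(f)`).
#' @param schedule data.frame `f`, `n_cases` (see [campaign_schedule()]).
#' @param master_seed integer master seed.
#' @param sum_tol acceptance tolerance on `|sum(p) - 1|`.
#' @param richness_threshold abundance threshold for the richness count.
#' @return A `tradeoff_campaign`: list with `cases` (one record per case),
#'   `schedule`, `master_seed`, `mu_max`, `n_accepted`, `acceptance_rate`.
#' @export
run_campaign <- function(community, mu_max, fva_by_level, schedule,
                         master_seed = 1L, sum_tol = 1e-4,
                         richness_threshold = 0.01) {
  stopifnot(is.data.frame(schedule),
            all(c("f", "n_cases") %in% names(schedule)))
  missing_lv <- setdiff(as.character(schedule$f), names(fva_by_level))
  if (length(missing_lv))
    stop("no FVA result for schedule level f = ", missing_lv[1L],
         call. = FALSE)
  scfa_ids <- community$policy$scfa_ids
  cases <- list()
  idx <- 0L
  for (li in seq_len(nrow(schedule))) {
    f <- schedule$f[li]
    p_max <- fva_by_level[[as.character(f)]]$table$p_max
    for (ci in seq_len(schedule$n_cases[li])) {
      idx <- idx + 1L
      seed <- (as.integer(master_seed) + 7919L * idx) %% 2147483562L
      set.seed(seed)
      rec <- list(case_id = idx, f_level = f, seed = seed)
      smp <- tryCatch(sample_bounds(p_max), error = function(e) e)
      if (inherits(smp, "error")) {
        rec$status <- "sampling_failed"
        rec$accepted <- FALSE
        cases[[idx]] <- rec
        next
      }
      rec$r <- smp$r
      rec$p_U <- smp$p_U
      ab <- community$abundance_bounds
      ab[, 2L] <- pmin(ab[, 2L], smp$p_U)
      sol <- tryCatch(maximize_community_growth(community, ab),
                      error = function(e) e)
      if (inherits(sol, "error")) {
        rec$status <- "solve_failed"
        rec$accepted <- FALSE
        cases[[idx]] <- rec
        next
      }
      rec$solution <- sol
      rec$growth_rate <- sol$mu
      rec$growth_fraction <- sol$mu / mu_max
      rec$sum_p <- sol$sum_p
      if (abs(sol$sum_p - 1) > sum_tol) {
        rec$status <- "discarded"
        rec$accepted <- FALSE
        cases[[idx]] <- rec
        next
      }
      rec$status <- "accepted"
      rec$accepted <- TRUE
      rec$equitability <- equitability(sol$abundances)
      rec$richness <- sum(sol$abundances > richness_threshold)
      if (!is.null(scfa_ids)) {
        fr <- scfa_fractions(sol, scfa_ids)
        rec$scfa <- fr
      }
      cases[[idx]] <- rec
    }
  }
  n_acc <- sum(vapply(cases, function(cs) isTRUE(cs$accepted), logical(1)))
  structure(list(cases = cases, schedule = schedule,
                 master_seed = master_seed, mu_max = mu_max,
                 species = community$species,
                 n_accepted = n_acc,
                 acceptance_rate = n_acc / length(cases)),
            class = "tradeoff_campaign")
}

#' @export
print.tradeoff_campaign <- function(x, ...) {
  cat("<tradeoff_campaign> ", length(x$cases), " cases, ",
      x$n_accepted, " accepted (",
      sprintf("%.1f%%", 100 * x$acceptance_rate), "); mu_max = ",
      format(x$mu_max, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Flatten a campaign into a case table
#'
#' One row per case with identifiers, growth, diversity and SCFA metrics,
#' and the per-species abundances (columns `p_<species>`).
#'
#' @param x a `tradeoff_campaign`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame.
#' @export
as.data.frame.tradeoff_campaign <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  sp <- x$species
  rows <- lapply(x$cases, function(cs) {
    p <- if (!is.null(cs$solution)) cs$solution$abundances else
      stats::setNames(rep(NA_real_, length(sp)), sp)
    scfa <- if (!is.null(cs$scfa)) cs$scfa else
      c(acetate = NA_real_, butyrate = NA_real_, propionate = NA_real_)
    d <- data.frame(case_id = cs$case_id,
                    f_level = cs$f_level,
                    seed = cs$seed,
                    status = cs$status,
                    accepted = isTRUE(cs$accepted),
                    growth_rate = cs$growth_rate %||% NA_real_,
                    growth_fraction = cs$growth_fraction %||% NA_real_,
                    sum_p = cs$sum_p %||% NA_real_,
                    equitability = cs$equitability %||% NA_real_,
                    richness = cs$richness %||% NA_integer_,
                    scfa_acetate = unname(scfa[1L]),
                    scfa_butyrate = unname(scfa[2L]),
                    scfa_propionate = unname(scfa[3L]),
                    check.names = FALSE)
    for (s in sp) d[[paste0("p_", s)]] <- unname(p[[s]])
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
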