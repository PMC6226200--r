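#' Inverse Simpson equitability
#'
#' `D_com = (1/N) / sum(p_i^2)`: ranges from `1/N` for a monoculture to 1
#' for a maximally even community of all `N` species.  Scaling the inverse
#' Simpson index by the species count makes values comparable across
#' community sizes.
#'
#' @param p abundance vector (non-negative, summing to 1 within `tol`).
#' @param tol tolerance on `|sum(p) - 1|`.
#' @return equitability in `[1/N, 1]`.
#' @export
equitability <- function(p, tol = 1e-4) {
  if (all(p == 0)) stop("all-zero abundance vector", call. = FALSE)
  stopifnot(all(p >= -1e-9))
  if (abs(sum(p) - 1) > tol)
    stop("abundances must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  (1 / length(p)) / sum(p^2)
}

#' Community richness
#'
#' Number of species with abundance strictly above a threshold.
#'
#' @param p abundance vector.
#' @param threshold abundance cutoff (default 1%).
#' @return integer count.
#' @export
richness <- function(p, threshold = 0.01) {
  sum(p > threshold)
}

#' SCFA synthesis fractions
#'
#' Fraction of total short-chain fatty acid synthesis contributed by the
#' acetate-, butyrate- and propionate-like metabolites: net community
#' secretion of each divided by the summed net secretion of all three.
#' Negative net secretion violates the uptake-blocking policy and is an
#' error; when nothing is synthesized the fractions are undefined and
#' returned as `NA` with attribute `defined = FALSE`.
#'
#' @param solution a `community_solution`.
#' @param scfa_ids named character vector
#'   (`acetate`, `butyrate`, `propionate`) of lumen metabolite ids.
#' @param tol negativity tolerance on net secretion rates.
#' @return named numeric vector of three fractions (attribute `defined`).
#' @export
scfa_fractions <- function(solution, scfa_ids, tol = 1e-6) {
  stopifnot(length(scfa_ids) == 3L)
  if (is.null(names(scfa_ids)))
    names(scfa_ids) <- c("acetate", "butyrate", "propionate")
  net <- vapply(scfa_ids, function(m)
    if (m %in% names(solution$exchange)) solution$exchange[[m]] else 0,
    numeric(1))
  if (any(net < -tol))
    stop("negative net SCFA secretion for '",
         scfa_ids[which(net < -tol)[1L]],
         "' (uptake-blocking policy violated)", call. = FALSE)
  net <- pmax(net, 0)
  total <- sum(net)
  if (total <= tol) {
    out <- stats::setNames(rep(NA_real_, 3L), names(scfa_ids))
    attr(out, "defined") <- FALSE
    return(out)
  }
  out <- net / total
  attr(out, "defined") <- TRUE
  out
}

#' Crossfeeding exchange report
#'
#' Species-by-metabolite aggregate exchange rates (mmol/h per unit
#' community biomass; uptake negative, secretion positive) for the crossfed
#' metabolites, averaged entrywise when several solutions are given (e.g.
#' all cases of a growth-fraction bin).  Summary statistics -- per-metabolite
#' mean and standard deviation of the absolute exchange rate, and the same
#' over all entries -- include, by default, the zero entries of
#' non-exchanging species, so that "few species exchanging a lot" and
#' "many species exchanging a little" are distinguishable.
#'
#' @param community the `community_model` the solutions were computed on.
#' @param solutions a single `community_solution` or a list of them
#'   (shared species order).
#' @param crossfed_ids metabolites to report (default: the policy's
#'   crossfed list, restricted to the lumen).
#' @param include_zeros include zero entries in the |rate| statistics.
#' @return A `crossfeed_report`: list with `matrix` (species x metabolite
#'   mean exchange rates), `net` (per-metabolite net community secretion),
#'   `per_met` (data.frame `metabolite`, `mean_abs`, `sd_abs`),
#'   `overall_mean`, `overall_sd` and `n_solutions`.
#' @export
crossfeed_report <- function(community, solutions,
                             crossfed_ids = NULL, include_zeros = TRUE) {
  if (inherits(solutions, "community_solution"))
    solutions <- list(solutions)
  stopifnot(length(solutions) >= 1L)
  if (is.null(crossfed_ids))
    crossfed_ids <- intersect(community$policy$crossfed_ids,
                              community$lumen_mets)
  ids <- community$species
  for (s in solutions)
    if (!identical(names(s$abundances), ids))
      stop("solution species set does not match the community",
           call. = FALSE)
  n <- length(ids)
  m <- length(crossfed_ids)
  arr <- array(0, dim = c(n, m, length(solutions)),
               dimnames = list(ids, crossfed_ids, NULL))
  for (si in seq_along(solutions)) {
    V <- solutions[[si]]$fluxes
    for (k in seq_len(n)) {
      tpl <- community$templates[[k]]
      exm <- exchange_mets(tpl)
      for (mi in seq_len(m)) {
        r <- names(exm)[exm == crossfed_ids[mi]]
        if (length(r))
          arr[k, mi, si] <- V[[paste(ids[k], r, sep = ":")]]
      }
    }
  }
  avg <- apply(arr, c(1L, 2L), mean)
  net <- colSums(avg)
  entries <- abs(as.vector(arr))
  keep <- if (include_zeros) rep(TRUE, length(entries)) else
    entries > 1e-9
  per_met <- data.frame(
    metabolite = crossfed_ids,
    mean_abs = vapply(seq_len(m), function(mi) {
      v <- abs(as.vector(arr[, mi, ]))
      if (!include_zeros) v <- v[v > 1e-9]
      if (length(v)) mean(v) else 0
    }, numeric(1)),
    sd_abs = vapply(seq_len(m), function(mi) {
      v <- abs(as.vector(arr[, mi, ]))
      if (!include_zeros) v <- v[v > 1e-9]
      if (length(v) > 1L) stats::sd(v) else 0
    }, numeric(1)))
  ve <- entries[keep]
  structure(list(matrix = avg, net = net, per_met = per_met,
                 overall_mean = if (length(ve)) mean(ve) else 0,
                 overall_sd = if (length(ve) > 1L) stats::sd(ve) else 0,
                 n_solutions = length(solutions),
                 include_zeros = include_zeros),
            class = "crossfeed_report")
}

#' @export
print.crossfeed_report <- function(x, ...) {
  cat("<crossfeed_report> ", nrow(x$matrix), " species x ",
      ncol(x$matrix), " metabolites, averaged over ", x$n_solutions,
      " solution(s)\n", sep = "")
  cat("  mean |rate| = ", format(x$overall_mean, digits = 4),
      ", sd |rate| = ", format(x$overall_sd, digits = 4), " mmol/h\n",
      sep = "")
  invisible(x)
}

#' Rank crossfed metabolites by total exchange
#'
#' Orders metabolites by the summed absolute exchange rate across species
#' (descending), breaking ties lexically by metabolite id.
#'
#' @param report a [crossfeed_report()].
#' @param k number of top metabolites to return.
#' @return character vector of metabolite ids, length `min(k, n)`.
#' @export
rank_crossfed <- function(report, k = 5L) {
  stopifnot(inherits(report, "crossfeed_report"), k >= 0)
  totals <- colSums(abs(report$matrix))
  ord <- order(-totals, colnames(report$matrix))
  colnames(report$matrix)[ord][seq_len(min(k, length(totals)))]
}

#' Bin campaign cases by growth fraction
#'
#' Accepted cases are assigned to half-open bins
#' `[center - width/2, center + width/2)` over the growth fraction
#' `mu / mu_max`; cases outside every bin are counted as out-of-range.
#' Per bin: case count and mean/standard deviation of richness,
#' equitability and SCFA fractions.
#'
#' @param cases a `tradeoff_campaign` or its case table (data.frame).
#' @param centers bin centers (default 15 bins, 0.71 to 0.99).
#' @param width bin width (default 0.02).
#' @return A `binned_summary` data.frame (one row per bin) with attributes
#'   `out_of_range` (case count) and `width`.
#' @export
bin_cases <- function(cases, centers = seq(0.71, 0.99, by = 0.02),
                      width = 0.02) {
  df <- if (is.data.frame(cases)) cases else as.data.frame(cases)
  df <- df[df$accepted, , drop = FALSE]
  half <- width / 2
  bin_of <- function(fr) {
    hit <- which(fr >= centers - half & fr < centers + half)
    if (length(hit)) hit[1L] else NA_integer_
  }
  bi <- vapply(df$growth_fraction, bin_of, integer(1))
  stat <- function(v, idx, fun) {
    if (!length(idx)) return(NA_real_)
    x <- v[idx]
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    if (identical(fun, "mean")) mean(x) else
      if (length(x) > 1L) stats::sd(x) else 0
  }
  rows <- lapply(seq_along(centers), function(b) {
    idx <- which(!is.na(bi) & bi == b)
    data.frame(center = centers[b],
               n = length(idx),
               richness_mean = stat(df$richness, idx, "mean"),
               richness_sd = stat(df$richness, idx, "sd"),
               equitability_mean = stat(df$equitability, idx, "mean"),
               equitability_sd = stat(df$equitability, idx, "sd"),
               scfa_acetate_mean = stat(df$scfa_acetate, idx, "mean"),
               scfa_butyrate_mean = stat(df$scfa_butyrate, idx, "mean"),
               scfa_butyrate_sd = stat(df$scfa_butyrate, idx, "sd"),
               scfa_propionate_mean = stat(df$scfa_propionate, idx,
                                           "mean"),
               scfa_propionate_sd = stat(df$scfa_propionate, idx, "sd"))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("binned_summary", "data.frame")
  attr(out, "out_of_range") <- sum(is.na(bi))
  attr(out, "width") <- width
  out
}

#' Ordinary least squares fit of the growth-diversity tradeoff
#'
#' Regresses equitability on the growth fraction over accepted cases below
#' `max_fraction` (the tradeoff is linear away from the immediate vicinity
#' of the optimum, where the equitability collapses to the unique maximal
#' solution).
#'
#' @param cases a `tradeoff_campaign` or its case table.
#' @param max_fraction upper growth-fraction cutoff for the fit.
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
fit_tradeoff_line <- function(cases, max_fraction = 0.97) {
  df <- if (is.data.frame(cases)) cases else as.data.frame(cases)
  df <- df[df$accepted & df$growth_fraction < max_fraction, ,
           drop = FALSE]
  if (nrow(df) < 3L)
    stop("need at least 3 accepted cases below max_fraction = ",
         max_fraction, call. = FALSE)
  if (stats::sd(df$growth_fraction) < 1e-12)
    stop("degenerate fit: growth fractions have no variance",
         call. = FALSE)
  fit <- stats::lm(equitability ~ growth_fraction, data = df)
  sst <- sum((df$equitability - mean(df$equitability))^2)
  ssr <- sum(stats::residuals(fit)^2)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = if (sst < 1e-15) 1 else 1 - ssr / sst,
       n = nrow(df))
}

#' Per-species presence fraction across campaign cases
#'
#' Fraction of accepted cases in which a species' abundance exceeds the
#' threshold.
#'
#' @param cases a `tradeoff_campaign` or its case table.
#' @param threshold abundance threshold (strict).
#' @return named numeric vector, one entry per species.
#' @export
presence_fraction <- function(cases, threshold = 0.01) {
  df <- if (is.data.frame(cases)) cases else as.data.frame(cases)
  df <- df[df$accepted, , drop = FALSE]
  if (!nrow(df)) stop("no accepted cases", call. = FALSE)
  pcols <- grep("^p_", names(df), value = TRUE)
  out <- vapply(pcols, function(cl) mean(df[[cl]] > threshold),
                numeric(1))
  names(out) <- sub("^p_", "", pcols)
  out
}

#' Rank correlation between abundances and single-species growth rates
#'
#' Spearman rank correlation with a seeded permutation test (two-sided):
#' the observed |rho| is compared against `n_perm` permutations of one
#' vector.  Rank-based correlation is used because optimal communities
#' leave many species at zero abundance.
#'
#' @param abundances,growth_rates equal-length numeric vectors, `N >= 4`.
#' @param n_perm number of permutations.
#' @param seed optional integer seed for the permutation draw.
#' @return list with `rho` and `p_value`.
#' @export
abundance_growth_correlation <- function(abundances, growth_rates,
                                         n_perm = 10000L, seed = NULL) {
  stopifnot(length(abundances) == length(growth_rates),
            length(abundances) >= 4L)
  if (stats::sd(abundances) < 1e-15 || stats::sd(growth_rates) < 1e-15)
    stop("constant vector: rank correlation undefined", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rho <- stats::cor(abundances, growth_rates, method = "spearman")
  ra <- rank(abundances)
  rg <- rank(growth_rates)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    rp <- stats::cor(ra, sample(rg), method = "pearson")
    if (abs(rp) >= abs(rho) - 1e-12) hits <- hits + 1L
  }
  list(rho = rho, p_value = (hits + 1L) / (n_perm + 1L))
}
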