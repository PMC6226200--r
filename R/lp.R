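#' Solve a linear program
#'
#' Dense two-phase primal simplex with Dantzig pricing, a Bland's-rule
#' fallback for anti-cycling, and periodic refactorization: after bounded
#' bursts of tableau pivots the basis inverse is recomputed from the
#' original data by direct linear solve, which removes accumulated
#' round-off and certifies optimality on clean reduced costs.
#' Deterministic: identical inputs always yield the same optimal basis,
#' which the community analyses rely on for reproducibility.  Intended for
#' the small, sparse LPs that arise from toy community models (up to a few
#' hundred rows); it is not a general-purpose large-scale solver.
#'
#' Variables may have finite bounds on both sides, a finite lower bound
#' with `Inf` above, or be fully free (`-Inf`, `Inf`).  A finite upper
#' bound with an infinite lower bound is not supported.
#'
#' @param obj objective coefficients (length n).
#' @param mat constraint matrix (m x n).
#' @param dir character vector of constraint directions, one of
#'   `"<="`, `">="`, `"="`.
#' @param rhs right-hand sides (length m).
#' @param lower,upper variable bounds (length n).
#' @param maximize maximize (default) or minimize the objective.
#' @param tol pivot/feasibility tolerance.
#' @param max_rounds refactorization rounds per phase (each round runs up
#'   to 500 pivots).
#'
#' @return A list with elements `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`, `"maxiter"` or `"numeric_failure"`), and for optimal
#'   solutions `x` (primal solution) and `objval`.
#' @useDynLib commfba, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @export
solve_lp <- function(obj, mat, dir, rhs, lower, upper, maximize = TRUE,
                     tol = 1e-9, max_rounds = 60L) {
  n <- length(obj)
  mat <- as.matrix(mat)
  m <- nrow(mat)
  stopifnot(ncol(mat) == n, length(dir) == m, length(rhs) == m,
            length(lower) == n, length(upper) == n,
            all(dir %in% c("<=", ">=", "=")),
            all(lower <= upper + 1e-12))
  if (any(!is.finite(lower) & is.finite(upper)))
    stop("variables with -Inf lower and finite upper bound are not ",
         "supported")

  # free variables are split as x = x+ - x-
  free <- which(!is.finite(lower))
  n2 <- n + length(free)
  A0 <- mat
  lower2 <- lower
  upper2 <- upper
  if (length(free)) {
    A0 <- cbind(mat, -mat[, free, drop = FALSE])
    lower2[free] <- 0
    upper2[free] <- Inf
    lower2 <- c(lower2, rep(0, length(free)))
    upper2 <- c(upper2, rep(Inf, length(free)))
  }
  obj2 <- c(obj, if (length(free)) -obj[free])

  # shift to y = x - lower >= 0; finite upper bounds become rows
  shift <- lower2
  rhs2 <- rhs - as.vector(A0 %*% shift)
  ub <- upper2 - shift
  fin <- which(is.finite(ub))
  A <- A0
  d <- dir
  b <- rhs2
  if (length(fin)) {
    Aub <- matrix(0, length(fin), n2)
    Aub[cbind(seq_along(fin), fin)] <- 1
    A <- rbind(A, Aub)
    d <- c(d, rep("<=", length(fin)))
    b <- c(b, ub[fin])
  }
  mm <- nrow(A)
  # row equilibration: pivot magnitudes become comparable across rows,
  # which matters because stoichiometric coefficients and bound caps span
  # several orders of magnitude
  rs <- apply(abs(A), 1L, max)
  rs[rs < 1e-12] <- 1
  A <- A / rs
  b <- b / rs
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    d[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[d[neg]]
  }

  # standard form [A | slack | surplus | artificial], b >= 0
  n_sl <- sum(d == "<=")
  n_su <- sum(d == ">=")
  n_ar <- sum(d != "<=")
  ncols <- n2 + n_sl + n_su + n_ar
  A_std <- matrix(0, mm, ncols)
  A_std[, seq_len(n2)] <- A
  basis <- integer(mm)
  isl <- n2
  isu <- n2 + n_sl
  iar <- n2 + n_sl + n_su
  for (i in seq_len(mm)) {
    if (d[i] == "<=") {
      isl <- isl + 1L
      A_std[i, isl] <- 1
      basis[i] <- isl
    } else if (d[i] == ">=") {
      isu <- isu + 1L
      A_std[i, isu] <- -1
      iar <- iar + 1L
      A_std[i, iar] <- 1
      basis[i] <- iar
    } else {
      iar <- iar + 1L
      A_std[i, iar] <- 1
      basis[i] <- iar
    }
  }
  art <- if (n_ar > 0) (n2 + n_sl + n_su + 1L):ncols else integer(0)
  allowed <- rep(TRUE, ncols)

  # one phase: pivot bursts interleaved with refactorization until the
  # clean reduced costs certify optimality.  If drift still pushes the
  # basis out of primal feasibility the phase restarts once from the
  # initial basis with tiny bursts and Bland pricing throughout.
  run_phase <- function(Tm0, basis0, cost, allowed) {
    for (attempt in 1:2) {
      burst <- if (attempt == 1L) 40L else 15L
      bland_after <- if (attempt == 1L) 2000L else 0L
      Tm <- Tm0
      basis <- basis0
      unbounded_clean <- FALSE
      failed <- FALSE
      for (round in seq_len(max_rounds)) {
        r <- .simplex_core(Tm, basis, cost, allowed, tol, bland_after,
                           burst)
        basis <- r$basis
        B <- A_std[, basis, drop = FALSE]
        Tm <- tryCatch(solve(B, cbind(A_std, b)),
                       error = function(e) NULL)
        if (is.null(Tm)) {
          failed <- TRUE
          break
        }
        xb <- Tm[, ncols + 1L]
        if (any(xb < -5e-7)) {
          failed <- TRUE
          break
        }
        Tm[, ncols + 1L] <- pmax(xb, 0)
        red <- as.vector(crossprod(Tm[, seq_len(ncols), drop = FALSE],
                                   cost[basis])) - cost
        if (all(red[allowed] >= -1e-7))
          return(list(status = "optimal", Tm = Tm, basis = basis))
        if (r$status == 1L) {
          # unbounded must be reproduced from a refactorized tableau
          if (unbounded_clean) return(list(status = "unbounded"))
          unbounded_clean <- TRUE
        } else unbounded_clean <- FALSE
      }
      if (!failed) return(list(status = "maxiter"))
    }
    list(status = "numeric_failure")
  }

  Tm <- cbind(A_std, b)  # initial basis columns form an identity
  if (length(art)) {
    cost1 <- rep(0, ncols)
    cost1[art] <- -1
    ph1 <- run_phase(Tm, basis, cost1, allowed)
    if (ph1$status != "optimal") return(list(status = ph1$status))
    Tm <- ph1$Tm
    basis <- ph1$basis
    if (sum(Tm[basis %in% art, ncols + 1L]) > 1e-6)
      return(list(status = "infeasible"))
    # drive leftover zero-valued artificials out of the basis; rows where
    # no structural pivot exists are redundant and dropped
    drop_rows <- integer(0)
    for (i in which(basis %in% art)) {
      row <- Tm[i, seq_len(ncols)]
      row[art] <- 0
      q <- which(abs(row) > 1e-7)[1L]
      if (is.na(q)) {
        drop_rows <- c(drop_rows, i)
      } else {
        piv <- Tm[i, ] / Tm[i, q]
        Tm <- Tm - outer(Tm[, q], piv)
        Tm[i, ] <- piv
        basis[i] <- q
      }
    }
    if (length(drop_rows)) {
      A_std <- A_std[-drop_rows, , drop = FALSE]
      b <- b[-drop_rows]
      Tm <- Tm[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
    }
    allowed[art] <- FALSE
  }

  cost2 <- rep(0, ncols)
  cost2[seq_len(n2)] <- if (maximize) obj2 else -obj2
  ph2 <- run_phase(Tm, basis, cost2, allowed)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  y <- numeric(ncols)
  y[ph2$basis] <- ph2$Tm[, ncols + 1L]
  x <- y[seq_len(n)] + shift[seq_len(n)]
  if (length(free))
    x[free] <- y[free] - y[n + seq_along(free)]

  # final sanity check against the original constraints
  resid <- as.vector(mat %*% x) - rhs
  viol <- max(0,
              abs(resid[dir == "="]),
              resid[dir == "<="],
              -resid[dir == ">="],
              lower[is.finite(lower)] - x[is.finite(lower)],
              x[is.finite(upper)] - upper[is.finite(upper)])
  if (viol > 1e-6) return(list(status = "numeric_failure"))
  list(status = "optimal", x = x, objval = sum(obj * x))
}
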