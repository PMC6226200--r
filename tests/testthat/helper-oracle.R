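# Independent oracles.
#
# brute_lp: maximum of an LP over {A x <= b, l <= x <= u} by enumerating
# every vertex (all n-subsets of active constraints).  Exponential, for
# tiny problems only.
brute_lp <- function(cc, A, b, l, u) {
  n <- length(cc)
  rows <- rbind(A, diag(n), -diag(n))
  rhs <- c(b, u, -l)
  best <- -Inf
  cmb <- utils::combn(nrow(rows), n)
  for (j in seq_len(ncol(cmb))) {
    S <- rows[cmb[, j], , drop = FALSE]
    if (abs(det(S)) < 1e-9) next
    x <- tryCatch(solve(S, rhs[cmb[, j]]), error = function(e) NULL)
    if (is.null(x)) next
    if (all(rows %*% x <= rhs + 1e-8)) best <- max(best, sum(cc * x))
  }
  best
}

# all abundance vectors on the unit simplex with the given grid step
simplex_grid <- function(n, step = 0.01) {
  k <- round(1 / step)
  if (n == 2L) {
    i <- 0:k
    return(cbind(i, k - i) / k)
  }
  stopifnot(n == 3L)
  out <- matrix(0, 0, 3L)
  for (i in 0:k) {
    j <- 0:(k - i)
    out <- rbind(out, cbind(i, j, k - i - j))
  }
  out / k
}

# LP over fluxes and community exchanges at FIXED abundances p.  With p
# fixed the abundance-scaled flux bounds become plain variable bounds, so
# this is assembled independently of the package's community LP skeleton.
# mu = NULL adds mu as a variable and maximizes it; otherwise growth is
# fixed and feasibility is tested.
fixed_abundance_lp <- function(cm, p, mu = NULL) {
  tpl <- cm$templates
  ids <- cm$species
  lumen <- cm$lumen_mets
  nV <- sum(vapply(tpl, function(m) nrow(m$rxns), integer(1)))
  ne <- length(lumen)
  free_mu <- is.null(mu)
  nvar <- nV + ne + as.integer(free_mu)

  lower <- numeric(nvar)
  upper <- numeric(nvar)
  off <- 0L
  for (k in seq_along(ids)) {
    m <- tpl[[k]]
    idx <- off + seq_len(nrow(m$rxns))
    lower[idx] <- m$rxns$lb * p[k]
    upper[idx] <- m$rxns$ub * p[k]
    off <- off + nrow(m$rxns)
  }
  ie <- nV + seq_len(ne)
  lower[ie] <- -vapply(lumen, function(met)
    if (met %in% names(cm$diet$max_uptake)) cm$diet$max_uptake[[met]]
    else 0, numeric(1))
  upper[ie] <- cm$secretion_cap
  if (free_mu) {
    lower[nvar] <- 0
    upper[nvar] <- Inf
  }

  rows <- list()
  rhs <- numeric(0)
  add <- function(idx, coef, b) {
    r <- numeric(nvar)
    r[idx] <- coef
    rows[[length(rows) + 1L]] <<- r
    rhs <<- c(rhs, b)
  }
  off <- 0L
  for (k in seq_along(ids)) {
    m <- tpl[[k]]
    cols <- off + seq_len(nrow(m$rxns))
    for (i in seq_len(nrow(m$mets))) {
      nz <- which(m$S[i, ] != 0)
      add(cols[nz], m$S[i, nz], 0)
    }
    bcol <- cols[match(m$biomass_id, m$rxns$id)]
    if (free_mu) add(c(bcol, nvar), c(1, -p[k]), 0) else
      add(bcol, 1, mu * p[k])
    off <- off + nrow(m$rxns)
  }
  for (l in seq_along(lumen)) {
    excols <- integer(0)
    off <- 0L
    for (k in seq_along(ids)) {
      m <- tpl[[k]]
      exm <- exchange_mets(m)
      r <- names(exm)[exm == lumen[l]]
      if (length(r)) excols <- c(excols, off + match(r, m$rxns$id))
      off <- off + nrow(m$rxns)
    }
    add(c(excols, ie[l]), c(rep(1, length(excols)), -1), 0)
  }
  A <- do.call(rbind, rows)
  obj <- numeric(nvar)
  if (free_mu) obj[nvar] <- 1
  solve_lp(obj, A, rep("=", nrow(A)), rhs, lower, upper, maximize = TRUE)
}

# maximal community growth over an abundance-simplex grid scan
grid_max_mu <- function(cm, step = 0.01, p_cap = NULL) {
  pts <- simplex_grid(length(cm$species), step)
  best <- 0
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (!is.null(p_cap) && any(p > p_cap + 1e-12)) next
    r <- fixed_abundance_lp(cm, p)
    if (r$status == "optimal") best <- max(best, r$objval)
  }
  best
}

# feasible abundance ranges at fixed growth over a grid scan
grid_abundance_range <- function(cm, mu, step = 0.01) {
  pts <- simplex_grid(length(cm$species), step)
  n <- length(cm$species)
  p_min <- rep(Inf, n)
  p_max <- rep(-Inf, n)
  any_feasible <- FALSE
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    r <- fixed_abundance_lp(cm, p, mu = mu)
    if (r$status == "optimal") {
      any_feasible <- TRUE
      p_min <- pmin(p_min, p)
      p_max <- pmax(p_max, p)
    }
  }
  stopifnot(any_feasible)
  list(p_min = p_min, p_max = p_max)
}
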