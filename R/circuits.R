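#' Parameters of the bifurcation gene circuits
#'
#' Both circuit models share a Hill-type rate law: auto-activation of
#' strength `alpha` with an increasing sigmoid `x^n / (s^n + x^n)` (0 at
#' `x = 0`, 0.5 at `x = s`, saturating at 1), cross-inhibition of strength
#' `beta` with the decreasing sigmoid `s^n / (s^n + x^n)`, and first-order
#' degradation at rate `gamma`. A perturbation is expressed by raising the
#' degradation rate of one transcription factor (e.g. `gamma* = 1.5` versus
#' the basal 1).
#'
#' @param alpha Auto-activation strength (default 1.5).
#' @param beta Cross-inhibition strength (default 1).
#' @param n Hill steepness (default 4).
#' @param s Half-maximum concentration (default 0.5).
#' @param gamma Degradation rate(s): a scalar shared by all TFs, or one rate
#'   per TF (length 2 for the two-TF model in order `u`, `v`; length 4 for
#'   the two-cluster model in order `u1`, `u2`, `v1`, `v2`).
#' @return A list of class `"circuit_params"`.
#' @examples
#' circuit_params()                      # unperturbed defaults
#' circuit_params(gamma = c(1.5, 1))     # two-TF, u degraded 50% faster
#' @export
circuit_params <- function(alpha = 1.5, beta = 1, n = 4, s = 0.5, gamma = 1) {
  if (alpha < 0 || beta < 0 || s <= 0) abort("need alpha, beta >= 0 and s > 0")
  if (n < 1) abort("Hill steepness n must be >= 1")
  if (any(gamma <= 0)) abort("degradation rates must be positive")
  if (!length(gamma) %in% c(1, 2, 4)) {
    abort("gamma must have length 1 (shared), 2 (two-TF) or 4 (two-cluster)")
  }
  structure(list(alpha = alpha, beta = beta, n = n, s = s, gamma = gamma),
            class = "circuit_params")
}

gamma_for <- function(p, d) {
  g <- p$gamma
  if (length(g) == 1) rep(g, d)
  else if (length(g) == d) g
  else abort(paste0("gamma has length ", length(g), " but the model has ",
                    d, " TFs"))
}

#' Two-TF circuit right-hand side
#'
#' Rates of change of the opposing TF concentrations `u` and `v`:
#' `du/dt = alpha u^n/(s^n+u^n) + beta s^n/(s^n+v^n) - gamma_u u` and the
#' mirrored equation for `v`. Accepts a single state `c(u, v)` or a matrix
#' with one state per row (used by the population simulation).
#'
#' @param state Numeric length-2 vector `c(u, v)`, or an n-by-2 matrix.
#' @param p A [circuit_params()]; `gamma` of length 1 or 2.
#' @return Derivatives with the same shape as `state`.
#' @export
two_tf_rhs <- function(state, p = circuit_params()) {
  g <- gamma_for(p, 2)
  m <- if (is.matrix(state)) state else matrix(state, nrow = 1)
  if (any(m < 0)) abort("TF concentrations must be non-negative")
  sn <- p$s^p$n
  un <- m[, 1]^p$n
  vn <- m[, 2]^p$n
  du <- p$alpha * un / (sn + un) + p$beta * sn / (sn + vn) - g[1] * m[, 1]
  dv <- p$alpha * vn / (sn + vn) + p$beta * sn / (sn + un) - g[2] * m[, 2]
  out <- cbind(du, dv)
  if (is.matrix(state)) out else c(out)
}

#' Generic rate law of one TF inside a cluster
#'
#' `eta(a, b, c, d, gamma_a)` is the rate of change of TF `a` when `a` and
#' `b` form one cluster and `c` and `d` the opposing cluster: the cluster's
#' pooled auto-activation `alpha (a^n + b^n)/(s^n + a^n + b^n)`, plus
#' relief-of-inhibition `beta s^n/(s^n + c^n + d^n)` from the other cluster,
#' minus degradation `gamma_a * a`. Vectorised over its concentration
#' arguments.
#'
#' @param a,b Concentrations of the TF itself and its cluster partner.
#' @param c_,d_ Concentrations of the two TFs of the opposing cluster.
#' @param p A [circuit_params()].
#' @param gamma_a Degradation rate applied to `a`.
#' @return Rate of change of `a`.
#' @export
eta <- function(a, b, c_, d_, p = circuit_params(), gamma_a = p$gamma[1]) {
  if (any(c(a, b, c_, d_) < 0)) abort("concentrations must be non-negative")
  sn <- p$s^p$n
  act <- p$alpha * (a^p$n + b^p$n) / (sn + a^p$n + b^p$n)
  inh <- p$beta * sn / (sn + c_^p$n + d_^p$n)
  act + inh - gamma_a * a
}

#' Two-cluster circuit right-hand side
#'
#' Four TFs in two clusters (`u1`, `u2` versus `v1`, `v2`), each following
#' the [eta()] rate law with its own degradation rate. The cluster totals
#' `x = u1 + u2` and `y = v1 + v2` change at the sums of the member rates.
#'
#' @param state Numeric length-4 vector `c(u1, u2, v1, v2)`, or an n-by-4
#'   matrix of states.
#' @param p A [circuit_params()]; `gamma` of length 1 or 4 (order `u1`,
#'   `u2`, `v1`, `v2`).
#' @return Derivatives with the same shape as `state`.
#' @export
two_cluster_rhs <- function(state, p = circuit_params()) {
  g <- gamma_for(p, 4)
  m <- if (is.matrix(state)) state else matrix(state, nrow = 1)
  out <- cbind(
    eta(m[, 1], m[, 2], m[, 3], m[, 4], p, g[1]),
    eta(m[, 2], m[, 1], m[, 4], m[, 3], p, g[2]),
    eta(m[, 3], m[, 4], m[, 1], m[, 2], p, g[3]),
    eta(m[, 4], m[, 3], m[, 2], m[, 1], p, g[4])
  )
  if (is.matrix(state)) out else c(out)
}

circuit_dim <- function(model) {
  switch(match.arg(model, c("two_tf", "two_cluster")),
         two_tf = 2L, two_cluster = 4L)
}

circuit_rhs <- function(model, state, p) {
  switch(match.arg(model, c("two_tf", "two_cluster")),
         two_tf = two_tf_rhs(state, p),
         two_cluster = two_cluster_rhs(state, p))
}

#' Evaluate the circuit force field on a grid
#'
#' Samples the phase-space velocity on a regular 2-D grid. For the two-TF
#' model the grid is over `(u, v)`. For the two-cluster model the grid is
#' over the cluster totals `(x, y)` evaluated on the symmetric slice
#' `u1 = u2 = x/2`, `v1 = v2 = y/2` (within-cluster differences decay at
#' rate `gamma`, so the slice captures the long-run flow), with the plotted
#' vector `(dx/dt, dy/dt)`. Short arrows (low `speed`) mark the stable
#' regions of the landscape.
#'
#' @param model `"two_tf"` or `"two_cluster"`.
#' @param p A [circuit_params()].
#' @param domain Numeric length-2, the common axis range (default `c(0, 3)`).
#' @param resolution Grid points per axis (default 60, at least 2).
#' @return A tibble of class `"force_field"` with the grid coordinates, the
#'   velocity components (`du`,`dv` or `dx`,`dy`) and `speed`.
#' @export
force_field <- function(model, p = circuit_params(), domain = c(0, 3),
                        resolution = 60) {
  model <- match.arg(model, c("two_tf", "two_cluster"))
  if (resolution < 2) abort("resolution must be at least 2")
  if (domain[1] < 0) abort("the domain must lie in the non-negative orthant")
  ax <- seq(domain[1], domain[2], length.out = resolution)
  grid <- expand.grid(a = ax, b = ax)
  if (model == "two_tf") {
    d <- two_tf_rhs(cbind(grid$a, grid$b), p)
    out <- tibble(u = grid$a, v = grid$b, du = d[, 1], dv = d[, 2],
                  speed = sqrt(d[, 1]^2 + d[, 2]^2))
  } else {
    st <- cbind(grid$a / 2, grid$a / 2, grid$b / 2, grid$b / 2)
    d <- two_cluster_rhs(st, p)
    dx <- d[, 1] + d[, 2]
    dy <- d[, 3] + d[, 4]
    out <- tibble(x = grid$a, y = grid$b, dx = dx, dy = dy,
                  speed = sqrt(dx^2 + dy^2))
  }
  structure(out, model = model, params = p,
            class = c("force_field", class(tibble())))
}

# damped Newton iteration for one start; returns root or NULL
newton_root <- function(rhs, x0, tol, max_iter = 60, h = 1e-6) {
  x <- x0
  fx <- rhs(x)
  for (iter in seq_len(max_iter)) {
    nf <- sqrt(sum(fx^2))
    if (!is.finite(nf)) return(NULL)
    if (nf < tol) return(list(root = x, residual = nf))
    J <- num_jacobian(rhs, x, h)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      xn <- pmax(x - lambda * step, 0)
      fn <- rhs(xn)
      if (sqrt(sum(fn^2)) < nf || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (sqrt(sum((xn - x)^2)) < 1e-14 && sqrt(sum(fn^2)) >= tol) return(NULL)
    x <- xn
    fx <- fn
  }
  if (sqrt(sum(fx^2)) < tol) list(root = x, residual = sqrt(sum(fx^2))) else NULL
}

# central finite-difference Jacobian
num_jacobian <- function(rhs, x, h = 1e-6) {
  d <- length(x)
  J <- matrix(0, d, d)
  for (j in seq_len(d)) {
    e <- numeric(d)
    e[j] <- h
    xp <- pmax(x + e, 0)
    xm <- pmax(x - e, 0)
    J[, j] <- (rhs(xp) - rhs(xm)) / (xp[j] - xm[j])
  }
  J
}

#' Locate and classify the circuit's fixed points
#'
#' Multi-start damped Newton iteration on the circuit right-hand side. For
#' the two-TF model starts form an `n_starts` x `n_starts` lattice over the
#' domain square. For the two-cluster model the full 4-D system is searched
#' from a lattice on the symmetric slice (`u1 = u2`, `v1 = v2`) augmented
#' with a coarse full 4-D lattice, since perturbed circuits have
#' asymmetric roots. Converged roots are deduplicated, their Jacobians
#' computed by central finite differences (step 1e-6), and stability read
#' off the eigenvalue real parts: all negative is `stable`, all positive
#' `unstable`, mixed is `saddle`. Real parts within 1e-8 of zero are
#' treated as marginal and classified `saddle` to avoid silently
#' mislabelling states at a bifurcation.
#'
#' @param model `"two_tf"` or `"two_cluster"`.
#' @param p A [circuit_params()].
#' @param domain Numeric length-2 axis range searched (default `c(0, 3)`).
#' @param n_starts Lattice points per axis (default 40 for two-TF, 12 for
#'   the two-cluster slice).
#' @param coarse_4d Points per axis of the auxiliary full 4-D lattice for
#'   the two-cluster model (default 6).
#' @param tol Residual norm required of a root (default 1e-10).
#' @return A tibble of class `"fixed_points"`, one row per distinct root,
#'   with the coordinates (plus cluster totals `x`, `y` for the two-cluster
#'   model), `residual`, `max_re` (largest eigenvalue real part), `kind`
#'   (`stable`/`saddle`/`unstable`) and `marginal`. Sorted by coordinates.
#'   Empty (with a warning) if no start converges.
#' @examples
#' fp <- find_fixed_points("two_tf", circuit_params())
#' count_stable(fp)   # tristable: progenitor + two committed lineages
#' @export
find_fixed_points <- function(model, p = circuit_params(), domain = c(0, 3),
                              n_starts = NULL, coarse_4d = 6, tol = 1e-10) {
  model <- match.arg(model, c("two_tf", "two_cluster"))
  if (domain[1] < 0) abort("the domain must lie in the non-negative orthant")
  d <- circuit_dim(model)
  rhs <- function(x) circuit_rhs(model, x, p)
  if (is.null(n_starts)) n_starts <- if (d == 2) 40 else 12
  ax <- seq(domain[1], domain[2], length.out = n_starts)
  if (d == 2) {
    starts <- as.matrix(expand.grid(ax, ax))
  } else {
    slice <- as.matrix(expand.grid(ax, ax))
    starts <- cbind(slice[, 1] / 2, slice[, 1] / 2,
                    slice[, 2] / 2, slice[, 2] / 2)
    ax4 <- seq(domain[1], domain[2], length.out = coarse_4d)
    starts <- rbind(starts, as.matrix(expand.grid(ax4, ax4, ax4, ax4)))
  }
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    r <- newton_root(rhs, starts[i, ], tol = tol)
    if (is.null(r)) next
    if (any(r$root > domain[2] + 1) || any(r$root < -1e-8)) next
    dup <- FALSE
    for (rr in roots) {
      if (sqrt(sum((rr$root - r$root)^2)) < max(10 * tol, 1e-7)) {
        dup <- TRUE
        break
      }
    }
    if (!dup) roots[[length(roots) + 1]] <- r
  }
  if (length(roots) == 0) {
    warn("no Newton start converged; returning an empty fixed-point set")
  }
  rows <- lapply(roots, function(r) {
    J <- num_jacobian(rhs, r$root)
    ev <- eigen(J, only.values = TRUE)$values
    re <- Re(ev)
    marginal <- any(abs(re) <= 1e-8)
    kind <- if (marginal) "saddle"
            else if (all(re < 0)) "stable"
            else if (all(re > 0)) "unstable"
            else "saddle"
    loc <- as.list(setNames(r$root, paste0("c", seq_len(d))))
    c(loc, list(residual = r$residual, max_re = max(re), kind = kind,
                marginal = marginal))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(residual = numeric(), max_re = numeric(),
                  kind = character(), marginal = logical())
  } else {
    names(out)[seq_len(d)] <- if (d == 2) c("u", "v") else
      c("u1", "u2", "v1", "v2")
    if (d == 4) {
      out$x <- out$u1 + out$u2
      out$y <- out$v1 + out$v2
    }
    out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(
      if (d == 2) c("u", "v") else c("u1", "u2", "v1", "v2"))))
  }
  structure(out, model = model, params = p,
            class = c("fixed_points", class(tibble())))
}

#' Count the stable fixed points
#'
#' @param fps A [find_fixed_points()] result.
#' @return Number of attractors (rows with `kind == "stable"`).
#' @export
count_stable <- function(fps) {
  if (nrow(fps) == 0) return(0L)
  sum(fps$kind == "stable")
}
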