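# Analytic toy potentials, collective-variable definitions, a BAOAB Langevin
# integrator, and brute-force quadrature oracles. These systems play the role
# of the biomolecular benchmarks: the quadrature results are the ground truth
# that every sampling estimate is checked against.

.SYS_IDS <- c(double_well_1d = 1L, hidden_barrier_2d = 2L,
              mueller_brown = 3L, harmonic_2d = 4L)

.sys_defaults <- function(name) {
  switch(name,
    double_well_1d    = list(h = 5, d = 2),
    hidden_barrier_2d = list(h_x = 5, h_y = 25, k_c = 8, d = 2),
    mueller_brown     = list(scale = 1),
    harmonic_2d       = list(k = 1),
    stop("unknown model system: '", name, "'")
  )
}

.sys_domain <- function(name, params) {
  switch(name,
    double_well_1d    = matrix(c(-2.5, 2.5), 1, 2),
    hidden_barrier_2d = matrix(c(-2.5, -2.5, 2.5, 2.5), 2, 2),
    mueller_brown     = matrix(c(-1.7, -0.5, 1.3, 2.3), 2, 2),
    harmonic_2d       = {
      # +-7 thermal widths at 300 K so quadrature mass loss stays negligible
      # even when averaging at temperatures above the thermostat
      w <- 7 * sqrt(kB * 300 / params$k)
      matrix(c(-w, -w, w, w), 2, 2)
    }
  )
}

.sys_start <- function(name) {
  switch(name,
    double_well_1d    = -1,
    hidden_barrier_2d = c(-1, 1),
    mueller_brown     = c(-0.558, 1.442),
    harmonic_2d       = c(0, 0)
  )
}

#' Create a built-in model system
#'
#' Built-ins:
#' \describe{
#'   \item{`double_well_1d`}{\eqn{U = h (x^2-1)^2 + d x}. A tilted symmetric
#'     double well; the coordinate `x` is a near-ideal CV for it.}
#'   \item{`hidden_barrier_2d`}{\eqn{U = h_x (x^2-1)^2 + h_y (y^2-1)^2 +
#'     k_c x y + d x}. With the defaults (`h_x = 5`, `h_y = 25`, `k_c = 8`,
#'     `d = 2` kJ/mol) the two metastable states are separated along `x` by a
#'     low barrier, but interconversion requires crossing the much higher
#'     barrier along `y`: biasing `x` alone is the classic suboptimal-CV
#'     situation that replica-ladder methods are designed to rescue.}
#'   \item{`mueller_brown`}{The standard four-Gaussian Mueller-Brown surface
#'     (optionally scaled by `scale`).}
#'   \item{`harmonic_2d`}{\eqn{U = k(x^2+y^2)/2}, exactly solvable.}
#' }
#'
#' @param name one of the built-in system names.
#' @param ... named parameter overrides (see the defaults above).
#' @return an object of class `oneopes_system` with fields `name`, `dim`,
#'   `params`, `domain` (per-dimension quadrature bounds), vectorized `U(x)`
#'   and `grad(x)` closures, and a `start` coordinate guess.
#' @examples
#' sys <- make_system("double_well_1d", d = 0)
#' sys$U(rbind(-1, 0, 1))    # 0, h, 0
#' @export
make_system <- function(name, ...) {
  params <- .sys_defaults(name)
  over <- list(...)
  bad <- setdiff(names(over), names(params))
  if (length(bad) > 0)
    stop("unknown parameter(s) for '", name, "': ", paste(bad, collapse = ", "))
  params[names(over)] <- over
  if (name %in% c("double_well_1d", "hidden_barrier_2d")) {
    hs <- unlist(params[grep("^h", names(params))])
    if (any(hs <= 0))
      stop("well heights must be positive, otherwise U is unbounded below")
  }
  if (name == "harmonic_2d" && params$k <= 0)
    stop("k must be positive, otherwise U is unbounded below")
  id <- .SYS_IDS[[name]]
  dim <- if (name == "double_well_1d") 1L else 2L
  pvec <- as.numeric(unlist(params))
  sys <- list(
    name = name, id = id, dim = dim, params = params,
    param_vec = pvec,
    domain = .sys_domain(name, params),
    start = .sys_start(name)
  )
  sys$U <- function(x) {
    x <- .coerce_coords(x, dim)
    .sys_eval_cpp(id, pvec, x)$U
  }
  sys$grad <- function(x) {
    x <- .coerce_coords(x, dim)
    .sys_eval_cpp(id, pvec, x)$grad
  }
  class(sys) <- "oneopes_system"
  sys
}

.coerce_coords <- function(x, dim) {
  if (is.null(nrow(x))) x <- matrix(x, ncol = dim, byrow = TRUE)
  if (ncol(x) != dim) stop("coordinates must have ", dim, " column(s)")
  x
}

#' @export
print.oneopes_system <- function(x, ...) {
  cat("<oneopes_system>", x$name, sprintf("(%dD)\n", x$dim))
  cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Locate the starting minimum of a system
#'
#' Local minimization (BFGS with the analytic gradient) from the built-in
#' start guess; all replicas of a run begin here.
#' @param system a [make_system()] object.
#' @return coordinate vector of the relaxed minimum.
#' @export
start_minimum <- function(system) {
  res <- optim(system$start,
               fn = function(p) system$U(p),
               gr = function(p) as.numeric(system$grad(p)),
               method = "BFGS", control = list(reltol = 1e-14))
  res$par
}

# ---------------------------------------------------------------- CVs ------

#' Define a collective variable
#'
#' The built-in CVs `"x"` and `"y"` select a coordinate. A custom CV can be
#' given as a pair of functions (`map`, `gradient`); custom CVs are supported
#' by all analysis routines, while the compiled simulation engine requires
#' coordinate CVs.
#'
#' @param id `"x"`, `"y"`, or a name for a custom CV.
#' @param map for custom CVs, a function `coords-matrix -> numeric`.
#' @param gradient for custom CVs, a function `coords-matrix -> matrix`.
#' @param role `"leading"` or `"auxiliary"`.
#' @return object of class `oneopes_cv` with fields `id`, `fun`, `grad`,
#'   `role`, and `coord` (coordinate index or `NA`).
#' @export
make_cv <- function(id, map = NULL, gradient = NULL,
                    role = c("leading", "auxiliary")) {
  role <- match.arg(role)
  coord <- match(id, c("x", "y"))
  if (!is.na(coord)) {
    fun <- function(x) {
      if (is.null(nrow(x))) x <- matrix(x, nrow = 1)
      x[, coord]
    }
    grd <- function(x) {
      if (is.null(nrow(x))) x <- matrix(x, nrow = 1)
      g <- matrix(0, nrow(x), ncol(x))
      g[, coord] <- 1
      g
    }
  } else {
    if (is.null(map) || is.null(gradient))
      stop("custom CV '", id, "' needs both `map` and `gradient`")
    fun <- map
    grd <- gradient
  }
  structure(list(id = id, fun = fun, grad = grd, role = role, coord = coord),
            class = "oneopes_cv")
}

# ------------------------------------------------------------- Langevin ----

#' Langevin integrator parameters
#'
#' @param timestep integration step in ps (> 0).
#' @param friction friction coefficient in 1/ps (>= 0; 0 gives frictionless,
#'   symplectic velocity-Verlet dynamics).
#' @param mass particle mass (per-coordinate scalar).
#' @param temperature thermostat temperature in K (> 0).
#' @param seed integer RNG seed.
#' @export
langevin_params <- function(timestep = 0.002, friction = 5, mass = 1,
                            temperature = 300, seed = 1) {
  if (timestep <= 0) stop("timestep must be > 0")
  if (friction < 0) stop("friction must be >= 0")
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(timestep = timestep, friction = friction, mass = mass,
                 temperature = temperature, seed = as.integer(seed)),
            class = "langevin_params")
}

#' One BAOAB Langevin step
#'
#' Splitting B-A-O-A-B: half kick, half drift, Ornstein-Uhlenbeck velocity
#' refresh, half drift, half kick with the re-evaluated force. With
#' `friction = 0` the O-step is the identity and the update reduces to
#' symplectic velocity Verlet. Uses R's RNG stream (seed with [set.seed()]).
#'
#' @param state list with `coords`, `velocities`, `time` (a walker state).
#' @param force force at `state$coords` (i.e. \eqn{-\nabla(U + \sum V)}).
#' @param p a [langevin_params()] object.
#' @param force_fun function `coords -> force`, used to re-evaluate the force
#'   at the post-drift position for the final half kick. If `NULL` the initial
#'   force is reused (first-order accurate; fine for testing limits).
#' @param scheme `"baoab"` (default) or `"euler"` (Euler-Maruyama, provided
#'   for comparison).
#' @return updated walker state (with `potential_energy` set to `NA`; callers
#'   owning the potential should refresh it).
#' @export
langevin_step <- function(state, force, p, force_fun = NULL,
                          scheme = c("baoab", "euler")) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(force))) stop("non-finite force")
  kbt <- kB * p$temperature
  x <- state$coords
  v <- state$velocities
  m <- p$mass
  dt <- p$timestep
  if (scheme == "euler") {
    # overdamped-friendly explicit scheme, documented alternative
    v <- v + dt * force / m - dt * p$friction * v +
      sqrt(2 * p$friction * kbt * dt / m) * rnorm(length(v))
    x <- x + dt * v
  } else {
    c1 <- if (p$friction == 0) 1 else exp(-p$friction * dt)
    c2 <- if (p$friction == 0) 0 else sqrt(1 - c1^2)
    v <- v + 0.5 * dt * force / m
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * sqrt(kbt / m) * rnorm(length(v))
    x <- x + 0.5 * dt * v
    f2 <- if (is.null(force_fun)) force else force_fun(x)
    v <- v + 0.5 * dt * f2 / m
  }
  list(coords = x, velocities = v, time = state$time + dt,
       potential_energy = NA_real_)
}

# ----------------------------------------------------------- quadrature ----

# Marginal density of a coordinate CV on a fine grid, by Simpson integration
# over the transverse coordinate (2-D systems) or direct evaluation (1-D).
# Returns exp(-U_eff/kBT) up to a constant, evaluated at `svals`.
.marginal_weight <- function(system, coord, T, svals, npoints = 801) {
  kbt <- kB * T
  if (npoints %% 2 == 0) npoints <- npoints + 1
  # no energy shift: weights must be consistent across independent calls
  if (system$dim == 1)
    return(exp(-system$U(matrix(svals, ncol = 1)) / kbt))
  other <- if (coord == 1) 2 else 1
  tgrid <- seq(system$domain[other, 1], system$domain[other, 2],
               length.out = npoints)
  sw <- .simpson_weights(npoints) * diff(tgrid[1:2])
  X <- matrix(0, length(svals) * npoints, 2)
  X[, coord] <- rep(svals, each = npoints)
  X[, other] <- rep(tgrid, times = length(svals))
  W <- matrix(exp(-system$U(X) / kbt), nrow = npoints)
  as.numeric(crossprod(sw, W))
}

.simpson_weights <- function(n) {
  stopifnot(n %% 2 == 1)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  w / 3
}

# integral of the CV-marginal weight over [lo, hi] by fixed-order
# Gauss-Legendre panels (independent of the transverse grid resolution)
.basin_mass <- function(system, coord, T, lo, hi, npoints = 801) {
  gl <- .gauss_legendre(24)
  npan <- max(8L, ceiling((hi - lo) / 0.25))
  edges <- seq(lo, hi, length.out = npan + 1)
  total <- 0
  for (i in seq_len(npan)) {
    a <- edges[i]; b <- edges[i + 1]
    s <- 0.5 * (b - a) * gl$x + 0.5 * (a + b)
    w <- 0.5 * (b - a) * gl$w
    total <- total + sum(w * .marginal_weight(system, coord, T, s, npoints))
  }
  total
}

.gauss_legendre <- function(n) {
  # Golub-Welsch: eigen-decomposition of the Jacobi matrix
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

.cv_coord <- function(cv, system) {
  if (inherits(cv, "oneopes_cv")) {
    if (is.na(cv$coord)) return(NA_integer_)
    return(cv$coord)
  }
  co <- match(cv, c("x", "y"))
  if (is.na(co)) stop("cv must be an oneopes_cv or one of 'x', 'y'")
  co
}

#' Free-energy profile by dense quadrature (oracle)
#'
#' Computes \eqn{F(s_0) = -k_B T \log \int \delta(s(x)-s_0)\,
#' e^{-U(x)/k_B T} dx} exactly up to quadrature error. For coordinate CVs the
#' transverse dimension is integrated by Simpson's rule on `npoints` nodes and
#' each output bin by fixed-order Gauss-Legendre panels, so the result is
#' stable under grid refinement. Non-coordinate CVs fall back to a dense-grid
#' histogram (lower accuracy).
#'
#' @param system a [make_system()] object (`dim <= 2`).
#' @param cv a [make_cv()] object or `"x"`/`"y"`.
#' @param T temperature in K.
#' @param grid bin edges covering the reachable CV range.
#' @param npoints quadrature nodes per dimension (>= 801; forced odd).
#' @return a `fes_curve`: data frame with `cv` (bin centers) and `F` (kJ/mol,
#'   minimum shifted to 0) plus attributes `temperature` and `edges`.
#' @export
quadrature_fes <- function(system, cv, T = 300, grid = NULL, npoints = 801) {
  if (system$dim > 2) stop("quadrature oracle supports dim <= 2")
  coord <- .cv_coord(cv, system)
  if (is.null(grid)) {
    rng <- if (!is.na(coord)) system$domain[coord, ] else
      stop("grid (bin edges) required for a custom CV")
    grid <- seq(rng[1], rng[2], length.out = 101)
  }
  nb <- length(grid) - 1
  if (!is.na(coord)) {
    mass <- vapply(seq_len(nb), function(b)
      .basin_mass(system, coord, T, grid[b], grid[b + 1], npoints), 0)
    # coverage check: mass at the grid ends must be negligible
    total <- .basin_mass(system, coord, T,
                         system$domain[coord, 1], system$domain[coord, 2],
                         npoints)
    covered <- .basin_mass(system, coord, T, min(grid), max(grid), npoints)
    if ((total - covered) / total > 1e-6)
      stop("grid misses more than 1e-6 of the probability mass")
  } else {
    mass <- .histogram_mass(system, cv, T, grid, npoints)
  }
  kbt <- kB * T
  F <- ifelse(mass > 0, -kbt * log(mass), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  out <- data.frame(cv = (grid[-1] + grid[-length(grid)]) / 2, F = F)
  attr(out, "temperature") <- T
  attr(out, "edges") <- grid
  class(out) <- c("fes_curve", "data.frame")
  out
}

.histogram_mass <- function(system, cv, T, grid, npoints) {
  kbt <- kB * T
  axes <- lapply(seq_len(system$dim), function(d)
    seq(system$domain[d, 1], system$domain[d, 2], length.out = npoints))
  X <- as.matrix(expand.grid(axes))
  colnames(X) <- NULL
  U <- system$U(X)
  w <- exp(-(U - min(U)) / kbt)
  s <- cv$fun(X)
  out <- sum(w[s < min(grid) | s >= max(grid)]) / sum(w)
  if (out > 1e-6) stop("grid misses more than 1e-6 of the probability mass")
  bins <- findInterval(s, grid, rightmost.closed = TRUE)
  vapply(seq_len(length(grid) - 1), function(b) sum(w[bins == b]), 0)
}

#' Boltzmann average of an observable by quadrature (oracle)
#'
#' @param system a [make_system()] object.
#' @param observable function `coords-matrix -> numeric`, or `"U"` for the
#'   potential energy.
#' @param T temperature in K.
#' @param npoints quadrature nodes per dimension (forced odd; Simpson rule).
#' @return the equilibrium average at temperature `T`.
#' @export
quadrature_average <- function(system, observable, T = 300, npoints = 801) {
  if (npoints %% 2 == 0) npoints <- npoints + 1
  kbt <- kB * T
  axes <- lapply(seq_len(system$dim), function(d)
    seq(system$domain[d, 1], system$domain[d, 2], length.out = npoints))
  sw1 <- .simpson_weights(npoints)
  X <- as.matrix(expand.grid(axes))
  colnames(X) <- NULL
  wlist <- lapply(seq_len(system$dim), function(d)
    sw1 * diff(axes[[d]][1:2]))
  # expand.grid varies the first axis fastest; outer(w1, w2) matches that
  wq <- if (system$dim == 1) wlist[[1]] else
    as.numeric(outer(wlist[[1]], wlist[[2]]))
  U <- system$U(X)
  w <- wq * exp(-(U - min(U)) / kbt)
  edge <- rep(FALSE, nrow(X))
  for (d in seq_len(system$dim))
    edge <- edge | X[, d] %in% range(axes[[d]])
  if (sum(w[edge]) / sum(w) > 1e-6)
    stop("integration domain misses more than 1e-6 of the probability mass")
  o <- if (identical(observable, "U")) U else observable(X)
  sum(w * o) / sum(w)
}

#' Basin free-energy difference by quadrature (oracle)
#'
#' \eqn{\Delta F = F_A - F_B = -k_B T \log(m_A / m_B)} with basin masses from
#' the same panel quadrature as [quadrature_fes()].
#'
#' @param system,cv,T as in [quadrature_fes()].
#' @param basin_a,basin_b CV intervals `c(lo, hi)`.
#' @param npoints transverse quadrature nodes.
#' @return free-energy difference in kJ/mol.
#' @export
quadrature_delta_f <- function(system, cv, basin_a, basin_b, T = 300,
                               npoints = 801) {
  coord <- .cv_coord(cv, system)
  if (is.na(coord)) stop("quadrature_delta_f needs a coordinate CV")
  mA <- .basin_mass(system, coord, T, basin_a[1], basin_a[2], npoints)
  mB <- .basin_mass(system, coord, T, basin_b[1], basin_b[2], npoints)
  -kB * T * log(mA / mB)
}
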