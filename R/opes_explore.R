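# OPES Explore: a kernel-density estimate of the sampled CV distribution
# drives a barrier-capped, well-tempered bias
#
#   V(s) = kBT (gamma - 1) log( phat(s)/Z + epsilon ),   gamma = dE / kBT,
#
# with Gaussian kernels deposited every PACE steps, on-deposition compression
# (merge within one Mahalanobis unit of sigma0), and Z estimated as the mean
# kernel density over kernel centers. The `explore` epsilon variant
# epsilon = exp(-dE / (kBT (gamma - 1))) makes the bias range exactly
# dE-bounded from below: V >= -dE with equality where phat = 0.

#' Regularization epsilon from the BARRIER parameter
#'
#' Two selectable conventions:
#' * `"explore"` (default): \eqn{\epsilon = e^{-\Delta E / (k_B T (\gamma-1))}},
#'   the pairing under which the Explore bias prefactor
#'   \eqn{k_B T(\gamma-1)} gives \eqn{V = -\Delta E} exactly in unexplored
#'   regions.
#' * `"paper"`: \eqn{\epsilon = e^{-\Delta E / (k_B T (1 - 1/\gamma))}}, the
#'   standard-OPES relation.
#'
#' @param barrier BARRIER \eqn{\Delta E} in kJ/mol (> 0).
#' @param T temperature in K.
#' @param gamma bias factor (> 1); defaults to \eqn{\Delta E / k_B T}.
#' @param variant `"explore"` or `"paper"`.
#' @export
epsilon_from_barrier <- function(barrier, T, gamma = barrier / (kB * T),
                                 variant = c("explore", "paper")) {
  variant <- match.arg(variant)
  if (gamma <= 1)
    stop("gamma must exceed 1 (BARRIER must exceed kB*T); gamma = ", gamma)
  kbt <- kB * T
  if (variant == "paper") exp(-barrier / (kbt * (1 - 1 / gamma)))
  else exp(-barrier / (kbt * (gamma - 1)))
}

#' Initialize an OPES Explore bias state
#'
#' @param cvs a [make_cv()] object or list of them (leading CVs); dimension =
#'   number of CVs. May also be CV id strings.
#' @param barrier BARRIER \eqn{\Delta E} in kJ/mol; sets
#'   \eqn{\gamma = \Delta E / k_B T} and \eqn{\epsilon}.
#' @param pace steps between kernel depositions.
#' @param sigma0 fixed initial kernel width per CV (the standard deviation of
#'   the CV in the starting basin; the adaptive-sigma scheme is deliberately
#'   not implemented).
#' @param T thermostat temperature in K.
#' @param variant epsilon convention, see [epsilon_from_barrier()].
#' @return object of class `opes_explore` with an empty kernel list.
#' @export
init_explore <- function(cvs, barrier, pace, sigma0, T = 300,
                         variant = c("explore", "paper")) {
  variant <- match.arg(variant)
  if (inherits(cvs, "oneopes_cv") || is.character(cvs)) cvs <- list(cvs)
  cvs <- lapply(cvs, function(cv)
    if (inherits(cv, "oneopes_cv")) cv else make_cv(cv))
  d <- length(cvs)
  if (barrier <= 0) stop("barrier must be > 0")
  if (pace <= 0) stop("pace must be > 0")
  sigma0 <- rep_len(sigma0, d)
  if (any(sigma0 <= 0)) stop("sigma0 must be > 0")
  kbt <- kB * T
  gamma <- barrier / kbt
  if (abs(gamma - 1) < 1e-12 || gamma <= 1)
    stop("degenerate bias factor: BARRIER = ", barrier,
         " gives gamma <= 1 at T = ", T, " K (1 - 1/gamma vanishes)")
  eps <- epsilon_from_barrier(barrier, T, gamma, variant)
  structure(list(
    cvs = cvs, dim = d, barrier = barrier, gamma = gamma, epsilon = eps,
    temperature = T, kbt = kbt, pace = as.integer(pace), sigma0 = sigma0,
    variant = variant,
    centers = matrix(0, 0, d), sigmas = matrix(0, 0, d), heights = numeric(0),
    Z = NA_real_, n_deposited = 0L
  ), class = "opes_explore")
}

#' @export
print.opes_explore <- function(x, ...) {
  cat("<opes_explore>", nrow(x$centers), "kernels,",
      x$n_deposited, "deposited;",
      sprintf("barrier=%g kJ/mol gamma=%.3f eps=%.3g Z=%.4g (%s)\n",
              x$barrier, x$gamma, x$epsilon, x$Z, x$variant))
  invisible(x)
}

#' Deposit a Gaussian kernel
#'
#' Adds a height-1 kernel at `s` with width `sigma0`. If the nearest existing
#' kernel lies within Mahalanobis distance 1 (in units of `sigma0`) the two
#' are merged: heights add, the center becomes the height-weighted mean and
#' the variance the height-weighted second moment. Z is recomputed afterwards.
#' Compression keeps the kernel count proportional to the explored volume and
#' conserves the total weight (sum of heights = number of depositions).
#'
#' @param state an [init_explore()] state.
#' @param s CV-space point (length = state dimension).
#' @return the updated state.
#' @export
deposit <- function(state, s) {
  s <- as.numeric(s)
  if (length(s) != state$dim) stop("s must have length ", state$dim)
  if (any(!is.finite(s))) stop("non-finite CV value in deposit()")
  K <- nrow(state$centers)
  merged <- FALSE
  if (K > 0) {
    d2 <- colSums((t(state$centers) - s)^2 / state$sigma0^2)
    k <- which.min(d2)
    if (sqrt(d2[k]) < 1) {
      h1 <- state$heights[k]
      c1 <- state$centers[k, ]
      v1 <- state$sigmas[k, ]^2
      hn <- h1 + 1
      cn <- (h1 * c1 + s) / hn
      vn <- (h1 * (v1 + c1^2) + (state$sigma0^2 + s^2)) / hn - cn^2
      state$centers[k, ] <- cn
      state$sigmas[k, ] <- sqrt(vn)
      state$heights[k] <- hn
      merged <- TRUE
    }
  }
  if (!merged) {
    state$centers <- rbind(state$centers, s, deparse.level = 0)
    state$sigmas <- rbind(state$sigmas, state$sigma0, deparse.level = 0)
    state$heights <- c(state$heights, 1)
  }
  state$n_deposited <- state$n_deposited + 1L
  state$Z <- update_normalization(state)
  state
}

#' Normalized kernel-mixture density estimate
#'
#' \eqn{\hat p(s) = \sum_k h_k N(s; s_k, \sigma_k) / \sum_k h_k} with
#' diagonal-covariance Gaussians.
#'
#' @param state an `opes_explore` state with at least one kernel.
#' @param s a CV point or a matrix of points (rows).
#' @param deriv if `TRUE`, also return the gradient.
#' @return density values (and `deriv` matrix as an attribute if requested).
#' @export
opes_density <- function(state, s, deriv = FALSE) {
  K <- nrow(state$centers)
  if (K == 0) stop("empty estimator: no kernels deposited yet")
  S <- if (is.null(nrow(s))) matrix(s, ncol = state$dim, byrow = TRUE) else s
  H <- sum(state$heights)
  n <- nrow(S)
  p <- numeric(n)
  dp <- matrix(0, n, state$dim)
  for (k in seq_len(K)) {
    z <- sweep(S, 2, state$centers[k, ]) # s - c_k
    zs <- sweep(z, 2, state$sigmas[k, ], "/")
    g <- state$heights[k] * exp(-0.5 * rowSums(zs^2)) /
      prod(state$sigmas[k, ] * sqrt(2 * pi))
    p <- p + g
    if (deriv)
      dp <- dp - g * sweep(zs, 2, state$sigmas[k, ], "/")
  }
  out <- p / H
  if (deriv) attr(out, "deriv") <- dp / H
  out
}

#' Normalization factor Z
#'
#' Discrete estimate of the average probability density over the explored
#' region: the mean of [opes_density()] over the kernel centers.
#'
#' @param state an `opes_explore` state with at least one kernel.
#' @return the scalar Z.
#' @export
update_normalization <- function(state) {
  if (nrow(state$centers) == 0) stop("empty estimator: no kernels deposited yet")
  mean(opes_density(state, state$centers))
}

#' Evaluate the OPES Explore bias
#'
#' \eqn{V(s) = k_B T (\gamma - 1) \log(\hat p(s)/Z + \epsilon)}. Before the
#' first deposition the bias (and its gradient) is identically zero. With the
#' `explore` epsilon variant, \eqn{V \ge -\Delta E} everywhere with equality
#' in unexplored regions.
#'
#' @param state an `opes_explore` state.
#' @param s CV point or matrix of points (rows).
#' @param gradient if `TRUE`, attach the CV-space gradient (`"deriv"`
#'   attribute), needed for force evaluation via the chain rule.
#' @return bias values in kJ/mol.
#' @export
explore_bias <- function(state, s, gradient = FALSE) {
  S <- if (is.null(nrow(s))) matrix(s, ncol = state$dim, byrow = TRUE) else s
  if (nrow(state$centers) == 0) {
    v <- rep(0, nrow(S))
    if (gradient) attr(v, "deriv") <- matrix(0, nrow(S), state$dim)
    return(v)
  }
  p <- opes_density(state, S, deriv = gradient)
  arg <- p / state$Z + state$epsilon
  v <- state$kbt * (state$gamma - 1) * log(arg)
  if (gradient) {
    dp <- attr(p, "deriv")
    attr(v, "deriv") <- state$kbt * (state$gamma - 1) * (dp / state$Z) / arg
  }
  v
}

# --------------------------------------------------------- checkpointing ---

#' Write / read an OPES kernel checkpoint (PLUMED KERNELS dialect)
#'
#' Plain text, one kernel per row, header
#' `#! FIELDS center_* sigma_* height` plus `#! SET` lines carrying the
#' scalar state (barrier, gamma, epsilon, Z, n_deposited, variant).
#'
#' @param state an `opes_explore` state.
#' @param path file path.
#' @export
write_kernels <- function(state, path) {
  d <- state$dim
  ids <- vapply(state$cvs, function(cv) cv$id, "")
  cols <- c(paste0("center_", ids), paste0("sigma_", ids), "height")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(cols, collapse = " ")), con)
  for (f in c("barrier", "gamma", "epsilon", "Z", "n_deposited",
              "pace", "temperature"))
    writeLines(sprintf("#! SET %s %.17g", f, as.numeric(state[[f]])), con)
  writeLines(paste("#! SET variant", state$variant), con)
  writeLines(paste("#! SET sigma0", paste(sprintf("%.17g", state$sigma0),
                                          collapse = " ")), con)
  if (nrow(state$centers) > 0) {
    M <- cbind(state$centers, state$sigmas, state$heights)
    writeLines(apply(M, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_kernels
#' @param template an [init_explore()] state providing the CV definitions;
#'   scalar fields are overwritten from the file.
#' @export
read_kernels <- function(path, template) {
  lines <- readLines(path)
  state <- template
  hdr <- grep("^#! SET ", lines, value = TRUE)
  for (h in hdr) {
    parts <- strsplit(sub("^#! SET ", "", h), " ")[[1]]
    key <- parts[1]
    val <- parts[-1]
    if (key == "variant") state$variant <- val
    else if (key == "sigma0") state$sigma0 <- as.numeric(val)
    else if (key %in% c("n_deposited", "pace"))
      state[[key]] <- as.integer(as.numeric(val))
    else state[[key]] <- as.numeric(val)
  }
  rows <- lines[!startsWith(lines, "#")]
  d <- state$dim
  if (length(rows) > 0) {
    M <- do.call(rbind, lapply(strsplit(trimws(rows), "[ \t]+"), as.numeric))
    state$centers <- M[, seq_len(d), drop = FALSE]
    state$sigmas <- M[, d + seq_len(d), drop = FALSE]
    state$heights <- M[, 2 * d + 1]
  } else {
    state$centers <- matrix(0, 0, d)
    state$sigmas <- matrix(0, 0, d)
    state$heights <- numeric(0)
  }
  state$kbt <- kB * state$temperature
  state
}
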