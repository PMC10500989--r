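# OPES MultiThermal: an expanded-ensemble bias over a temperature grid acting
# on the potential energy U, letting a single thermostatted replica sample the
# multicanonical ensemble spanning [T_min, T_max]. The free-energy shifts
# DeltaF(T_j) of each grid temperature relative to the thermostat are learned
# on the fly from the weighted sample history:
#
#   exp(-beta_j DeltaF_j) = sum_k w_k exp(-(beta_j - beta0) U_k) / sum_k w_k,
#   w_k = exp(beta0 V_k^TOT),
#
# and the bias is V(U) = -kBT log( (1/N_T) sum_j exp(-(beta_j-beta0) U
#                                  + beta_j DeltaF_j) ).

#' Build a temperature grid
#'
#' `N_T` points geometric in beta between `1/(kB T_min)` and `1/(kB T_max)`,
#' with the thermostat beta inserted if absent, so betas are strictly
#' decreasing in the grid index (temperatures increasing).
#'
#' @param T_min,T_max grid range in K, with `T_min <= T0 <= T_max`.
#' @param T0 thermostat temperature in K.
#' @param N_T number of grid points (>= 1).
#' @return object of class `temperature_grid` with fields `T_min`, `T_max`,
#'   `T0`, `temperatures`, `betas`.
#' @export
build_grid <- function(T_min, T_max, T0, N_T = 20) {
  if (!(0 < T_min && T_min <= T0 && T0 <= T_max))
    stop("need 0 < T_min <= T0 <= T_max (got ", T_min, ", ", T0, ", ", T_max, ")")
  if (N_T < 1) stop("N_T must be >= 1")
  b_hi <- 1 / (kB * T_min)
  b_lo <- 1 / (kB * T_max)
  betas <- if (N_T == 1 || T_min == T_max) (1 / (kB * T0)) else
    exp(seq(log(b_hi), log(b_lo), length.out = N_T))
  b0 <- 1 / (kB * T0)
  if (!any(abs(betas / b0 - 1) < 1e-9)) betas <- sort(c(betas, b0), decreasing = TRUE)
  structure(list(T_min = T_min, T_max = T_max, T0 = T0,
                 temperatures = 1 / (kB * betas), betas = betas),
            class = "temperature_grid")
}

#' Initialize an expanded-ensemble (MultiThermal) state
#'
#' @param grid a [build_grid()] object.
#' @param update_pace steps between DeltaF updates (100x faster than the main
#'   OPES Explore PACE in the ladder defaults).
#' @return object of class `opes_expanded` with zero DeltaF and empty
#'   log-sum-exp accumulators.
#' @export
init_expanded <- function(grid, update_pace = 10) {
  stopifnot(inherits(grid, "temperature_grid"))
  n <- length(grid$betas)
  structure(list(
    grid = grid, beta0 = 1 / (kB * grid$T0), kbt = kB * grid$T0,
    update_pace = as.integer(update_pace),
    deltaF = numeric(n),
    acc = rep(-Inf, n), accw = -Inf, n_samples = 0L
  ), class = "opes_expanded")
}

#' @export
print.opes_expanded <- function(x, ...) {
  cat("<opes_expanded>", length(x$grid$betas), "temperatures in [",
      x$grid$T_min, ",", x$grid$T_max, "] K,", x$n_samples, "samples\n")
  invisible(x)
}

.logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[a == -Inf & b == -Inf] <- -Inf
  out
}

#' Update the DeltaF(T_j) estimates from weighted samples
#'
#' Streams `(U_k, log w_k)` pairs into persistent log-sum-exp accumulators and
#' recomputes \eqn{\Delta F_j = -\log(\sum_k w_k e^{-(\beta_j-\beta_0)U_k} /
#' \sum_k w_k)/\beta_j}. Deterministic given the history and invariant under
#' permutations of it; \eqn{\Delta F} at the thermostat temperature is 0 by
#' construction.
#'
#' @param state an [init_expanded()] state.
#' @param U potential-energy samples (kJ/mol).
#' @param logw log-weights \eqn{\beta_0 V^{TOT}_k} (default 0: unit weights).
#' @return the updated state.
#' @export
update_deltaF <- function(state, U, logw = 0) {
  U <- as.numeric(U)
  if (length(U) < 1) stop("empty sample history")
  logw <- rep_len(as.numeric(logw), length(U))
  for (k in seq_along(U)) {
    state$acc <- .logaddexp(state$acc,
                            logw[k] - (state$grid$betas - state$beta0) * U[k])
    state$accw <- .logaddexp(state$accw, logw[k])
  }
  state$deltaF <- -(state$acc - state$accw) / state$grid$betas
  state$n_samples <- state$n_samples + length(U)
  state
}

#' Evaluate the MultiThermal bias at a potential energy
#'
#' @param state an `opes_expanded` state.
#' @param U potential energy value(s) in kJ/mol.
#' @param gradient if `TRUE`, attach `dV/dU` (`"deriv"` attribute); the force
#'   on coordinates is `-dV/dU * grad U` by the chain rule.
#' @return bias value(s) in kJ/mol. A single-point grid at the thermostat
#'   temperature gives exactly 0.
#' @export
multithermal_bias <- function(state, U, gradient = FALSE) {
  b <- state$grid$betas
  b0 <- state$beta0
  n <- length(b)
  A <- outer(U, b - b0, function(u, db) -db * u) +
    matrix(b * state$deltaF, length(U), n, byrow = TRUE)
  m <- apply(A, 1, max)
  E <- exp(A - m)
  S <- rowSums(E)
  v <- -state$kbt * (m + log(S / n))
  if (gradient) {
    Sg <- as.numeric(E %*% (b - b0))
    attr(v, "deriv") <- state$kbt * Sg / S
  }
  v
}

#' Per-frame weights for reweighting to another temperature
#'
#' \eqn{w_t \propto \exp(\beta_0 V^{TOT}_t) \exp(-(\beta' - \beta_0) U_t)},
#' normalized to sum 1. Combines the usual bias unweighting at the thermostat
#' temperature with the canonical-ensemble tilt to `T_target`.
#'
#' @param table a `colvar_table` carrying `U` and `bias_total` columns.
#' @param T_target target temperature in K.
#' @param T0 thermostat temperature (default: the table's attribute, else 300).
#' @param discard_fraction initial fraction of frames zero-weighted.
#' @param T_range optional `c(T_min, T_max)` of the MultiThermal grid; a
#'   target outside it triggers an extrapolation warning (not an error).
#' @return normalized weight vector (length = rows of `table`).
#' @export
reweight_to_temperature <- function(table, T_target, T0 = NULL,
                                    discard_fraction = 0.1, T_range = NULL) {
  if (is.null(T0)) T0 <- attr(table, "temperature")
  if (is.null(T0)) T0 <- 300
  if (!is.null(T_range) && (T_target < T_range[1] || T_target > T_range[2]))
    warning("T_target = ", T_target,
            " K lies outside the sampled grid range [", T_range[1], ", ",
            T_range[2], "] K: extrapolating")
  if (!all(c("U", "bias_total") %in% names(table)))
    stop("table must carry 'U' and 'bias_total' columns")
  b0 <- 1 / (kB * T0)
  bp <- 1 / (kB * T_target)
  lw <- b0 * table$bias_total - (bp - b0) * table$U
  n <- length(lw)
  drop <- ceiling(discard_fraction * n)
  if (drop >= n) stop("discard_fraction leaves no frames")
  keep <- lw[seq.int(drop + 1, n)]
  keep <- exp(keep - max(keep))
  w <- numeric(n)
  w[seq.int(drop + 1, n)] <- keep / sum(keep)
  w
}

# --------------------------------------------------------- checkpointing ---

#' Write / read a DeltaF(T) checkpoint table
#'
#' Plain text with header `#! FIELDS T_j deltaF`, one grid point per row.
#' @param state an `opes_expanded` state.
#' @param path file path.
#' @export
write_deltaF <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS T_j deltaF", con)
  writeLines(sprintf("#! SET T0 %.17g", state$grid$T0), con)
  writeLines(sprintf("%.17g %.17g", state$grid$temperatures, state$deltaF), con)
  invisible(path)
}

#' @rdname write_deltaF
#' @export
read_deltaF <- function(path) {
  lines <- readLines(path)
  T0 <- as.numeric(sub("^#! SET T0 ", "", grep("^#! SET T0", lines, value = TRUE)))
  rows <- lines[!startsWith(lines, "#")]
  M <- do.call(rbind, lapply(strsplit(trimws(rows), "[ \t]+"), as.numeric))
  data.frame(T_j = M[, 1], deltaF = M[, 2], T0 = T0)
}
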