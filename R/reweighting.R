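# Reweighting analysis: turn the records of the convergence-focused replica 0
# into free-energy surfaces, basin free-energy differences with block-analysis
# errors, multi-temperature DeltaF(T) curves and Van't Hoff thermodynamics
# (enthalpy, entropy, melting temperature), plus multi-run convergence
# summaries.

#' Per-frame reweighting weights
#'
#' The first `ceiling(discard_fraction * N)` frames get weight 0 (transient
#' removal); the remaining frames get \eqn{w_t \propto e^{\beta V_t}} with
#' \eqn{V_t} the instantaneous OPES Explore main bias (`mode = "main"`,
#' the default) or the full bias stack (`mode = "total"`), normalized to sum 1.
#'
#' @param table a `colvar_table` with the required bias column.
#' @param mode `"main"` (column `opes_main`) or `"total"` (`bias_total`).
#' @param discard_fraction fraction of initial frames to zero-weight
#'   (default 0.10).
#' @param temperature thermostat temperature (default: table attribute).
#' @return normalized weight vector.
#' @export
frame_weights <- function(table, mode = c("main", "total"),
                          discard_fraction = 0.1, temperature = NULL) {
  mode <- match.arg(mode)
  col <- if (mode == "main") "opes_main" else "bias_total"
  if (!col %in% names(table))
    stop("table is missing the '", col, "' bias column")
  if (discard_fraction < 0 || discard_fraction >= 1)
    stop("discard_fraction must be in [0, 1)")
  if (is.null(temperature)) temperature <- attr(table, "temperature")
  if (is.null(temperature)) temperature <- 300
  V <- table[[col]]
  n <- length(V)
  drop <- ceiling(discard_fraction * n)
  if (drop >= n) stop("discard_fraction leaves no frames")
  lw <- V[seq.int(drop + 1, n)] / (kB * temperature)
  ew <- exp(lw - max(lw))
  if (!any(ew > 0)) stop("all weights are zero")
  w <- numeric(n)
  w[seq.int(drop + 1, n)] <- ew / sum(ew)
  w
}

#' Reweighted free-energy surface
#'
#' \eqn{F_b = -k_B T \log \sum_{t \in b} w_t}, minimum shifted to 0. Bins
#' with no weight are reported as `NA` (unpopulated), not zero.
#'
#' @param table a `colvar_table`.
#' @param weights normalized frame weights (see [frame_weights()]).
#' @param cv name of the CV column (e.g. `"cv_x"`).
#' @param bins bin edges, or a bin count over the sampled range.
#' @param temperature temperature for the kT prefactor.
#' @return a `fes_curve` data frame (`cv`, `F`).
#' @export
weighted_fes <- function(table, weights, cv = "cv_x", bins = 60,
                         temperature = NULL) {
  if (is.null(temperature)) temperature <- attr(table, "temperature")
  if (is.null(temperature)) temperature <- 300
  s <- table[[cv]]
  if (is.null(s)) stop("no column '", cv, "' in table")
  if (length(bins) == 1) {
    r <- range(s[weights > 0])
    bins <- seq(r[1], r[2] + 1e-12 * max(1, abs(r[2])), length.out = bins + 1)
  }
  idx <- findInterval(s, bins, rightmost.closed = TRUE)
  mass <- vapply(seq_len(length(bins) - 1),
                 function(b) sum(weights[idx == b]), 0)
  if (sum(mass > 0) < 2) stop("fewer than 2 populated bins")
  F <- ifelse(mass > 0, -kB * temperature * log(mass), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  out <- data.frame(cv = (bins[-1] + bins[-length(bins)]) / 2, F = F)
  attr(out, "temperature") <- temperature
  attr(out, "edges") <- bins
  class(out) <- c("fes_curve", "data.frame")
  out
}

.in_basin <- function(s, basin) s >= basin[1] & s < basin[2]

.check_basins <- function(basin_a, basin_b) {
  if (max(basin_a[1], basin_b[1]) < min(basin_a[2], basin_b[2]))
    stop("basins overlap")
}

#' Basin free-energy difference from weighted frames
#'
#' \eqn{\Delta F = F_A - F_B = -k_B T \log(\sum_A w / \sum_B w)} with a
#' block-analysis standard error (contiguous equal-length blocks, default 10).
#'
#' @param table a `colvar_table`.
#' @param weights normalized frame weights.
#' @param basin_a,basin_b disjoint CV intervals `c(lo, hi)` (frames with
#'   `lo <= s < hi`).
#' @param cv CV column name.
#' @param temperature temperature for the kT prefactor.
#' @param n_blocks number of blocks for the error estimate.
#' @return object of class `delta_f_estimate`: list with `value`, `stderr`,
#'   `basin_a`, `basin_b`, `temperature`.
#' @export
delta_f <- function(table, weights, basin_a, basin_b, cv = "cv_x",
                    temperature = NULL, n_blocks = 10) {
  if (is.null(temperature)) temperature <- attr(table, "temperature")
  if (is.null(temperature)) temperature <- 300
  .check_basins(basin_a, basin_b)
  s <- table[[cv]]
  wA <- sum(weights[.in_basin(s, basin_a)])
  wB <- sum(weights[.in_basin(s, basin_b)])
  if (wA <= 0) stop("basin A [", basin_a[1], ", ", basin_a[2], ") is empty")
  if (wB <= 0) stop("basin B [", basin_b[1], ", ", basin_b[2], ") is empty")
  kbt <- kB * temperature
  value <- -kbt * log(wA / wB)
  # block analysis on the per-block log-ratio
  n <- length(s)
  L <- floor(n / n_blocks)
  se <- NA_real_
  if (L >= 1 && n_blocks >= 2) {
    est <- W <- numeric(0)
    for (b in seq_len(n_blocks)) {
      i <- seq.int((b - 1) * L + 1, b * L)
      a <- sum(weights[i][.in_basin(s[i], basin_a)])
      bb <- sum(weights[i][.in_basin(s[i], basin_b)])
      if (a > 0 && bb > 0) {
        est <- c(est, -kbt * log(a / bb))
        W <- c(W, sum(weights[i]))
      }
    }
    if (length(est) >= 2) se <- .weighted_sem(est, W)
  }
  structure(list(value = value, stderr = se, basin_a = basin_a,
                 basin_b = basin_b, temperature = temperature),
            class = "delta_f_estimate")
}

#' @export
print.delta_f_estimate <- function(x, ...) {
  cat(sprintf("DeltaF = %.3f +- %.3f kJ/mol (T = %g K)\n",
              x$value, x$stderr, x$temperature))
  invisible(x)
}

.weighted_sem <- function(values, weights) {
  p <- weights / sum(weights)
  m <- sum(p * values)
  nb <- length(values)
  sqrt(nb / (nb - 1) * sum(p^2 * (values - m)^2))
}

#' Block-analysis standard error
#'
#' Splits the frame series into `n_blocks` contiguous equal-length blocks
#' (trailing remainder frames dropped), computes the weighted mean of each
#' block, and returns the weighted standard error of those block estimates.
#' With equal weights and one value per block this reduces to the textbook
#' \eqn{sd/\sqrt{n}}.
#'
#' @param values per-frame values.
#' @param weights per-frame weights (default equal).
#' @param n_blocks number of blocks (>= 2, default 10).
#' @return the standard error.
#' @export
block_stderr <- function(values, weights = NULL, n_blocks = 10) {
  n <- length(values)
  if (is.null(weights)) weights <- rep(1, n)
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  if (n < n_blocks) stop("fewer frames (", n, ") than blocks (", n_blocks, ")")
  L <- floor(n / n_blocks)
  est <- W <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    i <- seq.int((b - 1) * L + 1, b * L)
    W[b] <- sum(weights[i])
    est[b] <- if (W[b] > 0) sum(weights[i] * values[i]) / W[b] else NA_real_
  }
  ok <- is.finite(est) & W > 0
  if (sum(ok) < 2) stop("fewer than 2 populated blocks")
  .weighted_sem(est[ok], W[ok])
}

#' DeltaF as a function of temperature
#'
#' For each target temperature, frames of a MultiThermal-carrying replica are
#' reweighted with [reweight_to_temperature()] and the basin difference is
#' evaluated at that temperature.
#'
#' @param table a `colvar_table` from a MultiThermal replica (`U` and
#'   `bias_total` columns required).
#' @param basin_a,basin_b CV intervals.
#' @param T_list target temperatures (K).
#' @param cv CV column name.
#' @param T0 thermostat temperature.
#' @param discard_fraction initial fraction zero-weighted.
#' @param n_blocks blocks for the per-temperature error.
#' @return data frame with columns `T`, `deltaF`, `stderr`.
#' @export
deltaF_vs_temperature <- function(table, basin_a, basin_b, T_list,
                                  cv = "cv_x", T0 = NULL,
                                  discard_fraction = 0.1, n_blocks = 10) {
  out <- lapply(T_list, function(Tp) {
    w <- reweight_to_temperature(table, Tp, T0 = T0,
                                 discard_fraction = discard_fraction,
                                 T_range = attr(table, "T_range"))
    est <- delta_f(table, w, basin_a, basin_b, cv = cv, temperature = Tp,
                   n_blocks = n_blocks)
    c(Tp, est$value, est$stderr)
  })
  M <- do.call(rbind, out)
  data.frame(T = M[, 1], deltaF = M[, 2], stderr = M[, 3])
}

#' Van't Hoff fit of DeltaF(T)
#'
#' Weighted least squares of \eqn{\Delta F = \Delta H - T \Delta S}:
#' intercept \eqn{\Delta H}, slope \eqn{-\Delta S}. When standard errors are
#' supplied they are treated as known, so the parameter covariance is
#' \eqn{(X^T W X)^{-1}} with \eqn{W = 1/\sigma^2}; otherwise ordinary least
#' squares with the residual-variance covariance. The melting temperature is
#' the root \eqn{T_m = \Delta H / \Delta S}, with a first-order
#' error-propagated uncertainty.
#'
#' @param T temperatures (K), at least 2 distinct.
#' @param deltaF free-energy differences (kJ/mol).
#' @param stderr optional known standard errors of `deltaF`.
#' @param T_ref reference temperature for the `minusTdS_at_ref` report.
#' @return object of class `vant_hoff_fit`: `deltaH` (kJ/mol), `deltaS`
#'   (kJ/mol/K), `minusTdS_at_ref`, `T_melt` (K, `NA` if `deltaS ~ 0`),
#'   `se` (deltaH, deltaS, T_melt), `covariance`, `residuals`.
#' @export
vant_hoff_fit <- function(T, deltaF, stderr = NULL, T_ref = NULL) {
  if (length(unique(T)) < 2)
    stop("singular design: need at least 2 distinct temperatures")
  if (length(deltaF) != length(T)) stop("T and deltaF lengths differ")
  X <- cbind(1, -T)
  known_sigma <- !is.null(stderr)
  w <- if (known_sigma) 1 / stderr^2 else rep(1, length(T))
  XtWX <- crossprod(X * sqrt(w))
  beta <- solve(XtWX, crossprod(X, w * deltaF))
  dH <- beta[1]
  dS <- beta[2]
  resid <- deltaF - as.numeric(X %*% beta)
  cov <- solve(XtWX)
  if (!known_sigma && length(T) > 2)
    cov <- cov * sum(resid^2) / (length(T) - 2)
  # T_melt = dH/dS; delta-method propagation
  degenerate <- abs(dS) < 1e-12 * max(1, abs(dH))
  Tm <- if (degenerate) NA_real_ else dH / dS
  seTm <- if (degenerate) NA_real_ else {
    g <- c(1 / dS, -dH / dS^2)
    sqrt(as.numeric(t(g) %*% cov %*% g))
  }
  if (is.null(T_ref)) T_ref <- mean(T)
  structure(list(deltaH = dH, deltaS = dS,
                 minusTdS_at_ref = -T_ref * dS, T_ref = T_ref,
                 T_melt = Tm,
                 se = c(deltaH = sqrt(cov[1, 1]), deltaS = sqrt(cov[2, 2]),
                        T_melt = seTm),
                 covariance = cov, residuals = resid,
                 degenerate_slope = degenerate),
            class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("Van't Hoff fit: dH = %.2f +- %.2f kJ/mol, dS = %.4f +- %.4f kJ/mol/K\n",
              x$deltaH, x$se["deltaH"], x$deltaS, x$se["deltaS"]))
  cat(sprintf("  -T dS at %g K = %.2f kJ/mol; T_melt = %s K\n", x$T_ref,
              x$minusTdS_at_ref,
              if (is.na(x$T_melt)) "undefined (dS ~ 0)" else
                sprintf("%.1f +- %.1f", x$T_melt, x$se["T_melt"])))
  invisible(x)
}

#' Multi-run convergence report
#'
#' For each checkpoint time, recomputes the basin DeltaF of every run from all
#' data up to that time (weights recomputed with the same discard rule applied
#' to the truncated trajectory) and reports the cross-run mean and standard
#' deviation — the "DeltaF as a function of simulation time" diagnostic.
#'
#' @param runs list of >= 2 `oneopes_run` objects sharing a config (seeds may
#'   differ).
#' @param basin_a,basin_b CV intervals.
#' @param checkpoints times (ps) at which to evaluate; default 10 points over
#'   the run length.
#' @param cv CV column name.
#' @param replica replica index whose records are analysed (default 0, the
#'   convergence-focused one).
#' @param mode,discard_fraction passed to [frame_weights()].
#' @return data frame: `time`, per-run `deltaF_i` columns, `mean`, `sd`.
#' @export
convergence_report <- function(runs, basin_a, basin_b, checkpoints = NULL,
                               cv = "cv_x", replica = 0, mode = "main",
                               discard_fraction = 0.1) {
  if (length(runs) < 2) stop("need at least 2 runs")
  cfg0 <- runs[[1]]$config
  for (r in runs[-1]) {
    c1 <- r$config
    same <- identical(cfg0[setdiff(names(cfg0), "seed")],
                      c1[setdiff(names(c1), "seed")])
    if (!same) stop("runs have mismatched configurations")
  }
  tb1 <- runs[[1]]$tables[[replica + 1]]
  if (is.null(checkpoints))
    checkpoints <- seq(max(tb1$time) / 10, max(tb1$time), length.out = 10)
  rows <- lapply(checkpoints, function(tc) {
    vals <- vapply(runs, function(r) {
      tb <- r$tables[[replica + 1]]
      tb <- tb[tb$time <= tc, , drop = FALSE]
      w <- frame_weights(tb, mode = mode, discard_fraction = discard_fraction)
      delta_f(tb, w, basin_a, basin_b, cv = cv)$value
    }, 0)
    c(tc, vals, mean(vals), sd(vals))
  })
  M <- do.call(rbind, rows)
  colnames(M) <- c("time", paste0("deltaF_", seq_along(runs)), "mean", "sd")
  as.data.frame(M)
}
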