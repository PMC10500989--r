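# OneOPES orchestration: the 8-replica ladder layering (i) a main OPES
# Explore bias on the leading CVs in every replica, (ii) weak auxiliary-CV
# OPES biases introduced progressively (bias m in replicas >= m), and (iii)
# OPES MultiThermal in the upper replicas with a graded TEMP_MAX schedule,
# all at one thermostat temperature, coupled by Metropolis-Hastings
# coordinate swaps attempted tenfold faster than the deposition PACE.

#' OneOPES ladder configuration
#'
#' The stride relations are fixed by construction: exchanges are attempted
#' every `pace/10` steps, the MultiThermal shifts update every `pace/100`
#' steps, and auxiliary (MultiCV) kernels deposit every `2*pace` steps, so
#' `pace` must be divisible by 100.
#'
#' @param leading leading CV (id string or [make_cv()]); `NULL` disables the
#'   main bias (diagnostic use).
#' @param auxiliary auxiliary CV ids / definitions (at most `n_replicas - 1`;
#'   bias m appears in replicas `m` and above). Default one CV, `"y"`.
#' @param n_replicas number of replicas (default 8).
#' @param pace main deposition PACE in steps.
#' @param barrier main BARRIER in kJ/mol.
#' @param multicv_barrier auxiliary BARRIER in kJ/mol (default 3).
#' @param temp_max TEMP_MAX schedule (K) for the MultiThermal replicas
#'   `mt_start .. n_replicas-1`; must be nondecreasing.
#' @param t_min MultiThermal T_min (default: the thermostat temperature).
#' @param n_T MultiThermal grid size (default 20).
#' @param mt_start first replica index carrying MultiThermal (default 4).
#' @param temperature thermostat temperature in K (identical across replicas).
#' @param dt,friction,mass Langevin parameters (ps, 1/ps, reduced units).
#' @param n_steps integration steps per replica.
#' @param record_stride steps between records (default: the exchange stride).
#' @param sigma0 main-bias kernel width; `NULL` = harmonic estimate
#'   \eqn{\sqrt{k_B T / \partial_s^2 U}} at the starting minimum.
#' @param sigma0_aux auxiliary widths (recycled); `NULL` as above.
#' @param variant epsilon convention for all Explore biases.
#' @param basin_a,basin_b default analysis basins (leading-CV intervals).
#' @return validated object of class `oneopes_config`.
#' @export
ladder_config <- function(leading = "x", auxiliary = "y", n_replicas = 8,
                          pace = 1000, barrier = 30, multicv_barrier = 3,
                          temp_max = c(400, 450, 500, 600), t_min = NULL,
                          n_T = 20, mt_start = 4, temperature = 300,
                          dt = 0.002, friction = 5, mass = 1,
                          n_steps = 2e6, record_stride = NULL,
                          sigma0 = NULL, sigma0_aux = NULL,
                          variant = c("explore", "paper"),
                          basin_a = c(-3, 0), basin_b = c(0, 3)) {
  variant <- match.arg(variant)
  if (pace <= 0 || pace %% 100 != 0)
    stop("pace must be a positive multiple of 100 (strides are pace/10 and pace/100)")
  if (n_replicas < 1) stop("n_replicas must be >= 1")
  if (!is.null(leading) && barrier <= 0) stop("barrier must be > 0")
  if (is.null(auxiliary)) auxiliary <- list()
  if (is.character(auxiliary)) auxiliary <- as.list(auxiliary)
  if (inherits(auxiliary, "oneopes_cv")) auxiliary <- list(auxiliary)
  n_aux <- length(auxiliary)
  if (n_aux > n_replicas - 1)
    stop("more auxiliary CVs (", n_aux, ") than replicas - 1")
  if (n_aux > 0 && multicv_barrier > barrier)
    stop("multicv_barrier must not exceed the main barrier")
  mt_on <- n_replicas > mt_start && length(temp_max) > 0
  if (mt_on) {
    if (length(temp_max) != n_replicas - mt_start)
      stop("temp_max schedule must have length n_replicas - mt_start = ",
           n_replicas - mt_start)
    if (is.unsorted(temp_max))
      stop("temp_max schedule must be nondecreasing across replicas")
    if (is.null(t_min)) t_min <- temperature
    if (t_min > temperature || any(temp_max < temperature))
      stop("need t_min <= thermostat temperature <= temp_max")
  }
  cfg <- list(
    leading = leading, auxiliary = auxiliary, n_replicas = as.integer(n_replicas),
    pace = as.integer(pace), barrier = barrier, multicv_barrier = multicv_barrier,
    temp_max = if (mt_on) temp_max else numeric(0),
    t_min = if (mt_on) t_min else NULL, n_T = as.integer(n_T),
    mt_start = as.integer(mt_start), temperature = temperature,
    dt = dt, friction = friction, mass = mass, n_steps = n_steps,
    exchange_stride = as.integer(pace / 10),
    multithermal_stride = as.integer(pace / 100),
    multicv_pace = as.integer(2 * pace),
    record_stride = as.integer(if (is.null(record_stride)) pace / 10 else record_stride),
    sigma0 = sigma0, sigma0_aux = sigma0_aux, variant = variant,
    basin_a = basin_a, basin_b = basin_b
  )
  class(cfg) <- "oneopes_config"
  cfg
}

#' @export
print.oneopes_config <- function(x, ...) {
  cat("<oneopes_config>", x$n_replicas, "replicas, pace", x$pace,
      "barrier", x$barrier, "kJ/mol,", length(x$auxiliary), "auxiliary CV(s),",
      if (length(x$temp_max)) paste("TEMP_MAX", paste(x$temp_max, collapse = "/"))
      else "no MultiThermal", "\n")
  invisible(x)
}

# harmonic estimate of the unbiased CV standard deviation in the start basin
.calibrate_sigma <- function(system, coord, temperature) {
  x0 <- start_minimum(system)
  h <- 1e-4
  xp <- x0; xp[coord] <- xp[coord] + h
  xm <- x0; xm[coord] <- xm[coord] - h
  k_eff <- (system$U(xp) - 2 * system$U(x0) + system$U(xm)) / h^2
  if (k_eff <= 0) stop("non-convex start basin along coordinate ", coord)
  sqrt(kB * temperature / k_eff)
}

.as_cv <- function(cv, role = "leading") {
  if (inherits(cv, "oneopes_cv")) cv else make_cv(cv, role = role)
}

#' Build the per-replica bias stacks
#'
#' Applies the layering schedule: replica 0 carries only the main Explore
#' bias; auxiliary bias m is present in replicas m and above; MultiThermal is
#' present from `mt_start` up, with the graded TEMP_MAX schedule.
#'
#' @param config an [ladder_config()] object.
#' @param system a [make_system()] object (used to calibrate kernel widths
#'   when `sigma0` is not given explicitly).
#' @return list of `replica_spec` objects with fields `index`, `main_bias`,
#'   `multicv_biases`, `multithermal`, `thermostat_T`.
#' @export
build_ladder <- function(config, system) {
  T0 <- config$temperature
  lead <- if (is.null(config$leading)) NULL else .as_cv(config$leading)
  auxs <- lapply(config$auxiliary, .as_cv, role = "auxiliary")
  sig_main <- config$sigma0
  if (is.null(sig_main) && !is.null(lead)) {
    if (is.na(lead$coord)) stop("sigma0 must be given for a custom leading CV")
    sig_main <- .calibrate_sigma(system, lead$coord, T0)
  }
  sig_aux <- config$sigma0_aux
  if (is.null(sig_aux) && length(auxs) > 0)
    sig_aux <- vapply(auxs, function(cv) {
      if (is.na(cv$coord)) stop("sigma0_aux must be given for a custom CV")
      .calibrate_sigma(system, cv$coord, T0)
    }, 0)
  sig_aux <- rep_len(sig_aux, length(auxs))
  lapply(seq_len(config$n_replicas) - 1L, function(i) {
    main <- if (is.null(lead)) NULL else
      init_explore(lead, config$barrier, config$pace, sig_main, T0,
                   config$variant)
    multicv <- list()
    for (m in seq_along(auxs)) {
      if (i >= m)
        multicv[[length(multicv) + 1L]] <-
          init_explore(auxs[[m]], config$multicv_barrier, config$multicv_pace,
                       sig_aux[m], T0, config$variant)
    }
    mt <- NULL
    if (i >= config$mt_start && length(config$temp_max) > 0) {
      grid <- build_grid(config$t_min, config$temp_max[i - config$mt_start + 1L],
                         T0, config$n_T)
      mt <- init_expanded(grid, config$multithermal_stride)
    }
    structure(list(index = i, main_bias = main, multicv_biases = multicv,
                   multithermal = mt, thermostat_T = T0),
              class = "replica_spec")
  })
}

#' @export
print.replica_spec <- function(x, ...) {
  cat(sprintf("<replica %d> main:%s aux:%d mt:%s\n", x$index,
              if (is.null(x$main_bias)) "-" else "Explore",
              length(x$multicv_biases),
              if (is.null(x$multithermal)) "-" else
                paste0("[", x$multithermal$grid$T_min, ",",
                       x$multithermal$grid$T_max, "]K")))
  invisible(x)
}

#' Total bias of one replica at given coordinates
#'
#' Sum of the main Explore bias, every MultiCV bias (each on its own CV) and
#' the MultiThermal bias evaluated at the potential energy.
#'
#' @param replica a `replica_spec` from [build_ladder()].
#' @param coords coordinate vector.
#' @param U potential energy at `coords` (kJ/mol).
#' @return total bias in kJ/mol.
#' @export
total_bias <- function(replica, coords, U) {
  v <- 0
  if (!is.null(replica$main_bias)) {
    s <- vapply(replica$main_bias$cvs, function(cv) cv$fun(coords), 0)
    v <- v + as.numeric(explore_bias(replica$main_bias, s))
  }
  for (b in replica$multicv_biases) {
    s <- vapply(b$cvs, function(cv) cv$fun(coords), 0)
    v <- v + as.numeric(explore_bias(b, s))
  }
  if (!is.null(replica$multithermal))
    v <- v + as.numeric(multithermal_bias(replica$multithermal, U))
  v
}

#' Metropolis-Hastings exchange acceptance
#'
#' For neighbouring replicas at the same thermostat temperature, with
#' \eqn{\bar U_i(x) = U(x) + V_i^{TOT}(x)}:
#' \deqn{\alpha = \min\{1, e^{-\beta [\bar U_i(x_j) + \bar U_j(x_i)
#'   - \bar U_i(x_i) - \bar U_j(x_j)]}\}}
#' each replica evaluating its own full bias stack on both configurations.
#'
#' @param rep_i,rep_j `replica_spec` objects.
#' @param x_i,x_j coordinate vectors currently held by each replica.
#' @param system a [make_system()] object supplying `U`.
#' @return acceptance probability, with the exponent argument (kJ/mol)
#'   attached as attribute `"delta"`.
#' @export
exchange_acceptance <- function(rep_i, rep_j, x_i, x_j, system) {
  U_i <- system$U(x_i)
  U_j <- system$U(x_j)
  if (!all(is.finite(c(U_i, U_j)))) stop("non-finite energies")
  ubar <- function(r, x, U) U + total_bias(r, x, U)
  delta <- ubar(rep_i, x_j, U_j) + ubar(rep_j, x_i, U_i) -
    ubar(rep_i, x_i, U_i) - ubar(rep_j, x_j, U_j)
  beta <- 1 / (kB * rep_i$thermostat_T)
  structure(min(1, exp(-beta * delta)), delta = delta)
}
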