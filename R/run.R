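# Run drivers: thin R wrappers over the compiled simulation core. All replica
# bias parameters (gamma, epsilon, kernel widths, beta grids) are resolved
# here with the same module functions a user calls interactively, then handed
# to C++ as plain numbers; the core never re-derives physics.

.core_replica_cfg <- function(config, system) {
  T0 <- config$temperature
  lead <- if (is.null(config$leading)) NULL else .as_cv(config$leading)
  auxs <- lapply(config$auxiliary, .as_cv, role = "auxiliary")
  if (!is.null(lead) && is.na(lead$coord))
    stop("the compiled engine requires coordinate CVs ('x' or 'y')")
  for (cv in auxs)
    if (is.na(cv$coord))
      stop("the compiled engine requires coordinate CVs ('x' or 'y')")
  ladder <- build_ladder(config, system)  # validates + calibrates sigma
  reps <- lapply(ladder, function(r) {
    spec <- list()
    if (!is.null(r$main_bias)) {
      mb <- r$main_bias
      spec$main <- list(cv = mb$cvs[[1]]$coord - 1L, pace = config$pace,
                        gamma = mb$gamma, epsilon = mb$epsilon,
                        sigma0 = mb$sigma0)
    }
    if (length(r$multicv_biases) > 0) {
      spec$aux <- lapply(seq_along(r$multicv_biases), function(m) {
        b <- r$multicv_biases[[m]]
        list(cv = b$cvs[[1]]$coord - 1L, slot = m,
             pace = config$multicv_pace, gamma = b$gamma,
             epsilon = b$epsilon, sigma0 = b$sigma0)
      })
    }
    if (!is.null(r$multithermal))
      spec$mt <- list(betas = r$multithermal$grid$betas,
                      stride = config$multithermal_stride)
    spec
  })
  list(replicas = reps, ladder = ladder)
}

.table_names <- function(dim, n_aux) {
  c("time", c("cv_x", "cv_y")[seq_len(dim)], "U", "opes_main",
    if (n_aux > 0) paste0("opes_aux", seq_len(n_aux)), "opes_mt", "bias_total")
}

#' Run a OneOPES simulation
#'
#' Integrates all replicas of the ladder with BAOAB Langevin dynamics,
#' depositing main kernels every PACE steps, auxiliary kernels every 2 PACE,
#' updating the MultiThermal shifts every PACE/100, and attempting
#' Metropolis-Hastings coordinate swaps on alternating even/odd neighbour
#' pairs every PACE/10 steps. Deterministic given `seed` (per-replica RNG
#' streams are derived from it).
#'
#' @param config an [ladder_config()] object.
#' @param system a [make_system()] object.
#' @param seed integer root seed.
#' @param outdir optional directory; if given, `COLVAR.<replica>`,
#'   `EXCHANGE.log`, kernel and DeltaF checkpoints are written there.
#' @return object of class `oneopes_run`: `tables` (per-replica
#'   `colvar_table`s), `exchange` (event log), `states` (final bias states as
#'   module objects), `config`, `system`, `seed`.
#' @export
run_oneopes <- function(config, system, seed = 1, outdir = NULL) {
  stopifnot(inherits(config, "oneopes_config"), inherits(system, "oneopes_system"))
  cc <- .core_replica_cfg(config, system)
  x0 <- start_minimum(system)
  n_aux <- length(config$auxiliary)
  res <- .run_core_cpp(system$id, system$param_vec, system$dim, x0,
                       config$temperature, config$dt, config$friction,
                       config$mass, config$n_steps, config$exchange_stride,
                       config$record_stride, cc$replicas, n_aux,
                       as.integer(seed))
  cols <- .table_names(system$dim, n_aux)
  tables <- lapply(seq_along(res$tables), function(i) {
    tb <- as.data.frame(res$tables[[i]])
    names(tb) <- cols
    attr(tb, "temperature") <- config$temperature
    attr(tb, "replica") <- i - 1L
    class(tb) <- c("colvar_table", "data.frame")
    tb
  })
  xch <- as.data.frame(res$exchange)
  names(xch) <- c("time", "i", "j", "delta", "accepted", "draw")
  xch$accepted <- xch$accepted > 0
  class(xch) <- c("exchange_log", "data.frame")
  attr(xch, "n_replicas") <- config$n_replicas
  states <- .wrap_states(res$states, cc$ladder)
  run <- structure(list(tables = tables, exchange = xch, states = states,
                        config = config, system = system, seed = seed),
                   class = "oneopes_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

.wrap_states <- function(core_states, ladder) {
  lapply(seq_along(core_states), function(i) {
    st <- core_states[[i]]
    r <- ladder[[i]]
    if (!is.null(st$main) && !is.null(r$main_bias)) {
      r$main_bias$centers <- st$main$kernels[, "center", drop = FALSE]
      r$main_bias$sigmas <- st$main$kernels[, "sigma", drop = FALSE]
      r$main_bias$heights <- as.numeric(st$main$kernels[, "height"])
      r$main_bias$Z <- st$main$Z
      r$main_bias$n_deposited <- as.integer(st$main$n_deposited)
    }
    if (!is.null(st$aux)) {
      for (a in seq_along(st$aux)) {
        k <- st$aux[[a]]
        r$multicv_biases[[a]]$centers <- k$kernels[, "center", drop = FALSE]
        r$multicv_biases[[a]]$sigmas <- k$kernels[, "sigma", drop = FALSE]
        r$multicv_biases[[a]]$heights <- as.numeric(k$kernels[, "height"])
        r$multicv_biases[[a]]$Z <- k$Z
        r$multicv_biases[[a]]$n_deposited <- as.integer(k$n_deposited)
      }
    }
    if (!is.null(st$mt) && !is.null(r$multithermal)) {
      r$multithermal$deltaF <- as.numeric(st$mt$deltaF)
      r$multithermal$n_samples <- as.integer(st$mt$n_samples)
    }
    r
  })
}

#' @export
print.oneopes_run <- function(x, ...) {
  nacc <- if (nrow(x$exchange)) mean(x$exchange$accepted) else NA
  cat("<oneopes_run>", length(x$tables), "replica(s),",
      nrow(x$tables[[1]]), "records each;",
      nrow(x$exchange), "exchange attempts",
      if (!is.na(nacc)) sprintf("(%.0f%% accepted)", 100 * nacc), "\n")
  invisible(x)
}

#' Write run outputs to a directory
#'
#' `COLVAR.<replica>` files, `EXCHANGE.log`, per-bias `KERNELS.*` and
#' `DELTAF.*` checkpoints.
#' @param run an `oneopes_run`.
#' @param outdir output directory (created if needed).
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(run$tables))
    write_colvar(run$tables[[i]], file.path(outdir, paste0("COLVAR.", i - 1)))
  write_exchange_log(run$exchange, file.path(outdir, "EXCHANGE.log"))
  for (i in seq_along(run$states)) {
    r <- run$states[[i]]
    if (!is.null(r$main_bias))
      write_kernels(r$main_bias, file.path(outdir, sprintf("KERNELS.main.%d", i - 1)))
    for (m in seq_along(r$multicv_biases))
      write_kernels(r$multicv_biases[[m]],
                    file.path(outdir, sprintf("KERNELS.aux%d.%d", m, i - 1)))
    if (!is.null(r$multithermal))
      write_deltaF(r$multithermal, file.path(outdir, sprintf("DELTAF.%d", i - 1)))
  }
  invisible(outdir)
}

#' Run a single-replica OPES Explore simulation
#'
#' The non-ladder control: one walker, one Explore bias on the given CV.
#'
#' @param system a [make_system()] object.
#' @param cv leading CV id or definition.
#' @param barrier,pace BARRIER (kJ/mol) and PACE (steps).
#' @param n_steps integration steps.
#' @param seed integer seed.
#' @param temperature,dt,friction,mass Langevin parameters.
#' @param sigma0 kernel width (`NULL` = harmonic estimate at the start basin).
#' @param record_stride steps between records (default `pace/10`).
#' @param variant epsilon convention.
#' @return an `oneopes_run` with a single table.
#' @export
run_explore <- function(system, cv = "x", barrier = 30, pace = 1000,
                        n_steps = 2e6, seed = 1, temperature = 300,
                        dt = 0.002, friction = 5, mass = 1, sigma0 = NULL,
                        record_stride = NULL, variant = "explore") {
  config <- ladder_config(leading = cv, auxiliary = NULL, n_replicas = 1,
                          pace = pace, barrier = barrier,
                          temp_max = numeric(0), temperature = temperature,
                          dt = dt, friction = friction, mass = mass,
                          n_steps = n_steps, record_stride = record_stride,
                          sigma0 = sigma0, variant = variant)
  run_oneopes(config, system, seed)
}

#' Run a single-replica OPES MultiThermal simulation
#'
#' One walker carrying only the expanded-ensemble bias on U: the system
#' samples the whole `[t_min, t_max]` multicanonical range at a single
#' thermostat temperature.
#'
#' @param system a [make_system()] object.
#' @param t_min,t_max temperature range in K.
#' @param n_T grid size.
#' @param update_stride steps between DeltaF updates.
#' @param n_steps,seed,temperature,dt,friction,mass,record_stride as in
#'   [run_explore()].
#' @return an `oneopes_run` with a single table; `states[[1]]$multithermal`
#'   holds the final DeltaF grid.
#' @export
run_multithermal <- function(system, t_min = NULL, t_max, n_T = 20,
                             update_stride = 10, n_steps = 5e5, seed = 1,
                             temperature = 300, dt = 0.002, friction = 5,
                             mass = 1, record_stride = 100) {
  if (is.null(t_min)) t_min <- temperature
  grid <- build_grid(t_min, t_max, temperature, n_T)
  mtstate <- init_expanded(grid, update_stride)
  x0 <- start_minimum(system)
  res <- .run_core_cpp(system$id, system$param_vec, system$dim, x0,
                       temperature, dt, friction, mass, n_steps, 0L,
                       as.integer(record_stride),
                       list(list(mt = list(betas = grid$betas,
                                           stride = update_stride))),
                       0L, as.integer(seed))
  tb <- as.data.frame(res$tables[[1]])
  names(tb) <- .table_names(system$dim, 0)
  attr(tb, "temperature") <- temperature
  attr(tb, "replica") <- 0L
  attr(tb, "T_range") <- c(t_min, t_max)
  class(tb) <- c("colvar_table", "data.frame")
  mtstate$deltaF <- as.numeric(res$states[[1]]$mt$deltaF)
  mtstate$n_samples <- as.integer(res$states[[1]]$mt$n_samples)
  spec <- structure(list(index = 0L, main_bias = NULL, multicv_biases = list(),
                         multithermal = mtstate, thermostat_T = temperature),
                    class = "replica_spec")
  structure(list(tables = list(tb),
                 exchange = structure(
                   data.frame(time = numeric(0), i = numeric(0), j = numeric(0),
                              delta = numeric(0), accepted = logical(0),
                              draw = numeric(0)),
                   class = c("exchange_log", "data.frame"), n_replicas = 1L),
                 states = list(spec), config = NULL, system = system,
                 seed = seed),
            class = "oneopes_run")
}

#' Run unbiased Langevin sampling
#'
#' Reference dynamics with no bias at all (used by the distribution
#' self-tests).
#' @inheritParams run_explore
#' @param n_replicas number of independent walkers.
#' @param record_stride steps between records.
#' @return an `oneopes_run`.
#' @export
run_unbiased <- function(system, n_steps = 1e6, seed = 1, n_replicas = 1,
                         temperature = 300, dt = 0.002, friction = 5,
                         mass = 1, record_stride = 20) {
  x0 <- start_minimum(system)
  reps <- rep(list(list()), n_replicas)
  res <- .run_core_cpp(system$id, system$param_vec, system$dim, x0,
                       temperature, dt, friction, mass, n_steps, 0L,
                       as.integer(record_stride), reps, 0L, as.integer(seed))
  tables <- lapply(seq_len(n_replicas), function(i) {
    tb <- as.data.frame(res$tables[[i]])
    names(tb) <- .table_names(system$dim, 0)
    attr(tb, "temperature") <- temperature
    attr(tb, "replica") <- i - 1L
    class(tb) <- c("colvar_table", "data.frame")
    tb
  })
  structure(list(tables = tables, exchange = NULL, states = NULL,
                 config = NULL, system = system, seed = seed),
            class = "oneopes_run")
}
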