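# Shared fixtures, built in code. Expensive simulation batches are memoized so
# several test files (and the acceptance checks) reuse one computation.

.fixtures <- new.env(parent = emptyenv())

hb_system <- function() {
  if (is.null(.fixtures$hb)) .fixtures$hb <- make_system("hidden_barrier_2d")
  .fixtures$hb
}

hb_basins <- function() list(a = c(-3, 0), b = c(0, 3))

hb_oracle <- function(T = 300) {
  key <- paste0("oracle_", T)
  if (is.null(.fixtures[[key]])) {
    b <- hb_basins()
    .fixtures[[key]] <- quadrature_delta_f(hb_system(), "x", b$a, b$b, T = T)
  }
  .fixtures[[key]]
}

# the study batch: 5 independent default-ladder runs, seeds 1..5
hb_batch <- function() {
  if (is.null(.fixtures$batch)) {
    cfg <- ladder_config()
    .fixtures$batch <- lapply(1:5, function(s) run_oneopes(cfg, hb_system(), seed = s))
  }
  .fixtures$batch
}

batch_delta_f <- function(run) {
  tb <- run$tables[[1]]
  w <- frame_weights(tb, mode = "main", discard_fraction = 0.1)
  b <- hb_basins()
  delta_f(tb, w, b$a, b$b, cv = "cv_x")$value
}

# central finite-difference gradient, the oracle for every analytic gradient
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(d) {
    xp <- x; xm <- x
    xp[d] <- xp[d] + h
    xm[d] <- xm[d] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}
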