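test_that("COLVAR files round-trip at full precision", {
  tb <- data.frame(time = c(0.2, 0.4, 0.6),
                   cv_x = c(-1.0467213331231231, 0.3333333333333333, pi),
                   U = c(-9.9, 0, 1e-17),
                   bias_total = c(0.1, 0.2, 0.3))
  path <- tempfile()
  write_colvar(tb, path)
  tb2 <- read_colvar(path)
  expect_identical(names(tb2), names(tb))
  for (cn in names(tb)) expect_identical(tb2[[cn]], tb[[cn]])
  # empty table: header only
  empty <- tb[0, ]
  path2 <- tempfile()
  write_colvar(empty, path2)
  expect_equal(length(readLines(path2)), 1)
  tb3 <- read_colvar(path2)
  expect_equal(nrow(tb3), 0)
  expect_identical(names(tb3), names(tb))
})

test_that("a real COLVAR snippet with comment lines parses", {
  tb <- read_colvar(test_path("colvar-fixture.dat"))
  expect_equal(names(tb),
               c("time", "cv_x", "cv_y", "U", "opes_main", "bias_total"))
  expect_equal(nrow(tb), 4)  # comment and SET lines skipped
  expect_equal(tb$time, c(0.2, 0.4, 0.6, 0.8))
  expect_equal(tb$cv_x[1], -1.046721)
})

test_that("malformed COLVAR inputs are rejected with line information", {
  p1 <- tempfile()
  writeLines(c("1 2 3"), p1)
  expect_error(read_colvar(p1), "FIELDS")
  p2 <- tempfile()
  writeLines(c("#! FIELDS a b", "1 2", "3 4 5"), p2)
  expect_error(read_colvar(p2), "line 3")
  p3 <- tempfile()
  writeLines(c("#! FIELDS a a", "1 2"), p3)
  expect_error(read_colvar(p3), "duplicate")
})

test_that("exchange statistics aggregate rates and flag bottlenecks", {
  log <- data.frame(
    time = rep(1:100, each = 2),
    i = rep(c(0, 3), 100), j = rep(c(1, 4), 100),
    delta = 0,
    accepted = c(rbind(rep(TRUE, 100), rep(c(TRUE, rep(FALSE, 9)), 10))),
    draw = 0.5)
  st <- exchange_statistics(log)
  expect_equal(st$rate[st$i == 0], 1.0)
  expect_equal(st$rate[st$i == 3], 0.10)
  expect_true(st$bottleneck[st$i == 3])
  expect_false(st$bottleneck[st$i == 0])
  # order invariance
  st2 <- exchange_statistics(log[sample(nrow(log)), ])
  expect_equal(st2$rate, st$rate)
  expect_error(exchange_statistics(log[0, ]), "empty")
})

test_that("exchange logs round-trip through their file format", {
  run <- run_oneopes(ladder_config(n_steps = 2e4), hb_system(), seed = 4)
  path <- tempfile()
  write_exchange_log(run$exchange, path)
  lg <- read_exchange_log(path)
  expect_equal(lg$time, run$exchange$time)
  expect_equal(lg$accepted, run$exchange$accepted)
  expect_equal(attr(lg, "n_replicas"), 8L)
})

test_that("demux follows walkers through accepted swaps", {
  mk_tables <- function(n, nt) lapply(seq_len(n), function(r) {
    tb <- data.frame(time = seq_len(nt), cv_x = r * 100 + seq_len(nt))
    class(tb) <- c("colvar_table", "data.frame")
    tb
  })
  # no accepted swaps: walker k stays in replica k
  log0 <- data.frame(time = 2, i = 0, j = 1, delta = 0, accepted = FALSE,
                     draw = 0.9)
  d0 <- demux(log0, mk_tables(3, 4))
  for (k in 1:3) expect_true(all(d0[[k]]$replica == k - 1))
  # one accepted swap (0,1) at t = 2: walkers 0/1 exchange replicas after it
  log1 <- data.frame(time = 2, i = 0, j = 1, delta = 0, accepted = TRUE,
                     draw = 0.1)
  d1 <- demux(log1, mk_tables(3, 4))
  expect_equal(d1[[1]]$replica, c(0L, 1L, 1L, 1L))
  expect_equal(d1[[2]]$replica, c(1L, 0L, 0L, 0L))
  expect_equal(d1[[3]]$replica, rep(2L, 4))
  expect_equal(d1[[1]]$cv_x, c(101, 202, 203, 204))
  # mismatched time bases are rejected
  bad <- mk_tables(2, 4)
  bad[[2]]$time <- bad[[2]]$time + 0.5
  expect_error(demux(log1, bad), "time base")
})

test_that("demux equals the brute-force permutation composition", {
  set.seed(55)
  n <- 8
  nt <- 40
  times <- seq_len(nt)
  ev <- do.call(rbind, lapply(times, function(t) {
    parity <- t %% 2
    pairs <- seq(parity, n - 2, by = 2)
    data.frame(time = t - 0.5, i = pairs, j = pairs + 1, delta = 0,
               accepted = runif(length(pairs)) < 0.5, draw = 0)
  }))
  tables <- lapply(seq_len(n), function(r) {
    tb <- data.frame(time = times, cv_x = r * 1000 + times)
    class(tb) <- c("colvar_table", "data.frame")
    tb
  })
  d <- demux(ev, tables)
  # brute force: compose transpositions event by event for each record time
  acc <- ev[ev$accepted, ]
  for (t in times) {
    perm <- seq_len(n)
    for (e in seq_len(nrow(acc))) {
      if (acc$time[e] <= t) {
        a <- acc$i[e] + 1
        b <- acc$j[e] + 1
        perm[c(a, b)] <- perm[c(b, a)]
      }
    }
    for (r in seq_len(n)) {
      w <- perm[r]
      expect_equal(d[[w]]$replica[t], r - 1L)
      expect_equal(d[[w]]$cv_x[t], tables[[r]]$cv_x[t])
    }
  }
  # conservation: every (time, replica) slot appears in exactly one walker
  expect_equal(sum(vapply(d, nrow, 0L)), n * nt)
  for (t in times)
    expect_equal(sort(vapply(d, function(x) x$replica[t], 0L)), 0:(n - 1))
  # walkers only move to neighbouring replicas between records
  for (w in seq_len(n))
    expect_true(all(abs(diff(d[[w]]$replica)) <= 1))
})

test_that("transition counting uses full-entry hysteresis", {
  A <- c(-2, -0.5)
  B <- c(0.5, 2)
  expect_equal(transition_count(c(-1, -1.2, -0.8), A, B), 0L)
  # A, gap, B, gap, A -> 2 crossings
  expect_equal(transition_count(c(-1, 0, 1, 0, -1), A, B), 2L)
  # gap excursions that fail to enter the other basin do not count
  expect_equal(transition_count(c(-1, 0.2, -1, 0.4, -0.9), A, B), 0L)
  # time reversal gives the same count
  s <- c(-1, 0, 1, 1.2, 0, -1, 0.3, -0.8, 1)
  expect_equal(transition_count(s, A, B), transition_count(rev(s), A, B))
  # a telegraph signal with K programmed switches counts exactly K
  set.seed(77)
  K <- 13
  levels <- rep(c(-1, 1), length.out = K + 1)
  tele <- unlist(lapply(levels, function(l) rep(l, sample(3:7, 1))))
  tele <- tele + rnorm(length(tele), 0, 0.1)
  expect_equal(transition_count(tele, A, B), K)
  expect_error(transition_count(s, c(-1, 1), c(0, 2)), "overlap")
})

test_that("config files load with defaults and field-level validation", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "system:", "  name: hidden_barrier_2d",
    "cvs:", "  leading: x", "  auxiliary: [y]",
    "ladder:", "  pace: 1000", "  barrier: 30",
    "  temp_max: [350, 365, 380, 400]",
    "analysis:", "  basin_a: [-3, 0]", "  basin_b: [0, 3]"), path)
  cfg <- load_config(path)
  expect_s3_class(cfg$system, "oneopes_system")
  expect_equal(cfg$config$n_replicas, 8L)         # default filled
  expect_equal(cfg$analysis$discard, 0.1)         # default filled
  expect_equal(cfg$analysis$n_blocks, 10)         # default filled
  expect_equal(cfg$config$temp_max, c(350, 365, 380, 400))
  # the loaded schedule reproduces the built ladder's T_max sequence
  lad <- build_ladder(cfg$config, cfg$system)
  expect_equal(vapply(5:8, function(i) lad[[i]]$multithermal$grid$T_max, 0),
               c(350, 365, 380, 400))
  # invariant violations are rejected with the offending section named
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("system:", "  name: hidden_barrier_2d",
               "ladder:", "  pace: 1050"), bad)
  expect_error(load_config(bad), "\\[ladder\\].*multiple of 100")
  bad2 <- tempfile(fileext = ".yaml")
  writeLines(c("system:", "  name: hidden_barrier_2d",
               "ladder:", "  pacing: 1000"), bad2)
  expect_error(load_config(bad2), "unknown field")
  bad3 <- tempfile(fileext = ".yaml")
  writeLines("cvs: {leading: x}", bad3)
  expect_error(load_config(bad3), "\\[system\\]")
})

test_that("run outputs write a complete, re-readable directory", {
  run <- run_oneopes(ladder_config(n_steps = 2e4), hb_system(), seed = 5)
  out <- tempfile()
  write_run(run, out)
  files <- list.files(out)
  expect_true(all(paste0("COLVAR.", 0:7) %in% files))
  expect_true("EXCHANGE.log" %in% files)
  expect_true("KERNELS.main.0" %in% files)
  expect_true("DELTAF.7" %in% files)
  tb <- read_colvar(file.path(out, "COLVAR.0"))
  expect_equal(tb$cv_x, run$tables[[1]]$cv_x)
  unlink(out, recursive = TRUE)
})
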