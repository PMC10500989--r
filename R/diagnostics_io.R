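# COLVAR-dialect I/O, exchange statistics, demultiplexed continuous
# trajectories, transition counting, and the run-configuration surface.

#' Read / write COLVAR-dialect files
#'
#' Whitespace-separated numeric columns with a `#! FIELDS name1 name2 ...`
#' header, as written by PLUMED. Additional `#`-comment lines (including
#' `#! SET` lines) are skipped on read. Values are written with 17
#' significant digits so that `read_colvar(write_colvar(t))` is the identity
#' to full precision.
#'
#' @param path file path.
#' @return `read_colvar`: a `colvar_table` data frame.
#' @export
read_colvar <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#! FIELDS"))
    stop("malformed COLVAR file: missing '#! FIELDS' header in ", path)
  fields <- strsplit(trimws(sub("^#! FIELDS", "", lines[1])), "[ \t]+")[[1]]
  if (anyDuplicated(fields)) stop("duplicate field names in COLVAR header")
  keep <- !startsWith(lines, "#")
  rows <- which(keep & nzchar(trimws(lines)))
  if (length(rows) == 0) {
    tb <- as.data.frame(matrix(numeric(0), 0, length(fields)))
  } else {
    parsed <- strsplit(trimws(lines[rows]), "[ \t]+")
    nf <- lengths(parsed)
    if (any(nf != length(fields)))
      stop("ragged COLVAR row at line ", rows[which(nf != length(fields))[1]],
           ": expected ", length(fields), " fields, got ",
           nf[which(nf != length(fields))[1]])
    tb <- as.data.frame(do.call(rbind, lapply(parsed, as.numeric)))
  }
  names(tb) <- fields
  class(tb) <- c("colvar_table", "data.frame")
  tb
}

#' @rdname read_colvar
#' @param table a data frame of numeric columns.
#' @export
write_colvar <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(table), collapse = " ")), con)
  if (nrow(table) > 0) {
    M <- as.matrix(table)
    writeLines(apply(M, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
  }
  invisible(path)
}

#' Read / write an exchange log
#'
#' Columns `time i j delta accepted draw` with a `#! FIELDS` header.
#' @param log an `exchange_log` data frame.
#' @param path file path.
#' @export
write_exchange_log <- function(log, path) {
  tb <- as.data.frame(log)
  tb$accepted <- as.numeric(tb$accepted)
  write_colvar(tb, path)
}

#' @rdname write_exchange_log
#' @param n_replicas replica count (default: inferred from the pairs).
#' @export
read_exchange_log <- function(path, n_replicas = NULL) {
  tb <- read_colvar(path)
  tb$accepted <- tb$accepted > 0
  if (is.null(n_replicas))
    n_replicas <- if (nrow(tb)) max(tb$j) + 1 else 0
  attr(tb, "n_replicas") <- as.integer(n_replicas)
  class(tb) <- c("exchange_log", "data.frame")
  tb
}

#' Per-pair exchange acceptance statistics
#'
#' Acceptance rate (accepted/attempted) for each neighbour pair, with pairs
#' below the ~20% health threshold flagged as potential exchange bottlenecks.
#'
#' @param log an `exchange_log` (or data frame with `i`, `j`, `accepted`).
#' @param threshold flagging threshold (default 0.20).
#' @return data frame: `i`, `j`, `attempted`, `accepted`, `rate`,
#'   `bottleneck`.
#' @export
exchange_statistics <- function(log, threshold = 0.20) {
  if (nrow(log) == 0) stop("empty exchange log")
  key <- paste(log$i, log$j)
  pairs <- sort(unique(log$i))
  out <- do.call(rbind, lapply(split(seq_len(nrow(log)), key), function(idx) {
    data.frame(i = log$i[idx[1]], j = log$j[idx[1]],
               attempted = length(idx),
               accepted = sum(log$accepted[idx]))
  }))
  out <- out[order(out$i), ]
  rownames(out) <- NULL
  out$rate <- out$accepted / out$attempted
  out$bottleneck <- out$rate < threshold
  out
}

#' Demultiplex into continuous walker trajectories
#'
#' Inverts the accepted coordinate swaps so each trajectory follows one
#' physical walker through the replica ladder. For each record time, the
#' walker occupying each replica is obtained by composing the transpositions
#' of all accepted exchange events up to (and including) that time.
#'
#' @param log an `exchange_log`.
#' @param tables per-replica `colvar_table`s sharing one time base.
#' @return list of data frames (one per walker): `time`, `replica`, then the
#'   CV/energy columns of the records the walker visited.
#' @export
demux <- function(log, tables) {
  n <- length(tables)
  times <- tables[[1]]$time
  for (tb in tables[-1])
    if (!isTRUE(all.equal(tb$time, times))) stop("time base mismatch")
  ev <- log[log$accepted, , drop = FALSE]
  ev <- ev[order(ev$time), , drop = FALSE]
  nt <- length(times)
  perm <- seq_len(n)  # perm[replica slot] = walker id occupying it
  P <- matrix(0L, nt, n)  # walker occupying each replica at each record time
  ei <- 1
  ne <- nrow(ev)
  for (t in seq_len(nt)) {
    while (ei <= ne && ev$time[ei] <= times[t]) {
      a <- ev$i[ei] + 1
      b <- ev$j[ei] + 1
      perm[c(a, b)] <- perm[c(b, a)]
      ei <- ei + 1
    }
    P[t, ] <- perm
  }
  cols <- setdiff(names(tables[[1]]), "time")
  colmat <- lapply(cols, function(cn)
    do.call(cbind, lapply(tables, function(tb) tb[[cn]])))
  names(colmat) <- cols
  lapply(seq_len(n), function(w) {
    # replica index occupied by walker w at each time
    ridx <- as.integer(apply(P == w, 1, which.max))
    out <- data.frame(time = times, replica = ridx - 1L)
    for (cn in cols) out[[cn]] <- colmat[[cn]][cbind(seq_len(nt), ridx)]
    out
  })
}

#' Count basin-to-basin transitions
#'
#' Hysteresis counting: starting from the first frame inside either basin, a
#' transition is registered only when the series fully enters the opposite
#' basin; excursions into the gap between basins do not count. Time reversal
#' gives the same count.
#'
#' @param s CV time series.
#' @param basin_a,basin_b disjoint CV intervals `c(lo, hi)`.
#' @return nonnegative integer count of A-to-B plus B-to-A crossings.
#' @export
transition_count <- function(s, basin_a, basin_b) {
  .check_basins(basin_a, basin_b)
  state <- ifelse(.in_basin(s, basin_a), 1L, ifelse(.in_basin(s, basin_b), 2L, 0L))
  state <- state[state != 0L]
  if (length(state) < 2) return(0L)
  sum(diff(state) != 0L)
}

# ------------------------------------------------------------- config ------

#' Load a run configuration file
#'
#' YAML with sections `system`, `cvs`, `ladder`, `analysis`:
#' ```yaml
#' system: {name: hidden_barrier_2d}
#' cvs:    {leading: x, auxiliary: [y]}
#' ladder: {pace: 1000, barrier: 30, temp_max: [400, 450, 500, 600]}
#' analysis: {basin_a: [-3, 0], basin_b: [0, 3], discard: 0.1, n_blocks: 10}
#' ```
#' Defaults are filled in (8 replicas, 10% discard, 10-block analysis) and
#' every ladder invariant is enforced at load with field-level messages.
#'
#' @param path path to the YAML file.
#' @return list with `system` ([make_system()] object), `config`
#'   ([ladder_config()] object) and `analysis` (list).
#' @export
load_config <- function(path) {
  # keep YAML's boolean-ish bare tokens (y/n/...) as strings: 'y' is a CV id
  raw <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(v) if (identical(tolower(v), "true")) TRUE else v,
    "bool#no" = function(v) if (identical(tolower(v), "false")) FALSE else v))
  if (is.null(raw$system) || is.null(raw$system$name))
    stop("config error in [system]: 'name' is required")
  sys_args <- raw$system[setdiff(names(raw$system), "name")]
  system <- do.call(make_system, c(list(raw$system$name), sys_args))
  cvs <- raw$cvs
  leading <- if (is.null(cvs$leading)) "x" else cvs$leading
  auxiliary <- cvs$auxiliary
  lad <- if (is.null(raw$ladder)) list() else raw$ladder
  allowed <- c("n_replicas", "pace", "barrier", "multicv_barrier", "temp_max",
               "t_min", "n_T", "mt_start", "temperature", "dt", "friction",
               "mass", "n_steps", "record_stride", "sigma0", "sigma0_aux",
               "variant")
  bad <- setdiff(names(lad), allowed)
  if (length(bad) > 0)
    stop("config error in [ladder]: unknown field(s) ",
         paste(bad, collapse = ", "))
  if (!is.null(lad$temp_max)) lad$temp_max <- as.numeric(unlist(lad$temp_max))
  ana <- if (is.null(raw$analysis)) list() else raw$analysis
  cfg_args <- c(list(leading = leading, auxiliary = auxiliary), lad)
  if (!is.null(ana$basin_a)) cfg_args$basin_a <- as.numeric(unlist(ana$basin_a))
  if (!is.null(ana$basin_b)) cfg_args$basin_b <- as.numeric(unlist(ana$basin_b))
  config <- tryCatch(do.call(ladder_config, cfg_args),
                     error = function(e)
                       stop("config error in [ladder]: ", conditionMessage(e),
                            call. = FALSE))
  analysis <- list(
    discard = if (is.null(ana$discard)) 0.1 else ana$discard,
    n_blocks = if (is.null(ana$n_blocks)) 10 else ana$n_blocks,
    basin_a = config$basin_a, basin_b = config$basin_b,
    cv = if (is.null(ana$cv)) "cv_x" else ana$cv
  )
  if (analysis$discard < 0 || analysis$discard >= 1)
    stop("config error in [analysis]: discard must be in [0, 1)")
  list(system = system, config = config, analysis = analysis)
}
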