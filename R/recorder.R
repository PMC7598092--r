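#' Sparse snapshot series
#'
#' Holds the sparse record of a long simulation: at fixed biological-time
#' intervals (50 s by default, i.e. one snapshot per 50,000 solver steps at
#' 1 ms) the full activity state, the inter-region weight matrix and the
#' per-region internal weights are deep-copied into the series. Memory grows
#' only with the snapshot count, never with the step count.
#'
#' @param n Number of regions.
#' @param interval Snapshot interval in ms (default 50,000 = 50 s).
#' @param metadata Named list of run metadata (config hash, seed, version).
#' @return An object of class `snapshot_series`.
#' @seealso [record_snapshot()], [write_series()], [read_series()]
#' @export
snapshot_series <- function(n, interval = 50000, metadata = list()) {
  structure(list(n = as.integer(n), interval = interval,
                 times = numeric(0),
                 E = list(), Is = list(), Id = list(),
                 W = list(), internal_w = list(),
                 metadata = metadata),
            class = "snapshot_series")
}

#' Snapshot times implied by a horizon and interval
#'
#' Snapshots fall on every multiple of the interval from 0 to `t_end`
#' inclusive; e.g. a 24 h horizon at the 50 s default yields 1729 snapshots.
#'
#' @param t_end Total biological time (ms).
#' @param interval Snapshot interval (ms).
#' @return Numeric vector of snapshot times in ms.
#' @examples
#' length(snapshot_schedule(24 * 3600 * 1000))  # 1729
#' @export
snapshot_schedule <- function(t_end, interval = 50000) {
  if (interval <= 0) abort("snapshot_schedule: interval must be > 0.")
  seq(0, t_end, by = interval)
}

#' Append one snapshot
#'
#' @param series A [snapshot_series()].
#' @param t Snapshot time (ms); must exceed every recorded time.
#' @param state A [network_state()].
#' @param W Inter-region weight matrix at `t`.
#' @param internal_w n x 7 internal weight matrix at `t`.
#' @return The extended series.
#' @export
record_snapshot <- function(series, t, state, W, internal_w) {
  if (length(series$times) > 0 && t <= max(series$times)) {
    abort(sprintf("record_snapshot: out-of-order snapshot time %g (last was %g).",
                  t, max(series$times)))
  }
  k <- length(series$times) + 1L
  series$times[k] <- t
  series$E[[k]] <- as.numeric(state$E)
  series$Is[[k]] <- as.numeric(state$Is)
  series$Id[[k]] <- as.numeric(state$Id)
  series$W[[k]] <- W + 0          # force copies
  series$internal_w[[k]] <- internal_w + 0
  series
}

#' @export
print.snapshot_series <- function(x, ...) {
  cat(sprintf("<snapshot_series> %d regions, %d snapshots (interval %g ms)\n",
              x$n, length(x$times), x$interval))
  if (length(x$times)) {
    cat("  times [ms]:", paste(format(head(x$times, 5), trim = TRUE),
                               collapse = ", "),
        if (length(x$times) > 5) "..." else "", "\n")
  }
  invisible(x)
}

# ---- on-disk layout ---------------------------------------------------------
# dir/
#   manifest.json            n, interval, times, metadata, count
#   activities.csv           time,region,variable,value   (appended per snapshot)
#   snap_<k>_W.csv           full-precision weight matrix of snapshot k
#   snap_<k>_internal.csv    n x 7 internal weights of snapshot k

snap_tag <- function(k) sprintf("%06d", k)

write_manifest <- function(dir, n, interval, times, metadata) {
  jsonlite::write_json(
    list(format = "brainmass-snapshots-v1", n = n, interval = interval,
         count = length(times), times = times, metadata = metadata),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

append_activity_rows <- function(path, t, state, n, header = FALSE) {
  rows <- c(
    sprintf("%.17g,%d,E,%.17g", t, seq_len(n), state$E),
    sprintf("%.17g,%d,Is,%.17g", t, seq_len(n), state$Is),
    sprintf("%.17g,%d,Id,%.17g", t, seq_len(n), state$Id))
  if (header) rows <- c("time,region,variable,value", rows)
  cat(rows, file = path, sep = "\n", append = !header)
  cat("\n", file = path, append = TRUE)
}

#' Write a snapshot series to disk
#'
#' Writes a directory holding a JSON manifest, a long-format activities CSV
#' (`time, region, variable, value`) and one pair of full-precision weight
#' CSVs per snapshot. All floats are written with 17 significant digits, so
#' [read_series()] reproduces the series bit-exactly.
#'
#' @param series A [snapshot_series()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, dir) {
  stopifnot(inherits(series, "snapshot_series"))
  wr <- series_writer(dir, series$n, series$interval, series$metadata)
  for (k in seq_along(series$times)) {
    wr$append(series$times[k],
              network_state(series$E[[k]], series$Is[[k]], series$Id[[k]],
                            t = series$times[k]),
              series$W[[k]], series$internal_w[[k]])
  }
  wr$finalize()
  invisible(dir)
}

#' Streaming snapshot writer
#'
#' Opens a snapshot directory for incremental appends: each `append()` writes
#' the snapshot straight to disk and refreshes the manifest, so at most one
#' snapshot is ever held in working memory and an aborted run still leaves a
#' readable series ending at the last completed snapshot.
#'
#' @param dir Output directory.
#' @param n Number of regions.
#' @param interval Snapshot interval (ms).
#' @param metadata Named metadata list stored in the manifest.
#' @return List with functions `append(t, state, W, internal_w)`,
#'   `finalize()` and `count()`.
#' @export
series_writer <- function(dir, n, interval = 50000, metadata = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  act_path <- file.path(dir, "activities.csv")
  times <- numeric(0)
  append <- function(t, state, W, internal_w) {
    if (length(times) > 0 && t <= max(times)) {
      abort(sprintf("series_writer: out-of-order snapshot time %g.", t))
    }
    k <- length(times) + 1L
    append_activity_rows(act_path, t, state, n, header = (k == 1L))
    write_matrix_file(W, file.path(dir, sprintf("snap_%s_W.csv", snap_tag(k))))
    write_matrix_file(internal_w,
                      file.path(dir, sprintf("snap_%s_internal.csv", snap_tag(k))))
    times[k] <<- t
    write_manifest(dir, n, interval, times, metadata)  # keep manifest current
    invisible(k)
  }
  list(append = append,
       finalize = function() {
         write_manifest(dir, n, interval, times, metadata)
         invisible(dir)
       },
       count = function() length(times))
}

#' Read a snapshot series from disk
#'
#' Loads a directory written by [write_series()] or [series_writer()]. A
#' corrupt or truncated store (missing weight files, short activities table)
#' raises an integrity error naming the last valid snapshot.
#'
#' @param dir Snapshot directory.
#' @return A [snapshot_series()].
#' @export
read_series <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) abort(sprintf("read_series: no manifest in %s.", dir))
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  n <- as.integer(man$n)
  times <- as.numeric(man$times)
  series <- snapshot_series(n, man$interval,
                            metadata = as.list(man$metadata))
  act_path <- file.path(dir, "activities.csv")
  act <- if (file.exists(act_path) && length(times) > 0) {
    read.table(act_path, sep = ",", header = TRUE,
               colClasses = c("numeric", "integer", "character", "numeric"))
  } else {
    data.frame(time = numeric(0), region = integer(0),
               variable = character(0), value = numeric(0))
  }
  for (k in seq_along(times)) {
    t <- times[k]
    wpath <- file.path(dir, sprintf("snap_%s_W.csv", snap_tag(k)))
    ipath <- file.path(dir, sprintf("snap_%s_internal.csv", snap_tag(k)))
    sub <- act[act$time == t, , drop = FALSE]
    if (!file.exists(wpath) || !file.exists(ipath) || nrow(sub) != 3L * n) {
      last_ok <- if (k > 1) sprintf("snapshot %d (t = %g ms)", k - 1L, times[k - 1L])
                 else "none"
      abort(sprintf(
        "read_series: store is truncated or corrupt at snapshot %d; last valid: %s.",
        k, last_ok))
    }
    pick <- function(v) {
      x <- sub[sub$variable == v, , drop = FALSE]
      x$value[order(x$region)]
    }
    st <- network_state(pick("E"), pick("Is"), pick("Id"), t = t)
    W <- as.matrix(read.table(wpath, sep = ",", header = FALSE,
                              colClasses = "numeric"))
    dimnames(W) <- NULL
    iw <- as.matrix(read.table(ipath, sep = ",", header = FALSE,
                               colClasses = "numeric"))
    dimnames(iw) <- NULL
    series <- record_snapshot(series, t, st, W, iw)
  }
  series
}
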