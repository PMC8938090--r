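# Wall-field and flow series containers and their file formats.
#
# A wall series is the per-node wall shear stress vector (Pa) sampled on a
# common time grid; on disk it is a long CSV (node, t, tx, ty, tz) referenced
# from a small JSON manifest that also carries beat_period and n_beats.

#' Construct a wall-field series
#'
#' @param times strictly increasing sample times (s)
#' @param wss 3D array `[node, time, 3]` of WSS vectors (Pa), or a list of
#'   per-time n x 3 matrices
#' @param beat_period cardiac period (s)
#' @param n_beats number of simulated beats covered
#' @param node_ids integer indices into the associated mesh (default
#'   `1:nrow`)
#' @return object of class `wall_series`
#' @export
wall_series <- function(times, wss, beat_period, n_beats,
                        node_ids = NULL) {
  if (is.list(wss)) {
    arr <- array(0, c(nrow(wss[[1]]), length(wss), 3))
    for (i in seq_along(wss)) arr[, i, ] <- wss[[i]]
    wss <- arr
  }
  if (is.unsorted(times, strictly = TRUE)) {
    o <- order(times)
    times <- times[o]
    wss <- wss[, o, , drop = FALSE]
  }
  if (dim(wss)[2] != length(times)) {
    stop("wss time dimension does not match times", call. = FALSE)
  }
  if (is.null(node_ids)) node_ids <- seq_len(dim(wss)[1])
  if (dim(wss)[1] != length(node_ids)) {
    stop("wss node dimension does not match node_ids", call. = FALSE)
  }
  span <- diff(range(times))
  dt <- median(diff(times))
  if (span + dt + 1e-9 < n_beats * beat_period) {
    stop("times span less than n_beats x beat_period", call. = FALSE)
  }
  structure(list(times = times, wss = wss, beat_period = beat_period,
                 n_beats = as.integer(n_beats),
                 node_ids = as.integer(node_ids)),
            class = "wall_series")
}

#' @export
print.wall_series <- function(x, ...) {
  cat("wall_series:", dim(x$wss)[1], "nodes x", length(x$times),
      "timesteps;", x$n_beats, "beats of", x$beat_period, "s\n")
  invisible(x)
}

#' Construct a flow series
#'
#' @param times sample times (s)
#' @param q_ostium signed flow rate through the ostium plane (ml/s,
#'   positive = out of the LAA)
#' @param vel_samples matrix `[sample, time]` of speed magnitudes (m/s) at
#'   intra-LAA sample points
#' @param sample_weights volume weights (ml) per sample point; should sum to
#'   the LAA volume
#' @param beat_period,n_beats as in [wall_series()]
#' @return object of class `flow_series`
#' @export
flow_series <- function(times, q_ostium, vel_samples, sample_weights,
                        beat_period, n_beats) {
  if (length(times) != length(q_ostium)) {
    stop("q_ostium length does not match times", call. = FALSE)
  }
  vel_samples <- as.matrix(vel_samples)
  if (ncol(vel_samples) != length(times)) {
    stop("vel_samples columns do not match times", call. = FALSE)
  }
  if (nrow(vel_samples) != length(sample_weights)) {
    stop("sample_weights length does not match vel_samples rows",
         call. = FALSE)
  }
  structure(list(times = times, q_ostium = q_ostium,
                 vel_samples = vel_samples,
                 sample_weights = sample_weights,
                 beat_period = beat_period, n_beats = as.integer(n_beats)),
            class = "flow_series")
}

#' Read a wall-field series from a JSON manifest
#'
#' The manifest holds `beat_period`, `n_beats` and either `csv` (one long
#' CSV with columns node,t,tx,ty,tz) or `steps` (a list of `{t, file}`
#' per-timestep CSVs with columns node,tx,ty,tz). Timesteps may appear in
#' any order; the series is returned time-sorted. Node sets must be
#' identical across steps.
#'
#' @param manifest_path path to the JSON manifest
#' @return a [wall_series()]
#' @export
read_wall_series <- function(manifest_path) {
  man <- jsonlite::read_json(file.path(manifest_path), simplifyVector = TRUE)
  base <- dirname(manifest_path)
  if (!is.null(man$csv)) {
    df <- read.csv(file.path(base, man$csv))
    need <- c("node", "t", "tx", "ty", "tz")
    if (!all(need %in% names(df))) {
      stop("wall series CSV must have columns node,t,tx,ty,tz",
           call. = FALSE)
    }
    times <- sort(unique(df$t))
    nodes <- sort(unique(df$node))
    cnt <- table(df$t)
    if (length(unique(cnt)) != 1L) {
      stop("inconsistent node counts between timesteps", call. = FALSE)
    }
    arr <- array(NA_real_, c(length(nodes), length(times), 3))
    ni <- match(df$node, nodes); ti <- match(df$t, times)
    arr[cbind(ni, ti, 1L)] <- df$tx
    arr[cbind(ni, ti, 2L)] <- df$ty
    arr[cbind(ni, ti, 3L)] <- df$tz
    if (anyNA(arr)) {
      stop("missing node/time combinations in wall series CSV",
           call. = FALSE)
    }
  } else if (!is.null(man$steps)) {
    steps <- man$steps
    times <- as.numeric(steps$t)
    mats <- lapply(steps$file, function(f) {
      d <- read.csv(file.path(base, f))
      d[order(d$node), ]
    })
    nodes <- mats[[1]]$node
    for (m in mats) {
      if (!identical(m$node, nodes)) {
        stop("inconsistent node counts between timesteps", call. = FALSE)
      }
    }
    arr <- array(0, c(length(nodes), length(times), 3))
    for (i in seq_along(mats)) {
      arr[, i, ] <- as.matrix(mats[[i]][, c("tx", "ty", "tz")])
    }
  } else {
    stop("manifest must provide `csv` or `steps`", call. = FALSE)
  }
  wall_series(times, arr, beat_period = man$beat_period,
              n_beats = man$n_beats, node_ids = nodes)
}

#' Write a wall-field series (long CSV plus JSON manifest)
#'
#' @param series a [wall_series()]
#' @param manifest_path output manifest path; the CSV is written alongside
#' @return `manifest_path`, invisibly
#' @export
write_wall_series <- function(series, manifest_path) {
  base <- dirname(manifest_path)
  csv_name <- paste0(sub("\\.json$", "", basename(manifest_path)), ".csv")
  nt <- length(series$times)
  nn <- dim(series$wss)[1]
  df <- data.frame(node = rep(series$node_ids, times = nt),
                   t = rep(series$times, each = nn),
                   tx = as.vector(series$wss[, , 1]),
                   ty = as.vector(series$wss[, , 2]),
                   tz = as.vector(series$wss[, , 3]))
  write.csv(df, file.path(base, csv_name), row.names = FALSE)
  jsonlite::write_json(list(beat_period = series$beat_period,
                            n_beats = series$n_beats, csv = csv_name),
                       manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}
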