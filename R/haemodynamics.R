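# Wall-shear-stress derived indices and flow measures.
#
# Per node, over an averaging window of whole beats (default beats 2-3,
# beat 1 being the solver's stabilisation beat) and with trapezoidal time
# integration:
#   TAWSS = (1/T) int ||tau|| dt                         (Pa)
#   OSI   = 1/2 (1 - ||int tau dt|| / int ||tau|| dt)    (0..0.5)
#   ECAP  = OSI / TAWSS                                  (1/Pa)
#   RRT   = 1 / ((1 - 2 OSI) TAWSS)                      (s, capped)

#' Time indices of a beat window
#' @keywords internal
window_indices <- function(times, beat_period, window) {
  t0 <- (window[1] - 1) * beat_period
  t1 <- window[2] * beat_period
  which(times >= t0 - 1e-9 & times <= t1 + 1e-9)
}

#' Per-node WSS indices (TAWSS, OSI, ECAP, RRT)
#'
#' @param series a [wall_series()]
#' @param window integer beat range to average over, default `c(2, 3)`
#' @param rrt_max cap for RRT at fully oscillatory or zero-shear nodes (s)
#' @return data.frame with one row per node: `node`, `tawss`, `osi`,
#'   `ecap`, `rrt`, `rrt_capped`. Nodes with identically zero WSS get
#'   `tawss = 0`, `osi = 0` and missing ECAP/RRT. Attribute `n_capped`
#'   counts RRT-capped nodes.
#' @export
compute_wss_indices <- function(series, window = c(2, 3), rrt_max = 1e3) {
  stopifnot(inherits(series, "wall_series"))
  idx <- window_indices(series$times, series$beat_period, window)
  if (length(idx) < 2) stop("empty averaging window", call. = FALSE)
  tt <- series$times[idx]
  T_ <- diff(range(tt))
  if (T_ <= 0) stop("zero-duration averaging window", call. = FALSE)
  steps_per_beat <- length(idx) / (window[2] - window[1] + 1)
  if (steps_per_beat < 20) {
    stop("fewer than 20 timesteps per beat in the window", call. = FALSE)
  }
  w <- series$wss[, idx, , drop = FALSE]
  nn <- dim(w)[1]; nt <- dim(w)[2]
  comp <- function(k) matrix(w[, , k], nn, nt)
  mag <- sqrt(comp(1)^2 + comp(2)^2 + comp(3)^2)
  int_mag <- trapz_int(tt, t(mag))
  int_vec <- cbind(trapz_int(tt, t(comp(1))),
                   trapz_int(tt, t(comp(2))),
                   trapz_int(tt, t(comp(3))))
  mag_int <- row_norms(int_vec)
  tawss <- int_mag / T_
  zero <- int_mag <= 0
  osi <- ifelse(zero, 0, 0.5 * (1 - mag_int / pmax(int_mag, 1e-300)))
  osi <- pmin(pmax(osi, 0), 0.5)
  ecap <- ifelse(zero, NA_real_, osi / tawss)
  denom <- (1 - 2 * osi) * tawss
  rrt_capped <- !zero & (denom <= 1 / rrt_max)
  rrt <- ifelse(zero, NA_real_, ifelse(rrt_capped, rrt_max, 1 / denom))
  out <- data.frame(node = series$node_ids, tawss = tawss, osi = osi,
                    ecap = ecap, rrt = rrt, rrt_capped = rrt_capped)
  attr(out, "n_capped") <- sum(rrt_capped)
  attr(out, "window") <- window
  out
}

#' Percentile-trimmed mean, whole-LAA or per region
#'
#' Values outside the [P10, P90] band (linear-interpolation percentiles)
#' are discarded and the arithmetic mean of the kept values returned, for
#' robustness against extreme nodes.
#'
#' @param values numeric vector (per-node index values)
#' @param labels optional factor of region labels aligned with `values`;
#'   when given, one trimmed mean per level (plus `whole`) is returned
#' @param lower,upper trim percentiles (defaults 0.10 and 0.90)
#' @return a single trimmed mean, or a named vector with `whole` and one
#'   entry per region level
#' @export
trimmed_aggregate <- function(values, labels = NULL, lower = 0.1,
                              upper = 0.9) {
  tm <- function(v, who) {
    v <- v[!is.na(v)]
    if (length(v) < 10) {
      stop("fewer than 10 values in region '", who,
           "': trimmed mean undefined", call. = FALSE)
    }
    q <- quantile(v, c(lower, upper), names = FALSE, type = 7)
    mean(v[v >= q[1] & v <= q[2]])
  }
  if (is.null(labels)) return(tm(values, "whole"))
  out <- c(whole = tm(values, "whole"))
  for (lv in levels(labels)) {
    out[lv] <- tm(values[which(labels == lv)], lv)
  }
  out
}

#' Volume-normalised intra-LAA velocity
#'
#' Volume-weighted mean speed over the sample points, time-averaged over
#' the beat window, divided by the LAA volume.
#'
#' @param flow a [flow_series()]
#' @param laa_volume_ml LAA volume (ml)
#' @param window beat range, default `c(2, 3)`
#' @return scalar in (m/s)/ml
#' @export
velocity_index <- function(flow, laa_volume_ml, window = c(2, 3)) {
  if (!is.finite(laa_volume_ml) || laa_volume_ml <= 0) {
    stop("LAA volume must be positive", call. = FALSE)
  }
  idx <- window_indices(flow$times, flow$beat_period, window)
  tt <- flow$times[idx]
  wsum <- sum(flow$sample_weights)
  vmean_t <- colSums(flow$vel_samples[, idx, drop = FALSE] *
                       flow$sample_weights) / wsum
  vbar <- trapz_int(tt, vmean_t) / diff(range(tt))
  vbar / laa_volume_ml
}

#' Flow stagnation from the ostium flow-rate trace
#'
#' The outflow volume per beat `V_out = int max(q, 0) dt / n_beats` over
#' the window is compared with the LAA volume. Under the default
#' perfect-mixing washout model the stagnating (non-renewed) fraction is
#' `100 exp(-V_out / V_LAA)`; the piston alternative is
#' `100 max(0, 1 - V_out / V_LAA)`.
#'
#' @param flow a [flow_series()]
#' @param laa_volume_ml LAA volume (ml)
#' @param window beat range, default `c(2, 3)`
#' @param model `"mixing"` (default) or `"piston"`
#' @return stagnation percentage in \[0, 100\]
#' @export
stagnation_fraction <- function(flow, laa_volume_ml, window = c(2, 3),
                                model = c("mixing", "piston")) {
  model <- match.arg(model)
  if (!is.finite(laa_volume_ml) || laa_volume_ml <= 0) {
    stop("LAA volume must be positive", call. = FALSE)
  }
  idx <- window_indices(flow$times, flow$beat_period, window)
  tt <- flow$times[idx]
  v_out <- trapz_int(tt, pmax(flow$q_ostium[idx], 0))
  nb <- window[2] - window[1] + 1
  v_out <- v_out / nb
  switch(model,
         mixing = 100 * exp(-v_out / laa_volume_ml),
         piston = 100 * max(0, 1 - v_out / laa_volume_ml))
}

#' Min-max normalisation of cohort feature columns
#'
#' Each selected column is rescaled to `(x - min) / (max - min)` over the
#' cohort. The scaling record allows exact inversion; raw columns can be
#' retained alongside with suffix `_raw`.
#'
#' @param data data.frame
#' @param columns character vector of columns to normalise
#' @param keep_raw retain originals as `<col>_raw` (default TRUE)
#' @return list with `data` and `scaling` (data.frame col/min/max)
#' @export
minmax_normalize <- function(data, columns, keep_raw = TRUE) {
  sc <- data.frame(column = columns, min = NA_real_, max = NA_real_)
  for (i in seq_along(columns)) {
    cn <- columns[i]
    x <- data[[cn]]
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) <= 0) {
      stop("constant column cannot be min-max normalized: ", cn,
           call. = FALSE)
    }
    if (keep_raw) data[[paste0(cn, "_raw")]] <- x
    data[[cn]] <- (x - rng[1]) / (rng[2] - rng[1])
    sc$min[i] <- rng[1]; sc$max[i] <- rng[2]
  }
  list(data = data, scaling = sc)
}

#' Invert a min-max normalisation
#' @param data data.frame with normalised columns
#' @param scaling the `scaling` record from [minmax_normalize()]
#' @return data.frame with the listed columns back on their raw scale
#' @export
minmax_denormalize <- function(data, scaling) {
  for (i in seq_len(nrow(scaling))) {
    cn <- scaling$column[i]
    data[[cn]] <- data[[cn]] * (scaling$max[i] - scaling$min[i]) +
      scaling$min[i]
  }
  data
}

#' Full haemodynamic feature set for one subject
#'
#' @param series a [wall_series()] on the wall nodes of `mesh`
#' @param flow a [flow_series()]
#' @param mesh the subject's [laa_mesh()] (aligned)
#' @param centreline the subject's `laa_centreline`
#' @param laa_volume_ml LAA volume (ml)
#' @param window beat range, default `c(2, 3)`
#' @param stagnation_model `"mixing"` or `"piston"`
#' @return named list: whole-LAA and per-region trimmed means of
#'   tawss/osi/ecap/rrt, `vel_over_laav` and `stagnation_pct`
#' @export
haemo_features <- function(series, flow, mesh, centreline, laa_volume_ml,
                           window = c(2, 3),
                           stagnation_model = "mixing") {
  maps <- compute_wss_indices(series, window = window)
  regions <- region_partition(mesh, centreline)
  lab <- regions[series$node_ids]
  out <- list()
  for (nm in c("tawss", "osi", "ecap", "rrt")) {
    agg <- trimmed_aggregate(maps[[nm]], lab)
    names(agg) <- paste0(nm, "_", names(agg))
    out <- c(out, as.list(agg))
  }
  out$vel_over_laav <- velocity_index(flow, laa_volume_ml, window)
  out$stagnation_pct <- stagnation_fraction(flow, laa_volume_ml, window,
                                            model = stagnation_model)
  structure(out, class = "haemo_features", node_maps = maps)
}
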