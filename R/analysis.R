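## Summary statistics of trajectories: intrinsic-noise metrics, response and
## adaptation metrics, angle-resolved profiles, kymographs, and wave events.

#' Per-node and internodal noise statistics
#'
#' Temporal statistics are computed per node over the stationary window
#' (mean, variance, Fano factor = variance/mean, coefficient of variation =
#' sd/mean, each defined only where the mean is positive). Internodal
#' statistics compare nodes: at each snapshot the variance/mean of counts
#' across nodes, averaged over the window, and the same for the per-node
#' temporal means.
#'
#' @param traj an `rd_trajectory` with per-node recording of the species.
#' @param species species name(s); summed per node when several (e.g. the
#'   five occupied receptor states).
#' @param window `c(t_min, t_max)` stationary time window.
#' @param nodes restrict to these nodes (default: nodes that ever hold a
#'   molecule of the species).
#' @return list with per-node vectors (`mean`, `var`, `fano`, `cov`), their
#'   averages (`mean_fano`, `mean_cov`, `mean_sd`), and internodal metrics
#'   (`internodal_fano_inst`, `internodal_fano_mean`, `internodal_cov`,
#'   `internodal_skewness`).
#' @export
noise_stats <- function(traj, species, window = range(traj$times),
                        nodes = NULL) {
  sel <- traj$times >= window[1] & traj$times <= window[2]
  if (!any(sel)) stop("window outside trajectory")
  X <- NULL
  for (s in species) {
    if (is.null(traj$node[[s]]))
      stop("species ", s, " has no per-node recording")
    X <- if (is.null(X)) traj$node[[s]][, sel, drop = FALSE]
         else X + traj$node[[s]][, sel, drop = FALSE]
  }
  if (is.null(nodes)) nodes <- which(rowSums(X) > 0)
  X <- X[nodes, , drop = FALSE]
  m <- rowMeans(X)
  v <- apply(X, 1, stats::var)
  pos <- m > 0
  fano <- ifelse(pos, v / m, NA_real_)
  cv <- ifelse(pos, sqrt(v) / m, NA_real_)
  inst_fano <- apply(X, 2, function(col) {
    mu <- mean(col)
    if (mu > 0) stats::var(col) / mu else NA_real_
  })
  sk <- apply(X, 2, function(col) {
    s <- stats::sd(col)
    if (s > 0) mean((col - mean(col))^3) / s^3 else NA_real_
  })
  list(nodes = nodes, mean = m, var = v, fano = fano, cov = cv,
       mean_fano = mean(fano, na.rm = TRUE),
       mean_cov = mean(cv, na.rm = TRUE),
       mean_sd = mean(sqrt(v)),
       internodal_fano_inst = mean(inst_fano, na.rm = TRUE),
       internodal_fano_mean = if (mean(m) > 0) stats::var(m) / mean(m)
                              else NA_real_,
       internodal_cov = if (mean(m) > 0) stats::sd(m) / mean(m)
                        else NA_real_,
       internodal_skewness = mean(sk, na.rm = TRUE))
}

#' Response and adaptation metrics around a stimulus step
#'
#' Works on the nodal-mean response-regulator trace (or any response trace).
#' `RR_peak` is the maximal basal-subtracted value after the step, `T_peak`
#' its time; `RR_ss` is the mean over the final window; `T_adaptation` is
#' the first time after the peak at which the basal-subtracted trace enters,
#' and then remains for at least `hold` seconds, within `frac` of the peak
#' amplitude around zero.
#'
#' @param time,value the trace (value in any units; e.g. nodal-mean RR).
#' @param t_step stimulus changepoint time.
#' @param basal basal level (default: mean of the trace before the step).
#' @param ss_window length of the final steady-state window, seconds.
#' @param frac,hold adaptation-band parameters (defaults 0.1 and 20 s).
#' @return list with `RR_peak`, `T_peak`, `RR_ss`, `T_adaptation` (times
#'   relative to `t_step`).
#' @export
adaptation_metrics <- function(time, value, t_step, basal = NULL,
                               ss_window = 30, frac = 0.1, hold = 20) {
  post <- time >= t_step
  if (sum(post) < 2) stop("no post-step samples")
  if (is.null(basal)) {
    pre <- time < t_step
    basal <- if (any(pre)) mean(value[pre]) else value[1]
  }
  tt <- time[post]; y <- value[post] - basal
  ip <- which.max(y)
  peak <- y[ip]; t_peak <- tt[ip] - t_step
  ss <- mean(y[tt >= max(tt) - ss_window]) + basal
  band <- frac * max(peak, .Machine$double.eps)
  inband <- abs(y) <= band
  t_ad <- NA_real_
  for (q in which(inband & seq_along(tt) > ip)) {
    upto <- tt <= tt[q] + hold & tt >= tt[q]
    if (all(inband[upto])) { t_ad <- tt[q] - t_step; break }
  }
  list(RR_peak = peak, T_peak = t_peak, RR_ss = ss, T_adaptation = t_ad)
}

#' Polar angle of nodes around the front-back axis
#'
#' Angle from the needle direction (default +x) measured in the basal plane:
#' 0 at the front, 180 at the back.
#'
#' @param mesh a `shell_mesh`.
#' @param needle needle position (3D); only its azimuth matters.
#' @export
node_angles <- function(mesh, needle = c(mesh$spec$radius, 0, 0)) {
  phi0 <- atan2(needle[2], needle[1])
  phi <- atan2(mesh$vertices[, 2], mesh$vertices[, 1]) - phi0
  abs(((phi + pi) %% (2 * pi)) - pi) * 180 / pi
}

#' Angle-resolved front-back profiles
#'
#' Bins per-node traces by angle from the needle (basal diameter convention:
#' 0 degrees = front, 180 = back) and returns per-bin mean traces plus the
#' front-back difference time series.
#'
#' @param traj an `rd_trajectory` with per-node recording.
#' @param mesh the mesh the trajectory was run on.
#' @param species species name (per-node recorded).
#' @param needle needle point (gradient protocols).
#' @param bin_deg angular bin width, degrees.
#' @param front_deg,back_deg half-widths of the front/back sectors.
#' @return list: `angle` (bin centres), `profile` (bins x time), `front`,
#'   `back`, `difference` (time series of sector means).
#' @export
front_back_profiles <- function(traj, mesh, species,
                                needle = c(mesh$spec$radius, 0, 0),
                                bin_deg = 5, front_deg = 30,
                                back_deg = 30) {
  ang <- node_angles(mesh, needle)
  X <- traj$node[[species]]
  if (is.null(X)) stop("species has no per-node recording")
  occupied <- which(rowSums(X) >= 0)  # all nodes; localization rows are 0
  bins <- cut(ang, breaks = seq(0, 180, by = bin_deg),
              include.lowest = TRUE)
  prof <- rowsum(X, bins, reorder = TRUE) /
    as.vector(table(bins))
  front <- colMeans(X[ang <= front_deg, , drop = FALSE])
  back <- colMeans(X[ang >= 180 - back_deg, , drop = FALSE])
  list(angle = seq(bin_deg / 2, 180 - bin_deg / 2, by = bin_deg),
       profile = prof, front = front, back = back,
       difference = front - back, times = traj$times)
}

#' Kymograph along the front-back arc
#'
#' Bins nodes into angular sectors (default 5 degrees) along the basal
#' diameter / curved-arc parameterization and takes the maximal projection
#' (max across the nodes of a bin) of the species at each snapshot.
#'
#' @inheritParams front_back_profiles
#' @param statistic `"max"` (maximal projection) or `"mean"`.
#' @return matrix (angle bin x time) with attributes `angle`, `times`.
#' @export
kymograph <- function(traj, mesh, species,
                      needle = c(mesh$spec$radius, 0, 0), bin_deg = 5,
                      statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  ang <- node_angles(mesh, needle)
  X <- traj$node[[species]]
  if (is.null(X)) stop("species has no per-node recording")
  edges <- seq(0, 180, by = bin_deg)
  bins <- cut(ang, breaks = edges, include.lowest = TRUE)
  f <- if (statistic == "max") function(i) suppressWarnings(
         apply(X[i, , drop = FALSE], 2, max))
       else function(i) colMeans(X[i, , drop = FALSE])
  out <- t(vapply(split(seq_along(ang), bins), function(i) {
    if (!length(i)) rep(NA_real_, ncol(X)) else f(i)
  }, numeric(ncol(X))))
  structure(out, angle = edges[-1] - bin_deg / 2, times = traj$times,
            class = c("rd_kymograph", "matrix"))
}

## ---- wave events ------------------------------------------------------------

## Activity rule: a node counts active when RasGTP exceeds PIP2 in
## one-molecule-concentration units (the mutual-exclusivity readout); one
## frame of hysteresis suppresses flicker.
active_nodes <- function(traj, act = "RasGTP", inh = "PIP2") {
  A <- traj$node[[act]]; P <- traj$node[[inh]]
  if (is.null(A) || is.null(P))
    stop("wave detection needs per-node recording of ", act, " and ", inh)
  raw <- A > P
  out <- raw
  if (ncol(raw) >= 3)
    out[, 2:(ncol(raw) - 1)] <-
      raw[, 2:(ncol(raw) - 1)] &
      (raw[, 1:(ncol(raw) - 2)] | raw[, 3:ncol(raw)])
  out
}

## Connected components of an active node set on the mesh adjacency.
components_of <- function(active_idx, adj_ptr, adj_idx) {
  if (!length(active_idx)) return(list())
  mark <- integer(0)
  inset <- logical(length(adj_ptr) - 1L)
  inset[active_idx] <- TRUE
  comp <- integer(length(adj_ptr) - 1L)
  cid <- 0L
  for (s in active_idx) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj_idx[(adj_ptr[v] + 1L):adj_ptr[v + 1L]]
      nb <- nb[inset[nb] & comp[nb] == 0L]
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  split(which(comp > 0L), comp[comp > 0L])
}

#' Detect wave events in a trajectory
#'
#' Tracks connected components of active (RasGTP-dominated) nodes across
#' frames: components with no predecessor are initiations (labelled basal or
#' apical by their majority membrane side), a component with two or more
#' predecessors is a merge (annihilation check), a predecessor with two or
#' more successors is a split. Wave speed is estimated from the displacement
#' of the component's leading nodes between frames.
#'
#' @param traj `rd_trajectory` with per-node RasGTP and PIP2 recording.
#' @param mesh the mesh.
#' @param act,inh species names of the activity rule.
#' @param min_size ignore components smaller than this many nodes.
#' @param max_dt error if the snapshot cadence is coarser than this (s).
#' @return data.frame of events: `kind` (initiation/split/annihilation),
#'   `time`, `size`, `side`, `speed` (um/s, NA where undefined).
#' @export
detect_waves <- function(traj, mesh, act = "RasGTP", inh = "PIP2",
                         min_size = 3, max_dt = 1) {
  dt <- diff(traj$times)
  if (any(dt > max_dt + 1e-9))
    stop("snapshot cadence too coarse for wave tracking (need <= ",
         max_dt, " s)")
  on <- active_nodes(traj, act, inh)
  g <- jump_graph(mesh, nodes_of(mesh, "membrane"))
  events <- list()
  prev <- list()
  prev_cent <- list()
  side <- mesh$node_class$side
  coords <- mesh$vertices
  for (f in seq_len(ncol(on))) {
    comps <- components_of(which(on[, f]), g$ptr, g$idx)
    comps <- comps[vapply(comps, length, 0L) >= min_size]
    cent <- lapply(comps, function(i) colMeans(coords[i, , drop = FALSE]))
    ## match to previous frame by node overlap
    pred <- lapply(comps, function(i)
      which(vapply(prev, function(j) length(intersect(i, j)) > 0, TRUE)))
    succ_count <- integer(length(prev))
    for (k in seq_along(comps)) {
      for (q in pred[[k]]) succ_count[q] <- succ_count[q] + 1L
    }
    for (k in seq_along(comps)) {
      np <- length(pred[[k]])
      if (np == 0) {
        sd_lab <- names(which.max(table(side[comps[[k]]])))
        events[[length(events) + 1L]] <- data.frame(
          kind = "initiation", time = traj$times[f],
          size = length(comps[[k]]), side = sd_lab, speed = NA_real_)
      } else if (np >= 2) {
        events[[length(events) + 1L]] <- data.frame(
          kind = "annihilation", time = traj$times[f],
          size = length(comps[[k]]), side = NA_character_,
          speed = NA_real_)
      } else {
        q <- pred[[k]][1]
        disp <- sqrt(sum((cent[[k]] - prev_cent[[q]])^2))
        events[[length(events) + 1L]] <- data.frame(
          kind = "front", time = traj$times[f],
          size = length(comps[[k]]), side = NA_character_,
          speed = disp / dt[max(f - 1, 1)])
      }
    }
    for (q in which(succ_count >= 2)) {
      events[[length(events) + 1L]] <- data.frame(
        kind = "split", time = traj$times[f],
        size = length(prev[[q]]), side = NA_character_, speed = NA_real_)
    }
    prev <- comps
    prev_cent <- cent
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(0), time = numeric(0), size = integer(0),
               side = character(0), speed = numeric(0))
  ev[ev$kind != "front" | !is.na(ev$speed), , drop = FALSE]
}

#' Refractory recovery curve from double-pulse responses
#'
#' For each delay, the basal-subtracted whole-cell RasGTP peak of the second
#' response is compared to the first; the 50%-recovery delay is interpolated.
#' A second peak below 3 standard deviations of the basal noise counts as
#' "no distinct second response" (ratio 0).
#'
#' @param peak_pairs data.frame with columns `delay`, `first`, `second`
#'   (basal-subtracted peak counts; replicate rows allowed) and optionally
#'   `basal_sd`.
#' @return list: per-delay mean `ratio`, and `recovery50` (s, interpolated
#'   delay at ratio 0.5).
#' @export
refractory_curve <- function(peak_pairs) {
  pp <- peak_pairs
  if (!is.null(pp$basal_sd))
    pp$second[pp$second < 3 * pp$basal_sd] <- 0
  pp$ratio <- pp$second / pp$first
  agg <- stats::aggregate(ratio ~ delay, data = pp, FUN = mean)
  agg <- agg[order(agg$delay), ]
  rec <- if (all(agg$ratio < 0.5)) NA_real_
         else if (agg$ratio[1] >= 0.5) agg$delay[1]
         else stats::approx(agg$ratio, agg$delay, xout = 0.5,
                            ties = "ordered")$y
  list(curve = agg, recovery50 = rec)
}

#' Whole-cell peak of a basal-subtracted response in a window
#'
#' @param traj trajectory; @param species species (pooled).
#' @param window `c(t0, t1)` search window.
#' @param basal_window window used for the basal level and noise sd.
#' @return list `peak` (basal-subtracted), `t_peak`, `basal`, `basal_sd`.
#' @export
response_peak <- function(traj, species, window,
                          basal_window = c(min(traj$times), window[1])) {
  y <- wc_trace(traj, species)
  tb <- traj$times >= basal_window[1] & traj$times <= basal_window[2]
  tw <- traj$times >= window[1] & traj$times <= window[2]
  basal <- mean(y[tb])
  ip <- which.max(y[tw])
  list(peak = y[tw][ip] - basal, t_peak = traj$times[tw][ip],
       basal = basal, basal_sd = stats::sd(y[tb]))
}

#' @export
plot.rd_trajectory <- function(x, species = NULL, ...) {
  sp <- species %||% rownames(x$wc)[order(-rowSums(x$wc))][
    seq_len(min(5, nrow(x$wc)))]
  y <- x$wc[sp, , drop = FALSE]
  graphics::matplot(x$times, t(y), type = "l", lty = 1,
                    xlab = "time (s)", ylab = "whole-cell molecules", ...)
  graphics::legend("topright", legend = sp, col = seq_along(sp), lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' @export
plot.rd_kymograph <- function(x, ...) {
  graphics::image(attr(x, "times"), attr(x, "angle"), t(unclass(x)),
                  xlab = "time (s)", ylab = "angle (degrees)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
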